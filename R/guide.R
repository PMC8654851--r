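#' Guide RNA (protospacer + PAM pattern)
#'
#' Constructs the guide object used both for planting target/off-target sites
#' in synthetic genomes and for matching candidate cleavage sites back to the
#' guide. S. pyogenes Cas9 guides carry a 20-nt spacer and recognise an NGG
#' protospacer-adjacent motif (PAM) immediately 3' of the protospacer.
#'
#' @param protospacer 20-character string over A/C/G/T (genomic protospacer
#'   sequence, written 5'->3' on the protospacer strand).
#' @param name Label used in outputs.
#' @param pam_pattern 3-character IUPAC pattern, default `"NGG"`.
#' @return An object of class `guide_rna`.
#' @examples
#' guide_rna("GGGTGGGGGGAGTTTGCTCC", name = "VEGFA")
#' @export
guide_rna <- function(protospacer, name = "guide", pam_pattern = "NGG") {
  protospacer <- toupper(protospacer)
  pam_pattern <- toupper(pam_pattern)
  if (nchar(protospacer) != 20 ||
      !grepl("^[ACGT]{20}$", protospacer)) {
    stop("protospacer must be exactly 20 bases over A/C/G/T", call. = FALSE)
  }
  if (nchar(pam_pattern) != 3 ||
      !all(strsplit(pam_pattern, "")[[1]] %in% names(IUPAC))) {
    stop("pam_pattern must be a 3-character IUPAC pattern", call. = FALSE)
  }
  structure(
    list(name = name, protospacer = protospacer, pam_pattern = pam_pattern),
    class = "guide_rna"
  )
}

#' @export
print.guide_rna <- function(x, ...) {
  cat(sprintf("<guide_rna> %s: %s | PAM %s\n",
              x$name, x$protospacer, x$pam_pattern))
  invisible(x)
}

#' Random guide for simulations
#'
#' Draws a uniform 20-mer protospacer; convenient for fully seeded fixtures.
#'
#' @param seed Integer seed.
#' @param name Label.
#' @param pam_pattern IUPAC PAM pattern.
#' @return A `guide_rna`.
#' @export
random_guide <- function(seed, name = "guide", pam_pattern = "NGG") {
  seq <- withr::with_seed(derive_seed(seed, "guide"),
                          paste(sample(BASES, 20, replace = TRUE), collapse = ""))
  guide_rna(seq, name = name, pam_pattern = pam_pattern)
}
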