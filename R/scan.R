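#' Exhaustive guide-match scan of a genome
#'
#' Scans both strands for 20-mers followed by a PAM (IUPAC pattern, NGG by
#' default) within a Hamming-distance budget of the guide protospacer. This is
#' a position-by-position exhaustive scan (vectorised over placements), usable
#' both as a candidate restriction for the caller and as a ground-truth
#' enumeration in simulations.
#'
#' @param genome Named character vector of contigs.
#' @param guide A [guide_rna()].
#' @param max_mismatches Maximum Hamming distance of the 20-mer (PAM not
#'   counted).
#' @return Data frame with columns `chrom`, `position` (0-based forward-strand
#'   start of the 20-mer), `strand`, `mismatches`, `cut_position` (0-based
#'   breakpoint, 3 bp upstream of the PAM in protospacer orientation), sorted
#'   by (chrom, position, strand).
#' @examples
#' g <- c(chr1 = paste0(strrep("A", 30), "GGGTGGGGGGAGTTTGCTCC", "TGG",
#'                      strrep("A", 30)))
#' enumerate_genome_matches(g, guide_rna("GGGTGGGGGGAGTTTGCTCC"), 3)
#' @export
enumerate_genome_matches <- function(genome, guide, max_mismatches) {
  genome <- as_genome(genome)
  stopifnot(inherits(guide, "guide_rna"), max_mismatches >= 0)
  out <- lapply(names(genome), function(chrom) {
    scan_chrom(genome[[chrom]], chrom, guide, max_mismatches)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

scan_chrom <- function(seq, chrom, guide, max_mm) {
  n <- nchar(seq)
  empty <- data.frame(chrom = character(), position = integer(),
                      strand = character(), mismatches = integer(),
                      cut_position = integer(), stringsAsFactors = FALSE)
  if (n < 23) return(empty)
  gi <- utf8ToInt(seq)
  m <- n - 22L  # number of 23-mer placements, starts t = 0..m-1

  pam_sets <- lapply(strsplit(guide$pam_pattern, "")[[1]],
                     function(code) utf8ToInt(paste(IUPAC[[code]], collapse = "")))
  proto_int <- utf8ToInt(guide$protospacer)

  # plus strand: protospacer at offsets 1..20, PAM at 21..23
  mm_p <- integer(m)
  for (i in 1:20) mm_p <- mm_p + (gi[i:(m + i - 1L)] != proto_int[i])
  ok_p <- mm_p <= max_mm
  for (j in 1:3) {
    i <- 20L + j
    ok_p <- ok_p & (gi[i:(m + i - 1L)] %in% pam_sets[[j]])
  }

  # minus strand: forward-strand image is revcomp(PAM) then revcomp(protospacer)
  rc23 <- revcomp(paste0(guide$protospacer, guide$pam_pattern))
  rc_pam_sets <- lapply(strsplit(substr(rc23, 1, 3), "")[[1]],
                        function(code) utf8ToInt(paste(IUPAC[[code]], collapse = "")))
  rc_proto_int <- utf8ToInt(substr(rc23, 4, 23))
  mm_m <- integer(m)
  for (i in 1:20) {
    off <- 3L + i
    mm_m <- mm_m + (gi[off:(m + off - 1L)] != rc_proto_int[i])
  }
  ok_m <- mm_m <= max_mm
  for (j in 1:3) ok_m <- ok_m & (gi[j:(m + j - 1L)] %in% rc_pam_sets[[j]])

  t_p <- which(ok_p) - 1L
  t_m <- which(ok_m) - 1L
  res <- rbind(
    if (length(t_p)) data.frame(chrom = chrom, position = t_p, strand = "+",
                                mismatches = mm_p[t_p + 1L],
                                cut_position = t_p + 17L,
                                stringsAsFactors = FALSE),
    if (length(t_m)) data.frame(chrom = chrom, position = t_m + 3L,
                                strand = "-", mismatches = mm_m[t_m + 1L],
                                cut_position = t_m + 6L,
                                stringsAsFactors = FALSE)
  )
  if (is.null(res)) empty else res
}
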