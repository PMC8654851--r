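# Internal helpers shared across modules. All public coordinates in the
# package are 0-based, half-open (BED convention); base R strings are 1-based,
# so the translation happens only inside subseq0().

BASES <- c("A", "C", "G", "T")

# IUPAC code -> set of plain bases it matches
IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' @importFrom withr with_seed
with_derived_seed <- function(seed, stage, code) {
  withr::with_seed(derive_seed(seed, stage), code)
}

# Fan one user seed out into per-stage seeds so stages can be rerun
# independently yet reproducibly. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# 0-based half-open substring of a single sequence string
subseq0 <- function(x, start, end) {
  substring(x, start + 1, end)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(COMPLEMENT[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# does a plain-base 3-mer match an IUPAC pattern?
matches_iupac <- function(seq, pattern) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  if (length(s) != length(p)) return(FALSE)
  all(mapply(function(base, code) base %in% IUPAC[[code]], s, p))
}

# genome container: named character vector, one element per contig
as_genome <- function(genome) {
  if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
  stopifnot(is.character(genome), all(nzchar(names(genome))))
  genome
}

`%||%` <- function(a, b) if (is.null(a)) b else a
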