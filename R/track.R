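#' Read 5'-end track
#'
#' The central intermediate of the method: per-chromosome, per-strand sparse
#' counts of read 5'-end reference positions. Cleavage sites appear in this
#' track as a junction of reverse-strand ends immediately left of the
#' breakpoint and forward-strand ends at the breakpoint.
#'
#' @param ends data.table/data.frame with columns `chrom`, `pos` (0-based),
#'   `strand` (`"+"`/`"-"`), `count` (>= 1).
#' @param total_mapped Number of reads that passed filters.
#' @param seqlengths Named integer vector of contig lengths (optional but
#'   recommended; used to bound window scans).
#' @return An object of class `read_end_track`.
#' @export
read_end_track <- function(ends, total_mapped, seqlengths = NULL) {
  ends <- data.table::as.data.table(ends)[, .(chrom, pos, strand, count)]
  stopifnot(all(ends$count >= 1), all(ends$strand %in% c("+", "-")))
  data.table::setkey(ends, chrom, pos, strand)
  structure(list(ends = ends, total_mapped = as.integer(total_mapped),
                 seqlengths = seqlengths),
            class = "read_end_track")
}

#' @export
print.read_end_track <- function(x, ...) {
  cat(sprintf("<read_end_track> %d mapped reads, %d distinct end positions on %d contig(s)\n",
              x$total_mapped, nrow(x$ends), length(unique(x$ends$chrom))))
  invisible(x)
}

#' Build a track directly from simulated reads
#'
#' @param reads data.table with `chrom`, `pos5`, `strand` (one row per read),
#'   e.g. the `reads` element of a `sim_result`.
#' @param seqlengths Named contig lengths.
#' @return A [read_end_track()].
#' @export
track_from_reads <- function(reads, seqlengths = NULL) {
  reads <- data.table::as.data.table(reads)
  ends <- reads[, .(count = .N), by = .(chrom, pos = pos5, strand)]
  read_end_track(ends, total_mapped = nrow(reads), seqlengths = seqlengths)
}

#' Extract read 5'-end positions from SAM/BAM alignments
#'
#' For a forward-strand alignment the 5' end is the leftmost aligned
#' reference position; for a reverse-strand alignment the rightmost (computed
#' from the CIGAR reference span, so soft clips do not shift it). Unmapped,
#' secondary and supplementary records and records below `min_mapq` are
#' excluded. Since the library is amplification-free, identical ends are
#' genuine signal: no duplicate marking is performed.
#'
#' @param path SAM or BAM file. BAM must be coordinate-sorted and indexed;
#'   SAM input is converted (sorted and indexed) on the fly.
#' @param min_mapq Minimum mapping quality (default 20, excluding ambiguous
#'   placements that would smear pileups).
#' @return A [read_end_track()].
#' @importFrom Rsamtools asBam scanBam ScanBamParam scanBamFlag scanBamHeader
#' @export
load_read_starts <- function(path, min_mapq = 20) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  } else {
    bai <- c(paste0(path, ".bai"), sub("\\.bam$", ".bai", path))
    if (!any(file.exists(bai))) {
      stop("BAM input must be coordinate-sorted and indexed (no .bai found ",
           "for ", path, ")", call. = FALSE)
    }
    hd <- Rsamtools::scanBamHeader(path)[[1]]$text
    so <- hd[names(hd) == "@HD"]
    if (length(so) && !any(grepl("SO:coordinate", unlist(so)))) {
      stop("BAM input must be coordinate-sorted (header SO is not ",
           "'coordinate')", call. = FALSE)
    }
    bam <- path
  }
  seqlengths <- Rsamtools::scanBamHeader(bam)[[1]]$targets

  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = c("flag", "rname", "pos", "mapq", "cigar")
  )
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- !is.na(x$mapq) & x$mapq >= min_mapq & !is.na(x$pos)
  if (!any(keep)) {
    return(read_end_track(
      data.table::data.table(chrom = character(), pos = integer(),
                             strand = character(), count = integer()),
      total_mapped = 0L, seqlengths = seqlengths))
  }
  flag <- x$flag[keep]
  rev <- bitwAnd(flag, 16L) > 0L
  pos0 <- x$pos[keep] - 1L
  span <- cigar_ref_span(x$cigar[keep])
  end5 <- ifelse(rev, pos0 + span - 1L, pos0)
  ends <- data.table::data.table(
    chrom = as.character(x$rname[keep]),
    pos = as.integer(end5),
    strand = ifelse(rev, "-", "+")
  )[, .(count = .N), by = .(chrom, pos, strand)]
  read_end_track(ends, total_mapped = sum(keep), seqlengths = seqlengths)
}

# reference-space span of CIGAR strings (M/D/N/=/X consume reference)
cigar_ref_span <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  vapply(toks, function(t) {
    op <- substring(t, nchar(t))
    len <- as.integer(substring(t, 1, nchar(t) - 1L))
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Subsample a read-end track
#'
#' Each read end is retained independently, without replacement, with
#' probability `fraction`. Under a fixed seed the retained sets are nested
#' across fractions (a read kept at fraction f is kept at every f' > f),
#' which makes saturation curves monotone by construction.
#'
#' @param track A [read_end_track()].
#' @param fraction Retention probability in \[0, 1\].
#' @param seed Integer seed.
#' @return A [read_end_track()].
#' @export
subsample_track <- function(track, fraction, seed) {
  stopifnot(inherits(track, "read_end_track"))
  if (fraction < 0 || fraction > 1) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  if (fraction == 1) return(track)
  ends <- data.table::copy(track$ends)
  data.table::setorder(ends, chrom, pos, strand)
  expanded <- ends[rep(seq_len(.N), count)]
  u <- withr::with_seed(derive_seed(seed, "subsample"),
                        stats::runif(nrow(expanded)))
  kept <- expanded[u <= fraction]
  if (nrow(kept) == 0) {
    return(read_end_track(
      data.table::data.table(chrom = character(), pos = integer(),
                             strand = character(), count = integer()),
      total_mapped = 0L, seqlengths = track$seqlengths))
  }
  agg <- kept[, .(count = .N), by = .(chrom, pos, strand)]
  read_end_track(agg, total_mapped = nrow(kept),
                 seqlengths = track$seqlengths)
}

#' Total read ends in a genomic interval
#'
#' @param track A [read_end_track()].
#' @param chrom Contig name.
#' @param start,end 0-based half-open interval.
#' @param strand Optional strand restriction (`"+"` or `"-"`).
#' @return Integer count.
#' @export
count_ends <- function(track, chrom, start, end, strand = NULL) {
  e <- track$ends
  sel <- e$chrom == chrom & e$pos >= start & e$pos < end
  if (!is.null(strand)) sel <- sel & e$strand == strand
  sum(e$count[sel])
}
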