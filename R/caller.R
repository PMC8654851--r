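#' Caller parameters
#'
#' Tunables of the cut-site caller. The score of a site is the sum of read
#' 5'-ends in a `window_width`-bp window centered on the cut (default 10 bp,
#' realized as the half-open interval \[c - w/2, c + w/2)). `cut_offset` is
#' the blunt-cut distance upstream of the PAM and is fixed at 3 bp for
#' SpCas9.
#'
#' @param window_width Even window width in bp (default 10).
#' @param min_score Minimum window score for a candidate (default 5).
#' @param require_bidirectional Require at least one forward- and one
#'   reverse-strand end in the window (default `TRUE`); suppresses one-sided
#'   background spikes, but can be disabled when end degradation depletes one
#'   flank.
#' @param max_mismatches Maximum protospacer mismatches for guide matching
#'   (default 7).
#' @param pam_search_flank Flanking context (bp) retained around candidates
#'   for reporting (default 6).
#' @param cut_offset Cut distance upstream of the PAM (bp; fixed 3).
#' @param position_tolerance Maximum distance between a candidate position
#'   and a placement's implied breakpoint (default 2 bp).
#' @return List of class `caller_params`.
#' @export
caller_params <- function(window_width = 10, min_score = 5,
                          require_bidirectional = TRUE, max_mismatches = 7,
                          pam_search_flank = 6, cut_offset = 3,
                          position_tolerance = 2) {
  if (window_width %% 2 != 0 || window_width < 2) {
    stop("window_width must be even and >= 2", call. = FALSE)
  }
  structure(list(window_width = as.integer(window_width),
                 min_score = min_score,
                 require_bidirectional = isTRUE(require_bidirectional),
                 max_mismatches = as.integer(max_mismatches),
                 pam_search_flank = as.integer(pam_search_flank),
                 cut_offset = as.integer(cut_offset),
                 position_tolerance = as.integer(position_tolerance)),
            class = "caller_params")
}

#' Window read-end score at a position
#'
#' Sum of read 5'-end counts on both strands at positions in
#' \[position - w/2, position + w/2); for the default w = 10 these are the 10
#' positions position-5 ... position+4.
#'
#' @param track A [read_end_track()].
#' @param chrom Contig name (must exist in the track's `seqlengths` when
#'   those are set).
#' @param position 0-based candidate position.
#' @param window_width Even window width (default 10).
#' @return Integer score.
#' @export
window_score <- function(track, chrom, position, window_width = 10) {
  if (!is.null(track$seqlengths) && !(chrom %in% names(track$seqlengths))) {
    stop("unknown chromosome: ", chrom, call. = FALSE)
  }
  h <- window_width %/% 2
  count_ends(track, chrom, position - h, position + h)
}

#' Detect candidate cleavage positions from the pileup signature
#'
#' A cleaved site leaves reverse-strand read ends immediately left of the
#' breakpoint and forward-strand ends at the breakpoint. Candidates are
#' positions whose window score reaches `min_score` (with both orientations
#' represented when `require_bidirectional`), restricted to
#' junction-consistent positions -- a forward 5' end at c or a reverse 5' end
#' at c - 1 -- so the call lands on the breakpoint rather than anywhere on
#' the window-score plateau. Overlapping candidates within `window_width` are
#' reduced by non-maximum suppression (highest score kept; tie broken
#' leftmost).
#'
#' @param track A [read_end_track()].
#' @param params A [caller_params()].
#' @return data.table with `chrom`, `pos`, `score`, `fwd_in_window`,
#'   `rev_in_window`; empty when the track is empty.
#' @export
detect_candidates <- function(track, params = caller_params()) {
  stopifnot(inherits(track, "read_end_track"))
  w <- params$window_width
  h <- w %/% 2
  empty <- data.table::data.table(chrom = character(), pos = integer(),
                                  score = integer(),
                                  fwd_in_window = integer(),
                                  rev_in_window = integer())
  if (nrow(track$ends) == 0) return(empty)
  out <- lapply(unique(track$ends$chrom), function(cc) {
    e <- track$ends[chrom == cc]
    off <- min(e$pos) - w
    hi <- max(e$pos) + w
    n <- hi - off + 1L
    vF <- numeric(n); vR <- numeric(n)
    eF <- e[strand == "+"]; eR <- e[strand == "-"]
    vF[eF$pos - off + 1L] <- eF$count
    vR[eR$pos - off + 1L] <- eR$count
    SF <- c(0, cumsum(vF)); SR <- c(0, cumsum(vR))
    cand_pos <- off:hi
    idx <- seq_len(n)
    lo_i <- pmax(idx - h, 1L); hi_i <- pmin(idx + h - 1L, n)
    wsF <- SF[hi_i + 1L] - SF[lo_i]
    wsR <- SR[hi_i + 1L] - SR[lo_i]
    ws <- wsF + wsR
    junction <- vF > 0 | c(0, vR[-n]) > 0
    ok <- ws >= params$min_score & junction
    if (params$require_bidirectional) ok <- ok & wsF >= 1 & wsR >= 1
    if (!any(ok)) return(NULL)
    data.table::data.table(chrom = cc, pos = cand_pos[ok],
                           score = as.integer(ws[ok]),
                           fwd_in_window = as.integer(wsF[ok]),
                           rev_in_window = as.integer(wsR[ok]))
  })
  cand <- data.table::rbindlist(out)
  if (nrow(cand) == 0) return(empty)
  nms_reduce(cand, w)
}

# greedy non-maximum suppression within `w` bp (score desc, then leftmost)
nms_reduce <- function(cand, w) {
  data.table::setorder(cand, chrom, -score, pos)
  keep <- logical(nrow(cand))
  for (cc in unique(cand$chrom)) {
    rows <- which(cand$chrom == cc)
    kept_pos <- integer(0)
    for (r in rows) {
      p <- cand$pos[r]
      if (!length(kept_pos) || all(abs(kept_pos - p) >= w)) {
        keep[r] <- TRUE
        kept_pos <- c(kept_pos, p)
      }
    }
  }
  out <- cand[keep]
  data.table::setorder(out, chrom, pos)
  out
}

#' Match a candidate position to the guide
#'
#' Considers every protospacer+PAM placement on either strand whose implied
#' breakpoint (3 bp upstream of the PAM in protospacer orientation) lies
#' within `position_tolerance` of the candidate. Among placements whose PAM
#' matches the guide's pattern and whose protospacer Hamming distance is at
#' most `max_mismatches`, returns the one minimizing (mismatches, |implied
#' breakpoint - candidate|, plus strand preferred, leftmost).
#'
#' @param genome Named character vector of contigs.
#' @param chrom Contig of the candidate.
#' @param position 0-based candidate position.
#' @param guide A [guide_rna()].
#' @param params A [caller_params()].
#' @return List with `strand`, `protospacer_start` (0-based forward start of
#'   the 20-mer), `mismatches`, `matched_seq` (23-mer in protospacer
#'   orientation), `cut_position` (the placement's implied breakpoint), or
#'   `NULL` when no placement qualifies.
#' @export
match_guide <- function(genome, chrom, position, guide,
                        params = caller_params()) {
  genome <- as_genome(genome)
  if (!chrom %in% names(genome)) {
    stop("unknown chromosome: ", chrom, call. = FALSE)
  }
  seq <- genome[[chrom]]
  L <- nchar(seq)
  if (position < 30 || position > L - 30) {
    stop("insufficient flanking sequence around candidate at ", chrom, ":",
         position, call. = FALSE)
  }
  tol <- params$position_tolerance
  offs <- -tol:tol
  hits <- list()
  # plus strand: protospacer at [s, s+20), PAM [s+20, s+23), breakpoint s+17
  for (s in position - 17L + offs) {
    if (s < 0 || s + 23 > L) next
    pam <- subseq0(seq, s + 20, s + 23)
    if (!matches_iupac(pam, guide$pam_pattern)) next
    mm <- hamming(subseq0(seq, s, s + 20), guide$protospacer)
    if (mm > params$max_mismatches) next
    hits[[length(hits) + 1L]] <- list(
      strand = "+", protospacer_start = s, mismatches = mm,
      matched_seq = subseq0(seq, s, s + 23), cut_position = s + 17L,
      delta = abs(s + 17L - position))
  }
  # minus strand: forward image CCN-pattern at [t, t+3), 20-mer at [t+3, t+23),
  # breakpoint t+6; protospacer_start reported as t+3
  for (t in position - 6L + offs) {
    if (t < 0 || t + 23 > L) next
    pam <- revcomp(subseq0(seq, t, t + 3))
    if (!matches_iupac(pam, guide$pam_pattern)) next
    seq20 <- revcomp(subseq0(seq, t + 3, t + 23))
    mm <- hamming(seq20, guide$protospacer)
    if (mm > params$max_mismatches) next
    hits[[length(hits) + 1L]] <- list(
      strand = "-", protospacer_start = t + 3L, mismatches = mm,
      matched_seq = revcomp(subseq0(seq, t, t + 23)),
      cut_position = t + 6L, delta = abs(t + 6L - position))
  }
  if (!length(hits)) return(NULL)
  ord <- order(vapply(hits, `[[`, 0, "mismatches"),
               vapply(hits, `[[`, 0, "delta"),
               vapply(hits, function(x) x$strand == "-", TRUE),
               vapply(hits, `[[`, 0, "protospacer_start"))
  best <- hits[[ord[1]]]
  best$delta <- NULL
  best
}

#' Call cleavage sites from a track
#'
#' Pipeline: [detect_candidates()] then [match_guide()] on each candidate.
#' For matched candidates the reported position is the placement's implied
#' breakpoint; the score and per-strand window counts are recomputed at that
#' position. Deterministic for fixed inputs; sorted by (chrom, start).
#'
#' @param track A [read_end_track()].
#' @param genome Named character vector of contigs (same assembly as the
#'   alignments the track came from).
#' @param guide A [guide_rna()].
#' @param params A [caller_params()].
#' @param keep_unmatched Keep candidates without a guide match, flagged with
#'   `strand = "."` and `mismatches = NA` (default `FALSE`).
#' @return BED6+ site data frame: `chrom`, `start` (0-based breakpoint),
#'   `end` (= start + 1), `name`, `score` (window read-end sum), `strand`
#'   (of the matched protospacer), `mismatches`, `matched_seq`,
#'   `proto_start`, `fwd_ends`, `rev_ends`.
#' @export
call_cut_sites <- function(track, genome, guide, params = caller_params(),
                           keep_unmatched = FALSE) {
  cand <- detect_candidates(track, params)
  rows <- vector("list", nrow(cand))
  h <- params$window_width %/% 2
  for (i in seq_len(nrow(cand))) {
    m <- tryCatch(
      match_guide(genome, cand$chrom[i], cand$pos[i], guide, params),
      error = function(e) NULL
    )
    if (is.null(m)) {
      if (!keep_unmatched) next
      rows[[i]] <- data.frame(
        chrom = cand$chrom[i], start = cand$pos[i],
        end = cand$pos[i] + 1L, name = NA_character_,
        score = cand$score[i], strand = ".",
        mismatches = NA_integer_, matched_seq = NA_character_,
        proto_start = NA_integer_,
        fwd_ends = cand$fwd_in_window[i], rev_ends = cand$rev_in_window[i],
        stringsAsFactors = FALSE)
    } else {
      b <- m$cut_position
      fwd <- count_ends(track, cand$chrom[i], b - h, b + h, strand = "+")
      rev <- count_ends(track, cand$chrom[i], b - h, b + h, strand = "-")
      rows[[i]] <- data.frame(
        chrom = cand$chrom[i], start = b, end = b + 1L,
        name = NA_character_, score = fwd + rev, strand = m$strand,
        mismatches = m$mismatches, matched_seq = m$matched_seq,
        proto_start = m$protospacer_start,
        fwd_ends = fwd, rev_ends = rev, stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, rows)
  if (is.null(sites)) {
    sites <- data.frame(chrom = character(), start = integer(),
                        end = integer(), name = character(),
                        score = integer(), strand = character(),
                        mismatches = integer(), matched_seq = character(),
                        proto_start = integer(), fwd_ends = integer(),
                        rev_ends = integer(), stringsAsFactors = FALSE)
    return(sites)
  }
  # two candidates can resolve to the same placement; keep the best-scoring
  sites <- sites[order(sites$chrom, sites$start, -sites$score), , drop = FALSE]
  sites <- sites[!duplicated(sites[, c("chrom", "start")]), , drop = FALSE]
  sites <- sites[order(sites$chrom, sites$start), , drop = FALSE]
  sites$name <- sprintf("cut_%04d", seq_len(nrow(sites)))
  rownames(sites) <- NULL
  sites
}

#' Distance from a called cut to the 5' edge of its matched PAM
#'
#' Computed in protospacer orientation; 3 bp for a blunt SpCas9 cut.
#'
#' @param sites A site data frame from [call_cut_sites()] (needs
#'   `proto_start`, `start`, `strand`).
#' @return Integer vector (NA for unmatched sites).
#' @export
pam_distance <- function(sites) {
  ifelse(sites$strand == "+",
         sites$proto_start + 20L - sites$start,
         ifelse(sites$strand == "-", sites$start - sites$proto_start,
                NA_integer_))
}
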