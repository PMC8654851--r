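#' Coverage skewness between the two flanks of a cut site
#'
#' `%skewness = |L_cov - R_cov| / (L_cov + R_cov) * 100`: the imbalance of
#' read coverage between the PAM-proximal and PAM-distal sides of a cleavage
#' site. 0 for perfectly even flanks, 100 when all reads fall on one side.
#' End degradation of the distal flank (no end repair) raises it.
#'
#' @param L_cov,R_cov Non-negative flank read counts.
#' @return Percentage in \[0, 100\]; `NA` (with a warning) when both counts
#'   are zero, where the statistic is undefined.
#' @examples
#' skewness(75, 25) # 50
#' @export
skewness <- function(L_cov, R_cov) {
  stopifnot(all(L_cov >= 0), all(R_cov >= 0))
  tot <- L_cov + R_cov
  out <- ifelse(tot == 0, NA_real_, abs(L_cov - R_cov) / tot * 100)
  if (anyNA(out)) warning("skewness undefined where L_cov + R_cov == 0")
  out
}

#' Per-site flank coverage and skewness
#'
#' Counts read 5' ends on each side of every called (or planted) cut:
#' left flank \[cut - flank, cut), right flank \[cut, cut + flank). Sides are
#' labeled proximal/distal by the matched protospacer strand (the PAM side is
#' proximal); for a plus-strand protospacer the PAM lies right of the cut.
#' The labeling affects only which side is reported as `L_cov`; the skewness
#' value is symmetric.
#'
#' @param track A [read_end_track()].
#' @param sites Site data frame with `chrom`, `strand` and either `start`
#'   (calls) or `cut_position` (truth tables).
#' @param flank Flank width in bp (default 200; must exceed the score-window
#'   half-width).
#' @return Data frame: `name`, `chrom`, `cut`, `strand`, `L_cov` (proximal),
#'   `R_cov` (distal), `skewness_percent`, `truncated` (flank clipped at a
#'   contig edge).
#' @export
site_skewness <- function(track, sites, flank = 200) {
  stopifnot(flank > 5)
  cut <- if ("start" %in% names(sites)) sites$start else sites$cut_position
  n <- nrow(sites)
  left <- integer(n); right <- integer(n); trunc <- logical(n)
  for (i in seq_len(n)) {
    sl <- track$seqlengths[sites$chrom[i]]
    lo <- cut[i] - flank
    hi <- cut[i] + flank
    trunc[i] <- lo < 0 || (!is.na(sl) && length(sl) && hi > sl)
    left[i] <- count_ends(track, sites$chrom[i], max(0, lo), cut[i])
    right[i] <- count_ends(track, sites$chrom[i], cut[i], hi)
  }
  if (any(trunc)) {
    warning(sum(trunc), " site(s) nearer than `flank` to a contig edge; ",
            "computed on the available span")
  }
  prox_right <- sites$strand == "+"
  L <- ifelse(prox_right, right, left)
  R <- ifelse(prox_right, left, right)
  data.frame(
    name = if ("name" %in% names(sites)) sites$name else as.character(seq_len(n)),
    chrom = sites$chrom, cut = cut, strand = sites$strand,
    L_cov = L, R_cov = R,
    skewness_percent = suppressWarnings(skewness(L, R)),
    truncated = trunc, stringsAsFactors = FALSE
  )
}

#' Fraction of reads aligned to RGEN-generated ends
#'
#' Percentage of total mapped read ends lying within `window` bp of any known
#' cut position -- the productive-read output of a library, the headline
#' quality metric of the chemistry.
#'
#' @param track A [read_end_track()].
#' @param sites Known cuts (truth table or calls); empty set gives 0.
#' @param window Tolerance in bp (default 5).
#' @return Percentage in \[0, 100\].
#' @export
productive_read_fraction <- function(track, sites, window = 5) {
  if (track$total_mapped == 0) stop("empty track", call. = FALSE)
  if (is.null(sites) || nrow(sites) == 0) return(0)
  cut <- if ("start" %in% names(sites)) sites$start else sites$cut_position
  cuts <- split(cut, if ("chrom" %in% names(sites)) sites$chrom
                     else rep("chr1", length(cut)))
  e <- track$ends
  productive <- 0L
  for (cc in unique(e$chrom)) {
    if (!cc %in% names(cuts)) next
    cs <- sort(unique(cuts[[cc]]))
    ec <- e[chrom == cc]
    idx <- findInterval(ec$pos, cs)
    d_lo <- ifelse(idx >= 1, ec$pos - cs[pmax(idx, 1)], Inf)
    d_hi <- ifelse(idx < length(cs), cs[pmin(idx + 1, length(cs))] - ec$pos,
                   Inf)
    productive <- productive + sum(ec$count[pmin(d_lo, d_hi) <= window])
  }
  100 * productive / track$total_mapped
}

#' Site recovery as a function of sequencing depth
#'
#' Subsamples the track at each fraction (nested under the fixed seed, so
#' smaller samples are subsets of larger ones and the curve is monotone by
#' construction) and re-calls sites.
#'
#' @param track A [read_end_track()].
#' @param genome,guide,params As for [call_cut_sites()].
#' @param fractions Ascending retention fractions in (0, 1\].
#' @param seed Integer seed shared across fractions.
#' @return Data frame with one row per fraction: `fraction`,
#'   `retained_reads`, `recovered_sites`, `recovered_le3` (sites with <= 3
#'   mismatches). The per-fraction site tables are attached as
#'   `attr(, "calls")`.
#' @export
saturation_curve <- function(track, genome, guide, params = caller_params(),
                             fractions = c(0.05, 0.1, 0.25, 0.5, 1.0),
                             seed = 1L) {
  stopifnot(all(diff(fractions) > 0), all(fractions > 0), all(fractions <= 1))
  calls <- vector("list", length(fractions))
  rows <- vector("list", length(fractions))
  for (i in seq_along(fractions)) {
    sub <- subsample_track(track, fractions[i], seed)
    s <- call_cut_sites(sub, genome, guide, params)
    calls[[i]] <- s
    rows[[i]] <- data.frame(
      fraction = fractions[i], retained_reads = sub$total_mapped,
      recovered_sites = nrow(s),
      recovered_le3 = sum(s$mismatches <= 3, na.rm = TRUE))
  }
  out <- do.call(rbind, rows)
  attr(out, "calls") <- calls
  out
}

#' Site recovery and score across RGEN concentrations
#'
#' Runs the simulate -> call pipeline over a concentration grid with a shared
#' truth set and shared randomness: each (site, genome copy) pair draws one
#' uniform and is cleaved at concentration C when it falls below the Hill
#' probability, so realized cleavage counts are exactly non-decreasing in C.
#' An optional fixed read budget mimics a sequencing run: when the library
#' yields more productive molecules than the budget, reads are down-sampled,
#' so at high concentration many low-affinity sites share the same total
#' depth and the median score falls after its initial rise.
#'
#' @param genome Named character vector (with planted sites).
#' @param guide A [guide_rna()].
#' @param truth Planted-site data frame (needs `affinity_K`).
#' @param concentrations Ascending RGEN concentrations (nM), spanning at
#'   least two orders of magnitude in typical use (16-1024 nM).
#' @param params A [caller_params()].
#' @param config A [sim_config()] providing copies, efficiency, read length.
#' @param read_budget Optional maximum number of reads retained per
#'   concentration.
#' @param seed Integer seed.
#' @return Data frame: `concentration_nM`, `total_reads`, `retained_reads`,
#'   `recovered_sites`, `recovered_le3`, `median_score`.
#' @export
concentration_response <- function(genome, guide, truth, concentrations,
                                   params = caller_params(),
                                   config = sim_config(),
                                   read_budget = NULL, seed = 1L) {
  stopifnot(all(diff(concentrations) > 0), all(concentrations >= 0))
  genome <- as_genome(genome)
  n <- nrow(truth)
  copies <- config$genome_copies
  h <- config$hill_coefficient
  U <- withr::with_seed(derive_seed(seed, "occupancy"),
                        matrix(stats::runif(n * copies), nrow = n))
  seqlen <- stats::setNames(nchar(genome), names(genome))
  rows <- vector("list", length(concentrations))
  for (i in seq_along(concentrations)) {
    C <- concentrations[i]
    p <- if (C == 0) rep(0, n) else C^h / (C^h + truth$affinity_K^h)
    sites <- truth
    sites$cleaved_count <- as.integer(rowSums(U < p))
    cfg <- config
    cfg$rgen_concentration_nM <- C
    sim <- simulate_reads(genome, sites, cfg,
                          seed = derive_seed(seed, "reads"))
    track <- track_from_reads(sim$reads, seqlengths = seqlen)
    total <- track$total_mapped
    if (!is.null(read_budget) && total > read_budget) {
      track <- subsample_track(track, read_budget / total, seed)
    }
    calls <- call_cut_sites(track, genome, guide, params)
    rows[[i]] <- data.frame(
      concentration_nM = C, total_reads = total,
      retained_reads = track$total_mapped,
      recovered_sites = nrow(calls),
      recovered_le3 = sum(calls$mismatches <= 3, na.rm = TRUE),
      median_score = if (nrow(calls)) stats::median(calls$score) else NA_real_)
  }
  do.call(rbind, rows)
}

#' Score distribution by mismatch group
#'
#' Groups sites by protospacer mismatch count using the reporting convention
#' in which the 3-mismatch group includes all sites with 0-3 mismatches;
#' higher counts form their own groups (4, 5, 6, 7). Unmatched sites are
#' excluded.
#'
#' @param sites Site data frame with `mismatches` and `score`.
#' @param log_scale If `TRUE`, the variance is computed on log10 scores (the
#'   scale on which score spread is usually compared).
#' @return Data frame: `group`, `count`, `median_score`, `score_variance`
#'   (`NA` for empty groups).
#' @export
score_stats_by_mismatch <- function(sites, log_scale = FALSE) {
  sites <- sites[!is.na(sites$mismatches), , drop = FALSE]
  grp <- ifelse(sites$mismatches <= 3, "0-3",
                as.character(sites$mismatches))
  levels <- c("0-3", "4", "5", "6", "7")
  rows <- lapply(levels, function(g) {
    sc <- sites$score[grp == g]
    v <- if (log_scale) log10(sc) else sc
    data.frame(group = g, count = length(sc),
               median_score = if (length(sc)) stats::median(sc) else NA_real_,
               score_variance = if (length(sc) >= 2) stats::var(v)
                                else if (length(sc) == 1) 0 else NA_real_)
  })
  do.call(rbind, rows)
}
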