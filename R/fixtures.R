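#' Standard ground-truthed benchmark fixture
#'
#' The package's reference simulation for caller benchmarking: a 1-Mb random
#' genome (GC 0.41) with 12 planted sites at 0-6 protospacer mismatches on
#' alternating strands, site affinities log-spaced over 16-64 nM, digested at
#' 256 nM RGEN with 10,000 template molecules, end repair on, ligation
#' efficiency 0.9 and a low uniform background -- roughly 190k productive
#' reads, heavily oversequenced so that sub-million-read behaviour can be
#' probed by subsampling.
#'
#' @param seed Integer seed controlling genome, guide, planting and
#'   chemistry.
#' @param sam_path Optional SAM output path.
#' @param config_overrides Named list of [sim_config()] fields to override.
#' @return As [simulate_library()]: `genome`, `guide`, `truth`, `sim`,
#'   `track`.
#' @export
standard_fixture <- function(seed = 1L, sam_path = tempfile(fileext = ".sam"),
                             config_overrides = list()) {
  guide <- random_guide(seed)
  site_spec <- data.frame(
    mismatches = c(0L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L, 6L),
    strand = rep(c("+", "-"), 6),
    affinity_K = round(10^seq(log10(16), log10(64), length.out = 12), 1)
  )
  cfg <- list(genome_length = 1e6, gc_content = 0.41, genome_copies = 10000,
              rgen_concentration_nM = 256, end_repair = TRUE,
              resection_mean = 5, background_break_rate = 2e-5,
              p7L_ligation_efficiency = 0.9, read_length = 151, seed = seed)
  cfg[names(config_overrides)] <- config_overrides
  config <- do.call(sim_config, cfg)
  simulate_library(guide, site_spec, config, sam_path = sam_path)
}

#' Recovery of planted sites by a call set
#'
#' Matches called sites to a planted truth table within a positional
#' tolerance and reports per-site recovery; the workhorse of recall
#' benchmarks.
#'
#' @param calls Site data frame from [call_cut_sites()].
#' @param truth Planted-site data frame (with `cut_position`).
#' @param tolerance Maximum |called - true| distance in bp (default 1).
#' @return `truth` with added columns `recovered` (logical), `called_start`,
#'   `called_score`, `position_error`.
#' @export
recovery_table <- function(calls, truth, tolerance = 1) {
  out <- truth
  out$recovered <- FALSE
  out$called_start <- NA_integer_
  out$called_score <- NA_real_
  out$position_error <- NA_integer_
  for (i in seq_len(nrow(truth))) {
    d <- abs(calls$start - truth$cut_position[i])
    hit <- which(calls$chrom == truth$chrom[i] & d <= tolerance)
    if (length(hit)) {
      j <- hit[which.min(d[hit])]
      out$recovered[i] <- TRUE
      out$called_start[i] <- calls$start[j]
      out$called_score[i] <- calls$score[j]
      out$position_error[i] <- calls$start[j] - truth$cut_position[i]
    }
  }
  out
}
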