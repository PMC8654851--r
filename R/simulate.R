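#' Simulation configuration for the amplification-free library
#'
#' Bundles the parameters of the library-chemistry model: how many template
#' molecules are digested, the RGEN (Cas9:sgRNA) concentration driving
#' single-turnover cleavage, whether cut ends are repaired before adapter
#' ligation, the depth of end degradation when they are not, the rate of
#' background (non-RGEN) breaks that carry residual adapter, and read
#' geometry.
#'
#' @param genome_length Genome length in bp (used for background-break
#'   expectations; the genome itself is passed to the simulation functions).
#' @param gc_content GC fraction of generated genomes.
#' @param genome_copies Number of template molecules digested.
#' @param rgen_concentration_nM RGEN concentration C (nM).
#' @param hill_coefficient Hill coefficient h of the cleavage saturation
#'   p = C^h / (C^h + K^h); default 1.
#' @param end_repair If `TRUE`, cut ends are repaired and read 5' ends sit
#'   exactly at the breakpoint; if `FALSE`, the PAM-distal flank is degraded.
#' @param resection_mean Mean of the geometric distal-end trimming (bp) when
#'   `end_repair` is off.
#' @param background_break_rate Expected background cut ends per kb per
#'   genome copy.
#' @param p7L_ligation_efficiency Probability that a cut end is successfully
#'   ligated to the p7L adapter (and so yields a productive read).
#' @param read_length Read length in bp (the paper's libraries use 151-cycle
#'   R2 reads).
#' @param seed Integer seed; all stage seeds are derived from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e6,
                       gc_content = 0.41,
                       genome_copies = 1000,
                       rgen_concentration_nM = 256,
                       hill_coefficient = 1,
                       end_repair = TRUE,
                       resection_mean = 5,
                       background_break_rate = 0,
                       p7L_ligation_efficiency = 0.9,
                       read_length = 151,
                       seed = 1L) {
  stopifnot(genome_length >= 1, genome_copies >= 1,
            gc_content >= 0, gc_content <= 1,
            p7L_ligation_efficiency >= 0, p7L_ligation_efficiency <= 1,
            background_break_rate >= 0, resection_mean >= 0,
            read_length >= 20, hill_coefficient > 0)
  if (rgen_concentration_nM < 0) {
    stop("rgen_concentration_nM must be >= 0", call. = FALSE)
  }
  structure(list(
    genome_length = genome_length, gc_content = gc_content,
    genome_copies = as.integer(genome_copies),
    rgen_concentration_nM = rgen_concentration_nM,
    hill_coefficient = hill_coefficient,
    end_repair = isTRUE(end_repair), resection_mean = resection_mean,
    background_break_rate = background_break_rate,
    p7L_ligation_efficiency = p7L_ligation_efficiency,
    read_length = as.integer(read_length), seed = as.integer(seed)
  ), class = "sim_config")
}

#' Single-turnover cleavage of planted sites
#'
#' Each genome copy is cleaved at each site independently at most once, with
#' probability `p = C^h / (C^h + K^h)` where C is the RGEN concentration and
#' K the site's affinity (concentration of half-maximal cleavage). This Hill
#' saturation is the simplest occupancy model consistent with Cas9 acting as
#' a single-turnover enzyme: recovery is governed by site occupancy, not
#' catalytic recycling.
#'
#' @param sites Planted-site data frame from [plant_sites()] (needs
#'   `affinity_K`).
#' @param config A [sim_config()].
#' @param seed Optional override of the stage seed derived from
#'   `config$seed`.
#' @return `sites` with an added integer column `cleaved_count`.
#' @importFrom stats rbinom rgeom rpois runif
#' @export
simulate_cleavage <- function(sites, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  C <- config$rgen_concentration_nM
  if (C < 0) stop("rgen_concentration_nM must be >= 0", call. = FALSE)
  h <- config$hill_coefficient
  p <- if (C == 0) rep(0, nrow(sites)) else C^h / (C^h + sites$affinity_K^h)
  sites$cleavage_prob <- p
  sites$cleaved_count <- withr::with_seed(
    seed %||% derive_seed(config$seed, "cleave"),
    stats::rbinom(nrow(sites), config$genome_copies, p)
  )
  sites
}

#' Simulate productive reads and emit aligned SAM
#'
#' Implements the productive-molecule selection of the library chemistry:
#' only fragments with one RGEN-cut end (p7L adapter) and one fragmented end
#' (p5L adapter) form clusters, so each cleaved molecule yields up to two
#' productive reads, one per flank, each accepted with probability
#' `p7L_ligation_efficiency`. With end repair on, read 5' ends sit exactly at
#' the breakpoint: the PAM-proximal flank gives a read pointing away from the
#' cut on the protospacer-PAM side, the distal flank the mirror read, which
#' reproduces the bidirectional pileup signature flanking a cut. With end
#' repair off, the distal end is degraded: its 5' end is shifted away from
#' the cut by a geometric offset with mean `resection_mean`, and ligation of
#' a degraded end succeeds with probability `theta^k` (theta the geometric
#' continuation probability), depleting the distal flank. Background breaks
#' contribute single reads at their positions at the ligation efficiency.
#'
#' @param genome Named character vector of contigs.
#' @param sites Sites with `cleaved_count`, from [simulate_cleavage()].
#' @param config A [sim_config()].
#' @param sam_path Output SAM path (coordinate-sorted, with `@HD`/`@SQ`).
#' @param seed Optional override of the derived stage seed.
#' @return A `sim_result` list: `sam` (path), `truth` (sites with realized
#'   counts), `reads` (data.table of `chrom`, `pos5` — the 0-based 5'-end
#'   reference position — `strand`, `origin`), `background_positions`,
#'   `n_dropped` (reads dropped for falling off a contig end).
#' @import data.table
#' @export
simulate_reads <- function(genome, sites, config,
                           sam_path = tempfile(fileext = ".sam"),
                           seed = NULL) {
  stopifnot(inherits(config, "sim_config"),
            "cleaved_count" %in% names(sites))
  genome <- as_genome(genome)
  chrom <- names(genome)[1]
  L <- nchar(genome[[1]])
  eff <- config$p7L_ligation_efficiency
  mu <- config$resection_mean

  res <- withr::with_seed(seed %||% derive_seed(config$seed, "reads"), {
    parts <- vector("list", nrow(sites) + 1L)
    for (i in seq_len(nrow(sites))) {
      m <- sites$cleaved_count[i]
      if (m == 0) next
      b <- sites$cut_position[i]
      plus <- sites$strand[i] == "+"
      # proximal flank (PAM side): intact end at the breakpoint
      n_prox <- stats::rbinom(1, m, eff)
      prox <- data.table::data.table(
        pos5 = rep(if (plus) b else b - 1L, n_prox),
        strand = rep(if (plus) "+" else "-", n_prox)
      )
      # distal flank: intact when end-repaired, degraded otherwise
      if (config$end_repair || mu == 0) {
        n_dist <- stats::rbinom(1, m, eff)
        offs <- integer(n_dist)
      } else {
        theta <- mu / (1 + mu)
        k <- stats::rgeom(m, 1 / (1 + mu))
        keep <- stats::runif(m) < eff * theta^k
        offs <- k[keep]
        n_dist <- length(offs)
      }
      dist <- data.table::data.table(
        pos5 = if (plus) b - 1L - offs else b + offs,
        strand = rep(if (plus) "-" else "+", n_dist)
      )
      parts[[i]] <- rbind(prox, dist)[, origin := sites$name[i]]
    }
    n_bg <- stats::rpois(1, config$background_break_rate * (L / 1000) *
                           config$genome_copies)
    bg_pos <- if (n_bg > 0) sort(sample.int(L, n_bg, replace = TRUE) - 1L)
              else integer(0)
    if (n_bg > 0) {
      keep <- stats::runif(n_bg) < eff
      parts[[nrow(sites) + 1L]] <- data.table::data.table(
        pos5 = bg_pos[keep],
        strand = sample(c("+", "-"), sum(keep), replace = TRUE),
        origin = "background"
      )
    }
    list(reads = data.table::rbindlist(parts), background = bg_pos)
  })

  reads <- res$reads
  if (nrow(reads) == 0) {
    reads <- data.table::data.table(pos5 = integer(), strand = character(),
                                    origin = character())
  }
  reads[, chrom := chrom]
  rl <- config$read_length

  # reference span of each read; truncated at contig ends, dropped if < 20 bp
  reads[, start := ifelse(strand == "+", pos5, pmax(0L, pos5 - rl + 1L))]
  reads[, end := ifelse(strand == "+", pmin(L, pos5 + rl), pos5 + 1L)]
  reads[, span := end - start]
  n_dropped <- sum(reads$span < 20 | reads$pos5 < 0 | reads$pos5 >= L)
  if (n_dropped > 0) {
    message(n_dropped, " read(s) dropped at contig edges")
    reads <- reads[span >= 20 & pos5 >= 0 & pos5 < L]
  }
  data.table::setorder(reads, start, pos5, strand, origin)
  reads[, qname := sprintf("sim%07d", .I)]

  write_sim_sam(reads, genome, sam_path)
  out <- reads[, .(qname, chrom, pos5, strand, origin)]
  structure(list(sam = sam_path, truth = sites, reads = out,
                 background_positions = res$background,
                 n_dropped = n_dropped, config = config),
            class = "sim_result")
}

# Coordinate-sorted SAM with header matching the genome. Plain text writer:
# the simulator emits already-aligned records by design, so no aligner or
# FASTQ round-trip is involved.
write_sim_sam <- function(reads, genome, sam_path) {
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)),
    "@PG\tID:rgenseq\tPN:rgenseq"
  )
  con <- file(sam_path, "w")
  writeLines(header, con)
  close(con)
  if (nrow(reads) > 0) {
    seqs <- substring(genome[[reads$chrom[1]]], reads$start + 1, reads$end)
    rev <- reads$strand == "-"
    if (any(rev)) {
      seqs[rev] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[rev])))
    }
    rec <- data.table::data.table(
      qname = reads$qname,
      flag = ifelse(rev, 16L, 0L),
      rname = reads$chrom,
      pos = reads$start + 1L,
      mapq = 60L,
      cigar = paste0(reads$span, "M"),
      rnext = "*", pnext = 0L, tlen = 0L,
      seq = seqs,
      qual = strrep("I", reads$span)
    )
    data.table::fwrite(rec, sam_path, sep = "\t", col.names = FALSE,
                       append = TRUE, quote = FALSE)
  }
  invisible(sam_path)
}

#' One-call simulation of a ground-truthed library
#'
#' Convenience pipeline: generate a genome, plant sites, cleave, and emit
#' reads plus the truth table.
#'
#' @param guide A [guide_rna()].
#' @param site_spec Data frame for [plant_sites()].
#' @param config A [sim_config()].
#' @param sam_path Optional SAM output path.
#' @return List: `genome`, `guide`, `truth` (planted sites with realized
#'   `cleaved_count`), `sim` (the `sim_result`), `track` (a
#'   [read_end_track]-classed object built directly from the emitted reads).
#' @export
simulate_library <- function(guide, site_spec, config,
                             sam_path = tempfile(fileext = ".sam")) {
  genome <- generate_genome(config$genome_length, config$gc_content,
                            derive_seed(config$seed, "genome"))
  planted <- plant_sites(genome, guide, site_spec,
                         seed = derive_seed(config$seed, "sites"))
  sites <- simulate_cleavage(planted$sites, config)
  sim <- simulate_reads(planted$genome, sites, config, sam_path = sam_path)
  list(genome = planted$genome, guide = guide, truth = sim$truth, sim = sim,
       track = track_from_reads(sim$reads,
                                seqlengths = stats::setNames(
                                  nchar(planted$genome), names(planted$genome))))
}

#' Write a planted/called truth table as BED6
#'
#' @param sites Data frame with `chrom`, `cut_position`, `name`,
#'   `mismatches`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(sites, path) {
  df <- data.frame(chrom = sites$chrom, start = sites$cut_position,
                   end = sites$cut_position + 1L, name = sites$name,
                   score = sites$mismatches, strand = sites$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
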