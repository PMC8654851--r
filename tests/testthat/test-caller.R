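make_track <- function(df, len = 10000) {
  read_end_track(data.table::as.data.table(df),
                 total_mapped = sum(df$count),
                 seqlengths = c(chr1 = len))
}

test_that("window score sums the half-open 10-bp window", {
  empty <- read_end_track(
    data.frame(chrom = character(), pos = integer(), strand = character(),
               count = integer()),
    total_mapped = 0L, seqlengths = c(chr1 = 1000L))
  expect_equal(window_score(empty, "chr1", 500), 0)

  tr <- make_track(data.frame(chrom = "chr1", pos = 500L, strand = "+",
                              count = 7L))
  expect_equal(window_score(tr, "chr1", 500), 7)
  expect_error(window_score(tr, "chrX", 500), "unknown chromosome")

  # boundary enumeration: pos-5 and pos+4 inside, pos+5 outside
  tr2 <- make_track(data.frame(chrom = "chr1",
                               pos = c(495L, 504L, 505L),
                               strand = c("+", "-", "+"),
                               count = c(1L, 1L, 1L)))
  expect_equal(window_score(tr2, "chr1", 500), 2)
})

test_that("candidate detection lands on the breakpoint junction", {
  expect_equal(nrow(detect_candidates(read_end_track(
    data.frame(chrom = character(), pos = integer(), strand = character(),
               count = integer()), 0L))), 0)

  # clean signature: forward ends at b, reverse ends at b-1
  tr <- make_track(data.frame(chrom = "chr1", pos = c(1000L, 999L),
                              strand = c("+", "-"), count = c(40L, 35L)))
  cand <- detect_candidates(tr, caller_params())
  expect_equal(nrow(cand), 1)
  expect_equal(cand$pos, 1000L)
  expect_equal(cand$score, 75L)
  expect_equal(cand$fwd_in_window, 40L)
  expect_equal(cand$rev_in_window, 35L)

  # two sites 1 kb apart stay separate
  tr2 <- make_track(data.frame(chrom = "chr1",
                               pos = c(1000L, 999L, 2000L, 1999L),
                               strand = c("+", "-", "+", "-"),
                               count = c(40L, 35L, 20L, 25L)))
  expect_equal(detect_candidates(tr2)$pos, c(1000L, 2000L))

  # bidirectional filter suppresses one-sided spikes
  spike <- make_track(data.frame(chrom = "chr1", pos = 3000L, strand = "+",
                                 count = 50L))
  expect_equal(nrow(detect_candidates(spike, caller_params())), 0)
  expect_equal(nrow(detect_candidates(
    spike, caller_params(require_bidirectional = FALSE))), 1)
})

test_that("simulated sites are detected exactly at the planted breakpoints", {
  fix <- get_small_fixture()
  cand <- detect_candidates(fix$track, caller_params())
  expect_setequal(cand$pos, fix$truth$cut_position)
})

test_that("guide matching recovers planted placements on both strands", {
  fix <- get_small_fixture()
  params <- caller_params()
  for (i in seq_len(nrow(fix$truth))) {
    s <- fix$truth[i, ]
    m <- match_guide(fix$genome, s$chrom, s$cut_position, fix$guide, params)
    expect_equal(m$strand, s$strand)
    expect_equal(m$mismatches, s$mismatches)
    expect_equal(m$protospacer_start, s$protospacer_start)
    expect_equal(m$cut_position, s$cut_position)
  }
  # plus-strand arithmetic: cut 3 bp upstream of the PAM
  plus <- fix$truth[fix$truth$strand == "+", ][1, ]
  m <- match_guide(fix$genome, plus$chrom, plus$cut_position, fix$guide,
                   params)
  expect_equal(m$cut_position, m$protospacer_start + 17L)

  # random sequence without a qualifying placement
  bare <- generate_genome(200, 0.5, seed = 77)
  strict <- caller_params(max_mismatches = 0)
  expect_null(match_guide(bare, "chr1", 100, fix$guide, strict))
  expect_error(match_guide(bare, "chr1", 5, fix$guide, params),
               "insufficient flanking")
})

test_that("full calling recovers planted sites and recomputes scores", {
  fix <- get_small_fixture()
  calls <- call_cut_sites(fix$track, fix$genome, fix$guide, caller_params())
  rec <- recovery_table(calls, fix$truth, tolerance = 1)
  expect_true(all(rec$recovered))
  expect_true(all(abs(rec$position_error) <= 1))

  # invariant: stored score equals the window sum recomputed at the call
  for (i in seq_len(nrow(calls))) {
    expect_equal(calls$score[i],
                 window_score(fix$track, calls$chrom[i], calls$start[i]))
  }
  # offset law on end-repaired data
  expect_true(all(pam_distance(calls) == 3L))
})

test_that("raising min_score never adds sites (nested outputs)", {
  fix <- get_small_fixture()
  loose <- call_cut_sites(fix$track, fix$genome, fix$guide,
                          caller_params(min_score = 5))
  strict <- call_cut_sites(fix$track, fix$genome, fix$guide,
                           caller_params(min_score = 600))
  expect_true(all(strict$start %in% loose$start))
  expect_lte(nrow(strict), nrow(loose))
})

test_that("a background-only track below threshold yields no sites", {
  guide <- random_guide(61)
  g <- generate_genome(5e4, 0.41, seed = 61)
  # sparse one-per-position background can never reach min_score 5
  bg <- data.frame(chrom = "chr1",
                   pos = as.integer(seq(100, 49000, by = 600)),
                   strand = rep(c("+", "-"), length.out = 82),
                   count = 1L)
  tr <- read_end_track(bg, total_mapped = nrow(bg),
                       seqlengths = c(chr1 = 5e4))
  expect_equal(nrow(call_cut_sites(tr, g, guide, caller_params())), 0)
})

test_that("genome match enumeration agrees with the independent oracle", {
  guide <- random_guide(71)
  g <- generate_genome(1e5, 0.41, seed = 71)
  spec <- data.frame(mismatches = c(0L, 2L, 3L, 4L),
                     strand = c("+", "-", "-", "+"),
                     affinity_K = rep(32, 4))
  pl <- plant_sites(g, guide, spec, seed = 71)

  hits <- enumerate_genome_matches(pl$genome, guide, max_mismatches = 4)
  expect_equal(hits, oracle_scan(pl$genome, guide, 4))

  # trivial cases
  one <- c(chr1 = paste0(strrep("T", 40), guide$protospacer, "AGG",
                         strrep("T", 40)))
  h1 <- enumerate_genome_matches(one, guide, 0)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$position, 40L)
  expect_equal(h1$mismatches, 0L)

  polyA <- guide_rna(strrep("A", 20))
  polyC <- c(chr1 = strrep("C", 200))
  expect_equal(nrow(enumerate_genome_matches(polyC, polyA, 3)), 0)
})

test_that("unmatched candidates are kept only when requested", {
  # a strong pileup in sequence with no guide placement nearby
  guide <- random_guide(81)
  g <- generate_genome(5000, 0.5, seed = 81)
  tr <- make_track(data.frame(chrom = "chr1", pos = c(2500L, 2499L),
                              strand = c("+", "-"), count = c(30L, 30L)),
                   len = 5000)
  drop <- call_cut_sites(tr, g, guide, caller_params(max_mismatches = 0))
  keep <- call_cut_sites(tr, g, guide, caller_params(max_mismatches = 0),
                         keep_unmatched = TRUE)
  expect_equal(nrow(drop), 0)
  expect_equal(nrow(keep), 1)
  expect_equal(keep$strand, ".")
  expect_true(is.na(keep$mismatches))
})
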