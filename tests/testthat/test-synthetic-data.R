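test_that("generated genomes honour length, composition and seed", {
  g <- generate_genome(1000, 0.5, seed = 1)
  expect_equal(nchar(g[[1]]), 1000)
  expect_true(grepl("^[ACGT]+$", g[[1]]))
  expect_identical(g, generate_genome(1000, 0.5, seed = 1))
  expect_false(identical(g, generate_genome(1000, 0.5, seed = 2)))

  gc_only <- generate_genome(500, 1.0, seed = 7)
  expect_true(grepl("^[GC]+$", gc_only[[1]]))
  at_only <- generate_genome(500, 0.0, seed = 7)
  expect_true(grepl("^[AT]+$", at_only[[1]]))

  expect_error(generate_genome(0, 0.5, seed = 1), "positive")
  expect_error(generate_genome(100, 1.5, seed = 1), "gc_content")
})

test_that("planted sites are written with the requested mismatches and PAM", {
  guide <- random_guide(5)
  g <- generate_genome(5e4, 0.45, seed = 5)
  spec <- data.frame(mismatches = c(0L, 2L), strand = c("+", "-"),
                     affinity_K = c(16, 32))
  pl <- plant_sites(g, guide, spec, seed = 5)
  s <- pl$sites
  expect_equal(nrow(s), 2)

  # plus-strand 0-mismatch site: genome carries protospacer + PAM verbatim
  plus <- s[s$strand == "+", ]
  seq23 <- substring(pl$genome[[1]], plus$protospacer_start + 1,
                     plus$protospacer_start + 23)
  expect_equal(substr(seq23, 1, 20), guide$protospacer)
  expect_match(substr(seq23, 21, 23), "^[ACGT]GG$")
  expect_equal(plus$cut_position, plus$protospacer_start + 17L)

  # minus-strand site: forward genome carries the reverse complement
  minus <- s[s$strand == "-", ]
  t0 <- minus$protospacer_start - 3L
  fwd23 <- substring(pl$genome[[1]], t0 + 1, t0 + 23)
  proto_oriented <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fwd23)))
  expect_equal(proto_oriented, minus$sequence)
  d <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
              substr(minus$sequence, 1, 20), guide$protospacer)
  expect_equal(unname(d), 2)
  expect_equal(minus$cut_position, t0 + 6L)
})

test_that("after planting, the genome contains exactly the planted matches", {
  guide <- random_guide(13)
  g <- generate_genome(1e5, 0.41, seed = 13)
  spec <- data.frame(mismatches = 0:3, strand = c("+", "-", "+", "-"),
                     affinity_K = rep(32, 4))
  pl <- plant_sites(g, guide, spec, seed = 13)
  found <- oracle_scan(pl$genome, guide, max_mm = 3)
  expect_equal(nrow(found), 4)
  expect_equal(found$position, sort(pl$sites$protospacer_start))
  key_found <- paste(found$position, found$strand, found$mismatches)
  key_truth <- paste(pl$sites$protospacer_start, pl$sites$strand,
                     pl$sites$mismatches)
  expect_setequal(key_found, key_truth)
})

test_that("planting fails loudly when the genome cannot hold the sites", {
  guide <- random_guide(1)
  g <- generate_genome(1000, 0.5, seed = 1)
  spec <- data.frame(mismatches = rep(0L, 10), strand = rep("+", 10),
                     affinity_K = rep(16, 10))
  expect_error(plant_sites(g, guide, spec, seed = 1), "too short")
})

test_that("cleavage follows single-turnover Hill saturation", {
  sites <- data.frame(name = paste0("s", 1:3), chrom = "chr1",
                      cut_position = c(100L, 400L, 700L),
                      strand = "+", mismatches = 0L,
                      protospacer_start = c(83L, 383L, 683L),
                      affinity_K = c(16, 64, 256))

  none <- simulate_cleavage(sites, sim_config(rgen_concentration_nM = 0,
                                              genome_copies = 1000, seed = 3))
  expect_true(all(none$cleaved_count == 0))

  sat <- simulate_cleavage(
    data.frame(sites[1, ], row.names = NULL),
    sim_config(rgen_concentration_nM = 16e6, genome_copies = 10000, seed = 3))
  expect_gte(sat$cleaved_count / 10000, 0.999)

  half <- simulate_cleavage(
    data.frame(name = "s", affinity_K = 64),
    sim_config(rgen_concentration_nM = 64, genome_copies = 10000, seed = 9))
  ci <- qbinom(c(0.005, 0.995), 10000, 0.5)
  expect_gte(half$cleaved_count, ci[1])
  expect_lte(half$cleaved_count, ci[2])
})

test_that("one repaired cleaved molecule yields the two-flank signature", {
  guide <- random_guide(21)
  g <- generate_genome(2000, 0.5, seed = 21)
  pl <- plant_sites(g, guide,
                    data.frame(mismatches = 0L, strand = "+",
                               affinity_K = 16),
                    seed = 21)
  sites <- pl$sites
  sites$cleaved_count <- 1L
  cfg <- sim_config(genome_length = 2000, genome_copies = 1,
                    p7L_ligation_efficiency = 1.0, end_repair = TRUE,
                    background_break_rate = 0, read_length = 50, seed = 21)
  sim <- simulate_reads(pl$genome, sites, cfg)
  b <- sites$cut_position
  expect_equal(nrow(sim$reads), 2)
  expect_setequal(paste(sim$reads$pos5, sim$reads$strand),
                  c(paste(b, "+"), paste(b - 1L, "-")))
})

test_that("without background every read end sits at a cut (mod resection)", {
  fix <- get_small_fixture()
  b <- fix$truth$cut_position
  near_cut <- vapply(fix$sim$reads$pos5,
                     function(p) min(abs(p - b), abs(p - (b - 1L))) == 0,
                     logical(1))
  expect_true(all(near_cut))  # end repair on: no offsets at all
  expect_identical(fix$sim$background_positions, integer(0))
})

test_that("productive-read counts follow the ligation-efficiency binomial", {
  guide <- random_guide(23)
  g <- generate_genome(5e4, 0.5, seed = 23)
  pl <- plant_sites(g, guide,
                    data.frame(mismatches = 0L, strand = "+",
                               affinity_K = 16), seed = 23)
  sites <- pl$sites
  sites$cleaved_count <- 1000L
  cfg <- sim_config(genome_length = 5e4, genome_copies = 1000,
                    p7L_ligation_efficiency = 0.8, end_repair = TRUE,
                    background_break_rate = 0, seed = 23)
  sim <- simulate_reads(pl$genome, sites, cfg)
  ci <- qbinom(c(0.005, 0.995), 2000, 0.8)
  expect_gte(nrow(sim$reads), ci[1])
  expect_lte(nrow(sim$reads), ci[2])
})

test_that("identical configurations give byte-identical SAM output", {
  guide <- random_guide(33)
  spec <- data.frame(mismatches = c(0L, 1L), strand = c("+", "-"),
                     affinity_K = c(16, 32))
  cfg <- sim_config(genome_length = 2e4, genome_copies = 200, seed = 33,
                    background_break_rate = 1e-4)
  p1 <- tempfile(fileext = ".sam"); p2 <- tempfile(fileext = ".sam")
  simulate_library(guide, spec, cfg, sam_path = p1)
  simulate_library(guide, spec, cfg, sam_path = p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("read output never exceeds two per cleaved molecule plus background", {
  fix <- get_small_fixture()
  expect_lte(nrow(fix$sim$reads),
             2 * sum(fix$truth$cleaved_count) +
               length(fix$sim$background_positions))
})

test_that("site recovery is monotone in RGEN concentration", {
  guide <- random_guide(41)
  g <- generate_genome(1e5, 0.41, seed = 41)
  spec <- data.frame(mismatches = rep(0:3, 2), strand = rep(c("+", "-"), 4),
                     affinity_K = 10^seq(log10(8), log10(800), length.out = 8))
  pl <- plant_sites(g, guide, spec, seed = 41)
  cfg <- sim_config(genome_length = 1e5, genome_copies = 60, seed = 41)
  cr <- concentration_response(pl$genome, guide, pl$sites,
                               c(4, 40, 400), config = cfg, seed = 41)
  expect_true(all(diff(cr$recovered_sites) >= 0))
})

test_that("end degradation skews flank coverage in the expected direction", {
  guide <- random_guide(51)
  g <- generate_genome(1e5, 0.41, seed = 51)
  spec <- data.frame(mismatches = rep(0:2, 2), strand = rep(c("+", "-"), 3),
                     affinity_K = rep(c(16, 32), 3))
  pl <- plant_sites(g, guide, spec, seed = 51)
  cfg_on <- sim_config(genome_length = 1e5, genome_copies = 150, seed = 51,
                       end_repair = TRUE, resection_mean = 3)
  sites <- simulate_cleavage(pl$sites, cfg_on)
  expect_true(all(sites$cleaved_count >= 100))
  cfg_off <- cfg_on; cfg_off$end_repair <- FALSE
  sl <- setNames(nchar(pl$genome), names(pl$genome))
  sk_on <- site_skewness(
    track_from_reads(simulate_reads(pl$genome, sites, cfg_on)$reads,
                     seqlengths = sl), sites)
  sk_off <- site_skewness(
    track_from_reads(simulate_reads(pl$genome, sites, cfg_off)$reads,
                     seqlengths = sl), sites)
  expect_gt(median(sk_off$skewness_percent), median(sk_on$skewness_percent))
})
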