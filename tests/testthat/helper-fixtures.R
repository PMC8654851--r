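# Shared fixtures (built once per run) and independent oracles.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, builder(), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# 1-Mb benchmark library: 12 sites at 0-6 mismatches, end repair on,
# ~190k reads, low background
get_standard_fixture <- function() {
  cached("standard", function() standard_fixture(seed = 101))
}

get_standard_calls <- function() {
  cached("standard_calls", function() {
    fix <- get_standard_fixture()
    call_cut_sites(fix$track, fix$genome, fix$guide, caller_params())
  })
}

# small, fast library for unit tests: 4 sites on 100 kb
get_small_fixture <- function() {
  cached("small", function() {
    guide <- random_guide(31)
    spec <- data.frame(mismatches = c(0L, 1L, 2L, 3L),
                       strand = c("+", "-", "+", "-"),
                       affinity_K = c(16, 24, 32, 48))
    cfg <- sim_config(genome_length = 1e5, genome_copies = 500, seed = 31,
                      background_break_rate = 0)
    simulate_library(guide, spec, cfg)
  })
}

# --- independent oracle: Biostrings/regex genome scan ------------------------

oracle_iupac <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                  S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                  D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

oracle_pam_regex <- function(pattern) {
  codes <- strsplit(pattern, "")[[1]]
  paste0("^", paste0("[", oracle_iupac[codes], "]", collapse = ""), "$")
}

# exhaustive both-strand scan via neditStartingAt + regex PAM check;
# shares no code with the package's integer-vector scan
oracle_scan <- function(genome, guide, max_mm) {
  rx <- oracle_pam_regex(guide$pam_pattern)
  pat <- Biostrings::DNAString(guide$protospacer)
  out <- list()
  for (chrom in names(genome)) {
    s <- genome[[chrom]]
    n <- nchar(s)
    if (n < 23) next
    starts <- 1:(n - 22)
    ned <- Biostrings::neditStartingAt(pat, Biostrings::DNAString(s),
                                       starting.at = starts)
    pam <- substring(s, starts + 20, starts + 22)
    ok <- ned <= max_mm & grepl(rx, pam)
    if (any(ok)) {
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, position = starts[ok] - 1L, strand = "+",
        mismatches = ned[ok], cut_position = starts[ok] - 1L + 17L,
        stringsAsFactors = FALSE)
    }
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    ned <- Biostrings::neditStartingAt(pat, Biostrings::DNAString(rc),
                                       starting.at = starts)
    pam <- substring(rc, starts + 20, starts + 22)
    ok <- ned <= max_mm & grepl(rx, pam)
    if (any(ok)) {
      j <- starts[ok]  # 1-based start on the reverse complement
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, position = n - j - 19L, strand = "-",
        mismatches = ned[ok], cut_position = n - j - 16L,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(), position = integer(),
                      strand = character(), mismatches = integer(),
                      cut_position = integer(), stringsAsFactors = FALSE)
  }
  res <- res[order(res$chrom, res$position, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# --- independent oracle: brute-force single-linkage clustering ---------------

# connected components of the |dpos| <= tol graph, by repeated expansion
brute_clusters <- function(df, tol) {
  n <- nrow(df)
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    df$chrom[i] == df$chrom[j] & abs(df$pos[i] - df$pos[j]) <= tol
  })
  comp <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), 0L)
    if (identical(new, comp)) break
    comp <- new
  }
  match(comp, unique(comp))
}

# hand-rolled SAM text for ingestion tests
write_mini_sam <- function(records, path, sq = "@SQ\tSN:chr1\tLN:10000") {
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", sq, records), path)
  path
}

sam_record <- function(qname, flag, pos, cigar, rname = "chr1", mapq = 60,
                       seq = NULL) {
  # SEQ must cover query-consuming ops (M/I/S/=/X)
  seqlen <- if (cigar == "*") 1 else sum(as.integer(
    sub("[A-Z=]$", "", regmatches(cigar, gregexpr("\\d+[MIS=X]", cigar))[[1]])))
  if (is.null(seq)) seq <- strrep("A", max(seqlen, 1))
  paste(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, seq,
        strrep("I", nchar(seq)), sep = "\t")
}
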