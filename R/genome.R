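#' Generate a random reference genome
#'
#' Bases are drawn i.i.d. with P(G) + P(C) = `gc_content`. The result is a
#' named character vector (one element per contig), the genome container used
#' throughout the package.
#'
#' @param length Contig length in bp (> 0).
#' @param gc_content GC fraction in \[0, 1\].
#' @param seed Integer seed; the same arguments always yield the same genome.
#' @param chrom Contig name, default `"chr1"`.
#' @return Named character vector of length 1.
#' @examples
#' g <- generate_genome(1000, 0.5, seed = 1)
#' nchar(g)
#' @export
generate_genome <- function(length, gc_content, seed, chrom = "chr1") {
  if (!is.numeric(length) || length(length) != 1 || length < 1) {
    stop("length must be a positive integer", call. = FALSE)
  }
  if (gc_content < 0 || gc_content > 1) {
    stop("gc_content must lie in [0, 1]", call. = FALSE)
  }
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
         (1 - gc_content) / 2)
  seq <- withr::with_seed(
    seed,
    paste(sample(BASES, as.integer(length), replace = TRUE, prob = p),
          collapse = "")
  )
  stats::setNames(seq, chrom)
}

#' Write / read a genome as FASTA
#'
#' 60-column wrapped FASTA via Biostrings.
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output (or input) FASTA path.
#' @return `write_genome_fasta()` returns `path` invisibly;
#'   `read_genome_fasta()` returns a named character vector.
#' @importFrom Biostrings DNAStringSet writeXStringSet readDNAStringSet
#' @export
write_genome_fasta <- function(genome, path) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path,
                              width = 60)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Plant guide target and off-target sites into a genome
#'
#' Writes protospacer + PAM placements (strand-aware) into a genome at
#' randomly chosen, well-separated positions. Each planted 20-mer is at the
#' requested Hamming distance from the guide protospacer and is followed (in
#' protospacer orientation) by a concrete PAM matching the guide's pattern.
#' The blunt-cut breakpoint sits 3 bp upstream of the PAM: for a plus-strand
#' protospacer at \[s, s+20) the breakpoint coordinate is `s + 17`; minus
#' strand mirrored.
#'
#' After planting, the genome is scanned for chance placements at up to
#' `max(mismatches)` and any unintended hit has its PAM disrupted, so the
#' planted truth set is exactly the set of matches the genome contains.
#'
#' @param genome Named character vector (sites are planted into the first
#'   contig).
#' @param guide A [guide_rna()].
#' @param site_spec Data frame with columns `mismatches` (integer >= 0),
#'   `strand` (`"+"`/`"-"`), `affinity_K` (nM at which cleavage probability
#'   is 0.5).
#' @param seed Integer seed.
#' @param min_separation Minimum distance between planted placements (bp).
#' @param edge_margin Minimum distance from contig ends (bp).
#' @return List with `genome` (modified) and `sites`, a data frame of planted
#'   sites: `chrom`, `protospacer_start` (0-based forward start of the
#'   20-mer), `strand`, `mismatches`, `affinity_K`, `cut_position` (0-based
#'   breakpoint), `name`, `sequence` (23-mer in protospacer orientation).
#' @export
plant_sites <- function(genome, guide, site_spec, seed,
                        min_separation = 200, edge_margin = 100) {
  genome <- as_genome(genome)
  stopifnot(inherits(guide, "guide_rna"),
            all(c("mismatches", "strand", "affinity_K") %in% names(site_spec)))
  chrom <- names(genome)[1]
  L <- nchar(genome[[1]])
  n <- nrow(site_spec)
  if (L < 2 * edge_margin + 23 + (n - 1) * min_separation) {
    stop("genome too short to plant ", n, " sites ", min_separation,
         " bp apart", call. = FALSE)
  }

  withr::with_seed(derive_seed(seed, "plant"), {
    starts <- draw_separated_starts(n, L, min_separation, edge_margin)
    for (attempt in 1:40) {
      seqs <- character(n)
      planted <- vector("list", n)
      chrom_seq <- genome[[1]]
      for (i in seq_len(n)) {
        t0 <- starts[i]
        mm <- site_spec$mismatches[i]
        strand <- site_spec$strand[i]
        proto <- mutate_protospacer(guide$protospacer, mm)
        pam <- concretize_pam(guide$pam_pattern)
        site23 <- paste0(proto, pam)
        insert <- if (strand == "+") site23 else revcomp(site23)
        substr(chrom_seq, t0 + 1, t0 + 23) <- insert
        planted[[i]] <- data.frame(
          chrom = chrom,
          protospacer_start = if (strand == "+") t0 else t0 + 3L,
          strand = strand,
          mismatches = mm,
          affinity_K = site_spec$affinity_K[i],
          cut_position = if (strand == "+") t0 + 17L else t0 + 6L,
          name = sprintf("site_%02d_mm%d", i, mm),
          sequence = site23,
          stringsAsFactors = FALSE
        )
      }
      sites <- do.call(rbind, planted)
      genome[1] <- chrom_seq
      genome <- scrub_unintended(genome, guide, sites,
                                 max_mm = max(site_spec$mismatches))
      if (!is.null(genome)) break
      if (attempt == 40) {
        stop("could not plant sites without unintended matches; try another ",
             "seed or a longer genome", call. = FALSE)
      }
    }
    list(genome = genome, sites = sites)
  })
}

draw_separated_starts <- function(n, L, min_separation, edge_margin) {
  lo <- edge_margin
  hi <- L - edge_margin - 23
  for (try in 1:200) {
    starts <- sort(sample(lo:hi, n))
    if (n == 1 || all(diff(starts) >= min_separation)) return(starts)
  }
  stop("genome too short to place ", n, " sites ", min_separation,
       " bp apart", call. = FALSE)
}

# exactly `mm` substitutions at distinct positions, each to a different base
mutate_protospacer <- function(protospacer, mm) {
  b <- strsplit(protospacer, "", fixed = TRUE)[[1]]
  if (mm > 0) {
    at <- sample(20L, mm)
    for (j in at) b[j] <- sample(setdiff(BASES, b[j]), 1)
  }
  paste(b, collapse = "")
}

concretize_pam <- function(pattern) {
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  paste(vapply(p, function(code) {
    set <- IUPAC[[code]]
    if (length(set) == 1) set else sample(set, 1)
  }, character(1)), collapse = "")
}

# Remove chance matches <= max_mm that are not planted sites by mutating one
# PAM base per hit. Returns the cleaned genome, or NULL if a hit overlapping a
# planted placement could not be disrupted (caller re-draws mismatch
# placements).
scrub_unintended <- function(genome, guide, sites, max_mm) {
  planted_iv <- cbind(ifelse(sites$strand == "+",
                             sites$protospacer_start,
                             sites$protospacer_start - 3L),
                      0L)
  planted_iv[, 2] <- planted_iv[, 1] + 23L
  key <- paste(sites$protospacer_start, sites$strand)
  for (iter in 1:30) {
    hits <- enumerate_genome_matches(genome, guide, max_mm)
    bad <- hits[!(paste(hits$position, hits$strand) %in% key), , drop = FALSE]
    if (nrow(bad) == 0) return(genome)
    chrom_seq <- genome[[1]]
    fixed_any <- FALSE
    for (r in seq_len(nrow(bad))) {
      # the two guaranteed-G (or pattern-fixed) PAM bases of the placement
      p <- bad$position[r]
      pam_pos <- if (bad$strand[r] == "+") c(p + 21L, p + 22L)
                 else c(p - 3L, p - 2L)
      pam_pos <- pam_pos[!vapply(pam_pos, function(x) {
        any(x >= planted_iv[, 1] & x < planted_iv[, 2])
      }, logical(1))]
      if (length(pam_pos) == 0) next
      x <- pam_pos[1]
      cur <- subseq0(chrom_seq, x, x + 1)
      repl <- if (cur == "A") "T" else "A"
      substr(chrom_seq, x + 1, x + 1) <- repl
      fixed_any <- TRUE
    }
    genome[1] <- chrom_seq
    if (!fixed_any) return(NULL)
  }
  NULL
}
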