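#' Merge site sets across replicates or methods
#'
#' Single-linkage clustering of sites from several experiments: two sites
#' join the same merged row when they lie on the same chromosome within
#' `tolerance` bp (directly or through intermediates). The representative
#' coordinate is the position of the highest-scoring member (ties broken
#' leftmost). Strand is ignored: a cleavage site is a genomic breakpoint and
#' the matched protospacer strand is annotation.
#'
#' @param sets Named list of site data frames (BED6+, with `chrom`, `start`,
#'   `score`).
#' @param tolerance Maximum distance (bp) for two sites to be considered the
#'   same breakpoint (default 5, covering caller jitter plus end
#'   heterogeneity).
#' @return Data frame of class `membership_matrix`: `chrom`, `position`,
#'   `n_members`, one `present_<set>` logical and one `score_<set>` column
#'   per input. Set names are kept in `attr(, "set_names")`.
#' @export
merge_site_sets <- function(sets, tolerance = 5) {
  stopifnot(is.list(sets), length(sets) >= 1, tolerance >= 0)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  chrom_sets <- lapply(sets, function(s) unique(s$chrom))
  nonempty <- which(vapply(chrom_sets, length, 0L) > 0)
  if (length(nonempty) >= 2 &&
      length(Reduce(intersect, chrom_sets[nonempty])) == 0) {
    stop("site sets share no chromosome names; are they on the same ",
         "assembly?", call. = FALSE)
  }
  all <- data.table::rbindlist(lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    data.table::data.table(chrom = as.character(s$chrom),
                           pos = as.integer(s$start),
                           score = if ("score" %in% names(s))
                                     as.numeric(s$score)
                                   else NA_real_,
                           set = nm)
  }))
  set_names <- names(sets)
  if (nrow(all) == 0) {
    out <- data.frame(chrom = character(), position = integer(),
                      n_members = integer())
    for (nm in set_names) {
      out[[paste0("present_", nm)]] <- logical(0)
      out[[paste0("score_", nm)]] <- numeric(0)
    }
    attr(out, "set_names") <- set_names
    class(out) <- c("membership_matrix", "data.frame")
    return(out)
  }
  data.table::setorder(all, chrom, pos)
  all[, cluster := cumsum(c(1L, (diff(pos) > tolerance) |
                                 (chrom[-1] != chrom[-.N])))]
  rows <- all[, {
    best <- which(score == suppressWarnings(max(score, na.rm = TRUE)))
    rep_pos <- if (all(is.na(score))) pos[1] else pos[min(best)]
    flags <- lapply(set_names, function(nm) nm %in% set)
    scores <- lapply(set_names, function(nm) {
      sc <- score[set == nm]
      if (!length(sc) || all(is.na(sc))) NA_real_ else max(sc, na.rm = TRUE)
    })
    c(list(chrom = chrom[1], position = rep_pos, n_members = .N),
      stats::setNames(flags, paste0("present_", set_names)),
      stats::setNames(scores, paste0("score_", set_names)))
  }, by = cluster][, cluster := NULL]
  out <- as.data.frame(rows)
  out <- out[order(out$chrom, out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "set_names") <- set_names
  class(out) <- c("membership_matrix", "data.frame")
  out
}

#' Combination counts (UpSet modes)
#'
#' Counts merged sites per input combination. In `distinct` mode a row counts
#' toward the combination it matches exactly (present in those inputs and no
#' others), so counts over all combinations partition the merged rows; in
#' `intersect` mode a row counts toward every combination it contains.
#'
#' @param matrix A `membership_matrix` from [merge_site_sets()].
#' @param mode `"distinct"` or `"intersect"`.
#' @return Data frame: `combination` (names joined by `+`), `n_sets`,
#'   `count`, over all non-empty input combinations.
#' @export
combination_counts <- function(matrix, mode = c("distinct", "intersect")) {
  mode <- match.arg(mode)
  set_names <- attr(matrix, "set_names")
  if (length(set_names) < 2) stop(">= 2 input sets required", call. = FALSE)
  pres <- as.matrix(matrix[, paste0("present_", set_names), drop = FALSE])
  k <- length(set_names)
  combos <- lapply(seq_len(2^k - 1), function(bits) {
    as.logical(bitwAnd(bits, 2^(seq_len(k) - 1)) > 0)
  })
  rows <- lapply(combos, function(sel) {
    count <- if (nrow(pres) == 0) 0L else if (mode == "distinct") {
      sum(apply(pres, 1, function(r) all(r == sel)))
    } else {
      sum(apply(pres, 1, function(r) all(r[sel])))
    }
    data.frame(combination = paste(set_names[sel], collapse = "+"),
               n_sets = sum(sel), count = as.integer(count))
  })
  out <- do.call(rbind, rows)
  out[order(out$n_sets, out$combination), , drop = FALSE]
}

#' Score correlation between two experiments
#'
#' Pearson correlation of site scores over shared sites (after tolerance
#' merging), as used to assess replicate reproducibility. Amplification-free
#' replicate libraries from the same digest are expected to correlate with
#' R^2 above ~0.9.
#'
#' @param x Either a two-set `membership_matrix` or a site data frame.
#' @param y Second site data frame when `x` is one.
#' @param shared_only Correlate only sites present in both inputs (default);
#'   otherwise absent sites enter with score 0.
#' @param tolerance Merge tolerance in bp when `x`/`y` are site sets.
#' @return List: `r` (Pearson), `r_squared`, `n_shared`.
#' @export
score_correlation <- function(x, y = NULL, shared_only = TRUE,
                              tolerance = 5) {
  if (!inherits(x, "membership_matrix")) {
    stopifnot(!is.null(y))
    x <- merge_site_sets(list(a = x, b = y), tolerance = tolerance)
  }
  set_names <- attr(x, "set_names")
  if (length(set_names) != 2) {
    stop("score_correlation needs exactly two sets", call. = FALSE)
  }
  sa <- x[[paste0("score_", set_names[1])]]
  sb <- x[[paste0("score_", set_names[2])]]
  pa <- x[[paste0("present_", set_names[1])]]
  pb <- x[[paste0("present_", set_names[2])]]
  if (shared_only) {
    keep <- pa & pb
    sa <- sa[keep]; sb <- sb[keep]
  } else {
    sa[!pa] <- 0; sb[!pb] <- 0
  }
  n <- length(sa)
  if (n < 3) {
    stop("insufficient shared sites for correlation (need >= 3, have ", n,
         ")", call. = FALSE)
  }
  r <- stats::cor(sa, sb)
  list(r = r, r_squared = r^2, n_shared = n)
}
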