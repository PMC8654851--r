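#' Read and write cleavage-site sets (BED6+ TSV)
#'
#' Site sets are plain data frames in BED6+ layout: `chrom`, `start`, `end`,
#' `name`, `score`, `strand`, followed by any extra annotation columns (the
#' caller adds `mismatches`, `matched_seq`, `fwd_ends`, `rev_ends`). Each
#' record is a single breakpoint, so `end == start + 1` is enforced.
#' Coordinates are 0-based half-open on disk and in memory. A `#`-prefixed
#' header names the columns; `write_sites()` then `read_sites()` is the
#' identity on all fields.
#'
#' @param path TSV path.
#' @param sites Site data frame.
#' @return `read_sites()` returns a data frame; `write_sites()` returns
#'   `path` invisibly.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  body_at <- 1L
  if (length(lines) && startsWith(lines[1], "#")) {
    cols <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
    body_at <- 2L
  }
  body <- lines[seq_along(lines) >= body_at & nzchar(lines)]
  if (length(body) == 0) {
    out <- as.data.frame(stats::setNames(
      replicate(length(cols), character(0), simplify = FALSE), cols))
    out$start <- integer(0); out$end <- integer(0)
    return(out)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(cols))) {
    stop("malformed site record at line ",
         body_at - 1L + which(nf != length(cols))[1],
         ": expected ", length(cols), " fields", call. = FALSE)
  }
  m <- do.call(rbind, fields)
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- cols
  for (cc in c("start", "end")) {
    v <- suppressWarnings(as.integer(out[[cc]]))
    if (anyNA(v)) {
      stop("malformed coordinate at line ",
           body_at - 1L + which(is.na(v))[1], " (column ", cc, ")",
           call. = FALSE)
    }
    out[[cc]] <- v
  }
  bad <- which(out$end != out$start + 1L)
  if (length(bad)) {
    stop("site record at line ", body_at - 1L + bad[1],
         " has end != start + 1 (a site is a single breakpoint)",
         call. = FALSE)
  }
  for (cc in setdiff(cols, c("chrom", "start", "end", "name", "strand"))) {
    out[[cc]] <- utils::type.convert(ifelse(out[[cc]] == ".", NA, out[[cc]]),
                                     as.is = TRUE)
  }
  out
}

#' @rdname read_sites
#' @export
write_sites <- function(sites, path) {
  stopifnot(all(c("chrom", "start", "end", "name", "score", "strand")
                %in% names(sites)))
  lead <- c("chrom", "start", "end", "name", "score", "strand")
  sites <- sites[, c(lead, setdiff(names(sites), lead)), drop = FALSE]
  con <- file(path, "w")
  writeLines(paste0("#", paste(names(sites), collapse = "\t")), con)
  if (nrow(sites) > 0) {
    m <- vapply(sites, function(col) {
      v <- as.character(col)
      ifelse(is.na(v), ".", v)
    }, character(nrow(sites)))
    if (nrow(sites) == 1) m <- matrix(m, nrow = 1)
    writeLines(apply(m, 1, paste, collapse = "\t"), con)
  }
  close(con)
  invisible(path)
}
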