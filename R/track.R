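#' Genome track objects
#'
#' A track is a set of genomic stretches (intervals) or points of one
#' feature type. Coordinates are BED-style: 0-based, half-open, so a
#' stretch spans `[start, end)` with `length = end - start`. A point is a
#' degenerate stretch with `start == end` and zero length. The anchor used
#' for ordering and all distance computations is the center
#' `(start + end) / 2`, which may be half-integer and is never rounded.
#'
#' @param elements data.frame with columns `chrom`, `start`, `end` and
#'   optionally `strand`.
#' @param name track label used in reports.
#' @param role `"A"` or `"B"`; fixed for one analysis.
#' @return An object of class `coloc_track`: a list with `name`, `role`,
#'   `is_point_track` and `elements`, a data.frame with columns `chrom`,
#'   `start`, `end`, `strand`, `center`, `length`, sorted by chromosome
#'   and center.
#' @export
coloc_track <- function(elements, name = "track", role = c("A", "B")) {
  role <- match.arg(role)
  stopifnot(is.data.frame(elements),
            all(c("chrom", "start", "end") %in% names(elements)))
  if (nrow(elements) == 0L) stop("track '", name, "' has no elements")
  if (is.null(elements$strand)) elements$strand <- "*"
  bad <- which(elements$end < elements$start)
  if (length(bad) > 0L)
    stop("track '", name, "': end < start at element(s) ",
         paste(head(bad, 5L), collapse = ", "))
  el <- data.frame(chrom  = as.character(elements$chrom),
                   start  = as.numeric(elements$start),
                   end    = as.numeric(elements$end),
                   strand = as.character(elements$strand),
                   stringsAsFactors = FALSE)
  el$center <- (el$start + el$end) / 2
  el$length <- el$end - el$start
  el <- el[order(el$chrom, el$center, el$start), , drop = FALSE]
  rownames(el) <- NULL
  dup <- duplicated(el[c("chrom", "start", "end")])
  if (any(dup))
    warning("track '", name, "': ", sum(dup),
            " duplicate element(s) kept as-is (no merging)")
  structure(list(name = name, role = role,
                 is_point_track = all(el$length == 0),
                 elements = el),
            class = "coloc_track")
}

#' Read a genome track from a BED file
#'
#' Reads BED3+ (plain or gzip-compressed). Only the first three columns
#' plus, when present, the strand column (column 6) are used. Lines
#' starting with `track`, `browser` or `#` are skipped. Chromosome names
#' are taken verbatim.
#'
#' @param path path to a BED or BED.gz file.
#' @param name track label; defaults to the file name.
#' @param role `"A"` or `"B"`.
#' @param strand_filter optional `"+"` or `"-"`; elements on the other
#'   strand are dropped (requires a BED6+ file).
#' @return A [coloc_track()].
#' @export
read_bed <- function(path, name = basename(path), role = c("A", "B"),
                     strand_filter = NULL) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  lines <- readLines(con)
  close(con)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  line_no <- which(keep)
  if (!any(keep)) stop("BED file '", path, "' has no data lines")
  dt <- tryCatch(
    data.table::fread(text = lines[keep], header = FALSE, sep = "\t",
                      fill = TRUE, data.table = FALSE,
                      colClasses = list(character = 1L)),
    error = function(e) stop("failed to parse BED file '", path, "': ",
                             conditionMessage(e)))
  if (ncol(dt) < 3L)
    stop("BED file '", path, "' has fewer than 3 columns")
  for (j in 2:3) {
    v <- suppressWarnings(as.numeric(dt[[j]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad) > 0L)
      stop("malformed BED line ", line_no[bad[1L]], " in '", path,
           "': column ", j, " is not a non-negative integer")
    dt[[j]] <- v
  }
  bad <- which(dt[[3L]] < dt[[2L]])
  if (length(bad) > 0L)
    stop("malformed BED line ", line_no[bad[1L]], " in '", path,
         "': end < start")
  strand <- if (ncol(dt) >= 6L) as.character(dt[[6L]]) else
    rep("*", nrow(dt))
  if (!is.null(strand_filter)) {
    strand_filter <- match.arg(strand_filter, c("+", "-"))
    keep <- strand == strand_filter
    dt <- dt[keep, , drop = FALSE]
    strand <- strand[keep]
    if (nrow(dt) == 0L)
      stop("track '", name, "' is empty after strand filtering")
  }
  coloc_track(data.frame(chrom = dt[[1L]], start = dt[[2L]], end = dt[[3L]],
                         strand = strand, stringsAsFactors = FALSE),
              name = name, role = role)
}

#' Write a track to a BED file
#'
#' Writes `chrom`, `start`, `end` (BED3) plus name, score and strand
#' columns when the strand is informative.
#'
#' @param track a [coloc_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(track, path) {
  stopifnot(inherits(track, "coloc_track"))
  el <- track$elements
  df <- data.frame(el$chrom, format(el$start, scientific = FALSE, trim = TRUE),
                   format(el$end, scientific = FALSE, trim = TRUE))
  if (any(el$strand %in% c("+", "-")))
    df <- cbind(df, ".", 0L, el$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-track length statistics
#'
#' Mean, sample standard deviation (denominator n - 1) and coefficient of
#' variation CV = sd/mean of stretch lengths, computed genome-wide. The
#' permutation test is only informative when lengths vary; tracks whose CV
#' falls at or below the analysis threshold are reduced to points. For a
#' point track (all lengths zero) the CV is undefined and returned as
#' `NA`.
#'
#' @param track a [coloc_track()].
#' @return list with `n_elements`, `mean_length`, `sd_length`, `cv`.
#' @export
compute_track_stats <- function(track) {
  stopifnot(inherits(track, "coloc_track"))
  len <- track$elements$length
  n <- length(len)
  m <- mean(len)
  s <- if (n > 1L) sd(len) else 0
  cv <- if (m > 0) s / m else NA_real_
  list(n_elements = n, mean_length = m, sd_length = s, cv = cv)
}

#' Reduce a stretch track to a point track
#'
#' Replaces every stretch with a zero-length element at the chosen anchor
#' (start, center or end). Used when a track fails the length-variability
#' criterion, or to analyze stretch-point coverage directly.
#'
#' @param track a [coloc_track()].
#' @param anchor one of `"center"`, `"start"`, `"end"`.
#' @return A point [coloc_track()].
#' @export
reduce_to_points <- function(track, anchor = c("center", "start", "end")) {
  stopifnot(inherits(track, "coloc_track"))
  anchor <- match.arg(anchor)
  el <- track$elements
  pos <- switch(anchor, center = el$center, start = el$start, end = el$end)
  out <- track
  out$elements$start <- pos
  out$elements$end <- pos
  out$elements$center <- pos
  out$elements$length <- 0
  out$is_point_track <- TRUE
  out
}

#' @export
print.coloc_track <- function(x, ...) {
  cat(sprintf("<coloc_track '%s'> role %s: %d element(s) on %d chromosome(s)%s\n",
              x$name, x$role, nrow(x$elements),
              length(unique(x$elements$chrom)),
              if (x$is_point_track) " [points]" else ""))
  invisible(x)
}
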