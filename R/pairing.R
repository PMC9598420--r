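#' Merge two tracks on one chromosome into a labelled sequence
#'
#' Elements of both tracks on `chrom` are pooled and sorted by center
#' coordinate; on an exact center tie the A element precedes the B
#' element (deterministic pairing).
#'
#' @param track_a,track_b [coloc_track()] objects with roles A and B.
#' @param chrom chromosome name.
#' @return data.frame with columns `label` ("A"/"B"), `center`, `start`,
#'   `end`, `length`, `idx` (row index into the source track's element
#'   table), sorted by center. Zero rows if the chromosome is missing
#'   from either track.
#' @export
merge_and_label <- function(track_a, track_b, chrom) {
  ea <- track_a$elements
  eb <- track_b$elements
  ia <- which(ea$chrom == chrom)
  ib <- which(eb$chrom == chrom)
  if (length(ia) == 0L || length(ib) == 0L)
    return(data.frame(label = character(), center = numeric(),
                      start = numeric(), end = numeric(),
                      length = numeric(), idx = integer()))
  seqd <- data.frame(
    label  = c(rep("A", length(ia)), rep("B", length(ib))),
    center = c(ea$center[ia], eb$center[ib]),
    start  = c(ea$start[ia], eb$start[ib]),
    end    = c(ea$end[ia], eb$end[ib]),
    length = c(ea$length[ia], eb$length[ib]),
    idx    = c(ia, ib),
    stringsAsFactors = FALSE)
  # A-before-B on exact center ties
  seqd <- seqd[order(seqd$center, seqd$label), , drop = FALSE]
  rownames(seqd) <- NULL
  seqd
}

# Pair extraction on one labelled sequence. Two disjoint classes:
#
# ABA_BAB: an interior element whose two flanking neighbors are both of
#   the opposite type is paired with the nearer flank (center distance;
#   tie -> upstream flank). Mutual selections deduplicate to one pair.
#
# AABB_BBAA: an adjacent opposite-type pair (i, i+1) whose outer
#   neighbors are same-type as their adjacent member (a chromosome
#   boundary counts as same-type). These are junction pairs between
#   same-type runs and can never coincide with an ABA_BAB pair.
.extract_pairs_seq <- function(seqd) {
  n <- nrow(seqd)
  empty <- data.frame(i = integer(), j = integer(),
                      pair_class = character(), stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  lab <- seqd$label
  ctr <- seqd$center
  out <- list()
  if (n >= 3L) {
    mid <- 2:(n - 1L)
    is_middle <- lab[mid - 1L] != lab[mid] & lab[mid + 1L] != lab[mid]
    mid <- mid[is_middle]
    if (length(mid) > 0L) {
      d_up <- ctr[mid] - ctr[mid - 1L]
      d_dn <- ctr[mid + 1L] - ctr[mid]
      flank <- ifelse(d_up <= d_dn, mid - 1L, mid + 1L)  # tie -> upstream
      i <- pmin(mid, flank)
      j <- pmax(mid, flank)
      keep <- !duplicated(cbind(i, j))
      out$aba <- data.frame(i = i[keep], j = j[keep],
                            pair_class = "ABA_BAB",
                            stringsAsFactors = FALSE)
    }
  }
  adj <- 1:(n - 1L)
  opp <- lab[adj] != lab[adj + 1L]
  # outer neighbors same-type as their adjacent member, or boundary
  left_ok <- c(TRUE, if (n > 2L) lab[seq_len(n - 2L)] == lab[2:(n - 1L)])
  right_ok <- c(if (n > 2L) lab[3:n] == lab[2:(n - 1L)], TRUE)
  sel <- adj[opp & left_ok & right_ok]
  if (length(sel) > 0L)
    out$aabb <- data.frame(i = sel, j = sel + 1L, pair_class = "AABB_BBAA",
                           stringsAsFactors = FALSE)
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Extract nearest-neighbor (A, B) pairs on one chromosome
#'
#' Builds both colocalization pair classes from the merged, center-sorted
#' sequence of A and B elements: the ABA-BAB class (an element flanked on
#' both sides by the opposite type, matched to its nearer flank) and the
#' AABB-BBAA class (adjacent opposite-type pairs at junctions between
#' same-type runs). The two classes are disjoint by construction and are
#' analyzed separately.
#'
#' @param seqd labelled sequence from [merge_and_label()].
#' @param chrom chromosome name recorded in the output.
#' @return data.frame with one row per pair: `chrom`, `pair_class`,
#'   `a_idx`, `b_idx` (element rows in the source tracks), `a_start`,
#'   `a_end`, `b_start`, `b_end`, `L` (center distance), `a`, `b`
#'   (lengths).
#' @export
extract_pairs <- function(seqd, chrom = "chr") {
  sel <- .extract_pairs_seq(seqd)
  if (nrow(sel) == 0L)
    return(data.frame(chrom = character(), pair_class = character(),
                      a_idx = integer(), b_idx = integer(),
                      a_start = numeric(), a_end = numeric(),
                      b_start = numeric(), b_end = numeric(),
                      L = numeric(), a = numeric(), b = numeric(),
                      stringsAsFactors = FALSE))
  ai <- ifelse(seqd$label[sel$i] == "A", sel$i, sel$j)
  bi <- ifelse(seqd$label[sel$i] == "A", sel$j, sel$i)
  stopifnot(all(seqd$label[ai] == "A"), all(seqd$label[bi] == "B"))
  data.frame(chrom = chrom, pair_class = sel$pair_class,
             a_idx = seqd$idx[ai], b_idx = seqd$idx[bi],
             a_start = seqd$start[ai], a_end = seqd$end[ai],
             b_start = seqd$start[bi], b_end = seqd$end[bi],
             L = abs(seqd$center[bi] - seqd$center[ai]),
             a = seqd$length[ai], b = seqd$length[bi],
             stringsAsFactors = FALSE)
}

#' Extract pairs for all shared chromosomes of two tracks
#'
#' @param track_a,track_b [coloc_track()] objects (roles A and B).
#' @return data.frame as in [extract_pairs()], rows for all chromosomes
#'   present in both tracks, in natural chromosome order.
#' @export
track_pairs <- function(track_a, track_b) {
  stopifnot(inherits(track_a, "coloc_track"),
            inherits(track_b, "coloc_track"))
  chroms <- intersect(unique(track_a$elements$chrom),
                      unique(track_b$elements$chrom))
  chroms <- chroms[order_chromosomes(chroms)]
  empty <- extract_pairs(merge_and_label(track_a, track_b, "\x01none"))
  res <- lapply(chroms, function(ch)
    extract_pairs(merge_and_label(track_a, track_b, ch), chrom = ch))
  out <- do.call(rbind, c(list(empty), res))
  rownames(out) <- NULL
  out
}

#' Natural ordering permutation for chromosome names
#'
#' Orders chr1, chr2, ..., chr10 numerically where possible, with
#' non-numeric names (chrX, chrY, chrM) after, alphabetically.
#'
#' @param chroms character vector of chromosome names.
#' @return integer permutation such that `chroms[order_chromosomes(chroms)]`
#'   is in natural order.
#' @export
order_chromosomes <- function(chroms) {
  num <- suppressWarnings(as.numeric(sub("^chr", "", chroms)))
  order(is.na(num), num, chroms)
}

#' Fraction of a track's elements participating in each pair class
#'
#' Genome-wide class shares: for each pair class, the fraction of the
#' given track's elements that appear in at least one pair of that class.
#' Used with the smaller of the two input tracks to decide which class
#' carries most of the signal when class conclusions diverge.
#'
#' @param pairs pair table from [track_pairs()].
#' @param track the track whose share is measured.
#' @param role `"A"` or `"B"`: which side of the pairs `track` occupies.
#' @return named numeric vector with entries `ABA_BAB` and `AABB_BBAA`.
#' @export
class_share <- function(pairs, track, role = c("A", "B")) {
  role <- match.arg(role)
  idx_col <- if (role == "A") "a_idx" else "b_idx"
  n <- nrow(track$elements)
  vapply(c(ABA_BAB = "ABA_BAB", AABB_BBAA = "AABB_BBAA"), function(cl) {
    p <- pairs[pairs$pair_class == cl, , drop = FALSE]
    length(unique(paste(p$chrom, p[[idx_col]]))) / n
  }, numeric(1L))
}
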