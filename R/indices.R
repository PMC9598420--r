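#' Colocalization indices for nearest-neighbor pairs
#'
#' All indices are dimensionless and vary in (-1, 1): -1 is complete
#' colocalization (coincident centers), values near +1 mean remote,
#' unrelated features. For a pair with center distance `L` and stretch
#' lengths `a` (type A) and `b` (type B):
#'
#' * overlap index `IO = (L - (a+b)/2) / (L + (a+b)/2)` — negative
#'   exactly when the two stretches physically overlap, zero when they
#'   are edge-touching;
#' * asymmetry index `IA = (a - b) / (a + b)` — length skew between the
#'   paired stretches, antisymmetric under swapping the track roles;
#' * coverage index `IC = (L - a/2) / (L + a/2)` — stretch-vs-point
#'   colocalization, negative exactly when the point lies strictly
#'   inside the stretch.
#'
#' Inputs are vectorized; no clamping or rounding is applied.
#'
#' @param L non-negative center distance(s) in bp.
#' @param a,b stretch length(s) in bp.
#' @return numeric vector of index values.
#' @name indices
NULL

#' @rdname indices
#' @export
index_overlap <- function(L, a, b) {
  if (any(a + b <= 0))
    stop("index_overlap requires a + b > 0 (stretch-stretch pairs)")
  (L - (a + b) / 2) / (L + (a + b) / 2)
}

#' @rdname indices
#' @export
index_asymmetry <- function(a, b) {
  if (any(a + b <= 0))
    stop("index_asymmetry requires a + b > 0")
  (a - b) / (a + b)
}

#' @rdname indices
#' @export
index_coverage <- function(L, a) {
  if (any(a <= 0))
    stop("index_coverage requires a > 0 (A must be a stretch)")
  (L - a / 2) / (L + a / 2)
}

#' Index values for a pair table
#'
#' @param pairs pair table from [track_pairs()] or [extract_pairs()].
#' @param kind `"IO"`, `"IA"` or `"IC"`.
#' @return numeric vector of per-pair index values.
#' @export
pair_index <- function(pairs, kind = c("IO", "IA", "IC")) {
  kind <- match.arg(kind)
  switch(kind,
         IO = index_overlap(pairs$L, pairs$a, pairs$b),
         IA = index_asymmetry(pairs$a, pairs$b),
         IC = index_coverage(pairs$L, pairs$a))
}

#' Mean and unbiased variance of an index series
#'
#' Arithmetic mean over the K pairs and the sample variance with
#' denominator K - 1. The variance is `NA` for K = 1.
#'
#' @param values per-pair index values.
#' @return list with `mean`, `variance`, `K`.
#' @export
summarize_index <- function(values) {
  K <- length(values)
  if (K < 1L) stop("empty index series")
  list(mean = mean(values),
       variance = if (K >= 2L) var(values) else NA_real_,
       K = K)
}
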