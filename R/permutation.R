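.perm_schemes <- c("perm_A", "perm_B", "perm_both", "perm_IA", "perm_IC")

.scheme_code <- function(scheme) {
  match(match.arg(scheme, .perm_schemes), .perm_schemes)
}

.scheme_index_kind <- function(scheme) {
  switch(scheme, perm_A = "IO", perm_B = "IO", perm_both = "IO",
         perm_IA = "IA", perm_IC = "IC")
}

#' Permuted index for one pair of pairs
#'
#' The complete permutation test swaps stretch lengths between the k-th
#' and k'-th nearest-neighbor pairs while keeping the center distances
#' fixed, and averages the index over the two swapped configurations:
#'
#' * `perm_A`: the type-A lengths are exchanged between the two pairs;
#' * `perm_B`: the type-B lengths are exchanged;
#' * `perm_both`: both lengths are exchanged simultaneously;
#' * `perm_IA`: asymmetry index with B lengths exchanged (both cross
#'   configurations averaged);
#' * `perm_IC`: coverage index with the stretch lengths exchanged.
#'
#' The value is symmetric under exchanging the two source pairs.
#'
#' @param pair_k,pair_k2 single-row pair records (lists or data.frame
#'   rows) with fields `L`, `a`, `b`.
#' @param scheme one of `"perm_A"`, `"perm_B"`, `"perm_both"`,
#'   `"perm_IA"`, `"perm_IC"`.
#' @return the permuted index value.
#' @export
permuted_index <- function(pair_k, pair_k2,
                           scheme = c("perm_A", "perm_B", "perm_both",
                                      "perm_IA", "perm_IC")) {
  scheme <- match.arg(scheme)
  L <- c(pair_k$L, pair_k2$L); a <- c(pair_k$a, pair_k2$a)
  b <- c(pair_k$b, pair_k2$b)
  switch(scheme,
    perm_A = mean(index_overlap(L, rev(a), b)),
    perm_B = mean(index_overlap(L, a, rev(b))),
    perm_both = mean(index_overlap(L, rev(a), rev(b))),
    perm_IA = mean(index_asymmetry(a, rev(b))),
    perm_IC = mean(index_coverage(L, rev(a))))
}

.check_scheme_kind <- function(index_kind, scheme, pairs) {
  need <- .scheme_index_kind(scheme)
  if (index_kind != need)
    stop("scheme ", scheme, " applies to index ", need, ", not ", index_kind)
  if (index_kind == "IC") {
    if (any(pairs$b != 0) || any(pairs$a <= 0))
      stop("IC requires stretch-point pairs (a > 0, b = 0)")
  } else {
    if (any(pairs$a + pairs$b <= 0))
      stop(index_kind, " requires stretch-stretch pairs (a + b > 0)")
  }
}

.perm_result <- function(pairs, index_kind, scheme, moments) {
  I <- pair_index(pairs, index_kind)
  K <- length(I)
  obs <- summarize_index(I)
  delta <- obs$mean - moments$permuted_mean
  sigma2_eff <- obs$variance / K + 2 * moments$permuted_variance / K -
    2 * moments$covariance
  zeta <- NA_real_
  note <- NULL
  if (is.finite(sigma2_eff) && sigma2_eff > 0) {
    zeta <- delta / sqrt(sigma2_eff)
  } else {
    note <- "effective variance <= 0; zeta undefined"
  }
  structure(list(index_kind = index_kind, scheme = scheme, K = K,
                 mean = obs$mean, variance = obs$variance,
                 permuted_mean = moments$permuted_mean,
                 permuted_variance = moments$permuted_variance,
                 covariance = moments$covariance,
                 delta = delta, sigma2_eff = sigma2_eff,
                 sigma_eff = if (is.finite(sigma2_eff) && sigma2_eff > 0)
                   sqrt(sigma2_eff) else NA_real_,
                 zeta = zeta,
                 n_permuted_pairs = moments$n_permuted_pairs,
                 note = note),
            class = "perm_result")
}

#' Complete permutation test for a pair set
#'
#' Evaluates all K(K-1)/2 unordered length swaps between nearest-neighbor
#' pairs (no sampling), accumulating the permuted mean, its unbiased
#' variance, and the covariance between observed and permuted indices in
#' a streaming pass. The result is the zeta statistic
#' `zeta = (mean(I) - mean_permuted(I)) / sigma_eff`, where
#' `sigma_eff^2 = var(I)/K + 2 var_p/K - 2 Cov`. Negative zeta means
#' stronger colocalization than the permuted configurations for the
#' overlap and coverage indices.
#'
#' @param pairs pair table (rows of one chromosome and one pair class).
#' @param index_kind `"IO"`, `"IA"` or `"IC"`; must match the scheme.
#' @param scheme permutation scheme, see [permuted_index()].
#' @param max_pairs hard cap on K; the complete test is quadratic in K
#'   and the cap guards against accidental huge inputs.
#' @return A `perm_result` list: observed and permuted moments,
#'   `delta`, `sigma_eff`, `zeta`, `K` and `n_permuted_pairs`. `zeta` is
#'   `NA` with a diagnostic `note` if the effective variance is not
#'   positive (degenerate input).
#' @export
complete_permutation <- function(pairs, index_kind = c("IO", "IA", "IC"),
                                 scheme = c("perm_both", "perm_A", "perm_B",
                                            "perm_IA", "perm_IC"),
                                 max_pairs = 1e5) {
  index_kind <- match.arg(index_kind)
  scheme <- match.arg(scheme)
  K <- nrow(pairs)
  if (K < 3L) stop("complete permutation requires K >= 3 pairs, got ", K)
  if (K > max_pairs)
    stop("K = ", K, " exceeds max_pairs = ", max_pairs,
         "; the complete test is O(K^2)")
  .check_scheme_kind(index_kind, scheme, pairs)
  I <- pair_index(pairs, index_kind)
  moments <- .perm_core(pairs$L, pairs$a, pairs$b, I, mean(I),
                        .scheme_code(scheme))
  .perm_result(pairs, index_kind, scheme, moments)
}

#' Brute-force complete permutation (test oracle)
#'
#' Materializes every permuted index value for all k < k' and evaluates
#' the moment formulas literally. Quadratic in memory; intended only for
#' validating [complete_permutation()] on small inputs.
#'
#' @inheritParams complete_permutation
#' @param max_pairs guard on K (default 2000).
#' @return A `perm_result`, as [complete_permutation()].
#' @export
brute_force_permutation <- function(pairs,
                                    index_kind = c("IO", "IA", "IC"),
                                    scheme = c("perm_both", "perm_A",
                                               "perm_B", "perm_IA",
                                               "perm_IC"),
                                    max_pairs = 2000) {
  index_kind <- match.arg(index_kind)
  scheme <- match.arg(scheme)
  K <- nrow(pairs)
  if (K < 3L) stop("complete permutation requires K >= 3 pairs, got ", K)
  if (K > max_pairs) stop("brute-force guard: K > ", max_pairs)
  .check_scheme_kind(index_kind, scheme, pairs)
  comb <- utils::combn(K, 2L)
  k <- comb[1L, ]; k2 <- comb[2L, ]
  L <- pairs$L; a <- pairs$a; b <- pairs$b
  vals <- switch(scheme,
    perm_A = (index_overlap(L[k], a[k2], b[k]) +
              index_overlap(L[k2], a[k], b[k2])) / 2,
    perm_B = (index_overlap(L[k], a[k], b[k2]) +
              index_overlap(L[k2], a[k2], b[k])) / 2,
    perm_both = (index_overlap(L[k], a[k2], b[k2]) +
                 index_overlap(L[k2], a[k], b[k])) / 2,
    perm_IA = (index_asymmetry(a[k], b[k2]) +
               index_asymmetry(a[k2], b[k])) / 2,
    perm_IC = (index_coverage(L[k], a[k2]) +
               index_coverage(L[k2], a[k])) / 2)
  M <- K * (K - 1) / 2
  I <- pair_index(pairs, index_kind)
  I_mean <- mean(I)
  mean_p <- sum(vals) / M
  var_p <- sum((vals - mean_p)^2) / (M - 1)
  cov <- 2 / (K^2 * (K - 1)) *
    sum(((I[k] - I_mean) + (I[k2] - I_mean)) * (vals - mean_p))
  .perm_result(pairs, index_kind, scheme,
               list(permuted_mean = mean_p, permuted_variance = var_p,
                    covariance = cov, n_permuted_pairs = M))
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf(
    "<perm_result %s/%s> K=%d  mean=%.5g  permuted=%.5g  delta=%.5g  zeta=%.5g\n",
    x$index_kind, x$scheme, x$K, x$mean, x$permuted_mean, x$delta, x$zeta))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
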