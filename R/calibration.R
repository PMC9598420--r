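# Draw per-realization sub-seeds from a master seed; keeps every stream
# reproducible and below .Machine$integer.max.
.sub_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a pair of random genome tracks
#'
#' The random-set model used throughout calibration and validation:
#' stretch centers i.i.d. uniform on the span, lengths i.i.d. uniform
#' integers on `[1, max_length]`, the two tracks independent, all on one
#' synthetic chromosome.
#'
#' @param span numeric length-2, minimum and maximum center coordinate
#'   in bp.
#' @param max_length maximum stretch length in bp (minimum is 1).
#' @param n_a,n_b element counts of the two tracks.
#' @param seed optional RNG seed (uses the current RNG state if `NULL`).
#' @param chrom chromosome name given to the simulated elements.
#' @return list of two [coloc_track()] objects with roles A and B.
#' @export
generate_random_track_pair <- function(span = c(0, 2e8), max_length = 1e4,
                                       n_a = 1000, n_b = 1000, seed = NULL,
                                       chrom = "sim") {
  stopifnot(length(span) == 2L, span[2] > span[1], n_a >= 1, n_b >= 1)
  if (max_length < 1) stop("max_length must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  mk <- function(n, role, nm) {
    center <- runif(n, span[1], span[2])
    len <- sample.int(max_length, n, replace = TRUE)
    coloc_track(data.frame(chrom = chrom, start = center - len / 2,
                           end = center + len / 2),
                name = nm, role = role)
  }
  list(A = mk(n_a, "A", "randomA"), B = mk(n_b, "B", "randomB"))
}

# Median ABA_BAB pair count over a few random realizations at counts n.
.mean_pair_count <- function(n, span, max_length, n_rep, seeds) {
  ks <- vapply(seq_len(n_rep), function(i) {
    tr <- generate_random_track_pair(span, max_length, n, n, seed = seeds[i])
    sum(track_pairs(tr$A, tr$B)$pair_class == "ABA_BAB")
  }, numeric(1L))
  mean(ks)
}

#' Tune the element count of random tracks to a target pair count
#'
#' Finds an element count n (used for both tracks) such that two random
#' tracks yield approximately `target_pairs` nearest-neighbor pairs of
#' the ABA-BAB class. Iterative proportional adjustment with a relative
#' tolerance.
#'
#' @inheritParams generate_random_track_pair
#' @param target_pairs desired pair count K.
#' @param tol relative tolerance on the mean realized K (default 0.05,
#'   half the 10 percent acceptance band so per-realization scatter
#'   stays inside it).
#' @param n_rep realizations averaged per candidate count.
#' @return integer element count.
#' @export
tune_element_count <- function(target_pairs, span = c(0, 2e8),
                               max_length = 1e4, seed = NULL, tol = 0.05,
                               n_rep = 5L) {
  stopifnot(target_pairs >= 3)
  seeds <- .sub_seeds(seed, 50L * n_rep)
  n <- max(8L, as.integer(2.4 * target_pairs))
  for (it in seq_len(50L)) {
    sds <- seeds[((it - 1L) * n_rep + 1L):(it * n_rep)]
    k_hat <- .mean_pair_count(n, span, max_length, n_rep, sds)
    if (k_hat >= 3 && abs(k_hat - target_pairs) / target_pairs <= tol)
      return(n)
    n <- max(8L, as.integer(round(n * target_pairs / max(k_hat, 1))))
  }
  stop("could not tune element count to ~", target_pairs,
       " pairs within tolerance")
}

#' Null sample of zeta statistics at fixed pair count
#'
#' Draws independent random track pairs tuned to approximately `K`
#' nearest-neighbor pairs, runs the complete permutation test on the
#' ABA-BAB pair set of each, and returns the zeta values. This is the
#' Monte-Carlo null used for threshold calibration and Gaussianity
#' diagnostics.
#'
#' @inheritParams generate_random_track_pair
#' @param K target nearest-neighbor pair count.
#' @param n_realizations number of independent realizations.
#' @param scheme permutation scheme (overlap schemes only).
#' @param index_kind index computed (`"IO"` default; `"IC"` reduces the
#'   B track to points).
#' @param n_elements optional pre-tuned element count; tuned from `K`
#'   when `NULL`.
#' @return numeric vector of zeta values with attribute `K_realized`
#'   (the per-realization pair counts).
#' @export
null_zeta_sample <- function(K, n_realizations, seed = NULL,
                             span = c(0, 2e8), max_length = 1e4,
                             scheme = "perm_both", index_kind = "IO",
                             n_elements = NULL) {
  stopifnot(K >= 3, n_realizations >= 1)
  seeds <- .sub_seeds(seed, n_realizations + 1L)
  if (is.null(n_elements))
    n_elements <- tune_element_count(K, span, max_length,
                                     seed = seeds[n_realizations + 1L])
  zeta <- numeric(n_realizations)
  k_real <- integer(n_realizations)
  for (i in seq_len(n_realizations)) {
    tr <- generate_random_track_pair(span, max_length, n_elements,
                                     n_elements, seed = seeds[i])
    if (index_kind == "IC") tr$B <- reduce_to_points(tr$B)
    pp <- track_pairs(tr$A, tr$B)
    pp <- pp[pp$pair_class == "ABA_BAB", , drop = FALSE]
    k_real[i] <- nrow(pp)
    zeta[i] <- if (nrow(pp) >= 3L)
      complete_permutation(pp, index_kind, scheme)$zeta else NA_real_
  }
  structure(zeta, K_realized = k_real, n_elements = n_elements)
}

#' Empirical |zeta| threshold at one pair count
#'
#' The (1 - level) quantile of |zeta| over Monte-Carlo null realizations
#' at pair count approximately K (quantile type 7: linear interpolation
#' of order statistics). Realizations whose pair count drifts outside
#' +/-10 percent of K are an error.
#'
#' @inheritParams null_zeta_sample
#' @param level tail probability (0.05 or 0.01).
#' @return the |zeta| quantile, with attribute `se` (asymptotic standard
#'   error of the quantile estimate).
#' @export
empirical_threshold <- function(K, level = 0.05, n_realizations = 1e4,
                                seed = NULL, span = c(0, 2e8),
                                max_length = 1e4, scheme = "perm_both") {
  stopifnot(n_realizations >= 1e3)
  z <- null_zeta_sample(K, n_realizations, seed = seed, span = span,
                        max_length = max_length, scheme = scheme)
  kr <- attr(z, "K_realized")
  if (abs(mean(kr) - K) / K > 0.1)
    stop("realized pair count ", round(mean(kr)),
         " outside 10% tolerance of target ", K)
  az <- abs(z[!is.na(z)])
  q <- unname(quantile(az, 1 - level, type = 7))
  # SE via the binomial/density approximation
  dens <- stats::density(az, n = 512)
  f_q <- stats::approx(dens$x, dens$y, xout = q, rule = 2)$y
  se <- sqrt(level * (1 - level) / length(az)) / max(f_q, .Machine$double.eps)
  structure(q, se = se)
}

#' Fit the saturating threshold-vs-K curve
#'
#' Least-squares fit of
#' `thr(K) = z_min + (z_max - z_min) * (1 + b / (K - K_min))`
#' to an empirical threshold grid. Since `z_min` enters only through the
#' products `z_max - z_min`, it is not separately identifiable and is
#' held fixed (default 0), leaving (z_max, b, K_min) free.
#'
#' @param k_grid pair counts (>= 4 points).
#' @param thresholds empirical |zeta| thresholds at `k_grid`.
#' @param z_min fixed offset parameter.
#' @return list with `z_min`, `z_max`, `b`, `k_min`, `residuals`, and
#'   `converged`; on non-convergence `converged = FALSE` and the curve
#'   parameters are `NA` (interpolation of the raw grid is then used).
#' @export
fit_threshold_curve <- function(k_grid, thresholds, z_min = 0) {
  stopifnot(length(k_grid) >= 4L, length(k_grid) == length(thresholds))
  df <- data.frame(K = as.numeric(k_grid), thr = as.numeric(thresholds))
  start <- list(z_max = min(df$thr),
                b = (max(df$thr) / min(df$thr) - 1) * min(df$K),
                k_min = 0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      thr ~ z_min + (z_max - z_min) * (1 + b / (K - k_min)),
      data = df, start = start,
      upper = c(z_max = Inf, b = Inf, k_min = min(df$K) - 1),
      lower = c(z_max = 0, b = -Inf, k_min = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(z_min = z_min, z_max = NA_real_, b = NA_real_,
                k_min = NA_real_, residuals = rep(NA_real_, nrow(df)),
                converged = FALSE))
  cf <- coef(fit)
  list(z_min = z_min, z_max = unname(cf["z_max"]), b = unname(cf["b"]),
       k_min = unname(cf["k_min"]),
       residuals = unname(stats::residuals(fit)), converged = TRUE)
}

.curve_eval <- function(fp, K) {
  fp$z_min + (fp$z_max - fp$z_min) * (1 + fp$b / (K - fp$k_min))
}

#' Calibrate |zeta| significance thresholds over a grid of pair counts
#'
#' For each K in the grid, draws `n_realizations` random track pairs,
#' computes the null zeta sample, and stores the empirical |zeta|
#' quantiles at the requested probability levels. A saturating curve is
#' fitted per level for interpolation; the Gaussian mapping factor
#' `lambda(K) = 1.96 / thr_0.05(K)` converts zeta values to approximate
#' standard-normal z-variables.
#'
#' The defaults (grid 50..5000, 1e4 realizations) reproduce a desk-scale
#' version of the full calibration; smaller grids are fine for targeted
#' analyses, as thresholds are approximately universal across indices
#' and schemes for random sets.
#'
#' @inheritParams null_zeta_sample
#' @param k_grid pair counts to calibrate at.
#' @param levels tail probabilities.
#' @return A `threshold_table` object.
#' @export
calibrate_thresholds <- function(k_grid = c(50, 100, 200, 400, 800, 1600,
                                            3200, 5000),
                                 levels = c(0.05, 0.01),
                                 n_realizations = 1e4, seed = NULL,
                                 span = c(0, 2e8), max_length = 1e4,
                                 scheme = "perm_both") {
  k_grid <- sort(as.numeric(k_grid))
  seeds <- .sub_seeds(seed, length(k_grid))
  thr <- matrix(NA_real_, length(levels), length(k_grid),
                dimnames = list(paste0("p", levels), paste0("K", k_grid)))
  se <- thr
  for (j in seq_along(k_grid)) {
    z <- null_zeta_sample(k_grid[j], n_realizations, seed = seeds[j],
                          span = span, max_length = max_length,
                          scheme = scheme)
    az <- abs(z[!is.na(z)])
    for (i in seq_along(levels)) {
      thr[i, j] <- unname(quantile(az, 1 - levels[i], type = 7))
      se[i, j] <- sqrt(levels[i] * (1 - levels[i]) / length(az))
    }
  }
  fits <- if (length(k_grid) >= 4L)
    lapply(seq_along(levels), function(i)
      fit_threshold_curve(k_grid, thr[i, ])) else
    replicate(length(levels), list(converged = FALSE), simplify = FALSE)
  structure(list(levels = levels, k_grid = k_grid, thresholds = thr,
                 quantile_se = se, fits = fits,
                 n_realizations = n_realizations, seed = seed,
                 span = span, max_length = max_length, scheme = scheme,
                 index_kind = "IO", version = 1L),
            class = "threshold_table")
}

#' Interpolated |zeta| threshold at a pair count
#'
#' Uses the fitted saturating curve when available, otherwise monotone
#' linear interpolation of the empirical grid. K below the calibrated
#' range is an error (extrapolating the steep small-K part is unsafe);
#' K above the range uses the curve/last grid value (the threshold is
#' flat there).
#'
#' @param table a `threshold_table`.
#' @param K pair count.
#' @param level one of the calibrated levels.
#' @return threshold value.
#' @export
threshold_at <- function(table, K, level = 0.05) {
  stopifnot(inherits(table, "threshold_table"))
  i <- match(level, table$levels)
  if (is.na(i)) stop("level ", level, " not calibrated")
  if (K < min(table$k_grid))
    stop("K = ", K, " below calibrated range [", min(table$k_grid), ", ",
         max(table$k_grid), "]; calibrate directly at this K")
  fp <- table$fits[[i]]
  if (isTRUE(fp$converged)) return(.curve_eval(fp, K))
  approx(table$k_grid, table$thresholds[i, ], xout = min(K, max(table$k_grid)),
         rule = 2)$y
}

#' Approximate p-value for an observed zeta
#'
#' Maps zeta onto a standard-normal scale with
#' `lambda(K) = 1.96 / thr_0.05(K)` and reports the two-sided Gaussian
#' tail probability of `lambda * |zeta|`, together with hard
#' significance flags from the calibrated 0.05 and 0.01 thresholds and
#' the colocalization direction (negative zeta = colocalized for the
#' overlap and coverage indices).
#'
#' @param table a calibrated `threshold_table` containing level 0.05.
#' @param K pair count of the analyzed set.
#' @param zeta observed zeta.
#' @return list with `p`, `lambda`, `lambda_zeta`, `significant_at`
#'   (`"none"`, `"0.05"` or `"0.01"`) and `direction`.
#' @export
approx_pvalue <- function(table, K, zeta) {
  stopifnot(inherits(table, "threshold_table"))
  if (!0.05 %in% table$levels)
    stop("threshold table must be calibrated at level 0.05")
  if (is.na(zeta))
    return(list(p = NA_real_, lambda = NA_real_, lambda_zeta = NA_real_,
                significant_at = "none", direction = NA_character_))
  thr05 <- threshold_at(table, K, 0.05)
  lambda <- 1.96 / thr05
  lz <- lambda * abs(zeta)
  p <- 2 * pnorm(-lz)
  sig <- "none"
  if (abs(zeta) > thr05) sig <- "0.05"
  if (0.01 %in% table$levels && abs(zeta) > threshold_at(table, K, 0.01))
    sig <- "0.01"
  list(p = p, lambda = lambda, lambda_zeta = lz, significant_at = sig,
       direction = if (zeta < 0) "colocalized" else "anti_colocalized")
}

#' Save / load a threshold table as versioned JSON
#'
#' Full provenance (grid, levels, seed, realization count, generator
#' settings, fit parameters) is serialized, so reloading reproduces
#' identical interpolation.
#'
#' @param table a `threshold_table`.
#' @param path JSON file path.
#' @return `save_threshold_table`: `path` invisibly;
#'   `load_threshold_table`: the restored `threshold_table`.
#' @export
save_threshold_table <- function(table, path) {
  stopifnot(inherits(table, "threshold_table"))
  obj <- unclass(table)
  obj$thresholds <- lapply(seq_along(obj$levels), function(i)
    unname(obj$thresholds[i, ]))
  obj$quantile_se <- lapply(seq_along(obj$levels), function(i)
    unname(obj$quantile_se[i, ]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_threshold_table
#' @export
load_threshold_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lv <- as.numeric(unlist(obj$levels))
  kg <- as.numeric(unlist(obj$k_grid))
  mk <- function(x) matrix(as.numeric(unlist(x)), nrow = length(lv),
                           byrow = TRUE,
                           dimnames = list(paste0("p", lv),
                                           paste0("K", kg)))
  out <- list(levels = lv, k_grid = kg,
              thresholds = mk(obj$thresholds),
              quantile_se = mk(obj$quantile_se),
              fits = lapply(obj$fits, function(f) {
                num1 <- function(x) if (is.null(x)) NA_real_ else
                  as.numeric(x)
                list(z_min = num1(f$z_min), z_max = num1(f$z_max),
                     b = num1(f$b), k_min = num1(f$k_min),
                     residuals = as.numeric(unlist(f$residuals)),
                     converged = isTRUE(as.logical(f$converged)))
              }),
              n_realizations = as.numeric(obj$n_realizations),
              seed = if (is.null(obj$seed)) NULL else as.numeric(obj$seed),
              span = as.numeric(unlist(obj$span)),
              max_length = as.numeric(obj$max_length),
              scheme = as.character(obj$scheme),
              index_kind = as.character(obj$index_kind),
              version = as.integer(obj$version))
  structure(out, class = "threshold_table")
}

#' @export
print.threshold_table <- function(x, ...) {
  cat(sprintf(
    "<threshold_table> scheme %s, %d realizations/K, K grid: %s\n",
    x$scheme, x$n_realizations, paste(x$k_grid, collapse = ", ")))
  print(round(x$thresholds, 4))
  invisible(x)
}
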