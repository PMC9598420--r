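# Spacing-entropy statistic for one sorted coordinate vector, computed
# on bins whose edges are the equal-probability quantiles of the null
# spacing distribution. For n i.i.d. uniform points the marginal of a
# consecutive spacing (relative to the span) is Beta(1, n), so the bin
# edges are 1 - (1 - j/nb)^(1/n). The statistic is scale- and
# shift-invariant, which lets the null moments be cached by n alone.
.spacing_entropy <- function(x_sorted, n_bins = 20L) {
  n <- length(x_sorted)
  span <- x_sorted[n] - x_sorted[1L]
  if (span <= 0) return(0)
  s <- diff(x_sorted) / span
  edges <- 1 - (1 - seq_len(n_bins - 1L) / n_bins)^(1 / n)
  cnt <- tabulate(findInterval(s, edges) + 1L, nbins = n_bins)
  p <- cnt / length(s)
  p <- p[p > 0]
  -sum(p * log(p))
}

.null_entropy_moments <- function(n, n_bins, n_null, seed) {
  key <- paste("ent", n, n_bins, n_null, seed, sep = "_")
  hit <- .tc_cache[[key]]
  if (!is.null(hit)) return(hit)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- vapply(seq_len(n_null), function(i)
    .spacing_entropy(sort(runif(n)), n_bins), numeric(1L))
  out <- list(mean = mean(s), sd = sd(s))
  .tc_cache[[key]] <- out
  out
}

#' Randomness z-score for center positioning
#'
#' Assesses whether a set of center coordinates is compatible with
#' uniform random placement, via the Shannon entropy of consecutive
#' center spacings binned into equal-probability bins under the uniform
#' null. The observed entropy is standardized against `n_null`
#' Monte-Carlo uniform placements of the same count:
#' `z_s = (S_obs - mean_null) / sd_null`. Clustered or regularized
#' positioning gives |z_s| >= 1.96; |z_s| < 1.96 is treated as random.
#' This spacing-entropy statistic is this package's own construction of
#' a structural-entropy randomness screen.
#'
#' @param centers coordinate vector (any order).
#' @param n_null Monte-Carlo null size (default 1000).
#' @param seed seed for the null sample (moments are cached per
#'   (n, bins, n_null, seed), so repeated calls are cheap).
#' @param n_bins number of spacing bins.
#' @return z-score; `NA` with attribute `reason` for fewer than 20
#'   centers (too few spacings for a stable entropy).
#' @export
randomness_z <- function(centers, n_null = 1000L, seed = 1L,
                         n_bins = 20L) {
  centers <- sort(as.numeric(centers))
  n <- length(centers)
  if (n < 20L)
    return(structure(NA_real_, reason = "fewer than 20 centers"))
  s_obs <- .spacing_entropy(centers, n_bins)
  null <- .null_entropy_moments(n, n_bins, as.integer(n_null),
                                as.integer(seed))
  (s_obs - null$mean) / null$sd
}

#' Select the permutation scheme from randomness z-scores
#'
#' The united criterion: if both tracks' center positions are non-random
#' (|z_s| >= 1.96 for each), both length sets are permuted
#' simultaneously (`perm_both`); if exactly one track is random, the
#' lengths of the random track are permuted (`perm_A` when A is random,
#' `perm_B` when B is); if both are random, `perm_both` again. An
#' undefined z-score on either side falls back to `perm_both` with a
#' warning.
#'
#' @param zs_a,zs_b randomness z-scores of tracks A and B.
#' @return scheme string.
#' @export
select_scheme <- function(zs_a, zs_b) {
  if (is.na(zs_a) || is.na(zs_b)) {
    warning("undefined randomness z-score; defaulting to perm_both")
    return("perm_both")
  }
  a_random <- abs(zs_a) < 1.96
  b_random <- abs(zs_b) < 1.96
  if (a_random && !b_random) return("perm_A")
  if (b_random && !a_random) return("perm_B")
  "perm_both"
}

#' Exact binomial assessment of chromosome-level exceedances
#'
#' Probability model for the number of chromosomes whose |zeta| exceeds
#' a significance threshold by chance:
#' `Pr(n) = choose(N_chr, n) p^n (1-p)^(N_chr - n)`.
#'
#' @param n observed number of exceedances.
#' @param n_chr number of chromosomes tested.
#' @param p per-chromosome tail probability (threshold level).
#' @return list with `point_mass` (exact Pr(n)), `p_upper`
#'   (Pr(X >= n)), and `max_expected` — the smallest n with binomial
#'   CDF >= 0.95, i.e. the largest count still compatible with chance.
#' @export
binomial_exceedance <- function(n, n_chr, p) {
  if (n < 0 || n > n_chr || n_chr < 1 || p < 0 || p > 1)
    stop("invalid binomial arguments")
  list(point_mass = dbinom(n, n_chr, p),
       p_upper = pbinom(n - 1, n_chr, p, lower.tail = FALSE),
       max_expected = qbinom(0.95, n_chr, p))
}

.analyze_one_class <- function(pp, mode, scheme_io, min_pairs, thresholds) {
  K <- nrow(pp)
  out <- list(K = K, mean_IO = NA_real_, mean_IA = NA_real_,
              mean_IC = NA_real_, zeta = NA_real_, zeta_IA = NA_real_,
              lambda_zeta = NA_real_, p_approx = NA_real_,
              sig_flag = "none", scheme = NA_character_,
              reliable = K >= min_pairs)
  if (K < 3L) return(out)
  if (mode == "coverage") {
    out$mean_IC <- mean(pair_index(pp, "IC"))
    out$scheme <- "perm_IC"
    out$zeta <- complete_permutation(pp, "IC", "perm_IC")$zeta
  } else {
    out$mean_IO <- mean(pair_index(pp, "IO"))
    out$mean_IA <- mean(pair_index(pp, "IA"))
    out$scheme <- scheme_io
    out$zeta <- complete_permutation(pp, "IO", scheme_io)$zeta
    out$zeta_IA <- complete_permutation(pp, "IA", "perm_IA")$zeta
  }
  if (!is.null(thresholds) && out$reliable && !is.na(out$zeta) &&
      K >= min(thresholds$k_grid)) {
    pv <- approx_pvalue(thresholds, K, out$zeta)
    out$lambda_zeta <- pv$lambda_zeta
    out$p_approx <- pv$p
    out$sig_flag <- pv$significant_at
  }
  out
}

#' End-to-end colocalization analysis of two tracks
#'
#' Runs the full pipeline: length-variability (CV) screening with
#' automatic reduction to points, per-chromosome nearest-neighbor
#' pairing in both pair classes, per-chromosome randomness assessment
#' and permutation-scheme selection, the complete permutation test, and
#' genome-wide aggregation (exceedance counts with exact binomial
#' assessment, class shares of the smaller track, and
#' Kolmogorov-Smirnov / Mann-Whitney divergence between the two pair
#' classes' index values).
#'
#' In stretch-stretch mode the overlap (IO) and asymmetry (IA) indices
#' are reported; when one track is (or is reduced to) points, the
#' coverage index (IC) is used instead. A track whose length CV is at or
#' below `cv_thr` carries too little length variability for the
#' permutations to be informative and is reduced to points at `anchor`.
#' Significance is never reported for chromosomes with fewer than
#' `min_pairs` pairs (they are still listed, flagged unreliable).
#'
#' @param track_a,track_b [coloc_track()] objects (roles A and B).
#' @param thresholds optional calibrated `threshold_table`; without it,
#'   zeta values are reported but p-values and flags are omitted.
#' @param cv_thr length-CV threshold (default 0.5).
#' @param min_pairs minimum pair count for significance (default 50).
#' @param scheme `"auto"` (select per chromosome from randomness
#'   z-scores) or a forced `"perm_A"`, `"perm_B"`, `"perm_both"`.
#' @param anchor anchor used if a track must be reduced to points.
#' @param n_null,seed passed to [randomness_z()].
#' @return object of class `coloc_analysis`: list with `chromosomes`
#'   (one row per chromosome x pair class), `summary` (per-class
#'   genome-wide aggregation), `mode`, and the screening statistics.
#' @export
analyze_colocalization <- function(track_a, track_b, thresholds = NULL,
                                   cv_thr = 0.5, min_pairs = 50,
                                   scheme = c("auto", "perm_A", "perm_B",
                                              "perm_both"),
                                   anchor = "center", n_null = 1000L,
                                   seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(track_a, "coloc_track"),
            inherits(track_b, "coloc_track"))
  st_a <- compute_track_stats(track_a)
  st_b <- compute_track_stats(track_b)
  mode <- "stretch-stretch"
  a_pt <- track_a$is_point_track ||
    (!is.na(st_a$cv) && st_a$cv <= cv_thr)
  b_pt <- track_b$is_point_track ||
    (!is.na(st_b$cv) && st_b$cv <= cv_thr)
  if (!track_a$is_point_track && a_pt && !b_pt) {
    message("track A fails the length-CV criterion (CV = ",
            signif(st_a$cv, 3), " <= ", cv_thr, "); reduced to points")
    track_a <- reduce_to_points(track_a, anchor)
  }
  if (!track_b$is_point_track && b_pt && !a_pt) {
    message("track B fails the length-CV criterion (CV = ",
            signif(st_b$cv, 3), " <= ", cv_thr, "); reduced to points")
    track_b <- reduce_to_points(track_b, anchor)
  }
  if (a_pt && b_pt)
    stop("both tracks are points (or fail the CV criterion); ",
         "point-point correlation is outside this package's scope")
  if (a_pt || b_pt) mode <- "coverage"
  # coverage index is defined for stretch A vs point B; swap roles if
  # needed so the stretch track sits on the A side of each pair
  swapped <- FALSE
  if (mode == "coverage" && a_pt) {
    tmp <- track_a; track_a <- track_b; track_b <- tmp
    track_a$role <- "A"; track_b$role <- "B"
    swapped <- TRUE
    message("roles swapped for coverage mode: stretch track is now A")
  }

  chroms <- intersect(unique(track_a$elements$chrom),
                      unique(track_b$elements$chrom))
  if (length(chroms) == 0L) stop("no shared chromosomes between tracks")
  chroms <- chroms[order_chromosomes(chroms)]

  rows <- list()
  idx_values <- list(ABA_BAB = numeric(), AABB_BBAA = numeric())
  all_pairs <- list()
  for (ch in chroms) {
    sq <- merge_and_label(track_a, track_b, ch)
    pp_all <- extract_pairs(sq, chrom = ch)
    all_pairs[[ch]] <- pp_all
    ca <- track_a$elements$center[track_a$elements$chrom == ch]
    cb <- track_b$elements$center[track_b$elements$chrom == ch]
    zs_a <- randomness_z(ca, n_null = n_null, seed = seed)
    zs_b <- randomness_z(cb, n_null = n_null, seed = seed)
    scheme_io <- if (scheme == "auto")
      suppressWarnings(select_scheme(zs_a, zs_b)) else scheme
    for (cl in c("ABA_BAB", "AABB_BBAA")) {
      pp <- pp_all[pp_all$pair_class == cl, , drop = FALSE]
      r <- .analyze_one_class(pp, mode, scheme_io, min_pairs, thresholds)
      if (nrow(pp) > 0L)
        idx_values[[cl]] <- c(idx_values[[cl]],
          pair_index(pp, if (mode == "coverage") "IC" else "IO"))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, pair_class = cl, K = r$K, scheme = r$scheme,
        mean_IO = r$mean_IO, mean_IA = r$mean_IA, mean_IC = r$mean_IC,
        zeta = r$zeta, zeta_IA = r$zeta_IA, lambda_zeta = r$lambda_zeta,
        p_approx = r$p_approx, sig_flag = r$sig_flag,
        reliable = r$reliable,
        cv_a = st_a$cv, cv_b = st_b$cv, zs_a = as.numeric(zs_a),
        zs_b = as.numeric(zs_b), stringsAsFactors = FALSE)
    }
  }
  chrom_df <- do.call(rbind, rows)
  rownames(chrom_df) <- NULL
  pairs_df <- do.call(rbind, all_pairs)

  # genome-wide aggregation per class
  smaller_role <- if (nrow(track_a$elements) <= nrow(track_b$elements))
    "A" else "B"
  smaller_track <- if (smaller_role == "A") track_a else track_b
  shares <- class_share(pairs_df, smaller_track, smaller_role)
  summary <- list()
  for (cl in c("ABA_BAB", "AABB_BBAA")) {
    d <- chrom_df[chrom_df$pair_class == cl & chrom_df$reliable &
                    !is.na(chrom_df$zeta), , drop = FALSE]
    tested <- d[!is.na(d$p_approx), , drop = FALSE]
    n_tested <- nrow(tested)
    n05 <- sum(tested$sig_flag %in% c("0.05", "0.01"))
    n01 <- sum(tested$sig_flag == "0.01")
    bn <- if (n_tested > 0L) binomial_exceedance(n05, n_tested, 0.05) else
      NULL
    summary[[cl]] <- list(
      n_chromosomes_tested = n_tested, n_exceeding_005 = n05,
      n_exceeding_001 = n01,
      binomial_p = if (is.null(bn)) NA_real_ else bn$p_upper,
      max_expected_by_chance = if (is.null(bn)) NA_real_ else
        bn$max_expected,
      class_share = unname(shares[cl]),
      colocalization_call = !is.null(bn) && bn$p_upper < 0.05)
  }
  div <- list(ks_p = NA_real_, mw_p = NA_real_, ks_stat = NA_real_)
  if (length(idx_values$ABA_BAB) >= 3L &&
      length(idx_values$AABB_BBAA) >= 3L) {
    ks <- suppressWarnings(ks.test(idx_values$ABA_BAB,
                                   idx_values$AABB_BBAA))
    mw <- suppressWarnings(wilcox.test(idx_values$ABA_BAB,
                                       idx_values$AABB_BBAA))
    div <- list(ks_p = ks$p.value, mw_p = mw$p.value,
                ks_stat = unname(ks$statistic))
  }
  calls <- c(summary$ABA_BAB$colocalization_call,
             summary$AABB_BBAA$colocalization_call)
  recommended <- NA_character_
  if (!any(is.na(calls)) && calls[1] != calls[2])
    recommended <- names(which.max(shares))
  structure(list(chromosomes = chrom_df,
                 summary = summary,
                 class_divergence = div,
                 recommended_class = recommended,
                 mode = mode, swapped_roles = swapped,
                 track_a = track_a$name, track_b = track_b$name,
                 stats_a = st_a, stats_b = st_b,
                 min_pairs = min_pairs, cv_thr = cv_thr,
                 scheme_setting = scheme),
            class = "coloc_analysis")
}

#' @export
print.coloc_analysis <- function(x, ...) {
  cat(sprintf("<coloc_analysis> %s vs %s (%s mode)\n",
              x$track_a, x$track_b, x$mode))
  for (cl in names(x$summary)) {
    s <- x$summary[[cl]]
    cat(sprintf(
      "  %-10s: %d/%d chromosomes exceed Pr=0.05 (binomial p = %.3g); share %.3f\n",
      cl, s$n_exceeding_005, s$n_chromosomes_tested, s$binomial_p,
      s$class_share))
  }
  if (!is.na(x$recommended_class))
    cat("  class conclusions diverge; recommended class:",
        x$recommended_class, "\n")
  invisible(x)
}
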