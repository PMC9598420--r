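#' Generate a clustered (non-random) synthetic track
#'
#' A deliberately non-uniform track used to probe scheme selection and
#' misapplied-permutation behavior. Centers fall in tight clusters whose
#' positions are uniform over the span, and each stretch length is a
#' random fraction of the gap to its nearest neighbor, so elements
#' rarely overlap and lengths are strongly coupled to the local element
#' density — short stretches inside dense clusters, long ones in sparse
#' regions, as in real annotation tracks such as exons. This track
#' fails the uniform-randomness screen with high probability, and
#' permuting its lengths (rather than those of a random partner track)
#' violates the exchangeability the permutation null assumes.
#'
#' @param n_clusters number of clusters.
#' @param per_cluster elements per cluster.
#' @param span genomic span for cluster centers.
#' @param cluster_sd within-cluster center spread (bp).
#' @param length_frac range of the fraction of the nearest-neighbor gap
#'   used as stretch length.
#' @param seed RNG seed.
#' @param role,name,chrom passed to [coloc_track()].
#' @return A [coloc_track()], synthetic.
#' @export
generate_clustered_track <- function(n_clusters = 30, per_cluster = 40,
                                     span = c(0, 2e8), cluster_sd = 5e4,
                                     length_frac = c(0.45, 0.9),
                                     seed = NULL, role = "A",
                                     name = "clustered_synthetic",
                                     chrom = "sim") {
  if (!is.null(seed)) set.seed(seed)
  n <- n_clusters * per_cluster
  cc <- runif(n_clusters, span[1], span[2])
  center <- sort(pmin(pmax(rep(cc, each = per_cluster) +
                             rnorm(n, 0, cluster_sd), span[1]), span[2]))
  gap <- pmin(c(diff(center), Inf), c(Inf, diff(center)))
  gap[!is.finite(gap)] <- max(gap[is.finite(gap)])
  len <- pmax(1, floor(gap * runif(n, length_frac[1], length_frac[2])))
  coloc_track(data.frame(chrom = chrom, start = center - len / 2,
                         end = center + len / 2),
              name = name, role = role)
}

#' Binomial standard error of an FDR estimate
#'
#' Expected standard deviation of the observed false-discovery fraction
#' at a nominal level over `n_realizations` independent trials:
#' `sqrt(level (1 - level) / n_realizations)`.
#'
#' @param level nominal significance level.
#' @param n_realizations number of Monte-Carlo realizations.
#' @return the standard error.
#' @export
fdr_binomial_se <- function(level = 0.05, n_realizations = 1000) {
  sqrt(level * (1 - level) / n_realizations)
}

#' False-discovery-rate experiment on random tracks
#'
#' Validation protocol for the united zeta-criterion: for each
#' realization, draw a query track (and, unless a fixed reference is
#' supplied, a reference track) at random, tune counts so that the
#' ABA-BAB pair set has approximately `target_pairs` pairs, select the
#' permutation scheme from the randomness z-scores (or use a forced
#' scheme), run the complete permutation test on the overlap index, and
#' flag the realization when the approximate p-value is below `level`.
#' With independent random tracks the flagged fraction estimates the
#' empirical false discovery rate and should equal `level` within
#' binomial scatter.
#'
#' @param thresholds calibrated `threshold_table` covering
#'   `target_pairs`.
#' @param target_pairs target ABA-BAB pair count K.
#' @param n_realizations number of realizations (>= 100).
#' @param level nominal level.
#' @param seed master seed.
#' @param reference optional fixed reference [coloc_track()] (role A);
#'   when supplied, only the query track B is redrawn per realization,
#'   with span and maximum length matched to the reference.
#' @param scheme `"auto"` (united criterion) or a forced scheme.
#' @param span,max_length random-set parameters when no reference is
#'   given.
#' @return list of class `fdr_experiment`: `observed_fdr`, `n_flagged`,
#'   `n_realizations`, `binomial_se`, `level`, `target_pairs`,
#'   `mean_K`, `scheme_counts`, `seed`, and per-realization `decisions`.
#' @export
run_fdr_experiment <- function(thresholds, target_pairs = 500,
                               n_realizations = 1000, level = 0.05,
                               seed = NULL, reference = NULL,
                               scheme = c("auto", "perm_A", "perm_B",
                                          "perm_both"),
                               span = c(0, 2e8), max_length = 1e4) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(thresholds, "threshold_table"),
            n_realizations >= 100)
  if (level < 0 || level > 1) stop("invalid level")
  seeds <- .sub_seeds(seed, n_realizations + 2L)
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "coloc_track"))
    span <- range(reference$elements$center)
    max_length <- max(reference$elements$length, 1)
  }
  # tune the element count once; the generator is stationary across
  # realizations so the realized K scatters tightly around the target
  n_el <- if (is.null(reference)) {
    tune_element_count(target_pairs, span, max_length,
                       seed = seeds[n_realizations + 1L])
  } else {
    .tune_query_count(reference, target_pairs, span, max_length,
                      seed = seeds[n_realizations + 1L])
  }
  zs_seed <- seeds[n_realizations + 2L]
  dec <- vector("list", n_realizations)
  for (i in seq_len(n_realizations)) {
    set.seed(seeds[i])
    if (is.null(reference)) {
      tr <- generate_random_track_pair(span, max_length, n_el, n_el)
      A <- tr$A; B <- tr$B
    } else {
      A <- reference
      B <- generate_random_track_pair(span, max_length, 1, n_el,
                                      chrom = A$elements$chrom[1])$B
    }
    pp <- track_pairs(A, B)
    pp <- pp[pp$pair_class == "ABA_BAB", , drop = FALSE]
    K <- nrow(pp)
    if (K < 3L) {
      dec[[i]] <- data.frame(K = K, scheme = NA, zeta = NA, p = NA,
                             flagged = NA)
      next
    }
    sch <- if (scheme == "auto") {
      zs_a <- randomness_z(A$elements$center, seed = zs_seed)
      zs_b <- randomness_z(B$elements$center, seed = zs_seed)
      suppressWarnings(select_scheme(zs_a, zs_b))
    } else scheme
    zeta <- complete_permutation(pp, "IO", sch)$zeta
    pv <- approx_pvalue(thresholds, K, zeta)
    dec[[i]] <- data.frame(K = K, scheme = sch, zeta = zeta, p = pv$p,
                           flagged = !is.na(pv$p) && pv$p < level,
                           stringsAsFactors = FALSE)
  }
  dec <- do.call(rbind, dec)
  ok <- !is.na(dec$flagged)
  structure(list(observed_fdr = mean(dec$flagged[ok]),
                 n_flagged = sum(dec$flagged[ok]),
                 n_realizations = sum(ok),
                 binomial_se = fdr_binomial_se(level, sum(ok)),
                 level = level, target_pairs = target_pairs,
                 mean_K = mean(dec$K[ok]),
                 scheme_counts = table(dec$scheme[ok]),
                 seed = seed, decisions = dec),
            class = "fdr_experiment")
}

# Tune the query-track element count against a fixed reference track.
.tune_query_count <- function(reference, target_pairs, span, max_length,
                              seed = NULL, tol = 0.05) {
  seeds <- .sub_seeds(seed, 150L)
  n <- max(8L, as.integer(2 * target_pairs))
  chrom <- reference$elements$chrom[1]
  for (it in seq_len(50L)) {
    ks <- vapply(1:3, function(r) {
      B <- generate_random_track_pair(span, max_length, 1, n,
                                      seed = seeds[(it - 1L) * 3L + r],
                                      chrom = chrom)$B
      sum(track_pairs(reference, B)$pair_class == "ABA_BAB")
    }, numeric(1L))
    k_hat <- mean(ks)
    if (k_hat >= 3 && abs(k_hat - target_pairs) / target_pairs <= tol)
      return(n)
    n <- max(8L, as.integer(round(n * target_pairs / max(k_hat, 1))))
  }
  stop("could not tune query count to ~", target_pairs, " pairs")
}

#' @export
print.fdr_experiment <- function(x, ...) {
  cat(sprintf(
    "<fdr_experiment> K~%d, %d realizations at level %.3g\n  observed FDR = %.4f (expected %.3g +/- %.4f)\n",
    x$target_pairs, x$n_realizations, x$level, x$observed_fdr, x$level,
    x$binomial_se))
  invisible(x)
}
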