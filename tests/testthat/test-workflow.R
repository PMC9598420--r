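test_that("randomness z-score accepts uniform and rejects clustered placement", {
  set.seed(61)
  frac_ok <- mean(replicate(300, abs(randomness_z(runif(400, 0, 2e8),
                                                  seed = 5)) < 1.96))
  expect_gt(frac_ok, 0.90)
  expect_lt(frac_ok, 0.99)
  detected <- mean(replicate(60, {
    cc <- runif(20, 0, 2e8)
    x <- rep(cc, each = 25) + rnorm(500, 0, 1e4)
    abs(randomness_z(x, seed = 5)) >= 1.96
  }))
  expect_gte(detected, 0.9)
  # deterministic given the same input and seed
  x <- runif(100, 0, 1e6)
  expect_identical(randomness_z(x, seed = 3), randomness_z(x, seed = 3))
  z <- randomness_z(runif(10), seed = 3)
  expect_true(is.na(z))
  expect_match(attr(z, "reason"), "fewer than 20")
})

test_that("scheme selection follows the united randomness criterion", {
  expect_equal(select_scheme(3.1, 2.4), "perm_both")   # both non-random
  expect_equal(select_scheme(2.5, 0.7), "perm_B")      # B is the random set
  expect_equal(select_scheme(0.7, 2.5), "perm_A")      # A is the random set
  expect_equal(select_scheme(0.3, 1.1), "perm_both")   # both random
  expect_warning(s <- select_scheme(NA, 1.0), "perm_both")
  expect_equal(s, "perm_both")
})

test_that("binomial exceedance model gives exact chance bounds", {
  b <- binomial_exceedance(3, 23, 0.05)
  expect_lte(b$max_expected, 3)
  expect_equal(b$max_expected, qbinom(0.95, 23, 0.05))
  expect_gte(pbinom(b$max_expected, 23, 0.05), 0.95)
  expect_lt(pbinom(b$max_expected - 1, 23, 0.05), 0.95)
  b0 <- binomial_exceedance(0, 23, 0.05)
  expect_equal(b0$point_mass, 0.95^23)
  expect_equal(b0$p_upper, 1)
  expect_equal(binomial_exceedance(0, 10, 0)$point_mass, 1)
  expect_error(binomial_exceedance(5, 3, 0.05), "invalid")
})

test_that("planted points inside stretches are flagged as colocalized", {
  tb <- test_thresholds()
  set.seed(77)
  nA <- 600
  ctr <- runif(nA, 0, 2e8)
  len <- sample.int(1e4, nA, replace = TRUE)
  A <- coloc_track(data.frame(chrom = "sim", start = ctr - len / 2,
                              end = ctr + len / 2), role = "A")
  pick <- sample(nA, 400, replace = TRUE)
  bpos <- ctr[pick] + (runif(400) - 0.5) * len[pick]
  B <- coloc_track(data.frame(chrom = "sim", start = bpos, end = bpos),
                   role = "B")
  res <- analyze_colocalization(A, B, thresholds = tb, seed = 5)
  expect_equal(res$mode, "coverage")
  d <- res$chromosomes[res$chromosomes$pair_class == "ABA_BAB", ]
  expect_gte(d$K, 50)
  expect_lt(d$mean_IC, 0)
  expect_lt(d$zeta, 0)
  expect_equal(d$sig_flag, "0.01")
})

test_that("coincident tracks give mean IO of -1; jittered copies give strong negative zeta", {
  set.seed(31)
  ctr <- runif(300, 0, 1e8)
  len <- sample.int(5e3, 300, replace = TRUE)
  A <- coloc_track(data.frame(chrom = "sim", start = ctr - len / 2,
                              end = ctr + len / 2), role = "A")
  B_same <- coloc_track(A$elements, role = "B")
  res <- suppressWarnings(analyze_colocalization(A, B_same, seed = 5))
  d <- res$chromosomes[res$chromosomes$pair_class == "ABA_BAB", ]
  expect_equal(d$mean_IO, -1)
  expect_true(is.na(d$zeta))  # zero variance in observed AND permuted sets
  # B stretches centered uniformly inside the A stretches: the center
  # distances are coupled to the A lengths, which is exactly the signal
  # the length-swap null destroys
  ctr2 <- ctr + (runif(300) - 0.5) * len
  len2 <- sample.int(5e3, 300, replace = TRUE)
  B_in <- coloc_track(data.frame(chrom = "sim", start = ctr2 - len2 / 2,
                                 end = ctr2 + len2 / 2), role = "B")
  res2 <- analyze_colocalization(A, B_in, seed = 5)
  d2 <- res2$chromosomes[res2$chromosomes$pair_class == "ABA_BAB", ]
  expect_lt(d2$mean_IO, -0.5)
  expect_lt(d2$zeta, -3)
})

test_that("a low-CV track is reduced to points and analyzed in coverage mode", {
  set.seed(41)
  ctr_a <- runif(400, 0, 1e8)
  A <- coloc_track(data.frame(chrom = "sim", start = ctr_a - 500,
                              end = ctr_a + 500), role = "A")  # CV = 0
  ctr_b <- runif(400, 0, 1e8)
  len_b <- sample.int(2e4, 400, replace = TRUE)
  B <- coloc_track(data.frame(chrom = "sim", start = ctr_b - len_b / 2,
                              end = ctr_b + len_b / 2), role = "B")
  expect_message(res <- analyze_colocalization(A, B, seed = 5),
                 "length-CV criterion")
  expect_equal(res$mode, "coverage")
  expect_true(res$swapped_roles)  # stretch track (B) moved to the A side
  # both tracks degenerate is out of scope
  A2 <- coloc_track(data.frame(chrom = "sim", start = ctr_b,
                               end = ctr_b), role = "A")
  expect_error(
    suppressMessages(analyze_colocalization(A2, reduce_to_points(B), seed = 5)),
    "point-point")
})

test_that("role swap preserves |zeta| for IO and negates the asymmetry mean", {
  set.seed(51)
  tr <- generate_random_track_pair(n_a = 400, n_b = 400, seed = 8,
                                   max_length = 1e5)
  A <- tr$A
  B <- tr$B
  r1 <- analyze_colocalization(A, B, scheme = "perm_both", seed = 5)
  Bsw <- coloc_track(A$elements, role = "B")
  Asw <- coloc_track(B$elements, role = "A")
  r2 <- analyze_colocalization(Asw, Bsw, scheme = "perm_both", seed = 5)
  d1 <- r1$chromosomes[r1$chromosomes$pair_class == "ABA_BAB", ]
  d2 <- r2$chromosomes[r2$chromosomes$pair_class == "ABA_BAB", ]
  expect_equal(abs(d2$zeta), abs(d1$zeta), tolerance = 1e-10)
  expect_equal(d2$mean_IA, -d1$mean_IA, tolerance = 1e-12)
})

test_that("independent multi-chromosome tracks stay within chance exceedance", {
  tb <- test_thresholds()
  set.seed(123)
  mk <- function(role) {
    d <- do.call(rbind, lapply(1:20, function(i) {
      n <- 700
      c0 <- runif(n, 0, 2e8)
      l <- sample.int(1e4, n, replace = TRUE)
      data.frame(chrom = paste0("chr", i), start = c0 - l / 2,
                 end = c0 + l / 2)
    }))
    coloc_track(d, role = role)
  }
  res <- analyze_colocalization(mk("A"), mk("B"), thresholds = tb, seed = 5)
  for (cl in c("ABA_BAB", "AABB_BBAA")) {
    s <- res$summary[[cl]]
    expect_gte(s$n_chromosomes_tested, 15)
    # observed exceedances compatible with the binomial chance model
    expect_gt(s$binomial_p, 0.001)
    expect_false(s$colocalization_call)
  }
  expect_true(res$summary$ABA_BAB$class_share > 0 &&
                res$summary$ABA_BAB$class_share < 1)
  expect_true(is.finite(res$class_divergence$ks_p))
})
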