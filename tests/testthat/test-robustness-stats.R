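test_that("nodal reliability reproduces its fixed points", {
  # constructed components: a contact profile plus a per-iteration shift
  base <- c(0, 2, 4, 6)               # across-contact variance fixed
  shift <- c(-1, 1)                   # across-iteration variance 2 each
  m <- outer(shift, rep(1, 4)) + outer(rep(1, 2), base)
  ve <- mean(apply(m, 2, var))        # = 2
  vt <- mean(apply(m, 1, var))        # = var(base)
  rep1 <- reliability_nodal(m)
  expect_equal(rep1$R, vt / (vt + ve), tolerance = 1e-12)
  # identical iterations: R = 1
  ident <- rbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(reliability_nodal(ident)$R, 1)
  # error variance equal to true variance: R = 0.5
  half <- rbind(c(0, 2), c(2, 0))
  expect_equal(reliability_nodal(half)$R, 0.5)
  expect_error(reliability_nodal(rbind(c(1, 1), c(1, 1))), "total variance")
})

test_that("nodal reliability handles missingness from removal", {
  m <- rbind(c(1, 2, NA), c(1.5, 2.5, 3), c(0.5, 1.5, 3.5))
  rep <- reliability_nodal(m)
  ve <- mean(c(var(c(1, 1.5, 0.5)), var(c(2, 2.5, 1.5)), var(c(3, 3.5))))
  vt <- mean(c(var(c(1, 2)), var(c(1.5, 2.5, 3)), var(c(0.5, 1.5, 3.5))))
  expect_equal(rep$R, vt / (vt + ve), tolerance = 1e-12)
  # a contact retained once is excluded with a warning
  m2 <- rbind(c(1, 2, NA), c(1.5, 2.5, NA), c(0.5, 1.5, 3.5))
  expect_warning(reliability_nodal(m2), "fewer than 2 iterations")
})

test_that("global reliability uses patient and iteration variance components", {
  # patients differ, iterations constant per patient: R = 1
  m <- matrix(rep(c(1, 2, 3), 4), 3, 4)
  expect_equal(reliability_global(m)$R, 1)
  expect_error(reliability_global(matrix(2, 3, 4)), "total variance")
  # constructed components: across-patient variance 4, across-iteration 1
  set.seed(1)
  patients <- c(0, 2, 4, 6)
  m2 <- outer(patients, rep(1, 3)) + rbind(c(-1, 0, 1), c(-1, 0, 1),
                                           c(-1, 0, 1), c(-1, 0, 1))
  ve <- mean(apply(m2, 1, var))
  vt <- mean(apply(m2, 2, var))
  expect_equal(reliability_global(m2)$R, vt / (vt + ve), tolerance = 1e-12)
  expect_equal(reliability_global(m2)$R, (20 / 3) / (20 / 3 + 1),
               tolerance = 1e-12)
})

test_that("reliability is invariant to affine rescaling and decreasing in error", {
  set.seed(2)
  m <- matrix(rnorm(200), 10, 20)
  r0 <- reliability_nodal(m)$R
  expect_equal(reliability_nodal(m * 7 + 3)$R, r0, tolerance = 1e-12)
  expect_equal(reliability_nodal(-2 * m)$R, r0, tolerance = 1e-12)
  # inflate only the across-iteration component (row shifts leave the
  # within-iteration contact variance untouched): R must drop
  noisy <- sweep(m, 1, rnorm(10, sd = 3), "+")
  expect_lt(reliability_nodal(noisy)$R, r0)
})

test_that("rank stability matches the textbook Spearman oracle", {
  orig <- c(5, 3, 8, 1, 9, 2, 7, 4, 6, 10)
  ident <- matrix(orig, 3, 10, byrow = TRUE)
  expect_equal(rank_stability(orig, ident)$mean_rho, 1)
  rev <- matrix(-orig, 2, 10, byrow = TRUE)
  expect_equal(rank_stability(orig, rev)$mean_rho, -1)
  set.seed(3)
  orig20 <- rnorm(20)
  vals <- matrix(NA, 5, 20)
  for (i in 1:5) {
    keep <- sort(sample(20, 15))
    vals[i, keep] <- rnorm(15)
  }
  rs <- rank_stability(orig20, vals)
  manual <- vapply(1:5, function(i) {
    keep <- !is.na(vals[i, ])
    oracle_spearman(orig20[keep], vals[i, keep])
  }, numeric(1))
  expect_equal(rs$rho, manual, tolerance = 1e-12)
  expect_equal(rs$mean_rho, mean(manual), tolerance = 1e-12)
  # constant subsample vectors are dropped with a warning
  vals[1, ] <- 1
  expect_warning(rs2 <- rank_stability(orig20, vals), "undefined")
  expect_equal(rs2$n_dropped, 1)
})

test_that("agreement takes its defined forms and fixed points", {
  expect_equal(agreement(0.5, 0.5, "global"), 0)
  expect_equal(agreement(0.5, 0.4, "global"), -0.2, tolerance = 1e-12)
  expect_equal(agreement(0.5, 0.6, "global"), -0.2, tolerance = 1e-12)
  expect_error(agreement(0, 1, "global"), "original metric is 0")
  orig <- c(a = 1, b = 2, c = 3, d = 4)
  expect_equal(agreement(orig, c(a = 10, c = 30, d = 40), "nodal"), 1)
  expect_equal(agreement(orig, c(a = 3, c = 2, d = 1), "nodal"), -1)
  expect_error(agreement(orig, c(a = 1, b = 2), "nodal"), "3 aligned")
})

test_that("distance-agreement association returns Spearman rho and Fisher z", {
  d <- c(5, 10, 20, 40, 80)
  a_mono <- c(-0.5, -0.4, -0.3, -0.2, -0.1)
  expect_error(distance_agreement_association(d, a_mono), "infinite")
  a_mixed <- c(-0.5, -0.1, -0.4, -0.2, -0.3)
  res <- distance_agreement_association(d, a_mixed)
  expect_equal(res$rho, oracle_spearman(d, a_mixed), tolerance = 1e-12)
  expect_equal(res$z, atanh(res$rho), tolerance = 1e-12)
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  expect_error(distance_agreement_association(d[1:3], a_mixed[1:3]),
               "at least 4")
})

test_that("SOZ comparison counts percentiles as defined", {
  res <- soz_comparison(-0.25, c(-0.1, -0.2, -0.3))
  expect_equal(res$mean_sparing_a, -0.2)
  expect_equal(res$diff, 0.05)
  expect_equal(res$percentile, 2 / 3)
  expect_equal(soz_comparison(-0.2, c(-0.1, -0.2, -0.3))$diff, 0)
  expect_equal(soz_comparison(-0.05, c(-0.1, -0.2))$percentile, 0)
})

test_that("signed relative difference keeps its sign", {
  expect_equal(signed_relative_difference(0.5, 0.6), 0.2, tolerance = 1e-12)
  expect_equal(signed_relative_difference(0.5, 0.5), 0)
  expect_equal(signed_relative_difference(0.5, 0.25), -0.5)
  expect_error(signed_relative_difference(0, 1), "undefined")
})

test_that("cohort comparison controls type I error and finds real differences", {
  # null behaviour: exchangeable columns rarely reach significance
  n_sig <- 0
  for (s in 1:100) {
    set.seed(s)
    vals <- matrix(rnorm(30), 10, 3)
    if (cohort_metric_comparison(vals)$p < 0.05) n_sig <- n_sig + 1
  }
  expect_lte(n_sig / 100, 0.12)
  # a dominated metric is detected and flagged post hoc
  set.seed(99)
  vals <- cbind(m1 = rnorm(30, 0), m2 = rnorm(30, 0), m3 = rnorm(30, -3))
  res <- cohort_metric_comparison(vals)
  expect_lt(res$p, 0.05)
  flagged <- res$posthoc[res$posthoc$significant, ]
  expect_true(all(grepl("m3", paste(flagged$metric_1, flagged$metric_2))))
  # Sidak per-comparison threshold closed form
  expect_equal(res$sidak_alpha, 1 - 0.95^(1 / 3), tolerance = 1e-12)
  expect_equal(1 - 0.95^(1 / 3), 0.01695, tolerance = 1e-3)
  expect_error(cohort_metric_comparison(matrix(c(1, NA, 2, 3, 4, 5), 3, 2)),
               "missing")
})

test_that("Bonferroni alpha is family alpha over test count", {
  expect_equal(bonferroni_alpha(0.05, 8), 0.00625)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.01, 4), 0.0025)
})

test_that("size-reliability association is a Spearman correlation across patients", {
  n <- c(16, 40, 77, 118)
  expect_equal(size_reliability_association(n, c(0.8, 0.85, 0.9, 0.95))$rho, 1)
  set.seed(4)
  nc <- sample(16:118, 12)
  R <- runif(12)
  res <- size_reliability_association(nc, R)
  expect_equal(res$rho, oracle_spearman(nc, R), tolerance = 1e-12)
  expect_error(size_reliability_association(rep(10, 5), runif(5)),
               "constant")
  # permuted pairs show no systematic association on average
  rhos <- vapply(1:50, function(s) {
    set.seed(s)
    size_reliability_association(sample(nc), sample(R))$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.15)
})
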