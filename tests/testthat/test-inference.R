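test_that("weighted mean and SD reduce to the unweighted forms", {
  x <- c(1.2, -0.4, 3.1, 0.8, 2.2)
  expect_equal(weighted_mean(x, rep(2.5, 5)), mean(x))
  expect_equal(weighted_sd(x, rep(0.3, 5)), sd(x))
  expect_equal(weighted_sd(c(1, 2, 3)), 1)
  # integer weights equal replication for the mean; the SD follows the
  # probability-weight convention (normalize to sum n, divisor sum(w) - 1)
  expect_equal(weighted_mean(c(1, 2, 3), c(1, 1, 2)), mean(c(1, 2, 3, 3)))
  wn <- c(1, 1, 2) * 3 / 4
  mw <- sum(wn * c(1, 2, 3)) / 3
  expect_equal(weighted_sd(c(1, 2, 3), c(1, 1, 2)),
               sqrt(sum(wn * (c(1, 2, 3) - mw)^2) / 2))
  expect_error(weighted_mean(numeric(0)), "empty")
  expect_error(weighted_sd(c(1, 2), c(1, -1)))
})

test_that("the bivariate WLS slope and HC sandwich match the matrix oracle", {
  y <- c(0, 1, 0, 1, 1, 0)
  x <- c(0, 0, 1, 1, 2, 2)
  w <- c(1, 2, 0.5, 1.5, 3, 1)
  for (hc in c("HC1", "HC0")) {
    got_u <- fit_bivariate_lpm(y, x, hc = hc)
    orc_u <- oracle_wls_hc1(y, x, hc = hc)
    expect_equal(got_u$beta, orc_u$beta[2], tolerance = 1e-10)
    expect_equal(got_u$robust_se, orc_u$se[2], tolerance = 1e-10)
    got_w <- fit_bivariate_lpm(y, x, w, hc = hc)
    orc_w <- oracle_wls_hc1(y, x, w, hc = hc)
    expect_equal(got_w$beta, orc_w$beta[2], tolerance = 1e-10)
    expect_equal(got_w$robust_se, orc_w$se[2], tolerance = 1e-10)
  }
  expect_error(fit_bivariate_lpm(y, rep(1, 6)), "constant")
})

test_that("rows with missing values are dropped consistently", {
  y <- c(0, 1, NA, 1, 0, 0)
  x <- c(0, 1, 1, NA, 0, 1)
  got <- fit_bivariate_lpm(y, x)
  keep <- complete.cases(y, x)
  orc <- oracle_wls_hc1(y[keep], x[keep])
  expect_equal(got$beta, orc$beta[2], tolerance = 1e-10)
  expect_equal(got$n_used, sum(keep))
})

test_that("standardized slopes equal the correlation on Gaussian data", {
  set.seed(5)
  n <- 5000
  x <- rnorm(n)
  y <- 0.6 * x + rnorm(n, sd = 0.8)
  est <- fit_standardized_linear(y, x)
  expect_equal(est$beta, cor(x, y), tolerance = 1e-10)
  # weighted version with uniform weights is identical
  estw <- fit_standardized_linear(y, x, w = rep(2, n))
  expect_equal(estw$beta, est$beta, tolerance = 1e-10)
})

test_that("the Z-statistic matches the normal-CDF oracle", {
  a <- volunteerbias:::.new_assoc_estimate("y", "x", beta = 0.5,
                                           robust_se = 0.1, n_used = 100,
                                           weighted = FALSE)
  b <- volunteerbias:::.new_assoc_estimate("y", "x", beta = 0.3,
                                           robust_se = 0.1, n_used = 100,
                                           weighted = FALSE)
  cmp <- compare_associations(a, b)
  expect_equal(cmp$z, 0.2 / sqrt(0.02), tolerance = 1e-12)
  expect_equal(cmp$z, 1.4142136, tolerance = 1e-6)
  expect_equal(cmp$p_two_sided, 2 * (1 - oracle_phi(abs(cmp$z))),
               tolerance = 1e-10)
  expect_equal(cmp$p_two_sided, 0.1572992, tolerance = 1e-6)
  # two tight, widely separated estimates are overwhelmingly different
  c1 <- volunteerbias:::.new_assoc_estimate("y", "x", -0.501, 0.0015,
                                            1e5, FALSE)
  c2 <- volunteerbias:::.new_assoc_estimate("y", "x", -0.300, 0.003,
                                            1e5, FALSE)
  expect_lt(compare_associations(c1, c2)$p_two_sided, 1e-8)
  mis <- volunteerbias:::.new_assoc_estimate("y2", "x", 0, 1, 10, FALSE)
  expect_error(compare_associations(a, mis), "different outcome")
})

test_that("bias reduction follows its definition and flags zero bias", {
  expect_equal(bias_reduction(ref = 1, unweighted = 0.5, weighted = 0.9),
               1 - 0.1 / 0.5)
  expect_equal(bias_reduction(1, 0.5, 1), 1)
  expect_equal(bias_reduction(1, 0.5, 0.5), 0)
  expect_lt(bias_reduction(1, 0.9, 0.5), 0)
  br <- bias_reduction(1, 1 + 1e-12, 2)
  expect_true(is.na(br))
  expect_true(attr(br, "undefined"))
})

test_that("association sides resolve to indicators or numeric maps", {
  cbk <- tiny_codebook()
  tab <- data.frame(health = c("good", "poor", "fair"),
                    work = c("yes", "no", "yes"))
  expect_equal(volunteerbias:::.assoc_column("health=poor", tab, cbk),
               c(0, 1, 0))
  expect_equal(volunteerbias:::.assoc_column("health", tab, cbk),
               c(1, 3, 2))
  expect_error(volunteerbias:::.assoc_column("health=great", tab, cbk),
               "not a level")
})

test_that("uniform weights make the weighted estimates equal the unweighted", {
  cbk <- tiny_codebook()
  set.seed(31)
  mk <- function(n) data.frame(
    person_id = as.character(seq_len(n)),
    health = sample(c("good", "fair", "poor"), n, TRUE,
                    prob = c(0.6, 0.25, 0.15)),
    work = sample(c("yes", "no"), n, TRUE),
    stringsAsFactors = FALSE)
  coh <- mk(800); ref <- mk(700)
  wu <- compute_ip_weights(rep(0.5, 800), person_id = coh$person_id)
  cmp <- estimate_associations(
    list(assoc("health=poor", "work=yes"), assoc("health", "work=yes",
                                                 type = "std")),
    coh, ref, wu, cbk)
  expect_equal(cmp$beta_weighted, cmp$beta_unweighted, tolerance = 1e-10)
  expect_equal(cmp$se_weighted, cmp$se_unweighted, tolerance = 1e-10)
  expect_s3_class(cmp, "association_comparison")
  expect_true(all(c("z", "p", "z_weighted", "p_weighted",
                    "bias_reduction") %in% names(cmp)))
})

test_that("long export has the stable layout", {
  cbk <- tiny_codebook()
  set.seed(32)
  coh <- data.frame(person_id = as.character(1:300),
                    health = sample(c("good", "poor"), 300, TRUE),
                    work = sample(c("yes", "no"), 300, TRUE))
  ref <- coh[sample(300, 250), ]
  w <- compute_ip_weights(runif(300, 0.2, 0.8), person_id = coh$person_id)
  cmp <- estimate_associations(list(assoc("health=poor", "work=yes")),
                               coh, ref, w, cbk)
  path <- withr::local_tempfile(fileext = ".csv")
  long <- association_long(cmp, path)
  expect_equal(names(long),
               c("outcome", "exposure", "sample", "weighted", "beta",
                 "robust_se", "ci_low", "ci_high", "z_vs_reference", "p",
                 "bias_reduction"))
  expect_equal(nrow(long), 3L)  # reference, cohort, weighted cohort
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 3L)
})

test_that("mean bias reduction averages and filters by type", {
  cmp <- data.frame(type = c("lpm", "lpm", "std"),
                    bias_reduction = c(0.8, NA, 0.6))
  class(cmp) <- c("association_comparison", "data.frame")
  expect_equal(mean_bias_reduction(cmp), 0.7)
  expect_equal(mean_bias_reduction(cmp, type = "std"), 0.6)
})
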