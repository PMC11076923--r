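test_that("scenario covariance assembles the structural equations", {
  sc <- collider_scenario(b = 0.4, a_x = 1, a_y = 0.5, u_x = 0.7,
                          u_y = 0.3, sd_y = 1.2)
  S <- volunteerbias:::.scenario_sigma(sc)
  # direct moment algebra: Var(X) = u_x^2 + sd_x^2, Cov(X, Y) = b Var(X) +
  # u_y u_x, Var(Y) = b^2 Var(X) + 2 b u_x u_y + u_y^2 + sd_y^2
  vx <- 0.7^2 + 1
  expect_equal(S["X", "X"], vx)
  expect_equal(S["X", "Y"], 0.4 * vx + 0.3 * 0.7)
  expect_equal(S["Y", "Y"], 0.4^2 * vx + 2 * 0.4 * 0.7 * 0.3 + 0.3^2 + 1.2^2)
  expect_equal(S["X", "L"], 1 * S["X", "X"] + 0.5 * S["X", "Y"])
})

test_that("closed-form truncated moments match numerical integration", {
  for (nm in c("selection-on-exposure", "selection-on-outcome",
               "selection-on-both", "selection-on-common-cause")) {
    sc <- collider_preset(nm, selection_rate = 0.15)
    S <- volunteerbias:::.scenario_sigma(sc)
    cc <- volunteerbias:::.scenario_cutoff(sc)
    th <- scenario_theory(sc)
    S3 <- S[c("X", "Y", "L"), c("X", "Y", "L")]
    expect_equal(unname(th$truncated["cov_xy"]),
                 oracle_truncated_cov(S3, cc), tolerance = 1e-8)
    Sxx <- S[c("X", "X", "L"), c("X", "X", "L")]
    expect_equal(unname(th$truncated["var_x"]),
                 oracle_truncated_cov(Sxx, cc), tolerance = 1e-8)
  }
})

test_that("selection archetypes bias the slope in the predicted direction", {
  # selection on the exposure alone leaves E[Y | X] intact: no bias
  th_x <- scenario_theory(collider_preset("selection-on-exposure"))
  expect_equal(th_x$bias, 0, tolerance = 1e-12)
  # selection on the outcome attenuates a positive slope
  th_y <- scenario_theory(collider_preset("selection-on-outcome"))
  expect_lt(th_y$bias, 0)
  expect_gt(th_y$selected_slope, 0)
  # selection on both makes independent variables negatively associated
  th_b <- scenario_theory(collider_preset("selection-on-both"))
  expect_equal(th_b$population_slope, 0)
  expect_lt(th_b$selected_slope, 0)
  expect_lt(th_b$selected_cor, 0)
  # selection on a common cause biases the (confounded) slope downward too
  th_u <- scenario_theory(collider_preset("selection-on-common-cause"))
  expect_lt(th_u$bias, 0)
})

test_that("stronger outcome selection means more attenuation", {
  biases <- vapply(c(0.25, 0.5, 1, 2), function(a) {
    scenario_theory(collider_scenario(b = 0.3, a_y = a))$bias
  }, numeric(1))
  expect_true(all(diff(biases) < 0))  # increasingly negative
})

test_that("Monte-Carlo selected slopes agree with theory", {
  for (nm in c("selection-on-outcome", "selection-on-both")) {
    sc <- collider_preset(nm, n = 20000L)
    sb <- scenario_bias(sc, replicates = 12, seed = 7)
    th <- scenario_theory(sc)
    expect_lt(abs(sb$mean_selected_slope - th$selected_slope), 3 * sb$mc_se)
    expect_equal(sign(sb$bias), sign(th$bias))
  }
})

test_that("simulated scenarios are deterministic and carry true probabilities", {
  sc <- collider_preset("selection-on-both", n = 5000L)
  d1 <- simulate_scenario(sc, seed = 3)
  d2 <- simulate_scenario(sc, seed = 3)
  expect_identical(d1, d2)
  expect_true(all(d1$prob_select > 0 & d1$prob_select < 1))
  # realized selection tracks the stated probabilities (absolute binomial
  # bound, 3 SEs at n = 5000)
  expect_lt(abs(mean(d1$S) - sc$selection_rate),
            3 * sqrt(0.1 * 0.9 / 5000))
  expect_gt(mean(d1$prob_select[d1$S == 1]),
            mean(d1$prob_select[d1$S == 0]))
})

test_that("adjusting for a collider-path covariate fails where weighting works", {
  # H is downstream of Y and drives selection: conditioning on it opens the
  # collider path; weighting by the true selection probability does not
  # sd_s keeps the true selection probabilities away from zero so the
  # inverse-probability weights are not heavy-tailed
  sc <- collider_scenario(b = 0.3, a_h = 1.2, h_y = 0.9, n = 30000L,
                          sd_s = 2.5, selection_rate = 0.25)
  cmp <- adjustment_vs_weighting(sc, control = "H", replicates = 12,
                                 seed = 5)
  b_pop <- cmp$population_slope
  expect_gt(abs(cmp$estimates["adjusted"] - b_pop),
            4 * cmp$mc_se["adjusted"])
  expect_lt(abs(cmp$estimates["weighted"] - b_pop),
            3 * cmp$mc_se["weighted"])
  # the naive selected slope is biased as well
  expect_gt(abs(cmp$estimates["naive"] - b_pop), 4 * cmp$mc_se["naive"])
})

test_that("adjustment recovers the structural slope for a true confounder", {
  sc <- collider_preset("selection-on-common-cause", n = 30000L)
  cmp <- adjustment_vs_weighting(sc, control = "U", replicates = 12,
                                 seed = 5)
  # adjusting for the common cause targets the structural slope b,
  # weighting targets the (confounded) population slope
  expect_lt(abs(cmp$estimates["adjusted"] - sc$b), 3 * cmp$mc_se["adjusted"])
  expect_lt(abs(cmp$estimates["weighted"] - cmp$population_slope),
            3 * cmp$mc_se["weighted"])
})

test_that("collider batch summarizes scenarios and writes CSV", {
  scs <- list(outcome = collider_preset("selection-on-outcome", n = 8000L),
              both = collider_preset("selection-on-both", n = 8000L))
  path <- withr::local_tempfile(fileext = ".csv")
  out <- collider_batch(scs, replicates = 6, seed = 2, path = path)
  expect_equal(out$scenario, c("outcome", "both"))
  expect_true(all(abs(out$selected_slope - out$theory_selected_slope) <
                    6 * out$mc_se))
  expect_true(file.exists(path))
})
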