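test_that("population_spec validates marginals and the latent correlation", {
  v <- list(list(name = "a", levels = c("x", "y"), probs = c(0.6, 0.4)))
  expect_s3_class(population_spec(100, v), "population_spec")
  bad <- list(list(name = "a", levels = c("x", "y"), probs = c(0.6, 0.5)))
  expect_error(population_spec(100, bad), "sum to 1")
  v2 <- c(v, list(list(name = "b", levels = c("x", "y"), probs = c(0.5, 0.5))))
  R_asym <- matrix(c(1, 0.2, 0.3, 1), 2, 2)
  expect_error(population_spec(100, v2, latent_correlation = R_asym),
               "symmetric")
  R_npd <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(population_spec(100, v2, latent_correlation = R_npd),
               "positive semi-definite")
  expect_error(population_spec(100, v2, latent_correlation = diag(3)), "2x2")
})

test_that("generated marginals match the specification", {
  v <- list(
    list(name = "a", levels = c("x", "y", "z"), probs = c(0.5, 0.3, 0.2)),
    list(name = "b", levels = c("u", "v"), probs = c(0.75, 0.25)))
  spec <- population_spec(40000, v, seed = 3)
  pop <- generate_population(spec)
  expect_equal(nrow(pop), 40000)
  expect_equal(as.numeric(table(pop$a)[c("x", "y", "z")]) / 40000,
               c(0.5, 0.3, 0.2), tolerance = 0.015)
  expect_equal(mean(pop$b == "u"), 0.75, tolerance = 0.01)
  # determinism
  pop2 <- generate_population(spec)
  expect_identical(pop, pop2)
})

test_that("copula dependence matches the orthant-probability oracle", {
  # two variables, joint probability of both top levels under latent
  # correlation rho must equal P(Z1 > qnorm(p1), Z2 > qnorm(p2); rho)
  rho <- 0.5
  v <- list(
    list(name = "a", levels = c("lo", "hi"), probs = c(0.6, 0.4)),
    list(name = "b", levels = c("lo", "hi"), probs = c(0.7, 0.3)))
  R <- matrix(c(1, rho, rho, 1), 2, 2)
  spec <- population_spec(200000, v, latent_correlation = R, seed = 11)
  pop <- generate_population(spec)
  p_joint <- mean(pop$a == "hi" & pop$b == "hi")
  p_oracle <- oracle_orthant_prob(qnorm(0.6), qnorm(0.7), rho)
  se <- sqrt(p_oracle * (1 - p_oracle) / 200000)
  expect_lt(abs(p_joint - p_oracle), 4 * se)
  # independence control
  spec0 <- population_spec(200000, v, seed = 11)
  pop0 <- generate_population(spec0)
  expect_lt(abs(mean(pop0$a == "hi" & pop0$b == "hi") - 0.4 * 0.3),
            4 * sqrt(0.12 * 0.88 / 200000))
})

test_that("reference sample has the configured design", {
  v <- list(list(name = "a", levels = c("x", "y"), probs = c(0.5, 0.5)))
  pop <- generate_population(population_spec(50000, v, seed = 2))
  ref <- draw_reference_sample(pop, 0.05, 0.95, seed = 2)
  expect_equal(nrow(ref), 50000 * 0.05 * 0.95, tolerance = 0.08)
  expect_true(all(ref$source == "reference"))
  expect_false("true_prob" %in% names(ref))
  expect_error(draw_reference_sample(pop[1:500, ], 0.05, 0.95),
               "fewer than 50")
  expect_error(draw_reference_sample(pop, 1.5), "sampling_fraction")
  # covariate-dependent response override
  rp <- ifelse(pop$a == "x", 0.9, 0.1)
  ref2 <- draw_reference_sample(pop, 0.5, seed = 2, response_prob = rp)
  expect_gt(mean(ref2$a == "x"), 0.85)
})

test_that("volunteer draw hits the target rate and records ground truth", {
  cbk <- tiny_codebook()
  pop <- data.frame(
    person_id = as.character(1:60000),
    health = sample(c("good", "fair", "poor"), 60000, TRUE,
                    prob = c(0.7, 0.2, 0.1)),
    work = sample(c("yes", "no"), 60000, TRUE, prob = c(0.6, 0.4)))
  sel <- selection_spec(c("main:health=poor" = -0.8,
                          "main:work=yes" = 0.4),
                        target_rate = 0.055, seed = 9)
  coh <- draw_volunteers(pop, sel, cbk)
  expect_lt(abs(attr(coh, "realized_rate") - 0.055), 0.001)
  expect_true(all(coh$true_prob > 0 & coh$true_prob < 1))
  expect_true(is.numeric(attr(coh, "intercept")))
  # selection works in the declared direction
  expect_lt(mean(coh$health == "poor"), mean(pop$health == "poor"))
  # unknown design column is rejected
  bad <- selection_spec(c("main:health=excellent" = 1), target_rate = 0.1)
  expect_error(draw_volunteers(pop, bad, cbk), "unknown design columns")
})

test_that("realized participation probabilities are honest", {
  # group persons by their true probability and compare with the realized
  # participation frequency
  cbk <- codebook(list(cb_variable("g", c("a", "b"))))
  pop <- data.frame(person_id = as.character(1:80000),
                    g = rep(c("a", "b"), 40000))
  sel <- selection_spec(c("main:g=a" = -0.7), target_rate = 0.1, seed = 4)
  coh <- draw_volunteers(pop, sel, cbk)
  p_a <- unique(coh$true_prob[coh$g == "a"])
  expect_length(p_a, 1L)
  n_a <- sum(pop$g == "a")
  realized_a <- sum(coh$g == "a") / n_a
  expect_lt(abs(realized_a - p_a), 4 * sqrt(p_a * (1 - p_a) / n_a))
})

test_that("missingness injection respects rates and streams", {
  tab <- data.frame(person_id = as.character(1:20000),
                    a = "x", b = "y", stringsAsFactors = FALSE)
  out <- inject_missingness(tab, c(a = 0.2, b = 0), seed = 8)
  # absolute binomial bound (4 SEs at n = 20000)
  expect_lt(abs(mean(is.na(out$a)) - 0.2),
            4 * sqrt(0.2 * 0.8 / 20000))
  expect_false(anyNA(out$b))
  expect_identical(out, inject_missingness(tab, c(a = 0.2, b = 0), seed = 8))
  expect_error(inject_missingness(tab, c(zz = 0.1)), "unknown variable")
  expect_error(inject_missingness(tab, c(a = 1)), "rates must lie")
})

test_that("person tables round-trip through CSV with empty-field missing", {
  cbk <- tiny_codebook()
  tab <- data.frame(person_id = c("1", "2", "3"),
                    health = c("good", NA, "poor"),
                    work = c("yes", "no", NA),
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_person_table(tab, path, provenance = list(seed = 7))
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_person_table(path, cbk)
  expect_equal(back$health, tab$health)
  expect_equal(back$work, tab$work)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$seed, 7)
})
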