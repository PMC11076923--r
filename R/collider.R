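# Collider-bias scenarios: linear-Gaussian structural equations with
# threshold selection. Because everything is jointly Gaussian, the selected
# sample's moments have exact closed forms (one-sided truncation of a
# Gaussian selection index), giving an analytic oracle for every scenario.
#
# Structure:
#   U ~ N(0,1)                      (common cause)
#   X = u_x U + e_x                 (exposure)
#   Y = b X + u_y U + e_y           (outcome)
#   H = h_y Y + e_h                 (selection-driving covariate, e.g.
#                                    a health measure downstream of Y)
#   L = a_x X + a_y Y + a_u U + a_h H + e_s   (selection index)
#   S = 1{ L > c },  c solved so that P(S = 1) = selection_rate

#' Specify a collider selection scenario
#'
#' @param b structural slope of the exposure on the outcome.
#' @param a_x,a_y,a_u,a_h selection-index loadings of the exposure,
#'   outcome, common cause, and downstream covariate.
#' @param u_x,u_y loadings of the common cause on exposure and outcome.
#' @param h_y loading of the outcome on the downstream covariate `H`.
#' @param sd_x,sd_y,sd_h,sd_s structural noise SDs (all > 0).
#' @param selection_rate target participation rate in (0, 1).
#' @param n sample size per simulated replicate.
#' @param seed integer seed for the collider stream.
#' @return an object of class `collider_scenario`.
#' @export
collider_scenario <- function(b = 0.3, a_x = 0, a_y = 0, a_u = 0, a_h = 0,
                              u_x = 0, u_y = 0, h_y = 0,
                              sd_x = 1, sd_y = 1, sd_h = 1, sd_s = 1,
                              selection_rate = 0.1, n = 50000L, seed = 1L) {
  if (any(c(sd_x, sd_y, sd_h, sd_s) <= 0)) stop("all noise SDs must be > 0")
  if (!(selection_rate > 0 && selection_rate < 1)) {
    stop("selection_rate must lie in (0, 1)")
  }
  stopifnot(.is_count(n))
  structure(list(b = b, a_x = a_x, a_y = a_y, a_u = a_u, a_h = a_h,
                 u_x = u_x, u_y = u_y, h_y = h_y,
                 sd_x = sd_x, sd_y = sd_y, sd_h = sd_h, sd_s = sd_s,
                 selection_rate = selection_rate, n = as.integer(n),
                 seed = as.integer(seed)),
            class = "collider_scenario")
}

#' Named scenario presets
#'
#' Archetypes of the canonical selection diagrams: selection on the
#' exposure only, on the outcome only, on both (the classic collider), and
#' on a common cause of both.
#'
#' @param preset one of `"selection-on-exposure"`, `"selection-on-outcome"`,
#'   `"selection-on-both"`, `"selection-on-common-cause"`. (The formal is
#'   deliberately not called `name` so that a partially matching `n = ...`
#'   override falls through to [collider_scenario()].)
#' @param ... overrides passed to [collider_scenario()].
#' @return a `collider_scenario`.
#' @export
collider_preset <- function(preset = c("selection-on-exposure",
                                       "selection-on-outcome",
                                       "selection-on-both",
                                       "selection-on-common-cause"), ...) {
  name <- match.arg(preset)
  args <- switch(name,
    "selection-on-exposure" = list(b = 0.3, a_x = 1),
    "selection-on-outcome" = list(b = 0.3, a_y = 1),
    "selection-on-both" = list(b = 0, a_x = 1, a_y = 1),
    "selection-on-common-cause" = list(b = 0.3, a_u = 1, u_x = 0.7,
                                       u_y = 0.7))
  sc <- do.call(collider_scenario, utils::modifyList(args, list(...)))
  sc$preset <- name
  sc
}

# joint covariance of (U, X, Y, H, L) implied by a scenario
.scenario_sigma <- function(sc) {
  # rows: loadings of each variable on the independent shocks
  # (e_u, e_x, e_y, e_h, e_s)
  rU <- c(1, 0, 0, 0, 0)
  rX <- sc$u_x * rU + c(0, 1, 0, 0, 0)
  rY <- sc$b * rX + sc$u_y * rU + c(0, 0, 1, 0, 0)
  rH <- sc$h_y * rY + c(0, 0, 0, 1, 0)
  rL <- sc$a_x * rX + sc$a_y * rY + sc$a_u * rU + sc$a_h * rH +
    c(0, 0, 0, 0, 1)
  A <- rbind(U = rU, X = rX, Y = rY, H = rH, L = rL)
  D <- diag(c(1, sc$sd_x^2, sc$sd_y^2, sc$sd_h^2, sc$sd_s^2))
  A %*% D %*% t(A)
}

.scenario_cutoff <- function(sc) {
  stats::qnorm(1 - sc$selection_rate, sd = sqrt(.scenario_sigma(sc)["L", "L"]))
}

#' Exact selected-sample moments and slope for a scenario
#'
#' Conditioning the jointly Gaussian `(X, Y)` on the Gaussian selection
#' index exceeding its cutoff gives closed-form truncated moments: with
#' `alpha = c / sd_L`, `lambda = phi(alpha) / (1 - Phi(alpha))` and
#' `delta = lambda * (lambda - alpha)`,
#' `Cov(V, W | L > c) = Cov(V, W) - Cov(V, L) Cov(W, L) delta / Var(L)`.
#' The selected-sample regression slope is the ratio of the truncated
#' covariance to the truncated exposure variance.
#'
#' @param sc a [collider_scenario()].
#' @return list with `population_slope`, `selected_slope`, `bias`,
#'   `selected_cor` (corr(X, Y | S = 1)) and the truncated moments.
#' @export
scenario_theory <- function(sc) {
  S <- .scenario_sigma(sc)
  cc <- .scenario_cutoff(sc)
  sdL <- sqrt(S["L", "L"])
  alpha <- cc / sdL
  lam <- .mills(-alpha)            # phi(alpha) / (1 - Phi(alpha))
  delta <- lam * (lam - alpha)
  tc <- function(v, w) S[v, w] - S[v, "L"] * S[w, "L"] * delta / S["L", "L"]
  vxx <- tc("X", "X"); vyy <- tc("Y", "Y"); vxy <- tc("X", "Y")
  list(population_slope = S["X", "Y"] / S["X", "X"],
       selected_slope = vxy / vxx,
       bias = vxy / vxx - S["X", "Y"] / S["X", "X"],
       selected_cor = vxy / sqrt(vxx * vyy),
       truncated = c(var_x = vxx, var_y = vyy, cov_xy = vxy))
}

#' Simulate one scenario replicate
#'
#' @param sc a [collider_scenario()].
#' @param seed optional seed override (defaults to the scenario's).
#' @return data frame with columns `X`, `Y`, `U`, `H`, `S` (0/1) and
#'   `prob_select` (the true per-person selection probability given the
#'   structural variables).
#' @export
simulate_scenario <- function(sc, seed = NULL) {
  stopifnot(inherits(sc, "collider_scenario"))
  set.seed(stream_seed(seed %||% sc$seed, "collider"))
  n <- sc$n
  U <- stats::rnorm(n)
  X <- sc$u_x * U + stats::rnorm(n, sd = sc$sd_x)
  Y <- sc$b * X + sc$u_y * U + stats::rnorm(n, sd = sc$sd_y)
  H <- sc$h_y * Y + stats::rnorm(n, sd = sc$sd_h)
  idx <- sc$a_x * X + sc$a_y * Y + sc$a_u * U + sc$a_h * H
  cc <- .scenario_cutoff(sc)
  L <- idx + stats::rnorm(n, sd = sc$sd_s)
  p <- stats::pnorm((idx - cc) / sc$sd_s)
  data.frame(X = X, Y = Y, U = U, H = H, S = as.integer(L > cc),
             prob_select = p)
}

#' Monte-Carlo bias of the selected-sample slope
#'
#' @param sc a [collider_scenario()].
#' @param replicates number of replicates (>= 2).
#' @param seed master seed; replicate r uses `seed + r`.
#' @return list with `population_slope` (exact), `mean_selected_slope`,
#'   `bias`, `mc_se` and the per-replicate slopes.
#' @export
scenario_bias <- function(sc, replicates = 20L, seed = 1L) {
  if (replicates < 2L) stop("need at least 2 replicates")
  slopes <- vapply(seq_len(replicates), function(r) {
    d <- simulate_scenario(sc, seed = seed + r)
    d <- d[d$S == 1L, ]
    unname(stats::coef(stats::lm(Y ~ X, data = d))[2L])
  }, numeric(1))
  th <- scenario_theory(sc)
  list(population_slope = th$population_slope,
       mean_selected_slope = mean(slopes),
       bias = mean(slopes) - th$population_slope,
       mc_se = stats::sd(slopes) / sqrt(replicates),
       slopes = slopes)
}

#' Covariate adjustment versus inverse-probability weighting
#'
#' On the selected sample, compares three estimators of the exposure
#' effect: (i) the naive slope, (ii) the slope adjusting linearly for a
#' selection-driving covariate, (iii) the slope weighted by the true
#' inverse selection probabilities. When the covariate sits on a collider
#' path (it drives selection and is downstream of the outcome), adjustment
#' does not remove the bias but weighting does; when it is a classic
#' confounder and selection is random, adjustment is the correct fix.
#'
#' @param sc a [collider_scenario()].
#' @param control name of the covariate to adjust for, `"H"` or `"U"`.
#' @param replicates Monte-Carlo replicates.
#' @param seed master seed.
#' @return list of class `adjustment_comparison` with the population slope
#'   and, for each estimator, its Monte-Carlo mean and SE.
#' @export
adjustment_vs_weighting <- function(sc, control = c("H", "U"),
                                    replicates = 20L, seed = 1L) {
  control <- match.arg(control)
  est <- matrix(NA_real_, nrow = replicates, ncol = 3L,
                dimnames = list(NULL, c("naive", "adjusted", "weighted")))
  for (r in seq_len(replicates)) {
    d <- simulate_scenario(sc, seed = seed + r)
    s <- d[d$S == 1L, ]
    est[r, "naive"] <- stats::coef(stats::lm(Y ~ X, data = s))[2L]
    fml <- stats::as.formula(paste("Y ~ X +", control))
    est[r, "adjusted"] <- stats::coef(stats::lm(fml, data = s))[2L]
    est[r, "weighted"] <- stats::coef(
      stats::lm(Y ~ X, data = s, weights = 1 / s$prob_select))[2L]
  }
  th <- scenario_theory(sc)
  structure(list(population_slope = th$population_slope,
                 estimates = colMeans(est),
                 mc_se = apply(est, 2L, stats::sd) / sqrt(replicates),
                 control = control, replicates = replicates),
            class = "adjustment_comparison")
}

#' @export
print.adjustment_comparison <- function(x, ...) {
  cat(sprintf("Population slope: %.4f (adjusting for %s)\n",
              x$population_slope, x$control))
  for (e in names(x$estimates)) {
    cat(sprintf("  %-9s %.4f (MC SE %.4f)\n", e, x$estimates[[e]],
                x$mc_se[[e]]))
  }
  invisible(x)
}

#' Run a batch of collider scenarios
#'
#' @param scenarios named list of [collider_scenario()] objects.
#' @param replicates,seed passed to [scenario_bias()].
#' @param path optional CSV output (scenario, estimator, slope, bias,
#'   mc_se).
#' @return data frame with one row per scenario.
#' @export
collider_batch <- function(scenarios, replicates = 20L, seed = 1L,
                           path = NULL) {
  rows <- lapply(names(scenarios), function(nm) {
    sb <- scenario_bias(scenarios[[nm]], replicates = replicates,
                        seed = seed)
    th <- scenario_theory(scenarios[[nm]])
    data.frame(scenario = nm,
               population_slope = sb$population_slope,
               selected_slope = sb$mean_selected_slope,
               theory_selected_slope = th$selected_slope,
               bias = sb$bias, theory_bias = th$bias, mc_se = sb$mc_se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
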