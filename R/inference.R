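#' Weighted mean
#'
#' @param x numeric vector.
#' @param w positive weights (default uniform).
#' @return `sum(w * x) / sum(w)`.
#' @export
weighted_mean <- function(x, w = NULL) {
  if (length(x) == 0L) stop("empty input")
  if (is.null(w)) return(mean(x))
  stopifnot(length(w) == length(x), all(w > 0))
  sum(w * x) / sum(w)
}

#' Weighted standard deviation
#'
#' Weights are internally normalized to sum to the number of observations,
#' then `sqrt(sum(w * (x - xbar_w)^2) / (sum(w) - 1))` — the convention that
#' reduces to the ordinary sample SD under uniform weights.
#'
#' @inheritParams weighted_mean
#' @return nonnegative scalar; 0 for constant input.
#' @export
weighted_sd <- function(x, w = NULL) {
  n <- length(x)
  if (n == 0L) stop("empty input")
  if (is.null(w)) w <- rep(1, n)
  stopifnot(length(w) == n, all(w > 0))
  w <- w * n / sum(w)
  if (sum(w) <= 1) stop("need total weight > 1")
  m <- sum(w * x) / sum(w)
  sqrt(sum(w * (x - m)^2) / (sum(w) - 1))
}

.new_assoc_estimate <- function(outcome, exposure, beta, robust_se, n_used,
                                weighted) {
  structure(list(outcome = outcome, exposure = exposure, beta = beta,
                 robust_se = robust_se, n_used = n_used, weighted = weighted,
                 ci95 = c(beta - 1.96 * robust_se, beta + 1.96 * robust_se)),
            class = "association_estimate")
}

#' @export
print.association_estimate <- function(x, ...) {
  cat(sprintf("%s ~ %s: beta = %.4f (robust SE %.4f, 95%% CI %.4f..%.4f), n = %d%s\n",
              x$outcome, x$exposure, x$beta, x$robust_se,
              x$ci95[1], x$ci95[2], x$n_used,
              if (x$weighted) ", weighted" else ""))
  invisible(x)
}

#' Bivariate linear (probability) model with robust standard errors
#'
#' Fits `y ~ x` by (weighted) least squares and reports the slope with an
#' HC1 heteroskedasticity-robust sandwich standard error,
#' `(X'WX)^-1 (sum w_i^2 e_i^2 x_i x_i') (X'WX)^-1 * n/(n-2)`. With a binary
#' outcome this is a linear probability model whose slope is a risk
#' difference. Weights are treated as sampling weights.
#'
#' @param y outcome (binary 0/1 or real).
#' @param x exposure (binary 0/1 or real), non-constant.
#' @param w optional positive weights.
#' @param outcome,exposure names recorded on the estimate.
#' @param hc sandwich flavour, `"HC1"` (default) or `"HC0"`.
#' @return an `association_estimate`.
#' @export
fit_bivariate_lpm <- function(y, x, w = NULL, outcome = "y", exposure = "x",
                              hc = c("HC1", "HC0")) {
  hc <- match.arg(hc)
  ok <- if (is.null(w)) stats::complete.cases(y, x) else
    stats::complete.cases(y, x, w)
  y <- y[ok]; x <- x[ok]
  if (!is.null(w)) w <- w[ok]
  if (length(unique(x)) < 2L) stop("exposure is constant among used rows")
  fit <- if (is.null(w)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = w)
  V <- sandwich::vcovHC(fit, type = ifelse(hc == "HC1", "HC1", "HC0"))
  .new_assoc_estimate(outcome, exposure,
                      beta = unname(stats::coef(fit)[2L]),
                      robust_se = sqrt(V[2L, 2L]),
                      n_used = length(y), weighted = !is.null(w))
}

#' Standardized bivariate linear model
#'
#' Standardizes both variables to mean 0 and variance 1 — with weighted
#' moments when weights are supplied, ordinary moments otherwise — and then
#' fits the bivariate model of [fit_bivariate_lpm()]. On bivariate Gaussian
#' data the slope is the Pearson correlation.
#'
#' @inheritParams fit_bivariate_lpm
#' @return an `association_estimate`.
#' @export
fit_standardized_linear <- function(y, x, w = NULL, outcome = "y",
                                    exposure = "x", hc = "HC1") {
  ok <- if (is.null(w)) stats::complete.cases(y, x) else
    stats::complete.cases(y, x, w)
  y <- y[ok]; x <- x[ok]
  if (!is.null(w)) w <- w[ok]
  sy <- weighted_sd(y, w); sx <- weighted_sd(x, w)
  if (sy == 0 || sx == 0) stop("zero variance; cannot standardize")
  ys <- (y - weighted_mean(y, w)) / sy
  xs <- (x - weighted_mean(x, w)) / sx
  fit_bivariate_lpm(ys, xs, w, outcome = outcome, exposure = exposure,
                    hc = hc)
}

#' Compare two association estimates with a Z-statistic
#'
#' Tests the null that the two slopes are equal, treating the samples as
#' independent: `z = (beta_a - beta_b) / sqrt(se_a^2 + se_b^2)`,
#' `p = 2 * (1 - Phi(|z|))`. The variances are added; a subtracted-variance
#' variant sometimes seen in print is not a valid standard error for a
#' difference of independent estimates.
#'
#' @param a,b `association_estimate`s for the same outcome/exposure pair.
#' @return list with `z` and `p_two_sided`.
#' @export
compare_associations <- function(a, b) {
  stopifnot(inherits(a, "association_estimate"),
            inherits(b, "association_estimate"))
  if (a$outcome != b$outcome || a$exposure != b$exposure) {
    stop("estimates are for different outcome/exposure pairs")
  }
  z <- (a$beta - b$beta) / sqrt(a$robust_se^2 + b$robust_se^2)
  list(z = z, p_two_sided = 2 * stats::pnorm(-abs(z)))
}

#' Fraction of selection bias removed by weighting
#'
#' `1 - |weighted - ref| / |unweighted - ref|`: 1 means weighting fully
#' recovers the reference association, 0 means no change, negative values
#' mean weighting moved the estimate further from the reference. Undefined
#' (returns `NA` with attribute `undefined = TRUE`) when the unweighted
#' estimate is already within `tol` of the reference.
#'
#' @param ref reference-sample slope.
#' @param unweighted unweighted cohort slope.
#' @param weighted weighted cohort slope.
#' @param tol minimum unweighted bias for the ratio to be defined.
#' @return scalar in (-Inf, 1], or flagged `NA`.
#' @export
bias_reduction <- function(ref, unweighted, weighted, tol = 1e-8) {
  denom <- abs(unweighted - ref)
  if (denom <= tol) {
    return(structure(NA_real_, undefined = TRUE))
  }
  1 - abs(weighted - ref) / denom
}

# ---- association batch machinery -------------------------------------------

#' Declare one outcome/exposure association
#'
#' Each side is either `"var=level"` (the 0/1 indicator of a level) or a
#' bare variable name (its numeric map via [derive_numeric()]).
#'
#' @param outcome,exposure side specifications.
#' @param type `"lpm"` (bivariate linear probability / linear model on the
#'   raw scale) or `"std"` (both sides standardized).
#' @return a list of class `association_spec`.
#' @export
assoc <- function(outcome, exposure, type = c("lpm", "std")) {
  structure(list(outcome = outcome, exposure = exposure,
                 type = match.arg(type)),
            class = "association_spec")
}

# variable name underlying a side spec
.assoc_var <- function(side) sub("=.*$", "", side)

# numeric column for a side spec
.assoc_column <- function(side, table, cb) {
  if (grepl("=", side, fixed = TRUE)) {
    var <- sub("=.*$", "", side)
    lev <- sub("^[^=]*=", "", side)
    if (!lev %in% cb_levels(cb, var)) {
      stop("'", lev, "' is not a level of '", var, "'")
    }
    as.numeric(table[[var]] == lev)
  } else {
    derive_numeric(table, cb, side)
  }
}

#' Estimate a batch of associations in reference, cohort and weighted cohort
#'
#' For every declared association this computes the reference-sample
#' estimate, the unweighted cohort estimate and the IP-weighted cohort
#' estimate, the Z-test of cohort versus reference, and the fraction of the
#' cohort's bias removed by weighting.
#'
#' @param associations list of [assoc()] specifications.
#' @param cohort,reference harmonized person tables.
#' @param weights a `weight_set` for the cohort (e.g.
#'   `weights(participation_model(...))` or [oracle_weights()]).
#' @param cb a [codebook()].
#' @return a data frame of class `association_comparison` with one row per
#'   association: slopes and robust SEs for the three estimates, `z`
#'   (unweighted cohort vs reference), `p`, `z_weighted`, `p_weighted`, and
#'   `bias_reduction`.
#' @export
estimate_associations <- function(associations, cohort, reference, weights,
                                  cb) {
  stopifnot(inherits(weights, "weight_set"))
  w <- weights$weight[match(cohort$person_id, weights$person_id)]
  keep <- !is.na(w)
  cohort_w <- cohort[keep, , drop = FALSE]
  w <- w[keep]
  rows <- lapply(associations, function(a) {
    fitter <- if (a$type == "lpm") fit_bivariate_lpm else
      fit_standardized_linear
    yr <- .assoc_column(a$outcome, reference, cb)
    xr <- .assoc_column(a$exposure, reference, cb)
    yc <- .assoc_column(a$outcome, cohort, cb)
    xc <- .assoc_column(a$exposure, cohort, cb)
    ycw <- .assoc_column(a$outcome, cohort_w, cb)
    xcw <- .assoc_column(a$exposure, cohort_w, cb)
    ref <- fitter(yr, xr, outcome = a$outcome, exposure = a$exposure)
    unw <- fitter(yc, xc, outcome = a$outcome, exposure = a$exposure)
    wtd <- fitter(ycw, xcw, w = w, outcome = a$outcome,
                  exposure = a$exposure)
    cmp_u <- compare_associations(ref, unw)
    cmp_w <- compare_associations(ref, wtd)
    br <- bias_reduction(ref$beta, unw$beta, wtd$beta)
    data.frame(outcome = a$outcome, exposure = a$exposure, type = a$type,
               beta_ref = ref$beta, se_ref = ref$robust_se,
               n_ref = ref$n_used,
               beta_unweighted = unw$beta, se_unweighted = unw$robust_se,
               n_cohort = unw$n_used,
               beta_weighted = wtd$beta, se_weighted = wtd$robust_se,
               z = cmp_u$z, p = cmp_u$p_two_sided,
               z_weighted = cmp_w$z, p_weighted = cmp_w$p_two_sided,
               bias_reduction = as.numeric(br),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("association_comparison", "data.frame")
  out
}

#' Long-format export of an association comparison
#'
#' One row per (association, sample) with the stable column layout
#' `outcome, exposure, sample, weighted, beta, robust_se, ci_low, ci_high,
#' z_vs_reference, p, bias_reduction`.
#'
#' @param comparison an `association_comparison`.
#' @param path optional CSV path; when given the table is also written.
#' @return the long-format data frame, invisibly when `path` is given.
#' @export
association_long <- function(comparison, path = NULL) {
  longs <- lapply(seq_len(nrow(comparison)), function(i) {
    r <- comparison[i, ]
    data.frame(
      outcome = r$outcome, exposure = r$exposure,
      sample = c("reference", "cohort", "cohort"),
      weighted = c(FALSE, FALSE, TRUE),
      beta = c(r$beta_ref, r$beta_unweighted, r$beta_weighted),
      robust_se = c(r$se_ref, r$se_unweighted, r$se_weighted),
      z_vs_reference = c(NA, r$z, r$z_weighted),
      p = c(NA, r$p, r$p_weighted),
      bias_reduction = c(NA, NA, r$bias_reduction),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, longs)
  out$ci_low <- out$beta - 1.96 * out$robust_se
  out$ci_high <- out$beta + 1.96 * out$robust_se
  out <- out[c("outcome", "exposure", "sample", "weighted", "beta",
               "robust_se", "ci_low", "ci_high", "z_vs_reference", "p",
               "bias_reduction")]
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, na = "")
    return(invisible(out))
  }
  out
}

#' Mean bias reduction over a comparison table
#'
#' Associations whose unweighted bias is undefined (below tolerance) carry
#' `NA` and are excluded from the average.
#'
#' @param comparison an `association_comparison`.
#' @param type optionally restrict to `"lpm"` or `"std"` rows.
#' @return scalar mean bias reduction.
#' @export
mean_bias_reduction <- function(comparison, type = NULL) {
  x <- comparison
  if (!is.null(type)) x <- x[x$type == type, , drop = FALSE]
  mean(x$bias_reduction, na.rm = TRUE)
}
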