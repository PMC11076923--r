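#' Kish effective sample size
#'
#' `(sum w)^2 / sum(w^2)`: the size of an equal-weight sample with the same
#' precision as the weighted one. Invariant to rescaling of the weights;
#' equals `n` iff all weights are equal.
#'
#' @param w a `weight_set` or a positive numeric vector.
#' @return scalar in (0, n].
#' @export
kish_ess <- function(w) {
  if (inherits(w, "weight_set")) w <- w$weight
  if (length(w) == 0L) stop("empty weights")
  if (any(w <= 0)) stop("weights must be positive")
  sum(w)^2 / sum(w^2)
}

#' Regression-specific effective sample size
#'
#' The equal-weight sample size that would give the weighted estimate's
#' precision: `n * (se_unweighted / se_weighted)^2`.
#'
#' @param se_unweighted,se_weighted robust standard errors of the same
#'   slope, unweighted and weighted.
#' @param n cohort size used in the regressions.
#' @return scalar.
#' @export
regression_ess <- function(se_unweighted, se_weighted, n) {
  if (se_unweighted <= 0 || se_weighted <= 0) stop("standard errors must be positive")
  n * (se_unweighted / se_weighted)^2
}

#' Weight distribution summary
#'
#' @param w a `weight_set` or positive numeric vector.
#' @param probs quantile probabilities.
#' @return data frame with quantiles, min, max, max/min ratio and the
#'   boundary-flag count.
#' @export
weight_summary <- function(w, probs = c(.01, .05, .25, .5, .75, .95, .99)) {
  n_boundary <- if (inherits(w, "weight_set"))
    length(attr(w, "boundary_ids")) else 0L
  if (inherits(w, "weight_set")) w <- w$weight
  if (length(w) == 0L) stop("empty weights")
  q <- stats::quantile(w, probs, names = FALSE)
  data.frame(statistic = c("min", paste0("q", probs * 100), "max",
                           "max_min_ratio", "n", "n_boundary"),
             value = c(min(w), q, max(w), max(w) / min(w), length(w),
                       n_boundary))
}

#' Effective-sample-size report
#'
#' Combines the weight-distribution (Kish) method with the
#' regression-specific method applied to every association in a comparison
#' table.
#'
#' @param weights a `weight_set` for the cohort.
#' @param comparison an `association_comparison` from
#'   [estimate_associations()].
#' @return list of class `ess_report`: `n_cohort`, `kish_ess`,
#'   `kish_fraction`, `per_association` (model, regression ESS, fraction)
#'   and `mean_regression_ess`.
#' @export
ess_report <- function(weights, comparison) {
  n <- nrow(weights)
  kish <- kish_ess(weights)
  per <- data.frame(
    model = paste(comparison$outcome, "~", comparison$exposure),
    regression_ess = mapply(regression_ess, comparison$se_unweighted,
                            comparison$se_weighted, comparison$n_cohort),
    stringsAsFactors = FALSE)
  per$fraction <- per$regression_ess / comparison$n_cohort
  structure(list(n_cohort = n, kish_ess = kish, kish_fraction = kish / n,
                 per_association = per,
                 mean_regression_ess = mean(per$regression_ess)),
            class = "ess_report")
}

#' @export
print.ess_report <- function(x, ...) {
  cat(sprintf("Effective sample size (cohort n = %d)\n", x$n_cohort))
  cat(sprintf("  Kish (weight distribution): %.0f (%.1f%%)\n",
              x$kish_ess, 100 * x$kish_fraction))
  cat(sprintf("  regression-specific: mean %.0f, range %.0f..%.0f over %d models\n",
              x$mean_regression_ess, min(x$per_association$regression_ess),
              max(x$per_association$regression_ess),
              nrow(x$per_association)))
  invisible(x)
}

#' Leave-one-out robustness of the weights
#'
#' For every association, both of its variables are removed from the
#' participation model (all their dummies and interactions), the penalized
#' probit is re-estimated from scratch — same penalty-selection procedure,
#' same seed, full penalty grid — the weights are recomputed, and the
#' association's bias reduction is re-evaluated under the reduced-model
#' weights. This measures how much of the correction survives when the
#' weights cannot use the very variables being associated.
#'
#' @param cohort,reference harmonized, complete person tables (as used for
#'   the full model).
#' @param cb a [codebook()].
#' @param associations list of [assoc()] specs.
#' @param full_comparison the `association_comparison` under the full-model
#'   weights.
#' @param vars model variables of the full model.
#' @param folds,seed,cv_tol,tol passed to [participation_model()].
#' @return list of class `robustness_report`: `per_association` data frame
#'   (dropped variables, refit lambda, reduced-model bias reduction),
#'   `mean_bias_reduction_full`, `mean_bias_reduction_reduced`.
#' @export
leave_one_out_robustness <- function(cohort, reference, cb, associations,
                                     full_comparison, vars = NULL,
                                     folds = 10L, seed = 1L,
                                     cv_tol = 1e-3, tol = 1e-6) {
  vars <- vars %||% cb_var_names(cb)
  rows <- lapply(seq_along(associations), function(i) {
    a <- associations[[i]]
    drop_vars <- unique(c(.assoc_var(a$outcome), .assoc_var(a$exposure)))
    bad <- setdiff(drop_vars, vars)
    if (length(bad)) {
      stop("association variable(s) not in the participation design: ",
           paste(bad, collapse = ", "))
    }
    red_vars <- setdiff(vars, drop_vars)
    m <- participation_model(cohort, reference, cb, vars = red_vars,
                             folds = folds, seed = seed, impute = FALSE,
                             cv_tol = cv_tol, tol = tol)
    cmp <- estimate_associations(list(a), cohort, reference,
                                 weights(m), cb)
    data.frame(outcome = a$outcome, exposure = a$exposure,
               dropped = paste(drop_vars, collapse = "+"),
               refit_lambda = m$fit$chosen_lambda,
               bias_reduction_full = full_comparison$bias_reduction[i],
               bias_reduction_reduced = cmp$bias_reduction[1L],
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  structure(list(per_association = per,
                 mean_bias_reduction_full =
                   mean(per$bias_reduction_full, na.rm = TRUE),
                 mean_bias_reduction_reduced =
                   mean(per$bias_reduction_reduced, na.rm = TRUE)),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("Leave-one-out robustness of the participation weights\n")
  cat(sprintf("  mean bias reduction, full model:    %.3f\n",
              x$mean_bias_reduction_full))
  cat(sprintf("  mean bias reduction, reduced models: %.3f\n",
              x$mean_bias_reduction_reduced))
  invisible(x)
}
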