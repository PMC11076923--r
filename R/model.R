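#' Fit the participation model and construct inverse-probability weights
#'
#' The central fitting function. Missing model variables are imputed by
#' exact matching within each source table, the cohort and reference tables
#' are concatenated with membership labels (cohort = 1, reference = 0), the
#' full dummy + two-way-interaction design is built, an L1-penalized probit
#' is fit with the penalty chosen by stratified cross-validation, and
#' normalized inverse-probability weights are computed for the cohort rows.
#'
#' @param cohort person table of volunteers.
#' @param reference person table of the representative reference sample.
#' @param cb a [codebook()] declaring the harmonized model variables.
#' @param vars model variables (default: all codebook variables).
#' @param lambdas optional decreasing penalty grid.
#' @param folds CV folds (default 10).
#' @param seed master seed (fold assignment, imputation draws).
#' @param interactions include two-way interactions (default `TRUE`).
#' @param weight_type see [compute_ip_weights()].
#' @param impute impute missing model variables first (default `TRUE`).
#' @param cv_tol,tol solver tolerances, see [cross_validate_lambda()].
#' @return an object of class `participation_model` with components `fit`
#'   (the `participation_fit`), `weights` (a `weight_set` for the cohort),
#'   `probabilities` (cohort participation probabilities), `design`
#'   metadata, `excluded_ids`, and sample sizes.
#' @examples
#' cbk <- codebook(list(
#'   cb_variable("health", c("good", "poor")),
#'   cb_variable("work", c("yes", "no"))))
#' set.seed(1)
#' pop <- data.frame(person_id = as.character(1:2000),
#'                   health = sample(c("good", "poor"), 2000, TRUE),
#'                   work = sample(c("yes", "no"), 2000, TRUE))
#' p <- ifelse(pop$health == "good", 0.3, 0.1)
#' cohort <- pop[runif(2000) < p, ]
#' reference <- pop[runif(2000) < 0.2, ]
#' m <- participation_model(cohort, reference, cbk, folds = 3, seed = 1)
#' print(m)
#' @export
participation_model <- function(cohort, reference, cb, vars = NULL,
                                lambdas = NULL, folds = 10L, seed = 1L,
                                interactions = TRUE,
                                weight_type = "inverse_odds",
                                impute = TRUE, cv_tol = 1e-3, tol = 1e-6) {
  stopifnot(is.data.frame(cohort), is.data.frame(reference),
            inherits(cb, "codebook"))
  vars <- vars %||% cb_var_names(cb)
  excluded <- character(0)
  imp_log <- NULL
  if (impute) {
    ic <- impute_exact_match(cohort, vars, seed = seed)
    ir <- impute_exact_match(reference, vars, seed = seed + 1L)
    cohort <- ic$table; reference <- ir$table
    excluded <- c(ic$excluded_ids, ir$excluded_ids)
    imp_log <- list(cohort = ic$log, reference = ir$log)
  }
  keep <- intersect(names(cohort), names(reference))
  stacked <- rbind(cohort[keep], reference[keep])
  labels <- c(rep(1L, nrow(cohort)), rep(0L, nrow(reference)))
  design <- build_design_matrix(stacked, cb, vars = vars,
                                interactions = interactions, prune = TRUE)
  fit <- cross_validate_lambda(design, labels, lambdas = lambdas,
                               folds = folds, seed = seed,
                               tol = tol, cv_tol = cv_tol)
  pi_hat <- predict_probability(fit, design)[labels == 1L]
  w <- compute_ip_weights(pi_hat, person_id = cohort$person_id,
                          type = weight_type)
  attr(w, "excluded_ids") <- excluded
  structure(list(fit = fit, weights = w,
                 probabilities = stats::setNames(as.numeric(pi_hat),
                                                 cohort$person_id),
                 n_clipped = attr(pi_hat, "n_clipped"),
                 vars = vars, codebook = cb,
                 design_cols = colnames(design$X),
                 n_col_full = design$n_col_full,
                 prune_log = design$prune_log,
                 interactions = interactions,
                 excluded_ids = excluded, impute_log = imp_log,
                 n_cohort = nrow(cohort), n_reference = nrow(reference),
                 seed = seed, weight_type = weight_type),
            class = "participation_model")
}

#' @export
print.participation_model <- function(x, ...) {
  cat("Participation model (penalized probit, cohort vs reference)\n")
  cat(sprintf("  cohort n = %d, reference n = %d\n", x$n_cohort,
              x$n_reference))
  cat(sprintf("  design: %d columns after pruning (%d before)\n",
              length(x$design_cols), x$n_col_full))
  cat(sprintf("  chosen lambda = %.6g; %d slope(s) selected\n",
              x$fit$chosen_lambda, x$fit$n_selected))
  cat(sprintf("  Kish effective sample size: %.0f (%.1f%% of cohort)\n",
              kish_ess(x$weights),
              100 * kish_ess(x$weights) / x$n_cohort))
  invisible(x)
}

#' @export
summary.participation_model <- function(object, ...) {
  w <- object$weights$weight
  out <- list(
    n_cohort = object$n_cohort, n_reference = object$n_reference,
    n_design_columns = length(object$design_cols),
    n_design_columns_full = object$n_col_full,
    chosen_lambda = object$fit$chosen_lambda,
    n_selected = object$fit$n_selected,
    kish_ess = kish_ess(object$weights),
    kish_fraction = kish_ess(object$weights) / object$n_cohort,
    weight_quantiles = stats::quantile(w, c(0, .01, .25, .5, .75, .99, 1)),
    n_excluded = length(object$excluded_ids),
    n_clipped = object$n_clipped %||% 0L)
  class(out) <- "summary.participation_model"
  out
}

#' @export
print.summary.participation_model <- function(x, ...) {
  cat("Participation model summary\n")
  cat(sprintf("  cohort n = %d, reference n = %d (%d excluded, no donor)\n",
              x$n_cohort, x$n_reference, x$n_excluded))
  cat(sprintf("  design columns: %d after pruning (%d before)\n",
              x$n_design_columns, x$n_design_columns_full))
  cat(sprintf("  chosen lambda: %.6g; selected slopes: %d\n",
              x$chosen_lambda, x$n_selected))
  cat(sprintf("  Kish ESS: %.0f (%.1f%% of cohort)\n",
              x$kish_ess, 100 * x$kish_fraction))
  cat("  weight quantiles:\n")
  print(round(x$weight_quantiles, 4))
  invisible(x)
}

#' @export
coef.participation_model <- function(object, ...) {
  coef(object$fit, ...)
}

#' Predict participation probabilities or weights for new persons
#'
#' @param object a `participation_model`.
#' @param newdata person table of harmonized values (no missing model
#'   variables); defaults to returning the cohort's fitted values.
#' @param type `"response"` (probability), `"link"` (probit index) or
#'   `"weight"` (normalized IP weight among `newdata` rows).
#' @param ... unused.
#' @export
predict.participation_model <- function(object, newdata = NULL,
                                        type = c("response", "link",
                                                 "weight"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    p <- object$probabilities
  } else {
    design <- build_design_matrix(newdata, object$codebook,
                                  vars = object$vars,
                                  interactions = object$interactions,
                                  prune = FALSE)
    p <- predict_probability(object$fit, design)
    names(p) <- newdata$person_id
  }
  switch(type,
         response = p,
         link = stats::qnorm(p),
         weight = compute_ip_weights(p, person_id = names(p),
                                     type = object$weight_type))
}

#' @export
weights.participation_model <- function(object, ...) object$weights

#' Plot the cross-validation deviance curve
#'
#' @param x a `participation_model`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.participation_model <- function(x, ...) {
  fit <- x$fit
  graphics::plot(log(fit$lambda_grid), fit$cv_deviance, type = "b",
                 xlab = "log(lambda)", ylab = "mean held-out deviance",
                 main = "Participation model cross-validation", ...)
  graphics::arrows(log(fit$lambda_grid), fit$cv_deviance - fit$cv_se,
                   log(fit$lambda_grid), fit$cv_deviance + fit$cv_se,
                   angle = 90, code = 3, length = 0.03, col = "grey50")
  graphics::abline(v = log(fit$chosen_lambda), lty = 2)
  invisible(x)
}
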