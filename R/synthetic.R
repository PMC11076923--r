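#' Specify a synthetic eligible population
#'
#' The generator emulates the harmonized person table of a cohort's target
#' population: a set of categorical socio-demographic and health variables
#' with given marginal distributions, whose cross-variable dependence is
#' induced by a Gaussian copula (correlated latent normal scores cut at the
#' marginal quantiles). This yields exact marginals with arbitrary pairwise
#' latent correlation.
#'
#' @param n_population number of eligible persons.
#' @param variables list of variables, each a list with `name`, `levels`
#'   (character) and `probs` (marginal probabilities summing to 1); a
#'   [cb_variable()]-compatible `numeric` map may be included and is carried
#'   into [population_codebook()].
#' @param latent_correlation symmetric positive semi-definite matrix with
#'   unit diagonal, one row/column per variable (in order). Defaults to
#'   independence.
#' @param seed integer seed for the population stream.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n_population, variables,
                            latent_correlation = NULL, seed = 1L) {
  stopifnot(.is_count(n_population))
  k <- length(variables)
  if (k == 0L) stop("at least one variable is required")
  for (v in variables) {
    if (is.null(v$name) || is.null(v$levels) || is.null(v$probs)) {
      stop("each variable needs 'name', 'levels' and 'probs'")
    }
    if (length(v$levels) != length(v$probs)) {
      stop("variable '", v$name, "': levels and probs differ in length")
    }
    if (abs(sum(v$probs) - 1) > 1e-12) {
      stop("variable '", v$name, "': marginal probabilities must sum to 1 (got ",
           format(sum(v$probs), digits = 15), ")")
    }
    if (any(v$probs < 0)) stop("variable '", v$name, "': negative probability")
  }
  if (is.null(latent_correlation)) latent_correlation <- diag(k)
  latent_correlation <- as.matrix(latent_correlation)
  if (!isTRUE(all.equal(dim(latent_correlation), c(k, k)))) {
    stop("latent_correlation must be ", k, "x", k)
  }
  if (max(abs(latent_correlation - t(latent_correlation))) > 1e-10) {
    stop("latent_correlation must be symmetric")
  }
  if (max(abs(diag(latent_correlation) - 1)) > 1e-10) {
    stop("latent_correlation must have unit diagonal")
  }
  ev <- eigen(latent_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("latent_correlation is not positive semi-definite: smallest eigenvalue ",
         format(min(ev), digits = 6))
  }
  nms <- vapply(variables, `[[`, character(1), "name")
  names(variables) <- nms
  structure(list(n_population = as.integer(n_population),
                 variables = variables,
                 latent_correlation = latent_correlation,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Codebook implied by a population specification
#'
#' @param spec a [population_spec()].
#' @param eligibility optional eligibility block, see [codebook()].
#' @return a `codebook` whose variables and levels match the generator.
#' @export
population_codebook <- function(spec, eligibility = NULL) {
  vars <- lapply(spec$variables, function(v) {
    cb_variable(v$name, v$levels, numeric = v$numeric)
  })
  codebook(vars, eligibility = eligibility)
}

#' Generate the eligible target population
#'
#' Draws `n_population` persons. For each person a vector of latent standard
#' normal scores with the specified correlation is discretized at the
#' cumulative-marginal quantile cut-points, so each variable has (up to
#' sampling noise) its specified marginal distribution and the cross-variable
#' dependence implied by the latent correlation.
#'
#' @param spec a [population_spec()].
#' @return a person table (`data.frame`) with columns `person_id`, one column
#'   per variable, and `source = "population"`.
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(stream_seed(spec$seed, "population"))
  n <- spec$n_population
  k <- length(spec$variables)
  L <- chol(spec$latent_correlation, pivot = FALSE)
  z <- matrix(stats::rnorm(n * k), nrow = n, ncol = k) %*% L
  out <- data.frame(person_id = sprintf("P%07d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    v <- spec$variables[[j]]
    cuts <- stats::qnorm(cumsum(v$probs))
    cuts[length(cuts)] <- Inf
    idx <- findInterval(z[, j], c(-Inf, cuts[-length(cuts)]))
    out[[v$name]] <- v$levels[idx]
  }
  out$source <- "population"
  out
}

#' Draw a census-like reference sample
#'
#' A simple random subsample of the eligible population followed by an
#' (by default) independent response filter, emulating a high-response
#' census microdata extract. Defaults follow the census design the pipeline
#' targets: a 5% random subsample with a 95% response rate.
#'
#' @param pop population person table from [generate_population()].
#' @param sampling_fraction fraction sampled, in (0, 1].
#' @param response_rate response rate among the sampled, in (0, 1].
#' @param seed integer seed for the reference stream.
#' @param response_prob optional per-person response probabilities (length
#'   `nrow(pop)`) for sensitivity runs with response dependent on covariates;
#'   overrides `response_rate`.
#' @return a person table with `source = "reference"`.
#' @export
draw_reference_sample <- function(pop, sampling_fraction = 0.05,
                                  response_rate = 0.95, seed = 1L,
                                  response_prob = NULL) {
  stopifnot(is.data.frame(pop))
  if (!(sampling_fraction > 0 && sampling_fraction <= 1)) {
    stop("sampling_fraction must be in (0, 1]")
  }
  if (!(response_rate > 0 && response_rate <= 1)) {
    stop("response_rate must be in (0, 1]")
  }
  n <- nrow(pop)
  if (sampling_fraction * response_rate * n < 50) {
    stop("reference sample would have fewer than 50 expected rows; ",
         "too small to estimate participation weights")
  }
  set.seed(stream_seed(seed, "reference"))
  sampled <- stats::runif(n) < sampling_fraction
  if (is.null(response_prob)) {
    responded <- stats::runif(n) < response_rate
  } else {
    stopifnot(length(response_prob) == n)
    .assert_prob(response_prob, "response_prob")
    responded <- stats::runif(n) < response_prob
  }
  out <- pop[sampled & responded, , drop = FALSE]
  out$source <- "reference"
  out$true_prob <- NULL
  rownames(out) <- NULL
  out
}

#' Specify the volunteer-selection mechanism
#'
#' Participation is modelled as a probit: each person volunteers with
#' probability `Phi(intercept + x' beta)`, where `x` are dummy (and
#' optionally dummy-interaction) columns of the population design matrix.
#' When `target_rate` is given the intercept is re-solved so that the
#' realized mean participation probability matches it to within 0.001,
#' emulating a cohort with a known overall participation rate (the default,
#' 0.055, is a low-participation volunteer cohort).
#'
#' @param coefficients named numeric vector; names are design-matrix column
#'   names (`main:VAR=LEVEL` or `int:V1=L1:V2=L2`).
#' @param intercept probit intercept (ignored when `target_rate` is set).
#' @param target_rate optional overall participation rate in (0, 1).
#' @param link `"probit"` (default) or `"logit"` for misspecification
#'   experiments.
#' @param seed integer seed for the selection stream.
#' @return an object of class `selection_spec`.
#' @export
selection_spec <- function(coefficients, intercept = 0,
                           target_rate = NULL, link = c("probit", "logit"),
                           seed = 1L) {
  link <- match.arg(link)
  if (length(coefficients)) {
    stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  }
  if (!is.null(target_rate) &&
      !(target_rate > 0 && target_rate < 1)) {
    stop("target_rate must lie in (0, 1)")
  }
  structure(list(coefficients = coefficients, intercept = intercept,
                 target_rate = target_rate, link = link,
                 seed = as.integer(seed)),
            class = "selection_spec")
}

.sel_linkinv <- function(eta, link) {
  if (link == "probit") stats::pnorm(eta) else stats::plogis(eta)
}

# linear predictor x'beta for a selection spec on a population table
.selection_index <- function(pop, sel, cb) {
  if (!length(sel$coefficients)) return(rep(0, nrow(pop)))
  dm <- build_design_matrix(pop, cb, prune = FALSE)
  miss <- setdiff(names(sel$coefficients), colnames(dm$X))
  if (length(miss)) {
    stop("selection coefficients name unknown design columns: ",
         paste(miss, collapse = ", "))
  }
  as.numeric(dm$X[, names(sel$coefficients), drop = FALSE] %*%
               sel$coefficients)
}

#' True participation probabilities under a selection mechanism
#'
#' Evaluates `Phi(intercept + x' beta)` (or the logistic analogue) for
#' every person in `pop`, solving the intercept for the target
#' participation rate when one is set. Useful when many replicate cohorts
#' are drawn from the same population: the probabilities depend only on
#' the population and the mechanism, so they can be computed once.
#'
#' @param pop population person table.
#' @param sel a [selection_spec()].
#' @param cb codebook used to build the selection design.
#' @return numeric vector of participation probabilities (one per row of
#'   `pop`) with the solved intercept attached as attribute `intercept`.
#' @export
participation_probabilities <- function(pop, sel, cb) {
  stopifnot(is.data.frame(pop), inherits(sel, "selection_spec"))
  idx <- .selection_index(pop, sel, cb)
  intercept <- sel$intercept
  if (!is.null(sel$target_rate)) {
    f <- function(b0) mean(.sel_linkinv(b0 + idx, sel$link)) - sel$target_rate
    intercept <- stats::uniroot(f, lower = -20, upper = 20, tol = 1e-10)$root
  }
  p <- .sel_linkinv(intercept + idx, sel$link)
  eps <- .Machine$double.eps
  if (any(p <= eps) || any(p >= 1 - eps)) {
    warning("some participation probabilities are 0 or 1 to machine ",
            "precision; weights for such strata are undefined or unstable")
  }
  if (!is.null(sel$target_rate) &&
      abs(mean(p) - sel$target_rate) > 0.001) {
    stop("could not solve intercept for target participation rate")
  }
  attr(p, "intercept") <- intercept
  p
}

#' Draw the volunteer cohort from the population
#'
#' Each person participates independently with probability
#' `Phi(intercept + x' beta)` (or the logistic analogue). The realized
#' participation probability is kept in column `true_prob`, giving every
#' downstream stage a ground truth for oracle weighting.
#'
#' @param pop population person table.
#' @param sel a [selection_spec()].
#' @param cb codebook used to build the selection design (defaults to the
#'   levels observed in `pop` in column order).
#' @return a person table of volunteers with `source = "cohort"` and
#'   `true_prob`; the solved intercept and realized rate are attached as
#'   attributes `intercept` and `realized_rate`.
#' @export
draw_volunteers <- function(pop, sel, cb) {
  p <- participation_probabilities(pop, sel, cb)
  intercept <- attr(p, "intercept")
  p <- as.vector(p)
  set.seed(stream_seed(sel$seed, "selection"))
  take <- stats::runif(nrow(pop)) < p
  out <- pop[take, , drop = FALSE]
  out$source <- "cohort"
  out$true_prob <- p[take]
  rownames(out) <- NULL
  attr(out, "intercept") <- intercept
  attr(out, "realized_rate") <- mean(p)
  out
}

#' Set values missing completely at random
#'
#' @param table a person table.
#' @param rates named numeric vector of per-variable missingness rates in
#'   `[0, 1)`.
#' @param seed integer seed for the missingness stream.
#' @return the table with the selected cells set to `NA`.
#' @export
inject_missingness <- function(table, rates, seed = 1L) {
  stopifnot(is.data.frame(table), is.numeric(rates), !is.null(names(rates)))
  if (any(rates < 0) || any(rates >= 1)) {
    stop("missingness rates must lie in [0, 1)")
  }
  bad <- setdiff(names(rates), names(table))
  if (length(bad)) stop("unknown variable(s): ", paste(bad, collapse = ", "))
  set.seed(stream_seed(seed, "missingness"))
  for (v in names(rates)) {
    if (rates[[v]] == 0) next
    hit <- stats::runif(nrow(table)) < rates[[v]]
    table[[v]][hit] <- NA
  }
  table
}

#' Write a person table as CSV with a seed/rate sidecar
#'
#' Missing values are written as empty fields; a JSON sidecar records the
#' provenance needed to regenerate the table.
#'
#' @param table person table.
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @param provenance named list recorded in the sidecar (seeds, realized
#'   rates, specs).
#' @return `path`, invisibly.
#' @export
write_person_table <- function(table, path, provenance = list()) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  jsonlite::write_json(provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
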