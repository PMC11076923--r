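#' Construct inverse-probability weights from participation probabilities
#'
#' The default raw weight is the inverse participation odds,
#' `w_i = (1 - pi_i) / pi_i`. With concatenated cohort (1) / reference (0)
#' data this is proportional to the target-population density over the
#' cohort density, which is the reweighting that makes the cohort mimic the
#' target population; any constant sampling-fraction factor is absorbed by
#' the normalization. A plain `1 / pi_i` variant is available via `type`.
#'
#' @param probabilities predicted participation probabilities for cohort
#'   rows, strictly in (0, 1); see [predict_probability()].
#' @param person_id identifiers aligned with `probabilities`.
#' @param normalization `"mean-one"` (mean weight 1; default) or `"sum-n"`
#'   (weights sum to the number of weighted persons) — numerically the same
#'   convention, both labels accepted.
#' @param type `"inverse_odds"` (default) or `"inverse_probability"`.
#' @param boundary_eps probabilities within this distance of 0 or 1 are
#'   flagged as boundary-unstable.
#' @return an object of class `weight_set`: data frame with columns
#'   `person_id`, `weight`, plus attributes `normalization`, `type`,
#'   `boundary_ids` and `excluded_ids`.
#' @export
compute_ip_weights <- function(probabilities,
                               person_id = names(probabilities),
                               normalization = c("mean-one", "sum-n"),
                               type = c("inverse_odds",
                                        "inverse_probability"),
                               boundary_eps = 1e-8) {
  normalization <- match.arg(normalization)
  type <- match.arg(type)
  p <- as.numeric(probabilities)
  if (length(p) == 0L) stop("no probabilities supplied")
  if (any(p <= 0) || any(p >= 1)) {
    stop("participation probabilities must lie strictly in (0, 1)")
  }
  if (is.null(person_id)) person_id <- as.character(seq_along(p))
  boundary <- p <= boundary_eps | p >= 1 - boundary_eps
  w <- if (type == "inverse_odds") (1 - p) / p else 1 / p
  w <- w / mean(w)  # mean-one == sum-n over the weighted persons
  out <- data.frame(person_id = as.character(person_id), weight = w,
                    stringsAsFactors = FALSE)
  structure(out, class = c("weight_set", "data.frame"),
            normalization = normalization, type = type,
            boundary_ids = out$person_id[boundary],
            excluded_ids = character(0))
}

#' Oracle weights from known selection probabilities
#'
#' For synthetic cohorts carrying the true per-person participation
#' probability, the Horvitz-Thompson weight `1 / true_prob`, normalized to
#' mean one. These are the ground-truth weights every estimated weight set
#' is validated against.
#'
#' @param cohort person table with a `true_prob` column.
#' @return a `weight_set`.
#' @export
oracle_weights <- function(cohort) {
  if (!"true_prob" %in% names(cohort)) {
    stop("cohort table has no 'true_prob' column (not of synthetic provenance)")
  }
  p <- cohort$true_prob
  .assert_prob(p, "true_prob")
  if (any(p == 0)) stop("true_prob contains zeros")
  w <- 1 / p
  w <- w / mean(w)
  structure(data.frame(person_id = as.character(cohort$person_id),
                       weight = w, stringsAsFactors = FALSE),
            class = c("weight_set", "data.frame"),
            normalization = "mean-one", type = "oracle",
            boundary_ids = character(0), excluded_ids = character(0))
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf("Weight set: %d person(s), %s normalization, type '%s'\n",
              nrow(x), attr(x, "normalization"), attr(x, "type")))
  q <- stats::quantile(x$weight, c(0, .25, .5, .75, 1))
  cat(sprintf("  weights: min %.3f / q25 %.3f / median %.3f / q75 %.3f / max %.3f\n",
              q[1], q[2], q[3], q[4], q[5]))
  nb <- length(attr(x, "boundary_ids")); ne <- length(attr(x, "excluded_ids"))
  if (nb) cat("  ", nb, "boundary-unstable weight(s)\n")
  if (ne) cat("  ", ne, "excluded person(s)\n")
  invisible(x)
}

#' Winsorize extreme weights (sensitivity analysis)
#'
#' Caps weights at the given upper percentile and renormalizes to mean one.
#' Off by default throughout the package; provided for sensitivity runs.
#'
#' @param w a `weight_set`.
#' @param upper upper percentile in (0, 1), e.g. 0.99.
#' @return a `weight_set`.
#' @export
trim_weights <- function(w, upper = 0.99) {
  stopifnot(inherits(w, "weight_set"), upper > 0, upper < 1)
  cap <- stats::quantile(w$weight, upper, names = FALSE)
  w$weight <- pmin(w$weight, cap)
  w$weight <- w$weight / mean(w$weight)
  w
}

#' Write weights as CSV plus a JSON provenance sidecar
#'
#' @param w a `weight_set`.
#' @param path CSV output path (`person_id, weight`); provenance goes to
#'   `<path>.json`.
#' @param provenance named list (chosen penalty, selected column count,
#'   clip/exclusion counts, seeds).
#' @return `path`, invisibly.
#' @export
write_weights <- function(w, path, provenance = list()) {
  utils::write.csv(as.data.frame(w)[c("person_id", "weight")], path,
                   row.names = FALSE)
  provenance$normalization <- attr(w, "normalization")
  provenance$type <- attr(w, "type")
  provenance$n_boundary <- length(attr(w, "boundary_ids"))
  provenance$n_excluded <- length(attr(w, "excluded_ids"))
  jsonlite::write_json(provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
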