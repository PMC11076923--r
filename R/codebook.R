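#' Define a harmonized categorical variable
#'
#' A codebook variable carries the ordered set of harmonized levels, an
#' optional recode map from raw survey responses to those levels, and an
#' optional numeric score per level (e.g. years of education for a
#' qualification category).
#'
#' @param name variable name (column name in person tables).
#' @param levels character vector of ordered harmonized levels (non-empty).
#' @param recode optional named character vector mapping raw values to
#'   levels; raw values equal to a level are always accepted without a map.
#' @param numeric optional named numeric vector giving a score for every
#'   level (names must cover `levels` exactly).
#' @return an object of class `cb_variable`.
#' @export
cb_variable <- function(name, levels, recode = NULL, numeric = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  levels <- as.character(levels)
  if (length(levels) == 0L) stop("variable '", name, "' has no levels")
  if (anyDuplicated(levels)) stop("variable '", name, "' has duplicated levels")
  if (!is.null(recode)) {
    if (is.null(names(recode)) || any(!nzchar(names(recode)))) {
      stop("recode map for '", name, "' must be a named character vector")
    }
    recode <- vapply(recode, as.character, character(1))
    bad <- setdiff(unname(recode), levels)
    if (length(bad)) {
      stop("recode map for '", name, "' targets unknown level(s): ",
           paste(bad, collapse = ", "))
    }
  }
  if (!is.null(numeric)) {
    if (!setequal(names(numeric), levels)) {
      stop("numeric map for '", name, "' must be defined on every level")
    }
    numeric <- numeric[levels]
  }
  structure(list(name = name, levels = levels, recode = recode,
                 numeric = numeric),
            class = "cb_variable")
}

#' Build a codebook of harmonized variables
#'
#' The codebook is the contract shared by the cohort and the reference
#' sample: every model variable takes values in its declared level set, so
#' that the two person tables are directly comparable.
#'
#' @param variables list of [cb_variable()] objects.
#' @param eligibility optional list describing the eligibility filter, with
#'   elements `birth_cohort_variable` (name), `birth_cohort_range`
#'   (numeric length-2, inclusive, applied to the variable's numeric map or
#'   to numeric raw values) and/or `region_flag` (name of a logical/0-1
#'   column marking residence in an eligible region).
#' @return an object of class `codebook`.
#' @seealso [recode_table()], [filter_eligible()], [build_design_matrix()]
#' @export
codebook <- function(variables, eligibility = NULL) {
  if (inherits(variables, "cb_variable")) variables <- list(variables)
  ok <- vapply(variables, inherits, logical(1), what = "cb_variable")
  if (!all(ok)) stop("all elements of 'variables' must be cb_variable objects")
  nms <- vapply(variables, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicated variable names in codebook")
  names(variables) <- nms
  if (!is.null(eligibility)) {
    allowed <- c("birth_cohort_variable", "birth_cohort_range", "region_flag")
    if (length(setdiff(names(eligibility), allowed))) {
      stop("unknown eligibility fields: ",
           paste(setdiff(names(eligibility), allowed), collapse = ", "))
    }
  }
  structure(list(variables = variables, eligibility = eligibility),
            class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat("Codebook with", length(x$variables), "harmonized variable(s)\n")
  for (v in x$variables) {
    cat(sprintf("  %-22s %d levels: %s%s\n", v$name, length(v$levels),
                paste(v$levels, collapse = ", "),
                if (!is.null(v$numeric)) "  [numeric map]" else ""))
  }
  if (!is.null(x$eligibility)) {
    cat("  eligibility:",
        if (!is.null(x$eligibility$birth_cohort_variable))
          sprintf("%s in [%s]", x$eligibility$birth_cohort_variable,
                  paste(x$eligibility$birth_cohort_range, collapse = ", "))
        else "",
        if (!is.null(x$eligibility$region_flag))
          sprintf("region flag '%s'", x$eligibility$region_flag) else "",
        "\n")
  }
  invisible(x)
}

cb_var_names <- function(cb) names(cb$variables)

cb_levels <- function(cb, var) {
  v <- cb$variables[[var]]
  if (is.null(v)) stop("variable '", var, "' not in codebook")
  v$levels
}

#' Read or write a codebook as YAML
#'
#' @param path file path.
#' @return `read_codebook()` returns a `codebook`; `write_codebook()`
#'   returns `path` invisibly.
#' @export
read_codebook <- function(path) {
  raw <- yaml::read_yaml(path)
  vars <- lapply(raw$variables, function(v) {
    cb_variable(v$name, unlist(v$levels),
                recode = if (!is.null(v$recode)) unlist(v$recode),
                numeric = if (!is.null(v$numeric)) unlist(v$numeric))
  })
  codebook(vars, eligibility = raw$eligibility)
}

#' @rdname read_codebook
#' @param cb a `codebook`.
#' @export
write_codebook <- function(cb, path) {
  out <- list(
    variables = lapply(cb$variables, function(v) {
      x <- list(name = v$name, levels = as.list(v$levels))
      if (!is.null(v$recode)) x$recode <- as.list(v$recode)
      if (!is.null(v$numeric)) x$numeric <- as.list(v$numeric)
      x
    }),
    eligibility = cb$eligibility
  )
  names(out$variables) <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}
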