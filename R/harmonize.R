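#' Recode raw responses into harmonized levels
#'
#' Applies each codebook variable's recode map. Raw values that already
#' equal a declared level pass through unchanged; raw values with no map
#' entry become missing and are counted in the recode log (attribute
#' `recode_log`, a named integer vector of nullified values per variable).
#'
#' @param raw person table with one column per codebook variable.
#' @param cb a [codebook()].
#' @return the recoded person table.
#' @export
recode_table <- function(raw, cb) {
  stopifnot(is.data.frame(raw), inherits(cb, "codebook"))
  missing_vars <- setdiff(cb_var_names(cb), names(raw))
  if (length(missing_vars)) {
    stop("table lacks codebook variable(s): ",
         paste(missing_vars, collapse = ", "))
  }
  log <- integer(0)
  for (v in cb$variables) {
    x <- as.character(raw[[v$name]])
    x[!is.na(x) & x == ""] <- NA
    mapped <- x
    if (!is.null(v$recode)) {
      hit <- !is.na(x) & x %in% names(v$recode)
      mapped[hit] <- unname(v$recode[x[hit]])
    }
    bad <- !is.na(mapped) & !(mapped %in% v$levels)
    if (any(bad)) {
      log[v$name] <- sum(bad)
      mapped[bad] <- NA
    }
    raw[[v$name]] <- mapped
  }
  attr(raw, "recode_log") <- log
  raw
}

#' Derive a numeric column from a categorical variable
#'
#' Uses the codebook's level-to-numeric map (e.g. qualification category to
#' years of education). Missing stays missing.
#'
#' @param table person table of harmonized values.
#' @param cb a [codebook()].
#' @param variable variable name; its codebook entry must carry a numeric map.
#' @return numeric vector aligned with `table` rows.
#' @export
derive_numeric <- function(table, cb, variable) {
  v <- cb$variables[[variable]]
  if (is.null(v)) stop("variable '", variable, "' not in codebook")
  if (is.null(v$numeric)) {
    stop("variable '", variable, "' has no numeric map")
  }
  unname(v$numeric[as.character(table[[variable]])])
}

#' Apply the eligibility filter
#'
#' Keeps rows inside the birth-cohort window (evaluated through the
#' variable's numeric map when one exists, otherwise as numeric raw values)
#' and with a true eligible-region flag, mirroring an age-and-catchment
#' eligibility rule. Exclusion counts by reason are attached as attribute
#' `exclusion_log`.
#'
#' @param table person table.
#' @param cb a [codebook()] whose `eligibility` block names the birth-cohort
#'   variable/range and/or the region flag column.
#' @return the filtered table.
#' @export
filter_eligible <- function(table, cb) {
  el <- cb$eligibility
  if (is.null(el)) return(table)
  keep <- rep(TRUE, nrow(table))
  log <- c(age = 0L, region = 0L)
  if (!is.null(el$birth_cohort_variable)) {
    v <- el$birth_cohort_variable
    if (!v %in% names(table)) {
      stop("birth-cohort variable '", v, "' not in table")
    }
    cbv <- cb$variables[[v]]
    val <- if (!is.null(cbv) && !is.null(cbv$numeric)) {
      unname(cbv$numeric[as.character(table[[v]])])
    } else {
      suppressWarnings(as.numeric(table[[v]]))
    }
    rng <- el$birth_cohort_range
    ok <- !is.na(val) & val >= rng[1] & val <= rng[2]
    log["age"] <- sum(keep & !ok)
    keep <- keep & ok
  }
  if (!is.null(el$region_flag)) {
    rf <- el$region_flag
    if (!rf %in% names(table)) {
      stop("region flag '", rf, "' not in table")
    }
    x <- table[[rf]]
    ok <- if (is.logical(x)) !is.na(x) & x else {
      !is.na(x) & as.character(x) %in% c("1", "TRUE", "true", "yes")
    }
    log["region"] <- sum(keep & !ok)
    keep <- keep & ok
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no rows remain after eligibility filter")
  attr(out, "exclusion_log") <- log
  out
}

#' Build the dummy + two-way-interaction design matrix
#'
#' Every variable is entered non-parametrically: one binary column per level
#' (full dummy coding, no reference level dropped) plus one column for every
#' level pair of every pair of distinct variables. Before pruning the column
#' count is `sum(L_k) + sum_{k<l} L_k * L_l`. Pruning removes constant
#' columns (all-zero, e.g. unobserved level combinations, or all-one) and
#' exact duplicates; the resulting collinearity of full dummy coding is left
#' to the L1 penalty. Column order is deterministic: main-effect blocks in
#' variable order, then interaction blocks in pair order, lexicographic in
#' level order within each block.
#'
#' @param table person table with no missing values among model variables
#'   (impute first, see [impute_exact_match()]).
#' @param cb a [codebook()].
#' @param vars variables to include (default: all codebook variables).
#' @param interactions include all two-way interactions (default `TRUE`).
#' @param prune drop constant and duplicated columns (default `TRUE`).
#' @return an object of class `ipw_design`: list with the sparse matrix `X`
#'   (`Matrix::dgCMatrix`, 0/1 entries), `row_ids`, `vars`, the pre-pruning
#'   column count `n_col_full`, and a `prune_log` data frame.
#' @export
build_design_matrix <- function(table, cb, vars = NULL,
                                interactions = TRUE, prune = TRUE) {
  stopifnot(is.data.frame(table), inherits(cb, "codebook"))
  vars <- vars %||% cb_var_names(cb)
  bad <- setdiff(vars, cb_var_names(cb))
  if (length(bad)) stop("not in codebook: ", paste(bad, collapse = ", "))
  bad <- setdiff(vars, names(table))
  if (length(bad)) stop("not in table: ", paste(bad, collapse = ", "))
  n <- nrow(table)
  codes <- list(); nlev <- integer(0)
  for (v in vars) {
    lev <- cb_levels(cb, v)
    x <- as.character(table[[v]])
    cd <- match(x, lev)
    if (anyNA(cd)) {
      nm <- sum(is.na(x))
      stop("variable '", v, "' has ", sum(is.na(cd)), " missing/unknown ",
           "value(s)", if (nm) " (missing values present; impute first)")
    }
    codes[[v]] <- cd
    nlev[v] <- length(lev)
  }
  # main-effect blocks
  col_names <- character(0)
  offsets <- integer(0)
  off <- 0L
  for (v in vars) {
    offsets[v] <- off
    col_names <- c(col_names, paste0("main:", v, "=", cb_levels(cb, v)))
    off <- off + nlev[v]
  }
  ii <- rep.int(seq_len(n), length(vars))
  jj <- unlist(lapply(vars, function(v) offsets[v] + codes[[v]]),
               use.names = FALSE)
  if (interactions && length(vars) > 1L) {
    for (k in seq_len(length(vars) - 1L)) {
      for (l in (k + 1L):length(vars)) {
        vk <- vars[k]; vl <- vars[l]
        lk <- cb_levels(cb, vk); ll <- cb_levels(cb, vl)
        nm <- as.vector(t(outer(seq_along(lk), seq_along(ll),
          function(a, b) paste0("int:", vk, "=", lk[a], ":", vl, "=", ll[b]))))
        col_names <- c(col_names, nm)
        jj <- c(jj, off + (codes[[vk]] - 1L) * nlev[vl] + codes[[vl]])
        ii <- c(ii, seq_len(n))
        off <- off + nlev[vk] * nlev[vl]
      }
    }
  }
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, off),
                            dimnames = list(NULL, col_names))
  n_col_full <- as.integer(unname(off))
  prune_log <- data.frame(column = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
  if (prune) {
    cs <- Matrix::colSums(X)
    const <- cs == 0 | cs == n
    if (any(const)) {
      prune_log <- rbind(prune_log, data.frame(
        column = col_names[const],
        reason = ifelse(cs[const] == 0, "all-zero", "constant"),
        stringsAsFactors = FALSE))
      X <- X[, !const, drop = FALSE]
    }
    # exact duplicates: hash each column's row-index pattern
    Xc <- methods::as(X, "CsparseMatrix")
    p <- Xc@p
    sig <- vapply(seq_len(ncol(Xc)), function(j) {
      paste(Xc@i[(p[j] + 1L):p[j + 1L]], collapse = ",")
    }, character(1))
    dup <- duplicated(sig)
    if (any(dup)) {
      first_of <- colnames(Xc)[match(sig[dup], sig)]
      prune_log <- rbind(prune_log, data.frame(
        column = colnames(Xc)[dup],
        reason = paste0("duplicate-of:", first_of),
        stringsAsFactors = FALSE))
      X <- Xc[, !dup, drop = FALSE]
    }
  }
  structure(list(X = X,
                 row_ids = if ("person_id" %in% names(table))
                   table$person_id else as.character(seq_len(n)),
                 vars = vars, nlev = nlev, n_col_full = n_col_full,
                 prune_log = prune_log),
            class = "ipw_design")
}

#' @export
print.ipw_design <- function(x, ...) {
  cat("Design matrix:", nrow(x$X), "rows x", ncol(x$X), "columns",
      sprintf("(%d before pruning)\n", x$n_col_full))
  cat("Variables:", paste(x$vars, collapse = ", "), "\n")
  if (nrow(x$prune_log)) {
    cat("Pruned", nrow(x$prune_log), "column(s):",
        sum(grepl("^all-zero$|^constant$", x$prune_log$reason)), "constant,",
        sum(grepl("^duplicate", x$prune_log$reason)), "duplicate\n")
  }
  invisible(x)
}

#' Export a design matrix as sparse triplets
#'
#' Writes `(row_id, column_name, 1)` rows, one per nonzero entry.
#'
#' @param design an `ipw_design`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_design_triplets <- function(design, path) {
  tm <- methods::as(design$X, "TsparseMatrix")
  utils::write.csv(
    data.frame(row_id = design$row_ids[tm@i + 1L],
               column_name = colnames(design$X)[tm@j + 1L],
               value = 1L),
    path, row.names = FALSE)
  invisible(path)
}
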