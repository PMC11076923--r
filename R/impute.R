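#' Impute missing model variables by exact matching
#'
#' For each person with missing model variables, the donor pool is the set
#' of persons in the same table who are fully observed on the model
#' variables and match the recipient exactly on every variable the
#' recipient did observe. Each missing value is filled by drawing one donor
#' uniformly at random from the pool (hot deck within exact-match cells).
#' Persons with an observed pattern matched by no donor are excluded.
#'
#' @param table person table.
#' @param model_vars names of the model variables to complete.
#' @param seed integer seed for the imputation stream.
#' @return list with elements `table` (completed, excluded rows removed),
#'   `excluded_ids` (person ids with reason `"no exact donor"`), and `log`
#'   (counts of imputed cells per variable).
#' @export
impute_exact_match <- function(table, model_vars, seed = 1L) {
  stopifnot(is.data.frame(table))
  bad <- setdiff(model_vars, names(table))
  if (length(bad)) stop("model_vars not in table: ", paste(bad, collapse = ", "))
  M <- as.matrix(table[model_vars])
  M[M == ""] <- NA
  miss <- is.na(M)
  need <- rowSums(miss) > 0L
  if (!any(need)) {
    return(list(table = table, excluded_ids = character(0),
                log = stats::setNames(integer(length(model_vars)), model_vars)))
  }
  donors <- which(!need)
  if (!length(donors)) {
    ids <- if ("person_id" %in% names(table)) table$person_id else
      as.character(seq_len(nrow(table)))
    return(list(table = table[0, , drop = FALSE],
                excluded_ids = stats::setNames(rep("no exact donor",
                                                   nrow(table)), ids),
                log = stats::setNames(integer(length(model_vars)), model_vars)))
  }
  set.seed(stream_seed(seed, "imputation"))
  excluded <- character(0)
  drop_rows <- integer(0)
  nimp <- stats::setNames(integer(length(model_vars)), model_vars)
  # group recipients by missingness pattern; one donor lookup per pattern
  pat <- apply(miss[need, , drop = FALSE], 1L, paste, collapse = "")
  for (p in unique(pat)) {
    rows <- which(need)[pat == p]
    obs <- !miss[rows[1L], ]
    if (!any(obs)) {
      # nothing observed: any complete case is an exact match
      pick <- donors[sample.int(length(donors), length(rows), replace = TRUE)]
      M[rows, ] <- M[pick, , drop = FALSE]
      nimp <- nimp + length(rows)
      next
    }
    dkey <- do.call(paste, c(as.data.frame(M[donors, obs, drop = FALSE],
                                           stringsAsFactors = FALSE),
                             sep = "\r"))
    rkey <- do.call(paste, c(as.data.frame(M[rows, obs, drop = FALSE],
                                           stringsAsFactors = FALSE),
                             sep = "\r"))
    pools <- split(donors, dkey)
    hit <- rkey %in% names(pools)
    if (any(!hit)) drop_rows <- c(drop_rows, rows[!hit])
    for (r in which(hit)) {
      pool <- pools[[rkey[r]]]
      d <- pool[sample.int(length(pool), 1L)]
      M[rows[r], !obs] <- M[d, !obs]
    }
    nimp[!obs] <- nimp[!obs] + sum(hit)
  }
  ids <- if ("person_id" %in% names(table)) table$person_id else
    as.character(seq_len(nrow(table)))
  if (length(drop_rows)) {
    excluded <- stats::setNames(rep("no exact donor", length(drop_rows)),
                                ids[drop_rows])
  }
  table[model_vars] <- as.data.frame(M, stringsAsFactors = FALSE)
  if (length(drop_rows)) {
    table <- table[-drop_rows, , drop = FALSE]
    rownames(table) <- NULL
  }
  list(table = table, excluded_ids = excluded, log = nimp)
}
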