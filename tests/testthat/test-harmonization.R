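test_that("recode_table maps raw responses and logs unmapped values", {
  cbk <- codebook(list(
    cb_variable("health", c("good", "poor"),
                recode = c("1" = "good", "2" = "poor", "excellent" = "good")),
    cb_variable("work", c("yes", "no"))))
  raw <- data.frame(health = c("1", "2", "excellent", "good", "unknown", ""),
                    work = c("yes", "no", "yes", "maybe", "no", "yes"),
                    stringsAsFactors = FALSE)
  out <- recode_table(raw, cbk)
  expect_equal(out$health, c("good", "poor", "good", "good", NA, NA))
  expect_equal(out$work, c("yes", "no", "yes", NA, "no", "yes"))
  expect_equal(attr(out, "recode_log"), c(health = 1L, work = 1L))
  expect_error(recode_table(raw["health"], cbk), "lacks codebook variable")
})

test_that("derive_numeric applies the level score map", {
  cbk <- tiny_codebook()
  tab <- data.frame(health = c("good", "poor", NA, "fair"))
  expect_equal(derive_numeric(tab, cbk, "health"), c(1, 3, NA, 2))
  expect_error(derive_numeric(tab, cbk, "work"), "no numeric map")
  expect_error(derive_numeric(tab, cbk, "zz"), "not in codebook")
})

test_that("eligibility filter applies the age window and region flag", {
  cbk <- codebook(list(
    cb_variable("age_group", c("30-39", "40-49", "70-79"),
                numeric = c("30-39" = 34.5, "40-49" = 44.5, "70-79" = 74.5))),
    eligibility = list(birth_cohort_variable = "age_group",
                       birth_cohort_range = c(40, 69),
                       region_flag = "in_region"))
  tab <- data.frame(age_group = c("30-39", "40-49", "70-79", "40-49"),
                    in_region = c(TRUE, TRUE, TRUE, FALSE))
  out <- filter_eligible(tab, cbk)
  expect_equal(nrow(out), 1L)
  expect_equal(out$age_group, "40-49")
  expect_equal(attr(out, "exclusion_log"), c(age = 2L, region = 1L))
})

test_that("design-matrix column count matches the combinatorial formula", {
  # worked example: variables with 2 and 3 levels -> 2 + 3 + 2*3 = 11
  cbk <- codebook(list(cb_variable("a", c("x", "y")),
                       cb_variable("b", c("p", "q", "r"))))
  tab <- data.frame(a = c("x", "y", "x"), b = c("p", "q", "r"))
  d <- build_design_matrix(tab, cbk, prune = FALSE)
  expect_equal(ncol(d$X), 11L)
  expect_equal(d$n_col_full, 11L)

  # random codebooks against brute-force enumeration
  set.seed(42)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    cbr <- random_codebook(k)
    L <- vapply(cbr$variables, function(v) length(v$levels), integer(1))
    expected <- sum(L) + sum(utils::combn(L, 2, prod))
    tabr <- random_table(cbr, 60)
    dr <- build_design_matrix(tabr, cbr, prune = FALSE)
    expect_equal(ncol(dr$X), expected)
    # without interactions only the main blocks remain
    dm <- build_design_matrix(tabr, cbr, interactions = FALSE, prune = FALSE)
    expect_equal(ncol(dm$X), sum(L))
  }
})

test_that("each row activates one dummy per block", {
  cbk <- random_codebook(4)
  tab <- random_table(cbk, 50)
  d <- build_design_matrix(tab, cbk, prune = FALSE)
  blocks <- 4 + choose(4, 2)
  expect_true(all(Matrix::rowSums(d$X) == blocks))
  # entries are exactly 0/1
  expect_true(all(d$X@x == 1))
})

test_that("dummy columns agree with direct indicator comparison", {
  cbk <- tiny_codebook()
  tab <- data.frame(health = c("good", "poor", "fair", "good"),
                    work = c("yes", "no", "yes", "no"))
  d <- build_design_matrix(tab, cbk, prune = FALSE)
  expect_equal(as.numeric(d$X[, "main:health=poor"]),
               as.numeric(tab$health == "poor"))
  expect_equal(as.numeric(d$X[, "int:health=good:work=no"]),
               as.numeric(tab$health == "good" & tab$work == "no"))
})

test_that("pruning removes constant and duplicate columns with a log", {
  cbk <- codebook(list(cb_variable("a", c("x", "y", "z")),
                       cb_variable("b", c("p", "q"))))
  # level z never observed; a and b perfectly aligned -> duplicates
  tab <- data.frame(a = c("x", "x", "y", "y"), b = c("p", "p", "q", "q"))
  d <- build_design_matrix(tab, cbk)
  lg <- d$prune_log
  expect_true("main:a=z" %in% lg$column[lg$reason == "all-zero"])
  expect_true(any(grepl("^duplicate-of:", lg$reason)))
  # pruned columns are gone; no column is constant or duplicated
  cs <- Matrix::colSums(d$X)
  expect_true(all(cs > 0 & cs < nrow(tab)))
  expect_equal(ncol(d$X) + nrow(lg), d$n_col_full)
})

test_that("missing model values are rejected with guidance", {
  cbk <- tiny_codebook()
  tab <- data.frame(health = c("good", NA), work = c("yes", "no"))
  expect_error(build_design_matrix(tab, cbk), "impute first")
})

test_that("triplet export reconstructs the matrix", {
  cbk <- tiny_codebook()
  tab <- data.frame(person_id = c("p1", "p2", "p3"),
                    health = c("good", "poor", "fair"),
                    work = c("yes", "no", "yes"))
  d <- build_design_matrix(tab, cbk, prune = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_design_triplets(d, path)
  tri <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(nrow(tri), sum(d$X))
  M <- matrix(0, nrow(d$X), ncol(d$X), dimnames = list(d$row_ids,
                                                       colnames(d$X)))
  for (r in seq_len(nrow(tri))) {
    M[tri$row_id[r], tri$column_name[r]] <- tri$value[r]
  }
  expect_equal(M, as.matrix(d$X), ignore_attr = TRUE)
})
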