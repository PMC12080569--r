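test_that("a three-row file parses into the right event kinds", {
  tab <- tiny_table()
  cnt <- event_counts(tab)
  expect_equal(cnt$n[match(c("dose", "pk_obs", "pd_obs"), cnt$kind)],
               c(1L, 1L, 1L))
})

test_that("concentrations under the LLOQ are retained but flagged", {
  tab <- tiny_table(pk_dv = 0.3)
  pk_row <- tab[tab$EVID == 0 & tab$DVID == 1, ]
  expect_equal(pk_row$BLQ, 1L)
  expect_equal(nrow(tab), 3L)
  # flag is recomputed from DV and lloq, not trusted from the file
  expect_equal(tiny_table(pk_dv = 0.5)$BLQ[2], 0L)
})

test_that("write-then-read round trip preserves the table", {
  fx <- make_small_table(n_subjects = 4, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_table(fx$table, path)
  back <- read_event_table(path, lloq = attr(fx$table, "lloq"))
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(fx$table))
  expect_equal(event_counts(back), event_counts(fx$table))
  expect_equal(event_counts(back, by_subject = TRUE),
               event_counts(fx$table, by_subject = TRUE))
})

test_that("format and validation errors name the problem", {
  expect_error(event_table(data.frame(ID = 1, TIME = 0)),
               "missing mandatory column")
  base <- data.frame(ID = 1, TIME = 0, EVID = 1, DVID = NA,
                     AMT = 5e6, DV = NA)
  bad_time <- base; bad_time$TIME <- -1
  expect_error(event_table(bad_time), "negative TIME in row")
  bad_amt <- base; bad_amt$AMT <- -5
  expect_error(event_table(bad_amt), "non-positive AMT")
  orphan <- data.frame(ID = 1, TIME = 3, EVID = 0, DVID = 1,
                       AMT = NA, DV = 2)
  expect_error(event_table(orphan), "without a preceding dose")
  # baseline HbA1c before any dose is legitimate
  baseline_ok <- data.frame(ID = 1, TIME = c(0, 0), EVID = c(0, 1),
                            DVID = c(2, NA), AMT = c(NA, 5e6),
                            DV = c(6.8, NA))
  expect_s3_class(event_table(baseline_ok), "event_table")
})

test_that("exclude_blq removes exactly the flagged concentration rows", {
  fx <- make_small_table(n_subjects = 10, seed = 21)
  tab <- fx$table
  n_blq <- sum(tab$BLQ)
  cnt0 <- event_counts(tab)
  expect_message(out <- exclude_blq(tab), "excluded")
  cnt1 <- event_counts(out)
  get <- function(cnt, k) {
    n <- cnt$n[cnt$kind == k]
    if (length(n) == 0) 0L else n
  }
  expect_equal(get(cnt1, "pk_obs"), get(cnt0, "pk_obs") - n_blq)
  expect_equal(get(cnt1, "dose"), get(cnt0, "dose"))
  expect_equal(get(cnt1, "pd_obs"), get(cnt0, "pd_obs"))
  # idempotent on a clean table
  expect_message(out2 <- exclude_blq(out), "0 below-LLOQ")
  expect_equal(nrow(out2), nrow(out))
})

test_that("all-BLQ tables warn and end up with zero concentration rows", {
  tab <- tiny_table(pk_dv = 0.1)
  expect_warning(expect_message(out <- exclude_blq(tab)), "below the LLOQ")
  expect_equal(sum(out$EVID == 0 & out$DVID == 1), 0L)
})

test_that("covariate lookup follows the step rule and carries forward", {
  tab <- event_table(data.frame(
    ID = 1, TIME = c(0, 90), EVID = 1, DVID = NA, AMT = 5e6, DV = NA,
    WT = c(77, 75)
  ))
  expect_equal(covariate_at(tab, 1, "WT", 90), 75)
  expect_equal(covariate_at(tab, 1, "WT", 45), 77)
  expect_equal(covariate_at(tab, 1, "WT", 400), 75)
  expect_equal(covariate_at(tab, 1, "WT", 45, rule = "linear"), 76)
  expect_error(covariate_at(tab, 1, "NOPE", 10), "unknown covariate")
  expect_warning(covariate_at(tab, 1, "WT", -1), "precedes first")
})
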