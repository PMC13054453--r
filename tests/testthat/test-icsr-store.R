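test_that("partial dates complete to mid-month and mid-year", {
  expect_equal(impute_date(2020, 5, NA), as.Date("2020-05-15"))
  expect_equal(impute_date(2020, NA, NA), as.Date("2020-07-02"))
  expect_equal(impute_date(2020, 5, 10), as.Date("2020-05-10"))
  expect_true(is.na(impute_date(NA, 5, 10)))
  # vectorised
  expect_equal(impute_date(c(2020, 2021), c(2, NA), c(NA, NA)),
               as.Date(c("2020-02-15", "2021-07-02")))
})

test_that("time to onset uses calendar arithmetic and drops negatives", {
  expect_equal(compute_tto(2020, 1, 1, 2020, 1, 31), 30)
  # onset known only to the year -> July 2 completion
  expect_equal(compute_tto(2020, 6, 1, 2020, NA, NA), 31)
  # completion yielding a negative interval is excluded
  expect_true(is.na(compute_tto(2020, 8, 1, 2020, NA, NA)))
  # missing dates are ignored, same-day kept as zero
  expect_true(is.na(compute_tto(NA, NA, NA, 2020, 1, 1)))
  expect_equal(compute_tto(2020, 3, 3, 2020, 3, 3), 0)
})

test_that("tto antisymmetry holds exactly when the exclusion does not fire", {
  set.seed(42)
  d1 <- as.Date("2015-01-01") + sample.int(3000, 50)
  d2 <- as.Date("2015-01-01") + sample.int(3000, 50)
  y1 <- as.integer(format(d1, "%Y")); m1 <- as.integer(format(d1, "%m"))
  dd1 <- as.integer(format(d1, "%d"))
  y2 <- as.integer(format(d2, "%Y")); m2 <- as.integer(format(d2, "%m"))
  dd2 <- as.integer(format(d2, "%d"))
  fwd <- compute_tto(y1, m1, dd1, y2, m2, dd2)
  bwd <- compute_tto(y2, m2, dd2, y1, m1, dd1)
  signed <- as.numeric(d2 - d1)
  expect_equal(is.na(fwd), signed < 0)
  expect_equal(is.na(bwd), signed > 0)
  expect_equal(fwd[signed >= 0], signed[signed >= 0])
  expect_equal(bwd[signed <= 0], -signed[signed <= 0])
})

test_that("case selection matches preferred-term membership", {
  db <- toy_db()
  rp <- select_cases(db, "PT01")
  expect_setequal(rp, c("R01", "R02", "R06", "R09"))
  expect_error(select_cases(db, "PT99"), "unknown preferred term")
  expect_length(select_cases(db, "PT03"), 1L)
  # broad definition is a superset of the narrow one
  broad <- select_cases(db, c("PT01", "PT02", "PT03"))
  expect_true(all(rp %in% broad))
  expect_setequal(broad, c("R01", "R02", "R03", "R04", "R06", "R08", "R09"))
})

test_that("treatment-drug exclusion removes cases in any role and logs the flow", {
  db <- toy_db()
  cases <- select_cases(db, "PT01")
  kept <- apply_exclusion(db, cases)
  # R02 carries nifedipine as concomitant only: still excluded
  expect_setequal(as.character(kept), c("R01", "R06", "R09"))
  expect_equal(attr(kept, "flow"),
               c(selected = 4L, excluded = 1L, included = 3L))
  # empty exclusion list leaves cases unchanged; idempotence
  expect_setequal(as.character(apply_exclusion(db, cases, character(0))), cases)
  again <- apply_exclusion(db, as.character(kept))
  expect_setequal(as.character(again), as.character(kept))
})

test_that("ATC-prefix flagging reproduces the treatment-drug set", {
  db <- toy_db()
  dd <- flag_rp_treatment(db$drug_dict)
  expect_equal(dd[dd$drug_id == "dE", ]$rp_treatment, TRUE)
  expect_false(any(dd[dd$drug_id != "dE", ]$rp_treatment))
})

test_that("malformed rows are skipped with a warning, valid data loads", {
  db <- toy_db()
  bad_events <- rbind(db$report_events,
                      data.frame(report_id = "R01", pt_code = "PT99",
                                 onset_year = 2020L, onset_month = 1L,
                                 onset_day = 1L))
  expect_warning(
    db2 <- icsr_db(db$reports, db$report_drugs, bad_events,
                   db$drug_dict, db$event_dict),
    "referential")
  expect_equal(nrow(db2$reports), 10L)
  expect_equal(nrow(db2$report_events), nrow(db$report_events))
  expect_error(
    suppressWarnings(icsr_db(db$reports[0, ], db$report_drugs[0, ],
                             db$report_events[0, ], db$drug_dict, db$event_dict)),
    "no valid reports")
})

test_that("write/read round-trip preserves the database", {
  dir <- withr::local_tempdir()
  g <- generate_database(sim_config(n_reports = 300, seed = 7))
  write_icsr_db(g$db, dir)
  db2 <- read_icsr_db(dir)
  for (tab in c("reports", "report_drugs", "report_events",
                "drug_dict", "event_dict")) {
    expect_equal(as.data.frame(db2[[tab]]), as.data.frame(g$db[[tab]]),
                 ignore_attr = TRUE)
  }
})

test_that("case summaries report demographics, TTO and co-medication", {
  db <- toy_db()
  cases <- apply_exclusion(db, select_cases(db, "PT01"))
  s <- summarize_cases(db, cases, "dA", pt_set = "PT01")
  expect_equal(s$n, 1L)  # dA suspect in R01 only among included cases
  s_b <- summarize_cases(db, cases, "dB", pt_set = "PT01")
  expect_equal(s_b$n, 2L)  # suspect in R06 and R09; concomitant R01 not counted
  # two known ages -> sample mean and SD
  ages <- db$reports[db$reports$report_id %in% c("R06", "R09"), ]$age_years
  expect_equal(s_b$age_mean, mean(ages))
  expect_equal(s_b$age_sd, sd(ages))
  # drug absent from cases -> empty summary, no error
  s0 <- summarize_cases(db, cases, "dD")
  expect_equal(s0$n, 0L)
  # all TTO missing is flagged unavailable, not an error
  db_na <- toy_db()
  db_na$report_drugs$start_year <- NA_integer_
  s_na <- summarize_cases(db_na, cases, "dB", pt_set = "PT01")
  expect_equal(s_na$tto_n, 0L)
  expect_true(is.na(s_na$tto_median))
})
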