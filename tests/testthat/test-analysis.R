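test_that("primary analysis evaluates exactly the drugs in included cases", {
  db <- toy_db()
  res <- run_analysis(db, "primary", pt_narrow = "PT01")
  # included cases are R01, R06, R09 (R02 excluded); suspect/interacting
  # drugs there: dA (R01), dB (R06, R09)
  expect_setequal(res$drug_id, c("dA", "dB"))
  expect_true(all(res$evaluable))
  ra <- res[res$drug_id == "dA", ]
  # universe drops the excluded case R02: N = 9
  tab <- build_table(db, "dA", c("R01", "R06", "R09"),
                     background_ids = setdiff(db$reports$report_id, "R02"))
  expect_equal(ra$O, tab$O)
  expect_equal(ra$E, tab$E)
  expect_equal(ra$IC_LB, ic_lower_bound(tab$O, tab$E))
})

test_that("reporter-type restriction recomputes margins within the subset", {
  db <- toy_db()
  res <- run_analysis(db, "hcp_only", pt_narrow = "PT01")
  # HCP universe: R01..R06 minus excluded R02; HCP cases: R01, R06
  hcp_u <- setdiff(sprintf("R%02d", 1:6), "R02")
  tab <- build_table(db, "dA", c("R01", "R06"), background_ids = hcp_u)
  ra <- res[res$drug_id == "dA", ]
  expect_equal(ra$O, tab$O)
  expect_equal(ra$E, tab$E)
  # dB appears in an included case (R09) but R09 is consumer-reported;
  # it is still evaluable here because R06 (HCP) carries it too
  expect_true(res[res$drug_id == "dB", ]$evaluable)
})

test_that("ATC level-3 background restricts the comparator per drug", {
  db <- toy_db()
  res <- run_analysis(db, "atc3_background", pt_narrow = "PT01")
  # dA (N06B) shares no ATC3 with other drugs: background = reports with dA
  ra <- res[res$drug_id == "dA", ]
  with_dA <- c("R01", "R02", "R04", "R07")
  bg <- setdiff(with_dA, "R02")  # excluded case leaves the universe
  tab <- build_table(db, "dA", intersect(c("R01", "R06", "R09"), bg),
                     background_ids = bg)
  expect_equal(ra$O, tab$O)
  expect_equal(ra$E, tab$E)
  # a drug with no ATC codes is flagged not evaluable, not dropped
  db2 <- toy_db()
  db2$drug_dict[db2$drug_dict$drug_id == "dB", "atc_codes"] <- ""
  res2 <- run_analysis(db2, "atc3_background", pt_narrow = "PT01")
  rb <- res2[res2$drug_id == "dB", ]
  expect_false(rb$evaluable)
  expect_true(is.na(rb$IC_LB))
  expect_false(rb$significant)
})

test_that("stratified expected counts pool sex x age strata", {
  db <- toy_db()
  res <- run_analysis(db, "mh_stratified", pt_narrow = "PT01")
  ra <- res[res$drug_id == "dA", ]
  # hand-pool over the strata of the 9-report universe
  uni <- setdiff(db$reports$report_id, "R02")
  rep_u <- db$reports[match(uni, db$reports$report_id), ]
  strat <- interaction(rep_u$sex, age_band(rep_u$age_years), drop = TRUE)
  cases <- c("R01", "R06", "R09")
  with_dA <- intersect(c("R01", "R04", "R07"), uni)
  E <- 0
  for (s in levels(strat)) {
    ids <- uni[strat == s]
    E <- E + length(intersect(with_dA, ids)) *
      length(intersect(cases, ids)) / length(ids)
  }
  expect_equal(ra$E, E)
  expect_equal(ra$O, length(intersect(with_dA, cases)))
})

test_that("broad definition widens the case set and the analysis follows", {
  db <- toy_db()
  broad <- run_analysis(db, "broad_definition", pt_narrow = "PT01",
                        pt_broad = c("PT01", "PT02", "PT03"))
  narrow <- run_analysis(db, "primary", pt_narrow = "PT01")
  expect_true(all(narrow$drug_id %in% broad$drug_id))
  nb <- attr(broad, "flow")
  expect_gte(nb["selected"], attr(narrow, "flow")["selected"])
})

test_that("a strong planted signal is flagged by all five analyses", {
  cfg <- sim_config(n_reports = 30000, seed = 31,
                    planted_signals = data.frame(
                      drug_id = "D010", pt_code = "PT0001", rate_ratio = 8))
  g <- generate_database(cfg)
  for (a in c("primary", "hcp_only", "atc3_background",
              "mh_stratified", "broad_definition")) {
    res <- run_analysis(g$db, a, pt_narrow = "PT0001",
                        pt_broad = c("PT0001", "PT0002", "PT0003"))
    row <- res[res$drug_id == "D010", ]
    expect_true(row$significant, label = paste("significant in", a))
  }
})
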