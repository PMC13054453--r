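test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(n_reports = 500, seed = 11)
  g1 <- generate_database(cfg)
  g2 <- generate_database(cfg)
  for (tab in c("reports", "report_drugs", "report_events"))
    expect_identical(as.data.frame(g1$db[[tab]]), as.data.frame(g2$db[[tab]]))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_icsr_db(g1$db, d1); write_icsr_db(g2$db, d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  # and the generator does not disturb the caller's RNG stream
  set.seed(99); x <- runif(1)
  set.seed(99); invisible(generate_database(cfg)); y <- runif(1)
  expect_identical(x, y)
})

test_that("reports respect structural invariants", {
  g <- generate_database(sim_config(n_reports = 2000, seed = 3))
  db <- g$db
  expect_true(all(table(db$report_drugs$report_id) >= 1))
  expect_true(all(db$reports$report_id %in% db$report_events$report_id))
  k <- table(db$report_drugs$report_id)
  expect_true(all(k >= 1 & k <= 5))
  # first drug entry of every report is a suspect drug
  first <- db$report_drugs[!duplicated(report_id)]
  expect_true(all(first$role == "suspect"))
  expect_true(all(db$reports$age_years >= 0 & db$reports$age_years <= 120,
                  na.rm = TRUE))
})

test_that("ground-truth ledger counts match generated data exactly", {
  g <- generate_database(sim_config(n_reports = 3000, seed = 5))
  strat <- as.data.frame(table(sex = g$db$reports$sex,
                               age_band = age_band(g$db$reports$age_years)))
  expect_equal(strat$Freq, g$truth$stratum_counts$Freq)
  rep_counts <- as.data.frame(table(reporter_type = g$db$reports$reporter_type))
  expect_equal(rep_counts$Freq, g$truth$reporter_counts$Freq)
})

test_that("null configuration yields near-independent drug-event pairs", {
  g <- generate_database(null_config(seed = 101, n_reports = 20000))
  ps <- pairwise_signals(g$db)
  ps5 <- ps[ps$O >= 5, ]
  # observed/expected ratios concentrate around 1
  expect_gt(nrow(ps5), 500)
  expect_lt(abs(median(ps5$O / ps5$E) - 1), 0.05)
  frac <- mean(ps[ps$O >= 3, ]$significant)
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.05)
})

test_that("planted rate ratios are recovered and grow consistent with n", {
  cfg <- sim_config(n_reports = 50000, seed = 17,
                    planted_signals = data.frame(
                      drug_id = "D010", pt_code = "PT0001", rate_ratio = 8))
  g <- generate_database(cfg)
  ps <- pairwise_signals(g$db)
  row <- ps[ps$drug_id == "D010" & ps$pt_code == "PT0001", ]
  expect_gte(row$O / row$E, 4)   # well above null, sampling error bounded
  expect_true(row$significant)
  # consistency: the empirical ratio approaches the planted one with size
  small <- generate_database(sim_config(
    n_reports = 5000, seed = 17,
    planted_signals = data.frame(drug_id = "D010", pt_code = "PT0001",
                                 rate_ratio = 8)))
  ps_s <- pairwise_signals(small$db)
  row_s <- ps_s[ps_s$drug_id == "D010" & ps_s$pt_code == "PT0001", ]
  expect_lte(abs(log(row$O / row$E / 8)), abs(log(row_s$O / row_s$E / 8)) + 0.5)
})

test_that("infeasible multiplied probabilities fail loudly", {
  cfg <- sim_config(n_reports = 100, seed = 1,
                    planted_signals = data.frame(
                      drug_id = "D010", pt_code = "PT0001", rate_ratio = 50))
  expect_error(generate_database(cfg), "infeasible.*PT0001")
})

test_that("confounded scenario inflates the crude ratio but not the stratified one", {
  g <- generate_database(confounded_config(seed = 21))
  prim <- run_analysis(g$db, "primary", pt_narrow = "PT0001")
  mh <- run_analysis(g$db, "mh_stratified", pt_narrow = "PT0001")
  crude <- prim[prim$drug_id == "D001", ]
  adj <- mh[mh$drug_id == "D001", ]
  expect_gt(crude$O / crude$E, 1.1)
  expect_lt(adj$IC_LB, crude$IC_LB)
  expect_lt(abs(adj$O / adj$E - 1), 0.1)  # per-stratum independence by construction
  # identity multipliers change nothing
  cfg0 <- plant_confounded_scenario(sim_config(n_reports = 400, seed = 9,
                                               n_rp_treatment = 0L),
                                    multiplier = 1)
  base <- generate_database(sim_config(n_reports = 400, seed = 9,
                                       n_rp_treatment = 0L))
  expect_identical(as.data.frame(generate_database(cfg0)$db$report_events),
                   as.data.frame(base$db$report_events))
})
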