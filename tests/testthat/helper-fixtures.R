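# Small hand-built database used across tests: 10 reports, 5 drugs
# (one flagged as a disease treatment), 6 preferred terms, with the index
# condition "Raynaud's phenomenon" on PT01.
toy_db <- function() {
  reports <- data.frame(
    report_id = sprintf("R%02d", 1:10),
    country = "US",
    report_year = 2020L,
    reporter_type = c(rep("health_professional", 6), rep("consumer", 4)),
    serious = c(1, 0, 1, 0, 0, 1, 0, 0, 1, 0),
    age_years = c(40, 60, NA, 35, 70, 55, 25, 80, 45, 50),
    sex = c("F", "F", "M", "F", "M", "F", "F", "M", "F", "unknown"))
  report_drugs <- data.frame(
    report_id = c("R01", "R01", "R02", "R03", "R04", "R05", "R06", "R07",
                  "R08", "R09", "R10", "R02"),
    drug_id   = c("dA",  "dB",  "dA",  "dC",  "dA",  "dB",  "dB",  "dA",
                  "dD",  "dB",  "dC",  "dE"),
    role      = c("suspect", "concomitant", "suspect", "suspect", "suspect",
                  "interacting", "suspect", "suspect", "suspect", "suspect",
                  "suspect", "concomitant"),
    start_year = c(2020L, 2020L, 2019L, 2020L, NA, 2020L, 2020L, 2020L,
                   2020L, 2020L, 2020L, 2020L),
    start_month = c(1L, 1L, 6L, NA, NA, 5L, 3L, 8L, 2L, 4L, 7L, 1L),
    start_day = c(1L, 15L, 10L, NA, NA, NA, 2L, 1L, 28L, 30L, 15L, 1L))
  report_events <- data.frame(
    report_id = c("R01", "R02", "R03", "R04", "R05", "R06", "R07", "R08",
                  "R09", "R10", "R01", "R02"),
    pt_code   = c("PT01", "PT01", "PT02", "PT03", "PT04", "PT01", "PT05",
                  "PT02", "PT01", "PT06", "PT05", "PT05"),
    onset_year = c(2020L, 2020L, 2019L, 2020L, 2020L, 2020L, 2020L, 2020L,
                   2020L, 2020L, 2020L, NA),
    onset_month = c(1L, 8L, 7L, NA, 5L, 6L, 3L, 9L, 3L, 8L, 2L, NA),
    onset_day = c(31L, 1L, NA, NA, 10L, 15L, 20L, 1L, 15L, 2L, 1L, NA))
  drug_dict <- data.frame(
    drug_id = c("dA", "dB", "dC", "dD", "dE"),
    name = c("alphadrug", "betadrug", "gammadrug", "deltadrug", "nifedipine"),
    atc_codes = c("N06BA07", "C07AB02;N02CC01", "N02CC05", "L01EA01", "C08CA05"),
    rp_treatment = c(0, 0, 0, 0, 1),
    class_tags = c("amphetamine_like", "beta_blocker;antimigraine",
                   "antimigraine", "tki", ""))
  event_dict <- data.frame(
    pt_code = sprintf("PT%02d", 1:6),
    pt_name = c("Raynaud's phenomenon", "Peripheral ischaemia", "Chilblains",
                "Headache", "Peripheral coldness", "Nausea"),
    hlt = c("H1", "H1", "H1", "H2", "H1", "H3"),
    soc = c("S1", "S1", "S1", "S2", "S1", "S3"))
  icsr_db(reports, report_drugs, report_events, drug_dict, event_dict)
}

# two-cluster Ising model used by network-recovery tests: within-cluster
# coupling `within`, no between-cluster coupling, common threshold h
two_cluster_ising <- function(p_per = 4L, within = 1.0, h = -1) {
  p <- 2L * p_per
  J <- matrix(0, p, p)
  J[1:p_per, 1:p_per] <- within
  J[(p_per + 1):p, (p_per + 1):p] <- within
  diag(J) <- 0
  colnames(J) <- rownames(J) <- sprintf("V%02d", 1:p)
  list(J = J, h = rep(h, p),
       labels = rep(1:2, each = p_per))
}
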