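#' Canonical validation scenarios
#'
#' Three generator configurations used throughout the package's validation
#' studies, each at 20,000 reports:
#'
#' * `null_config()`: no planted structure; drug and event indicators are
#'   independent given the stratum, so the fraction of drug-event pairs
#'   (O >= 3) flagged at IC_LB > 0 estimates the one-sided miscoverage of
#'   the 95% credibility interval (nominal 2.5%).
#' * `planted_config()`: one drug-event pair with reporting-rate ratio
#'   `rate_ratio` (default 4), dimensioned so the expected observed count in
#'   the disproportionality margins is about 25; optionally extra pairs with
#'   rate ratio 1 as in-sample negative controls.
#' * `confounded_config()`: the [plant_confounded_scenario()] case - a
#'   three-fold female enrichment of both a common drug and the index event
#'   with conditional independence within every stratum, where the crude
#'   analysis flags the pair and the Mantel-Haenszel stratified one must not.
#'
#' @param seed integer seed.
#' @param n_reports database size.
#' @param rate_ratio planted reporting-rate ratio.
#' @param n_null_controls number of additional rate-ratio-1 control pairs.
#' @return a [sim_config()].
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
null_config <- function(seed = 1L, n_reports = 20000L) {
  sim_config(n_reports = n_reports, seed = seed)
}

#' @rdname scenarios
#' @export
planted_config <- function(seed = 1L, n_reports = 20000L, rate_ratio = 4,
                           n_null_controls = 3L) {
  # a mid-frequency drug and term dimensioned so that, at the default
  # rate ratio of 4, the expected suspect/interacting co-report count is ~25
  planted <- data.frame(drug_id = "D035", pt_code = "PT0048",
                        rate_ratio = rate_ratio)
  if (n_null_controls > 0L) {
    ctrl <- data.frame(drug_id = sprintf("D%03d", 30L + seq_len(n_null_controls)),
                       pt_code = sprintf("PT%04d", 40L + seq_len(n_null_controls)),
                       rate_ratio = 1)
    planted <- rbind(planted, ctrl)
  }
  sim_config(n_reports = n_reports, seed = seed, planted_signals = planted)
}

#' @rdname scenarios
#' @export
confounded_config <- function(seed = 1L, n_reports = 20000L) {
  # no treatment-flagged drugs: the exclusion step would otherwise couple
  # case status to drug co-occurrence (competition for report slots) and
  # spoil the within-stratum independence the scenario is built to show
  # scenario geometry: the enriched drug is the database's most-reported
  # one (so the crude shift is backed by enough observed reports to clear
  # the credibility bound) and the enriched stratum has 30% prevalence -
  # the crude observed-to-expected mixture ratio (1 + w(r_d r_e - 1)) /
  # ((1 + w(r_d - 1))(1 + w(r_e - 1))) peaks near w = 0.3 for three-fold
  # enrichment
  cfg <- sim_config(n_reports = n_reports, seed = seed, n_rp_treatment = 0L,
                    p_female = 0.30)
  plant_confounded_scenario(cfg, drug_id = "D001")
}
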