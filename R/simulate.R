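#' Configuration for the synthetic ICSR generator
#'
#' Defines a spontaneous-report database with known ground truth. Reports
#' draw demographics (sex, age band, reporter type), one to five drugs by
#' weighted sampling without replacement, and events as independent per-term
#' Bernoulli draws whose probabilities are baseline marginals multiplied by
#' (i) a planted rate ratio when the report carries the paired drug, (ii)
#' stratum multipliers for declared confounders, and (iii) a cluster boost
#' when a latent per-report cluster indicator is on and the report carries a
#' class-tagged drug. Per-term Bernoulli sampling makes planted rate ratios
#' exact in expectation and leaves drug-event indicators independent given
#' the stratum when nothing is planted.
#'
#' The default dictionary names term `PT0001` "Raynaud's phenomenon",
#' `PT0002` "Peripheral ischaemia" and `PT0003` "Chilblains" (narrow and
#' broad case definitions); a configurable handful of drugs carry
#' vasodilator-class ATC codes and are flagged as disease treatments so the
#' exclusion step is exercised.
#'
#' @param n_reports number of reports.
#' @param n_drugs,n_events dictionary sizes.
#' @param seed integer seed; the same config is byte-reproducible.
#' @param drug_alpha,event_alpha power-law exponents of the marginal weight
#'   decay across the dictionaries.
#' @param mean_events target expected number of events per report (sets the
#'   baseline Bernoulli scale).
#' @param planted_signals data.frame with columns `drug_id`, `pt_code`,
#'   `rate_ratio` (>= 1): drug-event pairs reported disproportionately.
#' @param confounders list of lists with fields `variable` (`"sex"`),
#'   `level`, `drug_id`, `drug_mult`, `pt_code`, `event_mult`: joint
#'   stratum-level enrichment with within-stratum independence.
#' @param symptom_clusters list of lists with fields `class_tag`,
#'   `pt_codes`, `p_on`, `boost`: latent per-report co-occurrence among the
#'   cluster's terms in reports carrying a drug of the class.
#' @param class_assignments named list mapping class tags to drug ids (for
#'   dictionary `class_tags`); defaults assign small beta-blocker,
#'   antimigraine, amphetamine-like and kinase-inhibitor classes.
#' @param n_rp_treatment number of drugs flagged as disease treatments
#'   (given calcium-channel-blocker style ATC codes).
#' @param p_female,p_sex_unknown sex distribution.
#' @param age_mean,age_sd,p_age_missing age distribution (years).
#' @param reporter_probs probabilities for health_professional, consumer,
#'   other, unknown.
#' @param p_serious probability a report is serious.
#' @param p_date_missing,p_day_missing,p_month_missing missing-date
#'   probabilities for drug start and event onset dates.
#' @param year_range reporting years sampled uniformly.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_reports = 20000L,
                       n_drugs = 50L,
                       n_events = 80L,
                       seed = 1L,
                       drug_alpha = 0.8,
                       event_alpha = 0.5,
                       mean_events = 2.5,
                       planted_signals = NULL,
                       confounders = list(),
                       symptom_clusters = list(),
                       class_assignments = NULL,
                       n_rp_treatment = 3L,
                       p_female = 0.60, p_sex_unknown = 0.02,
                       age_mean = 48, age_sd = 19, p_age_missing = 0.06,
                       reporter_probs = c(0.58, 0.30, 0.06, 0.06),
                       p_serious = 0.40,
                       p_date_missing = 0.30, p_day_missing = 0.30,
                       p_month_missing = 0.15,
                       year_range = c(2005L, 2024L)) {
  drug_ids <- sprintf("D%03d", seq_len(n_drugs))
  pt_codes <- sprintf("PT%04d", seq_len(n_events))
  if (is.null(class_assignments)) {
    pick <- function(i) drug_ids[i[i <= n_drugs]]
    class_assignments <- list(
      beta_blocker = pick(5:8),
      antimigraine = pick(9:12),
      amphetamine_like = pick(13:16),
      tki = pick(17:20))
  }
  if (!is.null(planted_signals)) {
    planted_signals <- as.data.table(planted_signals)
    stopifnot(all(c("drug_id", "pt_code", "rate_ratio") %in% names(planted_signals)),
              all(planted_signals$rate_ratio >= 1),
              all(planted_signals$drug_id %in% drug_ids),
              all(planted_signals$pt_code %in% pt_codes))
  }
  cfg <- list(n_reports = as.integer(n_reports), n_drugs = as.integer(n_drugs),
              n_events = as.integer(n_events), seed = as.integer(seed),
              drug_alpha = drug_alpha, event_alpha = event_alpha,
              mean_events = mean_events,
              planted_signals = planted_signals, confounders = confounders,
              symptom_clusters = symptom_clusters,
              class_assignments = class_assignments,
              n_rp_treatment = as.integer(n_rp_treatment),
              p_female = p_female, p_sex_unknown = p_sex_unknown,
              age_mean = age_mean, age_sd = age_sd,
              p_age_missing = p_age_missing,
              reporter_probs = reporter_probs, p_serious = p_serious,
              p_date_missing = p_date_missing, p_day_missing = p_day_missing,
              p_month_missing = p_month_missing,
              year_range = as.integer(year_range),
              drug_ids = drug_ids, pt_codes = pt_codes)
  class(cfg) <- "sim_config"
  cfg
}

# Baseline per-term Bernoulli probabilities, power-law decaying, scaled so
# their sum equals the target mean number of events per report. The three
# case-definition terms (index condition, peripheral ischaemia, chilblains)
# are mid-frequency events, not the database's most common terms, so they
# are pinned to mid ranks of the power law; everything else fills the
# remaining ranks in order.
.event_base_probs <- function(cfg) {
  n <- cfg$n_events
  ranks <- seq_len(n)
  if (n >= 20L) {
    special <- c(10L, 15L, 18L)
    ranks <- c(special, setdiff(seq_len(n), special))
  }
  w <- ranks^(-cfg$event_alpha)
  p <- cfg$mean_events * w / sum(w)
  setNames(p, cfg$pt_codes)
}

.drug_weights <- function(cfg) {
  w <- seq_len(cfg$n_drugs)^(-cfg$drug_alpha)
  setNames(w / sum(w), cfg$drug_ids)
}

.build_dictionaries <- function(cfg) {
  # ATC pool: realistic level-3 prefixes; treatment drugs get C08 codes so
  # ATC-based exclusion configuration works against them too
  atc_pool <- c("N06BA", "N02CC", "C07AB", "C07AA", "L01EA", "L01EX",
                "N06AX", "A10BA", "J01CA", "M01AE", "R03AC", "N05AH")
  class_atc <- c(beta_blocker = "C07AB", antimigraine = "N02CC",
                 amphetamine_like = "N06BA", tki = "L01EA")
  n <- cfg$n_drugs
  atc <- paste0(sample(atc_pool, n, replace = TRUE),
                sprintf("%02d", sample(1:99, n, replace = TRUE)))
  tags <- rep("", n)
  for (tag in names(cfg$class_assignments)) {
    idx <- match(cfg$class_assignments[[tag]], cfg$drug_ids)
    idx <- idx[!is.na(idx)]
    tags[idx] <- ifelse(tags[idx] == "", tag, paste(tags[idx], tag, sep = ";"))
    if (tag %in% names(class_atc))
      atc[idx] <- paste0(class_atc[[tag]], sprintf("%02d", seq_along(idx)))
  }
  # treatment drugs sit at mid frequency (vasodilators are common but not
  # the database's dominant reports); past the class-tagged block 5-20
  rp_idx <- if (n >= 20L + cfg$n_rp_treatment) {
    20L + seq_len(cfg$n_rp_treatment)
  } else {
    seq_len(cfg$n_rp_treatment)
  }
  if (cfg$n_rp_treatment > 0L)
    atc[rp_idx] <- paste0("C08CA", sprintf("%02d", seq_along(rp_idx)))
  drug_dict <- data.table(
    drug_id = cfg$drug_ids,
    name = paste0("drug_", tolower(cfg$drug_ids)),
    atc_codes = atc,
    rp_treatment = seq_len(n) %in% rp_idx,
    class_tags = tags)
  pt_names <- paste("Event", seq_len(cfg$n_events))
  pt_names[1] <- "Raynaud's phenomenon"
  if (cfg$n_events >= 2) pt_names[2] <- "Peripheral ischaemia"
  if (cfg$n_events >= 3) pt_names[3] <- "Chilblains"
  event_dict <- data.table(
    pt_code = cfg$pt_codes,
    pt_name = pt_names,
    hlt = paste0("HLT", sprintf("%02d", ((seq_len(cfg$n_events) - 1) %/% 5) + 1)),
    soc = paste0("SOC", sprintf("%02d", ((seq_len(cfg$n_events) - 1) %/% 20) + 1)))
  list(drug_dict = drug_dict, event_dict = event_dict)
}

#' Generate a synthetic ICSR database with known ground truth
#'
#' Samples a database according to a [sim_config()] and returns it together
#' with a ground-truth ledger (planted pairs, confounders, clusters, and the
#' exact per-stratum and per-reporter counts drawn). Deterministic given
#' `config$seed`: the same config yields byte-identical TSV output. Fails if
#' any multiplied event probability would exceed 1, naming the term.
#'
#' @param config a [sim_config()].
#' @return list with elements `db` (an [icsr_db()]) and `truth` (a list).
#' @export
generate_database <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  n <- config$n_reports
  dicts <- .build_dictionaries(config)
  p_event <- .event_base_probs(config)
  w_drug <- .drug_weights(config)

  # demographics and report-level fields
  sex <- sample(c("F", "M", "unknown"), n, replace = TRUE,
                prob = c(config$p_female,
                         1 - config$p_female - config$p_sex_unknown,
                         config$p_sex_unknown))
  age <- round(pmin(pmax(rnorm(n, config$age_mean, config$age_sd), 0), 110), 1)
  age[runif(n) < config$p_age_missing] <- NA_real_
  reporter <- sample(.reporter_levels, n, replace = TRUE,
                     prob = config$reporter_probs)
  serious <- runif(n) < config$p_serious
  country <- sample(c("US", "FR", "GB", "DE", "JP", "OTH"), n, replace = TRUE,
                    prob = c(0.45, 0.11, 0.10, 0.08, 0.06, 0.20))
  year <- sample(seq(config$year_range[1], config$year_range[2]), n, replace = TRUE)
  report_ids <- sprintf("R%07d", seq_len(n))

  # ---- drugs: weighted sampling without replacement via exponential races
  k <- 1L + rbinom(n, 4L, 0.3)  # 1-5 drugs per report
  W <- matrix(w_drug, nrow = n, ncol = config$n_drugs, byrow = TRUE,
              dimnames = list(NULL, config$drug_ids))
  for (cf in config$confounders) {
    if (!is.null(cf$drug_id) && !is.na(cf$drug_mult) && cf$drug_mult != 1) {
      in_stratum <- .stratum_flag(cf, sex, age)
      W[in_stratum, cf$drug_id] <- W[in_stratum, cf$drug_id] * cf$drug_mult
    }
  }
  keys <- matrix(rexp(n * config$n_drugs), n) / W
  ord <- apply(keys, 1L, order, simplify = FALSE)
  drug_idx <- lapply(seq_len(n), function(i) ord[[i]][seq_len(k[i])])
  has_drug <- Matrix::sparseMatrix(
    i = rep(seq_len(n), k), j = unlist(drug_idx), x = 1,
    dims = c(n, config$n_drugs), dimnames = list(NULL, config$drug_ids))

  # roles: first sampled drug suspect; others suspect/interacting/concomitant
  n_entries <- sum(k)
  rd_report <- rep(seq_len(n), k)
  rd_drug <- unlist(drug_idx)
  first <- !duplicated(rd_report)
  role <- sample(.role_levels, n_entries, replace = TRUE,
                 prob = c(0.35, 0.10, 0.55))
  role[first] <- "suspect"

  # ---- events: per-term Bernoulli probabilities with multipliers
  P <- matrix(p_event, nrow = n, ncol = config$n_events, byrow = TRUE,
              dimnames = list(NULL, config$pt_codes))
  if (!is.null(config$planted_signals)) {
    for (r in seq_len(nrow(config$planted_signals))) {
      ps <- config$planted_signals[r]
      carrier <- as.logical(has_drug[, ps$drug_id] > 0)
      P[carrier, ps$pt_code] <- P[carrier, ps$pt_code] * ps$rate_ratio
    }
  }
  for (cf in config$confounders) {
    if (!is.null(cf$pt_code) && !is.na(cf$event_mult) && cf$event_mult != 1) {
      in_stratum <- .stratum_flag(cf, sex, age)
      P[in_stratum, cf$pt_code] <- P[in_stratum, cf$pt_code] * cf$event_mult
    }
  }
  cluster_state <- list()
  for (ci in seq_along(config$symptom_clusters)) {
    cl <- config$symptom_clusters[[ci]]
    members <- config$class_assignments[[cl$class_tag]]
    carrier <- as.logical(Matrix::rowSums(has_drug[, members, drop = FALSE]) > 0)
    on <- carrier & (runif(n) < cl$p_on)
    P[on, cl$pt_codes] <- P[on, cl$pt_codes] * cl$boost
    cluster_state[[ci]] <- on
  }
  over <- which(P > 1, arr.ind = TRUE)
  if (nrow(over) > 0L) {
    stop("infeasible event probability > 1 for term ",
         colnames(P)[over[1, 2]], " (", signif(max(P), 4),
         "); lower baseline rates or multipliers")
  }
  has_event <- matrix(runif(n * config$n_events), n) < P
  # every report needs >= 1 event; fall back to one draw from the baseline
  # marginals, independent of the report's drugs (keeps the null clean)
  empty <- which(rowSums(has_event) == 0L)
  if (length(empty)) {
    fallback <- sample.int(config$n_events, length(empty), replace = TRUE,
                           prob = p_event)
    has_event[cbind(empty, fallback)] <- TRUE
  }

  # ---- dates: drug start uniform within the report year, onset lagged
  start_date <- as.Date(sprintf("%d-01-01", year[rd_report])) +
    sample.int(300L, n_entries, replace = TRUE) - 1L
  sy <- as.integer(format(start_date, "%Y"))
  sm <- as.integer(format(start_date, "%m"))
  sdd <- as.integer(format(start_date, "%d"))
  miss_all <- runif(n_entries) < config$p_date_missing
  miss_mon <- runif(n_entries) < config$p_month_missing
  miss_day <- runif(n_entries) < config$p_day_missing
  sy[miss_all] <- NA_integer_
  sm[miss_all | miss_mon] <- NA_integer_
  sdd[miss_all | miss_mon | miss_day] <- NA_integer_

  ev_idx <- which(has_event, arr.ind = TRUE)
  ev_idx <- ev_idx[order(ev_idx[, 1], ev_idx[, 2]), , drop = FALSE]
  n_ev <- nrow(ev_idx)
  # onset = report-level anchor (first drug start) + gamma lag in days
  anchor <- as.Date(sprintf("%d-01-01", year)) + sample.int(300L, n, replace = TRUE) - 1L
  lag <- round(rgamma(n_ev, shape = 1.5, scale = 40))
  onset <- anchor[ev_idx[, 1]] + lag
  oy <- as.integer(format(onset, "%Y"))
  om <- as.integer(format(onset, "%m"))
  od <- as.integer(format(onset, "%d"))
  miss_all <- runif(n_ev) < config$p_date_missing
  miss_mon <- runif(n_ev) < config$p_month_missing
  miss_day <- runif(n_ev) < config$p_day_missing
  oy[miss_all] <- NA_integer_
  om[miss_all | miss_mon] <- NA_integer_
  od[miss_all | miss_mon | miss_day] <- NA_integer_

  reports <- data.table(report_id = report_ids, country = country,
                        report_year = year, reporter_type = reporter,
                        serious = serious, age_years = age,
                        sex = sex)
  report_drugs <- data.table(report_id = report_ids[rd_report],
                             drug_id = config$drug_ids[rd_drug],
                             role = role,
                             start_year = sy, start_month = sm, start_day = sdd)
  report_events <- data.table(report_id = report_ids[ev_idx[, 1]],
                              pt_code = config$pt_codes[ev_idx[, 2]],
                              onset_year = oy, onset_month = om, onset_day = od)

  db <- icsr_db(reports, report_drugs, report_events,
                dicts$drug_dict, dicts$event_dict, validate = FALSE)

  truth <- list(
    planted = config$planted_signals,
    confounders = config$confounders,
    clusters = config$symptom_clusters,
    event_base_probs = p_event,
    drug_weights = w_drug,
    stratum_counts = as.data.frame(table(sex = sex, age_band = age_band(age))),
    reporter_counts = as.data.frame(table(reporter_type = reporter)),
    cluster_on_counts = vapply(cluster_state, sum, integer(1)),
    seed = config$seed)
  list(db = db, truth = truth)
}

.stratum_flag <- function(cf, sex, age) {
  if (cf$variable == "sex") sex == cf$level
  else if (cf$variable == "age_band") as.character(age_band(age)) == cf$level
  else stop("unknown stratum variable: ", cf$variable)
}

#' Construct the canonical confounded scenario
#'
#' Returns a config in which a chosen drug and a chosen event are both
#' enriched (default three-fold) in one stratum (default: females) while
#' remaining conditionally independent within every stratum. This is the
#' textbook case where the crude observed-to-expected ratio is inflated
#' (mixture of per-stratum products) but the Mantel-Haenszel stratified
#' expected count is null, so the stratified analysis should not flag the
#' pair.
#'
#' @param config a [sim_config()] to modify.
#' @param drug_id,pt_code the confounded pair (defaults: a mid-frequency
#'   drug and the first preferred term).
#' @param multiplier stratum-level enrichment for both drug and event.
#' @param level stratum level of `variable` carrying the enrichment.
#' @param variable stratum variable (`"sex"`).
#' @return the modified config.
#' @export
plant_confounded_scenario <- function(config, drug_id = config$drug_ids[4],
                                      pt_code = config$pt_codes[1],
                                      multiplier = 3, level = "F",
                                      variable = "sex") {
  stopifnot(inherits(config, "sim_config"))
  config$confounders <- c(config$confounders, list(list(
    variable = variable, level = level,
    drug_id = drug_id, drug_mult = multiplier,
    pt_code = pt_code, event_mult = multiplier)))
  config
}
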