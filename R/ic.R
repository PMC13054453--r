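#' Information component (IC) point estimate
#'
#' The IC is the log2 of the shrunk observed-to-expected reporting ratio,
#' `IC = log2((O + 0.5) / (E + 0.5))`, where `O` is the number of reports
#' with both drug and event and `E = n_drug * n_event / N` is the count
#' expected under independent reporting. The +0.5 offsets shrink estimates
#' for rare combinations towards zero and keep the statistic defined at
#' `O = 0`.
#'
#' @param O observed count(s), >= 0.
#' @param E expected count(s), >= 0.
#' @return IC in bits (vectorised).
#' @examples
#' ic_point(20, 5)            # about 1.898
#' ic_point(0, 0)             # exactly 0
#' @export
ic_point <- function(O, E) {
  stopifnot(all(O >= 0), all(E >= 0))
  log2((O + 0.5) / (E + 0.5))
}

#' Lower credibility bound of the information component
#'
#' The observed-to-expected ratio has a Gamma(shape = O + 0.5,
#' rate = E + 0.5) posterior under the shrinkage prior implied by the IC's
#' +0.5 offsets; `method = "exact_gamma"` (the default) takes the log2 of
#' the posterior's lower-tail quantile at `(1 - level)/2`. The closed-form
#' alternative `method = "approximate"`,
#' `IC - 3.3 (O + 0.5)^{-1/2} - 2 (O + 0.5)^{-3/2}` for a 95% interval, is
#' retained as an independent cross-check; the two agree within 0.1 bits
#' for O >= 10. A pair is a signal of disproportionate reporting (SDR) when
#' this bound exceeds 0.
#'
#' @param O,E observed and expected counts (vectorised).
#' @param level credibility level of the two-sided interval (default 0.95,
#'   i.e. the 2.5th posterior percentile).
#' @param method `"exact_gamma"` or `"approximate"`.
#' @return lower bound in bits.
#' @examples
#' ic_lower_bound(20, 5)                         # exact gamma bound
#' ic_lower_bound(20, 5, method = "approximate") # about 1.147
#' @export
ic_lower_bound <- function(O, E, level = 0.95,
                           method = c("exact_gamma", "approximate")) {
  stopifnot(level > 0, level < 1, all(O >= 0), all(E >= 0))
  method <- match.arg(method)
  if (method == "exact_gamma") {
    log2(stats::qgamma((1 - level) / 2, shape = O + 0.5, rate = E + 0.5))
  } else {
    if (abs(level - 0.95) > 1e-12)
      stop("the closed-form approximation is defined for level = 0.95 only")
    ic_point(O, E) - 3.3 * (O + 0.5)^(-0.5) - 2 * (O + 0.5)^(-1.5)
  }
}

#' Build a 2x2 contingency summary for a drug against a case series
#'
#' Counts, within a background set of reports, the reports carrying the drug
#' (as suspect or interacting by default; concomitant entries do not count
#' towards disproportionality), the case reports, their overlap, and the
#' background total. These four margins determine the expected count
#' `E = n_drug * n_event / N` and hence the IC.
#'
#' @param db an `icsr_db`.
#' @param drug_id drug to count.
#' @param case_ids ids of the case reports (must lie within the background).
#' @param background_ids ids forming the comparator universe; defaults to
#'   the whole database.
#' @param roles drug roles counting towards the drug margin.
#' @param stratum_label optional label carried through for stratified use.
#' @return a list of class `contingency_table` with `O`, `n_drug`,
#'   `n_event`, `N`, `E`.
#' @export
build_table <- function(db, drug_id, case_ids,
                        background_ids = db$reports$report_id,
                        roles = c("suspect", "interacting"),
                        stratum_label = NULL) {
  if (length(background_ids) == 0L) stop("empty background")
  if (!all(case_ids %in% background_ids))
    stop("case_ids must be a subset of background_ids")
  the_drug <- drug_id
  with_drug <- unique(db$report_drugs[drug_id == the_drug & role %in% roles,
                                      report_id])
  with_drug <- intersect(with_drug, background_ids)
  O <- length(intersect(with_drug, case_ids))
  tab <- list(O = O, n_drug = length(with_drug), n_event = length(case_ids),
              N = length(background_ids),
              E = length(with_drug) * length(case_ids) / length(background_ids),
              stratum_label = stratum_label)
  class(tab) <- "contingency_table"
  tab
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 margins%s: O=%d n_drug=%d n_event=%d N=%d (E=%.3f)\n",
              if (is.null(x$stratum_label)) "" else paste0(" [", x$stratum_label, "]"),
              x$O, x$n_drug, x$n_event, x$N, x$E))
  invisible(x)
}

#' Mantel-Haenszel stratified expected count
#'
#' Pools per-stratum 2x2 margins into an adjusted expected count:
#' `E_MH = sum_s n_drug[s] * n_event[s] / N[s]`, with the observed count
#' summed over strata. The IC computed from `(O_total, E_MH)` is the
#' stratification-adjusted statistic; with a single stratum it reduces
#' exactly to the crude analysis. Strata with `N = 0` are dropped with a
#' warning.
#'
#' @param tables list of `contingency_table` objects, one per stratum
#'   (strata must be disjoint and exhaustive over the background).
#' @return list with `O` (total observed) and `E` (pooled expected).
#' @export
mh_expected <- function(tables) {
  stopifnot(length(tables) >= 1L)
  Ns <- vapply(tables, `[[`, numeric(1), "N")
  if (any(Ns == 0)) {
    warning(sum(Ns == 0), " empty stratum(s) dropped")
    tables <- tables[Ns > 0]
  }
  O <- sum(vapply(tables, `[[`, numeric(1), "O"))
  E <- sum(vapply(tables, function(t) t$n_drug * t$n_event / t$N, numeric(1)))
  list(O = O, E = E)
}

# ---- vectorised counting machinery -----------------------------------------

# Sparse report x drug and report x event incidence over a set of reports.
# Drug incidence counts suspect/interacting roles only unless asked otherwise.
.incidence <- function(db, report_ids = db$reports$report_id,
                       roles = c("suspect", "interacting")) {
  rid <- sort(unique(report_ids))
  rd <- unique(db$report_drugs[report_id %in% rid & role %in% roles,
                               .(report_id, drug_id)])
  re <- unique(db$report_events[report_id %in% rid, .(report_id, pt_code)])
  drugs <- db$drug_dict$drug_id
  events <- db$event_dict$pt_code
  Md <- Matrix::sparseMatrix(
    i = match(rd$report_id, rid), j = match(rd$drug_id, drugs),
    x = 1, dims = c(length(rid), length(drugs)),
    dimnames = list(rid, drugs))
  Me <- Matrix::sparseMatrix(
    i = match(re$report_id, rid), j = match(re$pt_code, events),
    x = 1, dims = c(length(rid), length(events)),
    dimnames = list(rid, events))
  list(drug = Md, event = Me, report_ids = rid)
}

#' Disproportionality across all drug-event pairs
#'
#' Computes O, E, IC and the IC lower bound for every drug-event pair over a
#' background set of reports, used for database-wide screening, calibration
#' studies and event-event analyses. Drug margins count suspect/interacting
#' entries only.
#'
#' @param db an `icsr_db`.
#' @param report_ids background reports (default: all).
#' @param min_obs keep only pairs with `O >=` this (default 1).
#' @param level credibility level.
#' @return data.table with drug_id, pt_code, O, n_drug, n_event, N, E, IC,
#'   IC_LB, significant.
#' @export
pairwise_signals <- function(db, report_ids = db$reports$report_id,
                             min_obs = 1L, level = 0.95) {
  inc <- .incidence(db, report_ids)
  N <- length(inc$report_ids)
  Omat <- as.matrix(Matrix::crossprod(inc$drug, inc$event))
  n_drug <- Matrix::colSums(inc$drug)
  n_event <- Matrix::colSums(inc$event)
  keep <- which(Omat >= min_obs, arr.ind = TRUE)
  if (nrow(keep) == 0L) {
    return(data.table(drug_id = character(), pt_code = character(),
                      O = integer(), n_drug = integer(), n_event = integer(),
                      N = integer(), E = numeric(), IC = numeric(),
                      IC_LB = numeric(), significant = logical()))
  }
  O <- Omat[keep]
  nd <- n_drug[keep[, 1]]
  ne <- n_event[keep[, 2]]
  E <- nd * ne / N
  res <- data.table(
    drug_id = rownames(Omat)[keep[, 1]],
    pt_code = colnames(Omat)[keep[, 2]],
    O = as.integer(O), n_drug = as.integer(nd), n_event = as.integer(ne),
    N = N, E = E,
    IC = ic_point(O, E),
    IC_LB = ic_lower_bound(O, E, level = level))
  res[, significant := IC_LB > 0]
  res[order(-IC_LB)]
}

.analysis_ids <- c("primary", "hcp_only", "atc3_background",
                   "mh_stratified", "broad_definition")

#' Run the primary or a sensitivity disproportionality analysis
#'
#' Produces one signal row per drug appearing as suspect or interacting in at
#' least one included case. The five analyses share the same machinery and
#' differ in case definition, background or expected-count adjustment:
#'
#' * `primary`: cases by the narrow term set, background = all reports that
#'   survive the treatment-drug exclusion.
#' * `hcp_only`: cases and background restricted to reports from health care
#'   professionals.
#' * `atc3_background`: per drug, the background is restricted to reports
#'   carrying at least one drug sharing an ATC level-3 prefix (first four
#'   characters) with it, countering indication bias; drugs without ATC codes
#'   are flagged not evaluable.
#' * `mh_stratified`: expected counts pooled over sex x age-band strata
#'   (Mantel-Haenszel), countering confounding by age and sex.
#' * `broad_definition`: cases by the broad term set.
#'
#' @param db an `icsr_db`.
#' @param analysis_id one of `"primary"`, `"hcp_only"`, `"atc3_background"`,
#'   `"mh_stratified"`, `"broad_definition"`.
#' @param pt_narrow,pt_broad preferred-term sets defining the narrow and
#'   broad case definitions.
#' @param exclusion_drugs see [apply_exclusion()].
#' @param level credibility level for the bound.
#' @param roles roles counting towards drug margins.
#' @return data.table with drug_id, analysis_id, O, E, IC, IC_LB,
#'   significant, evaluable.
#' @export
run_analysis <- function(db, analysis_id, pt_narrow, pt_broad = pt_narrow,
                         exclusion_drugs = db$drug_dict[rp_treatment == TRUE, drug_id],
                         level = 0.95, roles = c("suspect", "interacting")) {
  analysis_id <- match.arg(analysis_id, .analysis_ids)
  pt_set <- if (analysis_id == "broad_definition") pt_broad else pt_narrow
  cases0 <- select_cases(db, pt_set)
  included <- apply_exclusion(db, cases0, exclusion_drugs)
  flow <- attr(included, "flow")
  # the analysis universe drops the excluded case reports entirely
  universe <- setdiff(db$reports$report_id, setdiff(cases0, included))

  if (analysis_id == "hcp_only") {
    hcp <- db$reports[reporter_type == "health_professional", report_id]
    universe <- intersect(universe, hcp)
  }
  cases <- intersect(included, universe)

  # drugs under evaluation: suspect/interacting in >= 1 included case
  eval_drugs <- sort(unique(
    db$report_drugs[report_id %in% included & role %in% roles, drug_id]))
  if (length(eval_drugs) == 0L) {
    res <- data.table(drug_id = character(), analysis_id = character(),
                      O = integer(), E = numeric(), IC = numeric(),
                      IC_LB = numeric(), significant = logical(),
                      evaluable = logical())
    attr(res, "flow") <- flow
    return(res)
  }

  inc <- .incidence(db, universe, roles)
  case_flag <- inc$report_ids %in% cases
  di <- match(eval_drugs, colnames(inc$drug))

  if (analysis_id %in% c("primary", "hcp_only", "broad_definition")) {
    O <- as.integer(Matrix::colSums(inc$drug[case_flag, di, drop = FALSE]))
    n_drug <- Matrix::colSums(inc$drug[, di, drop = FALSE])
    E <- n_drug * sum(case_flag) / length(inc$report_ids)
    evaluable <- rep(TRUE, length(eval_drugs))
    if (analysis_id == "hcp_only") evaluable <- n_drug > 0
  } else if (analysis_id == "mh_stratified") {
    rep_sub <- db$reports[match(inc$report_ids, report_id)]
    strat <- interaction(factor(ifelse(rep_sub$sex %in% c("F", "M"),
                                       rep_sub$sex, "unknown"),
                                levels = .sex_levels),
                         age_band(rep_sub$age_years), drop = TRUE)
    O <- as.integer(Matrix::colSums(inc$drug[case_flag, di, drop = FALSE]))
    E <- numeric(length(eval_drugs))
    for (s in levels(strat)) {
      idx <- strat == s
      Ns <- sum(idx)
      if (Ns == 0L) next
      nds <- Matrix::colSums(inc$drug[idx, di, drop = FALSE])
      nes <- sum(case_flag & idx)
      E <- E + nds * nes / Ns
    }
    evaluable <- rep(TRUE, length(eval_drugs))
  } else { # atc3_background
    atc3 <- .atc3_map(db$drug_dict)
    O <- integer(length(eval_drugs))
    E <- numeric(length(eval_drugs))
    evaluable <- logical(length(eval_drugs))
    # reports (row indices) carrying each ATC3 class, over the universe
    class_rows <- lapply(.atc3_class_members(atc3), function(dd) {
      cols <- match(intersect(dd, colnames(inc$drug)), colnames(inc$drug))
      which(Matrix::rowSums(inc$drug[, cols, drop = FALSE]) > 0)
    })
    for (k in seq_along(eval_drugs)) {
      d <- eval_drugs[k]
      classes <- atc3[[d]]
      if (is.null(classes) || length(classes) == 0L) {
        evaluable[k] <- FALSE
        next
      }
      rows <- sort(unique(unlist(class_rows[classes], use.names = FALSE)))
      if (length(rows) == 0L) { evaluable[k] <- FALSE; next }
      evaluable[k] <- TRUE
      dcol <- inc$drug[rows, di[k]]
      cf <- case_flag[rows]
      O[k] <- as.integer(sum(dcol[cf]))
      E[k] <- sum(dcol) * sum(cf) / length(rows)
    }
  }

  res <- data.table(drug_id = eval_drugs, analysis_id = analysis_id,
                    O = O, E = E,
                    IC = ic_point(O, E),
                    IC_LB = ic_lower_bound(O, E, level = level))
  res[, significant := evaluable & IC_LB > 0]
  res[, evaluable := evaluable]
  res[evaluable == FALSE, c("IC", "IC_LB") := NA_real_]
  attr(res, "flow") <- flow
  res[]
}

# drug_id -> character vector of 4-char ATC level-3 prefixes
.atc3_map <- function(drug_dict) {
  codes <- strsplit(drug_dict$atc_codes, ";", fixed = TRUE)
  m <- lapply(codes, function(cc) unique(substr(cc[nchar(cc) >= 4], 1, 4)))
  names(m) <- drug_dict$drug_id
  m
}

# ATC3 class -> drug ids belonging to it
.atc3_class_members <- function(atc3) {
  long <- data.table(drug_id = rep(names(atc3), lengths(atc3)),
                     class = unlist(atc3, use.names = FALSE))
  split(long$drug_id, long$class)
}
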