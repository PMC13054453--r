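#' Run the primary and all sensitivity analyses and join per drug
#'
#' Executes the five disproportionality analyses, joins the results per drug,
#' and derives cross-analysis consistency: a drug is `consistent_all` when it
#' is significant in the primary analysis and in every sensitivity analysis
#' in which it is evaluable (a drug with, say, no reports from health care
#' professionals cannot be assessed in the reporter-restricted analysis and
#' is not penalised for it, but is flagged via `n_not_evaluable`).
#'
#' @param db an `icsr_db`.
#' @param pt_narrow,pt_broad case-definition term sets; defaults are the
#'   terms named "Raynaud's phenomenon" (narrow) plus "Peripheral ischaemia"
#'   and "Chilblains" (broad) in the event dictionary.
#' @param analyses which analyses to run (primary always included).
#' @param exclusion_drugs see [apply_exclusion()].
#' @param summaries attach a [summarize_cases()] per drug (list column).
#' @param level credibility level.
#' @return data.table of consistency records, one row per drug evaluated in
#'   the primary analysis, with the per-analysis IC_LB in wide columns, the
#'   `significant_in` analysis list, and `consistent_all`. The full long
#'   results table is attached as attribute `"long"`, the case-selection
#'   flow as `"flow"`.
#' @export
run_all <- function(db,
                    pt_narrow = default_pt_narrow(db),
                    pt_broad = default_pt_broad(db),
                    analyses = .analysis_ids,
                    exclusion_drugs = db$drug_dict[rp_treatment == TRUE, drug_id],
                    summaries = FALSE, level = 0.95) {
  analyses <- union("primary", match.arg(analyses, .analysis_ids, several.ok = TRUE))
  long <- rbindlist(lapply(analyses, function(a) {
    run_analysis(db, a, pt_narrow = pt_narrow, pt_broad = pt_broad,
                 exclusion_drugs = exclusion_drugs, level = level)
  }))
  prim <- long[analysis_id == "primary"]
  sens <- long[analysis_id != "primary"]

  rec <- prim[, .(drug_id, O_primary = O, E_primary = E,
                  IC_primary = IC, IC_LB_primary = IC_LB,
                  significant_primary = significant)]
  if (nrow(sens)) {
    agg <- sens[rec, on = "drug_id"][, .(
      n_evaluable = sum(evaluable, na.rm = TRUE),
      n_not_evaluable = sum(!evaluable | is.na(evaluable)),
      all_sens_significant = all(significant[evaluable %in% TRUE])
    ), by = drug_id]
  } else {
    agg <- data.table(drug_id = rec$drug_id, n_evaluable = 0L,
                      n_not_evaluable = 0L, all_sens_significant = TRUE)
  }
  rec <- agg[rec, on = "drug_id"]
  sig_in <- long[significant %in% TRUE,
                 .(significant_in = list(sort(analysis_id))), by = drug_id]
  rec <- sig_in[rec, on = "drug_id"]
  rec[vapply(significant_in, is.null, logical(1)), significant_in := list(list(character(0)))]
  rec[, consistent_all := significant_primary & all_sens_significant]
  # wide IC_LB per analysis for circular-plot style exports
  wide <- dcast(long, drug_id ~ analysis_id, value.var = "IC_LB")
  setnames(wide, setdiff(names(wide), "drug_id"),
           paste0("IC_LB_", setdiff(names(wide), "drug_id")))
  if ("IC_LB_primary" %in% names(wide)) wide[, IC_LB_primary := NULL]
  rec <- wide[rec, on = "drug_id"]
  if (summaries) {
    cases0 <- select_cases(db, pt_narrow)
    included <- apply_exclusion(db, cases0, exclusion_drugs)
    rec[, case_summary := lapply(drug_id, function(d)
      summarize_cases(db, included, d, pt_set = pt_narrow))]
  }
  setcolorder(rec, c("drug_id", "O_primary", "E_primary", "IC_primary",
                     "IC_LB_primary", "significant_primary"))
  out <- rec[order(-IC_LB_primary)]
  attr(out, "long") <- long
  cases0 <- select_cases(db, pt_narrow)
  attr(out, "flow") <- attr(apply_exclusion(db, cases0, exclusion_drugs), "flow")
  out
}

#' Default narrow and broad case-definition term sets
#'
#' Looks up, in a database's event dictionary, the preferred terms named
#' "Raynaud's phenomenon" (narrow definition) and additionally "Peripheral
#' ischaemia" and "Chilblains" (broad definition, absorbing variability in
#' symptom coding).
#'
#' @param db an `icsr_db`.
#' @return character vector of pt codes.
#' @export
default_pt_narrow <- function(db) {
  pt <- db$event_dict[tolower(pt_name) %in% "raynaud's phenomenon", pt_code]
  if (length(pt) == 0L) stop("event dictionary has no term named Raynaud's phenomenon")
  pt
}

#' @rdname default_pt_narrow
#' @export
default_pt_broad <- function(db) {
  extra <- db$event_dict[tolower(pt_name) %in%
                           c("peripheral ischaemia", "peripheral ischemia",
                             "chilblains"), pt_code]
  union(default_pt_narrow(db), extra)
}

#' Rank consistency records for expert review
#'
#' Orders records by cross-analysis consistency, then by the primary IC
#' lower bound; optionally annotates prior awareness of each association
#' from a user-supplied lookup (drug_id, already_described). Fixed-dose
#' combination products (dictionary `class_tags` containing `combination`)
#' are dropped from the ranking, since their signals cannot be attributed to
#' a single substance. No plausibility category is assigned: that is expert
#' judgment, outside the scope of this package.
#'
#' @param records output of [run_all()].
#' @param awareness optional data.frame with `drug_id` and
#'   `already_described` (logical); unknown drug ids draw a warning.
#' @param drug_dict optional drug dictionary, used to drop combination
#'   products.
#' @return the ranked data.table (a permutation of the retained records).
#' @export
rank_signals <- function(records, awareness = NULL, drug_dict = NULL) {
  out <- as.data.table(records)
  if (!is.null(drug_dict)) {
    combos <- as.data.table(drug_dict)[grepl("\\bcombination\\b", class_tags), drug_id]
    out <- out[!drug_id %in% combos]
  }
  if (!is.null(awareness)) {
    awareness <- as.data.table(awareness)
    unknown <- setdiff(awareness$drug_id, out$drug_id)
    if (length(unknown))
      warning("awareness table lists drug(s) absent from records: ",
              paste(unknown, collapse = ", "))
    out <- merge(out, awareness[, .(drug_id, already_described)],
                 by = "drug_id", all.x = TRUE, sort = FALSE)
    out[, prior_awareness := fifelse(is.na(already_described), "unknown",
                                     fifelse(already_described,
                                             "already_described", "unknown"))]
    out[, already_described := NULL]
  }
  out[order(-consistent_all, -IC_LB_primary)]
}
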