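#' Read a drug-target map
#'
#' TSV with columns `drug_id`, `target_id`, `target_name`, `action`
#' (agonist/antagonist/inhibitor/substrate/other). Duplicate
#' (drug, target, action) rows are collapsed.
#'
#' @param path TSV path.
#' @return data.table.
#' @export
read_target_map <- function(path) {
  tm <- .read_tsv(path)
  stopifnot(all(c("drug_id", "target_id", "target_name", "action") %in% names(tm)))
  unique(tm, by = c("drug_id", "target_id", "action"))
}

#' Aggregate pharmacological targets across signal drugs
#'
#' For each (target, action) pair, counts the distinct signal drugs hitting
#' it and sums their supporting case counts (`O` from the primary
#' analysis), ranking targets by total cases. A drug with several targets
#' contributes its cases to each of them - the multiplicity is deliberate
#' and visible in the schema, since the ranking asks "how many reports sit
#' behind drugs sharing this target", not for a partition of reports.
#' Drugs absent from the map are tallied under the `unmapped` attribute.
#'
#' @param signal_records data.frame with `drug_id` and a case-count column
#'   (`O_primary` from [run_all()] or `O` from [run_analysis()]); typically
#'   pre-filtered to the signals of interest.
#' @param target_map data.frame from [read_target_map()] or equivalent.
#' @return data.table (target_id, target_name, action, n_drugs, n_icsrs)
#'   sorted by n_icsrs, ties by n_drugs then target_id; attribute
#'   `"unmapped"` lists drugs without any target.
#' @export
aggregate_targets <- function(signal_records, target_map) {
  rec <- as.data.table(signal_records)
  ocol <- intersect(c("O_primary", "O"), names(rec))[1]
  if (is.na(ocol)) stop("signal_records must carry O or O_primary")
  rec <- rec[, .(drug_id, n_cases = as.numeric(get(ocol)))]
  tm <- as.data.table(target_map)
  unmapped <- setdiff(rec$drug_id, tm$drug_id)
  joined <- merge(tm, rec, by = "drug_id")
  out <- joined[, .(n_drugs = uniqueN(drug_id), n_icsrs = sum(n_cases)),
                by = .(target_id, target_name, action)]
  out <- out[order(-n_icsrs, -n_drugs, target_id)]
  attr(out, "unmapped") <- unmapped
  if (length(unmapped))
    message(length(unmapped), " signal drug(s) have no target mapping")
  out
}
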