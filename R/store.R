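#' @import data.table
#' @importFrom stats median quantile rbinom rexp rgamma rnorm runif sd setNames
#' @importFrom utils head
NULL

# Preferred-term sets for the narrow and broad case definitions, and the
# default ATC prefixes defining drugs used to treat Raynaud's phenomenon or
# systemic-sclerosis digital ulcers (calcium channel blockers, PDE5
# inhibitors, endothelin receptor antagonists, ARBs, ACE inhibitors, alpha
# blockers, intravenous prostanoids). Both are configuration, not code:
# every function taking them accepts overrides.

#' Default ATC prefixes for drugs used in Raynaud's phenomenon treatment
#'
#' Reports carrying any drug whose ATC code starts with one of these prefixes
#' are excluded from the case series, since treated patients are selected for
#' pre-existing disease. Covers calcium channel blockers (C08), PDE5
#' inhibitors (G04BE), endothelin receptor antagonists (C02KX), angiotensin
#' receptor blockers (C09C, C09D), ACE inhibitors (C09A, C09B), alpha
#' blockers (C02CA) and prostanoids (B01AC09/11/21).
#'
#' @return character vector of ATC prefixes.
#' @export
default_exclusion_atc <- function() {
  c("C08", "G04BE", "C02KX", "C09C", "C09D", "C09A", "C09B",
    "C02CA", "B01AC09", "B01AC11", "B01AC21")
}

.role_levels <- c("suspect", "interacting", "concomitant")
.reporter_levels <- c("health_professional", "consumer", "other", "unknown")
.sex_levels <- c("F", "M", "unknown")

#' Construct an ICSR database object
#'
#' Bundles the five normalized tables of a spontaneous-report database into a
#' validated container: one row per report, long tables linking reports to
#' drugs and to events, and the two dictionaries. All disproportionality
#' statistics are computed against this universe.
#'
#' @param reports data.frame with columns `report_id`, `country`,
#'   `report_year`, `reporter_type`, `serious` (logical/0-1), `age_years`,
#'   `sex`.
#' @param report_drugs data.frame with `report_id`, `drug_id`, `role`
#'   (suspect/interacting/concomitant), `start_year`, `start_month`,
#'   `start_day`.
#' @param report_events data.frame with `report_id`, `pt_code`,
#'   `onset_year`, `onset_month`, `onset_day`.
#' @param drug_dict data.frame with `drug_id`, `name`, `atc_codes`
#'   (semicolon-separated), `rp_treatment` (logical/0-1), `class_tags`
#'   (semicolon-separated, may be empty).
#' @param event_dict data.frame with `pt_code`, `pt_name`, `hlt`, `soc`.
#' @param validate drop rows violating referential integrity (with a
#'   warning) instead of erroring.
#' @return an object of class `icsr_db`.
#' @export
icsr_db <- function(reports, report_drugs, report_events, drug_dict,
                    event_dict, validate = TRUE) {
  reports <- as.data.table(reports)
  report_drugs <- as.data.table(report_drugs)
  report_events <- as.data.table(report_events)
  drug_dict <- as.data.table(drug_dict)
  event_dict <- as.data.table(event_dict)

  reports[, report_id := as.character(report_id)]
  reports[, serious := as.logical(as.integer(serious))]
  reports[, age_years := as.numeric(age_years)]
  report_drugs[, report_id := as.character(report_id)]
  report_events[, report_id := as.character(report_id)]
  drug_dict[, rp_treatment := as.logical(as.integer(rp_treatment))]
  if (!"class_tags" %in% names(drug_dict)) drug_dict[, class_tags := ""]
  # empty string and missing are equivalent for the list-valued fields
  drug_dict[is.na(class_tags), class_tags := ""]
  drug_dict[is.na(atc_codes), atc_codes := ""]

  if (anyDuplicated(reports$report_id))
    stop("duplicate report_id in reports table")
  if (anyDuplicated(drug_dict$drug_id))
    stop("duplicate drug_id in drug dictionary")
  if (anyDuplicated(event_dict$pt_code))
    stop("duplicate pt_code in event dictionary")

  n_skipped <- 0L
  if (validate) {
    bad_age <- !is.na(reports$age_years) &
      (reports$age_years < 0 | reports$age_years > 120)
    if (any(bad_age)) {
      warning(sum(bad_age), " report(s) with age outside [0, 120]; age set missing")
      reports[bad_age, age_years := NA_real_]
    }
    bad <- which(!(report_drugs$report_id %in% reports$report_id) |
                   !(report_drugs$drug_id %in% drug_dict$drug_id) |
                   !(report_drugs$role %in% .role_levels))
    if (length(bad)) {
      warning(length(bad), " drug row(s) failed referential checks (rows ",
              paste(head(bad, 10L), collapse = ","), if (length(bad) > 10L) ",..." else "",
              "); skipped")
      report_drugs <- report_drugs[-bad]
      n_skipped <- n_skipped + length(bad)
    }
    bad <- which(!(report_events$report_id %in% reports$report_id) |
                   !(report_events$pt_code %in% event_dict$pt_code))
    if (length(bad)) {
      warning(length(bad), " event row(s) failed referential checks (rows ",
              paste(head(bad, 10L), collapse = ","), if (length(bad) > 10L) ",..." else "",
              "); skipped")
      report_events <- report_events[-bad]
      n_skipped <- n_skipped + length(bad)
    }
    # every report must carry at least one drug and one event
    ok <- reports$report_id %in% report_drugs$report_id &
      reports$report_id %in% report_events$report_id
    if (any(!ok)) {
      warning(sum(!ok), " report(s) without drugs or events dropped")
      reports <- reports[ok]
      report_drugs <- report_drugs[report_id %in% reports$report_id]
      report_events <- report_events[report_id %in% reports$report_id]
      n_skipped <- n_skipped + sum(!ok)
    }
  }
  if (nrow(reports) == 0L) stop("database contains no valid reports")

  db <- structure(list(reports = reports,
                       report_drugs = report_drugs,
                       report_events = report_events,
                       drug_dict = drug_dict,
                       event_dict = event_dict,
                       n_skipped = n_skipped),
                  class = "icsr_db")
  db
}

#' @export
print.icsr_db <- function(x, ...) {
  cat("ICSR database:", nrow(x$reports), "reports,",
      nrow(x$drug_dict), "drugs,", nrow(x$event_dict), "preferred terms\n")
  cat("  drug entries:", nrow(x$report_drugs),
      " event entries:", nrow(x$report_events), "\n")
  invisible(x)
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fread(path, sep = "\t", header = TRUE, na.strings = "",
        colClasses = list(character = 1L), keepLeadingZeros = TRUE)
}

#' Read an ICSR database from five TSV files
#'
#' Files are UTF-8, tab-separated with a header row; empty strings encode
#' missing values. Rows failing referential integrity (unknown report, drug
#' or preferred-term keys) are skipped with a warning that lists the
#' offending row numbers.
#'
#' @param dir directory containing `reports.tsv`, `report_drugs.tsv`,
#'   `report_events.tsv`, `drug_dictionary.tsv`, `event_dictionary.tsv`; or
#'   give the five paths individually.
#' @param reports_path,drugs_path,events_path,drug_dict_path,event_dict_path
#'   individual file paths overriding `dir`.
#' @return an [icsr_db()] object.
#' @export
read_icsr_db <- function(dir = NULL,
                         reports_path = file.path(dir, "reports.tsv"),
                         drugs_path = file.path(dir, "report_drugs.tsv"),
                         events_path = file.path(dir, "report_events.tsv"),
                         drug_dict_path = file.path(dir, "drug_dictionary.tsv"),
                         event_dict_path = file.path(dir, "event_dictionary.tsv")) {
  icsr_db(reports = .read_tsv(reports_path),
          report_drugs = .read_tsv(drugs_path),
          report_events = .read_tsv(events_path),
          drug_dict = .read_tsv(drug_dict_path),
          event_dict = .read_tsv(event_dict_path))
}

#' Write an ICSR database to five TSV files
#'
#' Inverse of [read_icsr_db()]; the round trip preserves every field for
#' TSV-representable values (missing written as empty string).
#'
#' @param db an `icsr_db` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_icsr_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) fwrite(x, file.path(dir, f), sep = "\t", na = "",
                              quote = FALSE, logical01 = TRUE)
  wr(db$reports, "reports.tsv")
  wr(db$report_drugs, "report_drugs.tsv")
  wr(db$report_events, "report_events.tsv")
  wr(db$drug_dict, "drug_dictionary.tsv")
  wr(db$event_dict, "event_dictionary.tsv")
  invisible(dir)
}

#' Select case reports by preferred term
#'
#' Returns the identifiers of all reports carrying at least one event whose
#' preferred term is in `pt_set`. Unknown codes in `pt_set` are an error so
#' that a typo cannot silently produce an empty case series.
#'
#' @param db an `icsr_db`.
#' @param pt_set character vector of preferred-term codes (the case
#'   definition; a single term for the narrow definition, several for the
#'   broad one).
#' @return character vector of report ids.
#' @export
select_cases <- function(db, pt_set) {
  stopifnot(length(pt_set) >= 1L)
  unknown <- setdiff(pt_set, db$event_dict$pt_code)
  if (length(unknown))
    stop("unknown preferred term code(s): ", paste(unknown, collapse = ", "))
  unique(db$report_events[pt_code %in% pt_set, report_id])
}

#' Exclude cases carrying disease-treatment drugs
#'
#' Removes every case report that contains at least one drug flagged as a
#' treatment for the condition under study (any role: suspect, interacting or
#' concomitant), since such reports are likely to reflect pre-existing
#' disease rather than drug-induced onset. The selected / excluded / included
#' counts of the selection flow are attached as the `"flow"` attribute.
#'
#' @param db an `icsr_db`.
#' @param case_ids report ids from [select_cases()].
#' @param exclusion_drugs drug ids to exclude on; defaults to dictionary
#'   entries with `rp_treatment = TRUE`. An empty vector disables exclusion.
#' @return character vector of retained report ids, with attribute `flow`.
#' @export
apply_exclusion <- function(db, case_ids,
                            exclusion_drugs = db$drug_dict[rp_treatment == TRUE, drug_id]) {
  stopifnot(all(case_ids %in% db$reports$report_id))
  if (length(exclusion_drugs) == 0L) {
    out <- case_ids
    excluded <- character(0)
  } else {
    hit <- unique(db$report_drugs[drug_id %in% exclusion_drugs, report_id])
    excluded <- intersect(case_ids, hit)
    out <- setdiff(case_ids, excluded)
  }
  attr(out, "flow") <- c(selected = length(case_ids),
                         excluded = length(excluded),
                         included = length(out))
  out
}

#' Flag drugs whose ATC codes match the treatment-exclusion list
#'
#' Utility for building dictionaries: sets `rp_treatment` from ATC prefixes.
#'
#' @param drug_dict drug dictionary table.
#' @param atc_prefixes prefixes; see [default_exclusion_atc()].
#' @return the dictionary with `rp_treatment` recomputed.
#' @export
flag_rp_treatment <- function(drug_dict, atc_prefixes = default_exclusion_atc()) {
  drug_dict <- as.data.table(drug_dict)
  codes <- strsplit(drug_dict$atc_codes, ";", fixed = TRUE)
  drug_dict[, rp_treatment := vapply(codes, function(cc) {
    any(vapply(atc_prefixes, function(p) any(startsWith(cc, p)), logical(1)))
  }, logical(1))]
  drug_dict[]
}

#' Summarise the case series supporting a drug signal
#'
#' Key features of the reports in which `drug_id` appears as suspect or
#' interacting: count, age distribution, sex, time to onset (median and IQR
#' over reports where both dates are available and the completed interval is
#' non-negative), seriousness, reporter type, and the most frequent
#' co-reported drugs.
#'
#' @param db an `icsr_db`.
#' @param case_ids case report ids (e.g. the included case series).
#' @param drug_id the drug to summarise.
#' @param pt_set preferred terms whose onset dates define the event date for
#'   time to onset; defaults to all events in the report (earliest onset).
#' @param top_k number of co-reported drugs to list.
#' @return a list of class `case_summary`.
#' @export
summarize_cases <- function(db, case_ids, drug_id, pt_set = NULL, top_k = 5L) {
  the_drug <- drug_id
  rd <- db$report_drugs[report_id %in% case_ids &
                          drug_id == the_drug &
                          role %in% c("suspect", "interacting")]
  ids <- unique(rd$report_id)
  if (length(ids) == 0L) {
    return(structure(list(drug_id = drug_id, n = 0L), class = "case_summary"))
  }
  rep_sub <- db$reports[report_id %in% ids]
  # time to onset: drug start vs onset of the case-defining events
  ev <- db$report_events[report_id %in% ids]
  if (!is.null(pt_set)) ev <- ev[pt_code %in% pt_set]
  ev_first <- ev[, .(onset_year = onset_year[1], onset_month = onset_month[1],
                     onset_day = onset_day[1]), by = report_id]
  m <- merge(rd[, .(report_id, start_year, start_month, start_day)],
             ev_first, by = "report_id")
  tto <- compute_tto(m$start_year, m$start_month, m$start_day,
                     m$onset_year, m$onset_month, m$onset_day)
  tto <- tto[!is.na(tto)]
  co <- db$report_drugs[report_id %in% ids & drug_id != the_drug,
                        .N, by = drug_id][order(-N)]
  structure(list(
    drug_id = drug_id,
    n = length(ids),
    age_mean = mean(rep_sub$age_years, na.rm = TRUE),
    age_sd = sd(rep_sub$age_years, na.rm = TRUE),
    pct_female = 100 * mean(rep_sub$sex == "F"),
    pct_serious = 100 * mean(rep_sub$serious, na.rm = TRUE),
    pct_hcp = 100 * mean(rep_sub$reporter_type == "health_professional"),
    tto_n = length(tto),
    tto_median = if (length(tto)) median(tto) else NA_real_,
    tto_iqr = if (length(tto)) unname(quantile(tto, c(0.25, 0.75))) else c(NA_real_, NA_real_),
    top_comedications = head(co, top_k)
  ), class = "case_summary")
}

#' @export
print.case_summary <- function(x, ...) {
  cat("Case summary for", x$drug_id, "- n =", x$n, "\n")
  if (x$n > 0L) {
    cat(sprintf("  age %.1f +/- %.1f y, %.0f%% female, %.0f%% serious, %.0f%% HCP-reported\n",
                x$age_mean, x$age_sd, x$pct_female, x$pct_serious, x$pct_hcp))
    if (x$tto_n > 0L)
      cat(sprintf("  time to onset: median %.0f d (IQR %.0f-%.0f, n=%d)\n",
                  x$tto_median, x$tto_iqr[1], x$tto_iqr[2], x$tto_n))
    else cat("  time to onset: unavailable\n")
  }
  invisible(x)
}
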