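#' Run the full signal-detection pipeline
#'
#' Wires the stages - simulate (optional), disproportionality analyses with
#' consistency flags, per-class symptom networks, and target aggregation -
#' into one reproducible run driven by a single configuration. All
#' randomness flows from one top-level seed, from which each stage derives
#' a fixed sub-seed, so a rerun with the same configuration produces
#' byte-identical outputs. The configuration used, a manifest with input
#' hashes and the case-selection flow counts are written next to the data
#' outputs.
#'
#' @param config a named list (or path to a YAML file) with entries:
#' \describe{
#'   \item{output_dir}{directory for all artifacts (required).}
#'   \item{seed}{top-level integer seed (default 1).}
#'   \item{simulate}{optional list passed to [sim_config()] (less `seed`);
#'     when present the database is generated and written, otherwise}
#'   \item{input_dir}{directory holding the five database TSVs.}
#'   \item{analyses}{analysis ids for [run_all()] (default: all five).}
#'   \item{network_classes}{class tags for symptom networks (default none);
#'     each gets term selection, Ising + PPMI networks, communities and the
#'     partition comparison.}
#'   \item{target_map}{optional path to a drug-target TSV; targets are
#'     aggregated over drugs significant in the primary analysis.}
#'   \item{min_obs}{minimum observed count for reported signals (default 1).}
#' }
#' @return (invisibly) a list with the database, consistency records,
#'   network results and target table, plus the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$output_dir))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # provenance: record the configuration verbatim
  yaml::write_yaml(config, file.path(out_dir, "run_config.yaml"))

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- seed + 1000L
    cfg <- do.call(sim_config, sim_args)
    gen <- generate_database(cfg)
    db <- gen$db
    data_dir <- file.path(out_dir, "database")
    write_icsr_db(db, data_dir)
    jsonlite::write_json(.jsonable(gen$truth),
                         file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (!is.null(config$input_dir)) {
    data_dir <- config$input_dir
    db <- read_icsr_db(data_dir)
  } else {
    stop("config must provide either 'simulate' or 'input_dir'")
  }

  analyses <- config$analyses %||% .analysis_ids
  min_obs <- config$min_obs %||% 1L
  records <- run_all(db, analyses = analyses)
  flow <- attr(records, "flow")
  message(sprintf("case flow: %d selected, %d excluded, %d included",
                  flow["selected"], flow["excluded"], flow["included"]))
  long <- attr(records, "long")
  fwrite(long[O >= min_obs], file.path(out_dir, "signals.tsv"), sep = "\t", na = "")
  cons_out <- copy(records)[, significant_in := vapply(
    significant_in, paste, character(1), collapse = ";")]
  if ("case_summary" %in% names(cons_out)) cons_out[, case_summary := NULL]
  fwrite(cons_out, file.path(out_dir, "consistency.tsv"), sep = "\t", na = "")

  networks <- list()
  classes <- config$network_classes %||% character(0)
  if (length(classes)) {
    pt_narrow <- default_pt_narrow(db)
    cases <- apply_exclusion(db, select_cases(db, pt_narrow))
    edge_rows <- list()
    part_rows <- list()
    for (cl in classes) {
      set.seed(seed + 2000L + match(cl, classes))
      terms <- select_terms(db, cl, cases, exclude_pts = default_pt_broad(db))
      if (nrow(terms) < 3L) {
        message("class ", cl, ": fewer than 3 disproportionate terms; network skipped")
        next
      }
      m <- build_case_term_matrix(db, cl, cases, terms$pt_code)
      res <- list(terms = terms)
      res$ppmi <- compute_ppmi(m)
      res$ising <- tryCatch(fit_ising(m), error = function(e) {
        message("class ", cl, ": ", conditionMessage(e)); NULL
      })
      res$partition_ppmi <- detect_communities(res$ppmi)
      edge_rows[[paste0(cl, "_ppmi")]] <- cbind(class_tag = cl,
                                                network_edges(res$ppmi))
      part_rows[[paste0(cl, "_ppmi")]] <- data.table(
        class_tag = cl, method = "ppmi",
        pt_code = names(res$partition_ppmi),
        community = as.integer(res$partition_ppmi))
      if (!is.null(res$ising)) {
        res$partition_ising <- detect_communities(res$ising)
        res$agreement <- compare_partitions(
          res$partition_ising, res$partition_ppmi[names(res$partition_ising)],
          res$ising, res$ppmi)
        edge_rows[[paste0(cl, "_ising")]] <- cbind(class_tag = cl,
                                                   network_edges(res$ising))
        part_rows[[paste0(cl, "_ising")]] <- data.table(
          class_tag = cl, method = "ising",
          pt_code = names(res$partition_ising),
          community = as.integer(res$partition_ising))
      }
      networks[[cl]] <- res
    }
    if (length(edge_rows))
      fwrite(rbindlist(edge_rows), file.path(out_dir, "network_edges.tsv"),
             sep = "\t", na = "")
    if (length(part_rows))
      fwrite(rbindlist(part_rows), file.path(out_dir, "network_partitions.tsv"),
             sep = "\t", na = "")
  }

  targets <- NULL
  if (!is.null(config$target_map)) {
    tm <- read_target_map(config$target_map)
    sig <- records[significant_primary == TRUE]
    targets <- aggregate_targets(sig, tm)
    fwrite(targets, file.path(out_dir, "targets.tsv"), sep = "\t", na = "")
  }

  manifest <- list(
    seed = seed,
    created = "run",  # no timestamp: outputs must be byte-identical across reruns
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    flow = as.list(flow),
    inputs = as.list(tools::md5sum(list.files(data_dir, full.names = TRUE))),
    outputs = as.list(tools::md5sum(list.files(
      out_dir, pattern = "\\.tsv$", full.names = TRUE))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(db = db, records = records, networks = networks,
                 targets = targets, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# strip non-serialisable pieces from the ground-truth ledger
.jsonable <- function(truth) {
  truth$planted <- if (is.null(truth$planted)) list() else as.data.frame(truth$planted)
  truth$event_base_probs <- as.list(truth$event_base_probs)
  truth$drug_weights <- as.list(truth$drug_weights)
  truth
}
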