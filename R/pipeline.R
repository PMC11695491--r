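# End-to-end orchestration: simulate a study to disk, prioritize a zone,
# and produce the final ranked feature report. Each run writes its outputs
# plus a manifest (configuration, seed, package version) into one
# directory, so a run is reproducible from its archived config.

write_run_manifest <- function(dir, step, config, files) {
  jsonlite::write_json(list(
    step = step,
    package = "edatox",
    version = as.character(utils::packageVersion("edatox")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    files = files
  ), file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE, force = TRUE)
}

#' Simulate a study and write it to a directory
#'
#' Writes the feature table and sample manifest, MS2 spectra (MGF), feature
#' and candidate-structure fingerprints, the suspect list, per-endpoint
#' training data, ground truth, and a run manifest.
#'
#' @param cfg A [study_config()].
#' @param out_dir Output directory; must not already contain files.
#' @return The `synthetic_study`, invisibly.
#' @export
run_simulate <- function(cfg, out_dir) {
  if (dir.exists(out_dir) && length(list.files(out_dir))) {
    stop("output directory exists and is not empty: ", out_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- simulate_study(cfg)
  write_feature_table(study$feature_table, file.path(out_dir, "features.csv"))
  write_mgf(study$feature_table$ms2, file.path(out_dir, "ms2.mgf"))
  write_fingerprints(study$feature_fingerprints,
                     file.path(out_dir, "feature_fingerprints.csv"))
  write_fingerprints(study$structure_fingerprints,
                     file.path(out_dir, "structure_fingerprints.csv"))
  utils::write.csv(data.frame(id = names(study$structure_active),
                              active = unname(study$structure_active)),
                   file.path(out_dir, "structure_active.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(study$suspects),
                   file.path(out_dir, "suspects.csv"),
                   row.names = FALSE, quote = FALSE)
  for (nm in names(study$endpoints)) {
    d <- study$endpoints[[nm]]
    write_fingerprints(d$fingerprints,
                       file.path(out_dir, paste0("endpoint_", nm, "_fp.csv")))
    utils::write.csv(data.frame(chemical_id = names(d$active),
                                endpoint = nm, active = unname(d$active)),
                     file.path(out_dir, paste0("endpoint_", nm, "_labels.csv")),
                     row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(study$truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = FALSE, digits = NA, na = "null")
  cfg_json <- cfg
  cfg_json$spikes <- lapply(cfg$spikes, unclass)
  write_run_manifest(out_dir, "simulate", cfg_json, list.files(out_dir))
  invisible(study)
}

#' Load a simulated study directory
#'
#' @param study_dir Directory written by [run_simulate()].
#' @return A list with `feature_table`, fingerprints, `structure_active`,
#'   `suspects` and endpoint datasets.
#' @export
load_study <- function(study_dir) {
  ft <- read_feature_table(file.path(study_dir, "features.csv"),
                           mgf_path = file.path(study_dir, "ms2.mgf"))
  ep_fp <- list.files(study_dir, pattern = "^endpoint_.*_fp\\.csv$")
  endpoints <- list()
  for (f in ep_fp) {
    nm <- sub("^endpoint_(.*)_fp\\.csv$", "\\1", f)
    fp <- read_fingerprints(file.path(study_dir, f))
    lab <- utils::read.csv(file.path(study_dir,
                                     paste0("endpoint_", nm, "_labels.csv")),
                           stringsAsFactors = FALSE)
    endpoints[[nm]] <- endpoint_dataset(
      nm, fp, stats::setNames(as.logical(lab$active), lab$chemical_id))
  }
  sa <- utils::read.csv(file.path(study_dir, "structure_active.csv"),
                        stringsAsFactors = FALSE)
  list(
    feature_table = ft,
    feature_fingerprints = read_fingerprints(
      file.path(study_dir, "feature_fingerprints.csv")),
    structure_fingerprints = read_fingerprints(
      file.path(study_dir, "structure_fingerprints.csv")),
    structure_active = stats::setNames(as.logical(sa$active), sa$id),
    suspects = read_suspect_list(file.path(study_dir, "suspects.csv")),
    endpoints = endpoints
  )
}

#' Prioritize one zone of a study directory
#'
#' Runs the four-rule cascade and suspect matching, writing the per-feature
#' audit (`audit.csv`), the surviving ids and suspect annotations
#' (`surviving.json`), and a manifest into `out_dir`.
#'
#' @param study_dir Directory written by [run_simulate()] (or following its
#'   layout).
#' @param zone_id Zone of interest.
#' @param method Optional elution method.
#' @param cfg A [prioritization_config()].
#' @param out_dir Output directory (default
#'   `<study_dir>/prioritize_<zone>[_<method>]`).
#' @return The `zone_prioritization`, with suspect annotations of the
#'   surviving features attached as `$annotations`, invisibly.
#' @export
run_prioritize <- function(study_dir, zone_id, method = NULL,
                           cfg = prioritization_config(),
                           out_dir = NULL) {
  study <- load_study(study_dir)
  if (is.null(out_dir)) {
    out_dir <- file.path(study_dir, paste(
      c("prioritize", zone_id, method), collapse = "_"))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  zp <- prioritize_zone(study$feature_table, zone_id, method, cfg)
  surv_ft <- study$feature_table
  surv_ft$features <- surv_ft$features[
    surv_ft$features$feature_id %in% zp$surviving, ]
  ann <- suspect_match(surv_ft, study$suspects, cfg$suspect_ppm_tol)
  zp$annotations <- ann
  utils::write.csv(as.data.frame(zp$audit), file.path(out_dir, "audit.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    zone_id = zone_id, method = method,
    n_tested = nrow(zp$audit), n_surviving = length(zp$surviving),
    surviving = zp$surviving,
    suspect_hits = ann
  ), file.path(out_dir, "surviving.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE, null = "null")
  write_run_manifest(out_dir, "prioritize",
                     c(unclass(cfg), list(zone_id = zone_id, method = method)),
                     list.files(out_dir))
  invisible(zp)
}

#' Rank prioritized features of a study
#'
#' The full downstream stage: trains one classifier per endpoint dataset,
#' predicts each feature's per-endpoint activity probability from its
#' fingerprint and applies the any-endpoint rule; groups in-source
#' artifacts; ranks the candidate-structure library against each feature's
#' fingerprint, calls candidate genotoxicity with the trained models, and
#' computes overall/top-decile statistics; writes the final priority report
#' (`report.csv`, `report.json`).
#'
#' @param study_dir Directory written by [run_simulate()].
#' @param feature_ids Features to rank (e.g. the surviving set of
#'   [run_prioritize()]); default all features with fingerprints.
#' @param seed Seed for model training splits.
#' @param out_dir Output directory (default `<study_dir>/rank`).
#' @param rt_tol,mz_tol,min_shared In-source grouping tolerances, see
#'   [group_insource()].
#' @return The report tibble, invisibly.
#' @export
run_rank <- function(study_dir, feature_ids = NULL, seed = 1,
                     out_dir = file.path(study_dir, "rank"),
                     rt_tol = 0.05, mz_tol = 0.005, min_shared = 2) {
  study <- load_study(study_dir)
  ft <- study$feature_table
  if (is.null(feature_ids)) {
    feature_ids <- intersect(ft$features$feature_id,
                             rownames(study$feature_fingerprints))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!length(feature_ids)) {
    report <- tibble::tibble()
    utils::write.csv(report, file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(features = list()),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(report))
  }
  models <- lapply(study$endpoints, train_endpoint_model, seed = seed)
  fp <- study$feature_fingerprints[feature_ids, , drop = FALSE]
  probs <- vapply(models, function(m) predict_probability(m, fp),
                  numeric(nrow(fp)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1,
                                           dimnames = list(feature_ids,
                                                           names(models)))
  active_any <- apply(probs, 1, function(p) classify_any_endpoint(p))
  endpoints_called <- apply(probs, 1, function(p) {
    paste(names(models)[p > 0.5], collapse = ";")
  })
  groups <- group_insource(ft, feature_ids, rt_tol = rt_tol,
                           mz_tol = mz_tol, min_shared = min_shared)
  # candidate genotoxicity calls from the same trained models
  sp <- vapply(models, function(m)
    predict_probability(m, study$structure_fingerprints),
    numeric(nrow(study$structure_fingerprints)))
  struct_pred <- apply(sp, 1, function(p) any(p > 0.5))
  stats_list <- lapply(feature_ids, function(fid) {
    cs <- rank_candidates(study$feature_fingerprints[fid, ],
                          study$structure_fingerprints, feature_id = fid)
    candidate_stats(cs, struct_pred)
  })
  names(stats_list) <- feature_ids
  parent_area <- vapply(feature_ids, function(fid) {
    replicate_mean_area(ft, fid, parent_sample_ids(ft))
  }, numeric(1))
  report <- feature_priority_report(
    tibble::tibble(feature_id = feature_ids, parent_area = unname(parent_area)),
    tibble::tibble(feature_id = feature_ids, active_any = unname(active_any),
                   endpoints = unname(endpoints_called)),
    stats_list, groups)
  utils::write.csv(as.data.frame(report), file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  write_insource_report(groups, file.path(out_dir, "groups.json"))
  write_run_manifest(out_dir, "rank",
                     list(seed = seed, rt_tol = rt_tol, mz_tol = mz_tol,
                          min_shared = min_shared,
                          n_features = length(feature_ids)),
                     list.files(out_dir))
  invisible(report)
}
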