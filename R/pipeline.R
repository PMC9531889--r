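# End-to-end orchestration: derive a fingerprint on one cohort pair, score
# another cohort against it, with stage-level logging and a JSON run manifest
# recording input/output digests so any two runs are diffable.

stage_log <- function(fmt, ...) message(sprintf(paste0("[%s] ", fmt),
                                               format(Sys.time(), "%H:%M:%S"),
                                               ...))

file_digest <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(unname(h), basename(paths))
}

write_manifest <- function(out_dir, stage, inputs, outputs, extra = list()) {
  manifest <- c(list(
    stage = stage,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    registry_version = "table1-89",
    inputs = as.list(file_digest(inputs[file.exists(inputs)])),
    outputs = as.list(file_digest(outputs[file.exists(outputs)]))
  ), extra)
  path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Derive a fingerprint from control and case tables
#'
#' Fits the control age model, age-corrects and normalizes both cohorts,
#' screens every key with the case-control t-test, and writes the region
#' statistics, the bilateral fingerprint, the age model, the control
#' normative reference and a manifest to `out_dir`.
#'
#' @param controls_path,cases_path long-TSV paths (raw provenance).
#' @param out_dir output directory (created if needed).
#' @param alpha significance level for the bilateral filter.
#' @param registry the registry.
#' @return invisible list with `fingerprint`, `stats`, `age_model`,
#'   `reference` and the output file paths.
#' @export
run_derive <- function(controls_path, cases_path, out_dir, alpha = 0.05,
                       registry = build_default_registry()) {
  for (p in c(controls_path, cases_path)) {
    if (!file.exists(p)) stop_validation(paste("derive: no such input:", p))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  controls <- read_long_tsv(controls_path, registry)
  cases <- read_long_tsv(cases_path, registry)
  stage_log("derive: read %d controls, %d cases",
            nrow(controls$subjects), nrow(cases$subjects))
  model <- fit_age_model(controls)
  norm <- function(tb) normalize_volumes(age_correct(tb, model), registry)
  controls_n <- norm(controls); cases_n <- norm(cases)
  st <- compare_groups(cases_n, controls_n)
  fp <- build_fingerprint(st, alpha = alpha, registry = registry)
  if (!nrow(fp)) {
    stage_log("derive: fingerprint is EMPTY at alpha = %g", alpha)
    ref <- NULL
  } else {
    ref <- build_control_reference(controls_n, fp)
  }
  stage_log("derive: %d/%d keys tested, %d fingerprint entries",
            nrow(st), attr(fp, "n_tests"), nrow(fp))
  paths <- c(
    stats = file.path(out_dir, "region_stats.tsv"),
    fingerprint = file.path(out_dir, "fingerprint.tsv"),
    age_model = file.path(out_dir, "age_model.tsv"),
    reference = file.path(out_dir, "control_reference.tsv")
  )
  utils::write.table(as.data.frame(st), paths[["stats"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_fingerprint_tsv(fp, paths[["fingerprint"]])
  write_age_model_tsv(model, paths[["age_model"]])
  if (!is.null(ref)) write_control_reference_tsv(ref, paths[["reference"]])
  write_manifest(out_dir, "derive",
                 inputs = c(controls_path, cases_path), outputs = paths,
                 extra = list(alpha = alpha,
                              n_controls = nrow(controls$subjects),
                              n_cases = nrow(cases$subjects),
                              n_entries = nrow(fp)))
  invisible(list(fingerprint = fp, stats = st, age_model = model,
                 reference = ref, paths = paths))
}

#' Score a cohort against a derived fingerprint
#'
#' Reads the fingerprint, age model and control reference written by
#' [run_derive()], preprocesses the target cohort and the reference controls
#' with that age model, scores both, classifies the cohort at the control
#' mean + 2 SD outlier-count cutoff, and writes per-subject profiles, the
#' classification and a human-readable summary.
#'
#' @param derive_dir directory written by [run_derive()].
#' @param controls_path long TSV of the reference controls (raw).
#' @param cohort_path long TSV of the cohort to score (raw).
#' @param out_dir output directory.
#' @param z_threshold SD threshold for a region outlier (default 2).
#' @param registry the registry.
#' @return invisible list with `profiles`, `control_profiles`,
#'   `classification` and output paths.
#' @export
run_score <- function(derive_dir, controls_path, cohort_path, out_dir,
                      z_threshold = 2, registry = build_default_registry()) {
  fp_path <- file.path(derive_dir, "fingerprint.tsv")
  am_path <- file.path(derive_dir, "age_model.tsv")
  for (p in c(fp_path, am_path, controls_path, cohort_path)) {
    if (!file.exists(p)) stop_validation(paste("score: no such input:", p))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- read_fingerprint_tsv(fp_path)
  if (!nrow(fp)) stop_degenerate("score: fingerprint is empty")
  model <- read_age_model_tsv(am_path)
  controls <- read_long_tsv(controls_path, registry)
  cohort <- read_long_tsv(cohort_path, registry)
  if (!nrow(cohort$subjects)) stop_validation("score: empty cohort")
  norm <- function(tb) normalize_volumes(age_correct(tb, model), registry)
  controls_n <- norm(controls); cohort_n <- norm(cohort)
  ref <- build_control_reference(controls_n, fp)
  prof_cohort <- score_subjects(cohort_n, fp, ref, z_threshold = z_threshold)
  prof_controls <- score_subjects(controls_n, fp, ref,
                                  z_threshold = z_threshold)
  cls <- classify_cohort(prof_cohort, prof_controls)
  stage_log("score: cutoff %.2f; %d/%d cohort subjects at risk (%.1f%%)",
            cls$cutoff, cls$summary$n_at_risk[1], cls$summary$n[1],
            cls$summary$percent_at_risk[1])
  paths <- c(
    profiles = file.path(out_dir, "outlier_profiles.tsv"),
    counts = file.path(out_dir, "outlier_counts.tsv"),
    classification = file.path(out_dir, "classification.tsv"),
    summary = file.path(out_dir, "summary.txt")
  )
  utils::write.table(prof_cohort$details, paths[["profiles"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(rbind(cbind(prof_cohort$counts, cohort = "cases"),
                           cbind(prof_controls$counts, cohort = "controls")),
                     paths[["counts"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cls$subjects, paths[["classification"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(c(
    sprintf("fingerprint entries : %d", nrow(fp)),
    sprintf("z threshold         : %g", z_threshold),
    sprintf("control mean count  : %.2f", cls$control_mean),
    sprintf("control SD of counts: %.2f", cls$control_sd),
    sprintf("cutoff (mean + 2SD) : %.2f", cls$cutoff),
    sprintf("cohort n            : %d", cls$summary$n[1]),
    sprintf("cohort n at risk    : %d", cls$summary$n_at_risk[1]),
    sprintf("cohort percent      : %.1f%%", cls$summary$percent_at_risk[1])
  ), paths[["summary"]])
  write_manifest(out_dir, "score",
                 inputs = c(fp_path, am_path, controls_path, cohort_path),
                 outputs = paths,
                 extra = list(z_threshold = z_threshold,
                              cutoff = cls$cutoff))
  invisible(list(profiles = prof_cohort, control_profiles = prof_controls,
                 classification = cls, paths = paths))
}

#' Simulate cohorts and write them to disk
#'
#' @param out_dir output directory.
#' @param seed RNG seed.
#' @param config a `cohort_sim_config`.
#' @return invisible list of output paths (per-cohort long TSVs, neuropsych
#'   TSVs, truth-ledger TSVs).
#' @export
run_simulate <- function(out_dir, seed = 1L,
                         config = default_cohort_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohorts(config, seed = seed)
  paths <- character(0)
  for (g in unique(sim$morphometry$subjects$group)) {
    p <- file.path(out_dir, paste0(g, ".tsv"))
    write_long_tsv(subset_morph(sim$morphometry, group = g), p)
    paths[g] <- p
  }
  if (!is.null(sim$neuropsych)) {
    p <- file.path(out_dir, "neuropsych.tsv")
    utils::write.table(sim$neuropsych, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths["neuropsych"] <- p
  }
  tp <- file.path(out_dir, "truth_subjects.tsv")
  utils::write.table(sim$truth$subjects, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["truth_subjects"] <- tp
  te <- file.path(out_dir, "truth_effects.tsv")
  utils::write.table(sim$truth$effects, te, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["truth_effects"] <- te
  write_manifest(out_dir, "simulate", inputs = character(0), outputs = paths,
                 extra = list(seed = seed))
  stage_log("simulate: wrote %d cohort file(s) to %s",
            length(unique(sim$morphometry$subjects$group)), out_dir)
  invisible(paths)
}
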