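# Individual scoring against a fingerprint: region-wise z-scores relative to
# the control normative reference, direction-constrained outlier flags
# ("either hemisphere"), per-subject outlier-region counts, and cohort
# classification at the control mean + 2 SD count cutoff.

#' Build the control normative reference for a fingerprint
#'
#' For every fingerprint entry and hemisphere, the mean and sample SD of the
#' normalized, age-corrected control values.
#'
#' @param controls a normalized `morph_table` of control subjects.
#' @param fp a `fingerprint`.
#' @return data.frame of class `control_reference` with columns `region`,
#'   `hemisphere`, `metric`, `mean`, `sd`, `n`.
#' @export
build_control_reference <- function(controls, fp) {
  if (!nrow(fp)) stop_validation("empty fingerprint")
  if (!"normalized" %in% controls$provenance) {
    stop_validation("controls must be normalized")
  }
  m <- data.table::as.data.table(controls$measurements)
  keys <- fingerprint_keys(fp)
  ref <- merge(data.table::as.data.table(keys), m,
               by = c("region", "hemisphere", "metric"))
  ref <- ref[, .(mean = mean(value), sd = stats::sd(value), n = .N),
             by = .(region, hemisphere, metric)]
  if (nrow(ref) < nrow(keys)) {
    miss <- merge(data.table::as.data.table(keys), ref,
                  by = c("region", "hemisphere", "metric"), all.x = TRUE)
    miss <- miss[is.na(n)]
    stop_validation(paste(
      "no control measurements for fingerprint key(s):",
      paste(utils::head(paste(miss$region, miss$hemisphere, miss$metric,
                              sep = "/"), 5), collapse = ", ")))
  }
  degen <- ref$sd <= 0 | !is.finite(ref$sd) | ref$n < 2L
  if (any(degen)) {
    stop_degenerate(paste(
      "degenerate control reference (zero SD or n < 2) for:",
      paste(utils::head(paste(ref$region, ref$hemisphere,
                              ref$metric)[degen], 5), collapse = ", ")))
  }
  out <- data.table::setDF(ref)
  class(out) <- c("control_reference", "data.frame")
  out
}

# hemispheres implied by a fingerprint's entries
fingerprint_keys <- function(fp) {
  rows <- lapply(seq_len(nrow(fp)), function(i) {
    hemis <- if (is.na(fp$right_p[i])) "none" else c("left", "right")
    data.frame(region = fp$region[i], hemisphere = hemis,
               metric = fp$metric[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write / read a control reference TSV
#' @param ref a `control_reference`.
#' @param path file path.
#' @return `read_control_reference_tsv` returns a `control_reference`.
#' @export
write_control_reference_tsv <- function(ref, path) {
  df <- as.data.frame(ref)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_control_reference_tsv
#' @export
read_control_reference_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  class(df) <- c("control_reference", "data.frame")
  df
}

#' Score subjects against a fingerprint
#'
#' Each subject gets, per fingerprint entry, a left and right z-score
#' `(value - control_mean) / control_sd`; the entry is flagged as an outlier
#' iff the deviation exceeds `z_threshold` SDs in the entry's disease
#' direction (below the control mean for atrophy entries, above it for
#' dilation entries) in either hemisphere. The outlier count is the number of
#' flagged entries.
#'
#' @param tab a normalized `morph_table` (scored subjects), preprocessed with
#'   the same age model and registry as the reference controls.
#' @param fp a `fingerprint`.
#' @param ref a `control_reference`.
#' @param z_threshold SD threshold (default 2).
#' @param strict error (instead of message + unflagged) when a subject lacks
#'   a fingerprint key. Default lenient.
#' @return list of class `outlier_profiles` with elements `details` (one row
#'   per subject x entry x hemisphere: z and flag) and `counts` (one row per
#'   subject: `outlier_count` over region x metric entries and
#'   `outlier_count_regions` over distinct regions).
#' @export
score_subjects <- function(tab, fp, ref, z_threshold = 2, strict = FALSE) {
  if (!"normalized" %in% tab$provenance) {
    stop_validation("score_subjects requires a normalized table")
  }
  if (!nrow(fp)) stop_validation("empty fingerprint")
  m <- data.table::as.data.table(tab$measurements)
  keys <- data.table::as.data.table(fingerprint_keys(fp))
  fpd <- data.table::as.data.table(
    as.data.frame(fp)[, c("region", "metric", "direction")])
  keys <- merge(keys, fpd, by = c("region", "metric"), sort = FALSE)
  refd <- data.table::as.data.table(as.data.frame(ref))
  data.table::setnames(refd, c("mean", "sd"), c("ref_mean", "ref_sd"))

  grid <- data.table::CJ(subject_id = tab$subjects$subject_id, idx = seq_len(nrow(keys)))
  grid <- cbind(grid[, .(subject_id)], keys[grid$idx])
  d <- merge(grid, refd, by = c("region", "hemisphere", "metric"),
             all.x = TRUE, sort = FALSE)
  d <- merge(d, m, by = c("subject_id", "region", "hemisphere", "metric"),
             all.x = TRUE, sort = FALSE)
  miss <- is.na(d$value)
  if (any(miss)) {
    if (strict) {
      stop_validation(sprintf(
        "%d subject x key measurement(s) missing (strict mode)", sum(miss)))
    }
    message(sprintf(
      "%d subject x key measurement(s) missing; treated as unflagged",
      sum(miss)))
  }
  d[, z := (value - ref_mean) / ref_sd]
  d[, flagged := !is.na(z) &
      ((direction == "atrophy" & z < -z_threshold) |
       (direction == "dilation" & z > z_threshold))]
  entry_flags <- d[, .(flagged = any(flagged)),
                   by = .(subject_id, region, metric)]
  counts <- entry_flags[, .(
    outlier_count = sum(flagged),
    outlier_count_regions = length(unique(region[flagged]))
  ), by = subject_id]
  counts <- merge(data.table::data.table(subject_id = tab$subjects$subject_id),
                  counts, by = "subject_id", all.x = TRUE, sort = FALSE)
  details <- data.table::setDF(
    d[order(subject_id, region, metric, hemisphere),
      .(subject_id, region, metric, hemisphere, z, flagged)])
  out <- list(details = details,
              counts = data.table::setDF(counts),
              z_threshold = z_threshold,
              n_entries = nrow(fp))
  class(out) <- "outlier_profiles"
  out
}

#' @export
print.outlier_profiles <- function(x, ...) {
  cat(sprintf(
    "outlier_profiles: %d subjects vs %d fingerprint entries (z > %g); mean count %.2f\n",
    nrow(x$counts), x$n_entries, x$z_threshold, mean(x$counts$outlier_count)))
  invisible(x)
}

#' Score control subjects against a leave-one-out reference
#'
#' Naive self-scoring of the reference controls (each control z-scored
#' against a mean/SD that includes their own value) biases control counts
#' low. This variant rebuilds the normative reference for each control with
#' that subject held out, using closed-form leave-one-out mean/SD updates,
#' and otherwise applies the same flagging rule as [score_subjects()].
#'
#' @param controls the normalized control `morph_table` the reference is
#'   built from.
#' @param fp a `fingerprint`.
#' @param z_threshold SD threshold (default 2).
#' @return an `outlier_profiles` (see [score_subjects()]).
#' @export
score_controls_loo <- function(controls, fp, z_threshold = 2) {
  if (!"normalized" %in% controls$provenance) {
    stop_validation("score_controls_loo requires a normalized table")
  }
  m <- data.table::as.data.table(controls$measurements)
  keys <- data.table::as.data.table(fingerprint_keys(fp))
  fpd <- data.table::as.data.table(
    as.data.frame(fp)[, c("region", "metric", "direction")])
  keys <- merge(keys, fpd, by = c("region", "metric"), sort = FALSE)
  d <- merge(keys, m, by = c("region", "hemisphere", "metric"),
             allow.cartesian = TRUE)
  # leave-one-out mean and sample SD per key
  d[, `:=`(n = .N, m_all = mean(value), ss = sum((value - mean(value))^2)),
    by = .(region, hemisphere, metric)]
  if (any(d$n < 3L)) {
    stop_degenerate("leave-one-out reference needs >= 3 controls per key")
  }
  d[, loo_mean := (n * m_all - value) / (n - 1)]
  d[, loo_sd := sqrt(pmax(ss - (value - m_all)^2 * n / (n - 1), 0) / (n - 2))]
  if (any(d$loo_sd <= 0)) {
    stop_degenerate("degenerate leave-one-out reference (zero SD)")
  }
  d[, z := (value - loo_mean) / loo_sd]
  d[, flagged := (direction == "atrophy" & z < -z_threshold) |
      (direction == "dilation" & z > z_threshold)]
  entry_flags <- d[, .(flagged = any(flagged)),
                   by = .(subject_id, region, metric)]
  counts <- entry_flags[, .(
    outlier_count = sum(flagged),
    outlier_count_regions = length(unique(region[flagged]))
  ), by = subject_id]
  counts <- merge(
    data.table::data.table(subject_id = controls$subjects$subject_id),
    counts, by = "subject_id", all.x = TRUE, sort = FALSE)
  counts[is.na(outlier_count), `:=`(outlier_count = 0L,
                                    outlier_count_regions = 0L)]
  details <- data.table::setDF(
    d[order(subject_id, region, metric, hemisphere),
      .(subject_id, region, metric, hemisphere, z, flagged)])
  out <- list(details = details, counts = data.table::setDF(counts),
              z_threshold = z_threshold, n_entries = nrow(fp))
  class(out) <- "outlier_profiles"
  out
}

#' Outlier-count cutoff from a control count distribution
#'
#' `cutoff = mean(counts) + 2 * sd(counts)` (sample SD). With the control
#' counts reported for the reference cohort (mean 1.78, SD 1.83) this gives
#' the 5.44-region threshold.
#'
#' @param control_counts numeric vector of control outlier counts.
#' @return the cutoff (numeric scalar).
#' @export
risk_cutoff <- function(control_counts) {
  if (length(control_counts) < 3L) {
    stop_degenerate("need at least 3 control profiles for a cutoff")
  }
  mean(control_counts) + 2 * stats::sd(control_counts)
}

#' Classify a cohort by outlier-region count
#'
#' The cutoff is the control cohort's `mean + 2 SD` outlier count; a subject
#' is at risk iff their count is strictly greater than the cutoff.
#'
#' @param profiles_cases an `outlier_profiles` for the scored cohort.
#' @param profiles_controls an `outlier_profiles` for the reference controls
#'   (scored against the same fingerprint and reference).
#' @param basis count over region x metric `"entries"` (default) or distinct
#'   `"regions"`.
#' @return list of class `risk_classification`: `cutoff`, `control_mean`,
#'   `control_sd`, per-subject data.frame `subjects` (`outlier_count`,
#'   `at_risk`), and cohort `summary` (n, n_at_risk, percent_at_risk for both
#'   cohorts).
#' @export
classify_cohort <- function(profiles_cases, profiles_controls,
                            basis = c("entries", "regions")) {
  basis <- match.arg(basis)
  col <- if (basis == "entries") "outlier_count" else "outlier_count_regions"
  ctrl <- profiles_controls$counts[[col]]
  cutoff <- risk_cutoff(ctrl)
  mk <- function(prof) {
    df <- data.frame(subject_id = prof$counts$subject_id,
                     outlier_count = prof$counts[[col]],
                     stringsAsFactors = FALSE)
    df$at_risk <- df$outlier_count > cutoff
    df
  }
  cases <- mk(profiles_cases); controls <- mk(profiles_controls)
  summarize <- function(df, label) {
    data.frame(cohort = label, n = nrow(df), n_at_risk = sum(df$at_risk),
               percent_at_risk = 100 * sum(df$at_risk) / nrow(df),
               stringsAsFactors = FALSE)
  }
  out <- list(
    cutoff = cutoff, control_mean = mean(ctrl),
    control_sd = stats::sd(ctrl), basis = basis,
    subjects = rbind(cbind(cases, cohort = "cases"),
                     cbind(controls, cohort = "controls")),
    summary = rbind(summarize(cases, "cases"),
                    summarize(controls, "controls"))
  )
  class(out) <- "risk_classification"
  out
}

#' @export
print.risk_classification <- function(x, ...) {
  cat(sprintf(
    "risk_classification: cutoff %.2f (control mean %.2f + 2 x SD %.2f)\n",
    x$cutoff, x$control_mean, x$control_sd))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
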