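# Preprocessing: residualize every measurement to the control mean age using
# control-derived OLS slopes, then normalize volumes by intracranial volume or
# by the parent structure (whole hippocampus / whole amygdala). Order is
# fixed: age correction first, then normalization.

#' Fit per-region age slopes on a control cohort
#'
#' Ordinary least-squares of measurement value on age, fitted independently
#' for every (region, hemisphere, metric) key over the control subjects that
#' carry that key. Keys with fewer than 3 control observations get slope 0
#' (with a message). The model's reference age is the mean control age;
#' [age_correct()] residualizes every cohort to that age.
#'
#' @param controls a raw-provenance `morph_table` whose subjects are all
#'   controls.
#' @param by_cohort_tag fit a separate model per `cohort_tag` stratum
#'   (scanner/protocol). Default pools all controls.
#' @return An object of class `age_model`: data.frame with columns `region`,
#'   `hemisphere`, `metric`, `slope`, `intercept`, `n`, plus attribute
#'   `reference_age`.
#' @export
fit_age_model <- function(controls, by_cohort_tag = FALSE) {
  if (!nrow(controls$subjects)) stop_validation("empty control table")
  if (!all(controls$subjects$group == "control")) {
    stop_validation("fit_age_model requires an all-control table")
  }
  if (!"raw" %in% controls$provenance || "age_corrected" %in% controls$provenance) {
    stop_validation("fit_age_model expects a raw (uncorrected) table")
  }
  m <- data.table::as.data.table(controls$measurements)
  s <- controls$subjects
  m[, age := s$age[match(subject_id, s$subject_id)]]
  if (by_cohort_tag) {
    m[, tag := s$cohort_tag[match(subject_id, s$subject_id)]]
  } else {
    m[, tag := "pooled"]
  }
  fit <- m[, {
    if (.N >= 3L && stats::var(age) > 0) {
      b <- stats::cov(age, value) / stats::var(age)
    } else {
      b <- 0
    }
    list(slope = b, intercept = mean(value) - b * mean(age), n = .N)
  }, by = .(tag, region, hemisphere, metric)]
  n_low <- sum(fit$n < 3L)
  if (n_low) message(sprintf(
    "%d key(s) had < 3 control observations; slope set to 0", n_low))
  out <- data.table::setDF(fit)
  attr(out, "reference_age") <- mean(s$age)
  attr(out, "by_cohort_tag") <- by_cohort_tag
  class(out) <- c("age_model", "data.frame")
  out
}

#' @export
print.age_model <- function(x, ...) {
  cat(sprintf("age_model: %d keys, reference age %.1f y\n",
              nrow(x), attr(x, "reference_age")))
  invisible(x)
}

#' Write / read an age model as TSV
#' @param model an `age_model`.
#' @param path file path.
#' @return `read_age_model_tsv` returns an `age_model`.
#' @export
write_age_model_tsv <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# reference_age: %.17g", attr(model, "reference_age")),
             con)
  utils::write.table(as.data.frame(model), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_age_model_tsv
#' @export
read_age_model_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  ref <- as.numeric(sub("# reference_age:", "", first))
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  attr(df, "reference_age") <- ref
  class(df) <- c("age_model", "data.frame")
  df
}

#' Age-correct a morphometry table
#'
#' Applies `value' = value - slope * (age - reference_age)` per key, using the
#' control-derived model, so every subject is residualized to the control mean
#' age on the original measurement scale. The same model is applied to
#' control, case and exposed tables alike.
#'
#' @param tab a raw-provenance `morph_table`.
#' @param model an `age_model` from [fit_age_model()].
#' @return a `morph_table` with provenance `raw + age_corrected`.
#' @export
age_correct <- function(tab, model) {
  if ("age_corrected" %in% tab$provenance) {
    stop_validation("table is already age-corrected")
  }
  m <- data.table::as.data.table(tab$measurements)
  s <- tab$subjects
  mod <- data.table::as.data.table(as.data.frame(model))
  by_tag <- isTRUE(attr(model, "by_cohort_tag"))
  m[, age := s$age[match(subject_id, s$subject_id)]]
  m[, tag := if (by_tag) s$cohort_tag[match(subject_id, s$subject_id)]
             else "pooled"]
  merged <- merge(m, mod[, .(tag, region, hemisphere, metric, slope)],
                  by = c("tag", "region", "hemisphere", "metric"),
                  all.x = TRUE, sort = FALSE)
  if (anyNA(merged$slope)) {
    bad <- unique(merged[is.na(slope),
                         paste(region, hemisphere, metric, sep = "/")])
    stop_validation(paste("keys missing from age model:",
                          paste(utils::head(bad, 5), collapse = ", ")))
  }
  ref <- attr(model, "reference_age")
  merged[, value := value - slope * (age - ref)]
  out <- data.table::setDF(
    merged[, .(subject_id, region, hemisphere, metric, value)])
  morph_table(tab$subjects, out,
              provenance = union(tab$provenance, "age_corrected"),
              validate = FALSE)
}

#' Normalize volumes by head size and parent structure
#'
#' Volumes with registry `norm_parent = ICV` (cortical, subcortical, and the
#' whole hippocampus / whole amygdala themselves) are divided by the
#' subject's intracranial volume; hippocampal subfields and amygdalar nuclei
#' are divided by the subject's same-hemisphere, age-corrected whole
#' hippocampus / whole amygdala volume. Thickness passes through unchanged.
#'
#' @param tab an age-corrected `morph_table`.
#' @param registry the registry.
#' @return a `morph_table` with provenance including `normalized`.
#' @export
normalize_volumes <- function(tab, registry = build_default_registry()) {
  if (!"age_corrected" %in% tab$provenance) {
    stop_validation("normalize_volumes requires an age-corrected table (fixed pipeline order)")
  }
  if ("normalized" %in% tab$provenance) {
    stop_validation("table is already normalized")
  }
  m <- data.table::as.data.table(tab$measurements)
  s <- tab$subjects
  m[, norm_parent := registry$norm_parent[match(region, registry$name)]]
  m[metric == "thickness", norm_parent := "none"]

  # parent denominators: age-corrected, raw-scale volumes, hemisphere-matched
  parents <- m[region %in% c("Whole hippocampus", "Whole amygdala") &
                 metric == "volume",
               .(subject_id, hemisphere, parent = region, denom = value)]
  parents[, parent := as.character(ifelse(parent == "Whole hippocampus",
                                          "whole_hippocampus",
                                          "whole_amygdala"))]

  m[, denom := NA_real_]
  m[norm_parent == "ICV", denom := s$icv[match(subject_id, s$subject_id)]]
  need_parent <- m$norm_parent %in% c("whole_hippocampus", "whole_amygdala")
  if (any(need_parent)) {
    sub <- merge(m[need_parent, .(subject_id, hemisphere,
                                  parent = norm_parent)],
                 parents, by = c("subject_id", "hemisphere", "parent"),
                 all.x = TRUE, sort = FALSE)
    m[need_parent, denom := sub$denom]
  }
  active <- m$norm_parent != "none"
  bad <- active & (!is.finite(m$denom) | m$denom <= 0)
  if (any(bad)) {
    offenders <- unique(m$subject_id[bad])
    stop_degenerate(paste(
      "missing or non-positive normalization denominator for subject(s):",
      paste(utils::head(offenders, 5), collapse = ", ")))
  }
  m[active & metric == "volume", value := value / denom]
  out <- data.table::setDF(
    m[, .(subject_id, region, hemisphere, metric, value)])
  morph_table(tab$subjects, out,
              provenance = union(tab$provenance, "normalized"),
              validate = FALSE)
}
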