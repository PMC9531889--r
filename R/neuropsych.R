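# Neuropsychology: ANAM throughput Z composites, premorbid-comparison
# decline flags (vs the WRAT reading Z), and Pearson correlation of subtest
# scores with the outlier-region count. The module consumes already
# standardized Z-scores; raw-score norming is out of scope.

ANAM_SUBTESTS <- c("SRT", "CDS", "CDD", "M2S", "MTH", "PRO", "SPD", "ST6",
                   "SR2")

#' ANAM composite score
#'
#' Arithmetic mean of the available (non-missing) subtest throughput
#' Z-scores; subtests not taken are excluded from the denominator.
#'
#' @param anam_z named numeric vector (or single-subject list) of subtest
#'   Z-scores; `NA` marks subtests not taken.
#' @return composite Z (numeric scalar).
#' @export
anam_composite <- function(anam_z) {
  z <- unlist(anam_z)
  z <- z[!is.na(z)]
  if (!length(z)) stop_validation("all ANAM subtests missing")
  mean(z)
}

#' Cognitive decline flag
#'
#' Decline is current performance below the premorbid estimate:
#' `composite_z < wrat_z`. (The convention is deliberately
#' construct-oriented; see the methods vignette for the sign discussion.)
#'
#' @param composite_z ANAM composite Z.
#' @param wrat_z WRAT reading Z (premorbid estimate).
#' @return logical.
#' @export
decline_flag <- function(composite_z, wrat_z) {
  if (anyNA(c(composite_z, wrat_z))) {
    stop_validation("decline_flag requires both composite and WRAT scores")
  }
  composite_z < wrat_z
}

#' Read neuropsych TSVs
#'
#' `anam_path` holds one row per (subject_id, subtest, z); `wrat_path` one
#' row per (subject_id, wrat_z).
#'
#' @param anam_path,wrat_path TSV paths.
#' @return data.frame with one row per subject: subtest columns, `wrat_z`,
#'   `composite_z`, `decline`.
#' @export
read_neuropsych_tsv <- function(anam_path, wrat_path) {
  anam <- utils::read.table(anam_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  wrat <- utils::read.table(wrat_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  bad <- setdiff(unique(anam$subtest), ANAM_SUBTESTS)
  if (length(bad)) {
    stop_validation(paste("unknown ANAM subtests:", paste(bad, collapse = ", ")))
  }
  wide <- data.table::dcast(data.table::as.data.table(anam),
                            subject_id ~ subtest, value.var = "z")
  df <- merge(data.table::setDF(wide), wrat, by = "subject_id", all = TRUE)
  assemble_neuropsych(df)
}

#' Assemble per-subject neuropsych records
#'
#' @param df data.frame with `subject_id`, any of the nine subtest columns
#'   (SRT, CDS, CDD, M2S, MTH, PRO, SPD, ST6, SR2) and `wrat_z`.
#' @return the same data.frame with `composite_z` and `decline` added.
#' @export
assemble_neuropsych <- function(df) {
  sub_cols <- intersect(ANAM_SUBTESTS, names(df))
  if (!length(sub_cols)) stop_validation("no ANAM subtest columns present")
  zmat <- as.matrix(df[, sub_cols, drop = FALSE])
  n_avail <- rowSums(!is.na(zmat))
  df$composite_z <- ifelse(n_avail > 0, rowMeans(zmat, na.rm = TRUE), NA_real_)
  df$decline <- ifelse(
    is.na(df$composite_z) | is.na(df$wrat_z), NA,
    df$composite_z < df$wrat_z)
  df
}

# Pearson r with the two-sided t-based p-value.
pearson_test <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_validation("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop_degenerate("zero variance in correlation input")
  }
  r <- stats::cov(x, y) / (stats::sd(x) * stats::sd(y))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2), n = n)
}

#' Correlate cognitive scores with atrophy burden
#'
#' Pearson correlation (with the two-sided t-based p) between each ANAM
#' subtest throughput Z and the subject's outlier-region count, plus a
#' composite row; per-row n is carried explicitly because subjects can miss
#' individual subtests.
#'
#' @param records per-subject neuropsych data.frame (see
#'   [assemble_neuropsych()]).
#' @param profiles an `outlier_profiles` (or a data.frame with `subject_id`
#'   and `outlier_count`).
#' @param basis count over region x metric `"entries"` (default) or distinct
#'   `"regions"`.
#' @return data.frame with columns `subtest`, `r`, `p`, `n`.
#' @export
correlate_with_atrophy <- function(records, profiles,
                                   basis = c("entries", "regions")) {
  basis <- match.arg(basis)
  counts <- if (inherits(profiles, "outlier_profiles")) profiles$counts
            else profiles
  col <- if (basis == "entries") "outlier_count" else "outlier_count_regions"
  if (!col %in% names(counts)) col <- "outlier_count"
  df <- merge(records, counts[, c("subject_id", col)], by = "subject_id")
  vars <- c(intersect(ANAM_SUBTESTS, names(df)), "composite_z")
  rows <- lapply(vars, function(v) {
    res <- pearson_test(df[[v]], df[[col]])
    data.frame(subtest = if (v == "composite_z") "Composite" else v,
               r = res$r, p = res$p, n = res$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
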