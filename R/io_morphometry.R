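# MorphometryTable container and flat-file I/O. The canonical interchange
# format is a long TSV (one row per subject x region x hemisphere x metric);
# FreeSurfer stats readers are convenience importers onto the same container.

VALID_GROUPS <- c("control", "AD", "exposed")
VALID_SEX <- c("male", "female", "unknown")
VALID_HEMIS <- c("left", "right", "none")
VALID_METRICS <- c("thickness", "volume")

#' Construct a morphometry table
#'
#' A `morph_table` bundles per-subject demographics with sparse long-format
#' measurements. Provenance flags record the preprocessing state: `raw`
#' tables may be age-corrected ([age_correct()]) and then volume-normalized
#' ([normalize_volumes()]); the pipeline order is enforced.
#'
#' @param subjects data.frame with columns `subject_id`, `group` (one of
#'   control/AD/exposed), `age` (years), `sex`, `cohort_tag`, `icv` (mm^3).
#' @param measurements data.frame with columns `subject_id`, `region`
#'   (registry label), `hemisphere` (left/right/none), `metric`
#'   (thickness/volume), `value` (mm or mm^3).
#' @param provenance character subset of `c("raw","age_corrected","normalized")`.
#' @param registry registry used for validation; defaults to the shipped one.
#' @param validate set `FALSE` to skip checks (internal fast path).
#' @return An object of class `morph_table`.
#' @export
morph_table <- function(subjects, measurements,
                        provenance = "raw",
                        registry = build_default_registry(),
                        validate = TRUE) {
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  measurements <- as.data.frame(measurements, stringsAsFactors = FALSE)
  out <- structure(
    list(subjects = subjects, measurements = measurements,
         provenance = provenance),
    class = "morph_table"
  )
  if (validate) validate_morph_table(out, registry)
  out
}

#' @export
print.morph_table <- function(x, ...) {
  cat(sprintf(
    "morph_table: %d subjects (%s), %d measurements, provenance: %s\n",
    nrow(x$subjects),
    paste(sprintf("%s=%d", names(table(x$subjects$group)),
                  as.integer(table(x$subjects$group))), collapse = ", "),
    nrow(x$measurements), paste(x$provenance, collapse = "+")
  ))
  invisible(x)
}

validate_morph_table <- function(tab, registry = build_default_registry()) {
  s <- tab$subjects; m <- tab$measurements
  need_s <- c("subject_id", "group", "age", "sex", "cohort_tag", "icv")
  if (!all(need_s %in% names(s))) {
    stop_validation(paste("subjects table missing columns:",
                          paste(setdiff(need_s, names(s)), collapse = ", ")))
  }
  if (anyDuplicated(s$subject_id)) {
    stop_validation("duplicate subject_id in subjects table")
  }
  if (!all(s$group %in% VALID_GROUPS)) {
    stop_validation("group must be one of control, AD, exposed")
  }
  if (!all(s$sex %in% VALID_SEX)) stop_validation("invalid sex value")
  if (any(!is.finite(s$age) | s$age <= 0)) stop_validation("age must be > 0")
  if (any(!is.finite(s$icv) | s$icv <= 0)) stop_validation("icv must be > 0")

  need_m <- c("subject_id", "region", "hemisphere", "metric", "value")
  if (!all(need_m %in% names(m))) {
    stop_validation(paste("measurements missing columns:",
                          paste(setdiff(need_m, names(m)), collapse = ", ")))
  }
  if (nrow(m)) {
    if (!all(m$subject_id %in% s$subject_id)) {
      stop_validation("measurement rows reference unknown subject_id")
    }
    if (!all(m$hemisphere %in% VALID_HEMIS)) {
      stop_validation("hemisphere must be left, right or none")
    }
    if (!all(m$metric %in% VALID_METRICS)) {
      stop_validation("metric must be thickness or volume")
    }
    if (any(is.na(canonical_region(registry, m$region)))) {
      offenders <- unique(m$region[is.na(canonical_region(registry, m$region))])
      stop_validation(paste("unknown regions:",
                            paste(utils::head(offenders, 5), collapse = ", ")))
    }
    # registry consistency: hemisphere and metric availability
    idx <- match(canonical_region(registry, m$region), registry$name)
    hemi_ok <- ifelse(registry$hemispheric[idx],
                      m$hemisphere %in% c("left", "right"),
                      m$hemisphere == "none")
    if (!all(hemi_ok)) {
      bad <- unique(m$region[!hemi_ok])
      stop_validation(paste("hemisphere inconsistent with registry for:",
                            paste(utils::head(bad, 5), collapse = ", ")))
    }
    metric_ok <- mapply(function(met, ms) met %in% strsplit(ms, ",")[[1]],
                        m$metric, registry$metrics[idx])
    if (!all(metric_ok)) {
      bad <- unique(paste(m$region, m$metric)[!metric_ok])
      stop_validation(paste("metric not available for region:",
                            paste(utils::head(bad, 5), collapse = ", ")))
    }
    key <- paste(m$subject_id, m$region, m$hemisphere, m$metric, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- m[duplicated(key), ][1, ]
      stop_validation(sprintf(
        "duplicate measurement key: (%s, %s, %s, %s)",
        dup$subject_id, dup$region, dup$hemisphere, dup$metric))
    }
    if (any(!is.finite(m$value))) stop_validation("non-finite measurement value")
    if ("raw" %in% tab$provenance && !("normalized" %in% tab$provenance)) {
      th <- m$metric == "thickness"
      if (any(m$value[th] <= 0 | m$value[th] >= 10)) {
        stop_validation("raw thickness values must be in (0, 10) mm")
      }
      if (any(m$value[!th] <= 0)) {
        stop_validation("raw volumes must be > 0")
      }
    }
  }
  if ("normalized" %in% tab$provenance &&
      !("age_corrected" %in% tab$provenance)) {
    stop_validation("provenance 'normalized' requires 'age_corrected'")
  }
  invisible(tab)
}

#' Subset a morphometry table by group or subject
#' @param tab a `morph_table`.
#' @param group group label(s) to keep.
#' @param subject_ids subject ids to keep.
#' @return a `morph_table`.
#' @export
subset_morph <- function(tab, group = NULL, subject_ids = NULL) {
  keep <- rep(TRUE, nrow(tab$subjects))
  if (!is.null(group)) keep <- keep & tab$subjects$group %in% group
  if (!is.null(subject_ids)) keep <- keep & tab$subjects$subject_id %in% subject_ids
  ids <- tab$subjects$subject_id[keep]
  morph_table(tab$subjects[keep, , drop = FALSE],
              tab$measurements[tab$measurements$subject_id %in% ids, ,
                               drop = FALSE],
              provenance = tab$provenance, validate = FALSE)
}

LONG_TSV_COLS <- c("subject_id", "group", "age", "sex", "cohort_tag", "icv",
                   "region", "hemisphere", "metric", "value")

#' Read the canonical long-format morphometry TSV
#'
#' The long TSV carries one measurement per row together with the subject's
#' demographics (which must be identical across a subject's rows). A leading
#' `# provenance:` comment line, as written by [write_long_tsv()], restores
#' the preprocessing state.
#'
#' @param path TSV path.
#' @param registry registry for validation.
#' @return a `morph_table`.
#' @export
read_long_tsv <- function(path, registry = build_default_registry()) {
  if (!file.exists(path)) stop_validation(paste("no such file:", path))
  first <- readLines(path, n = 1L)
  provenance <- "raw"
  if (startsWith(first, "# provenance:")) {
    provenance <- strsplit(trimws(sub("# provenance:", "", first)), "\\+")[[1]]
  }
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                      comment.char = "#", stringsAsFactors = FALSE,
                      colClasses = c(value = "numeric", age = "numeric",
                                     icv = "numeric")),
    error = function(e) stop_validation(paste0("parse error in ", path, ": ",
                                               conditionMessage(e)))
  )
  if (!all(LONG_TSV_COLS %in% names(df))) {
    stop_validation(paste("long TSV missing columns:",
                          paste(setdiff(LONG_TSV_COLS, names(df)),
                                collapse = ", ")))
  }
  # demographics must agree within subject
  demo <- unique(df[, c("subject_id", "group", "age", "sex", "cohort_tag",
                        "icv")])
  if (anyDuplicated(demo$subject_id)) {
    bad <- demo$subject_id[duplicated(demo$subject_id)][1]
    stop_validation(sprintf(
      "inconsistent demographics for subject '%s'", bad))
  }
  canon <- canonical_region(registry, df$region)
  if (any(is.na(canon))) {
    stop_validation(paste(
      "unknown regions in", path, ":",
      paste(utils::head(unique(df$region[is.na(canon)]), 5), collapse = ", ")))
  }
  df$region <- canon
  morph_table(demo,
              df[, c("subject_id", "region", "hemisphere", "metric", "value")],
              provenance = provenance, registry = registry)
}

#' Write the canonical long-format morphometry TSV
#'
#' Rows are sorted by (subject_id, region, hemisphere, metric) and values are
#' written with full precision (17 significant digits) so that
#' `read_long_tsv(write_long_tsv(t))` round-trips bit-exactly.
#'
#' @param tab a `morph_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_long_tsv <- function(tab, path) {
  m <- merge(tab$measurements, tab$subjects, by = "subject_id")
  m <- m[order(m$subject_id, m$region, m$hemisphere, m$metric), LONG_TSV_COLS]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# provenance: ",
                    paste(tab$provenance, collapse = "+")), con)
  writeLines(paste(LONG_TSV_COLS, collapse = "\t"), con)
  if (nrow(m)) {
    fmt <- function(x) {
      if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
    }
    cols <- lapply(m, fmt)
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

# ---- FreeSurfer stats dialects ------------------------------------------

read_fs_measure_lines <- function(lines) {
  meas <- grep("^# Measure ", lines, value = TRUE)
  if (!length(meas)) return(data.frame())
  parts <- strsplit(sub("^# Measure ", "", meas), ",[ ]*")
  data.frame(
    name = vapply(parts, `[`, "", 1L),
    colname = vapply(parts, `[`, "", 2L),
    value = as.numeric(vapply(parts, function(p) p[length(p) - 1L], "")),
    stringsAsFactors = FALSE
  )
}

read_fs_table_rows <- function(lines) {
  hdr <- grep("^# ColHeaders ", lines, value = TRUE)
  if (!length(hdr)) return(NULL)
  cols <- strsplit(trimws(sub("^# ColHeaders ", "", hdr[1])), "[ ]+")[[1]]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(body)) return(NULL)
  df <- utils::read.table(text = body, stringsAsFactors = FALSE)
  names(df) <- cols[seq_len(ncol(df))]
  df
}

# aseg.stats: subcortical volume rows + global Measure lines (incl. ICV).
read_aseg_stats <- function(path, registry) {
  lines <- readLines(path, warn = FALSE)
  meas <- read_fs_measure_lines(lines)
  icv <- meas$value[meas$name == "EstimatedTotalIntraCranialVol"]
  if (!length(icv)) {
    stop_validation(paste("missing EstimatedTotalIntraCranialVol in", path))
  }
  out <- list()
  add <- function(label, value, file_line) {
    p <- parse_fs_label(label)
    canon <- canonical_region(registry, p$label)
    if (is.na(canon)) {
      message(sprintf("skipping unknown region '%s' (%s)", label, file_line))
      return()
    }
    out[[length(out) + 1L]] <<- data.frame(
      region = canon, hemisphere = p$hemisphere, metric = "volume",
      value = value, stringsAsFactors = FALSE)
  }
  tbl <- read_fs_table_rows(lines)
  if (!is.null(tbl) && all(c("StructName", "Volume_mm3") %in% names(tbl))) {
    for (i in seq_len(nrow(tbl))) {
      add(tbl$StructName[i], tbl$Volume_mm3[i], paste0(basename(path), " row ", i))
    }
  }
  keep_measures <- c("BrainSegVol", "TotalGrayVol", "lhCortexVol",
                     "rhCortexVol", "lhCerebralWhiteMatterVol",
                     "rhCerebralWhiteMatterVol")
  for (i in seq_len(nrow(meas))) {
    if (meas$colname[i] %in% keep_measures) {
      add(meas$colname[i], meas$value[i],
          paste0(basename(path), " measure ", meas$colname[i]))
    }
  }
  list(measurements = do.call(rbind, out), icv = icv)
}

# ?h.aparc.stats: cortical thickness (ThickAvg) and gray volume (GrayVol).
read_aparc_stats <- function(path, registry) {
  lines <- readLines(path, warn = FALSE)
  hemi_line <- grep("^# hemi ", lines, value = TRUE)
  hemi <- if (length(hemi_line)) {
    unname(c(lh = "left",
             rh = "right")[trimws(sub("^# hemi ", "", hemi_line[1]))])
  } else if (grepl("^rh", basename(path))) "right" else "left"
  tbl <- read_fs_table_rows(lines)
  if (is.null(tbl) || !all(c("StructName", "ThickAvg", "GrayVol") %in%
                           names(tbl))) {
    stop_validation(paste("not an aparc.stats table:", path))
  }
  canon <- canonical_region(registry, tbl$StructName)
  skipped <- tbl$StructName[is.na(canon)]
  for (s in skipped) message(sprintf("skipping unknown region '%s' (%s)",
                                     s, basename(path)))
  keep <- !is.na(canon)
  rbind(
    data.frame(region = canon[keep], hemisphere = hemi, metric = "thickness",
               value = tbl$ThickAvg[keep], stringsAsFactors = FALSE),
    data.frame(region = canon[keep], hemisphere = hemi, metric = "volume",
               value = tbl$GrayVol[keep], stringsAsFactors = FALSE)
  )
}

# hippoSfVolumes / amygNucVolumes: two-column "name value" files, hemisphere
# from the lh./rh. filename prefix.
read_subfield_table <- function(path, registry) {
  hemi <- if (grepl("^rh", basename(path))) "right" else "left"
  df <- utils::read.table(path, stringsAsFactors = FALSE,
                          col.names = c("name", "value"))
  canon <- canonical_region(registry, df$name)
  for (s in df$name[is.na(canon)]) {
    message(sprintf("skipping unknown region '%s' (%s)", s, basename(path)))
  }
  keep <- !is.na(canon)
  data.frame(region = canon[keep], hemisphere = hemi, metric = "volume",
             value = df$value[keep], stringsAsFactors = FALSE)
}

#' Read FreeSurfer stats outputs for a set of subjects
#'
#' Each subject directory is expected to contain a `stats/` folder with
#' `aseg.stats`, `lh.aparc.stats`, `rh.aparc.stats` and (optionally)
#' `?h.hippoSfVolumes*.txt` / `?h.amygNucVolumes*.txt` tables as emitted by
#' FreeSurfer 6. Intracranial volume is taken from the aseg
#' `EstimatedTotalIntraCranialVol` measure. Labels are mapped onto registry
#' names through the alias table; unknown labels are skipped with a message.
#'
#' @param subject_dirs named character vector of subject directories; names
#'   are subject ids.
#' @param demographics data.frame (or TSV path) with columns `subject_id`,
#'   `group`, `age`, `sex`, `cohort_tag`. Must cover exactly the subjects in
#'   `subject_dirs`.
#' @param registry registry for label mapping.
#' @return a raw-provenance `morph_table`.
#' @export
read_freesurfer_stats <- function(subject_dirs, demographics,
                                  registry = build_default_registry()) {
  if (is.character(demographics) && length(demographics) == 1L) {
    demographics <- utils::read.table(demographics, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE)
  }
  ids <- names(subject_dirs)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop_validation("subject_dirs must be a named vector (names = subject ids)")
  }
  missing_demo <- setdiff(ids, demographics$subject_id)
  extra_demo <- setdiff(demographics$subject_id, ids)
  if (length(missing_demo) || length(extra_demo)) {
    stop_validation(sprintf(
      "subject reconciliation failed; in stats but not demographics: [%s]; in demographics but not stats: [%s]",
      paste(missing_demo, collapse = ", "), paste(extra_demo, collapse = ", ")))
  }
  subjects <- list(); measures <- list()
  for (id in ids) {
    sdir <- subject_dirs[[id]]
    stats_dir <- if (dir.exists(file.path(sdir, "stats")))
      file.path(sdir, "stats") else sdir
    aseg <- file.path(stats_dir, "aseg.stats")
    if (!file.exists(aseg)) stop_validation(paste("no aseg.stats for", id))
    a <- read_aseg_stats(aseg, registry)
    rows <- list(a$measurements)
    for (f in list.files(stats_dir, pattern = "^[lr]h\\.aparc\\.stats$",
                         full.names = TRUE)) {
      rows[[length(rows) + 1L]] <- read_aparc_stats(f, registry)
    }
    for (f in list.files(stats_dir,
                         pattern = "^[lr]h\\.(hippoSf|amygNuc)Volumes.*\\.txt$",
                         full.names = TRUE)) {
      rows[[length(rows) + 1L]] <- read_subfield_table(f, registry)
    }
    m <- do.call(rbind, rows)
    m$subject_id <- id
    measures[[id]] <- m
    d <- demographics[demographics$subject_id == id, , drop = FALSE]
    d$icv <- a$icv
    if (!"cohort_tag" %in% names(d)) d$cohort_tag <- "default"
    subjects[[id]] <- d[, c("subject_id", "group", "age", "sex", "cohort_tag",
                            "icv")]
  }
  meas <- do.call(rbind, measures)
  morph_table(do.call(rbind, subjects),
              meas[, c("subject_id", "region", "hemisphere", "metric",
                       "value")],
              provenance = "raw", registry = registry)
}
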