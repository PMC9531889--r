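# Case-control screening and the bilateral-significance fingerprint.
# Every (region, hemisphere, metric) key is tested with a two-sided
# pooled-variance Student t-test; a region x metric pair enters the
# fingerprint only if both hemispheres are significant with concordant
# direction (atrophy = case mean below control mean; dilation = above).

#' Compare case and control groups per measurement key
#'
#' For every (region, hemisphere, metric) key with at least two
#' pairwise-complete subjects in each group, computes group means, percent
#' change `100 * (control_mean - case_mean) / control_mean` (positive =
#' atrophy, negative = dilation), and a two-sided pooled-variance Student
#' t-test. Keys with insufficient subjects are skipped with a message.
#'
#' @param cases,controls normalized `morph_table`s with disjoint subjects.
#' @param welch use the Welch (unequal-variance) test instead of the pooled
#'   Student test. Default `FALSE`.
#' @return data.frame of class `region_stats`: one row per key with columns
#'   `region`, `hemisphere`, `metric`, `case_mean`, `control_mean`,
#'   `percent_change`, `t_statistic`, `p_value`, `n_case`, `n_control`.
#' @export
compare_groups <- function(cases, controls, welch = FALSE) {
  for (tb in list(cases, controls)) {
    if (!"normalized" %in% tb$provenance) {
      stop_validation("compare_groups requires normalized tables")
    }
  }
  if (length(intersect(cases$subjects$subject_id,
                       controls$subjects$subject_id))) {
    stop_validation("case and control subject sets overlap")
  }
  ca <- data.table::as.data.table(cases$measurements)
  co <- data.table::as.data.table(controls$measurements)
  agg <- function(x) x[, .(m = mean(value), v = stats::var(value), n = .N),
                       by = .(region, hemisphere, metric)]
  st <- merge(agg(ca), agg(co), by = c("region", "hemisphere", "metric"),
              suffixes = c("_case", "_control"))
  low <- st$n_case < 2L | st$n_control < 2L
  if (any(low)) {
    message(sprintf("skipping %d key(s) with fewer than 2 subjects per group",
                    sum(low)))
    st <- st[!low]
  }
  tt <- pooled_t(st$m_case, st$v_case, st$n_case,
                 st$m_control, st$v_control, st$n_control, welch = welch)
  out <- data.frame(
    region = st$region, hemisphere = st$hemisphere, metric = st$metric,
    case_mean = st$m_case, control_mean = st$m_control,
    percent_change = 100 * (st$m_control - st$m_case) / st$m_control,
    t_statistic = tt$t, p_value = tt$p,
    n_case = st$n_case, n_control = st$n_control,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$region, out$metric, out$hemisphere), ]
  rownames(out) <- NULL
  class(out) <- c("region_stats", "data.frame")
  out
}

#' Assemble the bilateral-significance fingerprint
#'
#' A region x metric pair enters the fingerprint iff its case-control test is
#' significant at `alpha` in both hemispheres with the same direction;
#' non-lateralized regions (midline/global) need only their single test. The
#' summary also reports the expected number of false-positive keys at `alpha`
#' under the global null, as a multiple-testing caveat (no correction is
#' applied).
#'
#' @param stats a `region_stats` from [compare_groups()].
#' @param alpha significance level (default 0.05).
#' @param registry registry (category labels for the summary counts).
#' @return An object of class `fingerprint`: data.frame with one row per
#'   entry (`region`, `metric`, `direction`, left/right percent change, t, p
#'   and n columns; for non-lateralized regions the left slot carries the
#'   single test and right columns are `NA`), with attributes `alpha`,
#'   `n_tests`, `expected_false_positives`.
#' @export
build_fingerprint <- function(stats, alpha = 0.05,
                              registry = build_default_registry()) {
  st <- data.table::as.data.table(as.data.frame(stats))
  st[, direction := ifelse(percent_change > 0, "atrophy", "dilation")]
  one <- function(d) {
    if (nrow(d) == 2L) {
      L <- d[hemisphere == "left"]; R <- d[hemisphere == "right"]
      if (nrow(L) != 1L || nrow(R) != 1L) return(NULL)
      ok <- L$p_value <= alpha && R$p_value <= alpha &&
        L$direction == R$direction && L$percent_change != 0
      if (!ok) return(NULL)
      data.table::data.table(
        direction = L$direction,
        left_percent_change = L$percent_change,
        right_percent_change = R$percent_change,
        left_t = L$t_statistic, right_t = R$t_statistic,
        left_p = L$p_value, right_p = R$p_value,
        n_case = min(L$n_case, R$n_case),
        n_control = min(L$n_control, R$n_control))
    } else if (nrow(d) == 1L && d$hemisphere == "none") {
      if (!(d$p_value <= alpha) || d$percent_change == 0) return(NULL)
      data.table::data.table(
        direction = d$direction,
        left_percent_change = d$percent_change,
        right_percent_change = NA_real_,
        left_t = d$t_statistic, right_t = NA_real_,
        left_p = d$p_value, right_p = NA_real_,
        n_case = d$n_case, n_control = d$n_control)
    } else NULL
  }
  fp <- st[, one(.SD), by = .(region, metric)]
  fp <- data.table::setDF(fp)
  if (!nrow(fp)) {
    fp <- data.frame(region = character(), metric = character(),
                     direction = character(),
                     left_percent_change = numeric(),
                     right_percent_change = numeric(),
                     left_t = numeric(), right_t = numeric(),
                     left_p = numeric(), right_p = numeric(),
                     n_case = integer(), n_control = integer(),
                     stringsAsFactors = FALSE)
  }
  fp <- fp[order(fp$region, fp$metric), , drop = FALSE]
  rownames(fp) <- NULL
  attr(fp, "alpha") <- alpha
  attr(fp, "n_tests") <- nrow(as.data.frame(stats))
  attr(fp, "expected_false_positives") <- alpha * nrow(as.data.frame(stats))
  class(fp) <- c("fingerprint", "data.frame")
  fp
}

#' Summarize a fingerprint
#'
#' Reports both counting bases: distinct regions and region x metric entries
#' (cortical regions can contribute a thickness and a volume entry each),
#' broken down by anatomical category.
#'
#' @param fp a `fingerprint`.
#' @param registry the registry.
#' @return list with `n_entries` (region x metric), `n_regions` (distinct),
#'   `by_category_entries`, `by_category_regions`,
#'   `expected_false_positives`.
#' @export
fingerprint_summary <- function(fp, registry = build_default_registry()) {
  cat_of <- registry$category[match(fp$region, registry$name)]
  uniq <- !duplicated(fp$region)
  list(
    n_entries = nrow(fp),
    n_regions = sum(uniq),
    by_category_entries = table(factor(cat_of, levels = unique(registry$category))),
    by_category_regions = table(factor(cat_of[uniq],
                                       levels = unique(registry$category))),
    alpha = attr(fp, "alpha"),
    expected_false_positives = attr(fp, "expected_false_positives")
  )
}

#' @export
print.fingerprint <- function(x, ...) {
  s <- fingerprint_summary(x)
  cat(sprintf(
    "fingerprint: %d region x metric entries over %d regions (alpha = %s)\n",
    s$n_entries, s$n_regions, format(attr(x, "alpha"))))
  cat(sprintf("expected false-positive keys under global null: %.1f\n",
              attr(x, "expected_false_positives") %||% NA))
  invisible(x)
}

#' Write / read a fingerprint TSV
#'
#' The TSV carries one entry per row so a fingerprint derived on one dataset
#' (e.g. a case-control cohort) can be applied to score another cohort.
#'
#' @param fp a `fingerprint`.
#' @param path file path.
#' @return `read_fingerprint_tsv` returns a `fingerprint`.
#' @export
write_fingerprint_tsv <- function(fp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# alpha: %.17g", attr(fp, "alpha")), con)
  writeLines(sprintf("# n_tests: %d", attr(fp, "n_tests") %||% NA_integer_),
             con)
  df <- as.data.frame(fp)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprint_tsv
#' @export
read_fingerprint_tsv <- function(path) {
  lines <- readLines(path, n = 2L)
  alpha <- as.numeric(sub("# alpha:", "", lines[1]))
  n_tests <- suppressWarnings(as.integer(sub("# n_tests:", "", lines[2])))
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  attr(df, "alpha") <- alpha
  attr(df, "n_tests") <- n_tests
  attr(df, "expected_false_positives") <-
    if (is.na(n_tests)) NA_real_ else alpha * n_tests
  class(df) <- c("fingerprint", "data.frame")
  df
}
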