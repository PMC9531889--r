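# Age x group interaction regression: value ~ age + group + age:group, with
# group coded 0 = control, 1 = case. Default inputs are age-UNcorrected
# normalized volumes, since age is a regressor here (age-corrected inputs
# would null the age coefficient by construction).

#' Fit the age + group + age x group regression for one region/metric
#'
#' OLS with design matrix `[1, age, group, age * group]`, reporting
#' per-coefficient estimates, standard errors, t statistics and two-sided p
#' values, the overall ANOVA F test, and R-squared.
#'
#' @param values numeric response (regional volume or thickness).
#' @param ages numeric ages (years).
#' @param groups group labels coercible to a 0/1 indicator: either a
#'   numeric/logical 0-1 vector or a factor/character where `"control"` is 0
#'   and anything else 1.
#' @return list of class `interaction_fit`: `coefficients` data.frame
#'   (term, estimate, std_error, t_value, p_value), `n`, `r_squared`,
#'   `f_statistic`, `f_p_value`, `group_coding`.
#' @export
fit_interaction <- function(values, ages, groups) {
  if (is.numeric(groups) || is.logical(groups)) {
    g <- as.numeric(groups)
    if (!all(g %in% c(0, 1))) stop_validation("numeric groups must be 0/1")
  } else {
    g <- as.numeric(as.character(groups) != "control")
  }
  ok <- stats::complete.cases(values, ages, g)
  values <- values[ok]; ages <- ages[ok]; g <- g[ok]
  if (length(values) < 5L) stop_validation("need at least 5 subjects")
  if (length(unique(g)) < 2L) {
    stop_degenerate("both groups must be represented")
  }
  if (stats::var(ages) == 0) stop_degenerate("constant age: rank-deficient design")
  fit <- stats::lm(values ~ ages * g)
  if (any(is.na(stats::coef(fit)))) {
    stop_degenerate("rank-deficient design matrix")
  }
  sm <- summary(fit)
  co <- sm$coefficients
  coefs <- data.frame(
    term = c("intercept", "age", "group", "age_x_group"),
    estimate = co[, 1], std_error = co[, 2], t_value = co[, 3],
    p_value = co[, 4], row.names = NULL, stringsAsFactors = FALSE
  )
  fstat <- sm$fstatistic
  out <- list(
    coefficients = coefs,
    n = length(values),
    r_squared = sm$r.squared,
    f_statistic = unname(fstat[1]),
    f_p_value = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
    group_coding = "0 = control, 1 = case"
  )
  class(out) <- "interaction_fit"
  out
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf("interaction_fit (n = %d, R^2 = %.3f, F p = %.3g)\n",
              x$n, x$r_squared, x$f_p_value))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Run the interaction fit on a morphometry table
#'
#' Convenience wrapper that pulls one (region, hemisphere, metric) key out of
#' a table and regresses it on age, group and their interaction across the
#' requested groups.
#'
#' @param tab a `morph_table` (normalized but not age-corrected inputs are
#'   the documented default; raw tables are accepted).
#' @param region,metric key to model.
#' @param hemisphere `"left"`, `"right"`, `"none"`, or `"mean"` to average
#'   hemispheres per subject (default).
#' @param case_group which group plays the 1-coded case (default
#'   `"exposed"`).
#' @return an `interaction_fit`.
#' @export
fit_interaction_region <- function(tab, region, metric = "volume",
                                   hemisphere = "mean",
                                   case_group = "exposed") {
  m <- tab$measurements
  m <- m[m$region == region & m$metric == metric, , drop = FALSE]
  if (hemisphere != "mean") m <- m[m$hemisphere == hemisphere, , drop = FALSE]
  if (!nrow(m)) stop_validation(paste("no measurements for", region, metric))
  agg <- tapply(m$value, m$subject_id, mean)
  s <- tab$subjects[tab$subjects$group %in% c("control", case_group), ]
  idx <- match(s$subject_id, names(agg))
  fit_interaction(as.numeric(agg[idx]), s$age, s$group != "control")
}
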