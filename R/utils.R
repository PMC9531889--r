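# Internal helpers shared across modules.

#' @importFrom data.table data.table setDT setDF as.data.table := .N .SD setorder
#' @importFrom stats pt sd var cor coef lm pf setNames complete.cases rnorm runif
#'   qnorm quantile
NULL

# Squash a label to its comparison key: lowercase alphanumerics only, so that
# "CA-1 head", "ca1_head" and "CA1-head" all collide.
squash_label <- function(x) {
  gsub("[^a-z0-9]", "", tolower(x))
}

# Classed conditions so the CLI can map failures to exit codes.
adf_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "adf_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

stop_validation <- function(msg, ...) adf_stop(msg, "adf_validation_error", ...)
stop_degenerate <- function(msg, ...) adf_stop(msg, "adf_degenerate_error", ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pooled-variance (Student) two-sample t-test from sufficient statistics.
# Returns t, df, two-sided p. Welch available behind a flag.
pooled_t <- function(m1, v1, n1, m2, v2, n2, welch = FALSE) {
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}
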