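# Age model fitting, residualization to the control mean age, and
# ICV / parent-structure normalization.

noiseless_control_table <- function(ages, f, region = "Hippocampus",
                                    hemi = "left") {
  ids <- paste0("c", seq_along(ages))
  morph_table(mk_subjects(ids, age = ages),
              mk_meas(ids, region, hemi, "volume", f(ages)),
              provenance = "raw", validate = FALSE)
}

test_that("age model recovers noiseless slopes exactly", {
  ages <- c(30, 40, 50, 60, 70)
  tab <- noiseless_control_table(ages, function(a) 100 - 0.5 * a)
  model <- fit_age_model(tab)
  expect_equal(model$slope, -0.5, tolerance = 1e-12)
  expect_equal(attr(model, "reference_age"), mean(ages))
  # zero residuals: intercept consistent
  expect_equal(model$intercept, 100, tolerance = 1e-10)

  const <- noiseless_control_table(ages, function(a) rep(80, length(a)))
  expect_equal(fit_age_model(const)$slope, 0)
})

test_that("fitted slope matches the lm oracle and sampling error bound", {
  set.seed(401)
  n <- 100
  ages <- runif(n, 20, 80)
  vals <- 5000 - 2.0 * ages + rnorm(n, sd = 5)
  ids <- paste0("c", seq_len(n))
  tab <- morph_table(mk_subjects(ids, age = ages),
                     mk_meas(ids, "Hippocampus", "left", "volume", vals),
                     validate = FALSE)
  model <- fit_age_model(tab)
  # independent oracle: stats::lm
  expect_equal(model$slope, unname(coef(lm(vals ~ ages))[2]),
               tolerance = 1e-10)
  # closed-form OLS sampling SD ~ noise / (sd(age) * sqrt(n)) ~ 0.03, so
  # +/- 0.5 is a > 15-sigma band
  expect_lt(abs(model$slope - (-2.0)), 0.5)
})

test_that("age correction residualizes to the reference age", {
  ages <- c(40, 50, 60)
  tab <- noiseless_control_table(ages, function(a) 100 - 0.5 * (a - 50))
  model <- fit_age_model(tab)            # reference age 50, slope -0.5
  corr <- age_correct(tab, model)
  val <- function(id) {
    corr$measurements$value[corr$measurements$subject_id == id]
  }
  # subject at the reference age is unchanged
  expect_equal(val("c2"), 100)
  # subject at reference + 10 with slope -0.5 gains 5
  expect_equal(val("c3"), 95 + 0.5 * 10)
  expect_true("age_corrected" %in% corr$provenance)
  expect_error(age_correct(corr, model), "already age-corrected",
               class = "adf_validation_error")

  # missing key
  other <- morph_table(mk_subjects("x", age = 50),
                       mk_meas("x", "Amygdala", "left", "volume", 1500),
                       validate = FALSE)
  expect_error(age_correct(other, model), "missing from age model",
               class = "adf_validation_error")
})

test_that("refitting after self-correction gives zero slopes (noiseless)", {
  set.seed(402)
  ages <- seq(25, 75, length.out = 20)
  ids <- paste0("c", seq_along(ages))
  meas <- rbind(
    mk_meas(ids, "Hippocampus", "left", "volume", 4000 - 12 * ages),
    mk_meas(ids, "Entorhinal", "left", "thickness", 3.5 - 0.004 * ages))
  tab <- morph_table(mk_subjects(ids, age = ages), meas, validate = FALSE)
  corr <- age_correct(tab, fit_age_model(tab))
  corr$provenance <- "raw"   # refit on the corrected values
  refit <- fit_age_model(corr)
  expect_true(all(abs(refit$slope) < 1e-9))
})

test_that("normalization divides by ICV or the same-side corrected parent", {
  ids <- c("a", "b")
  meas <- rbind(
    mk_meas(ids, "Fimbria", "left", "volume", c(60, 80)),
    mk_meas(ids, "Whole hippocampus", "left", "volume", c(3000, 4000)),
    mk_meas(ids, "Entorhinal", "left", "thickness", c(3.2, 3.0)))
  tab <- morph_table(mk_subjects(ids, icv = c(1.6e6, 1.6e6)), meas,
                     provenance = c("raw", "age_corrected"), validate = FALSE)
  norm <- normalize_volumes(tab)
  m <- norm$measurements
  g <- function(region, id) m$value[m$region == region & m$subject_id == id]
  expect_equal(g("Fimbria", "a"), 60 / 3000)    # parent-normalized: 0.02
  expect_equal(g("Whole hippocampus", "b"), 4000 / 1.6e6)  # ICV: 2.5e-3
  expect_equal(g("Entorhinal", "a"), 3.2)       # thickness passes through
  expect_true("normalized" %in% norm$provenance)
})

test_that("normalization removes head-size scale exactly", {
  # identical regional fractions, ICVs 1.4e6 vs 1.8e6
  icvs <- c(1.4e6, 1.8e6)
  ids <- c("a", "b")
  frac <- 2.5e-3
  meas <- mk_meas(ids, "Hippocampus", "left", "volume", frac * icvs)
  tab <- morph_table(mk_subjects(ids, icv = icvs), meas,
                     provenance = c("raw", "age_corrected"), validate = FALSE)
  m <- normalize_volumes(tab)$measurements
  expect_identical(m$value[1], m$value[2])
  expect_equal(m$value[1], frac)

  # scale invariance under any c > 0
  for (c_mult in c(0.5, 2, 13.7)) {
    tab2 <- tab
    tab2$subjects$icv[1] <- icvs[1] * c_mult
    tab2$measurements$value[1] <- frac * icvs[1] * c_mult
    m2 <- normalize_volumes(tab2)$measurements
    expect_equal(m2$value[1], frac, tolerance = 1e-15)
  }
})

test_that("pipeline order is enforced and bad denominators are caught", {
  tab <- mk_onekey_table(c(4000, 4100), provenance = "raw")
  expect_error(normalize_volumes(tab), "age-corrected",
               class = "adf_validation_error")

  # subfield without its parent volume
  ids <- "a"
  tab2 <- morph_table(mk_subjects(ids),
                      mk_meas(ids, "Fimbria", "left", "volume", 60),
                      provenance = c("raw", "age_corrected"),
                      validate = FALSE)
  expect_error(normalize_volumes(tab2), "denominator",
               class = "adf_degenerate_error")
})

test_that("per-cohort-tag age models are supported", {
  ages <- rep(c(30, 50, 70), 2)
  ids <- paste0("c", 1:6)
  subj <- mk_subjects(ids, age = ages)
  subj$cohort_tag <- rep(c("s1", "s2"), each = 3)
  # different slopes per scanner stratum
  vals <- ifelse(subj$cohort_tag == "s1", 100 - 0.5 * ages, 200 - 1.5 * ages)
  tab <- morph_table(subj, mk_meas(ids, "Hippocampus", "left", "volume", vals),
                     validate = FALSE)
  model <- fit_age_model(tab, by_cohort_tag = TRUE)
  expect_equal(sort(model$slope), c(-1.5, -0.5), tolerance = 1e-12)
  corr <- age_correct(tab, model)
  corr$provenance <- "raw"
  expect_true(all(abs(fit_age_model(corr, by_cohort_tag = TRUE)$slope) < 1e-9))
})
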