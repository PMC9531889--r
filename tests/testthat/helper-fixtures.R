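# Fixtures built in code: tiny hand-sized tables for unit tests, plus a
# scaled-down simulation world used by the heavier integration tests.

REG <- build_default_registry()

# A minimal subjects frame.
mk_subjects <- function(ids, group = "control", age = 50, icv = 1.5e6,
                        tag = "t1") {
  data.frame(subject_id = ids, group = group, age = age, sex = "female",
             cohort_tag = tag, icv = icv, stringsAsFactors = FALSE)
}

# One-region-per-row measurement frame for explicit hand-built cases.
mk_meas <- function(subject_id, region, hemisphere, metric, value) {
  data.frame(subject_id = subject_id, region = region,
             hemisphere = hemisphere, metric = metric, value = value,
             stringsAsFactors = FALSE)
}

# Build a single-key table: `values[i]` for subject i in `region`/`hemi`.
mk_onekey_table <- function(values, region = "Hippocampus", hemi = "left",
                            metric = "volume", group = "control", age = 50,
                            provenance = c("raw", "age_corrected",
                                           "normalized"),
                            prefix = "s") {
  ids <- paste0(prefix, seq_along(values))
  morph_table(
    mk_subjects(ids, group = group, age = age),
    mk_meas(ids, region, hemi, metric, values),
    provenance = provenance, validate = FALSE)
}

# Small reference config: same structure and effects as the default world,
# but smaller cohorts, so integration tests stay fast. Cohort sizes are a
# stated scale-down, not tuning.
small_config <- function(n_control = 60, n_case = 40, n_exposed = 30) {
  cfg <- default_cohort_config()
  cfg$cohorts$control$n <- n_control
  cfg$cohorts$AD$n <- n_case
  cfg$cohorts$exposed$n <- n_exposed
  cfg
}

# Run the derive-side preprocessing on a simulated world.
preprocess_world <- function(sim, registry = REG) {
  controls <- subset_morph(sim$morphometry, group = "control")
  model <- fit_age_model(controls)
  norm <- function(tb) normalize_volumes(age_correct(tb, model), registry)
  list(model = model,
       controls = norm(controls),
       cases = norm(subset_morph(sim$morphometry, group = "AD")),
       exposed = norm(subset_morph(sim$morphometry, group = "exposed")))
}
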