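# Synthetic cohort generator: determinism, stated-world parameters,
# structural couplings, and the truth ledger.

test_that("default config transcribes the stated world", {
  cfg <- default_cohort_config()
  expect_equal(cfg$cohorts$exposed$age$mean, 48.4)
  expect_equal(cfg$cohorts$exposed$age$sd, 12.2)
  expect_equal(cfg$cohorts$AD$age$mean, 75.5)
  expect_equal(cfg$cohorts$control$age$min, 18)
  expect_equal(cfg$cohorts$control$age$max, 81)
  expect_equal(cfg$cohorts$control$n, 114)
  expect_equal(cfg$cohorts$AD$n, 58)
  expect_equal(cfg$cohorts$exposed$n, 46)
  p <- cfg$regions
  expect_equal(p$effect_AD[p$region == "Entorhinal" & p$metric == "volume"],
               1 - 0.27)
  expect_equal(p$effect_AD[p$region == "Entorhinal" &
                             p$metric == "thickness"], 1 - 0.191)
  expect_equal(p$effect_AD[p$region == "Inf-Lat-Vent"], 1 + 1.247)
  expect_equal(p$effect_AD[p$region == "Fimbria"], 1 - 0.237)
  expect_equal(cfg$cognition$r_targets[["M2S"]], -0.35)
  expect_equal(cfg$cognition$r_targets[["CDS"]], -0.31)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- small_config(10, 6, 6)
  s1 <- simulate_cohorts(cfg, seed = 123)
  s2 <- simulate_cohorts(cfg, seed = 123)
  expect_identical(s1$morphometry$measurements, s2$morphometry$measurements)
  expect_identical(s1$neuropsych, s2$neuropsych)
  s3 <- simulate_cohorts(cfg, seed = 124)
  expect_false(identical(s1$morphometry$measurements,
                         s3$morphometry$measurements))
  # bit-identical TSV under the same seed
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_long_tsv(s1$morphometry, p1)
  write_long_tsv(s2$morphometry, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("generated tables validate against the registry", {
  sim <- simulate_cohorts(small_config(12, 6, 6), seed = 21)
  expect_silent(adfingerprint:::validate_morph_table(sim$morphometry))
})

test_that("volumes are ICV-coupled and normalization removes the coupling", {
  cfg <- small_config(80, 4, 4)
  sim <- simulate_cohorts(cfg, seed = 22)
  pre <- preprocess_world(sim)
  ctrl_raw <- subset_morph(sim$morphometry, group = "control")
  s <- ctrl_raw$subjects
  pick <- function(tab) {
    m <- tab$measurements
    v <- m[m$region == "Hippocampus" & m$hemisphere == "left" &
             m$metric == "volume", ]
    v$value[match(s$subject_id, v$subject_id)]
  }
  r_raw <- cor(pick(ctrl_raw), s$icv)
  r_norm <- cor(pick(pre$controls), s$icv)
  expect_gt(r_raw, 0.5)           # head-size coupling present in raw data
  expect_lt(abs(r_norm), 0.25)    # removed by ICV normalization
})

test_that("subfields are generated as fractions of their simulated parent", {
  sim <- simulate_cohorts(small_config(40, 4, 4), seed = 23)
  m <- sim$morphometry$measurements
  m <- m[m$subject_id %in%
           sim$morphometry$subjects$subject_id[
             sim$morphometry$subjects$group == "control"], ]
  fim <- m[m$region == "Fimbria" & m$hemisphere == "left", ]
  par <- m[m$region == "Whole hippocampus" & m$hemisphere == "left", ]
  ratio <- fim$value / par$value[match(fim$subject_id, par$subject_id)]
  cfg <- default_cohort_config()
  base_frac <- cfg$regions$baseline[cfg$regions$region == "Fimbria"]
  # noisy fractions centred on the configured baseline fraction
  expect_equal(mean(ratio), base_frac, tolerance = 0.15)
})

test_that("family-wise missingness hits roughly the configured rate", {
  cfg <- small_config(200, 4, 4)
  sim <- simulate_cohorts(cfg, seed = 24)
  ctrl_ids <- sim$morphometry$subjects$subject_id[
    sim$morphometry$subjects$group == "control"]
  m <- sim$morphometry$measurements
  has_sf <- vapply(ctrl_ids, function(id) {
    any(m$subject_id == id & m$region == "Fimbria")
  }, TRUE)
  miss_rate <- mean(!has_sf)
  # binomial SE at n=200 is ~0.03; 0.228 +/- 0.1 is > 3 SE
  expect_gt(miss_rate, 0.128)
  expect_lt(miss_rate, 0.328)
})

test_that("the truth ledger records effects, directions and burdens", {
  cfg <- small_config(8, 4, 6)
  cfg$cohorts$exposed$affected <- list(fraction = 0.5, n_regions = 8,
                                       sd_shift = 3)
  sim <- simulate_cohorts(cfg, seed = 25)
  tr <- sim$truth
  expect_setequal(unique(tr$effects$group), c("control", "AD", "exposed"))
  ent <- tr$effects[tr$effects$group == "AD" &
                      tr$effects$region == "Entorhinal" &
                      tr$effects$metric == "volume", ]
  expect_equal(ent$effect, 0.73)
  expect_equal(ent$direction, "atrophy")
  vent <- tr$effects[tr$effects$group == "AD" &
                       tr$effects$region == "Inf-Lat-Vent", ]
  expect_equal(vent$direction, "dilation")
  subj <- tr$subjects
  expect_true(all(subj$n_affected_regions[subj$affected] == 8))
  expect_true(all(subj$n_affected_regions[!subj$affected] == 0))
  expect_true(all(subj$affected[subj$group != "exposed"] == FALSE))
  expect_equal(nrow(tr$affected_regions), 8)
  # burden is severity-driven for exposed, zero elsewhere
  expect_true(all(subj$true_burden[subj$group == "control"] == 0))
  expect_true(all(subj$true_burden[subj$group == "exposed"] > 0))
})

test_that("a single run recovers the configured entorhinal deficit roughly", {
  sim <- simulate_cohorts(small_config(114, 58, 1), seed = 26)
  pre <- preprocess_world(sim)
  st <- compare_groups(pre$cases, pre$controls)
  pc <- st$percent_change[st$region == "Entorhinal" & st$metric == "volume"]
  # per-hemisphere sampling SD is ~2 percentage points at this n
  expect_true(all(abs(pc - 27) < 8))
})

test_that("config validation rejects invalid fields", {
  cfg <- default_cohort_config()
  cfg$hemi_rho <- 1.4
  expect_error(simulate_cohorts(cfg, seed = 1), "hemi_rho",
               class = "adf_validation_error")
  cfg2 <- default_cohort_config()
  cfg2$regions$effect_AD[1] <- -0.2
  expect_error(simulate_cohorts(cfg2, seed = 1), "effects",
               class = "adf_validation_error")
  cfg3 <- default_cohort_config()
  cfg3$cohorts$control$n <- 0
  expect_error(simulate_cohorts(cfg3, seed = 1), "n must be",
               class = "adf_validation_error")
})

test_that("config export writes flat key paths plus the region table", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_sim_config_tsv(default_cohort_config(), path)
  lines <- readLines(path)
  expect_true(any(grepl("^cohorts.exposed.age.mean\t48.4$", lines)))
  expect_true(any(grepl("^## regions$", lines)))
})
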