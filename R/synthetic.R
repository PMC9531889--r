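# Synthetic three-cohort generator. Emulates the statistical structure the
# analysis assumes: region-specific age slopes shared across cohorts,
# multiplicative group atrophy/dilation effects at the percent magnitudes
# reported for the case and exposed cohorts, ICV-coupled raw volumes,
# correlated hemispheres, parent-coupled subfield volumes, family-wise
# missingness, and a cognition block whose ANAM throughput Z-scores are
# negatively coupled to each exposed subject's true atrophy burden.

# -- per-region generative parameters -------------------------------------

.baseline_overrides <- c(
  # cortical thickness, mm
  "Entorhinal|thickness" = 3.3, "Parahippocampal|thickness" = 2.8,
  "Temporal pole|thickness" = 3.6, "Insula|thickness" = 3.0,
  "Pericalcarine|thickness" = 1.6, "Cuneus|thickness" = 1.9,
  # cortical volume, mm^3 per hemisphere (rough Desikan-Killiany scale)
  "Entorhinal|volume" = 1900, "Parahippocampal|volume" = 2100,
  "Fusiform|volume" = 9500, "Middle temporal|volume" = 11000,
  "Inferior temporal|volume" = 10500, "Superior temporal|volume" = 11500,
  "Temporal pole|volume" = 2300, "Supramarginal|volume" = 10500,
  "Superior parietal|volume" = 13500, "Pre-cuneus|volume" = 9800,
  "Inferior parietal|volume" = 13000, "Lateral orbitofrontal|volume" = 7500,
  "Caudal middle frontal|volume" = 6500, "Superior frontal|volume" = 22000,
  "Lateral occipital|volume" = 11500, "Cuneus|volume" = 3300,
  "Isthmus cingulate|volume" = 2500,
  # subcortical volume, mm^3
  "Lateral-ventricle|volume" = 15000, "Inf-Lat-Vent|volume" = 500,
  "Cerebellum white matter|volume" = 14000,
  "Cerebellum cortex|volume" = 52000, "Caudate|volume" = 3600,
  "Putamen|volume" = 5000, "Pallidum|volume" = 1800,
  "Hippocampus|volume" = 4000, "Amygdala|volume" = 1700,
  "Accumbens area|volume" = 600, "Cortex|volume" = 230000,
  "Cerebral white matter|volume" = 220000,
  "Corpus callosum posterior|volume" = 950,
  "Corpus callosum midposterior|volume" = 450,
  "Corpus callosum central|volume" = 480,
  "Corpus callosum midanterior|volume" = 480,
  "Corpus callosum anterior|volume" = 850,
  "Third ventricle|volume" = 1000, "Fourth ventricle|volume" = 1900,
  "CSF|volume" = 1100, "Brainstem|volume" = 21000,
  "Brain Seg Vol|volume" = 1150000, "Total Gray Vol|volume" = 650000,
  # hippocampal subfields as fractions of whole hippocampus
  "Hippocampal tail|volume" = 0.155, "Subiculum body|volume" = 0.072,
  "CA-1 body|volume" = 0.040, "Subiculum head|volume" = 0.052,
  "Hippocampal fissure|volume" = 0.045, "Presubiculum head|volume" = 0.040,
  "CA-1 head|volume" = 0.150, "Pre-subiculum body|volume" = 0.020,
  "Parasubiculum|volume" = 0.018, "Molecular layer HP head|volume" = 0.098,
  "Molecular layer HP body|volume" = 0.062, "GC-ML-DG-head|volume" = 0.048,
  "CA-3 body|volume" = 0.025, "GC-ML-DG body|volume" = 0.030,
  "CA-4 head|volume" = 0.042, "CA-4 body|volume" = 0.030,
  "Fimbria|volume" = 0.022, "CA-3 head|volume" = 0.035,
  "HATA|volume" = 0.017, "Whole hippocampal body|volume" = 0.345,
  "Whole hippocampal head|volume" = 0.490, "Whole hippocampus|volume" = 3400,
  # amygdalar nuclei as fractions of whole amygdala
  "Lateral nucleus|volume" = 0.380, "Basal nucleus|volume" = 0.255,
  "Accessory basal nucleus|volume" = 0.150,
  "Anterior amygdaloid area|volume" = 0.033, "Central nucleus|volume" = 0.026,
  "Medial nucleus|volume" = 0.012, "Cortical nucleus|volume" = 0.015,
  "Cortical amygdaloid transition|volume" = 0.105,
  "Paralaminar nucleus|volume" = 0.030, "Whole amygdala|volume" = 1700
)

# percent case-cohort change printed for the case-control comparison
# (positive = atrophy, negative = dilation)
.ad_percent <- list(
  thickness = c(
    "Entorhinal" = 19.1, "Parahippocampal" = 10.9, "Fusiform" = 5.1,
    "Middle temporal" = 7.8, "Inferior temporal" = 5.3,
    "Superior temporal" = 6.0, "Temporal pole" = 6.7, "Supramarginal" = 3.6,
    "Superior parietal" = 3.6, "Pre-cuneus" = 3.9, "Inferior parietal" = 4.8,
    "Caudal middle frontal" = 3.0),
  volume = c(
    "Entorhinal" = 27.0, "Parahippocampal" = 8.5, "Fusiform" = 14.5,
    "Middle temporal" = 13.0, "Inferior temporal" = 15.8,
    "Superior temporal" = 14.5, "Temporal pole" = 11.9,
    "Supramarginal" = 11.8, "Superior parietal" = 9.0, "Pre-cuneus" = 10.0,
    "Inferior parietal" = 9.9, "Lateral orbitofrontal" = 10.0,
    "Caudal middle frontal" = 7.7, "Superior frontal" = 7.6,
    # the single reported occipital region; magnitude not printed, set to 10
    "Lateral occipital" = 10.0,
    # limbic (fraction scale for subfields/nuclei)
    "Fimbria" = 23.7, "Whole hippocampus" = 21.1, "Whole amygdala" = 24.0,
    "Hippocampal fissure" = -11.2,
    # "also significantly reduced", magnitudes not printed; set to 10
    "Presubiculum head" = 10.0, "Subiculum body" = 10.0,
    "Accessory basal nucleus" = 10.0, "Central nucleus" = 10.0,
    # subcortical
    "Amygdala" = 26.8, "Accumbens area" = 20.0, "Hippocampus" = 12.5,
    "Inf-Lat-Vent" = -124.7, "Lateral-ventricle" = -32.5,
    "Putamen" = -15.3, "Cerebral white matter" = 5.0)
)

# exposed-cohort percent change (mean of the printed right/left values)
.exposed_percent <- list(
  thickness = c(
    "Entorhinal" = 14.55, "Parahippocampal" = 9.15, "Fusiform" = 7.5,
    "Inferior temporal" = 5.7, "Isthmus cingulate" = 7.5),
  volume = c(
    "Entorhinal" = 15.7, "Parahippocampal" = 8.55, "Fusiform" = 10.4,
    "Lateral occipital" = 12.6, "Cuneus" = 10.2,
    "Fimbria" = 18.5, "HATA" = 8.9, "Whole hippocampus" = 7.25,
    "Hippocampal fissure" = -17.3,
    "Anterior amygdaloid area" = 6.55, "Whole amygdala" = 6.85,
    "Cerebellum cortex" = 14.85, "Amygdala" = 14.75, "Hippocampus" = 11.3,
    "Inf-Lat-Vent" = -28.95, "Lateral-ventricle" = -14.2)
)

build_region_params <- function(registry = build_default_registry()) {
  rows <- lapply(seq_len(nrow(registry)), function(i) {
    r <- registry[i, ]
    data.frame(region = r$name, category = r$category,
               metric = strsplit(r$metrics, ",")[[1]],
               norm_parent = r$norm_parent, stringsAsFactors = FALSE)
  })
  p <- do.call(rbind, rows)
  key <- paste(p$region, p$metric, sep = "|")
  p$baseline <- unname(.baseline_overrides[key])
  p$baseline[is.na(p$baseline) & p$metric == "thickness"] <- 2.5
  p$baseline[is.na(p$baseline)] <- 6000
  # coefficient of variation across subjects (incl. measurement noise)
  p$cv <- ifelse(p$metric == "thickness", 0.06, 0.12)
  vent <- p$region %in% c("Lateral-ventricle", "Inf-Lat-Vent",
                          "Third ventricle", "Fourth ventricle", "CSF")
  p$cv[vent] <- 0.45
  p$cv[p$region == "Hippocampal fissure"] <- 0.25
  # age slope as a fraction of baseline per year, shared across cohorts
  p$slope_frac <- ifelse(p$metric == "thickness", -0.002, -0.003)
  p$slope_frac[vent] <- 0.025
  p$slope_frac[p$norm_parent %in% c("whole_hippocampus", "whole_amygdala")] <- 0
  p$slope_frac[p$region == "Hippocampal fissure"] <- 0.01
  p$slope_frac[p$region %in% c("CSF")] <- 0.01
  pct_to_effect <- function(metric, region, tab) {
    v <- tab[[metric]][region]
    ifelse(is.na(v), 1, 1 - v / 100)
  }
  p$effect_AD <- mapply(function(me, re) pct_to_effect(me, re, .ad_percent),
                        p$metric, p$region)
  p$effect_exposed <- mapply(function(me, re)
    pct_to_effect(me, re, .exposed_percent), p$metric, p$region)
  p$effect_control <- 1
  rownames(p) <- NULL
  p
}

#' Default simulation configuration (the reference world)
#'
#' The stated world: 114 controls aged 18-81 (three scanner cohorts of
#' 38/50/26), 58 case-cohort subjects aged 75.5 +/- 6.6, 46 exposed subjects
#' aged 48.4 +/- 12.2 (range 29-75); region effects at the printed percent
#' magnitudes; hemisphere correlation 0.8; subfield family missing for ~23%
#' of controls; ANAM subtest Z-scores coupled to true atrophy burden at the
#' per-subtest target correlations.
#'
#' @param registry the registry.
#' @return list of class `cohort_sim_config`.
#' @export
default_cohort_config <- function(registry = build_default_registry()) {
  cfg <- list(
    cohorts = list(
      control = list(n = 114, group = "control",
                     age = list(dist = "uniform", min = 18, max = 81),
                     tags = c(c1 = 38, c2 = 50, c3 = 26)),
      AD = list(n = 58, group = "AD",
                age = list(dist = "normal", mean = 75.5, sd = 6.6,
                           min = 55, max = 95),
                tags = c(adni = 1)),
      exposed = list(n = 46, group = "exposed",
                     age = list(dist = "normal", mean = 48.4, sd = 12.2,
                                min = 29, max = 75),
                     tags = c(nfl = 1),
                     severity_sdlog = 0.5,
                     affected = NULL)
    ),
    icv = list(mean = 1.5e6, sd = 1.4e5),
    reference_age = 49.5,        # control age midpoint; generator anchor
    hemi_rho = 0.8,
    regions = build_region_params(registry),
    missingness = list(control = c(hippocampal_subfield = 0.228,
                                   amygdalar_nucleus = 0.228)),
    cognition = list(
      anam_mean = -0.13, anam_sd = 1,
      r_targets = c(SRT = -0.12, CDS = -0.31, CDD = -0.26, M2S = -0.35,
                    MTH = -0.11, PRO = -0.11, SPD = -0.13, ST6 = -0.18,
                    SR2 = -0.23),
      wrat_mean = 0, wrat_sd = 1,
      anam_missing_rate = 4 / 46)
  )
  class(cfg) <- "cohort_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  for (co in cfg$cohorts) {
    if (!is.numeric(co$n) || co$n < 1) stop_validation("cohort n must be >= 1")
  }
  if (cfg$hemi_rho < 0 || cfg$hemi_rho > 1) {
    stop_validation("hemi_rho must be in [0, 1]")
  }
  if (any(cfg$regions$cv <= 0) || any(cfg$regions$baseline <= 0)) {
    stop_validation("region baselines and cv must be > 0")
  }
  if (any(cfg$regions$effect_AD <= 0) || any(cfg$regions$effect_exposed <= 0)) {
    stop_validation("effects must be > 0")
  }
  if (cfg$icv$sd <= 0 || cfg$icv$mean <= 0) stop_validation("bad icv params")
  invisible(cfg)
}

draw_ages <- function(spec, n) {
  if (spec$dist == "uniform") {
    stats::runif(n, spec$min, spec$max)
  } else {
    x <- stats::rnorm(n, spec$mean, spec$sd)
    lo <- spec$min %||% -Inf; hi <- spec$max %||% Inf
    while (any(bad <- x < lo | x > hi)) {
      x[bad] <- stats::rnorm(sum(bad), spec$mean, spec$sd)
    }
    x
  }
}

# region x metric entries ranked by case-effect magnitude; used to pick the
# "affected profile" regions for exposed subjects with induced pathology
affected_region_set <- function(cfg, n_regions) {
  p <- cfg$regions
  p <- p[p$effect_AD != 1, ]
  p <- p[order(-abs(log(p$effect_AD))), ]
  if (n_regions > nrow(p)) {
    stop_validation("n_regions exceeds the number of case-affected entries")
  }
  out <- p[seq_len(n_regions), c("region", "metric", "effect_AD", "cv")]
  out$direction <- ifelse(out$effect_AD < 1, "atrophy", "dilation")
  out
}

#' Simulate the three cohorts
#'
#' Draws demographics, raw-scale morphometry (ICV-coupled volumes, bivariate
#' hemisphere noise at correlation `hemi_rho`, subfields as noisy fractions
#' of their simulated parent volume), family-wise missingness, and the
#' exposed cohort's neuropsychology block. A truth ledger records each
#' subject's severity multiplier, induced affected-region set, and every
#' cohort x region x metric true effect and direction.
#'
#' @param config a `cohort_sim_config` (see [default_cohort_config()]).
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @return list with elements `morphometry` (raw `morph_table`),
#'   `neuropsych` (data.frame for exposed subjects), and `truth`
#'   (list: `subjects`, `effects`, `affected_regions`).
#' @export
simulate_cohorts <- function(config = default_cohort_config(), seed = 1L) {
  validate_sim_config(config)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)

  ref_age <- config$reference_age
  icv_ref <- config$icv$mean
  subjects <- list(); truth_subj <- list()
  for (cname in names(config$cohorts)) {
    co <- config$cohorts[[cname]]
    n <- co$n
    ids <- sprintf("%s%03d", cname, seq_len(n))
    tags <- rep(names(co$tags), length.out = n,
                times = if (length(co$tags) > 1)
                  round(co$tags / sum(co$tags) * n) else n)
    icv <- stats::rnorm(n, config$icv$mean, config$icv$sd)
    icv <- pmax(icv, config$icv$mean / 2)
    sev <- if (!is.null(co$severity_sdlog)) {
      exp(stats::rnorm(n, 0, co$severity_sdlog))
    } else rep(1, n)
    aff <- rep(FALSE, n); n_aff_reg <- rep(0L, n)
    if (!is.null(co$affected)) {
      aff <- stats::runif(n) < co$affected$fraction
      n_aff_reg[aff] <- co$affected$n_regions
    }
    subjects[[cname]] <- data.frame(
      subject_id = ids, group = co$group,
      age = draw_ages(co$age, n),
      sex = if (cname == "exposed") "male"
            else sample(c("male", "female"), n, replace = TRUE),
      cohort_tag = tags[seq_len(n)], icv = icv, stringsAsFactors = FALSE)
    truth_subj[[cname]] <- data.frame(
      subject_id = ids, group = co$group, severity = sev, affected = aff,
      n_affected_regions = n_aff_reg, stringsAsFactors = FALSE)
  }
  subj <- do.call(rbind, subjects); rownames(subj) <- NULL
  tsub <- do.call(rbind, truth_subj); rownames(tsub) <- NULL

  params <- data.table::as.data.table(config$regions)
  # long frame: subject x region x metric (hemispheres handled as a pair)
  grid <- data.table::CJ(subject_id = subj$subject_id,
                         pkey = seq_len(nrow(params)), sorted = FALSE)
  d <- cbind(grid[, .(subject_id)], params[grid$pkey])
  si <- match(d$subject_id, subj$subject_id)
  d[, `:=`(group = subj$group[si], age = subj$age[si], icv = subj$icv[si],
           severity = tsub$severity[si], affected = tsub$affected[si])]

  d[, effect := data.table::fcase(
      group == "AD", effect_AD,
      group == "exposed", effect_exposed,
      default = 1)]
  # exposed severity scales the log-effect (heterogeneous pathology)
  d[group == "exposed", effect := exp(severity * log(effect))]

  # induced affected-profile shifts (exposed subjects flagged in the ledger)
  aff_set <- NULL
  aff_cfg <- config$cohorts$exposed$affected
  if (!is.null(aff_cfg)) {
    aff_set <- affected_region_set(config, aff_cfg$n_regions)
    akey <- paste(aff_set$region, aff_set$metric)
    dir <- ifelse(aff_set$direction == "atrophy", -1, 1)
    shift <- stats::setNames(1 + dir * aff_cfg$sd_shift * aff_set$cv, akey)
    dkey <- paste(d$region, d$metric)
    hit <- d$affected & dkey %in% akey
    d[hit, effect := effect * shift[paste(region, metric)]]
  }

  # expected value: group level plus a common (parallel-slope) age trend,
  # both scaled by relative head size for ICV-parent volumes
  is_fraction <- d$norm_parent %in% c("whole_hippocampus", "whole_amygdala")
  head_scale <- ifelse(d$metric == "volume" & !is_fraction,
                       d$icv / icv_ref, 1)
  d[, expected := head_scale * baseline *
      (effect + slope_frac * (age - ref_age))]

  # bivariate lognormal noise across hemispheres
  rho <- config$hemi_rho
  n_pairs <- nrow(d)
  z1 <- stats::rnorm(n_pairs); z2 <- stats::rnorm(n_pairs)
  reg <- build_default_registry()
  hemispheric <- reg$hemispheric[match(d$region, reg$name)]
  noise <- function(eta, cv) exp(cv * eta - cv^2 / 2)
  dl <- copy_with_hemi(d, ifelse(hemispheric, "left", "none"),
                       noise(z1, d$cv))
  dr <- copy_with_hemi(d[hemispheric], "right",
                       noise(rho * z1[hemispheric] +
                             sqrt(1 - rho^2) * z2[hemispheric],
                             d$cv[hemispheric]))
  long <- rbind(dl, dr)

  # subfields: value = fraction * same-side simulated parent volume
  parents <- long[region %in% c("Whole hippocampus", "Whole amygdala"),
                  .(subject_id, hemisphere,
                    parent = ifelse(region == "Whole hippocampus",
                                    "whole_hippocampus", "whole_amygdala"),
                    parent_value = value)]
  long <- merge(long, parents,
                by.x = c("subject_id", "hemisphere", "norm_parent"),
                by.y = c("subject_id", "hemisphere", "parent"),
                all.x = TRUE, sort = FALSE)
  long[!is.na(parent_value), value := value * parent_value]

  # family-wise missingness per subject
  for (cname in names(config$missingness)) {
    rates <- config$missingness[[cname]]
    grp <- config$cohorts[[cname]]$group
    ids <- subj$subject_id[subj$group == grp]
    for (fam in names(rates)) {
      drop_ids <- ids[stats::runif(length(ids)) < rates[[fam]]]
      long <- long[!(subject_id %in% drop_ids & category == fam)]
    }
  }

  meas <- data.table::setDF(
    long[order(subject_id, region, hemisphere, metric),
         .(subject_id, region, hemisphere, metric, value)])
  tab <- morph_table(subj, meas, provenance = "raw", validate = FALSE)

  neuro <- simulate_cognition(config, subj, tsub)

  effects <- data.table::setDF(data.table::rbindlist(lapply(
    c("control", "AD", "exposed"), function(g) {
      e <- if (g == "AD") params$effect_AD
           else if (g == "exposed") params$effect_exposed else 1
      data.table::data.table(
        group = g, region = params$region, metric = params$metric,
        effect = e,
        direction = data.table::fcase(e < 1, "atrophy", e > 1, "dilation",
                                      default = "none"))
    })))
  tsub$true_burden <- compute_burden(config, tsub)
  list(
    morphometry = tab,
    neuropsych = neuro,
    truth = list(subjects = tsub, effects = effects,
                 affected_regions = aff_set)
  )
}

copy_with_hemi <- function(d, hemi, noise_mult) {
  out <- d[, .(subject_id, region, metric, category, norm_parent)]
  out[, hemisphere := hemi]
  out[, value := d$expected * noise_mult]
  out
}

# continuous "true pathology burden" per subject: severity-weighted total
# exposed log-effect plus any induced affected-region count
compute_burden <- function(config, tsub) {
  p <- config$regions
  b_cohort <- sum(abs(log(p$effect_exposed)))
  burden <- ifelse(tsub$group == "exposed", tsub$severity * b_cohort, 0)
  burden + tsub$n_affected_regions
}

simulate_cognition <- function(config, subj, tsub) {
  cg <- config$cognition
  idx <- subj$group == "exposed"
  if (!any(idx)) return(NULL)
  ids <- subj$subject_id[idx]
  n <- length(ids)
  burden <- compute_burden(config, tsub)[match(ids, tsub$subject_id)]
  u <- if (n > 1 && stats::sd(burden) > 0) as.numeric(scale(burden))
       else rep(0, n)
  df <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (st in names(cg$r_targets)) {
    r <- abs(cg$r_targets[[st]])
    df[[st]] <- cg$anam_mean +
      cg$anam_sd * (-r * u + sqrt(1 - r^2) * stats::rnorm(n))
  }
  df$wrat_z <- stats::rnorm(n, cg$wrat_mean, cg$wrat_sd)
  miss <- stats::runif(n) < (cg$anam_missing_rate %||% 0)
  df[miss, names(cg$r_targets)] <- NA_real_
  assemble_neuropsych(df)
}

#' Write a simulation configuration as flat key-path text
#'
#' Human-editable `key.path<TAB>value` lines; the region parameter table is
#' written as an adjacent TSV block (documentation of the stated world, not
#' a round-trip format).
#'
#' @param config a `cohort_sim_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_config_tsv <- function(config, path) {
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(key, val) writeLines(paste(key, val, sep = "\t"), con)
  flat <- function(x, prefix) {
    for (nm in names(x)) {
      v <- x[[nm]]
      key <- paste(c(prefix, nm), collapse = ".")
      if (is.list(v)) flat(v, key)
      else if (is.null(v)) emit(key, "NULL")
      else if (length(v) > 1 && !is.null(names(v))) {
        for (vn in names(v)) emit(paste(key, vn, sep = "."), v[[vn]])
      } else emit(key, as.character(v))
    }
  }
  flat(config[setdiff(names(config), "regions")], character(0))
  writeLines("## regions", con)
  utils::write.table(config$regions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
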