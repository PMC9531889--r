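# Region registry: the parcellation inventory that every downstream stage
# validates against. 89 regions in four families: 34 cortical (thickness +
# volume), 23 subcortical, 22 hippocampal subfields, 10 amygdalar nuclei.

.cortical_regions <- c(
  "Bankssts", "Caudal anterior cingulate", "Caudal middle frontal", "Cuneus",
  "Entorhinal", "Fusiform", "Inferior parietal", "Inferior temporal",
  "Isthmus cingulate", "Lateral occipital", "Lateral orbitofrontal", "Lingual",
  "Medial orbitofrontal", "Middle temporal", "Parahippocampal", "Paracentral",
  "Pars opercularis", "Pars orbitalis", "Pars triangularis", "Pericalcarine",
  "Post-central", "Posterior cingulate", "Pre-central", "Pre-cuneus",
  "Rostral anterior cingulate", "Rostral middle frontal", "Superior frontal",
  "Superior parietal", "Superior temporal", "Supramarginal", "Frontal pole",
  "Temporal pole", "Transverse temporal", "Insula"
)

.subcortical_regions <- c(
  "Lateral-ventricle", "Inf-Lat-Vent", "Cerebellum white matter",
  "Cerebellum cortex", "Caudate", "Putamen", "Pallidum", "Hippocampus",
  "Amygdala", "Accumbens area", "Cortex", "Cerebral white matter",
  "Corpus callosum posterior", "Corpus callosum midposterior",
  "Corpus callosum central", "Corpus callosum midanterior",
  "Corpus callosum anterior", "Third ventricle", "Fourth ventricle", "CSF",
  "Brainstem", "Brain Seg Vol", "Total Gray Vol"
)

# Midline / whole-brain entries reported once per subject by FreeSurfer.
.nonhemispheric_regions <- c(
  "Corpus callosum posterior", "Corpus callosum midposterior",
  "Corpus callosum central", "Corpus callosum midanterior",
  "Corpus callosum anterior", "Third ventricle", "Fourth ventricle", "CSF",
  "Brainstem", "Brain Seg Vol", "Total Gray Vol"
)

.hippocampal_subfields <- c(
  "Hippocampal tail", "Subiculum body", "CA-1 body", "Subiculum head",
  "Hippocampal fissure", "Presubiculum head", "CA-1 head",
  "Pre-subiculum body", "Parasubiculum", "Molecular layer HP head",
  "Molecular layer HP body", "GC-ML-DG-head", "CA-3 body", "GC-ML-DG body",
  "CA-4 head", "CA-4 body", "Fimbria", "CA-3 head", "HATA",
  "Whole hippocampal body", "Whole hippocampal head", "Whole hippocampus"
)

.amygdalar_nuclei <- c(
  "Lateral nucleus", "Basal nucleus", "Accessory basal nucleus",
  "Anterior amygdaloid area", "Central nucleus", "Medial nucleus",
  "Cortical nucleus", "Cortical amygdaloid transition", "Paralaminar nucleus",
  "Whole amygdala"
)

# FreeSurfer spellings whose squashed form does not already collide with the
# canonical label.
.registry_aliases <- list(
  "Corpus callosum posterior"      = "CC_Posterior",
  "Corpus callosum midposterior"   = "CC_Mid_Posterior",
  "Corpus callosum central"        = "CC_Central",
  "Corpus callosum midanterior"    = "CC_Mid_Anterior",
  "Corpus callosum anterior"       = "CC_Anterior",
  "Third ventricle"                = "3rd-Ventricle",
  "Fourth ventricle"               = "4th-Ventricle",
  "Brainstem"                      = "Brain-Stem",
  "Cortex"                         = "CortexVol",
  "Cerebral white matter"          = "CerebralWhiteMatterVol",
  "Total Gray Vol"                 = "TotalGray",
  "Anterior amygdaloid area"       = "Anterior-amygdaloid-area-AAA",
  "Cortical amygdaloid transition" = "Corticoamygdaloid-transitio"
)

#' Build the default region registry
#'
#' Returns the full 89-region parcellation inventory used by the pipeline:
#' 34 cortical regions (measured as both thickness and volume, per
#' hemisphere), 23 subcortical structures, 22 hippocampal subfields and 10
#' amygdalar nuclei (volume only). Each descriptor records whether the region
#' is lateralized and which denominator its volume is normalized by
#' (intracranial volume, whole hippocampus, or whole amygdala).
#'
#' @return A `data.frame` of class `adf_registry` with columns `name`,
#'   `category`, `metrics` (comma-separated), `hemispheric` (logical),
#'   `norm_parent`, `aliases` (comma-separated, possibly empty).
#' @examples
#' reg <- build_default_registry()
#' table(reg$category)
#' @export
build_default_registry <- function() {
  mk <- function(names, category, metrics, hemispheric, norm_parent) {
    data.frame(
      name = names, category = category, metrics = metrics,
      hemispheric = hemispheric, norm_parent = norm_parent,
      stringsAsFactors = FALSE
    )
  }
  reg <- rbind(
    mk(.cortical_regions, "cortical", "thickness,volume", TRUE, "ICV"),
    mk(.subcortical_regions, "subcortical", "volume",
       !(.subcortical_regions %in% .nonhemispheric_regions), "ICV"),
    mk(.hippocampal_subfields, "hippocampal_subfield", "volume", TRUE,
       ifelse(.hippocampal_subfields == "Whole hippocampus",
              "ICV", "whole_hippocampus")),
    mk(.amygdalar_nuclei, "amygdalar_nucleus", "volume", TRUE,
       ifelse(.amygdalar_nuclei == "Whole amygdala", "ICV", "whole_amygdala"))
  )
  reg$aliases <- vapply(reg$name, function(n) {
    paste(.registry_aliases[[n]] %||% character(0), collapse = ",")
  }, character(1))
  rownames(reg) <- NULL
  stopifnot(!anyDuplicated(reg$name), !anyDuplicated(squash_label(reg$name)))
  class(reg) <- c("adf_registry", "data.frame")
  reg
}

registry_keys <- function(registry) {
  # squashed canonical names + aliases -> canonical name
  alias_lists <- strsplit(registry$aliases, ",", fixed = TRUE)
  keys <- c(squash_label(registry$name),
            squash_label(unlist(alias_lists)))
  vals <- c(registry$name,
            rep(registry$name, lengths(alias_lists)))
  keep <- nzchar(keys)
  stats::setNames(vals[keep], keys[keep])
}

#' Look up a region descriptor by (fuzzy-spelled) name
#'
#' Canonicalization is case-insensitive and ignores spaces, hyphens and
#' underscores, so `"CA-1 head"` and `"ca1_head"` resolve identically.
#' FreeSurfer stat-file spellings (e.g. `"CC_Posterior"`,
#' `"3rd-Ventricle"`) resolve through the shipped alias table.
#'
#' @param registry a registry from [build_default_registry()].
#' @param name a single region label.
#' @return A one-row `data.frame` (the descriptor).
#' @export
region_lookup <- function(registry, name) {
  stopifnot(is.character(name), length(name) == 1L)
  keys <- registry_keys(registry)
  hit <- keys[squash_label(name)]
  if (is.na(hit)) {
    d <- utils::adist(squash_label(name), names(keys))
    near <- unique(unname(keys[order(d)]))[seq_len(3)]
    stop_validation(sprintf(
      "unknown region '%s'; nearest candidates: %s",
      name, paste(near, collapse = ", ")
    ))
  }
  registry[registry$name == hit, , drop = FALSE]
}

# Vectorized canonicalization; returns NA for unknown labels.
canonical_region <- function(registry, names) {
  keys <- registry_keys(registry)
  unname(keys[squash_label(names)])
}

# Split a FreeSurfer-style label like "Left-Hippocampus" or
# "rh_entorhinal_thickness" into (label, hemisphere, metric-hint).
parse_fs_label <- function(label) {
  hemi <- "none"
  metric <- NA_character_
  x <- label
  if (grepl("^(Left[-_]|lh[-_.])", x, ignore.case = FALSE)) {
    hemi <- "left"; x <- sub("^(Left[-_]|lh[-_.])", "", x)
  } else if (grepl("^(Right[-_]|rh[-_.])", x)) {
    hemi <- "right"; x <- sub("^(Right[-_]|rh[-_.])", "", x)
  } else if (grepl("^lh", x) && grepl("Vol$", x)) {
    hemi <- "left"; x <- sub("^lh", "", x)
  } else if (grepl("^rh", x) && grepl("Vol$", x)) {
    hemi <- "right"; x <- sub("^rh", "", x)
  }
  if (grepl("_thickness$", x)) {
    metric <- "thickness"; x <- sub("_thickness$", "", x)
  } else if (grepl("_(volume|vol)$", x)) {
    metric <- "volume"; x <- sub("_(volume|vol)$", "", x)
  }
  list(label = x, hemisphere = hemi, metric = metric)
}

#' Write / read a registry as TSV
#'
#' @param registry a registry object.
#' @param path file path.
#' @return `read_registry_tsv` returns an `adf_registry`.
#' @export
write_registry_tsv <- function(registry, path) {
  utils::write.table(as.data.frame(registry), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_registry_tsv
#' @export
read_registry_tsv <- function(path) {
  reg <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  need <- c("name", "category", "metrics", "hemispheric", "norm_parent",
            "aliases")
  if (!all(need %in% names(reg))) {
    stop_validation("registry TSV missing required columns")
  }
  reg$aliases[is.na(reg$aliases)] <- ""
  reg$hemispheric <- as.logical(reg$hemispheric)
  class(reg) <- c("adf_registry", "data.frame")
  reg
}

# The set of measurable (region, hemisphere, metric) keys implied by a
# registry: cortical regions contribute thickness and volume per hemisphere.
registry_measurement_keys <- function(registry) {
  rows <- lapply(seq_len(nrow(registry)), function(i) {
    r <- registry[i, ]
    metrics <- strsplit(r$metrics, ",", fixed = TRUE)[[1]]
    hemis <- if (r$hemispheric) c("left", "right") else "none"
    expand.grid(region = r$name, hemisphere = hemis, metric = metrics,
                stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$region, out$hemisphere, out$metric), ]
}
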