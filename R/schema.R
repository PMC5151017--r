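#' Desikan-Killiany cortical parcellation labels (one hemisphere)
#'
#' The 34 cortical region labels of the Desikan-Killiany atlas in the row
#' order FreeSurfer writes them to `?h.aparc.stats`.
#'
#' @keywords internal
dk_region_names <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
  "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
  "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
  "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
  "postcentral", "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
  "temporalpole", "transversetemporal", "insula"
)

#' Subcortical segmentation structure labels
#'
#' The 45 structure labels of the `aseg.stats` volume table, in the row order
#' of the FreeSurfer 5.0 segmentation output. The list is pinned (versioned)
#' rather than inferred from input because later FreeSurfer releases emit a
#' different structure set.
#'
#' @keywords internal
aseg_structure_names <- c(
  "Left-Lateral-Ventricle", "Left-Inf-Lat-Vent",
  "Left-Cerebellum-White-Matter", "Left-Cerebellum-Cortex",
  "Left-Thalamus-Proper", "Left-Caudate", "Left-Putamen", "Left-Pallidum",
  "3rd-Ventricle", "4th-Ventricle", "Brain-Stem", "Left-Hippocampus",
  "Left-Amygdala", "CSF", "Left-Accumbens-area", "Left-VentralDC",
  "Left-vessel", "Left-choroid-plexus", "Right-Lateral-Ventricle",
  "Right-Inf-Lat-Vent", "Right-Cerebellum-White-Matter",
  "Right-Cerebellum-Cortex", "Right-Thalamus-Proper", "Right-Caudate",
  "Right-Putamen", "Right-Pallidum", "Right-Hippocampus", "Right-Amygdala",
  "Right-Accumbens-area", "Right-VentralDC", "Right-vessel",
  "Right-choroid-plexus", "5th-Ventricle", "WM-hypointensities",
  "Left-WM-hypointensities", "Right-WM-hypointensities",
  "non-WM-hypointensities", "Left-non-WM-hypointensities",
  "Right-non-WM-hypointensities", "Optic-Chiasm", "CC_Posterior",
  "CC_Mid_Posterior", "CC_Central", "CC_Mid_Anterior", "CC_Anterior"
)

#' Canonical morphometric feature schema
#'
#' Fixes the identity and order of the 113 morphometric features used
#' throughout the package: 68 cortical thickness features (34 Desikan-Killiany
#' regions per hemisphere, left then right, prefixed `lh_`/`rh_`) followed by
#' 45 subcortical/segmentation volumes. Fixing the order makes feature tables,
#' trained models and region reports column-compatible across runs.
#'
#' @return An object of class `feature_schema`: a list with
#'   `thickness_names` (length 68), `volume_names` (length 45) and
#'   `feature_names` (length 113, canonical order).
#' @examples
#' sch <- feature_schema()
#' length(sch$feature_names)
#' @export
feature_schema <- function() {
  thickness <- c(paste0("lh_", dk_region_names), paste0("rh_", dk_region_names))
  structure(
    list(
      thickness_names = thickness,
      volume_names = aseg_structure_names,
      feature_names = c(thickness, aseg_structure_names)
    ),
    class = "feature_schema"
  )
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("<feature_schema> ", length(x$thickness_names), " thickness + ",
      length(x$volume_names), " volume features\n", sep = "")
  invisible(x)
}

#' Diagnosis labels accepted throughout the package
#' @keywords internal
diagnosis_levels <- c("HC", "SCZ", "FEP")
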