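#' Regional morphometry feature registry
#'
#' The model operates on 57 bilaterally-averaged FreeSurfer-style measures:
#' 34 cortical thickness features (mm) and 23 subcortical/global volume
#' features (mm\eqn{^3}). Volumes (and the estimated intracranial volume,
#' `icv`) are on the mm\eqn{^3} scale and are normalised by ICV before
#' modelling; thickness features are not. The registry also records, per
#' feature, whether FreeSurfer reports it per hemisphere (`paired`), a coarse
#' lobe assignment used by the synthetic generator's block-correlation model,
#' plausible population mean/SD constants, and the default standardised
#' AD-vs-CTL effect used by [default_effect_profile()].
#'
#' Population means/SDs and effects are artifact-defined constants shipped as
#' a versioned fixture (`extdata/population_reference.tsv`); they are not
#' estimates from any real cohort.
#'
#' @return `feature_registry()` returns a data.frame with one row per feature
#'   and columns `feature`, `block` ("thickness"/"volume"), `paired`
#'   (logical), `lobe`, `pop_mean`, `pop_sd`, `effect_ad_vs_ctl`, in the
#'   canonical column order used throughout the package.
#' @export
feature_registry <- function() {
  reg <- .adindex_env$registry
  if (is.null(reg)) {
    path <- system.file("extdata", "population_reference.tsv",
                        package = "adindex", mustWork = TRUE)
    reg <- utils::read.delim(path, stringsAsFactors = FALSE)
    reg$paired <- as.logical(reg$paired)
    stopifnot(nrow(reg) == 57L, !anyDuplicated(reg$feature))
    .adindex_env$registry <- reg
  }
  reg
}

.adindex_env <- new.env(parent = emptyenv())

#' @rdname feature_registry
#' @param block optionally restrict to one block.
#' @return `feature_names()` returns the canonical character vector of
#'   feature names (57, or 34/23 when restricted to a block).
#' @export
feature_names <- function(block = c("all", "thickness", "volume")) {
  block <- match.arg(block)
  reg <- feature_registry()
  if (block == "all") reg$feature else reg$feature[reg$block == block]
}

#' @rdname feature_registry
#' @return `thickness_features()` / `volume_features()` return the 34
#'   thickness / 23 volume feature names.
#' @export
thickness_features <- function() feature_names("thickness")

#' @rdname feature_registry
#' @export
volume_features <- function() feature_names("volume")

# Meta columns a full cohort table may carry besides the features + icv.
.meta_columns <- c("subject_id", "timepoint", "dx", "mci_status", "apoe_e4",
                   "age", "mmse", "cdr_sob", "adas1")

.timepoints <- c("baseline", "m12")

#' The ten regions reported as most discriminative for AD vs CTL
#'
#' Medial-temporal and adjacent regions repeatedly found to dominate
#' AD-vs-control discrimination: hippocampus, entorhinal cortex, amygdala,
#' temporal pole, superior temporal gyrus, inferior lateral ventricle, middle
#' temporal gyrus, fusiform gyrus, inferior temporal gyrus and
#' parahippocampal gyrus. Used as the recovery target for importance-ranking
#' checks on synthetic cohorts.
#'
#' @return character vector of ten canonical feature names.
#' @export
medial_temporal_top10 <- function() {
  c("hippocampus", "entorhinal", "amygdala", "temporal_pole",
    "superior_temporal", "inferior_lateral_ventricle", "middle_temporal",
    "fusiform", "inferior_temporal", "parahippocampal")
}
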