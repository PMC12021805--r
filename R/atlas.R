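#' The bundled 96-region brain atlas
#'
#' The graph pipeline operates on a fixed parcellation of 96 regions of
#' interest: 80 cortical labels (AAL-style cerebral cortex plus cerebellar
#' cortex and vermis) and 16 subcortical labels (PD25-style basal ganglia
#' and brainstem nuclei).  The ordering is fixed; every feature table,
#' graph and report in a run shares it.
#'
#' @return A tibble with columns `index` (1-based integer), `name`
#'   (unique region label) and `system` (`"cortical"` or `"subcortical"`).
#' @examples
#' atlas <- default_atlas()
#' table(atlas$system)
#' @export
default_atlas <- function() {
  pairs <- c(
    "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
    "Frontal_Inf_Oper", "Frontal_Inf_Tri", "Frontal_Inf_Orb",
    "Rolandic_Oper", "Supp_Motor_Area", "Frontal_Sup_Medial",
    "Frontal_Med_Orb", "Rectus", "Insula", "Cingulum_Ant", "Cingulum_Mid",
    "Cingulum_Post", "Hippocampus", "ParaHippocampal", "Amygdala",
    "Calcarine", "Cuneus", "Lingual", "Occipital_Sup", "Occipital_Mid",
    "Occipital_Inf", "Fusiform", "Postcentral", "Parietal_Sup",
    "Parietal_Inf", "SupraMarginal", "Angular", "Precuneus",
    "Paracentral_Lobule", "Temporal_Sup", "Temporal_Pole_Sup",
    "Temporal_Mid", "Temporal_Inf",
    "Cerebelum_Crus1", "Cerebelum_VI"
  )
  cortical <- c(
    as.vector(t(outer(pairs, c("_L", "_R"), paste0))),
    "Vermis_VI", "Vermis_VIII"
  )
  sub_pairs <- c(
    "Caudate", "Putamen", "Pallidum_Ext", "Pallidum_Int", "Thalamus",
    "Subthalamic_Nucleus", "Substantia_Nigra", "Red_Nucleus"
  )
  subcortical <- as.vector(t(outer(sub_pairs, c("_L", "_R"), paste0)))
  tibble::tibble(
    index = seq_len(96L),
    name = c(cortical, subcortical),
    system = rep(c("cortical", "subcortical"), c(80L, 16L))
  )
}

validate_atlas <- function(atlas) {
  need <- c("index", "name", "system")
  if (!all(need %in% names(atlas))) {
    abort("atlas must have columns index, name, system")
  }
  if (nrow(atlas) != 96L) {
    abort(sprintf("atlas must have exactly 96 regions, got %d", nrow(atlas)))
  }
  if (!identical(as.integer(atlas$index), seq_len(96L))) {
    abort("atlas index must be 1..96 in order")
  }
  if (anyDuplicated(atlas$name)) abort("atlas region names must be unique")
  counts <- table(factor(atlas$system, c("cortical", "subcortical")))
  if (counts[["cortical"]] != 80L || counts[["subcortical"]] != 16L) {
    abort("atlas must contain 80 cortical and 16 subcortical regions")
  }
  invisible(atlas)
}

#' Read an atlas label table
#'
#' @param path TSV file with columns `index`, `name`, `system`.
#' @return A validated atlas tibble (see [default_atlas()]).
#' @export
read_atlas <- function(path) {
  atlas <- readr::read_tsv(path, col_types = readr::cols(
    index = readr::col_integer(),
    name = readr::col_character(),
    system = readr::col_character()
  ))
  validate_atlas(atlas)
  atlas
}

#' Write an atlas label table
#'
#' @param atlas atlas tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  validate_atlas(atlas)
  readr::write_tsv(atlas, path)
  invisible(path)
}
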