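# UK Biobank data-field identifiers for the five mental-health measures and
# the confound variables, used to bind column names to field IDs in the
# sidecar column map so synthetic tables and real UKB extracts share one
# code path.

rds4_fields <- c(
  rds_mood       = 2050, # frequency of depressed mood, last 2 weeks
  rds_disinterest = 2060,
  rds_restless   = 2070,
  rds_tired      = 2080
)

phq9_fields <- c(
  phq_interest = 20514, phq_down = 20510, phq_sleep = 20517,
  phq_tired = 20519, phq_appetite = 20511, phq_selfworth = 20507,
  phq_concentrate = 20508, phq_psychomotor = 20518, phq_death = 20513
)

gad7_fields <- c(
  gad_nervous = 20506, gad_uncontrollable = 20509, gad_worry = 20520,
  gad_relax = 20515, gad_restless = 20516, gad_irritable = 20505,
  gad_afraid = 20512
)

n12_fields <- c(
  n12_mood_swings = 1920, n12_miserable = 1930, n12_irritable = 1940,
  n12_sensitive = 1950, n12_fedup = 1960, n12_nervous = 1970,
  n12_worrier = 1980, n12_tense = 1990, n12_embarrassment = 2000,
  n12_nerves = 2010, n12_lonely = 2020, n12_guilt = 2030
)

depression_fields <- c(
  ever_depressed        = 4598,
  ever_disinterested    = 4631,
  dur_depressed_weeks   = 4609,
  dur_disinterest_weeks = 5375,
  seen_gp               = 2090,
  seen_psych            = 2100,
  age_first_episode     = 20433
)

#' Imaging modalities and their processing groups
#'
#' IDP columns carry one of eleven modality tags; modalities roll up into the
#' three processing groups used for separate PCA reduction (resting,
#' structural, task).
#'
#' @format A tibble with columns `modality` and `group`.
#' @export
idp_modalities <- function() {
  tibble::tibble(
    modality = c("amplitude", "full_edge", "partial_edge",
                 "volume", "area", "thickness", "fa", "md", "t2star", "wmh",
                 "task"),
    group = c(rep("resting", 3L), rep("structural", 7L), "task")
  )
}

#' Map modality tags to their PCA group
#'
#' @param modality Character vector of modality tags.
#' @return Character vector in `{resting, structural, task}`.
#' @export
modality_group <- function(modality) {
  tab <- idp_modalities()
  out <- tab$group[match(modality, tab$modality)]
  if (anyNA(out)) {
    abort(paste0("unknown modality tag(s): ",
                 paste(unique(modality[is.na(out)]), collapse = ", ")))
  }
  out
}

#' Retrieve the column map attached to a phenotype table
#'
#' The column map is a tibble binding each column name to its UKB data-field
#' ID, its role in the pipeline, and (for IDP columns) its modality tag.
#'
#' @param tbl A phenotype table produced by [simulate_cohort()] or read with
#'   [read_phenotypes()].
#' @return A tibble with columns `column`, `field_id`, `role`, `modality`.
#' @export
column_map <- function(tbl) {
  map <- attr(tbl, "column_map")
  if (is.null(map)) abort("table carries no column map attribute")
  map
}

idp_columns <- function(map, group = NULL) {
  map <- dplyr::filter(map, .data$role == "idp")
  if (!is.null(group)) {
    map <- dplyr::filter(map, modality_group(.data$modality) %in% !!group)
  }
  map
}
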