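#' Canonical schema order and naming
#'
#' The nine maladaptive schemas used throughout the package, in the fixed
#' canonical order of the schema classification rubric. All score vectors,
#' score columns (`s1..s9`) and result tables follow this order; the order is
#' normative while display names are cosmetic.
#'
#' @return Character vector of length 9 of snake_case schema identifiers.
#' @export
#' @examples
#' schema_names()
schema_names <- function() {
  c("attachment",
    "competence",
    "global_self_evaluation",
    "health",
    "power_control",
    "meta_cognition",
    "other_people",
    "hopelessness",
    "others_views_on_self")
}

#' @rdname schema_names
#' @return `schema_labels()` returns human-readable display labels.
#' @export
schema_labels <- function() {
  c("Attachment",
    "Competence",
    "Global self-evaluation",
    "Health",
    "Power and Control",
    "Meta-cognition",
    "Other people",
    "Hopelessness",
    "Others' views on self")
}

#' @rdname schema_names
#' @return `score_columns()` returns the nine score column names `s1..s9`.
#' @export
score_columns <- function() paste0("s", 1:9)

#' Mental-health scale identifiers
#'
#' The five participant-level outcome scales used by the schema-to-outcome
#' regressions: HDAS depression and anxiety subscales, the Beck Depression
#' Inventory, and the two Cognitive Distortions subscales.
#'
#' @return Character vector of length 5.
#' @export
scale_names <- function() {
  c("hdas_depression", "hdas_anxiety", "bdi",
    "cds_relatedness", "cds_achievement")
}

# number of schemas; used internally
N_SCHEMAS <- 9L

# valid categorical metadata values
RECORD_TYPES   <- c("closed", "open")
SCENARIO_TYPES <- c("interpersonal", "achievement")
EMOTIONS       <- c("sadness", "fear", "anger", "happiness")
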