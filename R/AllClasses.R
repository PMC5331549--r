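# Core S4 containers. Food records and portion methods are plain lists with
# constructor functions (they are row-level records, not containers); the
# database, session, submitted record, wizard and survey state are S4 with
# validity methods.

#' Mandatory nutrient fields tracked by every nutrient vector
#'
#' The seven quantities reported in dietary-assessment method comparisons
#' (weight of food, energy in kJ and kcal, carbohydrate, protein, fat,
#' vitamin C, iron). Composition tables may carry further nutrients; these
#' are always present.
#'
#' @export
NUTRIENT_FIELDS <- c("weight_g", "energy_kJ", "energy_kcal",
                     "carbohydrate_g", "protein_g", "fat_g",
                     "vitamin_C_mg", "iron_mg")

#' Indexed food database
#'
#' Holds food records, the per-100 g composition table, category
#' definitions, synonym sets used in search, and the wizard trigger terms.
#' Construct with [foodDatabase()], [loadFoodDb()] or [generateFoodDb()].
#'
#' @slot foods named list of food records (see [foodRecord()]), named by
#'   food code.
#' @slot composition data.frame keyed by `databank_code` with one column per
#'   nutrient (per 100 g).
#' @slot categories data.frame with columns `code`, `description`.
#' @slot synonymSets list of character vectors; terms within a set are
#'   treated as interchangeable during search.
#' @slot sandwichTriggers,saladTriggers character vectors of query tokens
#'   that surface the corresponding wizard at the top of the result list.
#' @export
setClass("FoodDatabase", representation(
  foods = "list",
  composition = "data.frame",
  categories = "data.frame",
  synonymSets = "list",
  sandwichTriggers = "character",
  saladTriggers = "character"
))

setValidity("FoodDatabase", function(object) {
  msgs <- character(0)
  codes <- vapply(object@foods, function(f) f$food_code %||% NA_character_,
                  character(1))
  if (anyNA(codes)) msgs <- c(msgs, "every food needs a food_code")
  if (anyDuplicated(codes))
    msgs <- c(msgs, paste("duplicate food codes:",
                          paste(unique(codes[duplicated(codes)]), collapse = ", ")))
  if (length(object@foods) && !identical(names(object@foods), unname(codes)))
    msgs <- c(msgs, "foods list must be named by food_code")
  if (!"databank_code" %in% names(object@composition))
    msgs <- c(msgs, "composition table needs a databank_code column")
  if (length(msgs)) msgs else TRUE
})

#' An in-progress multiple-pass recall session
#'
#' The evolving state of one respondent's 24-h recall: the meal list with
#' entries, the interview stage, the history of fired prompts, and the
#' prompt configuration. Sessions are value objects: every operation
#' returns an updated copy.
#'
#' @slot survey_id,user_id identifiers.
#' @slot stage one of MEAL_SETUP, FREE_ENTRY, MATCHING, PROMPTS,
#'   CUSTOM_QUESTIONS, REVIEW, SUBMITTED.
#' @slot meals list of meals (each `list(name, time, entries)`, time in
#'   minutes since midnight), kept sorted by time.
#' @slot fired list of fired prompt records (rule, key, answer summary).
#' @slot custom_answers named list of answers to end-of-recall questions.
#' @slot config prompt configuration, see [promptConfig()].
#' @slot db the [FoodDatabase-class] the session resolves against.
#' @slot start_time,submit_time numeric epoch seconds (submit_time is NA
#'   until submission).
#' @slot entry_seq internal counter for entry identifiers.
#' @export
setClass("RecallSession", representation(
  survey_id = "character",
  user_id = "character",
  stage = "character",
  meals = "list",
  fired = "list",
  custom_answers = "list",
  config = "list",
  db = "FoodDatabase",
  start_time = "numeric",
  submit_time = "numeric",
  entry_seq = "integer"
))

SESSION_STAGES <- c("MEAL_SETUP", "FREE_ENTRY", "MATCHING", "PROMPTS",
                    "CUSTOM_QUESTIONS", "REVIEW", "SUBMITTED")

setValidity("RecallSession", function(object) {
  msgs <- character(0)
  if (!object@stage %in% SESSION_STAGES)
    msgs <- c(msgs, paste("unknown stage", object@stage))
  times <- vapply(object@meals, function(m) m$time, numeric(1))
  if (is.unsorted(times)) msgs <- c(msgs, "meals must be sorted by time")
  if (any(times < 0 | times >= 1440)) msgs <- c(msgs, "meal time out of range")
  if (!is.na(object@submit_time) && object@submit_time < object@start_time)
    msgs <- c(msgs, "submit_time before start_time")
  if (length(msgs)) msgs else TRUE
})

#' An immutable submitted recall
#'
#' Produced by [reviewAndSubmit()]: entry-level weights, food codes and
#' nutrients, per-meal and per-day totals, and the completion time.
#'
#' @slot survey_id,user_id identifiers.
#' @slot start_time,submit_time numeric epoch seconds.
#' @slot completion_seconds submit minus start.
#' @slot entries data.frame, one row per food entry with identification,
#'   portion and nutrient columns.
#' @slot meal_totals data.frame of per-meal nutrient totals.
#' @slot day_total named numeric nutrient vector for the whole day.
#' @slot custom_answers named list.
#' @export
setClass("RecallRecord", representation(
  survey_id = "character",
  user_id = "character",
  start_time = "numeric",
  submit_time = "numeric",
  completion_seconds = "numeric",
  entries = "data.frame",
  meal_totals = "data.frame",
  day_total = "numeric",
  custom_answers = "list"
))

setValidity("RecallRecord", function(object) {
  if (object@completion_seconds < 0) "negative completion time" else TRUE
})

#' Guided-entry wizard state
#'
#' State machine decomposing a composite item (sandwich or salad) into
#' component foods. Sandwich stages run BREAD, SPREAD, MEAT_FISH,
#' CHEESE_DAIRY, EXTRA_FILLING (repeating), SAUCE_DRESSING, DONE; salad
#' stages run ITEMS (repeating), SAUCES, DONE.
#'
#' @slot kind "SANDWICH" or "SALAD".
#' @slot stage current stage name; "DONE" is absorbing.
#' @slot collected character vector of selected component food codes.
#' @slot extra_filling_rounds number of answers given at the repeating
#'   extra-filling (or salad items) stage.
#' @export
setClass("WizardState", representation(
  kind = "character",
  stage = "character",
  collected = "character",
  extra_filling_rounds = "integer"
))

SANDWICH_STAGES <- c("BREAD", "SPREAD", "MEAT_FISH", "CHEESE_DAIRY",
                     "EXTRA_FILLING", "SAUCE_DRESSING", "DONE")
SALAD_STAGES <- c("ITEMS", "SAUCES", "DONE")

setValidity("WizardState", function(object) {
  msgs <- character(0)
  if (!object@kind %in% c("SANDWICH", "SALAD"))
    msgs <- c(msgs, "kind must be SANDWICH or SALAD")
  stages <- if (identical(object@kind, "SANDWICH")) SANDWICH_STAGES else SALAD_STAGES
  if (!object@stage %in% stages)
    msgs <- c(msgs, paste("invalid stage", object@stage, "for", object@kind))
  if (object@extra_filling_rounds < 0) msgs <- c(msgs, "negative round count")
  if (length(msgs)) msgs else TRUE
})

#' Survey administration state
#'
#' Researcher-facing survey lifecycle: running/suspended/ended status, the
#' schedule window, and enrolled participant credentials (opaque strings).
#'
#' @slot survey_id identifier.
#' @slot status "RUNNING", "SUSPENDED" or "ENDED" (ENDED is absorbing).
#' @slot start_date,end_date Date; submissions are accepted only while
#'   RUNNING and within \code{[start_date, end_date]}.
#' @slot users data.frame with columns `username`, `password`.
#' @export
setClass("SurveyState", representation(
  survey_id = "character",
  status = "character",
  start_date = "Date",
  end_date = "Date",
  users = "data.frame"
))

setValidity("SurveyState", function(object) {
  msgs <- character(0)
  if (!object@status %in% c("RUNNING", "SUSPENDED", "ENDED"))
    msgs <- c(msgs, "unknown status")
  if (length(object@start_date) != 1L || length(object@end_date) != 1L ||
      object@start_date > object@end_date)
    msgs <- c(msgs, "start_date must not be after end_date")
  if (length(msgs)) msgs else TRUE
})
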