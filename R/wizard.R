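# Sandwich / salad guided entry. Decomposes a composite item into
# component foods so that nothing structural (notably the bread) can be
# omitted: entering "tuna sandwich" as a single food historically lost the
# bread, so the wizard walks through each component in a fixed order.

WIZARD_CATEGORIES <- list(
  SANDWICH = c(BREAD = "sandwich_bread", SPREAD = "sandwich_spread",
               MEAT_FISH = "sandwich_meat_fish",
               CHEESE_DAIRY = "sandwich_cheese_dairy",
               EXTRA_FILLING = "sandwich_extra",
               SAUCE_DRESSING = "sandwich_sauce"),
  SALAD = c(ITEMS = "salad_item", SAUCES = "salad_sauce"))

WIZARD_QUESTIONS <- list(
  SANDWICH = c(
    BREAD = "What kind of bread did you have in your sandwich?",
    SPREAD = "What kind of spread did you have in your sandwich?",
    MEAT_FISH = "What kind of meat or fish did you have in your sandwich?",
    CHEESE_DAIRY = "What kind of cheese or dairy product did you have in your sandwich?",
    EXTRA_FILLING = "What kind of extra filling did you have in your sandwich?",
    SAUCE_DRESSING = "What kind of sauce or dressing did you have in your sandwich?"),
  SALAD = c(
    ITEMS = "What items did you have in your salad?",
    SAUCES = "Did you have any sauces or dressings on your salad?"))

categoryFoods <- function(db, category_code) {
  names(db@foods)[vapply(db@foods, function(f)
    category_code %in% f$category_codes, logical(1))]
}

#' Start a guided-entry wizard
#'
#' Sandwich wizards begin at the mandatory BREAD stage; salad wizards at
#' the repeating ITEMS stage. The database must provide foods in every
#' component category of the requested kind.
#'
#' @param kind "SANDWICH" or "SALAD".
#' @param db a [FoodDatabase-class].
#' @return a [WizardState-class].
#' @export
startWizard <- function(kind, db) {
  kind <- match.arg(kind, c("SANDWICH", "SALAD"))
  cats <- WIZARD_CATEGORIES[[kind]]
  for (i in seq_along(cats))
    if (length(categoryFoods(db, cats[i])) == 0L)
      stopf("database has no foods in wizard component category '%s'", cats[i])
  new("WizardState", kind = kind, stage = names(cats)[1],
      collected = character(0), extra_filling_rounds = 0L)
}

#' Question text for the current wizard stage
#'
#' @param state a [WizardState-class] (not DONE).
#' @return the question string.
#' @export
wizardQuestion <- function(state) {
  if (state@stage == "DONE") stopf("wizard is complete")
  WIZARD_QUESTIONS[[state@kind]][[state@stage]]
}

#' Selectable foods for the current wizard stage
#'
#' @param state a [WizardState-class] (not DONE).
#' @param db the [FoodDatabase-class].
#' @return character vector of food codes in the stage's category.
#' @export
wizardOptions <- function(state, db) {
  if (state@stage == "DONE") stopf("wizard is complete")
  categoryFoods(db, WIZARD_CATEGORIES[[state@kind]][[state@stage]])
}

#' Advance a wizard with one answer
#'
#' Answers are a component food code, `"NONE_OF_THIS"` ("I didn't have
#' any" - allowed at every stage except the mandatory BREAD), or
#' `"NO_MORE"` at a repeating stage (sandwich EXTRA_FILLING, salad ITEMS)
#' to stop the loop. A food selection appends to the collected components;
#' repeating stages loop in place until `"NO_MORE"`. After the final
#' sauce/dressing stage the wizard is DONE (absorbing) and
#' [wizardComponents()] yields the component entries.
#'
#' @param state a [WizardState-class], not DONE.
#' @param answer a food code, "NONE_OF_THIS" or "NO_MORE".
#' @param db the [FoodDatabase-class] (used to check food selections).
#' @return the advanced [WizardState-class].
#' @export
advanceWizard <- function(state, answer, db) {
  if (state@stage == "DONE") stopf("wizard is complete; no further answers accepted")
  stages <- if (state@kind == "SANDWICH") SANDWICH_STAGES else SALAD_STAGES
  stage <- state@stage
  repeating <- stage %in% c("EXTRA_FILLING", "ITEMS")
  advance <- function(s) stages[match(s, stages) + 1L]
  if (identical(answer, "NONE_OF_THIS")) {
    if (stage == "BREAD")
      stopf("bread is a mandatory sandwich component and cannot be skipped")
    state@stage <- advance(stage)
    if (repeating)
      state@extra_filling_rounds <- state@extra_filling_rounds + 1L
  } else if (identical(answer, "NO_MORE")) {
    if (!repeating) stopf("NO_MORE only applies at a repeating stage")
    state@extra_filling_rounds <- state@extra_filling_rounds + 1L
    state@stage <- advance(stage)
  } else {
    options <- wizardOptions(state, db)
    if (!answer %in% options)
      stopf("'%s' is not a selectable food at stage %s", answer, stage)
    state@collected <- c(state@collected, answer)
    if (repeating) state@extra_filling_rounds <- state@extra_filling_rounds + 1L
    else state@stage <- advance(stage)
  }
  validObject(state)
  state
}

#' Components collected by a completed wizard
#'
#' @param state a DONE [WizardState-class].
#' @return character vector of component food codes (>= 1 bread for a
#'   sandwich, by construction).
#' @export
wizardComponents <- function(state) {
  if (state@stage != "DONE") stopf("wizard not complete")
  state@collected
}
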