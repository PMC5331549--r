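# Simulated respondents. Each respondent has a true day of intake drawn
# from meal templates, a degraded self-report script (class-specific
# omission, a systematic multiplicative portion-reporting bias), and a
# reference recall equal to the truth (modelling an interviewer able to
# elicit everything). Omitted associated items and drinks can be
# recovered when the engine's targeted prompts fire, with a configurable
# recovery probability - which is exactly the mechanism the prompts
# exist to exercise.

#' Respondent behaviour model
#'
#' @param omission_main,omission_drink,omission_condiment probabilities in
#'   \code{[0, 1]} that an item of that class is left out of the
#'   self-report.
#' @param portion_sdlog standard deviation (log scale) of the
#'   respondent-level multiplicative portion-reporting error; one factor
#'   is drawn per respondent and applied to all reported portions, so
#'   day-level intake ratios inherit this spread directly.
#' @param portion_bias systematic multiplicative reporting factor (1 =
#'   unbiased; 0.8 = systematic 20% under-reporting).
#' @param prompt_recovery probability that an omitted item is added when
#'   the matching targeted prompt (associated food / missing drink)
#'   fires.
#' @param meal_templates meal templates, see [defaultMealTemplates()].
#' @return a respondent-model list.
#' @export
respondentModel <- function(omission_main = 0.05, omission_drink = 0.15,
                            omission_condiment = 0.30,
                            portion_sdlog = 0.2, portion_bias = 1,
                            prompt_recovery = 0.8,
                            meal_templates = defaultMealTemplates()) {
  probs <- c(omission_main, omission_drink, omission_condiment,
             prompt_recovery)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (portion_sdlog < 0) stopf("portion_sdlog must be >= 0")
  if (portion_bias <= 0) stopf("portion_bias must be positive")
  list(omission = c(main = omission_main, drink = omission_drink,
                    condiment = omission_condiment),
       portion_sdlog = portion_sdlog, portion_bias = portion_bias,
       prompt_recovery = prompt_recovery,
       meal_templates = meal_templates)
}

#' Default meal templates for simulated respondents
#'
#' A typical three-meal day over the synthetic database: cereal with
#' milk, tea with sugar and buttered toast at breakfast; a tuna sandwich
#' (bread, tuna, butter) with cola at lunch; chips with chicken, ketchup
#' and orange juice in the evening. Condiments are associated-link
#' suggestions of their trigger foods, so omitting them is recoverable
#' through the associated-food prompts.
#'
#' @return list of meals, each `list(name, time, items)`; items carry
#'   `food_code`, `class` (main/drink/condiment) and, for condiments,
#'   the `trigger` food code.
#' @export
defaultMealTemplates <- function() {
  it <- function(code, class, trigger = NA_character_)
    list(food_code = code, class = class, trigger = trigger)
  list(
    list(name = "Breakfast", time = "08:00", items = list(
      it("STP2", "main"), it("DRK5", "drink"), it("DRK2", "drink"),
      it("SUG1", "condiment", "DRK2"),
      it("BRD1", "main"), it("SPR1", "condiment", "BRD1"))),
    list(name = "Lunch", time = "13:00", items = list(
      it("BRD2", "main"), it("MTF1", "main"),
      it("SPR1", "condiment", "BRD2"), it("DRK1", "drink"))),
    list(name = "Evening meal", time = "18:00", items = list(
      it("STP1", "main"), it("MTF3", "main"),
      it("SAU2", "condiment", "STP1"), it("DRK4", "drink"))))
}

# Sample a representable true portion answer for a method.
sampleTrueAnswer <- function(method) {
  switch(method$variant,
    AS_SERVED = portionAnswer("AS_SERVED",
      image_index = sample.int(length(method$image_weights_g), 1)),
    GUIDE = portionAnswer("GUIDE",
      object_index = sample.int(length(method$object_weights_g), 1),
      count = sample(1:2, 1)),
    DRINK_SCALE = portionAnswer("DRINK_SCALE",
      fill_fraction = stats::runif(1, 0.4, 1)),
    STANDARD = portionAnswer("STANDARD",
      unit_index = sample.int(nrow(method$units), 1),
      count = stats::runif(1, 0.5, 2.5)),
    stopf("unknown variant %s", method$variant))
}

# Closest representable answer to a target weight.
nearestAnswer <- function(method, target_g) {
  switch(method$variant,
    AS_SERVED = portionAnswer("AS_SERVED",
      image_index = which.min(abs(method$image_weights_g - target_g))),
    GUIDE = {
      best <- c(1, 1); best_err <- Inf
      for (oi in seq_along(method$object_weights_g))
        for (cc in 1:10) {
          err <- abs(method$object_weights_g[oi] * cc - target_g)
          if (err < best_err) { best <- c(oi, cc); best_err <- err }
        }
      portionAnswer("GUIDE", object_index = best[1], count = best[2])
    },
    DRINK_SCALE = portionAnswer("DRINK_SCALE",
      fill_fraction = min(1, max(
        0.01, target_g / (method$container_volume_ml * method$density_g_per_ml)))),
    STANDARD = portionAnswer("STANDARD", unit_index = 1L,
      count = target_g / method$units$unit_weight_g[1]),
    stopf("unknown variant %s", method$variant))
}

nutrientFields <- function(db) {
  unique(c("weight_g", setdiff(names(db@composition), "databank_code"),
           NUTRIENT_FIELDS))
}

#' Simulate one respondent
#'
#' Draws a true day from the model's meal templates, builds the degraded
#' self-report answer script (class-specific omission; all reported
#' portions scaled by one respondent-level lognormal factor and snapped
#' to the nearest representable portion answer), and the reference
#' recall, equal to the truth. Omitted condiments whose trigger food was
#' reported gain an accepting associated-food prompt response with
#' probability `prompt_recovery`; likewise an omitted drink that leaves
#' its meal drink-free gains an accepting missing-drink response.
#' Deterministic under `seed`.
#'
#' @param db the [FoodDatabase-class] (typically [generateFoodDb()]).
#' @param model a [respondentModel()].
#' @param seed integer seed.
#' @return list with `truth` (data.frame of true items and weights),
#'   `reference` (named day nutrient vector), and `script` (an
#'   [answerScript()] replayable with [runAnswerScript()]).
#' @export
simulateRespondent <- function(db, model, seed = 1L) {
  set.seed(seed)
  eps <- stats::rlnorm(1, log(model$portion_bias), model$portion_sdlog)

  truth_rows <- list(); items <- list(); responses <- list()
  true_vs <- list()
  fields <- nutrientFields(db)

  for (tm in model$meal_templates) {
    drawn <- lapply(tm$items, function(it) {
      f <- getFood(db, it$food_code)
      method <- f$portion_methods[[1]]
      ans <- sampleTrueAnswer(method)
      w <- resolvePortion(method, ans)
      omitted <- stats::runif(1) < model$omission[[it$class]]
      list(item = it, food = f, method = method, true_weight = w,
           omitted = omitted)
    })
    reported_codes <- vapply(
      drawn[!vapply(drawn, `[[`, logical(1), "omitted")],
      function(d) d$item$food_code, character(1))
    meal_has_reported_drink <- any(vapply(drawn, function(d)
      !d$omitted && d$food$is_drink, logical(1)))
    drink_response_added <- FALSE

    for (d in drawn) {
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        meal = tm$name, food_code = d$item$food_code,
        class = d$item$class, weight_g = d$true_weight)
      true_vs[[length(true_vs) + 1L]] <-
        foodNutrients(d$true_weight, compositionFor(db, d$item$food_code))
      target <- d$true_weight * eps
      if (!d$omitted) {
        items[[length(items) + 1L]] <- list(
          meal = tm$name, text = d$food$description,
          kind = if (d$food$is_drink) "drink" else "food",
          food_code = d$item$food_code, method_index = 1L,
          portion = nearestAnswer(d$method, target))
      } else if (d$item$class == "condiment" &&
                 !is.na(d$item$trigger) &&
                 d$item$trigger %in% reported_codes) {
        if (stats::runif(1) < model$prompt_recovery)
          responses[[length(responses) + 1L]] <- list(
            rule = "ASSOCIATED_FOOD", meal = tm$name,
            suggested_food_code = d$item$food_code, accept = TRUE,
            item = list(food_code = d$item$food_code, method_index = 1L,
                        portion = nearestAnswer(d$method, target)))
      } else if (d$item$class == "drink" && !meal_has_reported_drink) {
        # draw unconditionally so paired runs with different recovery
        # probabilities consume the same random stream
        u <- stats::runif(1)
        if (u < model$prompt_recovery && !drink_response_added) {
          responses[[length(responses) + 1L]] <- list(
            rule = "MISSING_DRINK", meal = tm$name, accept = TRUE,
            item = list(text = d$food$description,
                        food_code = d$item$food_code, method_index = 1L,
                        portion = nearestAnswer(d$method, target)))
          drink_response_added <- TRUE
        }
      }
    }
  }

  reference <- aggregateNutrients(true_vs, fields)
  meals <- lapply(model$meal_templates, function(tm)
    list(name = tm$name, time = tm$time))
  script <- answerScript(
    survey_id = "sim", user_id = sprintf("resp%06d", seed),
    meals = meals, items = items, prompt_responses = responses,
    duration_seconds = round(stats::runif(1, 500, 1100)),
    start_time = 0)
  list(truth = do.call(rbind, truth_rows), reference = reference,
       script = script)
}

#' Simulate a study arm and evaluate agreement
#'
#' Runs `n` seeded respondents through the full path - simulation,
#' scripted replay through the recall engine, submission, per-respondent
#' agreement ratio against the reference recall - and summarises the
#' ratios.
#'
#' @param db the [FoodDatabase-class].
#' @param model a [respondentModel()].
#' @param n number of respondents.
#' @param seed base seed; respondent i uses `seed + i`.
#' @return list with `ratios` (list of named ratio vectors), `records`
#'   (list of [RecallRecord-class]), `references`, and `summary` (from
#'   [summarizeRatios()]).
#' @export
simulateStudy <- function(db, model, n = 20L, seed = 1L) {
  fields <- nutrientFields(db)
  ratios <- vector("list", n); records <- vector("list", n)
  references <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- simulateRespondent(db, model, seed = seed + i)
    rec <- runAnswerScript(db, sim$script)
    ratios[[i]] <- agreementRatio(dayTotal(rec)[fields],
                                  sim$reference[fields])
    records[[i]] <- rec
    references[[i]] <- sim$reference
  }
  list(ratios = ratios, records = records, references = references,
       summary = summarizeRatios(ratios))
}
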