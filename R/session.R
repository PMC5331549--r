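# The multiple-pass recall engine. The respondent (or a scripted replay)
# first lists meals and free-text foods/drinks, then the engine drives a
# single uniform prompt loop: match each entry against the database,
# estimate its portion, then targeted rules (associated foods, missing
# drinks, meal-time gaps, a low-energy-day check), then any configured
# end-of-recall questions, then review and submission. Both interactive
# and scripted use drive exactly the same nextPrompt/answerPrompt loop.

#' Prompt configuration for a recall session
#'
#' @param energy_deficit_threshold_kcal positive; the day-energy check
#'   fires when the resolved day total is strictly below this. Default
#'   500 kcal.
#' @param gap_threshold_minutes positive; the meal-gap check fires for
#'   consecutive meals further apart than this. Default 180 min, which
#'   fires for the canonical 13:00 lunch / 18:00 dinner example.
#' @param custom_questions list of `list(id =, text =)` end-of-recall
#'   questions (e.g. "Did you eat as much yesterday as you would
#'   normally?").
#' @param predefined_meals data.frame with columns `name`, `time`
#'   ("HH:MM") instantiated at session start; the respondent can remove,
#'   add or re-time meals. Defaults to a six-slot day from breakfast to a
#'   late snack.
#' @return a prompt-config list.
#' @export
promptConfig <- function(energy_deficit_threshold_kcal = 500,
                         gap_threshold_minutes = 180,
                         custom_questions = list(),
                         predefined_meals = defaultMealList()) {
  if (!isCount(energy_deficit_threshold_kcal))
    stopf("energy_deficit_threshold_kcal must be positive")
  if (!isCount(gap_threshold_minutes))
    stopf("gap_threshold_minutes must be positive")
  predefined_meals <- as.data.frame(predefined_meals)
  if (nrow(predefined_meals))
    stopifnot(all(c("name", "time") %in% names(predefined_meals)))
  list(energy_deficit_threshold_kcal = energy_deficit_threshold_kcal,
       gap_threshold_minutes = gap_threshold_minutes,
       custom_questions = custom_questions,
       predefined_meals = predefined_meals)
}

#' Default predefined meal list
#'
#' Six meal slots spanning the day; purely a convention, fully
#' configurable via [promptConfig()].
#'
#' @return data.frame with columns `name`, `time`.
#' @export
defaultMealList <- function() {
  data.frame(
    name = c("Breakfast", "Mid-morning snack", "Lunch", "Afternoon snack",
             "Evening meal", "Late snack"),
    time = c("08:00", "10:30", "13:00", "15:30", "18:00", "21:00"))
}

newMeal <- function(name, time_min) list(name = name, time = time_min,
                                         entries = list())

#' Create a recall session
#'
#' Opens a session in the meal-setup stage with the configured predefined
#' meal list instantiated in chronological order.
#'
#' @param db a validated [FoodDatabase-class].
#' @param config a [promptConfig()].
#' @param survey_id,user_id identifiers.
#' @param now start time (POSIXct or epoch seconds); injectable so that
#'   completion times are testable.
#' @return a [RecallSession-class] in stage MEAL_SETUP.
#' @export
createSession <- function(db, config = promptConfig(), survey_id = "survey",
                          user_id = "user", now = Sys.time()) {
  meals <- list()
  pm <- config$predefined_meals
  if (nrow(pm)) {
    mins <- parseClock(pm$time)
    ord <- order(mins)
    meals <- lapply(ord, function(i) newMeal(pm$name[i], mins[i]))
  }
  new("RecallSession", survey_id = survey_id, user_id = user_id,
      stage = "MEAL_SETUP", meals = meals, fired = list(),
      custom_answers = list(), config = config, db = db,
      start_time = as.numeric(now), submit_time = NA_real_,
      entry_seq = 0L)
}

assertNotSubmitted <- function(session) {
  if (session@stage == "SUBMITTED")
    stopf("session already submitted")
}

findMeal <- function(session, name, time = NULL) {
  hits <- which(vapply(session@meals, function(m)
    identical(m$name, name) &&
      (is.null(time) || m$time == parseClock(time)), logical(1)))
  if (length(hits) == 0L) stopf("no such meal: %s", name)
  if (length(hits) > 1L)
    stopf("meal name '%s' is ambiguous; supply a time", name)
  hits
}

#' Edit the meal list
#'
#' Remove a predefined or added meal ("I did not have breakfast" removes
#' breakfast and discards its entries), add a meal at a time, or re-time
#' one. The list is kept sorted by time; duplicate (name, time) pairs are
#' rejected.
#'
#' @param session a [RecallSession-class] (not yet submitted).
#' @param action "add", "remove" or "retime".
#' @param name meal name.
#' @param time "HH:MM"; required for add/retime, disambiguates remove.
#' @return the updated session.
#' @export
editMeals <- function(session, action = c("add", "remove", "retime"),
                      name, time = NULL) {
  action <- match.arg(action)
  assertNotSubmitted(session)
  if (action == "add") {
    t <- parseClock(time)
    dup <- any(vapply(session@meals, function(m)
      identical(m$name, name) && m$time == t, logical(1)))
    if (dup) stopf("meal '%s' at %s already exists", name, time)
    if (!nzchar(trimws(name))) stopf("meal name must be non-empty")
    session@meals <- c(session@meals, list(newMeal(name, t)))
  } else if (action == "remove") {
    i <- findMeal(session, name, time)
    session@meals <- session@meals[-i]
  } else {
    i <- findMeal(session, name)
    session@meals[[i]]$time <- parseClock(time)
  }
  ord <- order(vapply(session@meals, function(m) m$time, numeric(1)))
  session@meals <- session@meals[ord]
  validObject(session)
  session
}

newEntry <- function(session, raw_text, kind, provenance,
                     matched_food_code = NULL) {
  session@entry_seq <- session@entry_seq + 1L
  entry <- list(id = session@entry_seq, raw_text = raw_text, kind = kind,
                matched_food_code = matched_food_code, missing_food = FALSE,
                method_index = NA_integer_, portion_answer = NULL,
                weight_g = NA_real_, skipped_portion = FALSE,
                provenance = provenance)
  list(session = session, entry = entry)
}

appendEntry <- function(session, meal_index, raw_text, kind, provenance,
                        matched_food_code = NULL) {
  made <- newEntry(session, raw_text, kind, provenance, matched_food_code)
  session <- made$session
  m <- session@meals[[meal_index]]
  m$entries <- c(m$entries, list(made$entry))
  session@meals[[meal_index]] <- m
  session
}

#' Add a free-text food or drink to a meal
#'
#' First-pass listing: the raw text is stored unmatched (provenance
#' USER_ENTERED); matching and portion estimation happen later through
#' the prompt loop. Food and drink entries are distinct kinds - a meal
#' holding at least one drink entry never triggers the missing-drink
#' question.
#'
#' @param session a [RecallSession-class].
#' @param meal meal name (optionally disambiguated with `time`).
#' @param text free text as entered; must be non-empty after
#'   normalization.
#' @param kind "food" or "drink".
#' @param time optional "HH:MM" disambiguator.
#' @return the updated session.
#' @export
addFreeTextItem <- function(session, meal, text, kind = c("food", "drink"),
                            time = NULL) {
  kind <- match.arg(kind)
  assertNotSubmitted(session)
  if (length(normalizeQuery(text)) == 0L)
    stopf("entry text is empty after normalization")
  i <- findMeal(session, meal, time)
  session <- appendEntry(session, i, text, kind, "USER_ENTERED")
  if (session@stage == "MEAL_SETUP") session@stage <- "FREE_ENTRY"
  session
}

#' Run a completed wizard into a meal
#'
#' Emits each collected component as its own entry with provenance
#' WIZARD_ADDED, already matched to its food code but still requiring
#' portion estimation through the prompt loop (sandwiches are stored as
#' their components, so nutrient totals are component sums).
#'
#' @param session a [RecallSession-class].
#' @param meal meal name.
#' @param state a DONE [WizardState-class].
#' @param time optional "HH:MM" disambiguator.
#' @return the updated session.
#' @export
addWizardResult <- function(session, meal, state, time = NULL) {
  assertNotSubmitted(session)
  comps <- wizardComponents(state)
  i <- findMeal(session, meal, time)
  for (code in comps) {
    f <- getFood(session@db, code)
    session <- appendEntry(session, i, f$description, "food",
                           "WIZARD_ADDED", matched_food_code = code)
  }
  if (session@stage == "MEAL_SETUP") session@stage <- "FREE_ENTRY"
  session
}

promptKey <- function(rule, target) paste(rule, target, sep = ":")

firedKeys <- function(session) vapply(session@fired, `[[`, character(1), "key")

makePrompt <- function(rule, target, text, meal = NULL, entry_id = NULL,
                       data = NULL) {
  structure(list(rule = rule, key = promptKey(rule, target), text = text,
                 meal = meal, entry_id = entry_id, data = data),
            class = "recallPrompt")
}

eachEntry <- function(session, fn) {
  for (mi in seq_along(session@meals)) {
    m <- session@meals[[mi]]
    for (ei in seq_along(m$entries)) {
      r <- fn(mi, ei, m, m$entries[[ei]])
      if (!is.null(r)) return(r)
    }
  }
  NULL
}

resolvedDayEnergyKcal <- function(session) {
  # NA when any non-missing entry is still unportioned
  total <- 0
  for (m in session@meals) for (e in m$entries) {
    if (e$missing_food) next
    if (is.na(e$weight_g)) {
      if (e$skipped_portion) next
      return(NA_real_)
    }
    comp <- compositionFor(session@db, e$matched_food_code)
    total <- total + unname(comp[["energy_kcal"]]) * e$weight_g / 100
  }
  total
}

#' Next pending prompt
#'
#' Pure inspection of the session state under a fixed priority order:
#' (1) unmatched entries need database matching; (2) matched entries need
#' a portion; (3) associated-food suggestions for matched trigger foods;
#' (4) the missing-drink question for meals with no drink entry; (5) the
#' meal-gap question for consecutive meals further apart than the
#' threshold; (6) the low-energy-day question, once, iff the fully
#' resolved day energy is strictly below the threshold; (7) configured
#' end-of-recall questions. Each (rule, target) pair fires at most once
#' per session; `NULL` when exhausted.
#'
#' @param session a [RecallSession-class] (not submitted).
#' @return a prompt (list with `rule`, `key`, `text`, ...) or `NULL`.
#' @export
nextPrompt <- function(session) {
  assertNotSubmitted(session)
  fired <- firedKeys(session)
  fresh <- function(p) if (p$key %in% fired) NULL else p
  db <- session@db

  p <- eachEntry(session, function(mi, ei, m, e) {
    if (is.null(e$matched_food_code) && !e$missing_food)
      fresh(makePrompt("MATCH_FOOD", e$id,
                       sprintf("Please match \"%s\" to a food in the list.", e$raw_text),
                       meal = m$name, entry_id = e$id))
  })
  if (!is.null(p)) return(p)

  p <- eachEntry(session, function(mi, ei, m, e) {
    if (!is.null(e$matched_food_code) && is.na(e$weight_g) &&
        !e$skipped_portion && !e$missing_food) {
      f <- getFood(db, e$matched_food_code)
      fresh(makePrompt("PORTION", e$id,
                       sprintf("How much %s did you have?", f$description),
                       meal = m$name, entry_id = e$id,
                       data = list(methods = f$portion_methods)))
    }
  })
  if (!is.null(p)) return(p)

  p <- eachEntry(session, function(mi, ei, m, e) {
    if (is.null(e$matched_food_code) || e$missing_food) return(NULL)
    links <- getFood(db, e$matched_food_code)$associated_foods
    for (li in seq_along(links)) {
      lk <- links[[li]]
      cand <- fresh(makePrompt(
        "ASSOCIATED_FOOD", paste(e$id, li, sep = "."), lk$prompt_text,
        meal = m$name, entry_id = e$id,
        data = list(suggested_food_code = lk$suggested_food_code)))
      if (!is.null(cand)) return(cand)
    }
    NULL
  })
  if (!is.null(p)) return(p)

  for (m in session@meals) {
    has_drink <- any(vapply(m$entries, function(e)
      identical(e$kind, "drink"), logical(1)))
    if (!has_drink) {
      p <- fresh(makePrompt(
        "MISSING_DRINK", paste(m$name, formatClock(m$time), sep = "@"),
        sprintf("Are you sure you did not have any drinks with %s?", m$name),
        meal = m$name))
      if (!is.null(p)) return(p)
    }
  }

  if (length(session@meals) > 1L) {
    for (i in seq_len(length(session@meals) - 1L)) {
      a <- session@meals[[i]]; b <- session@meals[[i + 1L]]
      if (b$time - a$time > session@config$gap_threshold_minutes) {
        p <- fresh(makePrompt(
          "TIME_GAP",
          paste0(a$name, "@", formatClock(a$time), "|",
                 b$name, "@", formatClock(b$time)),
          sprintf("Are you sure you didn't eat or drink anything between %s (%s) and %s (%s)?",
                  a$name, formatClock(a$time), b$name, formatClock(b$time)),
          data = list(from = a$name, to = b$name)))
        if (!is.null(p)) return(p)
      }
    }
  }

  kcal <- resolvedDayEnergyKcal(session)
  if (!is.na(kcal) && kcal < session@config$energy_deficit_threshold_kcal) {
    p <- fresh(makePrompt(
      "ENERGY_DEFICIT", "day",
      sprintf("Your day adds up to %.0f kcal, which seems low. Did you forget anything?", kcal)))
    if (!is.null(p)) return(p)
  }

  for (q in session@config$custom_questions) {
    p <- fresh(makePrompt("CUSTOM", q$id, q$text, data = list(question_id = q$id)))
    if (!is.null(p)) return(p)
  }

  NULL
}

#' Answer the current prompt
#'
#' `prompt` must be the current head of the queue (the value of
#' [nextPrompt()]). Answer shapes by rule:
#' \describe{
#'   \item{MATCH_FOOD}{`list(food_code =)` to match the entry, or
#'     `list(missing_food = TRUE)` to flag it for the missing-food
#'     function.}
#'   \item{PORTION}{`list(portion = portionAnswer(...), method_index =)`
#'     (method_index defaults to 1), or `list(skip = TRUE)` to leave the
#'     entry unresolved (submission will refuse it).}
#'   \item{ASSOCIATED_FOOD}{`list(accept = TRUE)` appends the suggested
#'     food to the meal with provenance PROMPT_ADDED (it then flows
#'     through portion estimation itself); `list(accept = FALSE)` records
#'     the decline and the prompt never re-fires.}
#'   \item{MISSING_DRINK}{`list(add = list(text =, kind = "drink",
#'     food_code = NULL))` appends a drink entry; `list(accept = FALSE)`
#'     declines.}
#'   \item{TIME_GAP}{`list(add_meal = list(name =, time =))` inserts a
#'     meal, or decline / empty acceptance consumes the prompt.}
#'   \item{ENERGY_DEFICIT}{decline or empty acceptance; any forgotten
#'     items are added with [addFreeTextItem()] afterwards.}
#'   \item{CUSTOM}{any value; stored under the question id.}
#' }
#'
#' @param session a [RecallSession-class].
#' @param prompt the current prompt from [nextPrompt()].
#' @param answer the answer, see above.
#' @return the updated session (the prompt moves to the fired history).
#' @export
answerPrompt <- function(session, prompt, answer = list()) {
  assertNotSubmitted(session)
  head <- nextPrompt(session)
  if (is.null(head) || !identical(head$key, prompt$key))
    stopf("prompt '%s' is not the current head of the queue", prompt$key)

  locateEntry <- function(id) {
    for (mi in seq_along(session@meals)) {
      eis <- which(vapply(session@meals[[mi]]$entries, function(e)
        e$id == id, logical(1)))
      if (length(eis)) return(c(mi, eis[1]))
    }
    stopf("entry %s not found", id)
  }
  updateEntry <- function(id, fn) {
    loc <- locateEntry(id)
    e <- session@meals[[loc[1]]]$entries[[loc[2]]]
    session@meals[[loc[1]]]$entries[[loc[2]]] <<- fn(e)
  }

  if (prompt$rule == "MATCH_FOOD") {
    if (isTRUE(answer$missing_food)) {
      updateEntry(prompt$entry_id, function(e) { e$missing_food <- TRUE; e })
    } else if (!is.null(answer$food_code)) {
      getFood(session@db, answer$food_code)  # errors on unknown code
      code <- answer$food_code
      updateEntry(prompt$entry_id, function(e) {
        e$matched_food_code <- code; e })
    } else stopf("MATCH_FOOD answer needs food_code or missing_food")
    session@stage <- "MATCHING"
  } else if (prompt$rule == "PORTION") {
    if (isTRUE(answer$skip)) {
      updateEntry(prompt$entry_id, function(e) { e$skipped_portion <- TRUE; e })
    } else {
      loc <- locateEntry(prompt$entry_id)
      e <- session@meals[[loc[1]]]$entries[[loc[2]]]
      f <- getFood(session@db, e$matched_food_code)
      mi <- answer$method_index %||% 1L
      if (mi > length(f$portion_methods)) stopf("method_index out of range")
      w <- resolvePortion(f$portion_methods[[mi]], answer$portion)
      updateEntry(prompt$entry_id, function(e) {
        e$method_index <- as.integer(mi)
        e$portion_answer <- answer$portion
        e$weight_g <- w
        e })
    }
    session@stage <- "MATCHING"
  } else if (prompt$rule == "ASSOCIATED_FOOD") {
    if (isTRUE(answer$accept)) {
      code <- prompt$data$suggested_food_code
      f <- getFood(session@db, code)
      loc <- locateEntry(prompt$entry_id)
      session <- appendEntry(session, loc[1], f$description,
                             if (f$is_drink) "drink" else "food",
                             "PROMPT_ADDED", matched_food_code = code)
    }
    session@stage <- "PROMPTS"
  } else if (prompt$rule == "MISSING_DRINK") {
    if (!is.null(answer$add)) {
      i <- findMeal(session, prompt$meal)
      session <- appendEntry(session, i, answer$add$text, "drink",
                             "PROMPT_ADDED",
                             matched_food_code = answer$add$food_code)
    }
    session@stage <- "PROMPTS"
  } else if (prompt$rule == "TIME_GAP") {
    if (!is.null(answer$add_meal))
      session <- editMeals(session, "add", answer$add_meal$name,
                           answer$add_meal$time)
    session@stage <- "PROMPTS"
  } else if (prompt$rule == "ENERGY_DEFICIT") {
    session@stage <- "PROMPTS"
  } else if (prompt$rule == "CUSTOM") {
    session@custom_answers[[prompt$data$question_id]] <- answer
    session@stage <- "CUSTOM_QUESTIONS"
  } else stopf("unknown prompt rule %s", prompt$rule)

  session@fired <- c(session@fired, list(list(
    rule = prompt$rule, key = prompt$key,
    declined = !(isTRUE(answer$accept) || !is.null(answer$add) ||
                   !is.null(answer$add_meal)))))
  session
}

entryNutrients <- function(db, entry, fields) {
  if (entry$missing_food || is.na(entry$weight_g))
    return(zeroNutrients(fields))
  v <- foodNutrients(entry$weight_g, compositionFor(db, entry$matched_food_code))
  aggregateNutrients(list(v), fields)
}

#' Review and submit a recall
#'
#' Requires the prompt queue to be exhausted and every entry either
#' matched and portioned or explicitly flagged through the missing-food
#' function; otherwise submission is refused naming the unresolved
#' entries. Produces an immutable [RecallRecord-class] with per-entry
#' weights and nutrients, per-meal and per-day totals and the completion
#' time; the session stage becomes SUBMITTED (in the returned record; the
#' session value passed in is unchanged, as sessions are value objects).
#'
#' @param session a [RecallSession-class].
#' @param now submission time (POSIXct or epoch seconds).
#' @return a [RecallRecord-class].
#' @export
reviewAndSubmit <- function(session, now = Sys.time()) {
  assertNotSubmitted(session)
  if (!is.null(p <- nextPrompt(session)))
    stopf("prompt queue not exhausted; next: %s", p$key)
  unresolved <- character(0)
  for (m in session@meals) for (e in m$entries) {
    if (e$missing_food) next
    if (is.null(e$matched_food_code) || is.na(e$weight_g))
      unresolved <- c(unresolved,
                      sprintf("%s: \"%s\" (entry %d)", m$name, e$raw_text, e$id))
  }
  if (length(unresolved))
    stopf("submission refused; unresolved entries: %s",
          paste(unresolved, collapse = "; "))

  db <- session@db
  comp_fields <- setdiff(names(db@composition), "databank_code")
  fields <- unique(c("weight_g", comp_fields, NUTRIENT_FIELDS))

  rows <- list(); meal_vs <- list()
  mealKey <- function(m) paste(m$name, m$time, sep = "@")
  for (m in session@meals) {
    entry_vs <- list()
    for (e in m$entries) {
      v <- entryNutrients(db, e, fields)
      entry_vs[[length(entry_vs) + 1L]] <- v
      f <- if (!is.null(e$matched_food_code)) getFood(db, e$matched_food_code)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(meal_name = m$name, meal_time = formatClock(m$time),
                   entry_id = e$id, raw_text = e$raw_text, kind = e$kind,
                   provenance = e$provenance,
                   food_code = e$matched_food_code %||% NA_character_,
                   missing_food = e$missing_food,
                   food_groups = if (is.null(f)) NA_character_
                     else paste(f$food_group_codes, collapse = ";"),
                   portion_method = if (is.null(f) || is.na(e$method_index))
                     NA_character_
                     else f$portion_methods[[e$method_index]]$variant,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(v)))
    }
    meal_vs[[mealKey(m)]] <- aggregateNutrients(entry_vs, fields)
  }
  entries <- if (length(rows)) do.call(rbind, rows) else
    cbind(data.frame(meal_name = character(0), meal_time = character(0),
                     entry_id = integer(0), raw_text = character(0),
                     kind = character(0), provenance = character(0),
                     food_code = character(0), missing_food = logical(0),
                     food_groups = character(0), portion_method = character(0)),
          as.data.frame(as.list(zeroNutrients(fields)))[0, , drop = FALSE])
  meal_totals <- if (length(session@meals)) cbind(
    data.frame(meal_name = vapply(session@meals, `[[`, character(1), "name"),
               meal_time = formatClock(vapply(session@meals, `[[`,
                                              numeric(1), "time"))),
    do.call(rbind, lapply(session@meals, function(m)
      as.data.frame(as.list(meal_vs[[mealKey(m)]])))))
  else cbind(data.frame(meal_name = character(0), meal_time = character(0)),
             as.data.frame(as.list(zeroNutrients(fields)))[0, , drop = FALSE])
  day_total <- aggregateNutrients(meal_vs, fields)
  submit <- as.numeric(now)
  new("RecallRecord", survey_id = session@survey_id,
      user_id = session@user_id, start_time = session@start_time,
      submit_time = submit,
      completion_seconds = submit - session@start_time,
      entries = entries, meal_totals = meal_totals, day_total = day_total,
      custom_answers = session@custom_answers)
}
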