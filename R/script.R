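# Scripted (non-interactive) recall replay. An answer script captures one
# respondent's whole interaction - meals, items with food codes and
# portion answers, wizard runs, and responses to targeted prompts - so
# the same engine code serves interactive use and batch simulation, and a
# given script always replays to the identical submitted record.

#' Build an answer script
#'
#' @param survey_id,user_id identifiers.
#' @param meals list of `list(name =, time = "HH:MM")`.
#' @param items list of scripted entries, each
#'   `list(meal =, text =, kind = "food"|"drink", food_code = NULL,
#'   method_index = 1, portion = portionAnswer(...))`; a `NULL` food_code
#'   flags the entry through the missing-food function. Optionally
#'   `wizard = list(kind =, answers = c(...))` instead of text/food_code
#'   (component portions then come from `component_portions`, a named
#'   list food_code -> list(method_index, portion)).
#' @param prompt_responses list of
#'   `list(rule =, meal = NULL, suggested_food_code = NULL, accept =,
#'   item = NULL)` consulted when targeted prompts fire; unmatched
#'   prompts are declined. An accepted response's `item` (same shape as
#'   in `items`) supplies the added entry.
#' @param custom_answers named list keyed by custom-question id.
#' @param duration_seconds completion time to record.
#' @param start_time epoch seconds of session start.
#' @return an answer-script list.
#' @export
answerScript <- function(survey_id = "survey", user_id = "user",
                         meals = list(), items = list(),
                         prompt_responses = list(),
                         custom_answers = list(),
                         duration_seconds = 780,
                         start_time = 0) {
  list(survey_id = survey_id, user_id = user_id, meals = meals,
       items = items, prompt_responses = prompt_responses,
       custom_answers = custom_answers,
       duration_seconds = duration_seconds, start_time = start_time)
}

#' Replay an answer script through the recall engine
#'
#' Creates a session whose meal list is the script's, adds every scripted
#' item (running wizards where scripted), then drives the
#' [nextPrompt()]/[answerPrompt()] loop to exhaustion, answering matching
#' and portion prompts from the script and targeted prompts from its
#' response table (default: decline), and finally submits. Deterministic:
#' identical script + database + config give an identical record.
#'
#' @param db a validated [FoodDatabase-class].
#' @param script an [answerScript()].
#' @param config a [promptConfig()]; its predefined meal list is replaced
#'   by the script's meals.
#' @return a [RecallRecord-class].
#' @export
runAnswerScript <- function(db, script, config = promptConfig()) {
  config$predefined_meals <- data.frame(
    name = vapply(script$meals, `[[`, character(1), "name"),
    time = vapply(script$meals, `[[`, character(1), "time"))
  session <- createSession(db, config, script$survey_id, script$user_id,
                           now = script$start_time %||% 0)

  # entry id -> scripted spec, for answering match/portion prompts
  specs <- new.env(parent = emptyenv())
  registerNew <- function(before, after, spec) {
    new_ids <- setdiff(allEntryIds(after), allEntryIds(before))
    for (id in new_ids) assign(as.character(id), spec, envir = specs)
    after
  }

  for (it in script$items) {
    before <- session
    if (!is.null(it$wizard)) {
      st <- startWizard(it$wizard$kind, db)
      for (a in it$wizard$answers) st <- advanceWizard(st, a, db)
      session <- addWizardResult(session, it$meal, st, time = it$time)
      # component portions looked up per food code
      for (id in setdiff(allEntryIds(session), allEntryIds(before))) {
        code <- entryById(session, id)$matched_food_code
        cp <- it$component_portions[[code]]
        if (is.null(cp)) stopf("no scripted portion for wizard component %s", code)
        assign(as.character(id), c(list(food_code = code), cp), envir = specs)
      }
    } else {
      session <- addFreeTextItem(session, it$meal, it$text,
                                 it$kind %||% "food", time = it$time)
      session <- registerNew(before, session, it)
    }
  }

  responses <- script$prompt_responses
  used <- logical(length(responses))
  findResponse <- function(p) {
    for (i in seq_along(responses)) {
      r <- responses[[i]]
      if (used[i] || !identical(r$rule, p$rule)) next
      if (!is.null(r$meal) && !identical(r$meal, p$meal)) next
      if (!is.null(r$suggested_food_code) &&
          !identical(r$suggested_food_code, p$data$suggested_food_code)) next
      used[i] <<- TRUE
      return(r)
    }
    NULL
  }

  guard <- 0L
  repeat {
    p <- nextPrompt(session)
    if (is.null(p)) break
    guard <- guard + 1L
    if (guard > 10000L) stopf("prompt loop did not terminate")
    ans <- switch(p$rule,
      MATCH_FOOD = {
        sp <- get0(as.character(p$entry_id), envir = specs)
        if (is.null(sp) || is.null(sp$food_code)) list(missing_food = TRUE)
        else list(food_code = sp$food_code)
      },
      PORTION = {
        sp <- get0(as.character(p$entry_id), envir = specs)
        if (is.null(sp) || is.null(sp$portion)) list(skip = FALSE,
          portion = NULL)  # caught below
        else list(portion = sp$portion, method_index = sp$method_index %||% 1L)
      },
      ASSOCIATED_FOOD = {
        r <- findResponse(p)
        if (is.null(r) || !isTRUE(r$accept)) list(accept = FALSE)
        else list(accept = TRUE)
      },
      MISSING_DRINK = {
        r <- findResponse(p)
        if (is.null(r) || !isTRUE(r$accept)) list(accept = FALSE)
        else list(add = list(text = r$item$text %||% r$item$food_code,
                             food_code = r$item$food_code))
      },
      TIME_GAP = {
        r <- findResponse(p)
        if (is.null(r) || !isTRUE(r$accept)) list(accept = FALSE)
        else list(add_meal = r$add_meal)
      },
      ENERGY_DEFICIT = list(accept = FALSE),
      CUSTOM = script$custom_answers[[p$data$question_id]] %||% "",
      stopf("unhandled prompt rule %s", p$rule))
    if (p$rule == "PORTION" && is.null(ans$portion))
      stopf("no scripted portion answer for entry %d (\"%s\")",
            p$entry_id, entryById(session, p$entry_id)$raw_text)
    before <- session
    session <- answerPrompt(session, p, ans)
    # entries added by accepted prompts take the response's item spec
    if (p$rule %in% c("ASSOCIATED_FOOD", "MISSING_DRINK")) {
      new_ids <- setdiff(allEntryIds(session), allEntryIds(before))
      for (id in new_ids) {
        code <- entryById(session, id)$matched_food_code
        spec <- promptItemSpec(responses, p, code)
        if (!is.null(spec)) assign(as.character(id), spec, envir = specs)
      }
    }
  }

  reviewAndSubmit(session,
                  now = (script$start_time %||% 0) +
                    (script$duration_seconds %||% 780))
}

allEntryIds <- function(session) {
  unlist(lapply(session@meals, function(m)
    vapply(m$entries, function(e) e$id, integer(1)))) %||% integer(0)
}

entryById <- function(session, id) {
  for (m in session@meals) for (e in m$entries) if (e$id == id) return(e)
  stopf("entry %d not found", id)
}

promptItemSpec <- function(responses, prompt, code) {
  for (r in responses) {
    if (!identical(r$rule, prompt$rule)) next
    if (!is.null(r$meal) && !identical(r$meal, prompt$meal)) next
    it <- r$item
    if (!is.null(it) && identical(it$food_code, code)) return(it)
    if (prompt$rule == "ASSOCIATED_FOOD" &&
        identical(r$suggested_food_code, code) && !is.null(it)) return(it)
  }
  NULL
}

#' Write / read answer scripts as JSON
#'
#' @param script an [answerScript()].
#' @param path file path.
#' @return `readAnswerScript` returns the script list.
#' @export
writeAnswerScript <- function(script, path) {
  strip <- function(x) {
    if (inherits(x, "portionAnswer"))
      return(Filter(Negate(is.null), unclass(x)))
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  jsonlite::write_json(strip(script), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeAnswerScript
#' @export
readAnswerScript <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  raw$items <- lapply(raw$items, function(it) {
    if (!is.null(it$portion)) it$portion <- rebuildAnswer(it$portion)
    if (!is.null(it$component_portions))
      it$component_portions <- lapply(it$component_portions, function(cp) {
        cp$portion <- rebuildAnswer(cp$portion); cp })
    if (!is.null(it$wizard)) it$wizard$answers <- unlist(it$wizard$answers)
    it
  })
  raw$prompt_responses <- lapply(raw$prompt_responses %||% list(), function(r) {
    if (!is.null(r$item) && !is.null(r$item$portion))
      r$item$portion <- rebuildAnswer(r$item$portion)
    r
  })
  raw
}

rebuildAnswer <- function(x) {
  portionAnswer(x$variant, image_index = x$image_index,
                object_index = x$object_index, count = x$count,
                fill_fraction = x$fill_fraction, unit_index = x$unit_index)
}
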