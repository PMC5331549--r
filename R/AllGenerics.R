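#' @name accessors
#' @title Accessors for recall objects
#' @description Extract components from submitted recall records and
#'   databases without touching slots directly.
#' @param x a [RecallRecord-class] or [FoodDatabase-class].
#' @return `dayTotal()` a named nutrient vector; `mealTotals()` and
#'   `recallEntries()` data.frames; `completionSeconds()` a number;
#'   `foodCodes()` a character vector; `getFood()` one food record.
NULL

#' @rdname accessors
#' @export
setGeneric("dayTotal", function(x) standardGeneric("dayTotal"))

#' @rdname accessors
#' @export
setGeneric("mealTotals", function(x) standardGeneric("mealTotals"))

#' @rdname accessors
#' @export
setGeneric("recallEntries", function(x) standardGeneric("recallEntries"))

#' @rdname accessors
#' @export
setGeneric("completionSeconds", function(x) standardGeneric("completionSeconds"))

#' @rdname accessors
#' @export
setGeneric("foodCodes", function(x) standardGeneric("foodCodes"))

#' @rdname accessors
#' @param code a food code present in the database.
#' @export
setGeneric("getFood", function(x, code) standardGeneric("getFood"))

#' @rdname accessors
#' @export
setMethod("dayTotal", "RecallRecord", function(x) x@day_total)

#' @rdname accessors
#' @export
setMethod("mealTotals", "RecallRecord", function(x) x@meal_totals)

#' @rdname accessors
#' @export
setMethod("recallEntries", "RecallRecord", function(x) x@entries)

#' @rdname accessors
#' @export
setMethod("completionSeconds", "RecallRecord", function(x) x@completion_seconds)

#' @rdname accessors
#' @export
setMethod("foodCodes", "FoodDatabase", function(x) names(x@foods))

#' @rdname accessors
#' @export
setMethod("getFood", "FoodDatabase", function(x, code) {
  f <- x@foods[[code]]
  if (is.null(f)) stopf("unknown food code: %s", code)
  f
})

setMethod("show", "FoodDatabase", function(object) {
  cat("FoodDatabase with", length(object@foods), "foods,",
      nrow(object@categories), "categories,",
      nrow(object@composition), "composition records\n")
  nd <- sum(vapply(object@foods, function(f) isTRUE(f$is_drink), logical(1)))
  cat("  drinks:", nd, " sandwich triggers:",
      paste(object@sandwichTriggers, collapse = "/"), "\n")
})

setMethod("show", "RecallSession", function(object) {
  ne <- sum(vapply(object@meals, function(m) length(m$entries), integer(1)))
  cat("RecallSession", object@survey_id, "/", object@user_id,
      "stage:", object@stage, "\n")
  cat(" ", length(object@meals), "meals,", ne, "entries,",
      length(object@fired), "prompts fired\n")
  for (m in object@meals)
    cat("  ", formatClock(m$time), m$name, "(", length(m$entries), "entries )\n")
})

setMethod("show", "RecallRecord", function(object) {
  cat("RecallRecord", object@survey_id, "/", object@user_id, "\n")
  cat(" ", nrow(object@entries), "entries over", nrow(object@meal_totals),
      "meals; completed in", round(object@completion_seconds), "s\n")
  cat("  day energy:", round(object@day_total[["energy_kcal"]], 1), "kcal (",
      round(object@day_total[["energy_kJ"]], 1), "kJ )\n")
})

setMethod("show", "WizardState", function(object) {
  cat("WizardState", object@kind, "stage:", object@stage, "collected:",
      if (length(object@collected)) paste(object@collected, collapse = ", ")
      else "(none)", "\n")
})

setMethod("show", "SurveyState", function(object) {
  cat("SurveyState", object@survey_id, object@status,
      format(object@start_date), "to", format(object@end_date),
      "-", nrow(object@users), "users\n")
})
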