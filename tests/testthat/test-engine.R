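mkSession <- function(meals = data.frame(
                        name = c("Lunch", "Evening meal"),
                        time = c("13:00", "18:00")), ...) {
  createSession(testDb(), promptConfig(predefined_meals = meals, ...),
                survey_id = "t", user_id = "u", now = 0)
}

test_that("sessions start in meal setup with the predefined list in time order", {
  s <- createSession(testDb(), promptConfig(), now = 0)
  expect_identical(s@stage, "MEAL_SETUP")
  nm <- vapply(s@meals, `[[`, character(1), "name")
  expect_identical(nm[1], "Breakfast")
  expect_identical(nm[3], "Lunch")
  expect_true(!is.unsorted(vapply(s@meals, `[[`, numeric(1), "time")))
  # empty predefined list is valid
  s0 <- mkSession(meals = data.frame(name = character(0), time = character(0)))
  expect_length(s0@meals, 0L)
  expect_error(promptConfig(gap_threshold_minutes = 0), "positive")
  expect_error(promptConfig(energy_deficit_threshold_kcal = -1), "positive")
})

test_that("meal edits remove, insert in order, and invert cleanly", {
  s <- createSession(testDb(), promptConfig(), now = 0)
  s2 <- editMeals(s, "remove", "Breakfast")
  expect_false("Breakfast" %in% vapply(s2@meals, `[[`, character(1), "name"))
  s3 <- editMeals(s2, "add", "Snack or drink", "16:00")
  nm <- vapply(s3@meals, `[[`, character(1), "name")
  t <- vapply(s3@meals, `[[`, numeric(1), "time")
  i <- match("Snack or drink", nm)
  expect_true(t[i - 1] < t[i] && t[i] < t[i + 1])
  s4 <- editMeals(s3, "remove", "Snack or drink")
  expect_equal(s4@meals, s2@meals)
  expect_error(editMeals(s, "remove", "Elevenses"), "no such meal")
  expect_error(editMeals(s3, "add", "Snack or drink", "16:00"),
               "already exists")
})

test_that("free-text entries append unmatched with user provenance", {
  s <- mkSession()
  s <- addFreeTextItem(s, "Lunch", "tuna sandwich", "food")
  e <- s@meals[[1]]$entries[[1]]
  expect_identical(e$provenance, "USER_ENTERED")
  expect_null(e$matched_food_code)
  expect_error(addFreeTextItem(s, "Lunch", "   ", "food"), "empty")
  expect_error(addFreeTextItem(s, "Elevenses", "toast", "food"), "no such meal")
})

test_that("the prompt queue follows the documented priority order", {
  s <- mkSession()
  s <- addFreeTextItem(s, "Lunch", "chips", "food")
  p1 <- nextPrompt(s)
  expect_identical(p1$rule, "MATCH_FOOD")
  s <- answerPrompt(s, p1, list(food_code = "STP1"))
  p2 <- nextPrompt(s)
  expect_identical(p2$rule, "PORTION")
  s <- answerPrompt(s, p2, list(portion = portionAnswer("AS_SERVED",
                                                        image_index = 4)))
  p3 <- nextPrompt(s)
  expect_identical(p3$rule, "ASSOCIATED_FOOD")  # ketchup with chips
  expect_identical(p3$data$suggested_food_code, "SAU2")
  s <- answerPrompt(s, p3, list(accept = FALSE))
  p4 <- nextPrompt(s)
  expect_identical(p4$rule, "MISSING_DRINK")
  expect_identical(p4$meal, "Lunch")
})

test_that("the gap prompt fires for 13:00/18:00 at the default threshold and respects the boundary", {
  s <- mkSession()
  s <- addFreeTextItem(s, "Lunch", "cola", "drink")
  p <- nextPrompt(s)
  s <- answerPrompt(s, p, list(food_code = "DRK1"))
  p <- nextPrompt(s)
  s <- answerPrompt(s, p, list(portion = portionAnswer("DRINK_SCALE",
                                                       fill_fraction = 1)))
  # walk past the missing-drink prompt for the evening meal
  repeat {
    p <- nextPrompt(s)
    if (is.null(p) || p$rule == "TIME_GAP") break
    s <- answerPrompt(s, p, list(accept = FALSE))
  }
  expect_identical(p$rule, "TIME_GAP")
  expect_match(p$text, "Lunch \\(13:00\\) and Evening meal \\(18:00\\)")
  # a 180-minute gap does not exceed the 180-minute threshold
  s2 <- mkSession(meals = data.frame(name = c("Lunch", "Snack"),
                                     time = c("13:00", "16:00")))
  s2 <- addFreeTextItem(s2, "Lunch", "cola", "drink")
  rules <- character(0)
  repeat {
    p <- nextPrompt(s2)
    if (is.null(p)) break
    rules <- c(rules, p$rule)
    s2 <- answerPrompt(s2, p, if (p$rule == "MATCH_FOOD")
      list(food_code = "DRK1") else if (p$rule == "PORTION")
      list(portion = portionAnswer("DRINK_SCALE", fill_fraction = 1))
      else list(accept = FALSE))
  }
  expect_false("TIME_GAP" %in% rules)
})

test_that("the energy-deficit prompt fires strictly below the threshold only", {
  # one cola at full fill: 343.2 g x 42 kcal/100 g = 144.1 kcal < 500
  runDay <- function(fill, threshold = 500) {
    s <- mkSession(meals = data.frame(name = "Lunch", time = "13:00"))
    s@config$energy_deficit_threshold_kcal <- threshold
    s <- addFreeTextItem(s, "Lunch", "cola", "drink")
    fired <- character(0)
    repeat {
      p <- nextPrompt(s)
      if (is.null(p)) break
      fired <- c(fired, p$rule)
      s <- answerPrompt(s, p, switch(p$rule,
        MATCH_FOOD = list(food_code = "DRK1"),
        PORTION = list(portion = portionAnswer("DRINK_SCALE",
                                               fill_fraction = fill)),
        list(accept = FALSE)))
    }
    fired
  }
  expect_true("ENERGY_DEFICIT" %in% runDay(1))
  # day energy exactly at the threshold: does not fire (strict <)
  kcal_full <- 330 * 1.04 * 42 / 100
  expect_false("ENERGY_DEFICIT" %in% runDay(1, threshold = kcal_full))
  # just above the day's energy: fires
  expect_true("ENERGY_DEFICIT" %in% runDay(1, threshold = kcal_full + 0.01))
})

test_that("missing-drink soundness: fires iff the meal has no drink entry", {
  s <- mkSession(meals = data.frame(name = "Lunch", time = "13:00"))
  s <- addFreeTextItem(s, "Lunch", "cola", "drink")
  p <- nextPrompt(s); s <- answerPrompt(s, p, list(food_code = "DRK1"))
  p <- nextPrompt(s)
  s <- answerPrompt(s, p, list(portion = portionAnswer("DRINK_SCALE",
                                                       fill_fraction = 0.5)))
  rules <- character(0)
  repeat {
    p <- nextPrompt(s); if (is.null(p)) break
    rules <- c(rules, p$rule); s <- answerPrompt(s, p, list(accept = FALSE))
  }
  expect_false("MISSING_DRINK" %in% rules)
})

test_that("accepting prompts appends entries; declines are final (prompt-once)", {
  s <- mkSession(meals = data.frame(name = "Lunch", time = "13:00"))
  s <- addFreeTextItem(s, "Lunch", "toast", "food")
  p <- nextPrompt(s); s <- answerPrompt(s, p, list(food_code = "BRD1"))
  p <- nextPrompt(s)
  s <- answerPrompt(s, p, list(portion = portionAnswer("GUIDE",
                                                       object_index = 2,
                                                       count = 1)))
  p <- nextPrompt(s)
  expect_identical(p$rule, "ASSOCIATED_FOOD")  # butter on bread
  s <- answerPrompt(s, p, list(accept = TRUE))
  added <- s@meals[[1]]$entries[[2]]
  expect_identical(added$matched_food_code, "SPR1")
  expect_identical(added$provenance, "PROMPT_ADDED")
  # the butter entry now needs its own portion
  p <- nextPrompt(s)
  expect_identical(p$rule, "PORTION")
  s <- answerPrompt(s, p, list(portion = portionAnswer("STANDARD",
                                                       unit_index = 2,
                                                       count = 1)))
  # decline the missing drink prompt; it never re-fires
  p <- nextPrompt(s)
  expect_identical(p$rule, "MISSING_DRINK")
  s <- answerPrompt(s, p, list(accept = FALSE))
  remaining <- character(0)
  repeat {
    p <- nextPrompt(s); if (is.null(p)) break
    remaining <- c(remaining, p$rule); s <- answerPrompt(s, p, list(accept = FALSE))
  }
  expect_false("MISSING_DRINK" %in% remaining)
  keys <- vapply(s@fired, `[[`, character(1), "key")
  expect_identical(anyDuplicated(keys), 0L)
  expect_error(answerPrompt(s, list(key = "MISSING_DRINK:Lunch@13:00"),
                            list(accept = FALSE)), "not the current head")
})

test_that("submission requires a resolved session and is idempotent-guarded", {
  s <- mkSession(meals = data.frame(name = "Lunch", time = "13:00"))
  s <- addFreeTextItem(s, "Lunch", "chips", "food")
  expect_error(reviewAndSubmit(s, now = 100), "not exhausted")
  repeat {
    p <- nextPrompt(s); if (is.null(p)) break
    s <- answerPrompt(s, p, switch(p$rule,
      MATCH_FOOD = list(food_code = "STP1"),
      PORTION = list(skip = TRUE),
      list(accept = FALSE)))
  }
  # portion was skipped: refusal names the entry
  expect_error(reviewAndSubmit(s, now = 100), "chips")
  s@meals[[1]]$entries[[1]]$weight_g <- 165
  rec <- reviewAndSubmit(s, now = 100)
  expect_s4_class(rec, "RecallRecord")
  expect_equal(completionSeconds(rec), 100)
  submitted <- s; submitted@stage <- "SUBMITTED"
  expect_error(nextPrompt(submitted), "already submitted")
  expect_error(reviewAndSubmit(submitted, now = 200), "already submitted")
})

test_that("replay of the same script is deterministic and totals are conserved", {
  db <- testDb()
  r1 <- runAnswerScript(db, dayAScript())
  r2 <- runAnswerScript(db, dayAScript())
  expect_equal(recallEntries(r1), recallEntries(r2))
  expect_equal(dayTotal(r1), dayTotal(r2))
  # conservation: day = sum of meals = sum of entries
  mt <- mealTotals(r1)
  fields <- intersect(names(dayTotal(r1)), names(mt))
  for (f in fields) {
    expect_equal(sum(mt[[f]]), unname(dayTotal(r1)[[f]]), tolerance = 1e-9)
    expect_equal(sum(recallEntries(r1)[[f]]), unname(dayTotal(r1)[[f]]),
                 tolerance = 1e-9)
  }
})

test_that("answer scripts survive a JSON round trip and replay identically", {
  db <- testDb()
  path <- withr::local_tempfile(fileext = ".json")
  writeAnswerScript(dayAScript(), path)
  script2 <- readAnswerScript(path)
  r1 <- runAnswerScript(db, dayAScript())
  r2 <- runAnswerScript(db, script2)
  expect_equal(dayTotal(r2), dayTotal(r1), tolerance = 1e-12)
})
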