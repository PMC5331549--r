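test_that("a full sandwich path visits all six question stages and collects each selection", {
  db <- testDb()
  st <- startWizard("SANDWICH", db)
  stages <- st@stage
  answers <- list("BRD2", "SPR1", "MTF1", "NONE_OF_THIS", "EXT1", "NO_MORE",
                  "SAU1")
  for (a in answers) {
    st <- advanceWizard(st, a, db)
    stages <- c(stages, st@stage)
  }
  expect_identical(st@stage, "DONE")
  visited <- setdiff(unique(stages), "DONE")
  expect_setequal(visited, c("BREAD", "SPREAD", "MEAT_FISH", "CHEESE_DAIRY",
                             "EXTRA_FILLING", "SAUCE_DRESSING"))
  expect_length(visited, 6L)
  expect_identical(wizardComponents(st), c("BRD2", "SPR1", "MTF1", "EXT1",
                                           "SAU1"))
})

test_that("bread cannot be skipped, so every sandwich contains bread", {
  db <- testDb()
  st <- startWizard("SANDWICH", db)
  expect_error(advanceWizard(st, "NONE_OF_THIS", db), "mandatory")
  expect_error(advanceWizard(st, "NO_MORE", db), "repeating")
  # minimal path: everything declined after bread
  st <- advanceWizard(st, "BRD1", db)
  for (a in c("NONE_OF_THIS", "NONE_OF_THIS", "NONE_OF_THIS", "NO_MORE",
              "NONE_OF_THIS"))
    st <- advanceWizard(st, a, db)
  expect_identical(st@stage, "DONE")
  expect_identical(wizardComponents(st), "BRD1")
})

test_that("the extra-filling stage loops and counts its rounds", {
  db <- testDb()
  st <- startWizard("SANDWICH", db)
  for (a in c("BRD1", "SPR1", "NONE_OF_THIS", "NONE_OF_THIS"))
    st <- advanceWizard(st, a, db)
  expect_identical(st@stage, "EXTRA_FILLING")
  for (a in c("EXT1", "EXT2", "EXT3")) st <- advanceWizard(st, a, db)
  expect_identical(st@stage, "EXTRA_FILLING")
  st <- advanceWizard(st, "NO_MORE", db)
  expect_identical(st@extra_filling_rounds, 4L)
  expect_identical(st@stage, "SAUCE_DRESSING")
  expect_length(grep("^EXT", st@collected), 3L)
})

test_that("salad wizard loops items then asks about sauces", {
  db <- testDb()
  st <- startWizard("SALAD", db)
  expect_identical(st@stage, "ITEMS")
  expect_match(wizardQuestion(st), "What items did you have in your salad")
  for (a in c("EXT3", "SLD1", "SLD2", "NO_MORE")) st <- advanceWizard(st, a, db)
  expect_identical(st@stage, "SAUCES")
  st <- advanceWizard(st, "SAU3", db)
  expect_identical(st@stage, "DONE")
  expect_identical(wizardComponents(st), c("EXT3", "SLD1", "SLD2", "SAU3"))
  expect_error(advanceWizard(st, "SAU1", db), "complete")
})

test_that("wizard errors on invalid selections and incomplete databases", {
  db <- testDb()
  st <- startWizard("SANDWICH", db)
  expect_error(advanceWizard(st, "DRK1", db), "not a selectable food")
  nobread <- foodDatabase(
    Filter(function(f) !"sandwich_bread" %in% f$category_codes, db@foods),
    db@composition, db@categories)
  expect_error(startWizard("SANDWICH", nobread), "sandwich_bread")
})

test_that("random valid answer sequences always terminate", {
  db <- testDb()
  set.seed(13)
  for (rep in 1:20) {
    st <- startWizard(sample(c("SANDWICH", "SALAD"), 1), db)
    steps <- 0L
    while (st@stage != "DONE") {
      steps <- steps + 1L
      expect_lt(steps, 60L)
      opts <- wizardOptions(st, db)
      repeating <- st@stage %in% c("EXTRA_FILLING", "ITEMS")
      # bound the loops: force NO_MORE once a repeating stage has run 3 rounds
      choices <- c(opts,
                   if (st@stage != "BREAD") "NONE_OF_THIS",
                   if (repeating) "NO_MORE")
      a <- if (repeating && st@extra_filling_rounds >= 3L) "NO_MORE"
        else sample(choices, 1)
      st <- advanceWizard(st, a, db)
    }
    if (st@kind == "SANDWICH") {
      comps <- wizardComponents(st)
      breads <- recall24:::categoryFoods(db, "sandwich_bread")
      expect_true(any(comps %in% breads))
    }
  }
})

test_that("wizard components land in the meal as matched entries needing portions", {
  db <- testDb()
  s <- createSession(db, promptConfig(predefined_meals = data.frame(
    name = "Lunch", time = "13:00")), now = 0)
  st <- startWizard("SANDWICH", db)
  for (a in c("BRD1", "SPR1", "MTF1", "NONE_OF_THIS", "NO_MORE",
              "NONE_OF_THIS"))
    st <- advanceWizard(st, a, db)
  s <- addWizardResult(s, "Lunch", st)
  entries <- s@meals[[1]]$entries
  expect_length(entries, 3L)
  expect_true(all(vapply(entries, `[[`, character(1), "provenance") ==
                    "WIZARD_ADDED"))
  p <- nextPrompt(s)
  expect_identical(p$rule, "PORTION")  # already matched, portions pending
})
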