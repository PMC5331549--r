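test_that("the generated database is clean and every ladder is a valid centile ladder", {
  db <- testDb()
  expect_identical(nrow(validateDb(db)), 0L)
  for (code in foodCodes(db))
    for (m in getFood(db, code)$portion_methods)
      if (m$variant == "AS_SERVED") {
        expect_lte(length(m$image_weights_g), 7L)
        expect_true(all(diff(m$image_weights_g) > 0))
      }
  # ladder construction matches the quantile definition
  lad <- asServedLadder(log(165), 0.4, 7)
  expect_equal(lad$image_weights_g,
               round(qlnorm(seq(0.05, 0.95, length.out = 7), log(165), 0.4), 1))
  expect_error(asServedLadder(log(100), 0.3, 8))
})

test_that("simulation is deterministic under a fixed seed", {
  db <- testDb()
  m <- respondentModel(0.1, 0.2, 0.5, portion_sdlog = 0.2)
  a <- simulateRespondent(db, m, seed = 123)
  b <- simulateRespondent(db, m, seed = 123)
  expect_equal(a, b)
  c <- simulateRespondent(db, m, seed = 124)
  expect_false(identical(a$truth$weight_g, c$truth$weight_g))
  ra <- runAnswerScript(db, a$script)
  rb <- runAnswerScript(db, b$script)
  expect_equal(dayTotal(ra), dayTotal(rb))
})

test_that("error-free respondents reproduce the reference exactly through the engine", {
  db <- testDb()
  m <- respondentModel(0, 0, 0, portion_sdlog = 0, prompt_recovery = 1)
  for (seed in c(1, 99)) {
    sim <- simulateRespondent(db, m, seed = seed)
    rec <- runAnswerScript(db, sim$script)
    fields <- recall24:::nutrientFields(db)
    expect_equal(unname(dayTotal(rec)[fields]), unname(sim$reference[fields]),
                 tolerance = 1e-12)
  }
})

test_that("fully omitted condiments are recovered when prompts always succeed", {
  db <- testDb()
  m <- respondentModel(0, 0, 1, portion_sdlog = 0, prompt_recovery = 1)
  sim <- simulateRespondent(db, m, seed = 7)
  rec <- runAnswerScript(db, sim$script)
  e <- recallEntries(rec)
  condiments <- sim$truth$food_code[sim$truth$class == "condiment"]
  for (code in unique(condiments))
    expect_true(code %in% e$food_code, label = code)
  expect_true(all(e$provenance[e$food_code %in% condiments] == "PROMPT_ADDED"))
  # energy identical to truth because recovery carries the exact portions
  expect_equal(unname(dayTotal(rec)[["energy_kJ"]]),
               unname(sim$reference[["energy_kJ"]]), tolerance = 1e-9)
})

test_that("omission lowers the energy ratio; prompt recovery moves it back toward 1", {
  db <- testDb()
  energyRatioMean <- function(model, n = 15, seed = 300) {
    s <- simulateStudy(db, model, n = n, seed = seed)
    mean(vapply(s$ratios, function(r) r[["energy_kJ"]], numeric(1)))
  }
  none <- energyRatioMean(respondentModel(0, 0, 0, portion_sdlog = 0,
                                          prompt_recovery = 0))
  some <- energyRatioMean(respondentModel(0, 0, 0.5, portion_sdlog = 0,
                                          prompt_recovery = 0))
  heavy <- energyRatioMean(respondentModel(0, 0, 1, portion_sdlog = 0,
                                           prompt_recovery = 0))
  expect_equal(none, 1, tolerance = 1e-12)
  expect_lt(some, none)
  expect_lt(heavy, some)
  recovered <- energyRatioMean(respondentModel(0, 0, 0.5, portion_sdlog = 0,
                                               prompt_recovery = 1))
  expect_gt(recovered, some)
  expect_lte(recovered, 1 + 1e-9)
})

test_that("model validation rejects out-of-range probabilities", {
  expect_error(respondentModel(omission_main = 1.2), "\\[0, 1\\]")
  expect_error(respondentModel(portion_sdlog = -0.1), ">= 0")
  expect_error(respondentModel(portion_bias = 0), "positive")
})
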