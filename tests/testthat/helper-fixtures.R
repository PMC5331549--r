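# Shared fixtures, built in code. The synthetic database is deterministic
# so one copy serves the whole suite.

testDb <- local({
  db <- NULL
  function() {
    if (is.null(db)) db <<- generateFoodDb()
    db
  }
})

# A hand-specified scripted day ("day A") with seven entries whose
# composition arithmetic is easy to sum by hand:
#   Lunch 13:00  - BRD1 white bread, 2 guide slices        = 72 g
#                - MTF1 tuna, as-served image 3 (ladder median)
#                - SPR1 butter, 1 medium spread unit       = 7 g
#                - DRK1 cola, fill 0.5 of 330 ml x 1.04    = 171.6 g
#   Evening 18:00- STP1 chips, as-served image 4 (ladder median)
#                - SAU2 ketchup, 2 tablespoons             = 52 g
#                - DRK4 juice, fill 1.0 of 200 ml x 1.05   = 210 g
dayAScript <- function() {
  pa <- portionAnswer
  answerScript(
    survey_id = "fixture", user_id = "dayA",
    meals = list(list(name = "Lunch", time = "13:00"),
                 list(name = "Evening meal", time = "18:00")),
    items = list(
      list(meal = "Lunch", text = "white bread", kind = "food",
           food_code = "BRD1",
           portion = pa("GUIDE", object_index = 2, count = 1)),
      list(meal = "Lunch", text = "tuna", kind = "food", food_code = "MTF1",
           portion = pa("AS_SERVED", image_index = 3)),
      list(meal = "Lunch", text = "butter", kind = "food",
           food_code = "SPR1",
           portion = pa("STANDARD", unit_index = 2, count = 1)),
      list(meal = "Lunch", text = "cola", kind = "drink",
           food_code = "DRK1",
           portion = pa("DRINK_SCALE", fill_fraction = 0.5)),
      list(meal = "Evening meal", text = "chips", kind = "food",
           food_code = "STP1",
           portion = pa("AS_SERVED", image_index = 4)),
      list(meal = "Evening meal", text = "ketchup", kind = "food",
           food_code = "SAU2",
           portion = pa("STANDARD", unit_index = 2, count = 2)),
      list(meal = "Evening meal", text = "orange juice", kind = "drink",
           food_code = "DRK4",
           portion = pa("DRINK_SCALE", fill_fraction = 1))),
    duration_seconds = 780)
}

# Expected day-A weights, straight from the portion definitions.
dayAWeights <- function() {
  db <- testDb()
  as3 <- function(code, i) getFood(db, code)$portion_methods[[1]]$image_weights_g[i]
  c(BRD1 = 72, MTF1 = as3("MTF1", 3), SPR1 = 7, DRK1 = 330 * 0.5 * 1.04,
    STP1 = as3("STP1", 4), SAU2 = 52, DRK4 = 200 * 1 * 1.05)
}

# Hand-computed day-A nutrient total: sum over entries of
# weight/100 x per-100 g value, using the raw composition table.
dayAExpectedTotal <- function(field) {
  db <- testDb()
  w <- dayAWeights()
  total <- 0
  for (code in names(w)) {
    dc <- getFood(db, code)$databank_code
    per100 <- db@composition[db@composition$databank_code == dc, field]
    total <- total + w[[code]] / 100 * per100
  }
  total
}

seven <- function(db = testDb()) {
  c("weight_g", "energy_kJ", "carbohydrate_g", "protein_g", "fat_g",
    "vitamin_C_mg", "iron_mg")
}
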