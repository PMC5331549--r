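test_that("the synthetic database loads clean and carries the fixture structure", {
  db <- testDb()
  expect_identical(nrow(validateDb(db)), 0L)
  # sandwich component categories exist with foods
  for (cat in c("sandwich_bread", "sandwich_spread", "sandwich_meat_fish",
                "sandwich_cheese_dairy", "sandwich_extra", "sandwich_sauce"))
    expect_gt(length(recall24:::categoryFoods(db, cat)), 0)
  apple <- getFood(db, "FRT1")$portion_methods[[1]]
  expect_identical(apple$variant, "GUIDE")
  expect_length(apple$object_weights_g, 4L)
  sweets <- getFood(db, "CNF1")$portion_methods[[1]]
  expect_length(sweets$object_weights_g, 23L)
})

test_that("an empty food list is a valid degenerate database", {
  db <- foodDatabase(list(),
                     data.frame(databank_code = character(0)))
  expect_identical(length(db@foods), 0L)
  expect_identical(nrow(validateDb(db)), 0L)
})

test_that("write/load round trip preserves the database field by field", {
  db <- testDb()
  jf <- withr::local_tempfile(fileext = ".json")
  cf <- withr::local_tempfile(fileext = ".csv")
  writeFoodDb(db, jf, cf)
  db2 <- loadFoodDb(jf, cf)
  expect_identical(names(db2@foods), names(db@foods))
  for (code in names(db@foods)) {
    a <- db@foods[[code]]; b <- db2@foods[[code]]
    expect_equal(b[!vapply(b, is.null, logical(1))],
                 a[!vapply(a, is.null, logical(1))],
                 info = code, tolerance = 1e-12)
  }
  expect_equal(db2@composition, db@composition, tolerance = 1e-12)
  expect_identical(db2@sandwichTriggers, db@sandwichTriggers)
  expect_equal(db2@synonymSets, db@synonymSets, ignore_attr = TRUE)
})

test_that("a deleted composition record fails the load naming the code", {
  db <- testDb()
  jf <- withr::local_tempfile(fileext = ".json")
  cf <- withr::local_tempfile(fileext = ".csv")
  writeFoodDb(db, jf, cf)
  comp <- read.csv(cf)
  comp <- comp[comp$databank_code != "DB_MTF1", ]
  write.csv(comp, cf, row.names = FALSE)
  expect_error(loadFoodDb(jf, cf), "DB_MTF1")
})

test_that("validateDb reports over-long and non-ascending as-served ladders", {
  comp <- data.frame(databank_code = "D1", energy_kcal = 100,
                     energy_kJ = 418.4, carbohydrate_g = 10, protein_g = 1,
                     fat_g = 1, vitamin_C_mg = 0, iron_mg = 0.1)
  f8 <- foodRecord("F8", "eight images", "D1",
                   list(asServedMethod(seq(10, 80, by = 10))))
  rep8 <- validateDb(foodDatabase(list(f8), comp))
  expect_true(any(grepl("image count exceeds 7", rep8$problem)))

  fdesc <- foodRecord("F9", "descending", "D1",
                      list(asServedMethod(c(100, 50))))
  repd <- validateDb(foodDatabase(list(fdesc), comp))
  expect_true(any(grepl("not ascending", repd$problem)))

  fnone <- foodRecord("F1", "fine", "D1", list(asServedMethod(c(50, 100))))
  expect_identical(nrow(validateDb(foodDatabase(list(fnone), comp))), 0L)
})

test_that("validateDb flags unresolved links and inconsistent energy columns", {
  comp <- data.frame(databank_code = "D1", energy_kcal = 100,
                     energy_kJ = 500,  # ~19% off 4.184 conversion
                     carbohydrate_g = 0, protein_g = 0, fat_g = 0,
                     vitamin_C_mg = 0, iron_mg = 0)
  f <- foodRecord("F1", "linked", "D1", list(asServedMethod(50)),
                  associated_foods = list(list(
                    prompt_text = "x?", suggested_food_code = "NOPE",
                    optional = TRUE)))
  rep <- validateDb(foodDatabase(list(f), comp))
  expect_true(any(grepl("unknown food NOPE", rep$problem)))
  expect_true(any(grepl("energy kJ and kcal inconsistent", rep$problem)))
})

test_that("a missing energy column is derived with factor 4.184", {
  comp <- data.frame(databank_code = "D1", energy_kJ = 418.4)
  db <- foodDatabase(list(foodRecord("F1", "f", "D1",
                                     list(asServedMethod(50)))), comp)
  expect_equal(db@composition$energy_kcal, 100)
  comp2 <- data.frame(databank_code = "D1", energy_kcal = 100)
  db2 <- foodDatabase(list(foodRecord("F1", "f", "D1",
                                      list(asServedMethod(50)))), comp2)
  expect_equal(db2@composition$energy_kJ, 418.4)
})

test_that("composition lookup is total over foods in a validated database", {
  db <- testDb()
  for (code in foodCodes(db)) {
    v <- compositionFor(db, code)
    expect_true(all(c("energy_kJ", "energy_kcal", "iron_mg") %in% names(v)))
    expect_true(all(v >= 0))
  }
})
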