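# Synthetic food database: a compact NDNS-flavoured fixture exercising
# every structural feature of the engine - the four portion-method
# variants (including a four-size apple guide and a 23-item sweets
# guide), as-served ladders spanning the 5th-95th centile of lognormal
# serve-weight distributions, sandwich/salad component categories with
# brand-named breads, associated-food links (butter on bread, ketchup on
# chips, sugar in tea/coffee), drinks on sliding scales, and a composite
# dish mapped to multiple food groups.

#' As-served ladder from a lognormal serve distribution
#'
#' Builds the image-weight ladder as evenly spaced quantiles between the
#' 5th and 95th centile of the stated lognormal serve-weight
#' distribution.
#'
#' @param meanlog,sdlog lognormal parameters of the serve weight (g).
#' @param n number of images (at most 7).
#' @return an [asServedMethod()].
#' @export
asServedLadder <- function(meanlog, sdlog, n = 7L) {
  stopifnot(n >= 1L, n <= 7L)
  w <- stats::qlnorm(seq(0.05, 0.95, length.out = n), meanlog, sdlog)
  asServedMethod(round(w, 1))
}

#' Generate the synthetic food database
#'
#' Deterministic construction of a small validated database (the `seed`
#' is accepted for interface symmetry with the simulators; construction
#' itself has no random component). The database passes [validateDb()]
#' with zero violations.
#'
#' @param seed unused placeholder kept for a uniform generator interface.
#' @return a [FoodDatabase-class].
#' @export
generateFoodDb <- function(seed = 1L) {
  std <- function(...) {
    u <- list(...)
    standardMethod(data.frame(description = names(u),
                              unit_weight_g = as.numeric(unlist(u))))
  }
  link <- function(text, code) list(prompt_text = text,
                                    suggested_food_code = code,
                                    optional = TRUE)
  butter_link <- link("Did you have butter or margarine on your bread?", "SPR1")
  foods <- list(
    foodRecord("BRD1", "White bread, Hovis 50/50", "DB_BRD1",
               list(guideMethod(c(one_slice = 36, two_slices = 72,
                                  three_slices = 108, four_slices = 144))),
               synonyms = c("toast", "loaf"),
               category_codes = "sandwich_bread", food_group_codes = "FG_BREAD",
               associated_foods = list(butter_link)),
    foodRecord("BRD2", "Seeded batch bread, Warburtons seeded batch", "DB_BRD2",
               list(guideMethod(c(one_slice = 44, two_slices = 88,
                                  three_slices = 132, four_slices = 176))),
               category_codes = "sandwich_bread", food_group_codes = "FG_BREAD",
               associated_foods = list(butter_link)),
    foodRecord("BRD3", "Wholemeal roll", "DB_BRD3",
               list(std(one_roll = 60, half_roll = 30)),
               category_codes = "sandwich_bread", food_group_codes = "FG_BREAD",
               associated_foods = list(butter_link)),
    foodRecord("SPR1", "Butter", "DB_SPR1",
               list(std(thin_spread = 5, medium_spread = 7, thick_spread = 10)),
               category_codes = "sandwich_spread", food_group_codes = "FG_FATS"),
    foodRecord("SPR2", "Soft margarine", "DB_SPR2",
               list(std(thin_spread = 5, medium_spread = 7, thick_spread = 10)),
               category_codes = "sandwich_spread", food_group_codes = "FG_FATS"),
    foodRecord("MTF1", "Tuna, canned in brine", "DB_MTF1",
               list(asServedLadder(log(45), 0.30, 5)),
               category_codes = "sandwich_meat_fish",
               food_group_codes = "FG_FISH"),
    foodRecord("MTF2", "Ham, sliced", "DB_MTF2",
               list(std(one_slice = 23, two_slices = 46)),
               category_codes = "sandwich_meat_fish",
               food_group_codes = "FG_MEAT"),
    foodRecord("MTF3", "Roast chicken", "DB_MTF3",
               list(asServedLadder(log(90), 0.35, 7)),
               category_codes = "sandwich_meat_fish",
               food_group_codes = "FG_MEAT"),
    foodRecord("CHD1", "Cheddar cheese", "DB_CHD1",
               list(asServedLadder(log(30), 0.35, 5)),
               category_codes = "sandwich_cheese_dairy",
               food_group_codes = "FG_DAIRY"),
    foodRecord("EXT1", "Cucumber", "DB_EXT1",
               list(std(one_slice = 6, five_slices = 30)),
               category_codes = c("sandwich_extra", "salad_item"),
               food_group_codes = "FG_VEG"),
    foodRecord("EXT2", "Tomato", "DB_EXT2",
               list(guideMethod(c(whole = 85, half = 43))),
               category_codes = c("sandwich_extra", "salad_item"),
               food_group_codes = "FG_VEG"),
    foodRecord("EXT3", "Lettuce", "DB_EXT3",
               list(std(one_handful = 15)),
               category_codes = c("sandwich_extra", "salad_item"),
               food_group_codes = "FG_VEG"),
    foodRecord("SLD1", "Sweetcorn", "DB_SLD1",
               list(std(one_tablespoon = 26)),
               category_codes = "salad_item", food_group_codes = "FG_VEG"),
    foodRecord("SLD2", "Grated carrot", "DB_SLD2",
               list(std(one_tablespoon = 14)),
               category_codes = "salad_item", food_group_codes = "FG_VEG"),
    foodRecord("SAU1", "Mayonnaise", "DB_SAU1",
               list(std(one_teaspoon = 11, one_tablespoon = 33)),
               category_codes = c("sandwich_sauce", "salad_sauce"),
               food_group_codes = "FG_FATS"),
    foodRecord("SAU2", "Tomato ketchup", "DB_SAU2",
               list(std(one_teaspoon = 9, one_tablespoon = 26)),
               category_codes = "sandwich_sauce",
               food_group_codes = "FG_CONDIMENTS"),
    foodRecord("SAU3", "Salad cream", "DB_SAU3",
               list(std(one_teaspoon = 10, one_tablespoon = 30)),
               category_codes = "salad_sauce",
               food_group_codes = "FG_CONDIMENTS"),
    foodRecord("FRT1", "Apple", "DB_FRT1",
               list(guideMethod(c(small = 71, medium = 112, large = 155,
                                  very_large = 203))),
               category_codes = "fruit", food_group_codes = "FG_FRUIT"),
    foodRecord("FRT2", "Banana, chopped", "DB_FRT2",
               list(asServedLadder(log(80), 0.30, 5),
                    std(one_whole_banana = 118)),
               synonyms = "banana",
               category_codes = "fruit", food_group_codes = "FG_FRUIT"),
    foodRecord("CNF1", "Sweets, assorted", "DB_CNF1",
               list(guideMethod(stats::setNames(
                 round(seq(2, 13, length.out = 23), 1),
                 paste0("item_", 1:23)))),
               synonyms = c("candy", "gums"),
               category_codes = "confectionery",
               food_group_codes = "FG_SUGAR_CONF"),
    foodRecord("STP1", "Chips, fried", "DB_STP1",
               list(asServedLadder(log(165), 0.40, 7)),
               synonyms = "fries",
               category_codes = "staples", food_group_codes = "FG_POTATOES",
               associated_foods = list(
                 link("Did you have ketchup or sauce with your chips?", "SAU2"))),
    foodRecord("STP2", "Cornflakes", "DB_STP2",
               list(asServedLadder(log(30), 0.40, 7)),
               synonyms = "cereal",
               category_codes = "staples", food_group_codes = "FG_CEREALS"),
    foodRecord("STP3", "Porridge, made with milk", "DB_STP3",
               list(asServedLadder(log(200), 0.35, 7)),
               category_codes = "staples",
               food_group_codes = c("FG_CEREALS", "FG_DAIRY"),
               food_group_weights = c(0.5, 0.5)),
    foodRecord("DSH1", "Pasta with tomato sauce", "DB_DSH1",
               list(asServedLadder(log(260), 0.35, 7)),
               category_codes = "dishes",
               food_group_codes = c("FG_CEREALS", "FG_VEG"),
               food_group_weights = c(0.6, 0.4)),
    foodRecord("SUG1", "White sugar", "DB_SUG1",
               list(std(one_teaspoon = 4, two_teaspoons = 8)),
               category_codes = "condiments",
               food_group_codes = "FG_SUGAR_CONF"),
    foodRecord("DRK1", "Cola", "DB_DRK1",
               list(drinkScaleMethod(330, 1.04)),
               synonyms = "coke",
               category_codes = "drinks", food_group_codes = "FG_SOFT_DRINKS",
               is_drink = TRUE),
    foodRecord("DRK2", "Tea", "DB_DRK2",
               list(drinkScaleMethod(250, 1.0)),
               category_codes = "drinks", food_group_codes = "FG_BEVERAGES",
               is_drink = TRUE,
               associated_foods = list(
                 link("Did you have sugar in your tea?", "SUG1"))),
    foodRecord("DRK3", "Coffee", "DB_DRK3",
               list(drinkScaleMethod(250, 1.0)),
               category_codes = "drinks", food_group_codes = "FG_BEVERAGES",
               is_drink = TRUE,
               associated_foods = list(
                 link("Did you have sugar in your coffee?", "SUG1"))),
    foodRecord("DRK4", "Orange juice", "DB_DRK4",
               list(drinkScaleMethod(200, 1.05)),
               synonyms = "juice",
               category_codes = "drinks", food_group_codes = "FG_FRUIT",
               is_drink = TRUE),
    foodRecord("DRK5", "Semi-skimmed milk", "DB_DRK5",
               list(drinkScaleMethod(200, 1.03)),
               synonyms = "milk",
               category_codes = "drinks", food_group_codes = "FG_DAIRY",
               is_drink = TRUE),
    foodRecord("ALC1", "Dry cider e.g., Strongbow", "DB_ALC1",
               list(drinkScaleMethod(568, 1.0)),
               synonyms = "cider",
               category_codes = "drinks", food_group_codes = "FG_ALCOHOL",
               is_drink = TRUE))

  categories <- data.frame(
    code = c("sandwich_bread", "sandwich_spread", "sandwich_meat_fish",
             "sandwich_cheese_dairy", "sandwich_extra", "sandwich_sauce",
             "salad_item", "salad_sauce", "fruit", "confectionery",
             "staples", "dishes", "condiments", "drinks"),
    description = c("Breads", "Spreads", "Meat and fish",
                    "Cheese and dairy", "Extra fillings",
                    "Sauces and dressings", "Salad items", "Salad sauces",
                    "Fruit", "Confectionery", "Staple foods",
                    "Composite dishes", "Condiments", "Drinks"))

  # per-100 g: energy kcal, carbohydrate g, protein g, fat g, vit C mg, iron mg
  comp_vals <- list(
    DB_BRD1 = c(235, 46.0, 8.0, 2.0, 0.0, 1.10),
    DB_BRD2 = c(265, 43.0, 10.5, 5.5, 0.0, 1.60),
    DB_BRD3 = c(218, 41.0, 9.0, 2.5, 0.0, 2.40),
    DB_SPR1 = c(744, 0.6, 0.5, 82.0, 0.0, 0.02),
    DB_SPR2 = c(630, 1.0, 0.2, 70.0, 0.0, 0.05),
    DB_MTF1 = c(109, 0.0, 25.0, 0.6, 0.0, 1.00),
    DB_MTF2 = c(107, 1.0, 18.0, 3.3, 0.0, 0.70),
    DB_MTF3 = c(170, 0.0, 27.0, 6.6, 0.0, 0.70),
    DB_CHD1 = c(416, 0.1, 25.4, 34.9, 0.0, 0.30),
    DB_EXT1 = c(15, 3.0, 0.7, 0.1, 2.8, 0.30),
    DB_EXT2 = c(18, 3.9, 0.9, 0.2, 13.7, 0.27),
    DB_EXT3 = c(15, 2.9, 1.4, 0.2, 9.2, 0.86),
    DB_SLD1 = c(86, 19.0, 3.2, 1.2, 6.8, 0.52),
    DB_SLD2 = c(41, 9.6, 0.9, 0.2, 5.9, 0.30),
    DB_SAU1 = c(680, 1.7, 1.1, 75.0, 0.0, 0.20),
    DB_SAU2 = c(102, 24.0, 1.2, 0.1, 4.0, 0.30),
    DB_SAU3 = c(348, 16.7, 1.5, 31.0, 0.0, 0.20),
    DB_FRT1 = c(52, 13.8, 0.3, 0.2, 6.0, 0.12),
    DB_FRT2 = c(89, 22.8, 1.1, 0.3, 8.7, 0.26),
    DB_CNF1 = c(334, 77.0, 4.2, 0.2, 0.0, 0.30),
    DB_STP1 = c(270, 36.0, 3.9, 12.4, 9.0, 0.80),
    DB_STP2 = c(378, 84.0, 7.0, 0.9, 0.0, 8.00),
    DB_STP3 = c(116, 15.3, 4.8, 4.4, 0.7, 0.60),
    DB_DSH1 = c(104, 17.5, 3.5, 2.2, 5.5, 0.90),
    DB_SUG1 = c(400, 100.0, 0.0, 0.0, 0.0, 0.00),
    DB_DRK1 = c(42, 10.6, 0.0, 0.0, 0.0, 0.00),
    DB_DRK2 = c(1, 0.2, 0.1, 0.0, 0.0, 0.00),
    DB_DRK3 = c(2, 0.3, 0.2, 0.0, 0.0, 0.00),
    DB_DRK4 = c(44, 10.4, 0.5, 0.1, 39.0, 0.20),
    DB_DRK5 = c(48, 4.8, 3.4, 1.8, 0.9, 0.02),
    DB_ALC1 = c(36, 2.6, 0.0, 0.0, 0.0, 0.10))
  composition <- do.call(rbind, lapply(names(comp_vals), function(dc) {
    v <- comp_vals[[dc]]
    data.frame(databank_code = dc, energy_kcal = v[1],
               energy_kJ = v[1] * 4.184, carbohydrate_g = v[2],
               protein_g = v[3], fat_g = v[4], vitamin_C_mg = v[5],
               iron_mg = v[6])
  }))

  foodDatabase(
    foods, composition, categories,
    synonymSets = list(c("chips", "fries"), c("cola", "coke"),
                       c("cornflakes", "cereal"), c("toast", "bread")),
    sandwichTriggers = c("sandwich", "roll", "butty", "wrap"),
    saladTriggers = "salad")
}
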