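# Food database: records, portion-method descriptors, construction,
# validation and (de)serialisation. Food DB travels as JSON (portion
# methods are nested), the composition table as a flat CSV with one row
# per databank code and one column per nutrient (per 100 g).

#' Portion-size estimation methods
#'
#' Four ways of mapping a respondent's answer to a weight in grams:
#' \describe{
#'   \item{AS_SERVED}{a ladder of up to seven photographs of the food at
#'     strictly increasing served weights; the respondent picks one image.
#'     Ladders conventionally span the 5th to 95th centile of served
#'     weights.}
#'   \item{GUIDE}{one photograph of several discrete items of known
#'     weights (e.g. four apple sizes); the respondent picks an item and a
#'     count.}
#'   \item{DRINK_SCALE}{a sliding fill-level scale on a container of known
#'     volume; weight is volume x fill fraction x density.}
#'   \item{STANDARD}{named standard units (e.g. "teaspoon") with known
#'     unit weights; the respondent picks a unit and an amount.}
#' }
#'
#' @param image_weights_g strictly increasing positive weights, length 1-7.
#' @param object_weights_g positive weights of the depicted guide objects.
#' @param container_volume_ml positive container volume.
#' @param density_g_per_ml positive density; defaults to 1 (water-like).
#' @param units data.frame with columns `description`, `unit_weight_g`.
#' @return a portion-method descriptor (list with a `variant` field).
#' @examples
#' asServedMethod(c(50, 100, 150, 200))
#' guideMethod(c(small = 71, medium = 112, large = 155, very_large = 203))
#' @export
asServedMethod <- function(image_weights_g) {
  w <- as.numeric(image_weights_g)
  structure(list(variant = "AS_SERVED", image_weights_g = w),
            class = "portionMethod")
}

#' @rdname asServedMethod
#' @export
guideMethod <- function(object_weights_g) {
  structure(list(variant = "GUIDE",
                 object_weights_g = as.numeric(object_weights_g)),
            class = "portionMethod")
}

#' @rdname asServedMethod
#' @export
drinkScaleMethod <- function(container_volume_ml, density_g_per_ml = 1) {
  structure(list(variant = "DRINK_SCALE",
                 container_volume_ml = as.numeric(container_volume_ml),
                 density_g_per_ml = as.numeric(density_g_per_ml)),
            class = "portionMethod")
}

#' @rdname asServedMethod
#' @export
standardMethod <- function(units) {
  units <- as.data.frame(units)
  stopifnot(all(c("description", "unit_weight_g") %in% names(units)))
  units$unit_weight_g <- as.numeric(units$unit_weight_g)
  structure(list(variant = "STANDARD", units = units),
            class = "portionMethod")
}

#' Construct a food record
#'
#' One food in the database: display description (brand examples such as
#' "e.g., Strongbow" belong in the description, where they aid search),
#' search synonyms, category membership, the databank code linking to a
#' per-100 g composition record, one-or-more food-group assignments
#' (composite dishes carry several, optionally with allocation fractions),
#' associated-food links, and a non-empty list of portion methods.
#'
#' @param food_code unique identifier.
#' @param description display name.
#' @param databank_code key into the composition table.
#' @param portion_methods non-empty list of portion-method descriptors.
#' @param synonyms extra search terms.
#' @param category_codes categories the food is listed under.
#' @param food_group_codes one or more food-group identifiers.
#' @param food_group_weights optional allocation fractions summing to 1;
#'   equal split when omitted.
#' @param associated_foods list of links, each
#'   `list(prompt_text =, suggested_food_code =, optional = TRUE)`.
#' @param is_drink logical; drinks satisfy the missing-drink prompt rule.
#' @return a food record (plain list).
#' @export
foodRecord <- function(food_code, description, databank_code,
                       portion_methods, synonyms = character(0),
                       category_codes = character(0),
                       food_group_codes = character(0),
                       food_group_weights = NULL,
                       associated_foods = list(), is_drink = FALSE) {
  stopifnot(isString(food_code), isString(description), isString(databank_code))
  if (!is.list(portion_methods) || length(portion_methods) == 0L)
    stopf("food %s: portion_methods must be a non-empty list", food_code)
  if (inherits(portion_methods, "portionMethod"))
    portion_methods <- list(portion_methods)
  list(food_code = food_code,
       description = description,
       synonyms = as.character(synonyms),
       category_codes = as.character(category_codes),
       databank_code = databank_code,
       food_group_codes = as.character(food_group_codes),
       food_group_weights = if (!is.null(food_group_weights))
         as.numeric(food_group_weights),
       associated_foods = associated_foods,
       portion_methods = portion_methods,
       is_drink = isTRUE(is_drink))
}

#' Assemble a food database
#'
#' Builds the indexed [FoodDatabase-class] from records and a composition
#' table. Use [validateDb()] to check semantic invariants; this
#' constructor enforces only structural ones (unique codes, table shape)
#' so that deliberately defective databases can be built for validation
#' testing.
#'
#' @param foods list of [foodRecord()]s.
#' @param composition data.frame with `databank_code` plus nutrient
#'   columns; if only one of `energy_kJ`/`energy_kcal` is present the
#'   other is derived with the factor 4.184.
#' @param categories data.frame with `code`, `description`.
#' @param synonymSets list of character vectors of interchangeable terms.
#' @param sandwichTriggers,saladTriggers tokens that surface the wizards.
#' @return a [FoodDatabase-class].
#' @export
foodDatabase <- function(foods, composition,
                         categories = data.frame(code = character(0),
                                                 description = character(0)),
                         synonymSets = list(),
                         sandwichTriggers = c("sandwich", "roll", "butty", "wrap"),
                         saladTriggers = "salad") {
  names(foods) <- vapply(foods, `[[`, character(1), "food_code")
  composition <- normalizeComposition(composition)
  new("FoodDatabase", foods = foods, composition = composition,
      categories = as.data.frame(categories), synonymSets = synonymSets,
      sandwichTriggers = sandwichTriggers, saladTriggers = saladTriggers)
}

normalizeComposition <- function(composition) {
  composition <- as.data.frame(composition)
  if (!"databank_code" %in% names(composition))
    stopf("composition table needs a databank_code column")
  has_kj <- "energy_kJ" %in% names(composition)
  has_kcal <- "energy_kcal" %in% names(composition)
  if (has_kj && !has_kcal) composition$energy_kcal <- composition$energy_kJ / 4.184
  if (has_kcal && !has_kj) composition$energy_kJ <- composition$energy_kcal * 4.184
  composition
}

#' Validate a food database
#'
#' Reports (does not throw) violations of the database invariants: empty
#' portion-method lists, as-served ladders longer than seven images or
#' with non-ascending weights, non-positive weights/volumes, guide methods
#' with no objects, dangling databank codes, unresolvable associated-food
#' links, food-group fractions not summing to 1, and kJ/kcal energy
#' columns inconsistent beyond 1% under the factor 4.184.
#'
#' @param db a [FoodDatabase-class].
#' @return data.frame with columns `food_code`, `problem`; zero rows for a
#'   clean database.
#' @export
validateDb <- function(db) {
  probs <- list()
  add <- function(code, msg) probs[[length(probs) + 1L]] <<-
    data.frame(food_code = code, problem = msg)
  comp_codes <- db@composition$databank_code
  for (f in db@foods) {
    fc <- f$food_code
    if (length(f$portion_methods) == 0L) add(fc, "no portion method")
    for (pm in f$portion_methods) {
      switch(pm$variant,
        AS_SERVED = {
          w <- pm$image_weights_g
          if (length(w) > 7L) add(fc, "image count exceeds 7")
          if (any(w <= 0)) add(fc, "non-positive as-served weight")
          if (length(w) > 1L && any(diff(w) <= 0))
            add(fc, "as-served weights not ascending")
        },
        GUIDE = {
          if (length(pm$object_weights_g) < 1L) add(fc, "guide has no objects")
          if (any(pm$object_weights_g <= 0)) add(fc, "non-positive guide weight")
        },
        DRINK_SCALE = {
          if (pm$container_volume_ml <= 0 || pm$density_g_per_ml <= 0)
            add(fc, "non-positive drink-scale volume or density")
        },
        STANDARD = {
          if (nrow(pm$units) < 1L) add(fc, "standard method has no units")
          if (any(pm$units$unit_weight_g <= 0))
            add(fc, "non-positive standard unit weight")
        },
        add(fc, paste("unknown portion method variant", pm$variant)))
    }
    if (!f$databank_code %in% comp_codes)
      add(fc, paste("dangling databank_code", f$databank_code))
    else if (sum(comp_codes == f$databank_code) > 1L)
      add(fc, paste("databank_code", f$databank_code, "not unique"))
    for (lk in f$associated_foods) {
      if (is.null(db@foods[[lk$suggested_food_code %||% ""]]))
        add(fc, paste("associated link suggests unknown food",
                      lk$suggested_food_code %||% "<missing>"))
    }
    if (!is.null(f$food_group_weights)) {
      if (length(f$food_group_weights) != length(f$food_group_codes) ||
          abs(sum(f$food_group_weights) - 1) > 1e-8)
        add(fc, "food group fractions do not sum to 1")
    }
    if (length(f$category_codes) &&
        !all(f$category_codes %in% db@categories$code))
      add(fc, "unknown category code")
  }
  if (all(c("energy_kJ", "energy_kcal") %in% names(db@composition))) {
    bad <- abs(db@composition$energy_kJ - db@composition$energy_kcal * 4.184) >
      0.01 * pmax(db@composition$energy_kJ, 1e-9)
    for (dc in db@composition$databank_code[bad])
      add(dc, "energy kJ and kcal inconsistent beyond 1%")
  }
  if (length(probs)) do.call(rbind, probs)
  else data.frame(food_code = character(0), problem = character(0))
}

#' Load a food database from disk
#'
#' Reads the JSON food file and CSV composition table, rebuilds the
#' indexed database and verifies every invariant; any violation (including
#' a databank code with no composition record, or an associated link to an
#' unknown food) aborts the load naming the offending record.
#'
#' @param path JSON food database file (see [writeFoodDb()] for schema).
#' @param composition_path CSV composition table, UTF-8, header row, dot
#'   decimal separator.
#' @return a validated [FoodDatabase-class].
#' @export
loadFoodDb <- function(path, composition_path) {
  if (!file.exists(path)) stopf("food database file not found: %s", path)
  if (!file.exists(composition_path))
    stopf("composition file not found: %s", composition_path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("foods", "categories"))
    if (is.null(raw[[field]])) stopf("food database missing '%s'", field)
  foods <- lapply(raw$foods, parseFoodJson)
  categories <- do.call(rbind, lapply(raw$categories, function(cc)
    data.frame(code = cc$code, description = cc$description)))
  if (is.null(categories))
    categories <- data.frame(code = character(0), description = character(0))
  composition <- utils::read.csv(composition_path, stringsAsFactors = FALSE)
  db <- foodDatabase(
    foods, composition, categories,
    synonymSets = lapply(raw$synonym_sets %||% list(), unlist),
    sandwichTriggers = unlist(raw$sandwich_triggers %||%
                                list("sandwich", "roll", "butty", "wrap")),
    saladTriggers = unlist(raw$salad_triggers %||% list("salad")))
  report <- validateDb(db)
  if (nrow(report))
    stopf("food database invalid: %s",
          paste(sprintf("[%s] %s", report$food_code, report$problem),
                collapse = "; "))
  db
}

parseFoodJson <- function(x) {
  pms <- lapply(x$portion_methods, function(pm) {
    switch(pm$variant,
      AS_SERVED = asServedMethod(unlist(pm$image_weights_g)),
      GUIDE = guideMethod(unlist(pm$object_weights_g)),
      DRINK_SCALE = drinkScaleMethod(pm$container_volume_ml,
                                     pm$density_g_per_ml %||% 1),
      STANDARD = standardMethod(data.frame(
        description = vapply(pm$units, `[[`, character(1), "description"),
        unit_weight_g = vapply(pm$units, function(u)
          as.numeric(u$unit_weight_g), numeric(1)))),
      stopf("food %s: unknown portion method variant '%s'",
            x$food_code %||% "<unnamed>", pm$variant %||% "<none>"))
  })
  foodRecord(
    food_code = x$food_code, description = x$description,
    databank_code = x$databank_code, portion_methods = pms,
    synonyms = unlist(x$synonyms %||% list()) %||% character(0),
    category_codes = unlist(x$category_codes %||% list()) %||% character(0),
    food_group_codes = unlist(x$food_group_codes %||% list()) %||% character(0),
    food_group_weights = if (!is.null(x$food_group_weights))
      unlist(x$food_group_weights),
    associated_foods = lapply(x$associated_foods %||% list(), function(lk)
      list(prompt_text = lk$prompt_text,
           suggested_food_code = lk$suggested_food_code,
           optional = isTRUE(lk$optional %||% TRUE))),
    is_drink = isTRUE(x$is_drink))
}

#' Write a food database to disk
#'
#' Inverse of [loadFoodDb()]: foods, categories, synonym sets and wizard
#' triggers as JSON; the composition table as CSV. A written database
#' re-loads to a field-by-field equivalent one.
#'
#' @param db a [FoodDatabase-class].
#' @param path output JSON file.
#' @param composition_path output CSV file.
#' @return invisibly, the two paths.
#' @export
writeFoodDb <- function(db, path, composition_path) {
  foods <- lapply(unname(db@foods), function(f) {
    f$portion_methods <- lapply(f$portion_methods, function(pm) {
      if (pm$variant == "STANDARD")
        pm$units <- lapply(seq_len(nrow(pm$units)), function(i)
          list(description = pm$units$description[i],
               unit_weight_g = pm$units$unit_weight_g[i]))
      unclass(pm)
    })
    f[!vapply(f, is.null, logical(1))]
  })
  cats <- lapply(seq_len(nrow(db@categories)), function(i)
    list(code = db@categories$code[i], description = db@categories$description[i]))
  jsonlite::write_json(
    list(foods = foods, categories = cats,
         synonym_sets = db@synonymSets,
         sandwich_triggers = db@sandwichTriggers,
         salad_triggers = db@saladTriggers),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(db@composition, composition_path, row.names = FALSE)
  invisible(c(path, composition_path))
}

#' Per-100 g composition for a food
#'
#' @param db a validated [FoodDatabase-class].
#' @param food_code a food code in the database.
#' @return named numeric of per-100 g nutrient values (without weight).
#' @export
compositionFor <- function(db, food_code) {
  f <- getFood(db, food_code)
  row <- db@composition[db@composition$databank_code == f$databank_code, , drop = FALSE]
  if (nrow(row) != 1L)
    stopf("food %s: databank code %s resolves to %d composition records",
          food_code, f$databank_code, nrow(row))
  cols <- setdiff(names(row), "databank_code")
  v <- as.numeric(row[1, cols])
  names(v) <- cols
  v
}
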