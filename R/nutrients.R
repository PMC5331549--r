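# Nutrient arithmetic: per-100 g composition scaled to entry weights,
# then additive aggregation to meal and day totals.

#' Nutrients in a consumed portion
#'
#' Scales a per-100 g composition record to the consumed weight: each
#' nutrient equals `weight_g / 100` times its per-100 g value. The weight
#' itself is carried through as the `weight_g` component, so totals of
#' food weight aggregate like any other quantity.
#'
#' @param weight_g positive consumed weight in grams.
#' @param composition named numeric of per-100 g values (e.g. from
#'   [compositionFor()]).
#' @return a named nutrient vector including `weight_g`.
#' @examples
#' foodNutrients(50, c(energy_kJ = 250, energy_kcal = 250 / 4.184,
#'                     carbohydrate_g = 10, protein_g = 2, fat_g = 1,
#'                     vitamin_C_mg = 0, iron_mg = 0.5))
#' @export
foodNutrients <- function(weight_g, composition) {
  if (!is.numeric(weight_g) || length(weight_g) != 1L ||
      !is.finite(weight_g) || weight_g <= 0)
    stopf("weight_g must be a positive number")
  v <- c(weight_g = weight_g, composition * (weight_g / 100))
  v
}

#' Zero nutrient vector over a nutrient set
#'
#' @param fields nutrient names; defaults to the mandatory set.
#' @return named numeric of zeros.
#' @export
zeroNutrients <- function(fields = NUTRIENT_FIELDS) {
  stats::setNames(numeric(length(fields)), fields)
}

#' Aggregate nutrient vectors
#'
#' Componentwise sum over a list of nutrient vectors; the empty list gives
#' the zero vector. Vectors may carry different nutrient sets; the union
#' is summed, treating absent components as zero.
#'
#' @param vectors list of named numeric nutrient vectors.
#' @param fields optional nutrient names fixing the output order; defaults
#'   to the union of names encountered (mandatory fields first).
#' @return a named numeric nutrient vector.
#' @export
aggregateNutrients <- function(vectors, fields = NULL) {
  if (is.null(fields)) {
    seen <- unique(unlist(lapply(vectors, names)))
    fields <- unique(c(intersect(NUTRIENT_FIELDS, seen), seen))
    if (length(fields) == 0L) fields <- NUTRIENT_FIELDS
  }
  out <- zeroNutrients(fields)
  for (v in vectors) {
    common <- intersect(names(v), fields)
    out[common] <- out[common] + v[common]
  }
  out
}
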