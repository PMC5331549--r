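# Portion resolution: answer + method -> grams.

#' Construct a portion answer
#'
#' The respondent's answer to a portion-size question, matching one of the
#' four method variants: an image index for an as-served ladder, an object
#' index and count for a guide photo, a fill fraction in (0, 1] for a
#' drink scale, or a unit index and amount for standard units.
#'
#' @param variant one of "AS_SERVED", "GUIDE", "DRINK_SCALE", "STANDARD".
#' @param image_index,object_index,unit_index 1-based indices into the
#'   method's images/objects/units.
#' @param count positive number of guide objects (integer) or standard
#'   units (may be fractional).
#' @param fill_fraction drink fill level in (0, 1].
#' @return a portion-answer list.
#' @export
portionAnswer <- function(variant, image_index = NULL, object_index = NULL,
                          count = NULL, fill_fraction = NULL,
                          unit_index = NULL) {
  structure(list(variant = variant, image_index = image_index,
                 object_index = object_index, count = count,
                 fill_fraction = fill_fraction, unit_index = unit_index),
            class = "portionAnswer")
}

#' Resolve a portion answer to a weight in grams
#'
#' \itemize{
#'   \item AS_SERVED: the weight of the selected image (nearest-image
#'     semantics, no between-image interpolation).
#'   \item GUIDE: object weight x count.
#'   \item DRINK_SCALE: container volume x fill fraction x density.
#'   \item STANDARD: unit weight x count.
#' }
#'
#' @param method a portion-method descriptor (see [asServedMethod()]).
#' @param answer a [portionAnswer()] of the same variant.
#' @return positive weight in grams.
#' @examples
#' resolvePortion(asServedMethod(c(50, 100, 150, 200)),
#'                portionAnswer("AS_SERVED", image_index = 3))
#' @export
resolvePortion <- function(method, answer) {
  if (!identical(method$variant, answer$variant))
    stopf("portion answer variant %s does not match method variant %s",
          answer$variant, method$variant)
  w <- switch(method$variant,
    AS_SERVED = {
      i <- answer$image_index
      if (!isCount(i) || i != round(i) || i > length(method$image_weights_g))
        stopf("image_index out of range")
      method$image_weights_g[i]
    },
    GUIDE = {
      i <- answer$object_index
      n <- answer$count
      if (!isCount(i) || i != round(i) || i > length(method$object_weights_g))
        stopf("object_index out of range")
      if (!isCount(n) || n != round(n)) stopf("guide count must be a positive integer")
      method$object_weights_g[i] * n
    },
    DRINK_SCALE = {
      fr <- answer$fill_fraction
      if (!is.numeric(fr) || length(fr) != 1L || !is.finite(fr) ||
          fr <= 0 || fr > 1)
        stopf("fill_fraction must lie in (0, 1]")
      method$container_volume_ml * fr * method$density_g_per_ml
    },
    STANDARD = {
      i <- answer$unit_index
      n <- answer$count
      if (!isCount(i) || i != round(i) || i > nrow(method$units))
        stopf("unit_index out of range")
      if (!isCount(n)) stopf("count must be positive")
      method$units$unit_weight_g[i] * n
    },
    stopf("unknown portion method variant %s", method$variant))
  if (!is.finite(w) || w <= 0) stopf("resolved weight must be positive")
  w
}
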