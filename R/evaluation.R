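# Method-comparison statistics: per-nutrient test/reference agreement
# ratios with arithmetic and geometric summaries, System Usability Scale
# scoring, and Kruskal-Wallis tests across testing rounds.

#' Per-nutrient agreement ratio
#'
#' For one respondent, the componentwise quotient of the test-method
#' intake by the reference-method intake. A ratio of 1 is perfect
#' agreement; below 1 the test method under-estimates, above 1 it
#' over-estimates. Components whose reference intake is zero are
#' undefined and returned as `NA` (they are excluded pairwise from
#' summaries - a day genuinely can contain, say, zero vitamin C).
#'
#' @param test,ref named numeric nutrient vectors over the same nutrient
#'   set.
#' @return named numeric of ratios, `NA` where the reference is zero.
#' @examples
#' agreementRatio(c(energy_kJ = 800), c(energy_kJ = 1000))
#' @export
agreementRatio <- function(test, ref) {
  if (!setequal(names(test), names(ref)))
    stopf("test and reference nutrient sets differ")
  ref <- ref[names(test)]
  out <- ifelse(ref == 0, NA_real_, test / ref)
  names(out) <- names(test)
  out
}

#' Summarise agreement ratios over respondents
#'
#' Per nutrient: the number of respondents with a defined ratio, the
#' arithmetic mean and sample SD (n-1 denominator; reported as 0 when
#' n = 1), the geometric mean and geometric SD (exp of the SD of log
#' ratios), and the direction of disagreement implied by the geometric
#' mean. Arithmetic and geometric summaries are both reported because
#' multiplicative spread is the norm for intake ratios.
#'
#' @param ratios non-empty list of ratio vectors from [agreementRatio()].
#' @return data.frame with columns `nutrient`, `n`, `mean`, `sd`,
#'   `geo_mean`, `geo_sd`, `direction`.
#' @export
summarizeRatios <- function(ratios) {
  if (length(ratios) == 0L) stopf("no ratios to summarise")
  nutrients <- names(ratios[[1]])
  rows <- lapply(nutrients, function(nm) {
    vals <- vapply(ratios, function(r) unname(r[[nm]]), numeric(1))
    vals <- vals[!is.na(vals)]
    n <- length(vals)
    if (n == 0L)
      return(data.frame(nutrient = nm, n = 0L, mean = NA_real_, sd = NA_real_,
                        geo_mean = NA_real_, geo_sd = NA_real_,
                        direction = NA_character_))
    gm <- exp(mean(log(vals)))
    data.frame(
      nutrient = nm, n = n, mean = mean(vals),
      sd = if (n > 1L) stats::sd(vals) else 0,
      geo_mean = gm,
      geo_sd = if (n > 1L) exp(stats::sd(log(vals))) else 0,
      direction = if (abs(gm - 1) < 1e-12) "agreement"
        else if (gm < 1) "under-estimation" else "over-estimation")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' System Usability Scale score
#'
#' Ten Likert items scored 1-5 (strongly disagree to strongly agree).
#' Odd-numbered items are positively worded and contribute
#' `score - 1`; even-numbered items are negatively worded and contribute
#' `5 - score`; the sum is scaled by 2.5, giving a score in [0, 100]
#' (above 80 is conventionally considered excellent).
#'
#' @param items integer vector of exactly 10 scores in 1..5.
#' @return the SUS score, a number in [0, 100].
#' @examples
#' susScore(rep(3, 10))  # 50
#' @export
susScore <- function(items) {
  if (length(items) != 10L) stopf("SUS needs exactly 10 items, got %d",
                                  length(items))
  if (any(is.na(items)) || any(items != round(items)) ||
      any(items < 1 | items > 5))
    stopf("SUS items must be integers in 1..5")
  odd <- items[c(1, 3, 5, 7, 9)]
  even <- items[c(2, 4, 6, 8, 10)]
  2.5 * (sum(odd - 1) + sum(5 - even))
}

#' Kruskal-Wallis rank test across groups
#'
#' Rank-based comparison of two or more independent samples (e.g. SUS
#' scores across testing rounds): the tie-corrected H statistic with a
#' chi-square approximation on k-1 degrees of freedom. A degenerate input
#' in which every value is identical has no separation: H = 0, p = 1.
#'
#' @param groups list of at least two non-empty numeric vectors.
#' @return list with `H`, `df` and `p`.
#' @export
kruskalWallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stopf("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0L))
    stopf("groups must be non-empty")
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}
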