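# Free-text lookup: normalisation, synonym expansion, scored ranking,
# wizard interception, and a terminal missing-food fallback.

#' Normalize a free-text query
#'
#' Lowercases, strips punctuation (digits are retained so brand names like
#' "50/50" stay findable) and tokenizes on whitespace. Deterministic; the
#' empty string yields an empty token vector.
#'
#' @param text a character string.
#' @return character vector of tokens.
#' @examples
#' normalizeQuery("Tuna  Sandwich!")
#' @export
normalizeQuery <- function(text) {
  if (length(text) != 1L || is.na(text)) return(character(0))
  s <- tolower(text)
  s <- gsub("[^a-z0-9]+", " ", s)
  toks <- strsplit(trimws(s), " +")[[1]]
  toks[nzchar(toks)]
}

expandTokens <- function(db, tokens) {
  out <- tokens
  for (set in db@synonymSets)
    if (any(tokens %in% set)) out <- c(out, set)
  unique(out)
}

# Scoring: exact full-description match dominates, then all-tokens-match,
# then per-token exact > prefix > fuzzy (edit distance 1). Isolated here as
# the single open ranking decision.
scoreFood <- function(query_tokens, expanded_tokens, food) {
  desc_tokens <- normalizeQuery(food$description)
  syn_tokens <- unique(unlist(lapply(food$synonyms, normalizeQuery)))
  food_tokens <- unique(c(desc_tokens, syn_tokens))
  if (length(query_tokens) == 0L || length(food_tokens) == 0L) return(0)
  if (identical(query_tokens, desc_tokens)) return(1e6)
  per_token <- vapply(expanded_tokens, function(qt) {
    if (qt %in% food_tokens) return(100)
    if (nchar(qt) >= 2L && any(startsWith(food_tokens, qt))) return(30)
    if (nchar(qt) >= 4L &&
        any(utils::adist(qt, food_tokens) <= 1L)) return(10)
    0
  }, numeric(1))
  score <- sum(per_token)
  matched_orig <- vapply(query_tokens, function(qt) {
    qt %in% food_tokens ||
      (nchar(qt) >= 2L && any(startsWith(food_tokens, qt))) ||
      (nchar(qt) >= 4L && any(utils::adist(qt, food_tokens) <= 1L))
  }, logical(1))
  if (length(matched_orig) && all(matched_orig)) score <- score + 500
  score
}

#' Look up foods matching a free-text query
#'
#' Returns a ranked match list. If any query token (after synonym
#' expansion) is a sandwich trigger term (default set: sandwich, roll,
#' butty, wrap) the sandwich-wizard entry is placed at rank 1; likewise a
#' salad trigger surfaces the salad wizard. Matching foods follow by
#' descending score (exact description match outranks everything else;
#' ties break alphabetically by description then food code), and a
#' missing-food fallback entry is always appended last so that items
#' absent from the database can still be captured.
#'
#' @param db a [FoodDatabase-class].
#' @param query raw query text.
#' @param max_results maximum number of food rows returned (wizard and
#'   missing-food entries not counted). Default 50.
#' @return data.frame with columns `target` (food code or one of
#'   `SANDWICH_WIZARD`, `SALAD_WIZARD`, `MISSING_FOOD`), `score`,
#'   `matched_text`.
#' @examples
#' db <- generateFoodDb()
#' head(lookupFood(db, "tuna sandwich"), 3)
#' @export
lookupFood <- function(db, query, max_results = 50L) {
  tokens <- normalizeQuery(query)
  expanded <- expandTokens(db, tokens)
  rows <- list()
  if (any(expanded %in% db@sandwichTriggers))
    rows[[length(rows) + 1L]] <- data.frame(
      target = "SANDWICH_WIZARD", score = Inf, matched_text = "Build my sandwich")
  if (any(expanded %in% db@saladTriggers))
    rows[[length(rows) + 1L]] <- data.frame(
      target = "SALAD_WIZARD", score = Inf, matched_text = "Build my salad")
  if (length(tokens)) {
    scores <- vapply(db@foods, function(f)
      scoreFood(tokens, expanded, f), numeric(1))
    keep <- which(scores > 0)
    if (length(keep)) {
      descs <- vapply(db@foods[keep], `[[`, character(1), "description")
      codes <- names(db@foods)[keep]
      ord <- order(-scores[keep], descs, codes)
      ord <- ord[seq_len(min(length(ord), max_results))]
      rows[[length(rows) + 1L]] <- data.frame(
        target = codes[ord], score = unname(scores[keep][ord]),
        matched_text = descs[ord])
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(
    target = "MISSING_FOOD", score = 0, matched_text = "My food is not in the list")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
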