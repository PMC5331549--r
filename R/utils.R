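`%||%` <- function(x, y) if (is.null(x)) y else x

#' Parse a clock time
#'
#' Converts "HH:MM" to minutes since midnight. Times must lie in
#' [00:00, 24:00).
#'
#' @param x character vector of "HH:MM" strings.
#' @return integer vector of minutes since midnight.
#' @examples
#' parseClock("13:00")
#' @export
parseClock <- function(x) {
  out <- vapply(x, function(s) {
    m <- regmatches(s, regexec("^([0-9]{1,2}):([0-9]{2})$", s))[[1]]
    if (length(m) != 3L) stop("invalid clock time: ", s, call. = FALSE)
    h <- as.integer(m[2]); mn <- as.integer(m[3])
    if (h >= 24L || mn >= 60L) stop("clock time out of range: ", s, call. = FALSE)
    h * 60L + mn
  }, integer(1), USE.NAMES = FALSE)
  out
}

#' Format minutes since midnight as "HH:MM"
#'
#' @param m integer vector of minutes since midnight.
#' @return character vector.
#' @export
formatClock <- function(m) {
  sprintf("%02d:%02d", m %/% 60L, m %% 60L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

isString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

isCount <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
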