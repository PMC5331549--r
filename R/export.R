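# Researcher-facing functions: entry-level CSV export, activity
# reporting, and the survey lifecycle (start / suspend / end /
# reschedule, with a submission gate).

#' Export submitted recalls as entry-level CSV
#'
#' One row per food entry in a stable long format: identification columns
#' (survey, user, submission time, meal name and time, raw text, food
#' code, food groups, portion method variant, weight), then one column
#' per nutrient. Rows are ordered deterministically by user, meal time,
#' then entry order; output is UTF-8 with RFC-4180 quoting, suitable for
#' direct upload to statistical packages.
#'
#' @param records list of [RecallRecord-class] objects from one survey.
#' @param path optional file path; when omitted the CSV is returned as a
#'   single string.
#' @return the CSV text (invisibly when written to `path`).
#' @export
exportCsv <- function(records, path = NULL) {
  surveys <- unique(vapply(records, function(r) r@survey_id, character(1)))
  if (length(surveys) > 1L)
    stopf("records span multiple surveys: %s", paste(surveys, collapse = ", "))
  rows <- lapply(records, function(r) {
    e <- r@entries
    if (nrow(e) == 0L) return(NULL)
    cbind(data.frame(survey_id = r@survey_id, user_id = r@user_id,
                     submission_time = r@submit_time),
          e[setdiff(names(e), "entry_id")],
          data.frame(entry_order = seq_len(nrow(e))))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  df <- if (length(rows)) do.call(rbind, rows) else emptyExportFrame(records)
  if (nrow(df)) {
    ord <- order(df$user_id, parseClock(df$meal_time), df$entry_order)
    df <- df[ord, setdiff(names(df), "entry_order"), drop = FALSE]
    rownames(df) <- NULL
  } else df <- df[, setdiff(names(df), "entry_order"), drop = FALSE]
  con <- textConnection("out", "w", local = TRUE)
  utils::write.csv(df, con, row.names = FALSE, fileEncoding = "")
  close(con)
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "", useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

emptyExportFrame <- function(records) {
  proto <- if (length(records)) records[[1]]@entries[0, , drop = FALSE] else
    data.frame(meal_name = character(0), meal_time = character(0),
               entry_id = integer(0), raw_text = character(0),
               kind = character(0), provenance = character(0),
               food_code = character(0), missing_food = logical(0),
               food_groups = character(0), portion_method = character(0))
  cbind(data.frame(survey_id = character(0), user_id = character(0),
                   submission_time = numeric(0)),
        proto[setdiff(names(proto), "entry_id")],
        data.frame(entry_order = integer(0)))
}

#' Participant activity report
#'
#' Per participant: number of recall submissions, mean / minimum /
#' maximum completion time in seconds, and the submission times.
#' Participants listed in `participants` but with no submissions appear
#' with a count of 0.
#'
#' @param records list of [RecallRecord-class] objects.
#' @param participants optional character vector of user ids to include
#'   even when they have no submissions.
#' @return data.frame with columns `user_id`, `submissions`,
#'   `mean_seconds`, `min_seconds`, `max_seconds`, `submission_dates`
#'   (semicolon-joined).
#' @export
activityReport <- function(records, participants = NULL) {
  users <- vapply(records, function(r) r@user_id, character(1))
  all_users <- sort(unique(c(users, participants)))
  rows <- lapply(all_users, function(u) {
    rs <- records[users == u]
    if (length(rs) == 0L)
      return(data.frame(user_id = u, submissions = 0L,
                        mean_seconds = NA_real_, min_seconds = NA_real_,
                        max_seconds = NA_real_, submission_dates = ""))
    secs <- vapply(rs, function(r) r@completion_seconds, numeric(1))
    subs <- vapply(rs, function(r) r@submit_time, numeric(1))
    data.frame(user_id = u, submissions = length(rs),
               mean_seconds = mean(secs), min_seconds = min(secs),
               max_seconds = max(secs),
               submission_dates = paste(
                 format(as.Date(as.POSIXct(subs, origin = "1970-01-01",
                                           tz = "UTC"))), collapse = ";"))
  })
  out <- do.call(rbind, rows) %||%
    data.frame(user_id = character(0), submissions = integer(0),
               mean_seconds = numeric(0), min_seconds = numeric(0),
               max_seconds = numeric(0), submission_dates = character(0))
  rownames(out) <- NULL
  out
}

#' Create a survey
#'
#' @param survey_id identifier.
#' @param start_date,end_date schedule window (coerced to Date).
#' @param users data.frame with columns `username`, `password` (opaque
#'   strings; no hashing - credential management is out of scope), e.g.
#'   read from a two-column CSV.
#' @return a [SurveyState-class] with status RUNNING.
#' @export
newSurvey <- function(survey_id, start_date, end_date,
                      users = data.frame(username = character(0),
                                         password = character(0))) {
  new("SurveyState", survey_id = survey_id, status = "RUNNING",
      start_date = as.Date(start_date), end_date = as.Date(end_date),
      users = as.data.frame(users))
}

#' Change survey lifecycle state or schedule
#'
#' `start` resumes a suspended survey, `suspend` pauses it, `end`
#' terminates it (ENDED is absorbing: no transition leaves it), and
#' `reschedule` updates the start/end dates (which must remain ordered).
#'
#' @param state a [SurveyState-class].
#' @param action "start", "suspend", "end" or "reschedule".
#' @param start_date,end_date new schedule for "reschedule".
#' @return the updated [SurveyState-class].
#' @export
surveyAction <- function(state, action = c("start", "suspend", "end",
                                           "reschedule"),
                         start_date = NULL, end_date = NULL) {
  action <- match.arg(action)
  if (state@status == "ENDED")
    stopf("survey %s has ended; no further transitions", state@survey_id)
  if (action == "start") state@status <- "RUNNING"
  else if (action == "suspend") state@status <- "SUSPENDED"
  else if (action == "end") state@status <- "ENDED"
  else {
    if (!is.null(start_date)) state@start_date <- as.Date(start_date)
    if (!is.null(end_date)) state@end_date <- as.Date(end_date)
  }
  validObject(state)
  state
}

#' Does the survey currently accept submissions?
#'
#' @param state a [SurveyState-class].
#' @param date submission date (coerced to Date).
#' @return TRUE iff the survey is RUNNING and `date` lies within the
#'   schedule window.
#' @export
acceptsSubmission <- function(state, date = Sys.Date()) {
  d <- as.Date(date)
  state@status == "RUNNING" && d >= state@start_date && d <= state@end_date
}
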