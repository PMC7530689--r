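#' Construct a cohort object
#'
#' A cohort couples a participant table (one row per participant, baseline
#' categorical covariates, empty string / `NA` = missing) with a test-event
#' table (participant ID, calendar date, result, condom-use response) and an
#' observation window. Events are stored sorted by participant and date;
#' ties (two tests by one participant on one date) are rejected.
#'
#' @param participants data.frame with column `participant_id` plus any
#'   subset of the [covariate_dictionary()] variables.
#' @param events data.frame with columns `participant_id`, `date` (Date or
#'   ISO 8601 string), `result` ("negative"/"positive"), `condom_use`
#'   (condom category or `NA`).
#' @param window length-2 Date vector (start, endpoint), start < endpoint.
#' @param check validate level membership and referential integrity
#'   (disable only for internal round trips).
#' @return An object of class `hivst_cohort`: list with elements
#'   `participants`, `events`, `window`.
#' @export
new_cohort <- function(participants, events, window, check = TRUE) {
  window <- unname(as.Date(window))
  stopifnot(length(window) == 2, !anyNA(window))
  if (!(window[1] < window[2])) stop("window start must precede the endpoint")

  participants <- as.data.frame(participants, stringsAsFactors = FALSE)
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  if (!"participant_id" %in% names(participants))
    stop("participants table lacks a participant_id column")
  participants$participant_id <- as.character(participants$participant_id)
  if (anyDuplicated(participants$participant_id))
    stop("duplicate participant_id in participant table: ",
         participants$participant_id[duplicated(participants$participant_id)][1])

  need <- c("participant_id", "date", "result", "condom_use")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("events table lacks column(s): ", paste(miss, collapse = ", "))
  events$participant_id <- as.character(events$participant_id)
  events$date <- as.Date(events$date)
  events$result <- as.character(events$result)
  events$condom_use <- as.character(events$condom_use)
  events$condom_use[!is.na(events$condom_use) & events$condom_use == ""] <- NA_character_

  if (check) {
    unknown <- setdiff(events$participant_id, participants$participant_id)
    if (length(unknown))
      stop("unknown participant in events table: ", unknown[1])
    bad <- !events$result %in% .results
    if (any(bad))
      stop("invalid test result '", events$result[bad][1], "'")
    badc <- !is.na(events$condom_use) & !events$condom_use %in% condom_levels()
    if (any(badc))
      stop("unknown categorical level '", events$condom_use[badc][1],
           "' for variable condom_use")
    dict <- covariate_dictionary()
    for (v in intersect(names(dict), names(participants))) {
      val <- as.character(participants[[v]])
      val[!is.na(val) & val == ""] <- NA_character_
      bad <- !is.na(val) & !val %in% dict[[v]]
      if (any(bad))
        stop("unknown categorical level '", val[bad][1], "' for variable ", v)
      participants[[v]] <- val
    }
  }

  dup <- duplicated(events[c("participant_id", "date")])
  if (any(dup))
    stop("duplicate (participant, date) test event: ",
         events$participant_id[dup][1], " on ", events$date[dup][1])

  events <- events[order(events$participant_id, events$date), , drop = FALSE]
  rownames(events) <- NULL
  rownames(participants) <- NULL

  structure(
    list(participants = participants, events = events,
         window = c(start = window[1], end = window[2])),
    class = "hivst_cohort")
}

#' @export
print.hivst_cohort <- function(x, ...) {
  cat("<hivst_cohort> ", nrow(x$participants), " participants, ",
      nrow(x$events), " test events\n", sep = "")
  cat("  window: ", format(x$window[1]), " .. ", format(x$window[2]), "\n", sep = "")
  invisible(x)
}

# strict ISO 8601 date parsing; returns Date with NA where invalid
.parse_iso_date <- function(x) {
  x <- as.character(x)
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out <- rep(as.Date(NA), length(x))
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d", optional = TRUE)
  out
}

#' Read a cohort from participant and event CSV files
#'
#' Ingests the two delimited tables, enforces the column schema, parses
#' dates strictly (any malformed date aborts naming the offending row),
#' checks referential integrity and level membership, rejects same-day
#' duplicate tests, and sorts events per participant by date. Events dated
#' strictly after the window endpoint are dropped with a warning (so one
#' event file can serve several analysis windows); dropped rows are listed
#' in the ingest report attached as attribute `"ingest_report"`.
#'
#' @param participants_path,events_path CSV paths (see the data dictionary
#'   in `inst/extdata` for the column schema).
#' @param window length-2 Date vector (start, endpoint).
#' @param warn_before_start warn when an event predates the window start.
#' @return A `hivst_cohort`; `attr(, "ingest_report")` is a list with
#'   `rows_read`, `rows_kept`, `rows_dropped` and a data.frame `dropped`
#'   (one row per rejected event, with its reason).
#' @export
read_cohort <- function(participants_path, events_path, window,
                        warn_before_start = TRUE) {
  window <- as.Date(window)
  participants <- utils::read.csv(participants_path, colClasses = "character",
                                  na.strings = "")
  events <- utils::read.csv(events_path, colClasses = "character", na.strings = "")
  need <- c("participant_id", "date", "result", "condom_use")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("events file lacks column(s): ", paste(miss, collapse = ", "))

  dates <- .parse_iso_date(events$date)
  if (anyNA(dates)) {
    i <- which(is.na(dates))[1]
    stop("malformed date '", events$date[i], "' in events row ", i)
  }
  events$date <- dates

  rows_read <- nrow(events)
  after_end <- events$date > window[2]
  dropped <- data.frame(row = which(after_end),
                        participant_id = events$participant_id[after_end],
                        date = events$date[after_end],
                        reason = rep("after window endpoint", sum(after_end)),
                        stringsAsFactors = FALSE)
  if (any(after_end)) {
    warning(sum(after_end), " event(s) after the window endpoint dropped")
    events <- events[!after_end, , drop = FALSE]
  }
  if (warn_before_start && any(events$date < window[1]))
    warning(sum(events$date < window[1]), " event(s) predate the window start")

  cohort <- new_cohort(participants, events, window)
  attr(cohort, "ingest_report") <- list(
    rows_read = rows_read,
    rows_kept = nrow(cohort$events),
    rows_dropped = nrow(dropped),
    dropped = dropped)
  cohort
}

#' Write a cohort to participant and event CSV files
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(c))` reproduces `c`
#' exactly (dates, levels, event order, missing sentinels). Missing values
#' are written as empty fields.
#'
#' @param cohort a `hivst_cohort`.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a named character vector of the two file paths.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "hivst_cohort"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory ", out_dir)
  pp <- file.path(out_dir, "participants.csv")
  ep <- file.path(out_dir, "events.csv")
  ev <- cohort$events
  ev$date <- format(ev$date, "%Y-%m-%d")
  utils::write.csv(cohort$participants, pp, row.names = FALSE, na = "")
  utils::write.csv(ev, ep, row.names = FALSE, na = "")
  invisible(c(participants = pp, events = ep))
}

#' Write / read the JSON mirror of a cohort
#'
#' One JSON document per participant with the covariates and the embedded,
#' date-ordered event list; the window is stored at the top level.
#'
#' @param cohort a `hivst_cohort`.
#' @param path JSON file path.
#' @return `write_cohort_json`: the path, invisibly. `read_cohort_json`:
#'   a `hivst_cohort`.
#' @export
write_cohort_json <- function(cohort, path) {
  stopifnot(inherits(cohort, "hivst_cohort"))
  ids <- cohort$participants$participant_id
  evs <- cohort$events
  evs$date <- format(evs$date, "%Y-%m-%d")
  by_id <- split(evs[c("date", "result", "condom_use")], evs$participant_id)
  docs <- lapply(seq_along(ids), function(i) {
    p <- as.list(cohort$participants[i, , drop = FALSE])
    p$events <- by_id[[ids[i]]] %||% data.frame(date = character(),
                                               result = character(),
                                               condom_use = character())
    p
  })
  jsonlite::write_json(
    list(window = format(unname(cohort$window), "%Y-%m-%d"), participants = docs),
    path, auto_unbox = TRUE, na = "null", dataframe = "rows", pretty = FALSE)
  invisible(path)
}

#' @rdname write_cohort_json
#' @export
read_cohort_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  window <- as.Date(unlist(doc$window))
  parts <- lapply(doc$participants, function(p) {
    p[setdiff(names(p), "events")]
  })
  pdf <- do.call(rbind, lapply(parts, function(p)
    as.data.frame(lapply(p, function(v) if (is.null(v)) NA_character_ else as.character(v)),
                  stringsAsFactors = FALSE)))
  evs <- do.call(rbind, lapply(doc$participants, function(p) {
    if (!length(p$events)) return(NULL)
    data.frame(participant_id = as.character(p$participant_id),
               date = vapply(p$events, function(e) as.character(e$date), ""),
               result = vapply(p$events, function(e) as.character(e$result), ""),
               condom_use = vapply(p$events, function(e)
                 if (is.null(e$condom_use)) NA_character_ else as.character(e$condom_use), ""),
               stringsAsFactors = FALSE)
  }))
  if (is.null(evs))
    evs <- data.frame(participant_id = character(), date = character(),
                      result = character(), condom_use = character())
  new_cohort(pdf, evs, window)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a cohort and report data-quality violations
#'
#' Report-only checks (nothing is modified, nothing errors): duplicate
#' same-day tests, events after the window endpoint, a negative test
#' following a confirmed positive, and the missingness fraction of every
#' dictionary covariate present.
#'
#' @param cohort a `hivst_cohort`.
#' @return List of class `hivst_validation`: `violations` (named counts) and
#'   `missingness` (named fractions).
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "hivst_cohort"))
  ev <- cohort$events
  dup <- sum(duplicated(ev[c("participant_id", "date")]))
  late <- sum(ev$date > cohort$window[2])
  neg_after_pos <- sum(vapply(split(ev$result, ev$participant_id), function(r) {
    pos <- which(r == "positive")
    if (!length(pos)) 0L else sum(r[seq_along(r) > pos[1]] == "negative")
  }, integer(1)))
  dict_vars <- intersect(names(covariate_dictionary()), names(cohort$participants))
  missingness <- vapply(dict_vars, function(v)
    mean(is.na(cohort$participants[[v]])), numeric(1))
  structure(list(
    violations = c(duplicate_same_day = dup,
                   after_endpoint = late,
                   negative_after_positive = neg_after_pos),
    missingness = missingness), class = "hivst_validation")
}

#' @export
print.hivst_validation <- function(x, ...) {
  cat("<cohort validation>\n")
  for (nm in names(x$violations))
    cat("  ", format(nm, width = 26), x$violations[[nm]], "\n")
  if (length(x$missingness)) {
    cat("  missingness:\n")
    for (nm in names(x$missingness))
      cat("    ", format(nm, width = 26), sprintf("%.3f", x$missingness[[nm]]), "\n")
  }
  invisible(x)
}
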