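# canonical pre-analytical flags
FLAG_LEVELS <- c("hemolysis", "lipemia", "clot")

#' Read a result stream from delimited text
#'
#' Reads a patient/QC result stream from CSV into the canonical tidy form used
#' throughout the package: one row per measurement with columns `timestamp`
#' (POSIXct, UTC), `center_id`, `analyte`, `value`, `flags` (list-column of
#' canonical flag names), `stream` (`"patient"` or `"qc"`), and `qc_level`.
#'
#' `schema` maps file column names and flag tokens onto the canonical form, so
#' exports from different middleware can be ingested without editing the file.
#' Timestamps must be non-decreasing within each (center, analyte, stream)
#' series; a regression is a hard error because the monitors' semantics (and
#' any lead-time computed from the event log) depend on time order.
#'
#' @param path CSV file path.
#' @param schema Optional list with elements `columns` (named character vector
#'   mapping canonical names to file column names) and `flag_map` (named
#'   character vector mapping file flag tokens to canonical flag names).
#'   Tokens `""`, `"none"`, and `NA` always mean "no flags"; multiple flags are
#'   separated by `;`.
#' @return A tibble of results in file order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' stream <- simulate_patient_stream(scenario_spec(n_samples = 5, seed = 1))$stream
#' write_results(stream, f)
#' read_results(f)
#' @export
read_results <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  columns <- c(
    timestamp = "timestamp", center_id = "center_id", analyte = "analyte",
    value = "value", flags = "flags", stream = "stream", qc_level = "qc_level"
  )
  flag_map <- stats::setNames(FLAG_LEVELS, FLAG_LEVELS)
  if (!is.null(schema)) {
    if (!is.null(schema$columns)) columns[names(schema$columns)] <- schema$columns
    if (!is.null(schema$flag_map)) flag_map <- unlist(schema$flag_map)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(unname(columns[c("timestamp", "analyte", "value")]), names(raw))
  optional <- c("center_id", "flags", "stream", "qc_level")
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  get_col <- function(canon, default) {
    nm <- columns[[canon]]
    if (nm %in% names(raw)) raw[[nm]] else rep(default, nrow(raw))
  }

  value <- suppressWarnings(as.numeric(get_col("value", NA_character_)))
  bad <- which(!is.finite(value))
  if (length(bad)) {
    stop("unparseable or non-finite value at data row ", bad[1], call. = FALSE)
  }
  ts_chr <- get_col("timestamp", NA_character_)
  timestamp <- parse_timestamp(ts_chr)
  bad <- which(is.na(timestamp))
  if (length(bad)) {
    stop("unparseable timestamp at data row ", bad[1], call. = FALSE)
  }

  flags <- parse_flags(get_col("flags", ""), flag_map)

  out <- tibble::tibble(
    timestamp = timestamp,
    center_id = get_col("center_id", "C1"),
    analyte = get_col("analyte", NA_character_),
    value = value,
    flags = flags,
    stream = get_col("stream", "patient"),
    qc_level = get_col("qc_level", NA_character_)
  )
  bad_stream <- setdiff(unique(out$stream), c("patient", "qc"))
  if (length(bad_stream)) {
    stop("unknown stream type(s): ", paste(bad_stream, collapse = ", "), call. = FALSE)
  }
  assert_time_ordered(out)
  out
}

parse_timestamp <- function(x) {
  ts <- as.POSIXct(x, tz = "UTC", tryFormats = c(
    "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"
  ))
  ts
}

parse_flags <- function(x, flag_map) {
  lapply(x, function(cell) {
    if (is.na(cell) || cell == "" || tolower(cell) == "none") {
      return(character(0))
    }
    tokens <- trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
    tokens <- tokens[tokens != ""]
    unknown <- setdiff(tokens, names(flag_map))
    if (length(unknown)) {
      stop("unknown flag token(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    unname(flag_map[tokens])
  })
}

assert_time_ordered <- function(stream) {
  ok <- stream |>
    dplyr::group_by(.data$center_id, .data$analyte, .data$stream) |>
    dplyr::summarise(ok = !is.unsorted(.data$timestamp), .groups = "drop")
  if (any(!ok$ok)) {
    bad <- ok[!ok$ok, ]
    stop(
      "timestamps regress within stream ",
      paste(bad$center_id[1], bad$analyte[1], bad$stream[1], sep = "/"),
      "; streams must be non-decreasing in time",
      call. = FALSE
    )
  }
  invisible(stream)
}

#' Write a result stream to delimited text
#'
#' Inverse of [read_results()]: writes the canonical stream columns as CSV
#' with ISO-8601 UTC timestamps and `;`-separated flag tokens, so that a
#' write-then-read round trip reproduces the stream exactly.
#'
#' @param stream A result tibble as produced by [read_results()] or
#'   [simulate_patient_stream()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(stream, path) {
  out <- stream
  out$timestamp <- format_timestamp(out$timestamp)
  out$flags <- vapply(out$flags, function(f) {
    if (length(f) == 0) "none" else paste(f, collapse = ";")
  }, character(1))
  readr::write_csv(out, path)
  invisible(path)
}

format_timestamp <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' Write / read a QC event log
#'
#' Event logs are tibbles with one row per QC event (see [run_monitoring()]):
#' columns `kind`, `classification`, `analyte`, `center_id`, `t_trigger`,
#' `t_confirmed`, `confirmed_by`, `action`, `note`. A confirmed alert keeps a
#' single row whose `classification` is `"dual"`, i.e. it counts under both
#' the alerting and the out-of-control tally. `write_events()` then
#' `read_events()` reproduces the log exactly.
#'
#' @param events Event tibble.
#' @param path CSV path.
#' @return `read_events()` returns the event tibble; `write_events()` returns
#'   `path` invisibly.
#' @export
write_events <- function(events, path) {
  events <- as_event_log(events)
  out <- events
  out$t_trigger <- format_timestamp(out$t_trigger)
  out$t_confirmed <- ifelse(
    is.na(events$t_confirmed), "", format_timestamp(events$t_confirmed)
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("kind", "classification", "analyte", "center_id", "t_trigger")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("missing event column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  blank_na <- function(x) ifelse(is.na(x) | x == "", NA_character_, x)
  tc <- blank_na(raw$t_confirmed %||% rep(NA_character_, nrow(raw)))
  tibble::tibble(
    kind = raw$kind,
    classification = raw$classification,
    analyte = raw$analyte,
    center_id = raw$center_id,
    t_trigger = parse_timestamp(raw$t_trigger),
    t_confirmed = as.POSIXct(
      ifelse(is.na(tc), NA, as.numeric(parse_timestamp(tc))),
      origin = "1970-01-01", tz = "UTC"
    ),
    confirmed_by = blank_na(raw$confirmed_by %||% rep(NA_character_, nrow(raw))),
    action = blank_na(raw$action %||% rep("none", nrow(raw))),
    note = blank_na(raw$note %||% rep(NA_character_, nrow(raw)))
  )
}

as_event_log <- function(events) {
  events <- tibble::as_tibble(events)
  n <- nrow(events)
  defaults <- list(
    t_confirmed = as.POSIXct(rep(NA_real_, n), origin = "1970-01-01", tz = "UTC"),
    confirmed_by = rep(NA_character_, n),
    action = rep("none", n),
    note = rep(NA_character_, n)
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(events)) events[[nm]] <- defaults[[nm]]
  }
  need <- c("kind", "classification", "analyte", "center_id", "t_trigger")
  missing <- setdiff(need, names(events))
  if (length(missing)) {
    stop("event log lacks column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(events$classification))) {
    stop("event classification must be populated before writing", call. = FALSE)
  }
  events[c(need, names(defaults))]
}
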