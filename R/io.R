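#' Read a minute-epoch actigraphy file
#'
#' Reads a long-format delimited text file (CSV, or TSV when the extension
#' is `.tsv`/`.txt`) with one row per recorded epoch, and returns a tidy
#' epoch table: one row per minute on each subject's complete minute grid,
#' with gaps in the recording marked as missing rather than dropped.
#'
#' The canonical dialect has columns `subject_id`, `timestamp`
#' (ISO-8601, minute resolution, local clock time -- no daylight-saving
#' adjustment is applied) and `count` (nonnegative activity counts).
#' Other column names can be mapped via the `subject`/`time`/`count`
#' arguments.
#'
#' @param file Path to a delimited epoch file.
#' @param subject,time,count Names of the subject-id, timestamp and count
#'   columns in `file`.
#' @param epoch_seconds Epoch length in seconds; must divide 86400.
#'   Only 60 s epochs are supported downstream by [daily_profiles()].
#' @return A tibble of class `tbl_epochs` with columns `subject_id`
#'   (character), `timestamp` (POSIXct, UTC-stored clock time), `count`
#'   (numeric, `NA` for missing minutes) and `missing` (logical), sorted
#'   by subject then time.  The epoch length is kept in the
#'   `epoch_seconds` attribute.
#' @seealso [write_epochs()], [read_covariates()], [daily_profiles()]
#' @export
read_epochs <- function(file, subject = "subject_id", time = "timestamp",
                        count = "count", epoch_seconds = 60L) {
  raw <- readr::read_delim(file, delim = .delim_for(file),
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  .assert_columns(raw, c(subject, time, count), paste0("read_epochs('", file, "')"))
  x <- tibble::tibble(
    subject_id = as.character(raw[[subject]]),
    timestamp  = lubridate::ymd_hms(raw[[time]], truncated = 3, tz = "UTC"),
    count      = as.numeric(raw[[count]])
  )
  if (anyNA(x$timestamp)) {
    abort(paste0("unparseable timestamp at row(s) ",
                 paste(head(which(is.na(x$timestamp)), 5), collapse = ", ")))
  }
  if (anyNA(x$count)) {
    abort(paste0("missing or non-numeric count at row(s) ",
                 paste(head(which(is.na(x$count)), 5), collapse = ", ")))
  }
  as_epochs(x, epoch_seconds = epoch_seconds)
}

#' Build a validated epoch table from a data frame
#'
#' Validates raw (subject_id, timestamp, count) rows, fills recording gaps
#' with explicit missing minutes, and returns the canonical `tbl_epochs`
#' used by the rest of the pipeline.  [read_epochs()] calls this after
#' parsing; call it directly on epochs assembled in R.
#'
#' @param x Data frame with columns `subject_id`, `timestamp` (POSIXct),
#'   `count`.  Within each subject, timestamps must be strictly
#'   increasing; duplicated (subject, timestamp) pairs and negative
#'   counts are errors.
#' @param epoch_seconds Epoch length in seconds (must divide 86400).
#' @return A `tbl_epochs` tibble (see [read_epochs()]).
#' @export
as_epochs <- function(x, epoch_seconds = 60L) {
  epoch_seconds <- as.integer(epoch_seconds)
  if (length(epoch_seconds) != 1 || is.na(epoch_seconds) ||
      epoch_seconds <= 0 || 86400L %% epoch_seconds != 0L) {
    abort("epoch_seconds must be a positive integer dividing 86400")
  }
  .assert_columns(x, c("subject_id", "timestamp", "count"), "as_epochs()")
  x <- tibble::as_tibble(x[c("subject_id", "timestamp", "count")])
  x$subject_id <- as.character(x$subject_id)

  neg <- which(!is.na(x$count) & x$count < 0)
  if (length(neg) > 0) {
    abort(paste0("negative count at row(s) ",
                 paste(head(neg, 5), collapse = ", ")))
  }
  key <- paste(x$subject_id, format(x$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort(paste0("duplicate (subject, timestamp): ", key[dup[1]]))
  }
  nonmono <- x |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::filter(dplyr::row_number() > 1 &
                    .data$timestamp <= dplyr::lag(.data$timestamp)) |>
    dplyr::ungroup()
  if (nrow(nonmono) > 0) {
    abort(paste0("non-monotone timestamps for subject '",
                 nonmono$subject_id[1], "' at row ", nonmono$.row[1]))
  }

  filled <- x |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::reframe({
      ts <- .data$timestamp
      cnt <- .data$count
      full <- seq(min(ts), max(ts), by = epoch_seconds)
      filled_cnt <- cnt[match(as.numeric(full), as.numeric(ts))]
      tibble::tibble(timestamp = full, count = filled_cnt)
    }) |>
    dplyr::mutate(missing = is.na(.data$count)) |>
    dplyr::arrange(.data$subject_id, .data$timestamp)

  new_tbl_epochs(filled, epoch_seconds)
}

new_tbl_epochs <- function(x, epoch_seconds) {
  structure(x,
            epoch_seconds = as.integer(epoch_seconds),
            class = c("tbl_epochs", class(tibble::tibble())))
}

#' Write a minute-epoch actigraphy file
#'
#' Writes the canonical long CSV dialect (`subject_id`, ISO-8601
#' `timestamp`, `count`); missing minutes are omitted, so
#' `read_epochs(write_epochs(x))` reconstructs `x` exactly.
#'
#' @param epochs A `tbl_epochs` (or compatible data frame).
#' @param file Destination path.
#' @return `file`, invisibly.
#' @export
write_epochs <- function(epochs, file) {
  .assert_columns(epochs, c("subject_id", "timestamp", "count"), "write_epochs()")
  keep <- if ("missing" %in% names(epochs)) !epochs$missing else !is.na(epochs$count)
  out <- tibble::tibble(
    subject_id = as.character(epochs$subject_id[keep]),
    timestamp = format(epochs$timestamp[keep], "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    count = epochs$count[keep]
  )
  readr::write_csv(out, file, progress = FALSE)
  invisible(file)
}

#' Read a subject covariate table
#'
#' Reads a delimited table with one row per subject: a subject-id column
#' plus one or more numeric covariates (e.g. apnea-hypopnea index, BMI).
#' Empty cells and `na` markers become `NA`; subjects with missing
#' covariates are retained here and dropped per-model by
#' [build_design()]'s complete-case rule.
#'
#' @param file Path to a CSV/TSV covariate file.
#' @param subject Name of the subject-id column.
#' @param na Strings read as missing.
#' @return A tibble with `subject_id` (character, unique) plus one numeric
#'   column per covariate.
#' @export
read_covariates <- function(file, subject = "subject_id",
                            na = c("", "NA", "na", ".")) {
  raw <- readr::read_delim(file, delim = .delim_for(file), na = na,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  .assert_columns(raw, subject, paste0("read_covariates('", file, "')"))
  covs <- setdiff(names(raw), subject)
  if (length(covs) == 0) abort("covariate file has no covariate columns")
  out <- tibble::tibble(subject_id = as.character(raw[[subject]]))
  if (anyDuplicated(out$subject_id)) {
    abort(paste0("duplicate subject_id: ",
                 out$subject_id[duplicated(out$subject_id)][1]))
  }
  for (v in covs) {
    val <- raw[[v]]
    num <- suppressWarnings(as.numeric(val))
    bad <- which(!is.na(val) & is.na(num))
    if (length(bad) > 0) {
      abort(paste0("non-numeric value '", val[bad[1]], "' in covariate '",
                   v, "' at row ", bad[1]))
    }
    out[[v]] <- num
  }
  out
}

#' Keep subjects with complete data on selected covariates
#'
#' @param covariates Covariate tibble from [read_covariates()].
#' @param vars Character vector of covariate column names.
#' @return The rows of `covariates` with no `NA` in any of `vars`.
#' @export
complete_cases <- function(covariates, vars) {
  .assert_columns(covariates, vars, "complete_cases()")
  dplyr::filter(covariates,
                dplyr::if_all(dplyr::all_of(vars), ~ !is.na(.x)))
}

#' Summarise an epoch table for validation
#'
#' @param epochs A `tbl_epochs`.
#' @param file Optional path; when given, the summary is also written as
#'   JSON.
#' @return A list with per-dataset and per-subject counts: subjects,
#'   total minutes, missing minutes, time span, and total non-missing
#'   count mass.
#' @export
epoch_validation <- function(epochs, file = NULL) {
  per <- epochs |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_minutes = dplyr::n(),
                     n_missing = sum(.data$missing),
                     first = format(min(.data$timestamp), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                     last = format(max(.data$timestamp), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                     total_count = sum(.data$count, na.rm = TRUE),
                     .groups = "drop")
  out <- list(
    n_subjects = nrow(per),
    n_minutes = sum(per$n_minutes),
    n_missing = sum(per$n_missing),
    total_count = sum(per$total_count),
    epoch_seconds = attr(epochs, "epoch_seconds") %||% 60L,
    subjects = per
  )
  if (!is.null(file)) {
    jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
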