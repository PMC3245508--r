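#' Split epoch recordings into calendar day vectors
#'
#' Cuts each subject's minute-epoch recording into calendar days, keeping
#' the days whose weekday is in `days`.  A day truncated by the start or
#' end of the recording (fewer than 1440 minutes inside the recorded
#' span) is dropped under `partial = "drop"`.  Minutes masked as missing
#' inside a kept day stay `NA`.
#'
#' @param epochs A `tbl_epochs` with 60-second epochs.
#' @param days Character vector of weekday names to keep
#'   (`"Mon"`..`"Sun"`); the default keeps midnight Monday to midnight
#'   Saturday, i.e. the five weekdays.
#' @param partial `"drop"` (default) discards edge days with incomplete
#'   coverage; `"keep"` retains them with the uncovered minutes `NA`.
#' @return A tibble with columns `subject_id`, `date`, `minute`
#'   (0--1439, minute `j` covering clock interval `[j, j+1)` after
#'   midnight) and `activity` (`NA` when missing/uncovered).
#' @export
split_days <- function(epochs, days = c("Mon", "Tue", "Wed", "Thu", "Fri"),
                       partial = c("drop", "keep")) {
  partial <- rlang::arg_match(partial)
  es <- attr(epochs, "epoch_seconds") %||% 60L
  if (es != 60L) abort("split_days() requires 60-second epochs; resample upstream")
  .assert_columns(epochs, c("subject_id", "timestamp", "count"), "split_days()")
  keep_wd <- .match_days(days)

  secs <- as.numeric(epochs$timestamp)
  date <- as.Date(floor(secs / 86400), origin = "1970-01-01")
  minute <- as.integer((secs %/% 60) %% 1440)
  x <- tibble::tibble(subject_id = as.character(epochs$subject_id),
                      date = date, minute = minute,
                      activity = as.numeric(epochs$count))
  if ("missing" %in% names(epochs)) {
    x$activity[epochs$missing] <- NA_real_
  }

  x <- x[.wday_mon1(x$date) %in% keep_wd, , drop = FALSE]
  if (nrow(x) == 0) abort("no usable days")

  # expand every (subject, kept day) to the full 1440-minute grid
  full <- x |>
    dplyr::distinct(.data$subject_id, .data$date) |>
    dplyr::reframe(minute = 0:1439, .by = c("subject_id", "date")) |>
    dplyr::left_join(x, by = c("subject_id", "date", "minute"))

  if (partial == "drop") {
    covered <- x |>
      dplyr::count(.data$subject_id, .data$date, name = "n_covered")
    full <- full |>
      dplyr::left_join(covered, by = c("subject_id", "date")) |>
      dplyr::filter(.data$n_covered == 1440L) |>
      dplyr::select(-"n_covered")
  }
  dplyr::arrange(full, .data$subject_id, .data$date, .data$minute)
}

#' Average weekday recordings into one circadian profile per subject
#'
#' Implements the averaging step of the pipeline: each subject's kept
#' weekdays are averaged minute by minute into a single midnight-to-
#' midnight 1440-point profile, the input to [smooth_profiles()].
#'
#' @inheritParams split_days
#' @param min_days Minimum number of usable days per subject; subjects
#'   below it are excluded with a warning (default 3).
#' @param missing Within-day missing-minute policy: `"ignore"` averages
#'   the available days at each minute (error if some minute has no data
#'   in any day); `"complete"` errors if any kept day has a missing
#'   minute.
#' @return A tibble of class `tbl_profiles` with columns `subject_id`,
#'   `minute` (0--1439), `activity` (counts/min, finite and >= 0) and
#'   `n_days` (days averaged), 1440 rows per retained subject.
#' @export
daily_profiles <- function(epochs, days = c("Mon", "Tue", "Wed", "Thu", "Fri"),
                           min_days = 3L, partial = c("drop", "keep"),
                           missing = c("ignore", "complete")) {
  partial <- rlang::arg_match(partial)
  missing <- rlang::arg_match(missing)
  dayrows <- split_days(epochs, days = days, partial = partial)
  if (nrow(dayrows) == 0) abort("no usable days")

  all_subjects <- sort(unique(as.character(epochs$subject_id)))
  kept <- list()
  excluded <- character(0)
  for (sid in all_subjects) {
    d <- dayrows[dayrows$subject_id == sid, , drop = FALSE]
    n_days <- length(unique(d$date))
    if (n_days < min_days) {
      excluded <- c(excluded, sid)
      next
    }
    # days x 1440 matrix: rows in date order, columns minute 0..1439
    m <- matrix(d$activity[order(d$date, d$minute)],
                nrow = n_days, ncol = 1440, byrow = TRUE)
    if (missing == "complete" && anyNA(m)) {
      abort(paste0("subject '", sid, "': missing minutes under missing = 'complete'"))
    }
    n_obs <- colSums(!is.na(m))
    if (any(n_obs == 0)) {
      abort(paste0("subject '", sid, "': no data at minute(s) ",
                   paste(head(which(n_obs == 0) - 1L, 10), collapse = ", ")))
    }
    prof <- colSums(m, na.rm = TRUE) / n_obs
    kept[[sid]] <- tibble::tibble(subject_id = sid, minute = 0:1439,
                                  activity = prof, n_days = n_days)
  }
  if (length(kept) == 0) abort("no usable days")
  if (length(excluded) > 0) {
    warn(paste0("excluded ", length(excluded), " subject(s) with < ",
                min_days, " usable days: ",
                paste(head(excluded, 10), collapse = ", ")))
  }
  out <- dplyr::bind_rows(kept)
  structure(out, class = c("tbl_profiles", class(tibble::tibble())))
}

# profiles tibble -> N x G matrix (rows = subjects in sorted order),
# checking every subject covers the same minute grid
profiles_matrix <- function(profiles) {
  .assert_columns(profiles, c("subject_id", "minute", "activity"),
                  "profiles_matrix()")
  grid <- sort(unique(profiles$minute))
  subj <- sort(unique(as.character(profiles$subject_id)))
  x <- dplyr::arrange(tibble::as_tibble(profiles), .data$subject_id, .data$minute)
  if (nrow(x) != length(grid) * length(subj)) {
    abort("profiles: subjects do not share a common minute grid")
  }
  if (anyNA(x$activity)) abort("profiles contain NA activity")
  m <- matrix(x$activity, nrow = length(subj), byrow = TRUE,
              dimnames = list(subj, NULL))
  attr(m, "grid") <- grid
  m
}

#' Write circadian profiles as a wide CSV
#'
#' One row per subject with columns `subject_id`, `n_days`,
#' `m0000`..`m1439`.
#'
#' @param profiles A `tbl_profiles` from [daily_profiles()].
#' @param file Destination path.
#' @return `file`, invisibly.
#' @export
write_profiles <- function(profiles, file) {
  wide <- profiles |>
    dplyr::mutate(minute = sprintf("m%04d", .data$minute)) |>
    tidyr::pivot_wider(id_cols = c("subject_id", dplyr::any_of("n_days")),
                       names_from = "minute", values_from = "activity")
  readr::write_csv(wide, file, progress = FALSE)
  invisible(file)
}
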