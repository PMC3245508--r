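# Day-name codes used throughout: Mon=1 .. Sun=7.
.day_names <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")

# Weekday index (Mon=1..Sun=7) of a Date; 1970-01-01 was a Thursday.
.wday_mon1 <- function(date) {
  ((as.integer(date) + 3L) %% 7L) + 1L
}

.match_days <- function(days) {
  idx <- match(days, .day_names)
  if (anyNA(idx)) {
    abort(paste0("unknown day name(s): ",
                 paste(days[is.na(idx)], collapse = ", "),
                 " (use ", paste(.day_names, collapse = "/"), ")"))
  }
  idx
}

#' Format minute-of-day as HH:MM clock time
#'
#' @param minute Integer minute of day (0--1439; values are taken mod 1440).
#' @return Character vector of "HH:MM" labels.
#' @examples
#' minute_to_hhmm(c(0, 420, 1259))
#' @export
minute_to_hhmm <- function(minute) {
  m <- as.integer(round(minute)) %% 1440L
  sprintf("%02d:%02d", m %/% 60L, m %% 60L)
}

# delimiter by file extension: .tsv/.txt -> tab, otherwise comma
.delim_for <- function(file) {
  if (grepl("\\.(tsv|txt)$", file, ignore.case = TRUE)) "\t" else ","
}

.assert_columns <- function(df, cols, where) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(where, ": missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
}
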