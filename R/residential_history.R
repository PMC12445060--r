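# Cleaning of month-resolution residential histories.
#
# Records carry a subject id, date of birth, a sector id, and FROM / TO
# month+year pairs. Cleaning applies the study's rules:
#   * missing FROM month -> 1 July of the FROM year; missing TO month ->
#     30 June of the TO year (the mid-year default);
#   * a FROM date before the subject's date of birth is replaced by the DOB,
#     provided the DOB falls inside the exposure window;
#   * records missing a FROM or TO year are dropped;
#   * sector ids absent from the grid are dropped;
#   * surviving intervals are clipped to the exposure window
#     (July 1952 - December 1988) intersected with the subject's lifetime.
# Residence is taken to start on the first day of the FROM month and end on
# the last day of the TO month. Cleaning is idempotent.

EXPOSURE_WINDOW_START <- as.Date("1952-07-01")
EXPOSURE_WINDOW_END <- as.Date("1988-12-31")

#' Decode a SAS day count into a date
#'
#' SAS stores dates as signed day counts from the origin 1 January 1960.
#'
#' @param days Integer day offsets (vectorised).
#' @return `Date` vector.
#' @export
sas_date_decode <- function(days) {
  as.Date(days, origin = "1960-01-01")
}

#' Clean a set of residential-history records
#'
#' @param records Data frame with columns `subject_id`, `dob` (ISO-8601 date
#'   string, `Date`, or SAS day integer; integers are auto-detected),
#'   `sector_id`, `from_year`, `from_month`, `to_year`, `to_month`
#'   (`NA` = missing).
#' @param grid Optional [sector_grid()]; when supplied, records whose
#'   `sector_id` is not on the grid are dropped.
#' @param window_start,window_end Exposure window (defaults July 1952 -
#'   December 1988, the coverage of the release timeline).
#' @return Tibble with the input columns plus `from_date`, `to_date`,
#'   `flags` (comma-joined), and `dropped` (logical). Dropped rows keep their
#'   drop reason in `flags`.
#' @export
clean_residences <- function(records, grid = NULL,
                             window_start = EXPOSURE_WINDOW_START,
                             window_end = EXPOSURE_WINDOW_END) {
  need <- c("subject_id", "dob", "sector_id",
            "from_year", "from_month", "to_year", "to_month")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  r <- tibble::as_tibble(records)
  n <- nrow(r)
  if (n == 0L) {
    r$from_date <- as.Date(character())
    r$to_date <- as.Date(character())
    r$flags <- character()
    r$dropped <- logical()
    return(r)
  }

  dob <- decode_dob(r$dob)
  flags <- vector("list", n)
  if ("flags" %in% names(records)) {
    # re-cleaning: keep previously assigned flags so cleaning is idempotent
    flags <- lapply(strsplit(ifelse(is.na(records$flags), "", records$flags), ","),
                    function(f) f[nzchar(f)])
  }
  add_flag <- function(i, f) flags[i] <<- lapply(flags[i], function(x) union(x, f))

  dropped <- rep(FALSE, n)

  # rule: missing year -> drop
  miss_year <- is.na(r$from_year) | is.na(r$to_year)
  dropped[miss_year] <- TRUE
  add_flag(which(miss_year), "dropped_missing_year")

  # rule: default months (flag only when the month was actually absent)
  dfm <- !miss_year & is.na(r$from_month)
  dtm <- !miss_year & is.na(r$to_month)
  add_flag(which(dfm), "defaulted_from_month")
  add_flag(which(dtm), "defaulted_to_month")
  from_month <- ifelse(is.na(r$from_month), 7L, as.integer(r$from_month))
  to_month <- ifelse(is.na(r$to_month), 6L, as.integer(r$to_month))

  from_date <- rep(as.Date(NA), n)
  to_date <- rep(as.Date(NA), n)
  ok <- !miss_year
  from_date[ok] <- index_first_day(ym_index(as.integer(r$from_year[ok]),
                                            from_month[ok]))
  to_date[ok] <- index_last_day(ym_index(as.integer(r$to_year[ok]),
                                         to_month[ok]))

  # carry an explicit FROM day when one is already present (re-cleaning a
  # dob-overridden record must not snap it back to the first of the month)
  if ("from_date" %in% names(records)) {
    prev <- as.Date(records$from_date)
    same_month <- month_index_of_date_safe(prev) ==
      ifelse(is.na(r$from_year), NA_integer_, 12L * as.integer(r$from_year) + (from_month - 1L))
    keep <- ok & !is.na(prev) & !is.na(same_month) & same_month
    from_date[keep] <- prev[keep]
  }

  # rule: unmappable sector
  if (!is.null(grid)) {
    bad_sector <- ok & (is.na(r$sector_id) | !(r$sector_id %in% grid$id))
    dropped[bad_sector] <- TRUE
    add_flag(which(bad_sector), "dropped_unmappable")
    ok <- ok & !bad_sector
  } else {
    bad_sector <- ok & is.na(r$sector_id)
    dropped[bad_sector] <- TRUE
    add_flag(which(bad_sector), "dropped_unmappable")
    ok <- ok & !bad_sector
  }

  # rule: DOB override, only for DOBs inside the window; subjects born after
  # the window contribute nothing and are dropped
  born_late <- ok & !is.na(dob) & dob > window_end
  dropped[born_late] <- TRUE
  add_flag(which(born_late), "dropped_outside_window")
  ok <- ok & !born_late

  ovr <- ok & !is.na(dob) & from_date < dob & dob >= window_start
  from_date[ovr] <- dob[ovr]
  add_flag(which(ovr), "dob_override")

  # clip to the exposure window (and implicitly to lifetime via the override)
  outside <- ok & (to_date < window_start | from_date > window_end)
  dropped[outside] <- TRUE
  add_flag(which(outside), "dropped_outside_window")
  ok <- ok & !outside
  from_date[ok] <- pmax(from_date[ok], window_start)
  to_date[ok] <- pmin(to_date[ok], window_end)

  # inverted interval after cleaning (e.g. defaulted months crossing)
  inv <- ok & to_date < from_date
  dropped[inv] <- TRUE
  add_flag(which(inv), "dropped_inverted")

  r$from_month <- ifelse(dropped, r$from_month, from_month)
  r$to_month <- ifelse(dropped, r$to_month, to_month)
  r$from_date <- as.Date(ifelse(dropped, NA, from_date),
                         origin = "1970-01-01")
  r$to_date <- as.Date(ifelse(dropped, NA, to_date), origin = "1970-01-01")
  r$flags <- vapply(flags, function(f) paste(sort(f %||% character()), collapse = ","),
                    character(1))
  r$dropped <- dropped
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

month_index_of_date_safe <- function(d) {
  out <- rep(NA_integer_, length(d))
  ok <- !is.na(d)
  out[ok] <- month_index_of_date(d[ok])
  out
}

decode_dob <- function(dob) {
  if (inherits(dob, "Date")) return(dob)
  if (is.numeric(dob)) return(sas_date_decode(dob))
  # character: ISO strings, or digit strings holding SAS day counts
  numlike <- grepl("^\\s*-?\\d+\\s*$", dob)
  out <- rep(as.Date(NA), length(dob))
  out[numlike & !is.na(dob)] <- sas_date_decode(as.integer(dob[numlike & !is.na(dob)]))
  out[!numlike & !is.na(dob)] <- as.Date(dob[!numlike & !is.na(dob)])
  out
}

#' Fraction of a calendar year covered by a residence record
#'
#' A month counts as resident when the record covers at least one day of it.
#'
#' @param record One cleaned record (a list or one-row data frame with
#'   `from_date` and `to_date`).
#' @param year Calendar year.
#' @return List with `fraction` (months resident / 12) and `months`
#'   (integer vector of resident months).
#' @export
occupancy_fraction <- function(record, year) {
  from <- as.Date(record$from_date[[1]])
  to <- as.Date(record$to_date[[1]])
  if (is.na(from) || is.na(to)) return(list(fraction = 0, months = integer()))
  lo <- max(ym_index(year, 1L), month_index_of_date(from))
  hi <- min(ym_index(year, 12L), month_index_of_date(to))
  if (lo > hi) return(list(fraction = 0, months = integer()))
  months <- index_month(seq.int(lo, hi))
  list(fraction = length(months) / 12, months = months)
}

#' Missing-data report for a set of raw records
#'
#' Tallies missing FROM/TO month and year at the residence level and at the
#' subject level (subjects with at least one affected record), with
#' percentages, plus counts surviving the full cleaning.
#'
#' @param records Raw records as for [clean_residences()].
#' @param grid Optional [sector_grid()] passed through to the cleaner.
#' @return List with tibbles `residences` and `subjects`, and scalar counts
#'   `n_residences`, `n_subjects`, `n_subjects_removed`,
#'   `n_subjects_retained`, `n_residences_retained`.
#' @export
cleaning_report <- function(records, grid = NULL) {
  r <- tibble::as_tibble(records)
  n_res <- nrow(r)
  n_sub <- length(unique(r$subject_id))
  fields <- c(from_month = "from_month", to_month = "to_month",
              from_year = "from_year", to_year = "to_year")
  res_counts <- vapply(fields, function(f) sum(is.na(r[[f]])), integer(1))
  sub_counts <- vapply(fields, function(f) {
    length(unique(r$subject_id[is.na(r[[f]])]))
  }, integer(1))
  pct <- function(k, n) if (n > 0) 100 * k / n else 0

  cleaned <- clean_residences(r, grid = grid)
  kept <- cleaned[!cleaned$dropped, ]
  retained_subjects <- length(unique(kept$subject_id))

  list(
    residences = tibble::tibble(field = names(fields),
                                missing = unname(res_counts),
                                pct = unname(pct(res_counts, n_res))),
    subjects = tibble::tibble(field = names(fields),
                              missing = unname(sub_counts),
                              pct = unname(pct(sub_counts, n_sub))),
    n_residences = n_res,
    n_subjects = n_sub,
    n_subjects_removed = n_sub - retained_subjects,
    n_subjects_retained = retained_subjects,
    n_residences_retained = nrow(kept)
  )
}

#' Subject accounting arithmetic
#'
#' Retained cohort size from an enrolled count and a removed count, as used
#' when reconciling published cohort tallies.
#'
#' @param n_enrolled Subjects entering the cleaning stage.
#' @param n_removed Subjects removed by filters.
#' @return List with `n_enrolled`, `n_removed`, `n_retained`.
#' @export
cohort_accounting <- function(n_enrolled, n_removed) {
  stopifnot(n_enrolled >= 0, n_removed >= 0, n_removed <= n_enrolled)
  list(n_enrolled = n_enrolled, n_removed = n_removed,
       n_retained = n_enrolled - n_removed)
}

#' Read residential-history records from CSV
#'
#' @param path CSV with columns `subject_id`, `dob`, `sector_id`,
#'   `from_year`, `from_month`, `to_year`, `to_month`; empty cells are
#'   missing. `dob` may be ISO-8601 or a SAS day integer.
#' @return Tibble of raw records.
#' @export
read_residences <- function(path) {
  tibble::as_tibble(read_csv_plain(path, na.strings = c("", "NA")))
}
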