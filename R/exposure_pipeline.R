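# Assembly of the sector x time concentration field and per-subject
# exposures.
#
# The concentration for a sector and month factorises as
#   conc(sector, y, m) = A(sector, m) * Q(y, m) * 1e9 / seconds_per_year
# where A(sector, m) folds the calibration factor, the month's per-stability
# wind ratios for the octet upwind of the sector, and the diffusion function
# at the sector's ring distance. The annual sector value is the mean of its
# 12 monthly values. Every subject resident in a sector for a month receives
# that sector-month concentration; annual subject exposure is the mean over
# resident months of the year, and the overall subject mean is the
# duration-weighted mean across years (equivalently the mean over all
# resident months).

#' Build the sector-by-time concentration matrix
#'
#' @param grid A [sector_grid()].
#' @param timeline An [emission_timeline()].
#' @param met List of 12 monthly [joint_frequency_table()]s.
#' @param calib A [calibration_params()].
#' @param config A [dispersion_config()].
#' @param years Calendar years to cover (default 1952-1988).
#' @param quantile Which release-rate quantile drives the source term.
#' @return Object of class `exposure_matrix`: list with `monthly`
#'   (sectors x months matrix, pCi/L), `annual` (sectors x years), the
#'   `sectors` tibble, `years`, and `month_idx`.
#' @export
build_exposure_matrix <- function(grid, timeline, met,
                                  calib = calibration_params(),
                                  config = dispersion_config(),
                                  years = 1952:1988,
                                  quantile = "median") {
  stopifnot(inherits(grid, "sector_grid"), inherits(timeline, "emission_timeline"),
            length(met) == 12L)
  for (tb in met) validate_jft(tb)

  upwind <- reciprocal_direction(grid$octet)
  xs <- grid$distance
  cf <- calibration_factor(calib, xs)

  # per-stability wind ratios on the octet grid, one 6 x 8 matrix per month
  ratios8 <- lapply(met, function(tb) {
    t(consolidate_16_to_8(wind_ratio_by_stability(tb)))  # 8 octets x 6 classes
  })

  # A[sector, month-of-year]: everything except the source term
  dmat <- matrix(vapply(STABILITY_CLASSES, function(s) diffusion(config, s, xs),
                        numeric(length(xs))), nrow = length(xs))  # sectors x 6
  A <- matrix(vapply(1:12, function(mo) {
    r <- ratios8[[mo]][upwind, , drop = FALSE]   # sectors x 6
    cf * rowSums(r * dmat)
  }, numeric(nrow(grid))), nrow = nrow(grid))    # sectors x 12

  month_idx <- seq.int(ym_index(min(years), 1L), ym_index(max(years), 12L))
  qv <- monthly_rate(timeline, index_year(month_idx), index_month(month_idx),
                     quantile)
  scale <- config$phi_resid * config$phi_met * 1e9 / config$seconds_per_year
  monthly <- A[, index_month(month_idx), drop = FALSE] *
    rep(qv * scale, each = nrow(grid))
  dimnames(monthly) <- list(grid$id, month_idx)

  annual <- matrix(vapply(years, function(y) {
    rowMeans(monthly[, as.character(ym_index(y, 1L:12L)), drop = FALSE])
  }, numeric(nrow(grid))), nrow = nrow(grid))
  dimnames(annual) <- list(grid$id, years)

  structure(list(monthly = monthly, annual = annual,
                 sectors = tibble::as_tibble(grid), years = years,
                 month_idx = month_idx),
            class = "exposure_matrix")
}

#' @export
print.exposure_matrix <- function(x, ...) {
  cat(sprintf("<exposure_matrix: %d sectors x %d years (monthly %d cells), max annual %.3g pCi/L>\n",
              nrow(x$annual), ncol(x$annual), length(x$monthly),
              max(x$annual)))
  invisible(x)
}

# look up sector-month concentrations for an expansion table
lookup_monthly <- function(matrix, expanded) {
  row <- match(expanded$sector_id, rownames(matrix$monthly))
  col <- match(as.character(expanded$month_idx), colnames(matrix$monthly))
  if (anyNA(row)) {
    stop("sector not in matrix: ",
         paste(unique(expanded$sector_id[is.na(row)]), collapse = ", "))
  }
  out <- numeric(nrow(expanded))
  ok <- !is.na(col)   # months outside matrix coverage contribute 0
  out[ok] <- matrix$monthly[cbind(row[ok], col[ok])]
  out
}

#' Per-subject annual and mean exposures
#'
#' @param matrix An [build_exposure_matrix()] result.
#' @param records Cleaned records from [clean_residences()].
#' @return List with `annual` (tibble: `subject_id`, `year`, `exposure`,
#'   `months`, `fraction`) and `means` (tibble: `subject_id`,
#'   `mean_exposure`, `years_resident`, `max_annual`). Subjects with no
#'   resident time have no rows.
#' @export
subject_exposures <- function(matrix, records) {
  ex <- expand_residence_months(matrix, records)
  annual <- ex |>
    dplyr::group_by(.data$subject_id, .data$year) |>
    dplyr::summarise(exposure = mean(.data$conc),
                     months = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(fraction = .data$months / 12)
  means <- annual |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      mean_exposure = sum(.data$exposure * .data$months) / sum(.data$months),
      years_resident = sum(.data$months) / 12,
      max_annual = max(.data$exposure),
      .groups = "drop"
    )
  list(annual = annual, means = means)
}

# shared month-level table: one row per resident subject-sector-month, with
# calendar year and the sector-month concentration attached
expand_residence_months <- local({
  inner <- function(records) {
    kept <- records[!records$dropped & !is.na(records$from_date), ]
    if (nrow(kept) == 0L) {
      return(tibble::tibble(subject_id = character(), sector_id = character(),
                            month_idx = integer()))
    }
    lo <- month_index_of_date(kept$from_date)
    hi <- month_index_of_date(kept$to_date)
    lens <- hi - lo + 1L
    tibble::tibble(
      subject_id = rep(kept$subject_id, lens),
      sector_id = rep(kept$sector_id, lens),
      month_idx = as.integer(sequence(lens) - 1L + rep(lo, lens))
    )
  }
  function(matrix, records) {
    ex <- inner(records)
    ex$year <- index_year(ex$month_idx)
    ex$conc <- lookup_monthly(matrix, ex)
    ex
  }
})

#' Annual exposure of one subject
#'
#' Occupancy-weighted mean over the subject's resident sector-months of the
#' year: monthly concentrations for partial years, which reduces to the
#' sector's annual value for a full year in one sector.
#'
#' @param matrix An exposure matrix.
#' @param records Cleaned records of one subject.
#' @param year Calendar year.
#' @return Exposure in pCi/L; `NA` when the subject was not resident.
#' @export
subject_annual_exposure <- function(matrix, records, year) {
  ex <- expand_residence_months(matrix, records)
  ex <- ex[ex$year == year, ]
  if (nrow(ex) == 0L) return(NA_real_)
  mean(ex$conc)
}

#' Duration-weighted mean exposure
#'
#' @param annual Numeric vector of annual exposures (pCi/L).
#' @param durations Matching vector of durations (years or months; only the
#'   relative weights matter).
#' @return Weighted arithmetic mean.
#' @export
subject_mean_exposure <- function(annual, durations) {
  stopifnot(length(annual) == length(durations))
  if (length(annual) == 0L || sum(durations) <= 0) {
    stop("subject has no resident time; mean exposure undefined")
  }
  sum(annual * durations) / sum(durations)
}

#' Count subjects exceeding an action level
#'
#' @param exposures Result of [subject_exposures()].
#' @param threshold Action level in pCi/L (EPA indoor action level: 4).
#' @param mode `"any_year"` counts subjects with at least one annual
#'   exposure above the threshold; `"overall_mean"` counts subjects whose
#'   duration-weighted mean exceeds it.
#' @return List with `count`, `fraction`, and `n` (cohort size with
#'   computed exposure).
#' @export
exceedance_count <- function(exposures, threshold,
                             mode = c("any_year", "overall_mean")) {
  mode <- match.arg(mode)
  n <- nrow(exposures$means)
  count <- if (mode == "any_year") {
    sum(exposures$means$max_annual > threshold)
  } else {
    sum(exposures$means$mean_exposure > threshold)
  }
  list(count = count, fraction = if (n > 0) count / n else 0, n = n)
}

#' Cohort summary statistics
#'
#' Arithmetic mean and SD, geometric mean and GSD, median, 95th and 99th
#' percentiles of subject mean exposures, and the maximum annual exposure
#' observed for any subject. Geometric statistics use strictly positive
#' means only; the number skipped is reported.
#'
#' @param exposures Result of [subject_exposures()].
#' @return One-row tibble.
#' @export
cohort_summary <- function(exposures) {
  m <- exposures$means$mean_exposure
  if (length(m) == 0L) stop("no subjects with computed exposure")
  pos <- m[m > 0]
  gm <- if (length(pos)) exp(mean(log(pos))) else NA_real_
  gsd <- if (length(pos) > 1) exp(sd(log(pos))) else NA_real_
  tibble::tibble(
    n = length(m),
    arithmetic_mean = mean(m),
    arithmetic_sd = sd(m),
    geometric_mean = gm,
    geometric_sd = gsd,
    median = median(m),
    p95 = quantile(m, 0.95, names = FALSE),
    p99 = quantile(m, 0.99, names = FALSE),
    max_annual = max(exposures$annual$exposure),
    n_nonpositive_skipped = length(m) - length(pos)
  )
}

#' Rank sectors by mean concentration
#'
#' Per-sector mean over the covered years and maximum annual value, sorted
#' descending by the mean. On a fixed (month-invariant) wind climate the
#' maximum/mean ratio is identical across sectors, because the field
#' factorises into a spatial and a temporal part.
#'
#' @param matrix An exposure matrix.
#' @param k Number of sectors to return (default 10).
#' @return Tibble: `sector_id`, `octet`, `distance`, `mean`, `maximum`,
#'   `max_mean_ratio`.
#' @export
sector_ranking <- function(matrix, k = 10) {
  mean_c <- rowMeans(matrix$annual)
  max_c <- apply(matrix$annual, 1, max)
  out <- tibble::tibble(
    sector_id = matrix$sectors$id,
    octet = matrix$sectors$octet,
    distance = matrix$sectors$distance,
    mean = mean_c,
    maximum = max_c,
    max_mean_ratio = ifelse(mean_c > 0, max_c / mean_c, NA_real_)
  )
  out <- out[order(-out$mean, out$sector_id), ]
  head(out, k)
}

#' Population time series, decade tables, and exposure footprint
#'
#' @param matrix An exposure matrix.
#' @param records Cleaned records.
#' @return List with `population_by_year` (subjects resident at least one
#'   month of the year), `population_by_decade_sector` (subjects resident in
#'   the sector at any time during the decade), and `footprint` (per-octet
#'   mean of subject-month exposures).
#' @export
population_and_footprint <- function(matrix, records) {
  ex <- expand_residence_months(matrix, records)
  if (nrow(ex) == 0L) {
    return(list(
      population_by_year = tibble::tibble(year = integer(), population = integer()),
      population_by_decade_sector = tibble::tibble(decade = character(),
                                                   sector_id = character(),
                                                   population = integer()),
      footprint = tibble::tibble(octet = octets(), mean_exposure = 0)
    ))
  }
  pop_year <- ex |>
    dplyr::distinct(.data$subject_id, .data$year) |>
    dplyr::count(.data$year, name = "population")
  pop_dec <- ex |>
    dplyr::mutate(decade = paste0((.data$year %/% 10) * 10, "s")) |>
    dplyr::distinct(.data$subject_id, .data$decade, .data$sector_id) |>
    dplyr::count(.data$decade, .data$sector_id, name = "population")
  oct_of <- setNames(matrix$sectors$octet, matrix$sectors$id)
  foot <- ex |>
    dplyr::mutate(octet = oct_of[.data$sector_id]) |>
    dplyr::group_by(.data$octet) |>
    dplyr::summarise(mean_exposure = mean(.data$conc), .groups = "drop")
  list(population_by_year = pop_year,
       population_by_decade_sector = pop_dec,
       footprint = foot)
}

#' Run the full reconstruction over a scenario directory
#'
#' Reads `sectors.csv`, `met_cond.csv`, `met_class.csv`, `emissions.csv`,
#' `residences.csv` and (optionally) `config.yaml` from `scenario_dir`,
#' cleans the histories, builds the concentration field, computes subject
#' exposures, summary statistics and exceedance counts, and writes
#' `matrix.csv`, `subject_exposures.csv`, `summary.csv` and `exceedance.csv`
#' into `out_dir` with comment-line metadata headers.
#'
#' @param scenario_dir Directory of input files.
#' @param out_dir Output directory (created if absent).
#' @param quantile Release-rate quantile (default `"median"`).
#' @param action_levels Thresholds (pCi/L) tabulated in `exceedance.csv`.
#' @return Invisibly, a list with all intermediate objects plus `digests`
#'   (md5 of each written file).
#' @export
reconstruct <- function(scenario_dir, out_dir,
                        quantile = "median", action_levels = c(2, 4)) {
  p <- function(f) file.path(scenario_dir, f)
  grid <- read_sector_grid(p("sectors.csv"))
  met <- read_met_tables(p("met_cond.csv"), p("met_class.csv"))
  timeline <- read_emission_timeline(p("emissions.csv"))
  raw <- read_residences(p("residences.csv"))
  cfg <- read_dispersion_config(p("config.yaml"))
  seed <- tryCatch(yaml::read_yaml(p("config.yaml"))$seed, error = function(e) NULL)

  cleaned <- clean_residences(raw, grid = grid)
  mat <- build_exposure_matrix(grid, timeline, met, calib = cfg$calib,
                               config = cfg$config, quantile = quantile)
  expo <- subject_exposures(mat, cleaned)
  summ <- cohort_summary(expo)
  exc <- dplyr::bind_rows(lapply(action_levels, function(th) {
    a <- exceedance_count(expo, th, "any_year")
    m <- exceedance_count(expo, th, "overall_mean")
    tibble::tibble(threshold = th,
                   mode = c("any_year", "overall_mean"),
                   count = c(a$count, m$count),
                   fraction = c(a$fraction, m$fraction),
                   n = c(a$n, m$n))
  }))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(quantile = quantile)
  if (!is.null(seed)) meta$seed <- seed

  mat_long <- tidyr::pivot_longer(
    tibble::as_tibble(mat$annual, rownames = "sector_id"),
    -"sector_id", names_to = "year", values_to = "concentration")
  mat_long$concentration <- round(mat_long$concentration, 6)
  outs <- c(
    write_csv_with_meta(mat_long, file.path(out_dir, "matrix.csv"), meta),
    write_csv_with_meta(
      dplyr::mutate(expo$means,
                    mean_exposure = round(.data$mean_exposure, 6),
                    max_annual = round(.data$max_annual, 6),
                    years_resident = round(.data$years_resident, 6)),
      file.path(out_dir, "subject_exposures.csv"), meta),
    write_csv_with_meta(dplyr::mutate(summ,
                                      dplyr::across(dplyr::where(is.numeric),
                                                    ~ round(.x, 6))),
                        file.path(out_dir, "summary.csv"), meta),
    write_csv_with_meta(dplyr::mutate(exc, fraction = round(.data$fraction, 6)),
                        file.path(out_dir, "exceedance.csv"), meta)
  )
  digests <- tools::md5sum(outs)

  invisible(list(grid = grid, timeline = timeline, met = met,
                 cleaned = cleaned, matrix = mat, exposures = expo,
                 summary = summ, exceedance = exc, digests = digests,
                 files = outs))
}
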