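# Synthetic cohorts, wind climatologies, and scenario bundles.
#
# The real residential histories are consent-restricted and the tower
# joint-frequency tables live in an out-of-print agency report, so the
# generator emulates their statistical structure: month-resolution residence
# intervals with the published missingness rates, and normalised monthly
# joint-frequency tables with prevailing north-west-through-south-west winds,
# a calm-class excess, and a winter-fast / summer-calm seasonal cycle. One
# integer seed drives every stream through named substreams, so adding a new
# generator never perturbs existing draws.

#' Specification of a synthetic cohort
#'
#' Missingness defaults are the published residence-level rates: 8.49% of
#' records missing the FROM month, 7.55% the TO month, 0.49% the FROM year
#' and 0.72% the TO year.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @param move_rate Per-year probability of relocating (default 0.08).
#' @param missing_from_month_p,missing_to_month_p Month-missingness
#'   probabilities per record.
#' @param missing_from_year_p,missing_to_year_p Year-missingness
#'   probabilities per record.
#' @param dob_before_residence_p Probability that a subject's first record
#'   starts before their date of birth (family moved in earlier).
#' @param population_growth Decade weights for when subjects enter the area.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 1000L, seed = 1L,
                        move_rate = 0.08,
                        missing_from_month_p = 0.0849,
                        missing_to_month_p = 0.0755,
                        missing_from_year_p = 0.0049,
                        missing_to_year_p = 0.0072,
                        dob_before_residence_p = 0.05,
                        population_growth = c("1950" = 0.8, "1960" = 1.1,
                                              "1970" = 1.3, "1980" = 1.2)) {
  stopifnot(n_subjects > 0,
            all(c(missing_from_month_p, missing_to_month_p,
                  missing_from_year_p, missing_to_year_p,
                  dob_before_residence_p, move_rate) >= 0),
            all(c(missing_from_month_p, missing_to_month_p,
                  missing_from_year_p, missing_to_year_p,
                  dob_before_residence_p, move_rate) <= 1),
            all(population_growth >= 0))
  structure(list(n_subjects = as.integer(n_subjects), seed = seed,
                 move_rate = move_rate,
                 missing_from_month_p = missing_from_month_p,
                 missing_to_month_p = missing_to_month_p,
                 missing_from_year_p = missing_from_year_p,
                 missing_to_year_p = missing_to_year_p,
                 dob_before_residence_p = dob_before_residence_p,
                 population_growth = population_growth),
            class = "cohort_spec")
}

#' Specification of a synthetic wind climatology
#'
#' @param seed Integer seed.
#' @param prevailing_octets Named octet weights for the direction
#'   distribution; the default favours NW, W and SW.
#' @param calm_bias Extra probability mass moved into the lowest (0-2 m/s)
#'   speed class.
#' @param seasonal_amplitude Winter-vs-summer modulation of the speed
#'   distribution (0 = no seasonal cycle).
#' @param month_variation Lognormal sd of month-to-month cell jitter
#'   (0 = all 12 tables identical when `seasonal_amplitude` is 0).
#' @return Object of class `met_spec`.
#' @export
met_spec <- function(seed = 1L,
                     prevailing_octets = c(N = 1, NE = 0.8, E = 0.9, SE = 1,
                                           S = 1, SW = 1.6, W = 1.9, NW = 1.8),
                     calm_bias = 0.15,
                     seasonal_amplitude = 0.12,
                     month_variation = 0.05) {
  stopifnot(all(octets() %in% names(prevailing_octets)),
            calm_bias >= 0, calm_bias < 1,
            seasonal_amplitude >= 0, seasonal_amplitude < 1,
            month_variation >= 0)
  structure(as.list(environment()), class = "met_spec")
}

# arrival/departure month weights: mild June/July excess, late-winter and
# late-autumn deficit, near-uniform otherwise
month_move_weights <- function() {
  w <- c(1, 0.8, 0.8, 1, 1, 1.3, 1.3, 1, 1, 1, 0.8, 0.8)
  w / sum(w)
}

#' Generate a synthetic cohort
#'
#' Produces both the "dirty" raw records (missingness and date anomalies
#' injected per the spec) and the clean ground truth, so the cleaning stage
#' can be validated exactly.
#'
#' @param spec A [cohort_spec()].
#' @param grid A [sector_grid()] supplying sector ids (default
#'   [default_sector_grid()]).
#' @return List with tibbles `raw` (columns as accepted by
#'   [clean_residences()]) and `truth` (the same records with nothing
#'   missing).
#' @export
generate_cohort <- function(spec, grid = default_sector_grid()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects

  octw <- c(N = 1, NE = 2.5, E = 1.5, SE = 2, S = 1, SW = 1.5, W = 1, NW = 1)
  sector_w <- unname(octw[grid$octet])
  mw <- month_move_weights()
  decades <- as.integer(names(spec$population_growth))
  dw <- spec$population_growth / sum(spec$population_growth)

  set.seed(substream_seed(spec$seed, "cohort-core"))
  dob <- as.Date("1920-01-01") +
    floor(runif(n) * as.numeric(as.Date("1976-01-01") - as.Date("1920-01-01")))
  entry_decade <- decades[sample.int(length(decades), n, replace = TRUE, prob = dw)]
  entry_year <- pmin(entry_decade + sample.int(10L, n, replace = TRUE) - 1L, 1988L)
  entry_year <- pmax(entry_year, 1950L)
  entry_month <- sample.int(12L, n, replace = TRUE, prob = mw)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    start <- ym_index(entry_year[i], entry_month[i])
    # first full month of life, so a mid-month birth never predates the record
    start <- max(start, month_index_of_date(dob[i]) + 1L)
    recs <- list()
    repeat {
      stay <- 1L + rgeom(1L, prob = spec$move_rate / 12)
      end <- start + stay - 1L
      recs[[length(recs) + 1L]] <- c(start, min(end, ym_index(1992L, 12L)))
      if (end >= ym_index(1992L, 12L) || runif(1) > 0.6) break
      start <- end + 1L
    }
    m <- do.call(rbind, recs)
    rows[[i]] <- tibble::tibble(
      subject_id = sprintf("S%05d", i),
      dob = dob[i],
      sector_id = grid$id[sample.int(nrow(grid), nrow(m), replace = TRUE,
                                     prob = sector_w)],
      from_idx = m[, 1], to_idx = m[, 2]
    )
  }
  truth <- dplyr::bind_rows(rows)
  truth$from_year <- index_year(truth$from_idx)
  truth$from_month <- index_month(truth$from_idx)
  truth$to_year <- index_year(truth$to_idx)
  truth$to_month <- index_month(truth$to_idx)
  truth$from_idx <- NULL
  truth$to_idx <- NULL

  raw <- truth
  set.seed(substream_seed(spec$seed, "cohort-anomalies"))
  nr <- nrow(raw)
  # DOB anomaly: first record of a sampled subject starts before the DOB
  first_of_subject <- !duplicated(raw$subject_id)
  anom <- first_of_subject & runif(nr) < spec$dob_before_residence_p
  if (any(anom)) {
    shift <- sample.int(36L, sum(anom), replace = TRUE)
    idx <- ym_index(raw$from_year[anom], raw$from_month[anom]) - shift
    raw$from_year[anom] <- index_year(idx)
    raw$from_month[anom] <- index_month(idx)
  }
  raw$from_month[runif(nr) < spec$missing_from_month_p] <- NA_integer_
  raw$to_month[runif(nr) < spec$missing_to_month_p] <- NA_integer_
  raw$from_year[runif(nr) < spec$missing_from_year_p] <- NA_integer_
  raw$to_year[runif(nr) < spec$missing_to_year_p] <- NA_integer_

  cols <- c("subject_id", "dob", "sector_id",
            "from_year", "from_month", "to_year", "to_month")
  list(raw = raw[cols], truth = truth[cols])
}

#' Generate 12 monthly joint-frequency tables
#'
#' Tables are normalised by construction: stability-class frequencies sum to
#' 1 per month and conditional frequencies sum to 1 per stability class.
#'
#' @param spec A [met_spec()].
#' @return List of 12 [joint_frequency_table()]s.
#' @export
generate_met <- function(spec) {
  stopifnot(inherits(spec, "met_spec"))
  set.seed(substream_seed(spec$seed, "met"))

  # direction weights over 16 points: retained directions carry the octet
  # weight, intermediates the mean of their flanking octets
  ow <- spec$prevailing_octets[octets()]
  w16 <- numeric(16L)
  w16[seq(1, 15, by = 2)] <- ow
  w16[seq(2, 16, by = 2)] <- (ow + ow[c(2:8, 1)]) / 2
  w16 <- w16 / sum(w16)

  base_speed <- c(0.32, 0.27, 0.18, 0.12, 0.07, 0.04)
  base_speed[1] <- base_speed[1] + spec$calm_bias
  base_speed <- base_speed / sum(base_speed)

  base_h <- c(A = 0.06, B = 0.10, C = 0.16, D = 0.34, E = 0.19, F = 0.15)

  lapply(1:12, function(mo) {
    season <- 1 + spec$seasonal_amplitude * cos(2 * pi * (mo - 1) / 12)
    sw <- base_speed * season^(seq_len(6) - 1)  # winter tilts fast, summer calm
    sw <- sw / sum(sw)
    g <- array(0, dim = c(6L, 16L, 6L))
    for (s in 1:6) {
      cell <- outer(w16, sw)  # 16 x 6
      if (spec$month_variation > 0) {
        cell <- cell * exp(matrix(rnorm(96, sd = spec$month_variation), 16, 6))
      }
      g[s, , ] <- cell / sum(cell)
    }
    h <- base_h
    if (spec$month_variation > 0) {
      h <- h * exp(rnorm(6, sd = spec$month_variation))
    }
    h <- h / sum(h)
    joint_frequency_table(mo, h, g)
  })
}

#' Generate a full scenario bundle on disk
#'
#' Writes `sectors.csv`, `met_cond.csv`, `met_class.csv`, `emissions.csv`
#' (the published release timeline), `residences.csv` and `config.yaml`
#' into a directory that [reconstruct()] consumes end to end.
#'
#' @param cohort A [cohort_spec()].
#' @param met A [met_spec()].
#' @param dir Output directory (created if absent).
#' @param grid Sector grid to ship (default [default_sector_grid()]).
#' @param timeline Emission timeline to ship (default
#'   [default_emission_timeline()]).
#' @return The directory, invisibly.
#' @export
generate_scenario <- function(cohort, met, dir,
                              grid = default_sector_grid(),
                              timeline = default_emission_timeline()) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(met, "met_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(seed = cohort$seed)

  write_sector_grid(grid, file.path(dir, "sectors.csv"), meta)
  write_met_tables(generate_met(met), file.path(dir, "met_cond.csv"),
                   file.path(dir, "met_class.csv"), meta)

  ev <- as.data.frame(timeline$events)[c("label", "start_year", "start_month",
                                         "end_year", "end_month",
                                         "rate_median", "rate_p05", "rate_p95")]
  write_csv_with_meta(ev, file.path(dir, "emissions.csv"), meta)

  ch <- generate_cohort(cohort, grid = grid)
  raw <- ch$raw
  raw$dob <- format(raw$dob, "%Y-%m-%d")
  write_csv_with_meta(raw, file.path(dir, "residences.csv"), meta)

  yaml::write_yaml(list(sigma_z_scheme = "briggs_rural", n_sectors = 8L,
                        min_distance = 100, lnK_mean = -0.44, c_mean = 0.19,
                        rho = 50, seconds_per_year = 3.1557e7,
                        seed = cohort$seed),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}
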