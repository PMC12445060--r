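small_grid <- function() {
  sector_grid(data.frame(id = c("X1", "X2", "Y1"),
                         octet = c("NE", "NE", "SE"),
                         ring = c(1, 2, 1)))
}

test_that("a silent source yields an all-zero matrix", {
  mat <- build_exposure_matrix(small_grid(), flat_timeline(rate = 0),
                               constant_met())
  expect_true(all(mat$monthly == 0))
  expect_true(all(mat$annual == 0))
})

test_that("nearer rings see strictly higher concentrations every year", {
  mat <- build_exposure_matrix(small_grid(), default_emission_timeline(),
                               generate_met(met_spec(seed = 2)))
  expect_true(all(mat$annual["X1", as.character(1953:1988)] >
                    mat$annual["X2", as.character(1953:1988)]))
})

test_that("annual sector values are the mean of their monthly values", {
  mat <- build_exposure_matrix(small_grid(), default_emission_timeline(),
                               generate_met(met_spec(seed = 3)))
  for (y in c(1953, 1979, 1988)) {
    expect_equal(mat$annual[, as.character(y)],
                 rowMeans(mat$monthly[, as.character(12 * y + 0:11)]))
  }
})

test_that("concentration ratios across years equal source-rate ratios", {
  mat <- build_exposure_matrix(default_sector_grid(),
                               default_emission_timeline(), constant_met())
  r <- mat$annual[, "1965"] / mat$annual[, "1985"]
  expect_equal(unname(r), rep(6200 / 950, 100), tolerance = 1e-9)
})

test_that("full-year residents receive the sector-year concentration", {
  g <- small_grid()
  mat <- build_exposure_matrix(g, default_emission_timeline(),
                               generate_met(met_spec(seed = 4)))
  cl <- clean_residences(rec(sector_id = "X1", fy = 1960, fm = 1,
                             ty = 1970, tm = 12), grid = g)
  expect_equal(subject_annual_exposure(mat, cl, 1965),
               unname(mat$annual["X1", "1965"]))
  expect_true(is.na(subject_annual_exposure(mat, cl, 1980)))
})

test_that("split years average the two sectors' monthly concentrations", {
  g <- small_grid()
  mat <- build_exposure_matrix(g, default_emission_timeline(),
                               generate_met(met_spec(seed = 5)))
  cl <- clean_residences(dplyr::bind_rows(
    rec(sector_id = "X1", fy = 1960, fm = 1, ty = 1960, tm = 6),
    rec(sector_id = "Y1", fy = 1960, fm = 7, ty = 1960, tm = 12)
  ), grid = g)
  got <- subject_annual_exposure(mat, cl, 1960)
  brute <- mean(c(mat$monthly["X1", as.character(12 * 1960 + 0:5)],
                  mat$monthly["Y1", as.character(12 * 1960 + 6:11)]))
  expect_equal(got, brute)
})

test_that("the duration-weighted mean follows the worked 5-and-7-year form", {
  expect_equal(subject_mean_exposure(c(2.0, 1.0), c(5, 7)), (5 * 2 + 7 * 1) / 12)
  expect_equal(subject_mean_exposure(rep(1.3, 4), rep(1, 4)), 1.3)
  expect_equal(subject_mean_exposure(2.7, 1), 2.7)
  expect_error(subject_mean_exposure(numeric(), numeric()), "undefined")
  expect_error(subject_mean_exposure(1, 0), "undefined")
})

test_that("subject means respect their annual bounds and month weighting", {
  g <- default_sector_grid()
  ch <- generate_cohort(cohort_spec(n_subjects = 150, seed = 8), grid = g)
  cl <- clean_residences(ch$raw, grid = g)
  mat <- build_exposure_matrix(g, default_emission_timeline(),
                               generate_met(met_spec(seed = 8)))
  ex <- subject_exposures(mat, cl)
  j <- dplyr::left_join(ex$annual, ex$means, by = "subject_id")
  expect_true(all(j$exposure <= j$max_annual + 1e-12))
  expect_true(all(ex$means$mean_exposure >= 0))
  # mean equals the month-weighted average of annual values
  chk <- ex$annual |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(m = sum(exposure * months) / sum(months))
  expect_equal(ex$means$mean_exposure[order(ex$means$subject_id)],
               chk$m[order(chk$subject_id)])
})

test_that("exceedance counts match a brute-force per-subject scan", {
  g <- default_sector_grid()
  ch <- generate_cohort(cohort_spec(n_subjects = 200, seed = 9), grid = g)
  cl <- clean_residences(ch$raw, grid = g)
  mat <- build_exposure_matrix(g, default_emission_timeline(),
                               generate_met(met_spec(seed = 9)))
  ex <- subject_exposures(mat, cl)

  thr <- stats::quantile(ex$means$mean_exposure, 0.8, names = FALSE)
  brute_any <- 0L
  brute_mean <- 0L
  for (id in unique(ex$means$subject_id)) {
    ann <- ex$annual$exposure[ex$annual$subject_id == id]
    if (any(ann > thr)) brute_any <- brute_any + 1L
    if (ex$means$mean_exposure[ex$means$subject_id == id] > thr) {
      brute_mean <- brute_mean + 1L
    }
  }
  expect_equal(exceedance_count(ex, thr, "any_year")$count, brute_any)
  expect_equal(exceedance_count(ex, thr, "overall_mean")$count, brute_mean)
  expect_equal(exceedance_count(ex, 0, "any_year")$count, nrow(ex$means))
  expect_equal(exceedance_count(ex, max(ex$annual$exposure), "any_year")$count, 0)
})

test_that("cohort summary statistics match textbook formulas", {
  fake <- list(
    annual = tibble::tibble(subject_id = c("a", "b"), year = 1960,
                            exposure = c(1, 4), months = 12),
    means = tibble::tibble(subject_id = c("a", "b"),
                           mean_exposure = c(1, 4),
                           years_resident = 1, max_annual = c(1, 4))
  )
  s <- cohort_summary(fake)
  expect_equal(s$arithmetic_mean, 2.5)
  expect_equal(s$geometric_mean, 2.0)
  expect_equal(s$max_annual, 4)

  same <- list(
    annual = tibble::tibble(subject_id = "a", year = 1960, exposure = 3,
                            months = 12),
    means = tibble::tibble(subject_id = letters[1:4], mean_exposure = 3,
                           years_resident = 1, max_annual = 3)
  )
  s2 <- cohort_summary(same)
  expect_equal(s2$arithmetic_mean, 3)
  expect_equal(s2$median, 3)
  expect_equal(s2$geometric_mean, 3)
  expect_equal(s2$arithmetic_sd, 0)

  # brute-force recomputation on a random cohort
  set.seed(12)
  m <- rlnorm <- exp(rnorm(50))
  fake3 <- list(annual = tibble::tibble(subject_id = as.character(1:50),
                                        year = 1960, exposure = m, months = 12),
                means = tibble::tibble(subject_id = as.character(1:50),
                                       mean_exposure = m, years_resident = 1,
                                       max_annual = m))
  s3 <- cohort_summary(fake3)
  expect_equal(s3$geometric_mean, exp(mean(log(m))))
  expect_equal(s3$geometric_sd, exp(stats::sd(log(m))))
  expect_equal(s3$p95, stats::quantile(m, 0.95, names = FALSE))
})

test_that("sector ranking orders by mean and shows a constant max/mean ratio", {
  g <- small_grid()
  mat <- build_exposure_matrix(g, default_emission_timeline(), constant_met())
  rk <- sector_ranking(mat, 3)
  expect_true(all(diff(rk$mean) <= 0))
  # same octet: the nearer ring always outranks the farther one
  expect_lt(which(rk$sector_id == "X1"), which(rk$sector_id == "X2"))
  expect_equal(max(rk$max_mean_ratio) - min(rk$max_mean_ratio), 0,
               tolerance = 1e-9)

  one <- sector_grid(data.frame(id = "Z1", octet = "N", ring = 1))
  mat1 <- build_exposure_matrix(one, default_emission_timeline(), constant_met())
  expect_equal(sector_ranking(mat1)$sector_id, "Z1")
})

test_that("population tallies and footprint match a brute-force scan", {
  g <- small_grid()
  mat <- build_exposure_matrix(g, default_emission_timeline(),
                               generate_met(met_spec(seed = 13)))
  cl <- clean_residences(dplyr::bind_rows(
    rec(subject_id = "P1", sector_id = "X1", fy = 1960, fm = 1,
        ty = 1965, tm = 12),
    rec(subject_id = "P2", sector_id = "Y1", fy = 1963, fm = 1,
        ty = 1963, tm = 6)
  ), grid = g)
  pf <- population_and_footprint(mat, cl)
  expect_equal(pf$population_by_year$population[pf$population_by_year$year == 1962], 1)
  expect_equal(pf$population_by_year$population[pf$population_by_year$year == 1963], 2)
  expect_equal(sort(unique(pf$population_by_year$year)), 1960:1965)

  dec <- pf$population_by_decade_sector
  expect_equal(dec$population[dec$decade == "1960s" & dec$sector_id == "X1"], 1)

  # footprint: NE octet mean over P1's 72 months, SE over P2's 6 months
  ne <- mean(mat$monthly["X1", as.character(ym_idx <- 12 * 1960 + 0:71)])
  se <- mean(mat$monthly["Y1", as.character(12 * 1963 + 0:5)])
  expect_equal(pf$footprint$mean_exposure[pf$footprint$octet == "NE"], ne)
  expect_equal(pf$footprint$mean_exposure[pf$footprint$octet == "SE"], se)

  empty <- population_and_footprint(mat, clean_residences(rec()[0, ], grid = g))
  expect_equal(nrow(empty$population_by_year), 0)
})

test_that("the whole pipeline is linear in the source strength", {
  g <- small_grid()
  met <- generate_met(met_spec(seed = 14))
  cl <- clean_residences(rec(sector_id = "X1", fy = 1958, fm = 3,
                             ty = 1972, tm = 9), grid = g)
  m1 <- build_exposure_matrix(g, flat_timeline(rate = 1000), met)
  m3 <- build_exposure_matrix(g, flat_timeline(rate = 3000), met)
  expect_equal(m3$monthly, 3 * m1$monthly)
  e1 <- subject_exposures(m1, cl)
  e3 <- subject_exposures(m3, cl)
  expect_equal(e3$means$mean_exposure, 3 * e1$means$mean_exposure)
  s1 <- cohort_summary(e1)
  s3 <- cohort_summary(e3)
  expect_equal(s3$arithmetic_mean, 3 * s1$arithmetic_mean)
  expect_equal(s3$p95, 3 * s1$p95)
})
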