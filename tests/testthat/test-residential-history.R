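test_that("SAS day counts decode against the 1960 origin", {
  expect_equal(sas_date_decode(0), as.Date("1960-01-01"))
  expect_equal(sas_date_decode(-1), as.Date("1959-12-31"))
  # 1960 is a leap year: day 365 is the last day of the year
  expect_equal(sas_date_decode(365), as.Date("1960-12-31"))
  expect_equal(sas_date_decode(366), as.Date("1961-01-01"))
})

test_that("missing months default to the mid-year convention", {
  r <- rec(fy = 1960, fm = NA, ty = 1962, tm = 3)
  cl <- clean_residences(r)
  expect_equal(cl$from_date, as.Date("1960-07-01"))
  expect_equal(cl$to_date, as.Date("1962-03-31"))
  expect_match(cl$flags, "defaulted_from_month")
  expect_false(cl$dropped)

  r2 <- rec(fy = 1960, fm = 2, ty = 1962, tm = NA)
  cl2 <- clean_residences(r2)
  expect_equal(cl2$to_date, as.Date("1962-06-30"))
  expect_match(cl2$flags, "defaulted_to_month")
})

test_that("records without years are excluded", {
  r <- rec(fy = NA, fm = 5, ty = NA, tm = NA)
  cl <- clean_residences(r)
  expect_true(cl$dropped)
  expect_match(cl$flags, "dropped_missing_year")
  expect_true(is.na(cl$from_date))
})

test_that("residence starts before birth are moved to the date of birth", {
  r <- rec(dob = as.Date("1955-06-10"), fy = 1950, fm = 1, ty = 1970, tm = 12)
  cl <- clean_residences(r)
  expect_equal(cl$from_date, as.Date("1955-06-10"))
  expect_match(cl$flags, "dob_override")
  # DOB before the exposure window: no override, plain clipping applies
  r2 <- rec(dob = as.Date("1945-03-01"), fy = 1944, fm = 1, ty = 1960, tm = 12)
  cl2 <- clean_residences(r2)
  expect_equal(cl2$from_date, as.Date("1952-07-01"))
  expect_false(grepl("dob_override", cl2$flags))
  # born after the window: the subject contributes nothing
  r3 <- rec(dob = as.Date("1990-01-01"), fy = 1989, fm = 1, ty = 1995, tm = 12)
  cl3 <- clean_residences(r3)
  expect_true(cl3$dropped)
  expect_match(cl3$flags, "dropped_outside_window")
})

test_that("intervals are clipped to the exposure window", {
  r <- rec(fy = 1950, fm = 1, ty = 1995, tm = 6)
  cl <- clean_residences(r)
  expect_equal(cl$from_date, as.Date("1952-07-01"))
  expect_equal(cl$to_date, as.Date("1988-12-31"))

  r2 <- rec(fy = 1945, fm = 1, ty = 1950, tm = 12)
  cl2 <- clean_residences(r2)
  expect_true(cl2$dropped)
  expect_match(cl2$flags, "dropped_outside_window")
})

test_that("unmappable sectors are dropped when a grid is supplied", {
  g <- default_sector_grid()
  r <- dplyr::bind_rows(rec(sector_id = "B03"), rec(sector_id = "Z99"),
                        rec(sector_id = NA))
  cl <- clean_residences(r, grid = g)
  expect_equal(cl$dropped, c(FALSE, TRUE, TRUE))
  expect_match(cl$flags[2], "dropped_unmappable")
})

test_that("cleaning is idempotent", {
  g <- default_sector_grid()
  raw <- dplyr::bind_rows(
    rec(fy = 1960, fm = NA, ty = 1962, tm = 3),
    rec(subject_id = "S2", dob = as.Date("1955-06-10"),
        fy = 1950, fm = 1, ty = 1970, tm = NA),
    rec(subject_id = "S3", fy = NA, fm = 1, ty = 1980, tm = 2),
    rec(subject_id = "S4", fy = 1945, fm = 1, ty = 1995, tm = 12),
    rec(subject_id = "S5", sector_id = "Q00")
  )
  once <- clean_residences(raw, grid = g)
  twice <- clean_residences(once, grid = g)
  expect_equal(twice$from_date, once$from_date)
  expect_equal(twice$to_date, once$to_date)
  expect_equal(twice$flags, once$flags)
  expect_equal(twice$dropped, once$dropped)
})

test_that("inverted intervals arising from defaults are dropped", {
  # missing FROM month defaults to July, after the explicit March TO date
  r <- rec(fy = 1962, fm = NA, ty = 1962, tm = 3)
  cl <- clean_residences(r)
  expect_true(cl$dropped)
  expect_match(cl$flags, "dropped_inverted")
})

test_that("occupancy fractions count resident months", {
  r <- rec(fy = 1960, fm = 1, ty = 1965, tm = 12)
  cl <- clean_residences(r)
  expect_equal(occupancy_fraction(cl, 1962)$fraction, 1.0)
  expect_equal(occupancy_fraction(cl, 1970)$fraction, 0.0)

  half <- clean_residences(rec(fy = 1960, fm = 3, ty = 1960, tm = 8))
  o <- occupancy_fraction(half, 1960)
  expect_equal(o$fraction, 0.5)
  expect_equal(o$months, 3:8)

  # total fractional years recover the interval month count
  long <- clean_residences(rec(fy = 1959, fm = 11, ty = 1963, tm = 4))
  total <- sum(vapply(1959:1963,
                      function(y) occupancy_fraction(long, y)$fraction,
                      numeric(1)))
  expect_equal(total * 12, 2 + 12 + 12 + 12 + 4)
})

test_that("dates of birth are accepted as ISO strings or SAS day counts", {
  r <- dplyr::bind_rows(
    rec(subject_id = "A", dob = "1955-06-10", fy = 1950, fm = 1,
        ty = 1970, tm = 12),
    rec(subject_id = "B", dob = "-1666", fy = 1950, fm = 1,
        ty = 1970, tm = 12)  # SAS day -1666 = 1955-06-10
  )
  r$dob <- as.character(r$dob)
  cl <- clean_residences(r)
  expect_equal(cl$from_date[1], as.Date("1955-06-10"))
  expect_equal(cl$from_date[2], as.Date("1955-06-10"))
})

test_that("the cleaning report tallies missingness and survivors", {
  raw <- dplyr::bind_rows(
    rec(subject_id = "S1", fm = NA),
    rec(subject_id = "S1", fm = NA, tm = NA),
    rec(subject_id = "S2"),
    rec(subject_id = "S3", fy = NA),
    rec(subject_id = "S4"), rec(subject_id = "S5"),
    rec(subject_id = "S6"), rec(subject_id = "S7"),
    rec(subject_id = "S8"), rec(subject_id = "S9")
  )
  rep <- cleaning_report(raw)
  res <- setNames(rep$residences$missing, rep$residences$field)
  expect_equal(unname(res["from_month"]), 2L)
  expect_equal(unname(res["to_month"]), 1L)
  expect_equal(unname(res["from_year"]), 1L)
  expect_equal(rep$residences$pct[rep$residences$field == "from_month"], 20)
  sub <- setNames(rep$subjects$missing, rep$subjects$field)
  expect_equal(unname(sub["from_month"]), 1L)  # both records are S1's
  expect_equal(rep$n_subjects, 9)
  expect_equal(rep$n_subjects_retained, 8)     # S3 lost its only record
  expect_equal(rep$n_subjects_removed, 1)

  empty <- cleaning_report(rec()[0, ])
  expect_equal(empty$n_residences, 0)
  expect_equal(sum(empty$residences$missing), 0)
})

test_that("cohort accounting reconciles enrolled and removed counts", {
  acc <- cohort_accounting(9375, 57)
  expect_equal(acc$n_retained, 9318)
  expect_error(cohort_accounting(10, 20), "n_removed")
})
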