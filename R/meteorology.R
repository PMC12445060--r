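# Monthly joint-frequency wind climatology.
#
# A joint-frequency table factors the monthly wind climate as
#   f_{q,d,s} = h_s * g_{q,d|s}
# where h_s is the frequency of Pasquill-Gifford stability class s within the
# month (sums to 1 over A..F) and g_{q,d|s} is the conditional frequency of
# speed class q and direction d given s (sums to 1 over all 96 (q,d) cells
# for each s). Speed classes are the six intervals 0-2, 2-4, 4-6, 6-8, 8-10
# and >10 m/s, represented by their midpoints 1, 3, 5, 7, 9, 11 m/s (the open
# top class by 11).
#
# The wind ratio for a direction is sum_s sum_q f_{q,d,s} / u_q (units s/m);
# concentration downwind scales with it, so calm frequent winds dominate.

STABILITY_CLASSES <- c("A", "B", "C", "D", "E", "F")
SPEED_MIDPOINTS <- c(1, 3, 5, 7, 9, 11)

#' Construct a monthly joint-frequency table
#'
#' @param month Month of year, 1-12.
#' @param class_freq Named numeric vector of stability-class frequencies
#'   `h_s`, names `A`..`F`, summing to 1.
#' @param cond_freq Numeric array `[stability, direction16, speed_class]`
#'   (6 x 16 x 6) of conditional frequencies `g_{q,d|s}`; for each stability
#'   class the 96 cells sum to 1.
#' @param speed_midpoints Representative speeds of the 6 classes in m/s.
#' @param tol Tolerance for the two normalisation checks.
#' @return Object of class `jft`.
#' @export
joint_frequency_table <- function(month, class_freq, cond_freq,
                                  speed_midpoints = SPEED_MIDPOINTS,
                                  tol = 1e-9) {
  stopifnot(length(month) == 1L, month %in% 1:12)
  class_freq <- class_freq[STABILITY_CLASSES]
  if (any(is.na(class_freq))) stop("class_freq must be named A..F")
  stopifnot(is.array(cond_freq), all(dim(cond_freq) == c(6L, 16L, 6L)))
  dimnames(cond_freq) <- list(STABILITY_CLASSES, directions16(),
                              as.character(seq_len(6L)))
  obj <- structure(
    list(month = as.integer(month),
         h = class_freq,
         g = cond_freq,
         u = speed_midpoints),
    class = "jft"
  )
  validate_jft(obj, tol = tol)
}

#' Validate a joint-frequency table
#'
#' Checks both normalisation constraints: stability-class frequencies sum to
#' 1 for the month, and the conditional speed-by-direction frequencies sum to
#' 1 within every stability class. All frequencies must be non-negative.
#'
#' @param table A `jft`.
#' @param tol Numeric tolerance.
#' @return The table, invisibly, or an error.
#' @export
validate_jft <- function(table, tol = 1e-9) {
  stopifnot(inherits(table, "jft"))
  if (any(table$h < 0) || any(table$g < 0)) {
    stop("negative frequency in joint-frequency table")
  }
  if (abs(sum(table$h) - 1) > tol) {
    stop(sprintf("stability-class frequencies sum to %.12f, not 1", sum(table$h)))
  }
  per_s <- apply(table$g, 1, sum)
  bad <- which(abs(per_s - 1) > tol)
  if (length(bad)) {
    stop(sprintf("conditional frequencies for class %s sum to %.12f, not 1",
                 STABILITY_CLASSES[bad[1]], per_s[bad[1]]))
  }
  if (length(table$u) != 6L || any(table$u <= 0)) {
    stop("need 6 positive speed midpoints")
  }
  invisible(table)
}

#' @export
print.jft <- function(x, ...) {
  cat(sprintf("<jft month=%d>\n  h: %s\n", x$month,
              paste(sprintf("%s=%.3f", STABILITY_CLASSES, x$h), collapse = " ")))
  invisible(x)
}

#' Stability-adjusted joint frequency
#'
#' The unconditional frequency of one (speed class, direction, stability)
#' cell: the product `h_s * g_{q,d|s}`.
#'
#' @param table A `jft`.
#' @param s Stability class `"A"`..`"F"`.
#' @param d Direction, one of [directions16()].
#' @param q Speed class 1-6.
#' @return Frequency in `[0, 1]`.
#' @export
stability_adjusted_frequency <- function(table, s, d, q) {
  stopifnot(inherits(table, "jft"),
            s %in% STABILITY_CLASSES, d %in% directions16(), q %in% 1:6)
  unname(table$h[s] * table$g[s, d, as.character(q)])
}

#' Per-stability wind ratios
#'
#' The wind ratio of every (stability, direction) pair before summing over
#' stability: `R[s, d] = sum_q f_{q,d,s} / u_q`. Columns for one direction
#' are the per-stability ratios the concentration model consumes.
#'
#' @param table A `jft`.
#' @return 6 x 16 matrix (stability class x direction), s/m.
#' @export
wind_ratio_by_stability <- function(table) {
  stopifnot(inherits(table, "jft"))
  inv_u <- 1 / table$u
  # g is [s, d, q]; weight speed axis by h_s/u_q and collapse q
  r <- sapply(seq_len(6L), function(q) table$g[, , q] * inv_u[q],
              simplify = "array")
  out <- apply(r, c(1, 2), sum) * as.numeric(table$h)
  dimnames(out) <- list(STABILITY_CLASSES, directions16())
  out
}

#' Wind-ratio rose over 16 directions
#'
#' For each direction, the wind ratio `sum_s sum_q f_{q,d,s} / u_q` in s/m,
#' summed across stability classes.
#'
#' @param table A `jft`.
#' @return Named numeric vector over the 16 directions.
#' @export
wind_ratio_rose <- function(table) {
  colSums(wind_ratio_by_stability(table))
}

#' Consolidate a 16-direction rose to the 8 octets
#'
#' Every intermediate direction (NNE, ENE, ...) is split in half and the
#' halves added to its two flanking retained directions, e.g.
#' `N <- N + NNW/2 + NNE/2`. Totals are conserved exactly. Works on a named
#' 16-vector or on any matrix whose columns are the 16 directions (rows are
#' carried through, e.g. per-stability ratios).
#'
#' @param rose16 Named numeric vector (length 16) or matrix with 16 columns,
#'   in [directions16()] order.
#' @return Named vector (length 8) or matrix with 8 columns over [octets()].
#' @export
consolidate_16_to_8 <- function(rose16) {
  d16 <- directions16()
  if (is.matrix(rose16)) {
    stopifnot(ncol(rose16) == 16L)
    m <- rose16[, d16, drop = FALSE]
    prev <- m[, c(16L, seq_len(15L)), drop = FALSE]  # intermediate before each retained
    nxt <- m[, c(seq(2L, 16L), 1L), drop = FALSE]    # intermediate after
    out <- m + prev / 2 + nxt / 2
    out <- out[, seq(1L, 15L, by = 2L), drop = FALSE]
    colnames(out) <- octets()
    return(out)
  }
  stopifnot(length(rose16) == 16L)
  v <- rose16[d16]
  if (any(is.na(names(v)))) stop("rose must be named by the 16 directions")
  retained <- seq(1L, 15L, by = 2L)
  out <- v[retained] +
    v[ifelse(retained - 1L < 1L, 16L, retained - 1L)] / 2 +
    v[retained + 1L] / 2
  names(out) <- octets()
  out
}

#' Average monthly roses into an annualised rose
#'
#' Unweighted per-direction arithmetic mean over the 12 monthly roses.
#'
#' @param roses List of 12 named numeric vectors (all with identical names).
#' @return Named numeric vector, the annualised rose.
#' @export
annualize <- function(roses) {
  if (length(roses) != 12L) stop("need exactly 12 monthly roses")
  nm <- names(roses[[1]])
  m <- vapply(roses, function(r) {
    if (!identical(names(r), nm)) stop("monthly roses have differing directions")
    as.numeric(r)
  }, numeric(length(nm)))
  setNames(rowMeans(m), nm)
}

#' Frequency-weighted wind velocity
#'
#' Wind power per direction: `sum_s sum_q f_{q,d,s} * u_q` (m/s), plus the
#' overall sum across directions (the frequency-weighted mean speed when the
#' table is normalised).
#'
#' @param table A `jft`.
#' @return List with `per_direction` (named 16-vector) and `overall`.
#' @export
weighted_wind_velocity <- function(table) {
  stopifnot(inherits(table, "jft"))
  r <- sapply(seq_len(6L), function(q) table$g[, , q] * table$u[q],
              simplify = "array")
  per_dir <- colSums(apply(r, c(1, 2), sum) * as.numeric(table$h))
  names(per_dir) <- directions16()
  list(per_direction = per_dir, overall = sum(per_dir))
}

#' Read monthly joint-frequency tables from CSV
#'
#' @param cond_path Long-format CSV with columns `month`, `stability`,
#'   `direction16`, `speed_class`, `frequency` holding the conditional
#'   frequencies `g_{q,d|s}`.
#' @param class_path CSV with columns `month`, `stability`, `h` holding the
#'   stability-class frequencies.
#' @return List of 12 `jft` objects, one per month, validated on load.
#' @export
read_met_tables <- function(cond_path, class_path) {
  g_long <- read_csv_plain(cond_path)
  h_long <- read_csv_plain(class_path)
  stopifnot(all(c("month", "stability", "direction16", "speed_class",
                  "frequency") %in% names(g_long)),
            all(c("month", "stability", "h") %in% names(h_long)))
  lapply(1:12, function(mo) {
    gm <- g_long[g_long$month == mo, ]
    hm <- h_long[h_long$month == mo, ]
    if (nrow(gm) != 6L * 16L * 6L) {
      stop(sprintf("month %d: expected %d conditional rows, got %d",
                   mo, 576L, nrow(gm)))
    }
    g <- array(0, dim = c(6L, 16L, 6L),
               dimnames = list(STABILITY_CLASSES, directions16(),
                               as.character(1:6)))
    g[cbind(match(gm$stability, STABILITY_CLASSES),
            match(gm$direction16, directions16()),
            gm$speed_class)] <- gm$frequency
    h <- setNames(hm$h, hm$stability)[STABILITY_CLASSES]
    joint_frequency_table(mo, h, g)
  })
}

#' Write monthly joint-frequency tables to CSV
#'
#' Inverse of [read_met_tables()].
#'
#' @param tables List of 12 `jft` objects.
#' @param cond_path,class_path Output paths.
#' @param meta Named list written as a comment header.
#' @return Invisibly, `c(cond_path, class_path)`.
#' @export
write_met_tables <- function(tables, cond_path, class_path, meta = list()) {
  stopifnot(length(tables) == 12L)
  g_long <- dplyr::bind_rows(lapply(tables, function(tb) {
    idx <- expand.grid(stability = STABILITY_CLASSES,
                       direction16 = directions16(),
                       speed_class = 1:6, stringsAsFactors = FALSE)
    idx$month <- tb$month
    idx$frequency <- tb$g[cbind(match(idx$stability, STABILITY_CLASSES),
                                match(idx$direction16, directions16()),
                                idx$speed_class)]
    idx[c("month", "stability", "direction16", "speed_class", "frequency")]
  }))
  h_long <- dplyr::bind_rows(lapply(tables, function(tb) {
    data.frame(month = tb$month, stability = STABILITY_CLASSES,
               h = as.numeric(tb$h))
  }))
  write_csv_with_meta(g_long, cond_path, meta)
  write_csv_with_meta(h_long, class_path, meta)
  invisible(c(cond_path, class_path))
}
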