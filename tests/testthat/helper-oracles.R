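# Independent oracles and small fixture builders. Everything here is
# deliberately brute force and kept separate from the package code paths it
# checks.

DIR16 <- c("N", "NNE", "NE", "ENE", "E", "ESE", "SE", "SSE",
           "S", "SSW", "SW", "WSW", "W", "WNW", "NW", "NNW")
STAB <- c("A", "B", "C", "D", "E", "F")

# a joint-frequency table with all conditional mass in one (d, q) cell for
# every stability class, and all class mass in one class
point_mass_jft <- function(month = 1, s = "F", d = "N", q = 1) {
  h <- setNames(rep(0, 6), STAB)
  h[s] <- 1
  g <- array(0, dim = c(6, 16, 6))
  for (si in 1:6) g[si, match(d, DIR16), q] <- 1
  joint_frequency_table(month, h, g)
}

uniform_jft <- function(month = 1) {
  h <- setNames(rep(1 / 6, 6), STAB)
  g <- array(1 / 96, dim = c(6, 16, 6))
  joint_frequency_table(month, h, g)
}

random_jft <- function(month = 1) {
  h <- runif(6)
  h <- setNames(h / sum(h), STAB)
  g <- array(runif(6 * 16 * 6), dim = c(6, 16, 6))
  for (si in 1:6) g[si, , ] <- g[si, , ] / sum(g[si, , ])
  joint_frequency_table(month, h, g)
}

# brute-force wind-ratio rose: explicit triple loop over all 576 cells
oracle_rose16 <- function(tb) {
  out <- setNames(rep(0, 16), DIR16)
  for (si in 1:6) for (di in 1:16) for (qi in 1:6) {
    out[di] <- out[di] + tb$h[si] * tb$g[si, di, qi] / tb$u[qi]
  }
  out
}

oracle_weighted_velocity <- function(tb) {
  out <- setNames(rep(0, 16), DIR16)
  for (si in 1:6) for (di in 1:16) for (qi in 1:6) {
    out[di] <- out[di] + tb$h[si] * tb$g[si, di, qi] * tb$u[qi]
  }
  out
}

# Briggs open-country coefficients, restated here so the quadrature oracle
# does not share code with the implementation
oracle_briggs <- list(
  z = rbind(A = c(0.20, 0, 0), B = c(0.12, 0, 0),
            C = c(0.08, 0.0002, -0.5), D = c(0.06, 0.0015, -0.5),
            E = c(0.03, 0.0003, -1), F = c(0.016, 0.0003, -1)),
  y = rbind(A = c(0.22, 0.0001, -0.5), B = c(0.16, 0.0001, -0.5),
            C = c(0.11, 0.0001, -0.5), D = c(0.08, 0.0001, -0.5),
            E = c(0.06, 0.0001, -0.5), F = c(0.04, 0.0001, -0.5))
)

# 2-D quadrature of ground-level point-source Gaussian plumes over the
# source disk, with the receptor swept across the 45-degree sector. Wind
# along +x; the wind speed and source strength are factored out, so the
# result has units 1/m^2, directly comparable with the sector-averaged
# diffusion function.
oracle_sector_diffusion <- function(s, x0, rho = 50,
                                    n_theta = 81, n_r = 16, n_phi = 48) {
  cz <- oracle_briggs$z[s, ]
  cy <- oracle_briggs$y[s, ]
  sig <- function(co, x) co[1] * x * (1 + co[2] * x)^co[3]

  theta <- seq(-pi / 8, pi / 8, length.out = n_theta + 1)
  theta <- (theta[-1] + theta[-length(theta)]) / 2  # midpoints
  rr <- (seq_len(n_r) - 0.5) / n_r * rho
  phi <- (seq_len(n_phi) - 0.5) / n_phi * 2 * pi
  src <- expand.grid(r = rr, phi = phi)
  ax <- src$r * cos(src$phi)
  ay <- src$r * sin(src$phi)
  w <- src$r * (rho / n_r) * (2 * pi / n_phi)  # area element weights
  area <- pi * rho^2

  vals <- vapply(theta, function(th) {
    dx <- x0 * cos(th) - ax
    yy <- x0 * sin(th) - ay
    sz <- sig(cz, dx)
    sy <- sig(cy, dx)
    k <- exp(-yy^2 / (2 * sy^2)) / (pi * sy * sz)
    k[dx <= 0] <- 0
    sum(k * w) / area
  }, numeric(1))
  mean(vals)
}

# tiny raw residence-record builder
rec <- function(subject_id = "S1", dob = as.Date("1940-01-01"),
                sector_id = "B03", fy = 1960, fm = 1, ty = 1970, tm = 12) {
  tibble::tibble(subject_id = subject_id, dob = dob, sector_id = sector_id,
                 from_year = fy, from_month = fm, to_year = ty, to_month = tm)
}

# constant-rate timeline helper (single event)
flat_timeline <- function(rate = 1000, y0 = 1952, m0 = 7, y1 = 1988, m1 = 12) {
  emission_timeline(data.frame(
    label = "flat", start_year = y0, start_month = m0,
    end_year = y1, end_month = m1,
    rate_median = rate, rate_p05 = rate, rate_p95 = rate))
}

# month-invariant synthetic climatology (12 identical tables)
constant_met <- function(seed = 11) {
  generate_met(met_spec(seed = seed, seasonal_amplitude = 0,
                        month_variation = 0))
}
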