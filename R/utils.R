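# Shared calendar and compass helpers.
#
# Months are indexed on a continuous scale: ym_index(y, m) = 12*y + (m-1),
# so interval arithmetic at month resolution is plain integer arithmetic.

#' The 16 compass directions of a full wind rose
#'
#' Directions follow the meteorological "blowing from" convention, clockwise
#' from north.
#' @return Character vector of length 16.
#' @export
directions16 <- function() {
  c("N", "NNE", "NE", "ENE", "E", "ESE", "SE", "SSE",
    "S", "SSW", "SW", "WSW", "W", "WNW", "NW", "NNW")
}

#' The 8 compass octets
#'
#' @return Character vector of length 8: the cardinal and intercardinal
#'   directions, clockwise from north.
#' @export
octets <- function() {
  c("N", "NE", "E", "SE", "S", "SW", "W", "NW")
}

# continuous month index; month defaults to 1
ym_index <- function(year, month = 1L) {
  stopifnot(all(month >= 1L & month <= 12L))
  as.integer(12L * year + (month - 1L))
}

index_year <- function(idx) idx %/% 12L
index_month <- function(idx) idx %% 12L + 1L

# first / last calendar day of the month holding a month index
index_first_day <- function(idx) {
  as.Date(sprintf("%04d-%02d-01", index_year(idx), index_month(idx)))
}

index_last_day <- function(idx) {
  index_first_day(idx + 1L) - 1L
}

month_index_of_date <- function(d) {
  d <- as.Date(d)
  ym_index(as.integer(format(d, "%Y")), as.integer(format(d, "%m")))
}

# derive a reproducible sub-seed for a named random stream, < 2^31
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(as.numeric(seed)) * 69061 + h * 7919) %% 2147483587)
}

# comment-prefixed metadata block used atop every CSV the pipeline writes
write_csv_with_meta <- function(df, path, meta = list()) {
  lines <- c(
    sprintf("# radonrecon %s", as.character(utils::packageVersion("radonrecon"))),
    vapply(names(meta), function(k) sprintf("# %s: %s", k, meta[[k]]), character(1))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_plain <- function(path, ...) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}
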