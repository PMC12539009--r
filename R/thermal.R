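#' Growing-degree-day configuration
#'
#' Thermal time is accumulated as the mean of the clamped daily minimum and
#' maximum temperature minus a base threshold. Temperatures below the base
#' or above the cap are set to those limits before averaging, so every daily
#' contribution is non-negative. Accumulation starts on 1 January by default
#' and the end date itself is excluded (imaging flights take place in the
#' morning, before that day's heat accumulates).
#'
#' @param baseTemp base threshold temperature in deg C (default 4.0).
#' @param upperCap upper temperature limit in deg C (default 25.0).
#' @param start accumulation start date (default "<year>-01-01"; a full date
#'   or NULL to use 1 January of the end date's year).
#' @param endExclusive if TRUE (default) the end date does not contribute.
#' @param clampMean if TRUE, clamp the daily mean instead of min and max
#'   separately (alternative reading of the clamping rule; default FALSE).
#' @return A list of class \code{gddConfig}.
#' @export
gddConfig <- function(baseTemp = 4.0, upperCap = 25.0, start = NULL,
                      endExclusive = TRUE, clampMean = FALSE) {
  stopIfNot(baseTemp < upperCap, "baseTemp must be below upperCap")
  structure(list(baseTemp = baseTemp, upperCap = upperCap, start = start,
                 endExclusive = endExclusive, clampMean = clampMean),
            class = "gddConfig")
}

#' Cumulative growing degree days
#'
#' Sums daily thermal-time contributions
#' \deqn{(clamp(T_{min}) + clamp(T_{max}))/2 - T_{base}}
#' with \code{clamp} mapping into [base, cap], from the configured start
#' date up to (and by default excluding) \code{endDate}. The daily series
#' must be contiguous over the accumulation window.
#'
#' @param temps data.frame with columns \code{date} (Date or parseable),
#'   \code{tmin}, \code{tmax} in deg C.
#' @param endDate date up to which to accumulate.
#' @param config a \code{\link{gddConfig}}.
#' @return Cumulative GDD in deg C day (a single number).
#' @examples
#' d <- data.frame(date = as.Date("2020-03-01"), tmin = 10, tmax = 20)
#' cumulativeGdd(d, as.Date("2020-03-02"),
#'               gddConfig(start = as.Date("2020-03-01")))  # 11
#' @export
cumulativeGdd <- function(temps, endDate, config = gddConfig()) {
  endDate <- as.Date(endDate)
  dates <- as.Date(temps$date)
  start <- if (is.null(config$start))
    as.Date(sprintf("%s-01-01", format(endDate, "%Y"))) else as.Date(config$start)
  last <- if (config$endExclusive) endDate - 1 else endDate
  if (last < start) return(0)
  wanted <- seq(start, last, by = "day")
  idx <- match(wanted, dates)
  if (anyNA(idx))
    stop("missing daily temperatures for: ",
         paste(format(head(wanted[is.na(idx)], 10)), collapse = ", "))
  tmin <- temps$tmin[idx]; tmax <- temps$tmax[idx]
  if (any(tmin > tmax)) stop("tmin exceeds tmax on some days")
  clamp <- function(x) pmin(pmax(x, config$baseTemp), config$upperCap)
  daily <- if (config$clampMean) {
    clamp((tmin + tmax) / 2) - config$baseTemp
  } else {
    (clamp(tmin) + clamp(tmax)) / 2 - config$baseTemp
  }
  sum(daily)
}

#' GDD at a series of dates
#'
#' Convenience wrapper returning cumulative GDD for each of several
#' (imaging) dates under one configuration.
#'
#' @inheritParams cumulativeGdd
#' @param dates vector of dates.
#' @return Named numeric vector of cumulative GDD.
#' @export
gddAtDates <- function(temps, dates, config = gddConfig()) {
  out <- vapply(as.list(as.Date(dates)), function(d)
    cumulativeGdd(temps, d, config), numeric(1))
  names(out) <- format(as.Date(dates))
  out
}
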