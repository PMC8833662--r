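#' Temperature-humidity index
#'
#' `THI = (1.8 t + 32) - (0.55 - 0.0055 rh) * (1.8 t - 26)`, with `t` the
#' daily maximum temperature in degrees Celsius and `rh` the daily minimum
#' relative humidity on a 0-100 scale. Evaluated exactly, no rounding. The
#' heat-stress threshold of 78 corresponds to the range from 25.5 degC at
#' 100% humidity to 40 degC at 0% humidity.
#'
#' @param t maximum temperature, degrees Celsius (vectorized).
#' @param rh minimum relative humidity, percent in \[0, 100\] (vectorized).
#' @return THI, same length as the inputs.
#' @examples
#' thi(25.5, 100)  # 77.9, rounds to the threshold 78
#' thi(40, 0)      # 78.7
#' @export
thi <- function(t, rh) {
  if (any(!is.finite(rh)) || any(rh < 0 | rh > 100))
    stop("relative humidity must lie in [0, 100]")
  (1.8 * t + 32) - (0.55 - 0.0055 * rh) * (1.8 * t - 26)
}

#' 30-day heat load before slaughter
#'
#' Arithmetic mean of the daily THI over the `windowDays` calendar days
#' immediately preceding (and excluding) the slaughter date, for one farm.
#' Every day in the window must be present in the weather series.
#'
#' @param weather data.frame with columns farm, date (Date), tmax_c, rhmin_pct.
#' @param farm farm identifier to look up.
#' @param slaughterDate slaughter date (Date or coercible).
#' @param windowDays window length in days (default 30).
#' @return Mean THI over the window (scalar).
#' @examples
#' w <- data.frame(farm = 1, date = as.Date("2012-06-01") + 0:39,
#'                 tmax_c = 30, rhmin_pct = 60)
#' heatLoad30d(w, 1, as.Date("2012-07-05"))
#' @export
heatLoad30d <- function(weather, farm, slaughterDate, windowDays = 30L) {
  slaughterDate <- as.Date(slaughterDate)
  want <- seq(slaughterDate - windowDays, by = "day", length.out = windowDays)
  wf <- weather[weather$farm == farm, ]
  hit <- match(want, wf$date)
  if (anyNA(hit))
    stop("missing weather for farm ", farm, " on: ",
         paste(format(want[is.na(hit)]), collapse = ", "))
  mean(thi(wf$tmax_c[hit], wf$rhmin_pct[hit]))
}

#' Assign the heat-stress trait from a heat load
#'
#' HS if and only if the mean THI is strictly above the threshold ("above 78");
#' a heat load exactly at the threshold is NHS.
#'
#' @param meanThi 30-day mean THI (vectorized).
#' @param threshold THI threshold (default 78).
#' @return Character vector of "HS"/"NHS".
#' @examples
#' assignTrait(c(80, 70, 78))
#' @export
assignTrait <- function(meanThi, threshold = 78) {
  stopifnot(all(is.finite(meanThi)))
  ifelse(meanThi > threshold, "HS", "NHS")
}

#' Assign traits to a phenotype table
#'
#' Convenience wrapper: computes the heat load for every record from the
#' weather series and appends/overwrites `mean_thi_30d` and `trait`.
#'
#' @param phenotypes data.frame with columns animal, farm, slaughter_date.
#' @param weather data.frame (farm, date, tmax_c, rhmin_pct).
#' @param threshold THI threshold (default 78).
#' @param windowDays window length (default 30).
#' @return The phenotype data.frame with `mean_thi_30d` and `trait` columns.
#' @export
assignTraits <- function(phenotypes, weather, threshold = 78, windowDays = 30L) {
  mthi <- mapply(function(f, d) heatLoad30d(weather, f, d, windowDays),
                 phenotypes$farm, as.character(phenotypes$slaughter_date))
  phenotypes$mean_thi_30d <- as.numeric(mthi)
  phenotypes$trait <- assignTrait(phenotypes$mean_thi_30d, threshold)
  phenotypes
}
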