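#' Meteorological conditions for atmospheric absorption
#'
#' Bundles the temperature / pressure / relative-humidity triple that
#' determines the atmospheric absorption coefficient alpha(f) via the
#' ISO 9613-1 relaxation model. Pressure can be supplied in kPa (default) or
#' hPa, matching typical station records; it is stored in kPa.
#'
#' The ISO model's stated accuracy envelope is limited; conditions outside a
#' configurable temperature window raise a warning (not an error) so that
#' exploratory use on extreme inputs remains possible.
#'
#' @param temperature air temperature in degrees Celsius.
#' @param pressure static air pressure, in the unit named by `pressure_unit`.
#' @param relative_humidity relative humidity in percent (0-100).
#' @param label free-text label (e.g. a month name).
#' @param pressure_unit `"kPa"` or `"hPa"`.
#' @param temp_range validity envelope in degrees C; values outside warn.
#' @return An object of class `meteo_conditions` with fields `temperature`
#'   (deg C), `pressure` (kPa), `relative_humidity` (percent), `label`.
#' @examples
#' meteo_conditions(4.8, 1009, 87, label = "July", pressure_unit = "hPa")
#' @export
meteo_conditions <- function(temperature, pressure, relative_humidity,
                             label = "", pressure_unit = c("kPa", "hPa"),
                             temp_range = c(-80, 50)) {
  pressure_unit <- match.arg(pressure_unit)
  if (pressure_unit == "hPa") pressure <- pressure / 10
  stopifnot(length(temperature) == 1L, length(pressure) == 1L,
            length(relative_humidity) == 1L)
  if (!is.finite(pressure) || pressure <= 0) stop("pressure must be positive")
  if (!is.finite(relative_humidity) || relative_humidity < 0 ||
      relative_humidity > 100)
    stop("relative_humidity must be within [0, 100]")
  if (!is.finite(temperature)) stop("temperature must be finite")
  if (temperature < temp_range[1] || temperature > temp_range[2])
    warning("temperature outside the model validity envelope [",
            temp_range[1], ", ", temp_range[2], "] degrees C")
  structure(list(temperature = as.numeric(temperature),
                 pressure = as.numeric(pressure),
                 relative_humidity = as.numeric(relative_humidity),
                 label = as.character(label)[1L]),
            class = "meteo_conditions")
}

#' @export
print.meteo_conditions <- function(x, ...) {
  cat(sprintf("meteo_conditions%s: %.1f degC, %.2f kPa, %.0f %% RH\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$temperature, x$pressure, x$relative_humidity))
  invisible(x)
}

P_REF_KPA <- 101.325   # reference pressure, kPa
T_REF_K   <- 293.15    # reference temperature, K
T_TRIPLE  <- 273.16    # triple point of water, K

kelvin <- function(temperature_C) temperature_C + 273.15

#' Saturation vapour pressure ratio
#'
#' The ratio p_sat / p_ref of the saturation vapour pressure of water to the
#' reference atmospheric pressure (101.325 kPa), as a function of absolute
#' temperature, using the ISO 9613-1 closed form
#' \code{10^(-6.8346 (273.16/T)^1.261 + 4.6151)}.
#'
#' @param temperature_K absolute temperature in Kelvin (> 0).
#' @return dimensionless ratio, strictly increasing in temperature.
#' @export
saturation_vapor_pressure_ratio <- function(temperature_K) {
  if (any(!is.finite(temperature_K)) || any(temperature_K <= 0))
    stop("temperature_K must be positive")
  10^(-6.8346 * (T_TRIPLE / temperature_K)^1.261 + 4.6151)
}

#' Molar concentration of water vapour
#'
#' Humidity enters the ISO 9613-1 relaxation frequencies as h, the molar
#' concentration of water vapour in percent:
#' \code{h = RH * (p_sat/p_ref) / (p/p_ref)}.
#'
#' @param conditions a [meteo_conditions()].
#' @return h in percent; zero iff relative humidity is zero.
#' @export
molar_water_concentration <- function(conditions) {
  stopifnot(inherits(conditions, "meteo_conditions"))
  psat <- saturation_vapor_pressure_ratio(kelvin(conditions$temperature))
  conditions$relative_humidity * psat / (conditions$pressure / P_REF_KPA)
}

#' Oxygen and nitrogen relaxation frequencies
#'
#' The two molecular relaxation frequencies of ISO 9613-1 that shape the
#' frequency dependence of atmospheric absorption.
#'
#' @param conditions a [meteo_conditions()].
#' @return named numeric vector `c(frO = , frN = )` in Hz.
#' @export
relaxation_frequencies <- function(conditions) {
  stopifnot(inherits(conditions, "meteo_conditions"))
  h <- molar_water_concentration(conditions)
  pr <- conditions$pressure / P_REF_KPA
  tr <- kelvin(conditions$temperature) / T_REF_K
  frO <- pr * (24 + 4.04e4 * h * (0.02 + h) / (0.391 + h))
  frN <- pr * tr^(-0.5) * (9 + 280 * h * exp(-4.170 * (tr^(-1 / 3) - 1)))
  c(frO = frO, frN = frN)
}

#' Atmospheric absorption coefficient (ISO 9613-1)
#'
#' Pure-tone atmospheric absorption alpha(f) in dB per metre from the
#' ISO 9613-1 closed form, combining classical/rotational absorption with the
#' O2 and N2 vibrational relaxation terms. Vectorised over frequency.
#'
#' @param frequency frequency in Hz (>= 0); may be a vector.
#' @param conditions a [meteo_conditions()].
#' @return alpha in dB/m, same length as `frequency`; `alpha(0) = 0`, and
#'   alpha grows ~ f^2 well below both relaxation frequencies.
#' @examples
#' july <- meteo_conditions(4.8, 1009, 87, pressure_unit = "hPa")
#' absorption_coefficient(c(500, 1000, 2000, 8000), july)
#' @export
absorption_coefficient <- function(frequency, conditions) {
  stopifnot(inherits(conditions, "meteo_conditions"))
  if (any(!is.finite(frequency)) || any(frequency < 0))
    stop("frequency must be non-negative")
  TK <- kelvin(conditions$temperature)
  pr <- conditions$pressure / P_REF_KPA
  tr <- TK / T_REF_K
  fr <- relaxation_frequencies(conditions)
  f2 <- frequency^2
  8.686 * f2 * (
    1.84e-11 / pr * sqrt(tr) +
    tr^(-2.5) * (0.01275 * exp(-2239.1 / TK) / (fr[["frO"]] + f2 / fr[["frO"]]) +
                 0.1068  * exp(-3352  / TK) / (fr[["frN"]] + f2 / fr[["frN"]]))
  )
}

#' Absorption curve over a frequency grid
#'
#' Evaluates [absorption_coefficient()] on a strictly increasing frequency
#' grid, keeping the generating conditions attached; the substrate for
#' frequency-profile plots and for tabulated export.
#'
#' @param frequencies strictly increasing frequencies in Hz, all >= 0.
#' @param conditions a [meteo_conditions()].
#' @return An object of class `absorption_curve`: a data.frame with columns
#'   `frequency_Hz` and `alpha_dB_per_m`, with the conditions as an attribute.
#' @export
absorption_curve <- function(frequencies, conditions) {
  if (length(frequencies) < 1L || any(frequencies < 0))
    stop("frequencies must be non-negative")
  if (is.unsorted(frequencies, strictly = TRUE))
    stop("frequencies must be strictly increasing")
  out <- data.frame(frequency_Hz = frequencies,
                    alpha_dB_per_m = absorption_coefficient(frequencies, conditions))
  attr(out, "conditions") <- conditions
  class(out) <- c("absorption_curve", "data.frame")
  out
}

#' @export
print.absorption_curve <- function(x, ...) {
  cond <- attr(x, "conditions")
  cat(sprintf("absorption_curve: %d frequencies, %.0f-%.0f Hz", nrow(x),
              min(x$frequency_Hz), max(x$frequency_Hz)))
  if (!is.null(cond) && nzchar(cond$label)) cat(" [", cond$label, "]", sep = "")
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Write an absorption curve to CSV
#'
#' @param curve an [absorption_curve()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_absorption_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve)[, c("frequency_Hz", "alpha_dB_per_m")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read monthly meteorological records
#'
#' Reads delimited station records with columns `year`, `month`,
#' `temperature_C`, `pressure_hPa`, `relative_humidity_pct` and returns the
#' table unchanged (validated); combine years with [monthly_mean_conditions()].
#'
#' @param path CSV path.
#' @return data.frame of the validated records.
#' @export
read_meteo_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "month", "temperature_C", "pressure_hPa",
            "relative_humidity_pct")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("meteo file lacks columns: ", paste(miss, collapse = ", "))
  d
}

#' Multi-year monthly mean conditions
#'
#' Averages station records over years within each month and returns one
#' [meteo_conditions()] per requested month — the "long-term monthly mean"
#' conditions under which calls are propagated.
#'
#' @param records data.frame as returned by [read_meteo_csv()].
#' @param months months to keep, matched against the `month` column.
#' @return named list of [meteo_conditions()], one per month.
#' @export
monthly_mean_conditions <- function(records,
                                    months = c("May", "June", "July", "August")) {
  out <- list()
  for (m in months) {
    rows <- records[records$month == m, , drop = FALSE]
    if (!nrow(rows)) stop("no records for month: ", m)
    out[[m]] <- meteo_conditions(mean(rows$temperature_C),
                                 mean(rows$pressure_hPa),
                                 mean(rows$relative_humidity_pct),
                                 label = m, pressure_unit = "hPa")
  }
  out
}
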