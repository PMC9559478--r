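#' Temperature-humidity index (THI)
#'
#' Combines ambient temperature and relative humidity into the heat-load
#' index used for dairy cattle:
#' \deqn{THI = 0.8 T + (H/100)(T - 14.4) + 46.4}
#' with T in degrees Celsius and H in percent. At T = 14.4 the humidity
#' term vanishes.
#'
#' @param temperature temperature in degrees C.
#' @param humidity relative humidity in percent, in \[0, 100\].
#' @return numeric THI vector.
#' @examples
#' compute_thi(20, 60)   # 65.76
#' compute_thi(0, 100)   # 32
#' @export
compute_thi <- function(temperature, humidity) {
  if (any(humidity < 0 | humidity > 100)) {
    stop("`humidity` must be in [0, 100]", call. = FALSE)
  }
  0.8 * temperature + (humidity / 100) * (temperature - 14.4) + 46.4
}

#' Correlate a monthly probability curve with meteorology
#'
#' Joins a year-month GRASS-probability curve with a monthly meteorology
#' table on exact (year, month) keys (cells missing on either side are
#' dropped pairwise; years are pooled) and returns the Pearson
#' correlation of the mean probability with temperature, humidity, cloud
#' cover, rain and THI.
#'
#' @param curve data.frame from [monthly_probability_curve()].
#' @param meteo data.frame from [simulate_meteo()] (or the same columns).
#' @return named numeric vector of Pearson correlations for
#'   `temperature`, `humidity`, `cloud`, `rain`, `thi`.
#' @export
correlate_with_meteo <- function(curve, meteo) {
  vars <- c("temperature", "humidity", "cloud", "rain", "thi")
  missing <- setdiff(vars, names(meteo))
  if (length(missing)) {
    stop("meteo table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  merged <- merge(curve[, c("year", "month", "probability")],
                  meteo[, c("year", "month", vars)],
                  by = c("year", "month"))
  if (nrow(merged) < 3L) {
    stop("need at least 3 overlapping (year, month) cells", call. = FALSE)
  }
  vapply(vars, function(v) stats::cor(merged$probability, merged[[v]]),
         numeric(1))
}
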