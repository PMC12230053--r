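#' Generate a daily weather series
#'
#' Produces a reproducible series of daily minimum and maximum temperatures
#' that drives thermal-time development. `constant` mode repeats the stated
#' `tmin`/`tmax` every day; `sinusoidal` mode adds a seasonal sine wave and
#' optional day-to-day Gaussian noise around them.
#'
#' @param n_days number of days, `>= 1`.
#' @param mode `"constant"` or `"sinusoidal"`.
#' @param tmin,tmax mean daily minimum / maximum temperature, degrees C;
#'   `tmax >= tmin` required.
#' @param amplitude seasonal half-amplitude (sinusoidal mode), degrees C.
#' @param period seasonal period in days (sinusoidal mode); default 365.
#' @param noise_sd day-to-day noise sd, degrees C (sinusoidal mode).
#' @param start_day day number of the first day; default 1.
#' @param seed integer seed (sinusoidal mode).
#' @return A `weather_series` data.frame with columns `day`, `tmin`, `tmax`.
#' @examples
#' make_weather(5, tmin = 12, tmax = 20)
#' @export
make_weather <- function(n_days, mode = c("constant", "sinusoidal"),
                         tmin = 12, tmax = 20, amplitude = 4, period = 365,
                         noise_sd = 1.5, start_day = 1L, seed = 1L) {
  mode <- match.arg(mode)
  if (n_days < 1) stop("'n_days' must be >= 1", call. = FALSE)
  if (tmax < tmin) stop("'tmax' must be >= 'tmin'", call. = FALSE)
  day <- seq.int(start_day, length.out = n_days)
  if (mode == "constant") {
    lo <- rep(tmin, n_days); hi <- rep(tmax, n_days)
  } else {
    seas <- amplitude * sin(2 * pi * (day - start_day) / period)
    noise <- with_seed(seed, rnorm(n_days, 0, noise_sd))
    lo <- tmin + seas + noise
    hi <- tmax + seas + noise
    hi <- pmax(hi, lo)                       # noise never inverts the pair
  }
  structure(data.frame(day = day, tmin = lo, tmax = hi),
            class = c("weather_series", "data.frame"))
}
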