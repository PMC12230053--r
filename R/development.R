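#' Thermal-time development configuration
#'
#' Parameters of thermal-time driven development: base temperature for
#' growing degree days, phyllochron (thermal interval between successive
#' leaf appearances), and the sigmoid expansion parameters shared by leaves
#' and internodes.
#'
#' @param t_base base temperature, degrees C; default 8.
#' @param phyllochron thermal interval between leaf appearances, degree-days;
#'   default 30.
#' @param k sigmoid rate, per degree-day; default 0.05.
#' @param t_half thermal age at half of final size, degree-days; default 40.
#' @param final_leaf_number total leaf ranks; default 17.
#' @return A `development_config` object.
#' @export
development_config <- function(t_base = 8, phyllochron = 30, k = 0.05,
                               t_half = 40, final_leaf_number = 17L) {
  stopifnot(t_base > 0 || t_base >= -50, phyllochron > 0, k > 0, t_half > 0,
            final_leaf_number >= 1)
  structure(list(t_base = t_base, phyllochron = phyllochron, k = k,
                 t_half = t_half, final_leaf_number = as.integer(final_leaf_number)),
            class = "development_config")
}

#' Thermal time and leaf appearance schedule
#'
#' Daily growing degree days are `max(0, (tmin + tmax)/2 - t_base)`,
#' accumulated over days. Leaf rank `n` appears on the first day whose
#' cumulative thermal time reaches `n * phyllochron`, capped at
#' `final_leaf_number`.
#'
#' @param weather a [make_weather()] series (columns `day`, `tmin`, `tmax`).
#' @param cfg a [development_config()].
#' @return A list: `gdd` (daily degree days), `cum_gdd` (cumulative),
#'   `appearance_day` (integer vector of length `final_leaf_number`, `NA`
#'   for ranks that never appear within the series).
#' @examples
#' thermal_time(make_weather(40, tmin = 12, tmax = 20), development_config())
#' @export
thermal_time <- function(weather, cfg = development_config()) {
  if (!is.data.frame(weather) || nrow(weather) == 0L ||
      !all(c("tmin", "tmax") %in% names(weather)))
    stop("'weather' must be a non-empty series with tmin and tmax", call. = FALSE)
  if (any(weather$tmax < weather$tmin))
    stop("tmax < tmin in weather series", call. = FALSE)
  gdd <- pmax(0, (weather$tmin + weather$tmax) / 2 - cfg$t_base)
  cum <- cumsum(gdd)
  appearance <- vapply(seq_len(cfg$final_leaf_number), function(n) {
    d <- which(cum >= n * cfg$phyllochron)
    if (length(d)) d[1L] else NA_integer_
  }, integer(1))
  list(gdd = gdd, cum_gdd = cum, appearance_day = appearance)
}

#' Sigmoid organ expansion fraction
#'
#' Fraction of final organ size at thermal age `t` (degree-days since the
#' organ's appearance): `1 / (1 + exp(-k (t - t_half)))`. Note the sigmoid
#' starts at `1/(1 + exp(k t_half))` (about 0.12 for the defaults), not at
#' zero, matching its use as a simple expansion driver.
#'
#' @param t thermal age, degree-days, `>= 0`; vectorised.
#' @param cfg a [development_config()].
#' @return Expansion fraction in (0, 1).
#' @examples
#' expansion_fraction(40)  # 0.5 at the half-time
#' @export
expansion_fraction <- function(t, cfg = development_config()) {
  if (any(t < 0)) stop("thermal age must be >= 0", call. = FALSE)
  1 / (1 + exp(-cfg$k * (t - cfg$t_half)))
}
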