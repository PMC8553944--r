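#' Specify a synthetic SST-field simulation
#'
#' Configuration for [simulate_sst()]. Monthly temperature fields follow
#' `T(lat, lon, t) = monthly_mean - meridional_gradient * |lat - lat_ref|
#'  + seasonal_amplitude * cos(2 pi (month - peak_month)/12)
#'  + model bias + trend * decades elapsed + noise (+ heatwave pulse)`.
#' One observed grid (no bias, `observed_trend`) and one grid per pseudo-model
#' and scenario are produced on a shared grid.
#'
#' @param lat_range,lon_range Inclusive degree ranges (southern-hemisphere
#'   latitudes are negative).
#' @param grid_step Grid spacing in degrees.
#' @param years Inclusive year span `c(first, last)`.
#' @param monthly_mean Annual-mean temperature (deg C) at `lat_ref`.
#' @param lat_ref Reference latitude of the thermal maximum.
#' @param meridional_gradient Cooling rate away from `lat_ref`
#'   (deg C per degree latitude).
#' @param seasonal_amplitude Amplitude of the seasonal cycle (deg C).
#' @param peak_month Calendar month of the seasonal maximum (austral summer
#'   default: February).
#' @param scenario_trends Named numeric: scenario -> warming trend in deg C
#'   per decade (applied linearly from the first simulated year).
#' @param observed_trend Trend of the observed grid (deg C per decade).
#' @param model_biases Numeric vector of static per-model offsets (deg C);
#'   its length sets the number of pseudo-models.
#' @param noise_sd Gaussian noise s.d. (deg C) per cell-month.
#' @param heatwave Optional `list(year, months, amplitude, lat_range,
#'   lon_range)` adding a localized pulse to the observed grid.
#' @param land_mask Optional logical lat x lon matrix (`TRUE` = land).
#' @param seed Integer seed.
#' @return An `sst_sim_spec` list.
#' @export
sst_sim_spec <- function(lat_range = c(-45, 0), lon_range = c(110, 116),
                         grid_step = 1, years = c(1900, 2099),
                         monthly_mean = 28, lat_ref = 0,
                         meridional_gradient = 0.5, seasonal_amplitude = 3,
                         peak_month = 2,
                         scenario_trends = c(historical_GHG = 0.08,
                                             RCP4.5 = 0.2, RCP8.5 = 0.4),
                         observed_trend = 0.08,
                         model_biases = seq(-1, 1, length.out = 11),
                         noise_sd = 0.3, heatwave = NULL, land_mask = NULL,
                         seed = 1) {
  spec <- structure(
    list(lat_range = lat_range, lon_range = lon_range, grid_step = grid_step,
         years = as.integer(years), monthly_mean = monthly_mean,
         lat_ref = lat_ref, meridional_gradient = meridional_gradient,
         seasonal_amplitude = seasonal_amplitude, peak_month = peak_month,
         scenario_trends = scenario_trends, observed_trend = observed_trend,
         model_biases = model_biases, noise_sd = noise_sd,
         heatwave = heatwave, land_mask = land_mask, seed = as.integer(seed)),
    class = "sst_sim_spec"
  )
  spec
}

#' SST grid container
#'
#' @param temp Numeric array `(time, lat, lon)` of monthly temperatures (deg C).
#' @param lat,lon Coordinate vectors (lat ascending).
#' @param years Integer vector of simulated years; the time axis is strictly
#'   monthly and contiguous (`12 * length(years)` steps).
#' @param model Provenance label (`"observed"` or a model name).
#' @param scenario Scenario label.
#' @param mask Optional logical lat x lon land mask.
#' @return An `sst_grid` object.
#' @export
sst_grid <- function(temp, lat, lon, years, model = "observed",
                     scenario = "observed", mask = NULL) {
  stopifnot(length(dim(temp)) == 3)
  years <- as.integer(years)
  if (dim(temp)[1] != 12L * length(years)) {
    abort("time axis must hold 12 contiguous months per year")
  }
  if (dim(temp)[2] != length(lat) || dim(temp)[3] != length(lon)) {
    abort("temp dimensions must be (time, lat, lon)")
  }
  rng <- range(temp, na.rm = TRUE)
  if (rng[1] < -5 || rng[2] > 45) {
    warn("temperatures outside physical bounds (-5, 45) deg C")
  }
  structure(
    list(temp = temp, lat = lat, lon = lon, years = years,
         month = rep(1:12, times = length(years)),
         year_of = rep(years, each = 12L),
         model = model, scenario = scenario, mask = mask),
    class = "sst_grid"
  )
}

#' @export
print.sst_grid <- function(x, ...) {
  cat(sprintf(
    "<sst_grid> %s/%s: %d-%d, %d x %d grid (lat %.1f..%.1f, lon %.1f..%.1f)\n",
    x$model, x$scenario, min(x$years), max(x$years),
    length(x$lat), length(x$lon), min(x$lat), max(x$lat), min(x$lon),
    max(x$lon)))
  invisible(x)
}

#' Simulate observed and model SST grids
#'
#' @param spec An [sst_sim_spec()].
#' @return A list with elements `observed` (an `sst_grid`) and `models` (a
#'   list of `sst_grid`s named `model_XX.scenario`, one per pseudo-model and
#'   scenario).
#' @export
simulate_sst <- function(spec) {
  stopifnot(inherits(spec, "sst_sim_spec"))
  lat <- seq(spec$lat_range[1], spec$lat_range[2], by = spec$grid_step)
  lon <- seq(spec$lon_range[1], spec$lon_range[2], by = spec$grid_step)
  years <- spec$years[1]:spec$years[2]
  nt <- 12L * length(years)
  base_profile <- spec$monthly_mean -
    spec$meridional_gradient * abs(lat - spec$lat_ref)
  month <- rep(1:12, times = length(years))
  elapsed_dec <- (rep(years, each = 12L) + (month - 0.5) / 12 -
                    years[1]) / 10
  seasonal <- spec$seasonal_amplitude *
    cos(2 * pi * (month - spec$peak_month) / 12)
  make_field <- function(bias, trend, noise_seed, heatwave = NULL) {
    arr <- array(rep(base_profile, each = nt), dim = c(nt, length(lat),
                                                       length(lon)))
    arr <- arr + (seasonal + bias + trend * elapsed_dec)
    if (spec$noise_sd > 0) {
      arr <- arr + with_seed(noise_seed,
                             array(rnorm(length(arr), 0, spec$noise_sd),
                                   dim = dim(arr)))
    }
    if (!is.null(heatwave)) {
      ti <- which(rep(years, each = 12L) == heatwave$year &
                    month %in% heatwave$months)
      li <- which(lat >= heatwave$lat_range[1] & lat <= heatwave$lat_range[2])
      gi <- which(lon >= heatwave$lon_range[1] & lon <= heatwave$lon_range[2])
      arr[ti, li, gi] <- arr[ti, li, gi] + heatwave$amplitude
    }
    if (!is.null(spec$land_mask)) {
      for (tt in seq_len(nt)) arr[tt, , ][spec$land_mask] <- NA_real_
    }
    arr
  }
  obs <- sst_grid(
    make_field(0, spec$observed_trend, split_seed(spec$seed, "sst_obs"),
               heatwave = spec$heatwave),
    lat, lon, years, model = "observed", scenario = "observed",
    mask = spec$land_mask
  )
  models <- list()
  for (m in seq_along(spec$model_biases)) {
    for (sc in names(spec$scenario_trends)) {
      nm <- sprintf("model_%02d.%s", m, sc)
      models[[nm]] <- sst_grid(
        make_field(spec$model_biases[m], spec$scenario_trends[[sc]],
                   split_seed(spec$seed, nm)),
        lat, lon, years, model = sprintf("model_%02d", m), scenario = sc,
        mask = spec$land_mask
      )
    }
  }
  check_isotherm_coverage(obs, c(17, 20))
  list(observed = obs, models = models)
}

check_isotherm_coverage <- function(g, thresholds) {
  rng <- range(g$temp, na.rm = TRUE)
  missed <- thresholds[thresholds < rng[1] | thresholds > rng[2]]
  if (length(missed) > 0) {
    warn(paste("grid never crosses isotherm(s):",
               paste(missed, collapse = ", "), "deg C"))
  }
  invisible(g)
}
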