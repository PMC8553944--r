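# Delta-change projection of thermal-threshold isotherms from monthly SST
# grids.  All fields are (time, lat, lon) arrays wrapped in `sst_grid`.

#' Climatology of an SST grid
#'
#' `annual_mean` averages all months in the window; `MiMM` (minimum monthly
#' mean) first averages each calendar month across the window's years, then
#' takes the coldest month, cell-wise. `MiMM <= annual_mean` holds cell-wise
#' by construction.
#'
#' @param g An [sst_grid()].
#' @param window Inclusive year pair `c(first, last)`.
#' @param metric `"annual_mean"` or `"MiMM"`.
#' @return A `climatology_field`: list with `values` (lat x lon matrix),
#'   `metric`, `window`, `lat`, `lon`.
#' @export
climatology <- function(g, window, metric = c("annual_mean", "MiMM")) {
  metric <- arg_match(metric)
  stopifnot(inherits(g, "sst_grid"))
  missing_years <- setdiff(seq(window[1], window[2]), g$years)
  if (length(missing_years) > 0) {
    abort(paste("window years missing from grid:",
                paste(missing_years, collapse = ", ")))
  }
  sel <- g$year_of >= window[1] & g$year_of <= window[2]
  vals <- metric_field(g$temp[sel, , , drop = FALSE], g$month[sel], metric)
  structure(
    list(values = vals, metric = metric, window = as.integer(window),
         lat = g$lat, lon = g$lon),
    class = "climatology_field"
  )
}

# (time, lat, lon) block -> lat x lon metric field.
metric_field <- function(block, months, metric) {
  if (metric == "annual_mean") {
    colMeans(block, na.rm = TRUE, dims = 1)
  } else {
    monthly <- lapply(1:12, function(mo) {
      colMeans(block[months == mo, , , drop = FALSE], na.rm = TRUE, dims = 1)
    })
    Reduce(pmin, monthly)
  }
}

#' @export
print.climatology_field <- function(x, ...) {
  cat(sprintf("<climatology_field> %s over %d-%d (%d x %d grid)\n",
              x$metric, x$window[1], x$window[2], length(x$lat),
              length(x$lon)))
  invisible(x)
}

# Per-year metric fields: (year, lat, lon) array.
yearly_metric <- function(g, metric) {
  ny <- length(g$years)
  out <- array(NA_real_, dim = c(ny, length(g$lat), length(g$lon)))
  for (i in seq_len(ny)) {
    sel <- g$year_of == g$years[i]
    block <- g$temp[sel, , , drop = FALSE]
    out[i, , ] <- if (metric == "annual_mean") {
      colMeans(block, na.rm = TRUE, dims = 1)
    } else {
      Reduce(pmin, lapply(seq_len(dim(block)[1]), function(m) block[m, , ]))
    }
  }
  out
}

#' Delta-change projection of a model run onto an observed climatology
#'
#' For every model year, the corrected field is the observed climatology plus
#' the model's anomaly relative to its own base-window climatology:
#' `corrected(y) = obs_clim + (model_metric(y) - model_clim(base))`. Any
#' static model bias cancels exactly, and the corrected value averaged over
#' the base window equals the observed climatology.
#'
#' @param model An [sst_grid()] for one model/scenario run.
#' @param observed_clim A `climatology_field` from [climatology()] on the
#'   observed grid (its metric is used).
#' @param base Base-period year pair (the window `observed_clim` was computed
#'   on).
#' @return A `projection_series`: `values` is a (year, lat, lon) array of
#'   corrected fields, with `years`, `lat`, `lon`, `metric`, `scenario`,
#'   `model`.
#' @export
delta_change_project <- function(model, observed_clim, base = c(2008, 2017)) {
  stopifnot(inherits(model, "sst_grid"),
            inherits(observed_clim, "climatology_field"))
  if (!isTRUE(all.equal(model$lat, observed_clim$lat)) ||
      !isTRUE(all.equal(model$lon, observed_clim$lon))) {
    abort("model grid does not match the observed grid")
  }
  metric <- observed_clim$metric
  model_base <- climatology(model, base, metric)
  yearly <- yearly_metric(model, metric)
  anom <- sweep(yearly, c(2, 3), model_base$values)
  corrected <- sweep(anom, c(2, 3), observed_clim$values, FUN = "+")
  structure(
    list(values = corrected, years = model$years, lat = model$lat,
         lon = model$lon, metric = metric, scenario = model$scenario,
         model = model$model, base = as.integer(base)),
    class = "projection_series"
  )
}

#' @export
print.projection_series <- function(x, ...) {
  cat(sprintf("<projection_series> %s %s/%s: %d-%d\n", x$metric, x$model,
              x$scenario, min(x$years), max(x$years)))
  invisible(x)
}

#' Ensemble mean and spread of corrected projections
#'
#' Cell-wise mean of the member series (equivalently: mean member anomaly
#' re-added to the shared observed climatology), with the min-max envelope
#' across members retained for range shading.
#'
#' @param members List of `projection_series` on identical grids and years.
#' @return A `projection_series` whose `values` is the member mean, with
#'   `spread_min` / `spread_max` arrays attached and `model = "ensemble"`.
#' @export
ensemble_mean <- function(members) {
  if (length(members) < 1) abort("need at least one ensemble member")
  ref <- members[[1]]
  for (m in members[-1]) {
    if (!identical(dim(m$values), dim(ref$values)) ||
        !identical(m$years, ref$years)) {
      abort("ensemble members differ in grid or time coverage")
    }
  }
  flat <- vapply(members, function(m) as.vector(m$values),
                 numeric(length(ref$values)))
  dims <- dim(ref$values)
  out <- ref
  out$values <- array(rowMeans(flat), dim = dims)
  mn <- flat[, 1]; mx <- flat[, 1]
  for (j in seq_len(ncol(flat))[-1]) {
    mn <- pmin(mn, flat[, j]); mx <- pmax(mx, flat[, j])
  }
  out$spread_min <- array(mn, dim = dims)
  out$spread_max <- array(mx, dim = dims)
  out$model <- "ensemble"
  out
}

#' Decadal isotherm latitudes
#'
#' For each requested decade and each longitude column, finds the
#' poleward-most latitude where the yearly corrected field crosses the
#' threshold, by linear interpolation between adjacent grid latitudes, and
#' summarises the decade as the mean and min-max range of the yearly contour
#' latitudes. With multiple disjoint crossings the poleward-most one is taken.
#'
#' @param series A `projection_series` (e.g. the ensemble mean).
#' @param threshold Temperature threshold in deg C (17 for the overwintering
#'   MiMM threshold, 20 for the annual-mean spawning threshold).
#' @param decades Integer vector of decade start years (e.g. `c(1900, 2090)`);
#'   default: every full decade covered by the series.
#' @param poleward `"south"` (default) or `"north"`.
#' @return An `isotherm_series` tibble: `decade`, `scenario`, `longitude`,
#'   `mean_lat`, `min_lat`, `max_lat`, `threshold`.
#' @export
isotherm_latitude <- function(series, threshold, decades = NULL,
                              poleward = c("south", "north")) {
  poleward <- arg_match(poleward)
  stopifnot(inherits(series, "projection_series"))
  decades <- decades %||%
    unique(series$years[series$years %% 10 == 0])
  decades <- decades[vapply(decades, function(d) {
    all((d:(d + 9)) %in% series$years)
  }, logical(1))]
  rows <- list()
  for (d in decades) {
    yi <- which(series$years %in% d:(d + 9))
    for (li in seq_along(series$lon)) {
      lats <- vapply(yi, function(y) {
        contour_latitude(series$values[y, , li], series$lat, threshold,
                         poleward)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- tibble(
        decade = d, scenario = series$scenario,
        longitude = series$lon[li],
        mean_lat = mean(lats, na.rm = TRUE),
        min_lat = suppressWarnings(min(lats, na.rm = TRUE)),
        max_lat = suppressWarnings(max(lats, na.rm = TRUE)),
        n_crossed = sum(!is.na(lats)),
        threshold = threshold
      )
    }
  }
  out <- bind_rows(rows)
  if (any(out$n_crossed == 0)) {
    warn("threshold not crossed for some decade/longitude combinations")
  }
  class(out) <- c("isotherm_series", class(out))
  out
}

#' Threshold-crossing latitude of a meridional temperature profile
#'
#' Finds the poleward-most latitude at which a 1-D profile crosses a
#' temperature threshold, by linear interpolation between adjacent grid
#' latitudes; `NA` when the profile never crosses.
#'
#' @param profile Numeric temperatures along `lat`.
#' @param lat Latitude vector (degrees).
#' @param threshold Temperature threshold (deg C).
#' @param poleward `"south"` or `"north"`: which end counts as poleward.
#' @return A latitude in degrees, or `NA`.
#' @export
contour_latitude <- function(profile, lat, threshold, poleward = "south") {
  ok <- !is.na(profile)
  if (sum(ok) < 2) return(NA_real_)
  p <- profile[ok]; la <- lat[ok]
  sgn <- sign(p - threshold)
  cross <- which(sgn[-1] * sgn[-length(sgn)] <= 0 &
                   !(sgn[-1] == 0 & sgn[-length(sgn)] == 0))
  exact <- which(sgn == 0)
  cands <- numeric(0)
  for (i in cross) {
    if (p[i + 1] == p[i]) next
    frac <- (threshold - p[i]) / (p[i + 1] - p[i])
    cands <- c(cands, la[i] + frac * (la[i + 1] - la[i]))
  }
  cands <- c(cands, la[exact])
  if (length(cands) == 0) return(NA_real_)
  if (poleward == "south") min(cands) else max(cands)
}

#' @rdname isotherm_latitude
#' @param object An `isotherm_series`.
#' @param ... Unused.
#' @export
autoplot.isotherm_series <- function(object, ...) {
  d <- dplyr::group_by(object, .data$decade, .data$scenario,
                       .data$threshold)
  d <- dplyr::summarise(d, mean_lat = mean(.data$mean_lat, na.rm = TRUE),
                        min_lat = mean(.data$min_lat, na.rm = TRUE),
                        max_lat = mean(.data$max_lat, na.rm = TRUE),
                        .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$decade, y = .data$mean_lat,
                                  colour = factor(.data$threshold))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min_lat,
                                      ymax = .data$max_lat,
                                      fill = factor(.data$threshold)),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(x = "decade", y = "isotherm latitude (deg)",
                  colour = "threshold (deg C)", fill = "threshold (deg C)") +
    ggplot2::theme_minimal()
}

#' Seasonal heatwave anomaly fields
#'
#' Anomaly of one event season against the long-term mean of the same season:
#' `anomaly = mean(event-season months of event year) - mean(same months over
#' the baseline years)`, applied identically to SST and, when given, to each
#' near-surface current component.
#'
#' @param g An [sst_grid()] of SST.
#' @param currents Optional named list of `sst_grid`-like component grids
#'   (e.g. `list(u = ..., v = ...)`, in m/s) sharing `g`'s grid and time axis.
#' @param event `list(year, months)`; defaults to austral summer (JFM) 2011.
#' @param baseline Baseline year pair.
#' @return A `heatwave_anomaly`: `sst` (lat x lon anomaly matrix), `currents`
#'   (named list of anomaly matrices or NULL), `event`, `baseline`.
#' @export
heatwave_anomaly <- function(g, currents = NULL,
                             event = list(year = 2011, months = 1:3),
                             baseline = c(1980, 2015)) {
  stopifnot(inherits(g, "sst_grid"))
  season_anom <- function(grid) {
    ev <- grid$year_of == event$year & grid$month %in% event$months
    if (sum(ev) != length(event$months)) {
      abort("event season months missing from grid")
    }
    base <- grid$year_of >= baseline[1] & grid$year_of <= baseline[2] &
      grid$month %in% event$months
    if (!any(base)) abort("baseline window not covered")
    apply(grid$temp[ev, , , drop = FALSE], c(2, 3), mean, na.rm = TRUE) -
      apply(grid$temp[base, , , drop = FALSE], c(2, 3), mean, na.rm = TRUE)
  }
  structure(
    list(sst = season_anom(g),
         currents = if (!is.null(currents)) lapply(currents, season_anom),
         lat = g$lat, lon = g$lon, event = event,
         baseline = as.integer(baseline)),
    class = "heatwave_anomaly"
  )
}

#' @export
print.heatwave_anomaly <- function(x, ...) {
  cat(sprintf("<heatwave_anomaly> year %d months %s vs %d-%d; SST range %.2f..%.2f deg C\n",
              x$event$year, paste(x$event$months, collapse = ","),
              x$baseline[1], x$baseline[2],
              min(x$sst, na.rm = TRUE), max(x$sst, na.rm = TRUE)))
  invisible(x)
}
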