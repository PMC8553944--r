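noise_free_spec <- function(...) {
  sst_sim_spec(lat_range = c(-40, 0), lon_range = c(110, 113),
               years = c(2000, 2019), noise_sd = 0, model_biases = c(0.5, -0.5),
               scenario_trends = c(RCP8.5 = 0.4), observed_trend = 0, ...)
}

test_that("noise-free fields equal the deterministic plane and its climatologies", {
  s <- simulate_sst(noise_free_spec(seasonal_amplitude = 0))
  g <- s$observed
  expected <- 28 - 0.5 * abs(g$lat)
  expect_equal(g$temp[7, , 2], expected, tolerance = 1e-12)
  cl <- climatology(g, c(2000, 2009), "annual_mean")
  expect_equal(cl$values[, 1], expected, tolerance = 1e-12)
})

test_that("MiMM of a sinusoid is the mean minus the amplitude; MiMM <= annual mean everywhere", {
  s <- simulate_sst(noise_free_spec(seasonal_amplitude = 3))
  ann <- climatology(s$observed, c(2005, 2014), "annual_mean")
  mimm <- climatology(s$observed, c(2005, 2014), "MiMM")
  expect_equal(mimm$values, ann$values - 3, tolerance = 1e-10)
  s2 <- simulate_sst(sst_sim_spec(years = c(2000, 2009), noise_sd = 0.5,
                                  model_biases = 0, seed = 2))
  ann2 <- climatology(s2$observed, c(2000, 2009), "annual_mean")
  mimm2 <- climatology(s2$observed, c(2000, 2009), "MiMM")
  expect_true(all(mimm2$values <= ann2$values + 1e-12))
})

test_that("climatology windows outside the series raise a named error, masks propagate", {
  s <- simulate_sst(noise_free_spec())
  expect_error(climatology(s$observed, c(1995, 2005)), "missing")
  mask <- matrix(FALSE, 41, 4); mask[5, 2] <- TRUE
  sm <- simulate_sst(noise_free_spec(land_mask = mask))
  cl <- climatology(sm$observed, c(2000, 2009), "annual_mean")
  expect_true(is.nan(cl$values[5, 2]) || is.na(cl$values[5, 2]))
})

test_that("delta change cancels static model bias to machine precision", {
  s <- simulate_sst(noise_free_spec())
  cl <- climatology(s$observed, c(2000, 2009), "annual_mean")
  pr_biased <- delta_change_project(s$models[["model_01.RCP8.5"]], cl,
                                    base = c(2000, 2009))
  pr_other <- delta_change_project(s$models[["model_02.RCP8.5"]], cl,
                                   base = c(2000, 2009))
  # biases +0.5 and -0.5 with the same trend and no noise: identical output
  expect_equal(pr_biased$values, pr_other$values, tolerance = 1e-12)
  # corrected average over the base window equals the observed climatology
  expect_equal(apply(pr_biased$values[1:10, , ], c(2, 3), mean), cl$values,
               tolerance = 1e-12)
})

test_that("ensemble mean of identical members is each member; symmetric offsets cancel", {
  s <- simulate_sst(noise_free_spec())
  cl <- climatology(s$observed, c(2000, 2009), "annual_mean")
  prs <- lapply(s$models[c("model_01.RCP8.5", "model_02.RCP8.5")],
                delta_change_project, observed_clim = cl,
                base = c(2000, 2009))
  ens <- ensemble_mean(prs)
  expect_equal(ens$values, prs[[1]]$values, tolerance = 1e-12)
  expect_equal(ens$spread_max, pmax(prs[[1]]$values, prs[[2]]$values),
               tolerance = 1e-12)
  expect_error(ensemble_mean(list()), "at least one")
})

test_that("isotherm latitude is exact for a linear profile and monotone in threshold", {
  profile <- 30 - 0.5 * seq(0, 40)          # T(lat) on lat = -(0:40)
  lat <- -(0:40)
  expect_equal(contour_latitude(profile, lat, 20), -20)
  expect_equal(contour_latitude(profile, lat, 17), -26)
  expect_true(is.na(contour_latitude(profile, lat, 35)))
  # monotone: warmer thresholds sit equatorward
  ths <- c(14, 17, 20, 23)
  lats <- sapply(ths, function(th) contour_latitude(profile, lat, th))
  expect_true(all(diff(lats) > 0))
})

test_that("a uniform +1 degC warming shifts the contour poleward by 1/gradient degrees", {
  s <- simulate_sst(noise_free_spec(seasonal_amplitude = 0))
  cl <- climatology(s$observed, c(2000, 2009), "annual_mean")
  base_lat <- contour_latitude(cl$values[, 1], cl$lat, 20)
  warmed <- cl$values + 1
  expect_equal(contour_latitude(warmed[, 1], cl$lat, 20), base_lat - 2,
               tolerance = 1e-10)
})

test_that("isotherm series flags never-crossed thresholds and brackets its mean", {
  s <- simulate_sst(noise_free_spec())
  cl <- climatology(s$observed, c(2000, 2009), "annual_mean")
  pr <- delta_change_project(s$models[["model_01.RCP8.5"]], cl,
                             base = c(2000, 2009))
  iso <- isotherm_latitude(pr, 20, decades = 2010)
  expect_true(all(iso$min_lat <= iso$mean_lat & iso$mean_lat <= iso$max_lat))
  expect_warning(isotherm_latitude(pr, 45, decades = 2010), "not crossed")
})

test_that("heatwave anomalies recover the planted pulse and vanish on the baseline", {
  hw <- list(year = 2011, months = 1:3, amplitude = 3,
             lat_range = c(-30, -22), lon_range = c(110, 112))
  s <- simulate_sst(sst_sim_spec(lat_range = c(-40, 0), lon_range = c(110, 113),
                                 years = c(1980, 2015), noise_sd = 0,
                                 observed_trend = 0, model_biases = 0,
                                 heatwave = hw))
  an <- heatwave_anomaly(s$observed, event = list(year = 2011, months = 1:3),
                         baseline = c(1980, 2015))
  inside <- s$observed$lat >= -30 & s$observed$lat <= -22
  # pulse leaks into the baseline mean by 1/36 of its amplitude
  expected <- 3 * (1 - 1 / 36)
  expect_equal(an$sst[inside, 1], rep(expected, sum(inside)),
               tolerance = 1e-10)
  expect_equal(an$sst[!inside, 4], rep(0, sum(!inside)), tolerance = 1e-10)
  # an event year equal to climatology gives zero anomaly
  an2 <- heatwave_anomaly(s$observed, event = list(year = 2000, months = 1:3),
                          baseline = c(1980, 2015))
  expect_equal(an2$sst[inside, 2], rep(-3 / 36, sum(inside)),
               tolerance = 1e-10)
  expect_equal(an2$sst[!inside, 2], rep(0, sum(!inside)), tolerance = 1e-10)
})

test_that("current component anomalies follow the same seasonal arithmetic", {
  # steady flow + one-off seasonal pulse in the u component
  lat <- -(0:10); lon <- 110:112; years <- 1980:1990
  nt <- 12 * length(years)
  u <- array(0.2, dim = c(nt, length(lat), length(lon)))
  month <- rep(1:12, length(years)); yr <- rep(years, each = 12)
  u[yr == 1985 & month %in% 1:3, 3, 2] <-
    u[yr == 1985 & month %in% 1:3, 3, 2] + 0.4
  ug <- sst_grid(u, lat, lon, years, model = "soda", scenario = "observed")
  g <- sst_grid(array(20, dim = c(nt, length(lat), length(lon))), lat, lon,
                years)
  an <- heatwave_anomaly(g, currents = list(u = ug),
                         event = list(year = 1985, months = 1:3),
                         baseline = c(1980, 1990))
  expect_equal(an$currents$u[3, 2], 0.4 * (1 - 1 / 11), tolerance = 1e-10)
  expect_equal(an$currents$u[1, 1], 0, tolerance = 1e-12)
})
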