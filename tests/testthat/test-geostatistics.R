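test_that("empirical semivariogram matches exhaustive pairwise computation", {
  # 5 collinear points with fixed coordinates/values
  x <- c(0, 1, 2, 3, 4)
  v <- c(2.0, 3.5, 1.0, 4.0, 2.5)
  s <- station_samples(data.frame(x = x, y = rep(0, 5)), v)
  emp <- empirical_semivariogram(s, n_lags = 2, max_lag = 4)
  # brute force over all C(5,2) pairs
  pairs <- utils::combn(5, 2)
  d <- abs(x[pairs[1, ]] - x[pairs[2, ]])
  sq <- (v[pairs[1, ]] - v[pairs[2, ]])^2
  for (b in 1:2) {
    in_bin <- d > (b - 1) * 2 & d <= b * 2
    expect_equal(emp$gamma[b], sum(sq[in_bin]) / (2 * sum(in_bin)))
    expect_equal(emp$pairs[b], sum(in_bin))
  }
})

test_that("single-pair bins give gamma = d^2/2; constants give zero", {
  s <- station_samples(data.frame(x = c(0, 1, 10), y = c(0, 0, 0)),
                       c(1, 4, 2))
  emp <- empirical_semivariogram(s, n_lags = 10, max_lag = 10)
  # lag bin (0,1] holds exactly the pair with value difference 3
  expect_equal(emp$gamma[emp$pairs == 1 & emp$lag_center == 0.5], 3^2 / 2)

  const <- station_samples(data.frame(x = c(0, 1, 2, 5), y = rep(0, 4)),
                           rep(7, 4))
  empc <- empirical_semivariogram(const, n_lags = 3, max_lag = 6)
  expect_true(all(empc$gamma == 0))

  expect_error(empirical_semivariogram(s, n_lags = 3, max_lag = 0.5),
               class = "spatrisk_estimation_error")
})

test_that("variogram is shift-invariant and scales quadratically", {
  withr::with_seed(4, {
    xy <- data.frame(x = runif(25, 0, 10), y = runif(25, 0, 10))
    v <- rnorm(25)
  })
  base <- empirical_semivariogram(station_samples(xy, v))
  shift <- empirical_semivariogram(station_samples(xy, v + 100))
  scaled <- empirical_semivariogram(station_samples(xy, 3 * v))
  expect_equal(shift$gamma, base$gamma)
  expect_equal(scaled$gamma, 9 * base$gamma)
})

test_that("noiseless spherical curves are recovered to <= 1%", {
  h <- seq(0.02, 0.6, by = 0.02)
  true <- list(nugget = 0.1, psill = 0.9, range = 0.3)
  g <- variogram_curve(h, true$nugget, true$psill, true$range, "spherical")
  emp <- structure(data.frame(lag_center = h, gamma = g,
                              pairs = rep(10L, length(h))),
                   class = c("empirical_variogram", "data.frame"))
  fit <- fit_variogram_model(emp, "spherical")
  expect_lt(abs(fit$nugget - true$nugget) / true$nugget, 0.01)
  expect_lt(abs(fit$partial_sill - true$psill) / true$psill, 0.01)
  expect_lt(abs(fit$range - true$range) / true$range, 0.01)
})

test_that("flat variograms collapse to nugget and class as weak", {
  h <- seq(0.1, 1, by = 0.1)
  emp <- structure(data.frame(lag_center = h, gamma = rep(0.8, 10),
                              pairs = rep(5L, 10)),
                   class = c("empirical_variogram", "data.frame"))
  fit <- fit_variogram_model(emp)
  expect_lt(fit$partial_sill, 0.05 * (fit$nugget + fit$partial_sill))
  expect_gt(fit$sd_index, 75)
  expect_identical(fit$sd_class, "weak")
  expect_error(fit_variogram_model(emp[1:2, ]), class = "spatrisk_fitting_error")
})

test_that("SD index follows its definition, thresholds and invariances", {
  expect_equal(spatial_dependence_index(0.193513, 1.36949)$sd_index, 12.38,
               tolerance = 0.01 / 12.38)
  expect_identical(spatial_dependence_index(0.193513, 1.36949)$sd_class, "strong")
  expect_equal(spatial_dependence_index(0, 0.90347)$sd_index, 0)
  expect_equal(spatial_dependence_index(1, 0)$sd_index, 100)
  expect_identical(spatial_dependence_index(1, 0)$sd_class, "weak")
  expect_equal(spatial_dependence_index(0.11694, 0.8771)$sd_index, 11.76,
               tolerance = 0.01 / 11.76)
  # scale invariance
  for (k in c(0.01, 1, 250)) {
    expect_equal(spatial_dependence_index(k * 0.3, k * 0.7)$sd_index, 30)
  }
  expect_error(spatial_dependence_index(0, 0), class = "spatrisk_parameter_error")
  expect_error(spatial_dependence_index(-1, 2), class = "spatrisk_parameter_error")
})

test_that("ordinary kriging is exact, unbiased and symmetric", {
  area <- tiny_area(8, cell = 1)
  model <- variogram_model("spherical", nugget = 0, partial_sill = 1, range = 5)
  # stations on cell centers
  s <- station_samples(data.frame(x = c(0.5, 6.5, 0.5, 6.5),
                                  y = c(0.5, 0.5, 6.5, 6.5)),
                       c(1, 3, 1, 3))
  ok <- ordinary_kriging(s, model, area)
  expect_equal(raster_value_at(ok$prediction, s$x, s$y), s$value)
  expect_lt(max(abs(ok$weights_sum_range - 1)), 1e-8)
  # symmetry: center point equidistant from the a,a and b,b pairs
  center <- raster_value_at(ok$prediction, 3.5, 3.5)
  expect_equal(center, 2, tolerance = 1e-8)

  # constant stations -> constant surface
  sc <- station_samples(data.frame(x = c(0.5, 3.5, 6.5), y = c(0.5, 3.5, 6.5)),
                        rep(5, 3))
  okc <- ordinary_kriging(sc, model, area)
  expect_true(all(abs(okc$prediction$values - 5) < 1e-8))

  dup <- data.frame(x = c(0.5, 0.5, 3.5), y = c(0.5, 0.5, 3.5))
  expect_error(station_samples(dup, 1:3), class = "spatrisk_parameter_error")
})

test_that("variogram_report tabulates one row per variable", {
  area <- tiny_area(25)
  rs <- list(a = generate_criterion_field(area, 10, 0, seed = 1, name = "a"),
             b = generate_criterion_field(area, 10, 0.5, seed = 2, name = "b"))
  stns <- lapply(rs, sample_stations, n = 80, noise_sd = 0, seed = 5)
  rep1 <- variogram_report(stns)
  expect_equal(nrow(rep1), 2)
  expect_true(all(c("criterion", "nugget", "range", "partial_sill",
                    "sd_index", "sd_class") %in% names(rep1)))
  rep2 <- variogram_report(rs, from_rasters = TRUE, n_subsample = 80)
  expect_equal(rep2$criterion, c("a", "b"))
})
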