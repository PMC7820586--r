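#' Synthetic study worlds with known spatial structure
#'
#' The analysis this package implements was designed for observational data
#' (hospital case locations plus monitoring-station measurements) that are
#' not redistributable. The synthetic module generates stand-ins with the
#' statistical structure the method assumes — spatially autocorrelated
#' criterion surfaces, sparse noisy station samples of them, and clustered
#' case point patterns whose intensity is driven by a known subset of
#' criteria — so every downstream stage can be tested against ground truth.
#'
#' All generators are pure functions of their parameters and a seed.
#'
#' @name synthetic-data
NULL

#' Simulate a stationary Gaussian random field on a study-area grid
#'
#' Produces a zero-mean, unit-variance field whose theoretical semivariogram
#' has the requested practical range and nugget fraction: the correlated
#' component (weight `1 - nugget_fraction`) is synthesised by FFT circulant
#' embedding of the chosen covariance family, and an independent white-noise
#' component (weight `nugget_fraction`) supplies the nugget.
#'
#' @param area a [study_area()].
#' @param range practical range of the correlated component, map units, > 0.
#' @param nugget_fraction share of the unit variance that is spatially
#'   unstructured, in `[0, 1]`.
#' @param seed integer seed; same seed, same field.
#' @param family covariance family (see [variogram_curve()]).
#' @param name name carried by the returned raster.
#' @return A [criterion_raster()].
#' @export
generate_criterion_field <- function(area, range, nugget_fraction, seed,
                                     family = "spherical",
                                     name = "criterion") {
  stopifnot(inherits(area, "study_area"))
  if (!is.numeric(range) || range <= 0)
    stop_spatrisk("parameter", "range must be > 0")
  if (nugget_fraction < 0 || nugget_fraction > 1)
    stop_spatrisk("parameter", "nugget_fraction must be in [0, 1]")
  if (area$nrow * area$ncol < 2L)
    stop_spatrisk("parameter", "degenerate 1-cell grid")
  withr::with_seed(as.integer(seed), {
    corr <- if (nugget_fraction < 1)
      .grf_circulant(area$nrow, area$ncol, area$cell, range, family)
    else matrix(0, area$nrow, area$ncol)
    wn <- matrix(stats::rnorm(area$nrow * area$ncol), area$nrow, area$ncol)
    vals <- sqrt(1 - nugget_fraction) * corr + sqrt(nugget_fraction) * wn
  })
  criterion_raster(area, vals, name = name)
}

# 2-D circulant embedding on an enlarged torus; tiny negative eigenvalues
# from imperfect embeddability are clamped (warn if the deficit is material)
.grf_circulant <- function(nr, nc, cell, range, family) {
  # enlarge so the torus wrap-around distance exceeds the range
  need_r <- max(2 * nr, nr + ceiling(range / cell) + 1)
  need_c <- max(2 * nc, nc + ceiling(range / cell) + 1)
  mr <- stats::nextn(need_r, c(2, 3, 5))
  mc <- stats::nextn(need_c, c(2, 3, 5))
  dr <- cell * pmin(0:(mr - 1), mr - (0:(mr - 1)))
  dc <- cell * pmin(0:(mc - 1), mc - (0:(mc - 1)))
  dist <- sqrt(outer(dr^2, dc^2, "+"))
  covm <- vgm_correlation(dist, family, range)
  lambda <- Re(stats::fft(covm))
  neg <- lambda < 0
  if (any(neg)) {
    deficit <- -sum(lambda[neg]) / sum(abs(lambda))
    if (deficit > 1e-3)
      warning(sprintf("circulant embedding not nonnegative definite (deficit %.2g); clamping",
                      deficit))
    lambda[neg] <- 0
  }
  eps <- matrix(complex(real = stats::rnorm(mr * mc),
                        imaginary = stats::rnorm(mr * mc)), mr, mc)
  f <- stats::fft(sqrt(lambda) * eps) / sqrt(mr * mc)
  # normalise so the marginal variance is exactly the embedded C(0)
  field <- Re(f)[seq_len(nr), seq_len(nc), drop = FALSE] / sqrt(sum(lambda) / (mr * mc))
  field
}

#' Station samples of a criterion variable
#'
#' @param points data.frame-like with `x`, `y` columns.
#' @param values measurements at the points.
#' @param variable_name label.
#' @return An object of class `station_samples`.
#' @export
station_samples <- function(points, values, variable_name = "variable") {
  x <- points$x; y <- points$y
  if (length(x) < 3L)
    stop_spatrisk("parameter", "station samples need at least 3 points")
  if (anyDuplicated(cbind(x, y)))
    stop_spatrisk("parameter", "station locations must be distinct")
  if (anyNA(values) || length(values) != length(x))
    stop_spatrisk("parameter", "one non-missing value per station required")
  structure(data.frame(x = x, y = y, value = as.numeric(values)),
            variable_name = variable_name,
            class = c("station_samples", "data.frame"))
}

#' Sample monitoring stations from a criterion raster
#'
#' Draws `n` distinct in-mask cells, places a station at each cell center
#' and records the raster value plus optional Gaussian measurement noise.
#' Mirrors sparse monitoring networks (a dozen to a couple dozen stations
#' per variable) feeding the kriging stage.
#'
#' @param raster a [criterion_raster()].
#' @param n number of stations (>= 3, <= number of valid cells).
#' @param noise_sd measurement-noise standard deviation in value units.
#' @param seed integer seed.
#' @return A [station_samples()] object.
#' @export
sample_stations <- function(raster, n, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(raster, "criterion_raster"))
  valid <- which(!is.na(raster$values))
  if (n < 3L) stop_spatrisk("parameter", "need n >= 3 stations")
  if (n > length(valid))
    stop_spatrisk("sampling", "n = %d exceeds the %d valid cells", n, length(valid))
  area <- raster$area
  withr::with_seed(as.integer(seed), {
    pick <- sample(valid, n)
    noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  })
  rc <- arrayInd(pick, c(area$nrow, area$ncol))
  station_samples(
    data.frame(x = area$xmin + (rc[, 2] - 0.5) * area$cell,
               y = area$ymax - (rc[, 1] - 0.5) * area$cell),
    values = raster$values[pick] + noise,
    variable_name = raster$name)
}

#' Default scenario: the scale of the motivating study
#'
#' 13 environmental criteria over a ~730 km^2 urban frame (27 x 27 km at
#' 300 m resolution), 872 presence points, 70/30 train/test split. Nugget
#' fractions and relative ranges of the criterion fields echo the
#' spatial-dependence structure reported for real urban pollution,
#' meteorology and land-use distance surfaces: distance and particulate
#' surfaces almost nugget-free and strongly dependent, gas pollutants
#' noisier. The true drivers of case intensity are the distance-to-park,
#' distance-to-street and PM 2.5 surfaces.
#'
#' @param seed master seed for the scenario.
#' @param n_criteria number of criterion surfaces.
#' @param n_cases number of presence points (>= 10).
#' @param driver_indices which criteria truly drive log-intensity.
#' @param driver_coefficients their weights on the log scale.
#' @param spatial_range range (map units) per criterion.
#' @param nugget_fraction nugget fraction per criterion, in `[0, 1]`.
#' @param station_count stations per criterion (NA = no station network;
#'   the surface is used directly, as for land-use distance layers).
#' @param criterion_names labels.
#' @param train_fraction presence split used downstream.
#' @return An object of class `synthetic_scenario` (a list).
#' @export
synthetic_scenario <- function(seed = 1L,
                               n_criteria = 13L,
                               n_cases = 872L,
                               driver_indices = NULL,
                               driver_coefficients = NULL,
                               spatial_range = NULL,
                               nugget_fraction = NULL,
                               station_count = NULL,
                               criterion_names = NULL,
                               train_fraction = 0.7) {
  default_names <- c("dist_street", "pressure", "wind_speed", "humidity",
                     "temperature", "dist_park", "pm25", "pm10", "so2",
                     "no2", "co", "o3", "rainfall")
  default_range <- c(2585, 10298, 13484, 5386, 5128, 6541, 7563, 7705,
                     11833, 6678, 12283, 9578, 11617)
  default_nugfr <- c(0, 0.0177, 0.0883, 0.0412, 0.0499, 0, 0, 0,
                     0.1238, 0.0253, 0.1176, 0.0634, 0)
  default_stn <- c(NA, 12, 12, 12, 12, NA, 23, 23, 23, 23, 23, 23, 12)
  n_criteria <- as.integer(n_criteria)
  if (is.null(criterion_names))
    criterion_names <- rep_len(default_names, n_criteria)
  if (anyDuplicated(criterion_names))
    criterion_names <- make.unique(criterion_names, sep = "_")
  if (is.null(spatial_range)) spatial_range <- rep_len(default_range, n_criteria)
  if (is.null(nugget_fraction)) nugget_fraction <- rep_len(default_nugfr, n_criteria)
  if (is.null(station_count)) station_count <- rep_len(default_stn, n_criteria)
  if (is.null(driver_indices))
    driver_indices <- which(criterion_names %in% c("dist_park", "dist_street", "pm25"))
  if (is.null(driver_coefficients))
    driver_coefficients <- c(1.0, 0.9, 0.8)[seq_along(driver_indices)]
  if (length(driver_coefficients) != length(driver_indices))
    stop_spatrisk("parameter", "one coefficient per driver required")
  if (!all(driver_indices %in% seq_len(n_criteria)))
    stop_spatrisk("parameter", "driver_indices must lie in 1..n_criteria")
  if (n_cases < 10L) stop_spatrisk("parameter", "n_cases must be >= 10")
  if (any(spatial_range <= 0)) stop_spatrisk("parameter", "all ranges must be > 0")
  if (any(nugget_fraction < 0 | nugget_fraction > 1))
    stop_spatrisk("parameter", "nugget fractions must be in [0, 1]")
  if (!all(is.finite(driver_coefficients)))
    stop_spatrisk("parameter", "driver coefficients must be finite")
  structure(list(seed = as.integer(seed),
                 n_criteria = n_criteria,
                 n_cases = as.integer(n_cases),
                 driver_indices = as.integer(driver_indices),
                 driver_coefficients = as.numeric(driver_coefficients),
                 spatial_range = as.numeric(spatial_range),
                 nugget_fraction = as.numeric(nugget_fraction),
                 station_count = as.integer(station_count),
                 criterion_names = criterion_names,
                 train_fraction = train_fraction),
            class = "synthetic_scenario")
}

#' Default study frame for the default scenario
#'
#' @param cell grid resolution, map units (default 300 m -> 90 x 90 grid).
#' @return A [study_area()] of 27 x 27 km.
#' @export
default_study_area <- function(cell = 300) {
  study_area(width = 27000, height = 27000, cell = cell)
}

#' Generate all criterion surfaces of a scenario
#'
#' @param area a [study_area()].
#' @param scenario a [synthetic_scenario()].
#' @return named list of [criterion_raster()]s.
#' @export
generate_criteria <- function(area, scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  out <- vector("list", scenario$n_criteria)
  for (k in seq_len(scenario$n_criteria)) {
    out[[k]] <- generate_criterion_field(
      area,
      range = scenario$spatial_range[k],
      nugget_fraction = scenario$nugget_fraction[k],
      seed = scenario$seed + 1000L * k,
      name = scenario$criterion_names[k])
  }
  names(out) <- scenario$criterion_names
  out
}

#' Draw case presence points from a criterion-driven point process
#'
#' Cases follow an inhomogeneous Poisson-type process whose log-intensity
#' is the linear combination of the scenario's driver surfaces. Sampling is
#' by thinning (accept/reject against the normalised intensity), which is
#' exact for any bounded intensity; within an accepted cell the point is
#' placed uniformly. With all driver coefficients zero the pattern is
#' complete spatial randomness over the mask.
#'
#' @param area a [study_area()].
#' @param criteria named list of [criterion_raster()]s on the area grid.
#' @param scenario a [synthetic_scenario()].
#' @return [case_points()] with `label = 1`; the attribute
#'   `driver_indices` records the ground truth for recovery tests.
#' @export
generate_cases <- function(area, criteria, scenario) {
  stopifnot(inherits(area, "study_area"), inherits(scenario, "synthetic_scenario"))
  if (!any(area$mask)) stop_spatrisk("generation", "empty study-area mask")
  for (r in criteria)
    if (!same_grid(r$area, area))
      stop_spatrisk("alignment", "criterion '%s' is not on the study-area grid", r$name)
  eta <- matrix(0, area$nrow, area$ncol)
  for (j in seq_along(scenario$driver_indices)) {
    k <- scenario$driver_indices[j]
    eta <- eta + scenario$driver_coefficients[j] * criteria[[k]]$values
  }
  lam <- exp(eta)
  lam[!area$mask] <- NA_real_
  valid <- which(!is.na(lam))
  lmax <- max(lam[valid])
  n <- scenario$n_cases
  withr::with_seed(scenario$seed + 7L, {
    xs <- numeric(0); ys <- numeric(0)
    while (length(xs) < n) {
      m <- max(2L * (n - length(xs)), 100L)
      cand <- sample(valid, m, replace = TRUE)
      keep <- stats::runif(m) < lam[cand] / lmax
      cand <- cand[keep]
      rc <- arrayInd(cand, c(area$nrow, area$ncol))
      xs <- c(xs, area$xmin + (rc[, 2] - 1 + stats::runif(length(cand))) * area$cell)
      ys <- c(ys, area$ymax - (rc[, 1] - 1 + stats::runif(length(cand))) * area$cell)
    }
  })
  pts <- case_points(xs[seq_len(n)], ys[seq_len(n)], label = 1L)
  attr(pts, "driver_indices") <- scenario$driver_indices
  attr(pts, "driver_coefficients") <- scenario$driver_coefficients
  pts
}
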