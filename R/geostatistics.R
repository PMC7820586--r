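#' Empirical omnidirectional semivariogram
#'
#' Classical Matheron estimator: for each lag bin,
#' `gamma(h) = 1 / (2 N(h)) * sum over pairs [Z(x_i) - Z(x_j)]^2`,
#' with every unordered pair counted once. Binning is omnidirectional over
#' `n_lags` equal-width bins on `(0, max_lag]`; empty bins are dropped.
#'
#' @param samples a [station_samples()] object.
#' @param n_lags number of lag bins (default 12).
#' @param max_lag largest pair distance considered; default half the
#'   maximum inter-station distance (geostatistical convention).
#' @return An object of class `empirical_variogram`: data.frame with
#'   `lag_center`, `gamma`, `pairs`.
#' @export
empirical_semivariogram <- function(samples, n_lags = 12L, max_lag = NULL) {
  stopifnot(inherits(samples, "station_samples"))
  d <- stats::dist(cbind(samples$x, samples$y))
  if (is.null(max_lag)) max_lag <- max(d) / 2
  sq <- stats::dist(samples$value)^2
  keep <- d > 0 & d <= max_lag
  if (!any(keep))
    stop_spatrisk("estimation",
                  "no station pairs within max_lag = %g (all %d bins empty)",
                  max_lag, n_lags)
  width <- max_lag / n_lags
  bin <- pmin(ceiling(d[keep] / width), n_lags)
  gamma <- tapply(sq[keep], bin, function(s) sum(s) / (2 * length(s)))
  pairs <- tapply(sq[keep], bin, length)
  bins <- as.integer(names(gamma))
  out <- data.frame(lag_center = (bins - 0.5) * width,
                    gamma = as.numeric(gamma),
                    pairs = as.integer(pairs))
  out <- out[order(out$lag_center), ]
  rownames(out) <- NULL
  structure(out, max_lag = max_lag, n_lags = n_lags,
            variable_name = attr(samples, "variable_name"),
            class = c("empirical_variogram", "data.frame"))
}

#' Fit a variogram model to an empirical semivariogram
#'
#' Minimises the pair-count-weighted squared error between the model curve
#' and the empirical semivariances. Given the family and a candidate range,
#' the (nugget, partial sill) pair solves a weighted linear least-squares
#' problem (clamped at zero); the range itself is found by profiling that
#' inner solution over a dense grid followed by local refinement, which
#' avoids the local minima a free 3-parameter descent can fall into.
#'
#' @param emp an [empirical_semivariogram()] result with >= 3 bins.
#' @param family model family (default spherical).
#' @return A [variogram_model()] carrying the SD index and its class.
#' @export
fit_variogram_model <- function(emp, family = "spherical") {
  stopifnot(inherits(emp, "empirical_variogram"))
  if (nrow(emp) < 3L)
    stop_spatrisk("fitting", "need >= 3 non-empty lag bins, got %d", nrow(emp))
  h <- emp$lag_center; g <- emp$gamma; w <- as.numeric(emp$pairs)

  sse_for_range <- function(a) {
    x <- 1 - vgm_correlation(h, family, a)      # gamma = n + p * x
    fit <- .wls_nonneg(x, g, w)
    attr(fit, "sse")
  }
  params_for_range <- function(a) {
    x <- 1 - vgm_correlation(h, family, a)
    .wls_nonneg(x, g, w)
  }

  lo <- max(min(h) / 4, 1e-9)
  hi <- 3 * max(h)
  grid <- exp(seq(log(lo), log(hi), length.out = 200L))
  sse <- vapply(grid, sse_for_range, numeric(1))
  if (!any(is.finite(sse)))
    stop_spatrisk("fitting", "variogram fit did not converge (all candidate ranges degenerate)")
  i <- which.min(sse)
  bracket <- c(grid[max(1L, i - 1L)], grid[min(length(grid), i + 1L)])
  opt <- stats::optimize(sse_for_range, interval = bracket)
  a <- if (opt$objective <= sse[i]) opt$minimum else grid[i]
  np <- params_for_range(a)
  variogram_model(family, nugget = np[1], partial_sill = np[2], range = a)
}

# weighted LS of g ~ n + p x with n, p >= 0; returns c(n, p) with attr sse
.wls_nonneg <- function(x, g, w) {
  fit1 <- try(stats::lm.wfit(cbind(1, x), g, w)$coefficients, silent = TRUE)
  cand <- list()
  if (!inherits(fit1, "try-error") && !anyNA(fit1) && all(fit1 >= -1e-12))
    cand <- c(cand, list(pmax(fit1, 0)))
  # boundary solutions; pure nugget first so flat (unidentifiable) inputs
  # tie-break toward the unstructured interpretation
  cand <- c(list(c(max(stats::weighted.mean(g, w), 0), 0)),            # pure nugget
            cand,
            list(c(0, max(sum(w * x * g) / sum(w * x^2), 0))))         # nugget = 0
  best <- NULL; best_sse <- Inf
  for (p in cand) {
    sse <- sum(w * (g - p[1] - p[2] * x)^2)
    if (is.null(best) || sse < best_sse - 1e-12 * (1 + best_sse)) {
      best <- p; best_sse <- sse
    }
  }
  structure(as.numeric(best), sse = best_sse)
}

#' Spatial-dependence (SD) index of a variogram
#'
#' `SD = 100 * nugget / (nugget + partial_sill)`: the nugget's share of the
#' total sill, in percent. Under 25% the variable is classed as strongly
#' spatially correlated, 25-75% moderate, above 75% weak.
#'
#' @param nugget,partial_sill semivariances, both >= 0, not both zero.
#' @return list with `sd_index` (percent) and `sd_class`
#'   (`"strong"`/`"moderate"`/`"weak"`).
#' @export
spatial_dependence_index <- function(nugget, partial_sill) {
  if (nugget < 0 || partial_sill < 0)
    stop_spatrisk("parameter", "nugget and partial sill must be >= 0")
  if (nugget + partial_sill == 0)
    stop_spatrisk("parameter", "SD index undefined: nugget + partial sill = 0")
  sd <- 100 * nugget / (nugget + partial_sill)
  cls <- if (sd < 25) "strong" else if (sd <= 75) "moderate" else "weak"
  list(sd_index = sd, sd_class = cls)
}

#' Ordinary kriging of station samples onto a study-area grid
#'
#' Best linear unbiased prediction under an unknown constant mean: at every
#' cell the weights solve the ordinary-kriging system built from the fitted
#' variogram, with a Lagrange multiplier enforcing that weights sum to one.
#' Predictions are exact at station cells. Out-of-mask cells are nodata.
#'
#' @param samples a [station_samples()] object (>= 3 distinct stations).
#' @param model a fitted [variogram_model()].
#' @param area the target [study_area()].
#' @return list with `prediction` and `variance`, both [criterion_raster()]s.
#' @export
ordinary_kriging <- function(samples, model, area) {
  stopifnot(inherits(samples, "station_samples"),
            inherits(model, "variogram_model"),
            inherits(area, "study_area"))
  n <- nrow(samples)
  if (n < 3L) stop_spatrisk("parameter", "kriging needs >= 3 stations")
  xy <- cbind(samples$x, samples$y)
  dup <- which(duplicated(xy) | duplicated(xy, fromLast = TRUE))
  if (length(dup))
    stop_spatrisk("linear_algebra",
                  "singular kriging system: duplicate stations at rows %s",
                  paste(sort(unique(dup)), collapse = ", "))
  gam <- function(h) variogram_curve(h, model$nugget, model$partial_sill,
                                     model$range, model$family)
  A <- matrix(0, n + 1, n + 1)
  A[seq_len(n), seq_len(n)] <- gam(as.matrix(stats::dist(xy)))
  A[n + 1, seq_len(n)] <- 1
  A[seq_len(n), n + 1] <- 1
  cc <- cell_centers(area, mask_only = TRUE)
  D <- sqrt(outer(samples$x, cc$x, "-")^2 + outer(samples$y, cc$y, "-")^2)
  B <- rbind(gam(D), 1)
  W <- tryCatch(solve(A, B), error = function(e)
    stop_spatrisk("linear_algebra", "singular kriging system: %s", conditionMessage(e)))
  pred <- as.numeric(crossprod(W[seq_len(n), , drop = FALSE], samples$value))
  # exactness: gamma-based OK interpolates, but enforce it against round-off
  at_station <- which(D < 1e-9, arr.ind = TRUE)
  if (length(at_station)) pred[at_station[, 2]] <- samples$value[at_station[, 1]]
  krigvar <- pmax(colSums(W * B), 0)
  pm <- vm <- matrix(NA_real_, area$nrow, area$ncol)
  idx <- cbind(cc$row, cc$col)
  pm[idx] <- pred
  vm[idx] <- krigvar
  list(prediction = criterion_raster(area, pm, name = attr(samples, "variable_name")),
       variance = criterion_raster(area, vm,
                                   name = paste0(attr(samples, "variable_name"), "_krigvar")),
       weights_sum_range = range(colSums(W[seq_len(n), , drop = FALSE])))
}

#' Variogram report for a set of variables
#'
#' Fits a variogram per variable and tabulates nugget, range, partial sill
#' and the SD index with its class — the standard summary table of a
#' multi-criterion geostatistical screening. By default values are
#' standardized (zero mean, unit variance) before estimation so sills are
#' comparable across variables with different units.
#'
#' @param samples_list named list of [station_samples()] (or of
#'   [criterion_raster()]s when `from_rasters = TRUE`).
#' @param family model family.
#' @param standardize standardize values before estimation (default TRUE).
#' @param from_rasters estimate from a random subsample of raster cells
#'   instead of station data.
#' @param n_subsample,seed subsample size/seed when `from_rasters = TRUE`.
#' @return data.frame, one row per variable: `criterion`, `family`,
#'   `nugget`, `range`, `partial_sill`, `sd_index`, `sd_class`.
#' @export
variogram_report <- function(samples_list, family = "spherical",
                             standardize = TRUE, from_rasters = FALSE,
                             n_subsample = 200L, seed = 1L) {
  rows <- lapply(seq_along(samples_list), function(i) {
    s <- samples_list[[i]]
    if (from_rasters) s <- sample_stations(s, n = min(n_subsample, sum(!is.na(s$values))),
                                           noise_sd = 0, seed = seed + i)
    if (standardize) {
      v <- s$value
      s$value <- if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v - mean(v)
    }
    m <- fit_variogram_model(empirical_semivariogram(s), family = family)
    data.frame(criterion = attr(s, "variable_name") %||% names(samples_list)[i],
               family = m$family, nugget = m$nugget, range = m$range,
               partial_sill = m$partial_sill, sd_index = m$sd_index,
               sd_class = m$sd_class, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
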