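#' Theoretical variogram / correlation models
#'
#' Three classical isotropic families are supported. All use the
#' practical-range convention: `range` is the distance at which the model
#' (effectively) reaches its sill — exact for the spherical model, the
#' 95%-correlation-decay distance for the exponential and Gaussian models.
#'
#' @name variogram-models
NULL

.vgm_families <- c("spherical", "exponential", "gaussian")

# correlation rho(h) with rho(0) = 1, practical range a
vgm_correlation <- function(h, family, range) {
  family <- match.arg(family, .vgm_families)
  a <- range
  switch(family,
    spherical   = ifelse(h < a, 1 - 1.5 * h / a + 0.5 * (h / a)^3, 0),
    exponential = exp(-3 * h / a),
    gaussian    = exp(-3 * (h / a)^2))
}

#' Evaluate a theoretical semivariogram curve
#'
#' gamma(h) = nugget + partial_sill * (1 - rho(h)) for h > 0; gamma(0) = 0.
#'
#' @param h distances (map units).
#' @param nugget,partial_sill,range model parameters.
#' @param family one of `"spherical"`, `"exponential"`, `"gaussian"`.
#' @return semivariance values.
#' @export
variogram_curve <- function(h, nugget, partial_sill, range,
                            family = "spherical") {
  g <- nugget + partial_sill * (1 - vgm_correlation(h, family, range))
  g[h == 0] <- 0
  g
}

#' Construct a fitted variogram model object
#'
#' Bundles the nugget/partial-sill/range triple with its family and the
#' spatial-dependence (SD) index derived from it.
#'
#' @param family model family.
#' @param nugget,partial_sill,range parameters; nugget and partial sill are
#'   semivariances (value units squared), range is in map units.
#' @return An object of class `variogram_model`.
#' @export
variogram_model <- function(family, nugget, partial_sill, range) {
  family <- match.arg(family, .vgm_families)
  if (nugget < 0 || partial_sill < 0)
    stop_spatrisk("parameter", "nugget and partial sill must be >= 0")
  if (range <= 0) stop_spatrisk("parameter", "range must be > 0")
  sd <- spatial_dependence_index(nugget, partial_sill)
  structure(list(family = family, nugget = nugget,
                 partial_sill = partial_sill, range = range,
                 sd_index = sd$sd_index, sd_class = sd$sd_class),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model> %s: nugget %.4g, partial sill %.4g, range %.4g | SD %.2f%% (%s)\n",
              x$family, x$nugget, x$partial_sill, x$range, x$sd_index, x$sd_class))
  invisible(x)
}
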