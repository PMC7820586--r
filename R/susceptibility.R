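#' Split presence points into train/test partitions
#'
#' Seeded random partition. The training count follows the configured
#' rounding rule applied to `n * train_fraction` (default `round`, so 872
#' presences at 0.7 give 610 train / 262 test).
#'
#' @param points a [case_points()] set.
#' @param train_fraction in (0, 1).
#' @param seed integer seed.
#' @param rounding `"round"`, `"floor"` or `"ceiling"`.
#' @return The points with the `partition` column filled.
#' @export
split_points <- function(points, train_fraction = 0.7, seed = 1L,
                         rounding = c("round", "floor", "ceiling")) {
  rounding <- match.arg(rounding)
  n <- nrow(points)
  if (n < 2L) stop_spatrisk("split", "need at least 2 points to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_spatrisk("parameter", "train_fraction must be in (0, 1)")
  n_train <- switch(rounding,
                    round = round(n * train_fraction),
                    floor = floor(n * train_fraction),
                    ceiling = ceiling(n * train_fraction))
  n_train <- max(1L, min(n - 1L, as.integer(n_train)))
  idx <- withr::with_seed(as.integer(seed), sample.int(n, n_train))
  points$partition <- "test"
  points$partition[idx] <- "train"
  points
}

#' Sample pseudo-absence points
#'
#' Draws label-0 locations uniformly over the in-mask cells lying at least
#' `min_distance` from every presence, then jitters uniformly within the
#' cell. A non-zero buffer keeps background points from sitting on top of
#' cases (label noise); `min_distance = 0` reproduces plain random
#' background sampling.
#'
#' @param presences presence [case_points()].
#' @param area the [study_area()].
#' @param n number of pseudo-absences (default: one per presence, giving
#'   balanced labels).
#' @param min_distance exclusion radius in map units (default 2 cells).
#' @param seed integer seed.
#' @return [case_points()] with `label = 0`.
#' @export
sample_pseudo_absence <- function(presences, area, n = NULL,
                                  min_distance = NULL, seed = 1L) {
  stopifnot(inherits(area, "study_area"))
  pres <- presences[presences$label == 1, , drop = FALSE]
  if (is.null(n)) n <- nrow(pres)
  if (is.null(min_distance)) min_distance <- 2 * area$cell
  cc <- cell_centers(area, mask_only = TRUE)
  eligible <- rep(TRUE, nrow(cc))
  if (min_distance > 0 && nrow(pres) > 0) {
    # chunked nearest-presence distance from each candidate cell center
    md2 <- min_distance^2
    for (s in split(seq_len(nrow(cc)), ceiling(seq_len(nrow(cc)) / 2000))) {
      d2 <- outer(cc$x[s], pres$x, "-")^2 + outer(cc$y[s], pres$y, "-")^2
      eligible[s] <- apply(d2, 1, min) >= md2
    }
  }
  if (!any(eligible))
    stop_spatrisk("sampling",
                  "no eligible cells: mask too small for min_distance = %g",
                  min_distance)
  pool <- which(eligible)
  withr::with_seed(as.integer(seed), {
    cells <- sample(pool, n, replace = TRUE)
    jx <- stats::runif(n, -0.5, 0.5) * area$cell
    jy <- stats::runif(n, -0.5, 0.5) * area$cell
  })
  case_points(cc$x[cells] + jx, cc$y[cells] + jy, label = 0L)
}

#' Assemble the model feature matrix
#'
#' One row per point, one column per criterion holding the FR-weight
#' surface value at the point's cell; points falling on nodata in any
#' surface are dropped with a warning.
#'
#' @param points labeled [case_points()].
#' @param fr_surfaces named list of FR-weight [criterion_raster()]s on a
#'   common grid.
#' @return An object of class `feature_matrix`: list with `X` (matrix),
#'   `label`, `partition`, and `dropped` (count).
#' @export
extract_features <- function(points, fr_surfaces) {
  if (!length(fr_surfaces)) stop_spatrisk("parameter", "no feature surfaces given")
  g0 <- fr_surfaces[[1]]$area
  for (s in fr_surfaces)
    if (!same_grid(s$area, g0))
      stop_spatrisk("alignment", "surface '%s' is not on the common grid", s$name)
  X <- vapply(fr_surfaces, function(s) raster_value_at(s, points$x, points$y),
              numeric(nrow(points)))
  X <- matrix(X, nrow = nrow(points),
              dimnames = list(NULL, names(fr_surfaces)))
  keep <- stats::complete.cases(X)
  if (!all(keep))
    warning(sprintf("%d point(s) on nodata dropped from the feature matrix",
                    sum(!keep)))
  structure(list(X = X[keep, , drop = FALSE],
                 label = points$label[keep],
                 partition = points$partition[keep],
                 dropped = sum(!keep)),
            class = "feature_matrix")
}

# rows of a feature matrix belonging to a partition (NA partition = all)
fm_subset <- function(fm, part = NULL) {
  if (is.null(part)) return(fm)
  keep <- !is.na(fm$partition) & fm$partition == part
  structure(list(X = fm$X[keep, , drop = FALSE], label = fm$label[keep],
                 partition = fm$partition[keep], dropped = fm$dropped),
            class = "feature_matrix")
}

#' Train the random-forest susceptibility classifier
#'
#' Bagged CART ensemble: each tree is grown to purity on a bootstrap
#' resample with random feature subsampling (`mtry`, default `sqrt(p)`) at
#' every split. Importances are total Gini-impurity decreases, normalised
#' to sum 1. The model also records out-of-bag (OOB) vote fractions per
#' training row — the standard unsaturated estimate of training-data
#' performance for a forest grown to purity (resubstitution predictions
#' are near-perfect by construction). Fully deterministic for a fixed
#' seed.
#'
#' @param features a [extract_features()] matrix (training rows are used
#'   when a partition is present).
#' @param n_trees number of trees (default 100).
#' @param mtry features tried per split.
#' @param min_node minimal node size to attempt a split on.
#' @param seed integer seed.
#' @return An object of class `rf_model` with `$importance` (named,
#'   sums to 1).
#' @export
train_random_forest <- function(features, n_trees = 100L, mtry = NULL,
                                min_node = 1L, seed = 1L) {
  stopifnot(inherits(features, "feature_matrix"))
  fm <- if (any(!is.na(features$partition) & features$partition == "train"))
    fm_subset(features, "train") else features
  X <- fm$X; y <- as.integer(fm$label)
  if (nrow(X) < 10L) stop_spatrisk("training", "need >= 10 training rows")
  if (length(unique(y)) < 2L)
    stop_spatrisk("training", "both labels must be present in the training data")
  p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  res <- withr::with_seed(as.integer(seed),
    .rf_train_cpp(X, y, as.integer(n_trees), as.integer(mtry),
                  as.integer(min_node)))
  imp <- res$importance
  imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / p, p)
  names(imp) <- colnames(X)
  structure(list(forest = res$forest, importance = imp,
                 oob_prob = res$oob_prob, train_label = y,
                 schema = colnames(X), n_trees = as.integer(n_trees),
                 mtry = as.integer(mtry), seed = as.integer(seed)),
            class = "rf_model")
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("<rf_model> %d trees, mtry %d, %d features\n",
              x$n_trees, x$mtry, length(x$schema)))
  imp <- sort(x$importance, decreasing = TRUE)
  cat("  top importances:",
      paste(sprintf("%s=%.3f", names(imp)[seq_len(min(4, length(imp)))],
                    imp[seq_len(min(4, length(imp)))]), collapse = ", "), "\n")
  invisible(x)
}

#' Persist a fitted forest to a portable JSON file
#'
#' The file carries a format version, the feature schema and every tree
#' (plain matrices), so a model can be reloaded in a fresh session and
#' gives bit-identical predictions.
#'
#' @param model an `rf_model`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
save_rf_model <- function(model, path) {
  stopifnot(inherits(model, "rf_model"))
  payload <- list(format = "spatrisk_rf", version = 1L,
                  schema = model$schema, n_trees = model$n_trees,
                  mtry = model$mtry, seed = model$seed,
                  importance = as.numeric(model$importance),
                  oob_prob = model$oob_prob, train_label = model$train_label,
                  forest = lapply(model$forest, function(m) unclass(m)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' @rdname save_rf_model
#' @param path path written by [save_rf_model()].
#' @return `load_rf_model`: the restored `rf_model`.
#' @export
load_rf_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "spatrisk_rf"))
    stop_spatrisk("io", "%s is not a spatrisk random-forest file", path)
  imp <- as.numeric(p$importance)
  names(imp) <- p$schema
  structure(list(forest = lapply(p$forest, function(m)
                   matrix(as.numeric(m), ncol = 5, byrow = FALSE)),
                 importance = imp, oob_prob = as.numeric(p$oob_prob),
                 train_label = as.integer(p$train_label),
                 schema = p$schema, n_trees = as.integer(p$n_trees),
                 mtry = as.integer(p$mtry), seed = as.integer(p$seed)),
            class = "rf_model")
}

#' Predict presence probability
#'
#' Probability is the fraction of trees voting presence at the row.
#'
#' @param object an [train_random_forest()] model.
#' @param newdata a `feature_matrix` or plain numeric matrix with the
#'   training schema's columns.
#' @param ... unused.
#' @return numeric probabilities in \[0, 1\].
#' @export
predict.rf_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_matrix")) newdata$X else newdata
  if (!is.matrix(X)) X <- as.matrix(X)
  if (is.null(colnames(X)) && ncol(X) == length(object$schema))
    colnames(X) <- object$schema
  if (!identical(colnames(X), object$schema)) {
    if (!all(object$schema %in% colnames(X)))
      stop_spatrisk("prediction", "newdata does not carry the training schema (%s)",
                    paste(setdiff(object$schema, colnames(X)), collapse = ", "))
    X <- X[, object$schema, drop = FALSE]
  }
  .rf_predict_cpp(object$forest, X)
}

#' Predict the susceptibility surface
#'
#' Applies the fitted model to every valid cell of the FR-weight surfaces.
#'
#' @param model an `rf_model`.
#' @param fr_surfaces named list of FR-weight rasters matching the
#'   training schema.
#' @return A [criterion_raster()] of presence probabilities in \[0, 1\];
#'   nodata propagated.
#' @export
predict_susceptibility <- function(model, fr_surfaces) {
  stopifnot(inherits(model, "rf_model"))
  if (!all(model$schema %in% names(fr_surfaces)))
    stop_spatrisk("prediction", "surfaces missing for: %s",
                  paste(setdiff(model$schema, names(fr_surfaces)), collapse = ", "))
  fr_surfaces <- fr_surfaces[model$schema]
  area <- fr_surfaces[[1]]$area
  M <- vapply(fr_surfaces, function(s) as.vector(s$values),
              numeric(area$nrow * area$ncol))
  valid <- stats::complete.cases(M)
  prob <- rep(NA_real_, nrow(M))
  if (any(valid)) {
    Xv <- M[valid, , drop = FALSE]
    colnames(Xv) <- model$schema
    prob[valid] <- predict(model, Xv)
  }
  criterion_raster(area, matrix(prob, area$nrow, area$ncol),
                   name = "susceptibility")
}

#' Class a probability surface into ordinal risk classes
#'
#' Jenks natural breaks on the valid probabilities, five classes by
#' default (very-low ... very-high). Class ids are monotone in
#' probability.
#'
#' @param prob a probability [criterion_raster()].
#' @param k number of classes (default 5).
#' @return list with `classes` (integer raster), `breaks` (k + 1 edges)
#'   and `labels`.
#' @export
classify_map <- function(prob, k = 5L) {
  stopifnot(inherits(prob, "criterion_raster"))
  v <- prob$values[!is.na(prob$values)]
  if (length(unique(v)) < k)
    stop_spatrisk("degenerate_classing",
                  "only %d distinct probabilities for k = %d classes",
                  length(unique(v)), k)
  edges <- jenks_breaks(v, k)
  scheme <- structure(list(criterion = prob$name, method = "natural_breaks",
                           edges = edges, k = as.integer(k), strict = FALSE),
                      class = "class_scheme")
  cls <- assign_classes(as.vector(prob$values), scheme)
  labels <- if (k == 5L) c("very-low", "low", "moderate", "high", "very-high")
            else paste0("class-", seq_len(k))
  list(classes = criterion_raster(prob$area,
                                  matrix(as.numeric(cls), prob$area$nrow, prob$area$ncol),
                                  name = paste0(prob$name, "_class")),
       breaks = edges, labels = labels)
}
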