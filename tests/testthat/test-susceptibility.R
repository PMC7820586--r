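test_that("split_points follows the rounding rule and is seeded", {
  withr::with_seed(1, pts <- case_points(runif(872), runif(872)))
  sp <- split_points(pts, 0.7, seed = 4)
  expect_equal(sum(sp$partition == "train"), 610)   # round(872 * 0.7)
  expect_equal(sum(sp$partition == "test"), 262)
  expect_equal(sum(split_points(pts, 0.7, seed = 4,
                                rounding = "ceiling")$partition == "train"), 611)

  ten <- case_points(runif(10), runif(10))
  s5 <- split_points(ten, 0.5, seed = 1)
  expect_equal(as.vector(table(s5$partition)), c(5L, 5L))

  expect_identical(split_points(pts, 0.7, seed = 9),
                   split_points(pts, 0.7, seed = 9))
  expect_error(split_points(pts[1, ], 0.7), class = "spatrisk_split_error")
  expect_error(split_points(pts, 1.2), class = "spatrisk_parameter_error")
})

test_that("pseudo-absences respect the exclusion buffer and balance labels", {
  area <- tiny_area(20, cell = 1)
  withr::with_seed(2, pres <- case_points(runif(30, 0, 20), runif(30, 0, 20)))
  abs1 <- sample_pseudo_absence(pres, area, min_distance = 3, seed = 5)
  expect_equal(nrow(abs1), nrow(pres))           # balanced by default
  expect_true(all(abs1$label == 0))
  # exhaustive pairwise check: cell centers of absences >= 3 from presences
  cc <- spatrisk:::cell_centers(area)
  for (i in seq_len(nrow(abs1))) {
    ctr <- locate_cells(area, abs1$x[i], abs1$y[i])
    cx <- area$xmin + (ctr$col - 0.5) * area$cell
    cy <- area$ymax - (ctr$row - 0.5) * area$cell
    expect_gte(min(sqrt((cx - pres$x)^2 + (cy - pres$y)^2)), 3)
  }
  # min_distance = 0: anywhere in the mask
  abs0 <- sample_pseudo_absence(pres, area, n = 500, min_distance = 0, seed = 6)
  expect_true(all(locate_cells(area, abs0$x, abs0$y)$inside))
  expect_error(sample_pseudo_absence(pres, area, min_distance = 100, seed = 1),
               class = "spatrisk_sampling_error")
})

test_that("extract_features samples the containing cell and conserves rows", {
  area <- tiny_area(5)
  surfaces <- lapply(1:13, function(k)
    criterion_raster(area, matrix(k * seq_len(25), 5, 5), name = paste0("s", k)))
  names(surfaces) <- paste0("s", seq_along(surfaces))
  pts <- case_points(c(0.5, 2.5, 4.5), c(0.5, 2.5, 4.5), label = c(1, 0, 1))
  fm <- extract_features(pts, surfaces)
  expect_equal(ncol(fm$X), 13)
  # point at a cell center carries exactly that cell's value
  expect_equal(unname(fm$X[1, "s1"]), surfaces$s1$values[5, 1])
  expect_equal(fm$dropped + nrow(fm$X), nrow(pts))

  surf2 <- surfaces
  surf2$s1 <- criterion_raster(tiny_area(5, cell = 2), surfaces$s1$values)
  expect_error(extract_features(pts, surf2), class = "spatrisk_alignment_error")
  masked <- tiny_area(5, mask = {
    m <- matrix(TRUE, 5, 5); m[5, 1] <- FALSE; m
  })
  surf2 <- lapply(surfaces, function(s) criterion_raster(masked, s$values))
  expect_warning(fm2 <- extract_features(pts, surf2), "nodata")
  expect_equal(nrow(fm2$X) + fm2$dropped, nrow(pts))
})

test_that("random forest separates an indicator feature and is deterministic", {
  withr::with_seed(8, {
    X <- cbind(sig = runif(200), noise1 = runif(200), noise2 = runif(200))
  })
  y <- as.integer(X[, "sig"] > 0.5)
  fm <- structure(list(X = X, label = y, partition = rep(NA_character_, 200),
                       dropped = 0L), class = "feature_matrix")
  m <- train_random_forest(fm, n_trees = 50, seed = 3)
  expect_equal(names(which.max(m$importance)), "sig")
  expect_equal(sum(m$importance), 1, tolerance = 1e-12)
  p1 <- predict(m, X)
  m2 <- train_random_forest(fm, n_trees = 50, seed = 3)
  expect_identical(p1, predict(m2, X))
  expect_true(all(p1 >= 0 & p1 <= 1))
  # separable pattern is learned
  expect_gt(suppressWarnings(roc_curve(y, p1)$auc), 0.99)

  bad <- fm; bad$label <- rep(1L, 200)
  expect_error(train_random_forest(bad), class = "spatrisk_training_error")
  expect_error(train_random_forest(structure(list(X = X[1:5, ], label = y[1:5],
                                                  partition = rep(NA, 5), dropped = 0L),
                                             class = "feature_matrix")),
               class = "spatrisk_training_error")
})

test_that("a persisted model reloads with identical predictions", {
  withr::with_seed(12, {
    X <- cbind(a = runif(80), b = runif(80))
    y <- as.integer(X[, "a"] > 0.5)
  })
  fm <- structure(list(X = X, label = y, partition = rep(NA_character_, 80),
                       dropped = 0L), class = "feature_matrix")
  m <- train_random_forest(fm, n_trees = 20, seed = 1)
  f <- tempfile(fileext = ".json")
  save_rf_model(m, f)
  m2 <- load_rf_model(f)
  expect_identical(predict(m, X), predict(m2, X))
  expect_equal(m2$importance, m$importance)
  expect_identical(m2$schema, m$schema)
})

test_that("susceptibility surfaces are bounded, constant-consistent and classed", {
  area <- tiny_area(8)
  withr::with_seed(5, {
    X <- cbind(a = runif(60), b = runif(60))
    y <- as.integer(X[, "a"] + 0.3 * rnorm(60) > 0.5)
  })
  fm <- structure(list(X = X, label = y, partition = rep(NA_character_, 60),
                       dropped = 0L), class = "feature_matrix")
  m <- train_random_forest(fm, n_trees = 30, seed = 2)
  flat <- list(a = criterion_raster(area, matrix(0.8, 8, 8), name = "a"),
               b = criterion_raster(area, matrix(0.2, 8, 8), name = "b"))
  pf <- predict_susceptibility(m, flat)
  v <- pf$values[!is.na(pf$values)]
  expect_equal(length(unique(v)), 1L)   # constant features -> constant probability
  expect_true(all(v >= 0 & v <= 1))
  expect_error(predict_susceptibility(m, flat["a"]), class = "spatrisk_prediction_error")

  # classify_map: two well-separated modes, k = 2 -> break between them
  pm <- criterion_raster(area, matrix(rep(c(0.1, 0.9), each = 32), 8, 8))
  cm <- classify_map(pm, k = 2)
  expect_gt(cm$breaks[2], 0.1)
  expect_lt(cm$breaks[2], 0.9)
  cls <- cm$classes$values
  expect_true(all(cls[pm$values < 0.5] == 1))
  expect_true(all(cls[pm$values > 0.5] == 2))
  expect_equal(sum(is.na(cls)), 0)
  expect_error(classify_map(criterion_raster(area, matrix(0.5, 8, 8))),
               class = "spatrisk_degenerate_classing_error")
})
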