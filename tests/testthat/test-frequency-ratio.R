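test_that("jenks_breaks matches exhaustive search on small inputs", {
  v <- c(1, 1, 1, 10, 10, 10)
  e <- jenks_breaks(v, 2)
  expect_equal(e, c(1, 5.5, 10))   # break between 1 and 10

  # random small fixtures against brute-force enumeration of breakpoints
  withr::with_seed(42, {
    for (rep in 1:8) {
      v <- round(runif(12, 0, 100), 1)
      for (k in 2:3) {
        e <- jenks_breaks(v, k)
        scheme <- structure(list(criterion = "t", method = "natural_breaks",
                                 edges = e, k = k, strict = FALSE),
                            class = "class_scheme")
        cls <- spatrisk:::assign_classes(sort(v), scheme)
        starts <- match(unique(cls), cls)
        got <- bf_jenks_cost(v, starts)
        best <- bf_jenks_best(v, k)$cost
        expect_equal(got, best, tolerance = 1e-12)
      }
    }
  })
  expect_error(jenks_breaks(v, 1), class = "spatrisk_parameter_error")
  expect_error(jenks_breaks(c(1, 1, 2), 3), class = "spatrisk_degenerate_binning_error")
})

test_that("classify_raster validates and follows the left-closed convention", {
  r <- raster_from_matrix(matrix(c(50, 150, 100, 250), 2, 2), name = "dist")
  sch <- classify_raster(r, "manual", edges = c(0, 100, 200, Inf))
  expect_equal(sch$k, 3L)
  # a pixel exactly at 100 goes to the upper class
  expect_equal(spatrisk:::assign_classes(c(50, 100, 150, 200, 999), sch),
               c(1L, 2L, 2L, 3L, 3L))
  expect_error(spatrisk:::assign_classes(-5, sch),
               class = "spatrisk_reclassification_error")
  expect_error(classify_raster(r, "natural_breaks", k = 1),
               class = "spatrisk_parameter_error")
  expect_error(classify_raster(raster_from_matrix(matrix(1, 3, 3)), "natural_breaks", k = 3),
               class = "spatrisk_degenerate_binning_error")
})

test_that("FR table equals manual counting on a printed 10x10 toy", {
  # left half of the raster is class A (value 1), right half class B (value 5):
  # 50 pixels each, P_i = 50% / 50%
  m <- cbind(matrix(1, 10, 5), matrix(5, 10, 5))
  r <- raster_from_matrix(m, name = "toy")
  sch <- classify_raster(r, "manual", edges = c(0, 3, 10))
  # 8 points: 6 in the left half, 2 in the right half
  pts <- case_points(x = c(0.5, 1.5, 2.5, 3.5, 4.2, 4.8, 5.5, 9.5),
                     y = c(1.5, 2.5, 3.5, 4.5, 5.5, 6.5, 7.5, 8.5))
  fr <- compute_fr(pts, r, sch)
  expect_equal(fr$n_points, c(6L, 2L))
  expect_equal(fr$F_i, c(75, 25))
  expect_equal(fr$P_i, c(50, 50))
  expect_equal(fr$fr, c(1.5, 0.5))

  # reclassification equals manual lookup
  surf <- fr_reclassify(r, fr, sch)
  expect_true(all(surf$values[, 1:5] == 1.5))
  expect_true(all(surf$values[, 6:10] == 0.5))
})

test_that("FR degenerate cases: proportional points, empty classes, nodata", {
  m <- cbind(matrix(1, 4, 1), matrix(5, 4, 3))   # 25% / 75% of area
  r <- raster_from_matrix(m)
  sch <- classify_raster(r, "manual", edges = c(0, 3, 10))
  # points proportional to area -> FR = 1 everywhere
  prop <- case_points(x = c(0.5, 1.5, 2.5, 3.5), y = rep(0.5, 4))
  frp <- compute_fr(prop, r, sch)
  expect_equal(frp$fr, c(1, 1))
  # 50% of points on the 25% class -> FR = 2
  half <- case_points(x = c(0.5, 0.5, 1.5, 3.5), y = c(0.5, 1.5, 2.5, 3.5))
  frh <- compute_fr(half, r, sch)
  expect_equal(frh$fr[1], 2)
  # class with zero points -> FR = 0
  none <- case_points(x = rep(3.5, 3), y = c(0.5, 1.5, 2.5))
  frn <- compute_fr(none, r, sch)
  expect_equal(frn$fr[1], 0)

  masked <- tiny_area(2, mask = matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2))
  rm2 <- criterion_raster(masked, matrix(c(1, 2, 3, 4), 2, 2))
  schm <- classify_raster(rm2, "manual", edges = c(0, 2.5, 5))
  expect_error(compute_fr(case_points(1.5, 0.5), rm2, schm),
               class = "spatrisk_computation_error")
})

test_that("area-weighted mean FR is exactly 1 on random fixtures", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      r <- generate_criterion_field(tiny_area(15), range = 6,
                                    nugget_fraction = runif(1), seed = rep)
      sch <- classify_raster(r, "natural_breaks", k = 5)
      pts_xy <- cell_centers(r$area, mask_only = TRUE)
      take <- sample(nrow(pts_xy), 40)
      fr <- compute_fr(case_points(pts_xy$x[take], pts_xy$y[take]), r, sch)
      expect_equal(sum(fr$P_i * fr$fr), 100, tolerance = 1e-9)
      expect_equal(sum(fr$F_i), 100, tolerance = 1e-9)
      expect_equal(sum(fr$P_i), 100, tolerance = 1e-9)
    }
  })
})

test_that("FR only uses the training partition (anti-leakage)", {
  r <- raster_from_matrix(matrix(seq(0, 99), 10, 10), name = "c")
  sch <- classify_raster(r, "natural_breaks", k = 4)
  withr::with_seed(3, {
    xy <- data.frame(x = runif(40, 0, 10), y = runif(40, 0, 10))
  })
  pts <- case_points(xy$x, xy$y,
                     partition = rep(c("train", "test"), each = 20))
  moved <- pts
  moved$x[moved$partition == "test"] <- 10 - moved$x[moved$partition == "test"]
  expect_identical(compute_fr(pts, r, sch), compute_fr(moved, r, sch))
})

test_that("driver criteria show monotone FR trends in the default scenario", {
  # scaled grid (600 m) for speed; scenario counts are the defaults
  mono <- function(x) all(diff(x) > 0) || all(diff(x) < 0)
  hits <- 0L; total <- 0L
  for (s in 1:5) {
    area <- default_study_area(cell = 600)
    sc <- synthetic_scenario(seed = 400 + s)
    crit <- generate_criteria(area, sc)
    cases <- generate_cases(area, crit, sc)
    fr <- fr_pipeline(cases, crit)
    drv <- sc$criterion_names[sc$driver_indices]
    mm <- vapply(fr$tables[drv], function(t) mono(t$fr), logical(1))
    hits <- hits + sum(mm); total <- total + length(mm)
  }
  expect_gte(hits, ceiling(0.8 * total))
})

test_that("FR is invariant under monotone transforms with transformed edges", {
  r <- raster_from_matrix(matrix(seq(1, 100), 10, 10))
  tr <- raster_from_matrix(matrix(log(seq(1, 100)), 10, 10))
  edges <- c(1, 20, 60, 101)
  s1 <- classify_raster(r, "manual", edges = edges)
  s2 <- classify_raster(tr, "manual", edges = log(edges))
  withr::with_seed(11, pts <- case_points(runif(30, 0, 10), runif(30, 0, 10)))
  f1 <- compute_fr(pts, r, s1)
  f2 <- compute_fr(pts, tr, s2)
  expect_equal(f1$fr, f2$fr, tolerance = 1e-12)
})
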