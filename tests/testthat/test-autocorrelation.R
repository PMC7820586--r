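test_that("aggregate_points conserves counts and applies the boundary convention", {
  area <- tiny_area(10, cell = 1)
  one <- aggregate_points(case_points(2.3, 7.6), area, cell = 2)
  expect_equal(sum(one$count), 1)
  expect_equal(sum(one$count > 0), 1)

  # a point exactly on the shared edge x = 2 belongs to the right-hand cell
  edge <- aggregate_points(case_points(2, 5), area, cell = 2)
  hit <- edge[edge$count == 1, ]
  expect_equal(hit$col, 2L)
  expect_equal(sum(edge$count), 1)

  withr::with_seed(1, {
    pts <- case_points(runif(872, 0, 10), runif(872, 0, 10))
  })
  agg <- aggregate_points(pts, area, cell = 2)
  expect_equal(sum(agg$count), 872)
  expect_error(aggregate_points(case_points(99, 99), area, cell = 2),
               class = "spatrisk_aggregation_error")
})

test_that("contiguity weights have the textbook neighbour counts", {
  u <- units_from_matrix(matrix(0, 3, 3))
  q <- build_weights(u, "queen", row_standardize = FALSE)
  r <- build_weights(u, "rook", row_standardize = FALSE)
  center <- which(u$row == 2 & u$col == 2)
  expect_equal(sum(q$W[center, ]), 8)
  expect_equal(sum(r$W[center, ]), 4)
  expect_true(all(diag(q$W) == 0))

  idw <- build_weights(u, "inverse_distance", row_standardize = FALSE)
  expect_equal(idw$W, t(idw$W))

  qs <- build_weights(u, "queen", row_standardize = TRUE)
  expect_equal(rowSums(qs$W), rep(1, 9))
  expect_error(build_weights(u[1, , drop = FALSE], "queen"),
               class = "spatrisk_parameter_error")
})

test_that("global Moran's I equals the brute-force double sum", {
  # 4x4 checkerboard with rook weights: perfect dispersion, I = -1
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  u <- units_from_matrix(cb)
  W <- build_weights(u, "rook", row_standardize = TRUE)
  res <- global_morans_i(u, W)
  expect_equal(res$index_value, -1, tolerance = 1e-12)
  expect_identical(res$pattern, "dispersed")
  expect_equal(res$index_value, bf_morans_i(u$count, W$W), tolerance = 1e-12)

  # two half-planes of high/low counts: clustered, I > 0
  hp <- rbind(matrix(9, 3, 6), matrix(1, 3, 6))
  uh <- units_from_matrix(hp)
  Wh <- build_weights(uh, "queen")
  resh <- global_morans_i(uh, Wh)
  expect_gt(resh$index_value, 0)
  expect_identical(resh$pattern, "clustered")
  expect_equal(resh$index_value, bf_morans_i(uh$count, Wh$W), tolerance = 1e-12)

  expect_error(global_morans_i(units_from_matrix(matrix(3, 3, 3)), W),
               class = "spatrisk_statistic_error")
})

test_that("Moran permutation and analytic inference agree on a random field", {
  withr::with_seed(10, cm <- matrix(rpois(36, 4), 6, 6))
  u <- units_from_matrix(cm)
  W <- build_weights(u, "queen")
  a <- global_morans_i(u, W, inference = "analytic")
  p <- global_morans_i(u, W, inference = "permutation", n_perm = 999, seed = 5)
  expect_equal(a$index_value, p$index_value)
  # Monte-Carlo error at n_perm = 999
  expect_lt(abs(a$p_value - p$p_value), 0.1)
  p2 <- global_morans_i(u, W, inference = "permutation", n_perm = 999, seed = 5)
  expect_identical(p$p_value, p2$p_value)
})

test_that("Moran's I is invariant under positive affine transforms", {
  withr::with_seed(2, cm <- matrix(rpois(25, 3), 5, 5))
  u <- units_from_matrix(cm)
  W <- build_weights(u, "queen")
  base <- global_morans_i(u, W)
  for (ab in list(c(2, 0), c(1, 10), c(0.5, -3))) {
    ut <- u
    ut$count <- ab[1] * u$count + ab[2]
    tr <- global_morans_i(ut, W)
    expect_equal(tr$index_value, base$index_value, tolerance = 1e-12)
  }
})

test_that("local Moran labels the four quadrant cases and sums to global I", {
  m <- matrix(1, 5, 5)
  m[3:5, 3:5] <- 9            # high block in a low field
  m[1, 1] <- 12               # lone high cell among lows
  u <- units_from_matrix(m)
  W <- build_weights(u, "queen")
  loc <- local_morans_i(u, W, n_perm = 499, seed = 3)
  center <- which(u$row == 4 & u$col == 4)
  corner <- which(u$row == 1 & u$col == 1)
  expect_identical(loc$local$quadrant[center], "H-H")
  expect_identical(loc$local$label[center], "H-H")
  expect_identical(loc$local$quadrant[corner], "H-L")
  glob <- global_morans_i(u, W)
  expect_equal(sum(loc$local$local_i) / sum(W$W), glob$index_value,
               tolerance = 1e-12)
})

test_that("global G matches hand evaluation on a 3-unit toy", {
  # hand-set weights and counts
  u <- units_from_matrix(matrix(c(2, 5, 1), 1, 3))
  W <- list(W = matrix(c(0, 0.6, 0.1,
                         0.6, 0, 0.3,
                         0.1, 0.3, 0), 3, 3, byrow = TRUE),
            scheme = "manual", row_standardized = FALSE)
  class(W) <- "spatial_weights"
  g <- getis_ord(u, W, mode = "global_G", n_perm = 199, seed = 1)
  # numerator: 2*0.6*2*5 + 2*0.1*2*1 + 2*0.3*5*1 = 12 + 0.4 + 3 = 15.4
  # denominator: 2*(2*5 + 2*1 + 5*1) = 34
  expect_equal(g$index_value, 15.4 / 34, tolerance = 1e-12)
  expect_equal(g$index_value, bf_global_g(u$count, W$W), tolerance = 1e-12)
})

test_that("the default driven scenario is diagnosed as clustered", {
  area <- default_study_area(cell = 900)
  sc <- synthetic_scenario(seed = 21)
  crit <- generate_criteria(area, sc)
  cases <- generate_cases(area, crit, sc)
  u <- aggregate_points(cases, area)
  res <- global_morans_i(u, build_weights(u, "queen"))
  expect_gt(res$index_value, 0)
  expect_identical(res$pattern, "clustered")
  rep <- autocorr_report(u, build_weights(u, "queen"),
                         build_weights(u, "distance_band", row_standardize = FALSE),
                         seed = 2)
  expect_identical(rep$distribution_type[1], "clustered")
})

test_that("Gi* flags a planted high block hot and uniform fields not at all", {
  m <- matrix(1, 5, 5)
  m[2:3, 2:3] <- 20
  u <- units_from_matrix(m)
  W <- build_weights(u, "distance_band", row_standardize = FALSE)
  res <- getis_ord(u, W, mode = "local_Gi_star")
  block <- u$row %in% 2:3 & u$col %in% 2:3
  far <- u$row == 5 & u$col == 5
  expect_true(all(res$local$label[block] == "hot"))
  expect_true(all(res$local$label[far] != "hot"))

  uni <- units_from_matrix(matrix(4, 4, 4))
  resu <- getis_ord(uni, build_weights(uni, "distance_band",
                                       row_standardize = FALSE),
                    mode = "local_Gi_star")
  expect_true(all(abs(resu$local$gi_star_z) < 1e-12))
  expect_true(all(resu$local$label == "not-significant"))
  expect_error(getis_ord(units_from_matrix(matrix(0, 3, 3)), W),
               class = "spatrisk_statistic_error")
})
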