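#' Aggregate case points to grid units
#'
#' Spatial-autocorrelation statistics operate on areal counts. Points are
#' binned into a square aggregation grid laid over the study-area extent;
#' a unit is any aggregation cell containing at least one in-mask cell of
#' the underlying grid. Boundary points follow the half-open convention of
#' [locate_cells()], so no point is ever counted twice.
#'
#' @param points a [case_points()] set (presences are counted; label-0
#'   points are ignored).
#' @param area the [study_area()].
#' @param cell aggregation cell size in map units (> 0); default picks a
#'   size giving roughly a 15 x 15 lattice.
#' @return An object of class `aggregation_units`: data.frame with unit
#'   `id`, `row`, `col`, center `x`, `y` and `count`; attributes carry the
#'   grid geometry and the number of points aggregated.
#' @export
aggregate_points <- function(points, area, cell = NULL) {
  stopifnot(inherits(area, "study_area"))
  if (is.null(cell)) cell <- max(area$xmax - area$xmin, area$ymax - area$ymin) / 15
  if (cell <= 0) stop_spatrisk("parameter", "aggregation cell must be > 0")
  pts <- points[points$label == 1, , drop = FALSE]
  nr <- ceiling((area$ymax - area$ymin) / cell)
  nc <- ceiling((area$xmax - area$xmin) / cell)
  agg <- study_area(width = nc * cell, height = nr * cell, cell = cell,
                    xmin = area$xmin, ymin = area$ymax - nr * cell)
  # units = aggregation cells that contain at least one in-mask fine cell
  fine <- cell_centers(area, mask_only = TRUE)
  floc <- locate_cells(agg, fine$x, fine$y)
  occupied <- unique(floc[, c("row", "col")])
  occupied <- occupied[order(occupied$row, occupied$col), ]
  key <- function(r, c) (r - 1L) * nc + c
  unit_of <- integer(nr * nc)
  unit_of[key(occupied$row, occupied$col)] <- seq_len(nrow(occupied))
  ploc <- locate_cells(agg, pts$x, pts$y)
  ok <- !is.na(ploc$row)
  uid <- ifelse(ok, unit_of[key(ploc$row, ploc$col)], 0L)
  kept <- uid > 0L
  if (nrow(pts) > 0 && !any(kept))
    stop_spatrisk("aggregation", "all points fall outside the study area units")
  counts <- tabulate(uid[kept], nbins = nrow(occupied))
  structure(data.frame(id = seq_len(nrow(occupied)),
                       row = occupied$row, col = occupied$col,
                       x = agg$xmin + (occupied$col - 0.5) * cell,
                       y = agg$ymax - (occupied$row - 0.5) * cell,
                       count = counts),
            cell = cell, grid_nrow = nr, grid_ncol = nc,
            n_points = sum(kept), n_dropped = sum(!kept),
            class = c("aggregation_units", "data.frame"))
}

#' Spatial weights between aggregation units
#'
#' @param units an [aggregate_points()] result (>= 2 units).
#' @param scheme `"queen"` or `"rook"` contiguity, `"inverse_distance"`,
#'   or `"distance_band"` (binary within `band`).
#' @param row_standardize scale each non-empty row to sum 1.
#' @param band distance band in map units (default 1.5x the aggregation
#'   cell, i.e. queen-like reach) — used by `"distance_band"` only.
#' @param power exponent for inverse-distance weights.
#' @return An object of class `spatial_weights`: list with the dense `W`
#'   matrix (`w_ii = 0`), the scheme label and the standardization flag.
#' @export
build_weights <- function(units, scheme = c("queen", "rook", "inverse_distance",
                                            "distance_band"),
                          row_standardize = TRUE, band = NULL, power = 1) {
  stopifnot(inherits(units, "aggregation_units"))
  scheme <- match.arg(scheme)
  n <- nrow(units)
  if (n < 2L) stop_spatrisk("parameter", "need >= 2 units for spatial weights")
  if (is.null(band)) band <- 1.5 * attr(units, "cell")
  dr <- abs(outer(units$row, units$row, "-"))
  dc <- abs(outer(units$col, units$col, "-"))
  W <- switch(scheme,
    queen = (pmax(dr, dc) == 1) * 1,
    rook  = (dr + dc == 1) * 1,
    inverse_distance = {
      D <- sqrt(outer(units$x, units$x, "-")^2 + outer(units$y, units$y, "-")^2)
      Wi <- 1 / D^power; diag(Wi) <- 0; Wi
    },
    distance_band = {
      D <- sqrt(outer(units$x, units$x, "-")^2 + outer(units$y, units$y, "-")^2)
      (D > 0 & D <= band) * 1
    })
  diag(W) <- 0
  isolated <- which(rowSums(W) == 0)
  if (length(isolated))
    warning(sprintf("%d isolated unit(s) with no neighbours (ids: %s); rows left zero",
                    length(isolated), paste(utils::head(isolated, 5), collapse = ", ")))
  if (row_standardize) {
    rs <- rowSums(W)
    W[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  structure(list(W = W, scheme = scheme, row_standardized = row_standardize,
                 band = if (scheme == "distance_band") band else NULL),
            class = "spatial_weights")
}

.autocorr_result <- function(statistic, index_value, expected, z, p, pattern,
                             local = NULL, extra = list()) {
  structure(c(list(statistic = statistic, index_value = index_value,
                   expected = expected, z_score = z, p_value = p,
                   pattern = pattern, local = local), extra),
            class = "autocorr_result")
}

#' @export
print.autocorr_result <- function(x, ...) {
  cat(sprintf("<autocorr_result> %s: index %.6g, z = %.4g, p = %.4g -> %s\n",
              x$statistic, x$index_value, x$z_score, x$p_value, x$pattern))
  if (!is.null(x$local))
    cat("  local labels: ", paste(sprintf("%s=%d", names(table(x$local$label)),
                                          table(x$local$label)), collapse = ", "), "\n")
  invisible(x)
}

# Moran's I statistic on raw numbers; shared by global/permutation paths
.morans_i_stat <- function(x, W) {
  z <- x - mean(x)
  n <- length(x)
  (n / sum(W)) * sum(W * tcrossprod(z)) / sum(z^2)
}

#' Global Moran's I
#'
#' `I = (N / sum w_ij) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' over the aggregation units. Positive values indicate clustering of
#' similar counts, negative values dispersion. Inference is either analytic
#' under the randomization assumption or by seeded permutation.
#'
#' @param units an [aggregate_points()] result with non-constant counts.
#' @param weights a [build_weights()] result.
#' @param inference `"analytic"` (randomization moments) or `"permutation"`.
#' @param n_perm permutations for `"permutation"` inference.
#' @param seed permutation seed.
#' @param alpha two-sided significance level for the pattern verdict.
#' @return An `autocorr_result` with `index_value`, `z_score`, `p_value`
#'   and `pattern` in clustered/random/dispersed.
#' @export
global_morans_i <- function(units, weights, inference = c("analytic", "permutation"),
                            n_perm = 999L, seed = 1L, alpha = 0.05) {
  inference <- match.arg(inference)
  x <- as.numeric(units$count)
  W <- weights$W
  n <- length(x)
  if (stats::sd(x) == 0)
    stop_spatrisk("statistic", "Moran's I undefined: counts are constant (zero variance)")
  if (sum(W) <= 0) stop_spatrisk("statistic", "total spatial weight must be > 0")
  I <- .morans_i_stat(x, W)
  EI <- -1 / (n - 1)
  if (inference == "analytic") {
    S0 <- sum(W)
    S1 <- 0.5 * sum((W + t(W))^2)
    S2 <- sum((rowSums(W) + colSums(W))^2)
    z <- x - mean(x)
    b2 <- n * sum(z^4) / (sum(z^2))^2
    varI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
             b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
            ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
    zs <- (I - EI) / sqrt(varI)
    p <- 2 * stats::pnorm(-abs(zs))
  } else {
    perm <- withr::with_seed(as.integer(seed),
      replicate(n_perm, .morans_i_stat(sample(x), W)))
    zs <- (I - mean(perm)) / stats::sd(perm)
    p_up <- (1 + sum(perm >= I)) / (n_perm + 1)
    p_dn <- (1 + sum(perm <= I)) / (n_perm + 1)
    p <- min(1, 2 * min(p_up, p_dn))
  }
  zcrit <- stats::qnorm(1 - alpha / 2)
  pattern <- if (zs > zcrit) "clustered" else if (zs < -zcrit) "dispersed" else "random"
  .autocorr_result("global_morans_i", I, EI, zs, p, pattern,
                   extra = list(inference = inference))
}

#' Local Moran's I with H-H / H-L / L-H / L-L cluster labels
#'
#' Per-unit local Moran `I_i = z_i * sum_j w_ij z_j / m2` (deviations from
#' the global mean, `m2 = sum z^2 / n`), with conditional-permutation
#' p-values. Every unit gets a `quadrant` (H-H when both the unit and its
#' neighbourhood lie above the mean, H-L when the unit is high among low
#' neighbours, and so on; NA for ties at exactly the mean); the `label`
#' keeps the quadrant only for units significant at `alpha`, else
#' `"not-significant"`.
#'
#' @inheritParams global_morans_i
#' @param n_perm conditional permutations per unit.
#' @return An `autocorr_result`; `$local` holds per-unit `local_i`,
#'   `p_value` and `label`.
#' @export
local_morans_i <- function(units, weights, n_perm = 999L, seed = 1L, alpha = 0.05) {
  x <- as.numeric(units$count)
  W <- weights$W
  n <- length(x)
  if (stats::sd(x) == 0)
    stop_spatrisk("statistic", "local Moran undefined: counts are constant")
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  lag <- as.numeric(W %*% z)
  Ii <- z * lag / m2
  pvals <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n), function(i) {
      wi <- W[i, -i]
      others <- z[-i]
      ref <- replicate(n_perm, z[i] * sum(wi * sample(others)) / m2)
      p_up <- (1 + sum(ref >= Ii[i])) / (n_perm + 1)
      p_dn <- (1 + sum(ref <= Ii[i])) / (n_perm + 1)
      min(1, 2 * min(p_up, p_dn))
    }, numeric(1))
  })
  quadrant <- rep(NA_character_, n)          # ties at the mean stay NA
  quadrant[z > 0 & lag > 0] <- "H-H"
  quadrant[z > 0 & lag < 0] <- "H-L"
  quadrant[z < 0 & lag > 0] <- "L-H"
  quadrant[z < 0 & lag < 0] <- "L-L"
  sig <- pvals <= alpha & !is.na(quadrant)
  label <- ifelse(sig, quadrant, "not-significant")
  I <- sum(Ii) / sum(W)   # proportionality: sum(I_i) = S0 * I_global
  .autocorr_result("local_morans_i", I, -1 / (n - 1), NA_real_, NA_real_, NA_character_,
                   local = data.frame(id = units$id, local_i = Ii,
                                      quadrant = quadrant,
                                      p_value = pvals, label = label,
                                      stringsAsFactors = FALSE))
}

#' Getis-Ord statistics: global G and local Gi*
#'
#' The global statistic is
#' `G = sum_{i != j} w_ij x_i x_j / sum_{i != j} x_i x_j`, measuring
#' whether high values co-locate within the weight structure; inference is
#' by seeded permutation. The local Gi* uses self-inclusive weights
#' (`w_ii = 1`) and the standard analytic z-score; positive significant z
#' marks hot spots, negative cold spots.
#'
#' @inheritParams global_morans_i
#' @param mode `"global_G"` or `"local_Gi_star"`.
#' @param n_perm permutations for global-G inference.
#' @return An `autocorr_result`; for `"local_Gi_star"`, `$local` holds
#'   per-unit `gi_star_z` and `label` (hot/cold/not-significant).
#' @export
getis_ord <- function(units, weights, mode = c("global_G", "local_Gi_star"),
                      n_perm = 999L, seed = 1L, alpha = 0.05) {
  mode <- match.arg(mode)
  x <- as.numeric(units$count)
  W <- weights$W
  n <- length(x)
  if (all(x == 0)) stop_spatrisk("statistic", "Getis-Ord undefined: all counts zero")
  zcrit <- stats::qnorm(1 - alpha / 2)
  if (mode == "global_G") {
    gstat <- function(v) {
      num <- sum(W * tcrossprod(v)) - sum(diag(W) * v^2)
      den <- sum(v)^2 - sum(v^2)
      num / den
    }
    G <- gstat(x)
    perm <- withr::with_seed(as.integer(seed),
      replicate(n_perm, gstat(sample(x))))
    zs <- (G - mean(perm)) / stats::sd(perm)
    p_up <- (1 + sum(perm >= G)) / (n_perm + 1)
    p_dn <- (1 + sum(perm <= G)) / (n_perm + 1)
    p <- min(1, 2 * min(p_up, p_dn))
    pattern <- if (zs > zcrit) "clustered" else if (zs < -zcrit) "dispersed" else "random"
    return(.autocorr_result("global_G", G, mean(perm), zs, p, pattern))
  }
  # local Gi*: self-inclusive weights, analytic moments (Ord & Getis 1995)
  Ws <- W
  diag(Ws) <- 1
  xbar <- mean(x)
  s <- sqrt(sum(x^2) / n - xbar^2)
  wsum <- rowSums(Ws)
  w2sum <- rowSums(Ws^2)
  num <- as.numeric(Ws %*% x) - xbar * wsum
  den <- s * sqrt((n * w2sum - wsum^2) / (n - 1))
  # constant counts: no deviation anywhere, z is identically zero
  zi <- ifelse(den > 0, num / den, 0)
  label <- rep("not-significant", n)
  label[zi > zcrit] <- "hot"
  label[zi < -zcrit] <- "cold"
  .autocorr_result("local_Gi_star", NA_real_, NA_real_, NA_real_, NA_real_,
                   NA_character_,
                   local = data.frame(id = units$id, gi_star_z = zi,
                                      p_value = 2 * stats::pnorm(-abs(zi)),
                                      label = label, stringsAsFactors = FALSE))
}

#' Table-style autocorrelation report
#'
#' Runs global Moran's I and global Getis-Ord G on one set of units and
#' returns the classic four-column summary (index value, z-score, p-value,
#' distribution type) of a spatial-pattern screening.
#'
#' @inheritParams global_morans_i
#' @param gi_weights optional separate weights for the Getis-Ord statistic
#'   (convention: binary distance-band); defaults to `weights`.
#' @return data.frame with one row per index.
#' @export
autocorr_report <- function(units, weights, gi_weights = weights,
                            n_perm = 999L, seed = 1L) {
  m <- global_morans_i(units, weights)
  g <- getis_ord(units, gi_weights, mode = "global_G", n_perm = n_perm, seed = seed)
  data.frame(index = c("Moran's I", "Getis-Ord G"),
             index_value = c(m$index_value, g$index_value),
             z_score = c(m$z_score, g$z_score),
             p_value = c(m$p_value, g$p_value),
             distribution_type = c(m$pattern, g$pattern),
             stringsAsFactors = FALSE)
}
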