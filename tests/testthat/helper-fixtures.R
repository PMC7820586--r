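# Shared fixtures, built in code at test time.

# small square study area: n x n cells of unit size
tiny_area <- function(n = 10, cell = 1, mask = NULL) {
  study_area(width = n * cell, height = n * cell, cell = cell, mask = mask)
}

# raster from an explicit matrix on a unit grid
raster_from_matrix <- function(m, cell = 1, name = "toy") {
  a <- study_area(width = ncol(m) * cell, height = nrow(m) * cell, cell = cell)
  criterion_raster(a, m, name = name)
}

# aggregation units straight from a count matrix (unit cells, no mask)
units_from_matrix <- function(cm, cell = 1) {
  nr <- nrow(cm); nc <- ncol(cm)
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  structure(data.frame(id = seq_len(nr * nc), row = rows, col = cols,
                       x = (cols - 0.5) * cell, y = (nr - rows + 0.5) * cell,
                       count = as.vector(cm)),
            cell = cell, grid_nrow = nr, grid_ncol = nc,
            n_points = sum(cm), n_dropped = 0L,
            class = c("aggregation_units", "data.frame"))
}

# brute-force Moran's I: direct double-sum evaluation
bf_morans_i <- function(x, W) {
  n <- length(x)
  xb <- mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + W[i, j] * (x[i] - xb) * (x[j] - xb)
  (n / sum(W)) * num / sum((x - xb)^2)
}

# brute-force global Getis-Ord G (i != j)
bf_global_g <- function(x, W) {
  n <- length(x)
  num <- 0; den <- 0
  for (i in 1:n) for (j in 1:n) if (i != j) {
    num <- num + W[i, j] * x[i] * x[j]
    den <- den + x[i] * x[j]
  }
  num / den
}

# Mann-Whitney AUC oracle: P(score_pos > score_neg) + 0.5 P(tie)
bf_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exhaustive 1-D natural breaks for k classes (small inputs only)
bf_jenks_cost <- function(v, starts) {
  v <- sort(v)
  bounds <- c(starts, length(v) + 1L)
  tot <- 0
  for (c in seq_along(starts)) {
    seg <- v[bounds[c]:(bounds[c + 1] - 1L)]
    tot <- tot + sum((seg - mean(seg))^2)
  }
  tot
}

bf_jenks_best <- function(v, k) {
  v <- sort(v)
  u <- length(v)
  combs <- utils::combn(2:u, k - 1, simplify = FALSE)
  best <- NULL; best_cost <- Inf
  for (s in combs) {
    cost <- bf_jenks_cost(v, c(1L, s))
    if (cost < best_cost) { best_cost <- cost; best <- c(1L, s) }
  }
  list(starts = best, cost = best_cost)
}

# small default-shaped scenario on a coarse grid, for fast end-to-end runs
fast_config <- function(seed = 1L, out_dir = tempfile("spatrisk_test_")) {
  pipeline_config(seed = seed, cell = 600, out_dir = out_dir)
}

# one cached full pipeline run shared by io/pipeline assertions
pipeline_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$man)) {
      cache$dir <- tempfile("spatrisk_fix_")
      cache$man <- run_pipeline(fast_config(seed = 11L, out_dir = cache$dir),
                                quiet = TRUE)
    }
    list(manifest = cache$man, dir = cache$dir)
  }
})
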