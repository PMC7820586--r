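#' Jenks natural breaks (Fisher's exact dynamic programme)
#'
#' Partitions 1-D values into `k` classes minimising total within-class
#' squared deviation. Exact on the distinct values; when more than
#' `max_unique` distinct values exist they are first reduced to weighted
#' quantile bins (the usual large-raster compromise).
#'
#' @param values numeric vector (NAs dropped).
#' @param k number of classes (>= 2).
#' @param max_unique cap on distinct values fed to the exact programme.
#' @return numeric vector of `k + 1` class edges (first = min, last = max);
#'   interior edges are midpoints between adjacent class boundary values.
#' @export
jenks_breaks <- function(values, k, max_unique = 1000L) {
  v <- values[!is.na(values)]
  if (k < 2L) stop_spatrisk("parameter", "k must be >= 2")
  uv <- sort(unique(v))
  if (length(uv) < k)
    stop_spatrisk("degenerate_binning",
                  "only %d distinct values for k = %d classes", length(uv), k)
  tab <- table(v)
  x <- as.numeric(names(tab))
  w <- as.numeric(tab)
  if (length(x) > max_unique) {
    # reduce to weighted quantile bins, keeping counts
    q <- unique(stats::quantile(v, probs = seq(0, 1, length.out = max_unique),
                                names = FALSE, type = 1))
    grp <- findInterval(x, q, rightmost.closed = TRUE)
    x2 <- as.numeric(tapply(x * w, grp, sum) / tapply(w, grp, sum))
    w2 <- as.numeric(tapply(w, grp, sum))
    x <- x2; w <- w2
  }
  u <- length(x)
  cw <- cumsum(w); cs <- cumsum(w * x); cs2 <- cumsum(w * x^2)
  seg_cost <- function(i, j) { # vectorised over i, fixed j
    W <- cw[j] - ifelse(i > 1, cw[i - 1], 0)
    S <- cs[j] - ifelse(i > 1, cs[i - 1], 0)
    S2 <- cs2[j] - ifelse(i > 1, cs2[i - 1], 0)
    S2 - S^2 / W
  }
  cost <- matrix(Inf, k, u)      # cost[c, j]: best cost of v[1..j] in c classes
  back <- matrix(0L, k, u)       # start index of the last class
  cost[1, ] <- seg_cost(1L, seq_len(u))
  for (cc in 2:k) {
    for (j in cc:u) {
      i <- cc:j                       # last class is v[i..j]
      tot <- cost[cc - 1, i - 1] + seg_cost(i, j)
      b <- which.min(tot)
      cost[cc, j] <- tot[b]
      back[cc, j] <- i[b]
    }
  }
  # recover class boundaries
  starts <- integer(k)
  j <- u
  for (cc in k:2) {
    starts[cc] <- back[cc, j]
    j <- starts[cc] - 1L
  }
  starts[1] <- 1L
  edges <- numeric(k + 1)
  edges[1] <- x[1]; edges[k + 1] <- x[u]
  for (cc in 2:k) edges[cc] <- (x[starts[cc] - 1] + x[starts[cc]]) / 2
  edges
}

#' Class scheme for a criterion raster
#'
#' Bins a continuous criterion into ordered classes. Assignment is
#' left-closed: value `v` belongs to class `j` when
#' `edges[j] <= v < edges[j + 1]` (a pixel exactly on an interior edge goes
#' to the upper class); for data-driven schemes values at or beyond the
#' outer edges are clamped into the first/last class.
#'
#' @param raster a [criterion_raster()].
#' @param method `"natural_breaks"`, `"quantile"`, or `"manual"`.
#' @param k number of classes (data-driven methods; default 5).
#' @param edges full edge vector for `method = "manual"` (length >= 3,
#'   strictly increasing; may use `-Inf`/`Inf`).
#' @return An object of class `class_scheme`.
#' @export
classify_raster <- function(raster, method = c("natural_breaks", "quantile", "manual"),
                            k = 5L, edges = NULL) {
  stopifnot(inherits(raster, "criterion_raster"))
  method <- match.arg(method)
  v <- raster$values[!is.na(raster$values)]
  if (method == "manual") {
    if (is.null(edges) || length(edges) < 3L || any(diff(edges) <= 0))
      stop_spatrisk("parameter", "manual edges must be strictly increasing, length >= 3")
    k <- length(edges) - 1L
    strict <- TRUE
  } else {
    if (k < 2L) stop_spatrisk("parameter", "k must be >= 2")
    if (length(unique(v)) < k)
      stop_spatrisk("degenerate_binning",
                    "raster '%s' has %d distinct values, fewer than k = %d",
                    raster$name, length(unique(v)), k)
    edges <- switch(method,
      natural_breaks = jenks_breaks(v, k),
      quantile = {
        e <- unique(stats::quantile(v, probs = seq(0, 1, length.out = k + 1),
                                    names = FALSE))
        if (length(e) < k + 1)
          stop_spatrisk("degenerate_binning",
                        "quantile edges collapse for raster '%s'", raster$name)
        e
      })
    strict <- FALSE
  }
  structure(list(criterion = raster$name, method = method,
                 edges = as.numeric(edges), k = as.integer(k), strict = strict),
            class = "class_scheme")
}

# class id per value under a scheme; NA passes through
assign_classes <- function(values, scheme) {
  stopifnot(inherits(scheme, "class_scheme"))
  interior <- scheme$edges[-c(1L, scheme$k + 1L)]
  cls <- findInterval(values, interior) + 1L
  if (scheme$strict) {
    bad <- which(!is.na(values) &
                 (values < scheme$edges[1] | values >= scheme$edges[scheme$k + 1L]))
    if (length(bad))
      stop_spatrisk("reclassification",
                    "value %g outside all classes [%g, %g)", values[bad[1]],
                    scheme$edges[1], scheme$edges[scheme$k + 1L])
  }
  cls[is.na(values)] <- NA_integer_
  cls
}

#' Frequency-ratio table for one criterion
#'
#' For each class of the scheme: `F_i`, the percentage of (training)
#' presence points falling in the class; `P_i`, the percentage of valid
#' study-area pixels in the class; and the frequency ratio `FR = F_i / P_i`.
#' FR above 1 marks classes over-represented among cases. When the point
#' set carries a train/test partition only training presences are used, so
#' held-out points never leak into the weights.
#'
#' @param presences a [case_points()] set (label-1 points used).
#' @param raster the criterion [criterion_raster()].
#' @param scheme a [classify_raster()] scheme for it.
#' @return An object of class `fr_table`: data.frame with `class`,
#'   `lower`, `upper`, `n_points`, `F_i`, `n_pixels`, `P_i`, `fr`.
#' @export
compute_fr <- function(presences, raster, scheme) {
  stopifnot(inherits(raster, "criterion_raster"), inherits(scheme, "class_scheme"))
  pts <- presences[presences$label == 1, , drop = FALSE]
  if (any(!is.na(pts$partition)))
    pts <- pts[!is.na(pts$partition) & pts$partition == "train", , drop = FALSE]
  vals_at <- raster_value_at(raster, pts$x, pts$y)
  if (all(is.na(vals_at)))
    stop_spatrisk("computation", "all presence points fall on nodata for '%s'",
                  raster$name)
  if (anyNA(vals_at)) {
    warning(sprintf("%d presence point(s) on nodata dropped for '%s'",
                    sum(is.na(vals_at)), raster$name))
    vals_at <- vals_at[!is.na(vals_at)]
  }
  pcls <- assign_classes(vals_at, scheme)
  rcls <- assign_classes(raster$values[!is.na(raster$values)], scheme)
  k <- scheme$k
  n_pts <- tabulate(pcls, nbins = k)
  n_pix <- tabulate(rcls, nbins = k)
  Fi <- 100 * n_pts / sum(n_pts)
  Pi <- 100 * n_pix / sum(n_pix)
  fr <- ifelse(Pi > 0, Fi / Pi, NA_real_)
  empty <- Pi == 0
  if (any(empty))
    warning(sprintf("class(es) %s cover zero pixels; excluded from FR",
                    paste(which(empty), collapse = ", ")))
  out <- data.frame(class = seq_len(k),
                    lower = scheme$edges[-(k + 1)], upper = scheme$edges[-1],
                    n_points = n_pts, F_i = Fi, n_pixels = n_pix, P_i = Pi,
                    fr = fr)[!empty, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, criterion = raster$name,
            class = c("fr_table", "data.frame"))
}

#' Reclassify a criterion raster to its FR-weight surface
#'
#' Replaces every valid pixel by the frequency ratio of its class; nodata
#' is preserved. These FR surfaces are the model features downstream.
#'
#' @param raster the criterion [criterion_raster()].
#' @param fr its [compute_fr()] table.
#' @param scheme the matching [classify_raster()] scheme.
#' @return A [criterion_raster()] of FR weights.
#' @export
fr_reclassify <- function(raster, fr, scheme) {
  stopifnot(inherits(raster, "criterion_raster"), inherits(fr, "fr_table"),
            inherits(scheme, "class_scheme"))
  if (!identical(attr(fr, "criterion"), raster$name))
    warning(sprintf("FR table is for '%s' but raster is '%s'",
                    attr(fr, "criterion"), raster$name))
  lut <- rep(NA_real_, scheme$k)
  lut[fr$class] <- fr$fr
  cls <- assign_classes(as.vector(raster$values), scheme)
  vals <- matrix(lut[cls], raster$area$nrow, raster$area$ncol)
  out <- criterion_raster(raster$area, vals, name = paste0(raster$name, "_fr"))
  out
}

#' FR tables and surfaces for a whole criterion set
#'
#' @param presences training presences.
#' @param criteria named list of [criterion_raster()]s.
#' @param method,k passed to [classify_raster()].
#' @return list with `tables` (named list of `fr_table`), `schemes`, and
#'   `surfaces` (named list of FR-weight rasters).
#' @export
fr_pipeline <- function(presences, criteria, method = "natural_breaks", k = 5L) {
  schemes <- lapply(criteria, classify_raster, method = method, k = k)
  tables <- mapply(function(r, s) compute_fr(presences, r, s),
                   criteria, schemes, SIMPLIFY = FALSE)
  surfaces <- mapply(function(r, f, s) fr_reclassify(r, f, s),
                     criteria, tables, schemes, SIMPLIFY = FALSE)
  list(tables = tables, schemes = schemes, surfaces = surfaces)
}
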