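#' Best-of-restarts K-means partition
#'
#' Lloyd-style K-means (via [stats::kmeans()], Hartigan-Wong) with
#' `n_starts` random starting points and up to `max_iter` iterations,
#' keeping the lowest within-group sum of squares (WGSS) solution.
#' Deterministic given the seed. An empty cluster is handled internally
#' by [stats::kmeans()] re-assignment.
#'
#' @param x numeric matrix, observations x features.
#' @param k number of clusters (<= nrow(x)).
#' @param n_starts random starts (default 50).
#' @param max_iter maximum iterations per start (default 100).
#' @param seed integer seed.
#' @return list with `labels` (integer vector) and `wgss`.
#' @export
kmeans_partition <- function(x, k, n_starts = 50, max_iter = 100,
                             seed = 1) {
  x <- as.matrix(x)
  stopifnot(k >= 1, k <= nrow(x))
  if (k == nrow(x))
    return(list(labels = seq_len(nrow(x)), wgss = 0))
  n_distinct <- nrow(unique(x))
  if (k >= n_distinct) {
    # every distinct point is its own centroid; WGSS is exactly zero
    lab <- as.integer(factor(apply(x, 1, paste, collapse = "\r")))
    return(list(labels = lab, wgss = 0))
  }
  fit <- with_seed(seed, {
    stats::kmeans(x, centers = k, iter.max = max_iter, nstart = n_starts)
  })
  list(labels = as.integer(fit$cluster), wgss = fit$tot.withinss)
}

#' WGSS evaluation curve over k
#'
#' Runs [kmeans_partition()] for k = 1..k_max and collects the
#' within-group sum of squares; the curve against k is the input of the
#' L-method knee search.
#'
#' @inheritParams kmeans_partition
#' @param k_max largest k evaluated (>= 4).
#' @return object of class `k_curve`: data.frame with `k`, `wgss`.
#' @export
wgss_curve <- function(x, k_max, n_starts = 50, max_iter = 100, seed = 1) {
  stopifnot(k_max >= 4, k_max <= nrow(as.matrix(x)))
  wgss <- vapply(seq_len(k_max), function(k)
    kmeans_partition(x, k, n_starts = n_starts, max_iter = max_iter,
                     seed = seed + k)$wgss, numeric(1))
  structure(data.frame(k = seq_len(k_max), wgss = wgss),
            class = c("k_curve", "data.frame"))
}

#' L-method knee detection on an evaluation-metric curve
#'
#' For each candidate knee c (the 3rd through (n-2)th point of the curve)
#' two least-squares lines are fitted: one to points 1..c, one to points
#' c..n. The candidate minimizing the length-weighted combined residual
#' standard error (n_L * RSE_L + n_R * RSE_R) / (n_L + n_R), with
#' RSE = sqrt(SSE / (n - 2)) per segment, is the knee; ties go to the
#' smallest k. Using RSE rather than RMSE keeps curves of different
#' lengths comparable through their residual degrees of freedom.
#'
#' @param curve a [wgss_curve()] result (or any data.frame with `k` and a
#'   metric in the second column), length >= 4.
#' @return the optimal k (integer); attribute `scores` holds the
#'   per-candidate combined RSE.
#' @export
lmethod_knee <- function(curve) {
  k <- curve[[1]]
  y <- curve[[2]]
  n <- length(k)
  if (n < 4) stop("curve must have at least 4 points")
  seg_rse <- function(idx) {
    fit <- stats::lm.fit(cbind(1, k[idx]), y[idx])
    sqrt(sum(fit$residuals^2) / (length(idx) - 2))
  }
  if (n < 5) stop("no candidate knee with >=3 points per segment")
  cand <- 3:(n - 2)
  scores <- vapply(cand, function(c_) {
    nl <- c_; nr <- n - c_ + 1
    (nl * seg_rse(1:c_) + nr * seg_rse(c_:n)) / (nl + nr)
  }, numeric(1))
  # ties (within numerical tolerance) go to the smallest candidate k
  best <- cand[which(scores <= min(scores) + 1e-10)[1]]
  out <- k[best]
  attr(out, "scores") <- data.frame(k = k[cand], score = scores)
  out
}

#' Modal consensus on the optimal number of clusters
#'
#' The knee found by the L-method depends on the largest k entered in the
#' curve, so the knee is recomputed for every maximum-k value from 4 up
#' to `max_k` (capped at n_sites - 1) and the most frequent optimum is
#' returned (ties to the smallest). Each run derives its own seed as
#' seed + max_k so runs are order-independent.
#'
#' @param scores site x axis coordinate matrix (e.g. Cailliez-corrected
#'   principal coordinates).
#' @param max_k upper end of the scanned maximum-k range; default
#'   n_sites - 1.
#' @param n_starts,max_iter K-means settings per run (defaults 50 / 100).
#' @param n_axes number of leading score axes used (default all).
#' @param seed integer seed.
#' @return object of class `k_consensus`: `optimal_k` per max-k run,
#'   `modal_k`, `freq` table.
#' @export
consensus_k <- function(scores, max_k = NULL, n_starts = 50,
                        max_iter = 100, n_axes = NULL, seed = 1) {
  x <- as.matrix(scores)
  if (!is.null(n_axes)) x <- x[, seq_len(min(n_axes, ncol(x))), drop = FALSE]
  n <- nrow(x)
  stopifnot(n >= 6)
  max_k <- min(max_k %||% (n - 1), n - 1)
  stopifnot(max_k >= 4)
  ks <- unlist(lapply(4:max_k, function(m) {
    # a 4-point curve admits no knee with >= 3 points per segment; such
    # runs contribute nothing to the consensus
    if (m < 5) return(integer(0))
    cur <- wgss_curve(x, k_max = m, n_starts = n_starts,
                      max_iter = max_iter, seed = seed + m)
    as.integer(lmethod_knee(cur))
  }))
  freq <- table(ks)
  modal <- as.integer(names(freq)[which.max(freq)]) # ties -> smallest
  structure(list(optimal_k = ks, modal_k = modal, freq = freq,
                 max_k_range = c(4L, as.integer(max_k))),
            class = "k_consensus")
}

#' @export
print.k_consensus <- function(x, ...) {
  cat(sprintf("k_consensus: modal k = %d over %d runs (max-k %d..%d)\n",
              x$modal_k, length(x$optimal_k), x$max_k_range[1],
              x$max_k_range[2]))
  print(x$freq)
  invisible(x)
}

#' K-means regionalization of interpolated compositional axes
#'
#' Clusters every unmasked grid cell on its three interpolated ordination
#' coordinates only — geographic position is deliberately not a feature,
#' so any spatial cohesion of the resulting regions reflects the
#' compositional surface itself. Labels are renumbered by descending
#' region size, and spatial cohesion is summarized afterwards as the
#' fraction of each region's cells in its largest rook-connected
#' component.
#'
#' @param axes list of 3 [grid_surface()]s sharing one geometry.
#' @param k number of regions (from [consensus_k()]).
#' @param n_starts,max_iter,seed K-means settings.
#' @return object of class `region_partition`: `geometry`, `labels`
#'   (integer per cell, NA on masked cells), `k`, `cell_counts`,
#'   `cohesion` (largest-component fraction per region), `wgss`.
#' @export
regionalize <- function(axes, k, n_starts = 50, max_iter = 100, seed = 1) {
  stopifnot(length(axes) == 3)
  geom <- axes[[1]]$geometry
  for (s in axes) stopifnot(geometry_equal(geom, s$geometry))
  mask <- axes[[1]]$mask & axes[[2]]$mask & axes[[3]]$mask
  x <- cbind(axes[[1]]$values, axes[[2]]$values, axes[[3]]$values)[mask, ,
                                                                   drop = FALSE]
  if (k > nrow(x)) stop("k exceeds the number of unmasked cells")
  km <- kmeans_partition(x, k, n_starts = n_starts, max_iter = max_iter,
                         seed = seed)
  lab <- km$labels
  # renumber by descending size; ties by original label for determinism
  sizes <- tabulate(lab, nbins = k)
  remap <- integer(k)
  remap[order(-sizes, seq_len(k))] <- seq_len(k)
  lab <- remap[lab]
  labels <- rep(NA_integer_, geom$n_rows * geom$n_cols)
  labels[mask] <- lab
  counts <- tabulate(lab, nbins = k)
  structure(list(geometry = geom, labels = labels, k = as.integer(k),
                 cell_counts = counts,
                 cohesion = region_cohesion(labels, geom),
                 wgss = km$wgss),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("region_partition: k = %d on a %d x %d grid\n", x$k,
              x$geometry$n_rows, x$geometry$n_cols))
  cat("cells per region:", paste(x$cell_counts, collapse = ", "), "\n")
  cat("largest-component fraction:",
      paste(sprintf("%.2f", x$cohesion), collapse = ", "), "\n")
  invisible(x)
}

# Fraction of each region's cells in its largest rook-connected component.
region_cohesion <- function(labels, geom) {
  nr <- geom$n_rows; nc <- geom$n_cols
  lab <- matrix(labels, nr, nc, byrow = TRUE)
  comp <- matrix(0L, nr, nc)
  nextc <- 0L
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    if (is.na(lab[r, cl]) || comp[r, cl] != 0L) next
    nextc <- nextc + 1L
    queue <- list(c(r, cl)); comp[r, cl] <- nextc
    while (length(queue)) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- p[1] + d[1]; cc <- p[2] + d[2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            comp[rr, cc] == 0L && !is.na(lab[rr, cc]) &&
            lab[rr, cc] == lab[p[1], p[2]]) {
          comp[rr, cc] <- nextc
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  k <- max(labels, na.rm = TRUE)
  vapply(seq_len(k), function(g) {
    sel <- !is.na(lab) & lab == g
    if (!any(sel)) return(NA_real_)
    max(table(comp[sel])) / sum(sel)
  }, numeric(1))
}

#' Look up the region of each site by its grid cell
#'
#' @param partition a [regionalize()] result.
#' @param registry data.frame with `lon`, `lat` (and optionally `cell`).
#' @return integer region label per site.
#' @export
site_regions <- function(partition, registry) {
  geom <- partition$geometry
  step <- geom$cell_arcmin / 60
  col <- round((registry$lon - geom$origin_lon) / step) + 1
  row <- round((registry$lat - geom$origin_lat) / step) + 1
  if (any(row < 1 | row > geom$n_rows | col < 1 | col > geom$n_cols))
    stop("site outside the grid")
  partition$labels[(row - 1) * geom$n_cols + col]
}

#' Export a region partition as GeoJSON
#'
#' Each region becomes one MultiPolygon feature made of its cells'
#' squares (unmerged), mirroring the role of a dissolved-region
#' shapefile while staying plain text.
#'
#' @param partition a `region_partition`.
#' @param path output `.geojson` file.
#' @export
write_region_geojson <- function(partition, path) {
  geom <- partition$geometry
  cells <- grid_cells(geom)
  h <- geom$cell_arcmin / 120   # half cell in degrees
  feats <- lapply(seq_len(partition$k), function(g) {
    idx <- which(!is.na(partition$labels) & partition$labels == g)
    polys <- lapply(idx, function(i) {
      x <- cells$lon[i]; y <- cells$lat[i]
      list(list(list(c(x - h, y - h), c(x + h, y - h), c(x + h, y + h),
                     c(x - h, y + h), c(x - h, y - h))))
    })
    list(type = "Feature",
         properties = list(region = g,
                           n_cells = partition$cell_counts[g]),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
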