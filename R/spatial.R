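#' Inverse-distance-weighted interpolation onto a grid
#'
#' Interpolates site values onto every unmasked grid cell using weights
#' d^(-power) on great-circle (haversine) distances in km. A cell whose
#' center lies within `eps_km` of a site takes that site's value exactly.
#' The output is a convex combination of site values, hence bounded by
#' their range.
#'
#' @param registry data.frame with `site_id`, `lon`, `lat`.
#' @param values numeric vector of site values (site order or named).
#' @param geometry target [grid_geometry()].
#' @param power IDW exponent (default 2).
#' @param n_neighbors number of nearest sites used per cell; default all.
#' @param mask optional logical validity mask for the output surface.
#' @param eps_km exact-hit tolerance in km (default 1e-6).
#' @return a [grid_surface()].
#' @export
idw_interpolate <- function(registry, values, geometry, power = 2,
                            n_neighbors = NULL, mask = NULL,
                            eps_km = 1e-6) {
  if (!is.null(names(values))) values <- values[registry$site_id]
  stopifnot(length(values) == nrow(registry), nrow(registry) >= 1)
  cells <- grid_cells(geometry)
  dmat <- haversine_km(cells[, c("lon", "lat")],
                       registry[, c("lon", "lat")])
  w <- dmat^(-power)
  if (!is.null(n_neighbors) && n_neighbors < ncol(w)) {
    for (i in seq_len(nrow(w))) {
      keep <- order(dmat[i, ])[seq_len(n_neighbors)]
      w[i, -keep] <- 0
    }
  }
  out <- as.numeric((w %*% values) / rowSums(w))
  hits <- which(dmat < eps_km, arr.ind = TRUE)
  if (nrow(hits)) out[hits[, 1]] <- values[hits[, 2]]
  grid_surface(geometry, out, mask = mask)
}

# spatial weights: symmetric non-negative matrix, zero diagonal
validate_weights <- function(w) {
  w <- as.matrix(w)
  stopifnot(isSymmetric(unname(w)), all(w >= 0), all(diag(w) == 0))
  if (any(rowSums(w) == 0)) stop("site with no positive weight")
  w
}

#' Global Moran's I with permutation test
#'
#' I = (n/W) * sum_ij w_ij z_i z_j / sum_i z_i^2 with z the centered
#' values and W the total weight. Expectation under no autocorrelation is
#' -1/(n-1). The p-value is two-sided, from random permutations of the
#' values over locations (with the +1 correction counting the observed
#' statistic).
#'
#' @param values numeric vector (non-constant).
#' @param w spatial weight matrix (symmetric, zero diagonal).
#' @param n_perm number of permutations (default 199; 0 skips the test).
#' @param seed integer seed.
#' @param alternative "two.sided" (default) or "greater" (positive
#'   autocorrelation only).
#' @return list with `I`, `expected`, `p`.
#' @export
morans_i <- function(values, w, n_perm = 199, seed = 1,
                     alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  w <- validate_weights(w)
  n <- length(values)
  stopifnot(nrow(w) == n)
  if (stats::sd(values) == 0) stop("constant values: Moran's I undefined")
  z <- values - mean(values)
  W <- sum(w)
  denom <- sum(z^2)
  istat <- function(z) (n / W) * sum(w * tcrossprod(z)) / denom
  i_obs <- istat(z)
  expected <- -1 / (n - 1)
  p <- NA_real_
  if (n_perm > 0) {
    i_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(k) istat(z[sample.int(n)]),
             numeric(1))
    })
    p_up <- (sum(i_perm >= i_obs) + 1) / (n_perm + 1)
    p_dn <- (sum(i_perm <= i_obs) + 1) / (n_perm + 1)
    p <- if (alternative == "greater") p_up
         else min(1, 2 * min(p_up, p_dn))
  }
  list(I = i_obs, expected = expected, p = p)
}

#' Moran's I spatial correlogram
#'
#' Splits the pairwise haversine distances into `n_classes` equal-width
#' classes, uses the binary within-class connectivity as weights, and
#' computes Moran's I with a permutation p-value per class. P-values are
#' Holm-adjusted across classes. Classes with no connected pair (or in
#' which some site has no neighbour) are flagged and skipped.
#'
#' @param values numeric site values.
#' @param registry data.frame with `lon`, `lat`.
#' @param n_classes number of distance classes (default 14).
#' @param n_perm permutations per class (default 199).
#' @param seed integer seed.
#' @return object of class `correlogram`: data.frame with class bounds,
#'   `n_pairs`, `I`, `expected`, `p`, `p_adj`, `ok`.
#' @export
correlogram <- function(values, registry, n_classes = 14, n_perm = 199,
                        seed = 1) {
  dmat <- haversine_pairwise(registry[, c("lon", "lat")])
  dv <- dmat[upper.tri(dmat)]
  if (length(unique(dv)) < n_classes)
    stop("fewer distinct pair distances than classes")
  breaks <- seq(0, max(dv), length.out = n_classes + 1)
  rows <- vector("list", n_classes)
  for (k in seq_len(n_classes)) {
    inb <- dmat > breaks[k] & dmat <= breaks[k + 1]
    if (k == 1) inb <- inb | (dmat > 0 & dmat <= breaks[2])
    w <- (inb | t(inb)) * 1
    diag(w) <- 0
    npairs <- sum(w) / 2
    ok <- npairs > 0 && all(rowSums(w) > 0)
    res <- if (ok) morans_i(values, w, n_perm = n_perm, seed = seed + k)
           else list(I = NA_real_, expected = NA_real_, p = NA_real_)
    rows[[k]] <- data.frame(class = k, lower = breaks[k],
                            upper = breaks[k + 1], n_pairs = npairs,
                            I = res$I, expected = res$expected,
                            p = res$p, ok = ok)
  }
  tab <- do.call(rbind, rows)
  tab$p_adj <- NA_real_
  tab$p_adj[tab$ok] <- stats::p.adjust(tab$p[tab$ok], method = "holm")
  structure(tab, class = c("correlogram", "data.frame"))
}

# Gabriel graph adjacency (binary) on great-circle distances, augmented
# with the minimum spanning tree to guarantee connectivity.
gabriel_graph <- function(dmat) {
  n <- nrow(dmat)
  adj <- matrix(FALSE, n, n)
  d2 <- dmat^2
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    others <- setdiff(seq_len(n), c(i, j))
    if (!any(d2[i, others] + d2[j, others] < d2[i, j])) {
      adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  mst <- vegan::spantree(stats::as.dist(dmat))
  for (i in seq_along(mst$kid)) {
    adj[i + 1, mst$kid[i]] <- adj[mst$kid[i], i + 1] <- TRUE
  }
  adj
}

#' Moran's Eigenvector Maps
#'
#' Spatial eigenfunctions in the style of Borcard et al.: a connectivity
#' graph (Gabriel graph on haversine distances, augmented with the
#' minimum spanning tree so it is connected) is weighted by
#' w_ij = 1 - (d_ij / d_max)^2, with d_max the overall diameter of the
#' point set, and the doubly-centered weight matrix is
#' eigendecomposed. Eigenvectors are orthonormal and sorted by descending
#' eigenvalue; each one's Moran's I (computed with the same weights) is
#' permutation-tested, and vectors with positive eigenvalue and
#' significantly positive I are marked selected for use as spatial
#' covariates.
#'
#' @param registry data.frame with `site_id`, `lon`, `lat` (>= 4 sites).
#' @param alpha significance level for selection (default 0.05).
#' @param n_perm permutations per eigenvector (default 199).
#' @param seed integer seed.
#' @param max_mem optional cap on the number of selected vectors; the
#'   largest-eigenvalue (broadest-scale) ones are kept. Keeps downstream
#'   regression models estimable when many eigenfunctions pass the test.
#' @return object of class `mem_basis`: `vectors` (site x m, orthonormal),
#'   `eigenvalues`, `moran` (data.frame I, p), `selected` (indices),
#'   `weights` (the spatial weight matrix used).
#' @export
mem_basis <- function(registry, alpha = 0.05, n_perm = 199, seed = 1,
                      max_mem = NULL) {
  stopifnot(nrow(registry) >= 4)
  dmat <- haversine_pairwise(registry[, c("lon", "lat")])
  adj <- gabriel_graph(dmat)
  if (any(rowSums(adj) == 0)) stop("disconnected connectivity graph")
  # scaled by the overall diameter, not the longest edge: keeps regular
  # lattices (equal edge lengths) non-degenerate
  dmax <- max(dmat)
  w <- ifelse(adj, 1 - (dmat / dmax)^2, 0)
  diag(w) <- 0
  b <- gower_center(w)
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  # drop the trivial (near-zero eigenvalue) constant-like vector
  keep <- abs(e$values) > 1e-9 * max(abs(e$values))
  vecs <- e$vectors[, keep, drop = FALSE]
  vals <- e$values[keep]
  rownames(vecs) <- registry$site_id
  colnames(vecs) <- paste0("MEM", seq_len(ncol(vecs)))
  mor <- do.call(rbind, lapply(seq_len(ncol(vecs)), function(j) {
    # one-sided (positive autocorrelation) p for selection
    r <- morans_i(vecs[, j], w, n_perm = n_perm, seed = seed + j,
                  alternative = "greater")
    data.frame(I = r$I, p = r$p)
  }))
  sel <- which(vals > 0 & mor$I > 0 & mor$p < alpha)
  if (!is.null(max_mem) && length(sel) > max_mem)
    sel <- sel[seq_len(max_mem)]   # eigenvalues sorted descending
  structure(list(vectors = vecs, eigenvalues = vals, moran = mor,
                 selected = sel, weights = w),
            class = "mem_basis")
}

#' @export
print.mem_basis <- function(x, ...) {
  cat(sprintf("mem_basis: %d eigenvectors over %d sites, %d selected (positive, significant Moran's I)\n",
              ncol(x$vectors), nrow(x$vectors), length(x$selected)))
  invisible(x)
}

#' Compose three compositional axes into an RGB raster
#'
#' Each interpolated ordination axis is mapped to one colour channel. All
#' three axes share a single scaling span (the largest axis range), so
#' the intensity spread of each channel is proportional to the
#' compositional variation its axis carries. A constant axis maps to
#' mid-intensity 128. Masked cells get alpha 0.
#'
#' @param axis1,axis2,axis3 [grid_surface()]s on one geometry.
#' @return object of class `rgb_raster`: integer array n_rows x n_cols x 4
#'   (RGBA, 0-255, row 1 = northern row) plus the geometry.
#' @export
rgb_compose <- function(axis1, axis2, axis3) {
  axes <- list(axis1, axis2, axis3)
  stopifnot(geometry_equal(axis1$geometry, axis2$geometry),
            geometry_equal(axis1$geometry, axis3$geometry))
  geom <- axis1$geometry
  mask <- axis1$mask & axis2$mask & axis3$mask
  spans <- vapply(axes, function(s) diff(range(s$values[mask])), numeric(1))
  span <- max(spans)
  arr <- array(0L, dim = c(geom$n_rows, geom$n_cols, 4))
  for (ch in 1:3) {
    v <- axes[[ch]]$values
    inten <- if (spans[ch] == 0) rep(128, length(v))
             else (v - min(v[mask])) / span * 255
    m <- matrix(round(inten), geom$n_rows, geom$n_cols, byrow = TRUE)
    arr[, , ch] <- m[rev(seq_len(geom$n_rows)), ]  # top row = north
  }
  am <- matrix(ifelse(mask, 255L, 0L), geom$n_rows, geom$n_cols,
               byrow = TRUE)
  arr[, , 4] <- am[rev(seq_len(geom$n_rows)), ]
  structure(list(array = arr, geometry = geom), class = "rgb_raster")
}

#' Write an RGB raster to PNG
#' @param x an `rgb_raster`.
#' @param path output PNG path.
#' @export
write_rgb_png <- function(x, path) {
  png::writePNG(x$array / 255, target = path)
  invisible(path)
}
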