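#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Thin, seeded wrapper around [vegan::metaMDS()] (global NMDS, Kruskal
#' stress-1, monotone regression), which restarts from random
#' configurations and keeps the lowest-stress solution, rotated to its
#' principal axes. Axis signs are then fixed by forcing the site with the
#' largest absolute score positive on each axis, since NMDS axes are
#' reflection-arbitrary.
#'
#' @param d a `dissimilarity_matrix`.
#' @param n_axes number of ordination axes (default 3).
#' @param n_starts maximum number of random restarts (default 20).
#' @param max_iter iterations per start (default 200).
#' @param seed integer seed (mandatory for reproducibility).
#' @return object of class `ordination_result`: `scores` (site x axis,
#'   column means 0), `stress` (fraction in [0, 1]), `n_starts`,
#'   `converged`, `seed`, and the underlying vegan object as `fit`.
#' @export
nmds <- function(d, n_axes = 3, n_starts = 20, max_iter = 200, seed = 1) {
  stopifnot(inherits(d, "dissimilarity_matrix"), n_axes >= 1)
  dd <- stats::as.dist(d$d)
  fit <- with_seed(seed, {
    vegan::metaMDS(dd, k = n_axes, trymax = n_starts, maxit = max_iter,
                   trace = 0, autotransform = FALSE, wascores = FALSE)
  })
  sc <- fit$points
  sc <- scale(sc, center = TRUE, scale = FALSE)
  for (j in seq_len(ncol(sc))) {
    i <- which.max(abs(sc[, j]))
    if (sc[i, j] < 0) sc[, j] <- -sc[, j]
  }
  rownames(sc) <- d$labels
  colnames(sc) <- paste0("axis", seq_len(ncol(sc)))
  if (!fit$converged)
    warning("NMDS did not converge under any start; best effort returned")
  structure(list(scores = sc, stress = fit$stress, n_starts = n_starts,
                 converged = isTRUE(fit$converged > 0) || isTRUE(fit$converged),
                 seed = seed, fit = fit),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("NMDS: %d sites, %d axes, stress %.4f (x100 = %.1f), converged: %s\n",
              nrow(x$scores), ncol(x$scores), x$stress, 100 * x$stress,
              x$converged))
  invisible(x)
}

#' Shepard diagram fit statistics
#'
#' Goodness of fit of an NMDS solution: the non-metric fit
#' R^2 = 1 - stress^2 and the linear fit R^2, the squared Pearson
#' correlation between the monotone-regression fitted values and the
#' configuration (ordination-space) distances. Stress is a fraction; a
#' reported "stress of 17.3" on the percentage convention corresponds to
#' 0.173 here and a non-metric R^2 of 0.970.
#'
#' @param d the `dissimilarity_matrix` the ordination was fitted to.
#' @param result an [nmds()] result.
#' @return object of class `shepard_fit`: `stress`, `nonmetric_r2`,
#'   `linear_r2`.
#' @export
shepard_fit <- function(d, result) {
  stopifnot(inherits(result, "ordination_result"))
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  sp <- vegan::stressplot(result$fit)
  structure(list(stress = result$stress,
                 nonmetric_r2 = 1 - result$stress^2,
                 linear_r2 = stats::cor(sp$yf, sp$y)^2),
            class = "shepard_fit")
}

#' @export
print.shepard_fit <- function(x, ...) {
  cat(sprintf("Shepard fit: stress %.4f, non-metric R2 %.3f, linear R2 %.3f\n",
              x$stress, x$nonmetric_r2, x$linear_r2))
  invisible(x)
}

#' Principal coordinates with Cailliez correction
#'
#' Projects a (generally non-Euclidean) dissimilarity matrix into a
#' Euclidean space that reproduces the observed distances exactly. Gower
#' double-centering followed by eigendecomposition; if the matrix has
#' negative eigenvalues, the smallest additive constant c making the
#' corrected distances d_ij + c (i != j) Euclidean is applied (Cailliez),
#' via [stats::cmdscale()]. Pairwise Euclidean distances among the
#' full-space scores then equal d_ij + c.
#'
#' @param d a `dissimilarity_matrix`.
#' @return object of class `pcoa_result`: `scores` (site x axis),
#'   `eigenvalues` (non-increasing, all >= -1e-8 after correction),
#'   `cailliez_constant` (0 when d is already Euclidean).
#' @export
pcoa_cailliez <- function(d) {
  stopifnot(inherits(d, "dissimilarity_matrix"))
  dm <- d$d
  n <- nrow(dm)
  # Gower-centered inner-product matrix of the raw distances
  g <- gower_center(-0.5 * dm^2)
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  needs_correction <- min(ev) < -1e-8 * max(abs(ev))
  res <- stats::cmdscale(stats::as.dist(dm), k = n - 1, eig = TRUE,
                         add = needs_correction)
  cc <- if (needs_correction) res$ac else 0
  eig <- res$eig
  keep <- which(eig > 1e-8 * max(eig))
  scores <- res$points[, keep, drop = FALSE]
  rownames(scores) <- d$labels
  colnames(scores) <- paste0("pco", seq_along(keep))
  structure(list(scores = scores, eigenvalues = eig,
                 cailliez_constant = cc),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d sites, %d retained axes, Cailliez constant %.4g\n",
              nrow(x$scores), ncol(x$scores), x$cailliez_constant))
  invisible(x)
}

# double-center a square matrix (Gower)
gower_center <- function(m) {
  n <- nrow(m)
  j <- diag(n) - matrix(1 / n, n, n)
  j %*% m %*% j
}
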