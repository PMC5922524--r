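geom44 <- grid_geometry(-42, -11, cell_arcmin = 15, n_rows = 4, n_cols = 4)

test_that("IDW honours exact hits, symmetry and the hand formula", {
  cells <- grid_cells(geom44)
  # site exactly on a cell center
  reg <- data.frame(site_id = c("a", "b"),
                    lon = cells$lon[c(1, 16)], lat = cells$lat[c(1, 16)])
  s <- idw_interpolate(reg, c(a = 5, b = 9), geom44)
  expect_equal(s$values[1], 5)
  expect_equal(s$values[16], 9)
  # two sites symmetric about a cell: midpoint value for any power
  regs <- data.frame(site_id = c("l", "r"),
                     lon = cells$lon[6] + c(-0.1, 0.1),
                     lat = rep(cells$lat[6], 2))
  for (p in c(1, 2, 4)) {
    sp <- idw_interpolate(regs, c(l = 0, r = 1), geom44, power = p)
    expect_equal(sp$values[6], 0.5, tolerance = 1e-9)
  }
  # direct formula oracle on 5 random sites, one cell
  reg5 <- toy_registry(5, seed = 8)
  vals <- withr::with_seed(9, rnorm(5))
  out <- idw_interpolate(reg5, vals, geom44, power = 2)
  dmat <- phytoregion:::haversine_km(grid_cells(geom44)[, c("lon", "lat")],
                                     reg5[, c("lon", "lat")])
  w <- dmat[11, ]^-2
  expect_equal(out$values[11], sum(w * vals) / sum(w), tolerance = 1e-10)
  # convex combination: bounded by the site value range
  expect_true(all(out$values >= min(vals) - 1e-12 &
                    out$values <= max(vals) + 1e-12))
})

test_that("Moran's I matches direct evaluation and flags constants", {
  # alternating +1/-1 on an 8-ring with binary adjacency: I = -1
  n <- 8
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w[i, i %% n + 1] <- 1
    w[i %% n + 1, i] <- 1
  }
  vals <- rep(c(1, -1), 4)
  res <- morans_i(vals, w, n_perm = 99, seed = 1)
  expect_equal(res$I, -1, tolerance = 1e-12)
  expect_equal(res$expected, -1 / 7)
  expect_error(morans_i(rep(2, n), w), "constant")
  # cross-check against an independent implementation
  v2 <- withr::with_seed(3, rnorm(n))
  expect_equal(morans_i(v2, w, n_perm = 0)$I,
               ape::Moran.I(v2, w)$observed, tolerance = 1e-10)
  # permutation null mean is near the expectation
  perm_i <- withr::with_seed(5, vapply(1:500, function(k)
    morans_i(sample(v2), w, n_perm = 0)$I, numeric(1)))
  se <- stats::sd(perm_i) / sqrt(500)
  expect_lt(abs(mean(perm_i) - (-1 / 7)), 3 * se + 0.02)
})

test_that("correlograms detect gradients and stay flat under shuffling", {
  reg <- toy_registry(40, seed = 12)
  grad <- 10 * reg$lon + withr::with_seed(2, rnorm(40, 0, 0.5))
  cg <- correlogram(grad, reg, n_classes = 5, n_perm = 199, seed = 3)
  expect_equal(nrow(cg), 5)
  expect_gt(cg$I[1], 0)
  expect_lt(cg$p[1], 0.05)
  shuf <- withr::with_seed(4, sample(grad))
  cg0 <- correlogram(shuf, reg, n_classes = 5, n_perm = 199, seed = 3)
  expect_true(all(cg0$p_adj[cg0$ok] > 0.05))
  # one class reduces to global Moran's I with all-pairs weights
  cg1 <- correlogram(grad, reg, n_classes = 1, n_perm = 0, seed = 1)
  dmat <- phytoregion:::haversine_pairwise(reg[, c("lon", "lat")])
  wall <- (dmat > 0) * 1
  expect_equal(cg1$I[1], morans_i(grad, wall, n_perm = 0)$I,
               tolerance = 1e-10)
})

test_that("MEM eigenvectors are orthonormal with Moran's I ordered by eigenvalue", {
  reg <- toy_registry(30, seed = 31)
  mb <- mem_basis(reg, n_perm = 99, seed = 2)
  g <- crossprod(mb$vectors)
  expect_equal(g, diag(ncol(mb$vectors)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(mb$eigenvalues) <= 1e-9))
  expect_gt(stats::cor(mb$moran$I, mb$eigenvalues, method = "spearman"),
            0.999)
})

test_that("ring-lattice MEMs are discrete sinusoids", {
  reg <- ring_registry(32)
  mb <- mem_basis(reg, n_perm = 0, seed = 1)
  n <- 32
  th <- 2 * pi * (seq_len(n) - 1) / n
  # leading eigenvector pair spans the first harmonic subspace
  for (j in 1:2) {
    basis <- cbind(cos(th), sin(th))
    q <- qr.Q(qr(basis))
    v <- mb$vectors[, j]
    proj <- q %*% crossprod(q, v)
    expect_gt(sum(proj * v) / sqrt(sum(v^2)), 0.99)
  }
})

test_that("MEM selection is stable under site relabeling", {
  reg <- toy_registry(25, seed = 77)
  mb1 <- mem_basis(reg, n_perm = 99, seed = 5)
  perm <- withr::with_seed(6, sample(nrow(reg)))
  reg2 <- reg[perm, ]
  mb2 <- mem_basis(reg2, n_perm = 99, seed = 5)
  expect_equal(sort(mb1$eigenvalues), sort(mb2$eigenvalues),
               tolerance = 1e-9)
  # the deterministic criteria (positive eigenvalue, positive Moran I)
  # are exactly invariant; the Monte-Carlo p can flip one borderline
  # vector between runs
  det1 <- sum(mb1$eigenvalues > 0 & mb1$moran$I > 0)
  det2 <- sum(mb2$eigenvalues > 0 & mb2$moran$I > 0)
  expect_equal(det1, det2)
  expect_lte(abs(length(mb1$selected) - length(mb2$selected)), 1)
})

test_that("RGB composition shares one span and handles constant axes", {
  g <- grid_geometry(-42, -11, 15, 2, 2)
  a1 <- grid_surface(g, c(0, 1, 2, 4))     # span 4 (the largest)
  a2 <- grid_surface(g, c(0, 2, 1, 2))     # span 2: half intensity range
  a3 <- grid_surface(g, rep(7, 4))         # constant: mid-intensity
  rgb <- rgb_compose(a1, a2, a3)
  red <- rgb$array[, , 1]; green <- rgb$array[, , 2]
  expect_equal(min(red), 0)                # all-axis minimum cell
  expect_equal(max(red), 255)
  expect_equal(max(green) - min(green), round(2 / 4 * 255))
  expect_true(all(rgb$array[, , 3] == 128))
  expect_true(all(rgb$array[, , 4] == 255))
})
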