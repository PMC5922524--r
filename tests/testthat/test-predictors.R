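geom22 <- grid_geometry(-42, -11, 15, 2, 2)

test_that("the aridity index follows MAP/(MAT+33) with its contract", {
  map <- grid_surface(geom22, rep(1000, 4))
  mat <- grid_surface(geom22, rep(27, 4))
  expect_equal(aridity_index(map, mat)$values, rep(1000 / 60, 4),
               tolerance = 1e-10)
  expect_equal(aridity_index(map, mat)$values[1], 16.6667,
               tolerance = 1e-4)
  expect_equal(aridity_index(grid_surface(geom22, rep(0, 4)), mat)$values,
               rep(0, 4))
  expect_error(aridity_index(map, grid_surface(geom22, rep(-33, 4))),
               "-33")
})

test_that("historical aridity change averages across circulation models", {
  cur <- grid_surface(geom22, c(10, 12, 14, 16))
  expect_equal(historical_ai(cur, list(cur))$values, rep(0, 4))
  offs <- lapply(1:3, function(o) grid_surface(geom22, cur$values + o))
  expect_equal(historical_ai(cur, offs)$values, rep(-2, 4))
  one <- grid_surface(geom22, cur$values - 3)
  expect_equal(historical_ai(cur, list(one))$values, rep(3, 4))
  bad <- grid_surface(grid_geometry(-42, -11, 15, 2, 3), rep(1, 6))
  expect_error(historical_ai(cur, list(bad)), "geometry")
})

test_that("envelope distance equals the standardized-row norm", {
  g <- grid_geometry(-42, -11, 15, 5, 5)
  layers <- withr::with_seed(11, lapply(1:8, function(j)
    grid_surface(g, rnorm(25, mean = j))))
  d <- envelope_distance(layers)
  x <- sapply(layers, function(s) s$values)
  z <- scale(x)
  expect_equal(d$values, sqrt(rowSums(z^2)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # a cell sitting at the mean of every delta variable maps to the origin
  x2 <- x; x2[13, ] <- colMeans(x[-13, ]) # make row 13 the centroid
  x2[13, ] <- colMeans(x2)
  layers2 <- lapply(1:8, function(j) grid_surface(g, x2[, j]))
  expect_lt(envelope_distance(layers2)$values[13], 1e-8)
  # single informative variable reduces to |z|
  two <- list(grid_surface(g, x[, 1]), grid_surface(g, rep(1, 25)))
  d1 <- suppressWarnings(envelope_distance(two))
  expect_equal(d1$values, abs(as.numeric(scale(x[, 1]))),
               tolerance = 1e-10)
})

test_that("envelope distance is rotation-invariant after standardization", {
  withr::with_seed(12, {
    g <- grid_geometry(-42, -11, 15, 6, 6)
    x <- matrix(rnorm(36 * 5), 36, 5)
    # whiten so the sample covariance is exactly the identity: then the
    # internal re-standardization of the rotated copy is a no-op
    z <- scale(x, scale = FALSE)
    z <- z %*% solve(chol(stats::cov(z)))
    q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
    d_orig <- envelope_distance(lapply(1:5, function(j)
      grid_surface(g, z[, j])))
    d_rot <- envelope_distance(lapply(1:5, function(j)
      grid_surface(g, (z %*% q)[, j])))
    expect_equal(d_rot$values, d_orig$values, tolerance = 1e-10)
  })
})

test_that("buffer aggregation matches a brute-force distance oracle", {
  g <- grid_geometry(-42, -11, 2.5, 10, 10)
  su <- const_surface(g, 3)
  reg <- toy_registry(4, seed = 9)
  reg$lon <- -42 + (reg$lon + 43) * 0.3   # keep sites inside the grid
  reg$lat <- -11 + (reg$lat + 11) * 0.3
  expect_equal(unname(buffer_aggregate(su, reg, 10, "mean")), rep(3, 4))
  expect_equal(unname(buffer_aggregate(su, reg, 10, "range")), rep(0, 4))
  expect_equal(unname(buffer_aggregate(su, reg, 10, "cv")), rep(0, 4))
  vals <- withr::with_seed(2, rnorm(100))
  sv <- grid_surface(g, vals)
  got <- buffer_aggregate(sv, reg, 12, "mean")
  cells <- grid_cells(g)
  for (i in 1:4) {
    dd <- geosphere::distHaversine(
      cbind(cells$lon, cells$lat), c(reg$lon[i], reg$lat[i])) / 1000
    expect_equal(unname(got[i]), mean(vals[dd <= 12]), tolerance = 1e-10)
  }
  expect_error(buffer_aggregate(sv, reg, 0.001), "empty buffer")
})

test_that("collinearity screening drops lower-priority partners until clean", {
  withr::with_seed(3, {
    n <- 40
    a <- rnorm(n); b <- a + rnorm(n, 0, 0.1); c_ <- a + rnorm(n, 0, 0.1)
    ind <- rnorm(n)
    tab <- data.frame(a = a, b = b, c = c_, ind = ind)
    out <- collinearity_screen(tab, 0.75, priority = c("a", "b", "c", "ind"))
    expect_true("a" %in% out$kept)
    expect_true("ind" %in% out$kept)
    expect_false(any(c("b", "c") %in% out$kept))
    r <- stats::cor(out$table); diag(r) <- 0
    expect_lte(max(abs(r)), 0.75)
    # a duplicated column loses to its original
    dup <- data.frame(x = a, x2 = a, y = ind)
    out2 <- collinearity_screen(dup, 0.75)
    expect_equal(out2$kept, c("x", "y"))
    # nothing correlated: identity
    clean <- data.frame(p = rnorm(n), q = rnorm(n))
    expect_equal(collinearity_screen(clean, 0.75)$kept, c("p", "q"))
  })
})

test_that("VIF equals the per-variable OLS oracle", {
  withr::with_seed(4, {
    x <- matrix(rnorm(200), 50, 4,
                dimnames = list(NULL, c("w", "x", "y", "z")))
    x[, 2] <- x[, 1] * 0.8 + rnorm(50, 0, 0.5)
    v <- vif(x)
    for (j in 1:4) {
      r2 <- summary(stats::lm(x[, j] ~ x[, -j]))$r.squared
      expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-8)
    }
    # orthogonal (and intercept-orthogonal) design: all VIFs exactly 1
    q <- unclass(stats::poly(1:20, 3))
    expect_equal(unname(vif(q)), rep(1, 3), tolerance = 1e-8)
    expect_error(vif(cbind(x, dup = x[, 1])), "collinearity")
  })
})

test_that("site-level predictors track the generating aridity field", {
  w <- small_world()
  pt <- predictor_table(w$land$stack, w$comm$registry)
  expect_true(all(c("AI") %in% colnames(pt$full_table)))
  r <- stats::cor(pt$full_table$AI,
                  w$land$truth$ai$values[w$comm$registry$cell])
  expect_gt(abs(r), 0.9)
  rr <- stats::cor(pt$table); diag(rr) <- 0
  expect_lte(max(abs(rr)), 0.75)
  expect_true(all(is.finite(as.matrix(pt$table))))
})
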