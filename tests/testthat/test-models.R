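sim_multiclass <- function(n = 90, k = 3, seed = 1, beta = 2) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    eta <- sapply(seq_len(k) - 1, function(g) beta * g * x)
    pr <- exp(eta - apply(eta, 1, max))
    pr <- pr / rowSums(pr)
    y <- factor(apply(pr, 1, function(p) sample(k, 1, prob = p)))
    list(y = y, x = data.frame(x = x, noise = rnorm(n)))
  })
}

test_that("a two-class multinomial fit matches binary logistic regression", {
  withr::with_seed(7, {
    x <- rnorm(80)
    y <- factor(rbinom(80, 1, stats::plogis(1 + 1.5 * x)))
  })
  xs <- as.numeric(scale(x))
  fit <- fit_multinomial(y, data.frame(x = x))
  ref <- stats::glm(y ~ xs, family = stats::binomial())
  # our reference class is the largest; align signs accordingly
  flip <- if (levels(fit$labels)[1] == "1") -1 else 1
  expect_equal(unname(flip * as.numeric(fit$coefficients)),
               unname(stats::coef(ref)), tolerance = 1e-6)
  expect_equal(fit$log_lik, as.numeric(stats::logLik(ref)),
               tolerance = 1e-8)
})

test_that("the intercept-only deviance has its closed form", {
  y <- factor(rep(c("a", "b", "c"), times = c(20, 12, 8)))
  fit <- fit_multinomial(y, NULL)
  ng <- c(20, 12, 8)
  expect_equal(fit$deviance, -2 * sum(ng * log(ng / 40)),
               tolerance = 1e-6)
  expect_equal(rowSums(fit$probabilities), rep(1, 40), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("separable classes drive the deviance to zero under a tiny ridge", {
  y <- factor(rep(c("lo", "hi"), each = 15))
  x <- data.frame(x = c(seq(-2, -1, length.out = 15),
                        seq(1, 2, length.out = 15)))
  fit <- fit_multinomial(y, x, ridge = 1e-8, max_iter = 2000)
  expect_lt(fit$deviance, 1e-3)
})

test_that("AICc and Akaike weights follow their formulas", {
  expect_equal(aicc(-100, k = 5, n = 50), 211.3636, tolerance = 1e-4)
  expect_equal(aicc(-100, k = 5, n = 50),
               200 + 10 + 2 * 5 * 6 / 44, tolerance = 1e-12)
  expect_error(aicc(-10, k = 10, n = 11), "undefined")
  expect_equal(waicc(c(100, 100)), c(0.5, 0.5))
  w <- waicc(c(103.2, 100, 108.9))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(which.max(w), 2L)
  # invariance to a constant shift
  expect_equal(waicc(c(103.2, 100, 108.9) + 57), w, tolerance = 1e-12)
})

test_that("candidate enumeration covers singles, sets, combinations and the full model", {
  sets <- list(soil = c("sand", "cec"),
               topography = c("elevation", "elevation_cv"),
               current = "AI",
               historical = c("HAI", "hydric_change", "thermal_change"),
               footprint = "footprint")
  cands <- build_candidates(sets, mem_columns = c("MEM1", "MEM2"))
  expect_true(all(c("AI", "sand", "soil", "historical",
                    "current+historical", "full") %in% cands$name))
  # 9 singles + 4 multi-predictor sets (current/footprint singles
  # duplicate their sets) + current x historical + full
  expect_equal(nrow(cands), 9 + 3 + 1 + 1)
  key <- vapply(cands$predictors, function(v)
    paste(sort(v), collapse = "|"), character(1))
  expect_false(any(duplicated(key)))
  expect_true(all(vapply(cands$mems, identical, logical(1),
                         c("MEM1", "MEM2"))))
  full <- cands$predictors[[match("full", cands$name)]]
  expect_setequal(full, unlist(sets))
  expect_error(build_candidates(list(a = character())), "empty")
})

test_that("explained deviance is 0 for null, 1 for perfect, monotone when nested", {
  sim <- sim_multiclass(n = 120, seed = 3)
  null_fit <- fit_multinomial(sim$y, NULL)
  expect_equal(explained_deviance(null_fit, null_fit), 0)
  fit1 <- fit_multinomial(sim$y, sim$x["x"])
  fit2 <- fit_multinomial(sim$y, sim$x)
  e1 <- explained_deviance(fit1, null_fit)
  e2 <- explained_deviance(fit2, null_fit)
  expect_gte(e2, e1 - 1e-6)     # nested-model likelihood monotonicity
  expect_true(e1 > 0 && e2 < 1)
  ysep <- factor(rep(c("a", "b"), each = 10))
  perfect <- fit_multinomial(ysep, data.frame(x = rep(c(-1, 1), each = 10)))
  expect_equal(explained_deviance(perfect, fit_multinomial(ysep, NULL)),
               1, tolerance = 1e-4)
})

test_that("deviance partition is additive and attributes structure correctly", {
  sim <- sim_multiclass(n = 120, seed = 5)
  withr::with_seed(6, {
    mem <- data.frame(m1 = rnorm(120), m2 = rnorm(120))
  })
  dp <- partition_deviance(sim$y, sim$x["x"], mem)
  expect_equal(dp$unique_env + dp$unique_mem + dp$shared, dp$total,
               tolerance = 1e-10)
  expect_equal(dp$unexplained, 1 - dp$total, tolerance = 1e-12)
  # labels driven by the "spatial" columns only: unique env is tiny
  withr::with_seed(8, {
    m <- rnorm(150)
    ym <- factor(ifelse(m + rnorm(150, 0, 0.4) > 0, "a", "b"))
    env_noise <- data.frame(e = rnorm(150))
  })
  dp2 <- partition_deviance(ym, env_noise, data.frame(m = m))
  expect_lt(dp2$unique_env, 0.05)
  # exactly orthogonal moderate effects share almost nothing
  withr::with_seed(9, {
    e <- rnorm(400)
    m2 <- stats::residuals(stats::lm(rnorm(400) ~ e))
    y3 <- factor(ifelse(0.5 * e + 0.5 * m2 + rnorm(400) > 0, "a", "b"))
  })
  dp3 <- partition_deviance(y3, data.frame(e = e), data.frame(m = m2))
  expect_lt(abs(dp3$shared), 0.05)
})

test_that("single-factor PERMANOVA on Euclidean distances equals classical ANOVA", {
  withr::with_seed(10, {
    g <- factor(rep(c("a", "b", "c"), each = 8))
    y <- rnorm(24) + 2 * (g == "b")
  })
  d <- as_dissimilarity_matrix(as.matrix(stats::dist(y)))
  tab <- permanova_2way(d, g, n_perm = 99, seed = 1)
  f_ref <- summary(stats::aov(y ~ g))[[1]][["F value"]][1]
  expect_equal(tab$pseudo_f[1], f_ref, tolerance = 1e-8)
  expect_equal(sum(tab$r2), 1, tolerance = 1e-10)
})

test_that("two-way PERMANOVA agrees with an independent implementation", {
  withr::with_seed(11, {
    a <- factor(rep(c("x", "y"), each = 12))
    b <- factor(rep(rep(c("u", "v", "w"), each = 4), 2))
    pts <- matrix(rnorm(48), ncol = 2) + 1.5 * cbind(a == "y", b == "v")
  })
  d <- as_dissimilarity_matrix(as.matrix(stats::dist(pts)))
  ours <- permanova_2way(d, a, b, n_perm = 0, seed = 1)
  df <- data.frame(a = a, b = b)
  ref <- vegan::adonis2(stats::as.dist(d$d) ~ a * b, data = df,
                        permutations = 2, by = "terms")
  expect_equal(ours$ss[1:3], ref$SumOfSqs[1:3], tolerance = 1e-8)
  expect_equal(ours$pseudo_f[1:3], ref$F[1:3], tolerance = 1e-8)
})

test_that("irrelevant factors earn low R2 and honest p-values", {
  withr::with_seed(12, {
    pts <- matrix(rnorm(60), ncol = 2)
    g <- factor(rep(c("a", "b", "c"), each = 10))
  })
  d <- as_dissimilarity_matrix(as.matrix(stats::dist(pts)))
  tab <- permanova_2way(d, g, n_perm = 199, seed = 3)
  expect_lt(tab$r2[1], 0.15)
  expect_gt(tab$p[1], 0.1)
})

test_that("residual correlograms flag missing spatial structure only", {
  reg <- toy_registry(90, seed = 20)
  withr::with_seed(21, {
    lon_s <- as.numeric(scale(reg$lon))
    lat_s <- as.numeric(scale(reg$lat))
    # membership driven by two spatial gradients; a model seeing only one
    # leaves spatially clustered misclassification behind
    y <- factor(ifelse(2 * lon_s + 2 * lat_s + rnorm(90, 0, 0.5) > 0,
                       "a", "b"))
    x_iid <- rnorm(90)
    y_iid <- factor(ifelse(1.5 * x_iid + rnorm(90, 0, 0.7) > 0, "a", "b"))
  })
  fit_without <- fit_multinomial(y, data.frame(x = lon_s))
  cg_bad <- residual_diagnostics(fit_without, reg, n_classes = 6,
                                 n_perm = 199, seed = 4)
  expect_lt(cg_bad$p[1], 0.05)
  expect_gt(cg_bad$I[1], 0)
  # a correctly specified non-spatial model leaves clean residuals
  fit_good <- fit_multinomial(y_iid, data.frame(x = x_iid))
  cg_good <- residual_diagnostics(fit_good, reg, n_classes = 6,
                                  n_perm = 199, seed = 4)
  expect_true(all(cg_good$p_adj[cg_good$ok] > 0.05))
  yconst <- factor(rep(c("a", "b"), 45))
  sep <- data.frame(s = ifelse(yconst == "a", -1, 1))
  fit_sep <- fit_multinomial(yconst, sep)
  expect_error(residual_diagnostics(fit_sep, reg), "constant")
})
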