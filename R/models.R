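#' Multinomial logistic model of sub-region membership
#'
#' Maximum-likelihood multinomial logistic regression (via
#' [nnet::multinom()]) of a categorical site label on a numeric design.
#' Predictors are standardized internally; a tiny ridge penalty keeps
#' separable data finite. The reference class is the largest class. The
#' log-likelihood and deviance are recomputed from the fitted class
#' probabilities so the reported deviance is the unpenalized one.
#'
#' @param labels factor-like vector of class labels per site (>= 2
#'   classes, each with >= 2 observations).
#' @param design numeric matrix or data.frame of predictors (may have 0
#'   columns for the intercept-only model).
#' @param ridge ridge (weight-decay) penalty, default 1e-8.
#' @param max_iter optimizer iteration cap (default 500).
#' @param tol relative convergence tolerance (default 1e-12).
#' @return object of class `multinomial_fit`: `classes`, `coefficients`
#'   ((K-1) x (p+1)), `log_lik`, `deviance`, `n`, `p_effective`
#'   (all free coefficients, (K-1)(p+1)), `probabilities`
#'   (n x K), `labels`, `fit`.
#' @export
fit_multinomial <- function(labels, design = NULL, ridge = 1e-8,
                            max_iter = 500, tol = 1e-12) {
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least two classes")
  if (any(table(y) < 2)) stop("every class needs at least 2 observations")
  ref <- names(which.max(table(y)))
  y <- stats::relevel(y, ref = ref)
  if (is.null(design) || NCOL(design) == 0) {
    df <- data.frame(y = y)
    form <- y ~ 1
    p <- 0
  } else {
    x <- scale(as.matrix(design))
    x <- x[, apply(x, 2, function(v) all(is.finite(v))), drop = FALSE]
    df <- data.frame(y = y, x, check.names = FALSE)
    p <- ncol(x)
    form <- if (p > 0) y ~ . else y ~ 1
  }
  fit <- nnet::multinom(form, data = df, decay = ridge, maxit = max_iter,
                        reltol = tol, trace = FALSE,
                        MaxNWts = 100000)
  pr <- stats::fitted(fit)
  if (is.null(dim(pr)) || ncol(pr) == 1)          # K = 2 case
    pr <- cbind(1 - as.numeric(pr), as.numeric(pr))
  colnames(pr) <- levels(y)
  ll <- sum(log(pmax(pr[cbind(seq_along(y), as.integer(y))], 1e-300)))
  k_par <- (nlevels(y) - 1) * (p + 1)
  structure(list(classes = levels(y),
                 coefficients = stats::coef(fit),
                 log_lik = ll, deviance = -2 * ll,
                 n = length(y), p_effective = k_par,
                 probabilities = pr, labels = y, fit = fit),
            class = "multinomial_fit")
}

#' @export
print.multinomial_fit <- function(x, ...) {
  cat(sprintf("multinomial_fit: %d classes, n = %d, %d free parameters, logLik %.3f\n",
              length(x$classes), x$n, x$p_effective, x$log_lik))
  invisible(x)
}

#' Small-sample Akaike information criterion
#'
#' AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1), with k the number of free
#' parameters (all multinomial coefficients).
#'
#' @param fit a `multinomial_fit`, or a log-likelihood if `k` and `n`
#'   are given.
#' @param k,n parameter count and sample size (taken from `fit` if a
#'   `multinomial_fit` is supplied).
#' @return AICc value.
#' @export
aicc <- function(fit, k = NULL, n = NULL) {
  if (inherits(fit, "multinomial_fit")) {
    ll <- fit$log_lik; k <- fit$p_effective; n <- fit$n
  } else ll <- fit
  if (n - k - 1 <= 0)
    stop("AICc undefined: n <= k + 1")
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' w_m = exp(-Delta_m / 2) / sum(exp(-Delta / 2)) over a set of AICc
#' values; invariant to adding a constant to all of them.
#'
#' @param aicc_values numeric vector of AICc values.
#' @return weights summing to 1.
#' @export
waicc <- function(aicc_values) {
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Candidate model designs from named predictor sets
#'
#' Enumerates the candidate set used for driver ranking: every single
#' predictor, every named set, every combination of the current-climate
#' set with the historical-climate set, and the full model; duplicate
#' predictor combinations are removed. Selected spatial eigenvectors
#' (MEMs) are appended to every candidate so all models control for
#' spatial structure alike.
#'
#' @param sets named list of character vectors of predictor names; the
#'   combination rule applies to elements named `current` and
#'   `historical` when both are present.
#' @param mem_columns character vector of MEM column names appended to
#'   every design (may be empty).
#' @return data.frame with `name` and list-column `predictors`
#'   (environmental predictors only, MEMs excluded) and `mems`.
#' @export
build_candidates <- function(sets, mem_columns = character()) {
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  if (any(vapply(sets, length, integer(1)) == 0)) stop("empty predictor set")
  singles <- unique(unlist(sets))
  cand <- c(
    stats::setNames(as.list(singles), singles),
    lapply(sets, identity))
  if (all(c("current", "historical") %in% names(sets)))
    cand[["current+historical"]] <-
      c(sets$current, sets$historical)
  cand[["full"]] <- singles
  key <- vapply(cand, function(v) paste(sort(unique(v)), collapse = "|"),
                character(1))
  cand <- cand[!duplicated(key)]
  out <- data.frame(name = names(cand), stringsAsFactors = FALSE)
  out$predictors <- unname(lapply(cand, unique))
  out$mems <- rep(list(mem_columns), nrow(out))
  out
}

#' Explained deviance of a categorical model
#'
#' (D_null - D_model) / D_null, the likelihood-based fraction of
#' variability in class membership the model accounts for.
#'
#' @param fit,null_fit `multinomial_fit`s on the same observations
#'   (`null_fit` intercept-only).
#' @return fraction in [0, 1] (up to optimizer tolerance).
#' @export
explained_deviance <- function(fit, null_fit) {
  stopifnot(fit$n == null_fit$n)
  if (null_fit$deviance <= 0) stop("null deviance is zero")
  (null_fit$deviance - fit$deviance) / null_fit$deviance
}

#' Rank candidate driver models by AICc
#'
#' Fits every candidate design (plus shared MEM columns) and the null
#' model, and tabulates logLik, parameter count, AICc, delta-AICc,
#' Akaike weights and explained deviance.
#'
#' @param labels class labels per site.
#' @param data data.frame holding all predictor and MEM columns.
#' @param candidates a [build_candidates()] table.
#' @param ... passed to [fit_multinomial()].
#' @return object of class `model_table`: data.frame sorted by AICc, with
#'   attribute `fits` (the fitted models) and `null_fit`.
#' @export
rank_models <- function(labels, data, candidates, ...) {
  null_fit <- fit_multinomial(labels, NULL, ...)
  fits <- lapply(seq_len(nrow(candidates)), function(i) {
    cols <- c(candidates$predictors[[i]], candidates$mems[[i]])
    fit_multinomial(labels, data[, cols, drop = FALSE], ...)
  })
  names(fits) <- candidates$name
  tab <- data.frame(
    name = candidates$name,
    predictors = vapply(candidates$predictors, paste, character(1),
                        collapse = "+"),
    log_lik = vapply(fits, function(f) f$log_lik, numeric(1)),
    k = vapply(fits, function(f) f$p_effective, numeric(1)),
    aicc = vapply(fits, aicc, numeric(1)),
    explained_deviance = vapply(fits, explained_deviance, numeric(1),
                                null_fit = null_fit),
    stringsAsFactors = FALSE)
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  tab$waicc <- waicc(tab$aicc)
  tab <- tab[order(tab$aicc), ]
  rownames(tab) <- NULL
  structure(tab, class = c("model_table", "data.frame"),
            fits = fits, null_fit = null_fit)
}

#' Partition explained deviance into unique and shared components
#'
#' From the fits of {environment + MEMs}, {environment}, {MEMs} and the
#' null model: total = ED(env+mem), unique_env = total - ED(mem),
#' unique_mem = total - ED(env), shared = ED(env) + ED(mem) - total.
#' The three components sum to the total exactly.
#'
#' @param labels class labels per site.
#' @param env_design environmental predictor columns.
#' @param mem_design spatial eigenvector columns.
#' @param ... passed to [fit_multinomial()].
#' @return object of class `deviance_partition`: `total`, `unique_env`,
#'   `unique_mem`, `shared`, `unexplained`.
#' @export
partition_deviance <- function(labels, env_design, mem_design, ...) {
  null_fit <- fit_multinomial(labels, NULL, ...)
  ed <- function(design) explained_deviance(
    fit_multinomial(labels, design, ...), null_fit)
  both <- ed(cbind(as.data.frame(env_design), as.data.frame(mem_design)))
  env <- ed(env_design)
  mem <- ed(mem_design)
  structure(list(total = both,
                 unique_env = both - mem,
                 unique_mem = both - env,
                 shared = env + mem - both,
                 unexplained = 1 - both),
            class = "deviance_partition")
}

#' @export
print.deviance_partition <- function(x, ...) {
  cat(sprintf("deviance partition: total %.4f = unique env %.4f + unique spatial %.4f + shared %.4f (unexplained %.4f)\n",
              x$total, x$unique_env, x$unique_mem, x$shared,
              x$unexplained))
  invisible(x)
}

#' Two-way PERMANOVA on a dissimilarity matrix
#'
#' Distance-based linear model in the McArdle-Anderson form: the
#' Gower-centered inner-product matrix G of the dissimilarities is
#' partitioned by sequential (Type I) projections onto the design of
#' factor A, then B, then A:B; each term's pseudo-F is tested by free
#' permutation of the rows/columns of G.
#'
#' @param d a `dissimilarity_matrix`.
#' @param factor_a,factor_b factors (>= 2 levels each), one value per
#'   site; `factor_b = NULL` gives a one-way analysis.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @param interaction include the A:B term (default TRUE when B given).
#' @return object of class `permanova_table`: data.frame with `term`,
#'   `df`, `ss`, `pseudo_f`, `r2`, `p`.
#' @export
permanova_2way <- function(d, factor_a, factor_b = NULL, n_perm = 1000,
                           seed = 1, interaction = !is.null(factor_b)) {
  stopifnot(inherits(d, "dissimilarity_matrix"))
  n <- nrow(d$d)
  fa <- factor(factor_a)
  stopifnot(length(fa) == n, nlevels(fa) >= 2, !anyNA(fa))
  g <- gower_center(-0.5 * d$d^2)

  terms <- list(A = stats::model.matrix(~fa))
  if (!is.null(factor_b)) {
    fb <- factor(factor_b)
    stopifnot(length(fb) == n, nlevels(fb) >= 2, !anyNA(fb))
    terms$B <- stats::model.matrix(~ fa + fb)
    if (interaction) terms$`A:B` <- stats::model.matrix(~ fa * fb)
  }
  hat <- function(x) {
    q <- qr.Q(qr(x))
    tcrossprod(q)
  }
  hats <- lapply(terms, hat)
  dfs <- diff(c(1, vapply(terms, function(x) qr(x)$rank, numeric(1))))
  names(dfs) <- names(terms)
  df_res <- n - qr(terms[[length(terms)]])$rank
  if (df_res <= 0) stop("no residual degrees of freedom (confounded factors)")
  one <- matrix(1 / n, n, n)
  # sequential hat increments (the intercept projection annihilates
  # centered G, so tr(H G) already measures the centered fit)
  h_seq <- vector("list", length(hats))
  prev <- one
  for (i in seq_along(hats)) {
    h_seq[[i]] <- hats[[i]] - prev
    prev <- hats[[i]]
  }
  names(h_seq) <- names(terms)
  ss_total <- sum(diag(g))
  term_ss <- function(gmat)
    vapply(h_seq, function(h) sum(h * gmat), numeric(1))
  ss <- term_ss(g)
  ss_res <- ss_total - sum(ss)
  f_obs <- (ss / dfs) / (ss_res / df_res)

  p <- rep(NA_real_, length(ss))
  if (n_perm > 0) {
    exceed <- rep(0L, length(ss))
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        idx <- sample.int(n)
        gp <- g[idx, idx]
        ssp <- term_ss(gp)
        fp <- (ssp / dfs) / ((ss_total - sum(ssp)) / df_res)
        exceed <- exceed + (fp >= f_obs)
      }
    })
    p <- (exceed + 1) / (n_perm + 1)
  }
  structure(data.frame(term = c(names(terms), "Residual"),
                       df = c(dfs, df_res),
                       ss = c(ss, ss_res),
                       pseudo_f = c(f_obs, NA),
                       r2 = c(ss, ss_res) / ss_total,
                       p = c(p, NA)),
            class = c("permanova_table", "data.frame"))
}

#' Spatial correlogram of multinomial residuals
#'
#' Per-site residual = 1 - fitted probability of the observed class,
#' passed to [correlogram()] with 14 distance classes; a model that
#' captures the spatial structure should show no significant class after
#' the Holm adjustment.
#'
#' @param fit a `multinomial_fit`.
#' @param registry site registry with `lon`, `lat`.
#' @param n_classes,n_perm,seed passed to [correlogram()].
#' @return a [correlogram()] table.
#' @export
residual_diagnostics <- function(fit, registry, n_classes = 14,
                                 n_perm = 199, seed = 1) {
  stopifnot(inherits(fit, "multinomial_fit"))
  res <- 1 - fit$probabilities[cbind(seq_len(fit$n),
                                     as.integer(fit$labels))]
  if (stats::sd(res) == 0) stop("constant residuals")
  correlogram(res, registry, n_classes = n_classes, n_perm = n_perm,
              seed = seed)
}
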