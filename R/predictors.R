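#' Koeppen aridity index surface
#'
#' AI = MAP / (MAT + 33), with MAP the mean annual precipitation (mm) and
#' MAT the mean annual temperature (degrees C). Low values indicate arid
#' conditions; the index integrates water supply and temperature-driven
#' demand and serves as a productivity proxy.
#'
#' @param map_surface [grid_surface()] of annual precipitation (mm).
#' @param mat_surface [grid_surface()] of mean annual temperature (deg C),
#'   must exceed -33 on every unmasked cell.
#' @return a [grid_surface()] of AI values.
#' @export
aridity_index <- function(map_surface, mat_surface) {
  stopifnot(geometry_equal(map_surface$geometry, mat_surface$geometry))
  mask <- map_surface$mask & mat_surface$mask
  if (any(mat_surface$values[mask] <= -33))
    stop("MAT <= -33 at an unmasked cell: aridity index undefined")
  v <- rep(0, length(map_surface$values))
  v[mask] <- map_surface$values[mask] / (mat_surface$values[mask] + 33)
  grid_surface(map_surface$geometry, v, mask = mask, name = "AI")
}

#' Historical aridity change with GCM consensus
#'
#' Per circulation model, the change is current AI minus glacial-maximum
#' AI; the consensus surface averages the per-model changes, which
#' absorbs part of the uncertainty in any single paleoclimate
#' reconstruction.
#'
#' @param current_ai [grid_surface()] of present-day AI.
#' @param lgm_ai_per_gcm list of [grid_surface()]s, one per GCM.
#' @return a [grid_surface()] of the consensus AI change.
#' @export
historical_ai <- function(current_ai, lgm_ai_per_gcm) {
  stopifnot(length(lgm_ai_per_gcm) >= 1)
  acc <- 0
  mask <- current_ai$mask
  for (s in lgm_ai_per_gcm) {
    if (!geometry_equal(current_ai$geometry, s$geometry))
      stop("geometry mismatch between current and LGM layers")
    mask <- mask & s$mask
    acc <- acc + (current_ai$values - s$values)
  }
  grid_surface(current_ai$geometry, acc / length(lgm_ai_per_gcm),
               mask = mask, name = "HAI")
}

#' Multivariate envelope-change distance
#'
#' Summarizes a set of current-minus-glacial "delta" bioclimatic layers
#' (e.g. the 11 thermal or 8 hydric ones) into one surface: cells are
#' rows, delta variables are standardized columns, a PCA is taken over
#' all axes and each cell's distance to the ordination origin is its
#' overall envelope change. Because all axes are retained, the distance
#' equals the Euclidean norm of the standardized row — the PCA rotation
#' cannot change it — which makes the statistic invariant to any
#' orthogonal rotation of the delta space.
#'
#' @param delta_layers list of >= 2 [grid_surface()]s (current - LGM).
#' @return a [grid_surface()] of envelope-change distances.
#' @export
envelope_distance <- function(delta_layers) {
  stopifnot(length(delta_layers) >= 2)
  geom <- delta_layers[[1]]$geometry
  mask <- Reduce(`&`, lapply(delta_layers, function(s) s$mask))
  x <- sapply(delta_layers, function(s) {
    stopifnot(geometry_equal(geom, s$geometry))
    s$values[mask]
  })
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance delta variable(s)")
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) == 0) stop("no delta variable with variance left")
  z <- scale(x)
  scores <- stats::prcomp(z, center = FALSE, scale. = FALSE)$x
  v <- rep(0, length(delta_layers[[1]]$values))
  v[mask] <- sqrt(rowSums(scores^2))
  grid_surface(geom, v, mask = mask)
}

#' Aggregate a surface within a radius around each site
#'
#' Computes a summary statistic of the cell values whose centers lie
#' within `radius_km` (haversine) of each site — the standard way of
#' matching gridded environmental layers to the effective footprint of a
#' floristic locality.
#'
#' @param surface a [grid_surface()].
#' @param registry data.frame with `site_id`, `lon`, `lat`.
#' @param radius_km buffer radius in km (default 10).
#' @param stat one of "mean", "range", "cv" (cv = sd / |mean|).
#' @return named numeric vector, one value per site.
#' @export
buffer_aggregate <- function(surface, registry, radius_km = 10,
                             stat = c("mean", "range", "cv")) {
  stat <- match.arg(stat)
  cells <- grid_cells(surface$geometry)
  dmat <- haversine_km(registry[, c("lon", "lat")],
                       cells[, c("lon", "lat")])
  out <- vapply(seq_len(nrow(registry)), function(i) {
    sel <- dmat[i, ] <= radius_km & surface$mask
    if (!any(sel))
      stop("empty buffer around site ", registry$site_id[i])
    v <- surface$values[sel]
    switch(stat,
           mean = mean(v),
           range = diff(range(v)),
           cv = if (length(v) < 2 || mean(v) == 0) 0
                else stats::sd(v) / abs(mean(v)))
  }, numeric(1))
  stats::setNames(out, registry$site_id)
}

#' Greedy collinearity screen
#'
#' Repeatedly finds the pair of variables with the largest absolute
#' Pearson correlation above the threshold and drops the lower-priority
#' member, until no pair exceeds the threshold. Priority is the order of
#' `priority` (earlier = kept preferentially), defaulting to column
#' order.
#'
#' @param table data.frame or matrix of candidate predictors (>= 3 rows).
#' @param r_threshold absolute-correlation cutoff (default 0.75).
#' @param priority character vector of variable names, most important
#'   first.
#' @return list with `kept` (names), `table` (screened columns) and
#'   `dropped` (data.frame of removed variables, their partner and r).
#' @export
collinearity_screen <- function(table, r_threshold = 0.75,
                                priority = colnames(table)) {
  x <- as.data.frame(table)
  stopifnot(ncol(x) >= 2, nrow(x) >= 3)
  rank_of <- function(v) match(v, priority)
  dropped <- list()
  repeat {
    r <- stats::cor(x)
    diag(r) <- 0
    if (max(abs(r)) <= r_threshold) break
    ij <- which(abs(r) == max(abs(r)), arr.ind = TRUE)[1, ]
    pair <- colnames(x)[ij]
    loser <- pair[which.max(rank_of(pair))]
    keeper <- setdiff(pair, loser)
    dropped[[length(dropped) + 1]] <-
      data.frame(dropped = loser, kept = keeper, r = r[ij[1], ij[2]])
    x[[loser]] <- NULL
  }
  list(kept = colnames(x), table = x,
       dropped = if (length(dropped)) do.call(rbind, dropped)
                 else data.frame(dropped = character(), kept = character(),
                                 r = numeric()))
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) from the OLS regression of predictor j on all
#' other predictors.
#'
#' @param table data.frame or matrix of predictors (full rank).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(table) {
  x <- as.matrix(table)
  stopifnot(ncol(x) >= 2)
  out <- vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    if (r2 > 1 - 1e-12) stop("exact collinearity involving ",
                             colnames(x)[j])
    1 / (1 - r2)
  }, numeric(1))
  stats::setNames(out, colnames(x))
}

#' Assemble the site-level predictor table
#'
#' Derives AI, consensus historical AI change, hydric and thermal
#' envelope-change distances from an [generate_landscape()] stack (or any
#' equally structured `env_stack`), aggregates them plus elevation
#' (mean and cv), sand, cation exchange capacity and human footprint in
#' 10-km buffers around each site, and applies the collinearity screen.
#'
#' @param stack an `env_stack`.
#' @param registry site registry data.frame.
#' @param radius_km buffer radius (default 10).
#' @param r_threshold collinearity cutoff (default 0.75).
#' @param priority screening priority; defaults to putting current
#'   aridity first, mirroring a productivity-first reading of candidate
#'   drivers.
#' @return list with `table` (screened data.frame, rownames = site ids),
#'   `full_table` (pre-screen), `screen` (report), `vif` (post-screen).
#' @export
predictor_table <- function(stack, registry, radius_km = 10,
                            r_threshold = 0.75,
                            priority = c("AI", "HAI", "hydric_change",
                                         "thermal_change", "elevation",
                                         "elevation_cv", "sand", "cec",
                                         "footprint")) {
  ai <- aridity_index(stack$layers$bio12, stack$layers$bio1)
  lgm_ai <- lapply(stack$lgm, function(g)
    aridity_index(g$bio12, g$bio1))
  hai <- historical_ai(ai, lgm_ai)

  delta_env <- function(idx) {
    # per-GCM envelope distance, averaged into a consensus surface
    per_gcm <- lapply(stack$lgm, function(g) {
      envelope_distance(lapply(idx, function(j) {
        nm <- paste0("bio", j)
        grid_surface(stack$geometry,
                     stack$layers[[nm]]$values - g[[nm]]$values,
                     mask = stack$layers[[nm]]$mask & g[[nm]]$mask)
      }))
    })
    acc <- Reduce(`+`, lapply(per_gcm, function(s) s$values))
    grid_surface(stack$geometry, acc / length(per_gcm),
                 mask = Reduce(`&`, lapply(per_gcm, function(s) s$mask)))
  }
  thermal <- delta_env(1:11)
  hydric <- delta_env(12:19)

  agg <- function(s, stat = "mean") buffer_aggregate(s, registry,
                                                     radius_km, stat)
  full <- data.frame(
    AI = agg(ai), HAI = agg(hai),
    hydric_change = agg(hydric), thermal_change = agg(thermal),
    elevation = agg(stack$elevation),
    elevation_cv = agg(stack$elevation, "cv"),
    sand = agg(stack$sand), cec = agg(stack$cec),
    footprint = agg(stack$footprint),
    row.names = registry$site_id)
  scr <- collinearity_screen(full, r_threshold = r_threshold,
                             priority = priority)
  list(table = scr$table, full_table = full, screen = scr,
       vif = if (ncol(scr$table) >= 2) vif(scr$table) else NULL)
}
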