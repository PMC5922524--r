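#' Synthetic landscape and community generator
#'
#' The generator emulates the data situation of a semi-arid floristic
#' compilation: a rainfall gradient crossed with topography yields an
#' aridity surface, species occupy Gaussian niches along that surface
#' within bounded geographic ranges, and the "true" sub-regions are
#' contiguous aridity bands. Soil and human-footprint layers are generated
#' independently of the planted structure so that driver-inference methods
#' can be benchmarked against a known answer.
#'
#' @name synthetic
NULL

# Smoothed Gaussian random field on an n_rows x n_cols grid, standardized
# to mean 0, sd 1. Smoothing by row/column Gaussian weight matrices.
gaussian_field <- function(n_rows, n_cols, range_cells) {
  smoother <- function(n, r) {
    s <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * r^2))
    s / rowSums(s)
  }
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  f <- smoother(n_rows, range_cells) %*% z %*% t(smoother(n_cols, range_cells))
  (f - mean(f)) / stats::sd(f)
}

#' Default configuration for the synthetic landscape
#'
#' Values approximate a 2.5 arc-min window over a seasonally dry tropical
#' landscape: annual rainfall running from about 400 mm in the arid east
#' to 1400 mm in the west, mean annual temperature near 26 degrees C
#' lowered by elevation at a standard lapse rate, and moderate
#' spatially-autocorrelated noise on every layer.
#'
#' @param n_rows,n_cols grid size (default 60 x 60).
#' @param cell_arcmin cell size, arc-minutes.
#' @param origin_lon,origin_lat SW cell-center coordinates.
#' @param planted_k number of planted sub-regions (aridity bands).
#' @param gradient_mm west-to-east rainfall drop across the grid (mm).
#' @param base_map minimum of the rainfall gradient (mm).
#' @param noise_sd sd of the rainfall random field (mm); 0 gives planted
#'   regions whose borders are exact aridity-quantile contours.
#' @param band_curvature weight of the large-scale random field mixed
#'   into the east-west gradient before terracing; 0 gives straight
#'   vertical bands, larger values give curved, blobbier (but still
#'   contiguous, equal-area) bands.
#' @param grf_range autocorrelation range of the random fields, in cells.
#' @param n_gcm number of pseudo circulation models for the glacial layers.
#' @return named list of generator settings.
#' @export
landscape_config <- function(n_rows = 60, n_cols = 60, cell_arcmin = 2.5,
                             origin_lon = -42.5, origin_lat = -12,
                             planted_k = 5, gradient_mm = 1000,
                             base_map = 400, noise_sd = 40,
                             band_curvature = 0.35,
                             grf_range = 6, n_gcm = 3) {
  as.list(environment())
}

#' Generate a seeded synthetic environmental stack with planted regions
#'
#' Builds 19 current bioclimatic surfaces, glacial-maximum counterparts
#' for `n_gcm` pseudo circulation models, elevation, two soil layers and a
#' human-footprint layer, all sharing one grid geometry. The aridity index
#' MAP/(MAT+33) derived from the stack defines `planted_k` contiguous
#' quantile bands which are the ground-truth sub-regions; soil and
#' footprint layers are independent of them.
#'
#' @param config a [landscape_config()].
#' @param seed integer seed; identical (config, seed) give identical output.
#' @return list with `stack` (class `env_stack`) and `truth` (class
#'   `synthetic_truth`: `planted_k`, `region_of_cell`, `ai`, `seed`).
#' @export
generate_landscape <- function(config = landscape_config(), seed = 1) {
  cfg <- config
  with_seed(seed, {
    geom <- grid_geometry(cfg$origin_lon, cfg$origin_lat, cfg$cell_arcmin,
                          cfg$n_rows, cfg$n_cols)
    nr <- cfg$n_rows; nc <- cfg$n_cols
    grf <- function(range = cfg$grf_range) {
      # surfaces are stored row-wise from the SW corner
      as.numeric(t(gaussian_field(nr, nc, range)))
    }
    col_frac <- (grid_cells(geom)$col - 1) / max(1, nc - 1)

    elev <- pmax(0, 400 + 150 * grf(8))
    # Banded rainfall: the smooth east-west gradient is mixed with a
    # large-scale random field, rank-transformed, and terraced into
    # planted_k equal-area plateaus separated by steep logistic steps.
    # The aridity surface therefore carries planted_k distinguishable
    # contiguous bands (a detectable "true" number of regions) rather
    # than a featureless continuum, and the equal-mass plateaus align
    # with aridity quantile contours at any k.
    if (cfg$planted_k < 2) stop("planted_k must be at least 2")
    sep_ratio <- cfg$gradient_mm /
      ((cfg$planted_k - 1) * max(cfg$noise_sd, 1e-12))
    if (cfg$noise_sd > 0 && sep_ratio < 2)
      stop("planted_k exceeds the number of distinguishable aridity ",
           "bands (plateau separation below twice the noise sd)")
    base_field <- (1 - col_frac) + cfg$band_curvature * grf(12)
    u <- (rank(base_field, ties.method = "first") - 0.5) /
      length(base_field)
    s <- u * cfg$planted_k
    terrace <- rowSums(stats::plogis(
      outer(s, seq_len(cfg$planted_k - 1), "-") * 40)) /
      (cfg$planted_k - 1)
    map <- cfg$base_map + cfg$gradient_mm * (1 - terrace) +
      cfg$noise_sd * grf(4)
    map <- pmax(map, 10)
    mat <- 28 - 6.5 * elev / 1000 + 0.3 * grf()

    lyr <- function(v, nm) grid_surface(geom, v, name = nm)
    layers <- list(bio1 = lyr(mat, "bio1"), bio12 = lyr(map, "bio12"))
    # remaining thermal (bio2-bio11) and hydric (bio13-bio19) variables as
    # noisy affine companions of bio1 / bio12
    th_a <- c(10, 40, 450, 33, 20, 13, 26, 21, 29, 22)
    th_b <- c(0.10, 0.5, 12, 0.25, 0.35, 0.3, 0.9, 0.85, 0.95, 0.88)
    for (j in 2:11)
      layers[[paste0("bio", j)]] <-
        lyr(th_a[j - 1] + th_b[j - 1] * (mat - 26) + 0.6 * grf(),
            paste0("bio", j))
    hy_b <- c(0.22, 0.01, 55, 0.30, 0.05, 0.18, 0.08)
    for (j in 13:19)
      layers[[paste0("bio", j)]] <-
        lyr(pmax(0, hy_b[j - 12] * map + 15 * grf()), paste0("bio", j))

    # glacial-maximum stacks: per-model smooth offsets plus noise
    lgm <- vector("list", cfg$n_gcm)
    names(lgm) <- paste0("gcm", seq_len(cfg$n_gcm))
    for (g in seq_len(cfg$n_gcm)) {
      d_t <- -(2 + g) + 1.0 * grf(12)        # cooler glacial climate
      d_p <- (100 + 60 * g) * (0.5 + 0.5 * grf(12)) # wetter glacial climate
      gl <- list()
      for (nm in names(layers)) {
        j <- as.integer(sub("bio", "", nm))
        shift <- if (j <= 11) d_t * (if (j == 4) 8 else 1)
                 else d_p * (if (j == 12) 1 else 0.15)
        gl[[nm]] <- lyr(layers[[nm]]$values + shift + 0.3 * grf(),
                        paste0(nm, "_lgm_gcm", g))
      }
      lgm[[g]] <- gl
    }

    sand <- 50 + 15 * grf(7)
    cec <- pmax(1, 12 + 4 * grf(7))
    foot <- pmin(50, pmax(0, 15 + 8 * grf(5)))

    stack <- structure(list(
      geometry = geom, layers = layers, lgm = lgm,
      elevation = lyr(elev, "elevation"), sand = lyr(sand, "sand"),
      cec = lyr(cec, "cec"), footprint = lyr(foot, "footprint")),
      class = "env_stack")

    ai <- aridity_index(layers$bio12, layers$bio1)
    qs <- stats::quantile(ai$values, probs = seq(0, 1, length.out =
                                                   cfg$planted_k + 1))
    if (anyDuplicated(qs))
      stop("planted_k exceeds the number of distinguishable aridity bands")
    region <- as.integer(cut(ai$values, breaks = qs, include.lowest = TRUE))
    truth <- structure(list(planted_k = cfg$planted_k,
                            region_of_cell = region, ai = ai,
                            seed = seed),
                       class = "synthetic_truth")
    list(stack = stack, truth = truth)
  })
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack: %d current bioclim layers, %d GCM glacial stacks, elevation/sand/cec/footprint on a %d x %d grid\n",
              length(x$layers), length(x$lgm),
              x$geometry$n_rows, x$geometry$n_cols))
  invisible(x)
}

#' Generate a niche-structured synthetic community
#'
#' Each species gets an aridity optimum `mu`, niche breadth `sigma`, a
#' circular geographic range (center cell, radius in km) and a maximum
#' occupancy `p_max`. Presence at a site is a Bernoulli draw with
#' probability `p_max * exp(-(AI - mu)^2 / (2 sigma^2))` inside the range
#' and 0 outside. Sites are grid cells sampled without replacement;
#' species-poor sites are removed afterwards with [filter_localities()].
#'
#' @param stack,truth output of [generate_landscape()].
#' @param n_sites number of sampled localities (default 150).
#' @param n_species species pool size before filtering (default 600).
#' @param seed integer seed.
#' @param p_max maximum occupancy probability (default 0.6).
#' @param sigma_frac range of niche breadths as a fraction of the aridity
#'   span (default 0.04-0.10): species occupy about one aridity band
#'   at the default planted_k while still overlapping their neighbours,
#'   so composition orders the bands along the gradient.
#' @param radius_km range radii drawn uniformly in this interval (km).
#' @param min_species richness filter threshold passed on.
#' @return list with `occurrences` ([occurrence_table()]), `registry`
#'   (site_id, lon, lat, cell), and `species` (data.frame of niche
#'   parameters).
#' @export
generate_community <- function(stack, truth, n_sites = 150,
                               n_species = 600, seed = 1, p_max = 0.6,
                               sigma_frac = c(0.04, 0.10),
                               radius_km = c(200, 450), min_species = 5) {
  stopifnot(inherits(stack, "env_stack"), inherits(truth, "synthetic_truth"))
  with_seed(seed, {
    cells <- grid_cells(stack$geometry)
    valid <- which(truth$ai$mask)
    if (n_sites > length(valid)) stop("n_sites exceeds valid cells")
    site_cells <- sort(sample(valid, n_sites))
    reg <- data.frame(site_id = sprintf("S%04d", seq_len(n_sites)),
                      lon = cells$lon[site_cells],
                      lat = cells$lat[site_cells],
                      cell = site_cells, stringsAsFactors = FALSE)
    ai_site <- truth$ai$values[site_cells]
    ai_rng <- range(truth$ai$values[truth$ai$mask])
    span <- diff(ai_rng)

    mu <- stats::runif(n_species, ai_rng[1] - 0.05 * span,
                       ai_rng[2] + 0.05 * span)
    sigma <- stats::runif(n_species, sigma_frac[1], sigma_frac[2]) * span
    center <- sample(valid, n_species, replace = TRUE)
    radius <- stats::runif(n_species, radius_km[1], radius_km[2])
    spp_names <- sprintf("sp%04d", seq_len(n_species))

    d_site_center <- haversine_km(reg[, c("lon", "lat")],
                                  cells[center, c("lon", "lat")])
    niche <- exp(-outer(ai_site, mu, "-")^2 /
                   matrix(2 * sigma^2, n_sites, n_species, byrow = TRUE))
    prob <- p_max * niche * (d_site_center <=
                               matrix(radius, n_sites, n_species,
                                      byrow = TRUE))
    inc <- matrix(as.integer(stats::runif(length(prob)) < prob),
                  n_sites, n_species,
                  dimnames = list(reg$site_id, spp_names))
    inc <- inc[, colSums(inc) > 0, drop = FALSE]
    occ <- filter_localities(occurrence_table(inc),
                             min_species = min_species, quiet = TRUE)
    if (nrow(occ$incidence) < 2)
      stop("degenerate configuration: fewer than 2 sites survive filtering")
    reg <- reg[reg$site_id %in% rownames(occ$incidence), , drop = FALSE]
    rownames(reg) <- NULL
    list(occurrences = occ, registry = reg,
         species = data.frame(species = spp_names, mu = mu, sigma = sigma,
                              center = center, radius = radius,
                              stringsAsFactors = FALSE))
  })
}
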