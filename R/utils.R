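# Shared internal helpers: distances, seeds, small utilities.

# Haversine distance in km between two coordinate sets (lon/lat, degrees).
# a, b: matrices or data.frames with columns lon, lat. Returns the full
# nrow(a) x nrow(b) distance matrix.
haversine_km <- function(a, b) {
  a <- as.matrix(a[, c("lon", "lat")])
  b <- as.matrix(b[, c("lon", "lat")])
  out <- matrix(0, nrow(a), nrow(b))
  for (j in seq_len(nrow(b))) {
    out[, j] <- geosphere::distHaversine(a, b[j, ]) / 1000
  }
  out
}

# Pairwise haversine distances among one coordinate set (symmetric, km).
haversine_pairwise <- function(xy) {
  haversine_km(xy, xy)
}

# All stochastic stages derive their seed from one run seed plus a fixed
# per-stage offset, so any stage can be re-run in isolation.
stage_seeds <- function(seed) {
  seed <- as.integer(seed)
  list(landscape = seed + 1L, community = seed + 2L, nmds = seed + 3L,
       consensus = seed + 4L, kmeans = seed + 5L, mem = seed + 6L,
       bootstrap = seed + 7L, permanova = seed + 8L)
}

# Run code under a local RNG state so package functions do not disturb the
# caller's random stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
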