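# Shared fixtures and independent oracles, built in code at test time.

# occurrence table from a named list of species vectors
occ_from_lists <- function(lists) {
  spp <- sort(unique(unlist(lists)))
  m <- t(sapply(lists, function(v) as.integer(spp %in% v)))
  colnames(m) <- spp
  occurrence_table(m)
}

# independent set-operation oracle for beta-sim
simpson_oracle <- function(set_i, set_j) {
  a <- length(intersect(set_i, set_j))
  b <- length(setdiff(set_i, set_j))
  c_ <- length(setdiff(set_j, set_i))
  if (min(b, c_) + a == 0) return(0)
  min(b, c_) / (min(b, c_) + a)
}

# random binary incidence with guaranteed non-empty rows
random_incidence <- function(n_sites, n_species, fill = 0.2, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rbinom(n_sites * n_species, 1, fill), n_sites, n_species)
    empty <- rowSums(m) == 0
    m[cbind(which(empty), sample(n_species, sum(empty), TRUE))] <- 1L
    dimnames(m) <- list(sprintf("s%03d", seq_len(n_sites)),
                        sprintf("sp%03d", seq_len(n_species)))
    m
  })
}

# small site registry on a regular grid of coordinates
toy_registry <- function(n, seed = 1) {
  withr::with_seed(seed, {
    data.frame(site_id = sprintf("s%03d", seq_len(n)),
               lon = runif(n, -43, -41), lat = runif(n, -11, -9),
               stringsAsFactors = FALSE)
  })
}

# regular ring of sites near the equator (spatial eigenfunction tests)
ring_registry <- function(n, radius_deg = 0.5) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  data.frame(site_id = sprintf("r%02d", seq_len(n)),
             lon = -42 + radius_deg * cos(th),
             lat = 0 + radius_deg * sin(th))
}

# constant surface helper
const_surface <- function(geom, value) {
  grid_surface(geom, rep(value, geom$n_rows * geom$n_cols))
}

# a small cached synthetic world shared by several test files
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      land <- generate_landscape(
        landscape_config(n_rows = 30, n_cols = 30, planted_k = 4),
        seed = 42)
      comm <- generate_community(land$stack, land$truth, n_sites = 70,
                                 n_species = 250, seed = 43)
      cache <<- list(land = land, comm = comm)
    }
    cache
  }
})
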