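#' Site-by-species incidence table
#'
#' Binary presence/absence matrix with lexicographically ordered sites and
#' species, the primary input of the regionalization pipeline.
#'
#' @param incidence binary matrix, sites in rows (rownames = site ids),
#'   species in columns (colnames = species names).
#' @return object of class `occurrence_table`.
#' @export
occurrence_table <- function(incidence) {
  incidence <- as.matrix(incidence)
  if (is.null(rownames(incidence)) || is.null(colnames(incidence)))
    stop("incidence needs site rownames and species colnames")
  if (!all(incidence %in% c(0, 1)))
    stop("incidence must be binary")
  if (anyDuplicated(rownames(incidence)))
    stop("duplicated site ids")
  if (anyDuplicated(colnames(incidence)))
    stop("duplicated species names")
  incidence <- incidence[order(rownames(incidence)),
                         order(colnames(incidence)), drop = FALSE]
  storage.mode(incidence) <- "integer"
  structure(list(incidence = incidence), class = "occurrence_table")
}

#' @export
print.occurrence_table <- function(x, ...) {
  m <- x$incidence
  cat(sprintf("occurrence_table: %d sites x %d species, fill %.1f%%\n",
              nrow(m), ncol(m), 100 * mean(m)))
  invisible(x)
}

#' Read a long-format occurrence CSV
#'
#' Expects columns `site_id` and `species`; each row records one presence.
#' Duplicated (site, species) pairs are collapsed to a single presence and
#' sites/species are ordered lexicographically, so the result does not
#' depend on row order in the file.
#'
#' @param path CSV file path.
#' @return an [occurrence_table()].
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty occurrence file")
  if (!all(c("site_id", "species") %in% names(df)))
    stop("occurrence CSV needs columns 'site_id' and 'species'")
  df <- unique(df[, c("site_id", "species")])
  sites <- sort(unique(as.character(df$site_id)))
  spp <- sort(unique(as.character(df$species)))
  m <- matrix(0L, length(sites), length(spp),
              dimnames = list(sites, spp))
  m[cbind(match(df$site_id, sites), match(df$species, spp))] <- 1L
  occurrence_table(m)
}

#' Read a site registry CSV
#'
#' Columns `site_id`, `lon`, `lat` (decimal degrees WGS84).
#'
#' @param path CSV file path.
#' @return data.frame ordered by `site_id`.
#' @export
read_site_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("site_id", "lon", "lat") %in% names(df)))
    stop("registry CSV needs columns 'site_id', 'lon', 'lat'")
  validate_registry(df)
}

validate_registry <- function(df) {
  df$site_id <- as.character(df$site_id)
  if (anyDuplicated(df$site_id)) stop("duplicated site ids in registry")
  if (any(df$lon < -180 | df$lon > 180) || any(df$lat < -90 | df$lat > 90))
    stop("coordinates outside WGS84 bounds")
  df <- df[order(df$site_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Drop species-poor localities
#'
#' Sites with fewer than `min_species` species are removed (compiled
#' floristic datasets routinely exclude such under-sampled localities),
#' then species left with no occurrence are dropped.
#'
#' @param t an [occurrence_table()].
#' @param min_species minimum site richness retained (default 5).
#' @param quiet suppress the removal report message.
#' @return filtered [occurrence_table()] with attribute `removed`, a list
#'   of dropped site ids and species names.
#' @export
filter_localities <- function(t, min_species = 5, quiet = FALSE) {
  stopifnot(inherits(t, "occurrence_table"))
  m <- t$incidence
  keep_sites <- rowSums(m) >= min_species
  if (!any(keep_sites)) stop("all sites removed by richness filter")
  m2 <- m[keep_sites, , drop = FALSE]
  keep_spp <- colSums(m2) > 0
  dropped_sites <- rownames(m)[!keep_sites]
  dropped_spp <- colnames(m2)[!keep_spp]
  m2 <- m2[, keep_spp, drop = FALSE]
  if (!quiet && (length(dropped_sites) || length(dropped_spp)))
    message(sprintf("filter_localities: dropped %d site(s), %d species",
                    length(dropped_sites), length(dropped_spp)))
  out <- occurrence_table(m2)
  attr(out, "removed") <- list(sites = dropped_sites,
                               species = dropped_spp)
  out
}
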