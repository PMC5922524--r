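#' Pairwise Simpson (beta-sim) turnover among sites
#'
#' For sites i and j with a shared species, b species only in i and c
#' species only in j, beta-sim = min(b, c) / (min(b, c) + a). The index
#' measures pure turnover: it is 0 whenever one site's flora is nested in
#' the other's, making it insensitive to richness differences — the
#' property that recommends it for regionalization. When two sites share
#' no species and at least one has none exclusive (a + min(b, c) = 0) the
#' value is defined as 0.
#'
#' @param t an [occurrence_table()] with at least two sites, each holding
#'   at least one species.
#' @return object of class `dissimilarity_matrix`: list with `labels` and
#'   symmetric matrix `d` with zero diagonal, values in [0, 1].
#' @export
simpson_dissimilarity <- function(t) {
  stopifnot(inherits(t, "occurrence_table"))
  m <- t$incidence
  if (nrow(m) < 2) stop("need at least two sites")
  if (any(rowSums(m) == 0)) stop("empty site row; filter localities first")
  a <- m %*% t(m)                       # shared species counts
  rich <- rowSums(m)
  b <- outer(rich, rep(1, nrow(m))) - a # exclusive to i
  c_ <- t(b)                            # exclusive to j
  minbc <- pmin(b, c_)
  denom <- minbc + a
  d <- ifelse(denom == 0, 0, minbc / denom)
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  structure(list(labels = rownames(m), d = d),
            class = "dissimilarity_matrix")
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  v <- x$d[upper.tri(x$d)]
  cat(sprintf("dissimilarity_matrix: %d labels, beta-sim range [%.3f, %.3f], mean %.3f\n",
              length(x$labels), min(v), max(v), mean(v)))
  invisible(x)
}

as_dissimilarity_matrix <- function(d, labels = NULL) {
  d <- as.matrix(d)
  if (is.null(labels)) labels <- rownames(d) %||% as.character(seq_len(nrow(d)))
  dimnames(d) <- list(labels, labels)
  stopifnot(isSymmetric(unname(d)), all(abs(diag(d)) < 1e-12))
  structure(list(labels = labels, d = d), class = "dissimilarity_matrix")
}

#' Write / read a dissimilarity matrix as labeled square CSV
#' @param x a `dissimilarity_matrix`.
#' @param path CSV file.
#' @export
write_dissimilarity <- function(x, path) {
  utils::write.csv(as.data.frame(x$d), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_dissimilarity
#' @export
read_dissimilarity <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as_dissimilarity_matrix(as.matrix(df))
}

#' Shared and exclusive species among site groups
#'
#' Pools member sites' species lists into one list per group (set union)
#' and tabulates total, exclusive and pairwise shared species counts —
#' the quantities drawn as a turnover network (circle sizes proportional
#' to totals, line widths to shared counts).
#'
#' @param t an [occurrence_table()].
#' @param site_group vector of group labels, one per site (named by site
#'   id or in site order).
#' @return object of class `turnover_network`: `groups`, `total_species`,
#'   `exclusive_species`, symmetric `shared` count matrix (diagonal =
#'   totals), and the pooled `group_incidence` matrix.
#' @export
shared_species_counts <- function(t, site_group) {
  stopifnot(inherits(t, "occurrence_table"))
  m <- t$incidence
  if (!is.null(names(site_group))) {
    if (!all(rownames(m) %in% names(site_group)))
      stop("unlabeled site(s): ",
           paste(setdiff(rownames(m), names(site_group)), collapse = ", "))
    site_group <- site_group[rownames(m)]
  }
  if (length(site_group) != nrow(m)) stop("one label per site required")
  if (anyNA(site_group)) stop("unlabeled site (NA group)")
  g <- factor(site_group)
  gi <- t(sapply(levels(g), function(lv) {
    as.integer(colSums(m[g == lv, , drop = FALSE]) > 0)
  }))
  colnames(gi) <- colnames(m)
  shared <- gi %*% t(gi)
  total <- diag(shared)
  npres <- colSums(gi)
  exclusive <- sapply(seq_len(nrow(gi)), function(i)
    sum(gi[i, ] == 1 & npres == 1))
  structure(list(groups = levels(g), total_species = total,
                 exclusive_species = stats::setNames(exclusive, levels(g)),
                 shared = shared, group_incidence = gi),
            class = "turnover_network")
}

#' @export
print.turnover_network <- function(x, ...) {
  cat(sprintf("turnover_network: %d groups, totals %s, exclusives %s\n",
              length(x$groups),
              paste(x$total_species, collapse = "/"),
              paste(x$exclusive_species, collapse = "/")))
  invisible(x)
}
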