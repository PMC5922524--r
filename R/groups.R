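#' UPGMA dendrogram of sub-region floras
#'
#' Average-linkage agglomerative clustering of a group-level Simpson
#' dissimilarity matrix (via [stats::hclust()], method "average"), so
#' merge heights are mean between-cluster dissimilarities and the
#' cophenetic distances are ultrametric.
#'
#' @param d a `dissimilarity_matrix` over >= 3 groups.
#' @return object of class `upgma_tree`: the `hclust` object, the
#'   [ape::as.phylo()] tree, and `labels`.
#' @export
upgma <- function(d) {
  stopifnot(inherits(d, "dissimilarity_matrix"))
  if (nrow(d$d) < 3) stop("need at least 3 groups")
  if (anyNA(d$d)) stop("NaN in dissimilarity matrix")
  hc <- stats::hclust(stats::as.dist(d$d), method = "average")
  structure(list(hclust = hc, phylo = ape::as.phylo(hc),
                 labels = d$labels),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("upgma_tree over %d groups, merge heights %.3f..%.3f\n",
              length(x$labels), min(x$hclust$height),
              max(x$hclust$height)))
  invisible(x)
}

#' Cophenetic distance matrix of a UPGMA tree
#' @param tree an [upgma()] result.
#' @return `dissimilarity_matrix` of cophenetic distances.
#' @export
cophenetic_distances <- function(tree) {
  m <- as.matrix(stats::cophenetic(tree$hclust))
  m <- m[tree$labels, tree$labels]
  as_dissimilarity_matrix(m)
}

#' Bootstrap support for UPGMA nodes
#'
#' Resamples species columns of the group x species incidence with
#' replacement (species are the exchangeable unit for pooled group
#' lists), recomputes the group Simpson matrix and UPGMA tree for each
#' replicate, and scores every internal node of the original tree by the
#' fraction of replicate trees containing its leaf bipartition.
#' Replicates in which some group ends up with zero species are redrawn
#' (and counted).
#'
#' @param group_incidence binary group x species matrix (e.g. the
#'   `group_incidence` of [shared_species_counts()]).
#' @param n_boot number of bootstrap trees (default 1000).
#' @param seed integer seed.
#' @return object of class `bootstrap_support`: `tree` (the original
#'   [upgma()] result), `support` (per internal node, in
#'   [ape::prop.clades()] node order), `n_boot`, `n_redrawn`.
#' @export
bootstrap_support <- function(group_incidence, n_boot = 1000, seed = 1) {
  gi <- as.matrix(group_incidence)
  stopifnot(nrow(gi) >= 3, ncol(gi) >= 2)
  base_d <- group_simpson(gi)
  base_tree <- upgma(base_d)
  n_redrawn <- 0L
  trees <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      repeat {
        cols <- sample.int(ncol(gi), replace = TRUE)
        rep_gi <- gi[, cols, drop = FALSE]
        if (all(rowSums(rep_gi) > 0)) break
        n_redrawn <<- n_redrawn + 1L
      }
      upgma(group_simpson(rep_gi))$phylo
    })
  })
  counts <- ape::prop.clades(base_tree$phylo, trees, rooted = TRUE)
  counts[is.na(counts)] <- 0
  structure(list(tree = base_tree, support = counts / n_boot,
                 n_boot = n_boot, n_redrawn = n_redrawn),
            class = "bootstrap_support")
}

# Simpson dissimilarity between rows of a binary matrix (no filtering).
group_simpson <- function(m) {
  a <- m %*% t(m)
  rich <- rowSums(m)
  b <- outer(rich, rep(1, nrow(m))) - a
  minbc <- pmin(b, t(b))
  denom <- minbc + a
  d <- ifelse(denom == 0, 0, minbc / denom)
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  as_dissimilarity_matrix(d)
}

#' @export
print.bootstrap_support <- function(x, ...) {
  cat(sprintf("bootstrap_support: %d trees, node support %s\n", x$n_boot,
              paste(sprintf("%.2f", x$support), collapse = ", ")))
  invisible(x)
}

#' Write a supported dendrogram as Newick
#'
#' Internal-node bootstrap supports become node labels.
#'
#' @param bs a [bootstrap_support()] result (or an [upgma()] tree).
#' @param path output file.
#' @export
write_newick <- function(bs, path) {
  if (inherits(bs, "bootstrap_support")) {
    phy <- bs$tree$phylo
    phy$node.label <- sprintf("%.3f", bs$support)
  } else phy <- bs$phylo
  ape::write.tree(phy, file = path)
  invisible(path)
}
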