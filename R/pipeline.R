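#' Configuration for a full pipeline run
#'
#' Collects every stage's settings with the defaults used throughout the
#' package. All randomness is controlled by `seed`; each stage derives a
#' fixed sub-seed from it (see the manifest of [run_pipeline()]).
#'
#' @param seed master seed.
#' @param landscape a [landscape_config()] (synthetic input mode).
#' @param n_sites,n_species community size.
#' @param min_species locality richness filter.
#' @param nmds_axes,nmds_starts NMDS settings.
#' @param idw_power IDW exponent.
#' @param consensus_max_k cap on the consensus max-k scan (NULL = sites-1).
#' @param consensus_axes leading PCoA axes used in the scan (NULL = all).
#' @param kmeans_starts,kmeans_iter K-means settings.
#' @param buffer_km predictor aggregation radius.
#' @param n_perm permutation count for tests.
#' @param max_mem cap on selected spatial eigenvectors (default 8).
#' @param n_boot bootstrap tree count.
#' @param out_dir output directory (NULL = no files written).
#' @return named list of class `run_config`.
#' @export
run_config <- function(seed = 1, landscape = landscape_config(),
                       n_sites = 150, n_species = 600, min_species = 5,
                       nmds_axes = 3, nmds_starts = 20, idw_power = 2,
                       consensus_max_k = 40, consensus_axes = 10,
                       kmeans_starts = 50, kmeans_iter = 100,
                       buffer_km = 10, n_perm = 199, n_boot = 200,
                       max_mem = 8, out_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full regionalization and driver-inference pipeline
#'
#' Synthetic-input orchestration: generates a landscape and community,
#' computes Simpson turnover, 3-D NMDS, interpolates the axes, estimates
#' the number of sub-regions by L-method consensus on Cailliez-corrected
#' principal coordinates, partitions the interpolated surface by K-means,
#' assembles predictors, ranks multinomial driver models with AICc,
#' partitions the best model's deviance against spatial eigenvectors,
#' compares the partition against the planted truth with a two-way
#' PERMANOVA, and builds the group dendrogram and turnover network.
#' When `config$out_dir` is set, all artifacts (ASCII rasters, GeoJSON,
#' PNG, CSV, Newick, JSON manifest with file checksums) are written
#' there.
#'
#' @param config a [run_config()].
#' @return a list of stage results (class `pipeline_run`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seeds <- stage_seeds(config$seed)

  land <- generate_landscape(config$landscape, seed = seeds$landscape)
  comm <- generate_community(land$stack, land$truth,
                             n_sites = config$n_sites,
                             n_species = config$n_species,
                             seed = seeds$community,
                             min_species = config$min_species)

  d <- simpson_dissimilarity(comm$occurrences)
  ord <- nmds(d, n_axes = config$nmds_axes,
              n_starts = config$nmds_starts, seed = seeds$nmds)
  shep <- shepard_fit(d, ord)

  geom <- land$stack$geometry
  axes <- lapply(seq_len(config$nmds_axes), function(j)
    idw_interpolate(comm$registry, ord$scores[, j], geom,
                    power = config$idw_power))

  pco <- pcoa_cailliez(d)
  cons <- consensus_k(pco$scores, max_k = config$consensus_max_k,
                      n_starts = config$kmeans_starts,
                      max_iter = config$kmeans_iter,
                      n_axes = config$consensus_axes,
                      seed = seeds$consensus)

  part <- regionalize(axes[1:3], k = cons$modal_k,
                      n_starts = config$kmeans_starts,
                      max_iter = config$kmeans_iter, seed = seeds$kmeans)
  site_region <- site_regions(part, comm$registry)

  rgb <- rgb_compose(axes[[1]], axes[[2]], axes[[3]])

  preds <- predictor_table(land$stack, comm$registry,
                           radius_km = config$buffer_km)
  mems <- mem_basis(comm$registry, n_perm = config$n_perm,
                    seed = seeds$mem, max_mem = config$max_mem)
  mem_cols <- paste0("MEM", mems$selected)
  data <- cbind(preds$table,
                as.data.frame(mems$vectors[, mems$selected,
                                           drop = FALSE]))
  sets <- predictor_sets(colnames(preds$table))
  cands <- build_candidates(sets, mem_cols)
  models <- rank_models(factor(site_region), data, cands)

  best <- attr(models, "fits")[[models$name[1]]]
  env_cols <- cands$predictors[[match(models$name[1], cands$name)]]
  dev_part <- if (length(mem_cols))
    partition_deviance(factor(site_region),
                       data[, env_cols, drop = FALSE],
                       data[, mem_cols, drop = FALSE]) else NULL
  resid_cor <- residual_diagnostics(best, comm$registry,
                                    n_perm = config$n_perm,
                                    seed = seeds$permanova)

  truth_site <- land$truth$region_of_cell[comm$registry$cell]
  comparison <- compare_classifications(
    d, our_labels = site_region,
    alternatives = list(planted_truth = truth_site),
    physiognomy = cut_physiognomy(comm$registry, land),
    n_perm = config$n_perm, seed = seeds$permanova)

  net <- shared_species_counts(comm$occurrences,
                               stats::setNames(site_region,
                                               comm$registry$site_id))
  dend <- if (length(unique(site_region)) >= 3)
    bootstrap_support(net$group_incidence, n_boot = config$n_boot,
                      seed = seeds$bootstrap) else NULL

  run <- structure(list(
    config = config, land = land, community = comm, dissimilarity = d,
    nmds = ord, shepard = shep, axes = axes, pcoa = pco,
    consensus = cons, partition = part, site_region = site_region,
    rgb = rgb, predictors = preds, mems = mems, models = models,
    deviance_partition = dev_part, residual_correlogram = resid_cor,
    comparison = comparison, network = net, dendrogram = dend),
    class = "pipeline_run")
  if (!is.null(config$out_dir)) run$manifest <- write_run(run)
  run
}

#' Default grouping of predictors into hypothesis families
#'
#' Soil, topography, current climate (aridity), historical climate and
#' human footprint; only families with at least one present column are
#' returned.
#'
#' @param cols predictor column names available.
#' @return named list of character vectors for [build_candidates()].
#' @export
predictor_sets <- function(cols) {
  sets <- list(
    soil = intersect(c("sand", "cec"), cols),
    topography = intersect(c("elevation", "elevation_cv"), cols),
    current = intersect("AI", cols),
    historical = intersect(c("HAI", "hydric_change", "thermal_change"),
                           cols),
    footprint = intersect("footprint", cols))
  sets[vapply(sets, length, integer(1)) > 0]
}

# placeholder physiognomy classification for synthetic runs: a coarse
# two-level vegetation-structure factor cut along the footprint layer
cut_physiognomy <- function(registry, land) {
  f <- land$stack$footprint$values[registry$cell]
  factor(ifelse(f > stats::median(f), "open", "wooded"))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run\n")
  cat(sprintf("  sites: %d   species: %d\n",
              nrow(x$community$occurrences$incidence),
              ncol(x$community$occurrences$incidence)))
  cat(sprintf("  NMDS stress: %.3f (non-metric R2 %.3f)\n",
              x$nmds$stress, x$shepard$nonmetric_r2))
  cat(sprintf("  planted k: %d   modal consensus k: %d\n",
              x$land$truth$planted_k, x$consensus$modal_k))
  cat(sprintf("  best driver model: %s (wAICc %.3f, explained deviance %.3f)\n",
              x$models$name[1], x$models$waicc[1],
              x$models$explained_deviance[1]))
  invisible(x)
}

#' Compare classification schemes with two-way PERMANOVAs
#'
#' One two-way PERMANOVA per alternative scheme, always entering the
#' physiognomic factor first, then the scheme, then their interaction;
#' the fraction of floristic variation (R2) each classification explains
#' is tabulated side by side with the package's own partition.
#'
#' @param d a `dissimilarity_matrix` among sites.
#' @param our_labels the package's sub-region label per site.
#' @param alternatives named list of alternative label vectors.
#' @param physiognomy factor entered first in every model.
#' @param n_perm,seed permutation settings.
#' @return object of class `classification_comparison`: data.frame with
#'   `scheme`, `r2`, `pseudo_f`, `p` for the scheme term, plus attribute
#'   `tables` holding the full PERMANOVA tables.
#' @export
compare_classifications <- function(d, our_labels, alternatives = list(),
                                    physiognomy, n_perm = 999, seed = 1) {
  schemes <- c(list(this_study = our_labels), alternatives)
  tabs <- lapply(seq_along(schemes), function(i) {
    permanova_2way(d, physiognomy, schemes[[i]], n_perm = n_perm,
                   seed = seed + i)
  })
  names(tabs) <- names(schemes)
  out <- do.call(rbind, lapply(names(tabs), function(nm) {
    row <- tabs[[nm]][tabs[[nm]]$term == "B", ]
    data.frame(scheme = nm, r2 = row$r2, pseudo_f = row$pseudo_f,
               p = row$p, stringsAsFactors = FALSE)
  }))
  structure(out, class = c("classification_comparison", "data.frame"),
            tables = tabs)
}

# Write all artifacts of a run; returns the manifest (also written as
# JSON with md5 checksums of every file).
write_run <- function(run) {
  dir.create(run$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(run$config$out_dir, f)

  for (j in seq_along(run$axes))
    write_esri_ascii(run$axes[[j]], out(sprintf("nmds_axis%d.asc", j)))
  write_esri_ascii(
    grid_surface(run$partition$geometry,
                 ifelse(is.na(run$partition$labels), 0,
                        run$partition$labels),
                 mask = !is.na(run$partition$labels)),
    out("regions.asc"))
  write_region_geojson(run$partition, out("regions.geojson"))
  write_rgb_png(run$rgb, out("composition_rgb.png"))
  write_dissimilarity(run$dissimilarity, out("simpson.csv"))
  utils::write.csv(data.frame(site_id = rownames(run$nmds$scores),
                              run$nmds$scores),
                   out("nmds_scores.csv"), row.names = FALSE)
  utils::write.csv(data.frame(max_k = seq_along(run$consensus$optimal_k) + 3,
                              optimal_k = run$consensus$optimal_k),
                   out("consensus_k.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(run$models), out("model_table.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(run$comparison), out("comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(run$residual_correlogram),
                   out("residual_correlogram.csv"), row.names = FALSE)
  utils::write.csv(data.frame(group = run$network$groups,
                              total = run$network$total_species,
                              exclusive = run$network$exclusive_species),
                   out("turnover_network.csv"), row.names = FALSE)
  if (!is.null(run$dendrogram))
    write_newick(run$dendrogram, out("dendrogram.nwk"))
  report <- list(
    seed = run$config$seed,
    sub_seeds = stage_seeds(run$config$seed),
    n_sites = nrow(run$community$occurrences$incidence),
    n_species = ncol(run$community$occurrences$incidence),
    stress = run$nmds$stress,
    nonmetric_r2 = run$shepard$nonmetric_r2,
    linear_r2 = run$shepard$linear_r2,
    modal_k = run$consensus$modal_k,
    planted_k = run$land$truth$planted_k,
    best_model = run$models$name[1],
    best_waicc = run$models$waicc[1],
    explained_deviance = run$models$explained_deviance[1],
    deviance_partition = if (!is.null(run$deviance_partition))
      unclass(run$deviance_partition) else NULL)
  jsonlite::write_json(report, out("run_report.json"),
                       auto_unbox = TRUE, digits = 12)
  files <- list.files(run$config$out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(files = data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)
  manifest
}
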