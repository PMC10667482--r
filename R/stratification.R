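#' Stratify one study group into two microbiota sub-clusters
#'
#' Within a single patient group, every genus is rank-normalised across the
#' subgroup's samples, sample-sample relatedness is measured by Spearman
#' correlation of those rank-normalised profiles, and Ward-D2 hierarchical
#' clustering of `1 - rho` is cut at `k = 2`. The procedure is deterministic.
#' When the subgroup is homogeneous the split is arbitrary; a mean silhouette
#' width below 0.25 triggers a warning to flag this (the threshold sits well
#' above the silhouettes seen on structureless simulated cohorts and well
#' below those of clearly two-configuration ones).
#'
#' @param t an `abundance_table` restricted to the samples of one group,
#'   with at least `2 k` samples.
#' @param k number of sub-clusters (fixed at 2 for the intended use).
#' @return list with `cluster` (named integer vector sample -> 1..k),
#'   `silhouette` (mean silhouette width) and `tree`.
#' @export
stratify_group <- function(t, k = 2) {
  if (nrow(t) < 2 * k)
    stop("need at least ", 2 * k, " samples to form ", k, " clusters")
  rn <- suppressWarnings(rank_normalize_table(t))
  rho <- spearman_matrix(rn, axis = "samples")
  diss <- 1 - rho
  diag(diss) <- 0
  tree <- stats::hclust(stats::as.dist(diss), method = "ward.D2")
  cl <- stats::cutree(tree, k = k)
  sil <- mean(cluster::silhouette(cl, stats::as.dist(diss))[, "sil_width"])
  if (sil < 0.25)
    warning(sprintf(paste("mean silhouette width %.3f < 0.25:",
                          "sub-cluster structure is weak and the split may be",
                          "arbitrary"), sil))
  list(cluster = cl, silhouette = sil, tree = tree)
}

#' Label sub-clusters as normal-like or disease-like
#'
#' Given a two-way split of one group and the median-centroid distances from
#' the FULL cohort's reference (control) ordination, the cluster whose
#' members lie on average closer to the control centroid is labelled
#' `NM-like` (normal microbiota) and the other `CDM-like` (Crohn's-disease
#' microbiota). Mean distance is the primary criterion; exact ties fall back
#' to the median, and a tie there is an error.
#'
#' @param clusters named integer vector (sample -> 1 or 2) from
#'   [stratify_group()].
#' @param cd a [median_centroid()] result from the full-cohort ordination,
#'   covering every stratified sample.
#' @return object of class `stratification`: list with `cluster`, `labels`
#'   (cluster id -> label), `label` (per-sample label), `evidence` (per-cluster
#'   mean centroid distance) and `sizes`.
#' @export
label_clusters <- function(clusters, cd) {
  ids <- names(clusters)
  missing <- setdiff(ids, names(cd$distance))
  if (length(missing))
    stop("no ordination coordinates for sample(s): ",
         paste(missing, collapse = ", "))
  dist <- cd$distance[ids]
  mean_d <- tapply(dist, clusters, mean)
  if (length(mean_d) != 2) stop("expected exactly 2 clusters")
  ord <- order(mean_d)
  if (mean_d[ord[1]] == mean_d[ord[2]]) {
    med_d <- tapply(dist, clusters, stats::median)
    ord <- order(med_d)
    if (med_d[ord[1]] == med_d[ord[2]])
      stop("clusters tie on mean and median centroid distance")
  }
  labels <- character(2)
  labels[as.integer(names(mean_d)[ord])] <- c("NM-like", "CDM-like")
  structure(list(cluster = clusters,
                 labels = stats::setNames(labels, seq_along(labels)),
                 label = stats::setNames(labels[clusters], ids),
                 evidence = mean_d,
                 sizes = table(clusters)),
            class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  cat("<stratification>\n")
  for (i in seq_along(x$labels))
    cat(sprintf("  cluster %d -> %s (n = %d, mean centroid distance %.3f)\n",
                i, x$labels[i], sum(x$cluster == i), x$evidence[[as.character(i)]]))
  invisible(x)
}

#' Replicate the two-configuration stratification in an external cohort
#'
#' Applies [stratify_group()] to an external genus table and labels the two
#' clusters by marker-set abundance instead of a centroid: per sample, the
#' summed relative abundance of a "normal" genus set and of a "CD-associated"
#' genus set are computed; the cluster with the higher mean normal-set
#' abundance is `NM-like`. Both marker sets are also compared between the
#' clusters by Wilcoxon tests.
#'
#' @param external_t an `abundance_table` for the external cohort (counts or
#'   relative; converted to relative internally).
#' @param normal_genera,cd_genera character vectors of marker genus ids.
#' @param min_overlap minimum fraction of each marker set that must be present
#'   in the external table (default 0.5).
#' @return a `stratification` object with extra elements `marker_abundance`
#'   (per-sample summed abundances) and `marker_tests` (Wilcoxon results).
#' @export
replicate_stratification <- function(external_t, normal_genera, cd_genera,
                                     min_overlap = 0.5) {
  tt <- if (table_mode(external_t) == "counts") to_relative(external_t) else external_t
  present_n <- intersect(normal_genera, genus_ids(tt))
  present_c <- intersect(cd_genera, genus_ids(tt))
  for (nm in list(c("normal", length(present_n), length(normal_genera)),
                  c("cd", length(present_c), length(cd_genera)))) {
    frac <- as.numeric(nm[2]) / as.numeric(nm[3])
    if (frac < min_overlap)
      stop("external table shares only ", round(100 * frac), "% of the ",
           nm[1], " marker set; missing: ",
           paste(setdiff(if (nm[1] == "normal") normal_genera else cd_genera,
                         genus_ids(tt)), collapse = ", "))
  }
  strat <- stratify_group(tt, k = 2)
  cl <- strat$cluster
  normal_ab <- rowSums(unclass(tt)[, present_n, drop = FALSE])
  cd_ab <- rowSums(unclass(tt)[, present_c, drop = FALSE])
  mean_normal <- tapply(normal_ab, cl, mean)
  ord <- order(mean_normal, decreasing = TRUE)
  labels <- character(2)
  labels[as.integer(names(mean_normal)[ord])] <- c("NM-like", "CDM-like")
  tests <- rbind(
    cbind(marker_set = "normal_genera",
          wilcoxon_rank_sum(normal_ab[cl == 1], normal_ab[cl == 2])),
    cbind(marker_set = "cd_genera",
          wilcoxon_rank_sum(cd_ab[cl == 1], cd_ab[cl == 2])))
  structure(list(cluster = cl,
                 labels = stats::setNames(labels, seq_along(labels)),
                 label = stats::setNames(labels[cl], names(cl)),
                 evidence = mean_normal,
                 sizes = table(cl),
                 silhouette = strat$silhouette,
                 marker_abundance = data.frame(sample_id = names(cl),
                                               normal = normal_ab, cd = cd_ab,
                                               row.names = NULL),
                 marker_tests = tests),
            class = "stratification")
}
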