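#' Diet-pattern ordination with centroid distances and PERMANOVA
#'
#' Runs the dietary arm of the pipeline with the same machinery as the
#' microbiota arm, swapping the metric: Kendall-tau distances between
#' food-frequency profiles, PCoA, median-centroid distances from the
#' reference group, and a PERMANOVA on the diet distances.
#'
#' @param d numeric matrix, samples x food items (daily consumption
#'   frequencies).
#' @param metadata data frame with `sample_id`, `group` and any confounders.
#' @param reference reference group for the median centroid (default
#'   "control").
#' @param confounders PERMANOVA confounder terms (default none).
#' @param n_perm,seed passed to [permanova()].
#' @return list with `distance`, `ordination`, `centroid` and `permanova`.
#' @export
diet_ordination <- function(d, metadata, reference = "control",
                            confounders = character(), n_perm = 999,
                            seed = 1L) {
  dist <- kendall_tau_distance(d)
  ord <- pcoa(dist, k = 2)
  cd <- median_centroid(ord, reference, metadata)
  pm <- permanova(dist, metadata, terms = c(confounders, "group"),
                  term_of_interest = "group", n_perm = n_perm, seed = seed)
  list(distance = dist, ordination = ord, centroid = cd, permanova = pm)
}

#' Correlate food-item consumption with a dietary centroid distance
#'
#' Per item, the Spearman correlation between consumption frequency and the
#' per-sample distance from a group's median dietary centroid, BH-corrected
#' across items. A significant negative correlation marks an item whose
#' consumption rises the closer a sample sits to that group's typical
#' pattern, i.e. an item associated with the group's diet; positive
#' correlations mark items least associated with it.
#'
#' @param d numeric matrix, samples x food items.
#' @param cd a [median_centroid()] result on a dietary ordination.
#' @return data frame: item, rho, p, q (constant items skipped with warning).
#' @export
item_centroid_correlation <- function(d, cd) {
  ids <- intersect(rownames(d), names(cd$distance))
  if (!length(ids)) stop("no shared samples")
  D <- d[ids, , drop = FALSE]
  dist <- cd$distance[ids]
  const <- apply(D, 2, function(v) max(v) == min(v))
  if (any(const))
    warning("constant item(s) skipped: ",
            paste(colnames(D)[const], collapse = ", "))
  D <- D[, !const, drop = FALSE]
  res <- lapply(colnames(D), function(it) {
    ct <- suppressWarnings(stats::cor.test(D[, it], dist, method = "spearman"))
    data.frame(item = it, rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- benjamini_hochberg(out$p)
  out
}

#' Pairwise group comparisons of food-item consumption
#'
#' For every food item and every pair of groups, a Wilcoxon test of
#' consumption frequency; BH correction spans the full item-by-pair grid.
#' Direction is the group with the higher median consumption.
#'
#' @param d numeric matrix, samples x food items.
#' @param metadata data frame with `sample_id` and `group` (or a named group
#'   vector).
#' @return data frame: item, pair, statistic, p, q, higher_in.
#' @export
item_group_tests <- function(d, metadata) {
  groups <- resolve_groups(metadata, rownames(d))
  lv <- levels(droplevels(groups))
  if (length(lv) < 2) stop("need at least 2 groups")
  pairs <- utils::combn(lv, 2)
  rows <- list()
  for (it in colnames(d)) for (i in seq_len(ncol(pairs))) {
    a <- d[groups == pairs[1, i], it]
    b <- d[groups == pairs[2, i], it]
    wt <- wilcoxon_rank_sum(a, b)
    med <- c(stats::median(a), stats::median(b))
    higher <- if (med[1] == med[2]) NA_character_ else pairs[which.max(med), i]
    rows[[length(rows) + 1L]] <-
      data.frame(item = it, pair = paste(pairs[1, i], "vs", pairs[2, i]),
                 statistic = wt$statistic, p = wt$p, higher_in = higher,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- benjamini_hochberg(out$p)
  out[, c("item", "pair", "statistic", "p", "q", "higher_in")]
}
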