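#' Detect co-abundance groups (CAGs)
#'
#' Genera are clustered by Ward-D2 agglomeration on `1 - rho`, where `rho` is
#' the genus-level Spearman correlation matrix, and the dendrogram is cut to
#' exactly `k` clusters. `1 - rho` is not guaranteed Euclidean; set
#' `sqrt_transform = TRUE` to cluster on `sqrt(1 - rho)` instead, which is a
#' metric whenever `1 - rho` satisfies the triangle inequality.
#'
#' @param t an `abundance_table` with >= k genera and >= 3 samples.
#' @param k number of co-abundance groups (default 4).
#' @param sqrt_transform cluster on the square-root dissimilarity.
#' @return object of class `cag_assignment`: list with `cluster` (named
#'   integer vector genus -> 1..k), `k`, `tree` (the `hclust` object) and
#'   `heights` (merge heights).
#' @export
detect_cags <- function(t, k = 4, sqrt_transform = FALSE) {
  if (k > ncol(t)) stop("k exceeds the number of genera")
  if (nrow(t) < 3) stop("need at least 3 samples")
  rho <- spearman_matrix(t, axis = "genera")
  diss <- 1 - rho
  if (sqrt_transform) diss <- sqrt(pmax(diss, 0))
  tree <- stats::hclust(stats::as.dist(diss), method = "ward.D2")
  cl <- stats::cutree(tree, k = k)
  structure(list(cluster = cl, k = k, tree = tree, heights = tree$height),
            class = "cag_assignment")
}

#' @export
print.cag_assignment <- function(x, ...) {
  cat(sprintf("<cag_assignment> %d genera in %d CAGs (sizes: %s)\n",
              length(x$cluster), x$k,
              paste(tabulate(x$cluster, x$k), collapse = ", ")))
  invisible(x)
}

#' Per-sample CAG relative abundances
#'
#' Sums each sample's member-genus proportions within every CAG. With a full
#' assignment the k CAG abundances of a sample sum to 1.
#'
#' @param t a relative-mode `abundance_table`.
#' @param assignment a [detect_cags()] result covering every genus in `t`.
#' @return numeric matrix, samples x k, columns `CAG1..CAGk`.
#' @export
cag_abundance <- function(t, assignment) {
  if (table_mode(t) != "relative") stop("cag_abundance requires relative mode")
  missing <- setdiff(genus_ids(t), names(assignment$cluster))
  if (length(missing))
    stop("genus (genera) missing from the CAG assignment: ",
         paste(missing, collapse = ", "))
  cl <- assignment$cluster[genus_ids(t)]
  out <- t(rowsum(t(unclass(t)), group = cl))
  colnames(out) <- paste0("CAG", colnames(out))
  full <- matrix(0, nrow(out), assignment$k,
                 dimnames = list(rownames(out), paste0("CAG", seq_len(assignment$k))))
  full[, colnames(out)] <- out
  full
}

#' Correlate CAG member genera with the reference-centroid distance
#'
#' For every genus, the Spearman correlation between its abundance and the
#' per-sample distance from a reference median centroid; results are grouped
#' by CAG so the correlation distributions can be compared across CAGs
#' (negative values mark genera associated with the reference community
#' configuration). `mode = "summed"` instead correlates each CAG's summed
#' relative abundance with the distance.
#'
#' @param t a relative-mode `abundance_table`.
#' @param assignment a [detect_cags()] result.
#' @param cd a [median_centroid()] result on the same samples.
#' @param mode `"member"` (default, one correlation per genus) or `"summed"`.
#' @return data frame: genus (or CAG), cag, rho.
#' @export
cag_centroid_correlation <- function(t, assignment, cd,
                                     mode = c("member", "summed")) {
  mode <- match.arg(mode)
  ids <- sample_ids(t)
  if (!all(ids %in% names(cd$distance)))
    stop("centroid distances missing for some samples")
  dist <- cd$distance[ids]
  if (max(dist) == min(dist)) stop("constant centroid-distance vector")
  if (mode == "member") {
    rho <- apply(unclass(t), 2, function(x)
      suppressWarnings(stats::cor(x, dist, method = "spearman")))
    rho[is.na(rho)] <- 0
    data.frame(genus = genus_ids(t),
               cag = assignment$cluster[genus_ids(t)],
               rho = rho, row.names = NULL, stringsAsFactors = FALSE)
  } else {
    ca <- cag_abundance(t, assignment)
    rho <- apply(ca, 2, function(x)
      suppressWarnings(stats::cor(x, dist, method = "spearman")))
    rho[is.na(rho)] <- 0
    data.frame(cag = seq_len(assignment$k), rho = rho,
               row.names = NULL, stringsAsFactors = FALSE)
  }
}
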