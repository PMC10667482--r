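#' Rank normalisation of a feature across samples
#'
#' Maps a vector of abundances to `[0, 1]` by average-tie ranking followed by
#' an affine rescale: `(rank(x) - min(rank(x))) / (max(rank(x)) - min(rank(x)))`.
#' A constant vector has no rank spread; it is mapped to all zeros with a
#' warning so degenerate simulated genera do not halt a pipeline.
#'
#' @param x numeric vector of length >= 2.
#' @return numeric vector in `[0, 1]` of the same length.
#' @export
rank_normalize <- function(x) {
  if (length(x) < 2) stop("rank_normalize needs at least 2 values")
  r <- rank(x, ties.method = "average")
  span <- max(r) - min(r)
  if (span == 0) {
    warning("constant vector: rank normalisation returns all zeros")
    return(rep(0, length(x)))
  }
  (r - min(r)) / span
}

#' Rank-normalise every genus of an abundance table
#' @param t an `abundance_table`.
#' @return numeric matrix, samples x genera, each column in `[0, 1]`.
#' @export
rank_normalize_table <- function(t) {
  m <- unclass(t)
  out <- apply(m, 2, rank_normalize)
  dimnames(out) <- dimnames(m)
  out
}

new_dist_matrix <- function(values, ids, metric) {
  values <- as.matrix(values)
  dimnames(values) <- list(ids, ids)
  structure(values, metric = metric,
            class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d samples, metric = %s\n",
              nrow(x), attr(x, "metric")))
  invisible(x)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(i, j) = sum_g |x_ig - x_jg| / sum_g (x_ig + x_jg)` over genera. Computed
#' on the values as given; microbiome practice is to supply per-sample
#' relative abundances (see [to_relative()]).
#'
#' @param t an `abundance_table` with no all-zero samples.
#' @return a symmetric `dist_matrix` with zero diagonal, values in `[0, 1]`.
#' @export
bray_curtis <- function(t) {
  m <- unclass(t)
  if (any(m < 0)) stop("Bray-Curtis requires non-negative values")
  if (any(rowSums(m) == 0))
    stop("all-zero sample(s): ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  new_dist_matrix(d, rownames(m), "bray_curtis")
}

#' Kendall-tau distance between dietary profiles
#'
#' For each pair of samples the tie-corrected Kendall correlation (tau-b)
#' between their food-item frequency vectors is computed and mapped to a
#' distance by `(1 - tau) / 2`, so identical rankings give 0 and exactly
#' reversed rankings give 1.
#'
#' @param d numeric matrix, samples x food items (>= 2 items).
#' @return a symmetric `dist_matrix` with values in `[0, 1]`.
#' @export
kendall_tau_distance <- function(d) {
  if (ncol(d) < 2) stop("need at least 2 food items")
  const <- apply(d, 1, function(v) max(v) == min(v))
  if (any(const))
    stop("constant diet vector(s), tau undefined: ",
         paste(rownames(d)[const], collapse = ", "))
  tau <- suppressWarnings(stats::cor(t(d), method = "kendall"))
  dist <- (1 - tau) / 2
  diag(dist) <- 0
  new_dist_matrix(dist, rownames(d), "kendall_tau")
}

#' Spearman correlation matrix over genera or samples
#'
#' Average-rank Spearman correlations between the columns (genera) or rows
#' (samples) of an abundance table. Constant vectors have undefined
#' correlations; their entries are set to 0 with a warning (diagonal stays 1).
#'
#' @param t an `abundance_table` (or plain matrix, samples x features).
#' @param axis correlate `"genera"` (columns) or `"samples"` (rows).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(t, axis = c("genera", "samples")) {
  axis <- match.arg(axis)
  m <- unclass(t)
  if (axis == "samples") m <- t(m)
  if (nrow(m) < 3) stop("need at least 3 observations per correlated vector")
  const <- apply(m, 2, function(v) max(v) == min(v))
  rho <- suppressWarnings(stats::cor(m, method = "spearman"))
  if (any(const)) {
    warning("constant vector(s), correlations set to 0: ",
            paste(colnames(m)[const], collapse = ", "))
    rho[const, ] <- 0
    rho[, const] <- 0
  }
  rho[is.na(rho)] <- 0
  diag(rho) <- 1
  rho
}

#' Write / read a distance matrix as square TSV
#' @param d a `dist_matrix`.
#' @param path file path.
#' @export
write_dist_matrix <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), unclass(d), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @param metric metric tag to attach on read.
#' @export
read_dist_matrix <- function(path, metric = "bray_curtis") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  new_dist_matrix(m, as.character(df[[1]]), metric)
}
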