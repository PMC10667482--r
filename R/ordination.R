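#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering of the squared dissimilarities,
#' `B = -1/2 J D^2 J` with `J = I - 11'/n`, followed by eigendecomposition.
#' Coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues. Negative eigenvalues -- expected for semi-metric
#' dissimilarities such as Bray-Curtis -- are excluded from the
#' explained-variance denominator and reported alongside the result.
#'
#' @param d a `dist_matrix` (or any symmetric dissimilarity matrix with ids).
#' @param k number of axes to retain (>= 2). Truncated with a warning if it
#'   exceeds the number of positive eigenvalues.
#' @return an object of class `ordination`: list with `coordinates`
#'   (n x k, columns `PCo1..PCok`), `eigenvalues` (all, descending),
#'   `explained` (fraction per retained axis, over positive eigenvalues only),
#'   and `negative_eigenvalues`.
#' @export
pcoa <- function(d, k = 2) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (k < 1) stop("k must be >= 1")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  vals <- eig$values
  tol <- max(abs(vals)) * 1e-9
  pos <- which(vals > tol)
  if (length(pos) == 0) stop("no positive eigenvalues: degenerate distance matrix")
  if (k > length(pos)) {
    warning("k = ", k, " exceeds the ", length(pos),
            " positive eigenvalue(s); truncating")
    k <- length(pos)
  }
  axes <- pos[seq_len(k)]
  coords <- eig$vectors[, axes, drop = FALSE] %*% diag(sqrt(vals[axes]), k, k)
  dimnames(coords) <- list(rownames(D), paste0("PCo", seq_len(k)))
  structure(list(coordinates = coords,
                 eigenvalues = vals,
                 explained = vals[axes] / sum(vals[pos]),
                 negative_eigenvalues = vals[vals < -tol]),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> %d samples, %d axes; explained: %s\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}

resolve_groups <- function(metadata, ids) {
  if (is.data.frame(metadata)) {
    if (!all(c("sample_id", "group") %in% names(metadata)))
      stop("metadata must have sample_id and group columns")
    idx <- match(ids, as.character(metadata$sample_id))
    if (anyNA(idx)) stop("metadata missing sample(s): ",
                         paste(ids[is.na(idx)], collapse = ", "))
    g <- metadata$group[idx]
  } else {
    g <- metadata[ids]
    if (anyNA(g) && !anyNA(metadata))
      stop("group vector missing sample(s)")
  }
  factor(g)
}

#' Median-centroid distance from a reference group
#'
#' The centroid is the coordinate-wise median of the reference group's
#' samples on the first two ordination axes; every sample's distance
#' (including reference samples) is the Euclidean distance from that point in
#' the PCo1/PCo2 plane. `n_axes` generalises to more axes if desired.
#'
#' @param o an [pcoa()] `ordination`.
#' @param reference group label of the reference group.
#' @param metadata data frame with `sample_id` and `group` columns, or a
#'   named group vector covering the ordinated samples.
#' @param n_axes number of leading axes used (default 2).
#' @return object of class `centroid_distance`: list with `reference`,
#'   `centroid` and named per-sample `distance`.
#' @export
median_centroid <- function(o, reference, metadata, n_axes = 2) {
  coords <- o$coordinates
  n_axes <- min(n_axes, ncol(coords))
  groups <- resolve_groups(metadata, rownames(coords))
  ref <- which(groups == reference)
  if (length(ref) == 0) stop("reference group '", reference,
                             "' absent from the ordination")
  centroid <- apply(coords[ref, seq_len(n_axes), drop = FALSE], 2, stats::median)
  delta <- sweep(coords[, seq_len(n_axes), drop = FALSE], 2, centroid)
  structure(list(reference = reference,
                 centroid = centroid,
                 distance = sqrt(rowSums(delta^2))),
            class = "centroid_distance")
}

#' @export
print.centroid_distance <- function(x, ...) {
  cat(sprintf("<centroid_distance> reference = %s, %d samples\n",
              x$reference, length(x$distance)))
  invisible(x)
}

#' Test group differences in centroid distance
#'
#' Kruskal-Wallis with Dunn's post hoc (>= 3 groups) or Wilcoxon (2 groups)
#' on the per-sample median-centroid distances.
#'
#' @param cd a [median_centroid()] result.
#' @param metadata data frame with `sample_id`/`group`, or named group vector.
#' @return as [compare_groups()].
#' @export
centroid_group_test <- function(cd, metadata) {
  groups <- resolve_groups(metadata, names(cd$distance))
  compare_groups(cd$distance, groups)
}

#' PERMANOVA with confounder adjustment
#'
#' Sequential (Type-I) partitioning of the distance matrix's sum of squares,
#' with confounders entered before the term of interest and significance from
#' free permutation of sample labels (pseudo-F, `p = (1 + #{F* >= F}) /
#' (1 + n_perm)`). A confounder that nests the term of interest (a patient
#' identifier when each patient belongs to one group; a study that recruited
#' a single group) or that saturates the design is a finer partition than the
#' grouping: entered first it would absorb the entire effect of interest, so
#' such confounders are dropped from the model with a warning.
#' `restrict_within` offers the restricted-permutation alternative: the named
#' variable becomes a permutation block (samples are only exchanged within
#' its levels), the appropriate adjustment when the term of interest varies
#' within blocks.
#'
#' @param d a `dist_matrix`.
#' @param metadata data frame with `sample_id` plus covariate columns.
#' @param terms ordered character vector of model terms; the LAST one is the
#'   term of interest unless `term_of_interest` says otherwise.
#' @param term_of_interest name of the term whose pseudo-F is tested.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed for the permutations.
#' @param restrict_within optional term name treated as a permutation stratum
#'   instead of a model term.
#' @return object of class `permanova`: list with `table` (term, df, SS, R2,
#'   F, p), `term_of_interest`, `n_perm`, `seed`, `strata`, and `dropped`
#'   (confounders removed because they nest the term of interest or saturate
#'   the design).
#' @export
permanova <- function(d, metadata, terms, term_of_interest = terms[length(terms)],
                      n_perm = 999, seed = 1L, restrict_within = NULL) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  ids <- rownames(d)
  idx <- match(ids, as.character(metadata$sample_id))
  if (anyNA(idx)) stop("metadata missing sample(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  md <- metadata[idx, , drop = FALSE]
  missing_terms <- setdiff(terms, names(md))
  if (length(missing_terms))
    stop("metadata lacks term(s): ", paste(missing_terms, collapse = ", "))
  for (tm in terms) {
    if (is.character(md[[tm]]) || is.logical(md[[tm]]))
      md[[tm]] <- factor(md[[tm]])
    if (is.factor(md[[tm]])) {
      md[[tm]] <- droplevels(md[[tm]])
      if (nlevels(md[[tm]]) < 2)
        stop("term '", tm, "' has a single level")
    }
  }
  strata <- restrict_within
  terms <- setdiff(terms, restrict_within)
  dropped <- character()
  # a factor confounder whose levels each sit inside a single level of the
  # term of interest (patient id nested in group; a study that recruited only
  # one group) is a finer partition than the term of interest: entered first
  # it absorbs the entire group effect, so it cannot be adjusted for as a
  # sequential model term
  toi <- term_of_interest
  if (is.factor(md[[toi]])) {
    for (tm in setdiff(terms, toi)) {
      if (!is.factor(md[[tm]])) next
      nested <- all(rowSums(table(md[[tm]], md[[toi]]) > 0) == 1)
      if (nested && nlevels(md[[tm]]) >= nlevels(md[[toi]])) {
        warning("confounder '", tm, "' nests the term of interest '", toi,
                "' and would absorb its effect; dropped from the model ",
                "(use restrict_within for restricted permutations instead)")
        dropped <- c(dropped, tm)
        terms <- setdiff(terms, tm)
      }
    }
  }
  # drop design-saturating confounders (no residual df left)
  model_df <- function(tms) {
    sum(vapply(tms, function(tm)
      if (is.factor(md[[tm]])) nlevels(md[[tm]]) - 1L else 1L, integer(1)))
  }
  n <- nrow(md)
  repeat {
    resid_df <- n - 1L - model_df(terms)
    if (resid_df > 0 || length(terms) <= 1) break
    confounders <- setdiff(terms, term_of_interest)
    if (!length(confounders)) break
    widest <- confounders[which.max(vapply(confounders, function(tm)
      if (is.factor(md[[tm]])) nlevels(md[[tm]]) else 2L, numeric(1)))]
    warning("confounder '", widest,
            "' saturates the design (residual df would be <= 0); dropped")
    dropped <- c(dropped, widest)
    terms <- setdiff(terms, widest)
  }
  terms <- union(setdiff(terms, term_of_interest), term_of_interest)
  dist_obj <- stats::as.dist(as.matrix(d))
  fml <- stats::as.formula(paste("dist_obj ~", paste(terms, collapse = " + ")),
                           env = environment())
  if (!is.null(strata)) {
    blk <- interaction(md[strata], drop = TRUE)
    perm <- permute::how(blocks = blk, nperm = n_perm)
  } else {
    perm <- n_perm
  }
  set.seed(seed)
  fit <- vegan::adonis2(fml, data = md, permutations = perm, by = "terms")
  tab <- data.frame(term = rownames(fit), df = fit$Df, SS = fit$SumOfSqs,
                    R2 = fit$R2, F = fit$F, p = fit$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, term_of_interest = term_of_interest,
                 n_perm = n_perm, seed = seed, strata = strata,
                 dropped = dropped),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("<permanova> term of interest = %s, %d permutations\n",
              x$term_of_interest, x$n_perm))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Extract the term-of-interest row of a PERMANOVA
#' @param x a `permanova` object.
#' @return one-row data frame (term, df, SS, R2, F, p).
#' @export
permanova_term <- function(x) {
  x$table[x$table$term == x$term_of_interest, , drop = FALSE]
}

#' Pairwise PERMANOVA over all group pairs
#'
#' Subsets the distance matrix to each pair of group levels, runs
#' [permanova()] with the same confounders, and Benjamini-Hochberg corrects
#' across the pairs.
#'
#' @param d a `dist_matrix`.
#' @param metadata data frame with `sample_id`, the grouping column and any
#'   confounders.
#' @param grouping name of the grouping column.
#' @param confounders character vector of confounder terms (may be empty).
#' @param n_perm,seed as [permanova()].
#' @return data frame: pair, df, SS, R2, F, p, q.
#' @export
pairwise_permanova <- function(d, metadata, grouping, confounders = character(),
                               n_perm = 999, seed = 1L) {
  ids <- rownames(d)
  groups <- resolve_groups(
    stats::setNames(metadata[match(ids, metadata$sample_id), grouping], ids), ids)
  lv <- levels(droplevels(groups))
  if (length(lv) < 2) stop("need at least 2 groups")
  pairs <- utils::combn(lv, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    keep <- ids[groups %in% pairs[, i]]
    sub <- new_dist_matrix(as.matrix(d)[keep, keep], keep, attr(d, "metric"))
    fit <- permanova(sub, metadata, terms = c(confounders, grouping),
                     term_of_interest = grouping,
                     n_perm = n_perm, seed = seed + i)
    cbind(pair = paste(pairs[1, i], "vs", pairs[2, i]), permanova_term(fit)[-1])
  })
  out <- do.call(rbind, rows)
  out$q <- benjamini_hochberg(out$p)
  rownames(out) <- NULL
  out
}
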