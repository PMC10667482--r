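#' Marker-genus simple linear regressions
#'
#' One simple linear regression `marker ~ genus abundance` per
#' (marker, genus) pair over the differential-abundance-significant genus
#' set, on pairwise-complete observations. Slopes, p-values and BH q-values
#' are corrected across the whole grid; pairs with fewer than `min_n`
#' complete observations or a constant predictor are skipped with a warning.
#'
#' @param markers numeric matrix, samples x markers (NAs allowed).
#' @param t an `abundance_table` on (at least) the same samples.
#' @param genus_set genus ids to test (default: all genera in `t`).
#' @param min_n minimum complete pairs per model (default 10).
#' @return list with `associations` (marker, genus, slope, se, p, q, n) and
#'   `per_marker_counts` (significant associations per marker at q < 0.05).
#' @export
marker_genus_regression <- function(markers, t, genus_set = NULL, min_n = 10) {
  if (is.null(genus_set)) genus_set <- genus_ids(t)
  ids <- intersect(rownames(markers), sample_ids(t))
  if (!length(ids)) stop("no shared samples")
  M <- markers[ids, , drop = FALSE]
  X <- unclass(t)[ids, genus_set, drop = FALSE]
  skipped <- character()
  rows <- list()
  for (mk in colnames(M)) for (g in genus_set) {
    ok <- !is.na(M[, mk])
    n <- sum(ok)
    if (n < min_n) { skipped <- c(skipped, paste(mk, g)); next }
    x <- X[ok, g]
    if (max(x) == min(x)) { skipped <- c(skipped, paste(mk, g)); next }
    fit <- stats::lm(M[ok, mk] ~ x)
    sm <- summary(fit)$coefficients
    rows[[length(rows) + 1L]] <-
      data.frame(marker = mk, genus = g, slope = sm[2, 1], se = sm[2, 2],
                 p = sm[2, 4], n = n, stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning(length(skipped), " pair(s) skipped (too few observations or ",
            "constant predictor)")
  if (!length(rows)) stop("no testable marker-genus pairs")
  out <- do.call(rbind, rows)
  out$q <- benjamini_hochberg(out$p)
  counts <- tapply(out$q < 0.05, out$marker, sum)
  list(associations = out[, c("marker", "genus", "slope", "se", "p", "q", "n")],
       per_marker_counts = counts)
}

#' Permute one genus and renormalise the composition
#'
#' Helper exposing one step of the compositionality-corrected null: the
#' chosen genus's relative abundances are permuted across samples and every
#' sample's composition is renormalised to sum to 1.
#'
#' @param X relative-abundance matrix (rows sum to 1).
#' @param genus column name or index to permute.
#' @param perm integer permutation of the rows.
#' @return renormalised matrix of the same shape.
#' @export
permute_renormalize <- function(X, genus, perm) {
  X[, genus] <- X[perm, genus]
  sweep(X, 1, rowSums(X), "/")
}

#' Compositionality-corrected marker-genus association
#'
#' A permutation-renormalisation procedure in the spirit of ReBoot/CCREPE:
#' the observed measure is the Spearman correlation between the ranked marker
#' and a genus's relative abundance; the null is built by permuting that
#' genus's abundances across samples, renormalising every sample's
#' composition to sum to 1 (so the null preserves the sum constraint that
#' induces spurious correlation in compositional data), and recomputing the
#' correlation. The two-sided p comes from a z-score against the null's mean
#' and standard deviation, with BH correction across all edges. This is a
#' simplified variant of the full CCREPE bootstrap-permutation z-test.
#'
#' @param markers numeric matrix, samples x markers (NAs allowed;
#'   pairwise-complete per edge).
#' @param t a relative-mode `abundance_table`.
#' @param n_perm number of permutations per edge (>= 100, default 1000).
#' @param seed RNG seed; the edge list is reproducible given the seed.
#' @param genus_set genus ids to test (default: all).
#' @return data frame of class `ccrepe_edges`: marker, genus, rho, null_mean,
#'   null_sd, z, p, q, n.
#' @export
ccrepe_association <- function(markers, t, n_perm = 1000, seed = 1L,
                               genus_set = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (table_mode(t) != "relative") stop("requires a relative-mode table")
  if (is.null(genus_set)) genus_set <- genus_ids(t)
  ids <- intersect(rownames(markers), sample_ids(t))
  if (!length(ids)) stop("no shared samples")
  M <- markers[ids, , drop = FALSE]
  X <- unclass(t)[ids, , drop = FALSE]
  set.seed(seed)
  rows <- list()
  for (mk in colnames(M)) {
    ok <- !is.na(M[, mk])
    n <- sum(ok)
    if (n < 5) next
    marker_rank <- rank(M[ok, mk], ties.method = "average")
    for (g in genus_set) {
      x <- X[ok, g, drop = TRUE]
      if (max(x) == min(x)) next
      obs <- suppressWarnings(stats::cor(marker_rank, x, method = "spearman"))
      other <- 1 - x  # rest of each sample's composition
      mr <- marker_rank - mean(marker_rank)
      mr_ss <- sqrt(sum(mr^2))
      null_rho <- vapply(seq_len(n_perm), function(i) {
        perm <- sample.int(n)
        # renormalised abundance of g after permuting its column:
        # everything else in the sample is unchanged
        xg <- x[perm] / (other + x[perm])
        xr <- rank(xg) # Spearman = Pearson on ranks
        xr <- xr - mean(xr)
        sum(mr * xr) / (mr_ss * sqrt(sum(xr^2)))
      }, numeric(1))
      mu <- mean(null_rho); sdev <- stats::sd(null_rho)
      z <- if (sdev == 0) 0 else (obs - mu) / sdev
      rows[[length(rows) + 1L]] <-
        data.frame(marker = mk, genus = g, rho = obs, null_mean = mu,
                   null_sd = sdev, z = z, p = 2 * stats::pnorm(-abs(z)),
                   n = n, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no testable edges")
  out <- do.call(rbind, rows)
  out$q <- benjamini_hochberg(out$p)
  class(out) <- c("ccrepe_edges", "data.frame")
  out
}
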