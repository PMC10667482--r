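#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected H statistic with a chi-square reference (k - 1 df). With two
#' groups this reduces to the rank-sum test's large-sample chi-square form.
#'
#' @param values numeric vector.
#' @param labels factor (or coercible) aligned to `values`, >= 2 groups.
#' @return a one-row data frame: comparison, statistic, df, p.
#' @export
kruskal_wallis <- function(values, labels) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2) stop("need at least 2 groups")
  if (any(tabulate(labels) == 0)) stop("empty group")
  kt <- stats::kruskal.test(values, labels)
  data.frame(comparison = "omnibus",
             statistic = unname(kt$statistic),
             df = unname(kt$parameter),
             p = kt$p.value,
             stringsAsFactors = FALSE)
}

#' Dunn's post hoc test for all group pairs
#'
#' For groups i, j the statistic is
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' where `Rbar` are mean ranks over the pooled data, `N` the total count and
#' `T = sum(t^3 - t)` over tie groups. Two-sided normal p-values are
#' Benjamini-Hochberg corrected across the family of pairs.
#'
#' @param values numeric vector.
#' @param labels factor aligned to `values`, >= 3 groups (2 allowed).
#' @return data frame: comparison, z, p, q (one row per pair).
#' @export
dunn_posthoc <- function(values, labels) {
  labels <- droplevels(factor(labels))
  k <- nlevels(labels)
  if (k < 2) stop("need at least 2 groups")
  if (any(tabulate(labels) == 0)) stop("empty group")
  N <- length(values)
  r <- rank(values, ties.method = "average")
  mean_ranks <- tapply(r, labels, mean)
  n <- tapply(r, labels, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  var_base <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  pairs <- utils::combn(levels(labels), 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(var_base * (1 / n[[i]] + 1 / n[[j]]))
    z <- if (se == 0) 0 else (mean_ranks[[i]] - mean_ranks[[j]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  out <- data.frame(comparison = paste(pairs[1, ], pairs[2, ], sep = " vs "),
                    z = res["z", ], p = res["p", ],
                    stringsAsFactors = FALSE)
  out$q <- benjamini_hochberg(out$p)
  rownames(out) <- NULL
  out
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact p by enumeration when `length(a) + length(b) <= 12` and the data are
#' tie-free; otherwise a normal approximation with tie and continuity
#' correction. Two-sided.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return one-row data frame: statistic (W for the first sample), p.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  exact <- (length(a) + length(b) <= 12) && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  data.frame(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p summing hypergeometric probabilities no larger than that of
#' the observed table.
#'
#' @param tab 2x2 matrix of non-negative integers.
#' @return one-row data frame: odds_ratio (conditional MLE), p.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("expected a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table entries must be non-negative integers")
  ft <- stats::fisher.test(tab)
  data.frame(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_i = min_{j >= rank(i)} (m p_(j) / j)`, capped at 1, returned in the
#' input order.
#'
#' @param p vector of p-values in `[0, 1]` (NAs propagated).
#' @return vector of q-values.
#' @export
benjamini_hochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Cohen's d effect size
#'
#' Standardised mean difference `(mean(a) - mean(b)) / s_pooled` with n-1
#' pooling of the variances. Sign preserved; screening rules use `abs(d)`.
#'
#' @param a,b numeric vectors with >= 2 values each.
#' @return a single number.
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 values per group")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) stop("pooled standard deviation is zero")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Per-sample alpha diversity
#'
#' Shannon `H = -sum p log p` (natural log, with `0 log 0 := 0`) or
#' Gini-Simpson `1 - sum p^2`, computed on per-sample proportions
#' (counts are converted automatically). No rarefaction is applied by
#' default; pass `rarefy_depth` to rarefy counts to a common depth first
#' (fixed seed for reproducibility).
#'
#' @param t an `abundance_table`.
#' @param index `"shannon"` or `"simpson"`.
#' @param rarefy_depth optional integer depth for rarefaction (counts mode
#'   only).
#' @param seed RNG seed used only when rarefying.
#' @return named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(t, index = c("shannon", "simpson"),
                            rarefy_depth = NULL, seed = 1L) {
  index <- match.arg(index)
  m <- unclass(t)
  if (any(rowSums(m) == 0))
    stop("all-zero sample(s): ", paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  if (!is.null(rarefy_depth)) {
    if (table_mode(t) != "counts") stop("rarefaction requires counts mode")
    set.seed(seed)
    m <- vegan::rrarefy(m, rarefy_depth)
  }
  p <- sweep(m, 1, rowSums(m), "/")
  if (index == "shannon") vegan::diversity(p, index = "shannon")
  else vegan::diversity(p, index = "simpson")
}

#' Group comparison dispatcher
#'
#' Applies the package's convention: Kruskal-Wallis with Dunn's post hoc when
#' three or more groups are compared, Wilcoxon when exactly two.
#'
#' @param values numeric vector.
#' @param labels group factor.
#' @return list with elements `omnibus` (data frame or NULL) and `pairwise`
#'   (data frame with q-values).
#' @export
compare_groups <- function(values, labels) {
  labels <- droplevels(factor(labels))
  k <- nlevels(labels)
  if (k < 2) stop("need at least 2 groups")
  if (k == 2) {
    lv <- levels(labels)
    wt <- wilcoxon_rank_sum(values[labels == lv[1]], values[labels == lv[2]])
    pairwise <- data.frame(comparison = paste(lv[1], "vs", lv[2]),
                           statistic = wt$statistic, p = wt$p,
                           q = wt$p, stringsAsFactors = FALSE)
    list(omnibus = NULL, pairwise = pairwise)
  } else {
    list(omnibus = kruskal_wallis(values, labels),
         pairwise = dunn_posthoc(values, labels))
  }
}
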