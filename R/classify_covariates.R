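#' Random-forest classification of microbiota configurations
#'
#' Trains a random forest on rank-normalised genus abundances to separate two
#' labelled groups, reports the out-of-bag (OOB) error, and optionally
#' predicts a third (held-out) group, reporting the fraction of its samples
#' voted into each class. Feature importance is the mean decrease in Gini
#' impurity, signed by the direction of the mean-abundance difference between
#' the classes (positive = higher in the first class level).
#'
#' @param t an `abundance_table` covering the labelled (and held-out) samples.
#' @param labels named factor (sample -> class) with exactly 2 levels; samples
#'   with `NA` are ignored. Both classes need >= 5 samples.
#' @param predict_on optional character vector of held-out sample ids to
#'   classify with the trained forest.
#' @param n_trees number of trees (default 1000).
#' @param seed RNG seed; the report is reproducible given the seed.
#' @param top_m number of top discriminatory genera to report.
#' @return object of class `rf_report`: list with `oob_error`, `votes`
#'   (per-sample class vote fractions), `importance` (data frame genus,
#'   importance, direction), `predicted_fraction` (named fractions for the
#'   held-out group, or NULL), `n_trees`, `seed`.
#' @export
rf_classify <- function(t, labels, predict_on = NULL, n_trees = 1000,
                        seed = 1L, top_m = 15) {
  labels <- labels[!is.na(labels)]
  labels <- droplevels(factor(labels, levels = unique(levels(factor(labels)))))
  if (nlevels(labels) != 2) stop("labels must have exactly 2 classes")
  if (any(table(labels) < 5)) stop("both classes need at least 5 samples")
  train_ids <- names(labels)
  if (!all(train_ids %in% sample_ids(t)))
    stop("abundance table missing labelled sample(s)")
  x <- suppressWarnings(rank_normalize_table(t))
  set.seed(seed)
  fit <- randomForest::randomForest(x = x[train_ids, , drop = FALSE],
                                    y = labels, ntree = n_trees,
                                    importance = FALSE)
  oob <- unname(fit$err.rate[n_trees, "OOB"])
  imp <- randomForest::importance(fit, type = 2)[, 1]
  lv <- levels(labels)
  mean_diff <- colMeans(x[train_ids[labels == lv[1]], , drop = FALSE]) -
    colMeans(x[train_ids[labels == lv[2]], , drop = FALSE])
  ord <- order(imp, decreasing = TRUE)[seq_len(min(top_m, length(imp)))]
  importance <- data.frame(genus = names(imp)[ord],
                           importance = unname(imp[ord]),
                           direction = ifelse(mean_diff[ord] > 0, lv[1], lv[2]),
                           row.names = NULL, stringsAsFactors = FALSE)
  predicted_fraction <- NULL
  votes_heldout <- NULL
  if (!is.null(predict_on)) {
    if (!all(predict_on %in% sample_ids(t)))
      stop("abundance table missing held-out sample(s)")
    votes_heldout <- stats::predict(fit, x[predict_on, , drop = FALSE],
                                    type = "vote", norm.votes = TRUE)
    pred <- lv[max.col(votes_heldout, ties.method = "first")]
    predicted_fraction <- c(prop.table(table(factor(pred, levels = lv))))
  }
  structure(list(oob_error = oob,
                 votes = fit$votes,
                 votes_heldout = votes_heldout,
                 importance = importance,
                 predicted_fraction = predicted_fraction,
                 classes = lv, n_trees = n_trees, seed = seed),
            class = "rf_report")
}

#' @export
print.rf_report <- function(x, ...) {
  cat(sprintf("<rf_report> OOB error %.3f (%s vs %s, %d trees)\n",
              x$oob_error, x$classes[1], x$classes[2], x$n_trees))
  if (!is.null(x$predicted_fraction)) {
    cat("  held-out fractions:",
        paste(sprintf("%s %.0f%%", names(x$predicted_fraction),
                      100 * x$predicted_fraction), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Rank-based differential abundance screen
#'
#' A simple nonparametric screen: per genus, a Wilcoxon (2 groups) or
#' Kruskal-Wallis (>= 3 groups) test on rank-normalised abundances, BH
#' correction across genera, and the direction given by the group with the
#' higher median abundance. This is NOT ANCOM-BC: it applies no
#' bias correction for compositionality and no covariate adjustment. Results
#' from an external ANCOM-BC run can be brought in with
#' [import_external_da_results()].
#'
#' @param t an `abundance_table`.
#' @param labels named group factor covering the samples.
#' @return data frame (attribute `method` = "rank_standin_not_ancombc"):
#'   genus, statistic, p, q, direction; constant genera are excluded with a
#'   warning.
#' @export
differential_abundance_standin <- function(t, labels) {
  labels <- droplevels(factor(labels))
  ids <- names(labels)
  if (is.null(ids)) {
    if (length(labels) != nrow(t)) stop("labels must be named or full-length")
    ids <- sample_ids(t)
    names(labels) <- ids
  }
  m <- unclass(t)[ids, , drop = FALSE]
  const <- apply(m, 2, function(v) max(v) == min(v))
  if (any(const))
    warning("constant genus (genera) excluded: ",
            paste(colnames(m)[const], collapse = ", "))
  m <- m[, !const, drop = FALSE]
  lv <- levels(labels)
  rows <- lapply(colnames(m), function(g) {
    x <- suppressWarnings(rank_normalize(m[, g]))
    if (length(lv) == 2) {
      res <- wilcoxon_rank_sum(x[labels == lv[1]], x[labels == lv[2]])
    } else {
      res <- kruskal_wallis(x, labels)[, c("statistic", "p")]
    }
    med <- tapply(m[, g], labels, stats::median)
    data.frame(genus = g, statistic = res$statistic, p = res$p,
               direction = names(med)[which.max(med)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- benjamini_hochberg(out$p)
  out <- out[, c("genus", "statistic", "p", "q", "direction")]
  attr(out, "method") <- "rank_standin_not_ancombc"
  out
}

#' Import externally computed differential-abundance results
#'
#' Normalises a results TSV (e.g. from an ANCOM-BC run performed outside this
#' package) into the internal schema. The file must contain columns mappable
#' to genus, effect, p and q.
#'
#' @param path TSV path.
#' @param columns named character vector mapping internal names
#'   (genus, effect, p, q) to the file's column names.
#' @return data frame: genus, effect, p, q.
#' @export
import_external_da_results <- function(path,
                                       columns = c(genus = "genus",
                                                   effect = "effect",
                                                   p = "p", q = "q")) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("genus", "effect", "p", "q")
  missing <- setdiff(need, names(columns))
  if (length(missing)) stop("column mapping lacks: ", paste(missing, collapse = ", "))
  absent <- setdiff(unname(columns[need]), names(df))
  if (length(absent))
    stop("input file lacks column(s): ", paste(absent, collapse = ", "))
  out <- data.frame(genus = as.character(df[[columns["genus"]]]),
                    effect = as.numeric(df[[columns["effect"]]]),
                    p = as.numeric(df[[columns["p"]]]),
                    q = as.numeric(df[[columns["q"]]]),
                    stringsAsFactors = FALSE)
  if (any(out$p < 0 | out$p > 1, na.rm = TRUE)) stop("p outside [0, 1]")
  out
}

#' Logistic screen of one exposure against a two-level configuration
#'
#' Fits `outcome ~ exposure + adjusters` by maximum-likelihood logistic
#' regression, mirroring a one-exposure-at-a-time covariate screen. Binary
#' exposures must reach `min_prevalence` in the cohort; continuous exposures
#' (e.g. diet frequencies) must have `|Cohen's d| >= min_cohens_d` between the
#' outcome groups -- both screens drop uninformative, small-effect variables
#' before modelling. Per-term p-values are likelihood-ratio ("Pr(>Chi)") and
#' BH-corrected across the model's terms. Quasi-separation (a huge estimate
#' with a huge standard error) is flagged, and a ridge-penalised refit of the
#' exposure effect can be requested rather than reporting the unstable
#' estimate.
#'
#' @param outcome named two-level factor (sample -> configuration label).
#' @param exposure named numeric or logical vector (sample -> exposure).
#' @param adjusters data frame of adjusters with a `sample_id` column (may
#'   have zero adjuster columns).
#' @param exposure_name name used for the exposure term.
#' @param min_prevalence minimum prevalence for a binary exposure (default 0.2).
#' @param min_cohens_d minimum absolute Cohen's d for a continuous exposure
#'   (default 0.5).
#' @param penalized refit with a small ridge penalty when separation is
#'   flagged (requires glmnet).
#' @return object of class `covariate_model`: list with `table` (term,
#'   estimate, std_error, z, p, q), `separation`, `screened_out`,
#'   `penalized_estimate`.
#' @export
covariate_logistic <- function(outcome, exposure, adjusters = NULL,
                               exposure_name = "exposure",
                               min_prevalence = 0.20, min_cohens_d = 0.5,
                               penalized = FALSE) {
  outcome <- droplevels(factor(outcome))
  if (nlevels(outcome) != 2) stop("outcome must have exactly 2 levels")
  ids <- names(outcome)
  if (is.null(ids)) stop("outcome must be a named vector")
  ex <- exposure[ids]
  if (anyNA(ex)) {
    keep <- !is.na(ex)
    ids <- ids[keep]; outcome <- outcome[keep]; ex <- ex[keep]
  }
  binary <- is.logical(exposure) || all(ex %in% c(0, 1))
  screened_out <- NULL
  if (binary) {
    prev <- mean(as.numeric(ex))
    if (prev < min_prevalence)
      screened_out <- sprintf("prevalence %.2f < %.2f", prev, min_prevalence)
  } else {
    lv <- levels(outcome)
    d <- tryCatch(cohens_d(ex[outcome == lv[1]], ex[outcome == lv[2]]),
                  error = function(e) 0)
    if (abs(d) < min_cohens_d)
      screened_out <- sprintf("|Cohen's d| %.2f < %.2f", abs(d), min_cohens_d)
  }
  if (!is.null(screened_out)) {
    return(structure(list(table = NULL, separation = FALSE,
                          screened_out = screened_out,
                          penalized_estimate = NULL),
                     class = "covariate_model"))
  }
  df <- data.frame(.outcome = outcome, row.names = ids, check.names = FALSE)
  df[[exposure_name]] <- as.numeric(ex)
  adj_terms <- character()
  if (!is.null(adjusters) && ncol(adjusters) > 1) {
    idx <- match(ids, as.character(adjusters$sample_id))
    if (anyNA(idx)) stop("adjusters missing sample(s)")
    adj_terms <- setdiff(names(adjusters), "sample_id")
    for (a in adj_terms) df[[a]] <- adjusters[[a]][idx]
  }
  fml <- stats::as.formula(paste(".outcome ~", paste(c(adj_terms, exposure_name),
                                                     collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, data = df, family = stats::binomial()))
  if (!fit$converged && max(abs(stats::coef(fit)), na.rm = TRUE) <= 10)
    stop("logistic fit failed to converge without separation")
  sm <- summary(fit)$coefficients
  lrt <- suppressWarnings(stats::drop1(fit, test = "Chisq"))
  terms_in <- rownames(lrt)[-1]
  # map single-df terms to their coefficient row where possible
  coef_row <- function(tm) {
    hits <- grep(paste0("^", tm), rownames(sm))
    if (length(hits) == 1) sm[hits, ] else rep(NA_real_, 4)
  }
  tab <- do.call(rbind, lapply(terms_in, function(tm) {
    cr <- coef_row(tm)
    data.frame(term = tm, estimate = cr[1], std_error = cr[2], z = cr[3],
               p = lrt[tm, "Pr(>Chi)"], stringsAsFactors = FALSE)
  }))
  tab$q <- benjamini_hochberg(tab$p)
  rownames(tab) <- NULL
  separation <- any(abs(tab$estimate) > 10 & tab$std_error > 100, na.rm = TRUE)
  penalized_estimate <- NULL
  if (separation && penalized && requireNamespace("glmnet", quietly = TRUE)) {
    X <- stats::model.matrix(fml, df)[, -1, drop = FALSE]
    pf <- glmnet::glmnet(X, df$.outcome, family = "binomial", alpha = 0,
                         lambda = 1e-2)
    penalized_estimate <- as.numeric(stats::coef(pf)[exposure_name, ])
  }
  structure(list(table = tab, separation = separation, screened_out = NULL,
                 penalized_estimate = penalized_estimate),
            class = "covariate_model")
}

#' @export
print.covariate_model <- function(x, ...) {
  if (!is.null(x$screened_out)) {
    cat("<covariate_model> exposure screened out:", x$screened_out, "\n")
  } else {
    cat("<covariate_model>", if (x$separation) "(separation flagged)" else "", "\n")
    print(x$table, row.names = FALSE)
  }
  invisible(x)
}

#' Taxon-covariate Spearman correlation grid
#'
#' Spearman correlations between selected taxa (typically the top
#' discriminatory genera of a random-forest model) and host covariates (age,
#' drug use, diet items, ...), with BH correction across the whole grid and a
#' significance mask at `q < q_threshold`. Constant covariates are dropped
#' with a warning.
#'
#' @param t an `abundance_table`.
#' @param covariates numeric matrix/data frame, samples x covariates, with
#'   rownames (or `sample_id` column) matching the table.
#' @param taxon_list genus ids to correlate (default: all).
#' @param q_threshold mask threshold (default 0.1).
#' @return list with `rho`, `p`, `q` matrices (taxa x covariates) and
#'   `significant` (logical mask at `q < q_threshold`).
#' @export
taxon_covariate_correlations <- function(t, covariates, taxon_list = NULL,
                                         q_threshold = 0.1) {
  if (is.data.frame(covariates)) {
    if ("sample_id" %in% names(covariates)) {
      rn <- as.character(covariates$sample_id)
      covariates <- as.matrix(covariates[setdiff(names(covariates), "sample_id")])
      rownames(covariates) <- rn
    } else covariates <- as.matrix(covariates)
  }
  ids <- intersect(sample_ids(t), rownames(covariates))
  if (!length(ids)) stop("no shared samples")
  if (is.null(taxon_list)) taxon_list <- genus_ids(t)
  if (!all(taxon_list %in% genus_ids(t)))
    stop("taxa absent from table: ",
         paste(setdiff(taxon_list, genus_ids(t)), collapse = ", "))
  X <- unclass(t)[ids, taxon_list, drop = FALSE]
  C <- covariates[ids, , drop = FALSE]
  storage.mode(C) <- "double"
  const <- apply(C, 2, function(v) max(v, na.rm = TRUE) == min(v, na.rm = TRUE))
  if (any(const)) {
    warning("constant covariate(s) dropped: ",
            paste(colnames(C)[const], collapse = ", "))
    C <- C[, !const, drop = FALSE]
  }
  if (!ncol(C)) stop("no usable covariates")
  rho <- matrix(NA_real_, length(taxon_list), ncol(C),
                dimnames = list(taxon_list, colnames(C)))
  p <- rho
  for (i in seq_along(taxon_list)) for (j in seq_len(ncol(C))) {
    ok <- !is.na(C[, j])
    ct <- suppressWarnings(stats::cor.test(X[ok, i], C[ok, j],
                                           method = "spearman"))
    rho[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  q <- matrix(benjamini_hochberg(as.vector(p)), nrow(p), ncol(p),
              dimnames = dimnames(p))
  list(rho = rho, p = p, q = q, significant = q < q_threshold)
}
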