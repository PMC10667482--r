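test_that("random forest separates planted configurations and is reproducible", {
  co <- generate_cohort(small_spec(seed = 2, n_control = 40, n_cd = 40))
  rel <- to_relative(suppressMessages(prevalence_filter(co$abundance)))
  md <- co$metadata
  labels <- droplevels(setNames(md$group, md$sample_id)[
    md$group %in% c("control", "CD")])
  hs_ids <- md$sample_id[md$group == "HS"]
  r1 <- rf_classify(rel, labels, predict_on = hs_ids, n_trees = 300, seed = 11)
  r2 <- rf_classify(rel, labels, predict_on = hs_ids, n_trees = 300, seed = 11)
  expect_identical(r1$oob_error, r2$oob_error)
  expect_identical(r1$importance, r2$importance)
  expect_lte(r1$oob_error, 0.10)
  expect_equal(unname(rowSums(r1$votes)), rep(1, nrow(r1$votes)),
               tolerance = 1e-9)
  expect_equal(sum(r1$predicted_fraction), 1, tolerance = 1e-9)
  expect_equal(nrow(r1$importance), 15)
  expect_true(all(r1$importance$direction %in% c("control", "CD")))

  expect_error(rf_classify(rel, labels[labels == "CD"]), "2 classes")
})

test_that("importance direction matches the planted enrichment", {
  co <- generate_cohort(small_spec(seed = 3, n_control = 40, n_cd = 40))
  rel <- to_relative(suppressMessages(prevalence_filter(co$abundance)))
  md <- co$metadata
  labels <- droplevels(setNames(md$group, md$sample_id)[
    md$group %in% c("control", "CD")])
  r <- rf_classify(rel, labels, n_trees = 300, seed = 5)
  top_cd <- r$importance$genus[r$importance$direction == "CD"]
  top_ctrl <- r$importance$genus[r$importance$direction == "control"]
  # directions must agree with the planted block geometry: CD-enriched calls
  # sit in the pathogen blocks, control-enriched calls in the health blocks
  blocks <- co$truth$genus_block
  expect_true(all(blocks[top_cd] >= 3))
  expect_true(all(blocks[top_ctrl] <= 2))
  expect_gt(length(top_cd) + length(top_ctrl), 0)
})

test_that("the rank-based DA screen finds planted shifts and controls the null", {
  set.seed(4)
  n <- 50
  base <- matrix(rpois(2 * n * 40, 30), 2 * n, 40)
  base[1:n, 1] <- rpois(n, 60)      # 2-fold planted shift in genus 1
  dimnames(base) <- list(paste0("s", 1:(2 * n)), paste0("g", 1:40))
  labels <- setNames(rep(c("A", "B"), each = n), rownames(base))
  da <- differential_abundance_standin(abundance_table(base), factor(labels))
  expect_lt(da$q[da$genus == "g1"], 0.05)
  expect_equal(da$direction[da$genus == "g1"], "A")
  expect_true(all(c("genus", "statistic", "p", "q", "direction") %in% names(da)))
  expect_identical(attr(da, "method"), "rank_standin_not_ancombc")

  # exchangeable null: BH keeps false positives near zero
  null_counts <- matrix(rpois(2 * n * 40, 30), 2 * n, 40,
                        dimnames = dimnames(base))
  da0 <- differential_abundance_standin(abundance_table(null_counts),
                                        factor(labels))
  expect_lte(sum(da0$q < 0.05), 2)

  const <- base; const[, 2] <- 7
  expect_warning(differential_abundance_standin(abundance_table(const),
                                                factor(labels)), "constant")
})

test_that("external DA results import maps columns into the internal schema", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\tlfc\tpval\tqval", "gA\t1.5\t0.001\t0.01",
               "gB\t-0.2\t0.6\t0.8"), path)
  out <- import_external_da_results(path, columns = c(genus = "taxon",
                                                      effect = "lfc",
                                                      p = "pval", q = "qval"))
  expect_identical(out$genus, c("gA", "gB"))
  expect_equal(out$effect, c(1.5, -0.2))
  expect_error(import_external_da_results(path), "lacks column")
  writeLines(c("taxon\tlfc\tpval\tqval", "gA\t1.5\t2\t0.01"), path)
  expect_error(import_external_da_results(path, columns = c(genus = "taxon",
                                                            effect = "lfc",
                                                            p = "pval",
                                                            q = "qval")),
               "\\[0, 1\\]")
})

test_that("logistic screen fits, screens, and flags separation", {
  set.seed(6)
  n <- 60
  ids <- paste0("s", 1:n)
  outcome <- setNames(factor(rep(c("NM", "CDM"), each = n / 2)), ids)
  # continuous exposure with a real effect
  x <- setNames(rnorm(n) + (outcome == "CDM") * 1.5, ids)
  adj <- data.frame(sample_id = ids, age = rnorm(n, 45, 10))
  m <- covariate_logistic(outcome, x, adj, exposure_name = "sugar")
  expect_true("sugar" %in% m$table$term)
  expect_lt(m$table$p[m$table$term == "sugar"], 0.01)
  expect_false(m$separation)

  # prevalence screen drops a rare binary exposure
  rare <- setNames(c(rep(1, 5), rep(0, n - 5)), ids)
  m2 <- covariate_logistic(outcome, rare, adj)
  expect_match(m2$screened_out, "prevalence")

  # Cohen's d screen drops a weak continuous exposure
  weak <- setNames(rnorm(n), ids)
  m3 <- covariate_logistic(outcome, weak, adj)
  expect_match(m3$screened_out, "Cohen")

  # perfect separation flagged
  sep <- setNames(as.numeric(outcome == "CDM"), ids)
  m4 <- suppressWarnings(covariate_logistic(outcome, sep, adj,
                                            exposure_name = "sep"))
  expect_true(m4$separation)
})

test_that("logistic null p-values are approximately uniform", {
  set.seed(7)
  p <- replicate(200, {
    n <- 55
    ids <- paste0("s", 1:n)
    outcome <- setNames(factor(rep(c("a", "b"), c(33, 22))), ids)
    x <- setNames(rnorm(n), ids)
    m <- suppressWarnings(covariate_logistic(outcome, x, NULL,
                                             min_cohens_d = 0))
    m$table$p[m$table$term == "exposure"]
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("taxon-covariate grids mask at q < 0.1 with planted couplings", {
  set.seed(8)
  n <- 100
  m <- matrix(rexp(n * 6), n, 6,
              dimnames = list(paste0("s", 1:n), paste0("g", 1:6)))
  rel <- to_relative(abundance_table(m))
  covs <- data.frame(sample_id = rownames(m),
                     coupled = rank(unclass(rel)[, 1]) + rnorm(n, 0, 8),
                     noise = rnorm(n),
                     flat = rep(1, n))
  expect_warning(out <- taxon_covariate_correlations(rel, covs), "constant")
  expect_true(out$significant["g1", "coupled"])
  expect_equal(dim(out$rho), c(6, 2))
  # covariate identical to a taxon correlates perfectly
  covs2 <- data.frame(sample_id = rownames(m), same = unclass(rel)[, 2])
  out2 <- taxon_covariate_correlations(rel, covs2, taxon_list = "g2")
  expect_equal(unname(out2$rho["g2", "same"]), 1)
})
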