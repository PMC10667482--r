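#' Default pipeline configuration
#'
#' Plain list of every tunable pipeline parameter. A configuration may also
#' be given as a YAML file; unknown keys are rejected so typos fail loudly.
#' One global `seed` is expanded into fixed per-stage seeds (documented
#' offsets), so stages remain reproducible when run standalone.
#'
#' @param ... overrides of the defaults.
#' @return a named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    simulate = TRUE,           # simulate a cohort (FALSE: read input_dir)
    input_dir = NULL,
    out_dir = NULL,
    min_prevalence = 0.10,
    reference_group = "control",
    confounders = c("study", "patient_id"),
    n_perm = 999,
    k_cags = 4,
    stratify_group_label = "HS",
    rf_trees = 1000,
    da_q_threshold = 0.05,
    ccrepe_n_perm = 1000)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(cfg, overrides)
}

read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

stage_seed <- function(cfg, stage) {
  offsets <- c(simulate = 0L, permanova = 101L, pairwise = 202L,
               rf = 303L, ccrepe = 404L, diet = 505L)
  cfg$seed + offsets[[stage]]
}

#' Run the full analysis pipeline
#'
#' Executes every stage on one cohort: prevalence filtering and
#' relative-abundance conversion, Bray-Curtis PCoA with control
#' median-centroid distances and their group tests, PERMANOVA (overall and
#' pairwise) with confounder adjustment, alpha diversity, CAG detection and
#' profiling, HS stratification into NM-like/CDM-like configurations,
#' random-forest configuration prediction, differential-abundance screening
#' between the HS sub-clusters, covariate logistic screens, the dietary
#' Kendall-tau arm, and marker-genus association (linear regression plus the
#' permutation-renormalisation correlation). When `out_dir` is set, every
#' stage's table is written as TSV together with a `manifest.yaml` recording
#' all parameters and seeds; re-running the same configuration reproduces all
#' numeric outputs exactly.
#'
#' @param config a [pipeline_config()] list or path to a YAML file.
#' @param cohort optional pre-generated cohort (as [generate_cohort()]);
#'   otherwise simulated (`simulate = TRUE`) or read from `input_dir`.
#' @return a list of stage results (invisible elements: see names).
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- do.call(pipeline_config, config[setdiff(names(config), NULL)])
  if (is.null(cohort)) {
    if (cfg$simulate) {
      cohort <- generate_cohort(cohort_spec(seed = stage_seed(cfg, "simulate")))
    } else {
      if (is.null(cfg$input_dir)) stop("input_dir required when simulate = FALSE")
      md <- read_metadata(file.path(cfg$input_dir, "metadata.tsv"))
      cohort <- list(
        abundance = read_abundance_table(
          file.path(cfg$input_dir, "abundance.tsv"),
          orientation = "auto", metadata_samples = md$sample_id),
        metadata = md,
        diet = read_diet_table(file.path(cfg$input_dir, "diet.tsv")),
        markers = read_marker_panel(file.path(cfg$input_dir, "markers.tsv")))
    }
  }
  md <- cohort$metadata
  res <- list(config = cfg, metadata = md)

  # --- community tables ---------------------------------------------------
  filtered <- suppressMessages(
    prevalence_filter(cohort$abundance, cfg$min_prevalence))
  rel <- to_relative(filtered)
  res$filtered <- filtered
  res$relative <- rel

  # --- ordination, centroid, PERMANOVA ------------------------------------
  bc <- bray_curtis(rel)
  ord <- pcoa(bc, k = 2)
  cd <- median_centroid(ord, cfg$reference_group, md)
  res$ordination <- ord
  res$centroid <- cd
  res$centroid_tests <- centroid_group_test(cd, md)
  res$permanova <- suppressWarnings(
    permanova(bc, md, terms = c(cfg$confounders, "group"),
              term_of_interest = "group", n_perm = cfg$n_perm,
              seed = stage_seed(cfg, "permanova")))
  res$pairwise_permanova <- suppressWarnings(
    pairwise_permanova(bc, md, grouping = "group",
                       confounders = intersect(cfg$confounders, "study"),
                       n_perm = cfg$n_perm, seed = stage_seed(cfg, "pairwise")))

  # --- alpha diversity ----------------------------------------------------
  groups <- stats::setNames(md$group, md$sample_id)[sample_ids(rel)]
  res$alpha <- data.frame(
    sample_id = sample_ids(rel),
    shannon = alpha_diversity(filtered, "shannon"),
    simpson = alpha_diversity(filtered, "simpson"),
    row.names = NULL)
  res$alpha_tests <- compare_groups(res$alpha$shannon, groups)

  # --- CAGs ---------------------------------------------------------------
  cags <- detect_cags(rel, k = cfg$k_cags)
  res$cags <- cags
  res$cag_abundance <- cag_abundance(rel, cags)
  res$cag_centroid <- cag_centroid_correlation(rel, cags, cd)

  # --- stratification of the HS group -------------------------------------
  hs_ids <- md$sample_id[md$group == cfg$stratify_group_label]
  hs_rel <- abundance_table(unclass(rel)[hs_ids, , drop = FALSE],
                            mode = "relative")
  strat_cl <- suppressWarnings(stratify_group(hs_rel, k = 2))
  res$stratification <- label_clusters(strat_cl$cluster, cd)

  # --- random-forest configuration prediction -----------------------------
  train_labels <- stats::setNames(md$group, md$sample_id)
  train_labels <- droplevels(train_labels[md$group %in% c("control", "CD")])
  res$rf <- rf_classify(rel, train_labels, predict_on = hs_ids,
                        n_trees = cfg$rf_trees, seed = stage_seed(cfg, "rf"))

  # --- differential abundance between the HS sub-clusters -----------------
  res$da <- suppressWarnings(
    differential_abundance_standin(hs_rel, res$stratification$label))
  da_genera <- res$da$genus[res$da$q < cfg$da_q_threshold]
  res$da_genera <- da_genera

  # --- covariate screens (within HS) --------------------------------------
  hs_md <- md[md$group == cfg$stratify_group_label, , drop = FALSE]
  outcome <- factor(res$stratification$label[hs_md$sample_id],
                    levels = c("NM-like", "CDM-like"))
  names(outcome) <- hs_md$sample_id
  adjusters <- hs_md[, c("sample_id", "age", "age_at_diagnosis", "gender",
                         "hurley", "surgery", "antibiotics_last_year",
                         "anti_tnf_current", "anti_tnf_previous",
                         "immunomodulator")]
  res$covariate_models <- list(
    cardiovascular_drugs = suppressWarnings(covariate_logistic(
      outcome, stats::setNames(as.numeric(hs_md$cardiovascular_drugs),
                               hs_md$sample_id),
      adjusters, exposure_name = "cardiovascular_drugs")),
    carbonated_soft_drinks = suppressWarnings(covariate_logistic(
      outcome, stats::setNames(cohort$diet[hs_md$sample_id,
                                           "carbonated_soft_drinks"],
                               hs_md$sample_id),
      adjusters, exposure_name = "carbonated_soft_drinks")))
  res$fisher_antibiotics <- fisher_exact_2x2(table(
    outcome, hs_md$antibiotics_last_year))
  covs <- data.frame(sample_id = hs_md$sample_id, age = hs_md$age,
                     age_at_diagnosis = hs_md$age_at_diagnosis,
                     antibiotics = as.numeric(hs_md$antibiotics_last_year),
                     cardiovascular = as.numeric(hs_md$cardiovascular_drugs),
                     soft_drinks = cohort$diet[hs_md$sample_id,
                                               "carbonated_soft_drinks"])
  res$taxon_covariate <- suppressWarnings(taxon_covariate_correlations(
    hs_rel, covs, taxon_list = res$rf$importance$genus))

  # --- dietary arm --------------------------------------------------------
  res$diet <- diet_ordination(cohort$diet, md,
                              reference = cfg$reference_group,
                              n_perm = cfg$n_perm,
                              seed = stage_seed(cfg, "diet"))
  res$diet_item_centroid <- suppressWarnings(
    item_centroid_correlation(cohort$diet, res$diet$centroid))
  res$diet_item_tests <- item_group_tests(cohort$diet, md)

  # --- inflammation arm (HS samples) --------------------------------------
  if (!is.null(cohort$markers) && length(da_genera) >= 1) {
    res$marker_regression <- suppressWarnings(
      marker_genus_regression(cohort$markers, hs_rel, genus_set = da_genera))
    res$ccrepe <- ccrepe_association(cohort$markers, hs_rel,
                                     n_perm = cfg$ccrepe_n_perm,
                                     seed = stage_seed(cfg, "ccrepe"),
                                     genus_set = da_genera)
  }

  if (!is.null(cfg$out_dir)) write_pipeline_outputs(res, cohort, cfg)
  invisible(res)
}

write_pipeline_outputs <- function(res, cohort, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(cfg$out_dir, name)
  wt <- function(df, name) utils::write.table(
    df, out(name), sep = "\t", quote = FALSE, row.names = FALSE)
  write_abundance_table(res$filtered, out("filtered_counts.tsv"))
  write_sample_matrix(res$ordination$coordinates, out("pcoa_coordinates.tsv"))
  wt(data.frame(sample_id = names(res$centroid$distance),
                distance = res$centroid$distance), "centroid_distance.tsv")
  wt(res$permanova$table, "permanova.tsv")
  wt(res$pairwise_permanova, "pairwise_permanova.tsv")
  wt(res$alpha, "alpha_diversity.tsv")
  wt(data.frame(genus = names(res$cags$cluster), cag = res$cags$cluster),
     "cag_assignment.tsv")
  write_sample_matrix(res$cag_abundance, out("cag_abundance.tsv"))
  wt(res$cag_centroid, "cag_centroid_correlation.tsv")
  wt(data.frame(sample_id = names(res$stratification$label),
                cluster = res$stratification$cluster,
                label = res$stratification$label), "stratification.tsv")
  wt(res$da, "differential_abundance.tsv")
  wt(res$rf$importance, "rf_importance.tsv")
  wt(res$diet_item_centroid, "diet_item_centroid.tsv")
  wt(res$diet_item_tests, "diet_item_tests.tsv")
  if (!is.null(res$ccrepe)) wt(res$ccrepe, "marker_associations.tsv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("microconfig")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    config = cfg[setdiff(names(cfg), "out_dir")],
    stage_seeds = lapply(
      stats::setNames(nm = c("simulate", "permanova", "pairwise", "rf",
                             "ccrepe", "diet")),
      function(s) stage_seed(cfg, s)))
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  invisible(cfg$out_dir)
}
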