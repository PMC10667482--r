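#' Specification for a synthetic diet-microbiome cohort
#'
#' Describes a three-group case-control cohort (controls, Crohn's disease,
#' hidradenitis suppurativa) with the statistical structure the analysis
#' pipeline assumes: four co-abundance blocks of genera driven by shared
#' latent factors, two community "configurations" (control-like vs CD-like)
#' defined by log-fold shifts on marker genus sets, a mixed HS group, a
#' longitudinal sampling design with a patient-level random effect and a
#' two-study batch structure, group-shifted food-frequency profiles,
#' configuration-coupled drug/diet covariates, and inflammatory markers
#' linearly coupled to selected genera. Defaults give 95/164
#' control patients/samples, 102/212 CD, 55/55 HS, with 40% of HS patients
#' carrying the CD-like configuration.
#'
#' @param n_control_patients,n_control_samples,n_cd_patients,n_cd_samples,n_hs_patients
#'   cohort sizes (HS is sampled once per patient).
#' @param n_genera number of genera (split over 4 co-abundance blocks).
#' @param block_weights relative sizes of the 4 blocks (health-associated
#'   "Ruminococcus"-like and "Lachnospiraceae"-like blocks, then two
#'   pathogen-like blocks).
#' @param block_rho within-block latent correlation (default 0.7).
#' @param block_sigma standard deviation of the genus log-intensity noise.
#' @param pathogen_base_offset log offset of pathogen-block baseline
#'   abundances (negative: pathogen taxa are rare in a healthy community).
#' @param patient_icc share of latent-factor variance at the patient level
#'   (longitudinal replicates of a patient are correlated through it).
#' @param study_sigma SD of per-study, per-genus batch offsets.
#' @param config_lfc log-fold shift applied by the CD-like configuration:
#'   `+config_lfc` on `n_cd_marker` pathogen-block genera, `-config_lfc` on
#'   `n_normal_marker` health-block genera.
#' @param config_block_shift shift (in latent-factor SD units) of the block
#'   factors under the CD-like configuration: health blocks down, pathogen
#'   blocks up, emulating dysbiosis moving whole co-abundance groups.
#' @param normal_dispersion latent-factor SD multiplier for control-like
#'   configuration samples (< 1: the normal community is the more stable
#'   one, mirroring the greater dispersion of dysbiotic microbiotas).
#' @param n_normal_marker,n_cd_marker sizes of the configuration marker sets.
#' @param hs_cd_fraction probability an HS patient carries the CD-like
#'   configuration (default 0.4).
#' @param depth_meanlog,depth_sdlog log-normal sequencing-depth parameters.
#' @param n_food_items number of FFQ items; the first items form a
#'   "western" set (shifted up in CD and HS) and a "fibre" set (shifted up in
#'   controls).
#' @param diet_shift size of the group diet shifts on the latent log scale
#'   (in SD units of the item noise).
#' @param soft_drink_shift extra shift of the carbonated-soft-drink item for
#'   CD-like-configuration samples.
#' @param zero_inflation probability an item is never consumed by a subject.
#' @param antibiotics_or odds ratio of antibiotics use (last year) for
#'   CD-like vs control-like configuration in HS (default 4).
#' @param cardio_or odds ratio of cardiovascular drug use for CD-like
#'   configuration (default 0.25, i.e. more use with the normal-like
#'   configuration).
#' @param age_shift years added to HS patients with the control-like
#'   configuration.
#' @param marker_r latent correlation of each planted marker-genus coupling.
#' @param seed RNG seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_control_patients = 95, n_control_samples = 164,
                        n_cd_patients = 102, n_cd_samples = 212,
                        n_hs_patients = 55,
                        n_genera = 120,
                        block_weights = c(0.33, 0.29, 0.21, 0.17),
                        block_rho = 0.7, block_sigma = 0.8,
                        pathogen_base_offset = -1,
                        patient_icc = 0.5, study_sigma = 0.3,
                        config_lfc = 2.0, config_block_shift = 2.0,
                        normal_dispersion = 0.7,
                        n_normal_marker = 20, n_cd_marker = 15,
                        hs_cd_fraction = 0.4,
                        depth_meanlog = log(20000), depth_sdlog = 0.25,
                        n_food_items = 40, diet_shift = 1.0,
                        soft_drink_shift = 1.0, zero_inflation = 0.2,
                        antibiotics_or = 4, cardio_or = 0.25, age_shift = 8,
                        marker_r = 0.6,
                        seed = 1L) {
  spec <- as.list(environment())
  if (n_control_samples < n_control_patients || n_cd_samples < n_cd_patients)
    stop("sample counts cannot be below patient counts")
  if (abs(sum(block_weights) - 1) > 1e-9) stop("block_weights must sum to 1")
  if (hs_cd_fraction < 0 || hs_cd_fraction > 1)
    stop("hs_cd_fraction must lie in [0, 1]")
  block_sizes <- diff(round(cumsum(c(0, block_weights)) * n_genera))
  if (n_normal_marker > sum(block_sizes[1:2]))
    stop("normal marker set larger than the health-associated blocks")
  if (n_cd_marker > sum(block_sizes[3:4]))
    stop("CD marker set larger than the pathogen blocks")
  spec$block_sizes <- block_sizes
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> control %d/%d, CD %d/%d, HS %d ",
                     "(patients/samples); %d genera in 4 blocks\n"),
              x$n_control_patients, x$n_control_samples,
              x$n_cd_patients, x$n_cd_samples, x$n_hs_patients, x$n_genera))
  invisible(x)
}

marker_panel_names <- c("IL-12", "IL-23", "IL-6", "TNFa", "leptin",
                        "adiponectin", "CRP", "C5a", "Gas6",
                        "faecal_calprotectin")

# distribute n_samples over n_patients: everyone gets one, extras cycle
assign_replicates <- function(n_patients, n_samples) {
  if (n_patients == 0) return(integer(0))
  reps <- rep(1L, n_patients)
  extra <- n_samples - n_patients
  if (extra > 0) {
    idx <- rep(seq_len(n_patients), length.out = extra)
    reps <- reps + tabulate(idx, n_patients)
  }
  reps
}

#' Generate a synthetic cohort
#'
#' Draws a full synthetic data set from a [cohort_spec()]: genus counts via
#' latent log-normal block factors and multinomial sampling at a drawn depth,
#' sample metadata (patients, studies, groups, drug exposures, demographics),
#' an FFQ-style diet table, an inflammatory-marker panel for the HS samples,
#' and a `truth` record of every planted parameter. Output is bit-identical
#' for a given spec (the seed lives in the spec).
#'
#' @param spec a [cohort_spec()].
#' @return list with `abundance` (counts-mode [abundance_table()]),
#'   `metadata` (data frame), `diet` (matrix), `markers` (matrix, HS samples),
#'   `truth` (list).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  bs <- spec$block_sizes
  n_genera <- sum(bs)
  block <- rep(seq_len(4), bs)
  genus_names <- sprintf("g%03d_b%d", seq_len(n_genera), block)

  # configuration marker sets: health-block genera depleted by the CD-like
  # configuration, pathogen-block genera enriched by it
  health_pool <- which(block %in% 1:2)
  path_pool <- which(block %in% 3:4)
  normal_idx <- health_pool[seq_len(spec$n_normal_marker)]
  cd_idx <- path_pool[seq_len(spec$n_cd_marker)]
  # dysbiosis reshapes most of the community, not just a few taxa: every
  # genus shifts in its block's direction with a genus-specific magnitude;
  # the marker sets carry the full effect
  block_sign <- c(-1, -1, 1, 1)
  lfc <- block_sign[block] * stats::runif(n_genera, 0.2, 0.8) * spec$config_lfc
  lfc[normal_idx] <- -spec$config_lfc
  lfc[cd_idx] <- spec$config_lfc

  # rank-abundance spread; pathogen-block genera start rarer (blooms grow
  # from low-abundance taxa, which also keeps their enrichment visible after
  # compositional renormalisation)
  base <- stats::rnorm(n_genera, 0, 1.3) + spec$pathogen_base_offset * (block >= 3)

  # ---- design: patients, replicates, studies, configurations -------------
  groups <- c("control", "CD", "HS")
  n_pat <- c(spec$n_control_patients, spec$n_cd_patients, spec$n_hs_patients)
  n_smp <- c(spec$n_control_samples, spec$n_cd_samples, spec$n_hs_patients)
  pat_group <- rep(groups, n_pat)
  pat_id <- unlist(lapply(seq_along(groups), function(i)
    sprintf("P_%s_%03d", groups[i], seq_len(n_pat[i]))))
  # controls drawn from both studies; CD from study B, HS from study A
  pat_study <- character(length(pat_id))
  pat_study[pat_group == "control"] <-
    rep(c("studyA", "studyB"), length.out = sum(pat_group == "control"))
  pat_study[pat_group == "CD"] <- "studyB"
  pat_study[pat_group == "HS"] <- "studyA"
  pat_config <- ifelse(pat_group == "CD", "cd_like", "control_like")
  hs_pat <- which(pat_group == "HS")
  pat_config[hs_pat] <- ifelse(
    stats::rbinom(length(hs_pat), 1, spec$hs_cd_fraction) == 1,
    "cd_like", "control_like")

  reps <- unlist(lapply(seq_along(groups), function(i)
    assign_replicates(n_pat[i], n_smp[i])))
  smp_pat <- rep(seq_along(pat_id), reps)
  n <- length(smp_pat)
  smp_id <- sprintf("S%04d", seq_len(n))
  smp_group <- pat_group[smp_pat]
  smp_study <- pat_study[smp_pat]
  smp_config <- pat_config[smp_pat]

  # ---- genus counts ------------------------------------------------------
  study_offset <- matrix(stats::rnorm(2 * n_genera, 0, spec$study_sigma),
                         2, n_genera, dimnames = list(c("studyA", "studyB"), NULL))
  z_pat <- matrix(stats::rnorm(length(pat_id) * 4), length(pat_id), 4)
  counts <- matrix(0L, n, n_genera, dimnames = list(smp_id, genus_names))
  depth <- pmax(1000L, as.integer(round(
    stats::rlnorm(n, spec$depth_meanlog, spec$depth_sdlog))))
  sr <- sqrt(spec$block_rho)
  sn <- sqrt(1 - spec$block_rho)
  # the CD-like configuration also shifts the block latent means: health
  # blocks (1, 2) down, pathogen blocks (3, 4) up -- whole CAGs move.
  # Normal-configuration communities are the more stable ones (colonisation
  # resistance; the "Anna Karenina" dispersion effect), so their latent
  # factors are drawn with tighter dispersion.
  for (i in seq_len(n)) {
    disp <- if (smp_config[i] == "cd_like") 1 else spec$normal_dispersion
    z_smp <- disp * (sqrt(spec$patient_icc) * z_pat[smp_pat[i], ] +
                       sqrt(1 - spec$patient_icc) * stats::rnorm(4)) +
      block_sign * spec$config_block_shift * (smp_config[i] == "cd_like")
    eps <- stats::rnorm(n_genera)
    loglam <- base + study_offset[smp_study[i], ] +
      spec$block_sigma * (sr * z_smp[block] + sn * eps) +
      lfc * (smp_config[i] == "cd_like")
    p <- exp(loglam - max(loglam))
    counts[i, ] <- stats::rmultinom(1, depth[i], p / sum(p))[, 1]
  }

  # ---- metadata ----------------------------------------------------------
  pat_age <- stats::rnorm(length(pat_id), 45, 12) +
    spec$age_shift * (pat_group == "HS" & pat_config == "control_like")
  pat_age <- pmax(18, pat_age)
  config_num <- as.numeric(pat_config == "cd_like")
  plogis_or <- function(base_p, or) {
    stats::plogis(stats::qlogis(base_p) + log(or) * config_num)
  }
  antibiotics <- stats::rbinom(length(pat_id), 1,
                               plogis_or(0.33, spec$antibiotics_or)) == 1
  cardio <- stats::rbinom(length(pat_id), 1,
                          plogis_or(0.40, spec$cardio_or)) == 1
  metadata <- data.frame(
    sample_id = smp_id,
    patient_id = pat_id[smp_pat],
    group = factor(smp_group, levels = groups),
    study = smp_study,
    age = round(pat_age[smp_pat], 1),
    age_at_diagnosis = round(pmax(10, pat_age[smp_pat] -
                                    stats::runif(n, 2, 15)), 1),
    gender = sample(c("F", "M"), n, replace = TRUE)[
      match(smp_pat, smp_pat)],
    hurley = ifelse(smp_group == "HS", sample(1:3, n, replace = TRUE,
                                              prob = c(0.4, 0.4, 0.2)), NA),
    antibiotics_last_year = antibiotics[smp_pat],
    current_antibiotics = stats::rbinom(n, 1, 0.10) == 1,
    cardiovascular_drugs = cardio[smp_pat],
    surgery = stats::rbinom(n, 1, 0.30) == 1,
    anti_tnf_current = stats::rbinom(n, 1, 0.20) == 1,
    anti_tnf_previous = stats::rbinom(n, 1, 0.15) == 1,
    immunomodulator = stats::rbinom(n, 1, 0.15) == 1,
    stringsAsFactors = FALSE)

  # ---- diet --------------------------------------------------------------
  n_items <- spec$n_food_items
  n_west <- min(10, n_items)
  n_fibre <- min(10, max(0, n_items - n_west))
  item_names <- c("carbonated_soft_drinks",
                  paste0("western_", seq_len(max(0, n_west - 1))),
                  paste0("fibre_", seq_len(n_fibre)),
                  paste0("item_", seq_len(n_items - n_west - n_fibre)))
  item_mu <- stats::rnorm(n_items, log(0.5), 0.6)
  west <- seq_len(n_west)
  fibre <- n_west + seq_len(n_fibre)
  shift <- matrix(0, n, n_items)
  disease <- smp_group %in% c("CD", "HS")
  shift[disease, west] <- spec$diet_shift
  shift[!disease, fibre] <- spec$diet_shift
  shift[smp_config == "cd_like", 1] <-
    shift[smp_config == "cd_like", 1] + spec$soft_drink_shift
  # subject-level zero inflation, over-dispersed positive frequencies
  consumed <- matrix(stats::rbinom(length(pat_id) * n_items, 1,
                                   1 - spec$zero_inflation) == 1,
                     length(pat_id), n_items)[smp_pat, , drop = FALSE]
  diet <- matrix(stats::rgamma(n * n_items, shape = 2,
                               scale = exp(sweep(shift, 2, item_mu, "+")) / 2),
                 n, n_items) * consumed
  dimnames(diet) <- list(smp_id, item_names)

  # ---- inflammatory markers (HS samples only, as assayed from serum) -----
  hs_samples <- smp_id[smp_group == "HS"]
  rel <- sweep(counts[hs_samples, , drop = FALSE], 1,
               rowSums(counts[hs_samples, , drop = FALSE]), "/")
  latent <- function(idx) {
    v <- log(rowSums(rel[, idx, drop = FALSE]) + 1e-6)
    as.numeric(scale(v))
  }
  couple <- function(z, r) r * z + sqrt(1 - r^2) * stats::rnorm(length(z))
  r <- spec$marker_r
  nh <- length(hs_samples)
  markers <- matrix(stats::rnorm(nh * 10), nh, 10,
                    dimnames = list(hs_samples, marker_panel_names))
  marker_couplings <- data.frame(
    marker = c("IL-12", "Gas6", "faecal_calprotectin", "C5a"),
    target = c("normal", "normal", "cd", "cd"),
    r = c(-r, r, r, r), stringsAsFactors = FALSE)
  if (r != 0) {
    z_norm <- latent(normal_idx)
    z_cd <- latent(cd_idx)
    for (k in seq_len(nrow(marker_couplings))) {
      z <- if (marker_couplings$target[k] == "normal") z_norm else z_cd
      markers[, marker_couplings$marker[k]] <-
        couple(z, abs(marker_couplings$r[k])) * sign(marker_couplings$r[k])
    }
  }
  # shift to positive assay-like scales
  markers <- sweep(markers, 2, 5 + abs(stats::rnorm(10)), "+")
  markers <- pmax(markers, 0.01)

  truth <- list(
    configuration = stats::setNames(smp_config, smp_id),
    patient_configuration = stats::setNames(pat_config, pat_id),
    genus_block = stats::setNames(block, genus_names),
    normal_genera = genus_names[normal_idx],
    cd_genera = genus_names[cd_idx],
    config_lfc = spec$config_lfc,
    antibiotics_or = spec$antibiotics_or,
    cardio_or = spec$cardio_or,
    diet_shifted_items = list(western = item_names[west],
                              fibre = item_names[fibre]),
    soft_drink_item = item_names[1],
    marker_couplings = marker_couplings,
    depth = stats::setNames(depth, smp_id))

  list(abundance = abundance_table(counts, mode = "counts"),
       metadata = metadata,
       diet = diet,
       markers = markers,
       truth = truth)
}

#' Generate a null cohort (all couplings zeroed)
#'
#' Same design as [generate_cohort()] but with every planted effect removed:
#' no configuration shifts, no diet group shifts, covariate odds ratios of 1,
#' no marker couplings and no age shift. Group labels and the co-abundance
#' block structure are retained, so downstream tests can be calibrated
#' against an exchangeable null.
#'
#' @param spec a [cohort_spec()].
#' @return as [generate_cohort()].
#' @export
generate_null_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  null_spec <- spec
  null_spec$config_lfc <- 0
  null_spec$config_block_shift <- 0
  null_spec$diet_shift <- 0
  null_spec$soft_drink_shift <- 0
  null_spec$antibiotics_or <- 1
  null_spec$cardio_or <- 1
  null_spec$age_shift <- 0
  null_spec$marker_r <- 0
  null_spec$study_sigma <- 0
  generate_cohort(null_spec)
}

#' Write a generated cohort to a directory of TSV files
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance_table(cohort$abundance, file.path(dir, "abundance.tsv"))
  utils::write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_sample_matrix(cohort$diet, file.path(dir, "diet.tsv"))
  write_sample_matrix(cohort$markers, file.path(dir, "markers.tsv"))
  invisible(dir)
}
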