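#' Construct a genus-by-sample abundance table
#'
#' The central container of the package: a numeric matrix of non-negative
#' abundances with samples in rows and genera in columns, tagged with a mode
#' flag distinguishing raw counts from per-sample proportions.
#'
#' @param values numeric matrix, samples in rows, genera in columns.
#' @param sample_ids character vector of unique sample identifiers
#'   (defaults to `rownames(values)`, or `s1..sn` when unnamed).
#' @param genus_ids character vector of unique genus identifiers
#'   (defaults to `colnames(values)`, or `g1..gm` when unnamed).
#' @param mode `"counts"` or `"relative"`. In relative mode every sample row
#'   must sum to 1 (tolerance 1e-9).
#' @return an object of class `abundance_table`: the matrix with dimnames set
#'   and a `mode` attribute.
#' @export
abundance_table <- function(values, sample_ids = rownames(values),
                            genus_ids = colnames(values),
                            mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- sprintf("s%d", seq_len(nrow(values)))
  if (is.null(genus_ids)) genus_ids <- sprintf("g%d", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  genus_ids <- as.character(genus_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(genus_ids))
    stop("duplicate genus ids: ",
         paste(unique(genus_ids[duplicated(genus_ids)]), collapse = ", "))
  if (length(sample_ids) != nrow(values) || length(genus_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions")
  if (anyNA(values)) stop("abundance values must not contain NA")
  if (any(values < 0)) stop("negative abundance values are not allowed")
  dimnames(values) <- list(sample_ids, genus_ids)
  if (mode == "relative") {
    rs <- rowSums(values)
    bad <- abs(rs - 1) > 1e-9
    if (any(bad))
      stop("relative-mode rows must sum to 1; offending sample(s): ",
           paste(sample_ids[bad], collapse = ", "))
  }
  structure(values, mode = mode, class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d samples x %d genera (%s mode)\n",
              nrow(x), ncol(x), table_mode(x)))
  invisible(x)
}

#' Mode flag of an abundance table
#' @param t an `abundance_table`.
#' @return `"counts"` or `"relative"`.
#' @export
table_mode <- function(t) attr(t, "mode")

sample_ids <- function(t) rownames(t)
genus_ids <- function(t) colnames(t)

#' Read a genus abundance table from TSV
#'
#' Expects a tab-separated file with a header row. By default genera are rows
#' and samples are columns (the common deposition layout); set
#' `orientation = "samples_rows"` for the transpose, or supply
#' `metadata_samples` to auto-detect the orientation by matching header tokens
#' against a known sample universe. Duplicate genus rows (e.g. several ASVs
#' assigned the same genus) are summed.
#'
#' @param path file path to a TSV.
#' @param orientation `"genera_rows"`, `"samples_rows"`, or `"auto"`.
#' @param metadata_samples optional character vector of known sample ids used
#'   by `"auto"` orientation detection.
#' @return a counts-mode [abundance_table()].
#' @export
read_abundance_table <- function(path,
                                 orientation = c("genera_rows", "samples_rows", "auto"),
                                 metadata_samples = NULL) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected at least one id column and one data column")
  ids <- as.character(df[[1]])
  m <- df[, -1, drop = FALSE]
  for (j in seq_len(ncol(m))) {
    v <- m[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (anyNA(num)) {
        bad <- which(is.na(num))[1]
        stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                     v[bad], ids[bad], colnames(m)[j]))
      }
      m[[j]] <- num
    }
  }
  m <- as.matrix(m)
  if (orientation == "auto") {
    if (is.null(metadata_samples))
      stop("orientation 'auto' requires metadata_samples")
    hdr_hits <- mean(colnames(m) %in% metadata_samples)
    id_hits <- mean(ids %in% metadata_samples)
    orientation <- if (hdr_hits >= id_hits) "genera_rows" else "samples_rows"
  }
  if (orientation == "genera_rows") {
    genera <- ids
    samples <- colnames(m)
    values <- t(m)
  } else {
    genera <- colnames(m)
    samples <- ids
    values <- m
  }
  if (anyDuplicated(samples))
    stop("duplicate sample id in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyDuplicated(genera)) {
    # sum ASV rows sharing a genus label
    values <- rowsum(t(values), group = genera)
    genera <- rownames(values)
    values <- t(values)
  }
  rownames(values) <- samples
  colnames(values) <- genera
  abundance_table(values, mode = "counts")
}

#' Write an abundance table to TSV (genera in rows)
#' @param t an `abundance_table`.
#' @param path output file path.
#' @export
write_abundance_table <- function(t, path) {
  df <- data.frame(genus_id = genus_ids(t), t(unclass(t)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate an ASV-level table to genus level
#'
#' Sums ASV columns sharing a genus label. ASVs with a missing/empty genus
#' assignment are dropped with a message reporting how many were discarded.
#'
#' @param t counts-mode `abundance_table` whose columns are ASVs.
#' @param genus_map character vector mapping each ASV column to a genus label;
#'   `NA` or `""` marks an unassigned ASV.
#' @return a counts-mode genus-level `abundance_table`.
#' @export
aggregate_to_genus <- function(t, genus_map) {
  if (length(genus_map) != ncol(t))
    stop("genus_map must have one entry per ASV column")
  genus_map <- as.character(genus_map)
  unassigned <- is.na(genus_map) | genus_map == ""
  if (any(unassigned))
    message(sum(unassigned), " unassigned ASV(s) dropped during genus aggregation")
  keep <- !unassigned
  if (!any(keep)) stop("no assigned ASVs remain")
  values <- rowsum(t(unclass(t)[, keep, drop = FALSE]), group = genus_map[keep])
  abundance_table(t(values), mode = "counts")
}

#' Prevalence filter for rare genera
#'
#' Retains genera detected (count strictly greater than zero) in at least
#' `min_fraction` of samples; the boundary is inclusive, so with the default
#' a genus present in exactly 10% of samples is kept. Removed genera are
#' reported via `message()`.
#'
#' @param t an `abundance_table` (counts or relative).
#' @param min_fraction minimum fraction of samples a genus must be present in
#'   (default 0.10).
#' @return the filtered `abundance_table`.
#' @export
prevalence_filter <- function(t, min_fraction = 0.10) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  prev <- colMeans(unclass(t) > 0)
  keep <- prev >= min_fraction - 1e-12
  if (!any(keep)) stop("prevalence filter removed every genus")
  dropped <- genus_ids(t)[!keep]
  if (length(dropped))
    message("prevalence filter removed ", length(dropped), " genera: ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ..." else "")
  abundance_table(unclass(t)[, keep, drop = FALSE], mode = table_mode(t))
}

#' Convert counts to per-sample relative abundances
#' @param t a counts-mode `abundance_table` with positive sample totals.
#' @return a relative-mode `abundance_table` (rows sum to 1).
#' @export
to_relative <- function(t) {
  if (table_mode(t) == "relative") return(t)
  totals <- rowSums(unclass(t))
  zero <- totals == 0
  if (any(zero))
    stop("sample(s) with zero total count: ",
         paste(sample_ids(t)[zero], collapse = ", "))
  abundance_table(sweep(unclass(t), 1, totals, "/"), mode = "relative")
}

#' Restrict a set of tables to their common samples
#'
#' Takes any number of sample-indexed objects (abundance tables, diet tables,
#' marker panels -- anything with sample ids in `rownames` -- or metadata
#' data frames with a `sample_id` column) and restricts each to the
#' intersection of sample ids, in one canonical (sorted) order.
#'
#' @param ... two or more tables.
#' @return a list of the same tables, each restricted and reordered; dropped
#'   ids are reported via `message()`.
#' @export
align_samples <- function(...) {
  tables <- list(...)
  if (length(tables) == 1 && is.list(tables[[1]]) && is.null(dim(tables[[1]])))
    tables <- tables[[1]]
  if (length(tables) < 2) stop("align_samples needs at least two tables")
  get_ids <- function(x) {
    if (is.data.frame(x) && "sample_id" %in% names(x)) as.character(x$sample_id)
    else rownames(x)
  }
  universes <- lapply(tables, get_ids)
  common <- Reduce(intersect, universes)
  if (length(common) == 0) stop("tables share no sample ids")
  common <- sort(common)
  dropped <- unique(unlist(lapply(universes, setdiff, y = common)))
  if (length(dropped))
    message("align_samples dropped ", length(dropped), " sample(s): ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ..." else "")
  out <- lapply(tables, function(x) {
    if (is.data.frame(x) && "sample_id" %in% names(x)) {
      x[match(common, as.character(x$sample_id)), , drop = FALSE]
    } else if (inherits(x, "abundance_table")) {
      abundance_table(unclass(x)[common, , drop = FALSE], mode = table_mode(x))
    } else {
      x[common, , drop = FALSE]
    }
  })
  names(out) <- names(tables)
  out
}

#' Read a sample metadata table
#'
#' Requires columns `sample_id`, `patient_id`, `group` and `study`; any other
#' columns (age, Hurley score, drug exposures, ...) are carried through.
#' Checks that every sample maps to exactly one patient.
#'
#' @param path TSV file path.
#' @param group_levels allowed group labels (default control/CD/HS).
#' @return a data frame with `group` as a factor.
#' @export
read_metadata <- function(path, group_levels = c("control", "CD", "HS")) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("sample_id", "patient_id", "group", "study")
  missing <- setdiff(required, names(md))
  if (length(missing))
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata")
  bad <- setdiff(unique(md$group), group_levels)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  md$group <- factor(md$group, levels = group_levels)
  md
}

#' Read a diet frequency table
#'
#' TSV with samples in rows, food items in columns; values are habitual daily
#' frequencies of consumption (non-negative).
#'
#' @param path TSV file path; first column holds sample ids.
#' @return a numeric matrix, samples x food items.
#' @export
read_diet_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  if (anyDuplicated(rownames(m))) stop("duplicate sample id in diet table")
  if (any(m < 0, na.rm = TRUE)) stop("diet frequencies must be non-negative")
  m
}

#' Read an inflammatory marker panel
#'
#' TSV with samples in rows and markers in columns (assay concentrations).
#' Missing values are allowed; a message reports how many are present.
#'
#' @param path TSV file path; first column holds sample ids.
#' @return a numeric matrix, samples x markers, possibly with NAs.
#' @export
read_marker_panel <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  if (anyDuplicated(rownames(m))) stop("duplicate sample id in marker panel")
  if (any(m < 0, na.rm = TRUE)) stop("marker concentrations must be non-negative")
  if (anyNA(m)) message(sum(is.na(m)), " missing marker value(s)")
  m
}

#' Write a generic samples-in-rows matrix as TSV
#' @param m numeric matrix with rownames.
#' @param path output path.
#' @param id_col name for the id column.
#' @export
write_sample_matrix <- function(m, path, id_col = "sample_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
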