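test_that("abundance tables round-trip through TSV and validate input", {
  m <- random_counts(4, 6, seed = 1)
  t1 <- abundance_table(m, mode = "counts")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(t1, path)
  t2 <- read_abundance_table(path)
  expect_equal(unclass(t2)[rownames(t1), colnames(t1)], unclass(t1),
               ignore_attr = TRUE)

  expect_error(abundance_table(-m), "negative")
  expect_error(abundance_table(m, sample_ids = rep("s", 4)), "duplicate sample")
  rel <- sweep(m, 1, rowSums(m), "/")
  expect_silent(abundance_table(rel, mode = "relative"))
  expect_error(abundance_table(rel * 2, mode = "relative"), "sum to 1")
})

test_that("reading sums duplicate genus rows and rejects bad cells", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genus\ts1\ts2", "gA\t2\t1", "gA\t3\t0", "gB\t1\t1"), path)
  t <- read_abundance_table(path)
  expect_equal(ncol(t), 2)
  expect_equal(unname(unclass(t)["s1", "gA"]), 5)

  writeLines(c("genus\ts1\ts2", "gA\t2\tx"), path)
  expect_error(read_abundance_table(path), "non-numeric")
  writeLines(c("genus\ts1\ts2", "gA\t-2\t1"), path)
  expect_error(read_abundance_table(path), "negative")
})

test_that("orientation auto-detection matches header tokens to sample ids", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgA\tgB", "s1\t2\t1", "s2\t3\t0"), path)
  t <- read_abundance_table(path, orientation = "auto",
                            metadata_samples = c("s1", "s2"))
  expect_setequal(rownames(t), c("s1", "s2"))
  expect_setequal(colnames(t), c("gA", "gB"))
})

test_that("prevalence filter keeps the inclusive 10% boundary and is idempotent", {
  m <- matrix(0, 10, 3, dimnames = list(paste0("s", 1:10), c("gA", "gB", "gC")))
  m[, 1] <- 5
  m[1, 2] <- 1          # present in exactly 1/10 samples: boundary, kept
  f <- suppressMessages(prevalence_filter(abundance_table(m), 0.10))
  expect_setequal(colnames(f), c("gA", "gB"))

  m2 <- matrix(0, 20, 2, dimnames = list(paste0("s", 1:20), c("gA", "gB")))
  m2[, 1] <- 2
  m2[1, 2] <- 1         # 5% < 10%: removed
  f2 <- suppressMessages(prevalence_filter(abundance_table(m2), 0.10))
  expect_identical(colnames(f2), "gA")

  f3 <- suppressMessages(prevalence_filter(f2, 0.10))
  expect_identical(unclass(f3), unclass(f2))

  expect_error(suppressMessages(
    prevalence_filter(abundance_table(m2 * 0 + 0), 0.10)), "every genus")
})

test_that("to_relative divides by sample totals and flags zero samples", {
  m <- rbind(s1 = c(2, 2, 0), s2 = c(5, 0, 0))
  colnames(m) <- c("gA", "gB", "gC")
  r <- to_relative(abundance_table(m))
  expect_equal(unname(unclass(r)["s1", ]), c(0.5, 0.5, 0))
  expect_equal(unname(unclass(r)["s2", ]), c(1, 0, 0))
  expect_equal(unname(rowSums(unclass(r))), c(1, 1), tolerance = 1e-12)
  expect_identical(table_mode(r), "relative")

  m0 <- rbind(s1 = c(1, 1), s2 = c(0, 0))
  colnames(m0) <- c("gA", "gB")
  expect_error(to_relative(abundance_table(m0)), "s2")
})

test_that("row sums stay 1 after to_relative on random tables", {
  for (seed in 1:5) {
    t <- abundance_table(random_counts(8, 12, seed = seed))
    expect_true(all(abs(rowSums(unclass(to_relative(t))) - 1) < 1e-9))
  }
})

test_that("align_samples intersects universes in canonical order", {
  tA <- abundance_table(random_counts(4, 3, seed = 2))
  mB <- random_counts(4, 5, seed = 3)
  rownames(mB) <- c("s02", "s03", "s04", "s05")
  tB <- abundance_table(mB)
  out <- suppressMessages(align_samples(tA, tB))
  expect_identical(rownames(out[[1]]), c("s02", "s03", "s04"))
  expect_identical(rownames(out[[1]]), rownames(out[[2]]))

  out2 <- suppressMessages(align_samples(tA, tA))
  expect_identical(unclass(out2[[1]]), unclass(out2[[2]]))

  mC <- random_counts(3, 3, seed = 4)
  rownames(mC) <- paste0("x", 1:3)
  expect_error(suppressMessages(align_samples(tA, abundance_table(mC))),
               "no sample ids")
})

test_that("ASV aggregation sums shared genus labels and drops unassigned", {
  m <- random_counts(3, 4, seed = 5)
  t <- abundance_table(m)
  g <- aggregate_to_genus(t, c("gX", "gX", NA, "gY"))
  expect_setequal(colnames(g), c("gX", "gY"))
  expect_equal(unname(unclass(g)[, "gX"]), unname(m[, 1] + m[, 2]))
  expect_message(aggregate_to_genus(t, c("gX", "gX", NA, "gY")), "unassigned")
})

test_that("metadata reader enforces required columns and group labels", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tpatient_id\tgroup\tstudy",
               "s1\tp1\tcontrol\tA", "s2\tp1\tCD\tA"), path)
  md <- read_metadata(path)
  expect_s3_class(md$group, "factor")
  writeLines(c("sample_id\tpatient_id\tgroup",
               "s1\tp1\tcontrol"), path)
  expect_error(read_metadata(path), "study")
  writeLines(c("sample_id\tpatient_id\tgroup\tstudy",
               "s1\tp1\tUC\tA"), path)
  expect_error(read_metadata(path), "UC")
})
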