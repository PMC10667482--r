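euclid <- function(pts) {
  d <- as.matrix(dist(pts))
  microconfig:::new_dist_matrix(d, rownames(pts), "euclidean_2d")
}

test_that("PCoA reconstructs Euclidean configurations", {
  # collinear points: PCo1 recovers the line, second eigenvalue ~ 0
  pts <- cbind(x = c(0, 1, 2, 5), y = 0)
  rownames(pts) <- paste0("s", 1:4)
  ord <- suppressWarnings(pcoa(euclid(pts), k = 2))
  expect_gt(abs(cor(ord$coordinates[, 1], pts[, "x"])), 1 - 1e-9)
  expect_lt(ord$eigenvalues[2] / ord$eigenvalues[1], 1e-9)

  # 2-D and 3-D clouds: pairwise coordinate distances equal the input
  for (k in 2:3) {
    set.seed(k)
    pts <- matrix(rnorm(12 * k), 12, k, dimnames = list(paste0("s", 1:12), NULL))
    ord <- pcoa(euclid(pts), k = k)
    expect_equal(as.matrix(dist(ord$coordinates)), as.matrix(dist(pts)),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_true(all(abs(colMeans(ord$coordinates)) < 1e-9))
  }

  # duplicated samples land on identical coordinates
  pts <- rbind(a = c(0, 0), b = c(1, 0), b2 = c(1, 0), c = c(0, 2))
  ord <- pcoa(euclid(pts), k = 2)
  expect_equal(ord$coordinates["b", ], ord$coordinates["b2", ],
               tolerance = 1e-9)
})

test_that("PCoA agrees with classical MDS as an independent route", {
  m <- random_counts(10, 8, seed = 21)
  d <- bray_curtis(to_relative(abundance_table(m)))
  ord <- pcoa(d, k = 2)
  cmd <- cmdscale(as.dist(as.matrix(d)), k = 2, eig = TRUE)
  for (j in 1:2)
    expect_equal(abs(ord$coordinates[, j]), abs(cmd$points[, j]),
                 tolerance = 1e-7, ignore_attr = TRUE)
  expect_true(all(ord$explained >= 0 & ord$explained <= 1))
  expect_true(length(ord$negative_eigenvalues) >= 0)
  expect_warning(pcoa(d, k = 50), "truncating")
})

test_that("median centroid is the coordinate-wise median on PCo1/2", {
  coords <- rbind(r1 = c(1, 0), r2 = c(-1, 0), r3 = c(0, 1), r4 = c(0, -1),
                  q = c(3, 4))
  ord <- structure(list(coordinates = coords, eigenvalues = c(2, 1),
                        explained = c(0.6, 0.4),
                        negative_eigenvalues = numeric(0)),
                   class = "ordination")
  groups <- setNames(c("ref", "ref", "ref", "ref", "other"), rownames(coords))
  cd <- median_centroid(ord, "ref", groups)
  expect_equal(unname(cd$centroid), c(0, 0))
  expect_equal(unname(cd$distance["q"]), 5)

  # translation invariance
  ord2 <- ord; ord2$coordinates <- coords + 7
  cd2 <- median_centroid(ord2, "ref", groups)
  expect_equal(cd2$distance, cd$distance, tolerance = 1e-12)

  # singleton reference has distance zero to itself
  cd3 <- median_centroid(ord, "other", groups)
  expect_equal(unname(cd3$distance["q"]), 0)
  expect_error(median_centroid(ord, "missing", groups), "absent")
})

test_that("centroid group test delegates to the rank machinery", {
  set.seed(31)
  coords <- matrix(rnorm(60), 30, 2, dimnames = list(paste0("s", 1:30), NULL))
  ord <- structure(list(coordinates = coords), class = "ordination")
  groups <- setNames(rep(c("a", "b", "c"), each = 10), rownames(coords))
  cd <- median_centroid(ord, "a", groups)
  out <- centroid_group_test(cd, groups)
  expect_equal(nrow(out$pairwise), 3)
  # identical distances in all groups give p = 1
  cd$distance[] <- rep(1:10, 3)
  out2 <- centroid_group_test(cd, groups)
  expect_equal(out2$omnibus$p, 1)
})

test_that("PERMANOVA partitions SS additively and is seed-reproducible", {
  co <- generate_cohort(small_spec(seed = 41, n_control = 20, n_cd = 20))
  md <- co$metadata[co$metadata$group %in% c("control", "CD"), ]
  rel <- to_relative(suppressMessages(prevalence_filter(
    abundance_table(unclass(co$abundance)[md$sample_id, , drop = FALSE]))))
  d <- bray_curtis(rel)
  fit1 <- permanova(d, md, terms = c("study", "group"), n_perm = 99, seed = 7)
  fit2 <- permanova(d, md, terms = c("study", "group"), n_perm = 99, seed = 7)
  expect_identical(fit1$table, fit2$table)
  tab <- fit1$table
  expect_equal(sum(tab$SS[tab$term != "Total"]), tab$SS[tab$term == "Total"],
               tolerance = 1e-9)
  expect_true(all(tab$R2 >= 0 & tab$R2 <= 1))
  expect_gte(permanova_term(fit1)$p, 1 / 100)
})

test_that("a confounder orthogonal to the grouping leaves its R2 unchanged", {
  set.seed(43)
  n <- 40
  md <- data.frame(sample_id = paste0("s", 1:n),
                   group = rep(c("a", "b"), each = n / 2),
                   batch = rep(c("x", "y"), times = n / 2))  # balanced
  pts <- matrix(rnorm(2 * n), n, 2)
  pts[md$group == "b", 1] <- pts[md$group == "b", 1] + 2
  rownames(pts) <- md$sample_id
  d <- euclid(pts)
  r2_alone <- permanova_term(permanova(d, md, "group", n_perm = 99, seed = 1))$R2
  r2_adj <- permanova_term(permanova(d, md, c("batch", "group"),
                                     term_of_interest = "group",
                                     n_perm = 99, seed = 1))$R2
  expect_equal(r2_adj, r2_alone, tolerance = 1e-9)
})

test_that("confounders nesting the grouping are dropped with a warning", {
  co <- generate_cohort(small_spec(seed = 47, n_control = 15, n_cd = 15))
  md <- co$metadata[co$metadata$group %in% c("control", "CD"), ]
  rel <- to_relative(abundance_table(unclass(co$abundance)[md$sample_id, ]))
  d <- bray_curtis(rel)
  expect_warning(
    fit <- permanova(d, md, terms = c("patient_id", "group"), n_perm = 99,
                     seed = 1),
    "nests")
  expect_true("patient_id" %in% fit$dropped)
  expect_true("group" %in% fit$table$term)
  expect_error(permanova(d, md, terms = "group", n_perm = 10, seed = 1), ">= 99")
})

test_that("pairwise PERMANOVA covers all pairs with BH correction", {
  co <- generate_cohort(small_spec(seed = 53, n_control = 12, n_cd = 12,
                                   n_hs = 12))
  md <- co$metadata
  rel <- to_relative(abundance_table(unclass(co$abundance)[md$sample_id, ]))
  d <- bray_curtis(rel)
  pp <- suppressWarnings(pairwise_permanova(d, md, "group", n_perm = 99,
                                            seed = 3))
  expect_equal(nrow(pp), 3)
  expect_true(all(pp$q >= pp$p - 1e-12))
  pp2 <- suppressWarnings(pairwise_permanova(d, md, "group", n_perm = 99,
                                             seed = 3))
  expect_identical(pp, pp2)
})
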