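# Brute-force reference implementations, kept deliberately naive and
# independent of the package's code paths.

oracle_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

oracle_bray_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- oracle_bray(m[i, ], m[j, ])
  d
}

# tau-b by explicit pair enumeration with tie handling
oracle_kendall_tau_b <- function(x, y) {
  n <- length(x)
  nc <- nd <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx * dy > 0) nc <- nc + 1
    else nd <- nd + 1
  }
  n0 <- n * (n - 1) / 2
  (nc - nd) / sqrt((n0 - tx) * (n0 - ty))
}

oracle_rank <- function(x) {
  # average ranks by explicit counting
  sapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2)
}

oracle_spearman <- function(x, y) {
  rx <- oracle_rank(x); ry <- oracle_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

oracle_shannon <- function(p) {
  p <- p / sum(p)
  -sum(ifelse(p > 0, p * log(p), 0))
}

oracle_simpson <- function(p) {
  p <- p / sum(p)
  1 - sum(p^2)
}

oracle_kruskal_H <- function(values, labels) {
  labels <- factor(labels)
  N <- length(values)
  r <- oracle_rank(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, labels, function(ri) length(ri) * mean(ri)^2)) -
    3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

oracle_dunn_z <- function(values, labels, g1, g2) {
  labels <- factor(labels)
  N <- length(values)
  r <- oracle_rank(values)
  ties <- table(values)
  v <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  m1 <- mean(r[labels == g1]); m2 <- mean(r[labels == g2])
  n1 <- sum(labels == g1); n2 <- sum(labels == g2)
  (m1 - m2) / sqrt(v * (1 / n1 + 1 / n2))
}

# exact two-sided rank-sum p by complete enumeration (no ties)
oracle_wilcoxon_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(n, na)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mu <- na * (n - na) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

oracle_cohens_d <- function(a, b) {
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  (mean(a) - mean(b)) / sp
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# small random counts table helper
random_counts <- function(n, g, seed, max_count = 50) {
  set.seed(seed)
  m <- matrix(rpois(n * g, lambda = runif(g, 1, max_count)), n, g, byrow = TRUE)
  m[1, ] <- m[1, ] + 1  # avoid all-zero rows
  if (any(rowSums(m) == 0)) m[rowSums(m) == 0, 1] <- 1
  dimnames(m) <- list(sprintf("s%02d", seq_len(n)), sprintf("g%02d", seq_len(g)))
  m
}

small_spec <- function(seed, n_control = 30, n_cd = 30, n_hs = 5, ...) {
  cohort_spec(seed = seed,
              n_control_patients = n_control, n_control_samples = n_control,
              n_cd_patients = n_cd, n_cd_samples = n_cd,
              n_hs_patients = n_hs, ...)
}
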