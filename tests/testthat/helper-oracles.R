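# Brute-force reference implementations, independent of the package's
# compiled shortest-path code: exhaustive simple-path enumeration, direct
# triple sums, explicit normal equations, min-over-tails FDR. Only usable
# at tiny n; that is the point.

oracle_lengths <- function(w, convention = "inverse") {
  len <- matrix(Inf, nrow(w), ncol(w))
  pos <- w > 0
  len[pos] <- switch(convention,
                     inverse = 1 / w[pos],
                     `one-minus` = 1 - w[pos],
                     neglog = -log(w[pos]))
  diag(len) <- 0
  len
}

# All-pairs shortest paths by exhaustive enumeration of simple paths.
oracle_distances <- function(w, convention = "inverse") {
  n <- nrow(w)
  len <- oracle_lengths(w, convention)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  for (src in seq_len(n)) {
    visited <- rep(FALSE, n)
    dfs <- function(v, dist) {
      visited[v] <<- TRUE
      for (u in seq_len(n)) {
        if (!visited[u] && is.finite(len[v, u])) {
          nd <- dist + len[v, u]
          if (nd < best[src, u]) best[src, u] <<- nd
          dfs(u, nd)
        }
      }
      visited[v] <<- FALSE
    }
    dfs(src, 0)
  }
  best
}

oracle_global_efficiency <- function(w, convention = "inverse") {
  d <- oracle_distances(w, convention)
  n <- nrow(w)
  if (n < 2) return(0)
  inv <- 1 / d[row(d) != col(d)]
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(w, convention = "inverse") {
  n <- nrow(w)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(w[nb, nb, drop = FALSE], convention)
  }, numeric(1))
  mean(vals)
}

oracle_cpl <- function(w, convention = "inverse") {
  d <- oracle_distances(w, convention)
  off <- d[row(d) != col(d)]
  if (all(is.infinite(off))) return(Inf)
  mean(off[is.finite(off)])
}

oracle_mean_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx <= 0) return(0)
  wh <- w / mx
  cs <- vapply(seq_len(n), function(i) {
    k <- sum(w[i, ] > 0)
    if (k < 2) return(0)
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h)
        acc <- acc + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
    }
    acc / (k * (k - 1))
  }, numeric(1))
  mean(cs)
}

oracle_strength_degree <- function(w) {
  n <- nrow(w)
  s <- k <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s[i] <- s[i] + w[i, j]
    if (w[i, j] > 0) k[i] <- k[i] + 1
  }
  c(average_strength = mean(s), average_degree = mean(k))
}

oracle_assortativity <- function(w) {
  n <- nrow(w)
  k <- rowSums(w > 0)
  a <- b <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (w[i, j] > 0) {
      a <- c(a, k[i], k[j])
      b <- c(b, k[j], k[i])
    }
  }
  if (length(a) < 4) return(NA_real_)
  ma <- mean(a); mb <- mean(b)
  num <- sum((a - ma) * (b - mb))
  den <- sqrt(sum((a - ma)^2) * sum((b - mb)^2))
  if (den == 0) return(NA_real_)
  num / den
}

oracle_all_measures <- function(w, convention = "inverse") {
  c(global_efficiency = oracle_global_efficiency(w, convention),
    local_efficiency = oracle_local_efficiency(w, convention),
    mean_clustering_coefficient = oracle_mean_clustering(w),
    characteristic_path_length = oracle_cpl(w, convention),
    oracle_strength_degree(w),
    assortative_coefficient = oracle_assortativity(w))
}

# Explicit normal-equations OLS residuals.
oracle_ols_residuals <- function(X, Y) {
  Y - X %*% solve(t(X) %*% X) %*% t(X) %*% Y
}

# Textbook Pearson correlation.
oracle_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# Benjamini-Hochberg by the min-over-tails definition:
# q_i = min over thresholds t in {p_j : p_j >= p_i} of m * t / #{p <= t}.
oracle_fdr <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- p[p >= pi]
    min(1, min(m * ts / vapply(ts, function(t) sum(p <= t), numeric(1))))
  }, numeric(1))
}

random_weight_matrix <- function(n, density = 0.6) {
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  vals <- runif(sum(up))
  keep <- runif(sum(up)) < density
  w[up] <- vals * keep
  w <- w + t(w)
  diag(w) <- 0
  w
}

# Small ready-made fixtures used across files.
k_complete <- function(n, weight = 1) {
  w <- matrix(weight, n, n); diag(w) <- 0; w
}

star_graph <- function(leaves = 3) {
  w <- matrix(0, leaves + 1, leaves + 1)
  w[1, -1] <- w[-1, 1] <- 1
  w
}

path_graph3 <- function() {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  w
}

# The worked 3-node weighted example used repeatedly: w12 = w23 = 0.9,
# w13 = 0.1, so the two-hop route beats the weak direct edge.
two_hop_triangle <- function() {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.9
  w[2, 3] <- w[3, 2] <- 0.9
  w[1, 3] <- w[3, 1] <- 0.1
  w
}

make_test_cohort <- function(sizes = c(a = 12, b = 12), regions = 5,
                             strength = 0, seed = 42) {
  tc <- if (strength > 0)
    correlation_template(regions, "uniform", strength)
  else NULL
  generate_cohort(synthetic_spec(sizes, regions = regions,
                                 target_correlation = tc, seed = seed))
}
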