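# shared small fixtures and independent oracles, built in code

std_design <- function(n_replicates = 4)
  make_design(dilution_series(50, 0.4, 7), n_replicates)

# brute-force Benjamini-Hochberg step-up, written directly from the
# definition as an oracle for bh_adjust()
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rep(NA_real_, m)
  for (i in m:1) {
    val <- p[o[i]] * m / i
    if (i < m) val <- min(val, q[o[i + 1]])
    q[o[i]] <- min(val, 1)
  }
  q
}

# brute-force betweenness by enumerating all simple paths between each node
# pair and counting shortest ones; feasible for <= 12 nodes
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  through <- matrix(0, n, n)  # through[v, ] unused; accumulate per node
  score <- numeric(n)
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(v, seen) {
      if (v == t) { paths[[length(paths) + 1]] <<- seen; return() }
      for (w in which(adj[v, ] > 0)) if (!(w %in% seen)) walk(w, c(seen, w))
    }
    walk(s, s)
    paths
  }
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- all_paths(s, t)
    if (!length(paths)) next
    lens <- lengths(paths)
    sp <- paths[lens == min(lens)]
    for (p in sp) {
      mid <- setdiff(p, c(s, t))
      score[mid] <- score[mid] + 1 / length(sp)
    }
  }
  score / ((n - 1) * (n - 2) / 2)
}

# adjusted Rand index from the contingency-table formula
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_ij <- sum_a * sum_b / choose(n, 2)
  max_ij <- (sum_a + sum_b) / 2
  (sum_ij - exp_ij) / (max_ij - exp_ij)
}
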