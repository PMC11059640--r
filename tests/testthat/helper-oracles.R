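# Independent oracles: brute-force or closed-form computations that never
# share code with the implementation paths they check.

# transition probabilities from the matrix exponential of the linear
# birth-death generator (q[m,m+1] = m r, q[m,m-1] = m r) truncated at `N`
oracle_transition_matrix <- function(t, r = 1, N = 200) {
  Q <- matrix(0, N + 1, N + 1)
  for (m in 0:N) {
    if (m < N) Q[m + 1, m + 2] <- m * r
    if (m > 0) Q[m + 1, m] <- m * r
    Q[m + 1, m + 1] <- -(if (m < N) m * r else 0) - m * r
  }
  as.matrix(Matrix::expm(Q * t))
}

# exhaustive-enumeration log likelihood of one bin: sum over every joint
# assignment of states 0..k to all nodes of the product of the diploid-stem
# root term, per-branch transition probabilities and leaf error densities
oracle_bin_loglik <- function(tree, obs, k, sigma) {
  m <- 2L * tree$ntip - 1L
  G <- as.matrix(expand.grid(rep(list(0:k), m)))
  Pd <- vapply(0:k, function(i)
    transition_probability(i, 2, tree$root_stem_d), numeric(1))
  lp <- log(Pd[G[, tree$root] + 1L])
  rate <- oracle_effective_rates(tree)
  for (v in setdiff(seq_len(m), tree$root)) {
    tlen <- (tree$height[tree$parent[v]] - tree$height[v]) * rate[v]
    P <- outer(0:k, 0:k, Vectorize(function(j, i)
      transition_probability(i, j, tlen)))
    lp <- lp + log(P[cbind(G[, tree$parent[v]] + 1L, G[, v] + 1L)])
  }
  for (v in seq_len(tree$ntip))
    lp <- lp + dnorm(obs[tree$tip_label[v]], G[, v], sigma, log = TRUE)
  M <- max(lp)
  M + log(sum(exp(lp - M)))
}

# independent re-derivation of the random-local-clock rate rule
oracle_effective_rates <- function(tree) {
  m <- 2L * tree$ntip - 1L
  rate <- rep(1, m)
  for (v in setdiff(seq_len(m), tree$root)) {
    u <- v
    while (u != tree$root && !tree$rate_on[u]) u <- tree$parent[u]
    rate[v] <- if (u != tree$root) tree$rate_mult[u] else 1
  }
  rate
}

# exhaustive joint maximum-likelihood reconstruction for one bin: argmax of
# the joint density over every assignment; returns the max log likelihood
# and one achieving assignment
oracle_joint_ml <- function(tree, obs, k, sigma) {
  m <- 2L * tree$ntip - 1L
  G <- as.matrix(expand.grid(rep(list(0:k), m)))
  Pd <- vapply(0:k, function(i)
    transition_probability(i, 2, tree$root_stem_d), numeric(1))
  lp <- log(Pd[G[, tree$root] + 1L])
  rate <- oracle_effective_rates(tree)
  for (v in setdiff(seq_len(m), tree$root)) {
    tlen <- (tree$height[tree$parent[v]] - tree$height[v]) * rate[v]
    P <- outer(0:k, 0:k, Vectorize(function(j, i)
      transition_probability(i, j, tlen)))
    lp <- lp + log(P[cbind(G[, tree$parent[v]] + 1L, G[, v] + 1L)])
  }
  for (v in seq_len(tree$ntip))
    lp <- lp + dnorm(obs[tree$tip_label[v]], G[, v], sigma, log = TRUE)
  best <- which.max(lp)
  list(loglik = lp[best], states = G[best, ])
}

# brute-force maximum clade credibility: clade frequencies by direct
# counting, per-tree product of its clades' frequencies, argmax
oracle_mcc_index <- function(samples) {
  clades_of <- function(tree) {
    n <- tree$ntip
    ch <- list()
    for (v in seq_len(2L * n - 1L)) ch[[v]] <- integer()
    for (v in which(tree$parent > 0L))
      ch[[tree$parent[v]]] <- c(ch[[tree$parent[v]]], v)
    below <- function(v) {
      if (v <= n) return(tree$tip_label[v])
      sort(c(below(ch[[v]][1]), below(ch[[v]][2])))
    }
    vapply((n + 1L):(2L * n - 1L), function(v)
      paste(below(v), collapse = "|"), character(1))
  }
  all_clades <- lapply(samples, clades_of)
  tab <- table(unlist(all_clades)) / length(samples)
  scores <- vapply(all_clades, function(cl)
    prod(tab[cl]), numeric(1))
  which.max(scores)
}

# enumerate-all-windows highest posterior density interval
oracle_hpd <- function(values, mass = 0.95) {
  x <- sort(values)
  n <- length(x)
  w <- ceiling(mass * n)
  if (w >= n) return(c(x[1], x[n]))
  best <- c(Inf, NA, NA)
  for (i in seq_len(n - w + 1)) {
    width <- x[i + w - 1] - x[i]
    if (width < best[1]) best <- c(width, x[i], x[i + w - 1])
  }
  best[2:3]
}

# grid-search minimizer of ||Y - beta X||^2
oracle_ols_beta <- function(x, y, grid = seq(0, 10, by = 1e-4)) {
  resid <- vapply(grid, function(b) sum((y - b * x)^2), numeric(1))
  grid[which.min(resid)]
}
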