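#' Leaf partial likelihoods under the observation-error model
#'
#' For one observed (estimated) copy number, the vector of log likelihoods of
#' each candidate true state `0:k` under the Gaussian error model. A missing
#' observation (`NA`) yields an uninformative partial (all zeros in log
#' space).
#'
#' @param c_obs Observed copy number (real-valued, possibly `NA`).
#' @param sigma Error standard deviation, `> 0`.
#' @param k Maximum copy-number state.
#' @return Numeric vector of `k + 1` log partials for states `0:k`.
#' @export
leaf_partials <- function(c_obs, sigma, k = 9) {
  if (is.na(c_obs)) return(rep(0, k + 1))
  log_error_density(c_obs, 0:k, sigma)
}

# log partial matrix for all bins of one cell: (k+1) x nbins, vectorized
leaf_partial_matrix <- function(obs, sigma, k) {
  M <- matrix(stats::dnorm(rep(obs, each = k + 1), mean = 0:k, sd = sigma,
                           log = TRUE), nrow = k + 1)
  M[is.na(M)] <- 0   # missing observations are uninformative
  M
}

# per-column maximum without apply() overhead (few rows, many columns);
# max.col is C-level, so transpose-and-index beats repeated pmax here
col_max <- function(M) {
  tm <- t(M)
  j <- max.col(tm, ties.method = "first")
  tm[seq_along(j) + (j - 1L) * length(j)]
}

# precompute rescaled leaf partials for every cell at a given sigma;
# reused across tree moves since they depend only on (values, sigma, k)
compute_leaf_cache <- function(values, sigma, k) {
  cells <- rownames(values)
  partials <- vector("list", length(cells))
  scaler <- vector("list", length(cells))
  names(partials) <- names(scaler) <- cells
  for (cell in cells) {
    lp <- leaf_partial_matrix(values[cell, ], sigma, k)
    mx <- col_max(lp)
    partials[[cell]] <- exp(lp - rep(mx, each = k + 1L))
    scaler[[cell]] <- mx
  }
  list(partials = partials, scaler = scaler)
}

# One pruning pass over the whole matrix at once.
# partials are stored per node as (k+1) x nbins matrices of log partials,
# rescaled per column (bin) to avoid underflow across 15k bins.
#
# Returns the vector of per-bin log likelihoods.
prune_log_likelihood_bins <- function(tree, values, model, sigma,
                                      leaf_cache = NULL, tmat_cache = NULL) {
  k <- model$k
  n <- tree$ntip
  if (is.null(rownames(values)) ||
      !setequal(rownames(values), tree$tip_label) ||
      nrow(values) != n)
    stop("cell labels of the matrix and tree tips must match bijectively",
         call. = FALSE)
  if (is.null(leaf_cache)) leaf_cache <- compute_leaf_cache(values, sigma, k)
  elen <- effective_lengths(tree)
  ch <- tree_children(tree)
  po <- tree_postorder(tree)
  # transition matrix cache keyed by quantized effective length; an
  # environment passed in persists across calls (MCMC steps)
  cache <- if (is.null(tmat_cache)) new.env(parent = emptyenv()) else tmat_cache
  tmat <- function(t) {
    key <- sprintf("%.12g", t)
    val <- cache[[key]]
    if (is.null(val)) {
      # entry counter kept under a dotted name (ls() skips it); an O(1)
      # check, since length() on a large environment is a full scan. The
      # cap is small: the live working set is one tree's branch lengths,
      # and a large cache only slows garbage collection down
      n <- cache[[".n"]]
      if (is.null(n)) n <- 0L
      if (n > 1500L) { rm(list = ls(cache), envir = cache); n <- 0L }
      val <- transition_matrix(t, model)
      cache[[key]] <- val
      cache[[".n"]] <- n + 1L
    }
    val
  }
  partials <- vector("list", 2L * n - 1L)
  scaler <- vector("list", 2L * n - 1L)
  for (v in po) {
    if (v <= n) {
      partials[[v]] <- leaf_cache$partials[[tree$tip_label[v]]]
      scaler[[v]] <- leaf_cache$scaler[[tree$tip_label[v]]]
    } else {
      c1 <- ch[[v]][1]; c2 <- ch[[v]][2]
      P1 <- tmat(elen[c1]); P2 <- tmat(elen[c2])
      M <- (P1 %*% partials[[c1]]) * (P2 %*% partials[[c2]])
      mx <- col_max(M)
      bad <- mx <= 0
      if (any(bad)) mx[bad] <- 1   # all-zero column: log partial -Inf, kept
      partials[[v]] <- M / rep(mx, each = k + 1L)
      scaler[[v]] <- log(mx) + scaler[[c1]] + scaler[[c2]]
    }
  }
  # diploid root stem: weight root states by P(x | 2, d)
  Pd <- tmat(tree$root_stem_d)
  w <- Pd[3L, ]                    # parent state 2
  root <- tree$root
  log(colSums(w * partials[[root]])) + scaler[[root]]
}

#' Log likelihood of a single bin
#'
#' Modified Felsenstein pruning for one genomic bin: leaf partials from the
#' Gaussian error model, transitions from the birth-death kernel at effective
#' branch lengths (time duration times the branch's local-clock rate), and a
#' root term \eqn{\sum_x P(x \mid 2, d)\, L_{root}(x)} replacing the usual
#' stationary-distribution weighting, reflecting descent from a diploid
#' ancestor over the root stem `d`.
#'
#' @param tree A [cn_tree()] whose tips match `names(column)`.
#' @param column Named numeric vector of observed copy numbers, one per cell.
#' @param model A [cn_bd_model()].
#' @param sigma Error standard deviation.
#' @return The log likelihood (scalar).
#' @export
bin_log_likelihood <- function(tree, column, model, sigma) {
  values <- matrix(column, ncol = 1, dimnames = list(names(column), NULL))
  out <- prune_log_likelihood_bins(tree, values, model, sigma)
  if (!is.finite(out))
    stop("non-finite log likelihood in bin 1", call. = FALSE)
  out
}

# Incremental pruning evaluator. Holds the per-node partials of the last few
# evaluated states (a small ring buffer); a new evaluation recomputes only
# the nodes whose subtree changed relative to the closest cached state —
# a node is dirty when its children set, a child branch's effective length,
# or a child's subtree changed. Reused partials are bit-identical to a full
# recomputation, so chains are unaffected by the caching.
make_incremental_pruner <- function(values, model, ring_size = 3L) {
  k <- model$k
  cells <- rownames(values)
  leaf_caches <- new.env(parent = emptyenv())
  tmat_cache <- new.env(parent = emptyenv())
  ring <- vector("list", ring_size)
  ring_pos <- 0L
  tmat <- function(t) {
    key <- sprintf("%.12g", t)
    val <- tmat_cache[[key]]
    if (is.null(val)) {
      n <- tmat_cache[[".n"]]
      if (is.null(n)) n <- 0L
      if (n > 1500L) { rm(list = ls(tmat_cache), envir = tmat_cache); n <- 0L }
      val <- transition_matrix(t, model)
      tmat_cache[[key]] <- val
      tmat_cache[[".n"]] <- n + 1L
    }
    val
  }
  get_leaf_cache <- function(sigma) {
    key <- sprintf("%.15g", sigma)
    lc <- leaf_caches[[key]]
    if (is.null(lc)) {
      n <- leaf_caches[[".n"]]
      if (is.null(n)) n <- 0L
      if (n > 40L) { rm(list = ls(leaf_caches), envir = leaf_caches); n <- 0L }
      lc <- compute_leaf_cache(values, sigma, k)
      leaf_caches[[key]] <- lc
      leaf_caches[[".n"]] <- n + 1L
    }
    lc
  }
  function(tree, sigma) {
    n <- tree$ntip
    m <- 2L * n - 1L
    elen <- effective_lengths(tree)
    ch <- tree_children(tree)
    po <- tree_postorder(tree)
    lc <- get_leaf_cache(sigma)
    # pick the cached state needing the fewest recomputations
    best <- NULL
    best_dirty <- NULL
    best_count <- Inf
    for (cand in ring) {
      if (is.null(cand) || cand$sigma != sigma) next
      dirty <- logical(m)
      cnt <- 0L
      for (v in po) {
        if (v <= n) next
        cv <- ch[[v]]
        cb <- cand$children[[v]]
        d <- is.null(cb) || cv[1] + cv[2] != cb[1] + cb[2] ||
          cv[1] * cv[2] != cb[1] * cb[2] ||
          dirty[cv[1]] || dirty[cv[2]] ||
          elen[cv[1]] != cand$elen[cv[1]] || elen[cv[2]] != cand$elen[cv[2]]
        if (d) { dirty[v] <- TRUE; cnt <- cnt + 1L }
      }
      if (cnt < best_count) { best <- cand; best_dirty <- dirty; best_count <- cnt }
      if (cnt == 0L) break
    }
    if (is.null(best)) {
      partials <- vector("list", m)
      scaler <- vector("list", m)
      best_dirty <- logical(m)
      best_dirty[(n + 1L):m] <- TRUE
    } else {
      partials <- best$partials
      scaler <- best$scaler
    }
    pget <- function(v) if (v <= n) lc$partials[[tree$tip_label[v]]] else partials[[v]]
    sget <- function(v) if (v <= n) lc$scaler[[tree$tip_label[v]]] else scaler[[v]]
    for (v in po) {
      if (v <= n || !best_dirty[v]) next
      c1 <- ch[[v]][1]; c2 <- ch[[v]][2]
      P1 <- tmat(elen[c1]); P2 <- tmat(elen[c2])
      M <- (P1 %*% pget(c1)) * (P2 %*% pget(c2))
      mx <- col_max(M)
      bad <- mx <= 0
      if (any(bad)) mx[bad] <- 1
      partials[[v]] <- M / rep(mx, each = k + 1L)
      scaler[[v]] <- log(mx) + sget(c1) + sget(c2)
    }
    root <- tree$root
    w <- tmat(tree$root_stem_d)[3L, ]
    ll <- sum(log(colSums(w * partials[[root]])) + scaler[[root]])
    ring_pos <<- ring_pos %% length(ring) + 1L
    ring[[ring_pos]] <<- list(sigma = sigma, elen = elen, children = ch,
                              partials = partials, scaler = scaler)
    ll
  }
}

#' Log likelihood of a copy-number matrix on a tree
#'
#' Sum of per-bin pruning log likelihoods under the independent-bins
#' assumption. Per-branch transition matrices are computed once and shared
#' across bins.
#'
#' @param tree A [cn_tree()].
#' @param D A [cn_profiles()] object or a cells-by-bins matrix with cell
#'   labels as row names.
#' @param model A [cn_bd_model()].
#' @param sigma Error standard deviation.
#' @return The total log likelihood (scalar).
#' @export
tree_log_likelihood <- function(tree, D, model, sigma) {
  values <- if (inherits(D, "cn_profiles")) D$values else D
  ll <- prune_log_likelihood_bins(tree, values, model, sigma)
  bad <- which(!is.finite(ll))
  if (length(bad))
    stop("non-finite log likelihood in bin ", bad[1], call. = FALSE)
  sum(ll)
}
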