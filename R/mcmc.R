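#' MCMC run configuration
#'
#' @param chain_length Number of Metropolis-Hastings steps.
#' @param n_log Number of states to log along the chain (evenly thinned);
#'   after the default 20% burn-in this leaves about 2000 posterior samples
#'   at the default value.
#' @param burnin_frac Fraction of logged samples discarded before
#'   summarization (default 0.2).
#' @param k Maximum copy-number state used by the likelihood (default 9).
#' @param r Per-copy birth-death rate, fixed at 1 by default (relative time).
#' @param priors A [cn_priors()] object.
#' @param likelihood_on If `FALSE`, the likelihood term is dropped and the
#'   chain samples from the prior (used for sampler validation).
#' @param move_weights Named numeric vector of relative move probabilities.
#' @param init_root_height,init_d,init_sigma Initial state values; the
#'   starting tree is an average-linkage clustering of per-cell L1 distances.
#' @param subsample_stride Optional bin-subsampling stride applied to the
#'   input before inference (`NULL` to use all bins; 20 reproduces a 1-in-20
#'   thinning of the genome bins).
#' @param subsample_offset 1-based offset of the first bin kept.
#' @param n_chains,delta_T,swap_every Metropolis-coupling settings used by
#'   [coupled_chains()]: number of chains, temperature increment (chain `c`
#'   has inverse temperature `1 / (1 + delta_T * (c - 1))`), and the interval
#'   between swap proposals.
#' @return A list of class `cn_mcmc_config`.
#' @export
mcmc_config <- function(chain_length = 20000, n_log = 2500,
                        burnin_frac = 0.2, k = 9, r = 1,
                        priors = cn_priors(), likelihood_on = TRUE,
                        move_weights = NULL,
                        init_root_height = 0.1, init_d = 0.5,
                        init_sigma = 0.5,
                        subsample_stride = NULL, subsample_offset = 1,
                        n_chains = 4, delta_T = 0.1, swap_every = 100) {
  if (chain_length < 0) stop("chain length must be non-negative", call. = FALSE)
  default_w <- c(node_height = 3, root_scale = 1, tree_scale = 2,
                 narrow_exchange = 3, wide_exchange = 1, wilson_balding = 2,
                 d_walk = 1, d_scale = 1, sigma_walk = 1, sigma_scale = 1,
                 rd_scale = 1, re_walk = 1, rlc_flip = 1, rlc_scale = 1)
  if (!is.null(move_weights)) {
    bad <- setdiff(names(move_weights), names(default_w))
    if (length(bad)) stop("unknown move(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    default_w[names(move_weights)] <- move_weights
  }
  structure(list(chain_length = as.integer(chain_length), n_log = n_log,
                 burnin_frac = burnin_frac, k = k, r = r, priors = priors,
                 likelihood_on = likelihood_on, move_weights = default_w,
                 init_root_height = init_root_height, init_d = init_d,
                 init_sigma = init_sigma,
                 subsample_stride = subsample_stride,
                 subsample_offset = subsample_offset,
                 n_chains = n_chains, delta_T = delta_T,
                 swap_every = swap_every),
            class = "cn_mcmc_config")
}

#' Posterior state of the sampler
#'
#' Bundles a tree (with root stem `d` and clock annotations), the error
#' standard deviation and the tree-prior parameters, together with cached
#' log likelihood / prior / posterior values.
#'
#' @param tree A [cn_tree()].
#' @param sigma Error standard deviation.
#' @param r_d,r_e Diversification rate and extinction fraction of the tree
#'   prior.
#' @param log_likelihood,log_prior Optional cached values.
#' @return A list of class `cn_state`.
#' @export
mcmc_state <- function(tree, sigma, r_d = 1, r_e = 0.5,
                       log_likelihood = NA_real_, log_prior = NA_real_) {
  structure(list(tree = tree, sigma = sigma, r_d = r_d, r_e = r_e,
                 ll = log_likelihood, lp = log_prior),
            class = "cn_state")
}

# ---------------------------------------------------------------------------
# proposal moves: each returns list(tree=, sigma=, r_d=, r_e=, lh= log
# Hastings ratio, lik_changed=) or NULL for an auto-rejected invalid proposal

reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  if (w <= 0) return(x)
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

move_node_height <- function(state) {
  tree <- state$tree
  n <- tree$ntip
  cand <- setdiff((n + 1L):(2L * n - 1L), tree$root)
  if (!length(cand)) return(NULL)
  v <- cand[sample.int(length(cand), 1)]
  ch <- which(tree$parent == v)
  lo <- max(tree$height[ch])
  hi <- tree$height[tree$parent[v]]
  if (hi <= lo) return(NULL)
  tree$height[v] <- stats::runif(1, lo, hi)
  list(tree = tree, lh = 0, lik_changed = TRUE)
}

move_root_scale <- function(state, w = 0.4) {
  tree <- state$tree
  s <- exp(stats::runif(1, -w, w))
  root <- tree$root
  ch <- which(tree$parent == root)
  newh <- tree$height[root] * s
  if (newh <= max(tree$height[ch])) return(NULL)
  tree$height[root] <- newh
  list(tree = tree, lh = log(s), lik_changed = TRUE)
}

move_tree_scale <- function(state, w = 0.3) {
  tree <- state$tree
  n <- tree$ntip
  s <- exp(stats::runif(1, -w, w))
  internal <- (n + 1L):(2L * n - 1L)
  tree$height[internal] <- tree$height[internal] * s
  list(tree = tree, lh = (n - 1) * log(s), lik_changed = TRUE)
}

move_narrow_exchange <- function(state) {
  tree <- state$tree
  n <- tree$ntip
  cand <- setdiff((n + 1L):(2L * n - 1L), tree$root)
  v <- cand[sample.int(length(cand), 1)]          # internal node with a parent
  g <- tree$parent[v]
  sib <- setdiff(which(tree$parent == g), v)
  ch <- which(tree$parent == v)
  c_pick <- ch[sample.int(2L, 1)]
  # swap sib and c_pick: sib becomes child of v, c_pick child of g
  if (tree$height[v] <= tree$height[sib]) return(NULL)
  tree$parent[sib] <- v
  tree$parent[c_pick] <- g
  list(tree = tree, lh = 0, lik_changed = TRUE)
}

move_wide_exchange <- function(state) {
  tree <- state$tree
  m <- 2L * tree$ntip - 1L
  cand <- setdiff(seq_len(m), tree$root)
  ij <- cand[sample.int(length(cand), 2)]
  i <- ij[1]; j <- ij[2]
  pi <- tree$parent[i]; pj <- tree$parent[j]
  if (pi == pj) return(NULL)
  if (is_ancestor(tree, i, j) || is_ancestor(tree, j, i)) return(NULL)
  if (tree$height[pi] <= tree$height[j] ||
      tree$height[pj] <= tree$height[i]) return(NULL)
  tree$parent[i] <- pj
  tree$parent[j] <- pi
  list(tree = tree, lh = 0, lik_changed = TRUE)
}

# is a an ancestor of b?
is_ancestor <- function(tree, a, b) {
  v <- b
  while (tree$parent[v] > 0L) {
    v <- tree$parent[v]
    if (v == a) return(TRUE)
  }
  FALSE
}

# Wilson-Balding subtree prune-and-regraft. Both the pruned node i and the
# attachment edge j are drawn uniformly from the fixed set of non-root nodes
# with infeasible draws auto-rejected, so the only Hastings contribution is
# the ratio of reattachment-height interval lengths.
move_wilson_balding <- function(state) {
  tree <- state$tree
  m <- 2L * tree$ntip - 1L
  root <- tree$root
  nonroot <- setdiff(seq_len(m), root)
  i <- nonroot[sample.int(length(nonroot), 1)]
  p <- tree$parent[i]
  if (p == root) return(NULL)           # the root is never detached/rebuilt
  g <- tree$parent[p]
  sib <- setdiff(which(tree$parent == p), i)
  j <- nonroot[sample.int(length(nonroot), 1)]
  if (j == i || j == p) return(NULL)
  if (is_ancestor(tree, i, j)) return(NULL)
  pj <- tree$parent[j]
  old_lo <- max(tree$height[i], tree$height[sib])
  old_hi <- tree$height[g]
  if (j == sib) {
    # same edge: resample the height of p within its current interval
    tree$height[p] <- stats::runif(1, old_lo, old_hi)
    return(list(tree = tree, lh = 0, lik_changed = TRUE))
  }
  new_lo <- max(tree$height[i], tree$height[j])
  new_hi <- tree$height[pj]
  if (new_hi <= new_lo) return(NULL)
  # detach p: sib takes p's place under g; reinsert p on the edge (j, pj)
  tree$parent[sib] <- g
  tree$parent[j] <- p
  tree$parent[p] <- pj
  tree$height[p] <- stats::runif(1, new_lo, new_hi)
  list(tree = tree, lh = log(new_hi - new_lo) - log(old_hi - old_lo),
       lik_changed = TRUE)
}

move_scalar_walk <- function(state, what, w, bounds) {
  x <- switch(what, d = state$tree$root_stem_d, sigma = state$sigma,
              r_d = state$r_d, r_e = state$r_e)
  xn <- reflect_into(x + stats::runif(1, -w, w), bounds[1], bounds[2])
  out <- list(tree = state$tree, lh = 0,
              lik_changed = what %in% c("d", "sigma"))
  switch(what,
         d = { out$tree$root_stem_d <- xn },
         sigma = { out$sigma <- xn },
         r_d = { out$r_d <- xn },
         r_e = { out$r_e <- xn })
  out
}

move_scalar_scale <- function(state, what, w = 0.3) {
  s <- exp(stats::runif(1, -w, w))
  x <- switch(what, d = state$tree$root_stem_d, sigma = state$sigma,
              r_d = state$r_d)
  out <- list(tree = state$tree, lh = log(s),
              lik_changed = what %in% c("d", "sigma"))
  switch(what,
         d = { out$tree$root_stem_d <- x * s },
         sigma = { out$sigma <- x * s },
         r_d = { out$r_d <- x * s })
  out
}

move_rlc_flip <- function(state) {
  tree <- state$tree
  branches <- setdiff(seq_len(2L * tree$ntip - 1L), tree$root)
  b <- branches[sample.int(length(branches), 1)]
  tree$rate_on[b] <- !tree$rate_on[b]
  list(tree = tree, lh = 0, lik_changed = TRUE)
}

move_rlc_scale <- function(state, w = 0.5) {
  tree <- state$tree
  branches <- setdiff(seq_len(2L * tree$ntip - 1L), tree$root)
  b <- branches[sample.int(length(branches), 1)]
  s <- exp(stats::runif(1, -w, w))
  tree$rate_mult[b] <- tree$rate_mult[b] * s
  list(tree = tree, lh = log(s), lik_changed = tree$rate_on[b])
}

propose_move <- function(state, move, config) {
  pr <- config$priors
  switch(move,
         node_height = move_node_height(state),
         root_scale = move_root_scale(state),
         tree_scale = move_tree_scale(state),
         narrow_exchange = move_narrow_exchange(state),
         wide_exchange = move_wide_exchange(state),
         wilson_balding = move_wilson_balding(state),
         d_walk = move_scalar_walk(state, "d", diff(pr$d_bounds) / 4,
                                   pr$d_bounds),
         d_scale = move_scalar_scale(state, "d"),
         sigma_walk = move_scalar_walk(state, "sigma",
                                       diff(pr$sigma_bounds) / 3,
                                       pr$sigma_bounds),
         sigma_scale = move_scalar_scale(state, "sigma"),
         rd_scale = move_scalar_scale(state, "r_d", w = 1),
         re_walk = move_scalar_walk(state, "r_e", diff(pr$re_bounds) / 3,
                                    pr$re_bounds),
         rlc_flip = move_rlc_flip(state),
         rlc_scale = move_rlc_scale(state))
}

# ---------------------------------------------------------------------------

# evaluator closure: incremental pruning with leaf-partial and transition
# caches; extra ring slots accommodate the interleaved states of coupled
# chains
make_lik_fn <- function(values, model, ring_size = 4L) {
  make_incremental_pruner(values, model, ring_size = ring_size)
}

#' One Metropolis-Hastings step
#'
#' Draws a move from the configured move set, proposes a new state, and
#' accepts or rejects by the Metropolis-Hastings rule (including the proposal
#' Hastings ratio). Invalid proposals (e.g. an exchange that would place a
#' node above its parent) are auto-rejected. Randomness comes from R's global
#' RNG stream, so a fixed seed yields an identical chain.
#'
#' @param state A [mcmc_state()] with cached `ll` and `lp`.
#' @param config An [mcmc_config()].
#' @param lik_fn Function `(tree, sigma) -> log likelihood`; ignored when the
#'   likelihood is disabled in `config`.
#' @param beta Inverse temperature applied to the likelihood (1 for the cold
#'   chain).
#' @return List with elements `state` (the new [mcmc_state()]) and `accepted`.
#' @export
mcmc_step <- function(state, config, lik_fn = NULL, beta = 1) {
  w <- config$move_weights
  move <- sample(names(w), 1, prob = w)
  prop <- propose_move(state, move, config)
  out <- list(state = state, accepted = FALSE, move = move)
  if (is.null(prop)) return(out)
  cand <- mcmc_state(prop$tree,
                     sigma = if (is.null(prop$sigma)) state$sigma else prop$sigma,
                     r_d = if (is.null(prop$r_d)) state$r_d else prop$r_d,
                     r_e = if (is.null(prop$r_e)) state$r_e else prop$r_e)
  cand$lp <- log_prior(cand, config$priors)
  if (!is.finite(cand$lp)) return(out)
  if (config$likelihood_on) {
    cand$ll <- if (prop$lik_changed) lik_fn(cand$tree, cand$sigma) else state$ll
  } else cand$ll <- 0
  log_alpha <- beta * (cand$ll - state$ll) + (cand$lp - state$lp) + prop$lh
  if (is.finite(log_alpha) && log(stats::runif(1)) < log_alpha) {
    out$state <- cand
    out$accepted <- TRUE
  }
  out
}

init_state <- function(values, config) {
  tree <- upgma_start_tree(values, height = config$init_root_height)
  tree$root_stem_d <- config$init_d
  st <- mcmc_state(tree, sigma = config$init_sigma, r_d = 1, r_e = 0.5)
  st$lp <- log_prior(st, config$priors)
  if (!is.finite(st$lp))
    stop("initial state outside the prior support", call. = FALSE)
  st
}

trace_row <- function(state, iter) {
  tree <- state$tree
  branches <- setdiff(seq_len(2L * tree$ntip - 1L), tree$root)
  tibble::tibble(iteration = iter,
                 log_posterior = state$ll + state$lp,
                 log_likelihood = state$ll,
                 log_prior = state$lp,
                 d = tree$root_stem_d,
                 sigma = state$sigma,
                 r_d = state$r_d,
                 r_e = state$r_e,
                 n_rate_changes = sum(tree$rate_on[branches]),
                 root_height = tree$height[tree$root])
}

#' Run the Metropolis-Hastings sampler
#'
#' Samples trees, the root stem `d`, the error standard deviation `sigma`,
#' the tree-prior parameters and the random-local-clock configuration from
#' their joint posterior given a copy-number matrix.
#'
#' @param D A [cn_profiles()] object or a cells-by-bins matrix with cell
#'   labels as row names.
#' @param config An [mcmc_config()].
#' @param seed Integer seed; every source of randomness in the run derives
#'   from it.
#' @return An object of class `cn_mcmc` with elements `trace` (a tibble, one
#'   row per logged state), `trees` (list of sampled [cn_tree()]s aligned
#'   with the trace), `acceptance` (per-move acceptance counts), `config` and
#'   `seed`.
#' @export
run_mcmc <- function(D, config = mcmc_config(), seed = 1) {
  values <- if (inherits(D, "cn_profiles")) D$values else D
  if (!is.null(config$subsample_stride))
    values <- values[, seq(config$subsample_offset, ncol(values),
                           by = config$subsample_stride), drop = FALSE]
  set.seed(seed)
  model <- cn_bd_model(r = config$r, k = config$k)
  lik_fn <- make_lik_fn(values, model)
  state <- init_state(values, config)
  state$ll <- if (config$likelihood_on) lik_fn(state$tree, state$sigma) else 0
  log_every <- max(1L, as.integer(floor(config$chain_length / config$n_log)))
  rows <- list(trace_row(state, 0L))
  trees <- list(state$tree)
  acc <- rej <- stats::setNames(numeric(length(config$move_weights)),
                                names(config$move_weights))
  if (config$chain_length > 0) {
    for (it in seq_len(config$chain_length)) {
      res <- mcmc_step(state, config, lik_fn)
      state <- res$state
      if (res$accepted) acc[res$move] <- acc[res$move] + 1
      else rej[res$move] <- rej[res$move] + 1
      if (it %% log_every == 0L) {
        rows[[length(rows) + 1L]] <- trace_row(state, it)
        trees[[length(trees) + 1L]] <- state$tree
      }
    }
  }
  structure(list(trace = dplyr::bind_rows(rows), trees = trees,
                 acceptance = tibble::tibble(
                   move = names(acc), accepted = acc, rejected = rej,
                   rate = ifelse(acc + rej > 0, acc / (acc + rej), NA_real_)),
                 config = config, seed = seed, final_state = state),
            class = "cn_mcmc")
}

#' @export
print.cn_mcmc <- function(x, ...) {
  cat("MCMC run: ", max(x$trace$iteration), " steps, ",
      nrow(x$trace), " logged states, seed ", x$seed, "\n", sep = "")
  cat("final log posterior: ", signif(utils::tail(x$trace$log_posterior, 1), 8),
      "\n", sep = "")
  invisible(x)
}

#' Metropolis-coupled MCMC
#'
#' Runs `n_chains` chains at inverse temperatures
#' `1 / (1 + delta_T * (c - 1))` applied to the likelihood; heated chains
#' explore more freely and periodically propose state swaps with the standard
#' tempered acceptance ratio. Only cold-chain samples are logged. With one
#' chain this degenerates to [run_mcmc()].
#'
#' @inheritParams run_mcmc
#' @return A `cn_mcmc` object (cold chain), with a `swap` tibble recording
#'   swap attempts.
#' @export
coupled_chains <- function(D, config = mcmc_config(), seed = 1) {
  nc <- config$n_chains
  if (nc < 1) stop("need at least one chain", call. = FALSE)
  if (nc == 1) return(run_mcmc(D, config, seed))
  betas <- 1 / (1 + config$delta_T * (seq_len(nc) - 1))
  if (any(diff(betas) >= 0))
    stop("inverse-temperature ladder must be strictly decreasing",
         call. = FALSE)
  values <- if (inherits(D, "cn_profiles")) D$values else D
  if (!is.null(config$subsample_stride))
    values <- values[, seq(config$subsample_offset, ncol(values),
                           by = config$subsample_stride), drop = FALSE]
  set.seed(seed)
  model <- cn_bd_model(r = config$r, k = config$k)
  lik_fn <- make_lik_fn(values, model, ring_size = 2L + config$n_chains)
  states <- vector("list", nc)
  st0 <- init_state(values, config)
  st0$ll <- if (config$likelihood_on) lik_fn(st0$tree, st0$sigma) else 0
  for (c_i in seq_len(nc)) states[[c_i]] <- st0
  log_every <- max(1L, as.integer(floor(config$chain_length / config$n_log)))
  rows <- list(trace_row(states[[1]], 0L))
  trees <- list(states[[1]]$tree)
  swaps <- list()
  n_acc <- 0
  for (it in seq_len(config$chain_length)) {
    for (c_i in seq_len(nc)) {
      res <- mcmc_step(states[[c_i]], config, lik_fn, beta = betas[c_i])
      states[[c_i]] <- res$state
      if (c_i == 1 && res$accepted) n_acc <- n_acc + 1
    }
    if (it %% config$swap_every == 0L && nc >= 2) {
      a <- sample.int(nc - 1L, 1L)  # adjacent pair (a, a + 1)
      b <- a + 1L
      log_sw <- (betas[a] - betas[b]) * (states[[b]]$ll - states[[a]]$ll)
      ok <- log(stats::runif(1)) < log_sw
      if (ok) {
        tmp <- states[[a]]; states[[a]] <- states[[b]]; states[[b]] <- tmp
      }
      swaps[[length(swaps) + 1L]] <-
        tibble::tibble(iteration = it, pair = a, accepted = ok)
    }
    if (it %% log_every == 0L) {
      rows[[length(rows) + 1L]] <- trace_row(states[[1]], it)
      trees[[length(trees) + 1L]] <- states[[1]]$tree
    }
  }
  structure(list(trace = dplyr::bind_rows(rows), trees = trees,
                 acceptance = tibble::tibble(move = "cold_chain_total",
                                             accepted = n_acc,
                                             rejected = config$chain_length - n_acc,
                                             rate = n_acc / max(1, config$chain_length)),
                 swap = dplyr::bind_rows(swaps),
                 config = config, seed = seed,
                 final_state = states[[1]]),
            class = "cn_mcmc")
}

#' Extract post-burn-in posterior samples
#'
#' @param fit A `cn_mcmc` object.
#' @param burnin_frac Fraction of logged samples to discard (defaults to the
#'   run configuration).
#' @param n_samples Maximum number of samples to keep (evenly spaced);
#'   default 2000.
#' @return List with `trace` (tibble) and `trees` (list of [cn_tree()]).
#' @export
posterior_samples <- function(fit, burnin_frac = NULL, n_samples = 2000) {
  stopifnot(inherits(fit, "cn_mcmc"))
  if (is.null(burnin_frac)) burnin_frac <- fit$config$burnin_frac
  m <- nrow(fit$trace)
  keep <- seq_len(m) > floor(burnin_frac * m)
  idx <- which(keep)
  if (length(idx) > n_samples)
    idx <- idx[unique(round(seq(1, length(idx), length.out = n_samples)))]
  list(trace = fit$trace[idx, ], trees = fit$trees[idx])
}
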