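#' Joint maximum-likelihood reconstruction of copy-number profiles
#'
#' Given a fixed tree, finds for every bin the single assignment of integer
#' copy-number states to all nodes — internal nodes and leaves alike — that
#' maximizes the joint likelihood under the birth-death kernel and the
#' Gaussian observation-error model. The dynamic program runs an upward pass
#' storing, for each node and each possible parent state, the best achievable
#' sub-likelihood and the arg-max child state (leaves maximize
#' \eqn{L_y(j \mid c_y, E) P_{ij}(t_y)} over states `j`, which builds profile
#' correction into the pass), weights root states by \eqn{P(x \mid 2, d)}
#' reflecting the diploid origin, and reads the joint arg-max off in a
#' downward pass. Bins are reconstructed independently. Ties in any arg-max
#' are broken toward the lowest state.
#'
#' @param tree A [cn_tree()] whose tips match the matrix cells.
#' @param D A [cn_profiles()] object or cells-by-bins matrix with cell labels
#'   as row names.
#' @param model A [cn_bd_model()].
#' @param sigma Error standard deviation, `> 0`.
#' @return An object of class `cn_reconstruction`: list with `states`
#'   (nodes-by-bins integer matrix; tips first in tree order, then internal
#'   nodes), `log_likelihood` (per-bin joint log likelihood of the returned
#'   assignment), `node_labels` (tips keep their cell labels; internal nodes
#'   get a deterministic postorder scheme `node<rank>`), and `tree`.
#' @export
joint_ml_reconstruction <- function(tree, D, model, sigma) {
  values <- if (inherits(D, "cn_profiles")) D$values else D
  if (!is.numeric(sigma) || sigma <= 0)
    stop("`sigma` must be positive", call. = FALSE)
  n <- tree$ntip
  if (is.null(rownames(values)) || !setequal(rownames(values), tree$tip_label))
    stop("cell labels of the matrix and tree tips must match bijectively",
         call. = FALSE)
  k <- model$k
  nb <- ncol(values)
  m <- 2L * n - 1L
  elen <- effective_lengths(tree)
  ch <- tree_children(tree)
  po <- tree_postorder(tree)
  cache <- new.env(parent = emptyenv())
  ltmat <- function(t) {
    key <- sprintf("%.12g", t)
    if (is.null(cache[[key]])) cache[[key]] <- log(transition_matrix(t, model))
    cache[[key]]
  }
  best <- vector("list", m)     # (k+1 parent states) x nbins best sub-scores
  argm <- vector("list", m)     # matching arg-max own state (0-based)
  for (v in po) {
    if (v == tree$root) next
    S <- if (v <= n) {
      leaf_partial_matrix(values[tree$tip_label[v], ], sigma, k)
    } else {
      best[[ch[[v]][1]]] + best[[ch[[v]][2]]]
    }
    lP <- ltmat(elen[v])
    B <- matrix(0, k + 1, nb)
    A <- matrix(0L, k + 1, nb)
    for (i in 0:k) {
      Ti <- S + lP[i + 1L, ]        # recycle log P(i -> x) down rows x
      A[i + 1L, ] <- max.col(t(Ti), ties.method = "first")   # lowest state
      B[i + 1L, ] <- Ti[cbind(A[i + 1L, ], seq_len(nb))]
    }
    best[[v]] <- B
    argm[[v]] <- A - 1L
  }
  # root: weight states by the diploid stem transition P(x | 2, d)
  root <- tree$root
  Sr <- best[[ch[[root]][1]]] + best[[ch[[root]][2]]]
  lPd <- ltmat(tree$root_stem_d)
  Tr <- Sr + lPd[3L, ]
  root_state <- max.col(t(Tr), ties.method = "first") - 1L
  loglik <- Tr[cbind(root_state + 1L, seq_len(nb))]
  # downward pass
  states <- matrix(0L, m, nb)
  states[root, ] <- root_state
  pre <- rev(po)                 # parents before children
  for (v in pre) {
    if (v == root) next
    ps <- states[tree$parent[v], ]
    states[v, ] <- argm[[v]][cbind(ps + 1L, seq_len(nb))]
  }
  labels <- character(m)
  labels[seq_len(n)] <- tree$tip_label
  internal_rank <- match(seq_len(m), po[po > n])
  labels[(n + 1L):m] <- paste0("node", internal_rank[(n + 1L):m])
  rownames(states) <- labels
  structure(list(states = states, log_likelihood = loglik,
                 node_labels = labels, tree = tree),
            class = "cn_reconstruction")
}

#' @export
print.cn_reconstruction <- function(x, ...) {
  cat("Joint ML copy-number reconstruction: ", nrow(x$states), " nodes x ",
      ncol(x$states), " bins, total log likelihood ",
      signif(sum(x$log_likelihood), 8), "\n", sep = "")
  invisible(x)
}

#' Per-node accuracy of reconstructed profiles
#'
#' Hamming error (fraction of bins whose states differ) and mean L1 error
#' per node, comparing a reconstruction against ground truth.
#'
#' @param truth,inferred Nodes-by-bins matrices of the same shape; rows are
#'   matched by row name when both are named, else positionally.
#' @return A tibble with columns `node`, `hamming`, `l1`.
#' @export
reconstruction_accuracy <- function(truth, inferred) {
  if (!all(dim(truth) == dim(inferred)))
    stop("profile matrices must have the same shape", call. = FALSE)
  if (!is.null(rownames(truth)) && !is.null(rownames(inferred))) {
    if (!setequal(rownames(truth), rownames(inferred)))
      stop("profile matrices must cover the same nodes", call. = FALSE)
    inferred <- inferred[rownames(truth), , drop = FALSE]
  }
  nb <- ncol(truth)
  tibble::tibble(
    node = if (is.null(rownames(truth))) as.character(seq_len(nrow(truth)))
           else rownames(truth),
    hamming = unname(rowSums(truth != inferred)) / nb,
    l1 = unname(rowSums(abs(truth - inferred))) / nb)
}
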