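#' Rooted ultrametric time tree with clock annotations
#'
#' The internal tree container used throughout the package. Cells are sampled
#' at a single time point, so the tree is ultrametric: every tip sits at
#' height 0 and internal nodes at positive heights (time before sampling).
#' Each non-root node carries the branch connecting it to its parent, with a
#' random-local-clock annotation: an indicator for whether a new rate
#' multiplier applies on that branch, and the multiplier value itself. The
#' `root_stem_d` field is the time separating the diploid ancestor (copy
#' number 2 in every bin) from the most recent common ancestor of the cells.
#'
#' Nodes are indexed `1:(2n-1)`: tips `1:n` (matching `tip_label`), internal
#' nodes `(n+1):(2n-1)`.
#'
#' @param parent Integer vector of parent indices, 0 for the root.
#' @param height Numeric node heights; all tips must be at height 0.
#' @param tip_label Character vector of unique cell labels.
#' @param rate_mult Per-branch rate multipliers (indexed by child node);
#'   defaults to 1.
#' @param rate_on Logical per-branch rate-change indicators; default all off.
#' @param root_stem_d Root stem length, time from the diploid ancestor to the
#'   root of the cell tree.
#' @return An object of class `cn_tree`.
#' @export
cn_tree <- function(parent, height, tip_label, rate_mult = NULL,
                    rate_on = NULL, root_stem_d = 0.5) {
  n <- length(tip_label)
  m <- 2L * n - 1L
  parent <- as.integer(parent)
  if (length(parent) != m || length(height) != m)
    stop("`parent` and `height` must have length 2 * ntip - 1", call. = FALSE)
  if (anyDuplicated(tip_label))
    stop("tip labels must be unique", call. = FALSE)
  if (sum(parent == 0L) != 1L)
    stop("exactly one node (the root) must have parent 0", call. = FALSE)
  root <- which(parent == 0L)
  if (root <= n) stop("the root must be an internal node", call. = FALSE)
  if (any(abs(height[seq_len(n)]) > 1e-8))
    stop("tree must be ultrametric: all tip heights 0", call. = FALSE)
  height[seq_len(n)] <- 0
  nonroot <- setdiff(seq_len(m), root)
  if (any(height[nonroot] > height[parent[nonroot]] + 1e-9))
    stop("child heights must not exceed parent heights", call. = FALSE)
  kids <- tabulate(parent, nbins = m)
  if (any(kids[(n + 1L):m] != 2L))
    stop("tree must be binary: every internal node needs exactly 2 children",
         call. = FALSE)
  if (is.null(rate_mult)) rate_mult <- rep(1, m)
  if (is.null(rate_on)) rate_on <- rep(FALSE, m)
  structure(list(ntip = n, tip_label = as.character(tip_label),
                 parent = parent, height = as.numeric(height),
                 rate_mult = as.numeric(rate_mult),
                 rate_on = as.logical(rate_on),
                 root_stem_d = root_stem_d, root = root),
            class = "cn_tree")
}

#' @export
print.cn_tree <- function(x, ...) {
  cat("Ultrametric cell tree: ", x$ntip, " tips, root height ",
      signif(x$height[x$root], 6), ", root stem d = ",
      signif(x$root_stem_d, 6), ", ", sum(x$rate_on),
      " active rate change(s)\n", sep = "")
  invisible(x)
}

# children as a list indexed by node (empty for tips)
tree_children <- function(tree) {
  m <- 2L * tree$ntip - 1L
  ch <- vector("list", m)
  idx <- which(tree$parent > 0L)
  for (v in idx) ch[[tree$parent[v]]] <- c(ch[[tree$parent[v]]], v)
  ch
}

# node indices in postorder (children before parents)
tree_postorder <- function(tree) {
  ch <- tree_children(tree)
  m <- 2L * tree$ntip - 1L
  out <- integer(m)
  pos <- 0L
  stack <- c(tree$root)
  visit <- integer(m)
  # iterative postorder
  while (length(stack)) {
    v <- stack[[length(stack)]]
    if (visit[v] == 0L && length(ch[[v]])) {
      visit[v] <- 1L
      stack <- c(stack, ch[[v]])
    } else {
      pos <- pos + 1L
      out[pos] <- v
      stack <- stack[-length(stack)]
    }
  }
  out
}

# branch time durations indexed by child node (NA at root)
branch_durations <- function(tree) {
  d <- rep(NA_real_, length(tree$parent))
  idx <- which(tree$parent > 0L)
  d[idx] <- tree$height[tree$parent[idx]] - tree$height[idx]
  d
}

# Random-local-clock resolution: a branch's effective rate is the multiplier
# of the nearest ancestor-or-self branch with its indicator on, else 1.
effective_rates <- function(tree) {
  m <- 2L * tree$ntip - 1L
  rate <- rep(NA_real_, m)
  ch <- tree_children(tree)
  # walk down from the root; the root itself carries no branch
  recurse_from <- tree$root
  rate_at <- function(v, inherited) {
    r <- if (tree$rate_on[v]) tree$rate_mult[v] else inherited
    rate[v] <<- r
    for (w in ch[[v]]) rate_at(w, r)
  }
  for (w in ch[[recurse_from]]) rate_at(w, 1)
  rate[tree$root] <- NA_real_
  rate
}

# effective branch lengths for the transition kernel (duration x rate)
effective_lengths <- function(tree) {
  branch_durations(tree) * effective_rates(tree)
}

#' Convert an ape phylo tree to the package tree container
#'
#' @param phy An ultrametric rooted binary `phylo` object with branch lengths.
#' @param root_stem_d Root stem length to attach (taken from `phy$root.edge`
#'   when present and this argument is missing).
#' @param tol Tolerance for the ultrametricity check, relative to tree height.
#' @return A [cn_tree()].
#' @export
as_cn_tree <- function(phy, root_stem_d = NULL, tol = 1e-6) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (!ape::is.binary(phy)) stop("tree must be binary", call. = FALSE)
  n <- length(phy$tip.label)
  m <- 2L * n - 1L
  depth <- ape::node.depth.edgelength(phy)
  h <- max(depth) - depth
  if (any(abs(h[seq_len(n)]) > tol * max(depth)))
    stop("tree is not ultrametric within tolerance", call. = FALSE)
  h[seq_len(n)] <- 0
  parent <- integer(m)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  if (is.null(root_stem_d))
    root_stem_d <- if (!is.null(phy$root.edge)) phy$root.edge else 0.5
  cn_tree(parent, h, phy$tip.label, root_stem_d = root_stem_d)
}

#' Convert the package tree container to an ape phylo object
#'
#' Branch lengths are time durations; the root stem is exported as
#' `root.edge`. Effective per-branch rates are attached as an `edge.rate`
#' vector aligned with the edge matrix.
#'
#' @param x A [cn_tree()].
#' @param ... Unused.
#' @return A `phylo` object.
#' @exportS3Method ape::as.phylo
as.phylo.cn_tree <- function(x, ...) {
  n <- x$ntip
  idx <- which(x$parent > 0L)
  edge <- cbind(x$parent[idx], idx)
  len <- x$height[x$parent[idx]] - x$height[idx]
  rates <- effective_rates(x)[idx]
  phy <- structure(list(edge = edge, edge.length = len,
                        tip.label = x$tip_label, Nnode = n - 1L,
                        root.edge = x$root_stem_d),
                   class = "phylo", order = "cladewise")
  phy <- ape::reorder.phylo(phy, "cladewise")
  # realign rates with the reordered edge matrix
  key <- paste(edge[, 1], edge[, 2])
  phy$edge.rate <- rates[match(paste(phy$edge[, 1], phy$edge[, 2]), key)]
  phy
}

#' Simulate a random ultrametric cell tree
#'
#' Draws a coalescent-shaped random ultrametric tree and rescales it to the
#' requested height; used as a model tree for simulations.
#'
#' @param n Number of tips.
#' @param height Root height after rescaling (relative time units).
#' @param labels Optional tip labels, default `cell1..celln`.
#' @return A [cn_tree()].
#' @export
random_ultrametric_tree <- function(n, height = 1, labels = NULL) {
  if (is.null(labels)) labels <- paste0("cell", seq_len(n))
  phy <- ape::rcoal(n, tip.label = labels)
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length * (height / depth)
  as_cn_tree(phy)
}

#' Deterministic starting tree from copy-number profiles
#'
#' Average-linkage (UPGMA-like) clustering on per-cell mean L1 distances
#' between profiles, rescaled to a given root height; used to initialize the
#' MCMC.
#'
#' @param values Cells-by-bins numeric matrix with cell names as row names.
#' @param height Root height of the starting tree.
#' @return A [cn_tree()].
#' @export
upgma_start_tree <- function(values, height = 0.1) {
  d <- stats::dist(values, method = "manhattan") / ncol(values)
  hc <- stats::hclust(d, method = "average")
  # identical profiles give tied (possibly zero) merge heights, which the
  # tree prior cannot support; break ties with a strictly increasing nudge
  eps <- max(hc$height, 1e-6) * 1e-4
  hc$height <- hc$height + seq_along(hc$height) * eps
  phy <- ape::as.phylo(hc)
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length * (height / depth)
  # average-linkage trees can carry tiny negative tip offsets; snap tips to 0
  as_cn_tree(phy, tol = 1e-3)
}

# clade key: canonical string of sorted tip labels under each node
clade_keys <- function(tree) {
  ch <- tree_children(tree)
  m <- 2L * tree$ntip - 1L
  sets <- vector("list", m)
  for (v in tree_postorder(tree)) {
    if (v <= tree$ntip) sets[[v]] <- tree$tip_label[v]
    else sets[[v]] <- sort(c(sets[[ch[[v]][1]]], sets[[ch[[v]][2]]]))
  }
  vapply(sets, paste, character(1), collapse = "\t")
}
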