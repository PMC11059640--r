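# clade bookkeeping: for each sampled tree, the internal clades as canonical
# tab-joined sorted tip-label strings, with the node height of each clade
sample_clades <- function(tree) {
  n <- tree$ntip
  keys <- clade_keys(tree)
  internal <- (n + 1L):(2L * n - 1L)
  tibble::tibble(clade = keys[internal], height = tree$height[internal],
                 node = internal)
}

# posterior clade frequencies and per-clade height lists over a sample set
clade_frequencies <- function(samples) {
  per <- purrr::map(samples, sample_clades)
  all <- dplyr::bind_rows(per, .id = "sample")
  ns <- length(samples)
  all |>
    dplyr::group_by(.data$clade) |>
    dplyr::summarise(support = dplyr::n() / ns,
                     heights = list(.data$height), .groups = "drop")
}

#' Maximum clade credibility tree
#'
#' Among the sampled trees, returns the one maximizing the product of the
#' posterior frequencies of its clades (the proportion of samples containing
#' each clade), with every clade annotated by its frequency.
#'
#' @param samples List of [cn_tree()] posterior samples sharing a leaf set.
#' @return List of class `cn_mcc`: `tree` (the winning sample), `index` (its
#'   position in `samples`), `supports` (tibble `clade`, `support`,
#'   `node`), `clade_table` (all clades seen, with heights across samples).
#' @export
mcc_tree <- function(samples) {
  if (!length(samples)) stop("need at least one sampled tree", call. = FALSE)
  leafsets <- purrr::map(samples, function(t) sort(t$tip_label))
  if (!all(purrr::map_lgl(leafsets, identical, leafsets[[1]])))
    stop("sampled trees must share one leaf set", call. = FALSE)
  freq <- clade_frequencies(samples)
  lookup <- stats::setNames(freq$support, freq$clade)
  score <- purrr::map_dbl(samples, function(t)
    sum(log(lookup[sample_clades(t)$clade])))
  best <- which.max(score)
  tree <- samples[[best]]
  sc <- sample_clades(tree)
  sc$support <- unname(lookup[sc$clade])
  structure(list(tree = tree, index = best,
                 supports = sc[, c("clade", "support", "node")],
                 clade_table = freq, log_score = score[best]),
            class = "cn_mcc")
}

#' @export
print.cn_mcc <- function(x, ...) {
  cat("Maximum clade credibility tree (sample ", x$index, "), ",
      x$tree$ntip, " tips, log clade-credibility ", signif(x$log_score, 6),
      "\n", sep = "")
  invisible(x)
}

#' Annotate an MCC tree with median node heights
#'
#' Each clade's height is the median of that clade's node heights across all
#' samples in which the clade appears. The annotated heights are point
#' estimates per clade and may violate parent-above-child ordering; such
#' violations are flagged in the `height_violations` attribute, never
#' silently repaired.
#'
#' @param mcc A `cn_mcc` object.
#' @param samples The sample list the MCC tree came from.
#' @return The MCC [cn_tree()] with `height` replaced by per-clade medians
#'   (tips stay at 0) and attribute `height_violations` (integer vector of
#'   nodes whose annotated height meets or exceeds their parent's).
#' @export
median_node_heights <- function(mcc, samples) {
  stopifnot(inherits(mcc, "cn_mcc"))
  freq <- clade_frequencies(samples)
  med <- stats::setNames(purrr::map_dbl(freq$heights, stats::median),
                         freq$clade)
  tree <- mcc$tree
  sc <- sample_clades(tree)
  tree$height[sc$node] <- unname(med[sc$clade])
  nonroot <- which(tree$parent > 0L)
  bad <- nonroot[tree$height[nonroot] >= tree$height[tree$parent[nonroot]] &
                   tree$height[nonroot] > 0]
  attr(tree, "height_violations") <- bad
  tree
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval over the sorted sample values containing
#' `ceiling(mass * n)` points.
#'
#' @param values Numeric sample vector, length at least 2.
#' @param mass Probability mass, in (0, 1); default 0.95.
#' @return Numeric `c(lo, hi)`.
#' @export
hpd_interval <- function(values, mass = 0.95) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values", call. = FALSE)
  if (mass <= 0 || mass >= 1) stop("`mass` must be in (0, 1)", call. = FALSE)
  x <- sort(values)
  w <- ceiling(mass * n)
  if (w >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - w + 1L)
  widths <- x[starts + w - 1L] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + w - 1L])
}

#' Ordinary-least-squares tree scale factor
#'
#' The factor `beta` minimizing `||Y - beta X||^2` without intercept, used to
#' put inferred node heights (relative time) on the scale of true node
#' heights: `beta = sum(x y) / sum(x^2)`. The same factor is applied to all
#' posterior samples of a run.
#'
#' @param x Inferred node heights over shared clades.
#' @param y True node heights over the same clades.
#' @return The scalar `beta`.
#' @export
ols_scale <- function(x, y) {
  if (length(x) != length(y) || !length(x))
    stop("need matched non-empty height vectors", call. = FALSE)
  sx2 <- sum(x^2)
  if (sx2 == 0) stop("inferred heights are all zero", call. = FALSE)
  sum(x * y) / sx2
}

# shared non-root clade heights between an estimated tree and the truth
matched_clade_heights <- function(est_tree, true_tree, include_root = FALSE) {
  et <- sample_clades(est_tree)
  tt <- sample_clades(true_tree)
  if (!include_root) {
    root_key <- paste(sort(true_tree$tip_label), collapse = "\t")
    et <- et[et$clade != root_key, ]
    tt <- tt[tt$clade != root_key, ]
  }
  shared <- intersect(et$clade, tt$clade)
  tibble::tibble(clade = shared,
                 inferred = et$height[match(shared, et$clade)],
                 true = tt$height[match(shared, tt$clade)])
}

#' OLS scale factor between an estimated tree and the true tree
#'
#' Matches clades (identical leaf sets, root excluded) and regresses true on
#' inferred node heights without intercept.
#'
#' @param est_tree Estimated [cn_tree()] (typically the MCC tree with median
#'   heights).
#' @param true_tree Ground-truth [cn_tree()].
#' @return The scalar `beta`.
#' @export
tree_scale_factor <- function(est_tree, true_tree) {
  m <- matched_clade_heights(est_tree, true_tree)
  if (!nrow(m)) stop("no shared non-root clades", call. = FALSE)
  ols_scale(m$inferred, m$true)
}

#' Branch true-positive rate by branch-length decile
#'
#' For each internal branch of the true tree (identified by the clade below
#' it), the recovery rate is the fraction of sampled trees containing that
#' clade. Branches are assigned to deciles of their true length (rank-based,
#' ties broken by stable order) and recovery is averaged per decile.
#'
#' @param true_tree Ground-truth [cn_tree()].
#' @param sampled_trees List of sampled/bootstrap [cn_tree()]s.
#' @return Tibble with `decile`, `recovery` (mean), `n_branches`,
#'   `mean_length`.
#' @export
branch_tpr_by_decile <- function(true_tree, sampled_trees) {
  if (!setequal(true_tree$tip_label, sampled_trees[[1]]$tip_label))
    stop("true and sampled trees must share a leaf set", call. = FALSE)
  tt <- sample_clades(true_tree)
  root_key <- paste(sort(true_tree$tip_label), collapse = "\t")
  tt <- tt[tt$clade != root_key, ]
  dur <- branch_durations(true_tree)
  tt$length <- dur[tt$node]
  freq <- clade_frequencies(sampled_trees)
  tt$recovery <- freq$support[match(tt$clade, freq$clade)]
  tt$recovery[is.na(tt$recovery)] <- 0
  tt$decile <- dplyr::ntile(tt$length, 10)
  tt |>
    dplyr::group_by(.data$decile) |>
    dplyr::summarise(recovery = mean(.data$recovery),
                     n_branches = dplyr::n(),
                     mean_length = mean(.data$length), .groups = "drop")
}

# pairwise leaf distances in mutation-count units: per-branch count is
# duration x effective local-clock rate (the proportionality constant cancels
# under the min-max normalization applied downstream)
mutation_distance_matrix <- function(tree) {
  phy <- as.phylo.cn_tree(tree)
  phy$edge.length <- phy$edge.length * phy$edge.rate
  D <- stats::cophenetic(phy)
  D[tree$tip_label, tree$tip_label]
}

#' Min-max-normalized pairwise-distance error between two trees
#'
#' Leaf-to-leaf distances are summed per-branch mutation counts along the
#' connecting path (for trees inferred here, branch duration times the
#' branch-specific rate). Each matrix is min-max normalized over its
#' off-diagonal entries, and the error is the Frobenius norm of the
#' difference divided by `(|L| - 1)^2`.
#'
#' @param est_tree,true_tree Trees sharing a leaf set `L` with `|L| >= 3`.
#' @param est_dist,true_dist Optional precomputed distance matrices
#'   (leaf-labeled), overriding the trees.
#' @return Scalar error.
#' @export
normalized_pairwise_distance_error <- function(est_tree = NULL,
                                               true_tree = NULL,
                                               est_dist = NULL,
                                               true_dist = NULL) {
  if (is.null(est_dist)) est_dist <- mutation_distance_matrix(est_tree)
  if (is.null(true_dist)) true_dist <- mutation_distance_matrix(true_tree)
  labs <- rownames(true_dist)
  if (length(labs) < 3) stop("need at least 3 leaves", call. = FALSE)
  est_dist <- est_dist[labs, labs]
  normalize <- function(D) {
    off <- D[row(D) != col(D)]
    rng <- range(off)
    if (diff(rng) == 0) stop("constant pairwise distances", call. = FALSE)
    N <- (D - rng[1]) / diff(rng)
    diag(N) <- 0
    N
  }
  NT <- normalize(est_dist)
  NR <- normalize(true_dist)
  sqrt(sum((NT - NR)^2)) / (length(labs) - 1)^2
}

#' Posterior coverage of true node heights
#'
#' For every clade of the true tree that has a corresponding clade
#' (identical leaf set) among the samples, computes the HPD interval of the
#' scaled sampled heights of that clade and checks whether the true height
#' falls inside.
#'
#' @param true_tree Ground-truth [cn_tree()].
#' @param samples List of posterior sample [cn_tree()]s.
#' @param scale Multiplier applied to sampled heights before comparison (the
#'   OLS factor from [tree_scale_factor()]).
#' @param mass HPD mass (default 0.95).
#' @param min_samples Minimum number of samples containing a clade for it to
#'   enter the comparison (HPD needs at least 2).
#' @return Tibble of class `cn_coverage` with `clade`, `true_height`, `lo`,
#'   `hi`, `n_samples`, `covered`; the overall covered fraction is the
#'   `coverage` attribute.
#' @export
posterior_coverage <- function(true_tree, samples, scale = 1, mass = 0.95,
                               min_samples = 2) {
  freq <- clade_frequencies(samples)
  tt <- sample_clades(true_tree)
  tt <- tt[tt$clade %in% freq$clade, ]
  if (!nrow(tt)) stop("no matched clades between truth and samples",
                      call. = FALSE)
  rows <- purrr::map(seq_len(nrow(tt)), function(i) {
    hs <- freq$heights[[match(tt$clade[i], freq$clade)]] * scale
    if (length(hs) < min_samples) return(NULL)
    int <- hpd_interval(hs, mass)
    tibble::tibble(clade = tt$clade[i], true_height = tt$height[i],
                   lo = int[1], hi = int[2], n_samples = length(hs),
                   covered = tt$height[i] >= int[1] & tt$height[i] <= int[2])
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "coverage") <- mean(out$covered)
  class(out) <- c("cn_coverage", class(out))
  out
}

#' Summarize a posterior run
#'
#' Applies burn-in and thinning, computes the MCC tree with median node
#' heights, per-parameter posterior medians and 95% HPD intervals.
#'
#' @param fit A `cn_mcmc` object.
#' @param burnin_frac,n_samples Passed to [posterior_samples()].
#' @return List of class `cn_posterior_summary`: `mcc` (a `cn_mcc`),
#'   `mcc_median` (MCC tree with median heights), `scalars` (tibble of
#'   posterior medians and HPD bounds), `samples`.
#' @export
posterior_summary <- function(fit, burnin_frac = NULL, n_samples = 2000) {
  ps <- posterior_samples(fit, burnin_frac, n_samples)
  mcc <- mcc_tree(ps$trees)
  mcc_med <- median_node_heights(mcc, ps$trees)
  vars <- c("d", "sigma", "r_d", "r_e", "root_height", "n_rate_changes")
  scalars <- purrr::map_dfr(vars, function(v) {
    x <- ps$trace[[v]]
    int <- hpd_interval(x, 0.95)
    tibble::tibble(parameter = v, median = stats::median(x),
                   hpd_lo = int[1], hpd_hi = int[2])
  })
  structure(list(mcc = mcc, mcc_median = mcc_med, scalars = scalars,
                 samples = ps),
            class = "cn_posterior_summary")
}

#' @export
print.cn_posterior_summary <- function(x, ...) {
  cat("Posterior summary over", length(x$samples$trees), "samples\n")
  print(x$scalars)
  print(x$mcc)
  invisible(x)
}
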