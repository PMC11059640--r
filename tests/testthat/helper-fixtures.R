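# small hand-built trees and matrices used across test files

# rooted 2-leaf tree: (a, b) joined at `height`, stem `d`
tree2 <- function(height = 0.3, d = 0.5) {
  cn_tree(parent = c(3L, 3L, 0L), height = c(0, 0, height),
          tip_label = c("a", "b"), root_stem_d = d)
}

# rooted 3-leaf caterpillar: ((a, b), c); inner node at h1, root at h2
tree3 <- function(h1 = 0.2, h2 = 0.5, d = 0.3) {
  cn_tree(parent = c(4L, 4L, 5L, 5L, 0L), height = c(0, 0, 0, h1, h2),
          tip_label = c("a", "b", "c"), root_stem_d = d)
}

# rooted 4-leaf balanced tree: ((a, b), (c, d))
tree4_balanced <- function(h1 = 0.2, h2 = 0.35, h3 = 0.6, d = 0.4) {
  cn_tree(parent = c(5L, 5L, 6L, 6L, 7L, 7L, 0L),
          height = c(0, 0, 0, 0, h1, h2, h3),
          tip_label = c("a", "b", "c", "d"), root_stem_d = d)
}

# rooted 4-leaf caterpillar: (((a, b), c), d)
tree4_caterpillar <- function(h1 = 0.15, h2 = 0.3, h3 = 0.55, d = 0.4) {
  cn_tree(parent = c(5L, 5L, 6L, 7L, 6L, 7L, 0L),
          height = c(0, 0, 0, 0, h1, h2, h3),
          tip_label = c("a", "b", "c", "d"), root_stem_d = d)
}

# named observation vector in tree tip order
obs_for <- function(tree, values) {
  stats::setNames(values, tree$tip_label)
}

# tiny observed matrix for MCMC smoke runs
toy_matrix <- function(ncell = 4, nbins = 12, seed = 5) {
  withr::with_seed(seed, {
    values <- matrix(pmax(0, pmin(9, rpois(ncell * nbins, 2))), nrow = ncell)
    rownames(values) <- paste0("cell", seq_len(ncell))
    values
  })
}

# event tibble built by hand (unit-interval coordinates)
manual_events <- function(branch, allele, start, length_bp, sign,
                          time = seq_along(branch) / (length(branch) + 1),
                          genome_length = 1e8) {
  ev <- tibble::tibble(branch = as.integer(branch), allele = allele,
                       start = start, length_bp = length_bp,
                       sign = as.integer(sign), time = time)
  attr(ev, "genome_length") <- genome_length
  class(ev) <- c("cn_events", class(ev))
  ev
}
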