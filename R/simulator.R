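#' Sum-of-sines genomic position density
#'
#' Density on the linearized unit-interval genome from which CNA start
#' positions are drawn:
#' \deqn{f(x) \propto \exp\Big(\sum_{i=1}^{30} \sin(1000 x + \phi_i)\,
#'   \lambda_i\Big)}
#' with phases \eqn{\phi_i \sim} Uniform(\eqn{-\pi, \pi}) and amplitudes
#' \eqn{\lambda_i \sim} Uniform(0, `a`). The non-uniformity parameter `a`
#' controls how clustered CNA positions are; `a = 0` gives the exact uniform
#' distribution. The density is evaluated on a fine midpoint grid and
#' sampled by inverse CDF with within-cell interpolation.
#'
#' @param a Non-uniformity parameter, `>= 0` (default 0.6, which makes
#'   simulated CNAs cluster the way they do in tumor data: most events
#'   overlap at least one other event).
#' @param n_terms Number of sine terms (default 30).
#' @param grid_n Grid resolution (default `1e6`).
#' @return An object of class `cn_position_density`.
#' @export
position_density <- function(a = 0.6, n_terms = 30, grid_n = 1e6) {
  if (a < 0) stop("`a` must be non-negative", call. = FALSE)
  phases <- stats::runif(n_terms, -pi, pi)
  amps <- stats::runif(n_terms, 0, a)
  grid_n <- as.integer(grid_n)
  if (a == 0) {
    pdf <- rep(1, grid_n)
  } else {
    x <- (seq_len(grid_n) - 0.5) / grid_n   # midpoints
    logf <- rep(0, grid_n)
    for (i in seq_len(n_terms))
      logf <- logf + sin(1000 * x + phases[i]) * amps[i]
    logf <- logf - max(logf)
    pdf <- exp(logf)
    pdf <- pdf * grid_n / sum(pdf)          # density, integrates to 1
  }
  structure(list(a = a, phases = phases, amps = amps, grid_n = grid_n,
                 pdf = pdf, cdf = cumsum(pdf) / grid_n),
            class = "cn_position_density")
}

#' @export
print.cn_position_density <- function(x, ...) {
  cat("Sum-of-sines position density: a = ", x$a, ", ", length(x$phases),
      " terms, grid ", x$grid_n, "\n", sep = "")
  invisible(x)
}

#' Draw CNA start positions
#'
#' @param density A [position_density()].
#' @param n Number of draws.
#' @return Numeric vector of positions in `[0, 1)`.
#' @export
sample_position <- function(density, n = 1) {
  stopifnot(inherits(density, "cn_position_density"))
  if (density$a == 0) return(stats::runif(n))
  u <- stats::runif(n)
  idx <- findInterval(u, density$cdf) + 1L     # grid cell containing u
  idx[idx > density$grid_n] <- density$grid_n
  lo_cdf <- c(0, density$cdf)[idx]
  frac <- (u - lo_cdf) / (density$pdf[idx] / density$grid_n)
  frac[!is.finite(frac)] <- 0.5
  pmin((idx - 1L + pmin(pmax(frac, 0), 1)) / density$grid_n, 1 - 1e-12)
}

#' Simulate CNA events along a tree
#'
#' On each branch of duration `t`, the number of copy-number aberrations is
#' Poisson with mean `c_mult * t`. Each event picks the maternal or paternal
#' allele with probability 1/2, a start position from the position density,
#' a size of `min_size` plus an Exponential(`size_mean`) draw, a gain or
#' loss with probability 1/2, and a Uniform(0,1) pseudo-time that orders
#' events within a branch.
#'
#' @param tree A [cn_tree()] (events fall on its `2n - 2` branches).
#' @param c_mult Event multiplier `c` (expected events per unit branch
#'   length); 90, 125 and 250 correspond to low, medium and high CNA loads.
#' @param density A [position_density()].
#' @param size_mean Mean of the exponential size component, bp (default 10 Mbp).
#' @param min_size Minimum event size, bp (default 2 Mbp).
#' @param genome_length Linearized genome length, bp (default 3 Gbp).
#' @return A tibble of class `cn_events` with columns `branch` (child-node
#'   index), `allele` (`"maternal"`/`"paternal"`), `start` (unit-interval
#'   coordinate), `length_bp`, `sign` (+1 gain, -1 loss) and `time` (order
#'   within the branch); `genome_length` is kept as an attribute.
#' @export
simulate_events <- function(tree, c_mult, density = position_density(),
                            size_mean = 10e6, min_size = 2e6,
                            genome_length = 3e9) {
  stopifnot(inherits(tree, "cn_tree"))
  if (c_mult <= 0) stop("`c_mult` must be positive", call. = FALSE)
  dur <- branch_durations(tree)
  branches <- which(!is.na(dur))
  counts <- stats::rpois(length(branches), c_mult * dur[branches])
  total <- sum(counts)
  if (total == 0) {
    ev <- tibble::tibble(branch = integer(), allele = character(),
                         start = numeric(), length_bp = numeric(),
                         sign = integer(), time = numeric())
  } else {
    ev <- tibble::tibble(
      branch = rep(branches, counts),
      allele = c("maternal", "paternal")[stats::rbinom(total, 1, 0.5) + 1L],
      start = sample_position(density, total),
      length_bp = min_size + stats::rexp(total, rate = 1 / size_mean),
      sign = ifelse(stats::rbinom(total, 1, 0.5) == 1L, 1L, -1L),
      time = stats::runif(total))
  }
  attr(ev, "genome_length") <- genome_length
  class(ev) <- c("cn_events", class(ev))
  ev
}

# unit-interval end coordinate, clipped at the genome end
event_ends <- function(events, genome_length = attr(events, "genome_length")) {
  pmin(events$start + events$length_bp / genome_length, 1)
}

#' Fraction of CNA events overlapping at least one other event
#'
#' Allele-agnostic, genome-wide: an event counts as overlapping if its
#' `[start, end)` interval intersects any other event's interval.
#'
#' @param events A `cn_events` tibble (or any data frame with `start` and
#'   `length_bp` plus a `genome_length` attribute).
#' @param genome_length Genome length in bp, used to convert sizes.
#' @return Fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(events,
                             genome_length = attr(events, "genome_length")) {
  ne <- nrow(events)
  if (ne == 0) stop("no events", call. = FALSE)
  if (ne == 1) return(0)
  s <- events$start
  e <- pmin(s + events$length_bp / genome_length, 1)
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  prev_max_end <- c(-Inf, cummax(e)[-ne])
  next_start <- c(s[-1], Inf)
  mean(prev_max_end > s | next_start < e)
}

#' Expand events into true copy-number profiles at every node
#'
#' Each allele of each bin starts with one copy at the diploid root. Walking
#' each root-to-node path and applying that path's events in order (branch
#' order, then within-branch pseudo-time), a gain adds one copy over its
#' interval on its allele and a loss removes one, floored at zero (a loss on
#' an already-absent interval is a no-op, matching the absorbing state of
#' the birth-death kernel). The genome is then divided into `n_bins`
#' equal-width bins and each bin takes the overlap-length-weighted mean of
#' the per-base total (maternal + paternal) copy number, rounded half-up.
#'
#' @param tree A [cn_tree()].
#' @param events A `cn_events` tibble from [simulate_events()].
#' @param n_bins Number of bins (default 15000).
#' @param genome_length Genome length in bp.
#' @return A list of class `cn_truth`: `profiles` (all-nodes-by-bins integer
#'   matrix: tips by label, internal nodes `node<i>` in postorder rank),
#'   `leaf_profiles` (the tip rows), `bins` (tibble with `chrom`,
#'   `start_bp`, `end_bp`), `tree`, `events`.
#' @export
events_to_profiles <- function(tree, events, n_bins = 15000,
                               genome_length = attr(events, "genome_length")) {
  if (n_bins < 1) stop("`n_bins` must be at least 1", call. = FALSE)
  n <- tree$ntip
  m <- 2L * n - 1L
  ends <- event_ends(events, genome_length)
  bks <- sort(unique(c(0, 1, events$start, ends)))
  nseg <- length(bks) - 1L
  seg_len <- diff(bks)
  # per-event segment span (half-open indices into segments)
  ev_lo <- findInterval(events$start, bks)
  ev_hi <- findInterval(ends, bks, left.open = TRUE)
  po <- tree_postorder(tree)
  pre <- rev(po)
  # path-ordered event application, reusing the parent's allele states
  mat_state <- vector("list", m)
  pat_state <- vector("list", m)
  profiles <- matrix(0L, m, n_bins)
  bin_edges <- seq(0, 1, length.out = n_bins + 1L)
  for (v in pre) {
    if (v == tree$root) {
      mat <- rep(1, nseg); pat <- rep(1, nseg)
    } else {
      mat <- mat_state[[tree$parent[v]]]
      pat <- pat_state[[tree$parent[v]]]
      idx <- which(events$branch == v)
      if (length(idx)) {
        idx <- idx[order(events$time[idx])]
        for (ei in idx) {
          span <- seq.int(ev_lo[ei], ev_hi[ei])
          if (events$allele[ei] == "maternal") {
            mat[span] <- if (events$sign[ei] > 0) mat[span] + 1
                         else pmax(mat[span] - 1, 0)
          } else {
            pat[span] <- if (events$sign[ei] > 0) pat[span] + 1
                         else pmax(pat[span] - 1, 0)
          }
        }
      }
    }
    mat_state[[v]] <- mat
    pat_state[[v]] <- pat
    total <- mat + pat
    cum <- c(0, cumsum(total * seg_len))
    j <- findInterval(bin_edges, bks, rightmost.closed = TRUE)
    I <- cum[j] + total[pmin(j, nseg)] * (bin_edges - bks[j])
    profiles[v, ] <- as.integer(floor(diff(I) * n_bins + 0.5))
  }
  labels <- character(m)
  labels[seq_len(n)] <- tree$tip_label
  internal_rank <- match(seq_len(m), po[po > n])
  labels[(n + 1L):m] <- paste0("node", internal_rank[(n + 1L):m])
  rownames(profiles) <- labels
  bins <- tibble::tibble(chrom = "linear",
                         start_bp = round(bin_edges[-(n_bins + 1L)] * genome_length),
                         end_bp = round(bin_edges[-1] * genome_length))
  structure(list(profiles = profiles,
                 leaf_profiles = profiles[seq_len(n), , drop = FALSE],
                 bins = bins, tree = tree, events = events),
            class = "cn_truth")
}

#' Add copy-number estimation noise
#'
#' Parametric stand-in for the error introduced when copy-number profiles
#' are called from sequencing reads: each entry is independently perturbed
#' by rounded Gaussian jitter and clipped to `[0, k]`. The jitter standard
#' deviation is calibrated so the expected per-entry (and hence per-cell)
#' Hamming error matches `target_error_rate`:
#' `sigma_noise = 0.5 / qnorm(1 - target_error_rate / 2)`.
#'
#' @param true_matrix Integer matrix of true copy numbers.
#' @param target_error_rate Desired fraction of perturbed entries in
#'   `[0, 1)`; default 0.24, the median per-cell error of read-based
#'   copy-number calling that this model stands in for.
#' @param sigma_noise Optional explicit jitter standard deviation,
#'   overriding the calibration.
#' @param k Maximum copy-number state for clipping (default 9).
#' @return Matrix of the same shape with integer perturbed values.
#' @export
add_estimation_noise <- function(true_matrix, target_error_rate = 0.24,
                                 sigma_noise = NULL, k = 9) {
  if (target_error_rate < 0 || target_error_rate >= 1)
    stop("`target_error_rate` must be in [0, 1)", call. = FALSE)
  if (is.null(sigma_noise)) {
    if (target_error_rate == 0) {
      out <- pmin(pmax(true_matrix, 0), k)
      storage.mode(out) <- "integer"
      dimnames(out) <- dimnames(true_matrix)
      return(out)
    }
    sigma_noise <- 0.5 / stats::qnorm(1 - target_error_rate / 2)
  }
  jitter <- matrix(stats::rnorm(length(true_matrix), 0, sigma_noise),
                   nrow = nrow(true_matrix))
  out <- round(true_matrix + jitter)
  out[out < 0] <- 0
  out[out > k] <- k
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(true_matrix)
  out
}

#' Keep every stride-th bin of a profile matrix
#'
#' Deterministic bin subsampling used to weaken dependence between adjacent
#' bins before inference (the default stride 20 keeps 1 bin in 20).
#'
#' @param values Cells-by-bins matrix.
#' @param stride Sampling stride, `>= 1`.
#' @param offset 1-based index of the first bin kept.
#' @return The subsampled matrix.
#' @export
subsample_bins <- function(values, stride = 20, offset = 1) {
  values[, seq(offset, ncol(values), by = stride), drop = FALSE]
}
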