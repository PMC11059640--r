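#' MCMC prior configuration
#'
#' Bundles the prior hyperparameters of the Bayesian model: uniform priors on
#' the root stem `d`, the error standard deviation `sigma`, the
#' diversification rate `r_d` and extinction fraction `r_e` of the
#' tree-generating birth-death process, and the random-local-clock prior
#' (Poisson number of rate changes with mean `lambda_R`, Gamma rate
#' multipliers).
#'
#' @param d_bounds Support of the uniform prior on the root stem length
#'   (default `c(0.001, 5)`).
#' @param sigma_bounds Support of the uniform prior on the error standard
#'   deviation (default `c(0, 9)`, the minimum and maximum copy-number states).
#' @param rd_bounds Support of the uniform prior on the diversification rate
#'   (default `c(0, 1e6)`).
#' @param re_bounds Support of the uniform prior on the extinction fraction
#'   (default `c(0, 1)`).
#' @param lambda_R Poisson mean of the number of rate changes; the default
#'   `log(2)` puts prior probability 0.5 on no rate change anywhere.
#' @param alpha_R,beta_R Shape and scale of the Gamma prior on rate
#'   multipliers (defaults 0.5 and 2, mean 1).
#' @param sigma_floor Numerical floor on `sigma` during inference. With
#'   integer-valued observed profiles the Gaussian error density grows
#'   without bound as `sigma` approaches 0 (every observation can be matched
#'   exactly by some state), making the posterior improper at the boundary;
#'   states with `sigma` below the floor get prior density 0 so the posterior
#'   stays evaluable. The default `1e-4` is negligible on the copy-number
#'   scale.
#' @return A list of class `cn_priors`.
#' @export
cn_priors <- function(d_bounds = c(0.001, 5), sigma_bounds = c(0, 9),
                      rd_bounds = c(0, 1e6), re_bounds = c(0, 1),
                      lambda_R = log(2), alpha_R = 0.5, beta_R = 2,
                      sigma_floor = 1e-4) {
  for (b in list(d_bounds, sigma_bounds, rd_bounds, re_bounds))
    if (length(b) != 2 || diff(b) <= 0)
      stop("prior bounds must be length-2 increasing", call. = FALSE)
  structure(list(d_bounds = d_bounds, sigma_bounds = sigma_bounds,
                 rd_bounds = rd_bounds, re_bounds = re_bounds,
                 lambda_R = lambda_R, alpha_R = alpha_R, beta_R = beta_R,
                 sigma_floor = sigma_floor),
            class = "cn_priors")
}

# log prior of the number of active rate changes: Poisson count plus the
# uniform-placement correction over the C(B, N) indicator configurations
rlc_count_log_prior <- function(n_changes, n_branches, lambda_R = log(2)) {
  stats::dpois(n_changes, lambda_R, log = TRUE) - lchoose(n_branches, n_changes)
}

# density of one internal node height under the conditioned (r_d, r_e)
# birth-death tree prior (point-process form; proper on (0, Inf))
bd_node_height_log_density <- function(t, r_d, r_e) {
  log(r_d) + log1p(-r_e) - r_d * t - 2 * log1p(-r_e * exp(-r_d * t))
}

dunif_log <- function(x, b) {
  ifelse(x >= b[1] & x <= b[2], -log(b[2] - b[1]), -Inf)
}

#' Log prior density of a posterior state
#'
#' Sum of: the conditioned two-parameter birth-death tree prior on the
#' labeled ultrametric tree (diversification rate `r_d`, extinction fraction
#' `r_e`; internal node heights iid with density
#' \eqn{g(t) = r_d (1-r_e) e^{-r_d t} / (1 - r_e e^{-r_d t})^2}, uniform over
#' labeled histories); uniform priors on `r_d`, `r_e`, the root stem `d` and
#' the error standard deviation `sigma`; and the random-local-clock prior
#' (Poisson count of active rate changes, uniform placement, Gamma rate
#' multipliers). Out-of-support states return `-Inf`, never an error.
#'
#' @param state A posterior state as produced by [mcmc_state()].
#' @param priors A [cn_priors()] object.
#' @return Log prior density (scalar; `-Inf` outside the support).
#' @export
log_prior <- function(state, priors = cn_priors()) {
  tree <- state$tree
  n <- tree$ntip
  out <- dunif_log(tree$root_stem_d, priors$d_bounds) +
    dunif_log(state$sigma, priors$sigma_bounds) +
    dunif_log(state$r_d, priors$rd_bounds) +
    dunif_log(state$r_e, priors$re_bounds)
  if (!is.finite(out)) return(-Inf)
  if (state$sigma < priors$sigma_floor) return(-Inf)
  if (state$r_d <= 0 || state$r_e < 0 || state$r_e >= 1) return(-Inf)
  internal <- (n + 1L):(2L * n - 1L)
  h <- tree$height[internal]
  if (any(h <= 0)) return(-Inf)
  out <- out + sum(bd_node_height_log_density(h, state$r_d, state$r_e))
  # random local clock: indicators live on the 2n - 2 branches
  branches <- setdiff(seq_len(2L * n - 1L), tree$root)
  if (any(tree$rate_mult[branches] <= 0)) return(-Inf)
  n_on <- sum(tree$rate_on[branches])
  out <- out + rlc_count_log_prior(n_on, length(branches), priors$lambda_R) +
    sum(stats::dgamma(tree$rate_mult[branches], shape = priors$alpha_R,
                      scale = priors$beta_R, log = TRUE))
  if (is.nan(out)) -Inf else out
}
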