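#' Birth-death model of copy-number evolution
#'
#' Constructs the continuous-time critical linear birth-death model used for
#' copy-number states. Each of the `m` copies present in a bin is independently
#' amplified (birth) or deleted (death) at per-copy rate `r`, so the chain
#' jumps from `m` to `m + 1` or `m - 1` at total rate `m * r`; state 0 is
#' absorbing (a fully deleted bin cannot regain copies). The state space used
#' during likelihood computation is truncated at `k`.
#'
#' @param r Per-copy event rate (birth rate equals death rate). Default 1: with
#'   equal birth and death rates the overall time scale is not identifiable
#'   from copy numbers alone, so branch lengths are in relative time units.
#' @param k Maximum copy-number state considered; states are `0:k`. Default 9,
#'   the largest value commonly observed in tumor copy-number calls.
#' @return An object of class `cn_bd_model`.
#' @examples
#' m <- cn_bd_model()
#' transition_matrix(0.5, m)[3, ]  # distribution of a child state given parent state 2
#' @export
cn_bd_model <- function(r = 1, k = 9) {
  if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || r <= 0)
    stop("`r` must be a single positive number", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1 || k < 2 || k != round(k))
    stop("`k` must be an integer >= 2", call. = FALSE)
  structure(list(r = r, k = as.integer(k)), class = "cn_bd_model")
}

#' @export
print.cn_bd_model <- function(x, ...) {
  cat("Linear birth-death copy-number model: r =", x$r,
      ", states 0..", x$k, "\n", sep = "")
  invisible(x)
}

#' Gaussian observation-error model for estimated copy numbers
#'
#' Estimated copy numbers are modeled as Gaussian around the true integer
#' state with standard deviation `sigma`; `sigma` carries a Uniform(lower,
#' upper) prior during inference.
#'
#' @param sigma Standard deviation of the observation noise, in copy-number
#'   units.
#' @param lower_bound,upper_bound Support of the uniform prior on `sigma`
#'   (defaults 0 and 9, the minimum and maximum copy-number states considered).
#' @return An object of class `cn_error_model`.
#' @export
cn_error_model <- function(sigma = 0.5, lower_bound = 0, upper_bound = 9) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("`sigma` must be a single positive number", call. = FALSE)
  if (upper_bound <= lower_bound)
    stop("error-model prior bounds must have positive length", call. = FALSE)
  structure(list(sigma = sigma, lower_bound = lower_bound,
                 upper_bound = upper_bound),
            class = "cn_error_model")
}

#' Transition probability of the critical linear birth-death process
#'
#' Probability that a bin ends in copy-number state `i` after time `t` given it
#' started in state `j`, under per-copy rate `r` with birth rate equal to
#' death rate. Closed form of the critical linear birth-death law: with
#' `a = rt / (1 + rt)`,
#' \deqn{P(i \mid j, t) = a^{i+j} \sum_{k=1}^{\min(i,j)}
#'   \binom{j}{k} \binom{i-1}{k-1} (rt)^{-2k}}
#' for `i, j >= 1`, `P(0 | j, t) = a^j`, and state 0 absorbing. The sum is
#' evaluated in log space with log-sum-exp.
#'
#' @param i Child (descendant) copy-number state, non-negative integer.
#' @param j Parent (ancestral) copy-number state, non-negative integer.
#' @param t Elapsed time, `>= 0`.
#' @param r Per-copy event rate, `> 0`.
#' @return A probability. At `t = 0` the Kronecker delta `i == j`.
#' @export
transition_probability <- function(i, j, t, r = 1) {
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t < 0)
    stop("`t` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || r <= 0)
    stop("`r` must be a single positive number", call. = FALSE)
  if (i < 0 || j < 0 || i != round(i) || j != round(j))
    stop("states `i` and `j` must be non-negative integers", call. = FALSE)
  rt <- r * t
  if (rt < 1e-12) return(as.numeric(i == j))
  if (j == 0) return(as.numeric(i == 0))
  la <- log(rt) - log1p(rt)          # log a
  if (i == 0) return(exp(j * la))
  ks <- seq_len(min(i, j))
  # log-sum-exp over the k-index sum
  lt <- (i + j) * la + lchoose(j, ks) + lchoose(i - 1, ks - 1) - 2 * ks * log(rt)
  m <- max(lt)
  exp(m + log(sum(exp(lt - m))))
}

#' Transition matrix over the truncated copy-number state space
#'
#' Builds the `(k+1) x (k+1)` matrix with entry `[j+1, i+1]` equal to
#' `P(child = i | parent = j, t)` for states `0:k`. Probability mass escaping
#' to states above `k` is dropped, not renormalized, so parent rows sum to at
#' most 1; the row for parent state 0 is the point mass at 0.
#'
#' @param t Elapsed time, `>= 0`.
#' @param model A [cn_bd_model()].
#' @return A numeric matrix, rows indexed by parent state, columns by child
#'   state (both `0:k`).
#' @export
transition_matrix <- function(t, model) {
  stopifnot(inherits(model, "cn_bd_model"))
  k <- model$k
  r <- model$r
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t < 0)
    stop("`t` must be a single non-negative number", call. = FALSE)
  n <- k + 1L
  rt <- r * t
  if (rt < 1e-12) return(diag(n))
  # the law from j copies is the j-fold convolution of the one-copy law
  # q(i) = P(i | 1, t); intermediate states in the convolution never exceed
  # the target state, so row-by-row truncated convolution is exact for i <= k
  a <- rt / (1 + rt)
  q <- c(a, (1 - a)^2 * a^(0:(k - 1)))
  C <- matrix(0, n, n)
  shift <- col(C) - row(C)
  C[shift >= 0] <- q[shift[shift >= 0] + 1L]     # upper-triangular Toeplitz
  P <- matrix(0, n, n)
  P[1, 1] <- 1                                   # parent 0: absorbing
  P[2, ] <- q
  if (k >= 2) for (j in 2:k) P[j + 1L, ] <- P[j, ] %*% C
  P
}

#' Log density of the Gaussian copy-number observation error
#'
#' @param c_obs Observed (estimated) copy number, real-valued.
#' @param c_true True integer copy-number state (may be a vector).
#' @param sigma Standard deviation of the observation noise, `> 0`.
#' @return Log of the Normal(`c_true`, `sigma`) density at `c_obs`,
#'   vectorized over `c_true`.
#' @export
log_error_density <- function(c_obs, c_true, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive number", call. = FALSE)
  stats::dnorm(c_obs, mean = c_true, sd = sigma, log = TRUE)
}
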