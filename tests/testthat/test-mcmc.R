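test_that("chains are deterministic under a fixed seed", {
  values <- toy_matrix()
  cfg <- mcmc_config(chain_length = 300, n_log = 50)
  f1 <- run_mcmc(values, cfg, seed = 11)
  f2 <- run_mcmc(values, cfg, seed = 11)
  expect_equal(f1$trace, f2$trace)
  expect_equal(f1$trees[[length(f1$trees)]]$height,
               f2$trees[[length(f2$trees)]]$height)
  f3 <- run_mcmc(values, cfg, seed = 12)
  expect_false(isTRUE(all.equal(f1$trace$log_posterior,
                                f3$trace$log_posterior)))
})

test_that("a zero-length chain returns only the initial state", {
  values <- toy_matrix()
  fit <- run_mcmc(values, mcmc_config(chain_length = 0), seed = 1)
  expect_identical(nrow(fit$trace), 1L)
  expect_identical(fit$trace$iteration, 0L)
  expect_length(fit$trees, 1L)
})

test_that("cached posterior values match from-scratch recomputation", {
  values <- toy_matrix(4, 10)
  cfg <- mcmc_config(chain_length = 400, n_log = 40)
  fit <- run_mcmc(values, cfg, seed = 23)
  model <- cn_bd_model(r = cfg$r, k = cfg$k)
  idx <- c(10, 25, 41)
  for (i in idx) {
    tr <- fit$trees[[i]]
    row <- fit$trace[i, ]
    st <- mcmc_state(tr, sigma = row$sigma, r_d = row$r_d, r_e = row$r_e)
    expect_equal(row$log_prior, log_prior(st, cfg$priors), tolerance = 1e-8)
    expect_equal(row$log_likelihood,
                 tree_log_likelihood(tr, values, model, row$sigma),
                 tolerance = 1e-8)
    expect_equal(row$log_posterior, row$log_likelihood + row$log_prior,
                 tolerance = 1e-10)
  }
})

test_that("proposals preserve tree validity", {
  values <- toy_matrix(6, 10)
  cfg <- mcmc_config(chain_length = 600, n_log = 100)
  fit <- run_mcmc(values, cfg, seed = 31)
  for (tr in fit$trees[seq(1, length(fit$trees), by = 10)]) {
    # reconstructing through the validating constructor must succeed
    expect_s3_class(cn_tree(tr$parent, tr$height, tr$tip_label,
                            tr$rate_mult, tr$rate_on, tr$root_stem_d),
                    "cn_tree")
  }
})

test_that("prior-only sampling matches the prior on 4-leaf topologies", {
  # under the conditioned birth-death prior every labeled history is equally
  # likely: with 4 tips the 18 histories give each balanced topology
  # probability 1/9 and each caterpillar 1/18
  values <- toy_matrix(4, 6)
  cfg <- mcmc_config(chain_length = 30000, n_log = 3000,
                     likelihood_on = FALSE)
  fit <- run_mcmc(values, cfg, seed = 41)
  ps <- posterior_samples(fit, 0.2, 2400)
  topo <- vapply(ps$trees, function(t)
    paste(sort(cnphylo:::clade_keys(t)[(t$ntip + 1):(2 * t$ntip - 1)]),
          collapse = ";"), character(1))
  freq <- table(topo) / length(topo)
  # balanced topologies contain two cherries (two 2-tip clades)
  n_cherries <- vapply(names(freq), function(s)
    sum(lengths(gregexpr("\t", strsplit(s, ";")[[1]])) == 1), numeric(1))
  balanced <- n_cherries == 2
  expect_equal(unname(sum(freq[balanced]) / sum(balanced)), 1 / 9,
               tolerance = 0.35)
  expect_equal(unname(sum(freq[!balanced]) / sum(!balanced)), 1 / 18,
               tolerance = 0.35)
  # all 15 labeled topologies are reached
  expect_gte(length(freq), 13)
})

test_that("prior-only sampling recovers the uniform moments", {
  values <- toy_matrix(4, 6)
  cfg <- mcmc_config(chain_length = 20000, n_log = 2000,
                     likelihood_on = FALSE)
  fit <- run_mcmc(values, cfg, seed = 43)
  tr <- posterior_samples(fit, 0.2, 1600)$trace
  expect_equal(mean(tr$sigma), 4.5, tolerance = 0.15)
  expect_equal(mean(tr$r_e), 0.5, tolerance = 0.15)
  expect_equal(mean(tr$d), 2.5, tolerance = 0.2)
  # no-change probability of the clock prior
  expect_equal(mean(tr$n_rate_changes == 0), 0.5, tolerance = 0.15)
})

test_that("coupling degenerates to a single chain and validates its ladder", {
  values <- toy_matrix()
  cfg1 <- mcmc_config(chain_length = 200, n_log = 40, n_chains = 1)
  expect_equal(coupled_chains(values, cfg1, seed = 7)$trace,
               run_mcmc(values, cfg1, seed = 7)$trace)
  bad <- mcmc_config(chain_length = 100, n_chains = 3, delta_T = 0)
  expect_error(coupled_chains(values, bad, seed = 7), "ladder")
})

test_that("coupled and single chains agree on a flat-likelihood problem", {
  values <- toy_matrix(4, 6)
  cfg <- mcmc_config(chain_length = 12000, n_log = 1200,
                     likelihood_on = FALSE, n_chains = 3, swap_every = 50)
  cold <- coupled_chains(values, cfg, seed = 51)
  single <- run_mcmc(values, mcmc_config(chain_length = 12000, n_log = 1200,
                                         likelihood_on = FALSE), seed = 52)
  a <- posterior_samples(cold, 0.2, 900)$trace$sigma
  b <- posterior_samples(single, 0.2, 900)$trace$sigma
  # with no likelihood the swap ratio is 0, so every swap is accepted
  expect_true(all(cold$swap$accepted))
  # both marginals are the Uniform(0, 9) prior; compare their moments with a
  # tolerance wide enough for the chains' autocorrelation
  expect_equal(mean(a), mean(b), tolerance = 0.2)
  expect_equal(sd(a), sd(b), tolerance = 0.25)
})

test_that("bin subsampling is a deterministic stride", {
  values <- toy_matrix(4, 40)
  cfg <- mcmc_config(chain_length = 50, n_log = 10, subsample_stride = 10,
                     subsample_offset = 3)
  fit <- run_mcmc(values, cfg, seed = 2)
  direct <- run_mcmc(values[, c(3, 13, 23, 33)],
                     mcmc_config(chain_length = 50, n_log = 10), seed = 2)
  expect_equal(fit$trace$log_likelihood, direct$trace$log_likelihood)
  expect_identical(subsample_bins(values, 10, 3), values[, c(3, 13, 23, 33)])
})

test_that("tidy, glance and autoplot expose the run", {
  values <- toy_matrix()
  fit <- run_mcmc(values, mcmc_config(chain_length = 100, n_log = 20),
                  seed = 3)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("iteration", "log_posterior", "d", "sigma",
                    "n_rate_changes") %in% names(td)))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$acceptance_rate >= 0 && gl$acceptance_rate <= 1)
  expect_s3_class(autoplot(fit), "ggplot")
})
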