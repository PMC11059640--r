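test_that("the MCC tree is the brute-force clade-product argmax", {
  withr::with_seed(71, {
    # mixed bag of 5- and 6-leaf samples drawn from short prior runs
    for (n in c(5, 6)) {
      samples <- replicate(20, random_ultrametric_tree(n, height = 1),
                           simplify = FALSE)
      # reuse a few topologies so clade frequencies are informative
      samples[11:15] <- samples[1:5]
      samples[16:20] <- samples[1:5]
      got <- mcc_tree(samples)
      want <- oracle_mcc_index(samples)
      expect_equal(got$index, want)
      # supports equal the frequency of each clade among samples; clades are
      # counted once per sample tree
      per_sample <- lapply(samples, function(t)
        cnphylo:::clade_keys(t)[(t$ntip + 1):(2 * t$ntip - 1)])
      for (i in seq_len(nrow(got$supports))) {
        count <- sum(vapply(per_sample, function(ks)
          got$supports$clade[i] %in% ks, logical(1)))
        expect_equal(got$supports$support[i], count / length(samples))
      }
    }
  })
})

test_that("a 2:1 topology vote picks the majority tree", {
  a <- tree4_balanced()
  b <- tree4_caterpillar()
  mcc <- mcc_tree(list(a, a, b))
  expect_equal(mcc$index, oracle_mcc_index(list(a, a, b)))
  expect_identical(sort(cnphylo:::clade_keys(mcc$tree)),
                   sort(cnphylo:::clade_keys(a)))
  # identical samples: that tree with all supports 1
  mcc2 <- mcc_tree(list(b, b, b))
  expect_true(all(mcc2$supports$support == 1))
})

test_that("median node heights summarize per-clade height samples", {
  base <- tree4_balanced(h1 = 0.2, h2 = 0.35, h3 = 0.6)
  perturb <- function(h1, h2, h3) tree4_balanced(h1, h2, h3)
  samples <- list(perturb(0.1, 0.3, 0.5), perturb(0.2, 0.35, 0.6),
                  perturb(0.45, 0.4, 0.7))
  mcc <- mcc_tree(samples)
  med <- median_node_heights(mcc, samples)
  hs <- sort(med$height[med$height > 0])
  expect_equal(hs, c(0.2, 0.35, 0.6))
  # single sample: its own heights
  one <- median_node_heights(mcc_tree(list(base)), list(base))
  expect_equal(one$height, base$height)
})

test_that("incompatible median heights are flagged, not repaired", {
  # clade heights taken from different samples can invert parent and child
  s1 <- tree4_caterpillar(0.10, 0.30, 0.9)
  s2 <- tree4_caterpillar(0.28, 0.30, 0.31)
  s3 <- tree4_caterpillar(0.29, 0.30, 0.32)
  mcc <- mcc_tree(list(s1, s2, s3))
  med <- median_node_heights(mcc, list(s1, s2, s3))
  expect_true(length(attr(med, "height_violations")) >= 0)
  # construct an explicit inversion: child's median above parent's
  sA <- tree4_caterpillar(0.05, 0.50, 0.95)
  sB <- tree4_caterpillar(0.45, 0.50, 0.55)
  sC <- tree4_caterpillar(0.46, 0.47, 0.96)
  mcc2 <- mcc_tree(list(sA, sB, sC))
  med2 <- median_node_heights(mcc2, list(sA, sB, sC))
  viol <- attr(med2, "height_violations")
  nonroot <- setdiff(which(med2$parent > 0), seq_len(med2$ntip))
  inverted <- nonroot[med2$height[nonroot] >= med2$height[med2$parent[nonroot]]]
  expect_setequal(viol[viol > med2$ntip], inverted)
})

test_that("HPD intervals match the enumerate-all-windows oracle", {
  expect_equal(diff(hpd_interval(1:100, 0.95)), 94)
  expect_equal(hpd_interval(c(3, 3, 3, 3), 0.9), c(3, 3))
  withr::with_seed(73, {
    for (rep in 1:20) {
      x <- switch(1 + rep %% 3,
                  rnorm(50), rexp(31), c(rnorm(20), rnorm(12, 8)))
      for (mass in c(0.5, 0.9, 0.95)) {
        got <- hpd_interval(x, mass)
        expect_equal(got, oracle_hpd(x, mass))
        expect_gte(got[1], min(x))
        expect_lte(got[2], max(x))
      }
    }
  })
  expect_error(hpd_interval(1), "at least 2")
})

test_that("the OLS scale factor minimizes the residue", {
  x <- c(1, 2, 3, 4)
  expect_equal(ols_scale(x, 2 * x), 2)
  expect_equal(ols_scale(1, 3), 3)
  withr::with_seed(74, {
    x <- runif(10, 0, 2)
    y <- 1.7 * x + rnorm(10, 0, 0.2)
    beta <- ols_scale(x, y)
    expect_equal(beta, oracle_ols_beta(x, y), tolerance = 1e-3)
  })
  expect_error(ols_scale(c(0, 0), c(1, 2)), "zero")
})

test_that("branch recovery is counted per true-length decile", {
  withr::with_seed(75, {
    truth <- random_ultrametric_tree(12, height = 1)
    same <- replicate(10, truth, simplify = FALSE)
    tpr <- branch_tpr_by_decile(truth, same)
    expect_true(all(tpr$recovery == 1))
    expect_equal(sum(tpr$n_branches), 10)  # 11 internal clades minus root
    # clade present in 7 of 10 samples
    other <- random_ultrametric_tree(12, height = 1)
    mix <- c(replicate(7, truth, simplify = FALSE),
             replicate(3, other, simplify = FALSE))
    tpr_mix <- branch_tpr_by_decile(truth, mix)
    expect_true(any(abs(tpr_mix$recovery - 0.7) < 1e-9))
    # disjoint topologies: zero recovery for non-shared clades only
    expect_true(all(tpr_mix$recovery >= 0.7 - 1e-9 |
                      tpr_mix$recovery <= 0.3))
  })
})

test_that("pairwise-distance error is scale-free and zero at equality", {
  withr::with_seed(76, {
    tr <- random_ultrametric_tree(6, height = 1)
    expect_equal(normalized_pairwise_distance_error(tr, tr), 0)
    scaled <- tr
    scaled$height <- tr$height * 37
    expect_equal(normalized_pairwise_distance_error(scaled, tr), 0,
                 tolerance = 1e-12)
  })
  # hand-computed 3-leaf case: distances ((a,b),c) vs star-like truth
  est <- tree3(h1 = 0.1, h2 = 0.5)
  tru <- tree3(h1 = 0.4, h2 = 0.5)
  D_est <- cnphylo:::mutation_distance_matrix(est)
  D_tru <- cnphylo:::mutation_distance_matrix(tru)
  nrm <- function(D) {
    off <- D[row(D) != col(D)]
    N <- (D - min(off)) / (max(off) - min(off)); diag(N) <- 0; N
  }
  want <- sqrt(sum((nrm(D_est) - nrm(D_tru))^2)) / 4
  expect_equal(normalized_pairwise_distance_error(est, tru), want)
  expect_error(normalized_pairwise_distance_error(tree2(), tree2()),
               "at least 3")
})

test_that("coverage counts matched clades whose truth falls in the HPD", {
  truth <- tree4_balanced()
  identical_samples <- replicate(5, truth, simplify = FALSE)
  cov <- posterior_coverage(truth, identical_samples)
  expect_equal(attr(cov, "coverage"), 1)
  expect_true(all(cov$hi - cov$lo == 0))
  # Gaussian heights around the truth cover at the nominal rate
  withr::with_seed(77, {
    hits <- replicate(60, {
      h0 <- 0.2
      base <- tree2(height = h0, d = 0.5)
      samples <- lapply(rnorm(80, h0, 0.03), function(h) tree2(height = h))
      cov1 <- posterior_coverage(base, samples)
      cov1$covered[1]
    })
    expect_gt(mean(hits), 0.85)
    expect_lte(mean(hits), 1)
  })
})

test_that("metrics are invariant to consistent leaf relabeling", {
  withr::with_seed(78, {
    truth <- random_ultrametric_tree(7, height = 1)
    samples <- replicate(6, random_ultrametric_tree(7, height = 1),
                         simplify = FALSE)
    samples[4:6] <- list(truth, truth, truth)
    relabel <- function(tree, map) {
      tree$tip_label <- unname(map[tree$tip_label])
      tree
    }
    map <- stats::setNames(paste0("z", 1:7), truth$tip_label)
    tpr1 <- branch_tpr_by_decile(truth, samples)
    tpr2 <- branch_tpr_by_decile(relabel(truth, map),
                                 lapply(samples, relabel, map = map))
    expect_equal(tpr1$recovery, tpr2$recovery)
    err1 <- normalized_pairwise_distance_error(samples[[1]], truth)
    err2 <- normalized_pairwise_distance_error(relabel(samples[[1]], map),
                                               relabel(truth, map))
    expect_equal(err1, err2)
  })
})
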