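test_that("a = 0 gives exactly uniform positions", {
  withr::with_seed(61, {
    dens <- position_density(a = 0)
    x <- sample_position(dens, 1e4)
    expect_true(all(x >= 0 & x < 1))
    expect_gt(suppressWarnings(ks.test(x, punif))$p.value, 0.01)
  })
})

test_that("draws reproduce the constructed density", {
  withr::with_seed(62, {
    dens <- position_density(a = 0.6, grid_n = 1e5)
    x <- sample_position(dens, 2e5)
    expect_true(all(x >= 0 & x < 1))
    # empirical mass per coarse window vs integral of the grid density
    brk <- seq(0, 1, by = 0.05)
    emp <- as.numeric(table(cut(x, brk))) / length(x)
    grid_bin <- findInterval((seq_len(dens$grid_n) - 0.5) / dens$grid_n, brk)
    want <- as.numeric(tapply(dens$pdf / dens$grid_n, grid_bin, sum))
    expect_lt(max(abs(emp - want)), 4 * sqrt(max(want) * (1 / length(x))) + 0.004)
  })
})

test_that("event counts and sizes follow the stated distributions", {
  withr::with_seed(63, {
    tr <- tree2(height = 1, d = 0)  # two branches of length 1 each
    dens <- position_density(0)
    reps <- 400
    counts <- vapply(seq_len(reps), function(i)
      nrow(simulate_events(tr, 125, dens)), numeric(1))
    # total branch length 2, so mean total events 250
    expect_equal(mean(counts), 250, tolerance = 0.03)
    ev <- simulate_events(tree2(height = 20, d = 0), 125, dens)
    expect_equal(mean(ev$length_bp), 12e6, tolerance = 0.03)
    expect_true(all(ev$length_bp >= 2e6))
    expect_true(all(ev$allele %in% c("maternal", "paternal")))
    expect_true(all(ev$sign %in% c(-1L, 1L)))
  })
})

test_that("event simulation is deterministic under a fixed seed", {
  tr <- withr::with_seed(1, random_ultrametric_tree(6))
  dens1 <- withr::with_seed(64, position_density(0.6, grid_n = 1e4))
  dens2 <- withr::with_seed(64, position_density(0.6, grid_n = 1e4))
  e1 <- withr::with_seed(65, simulate_events(tr, 90, dens1))
  e2 <- withr::with_seed(65, simulate_events(tr, 90, dens2))
  expect_equal(e1, e2)
  p1 <- events_to_profiles(tr, e1, n_bins = 200)
  p2 <- events_to_profiles(tr, e2, n_bins = 200)
  expect_identical(p1$profiles, p2$profiles)
})

test_that("no events means diploid profiles everywhere", {
  tr <- tree3()
  ev <- manual_events(integer(), character(), numeric(), numeric(), integer())
  prof <- events_to_profiles(tr, ev, n_bins = 50)
  expect_true(all(prof$profiles == 2L))
})

test_that("a single gain raises only the covered bins of its lineage", {
  tr <- tree3()          # tips a, b, c; branch 1 is the branch above tip a
  ev <- manual_events(branch = 1L, allele = "maternal", start = 0.2,
                      length_bp = 2e7, sign = 1L, genome_length = 1e8)
  # interval [0.2, 0.4) over 10 bins of width 0.1: bins 3 and 4
  prof <- events_to_profiles(tr, ev, n_bins = 10)
  expect_equal(unname(prof$profiles["a", ]), c(2, 2, 3, 3, 2, 2, 2, 2, 2, 2))
  expect_true(all(prof$profiles[c("b", "c"), ] == 2L))
  expect_true(all(prof$profiles["node1", ] == 2L))
})

test_that("losses floor at zero copies per allele", {
  tr <- tree2(height = 1, d = 0)
  # two successive losses then a nested loss on the same allele interval:
  # allele hits 0 and stays there; the other allele is untouched
  ev <- manual_events(branch = c(1L, 1L, 1L), allele = rep("maternal", 3),
                      start = c(0.1, 0.1, 0.15), length_bp = c(3e7, 3e7, 1e7),
                      sign = c(-1L, -1L, -1L), time = c(0.1, 0.5, 0.9),
                      genome_length = 1e8)
  prof <- events_to_profiles(tr, ev, n_bins = 10)
  expect_equal(unname(prof$profiles["a", 2:4]), c(1, 1, 1))  # paternal only
  expect_true(all(prof$profiles["b", ] == 2L))
})

test_that("partially covered bins take the rounded weighted mean", {
  tr <- tree2(height = 1, d = 0)
  # gain over [0.25, 0.5) on 4 bins of width 0.25: bin 2 fully covered;
  # a second gain over [0.30, 0.50) covers 80% of bin 2 -> mean 3.8 -> 4
  ev <- manual_events(branch = c(1L, 1L), allele = c("maternal", "paternal"),
                      start = c(0.25, 0.30), length_bp = c(25e6, 20e6),
                      sign = c(1L, 1L), genome_length = 1e8)
  prof <- events_to_profiles(tr, ev, n_bins = 4)
  expect_equal(unname(prof$profiles["a", ]), c(2, 4, 2, 2))
})

test_that("ancestral truth equals replaying the path events", {
  withr::with_seed(66, {
    tr <- random_ultrametric_tree(6, height = 1)
    ev <- simulate_events(tr, 60, position_density(0.4, grid_n = 1e4))
    truth <- events_to_profiles(tr, ev, n_bins = 120)
    # pick an internal node; replay only the events on its root path on a
    # fresh 2-leaf scaffold whose single loaded branch applies them in the
    # same root-to-node order
    node <- tr$parent[1]                    # parent of tip 1
    path <- integer()
    v <- node
    while (v != tr$root) { path <- c(path, v); v <- tr$parent[v] }
    keep <- ev[ev$branch %in% path, ]
    ord <- order(match(keep$branch, rev(path)), keep$time)
    keep <- keep[ord, ]
    keep$branch <- rep(1L, nrow(keep))
    keep$time <- seq_len(nrow(keep)) / (nrow(keep) + 1)
    scaffold <- tree2(height = 1, d = 0)
    prof2 <- events_to_profiles(scaffold, keep, n_bins = 120)
    label <- rownames(truth$profiles)[node]
    expect_identical(unname(truth$profiles[label, ]),
                     unname(prof2$profiles["a", ]))
  })
})

test_that("overlap fraction counts pairwise interval intersections", {
  one <- manual_events(1L, "maternal", 0.3, 5e6, 1L, genome_length = 1e8)
  expect_identical(overlap_fraction(one), 0)
  twin <- manual_events(c(1L, 2L), c("maternal", "paternal"), c(0.3, 0.3),
                        c(5e6, 5e6), c(1L, -1L), genome_length = 1e8)
  expect_identical(overlap_fraction(twin), 1)
  disjoint <- manual_events(c(1L, 2L), c("maternal", "maternal"),
                            c(0, 0.5), c(1e7, 1e7), c(1L, 1L),
                            genome_length = 1e8)
  expect_identical(overlap_fraction(disjoint), 0)
  # middle interval bridges two others that do not touch each other
  mixed <- manual_events(c(1L, 1L, 2L), rep("maternal", 3), c(0, 0.25, 0.6),
                         c(1e7, 4e7, 1e7), c(1L, 1L, 1L),
                         genome_length = 1e8)
  expect_equal(overlap_fraction(mixed), 2 / 3)
  empty <- manual_events(integer(), character(), numeric(), numeric(),
                         integer())
  expect_error(overlap_fraction(empty), "no events")
})

test_that("estimation noise hits its calibrated error rate", {
  withr::with_seed(67, {
    truth <- matrix(sample(1:4, 20 * 750, replace = TRUE), nrow = 20,
                    dimnames = list(paste0("c", 1:20), NULL))
    expect_identical(add_estimation_noise(truth, 0), truth)
    noisy <- add_estimation_noise(truth, 0.24)
    expect_true(all(noisy >= 0 & noisy <= 9))
    per_cell <- rowMeans(noisy != truth)
    expect_lt(abs(median(per_cell) - 0.24), 0.03)
  })
})
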