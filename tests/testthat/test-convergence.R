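test_that("count_entries: all states inside the region gives zero", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  S <- matrix(rnorm(7 * 3, sd = 0.05), 7, 3)
  big <- structure(list(center = colMeans(S), shape = diag(3) * 100,
                        radius = 1, degenerate = FALSE),
                   class = "ellipsoid_region")
  expect_identical(count_entries(tr, S, big), 0L)
})

test_that("count_entries matches manual enumeration on a hand-built tree", {
  # 4-tip tree; region placed so exactly (root->A) and (n6->C) cross inside
  tr <- ape::read.tree(text = "(A:1,((B:1,C:1):1,D:2):1);")
  n <- 4
  S <- rbind(A = c(0, 0, 0),      # inside
             B = c(5, 0, 0),      # outside
             C = c(0.1, 0, 0),    # inside
             D = c(6, 0, 0),      # outside
             c(3, 3, 3),          # node 5 (root): outside
             c(4, 0, 0),          # node 6: outside
             c(5, 5, 0))          # node 7: outside
  region <- structure(list(center = c(0, 0, 0), shape = diag(3),
                           radius = 1, degenerate = FALSE),
                      class = "ellipsoid_region")
  expect_identical(count_entries(tr, S, region), 2L)
  expect_identical(manual_count_entries(tr, S, region), 2L)

  # exhaustive agreement with the oracle over random configurations
  set.seed(83)
  for (i in 1:20) {
    S2 <- matrix(rnorm(7 * 3), 7, 3)
    expect_identical(count_entries(tr, S2, region),
                     as.integer(manual_count_entries(tr, S2, region)))
  }
})

test_that("count_entries is invariant under child reordering / relabeling", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:1.5,D:0.5):1);")
  set.seed(89)
  S <- matrix(rnorm(7 * 3), 7, 3)
  rownames(S) <- c(tr$tip.label, "5", "6", "7")
  region <- structure(list(center = c(0, 0, 0), shape = diag(3) * 2,
                           radius = 1, degenerate = FALSE),
                      class = "ellipsoid_region")
  c0 <- count_entries(tr, S, region)
  tr2 <- ape::rotate(tr, 6)             # swap children of one node
  S2 <- S[c(tr2$tip.label, "5", "6", "7"), ]
  expect_identical(count_entries(tr2, S2, region), c0)
})

test_that("count_entries errors on missing states", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  S <- matrix(c(0, 0, 0, NA, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  region <- far_region()
  expect_error(count_entries(tr, S, region), "without a state")
})

test_that("convergence_test: p-value estimator boundary cases", {
  cfg <- synthetic_config(seed = 97, n_species = 30, n_planted = 5)
  ds <- simulate_dataset(cfg)
  # region far away from everything: observed 0, every null >= 0, p = 1
  res0 <- convergence_test(ds$tree, ds$tips, far_region(), n_sim = 99,
                           seed = 7)
  expect_identical(res0$observed, 0L)
  expect_equal(res0$p, 1)
  expect_lte(res0$null_mean, 0.01)

  # strong planted convergence: observed beats every null, p = 1/(n_sim+1)
  cfg2 <- synthetic_config(seed = 97, n_species = 100, n_planted = 10,
                           convergence_pull = 0.8)
  ds2 <- simulate_dataset(cfg2)
  res2 <- convergence_test(ds2$tree, ds2$tips, ds2$region, n_sim = 199,
                           seed = 7)
  expect_gt(res2$observed, res2$null_max)
  expect_equal(res2$p, 1 / 200)
})

test_that("convergence_test is reproducible bit-for-bit under a fixed seed", {
  cfg <- synthetic_config(seed = 101, n_species = 40, n_planted = 6,
                          convergence_pull = 0.5)
  ds <- simulate_dataset(cfg)
  a <- convergence_test(ds$tree, ds$tips, ds$region, n_sim = 99, seed = 13)
  b <- convergence_test(ds$tree, ds$tips, ds$region, n_sim = 99, seed = 13)
  expect_identical(a$null_counts, b$null_counts)
  expect_identical(a$p, b$p)
  # summaries derive from the stored null counts
  expect_equal(a$null_mean, mean(a$null_counts))
  expect_equal(a$null_sd, sd(a$null_counts))
  expect_identical(a$null_max, max(a$null_counts))
  expect_true(a$p >= 1 / 100 && a$p <= 1)
})

test_that("null replicates equal repeated simulate_bm under subseeds", {
  cfg <- synthetic_config(seed = 103, n_species = 20)
  ds <- simulate_dataset(cfg)
  rate <- estimate_rate_matrix(ds$tree, ds$tips)$rate
  asr <- reconstruct_ancestral_states(ds$tree, ds$tips)
  res <- convergence_test(ds$tree, ds$tips, ds$region, n_sim = 25, seed = 500,
                          rate = rate, root_state = asr$root)
  manual <- vapply(1:25, function(r)
    count_entries(ds$tree,
                  simulate_bm(ds$tree, asr$root, rate, seed = 500 + r),
                  ds$region), integer(1))
  expect_identical(res$null_counts, manual)
})

test_that("reconstruct_null mode re-runs ASR on simulated tips", {
  cfg <- synthetic_config(seed = 107, n_species = 25, n_planted = 5,
                          convergence_pull = 0.6)
  ds <- simulate_dataset(cfg)
  a <- convergence_test(ds$tree, ds$tips, ds$region, n_sim = 30, seed = 3,
                        reconstruct_null = TRUE)
  expect_identical(a$observed,
                   convergence_test(ds$tree, ds$tips, ds$region, n_sim = 1,
                                    seed = 3)$observed)
  expect_true(all(a$null_counts >= 0))
})

test_that("holm_correction: hand calculations and edge cases", {
  one <- holm_correction(0.03, alpha = 0.05)
  expect_equal(one$adjusted_p, 0.03)
  expect_true(one$significant)

  two <- holm_correction(c(0.01, 0.04), alpha = 0.05)
  expect_equal(two$adjusted_p, c(0.02, 0.04))
  expect_true(all(two$significant))

  empty <- holm_correction(numeric(0))
  expect_identical(nrow(empty), 0L)
  expect_error(holm_correction(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(holm_correction(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("holm_correction agrees with stats::p.adjust and flags the
           published significance pattern", {
  set.seed(109)
  for (i in 1:10) {
    p <- runif(sample(2:12, 1))
    expect_equal(holm_correction(p)$adjusted_p, p.adjust(p, method = "holm"))
  }
  # an 18-test table from an empirical floral-colour convergence analysis:
  # the Holm-significant set must be the six 0.001 rows plus the 0.002 row;
  # 0.008 and 0.023 must not survive the correction
  p18 <- c(1, 0.001, 0.159, 0.541, 0.001, 0.055,
           0.665, 0.002, 0.001, 0.151, 0.008, 0.001,
           0.528, 0.001, 0.023, 1, 0.001, 0.115)
  hc <- holm_correction(p18, alpha = 0.05)
  expect_identical(hc$significant, p18 <= 0.002)
})
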