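test_that("read_tree parses Newick and Nexus, preserving polytomies", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1);", f)
  tr <- read_tree(f)
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(tr$edge.length, c(1, 1))

  f2 <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1,C:1);", f2)
  tr2 <- read_tree(f2)
  expect_equal(tr2$Nnode, 1L)          # trifurcating root preserved

  # Nexus TREES block round-trips to the same topology as Newick
  f3 <- withr::local_tempfile(fileext = ".nex")
  big <- ape::read.tree(text = "((A:1,B:2):0.5,(C:1.5,D:0.7,E:0.9):1);")
  ape::write.nexus(big, file = f3)
  tr3 <- read_tree(f3)
  expect_true(ape::all.equal.phylo(tr3, big, use.edge.length = TRUE))
})

test_that("read_tree rejects missing branch lengths and duplicate tips", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A,B);", f)
  expect_error(read_tree(f), "branch lengths")
  f2 <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,A:1);", f2)
  expect_error(read_tree(f2), "duplicate")
  f3 <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,(B:0,C:1):1);", f3)
  expect_warning(tr <- read_tree(f3), "perturbed")
  expect_true(all(tr$edge.length > 0))
})

test_that("ASR: constant tips reconstruct to the constant everywhere", {
  tr <- ape::read.tree(text = "((A:1,B:2):0.5,(C:1.5,D:0.7):1);")
  X <- matrix(3.14, 4, 3, dimnames = list(tr$tip.label, NULL))
  asr <- reconstruct_ancestral_states(tr, X)
  expect_equal(unname(asr$node_states), matrix(3.14, 3, 3), tolerance = 1e-10)
})

test_that("ASR: 2-tip closed form (inverse-branch-length weighting)", {
  tr <- ape::read.tree(text = "(A:1,B:3);")
  X <- matrix(c(0, 1), 2, 1, dimnames = list(c("A", "B"), NULL))
  asr <- reconstruct_ancestral_states(tr, X)
  expect_equal(unname(asr$root), (0 / 1 + 1 / 3) / (1 / 1 + 1 / 3),
               tolerance = 1e-12)
})

test_that("ASR matches the dense GLS oracle, including on polytomies", {
  trees <- list(
    ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"),
    ape::read.tree(text = "((A:0.4,B:2.1,C:0.9):0.7,(D:1.2,(E:0.3,F:0.8):0.6):1.1);"))
  set.seed(61)
  for (tr in trees) {
    X <- matrix(rnorm(length(tr$tip.label) * 3), ncol = 3,
                dimnames = list(tr$tip.label, NULL))
    asr <- reconstruct_ancestral_states(tr, X)
    expect_equal(unname(asr$node_states), unname(gls_asr_oracle(tr, X)),
                 tolerance = 1e-8)
  }
})

test_that("ASR is linear and reduces to the tip mean on an ultrametric star", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  set.seed(67)
  X <- matrix(rnorm(5), 5, 1, dimnames = list(star$tip.label, NULL))
  asr <- reconstruct_ancestral_states(star, X)
  expect_equal(unname(asr$root), mean(X), tolerance = 1e-12)
  asr2 <- reconstruct_ancestral_states(star, 2 + 3 * X)
  expect_equal(asr2$node_states, 2 + 3 * asr$node_states, tolerance = 1e-10)
})

test_that("ASR errors when tips lack states", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  X <- matrix(rnorm(2), 2, 1, dimnames = list(c("A", "B"), NULL))
  expect_error(reconstruct_ancestral_states(tr, X), "tips without states: C")
})

test_that("rate matrix: zero for identical tips, hand oracle on a star tree", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  X <- matrix(1, 4, 3, dimnames = list(tr$tip.label, NULL))
  expect_equal(unname(estimate_rate_matrix(tr, X)$rate), matrix(0, 3, 3))

  # star tree, unit branches: sequential-pairing contrasts by hand
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  x <- c(A = 2, B = 5, C = 1)
  res <- estimate_rate_matrix(star, matrix(x, dimnames = list(names(x), NULL)))
  u1 <- (2 - 5) / sqrt(2)
  u2 <- ((2 + 5) / 2 - 1) / sqrt(1 / 2 + 1)
  expect_equal(sort(as.numeric(res$contrasts)), sort(c(u1, u2)))
  expect_equal(as.numeric(res$rate), mean(c(u1^2, u2^2)))
})

test_that("rate matrix matches ape::pic on binary trees", {
  set.seed(71)
  tr <- ape::rtree(12)
  x <- rnorm(12)
  names(x) <- tr$tip.label
  mine <- estimate_rate_matrix(tr, matrix(x, dimnames = list(names(x), NULL)))
  expect_equal(as.numeric(mine$rate), mean(ape::pic(x, tr)^2),
               tolerance = 1e-10)
})

test_that("rate matrix recovers a known BM rate (parameter recovery)", {
  set.seed(73)
  tr <- ape::rphylo(200, 1, 0)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  Sigma <- matrix(c(0.04, 0.01, 0, 0.01, 0.03, -0.005, 0, -0.005, 0.02), 3, 3)
  errs <- vapply(1:50, function(r) {
    S <- simulate_bm(tr, c(0, 0, 0), Sigma, seed = 1000 + r)
    est <- estimate_rate_matrix(tr, S[seq_len(200), ])$rate
    norm(est - Sigma, "F") / norm(Sigma, "F")
  }, numeric(1))
  expect_lt(mean(errs), 0.25)
})

test_that("simulate_bm: degenerate and moment checks", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  S0 <- simulate_bm(tr, c(1, 2, 3), matrix(0, 3, 3), seed = 5)
  expect_true(all(apply(S0, 1, function(r) all(r == c(1, 2, 3)))))
  expect_error(simulate_bm(tr, c(0, 0, 0), diag(c(1, 1, -1))),
               "positive semi-definite")

  # tip variance ~ sigma^2 * depth, sister covariance ~ sigma^2 * shared path
  tr2 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  reps <- t(vapply(1:1200, function(i)
    simulate_bm(tr2, c(0, 0, 0), diag(3) * 0.5, seed = i)[c("A", "B"), 1],
    numeric(2)))
  se_var <- 0.5 * 2 * sqrt(2 / 1199)    # var of sample variance, normal data
  expect_lt(abs(var(reps[, 1]) - 1), 3 * se_var)
  expect_lt(abs(cov(reps[, 1], reps[, 2]) - 0.5), 3 * 0.04)

  # identical seed, identical realisation
  expect_identical(simulate_bm(tr2, c(0, 0, 0), diag(3), seed = 11),
                   simulate_bm(tr2, c(0, 0, 0), diag(3), seed = 11))
})

test_that("simulation then reconstruction centres on the true root", {
  tr <- ape::rphylo(40, 1, 0)
  roots <- vapply(1:200, function(i) {
    S <- simulate_bm(tr, c(0.3, 0, 0), diag(3) * 0.05, seed = i)
    reconstruct_ancestral_states(tr, S[seq_len(40), ])$root[1]
  }, numeric(1))
  expect_lt(abs(mean(roots) - 0.3), 3 * sd(roots) / sqrt(200))
})
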