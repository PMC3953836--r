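# Independent oracles and small fixture builders shared across tests.
# Each oracle deliberately uses a different algorithm than the package code
# it checks.

grid401 <- seq(300, 700, 1)

toy_vs <- function(centers = c(350, 450, 550, 650), width = 40) {
  make_toy_visual_system(synthetic_config(receptor_centers = centers,
                                          receptor_widths = width))
}

flat_spec <- function(value = 1, label = "flat")
  refl_spectrum(grid401, rep(value, length(grid401)), label)

# --- convex hull oracle: brute-force facet enumeration ----------------------
# a plane through three points is a hull facet iff every point lies on one
# side; membership = inside all such planes. O(n^3) but independent of the
# incremental hull construction.
brute_hull_planes <- function(P, eps = 1e-9) {
  n <- nrow(P)
  ctr <- colMeans(P)
  Ns <- NULL; ds <- NULL
  for (tri in utils::combn(n, 3, simplify = FALSE)) {
    a <- P[tri[1], ]; b <- P[tri[2], ]; cc <- P[tri[3], ]
    nr <- c((b - a)[2] * (cc - a)[3] - (b - a)[3] * (cc - a)[2],
            (b - a)[3] * (cc - a)[1] - (b - a)[1] * (cc - a)[3],
            (b - a)[1] * (cc - a)[2] - (b - a)[2] * (cc - a)[1])
    nn <- sqrt(sum(nr^2))
    if (nn < eps) next
    nr <- nr / nn
    s <- P %*% nr - sum(nr * a)
    if (all(s <= eps)) { Ns <- rbind(Ns, nr); ds <- c(ds, sum(nr * a)) }
    else if (all(s >= -eps)) { Ns <- rbind(Ns, -nr); ds <- c(ds, -sum(nr * a)) }
  }
  list(N = Ns, d = ds)
}

brute_in_hull <- function(planes, pts, tol = 1e-9) {
  slack <- pts %*% t(planes$N) - rep(planes$d, each = nrow(pts))
  apply(slack <= tol, 1, all)
}

mc_hull_volume <- function(P, n = 1e5, seed = 1) {
  set.seed(seed)
  lo <- apply(P, 2, min); hi <- apply(P, 2, max)
  pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
               runif(n, lo[3], hi[3]))
  pl <- brute_hull_planes(P)
  box <- prod(hi - lo)
  p <- mean(brute_in_hull(pl, pts))
  list(volume = p * box, se = box * sqrt(p * (1 - p) / n))
}

# --- dense GLS ancestral-state oracle ---------------------------------------
# x_hat_k = mu_hat + c_k' C^{-1} (x - mu_hat 1), shared-path covariances
# assembled explicitly from ancestor lists.
gls_asr_oracle <- function(tr, X) {
  n <- length(tr$tip.label)
  N <- n + tr$Nnode
  C <- ape::vcv(tr)[tr$tip.label, tr$tip.label]
  dep <- ape::node.depth.edgelength(tr)
  anc <- function(k) {
    out <- k
    repeat {
      e <- which(tr$edge[, 2] == k)
      if (!length(e)) break
      k <- tr$edge[e, 1]; out <- c(out, k)
    }
    out
  }
  paths <- lapply(seq_len(N), anc)
  Ci <- solve(C)
  one <- rep(1, n)
  est <- matrix(NA_real_, tr$Nnode, ncol(X))
  rownames(est) <- as.character((n + 1):N)
  for (ax in seq_len(ncol(X))) {
    x <- X[tr$tip.label, ax]
    mu <- drop(one %*% Ci %*% x / (one %*% Ci %*% one))
    for (k in (n + 1):N) {
      ck <- vapply(seq_len(n), function(j)
        max(dep[intersect(paths[[k]], paths[[j]])]), numeric(1))
      est[as.character(k), ax] <- mu + drop(ck %*% Ci %*% (x - mu))
    }
  }
  est
}

# --- ellipsoid membership oracle: eigendecomposition form -------------------
eigen_contains_oracle <- function(region, pts) {
  e <- eigen(region$shape, symmetric = TRUE)
  ctr <- sweep(pts, 2, region$center)
  proj <- ctr %*% e$vectors
  q <- rowSums(sweep(proj^2, 2, e$values, "/"))
  q <= region$radius^2 * (1 + 1e-7)
}

# --- manual branch-entry enumeration ----------------------------------------
manual_count_entries <- function(tr, S, region) {
  cnt <- 0L
  for (e in seq_len(nrow(tr$edge))) {
    pin <- eigen_contains_oracle(region, S[tr$edge[e, 1], , drop = FALSE])
    cin <- eigen_contains_oracle(region, S[tr$edge[e, 2], , drop = FALSE])
    if (!pin && cin) cnt <- cnt + 1L
  }
  cnt
}

# small ellipsoid well away from the data, for zero-count cases
far_region <- function(center = c(50, 50, 50), r = 0.5) {
  structure(list(center = center, shape = diag(3) * r^2, radius = 1,
                 degenerate = FALSE),
            class = "ellipsoid_region")
}
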