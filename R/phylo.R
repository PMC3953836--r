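# Tree I/O, ancestral state reconstruction under Brownian motion, rate-matrix
# estimation from standardized contrasts, and multivariate BM simulation.
# Polytomies are handled natively throughout: the ASR message passing works on
# any rooted tree, and contrasts at a k-furcation are formed by sequential
# pairing (equivalent to resolving with zero-length internal edges).

#' Read a dated phylogeny (Newick or Nexus)
#'
#' Format is auto-detected (`#NEXUS` header). Branch lengths are required;
#' duplicate tip labels are rejected; polytomies are preserved. Zero-length
#' branches are perturbed to `1e-8 x tree depth` with a warning so the BM
#' machinery stays defined.
#'
#' @param path file path
#' @return an [ape::read.tree()]-style `phylo` object
#' @export
read_tree <- function(path) {
  txt <- readLines(path, warn = FALSE)
  phy <- if (any(grepl("^\\s*#NEXUS", txt, ignore.case = TRUE)))
    ape::read.nexus(path)
  else
    ape::read.tree(path)
  if (inherits(phy, "multiPhylo")) phy <- phy[[1]]
  if (is.null(phy)) stop("could not parse tree file: ", path)
  sanitize_tree(phy)
}

sanitize_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a phylo object")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (anyNA(phy$edge.length)) stop("tree has missing branch lengths")
  if (any(phy$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(phy$tip.label)) stop("duplicate tip labels in tree")
  if (any(phy$edge.length == 0)) {
    depth <- max(ape::node.depth.edgelength(phy))
    if (depth <= 0) stop("tree has zero total depth")
    phy$edge.length[phy$edge.length == 0] <- 1e-8 * depth
    warning("zero-length branches perturbed to 1e-8 x tree depth")
  }
  phy
}

# validate and order a tip trait matrix against the tree
check_tip_states <- function(phy, tips) {
  X <- as.matrix(tips)
  storage.mode(X) <- "double"
  if (is.null(rownames(X))) {
    if (nrow(X) != length(phy$tip.label))
      stop("tip state matrix has no rownames and wrong number of rows")
    rownames(X) <- phy$tip.label
  }
  missing <- setdiff(phy$tip.label, rownames(X))
  if (length(missing))
    stop("tips without states: ", paste(missing, collapse = ", "))
  X <- X[phy$tip.label, , drop = FALSE]
  if (anyNA(X)) stop("NA tip states")
  X
}

# Gaussian belief propagation under BM on a rooted tree (any degree).
# Upward pass: message from each non-root node to its parent is the
# precision-weighted mean of its children's messages, with variance
# branch + 1/(sum of child precisions); tips send their observed state with
# variance equal to their branch length.
bm_up_messages <- function(phy, X) {
  n <- length(phy$tip.label)
  N <- n + phy$Nnode
  d <- ncol(X)
  po <- ape::reorder.phylo(phy, "postorder")
  mu <- matrix(NA_real_, N, d)
  sv <- rep(NA_real_, N)
  mu[seq_len(n), ] <- X
  prec <- numeric(N)
  wsum <- matrix(0, N, d)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]; L <- po$edge.length[e]
    if (ch > n) {                       # internal child: children all done
      mu[ch, ] <- wsum[ch, ] / prec[ch]
      sv[ch] <- L + 1 / prec[ch]
    } else {
      sv[ch] <- L
    }
    prec[p] <- prec[p] + 1 / sv[ch]
    wsum[p, ] <- wsum[p, ] + mu[ch, ] / sv[ch]
  }
  root <- n + 1L
  mu[root, ] <- wsum[root, ] / prec[root]
  list(mu = mu, sv = sv, prec = prec, wsum = wsum, n = n, N = N, root = root)
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Reconstructs every internal node's state by per-axis ML under BM
#' (equivalent to generalized least squares with the tree's covariance
#' structure), via an exact two-pass Gaussian message-passing scheme that is
#' linear in tree size and handles polytomies natively. Axes are
#' reconstructed independently.
#'
#' @param tree a `phylo` tree with branch lengths
#' @param tips numeric matrix of tip states (rownames = tip labels)
#' @return list with `tip_states` (input, tree order), `node_states`
#'   (internal nodes, rownames = ape node numbers), and `root` (root state)
#' @export
reconstruct_ancestral_states <- function(tree, tips) {
  phy <- sanitize_tree(tree)
  X <- check_tip_states(phy, tips)
  up <- bm_up_messages(phy, X)
  n <- up$n; N <- up$N; root <- up$root; d <- ncol(X)
  est <- matrix(NA_real_, N, d)
  est[seq_len(n), ] <- X
  est[root, ] <- up$mu[root, ]
  # downward pass: message from the parent side combines the parent's other
  # children and the parent's own parent message
  nu <- matrix(NA_real_, N, d)
  w <- rep(NA_real_, N)
  cw <- ape::reorder.phylo(phy, "cladewise")   # parents precede children
  for (e in seq_len(nrow(cw$edge))) {
    p <- cw$edge[e, 1]; ch <- cw$edge[e, 2]; L <- cw$edge.length[e]
    P_other <- up$prec[p] - 1 / up$sv[ch]
    W_other <- up$wsum[p, ] - up$mu[ch, ] / up$sv[ch]
    if (p != root) {
      P_other <- P_other + 1 / w[p]
      W_other <- W_other + nu[p, ] / w[p]
    }
    if (P_other <= 0) {                 # root with a single child
      w[ch] <- Inf
      nu[ch, ] <- 0
    } else {
      nu[ch, ] <- W_other / P_other
      w[ch] <- L + 1 / P_other
    }
    if (ch > n) {
      Ptot <- up$prec[ch] + 1 / w[ch]
      est[ch, ] <- (up$wsum[ch, ] + nu[ch, ] / w[ch]) / Ptot
    }
  }
  node_states <- est[(n + 1L):N, , drop = FALSE]
  rownames(node_states) <- as.character((n + 1L):N)
  colnames(node_states) <- colnames(X)
  list(tip_states = X, node_states = node_states, root = est[root, ])
}

#' Evolutionary rate matrix from standardized independent contrasts
#'
#' Computes Felsenstein's standardized contrasts per axis (sequential
#' pairing at polytomies) and returns their cross-product matrix divided by
#' the number of contrasts — a positive-semidefinite estimate of the BM
#' variance-covariance matrix in (trait units)^2 per unit branch length.
#'
#' @param tree a `phylo` tree
#' @param tips tip state matrix (rownames = tip labels)
#' @return list with `rate` (d x d matrix) and `contrasts`
#' @export
estimate_rate_matrix <- function(tree, tips) {
  phy <- sanitize_tree(tree)
  X <- check_tip_states(phy, tips)
  if (length(phy$tip.label) < 3L) stop("need >= 3 tips to estimate a rate matrix")
  n <- length(phy$tip.label)
  d <- ncol(X)
  po <- ape::reorder.phylo(phy, "postorder")
  kids <- split(seq_len(nrow(po$edge)), po$edge[, 1])
  mu <- matrix(NA_real_, n + phy$Nnode, d)
  sv <- rep(NA_real_, n + phy$Nnode)
  mu[seq_len(n), ] <- X
  contrasts <- NULL
  # postorder over internal nodes: edge rows grouped by parent appear in
  # postorder of the parent when iterated by last edge index
  ord <- order(vapply(kids, max, numeric(1)))
  for (k in ord) {
    p <- as.integer(names(kids)[k])
    rows <- kids[[k]]
    ch <- po$edge[rows, 2]
    len <- po$edge.length[rows]
    for (i in seq_along(ch))
      if (ch[i] <= n) sv[ch[i]] <- len[i] else sv[ch[i]] <- sv[ch[i]] + len[i]
    acc_mu <- mu[ch[1], ]; acc_s <- sv[ch[1]]
    for (i in seq_along(ch)[-1]) {
      tot <- acc_s + sv[ch[i]]
      if (tot <= 0)
        stop("zero-length branch pair makes contrast undefined at node ", p)
      contrasts <- rbind(contrasts, (acc_mu - mu[ch[i], ]) / sqrt(tot))
      acc_mu <- (acc_mu / acc_s + mu[ch[i], ] / sv[ch[i]]) /
        (1 / acc_s + 1 / sv[ch[i]])
      acc_s <- 1 / (1 / acc_s + 1 / sv[ch[i]])
    }
    mu[p, ] <- acc_mu
    sv[p] <- acc_s                      # parent edge length added when seen
  }
  rate <- crossprod(contrasts) / nrow(contrasts)
  dimnames(rate) <- list(colnames(X), colnames(X))
  list(rate = rate, contrasts = contrasts)
}

# symmetric PSD square root; errors on clearly negative eigenvalues
psd_sqrt <- function(M) {
  M <- as.matrix(M)
  if (max(abs(M - t(M))) > 1e-8 * max(abs(M), 1))
    stop("rate matrix must be symmetric")
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-10 * max(abs(e$values), 1))
    stop("rate matrix is not positive semi-definite")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate multivariate Brownian motion on a tree
#'
#' Each branch adds a multivariate normal displacement with covariance
#' `rate x branch length`. States are returned for all nodes (tips and
#' internal), since null convergence counting needs internal states.
#'
#' @param tree a `phylo` tree
#' @param root_state numeric d-vector, state at the root
#' @param rate d x d symmetric positive-semidefinite rate matrix
#' @param seed integer RNG seed
#' @return matrix of states, rows = ape node numbering (tips 1..n then
#'   internal nodes), columns = trait axes
#' @export
simulate_bm <- function(tree, root_state, rate, seed = 1L) {
  set.seed(seed)
  simulate_bm_stream(sanitize_tree(tree), root_state, psd_sqrt(rate))
}

# draws from the current RNG stream; sq = symmetric sqrt of the rate matrix
simulate_bm_stream <- function(phy, root_state, sq) {
  n <- length(phy$tip.label)
  N <- n + phy$Nnode
  d <- ncol(sq)
  cw <- ape::reorder.phylo(phy, "cladewise")
  Z <- matrix(rnorm(nrow(cw$edge) * d), ncol = d)
  disp <- (Z %*% sq) * sqrt(cw$edge.length)
  S <- matrix(NA_real_, N, d)
  S[n + 1L, ] <- root_state
  for (e in seq_len(nrow(cw$edge)))
    S[cw$edge[e, 2], ] <- S[cw$edge[e, 1], ] + disp[e, ]
  rownames(S) <- c(phy$tip.label, as.character((n + 1L):N))
  S
}

# vectorised multi-replicate BM simulation: replicate r uses seed `seed + r`
# and an RNG stream identical to simulate_bm(tree, root, rate, seed + r).
# Returns an N x (d * nrep) matrix, replicate r in columns (r-1)*d + 1:d.
simulate_bm_multi <- function(phy, root_state, rate, nrep, seed) {
  phy <- sanitize_tree(phy)
  sq <- psd_sqrt(rate)
  d <- ncol(sq)
  cw <- ape::reorder.phylo(phy, "cladewise")
  ne <- nrow(cw$edge)
  n <- length(phy$tip.label)
  N <- n + phy$Nnode
  D <- matrix(NA_real_, ne, d * nrep)
  for (r in seq_len(nrep)) {
    set.seed(seed + r)
    Z <- matrix(rnorm(ne * d), ncol = d)
    D[, (r - 1L) * d + seq_len(d)] <- (Z %*% sq) * sqrt(cw$edge.length)
  }
  S <- matrix(NA_real_, N, d * nrep)
  S[n + 1L, ] <- rep(root_state, nrep)
  for (e in seq_len(ne))
    S[cw$edge[e, 2], ] <- S[cw$edge[e, 1], ] + D[e, ]
  S
}
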