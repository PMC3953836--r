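# The convergence index: number of branches whose parent state lies outside
# an ellipsoidal target region and whose child state lies inside, and its
# significance against a Brownian-motion null simulated on the tree.

# assemble a full (tips + internal) state matrix from inputs
full_states <- function(tree, states) {
  n <- length(tree$tip.label)
  N <- n + tree$Nnode
  if (is.list(states) && !is.null(states$node_states)) {
    S <- rbind(check_tip_states(tree, states$tip_states),
               as.matrix(states$node_states))
  } else {
    S <- as.matrix(states)
  }
  if (nrow(S) != N) stop("need one state per node (tips + internal)")
  if (anyNA(S)) stop("node without a state")
  S
}

#' Count branches entering a target region
#'
#' A branch contributes one entry when its parent (ancestral) endpoint state
#' is outside the region and its child (derived) endpoint state — internal
#' node or tip — is inside. Membership uses endpoint states only; evolution
#' within the region, and subsequent exits, do not contribute. Boundary
#' points count as inside.
#'
#' @param tree a `phylo` tree
#' @param states full node-state matrix (ape node order), or the list
#'   returned by [reconstruct_ancestral_states()]
#' @param region an `ellipsoid_region`
#' @return integer entry count
#' @export
count_entries <- function(tree, states, region) {
  S <- full_states(tree, states)
  inside <- contains(region, S)
  sum(!inside[tree$edge[, 1]] & inside[tree$edge[, 2]])
}

#' Convergence significance test against a Brownian-motion null
#'
#' The observed index is [count_entries()] on ancestral states reconstructed
#' from the tip data. The null distribution is obtained by simulating BM on
#' the same tree (rate matrix estimated from the observed tips via
#' standardized contrasts, root at the observed root reconstruction) and
#' scoring each replicate against the same fixed region. The p-value uses
#' the add-one estimator `(1 + #(null >= observed)) / (n_sim + 1)`.
#'
#' @param tree a `phylo` tree
#' @param tips tip state matrix (rownames = tip labels)
#' @param region an `ellipsoid_region` target, fixed from the observed data
#' @param n_sim number of null simulations (>= 1); default 999
#' @param seed integer seed; replicate r uses subseed `seed + r`
#' @param rate optional rate matrix (default: estimated from `tips`)
#' @param root_state optional root state (default: observed reconstruction)
#' @param reconstruct_null if `TRUE`, ancestral states of each null
#'   replicate are re-reconstructed from its simulated tips before scoring;
#'   default uses the simulated internal states directly
#' @param region_label identifier carried into the result
#' @return object of class `convergence_result`
#' @export
convergence_test <- function(tree, tips, region, n_sim = 999L, seed = 1L,
                             rate = NULL, root_state = NULL,
                             reconstruct_null = FALSE,
                             region_label = "target") {
  if (n_sim < 1L) stop("n_sim must be >= 1")
  phy <- sanitize_tree(tree)
  X <- check_tip_states(phy, tips)
  asr <- reconstruct_ancestral_states(phy, X)
  observed <- count_entries(phy, asr, region)
  if (is.null(rate)) rate <- estimate_rate_matrix(phy, X)$rate
  if (is.null(root_state)) root_state <- asr$root
  d <- ncol(X)
  n <- length(phy$tip.label)
  S <- simulate_bm_multi(phy, root_state, rate, n_sim, seed)
  null_counts <- integer(n_sim)
  for (r in seq_len(n_sim)) {
    Sr <- S[, (r - 1L) * d + seq_len(d), drop = FALSE]
    if (reconstruct_null) {
      tips_r <- Sr[seq_len(n), , drop = FALSE]
      rownames(tips_r) <- phy$tip.label
      asr_r <- reconstruct_ancestral_states(phy, tips_r)
      Sr <- rbind(asr_r$tip_states, asr_r$node_states)
    }
    null_counts[r] <- count_entries(phy, Sr, region)
  }
  p <- (1 + sum(null_counts >= observed)) / (n_sim + 1)
  structure(list(observed = observed,
                 null_counts = null_counts,
                 null_mean = mean(null_counts),
                 null_sd = sd(null_counts),
                 null_max = max(null_counts),
                 p = p, n_sim = as.integer(n_sim), seed = as.integer(seed),
                 region_label = region_label,
                 reconstruct_null = reconstruct_null),
            class = "convergence_result")
}

#' @export
print.convergence_result <- function(x, ...) {
  cat(sprintf(
    "<convergence_result> %s: observed %d, null %.2f +/- %.2f (max %d), p = %.3f [%d sims]\n",
    x$region_label, x$observed, x$null_mean, x$null_sd, x$null_max,
    x$p, x$n_sim))
  invisible(x)
}

#' Holm sequential Bonferroni correction
#'
#' Step-down multiple-testing correction: with p-values sorted ascending,
#' `adjusted_i = max_{j <= i} (m - j + 1) p_(j)`, capped at 1; a test is
#' significant when its adjusted p-value is below `alpha`.
#'
#' @param p_values numeric vector of p-values in (0, 1]
#' @param alpha significance level (default 0.05)
#' @return data.frame with columns `p`, `adjusted_p`, `significant`, in the
#'   input order; empty input yields an empty data.frame
#' @export
holm_correction <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L)
    return(data.frame(p = numeric(0), adjusted_p = numeric(0),
                      significant = logical(0)))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  adj_sorted <- pmin(cummax((m - seq_len(m) + 1) * p_values[o]), 1)
  adj <- numeric(m)
  adj[o] <- adj_sorted
  data.frame(p = p_values, adjusted_p = adj, significant = adj < alpha)
}
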