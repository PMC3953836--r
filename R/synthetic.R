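# Synthetic data generation: toy visual systems, spectra batches, and
# simulated phylogeny + trait datasets with optionally planted convergence.
# Every generator is a pure function of its config seed.

#' Synthetic-data configuration
#'
#' @param seed integer master seed
#' @param n_species number of species (tips / spectra)
#' @param receptor_centers four ascending peak wavelengths (nm) in [300, 700]
#' @param receptor_widths Gaussian sd(s) in nm, recycled to four
#' @param tree_birth_rate Yule speciation rate (events per unit time)
#' @param bm_rate 3 x 3 BM rate matrix; default isotropic 0.02 per unit
#'   time, which on a unit-depth tree spreads loci over a realistic fraction
#'   of the tetrahedron
#' @param convergence_pull fraction in [0, 1] blending planted lineages'
#'   terminal displacements toward `target`
#' @param n_planted number of planted convergent tip lineages
#' @param target 3-D attractor point; default 60% of the way toward the
#'   long-wavelength vertex
#' @param noise_sd additive noise sd for generated reflectance spectra
#' @return object of class `synthetic_config`
#' @export
synthetic_config <- function(seed = 1L, n_species = 100L,
                             receptor_centers = c(350, 450, 550, 650),
                             receptor_widths = 40,
                             tree_birth_rate = 1,
                             bm_rate = diag(3) * 0.02,
                             convergence_pull = 0,
                             n_planted = 0L,
                             target = 0.6 * tetra_vertices()[4, ],
                             noise_sd = 0.005) {
  if (length(receptor_centers) != 4L || any(diff(receptor_centers) <= 0))
    stop("receptor_centers must be four ascending wavelengths")
  if (any(receptor_centers < GRID_MIN | receptor_centers > GRID_MAX))
    stop("receptor_centers must lie in [300, 700] nm")
  receptor_widths <- rep_len(receptor_widths, 4L)
  if (any(receptor_widths <= 0)) stop("receptor_widths must be positive")
  if (convergence_pull < 0 || convergence_pull > 1)
    stop("convergence_pull must be in [0, 1]")
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 receptor_centers = receptor_centers,
                 receptor_widths = receptor_widths,
                 tree_birth_rate = tree_birth_rate, bm_rate = bm_rate,
                 convergence_pull = convergence_pull,
                 n_planted = as.integer(n_planted),
                 target = as.numeric(target), noise_sd = noise_sd),
            class = "synthetic_config")
}

#' Toy Gaussian visual system
#'
#' Four Gaussian sensitivity curves at the configured centers/widths on the
#' common grid, with the standard tetrahedron geometry. Deterministic given
#' the config.
#'
#' @param cfg a [synthetic_config()]
#' @return a [visual_system]
#' @export
make_toy_visual_system <- function(cfg) {
  grid <- spectrum_grid()
  sens <- lapply(1:4, function(i)
    refl_spectrum(grid,
                  exp(-((grid - cfg$receptor_centers[i])^2) /
                        (2 * cfg$receptor_widths[i]^2)),
                  label = paste0("r", i)))
  visual_system(sens, name = "toy")
}

logistic_step <- function(grid, at, width = 15) 1 / (1 + exp(-(grid - at) / width))

#' Synthetic reflectance spectra batch
#'
#' Generates a named list that always contains a flat achromatic spectrum
#' (`"flat"`), a long-wavelength logistic step (`"red_like"`), a
#' mid-wavelength-peaked leaf background (`"leaf_background"`), a flat
#' illuminant (`"illuminant"`), and `n_species` random mixtures of logistic
#' steps and Gaussian bumps with seeded noise.
#'
#' @param cfg a [synthetic_config()]
#' @return named list of [refl_spectrum]
#' @export
make_spectra <- function(cfg) {
  set.seed(cfg$seed)
  grid <- spectrum_grid()
  out <- list(
    flat = refl_spectrum(grid, rep(0.3, length(grid)), "flat"),
    red_like = refl_spectrum(grid, 0.05 + 0.85 * logistic_step(grid, 610, 12),
                             "red_like"),
    leaf_background = refl_spectrum(
      grid, 0.05 + 0.12 * exp(-((grid - 550)^2) / (2 * 35^2)), "leaf_background"),
    illuminant = refl_spectrum(grid, rep(1, length(grid)), "illuminant"))
  for (i in seq_len(cfg$n_species)) {
    base <- 0.05 +
      runif(1, 0, 0.6) * logistic_step(grid, runif(1, 380, 660), runif(1, 8, 25)) +
      runif(1, 0, 0.4) * exp(-((grid - runif(1, 320, 680))^2) / (2 * runif(1, 15, 60)^2))
    y <- pmin(pmax(base + rnorm(length(grid), 0, cfg$noise_sd), 0), 1)
    out[[sprintf("sp%03d", i)]] <- refl_spectrum(grid, y, sprintf("sp%03d", i))
  }
  out
}

#' Simulated phylogeny + trait dataset with optional planted convergence
#'
#' Grows a Yule (pure-birth) tree with `n_species` tips, rescales it to unit
#' depth, and evolves 3-D traits by BM from the origin. When
#' `convergence_pull > 0`, `n_planted` designated tip lineages have their
#' terminal-branch displacement blended toward `target` by the pull
#' fraction, planting detectable entries. The target region returned is the
#' minimum ellipsoid around the designated tips' states (mirroring how
#' empirical target regions are built from the taxa of interest).
#'
#' @param cfg a [synthetic_config()]
#' @return list with `tree`, `tips` (tip-state matrix), `states` (all true
#'   node states), `region`, `planted` (tip labels), `truth` (entry count of
#'   the true states into `region`)
#' @export
simulate_dataset <- function(cfg) {
  if (cfg$n_planted > cfg$n_species)
    stop("planted lineage set larger than tip count")
  set.seed(cfg$seed)
  phy <- ape::rphylo(cfg$n_species, birth = cfg$tree_birth_rate, death = 0)
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length / depth
  phy <- sanitize_tree(phy)
  n <- cfg$n_species
  planted <- if (cfg$n_planted > 0L)
    sort(sample.int(n, cfg$n_planted)) else integer(0)

  sq <- psd_sqrt(cfg$bm_rate)
  cw <- ape::reorder.phylo(phy, "cladewise")
  Z <- matrix(rnorm(nrow(cw$edge) * 3), ncol = 3)
  disp <- (Z %*% sq) * sqrt(cw$edge.length)
  S <- matrix(NA_real_, n + phy$Nnode, 3)
  S[n + 1L, ] <- c(0, 0, 0)
  terminal <- cw$edge[, 2] %in% planted
  for (e in seq_len(nrow(cw$edge))) {
    p <- cw$edge[e, 1]; ch <- cw$edge[e, 2]
    d_e <- disp[e, ]
    if (terminal[e] && cfg$convergence_pull > 0)
      d_e <- (1 - cfg$convergence_pull) * d_e +
        cfg$convergence_pull * (cfg$target - S[p, ])
    S[ch, ] <- S[p, ] + d_e
  }
  rownames(S) <- c(phy$tip.label, as.character((n + 1L):(n + phy$Nnode)))
  colnames(S) <- c("x", "y", "z")
  tips <- S[seq_len(n), , drop = FALSE]

  region_pts <- if (length(planted) >= 4L) tips[planted, , drop = FALSE]
  else tips[seq_len(min(n, 8L)), , drop = FALSE]
  region <- min_ellipsoid(region_pts, on_degenerate = "flag")
  truth <- count_entries(phy, S, region)
  list(tree = phy, tips = tips, states = S, region = region,
       planted = phy$tip.label[planted], truth = truth)
}
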