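#' Tetrahedron vertex convention
#'
#' The colour space is a regular tetrahedron with unit edge length and its
#' centroid at the origin. Row i is the vertex of receptor i, ordered short
#' to long wavelength; the longest-wavelength receptor sits on the +x side,
#' so the long-wavelength ("red") arm of the space extends towards +x.
#'
#' @return 4 x 3 numeric matrix of vertex coordinates
#' @export
tetra_vertices <- function() {
  s <- 1 / (2 * sqrt(2))
  v <- s * rbind(c(-1, -1,  1),
                 c(-1,  1, -1),
                 c( 1, -1, -1),
                 c( 1,  1,  1))
  dimnames(v) <- list(paste0("r", 1:4), c("x", "y", "z"))
  v
}

#' Construct a visual system
#'
#' Bundles four receptor sensitivity curves (ordered short to long
#' wavelength) with the tetrahedron vertex geometry.
#'
#' @param sensitivities list of four [refl_spectrum] curves on the common
#'   grid, all values >= 0, peak wavelengths strictly increasing
#' @param name label, e.g. `"VS"`, `"UVS"` or `"custom"`
#' @param vertices 4 x 3 vertex matrix; default [tetra_vertices()]
#' @return object of class `visual_system`
#' @export
visual_system <- function(sensitivities, name = "custom",
                          vertices = tetra_vertices()) {
  if (length(sensitivities) != 4L) stop("exactly four sensitivity curves required")
  grid <- spectrum_grid()
  sens <- lapply(sensitivities, resample_spectrum, grid = grid)
  peaks <- vapply(sens, function(s) s$wl[which.max(s$refl)], numeric(1))
  for (s in sens) {
    if (any(s$refl < 0)) stop("sensitivity curves must be non-negative")
    if (max(s$refl) <= 0) stop("sensitivity curve is identically zero")
  }
  if (any(diff(peaks) <= 0))
    stop("sensitivity peaks must be ordered short to long wavelength")
  vertices <- as.matrix(vertices)
  if (!all(dim(vertices) == c(4L, 3L))) stop("vertices must be 4 x 3")
  structure(list(name = name, sensitivities = sens, vertices = vertices,
                 peaks = peaks),
            class = "visual_system")
}

#' @export
print.visual_system <- function(x, ...) {
  cat(sprintf("<visual_system> %s: peaks at %s nm\n", x$name,
              paste(x$peaks, collapse = ", ")))
  invisible(x)
}

#' Load a visual system from a sensitivity CSV
#'
#' The file uses the wide spectra layout: wavelength column plus exactly
#' four sensitivity columns ordered short to long wavelength.
#'
#' @param sens_path CSV path
#' @param name system label
#' @return a [visual_system]
#' @export
load_visual_system <- function(sens_path, name = "custom") {
  curves <- read_spectra(sens_path, unit = "fraction")
  if (length(curves) != 4L)
    stop(sprintf("sensitivity file must have 4 receptor columns, found %d",
                 length(curves)))
  visual_system(curves, name = name)
}

#' Packaged visual system (synthetic stand-in curves)
#'
#' Loads one of the shipped receptor-sensitivity tables. These are synthetic
#' stand-ins built from a visual-pigment template at average avian
#' lambda-max values, not measured curves; see the package vignette.
#'
#' @param name `"VS"` (violet-sensitive) or `"UVS"` (ultraviolet-sensitive)
#' @return a [visual_system]
#' @export
packaged_visual_system <- function(name = c("VS", "UVS")) {
  name <- match.arg(name)
  f <- system.file("extdata",
                   sprintf("%s_sensitivity_synthetic.csv", tolower(name)),
                   package = "tetraconv", mustWork = TRUE)
  load_visual_system(f, name = name)
}

#' Packaged illuminant / background spectra (synthetic stand-ins)
#'
#' @param which `"illuminant"` for the 6500 K standard-daylight-like table,
#'   `"background"` for the leaf-green adaptation background
#' @return a [refl_spectrum]
#' @export
packaged_spectrum <- function(which = c("illuminant", "background")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   if (which == "illuminant") "illuminant_6500k_synthetic.csv"
                   else "background_leaf_synthetic.csv",
                   package = "tetraconv", mustWork = TRUE)
  read_spectra(f)[[1]]
}

#' Quantum catches with von Kries chromatic adaptation
#'
#' For each receptor i, the raw catch is the integral of
#' R_i(lambda) S(lambda) I(lambda); von Kries adaptation divides it by the
#' same integral with the adapting background S_b in place of S. The
#' relative catches are normalised to sum to one.
#'
#' @param s stimulus [refl_spectrum]
#' @param vs a [visual_system]
#' @param illuminant incident-light spectrum (e.g. 6500 K daylight)
#' @param background adaptation background spectrum (e.g. leaf green)
#' @return object of class `quantum_catch` with fields `q` (adapted catches
#'   Q_i) and `relative` (normalised to unit sum)
#' @export
quantum_catches <- function(s, vs, illuminant, background) {
  grid <- spectrum_grid()
  s <- resample_spectrum(s, grid)
  illuminant <- resample_spectrum(illuminant, grid)
  background <- resample_spectrum(background, grid)
  q <- numeric(4)
  for (i in 1:4) {
    R <- vs$sensitivities[[i]]$refl
    den <- trapz(grid, R * background$refl * illuminant$refl)
    if (den <= 0)
      stop(sprintf("zero background catch for receptor %d: adaptation undefined", i))
    q[i] <- trapz(grid, R * s$refl * illuminant$refl) / den
  }
  if (any(q < 0)) stop("negative quantum catch: check input spectra")
  if (sum(q) == 0)
    stop("dark stimulus: all quantum catches are zero, relative catches undefined")
  structure(list(q = q, relative = q / sum(q)), class = "quantum_catch")
}

#' Map relative quantum catches to a colour locus
#'
#' The locus is the barycentric combination of the tetrahedron vertices
#' weighted by the relative catches; each vertex represents maximal
#' stimulation of a single receptor, the centroid (origin) the achromatic
#' point.
#'
#' @param q a `quantum_catch`
#' @param vs a [visual_system]
#' @param species identifier
#' @param visitation optional class: `"insect"`, `"bird"` or `"both"`
#' @param subgroup optional: `"red_arm"` or `"non_red_arm"`
#' @return object of class `colour_locus` with field `xyz`
#' @export
to_locus <- function(q, vs, species = "sp", visitation = NA_character_,
                     subgroup = NA_character_) {
  rel <- q$relative
  if (abs(sum(rel) - 1) > 1e-12 || any(rel < 0))
    stop("relative catches must be non-negative and sum to 1")
  xyz <- drop(rel %*% vs$vertices)
  names(xyz) <- c("x", "y", "z")
  structure(list(species = species, xyz = xyz, visitation = visitation,
                 subgroup = subgroup),
            class = "colour_locus")
}

#' Total tetrahedron volume for a visual system
#'
#' Baseline for occupancy percentages; computed from the vertex geometry,
#' never hard-coded.
#'
#' @param vs a [visual_system]
#' @return scalar volume in cubic colour-space units
#' @export
tetra_volume <- function(vs) {
  v <- vs$vertices
  abs(det(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ]))) / 6
}
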