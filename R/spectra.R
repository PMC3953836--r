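#' Reflectance spectrum object
#'
#' A wavelength-indexed reflectance curve for one surface (flower, leaf
#' background, illuminant table). Reflectance is stored as a unitless
#' fraction; wavelengths are in nm, strictly increasing, within 300--700 nm.
#'
#' @param wl numeric, wavelengths (nm), strictly increasing
#' @param refl numeric, reflectance values (fraction), same length as `wl`
#' @param label identifier for the surface/species
#' @return object of class `refl_spectrum`
#' @export
refl_spectrum <- function(wl, refl, label = "spectrum") {
  wl <- as.numeric(wl)
  refl <- as.numeric(refl)
  if (length(wl) != length(refl)) stop("wavelength and reflectance lengths differ")
  if (length(wl) < 2L) stop("a spectrum needs at least 2 points")
  if (any(!is.finite(wl)) || any(!is.finite(refl))) stop("non-finite values in spectrum")
  if (any(diff(wl) <= 0)) stop("wavelengths must be strictly increasing")
  if (wl[1] < GRID_MIN || wl[length(wl)] > GRID_MAX)
    stop("wavelengths must lie within [300, 700] nm (trim on read)")
  structure(list(wl = wl, refl = refl, label = as.character(label)),
            class = "refl_spectrum")
}

#' @export
print.refl_spectrum <- function(x, ...) {
  cat(sprintf("<refl_spectrum> %s: %d points, %g-%g nm, range [%.4g, %.4g]\n",
              x$label, length(x$wl), min(x$wl), max(x$wl),
              min(x$refl), max(x$refl)))
  invisible(x)
}

#' Read reflectance spectra from a wide CSV
#'
#' Expects the layout `wavelength_nm, <label1>, <label2>, ...`: first column
#' wavelength in nm, one column per measurement. Wavelengths outside
#' 300--700 nm are trimmed; percent input is divided by 100.
#'
#' @param path CSV file path
#' @param unit `"fraction"` (default) or `"percent"`
#' @return list of [refl_spectrum] objects, one per measurement column
#' @export
read_spectra <- function(path, unit = c("fraction", "percent")) {
  unit <- match.arg(unit)
  df <- read.csv(path, check.names = FALSE, comment.char = "#")
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("spectra file must have a wavelength column and >= 1 measurement column")
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("non-numeric cells in spectra file")
  wl <- df[[1]]
  if (any(diff(wl) <= 0)) stop("wavelengths must be strictly increasing")
  keep <- wl >= GRID_MIN & wl <= GRID_MAX
  if (sum(keep) < 2L) stop("no wavelengths within [300, 700] nm")
  div <- if (unit == "percent") 100 else 1
  lapply(names(df)[-1], function(lab)
    refl_spectrum(wl[keep], df[[lab]][keep] / div, label = lab))
}

#' Write spectra to a wide CSV
#'
#' Inverse of [read_spectra()]; all spectra must share one grid.
#'
#' @param spectra list of [refl_spectrum] on a common grid
#' @param path output CSV path
#' @export
write_spectra <- function(spectra, path) {
  wl <- spectra[[1]]$wl
  for (s in spectra)
    if (!isTRUE(all.equal(s$wl, wl))) stop("spectra are not on a common grid")
  df <- data.frame(wavelength_nm = wl)
  for (s in spectra) df[[s$label]] <- s$refl
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Resample a spectrum onto a wavelength grid
#'
#' Linear interpolation; values beyond the measured range are held constant
#' at the nearest endpoint.
#'
#' @param s a [refl_spectrum]
#' @param grid target wavelengths (default the common 1-nm grid)
#' @return a [refl_spectrum] on `grid`
#' @export
resample_spectrum <- function(s, grid = spectrum_grid()) {
  if (isTRUE(all.equal(s$wl, grid))) return(s)
  y <- approx(s$wl, s$refl, xout = grid, rule = 2)$y
  refl_spectrum(grid, y, label = s$label)
}

#' Average replicate spectra
#'
#' Pointwise arithmetic mean of two or more spectra on a common grid
#' (resample first if grids differ). The label of the first replicate is
#' inherited.
#'
#' @param spectra list of [refl_spectrum] on one common grid
#' @return a single averaged [refl_spectrum]
#' @export
average_replicates <- function(spectra) {
  if (length(spectra) < 2L) stop("need >= 2 spectra to average")
  wl <- spectra[[1]]$wl
  for (s in spectra)
    if (!isTRUE(all.equal(s$wl, wl)))
      stop("spectra are on mismatched grids; resample_spectrum() first")
  m <- rowMeans(vapply(spectra, `[[`, numeric(length(wl)), "refl"))
  refl_spectrum(wl, m, label = spectra[[1]]$label)
}

#' Smooth, de-negative and resample a spectrum
#'
#' Local polynomial regression (degree 2) with fractional span smooths the
#' curve; negative values (spectrophotometer electrical noise) are then
#' removed either by clipping to zero (default) or by adding a constant
#' offset; finally the spectrum is resampled to the fixed common grid.
#'
#' @param s a [refl_spectrum]
#' @param span loess span in (0, 1]; default 0.25
#' @param step resampling step in nm; default 1
#' @param negatives `"clip"` (set negatives to 0) or `"offset"` (shift the
#'   whole curve up by `-min` when the minimum is negative)
#' @return processed [refl_spectrum] on the common grid
#' @export
process_spectrum <- function(s, span = 0.25, step = GRID_STEP,
                             negatives = c("clip", "offset")) {
  negatives <- match.arg(negatives)
  if (!is.numeric(span) || span <= 0 || span > 1)
    stop("span must be in (0, 1]")
  fit <- loess(refl ~ wl, data = data.frame(wl = s$wl, refl = s$refl),
               span = span, degree = 2,
               control = loess.control(surface = "direct"))
  y <- predict(fit, newdata = data.frame(wl = s$wl))
  if (negatives == "clip") {
    y <- pmax(y, 0)
  } else if (min(y) < 0) {
    y <- y - min(y)
  }
  resample_spectrum(refl_spectrum(s$wl, y, label = s$label),
                    grid = spectrum_grid(step))
}
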