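# Build synthetic stand-in spectra tables shipped under inst/extdata.
# Receptor curves: Govardovskii et al. (2000) A1 visual-pigment template
# (alpha + beta band) at average avian lambda_max values; illuminant:
# Planck 6500 K normalized at 560 nm; background: parametric leaf-green.
grid <- 300:700

govardovskii <- function(lmax, wl) {
  x <- lmax / wl
  a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lmax
  b <- -40.5 + 0.195 * lmax
  beta <- 0.26 * exp(-((wl - lmb) / b)^2)
  y <- alpha + beta
  y / max(y)
}

write_wide <- function(path, cols) {
  df <- data.frame(wavelength_nm = grid)
  for (nm in names(cols)) df[[nm]] <- round(cols[[nm]], 6)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

vs_lmax  <- c(416, 478, 542, 607)   # average violet-sensitive set
uvs_lmax <- c(372, 456, 544, 609)   # average ultraviolet-sensitive set
write_wide("inst/extdata/vs_sensitivity_synthetic.csv",
           setNames(lapply(vs_lmax, govardovskii, wl = grid),
                    c("v", "s", "m", "l")))
write_wide("inst/extdata/uvs_sensitivity_synthetic.csv",
           setNames(lapply(uvs_lmax, govardovskii, wl = grid),
                    c("u", "s", "m", "l")))

planck <- function(wl, T = 6500) {
  l <- wl * 1e-9
  b <- l^-5 / (exp(1.4388e-2 / (l * T)) - 1)
  b / b[grid == 560]
}
write_wide("inst/extdata/illuminant_6500k_synthetic.csv",
           list(illuminant_6500k = planck(grid)))

leaf <- 0.05 + 0.12 * exp(-((grid - 550)^2) / (2 * 35^2)) +
  0.28 / (1 + exp(-(grid - 710) / 12))
write_wide("inst/extdata/background_leaf_synthetic.csv",
           list(leaf_green = leaf))
cat("done\n")
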