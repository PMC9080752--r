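# Photoreceptor spectral sensitivity and quantum catch.
#
# Sensitivities are built from the Govardovskii et al. (2000) A1
# visual-pigment template (alpha plus beta band), peak-normalised. The
# quantum catch of a stimulus is the wavelength integral of reflectance x
# illuminant x sensitivity; catches are reported relative to an ideal 100%
# reflector under the same illuminant, so illuminant scaling cancels.

#' Construct a spectrum
#'
#' @param wavelength_nm Ascending wavelength grid in nm.
#' @param value Nonnegative values (reflectance or irradiance).
#' @return Object of class `spectrum`.
#' @export
spectrum <- function(wavelength_nm, value) {
  if (length(wavelength_nm) != length(value))
    stop("wavelength and value must have equal length")
  if (is.unsorted(wavelength_nm, strictly = TRUE))
    stop("wavelength grid must be strictly ascending")
  if (any(value < 0)) stop("spectral values must be nonnegative")
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 value = as.numeric(value)), class = "spectrum")
}

#' Read a two-column spectrum CSV (wavelength_nm, value)
#'
#' @param path CSV file.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path) {
  d <- read.csv(path)
  spectrum(d[[1]], d[[2]])
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %g-%g nm, values %g-%g\n",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), min(x$value), max(x$value)))
  invisible(x)
}

#' @exportS3Method base::plot
plot.spectrum <- function(x, ...) {
  plot(x$wavelength_nm, x$value, type = "l",
       xlab = "wavelength (nm)", ylab = "value", ...)
  invisible(x)
}

resample_spectrum <- function(s, grid) {
  inside <- grid >= min(s$wavelength_nm) & grid <= max(s$wavelength_nm)
  v <- rep(0, length(grid))
  if (!any(inside)) stop("wavelength supports do not overlap")
  v[inside] <- approx(s$wavelength_nm, s$value, xout = grid[inside])$y
  v
}

govardovskii_a1 <- function(lambda, lambda_max) {
  # alpha band
  x <- lambda_max / lambda
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  # beta band
  lmb <- 189 + 0.315 * lambda_max
  b <- -40.5 + 0.195 * lambda_max
  beta <- 0.26 * exp(-((lambda - lmb) / b)^2)
  alpha + beta
}

#' A1 visual-pigment template sensitivity
#'
#' Evaluates the A1 (vitamin A1 chromophore) pigment absorbance template of
#' Govardovskii and colleagues -- alpha band plus beta band -- on a
#' wavelength grid and normalises it to peak 1 at the grid point nearest
#' the requested lambda-max. For lambda-max below about 390 nm the beta
#' band can pull the combined curve's maximum a nanometre short of the
#' alpha-band peak; over the range of typical single/double cone pigments
#' (about 400--570 nm) the maximum sits at lambda-max.
#'
#' @param lambda_max_nm Peak absorbance in nm (350--600).
#' @param grid Wavelength grid in nm (default 300--750 at 1 nm).
#' @param label Receptor label.
#' @return Object of class `receptor_sensitivity`: a [spectrum()] plus
#'   `lambda_max_nm` and `label`.
#' @export
pigment_template <- function(lambda_max_nm, grid = 300:750,
                             label = sprintf("pigment_%g", lambda_max_nm)) {
  if (lambda_max_nm < 350 || lambda_max_nm > 600)
    stop("'lambda_max_nm' must lie in 350..600 nm")
  if (min(grid) > 300 || max(grid) < 750)
    stop("grid must cover 300..750 nm")
  v <- govardovskii_a1(as.numeric(grid), lambda_max_nm)
  peak_idx <- which.min(abs(grid - lambda_max_nm))
  v <- v / v[peak_idx]
  structure(list(wavelength_nm = as.numeric(grid), value = v,
                 lambda_max_nm = lambda_max_nm, label = label),
            class = c("receptor_sensitivity", "spectrum"))
}

#' Quantum catch of a stimulus
#'
#' Integrates reflectance x illuminant x receptor sensitivity over
#' wavelength (trapezoidal rule on a common 1 nm grid) and normalises the
#' catch to that of an ideal unit reflector under the same illuminant, so
#' `normalised_catch` is a percentage of the ideal-white catch.
#'
#' @param reflectance [spectrum()] of stimulus reflectance.
#' @param illuminant [spectrum()] of the illuminant.
#' @param receptor A [pigment_template()] or equivalent sensitivity.
#' @param grid Integration grid (default 300--750 nm at 1 nm).
#' @return List with `receptor`, `catch`, `normalised_catch`.
#' @export
quantum_catch <- function(reflectance, illuminant, receptor,
                          grid = 300:750) {
  grid <- as.numeric(grid)
  r <- resample_spectrum(reflectance, grid)
  i <- resample_spectrum(illuminant, grid)
  s <- resample_spectrum(receptor, grid)
  if (all(i * s == 0)) stop("wavelength supports do not overlap")
  q <- pracma::trapz(grid, r * i * s)
  q_white <- pracma::trapz(grid, i * s)
  list(receptor = if (!is.null(receptor$label)) receptor$label else "receptor",
       catch = q, normalised_catch = 100 * q / q_white)
}

#' Double-cone luminance output
#'
#' The luminance channel is modelled as the arithmetic mean of the
#' normalised quantum catches of the two double-cone members.
#'
#' @param reflectance,illuminant Spectra.
#' @param members List of exactly two receptor sensitivities.
#' @param grid Integration grid.
#' @return Mean normalised catch (percent of ideal white).
#' @export
double_cone_output <- function(reflectance, illuminant, members,
                               grid = 300:750) {
  if (length(members) != 2) stop("exactly two double-cone members required")
  catches <- vapply(members, function(m)
    quantum_catch(reflectance, illuminant, m, grid)$normalised_catch,
    numeric(1))
  mean(catches)
}

#' Isoluminance gap between two colours
#'
#' Relative difference `|Qa - Qb| / mean(Qa, Qb)` of double-cone luminance
#' outputs. Either supply two reflectance spectra with an illuminant and
#' member sensitivities, or two pre-computed luminance outputs as scalars.
#'
#' @param a,b Reflectance spectra, or scalar luminance outputs.
#' @param illuminant Illuminant spectrum (ignored for scalar input).
#' @param members Two receptor sensitivities (ignored for scalar input).
#' @param grid Integration grid.
#' @return Nonnegative relative difference.
#' @export
isoluminance_gap <- function(a, b, illuminant = NULL, members = NULL,
                             grid = 300:750) {
  if (is.numeric(a) && is.numeric(b) && length(a) == 1 && length(b) == 1) {
    qa <- a; qb <- b
  } else {
    qa <- double_cone_output(a, illuminant, members, grid)
    qb <- double_cone_output(b, illuminant, members, grid)
  }
  m <- mean(c(qa, qb))
  if (m == 0) stop("both luminance outputs are zero")
  abs(qa - qb) / m
}
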