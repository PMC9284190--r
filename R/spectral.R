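#' Create a spectral curve
#'
#' A sampled response versus wavelength: LED emission, filter
#' transmission, fluorochrome excitation/emission, or sensor channel
#' sensitivity. Filter and sensitivity curves are dimensionless in
#' [0, 1]; emission/excitation curves are in arbitrary units.
#'
#' @param wavelengths strictly increasing wavelength grid (nm)
#' @param values non-negative response at each wavelength
#' @return a [SpectralCurve-class] object
#' @examples
#' sc <- spectralCurve(400:700, dnorm(400:700, 550, 20))
#' wavelengths(sc)[which.max(curveValues(sc))]
#' @export
spectralCurve <- function(wavelengths, values) {
  obj <- new("SpectralCurve", wavelengths = as.numeric(wavelengths),
             values = as.numeric(values))
  validObject(obj)
  obj
}

#' @describeIn spectralCurve wavelength grid accessor
#' @param x a `SpectralCurve`
#' @export
wavelengths <- function(x) x@wavelengths

#' @describeIn spectralCurve response-value accessor
#' @export
curveValues <- function(x) x@values

#' Resample a spectral curve onto a new wavelength grid
#'
#' Linear interpolation; wavelengths outside the original support get a
#' response of zero (a curve is dark where it was never measured).
#'
#' @param curve a [SpectralCurve-class]
#' @param grid numeric, strictly increasing target wavelengths (nm)
#' @return a [SpectralCurve-class] on `grid`
#' @export
resampleCurve <- function(curve, grid) {
  v <- approx(curve@wavelengths, curve@values, xout = grid,
              yleft = 0, yright = 0, rule = 1)$y
  v[is.na(v)] <- 0
  spectralCurve(grid, v)
}

# trapezoidal integral of a sampled product of curves (all on one grid)
.trapz <- function(w, v) {
  n <- length(w)
  sum((w[-1] - w[-n]) * (v[-1] + v[-n])) / 2
}

# common grid covering the overlap of several curves at the finest step
.commonGrid <- function(curves) {
  lo <- max(vapply(curves, function(cv) min(cv@wavelengths), 0))
  hi <- min(vapply(curves, function(cv) max(cv@wavelengths), 0))
  if (hi <= lo)
    stop("spectral curves have non-overlapping wavelength ranges")
  step <- min(vapply(curves, function(cv) min(diff(cv@wavelengths)), 0))
  seq(lo, hi, by = step)
}

# --------------------------------------------------------- curve shapes
# Parametric shapes used for the shipped default spectra (written to CSV
# by inst/scripts/make-default-spectra.R and read back as configuration).

#' Parametric spectrum generators
#'
#' Helpers used to build plausible spectra for LEDs, filters,
#' fluorochromes and sensor channels when no measured curves are
#' available. `gaussianSpectrum` is a (possibly multi-component)
#' Gaussian; `bandpassSpectrum` a flat-top window with raised-cosine
#' edges; `lowpassSpectrum` a high-transmission shoulder below a cutoff.
#'
#' @param grid wavelength grid (nm)
#' @param center,sd,amplitude component parameters (vectors for mixtures)
#' @param low,high window edges (nm)
#' @param cutoff lowpass cutoff (nm)
#' @param edge raised-cosine edge width (nm)
#' @param transmission peak transmission in [0, 1]
#' @return a [SpectralCurve-class]
#' @export
gaussianSpectrum <- function(grid, center, sd, amplitude = 1) {
  amplitude <- rep_len(amplitude, length(center))
  sd <- rep_len(sd, length(center))
  v <- Reduce(`+`, Map(function(m, s, a) a * exp(-0.5 * ((grid - m) / s)^2),
                       center, sd, amplitude))
  spectralCurve(grid, v / max(v))
}

#' @rdname gaussianSpectrum
#' @export
bandpassSpectrum <- function(grid, low, high, transmission = 0.93,
                             edge = 4) {
  rise <- pmin(pmax((grid - low) / edge + 0.5, 0), 1)
  fall <- pmin(pmax((high - grid) / edge + 0.5, 0), 1)
  ramp <- function(u) (1 - cos(pi * u)) / 2   # raised cosine
  spectralCurve(grid, transmission * ramp(rise) * ramp(fall))
}

#' @rdname gaussianSpectrum
#' @export
lowpassSpectrum <- function(grid, cutoff, transmission = 0.93, edge = 5) {
  u <- pmin(pmax((cutoff - grid) / edge + 0.5, 0), 1)
  spectralCurve(grid, transmission * (1 - cos(pi * u)) / 2)
}

# ------------------------------------------------------------- CSV I/O

#' Read or write a spectral curve as CSV
#'
#' Spectra are configuration data: two-column CSV files with columns
#' `wavelength_nm` and `value`, one file per curve.
#'
#' @param path CSV file path
#' @param curve a [SpectralCurve-class]
#' @return `readSpectrumCSV` returns a [SpectralCurve-class];
#'   `writeSpectrumCSV` returns `path` invisibly.
#' @export
readSpectrumCSV <- function(path) {
  df <- read.csv(path)
  if (!all(c("wavelength_nm", "value") %in% names(df)))
    stop("spectrum CSV must have columns wavelength_nm,value: ", path)
  spectralCurve(df$wavelength_nm, df$value)
}

#' @rdname readSpectrumCSV
#' @export
writeSpectrumCSV <- function(curve, path) {
  write.csv(data.frame(wavelength_nm = curve@wavelengths,
                       value = signif(curve@values, 6)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
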