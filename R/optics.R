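#' Optical chain constructors
#'
#' The optical chain of the imager is five excitation LEDs (each behind
#' its own in-line excitation filter), a set of fluorochromes, a single
#' multi-passband (penta) emission filter, and the R/G/B sensitivities
#' of a color CMOS sensor. The brightfield LED takes no part in
#' unmixing and is excluded from the configuration.
#'
#' @param name channel or fluorochrome name
#' @param emission,excitation,excitationFilter,transmission
#'   [SpectralCurve-class] objects
#' @param brightness positive scalar, relative quantum-yield x
#'   extinction proxy; doubles every fingerprint entry when doubled
#' @param passbands two-column matrix (or list of pairs) of disjoint
#'   (low_nm, high_nm) windows, sorted by wavelength
#' @param r,g,b sensor channel sensitivities on a common grid
#' @param leds list of `LEDChannel`
#' @param fluorochromes list of `Fluorochrome`
#' @param penta a `PentaFilter`
#' @param sensor a `SensorResponse`
#' @return the corresponding S4 object
#' @export
ledChannel <- function(name, emission, excitationFilter) {
  obj <- new("LEDChannel", name = name, emission = emission,
             excitationFilter = excitationFilter)
  validObject(obj)
  obj
}

#' @rdname ledChannel
#' @export
fluorochrome <- function(name, excitation, emission, brightness = 1) {
  obj <- new("Fluorochrome", name = name, excitation = excitation,
             emission = emission, brightness = as.numeric(brightness))
  validObject(obj)
  obj
}

#' @rdname ledChannel
#' @export
pentaFilter <- function(passbands, transmission) {
  if (is.list(passbands))
    passbands <- do.call(rbind, lapply(passbands, as.numeric))
  obj <- new("PentaFilter", passbands = passbands,
             transmission = transmission)
  validObject(obj)
  obj
}

#' @rdname ledChannel
#' @export
sensorResponse <- function(r, g, b) {
  obj <- new("SensorResponse", r = r, g = g, b = b)
  validObject(obj)
  obj
}

#' @rdname ledChannel
#' @export
opticalConfig <- function(leds, fluorochromes, penta, sensor) {
  obj <- new("OpticalConfig", leds = leds, fluorochromes = fluorochromes,
             penta = penta, sensor = sensor)
  validObject(obj)
  obj
}

#' @describeIn ledChannel LED names of a configuration
#' @param config an `OpticalConfig`
#' @export
ledNames <- function(config) {
  vapply(config@leds, function(l) l@name, character(1))
}

#' @describeIn ledChannel fluorochrome names of a configuration
#' @export
fluorochromeNames <- function(config) {
  vapply(config@fluorochromes, function(f) f@name, character(1))
}

# ------------------------------------------------- default optical chain

# Parametric default spectra: plausible shapes for the named parts
# (LED centers and filter windows from the part specifications;
# fluorochrome peaks from vendor data). These are written to CSV by
# inst/scripts/make-default-spectra.R; defaultOpticalConfig() reads the
# CSVs back, so the shipped files remain the single source of truth for
# analyses.
.makeDefaultOptics <- function(grid = seq(340, 900, by = 2)) {
  bp <- function(lo, hi) bandpassSpectrum(grid, lo, hi)
  led <- function(center, fwhm)
    gaussianSpectrum(grid, center, fwhm / 2.355)
  leds <- list(
    ledChannel("L385", led(385, 25), lowpassSpectrum(grid, 400)),
    ledChannel("L470", led(470, 28), bp(465, 475)),    # 470/10 filter
    ledChannel("L567", led(567, 70), bp(537.5, 562.5)),# 550/25 filter
    ledChannel("L627", led(627, 22), bp(635, 645)),    # 640/10 filter
    ledChannel("L720", led(720, 30), bp(737.5, 762.5)))# 750/25 filter
  fl <- function(name, exc, emc, exs, ems, bright = 1)
    fluorochrome(name, gaussianSpectrum(grid, exc, exs),
                 gaussianSpectrum(grid, emc, ems), bright)
  fluors <- list(
    fl("DAPI",  358, 461, 25, 25, 1.0),
    fl("BV605", 405, 605, 18, 16, 1.0),
    fl("AF488", 490, 525, 15, 16, 1.0),
    fl("AF555", 555, 580, 15, 18, 1.0),
    fl("AF647", 650, 668, 15, 18, 1.2),
    fl("CF750", 755, 780, 18, 28, 0.8))
  pb <- rbind(c(414, 450), c(500, 530), c(579, 611),
              c(661, 701), c(779, 839))
  trans <- Reduce(`+`, apply(pb, 1L, function(w)
    bandpassSpectrum(grid, w[1], w[2])@values, simplify = FALSE))
  penta <- pentaFilter(pb, spectralCurve(grid, pmin(trans, 1)))
  # Bayer channel sensitivities: visible peaks plus the common
  # near-infrared convergence of all three channels
  sens <- function(center, sd, peak, nir)
    spectralCurve(grid, pmin(peak * exp(-0.5 * ((grid - center) / sd)^2) +
                             nir * exp(-0.5 * ((grid - 800) / 60)^2), 1))
  sensor <- sensorResponse(r = sens(600, 45, 0.90, 0.45),
                           g = sens(535, 40, 0.95, 0.25),
                           b = sens(460, 35, 0.90, 0.20))
  opticalConfig(leds, fluors, penta, sensor)
}

#' Read an optical configuration from a YAML file
#'
#' The YAML lists one spectrum CSV per curve (paths relative to the YAML
#' file), fluorochrome brightnesses and the penta passband windows; see
#' `system.file("extdata", "optics.yaml", package = "ChromaPlex")` for
#' the shipped default.
#'
#' @param path YAML file path
#' @return an [OpticalConfig-class]
#' @export
readOpticalConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rd <- function(p) readSpectrumCSV(file.path(base, p))
  needed <- c("leds", "fluorochromes", "penta", "sensor")
  missing <- setdiff(needed, names(cfg))
  if (length(missing))
    stop("optics config is missing key(s): ", paste(missing, collapse = ", "))
  leds <- lapply(cfg$leds, function(l)
    ledChannel(l$name, rd(l$emission), rd(l$excitation_filter)))
  fluors <- lapply(cfg$fluorochromes, function(f)
    fluorochrome(f$name, rd(f$excitation), rd(f$emission),
                 if (is.null(f$brightness)) 1 else f$brightness))
  penta <- pentaFilter(cfg$penta$passbands, rd(cfg$penta$transmission))
  sensor <- sensorResponse(rd(cfg$sensor$r), rd(cfg$sensor$g),
                           rd(cfg$sensor$b))
  opticalConfig(leds, fluors, penta, sensor)
}

#' Default optical configuration
#'
#' The shipped five-LED (L385/L470/L567/L627/L720, each with its
#' excitation filter), six-fluorochrome (DAPI, BV605, AF488, AF555,
#' AF647, CF750), penta-filter (windows near 432/515/595/681/809 nm)
#' and RGB-sensor configuration, read from the spectrum CSVs under
#' `inst/extdata/spectra`.
#'
#' @return an [OpticalConfig-class]
#' @examples
#' cfg <- defaultOpticalConfig()
#' ledNames(cfg)
#' @export
defaultOpticalConfig <- function() {
  path <- system.file("extdata", "optics.yaml", package = "ChromaPlex")
  if (!nzchar(path)) stop("shipped optics.yaml not found")
  readOpticalConfig(path)
}
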