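#' @title Core S4 classes
#' @name ChromaPlex-classes
#' @description S4 containers for the optical model, the simulator and
#'   the acquisition data. All are created through their constructor
#'   functions ([spectralCurve()], [fluorochrome()], ...) rather than
#'   `new()`.
NULL

# ---------------------------------------------------------------- spectra

#' @rdname ChromaPlex-classes
#' @slot wavelengths numeric, strictly increasing grid in nm
#' @slot values numeric, non-negative response per wavelength
#' @exportClass SpectralCurve
setClass("SpectralCurve",
  representation(wavelengths = "numeric", values = "numeric"))

setValidity("SpectralCurve", function(object) {
  w <- object@wavelengths; v <- object@values
  if (length(w) != length(v))
    return("wavelengths and values must have the same length")
  if (length(w) < 2L)
    return("a spectral curve needs at least two samples")
  if (any(!is.finite(w)) || any(!is.finite(v)))
    return("non-finite entries in spectral curve")
  if (any(diff(w) <= 0))
    return("wavelengths must be strictly increasing")
  if (any(v < 0))
    return("spectral values must be non-negative")
  TRUE
})

#' @rdname ChromaPlex-classes
#' @slot name LED channel name (e.g. "L470"); "BF" marks brightfield
#' @slot emission,excitationFilter [SpectralCurve-class] objects
#' @exportClass LEDChannel
setClass("LEDChannel",
  representation(name = "character", emission = "SpectralCurve",
                 excitationFilter = "SpectralCurve"))

#' @rdname ChromaPlex-classes
#' @slot excitation,emission [SpectralCurve-class] objects
#' @slot brightness positive scalar, relative quantum-yield x extinction
#' @exportClass Fluorochrome
setClass("Fluorochrome",
  representation(name = "character", excitation = "SpectralCurve",
                 emission = "SpectralCurve", brightness = "numeric"))

setValidity("Fluorochrome", function(object) {
  exPeak <- object@excitation@wavelengths[which.max(object@excitation@values)]
  emPeak <- object@emission@wavelengths[which.max(object@emission@values)]
  if (emPeak < exPeak)
    return(sprintf("%s: emission peak (%g nm) below excitation peak (%g nm)",
                   object@name, emPeak, exPeak))
  if (length(object@brightness) != 1L || !is.finite(object@brightness) ||
      object@brightness <= 0)
    return("brightness must be a positive scalar")
  TRUE
})

#' @rdname ChromaPlex-classes
#' @slot passbands two-column matrix of (low_nm, high_nm) windows
#' @slot transmission [SpectralCurve-class], values in [0, 1]
#' @exportClass PentaFilter
setClass("PentaFilter",
  representation(passbands = "matrix", transmission = "SpectralCurve"))

setValidity("PentaFilter", function(object) {
  pb <- object@passbands
  if (ncol(pb) != 2L) return("passbands must be a two-column matrix")
  if (any(pb[, 1] >= pb[, 2])) return("passband low >= high")
  if (nrow(pb) > 1L) {
    o <- order(pb[, 1])
    if (any(pb[o, 1][-1] < pb[o, 2][-nrow(pb)]))
      return("passbands must be disjoint")
    if (any(o != seq_len(nrow(pb))))
      return("passbands must be sorted by wavelength")
  }
  if (any(object@transmission@values > 1))
    return("filter transmission must be <= 1")
  TRUE
})

#' @rdname ChromaPlex-classes
#' @slot r,g,b [SpectralCurve-class] channel sensitivities on one grid
#' @exportClass SensorResponse
setClass("SensorResponse",
  representation(r = "SpectralCurve", g = "SpectralCurve",
                 b = "SpectralCurve"))

setValidity("SensorResponse", function(object) {
  w <- object@r@wavelengths
  if (!identical(w, object@g@wavelengths) ||
      !identical(w, object@b@wavelengths))
    return("r, g, b sensitivities must share one wavelength grid")
  if (any(c(object@r@values, object@g@values, object@b@values) > 1))
    return("sensor sensitivities must be <= 1")
  TRUE
})

#' @rdname ChromaPlex-classes
#' @slot leds list of [LEDChannel-class] (brightfield excluded)
#' @slot fluorochromes list of [Fluorochrome-class]
#' @slot penta [PentaFilter-class]
#' @slot sensor [SensorResponse-class]
#' @exportClass OpticalConfig
setClass("OpticalConfig",
  representation(leds = "list", fluorochromes = "list",
                 penta = "PentaFilter", sensor = "SensorResponse"))

setValidity("OpticalConfig", function(object) {
  ln <- vapply(object@leds, function(l) l@name, character(1))
  fn <- vapply(object@fluorochromes, function(f) f@name, character(1))
  if (anyDuplicated(ln)) return("duplicate LED names")
  if (anyDuplicated(fn)) return("duplicate fluorochrome names")
  if ("BF" %in% ln) return("brightfield LED must not enter the unmixing config")
  TRUE
})

# ------------------------------------------------------------ fingerprint

#' @rdname ChromaPlex-classes
#' @slot A numeric matrix, (n_led x 3) rows x n_fluorochrome columns,
#'   entries >= 0, each column scaled to max 1
#' @slot rowInfo data.frame with columns `led` and `channel` per row of A
#' @slot conditionNumber 2-norm condition number of A
#' @exportClass FingerprintMatrix
setClass("FingerprintMatrix",
  representation(A = "matrix", rowInfo = "data.frame",
                 conditionNumber = "numeric"))

setValidity("FingerprintMatrix", function(object) {
  A <- object@A
  if (any(!is.finite(A))) return("non-finite fingerprint entries")
  if (any(A < 0)) return("fingerprint entries must be non-negative")
  if (any(apply(A, 2L, max) == 0))
    return(sprintf("all-zero fingerprint column: %s",
                   paste(colnames(A)[apply(A, 2L, max) == 0],
                         collapse = ", ")))
  if (is.null(rownames(A)) || is.null(colnames(A)))
    return("fingerprint matrix must carry row and column labels")
  if (nrow(object@rowInfo) != nrow(A))
    return("rowInfo must describe every row of A")
  TRUE
})

# -------------------------------------------------------------- simulator

#' @rdname ChromaPlex-classes
#' @slot width,height frame size in pixels
#' @slot pixelSizeUm pixel size, default 0.6 um
#' @slot cells data.frame of cell geometry and phenotype (one row per
#'   cell: id, row, col, cellA, cellB, nucA, nucB, theta, phenotype)
#' @slot markerLevels numeric matrix, cells x markers, true abundances
#' @slot autofluorescence scalar expected autofluorescence signal (counts)
#'   inside cell bodies, scaled per stacked row by `afProfile`
#' @slot afProfile numeric, per-(LED, channel) relative autofluorescence
#' @exportClass Scene
setClass("Scene",
  representation(width = "integer", height = "integer",
                 pixelSizeUm = "numeric", cells = "data.frame",
                 markerLevels = "matrix", autofluorescence = "numeric",
                 afProfile = "numeric"))

setValidity("Scene", function(object) {
  cl <- object@cells
  if (nrow(cl) != nrow(object@markerLevels))
    return("markerLevels must have one row per cell")
  if (nrow(cl) > 0L) {
    if (any(cl$nucA > cl$cellA + 1e-9) || any(cl$nucB > cl$cellB + 1e-9))
      return("nucleus semi-axes must not exceed cell semi-axes")
    a <- pmax(cl$cellA, cl$cellB)
    if (any(cl$row - a < 0.5) || any(cl$row + a > object@height + 0.5) ||
        any(cl$col - a < 0.5) || any(cl$col + a > object@width + 0.5))
      return("cell ellipses must lie within the frame")
    if (any(object@markerLevels < 0))
      return("marker levels must be non-negative")
  }
  if (object@autofluorescence < 0)
    return("autofluorescence level must be non-negative")
  TRUE
})

#' @rdname ChromaPlex-classes
#' @slot readNoiseSd Gaussian read-noise SD (counts)
#' @slot darkOffset constant camera offset (counts)
#' @slot shotNoise logical, Poisson noise on the expected signal
#' @slot quenchResidual fraction of fluorochrome signal surviving a
#'   quench, in [0, 1)
#' @slot seed integer RNG seed
#' @exportClass NoiseModel
setClass("NoiseModel",
  representation(readNoiseSd = "numeric", darkOffset = "numeric",
                 shotNoise = "logical", quenchResidual = "numeric",
                 seed = "integer"))

setValidity("NoiseModel", function(object) {
  if (object@readNoiseSd < 0 || object@darkOffset < 0)
    return("noise parameters must be non-negative")
  if (object@quenchResidual < 0 || object@quenchResidual >= 1)
    return("quenchResidual must lie in [0, 1)")
  TRUE
})

#' @rdname ChromaPlex-classes
#' @slot rotation rotation angle in radians (about the frame center)
#' @slot translation (drow, dcol) shift in pixels
#' @slot referenceCycle cycle the transform maps into
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotation = "numeric", translation = "numeric",
                 referenceCycle = "integer"))

setValidity("RigidTransform", function(object) {
  if (!is.finite(object@rotation) || abs(object@rotation) >= pi)
    return("|rotation| must be finite and < pi")
  if (length(object@translation) != 2L || any(!is.finite(object@translation)))
    return("translation must be a finite (drow, dcol) pair")
  TRUE
})

#' @rdname ChromaPlex-classes
#' @slot cycleIndex 0 for the autofluorescence reference, >= 1 for stains
#' @slot stained named list, LED -> height x width x 3 array (raw counts)
#' @slot quenched like `stained`, or empty list when not acquired
#' @slot dark single height x width x 3 dark frame
#' @slot transformTruth [RigidTransform-class] (simulator ground truth)
#'   or NULL
#' @slot meta free-form acquisition metadata
#' @exportClass AcquisitionStack
setClass("AcquisitionStack",
  representation(cycleIndex = "integer", stained = "list",
                 quenched = "list", dark = "array",
                 transformTruth = "ANY", meta = "list"))

setValidity("AcquisitionStack", function(object) {
  dims <- lapply(object@stained, dim)
  if (length(dims) == 0L) return("stack contains no LED planes")
  if (any(vapply(dims, length, 1L) != 3L) ||
      any(vapply(dims, `[`, 1L, 3L) != 3L))
    return("each LED plane must be a height x width x 3 array")
  if (length(unique(lapply(dims, `[`, 1:2))) != 1L)
    return("all LED planes must share one geometry")
  if (!identical(dim(object@dark), dims[[1L]]))
    return("dark frame geometry must match the LED planes")
  if (length(object@quenched) &&
      !identical(lapply(object@quenched, dim), dims))
    return("quenched planes must mirror the stained planes")
  if (any(unlist(lapply(object@stained, min)) < 0))
    return("raw counts must be non-negative")
  TRUE
})

# ------------------------------------------------------------ downstream

#' @rdname ChromaPlex-classes
#' @slot nucleusLabels,cellLabels integer label matrices (0 = background)
#' @slot nucleusToCell named integer vector, nucleus label -> cell label
#' @exportClass LabelMasks
setClass("LabelMasks",
  representation(nucleusLabels = "matrix", cellLabels = "matrix",
                 nucleusToCell = "integer"))

setValidity("LabelMasks", function(object) {
  if (!identical(dim(object@nucleusLabels), dim(object@cellLabels)))
    return("nucleus and cell label images must share geometry")
  if (min(object@nucleusLabels) < 0 || min(object@cellLabels) < 0)
    return("labels must be non-negative integers")
  TRUE
})

#' @rdname ChromaPlex-classes
#' @slot planes ordered list of focal-plane images
#' @slot stepUm axial step between planes (default 150 um)
#' @exportClass FocusStack
setClass("FocusStack",
  representation(planes = "list", stepUm = "numeric"))

setValidity("FocusStack", function(object) {
  if (length(object@planes) < 2L) return("a focus stack needs >= 2 planes")
  if (length(object@stepUm) != 1L || object@stepUm <= 0)
    return("stepUm must be a positive scalar")
  TRUE
})

# ------------------------------------------------------------------ show

setMethod("show", "SpectralCurve", function(object) {
  w <- object@wavelengths
  cat(sprintf("SpectralCurve: %d samples, %g-%g nm, peak %g at %g nm\n",
              length(w), min(w), max(w), max(object@values),
              w[which.max(object@values)]))
})

setMethod("show", "FingerprintMatrix", function(object) {
  cat(sprintf("FingerprintMatrix: %d x %d (%s), condition number %.3g\n",
              nrow(object@A), ncol(object@A),
              paste(colnames(object@A), collapse = ", "),
              object@conditionNumber))
})

setMethod("show", "Scene", function(object) {
  cat(sprintf("Scene: %d x %d px (%.2g um/px), %d cells, markers: %s\n",
              object@width, object@height, object@pixelSizeUm,
              nrow(object@cells),
              paste(colnames(object@markerLevels), collapse = ", ")))
  if (nrow(object@cells))
    print(table(object@cells$phenotype))
})

setMethod("show", "AcquisitionStack", function(object) {
  d <- dim(object@dark)
  cat(sprintf(
    "AcquisitionStack: cycle %d, %d LED planes (%s), %d x %d px%s\n",
    object@cycleIndex, length(object@stained),
    paste(names(object@stained), collapse = ", "), d[1], d[2],
    if (length(object@quenched)) ", with quenched planes" else ""))
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf(
    "RigidTransform: rotation %.4g deg, translation (%.3g, %.3g) px\n",
    object@rotation * 180 / pi, object@translation[1],
    object@translation[2]))
})

setMethod("show", "LabelMasks", function(object) {
  cat(sprintf("LabelMasks: %d nuclei, %d cells, %d x %d px\n",
              length(setdiff(unique(as.vector(object@nucleusLabels)), 0L)),
              length(setdiff(unique(as.vector(object@cellLabels)), 0L)),
              nrow(object@nucleusLabels), ncol(object@nucleusLabels)))
})
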