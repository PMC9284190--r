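#' Predict the RGB fingerprint of one fluorochrome
#'
#' The fingerprint of a fluorochrome is its characteristic vector of
#' expected sensor responses across all (LED, color-channel) pairs: the
#' column of the unmixing matrix A in S = A F. Under LED-sequential
#' illumination the entry for LED l and channel c factorizes into an
#' excitation coupling and an emission coupling,
#' \deqn{A_{(l,c)} = \beta \int E_l(\lambda) X_l(\lambda)
#'   \phi_{ex}(\lambda) d\lambda \times \int \phi_{em}(\lambda)
#'   P(\lambda) \sigma_c(\lambda) d\lambda,}
#' with \eqn{E_l} the LED emission, \eqn{X_l} its excitation filter,
#' \eqn{\phi_{ex}, \phi_{em}} the fluorochrome excitation and emission,
#' \eqn{P} the penta transmission, \eqn{\sigma_c} the sensor channel
#' sensitivity and \eqn{\beta} the fluorochrome brightness. The column
#' is scaled so its largest entry is 1; abundances then carry the
#' intensity scale.
#'
#' @param fluor a [Fluorochrome-class]
#' @param leds list of [LEDChannel-class]
#' @param penta a [PentaFilter-class]
#' @param sensor a [SensorResponse-class]
#' @param scale scale the column to max 1 (default TRUE)
#' @return named numeric vector of length `3 * length(leds)`, ordered
#'   LED-major with channels R, G, B
#' @examples
#' cfg <- defaultOpticalConfig()
#' predictFingerprintColumn(cfg@fluorochromes[[4]], cfg@leds,
#'                          cfg@penta, cfg@sensor)
#' @export
predictFingerprintColumn <- function(fluor, leds, penta, sensor,
                                     scale = TRUE) {
  grid <- .commonGrid(c(list(fluor@excitation, fluor@emission,
                             penta@transmission, sensor@r),
                        lapply(leds, function(l) l@emission)))
  rs <- function(cv) resampleCurve(cv, grid)@values
  exc <- rs(fluor@excitation)
  em <- rs(fluor@emission) * rs(penta@transmission)
  emCoupling <- c(R = .trapz(grid, em * rs(sensor@r)),
                  G = .trapz(grid, em * rs(sensor@g)),
                  B = .trapz(grid, em * rs(sensor@b)))
  exCoupling <- vapply(leds, function(l)
    .trapz(grid, rs(l@emission) * rs(l@excitationFilter) * exc), 0)
  # outer(em, ex) varies the channel fastest: LED-major, channels R,G,B
  col <- fluor@brightness * as.vector(outer(emCoupling, exCoupling))
  names(col) <- .rowLabels(vapply(leds, function(l) l@name, character(1)))
  if (max(col) == 0)
    stop("fluorochrome ", fluor@name,
         " is invisible to the optics (all-zero fingerprint column)")
  if (scale) col <- col / max(col)
  col
}

#' Build the fingerprint (unmixing) matrix A
#'
#' Assembles one [predictFingerprintColumn()] per fluorochrome into the
#' unmixing matrix A of S = A F, with `3 * n_led` rows (LED-major,
#' channels R, G, B) and one column per fluorochrome, each scaled to a
#' maximum of 1. The 2-norm condition number is computed and stored; a
#' large value warns that two fluorochromes have nearly collinear
#' fingerprints.
#'
#' @inheritParams predictFingerprintColumn
#' @param fluors list of [Fluorochrome-class], or an
#'   [OpticalConfig-class] given alone
#' @return a [FingerprintMatrix-class]
#' @examples
#' A <- buildFingerprintMatrix(defaultOpticalConfig())
#' conditionNumber(A)
#' @export
buildFingerprintMatrix <- function(fluors, leds = NULL, penta = NULL,
                                   sensor = NULL) {
  if (is(fluors, "OpticalConfig")) {
    cfg <- fluors
    fluors <- cfg@fluorochromes; leds <- cfg@leds
    penta <- cfg@penta; sensor <- cfg@sensor
  }
  if (length(fluors) < 1L || length(leds) < 1L)
    stop("need at least one fluorochrome and one LED")
  nm <- vapply(fluors, function(f) f@name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate fluorochrome names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  A <- vapply(fluors, predictFingerprintColumn, numeric(3L * length(leds)),
              leds = leds, penta = penta, sensor = sensor)
  colnames(A) <- nm
  ln <- vapply(leds, function(l) l@name, character(1))
  rownames(A) <- .rowLabels(ln)
  .fingerprintMatrix(A, ln)
}

.fingerprintMatrix <- function(A, ledNames) {
  ri <- data.frame(led = rep(ledNames, each = 3L),
                   channel = rep(CHANNELS, length(ledNames)))
  s <- svd(A, nu = 0, nv = 0)$d
  kappa <- if (min(s) > 0) max(s) / min(s) else Inf
  obj <- new("FingerprintMatrix", A = A, rowInfo = ri,
             conditionNumber = kappa)
  validObject(obj)
  obj
}

#' @describeIn buildFingerprintMatrix the matrix A itself
#' @param x a `FingerprintMatrix`
#' @export
fingerprint <- function(x) x@A

#' @describeIn buildFingerprintMatrix 2-norm condition number of A
#' @export
conditionNumber <- function(x) x@conditionNumber

#' Estimate the fingerprint matrix from single-fluorochrome stains
#'
#' The experimental route to A: image one slide per fluorochrome,
#' stained with that fluorochrome only. After dark subtraction,
#' foreground pixels are those above `fgThresholdQuantile` of the
#' brightest (LED, channel) plane; each plane is averaged over the
#' foreground and the column scaled to max 1.
#'
#' @param stacks named list, fluorochrome name -> [AcquisitionStack-class]
#' @param dark height x width x 3 dark frame shared by all stacks (each
#'   stack's own dark frame is used when `NULL`)
#' @param fgThresholdQuantile foreground quantile, default 0.95
#' @return a [FingerprintMatrix-class] with columns in `names(stacks)`
#'   order
#' @export
estimateFingerprint <- function(stacks, dark = NULL,
                                fgThresholdQuantile = 0.95) {
  if (is.null(names(stacks)) || any(!nzchar(names(stacks))))
    stop("stacks must be a named list (fluorochrome -> stack)")
  ln <- names(stacks[[1L]]@stained)
  cols <- lapply(names(stacks), function(fn) {
    stk <- stacks[[fn]]
    dk <- if (is.null(dark)) stk@dark else dark
    if (!identical(dim(dk), dim(stk@stained[[1L]])))
      stop("dark frame geometry does not match stack ", fn)
    sig <- .stackSignal(lapply(stk@stained, function(p) {
      if (!identical(dim(p), dim(dk)))
        stop("dark frame geometry does not match stack ", fn)
      p - dk
    }), ln)
    peak <- which.max(rowSums(sig))
    thr <- quantile(sig[peak, ], fgThresholdQuantile, names = FALSE)
    fg <- sig[peak, ] > thr
    if (!any(fg))
      stop("empty foreground for single-stain ", fn,
           " (no pixels above the ", fgThresholdQuantile, " quantile)")
    colMean <- rowMeans(sig[, fg, drop = FALSE])
    if (any(colMean < 0)) {
      warning("negative plane averages for ", fn,
              " clamped to 0 after dark subtraction")
      colMean <- pmax(colMean, 0)
    }
    if (max(colMean) == 0)
      stop("all-dark single-stain stack for ", fn)
    colMean / max(colMean)
  })
  A <- do.call(cbind, cols)
  dimnames(A) <- list(.rowLabels(ln), names(stacks))
  .fingerprintMatrix(A, ln)
}

#' Read or write a fingerprint matrix as labeled CSV
#'
#' @param x a [FingerprintMatrix-class]
#' @param path CSV file path (rows labeled `LED.channel`, columns by
#'   fluorochrome)
#' @export
writeFingerprintCSV <- function(x, path) {
  write.csv(x@A, path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFingerprintCSV
#' @export
readFingerprintCSV <- function(path) {
  df <- read.csv(path, row.names = 1L, check.names = FALSE)
  A <- as.matrix(df)
  leds <- unique(sub("\\.[RGB]$", "", rownames(A)))
  .fingerprintMatrix(A, leds)
}

#' Bleed-through fractions per fluorochrome and emission window
#'
#' Decomposes each fluorochrome's predicted emission signal (emission x
#' penta transmission x summed sensor sensitivity) over the penta
#' passband windows. The bleed-through of a fluorochrome is the
#' fraction of its total signal that falls outside its nominal window;
#' window fractions sum to 1 per fluorochrome.
#'
#' @inheritParams predictFingerprintColumn
#' @param fluors list of [Fluorochrome-class], or an [OpticalConfig-class]
#' @param nominalWindow named integer vector assigning each fluorochrome
#'   a passband index; defaults to the window holding most of its signal
#' @return matrix fluorochrome x window of fractions in [0, 1], with an
#'   `outside` attribute giving each fluorochrome's out-of-window
#'   (bleed-through) fraction
#' @examples
#' bt <- bleedthroughFraction(defaultOpticalConfig())
#' attr(bt, "outside")
#' @export
bleedthroughFraction <- function(fluors, penta = NULL, sensor = NULL,
                                 nominalWindow = NULL) {
  if (is(fluors, "OpticalConfig")) {
    cfg <- fluors
    fluors <- cfg@fluorochromes; penta <- cfg@penta; sensor <- cfg@sensor
  }
  pb <- penta@passbands
  windows <- paste0("W", round(rowMeans(pb)))
  frac <- t(vapply(fluors, function(f) {
    grid <- .commonGrid(list(f@emission, penta@transmission, sensor@r))
    rs <- function(cv) resampleCurve(cv, grid)@values
    sig <- rs(f@emission) * rs(penta@transmission) *
      (rs(sensor@r) + rs(sensor@g) + rs(sensor@b))
    perWin <- apply(pb, 1L, function(w)
      .trapz(grid, sig * (grid >= w[1] & grid <= w[2])))
    tot <- .trapz(grid, sig)
    if (tot == 0)
      stop("fluorochrome ", f@name, " has zero total emission signal")
    perWin / tot
  }, numeric(nrow(pb))))
  dimnames(frac) <- list(vapply(fluors, function(f) f@name, character(1)),
                         windows)
  if (is.null(nominalWindow))
    nominalWindow <- apply(frac, 1L, which.max)
  outside <- 1 - frac[cbind(seq_len(nrow(frac)), nominalWindow)]
  names(outside) <- rownames(frac)
  attr(frac, "nominalWindow") <- nominalWindow
  attr(frac, "outside") <- outside
  frac
}
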