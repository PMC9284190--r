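#' Signal-to-noise ratio of an image
#'
#' `(mean(foreground) - mean(background)) / sd(background)`, the
#' convention used throughout this package (adding a constant to the
#' whole image leaves it unchanged). A zero background SD is flagged
#' as infinite rather than an error.
#'
#' @param image numeric matrix
#' @param fgMask,bgMask disjoint logical masks
#' @return scalar SNR (Inf with a warning when sd(background) = 0)
#' @export
snr <- function(image, fgMask, bgMask) {
  stopifnot(identical(dim(image), dim(fgMask)),
            identical(dim(image), dim(bgMask)))
  if (any(fgMask & bgMask)) stop("foreground and background masks overlap")
  if (!any(fgMask) || !any(bgMask)) stop("empty foreground or background")
  s <- sd(image[bgMask])
  if (s == 0) {
    warning("background SD is zero; SNR undefined (flagged infinite)")
    return(Inf)
  }
  (mean(image[fgMask]) - mean(image[bgMask])) / s
}

#' Coefficient of variation, in percent
#'
#' `sd(values) / mean(values) * 100` with the sample (n - 1) standard
#' deviation; invariant under multiplication by a positive constant.
#'
#' @param values numeric vector (>= 2 values, non-zero mean)
#' @return CV as a percentage
#' @examples
#' cvPercent(c(9, 11))   # 14.1%
#' @export
cvPercent <- function(values) {
  if (length(values) < 2L) stop("CV needs at least two values")
  m <- mean(values)
  if (m == 0) stop("CV undefined: mean is zero")
  100 * sd(values) / m
}

#' Reference-free focus quality score
#'
#' Normalized gradient energy: mean squared finite-difference gradient
#' divided by the image variance, computed after a light Gaussian
#' pre-filter (`denoiseSigma`) that suppresses pixel-level camera noise
#' (whose gradient energy would otherwise reward defocused planes).
#' The score is invariant under linear intensity rescaling and
#' strictly decreases as a structured image is increasingly
#' Gaussian-defocused; a constant image scores 0.
#'
#' @param image numeric matrix
#' @param denoiseSigma pre-filter SD in px (default 1; 0 disables)
#' @return scalar sharpness score
#' @export
focusScore <- function(image, denoiseSigma = 1) {
  if (!length(image)) stop("empty image")
  if (denoiseSigma > 0)
    image <- as.matrix(EBImage::gblur(EBImage::Image(image),
                                      sigma = denoiseSigma))
  v <- stats::var(as.vector(image))
  if (v == 0) return(0)
  gx <- image[, -1L, drop = FALSE] - image[, -ncol(image), drop = FALSE]
  gy <- image[-1L, , drop = FALSE] - image[-nrow(image), , drop = FALSE]
  (mean(gx^2) + mean(gy^2)) / v
}

#' Select the best focal plane of a stack
#'
#' Arg-max of [focusScore()] over the planes; ties resolve to the
#' lower index.
#'
#' @param stack a [FocusStack-class]
#' @return list with `index` (best plane) and `scores` (per plane)
#' @export
selectFocusPlane <- function(stack) {
  scores <- vapply(stack@planes, focusScore, 0)
  list(index = which.max(scores), scores = scores)
}

#' Bead-based daily calibration check
#'
#' Detects calibration beads on a single-stain bead slide, unmixes the
#' stack, and compares each fluorochrome channel's SNR and
#' bead-to-bead CV against thresholds, reporting pass/fail with
#' reasons.
#'
#' @param beadStack an [AcquisitionStack-class] (see
#'   [generateBeadSlide()])
#' @param A a [FingerprintMatrix-class]
#' @param thresholds list per channel or shared: `minSnr` (default 10)
#'   and `maxCv` (percent, default 15)
#' @return a QC report list: per-channel `snr`, `cv`, `pass`, `reason`,
#'   plus an overall `pass`; serializable to JSON
#' @export
calibrationCheck <- function(beadStack, A,
                             thresholds = list(minSnr = 10, maxCv = 15)) {
  dk <- subtractDarkStack(beadStack)
  um <- unmixImage(dk@stained, A)
  total <- Reduce(`+`, um$abundances)
  rng <- range(total)
  report <- list(channels = list(), pass = FALSE)
  if (diff(rng) == 0) {
    report$reason <- "no beads detected"
    return(report)
  }
  tn <- (total - rng[1L]) / diff(rng)
  mask <- tn > EBImage::otsu(EBImage::Image(tn))
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask)))
  bg <- !as.matrix(EBImage::dilate(EBImage::Image(mask),
                                   EBImage::makeBrush(9L, "disc")))
  # thresholding pure noise yields either nothing or a frame-filling
  # "bead": both mean no detectable beads
  if (max(lab) == 0L || mean(mask) > 0.25 || !any(bg)) {
    report$reason <- "no beads detected"
    return(report)
  }
  # assign each bead to its dominant fluorochrome
  beadIds <- seq_len(max(lab))
  domFluor <- vapply(beadIds, function(b) {
    means <- vapply(um$abundances, function(img) mean(img[lab == b]), 0)
    names(means)[which.max(means)]
  }, character(1))
  allPass <- TRUE
  for (fl in names(um$abundances)) {
    img <- um$abundances[[fl]]
    beads <- beadIds[domFluor == fl]
    th <- if (!is.null(thresholds[[fl]])) thresholds[[fl]] else thresholds
    if (!length(beads)) {
      report$channels[[fl]] <- list(pass = FALSE,
                                    reason = "no beads detected")
      allPass <- FALSE
      next
    }
    fg <- lab %in% beads & mask
    dim(fg) <- dim(lab)
    chanSnr <- snr(img, fg, bg)
    beadMeans <- vapply(beads, function(b) mean(img[lab == b]), 0)
    chanCv <- if (length(beadMeans) >= 2L) cvPercent(beadMeans) else 0
    fail <- character()
    if (chanSnr < th$minSnr)
      fail <- c(fail, sprintf("SNR %.1f below minimum %.1f", chanSnr,
                              th$minSnr))
    if (chanCv > th$maxCv)
      fail <- c(fail, sprintf("CV %.1f%% above maximum %.1f%%", chanCv,
                              th$maxCv))
    ok <- !length(fail)
    report$channels[[fl]] <- list(
      snr = chanSnr, cv = chanCv, nBeads = length(beads), pass = ok,
      reason = if (ok) "within thresholds"
               else paste(fail, collapse = "; "))
    allPass <- allPass && ok
  }
  report$pass <- allPass
  report
}
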