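#' Dark-frame subtraction
#'
#' Removes the camera's fixed offset by subtracting a dark image
#' acquired without a sample, clamping at zero (signals are physical).
#' The fraction of clamped pixels is recorded in the `clampFraction`
#' attribute; pixels whose subtracted magnitude is below `clampTol` are
#' ignored by that statistic, so pure read-noise flicker around zero
#' does not count as clamping.
#'
#' @param image numeric matrix or array
#' @param dark dark frame of identical geometry
#' @param clampTol magnitude below which clamping is not counted
#' @return the clamped difference with attribute `clampFraction`
#' @export
subtractDark <- function(image, dark, clampTol = 0) {
  if (!identical(dim(image), dim(dark)))
    stop("image and dark frame geometries differ")
  delta <- image - dark
  clamped <- delta < -clampTol
  out <- pmax(delta, 0)
  attr(out, "clampFraction") <- mean(clamped)
  out
}

#' @describeIn subtractDark subtract a stack's dark frame from all its
#'   stained and quenched planes
#' @param stack an [AcquisitionStack-class]
#' @export
subtractDarkStack <- function(stack, clampTol = 0) {
  sub <- function(p) {
    out <- subtractDark(p, stack@dark, clampTol)
    attr(out, "clampFraction") <- NULL
    out
  }
  new("AcquisitionStack", cycleIndex = stack@cycleIndex,
      stained = lapply(stack@stained, sub),
      quenched = lapply(stack@quenched, sub),
      dark = array(0, dim(stack@dark)),
      transformTruth = stack@transformTruth,
      meta = c(stack@meta, list(darkSubtracted = TRUE)))
}

#' DAPI-window composite of an acquisition
#'
#' The registration (and autofocus) image: mean of the green and blue
#' channels under violet excitation, where the DAPI counterstain emits.
#' Computed from the raw stained planes after dark subtraction so that
#' registration sees consistent geometry regardless of unmixing.
#'
#' @param stack an [AcquisitionStack-class]
#' @param led LED channel carrying DAPI excitation (default "L385")
#' @return numeric matrix
#' @export
dapiComposite <- function(stack, led = "L385") {
  p <- stack@stained[[led]]
  if (is.null(p)) stop("stack has no LED plane ", led)
  d <- subtractDark(p, stack@dark)
  (d[, , 2L] + d[, , 3L]) / 2
}

# ------------------------------------------------------ blob detection

# nucleus-scale blob centroids (intensity-weighted), the registration
# keypoints
.detectBlobs <- function(img, sigma = 2, minArea = 15) {
  s <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma))
  rng <- range(s)
  if (diff(rng) == 0) return(matrix(numeric(), 0L, 2L))
  sn <- (s - rng[1L]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(sn))
  lab <- EBImage::bwlabel(EBImage::Image(sn > thr))
  lab <- as.matrix(lab)
  idx <- which(lab > 0L)
  if (!length(idx)) return(matrix(numeric(), 0L, 2L))
  lv <- lab[idx]
  wt <- s[idx]
  rows <- (idx - 1L) %% nrow(img) + 1L
  cols <- (idx - 1L) %/% nrow(img) + 1L
  area <- tabulate(lv)
  keep <- which(area >= minArea)
  if (!length(keep)) return(matrix(numeric(), 0L, 2L))
  wsum <- vapply(split(wt, lv), sum, 0)
  rsum <- vapply(split(wt * rows, lv), sum, 0)
  csum <- vapply(split(wt * cols, lv), sum, 0)
  ctr <- cbind(rsum / wsum, csum / wsum)
  ctr[keep, , drop = FALSE]
}

# integer translation estimate via FFT cross-correlation
.crossCorrShift <- function(moving, reference) {
  h <- nrow(reference); w <- ncol(reference)
  a <- moving - mean(moving); b <- reference - mean(reference)
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE))
  pk <- which.max(cc)
  dr <- (pk - 1L) %% h
  dc <- (pk - 1L) %/% h
  if (dr > h / 2) dr <- dr - h
  if (dc > w / 2) dc <- dc - w
  c(dr, dc)
}

# Kabsch rigid fit: returns (theta, t) with Q ~ R(theta) (P - c) + c + t
.fitRigid <- function(P, Q, center) {
  pbar <- colMeans(P); qbar <- colMeans(Q)
  X <- sweep(P, 2L, pbar); Y <- sweep(Q, 2L, qbar)
  H <- t(X) %*% Y
  sv <- svd(H)
  R <- sv$v %*% diag(c(1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
  theta <- atan2(R[2L, 1L], R[1L, 1L])
  tr <- qbar - as.vector(R %*% (pbar - center)) - center
  list(theta = theta, translation = tr)
}

#' Estimate the rigid transform between two cycles
#'
#' Recovers the rotation + translation mapping the reference frame onto
#' a moving cycle by keypoint detection (nucleus-blob centroids on the
#' DAPI composites), FFT cross-correlation for the coarse translation,
#' and a trimmed iterative-closest-point refinement with a rigid
#' (Kabsch) fit, which rejects unmatched or ambiguous keypoints.
#'
#' @param moving,reference DAPI composite images (see [dapiComposite()])
#' @param maxIter ICP iteration cap
#' @param matchRadius initial nearest-neighbor matching radius (px)
#' @return a [RigidTransform-class] with attribute `inliers` (number of
#'   matched keypoints in the final fit)
#' @export
estimateAlignment <- function(moving, reference, maxIter = 40L,
                              matchRadius = 15) {
  refPts <- .detectBlobs(reference)
  movPts <- .detectBlobs(moving)
  if (nrow(refPts) < 20L || nrow(movPts) < 20L)
    stop("registration failed: fewer than 20 detectable blob features ",
         "(", nrow(refPts), " reference, ", nrow(movPts), " moving)")
  center <- (dim(reference) + 1) / 2
  theta <- 0
  tr <- .crossCorrShift(moving, reference)
  radius <- matchRadius
  inliers <- 0L
  for (it in seq_len(maxIter)) {
    cs <- cos(theta); sn <- sin(theta)
    dr <- refPts[, 1L] - center[1L]; dc <- refPts[, 2L] - center[2L]
    pred <- cbind(cs * dr - sn * dc + center[1L] + tr[1L],
                  sn * dr + cs * dc + center[2L] + tr[2L])
    d2 <- outer(pred[, 1L], movPts[, 1L], "-")^2 +
      outer(pred[, 2L], movPts[, 2L], "-")^2
    nn <- max.col(-d2, ties.method = "first")
    nd <- sqrt(d2[cbind(seq_len(nrow(pred)), nn)])
    keep <- which(nd <= radius)
    # one moving point per reference point: keep the closest claimant
    if (anyDuplicated(nn[keep])) {
      keep <- keep[order(nd[keep])]
      keep <- keep[!duplicated(nn[keep])]
    }
    if (length(keep) < 8L)
      stop("registration failed: only ", length(keep),
           " inlier matches (>= 8 required)")
    fit <- .fitRigid(refPts[keep, , drop = FALSE],
                     movPts[nn[keep], , drop = FALSE], center)
    moved <- abs(fit$theta - theta) * max(dim(reference)) +
      sqrt(sum((fit$translation - tr)^2))
    theta <- fit$theta; tr <- fit$translation
    inliers <- length(keep)
    radius <- max(3, 3 * median(nd[keep]))
    if (moved < 1e-4) break
  }
  out <- rigidTransform(theta, tr)
  attr(out, "inliers") <- inliers
  out
}

#' Warp a cycle into the reference frame
#'
#' Applies the estimated rigid transform identically to every plane of
#' the cycle (bilinear interpolation; out-of-frame pixels zero-filled).
#'
#' @param x an [AcquisitionStack-class], a named list of planes, or a
#'   single matrix/array
#' @param tf a [RigidTransform-class]
#' @return object of the same shape, warped into the reference frame
#' @export
applyAlignment <- function(x, tf) {
  if (is(x, "AcquisitionStack")) {
    return(new("AcquisitionStack", cycleIndex = x@cycleIndex,
               stained = lapply(x@stained, warpRigid, tf = tf),
               quenched = lapply(x@quenched, warpRigid, tf = tf),
               dark = x@dark, transformTruth = x@transformTruth,
               meta = c(x@meta, list(aligned = TRUE))))
  }
  if (is.list(x)) return(lapply(x, warpRigid, tf = tf))
  warpRigid(x, tf)
}

#' Quench / autofluorescence subtraction
#'
#' Subtracts the previous cycle's post-quench acquisition (for cycle 1:
#' the cycle-0 autofluorescence reference) from the stained acquisition,
#' clamped at zero, removing quench-resistant carryover and
#' autofluorescence in one step. Both inputs must already be dark
#' subtracted and aligned to the reference frame.
#'
#' @param stained named list of the cycle's aligned stained planes (LED
#'   -> height x width x 3), or an [AcquisitionStack-class]
#' @param background the previous cycle's aligned quenched planes (or
#'   the cycle-0 autofluorescence stack); same shapes
#' @param cycleIndex cycle index recorded in the provenance
#' @param clampTol see [subtractDark()]
#' @param clampWarn warn when the counted clamp fraction exceeds this
#' @return a `CorrectedCycle`: list with `cycleIndex`, `planes` and a
#'   `provenance` log (clamp fractions per LED)
#' @export
quenchSubtract <- function(stained, background, cycleIndex = NA_integer_,
                           clampTol = 0, clampWarn = 0.2) {
  if (is(stained, "AcquisitionStack")) {
    if (is.na(cycleIndex)) cycleIndex <- stained@cycleIndex
    stained <- stained@stained
  }
  if (is(background, "AcquisitionStack")) {
    background <- if (background@cycleIndex == 0L) background@stained
                  else background@quenched
  }
  if (is.null(background) || !length(background))
    stop("missing predecessor (quenched or autofluorescence) stack for ",
         "cycle ", cycleIndex)
  missing <- setdiff(names(stained), names(background))
  if (length(missing))
    stop("background is missing LED plane(s): ",
         paste(missing, collapse = ", "))
  clampFrac <- numeric(length(stained))
  names(clampFrac) <- names(stained)
  planes <- lapply(names(stained), function(ln) {
    out <- subtractDark(stained[[ln]], background[[ln]], clampTol)
    clampFrac[[ln]] <<- attr(out, "clampFraction")
    attr(out, "clampFraction") <- NULL
    out
  })
  names(planes) <- names(stained)
  if (any(clampFrac > clampWarn))
    warning("quench subtraction clamped more than ",
            round(100 * clampWarn), "% of significant pixels in LED(s): ",
            paste(names(clampFrac)[clampFrac > clampWarn],
                  collapse = ", "))
  structure(list(cycleIndex = cycleIndex, planes = planes,
                 provenance = list(steps = c("dark", "align",
                                             "quench-subtract"),
                                   clampFraction = clampFrac)),
            class = "CorrectedCycle")
}

#' Maximum-intensity projection across cycles
#'
#' Pixel-wise maximum of the DAPI (or any) image across all cycles; the
#' segmentation input, since every nucleus is counterstained in every
#' cycle.
#'
#' @param images list of matrices with identical geometry
#' @return matrix of pixel-wise maxima
#' @export
dapiMaxProjection <- function(images) {
  stopifnot(length(images) >= 1L)
  Reduce(pmax, images)
}
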