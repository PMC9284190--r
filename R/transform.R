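#' Rigid transforms between staining cycles
#'
#' A rigid transform maps reference-frame pixel coordinates `p = (row,
#' col)` to moving-frame coordinates `T(p) = R(theta) (p - c) + c + t`,
#' where `c` is the frame center, `theta` the rotation and `t` the
#' translation in pixels. The simulator stores the truth transform of
#' each rendered cycle in this convention, [estimateAlignment()]
#' recovers it, and [applyAlignment()] resamples a moving image back
#' into the reference frame.
#'
#' @param rotation rotation in radians, |rotation| < pi
#' @param translation (drow, dcol) shift in pixels
#' @param referenceCycle index of the reference cycle (default 1)
#' @return a [RigidTransform-class]
#' @examples
#' tf <- rigidTransform(0.01, c(3, -2))
#' invertTransform(tf)
#' @export
rigidTransform <- function(rotation = 0, translation = c(0, 0),
                           referenceCycle = 1L) {
  obj <- new("RigidTransform", rotation = as.numeric(rotation),
             translation = as.numeric(translation),
             referenceCycle = as.integer(referenceCycle))
  validObject(obj)
  obj
}

#' @describeIn rigidTransform the inverse transform (`T^{-1}(q) =
#'   R(-theta) (q - c - t) + c`)
#' @param tf a `RigidTransform`
#' @export
invertTransform <- function(tf) {
  th <- -tf@rotation
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  rigidTransform(th, as.vector(-R %*% tf@translation), tf@referenceCycle)
}

#' Warp an image by a rigid transform
#'
#' Resamples `img` at the transformed coordinates: `out[p] =
#' img[T(p)]`, with bilinear interpolation and out-of-frame pixels set
#' to `fill`. Warping a moving-frame image by its cycle's transform
#' brings it into the reference frame.
#'
#' @param img numeric matrix, or height x width x k array (planes are
#'   warped identically)
#' @param tf a [RigidTransform-class]
#' @param fill value for source coordinates outside the frame
#' @return warped image of the same geometry, with attribute `mask`
#'   (logical matrix of in-frame pixels)
#' @export
warpRigid <- function(img, tf, fill = 0) {
  if (length(dim(img)) == 3L) {
    out <- img
    msk <- NULL
    for (k in seq_len(dim(img)[3L])) {
      w <- warpRigid(img[, , k], tf, fill)
      out[, , k] <- w
      msk <- attr(w, "mask")
    }
    attr(out, "mask") <- msk
    return(out)
  }
  h <- nrow(img); w <- ncol(img)
  c0 <- (c(h, w) + 1) / 2
  pr <- rep(seq_len(h), times = w) - c0[1L]
  pc <- rep(seq_len(w), each = h) - c0[2L]
  cs <- cos(tf@rotation); sn <- sin(tf@rotation)
  sr <- cs * pr - sn * pc + c0[1L] + tf@translation[1L]
  sc <- sn * pr + cs * pc + c0[2L] + tf@translation[2L]
  r0 <- floor(sr); c0i <- floor(sc)
  fr <- sr - r0; fc <- sc - c0i
  inside <- r0 >= 1 & r0 < h & c0i >= 1 & c0i < w
  r0[!inside] <- 1L; c0i[!inside] <- 1L
  i00 <- (c0i - 1L) * h + r0
  v <- img[i00] * (1 - fr) * (1 - fc) + img[i00 + 1L] * fr * (1 - fc) +
    img[i00 + h] * (1 - fr) * fc + img[i00 + h + 1L] * fr * fc
  v[!inside] <- fill
  out <- matrix(v, h, w)
  attr(out, "mask") <- matrix(inside, h, w)
  out
}

# fraction of the frame a transform pushes out of bounds
.outOfFrameFraction <- function(dim, tf) {
  h <- dim[1L]; w <- dim[2L]
  probe <- warpRigid(matrix(1, h, w), tf, fill = 0)
  1 - mean(attr(probe, "mask"))
}
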