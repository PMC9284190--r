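# stack per-LED RGB planes into the (3 * n_led) x n_pixel signal matrix
# whose row order matches the fingerprint matrix (LED-major, R, G, B)
.stackSignal <- function(planes, ledOrder = names(planes)) {
  mats <- lapply(ledOrder, function(ln) {
    p <- planes[[ln]]
    if (is.null(p)) stop("missing LED plane: ", ln)
    rbind(as.vector(p[, , 1L]), as.vector(p[, , 2L]), as.vector(p[, , 3L]))
  })
  do.call(rbind, mats)
}

#' Unmix a single pixel signal
#'
#' Solves the bounded linear least-squares problem of the fingerprint
#' model: \eqn{\hat F = \arg\min_{F \ge 0} \|A F - S\|_2}, the
#' non-negativity bound reflecting that fluorochrome abundances are
#' physical quantities. Solved by the Lawson-Hanson active-set method;
#' rank-deficient passive sets fall back to the minimum-norm solution.
#'
#' @param s numeric signal vector, ordered as the rows of `A`
#' @param A a [FingerprintMatrix-class] or plain non-negative matrix
#' @return list with `abundance` (named, >= 0) and `residual`
#'   (\eqn{\|A \hat F - S\|_2})
#' @examples
#' A <- diag(3)
#' dimnames(A) <- list(paste0("r", 1:3), paste0("f", 1:3))
#' unmixPixel(c(1, 2, 3), A)$abundance
#' @export
unmixPixel <- function(s, A) {
  Am <- if (is(A, "FingerprintMatrix")) A@A else as.matrix(A)
  if (length(s) != nrow(Am))
    stop("signal length (", length(s), ") does not match fingerprint rows (",
         nrow(Am), ")")
  if (any(!is.finite(s)) || any(!is.finite(Am)))
    stop("non-finite input to unmixPixel")
  fit <- .nnls_batch(Am, matrix(as.numeric(s), ncol = 1L))
  list(abundance = setNames(fit$coef[, 1L], colnames(Am)),
       residual = fit$resid[1L])
}

#' Unmix a corrected image stack pixel-wise
#'
#' Applies [unmixPixel()] to every pixel of a dark- and
#' quench-corrected acquisition (this function performs no background
#' work itself). Pixels whose largest stacked signal falls below
#' `noiseFloor` may skip the solver and return zero abundances, which
#' speeds up sparse fields considerably.
#'
#' @param planes named list, LED -> height x width x 3 array of
#'   corrected signals, or a `CorrectedCycle` as returned by
#'   [quenchSubtract()]
#' @param A a [FingerprintMatrix-class]
#' @param noiseFloor optional scalar; pixels with all stacked signals
#'   below it are set to zero abundance without solving
#' @return list with `abundances` (named list of height x width
#'   matrices, one per fluorochrome) and `residual` (height x width
#'   matrix of per-pixel residual norms)
#' @export
unmixImage <- function(planes, A, noiseFloor = NULL) {
  if (is.list(planes) && !is.null(planes$planes)) planes <- planes$planes
  ri <- A@rowInfo
  leds <- unique(ri$led)
  missing <- setdiff(leds, names(planes))
  if (length(missing))
    stop("missing LED plane(s): ", paste(missing, collapse = ", "))
  d <- dim(planes[[leds[1L]]])
  S <- .stackSignal(planes, leds)
  n <- ncol(S)
  Fhat <- matrix(0, ncol(A@A), n)
  resid <- numeric(n)
  solveIdx <- seq_len(n)
  if (!is.null(noiseFloor)) {
    mx <- apply(S, 2L, max)
    solveIdx <- which(mx >= noiseFloor)
    resid[] <- sqrt(colSums(S^2))
  }
  if (length(solveIdx)) {
    fit <- .nnls_batch(A@A, S[, solveIdx, drop = FALSE])
    Fhat[, solveIdx] <- fit$coef
    resid[solveIdx] <- fit$resid
  }
  abundances <- lapply(seq_len(nrow(Fhat)), function(i)
    matrix(Fhat[i, ], d[1L], d[2L]))
  names(abundances) <- colnames(A@A)
  list(abundances = abundances,
       residual = matrix(resid, d[1L], d[2L]))
}

#' Write unmixed abundance images as TIFF
#'
#' One 32-bit single-channel TIFF per fluorochrome plus the residual
#' image, values scaled by a recorded factor into [0, 1].
#'
#' @param unmixed result of [unmixImage()]
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @return invisibly, the paths written (with the scale factor as the
#'   `scale` attribute)
#' @export
writeFluorImages <- function(unmixed, dir, prefix = "abundance") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  imgs <- c(unmixed$abundances, list(residual = unmixed$residual))
  scale <- max(1e-12, max(vapply(imgs, max, 0)))
  paths <- vapply(names(imgs), function(nm) {
    p <- file.path(dir, sprintf("%s_%s.tif", prefix, nm))
    tiff::writeTIFF(imgs[[nm]] / scale, p, bits.per.sample = 16L,
                    compression = "none")
    p
  }, character(1))
  jsonlite::write_json(list(scale = scale, images = as.list(paths)),
                       file.path(dir, sprintf("%s_scale.json", prefix)),
                       auto_unbox = TRUE, digits = NA)
  attr(paths, "scale") <- scale
  invisible(paths)
}
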