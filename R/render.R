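# ------------------------------------------------------- rasterization

# label matrices (nucleus / whole cell) for a scene; later cells win on
# the rare overlapping boundary pixels
.rasterizeScene <- function(scene) {
  h <- scene@height; w <- scene@width
  nuc <- matrix(0L, h, w); cell <- matrix(0L, h, w)
  cl <- scene@cells
  for (i in seq_len(nrow(cl))) {
    a <- cl$cellA[i]; b <- cl$cellB[i]
    r0 <- cl$row[i]; c0 <- cl$col[i]; th <- cl$theta[i]
    rr <- max(1L, floor(r0 - a)):min(h, ceiling(r0 + a))
    cc <- max(1L, floor(c0 - a)):min(w, ceiling(c0 + a))
    dr <- rep(rr - r0, times = length(cc))
    dc <- rep(cc - c0, each = length(rr))
    u <- dr * cos(th) + dc * sin(th)
    v <- -dr * sin(th) + dc * cos(th)
    inCell <- (u / a)^2 + (v / b)^2 <= 1
    inNuc <- (u / cl$nucA[i])^2 + (v / cl$nucB[i])^2 <= 1
    idx <- cbind(rep(rr, times = length(cc)), rep(cc, each = length(rr)))
    cell[idx[inCell, , drop = FALSE]] <- cl$id[i]
    nuc[idx[inNuc, , drop = FALSE]] <- cl$id[i]
  }
  list(nucleus = nuc, cell = cell)
}

# abundance image of one marker: nuclear markers live on the nucleus,
# the rest on the cytoplasmic ring (cell minus nucleus)
.markerImage <- function(scene, labs, marker, nuclear) {
  lev <- c(0, scene@markerLevels[, marker])
  lab <- if (nuclear) labs$nucleus else labs$cell
  img <- matrix(lev[lab + 1L], nrow(lab), ncol(lab))
  if (!nuclear) img[labs$nucleus > 0L] <- 0
  img
}

# default relative autofluorescence per stacked row: strongest under
# violet/blue excitation, fading toward the near infrared
.defaultAfProfile <- function(ledOrder) {
  base <- c(L385 = 1, L470 = 0.6, L567 = 0.3, L627 = 0.15, L720 = 0.05)
  p <- base[ledOrder]
  p[is.na(p)] <- 0.3
  rep(unname(p), each = 3L)
}

#' Noise model constructor
#'
#' Camera noise model of the simulator: Poisson (shot) noise on the
#' expected photon-proportional signal, then Gaussian read noise, then
#' a constant dark offset, with negative counts clamped at zero.
#' `quenchResidual` is the fraction of fluorochrome signal surviving a
#' quench step; it compounds across cycles.
#'
#' @param readNoiseSd Gaussian read-noise SD in counts (default 6)
#' @param darkOffset constant offset in counts (default 100)
#' @param shotNoise apply Poisson noise (default TRUE)
#' @param quenchResidual fraction in [0, 1) (default 0.02)
#' @param seed integer RNG seed
#' @return a [NoiseModel-class]
#' @export
noiseModel <- function(readNoiseSd = 6, darkOffset = 100,
                       shotNoise = TRUE, quenchResidual = 0.02,
                       seed = 1L) {
  obj <- new("NoiseModel", readNoiseSd = readNoiseSd,
             darkOffset = darkOffset, shotNoise = shotNoise,
             quenchResidual = quenchResidual, seed = as.integer(seed))
  validObject(obj)
  obj
}

.applyNoise <- function(expected, noise) {
  v <- expected
  if (noise@shotNoise) v[] <- rpois(length(v), pmax(v, 0))
  if (noise@readNoiseSd > 0)
    v <- v + rnorm(length(v), 0, noise@readNoiseSd)
  pmax(v + noise@darkOffset, 0)
}

# per-fluorochrome abundance images of one cycle, including the
# compounded residual carryover of earlier cycles' stains
.cycleAbundance <- function(scene, panel, cycle, fluorNames, labs,
                            residual) {
  imgs <- lapply(fluorNames, function(f)
    matrix(0, scene@height, scene@width))
  names(imgs) <- fluorNames
  if (cycle < 1L) return(imgs)
  for (k in seq_len(cycle)) {
    map <- panel@cycles[[k]]
    decay <- residual^(cycle - k)   # quenched (cycle - k) times
    if (decay == 0 && k < cycle) next
    for (fl in names(map)) {
      if (!(fl %in% fluorNames))
        stop("unknown fluorochrome in panel cycle ", k, ": ", fl)
      mk <- map[[fl]]
      if (!(mk %in% colnames(scene@markerLevels))) next
      nuclear <- mk %in% panel@nuclearMarkers
      imgs[[fl]] <- imgs[[fl]] +
        decay * .markerImage(scene, labs, mk, nuclear)
    }
  }
  imgs
}

#' Render one cycle's acquisition through the forward optical model
#'
#' Builds per-pixel true abundance images from the scene's cell
#' geometry and marker levels (plus residual carryover of earlier
#' cycles' stains and cellular autofluorescence), computes the expected
#' stacked signal S = A F per pixel, warps it by the cycle's stage
#' transform, and applies the camera noise model. The quenched
#' acquisition repeats the render with fluorochrome terms multiplied by
#' the quench residual fraction. `cycle = 0` produces the
#' autofluorescence-only reference stack.
#'
#' @param scene a [Scene-class]
#' @param panel a `CyclePanel`
#' @param cycle cycle index (0 = autofluorescence reference)
#' @param A a [FingerprintMatrix-class]
#' @param noise a [NoiseModel-class]
#' @param transform the cycle's [RigidTransform-class] (identity when
#'   NULL)
#' @param quench also render the post-quench acquisition (default TRUE
#'   for cycles >= 1)
#' @return an [AcquisitionStack-class] with `transformTruth` recorded
#' @examples
#' cfg <- defaultOpticalConfig()
#' A <- buildFingerprintMatrix(cfg)
#' sc <- generateScene(20, width = 192, height = 192, seed = 3)
#' stk <- renderAcquisition(sc, defaultPanel(), 1, A,
#'                          noiseModel(seed = 3))
#' stk
#' @export
renderAcquisition <- function(scene, panel, cycle, A,
                              noise = noiseModel(), transform = NULL,
                              quench = cycle >= 1L) {
  cycle <- as.integer(cycle)
  if (is.null(transform)) transform <- rigidTransform()
  d <- c(scene@height, scene@width)
  if (.outOfFrameFraction(d, transform) > 0.20)
    stop("transform pushes more than 20% of the frame out of bounds")
  ri <- A@rowInfo
  leds <- unique(ri$led)
  fluorNames <- colnames(A@A)
  labs <- .rasterizeScene(scene)
  afProfile <- if (length(scene@afProfile)) scene@afProfile
               else .defaultAfProfile(leds)
  afImg <- scene@autofluorescence * (labs$cell > 0L)
  Fimgs <- .cycleAbundance(scene, panel, cycle, fluorNames, labs,
                           noise@quenchResidual)
  inv <- invertTransform(transform)

  expectedPlanes <- function(scaleFluor) {
    Fm <- do.call(rbind, lapply(Fimgs, as.vector)) * scaleFluor
    S <- A@A %*% Fm + outer(afProfile, as.vector(afImg))
    lapply(seq_along(leds), function(li) {
      arr <- array(0, c(d, 3L))
      for (ch in 1:3) {
        plane <- matrix(S[(li - 1L) * 3L + ch, ], d[1L], d[2L])
        arr[, , ch] <- warpRigid(plane, inv, fill = 0)
      }
      arr
    })
  }

  set.seed((noise@seed + 1009L * cycle) %% .Machine$integer.max)
  stained <- lapply(expectedPlanes(1), .applyNoise, noise = noise)
  names(stained) <- leds
  quenched <- list()
  if (quench && cycle >= 1L) {
    quenched <- lapply(expectedPlanes(noise@quenchResidual), .applyNoise,
                       noise = noise)
    names(quenched) <- leds
  }
  dark <- .applyNoise(array(0, c(d, 3L)), noise)
  obj <- new("AcquisitionStack", cycleIndex = cycle, stained = stained,
             quenched = quenched, dark = dark,
             transformTruth = transform,
             meta = list(leds = leds, fluorochromes = fluorNames,
                         seed = noise@seed))
  validObject(obj)
  obj
}

#' Render a single-fluorochrome calibration bead slide
#'
#' Uniform discs, one fluorochrome per bead, cycled through the
#' fingerprint's fluorochromes; the basis of SNR and daily-calibration
#' checks. Bead ground truth (center, fluorochrome, intensity) is
#' stored in `meta$beads`.
#'
#' @param nBeads number of beads (>= 1)
#' @param beadIntensity named vector of expected counts per
#'   fluorochrome (scalar recycled over all fluorochromes)
#' @param A a [FingerprintMatrix-class]
#' @param noise a [NoiseModel-class]
#' @param width,height frame size (px)
#' @param radius bead radius (px)
#' @param seed RNG seed
#' @return an [AcquisitionStack-class]
#' @export
generateBeadSlide <- function(nBeads, beadIntensity = 300, A,
                              noise = noiseModel(quenchResidual = 0),
                              width = 512, height = 512, radius = 4,
                              seed = 1L) {
  stopifnot(nBeads >= 1)
  fluorNames <- colnames(A@A)
  if (is.null(names(beadIntensity)))
    beadIntensity <- setNames(rep_len(beadIntensity, length(fluorNames)),
                              fluorNames)
  set.seed(seed)
  margin <- radius + 2
  centers <- matrix(numeric(), 0L, 2L)
  attempts <- 0L
  while (nrow(centers) < nBeads) {
    if ((attempts <- attempts + 1L) > 500L * nBeads)
      stop("could not place ", nBeads, " beads; use a larger frame")
    cand <- c(runif(1, margin, height - margin),
              runif(1, margin, width - margin))
    if (nrow(centers) == 0L ||
        min((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >=
        (4 * radius)^2)
      centers <- rbind(centers, cand)
  }
  fl <- fluorNames[(seq_len(nBeads) - 1L) %% length(fluorNames) + 1L]
  Fimgs <- lapply(fluorNames, function(f) matrix(0, height, width))
  names(Fimgs) <- fluorNames
  rows <- rep(seq_len(height), times = width)
  cols <- rep(seq_len(width), each = height)
  for (i in seq_len(nBeads)) {
    inBead <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2 <=
      radius^2
    Fimgs[[fl[i]]][inBead] <- Fimgs[[fl[i]]][inBead] +
      beadIntensity[[fl[i]]]
  }
  leds <- unique(A@rowInfo$led)
  Fm <- do.call(rbind, lapply(Fimgs, as.vector))
  S <- A@A %*% Fm
  stained <- lapply(seq_along(leds), function(li) {
    arr <- array(0, c(height, width, 3L))
    for (ch in 1:3)
      arr[, , ch] <- matrix(S[(li - 1L) * 3L + ch, ], height, width)
    .applyNoise(arr, noise)
  })
  names(stained) <- leds
  dark <- .applyNoise(array(0, c(height, width, 3L)), noise)
  new("AcquisitionStack", cycleIndex = 1L, stained = stained,
      quenched = list(), dark = dark, transformTruth = rigidTransform(),
      meta = list(leds = leds,
                  beads = data.frame(row = centers[, 1],
                                     col = centers[, 2], fluorochrome = fl,
                                     intensity = beadIntensity[fl]),
                  radius = radius, seed = seed))
}

#' Simulate a defocus stack
#'
#' Produces an ordered stack of focal planes by Gaussian-defocusing a
#' structured in-focus image symmetrically around the true focus plane:
#' plane i is blurred with sigma = `blurPerUm * stepUm * |i -
#' focusIndex|` pixels.
#'
#' @param image in-focus image (matrix); defaults to a rendered DAPI
#'   field when a [Scene-class] is given
#' @param nPlanes number of planes (default 7)
#' @param stepUm axial step (default 150 um)
#' @param focusIndex index of the true focus plane (default middle)
#' @param blurPerUm defocus blur growth, px of sigma per um of defocus
#' @param noise optional [NoiseModel-class] for camera noise per plane
#' @return a [FocusStack-class]; the truth index is kept in the
#'   `focusIndex` attribute
#' @export
simulateFocusStack <- function(image, nPlanes = 7L, stepUm = 150,
                               focusIndex = (nPlanes + 1L) %/% 2L,
                               blurPerUm = 0.02, noise = NULL) {
  stopifnot(nPlanes >= 2L)
  planes <- lapply(seq_len(nPlanes), function(i) {
    s <- blurPerUm * stepUm * abs(i - focusIndex)
    img <- if (s > 0)
      as.matrix(EBImage::gblur(EBImage::Image(image), sigma = s))
    else image
    if (!is.null(noise)) {
      set.seed((noise@seed + i) %% .Machine$integer.max)
      img <- matrix(.applyNoise(img, noise), nrow(image), ncol(image))
    }
    img
  })
  obj <- new("FocusStack", planes = planes, stepUm = stepUm)
  attr(obj, "focusIndex") <- as.integer(focusIndex)
  obj
}
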