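# shared fixtures, built once per test run

.fx <- new.env(parent = emptyenv())

fxOptics <- function() {
  if (is.null(.fx$cfg)) .fx$cfg <- defaultOpticalConfig()
  .fx$cfg
}

fxFingerprint <- function() {
  if (is.null(.fx$A)) .fx$A <- buildFingerprintMatrix(fxOptics())
  .fx$A
}

noiselessModel <- function(seed = 1L) {
  noiseModel(readNoiseSd = 0, darkOffset = 0, shotNoise = FALSE,
             quenchResidual = 0, seed = seed)
}

# a small corrected + unmixed field with known truth (noiseless)
fxNoiselessField <- function(nCells = 30, side = 224, seed = 4) {
  key <- sprintf("field_%d_%d_%d", nCells, side, seed)
  if (is.null(.fx[[key]])) {
    A <- fxFingerprint()
    panel <- defaultPanel()
    sc <- generateScene(nCells, width = side, height = side, seed = seed)
    nz <- noiselessModel(seed)
    stk1 <- renderAcquisition(sc, panel, 1, A, nz)
    stk0 <- renderAcquisition(sc, panel, 0, A, nz)
    cc <- quenchSubtract(subtractDarkStack(stk1), subtractDarkStack(stk0))
    um <- unmixImage(cc$planes, A)
    .fx[[key]] <- list(scene = sc, panel = panel, A = A, corrected = cc,
                       unmixed = um,
                       labs = ChromaPlex:::.rasterizeScene(sc))
  }
  .fx[[key]]
}

# true abundance image of one cycle-1 fluorochrome
fxTrueAbundance <- function(field, fluor) {
  map <- field$panel@cycles[[1L]]
  mk <- map[[fluor]]
  ChromaPlex:::.markerImage(field$scene, field$labs, mk,
                            mk %in% field$panel@nuclearMarkers)
}

# single-fluorochrome control slide through the forward model
fxSingleStain <- function(fluor, A, noise, intensity = 3000,
                          nCells = 300, side = 512, seed = 5) {
  mk <- paste0("only_", fluor)
  expr <- list(ctrl = setNames(list(c(log(intensity), 0.25)), mk))
  sc <- generateScene(nCells, phenotypeMix = c(ctrl = 1), width = side,
                      height = side, expression = expr, markers = mk,
                      autofluorescence = 0, seed = seed)
  pan <- cyclePanel(list(setNames(c(mk, "DAPI"), c(fluor, "DAPI"))),
                    nuclearMarkers = "DAPI")
  renderAcquisition(sc, pan, 1, A, noise, quench = FALSE)
}

# exhaustive grid minimizer of ||A f - s|| over f in [0, fmax]^2:
# coarse pass over the full square, then a fine pass (the requested
# step) in a window around the coarse minimum wide enough to contain
# the global fine-grid minimizer of the convex objective even along an
# ill-conditioned valley (width grows with sqrt of the Hessian
# condition number)
gridNNLS2 <- function(A, s, fmax = 4, step = 1e-3) {
  Q <- crossprod(A); c2 <- crossprod(A, s)
  obj <- function(f1, f2) {
    o1 <- Q[1, 1] * f1^2 - 2 * c2[1] * f1
    o2 <- Q[2, 2] * f2^2 - 2 * c2[2] * f2
    outer(o1, o2, "+") + 2 * Q[1, 2] * outer(f1, f2)
  }
  coarse <- step * 25
  g <- seq(0, fmax, by = coarse)
  o <- obj(g, g)
  ix <- arrayInd(which.min(o), dim(o))
  w <- coarse * (2 + ceiling(sqrt(kappa(Q))))
  f1 <- seq(max(0, g[ix[1]] - w), min(fmax, g[ix[1]] + w), by = step)
  f2 <- seq(max(0, g[ix[2]] - w), min(fmax, g[ix[2]] + w), by = step)
  o <- obj(f1, f2)
  ix <- arrayInd(which.min(o), dim(o))
  c(f1[ix[1]], f2[ix[2]])
}

# constructed label masks: nRetained valid cells plus known violations
fxQcMasks <- function() {
  # 10 cells on a 24 x 250 canvas, 10x10 blocks spaced 25 px apart
  nuc <- matrix(0L, 24, 250)
  cell <- matrix(0L, 24, 250)
  for (i in 1:10) {
    c0 <- (i - 1L) * 25L + 5L
    cell[8:17, c0:(c0 + 9L)] <- i
    if (i <= 2) {                       # two nuclei -> multi_nucleus
      nuc[10:13, c0:(c0 + 2L)] <- 20L + 2L * i
      nuc[10:13, (c0 + 6L):(c0 + 9L)] <- 21L + 2L * i
    } else if (i <= 4) {                # nucleus larger than cell
      nuc[7:18, (c0 - 1L):(c0 + 10L)] <- i
    } else {                            # well-formed
      nuc[10:14, (c0 + 2L):(c0 + 6L)] <- i
    }
  }
  new("LabelMasks", nucleusLabels = nuc, cellLabels = cell,
      nucleusToCell = integer())
}
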