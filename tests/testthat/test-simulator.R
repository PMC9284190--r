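test_that("scene generation is seeded, bounded and phenotype-faithful", {
  expect_equal(nrow(generateScene(0, seed = 1)@cells), 0L)

  sc <- generateScene(200, width = 448, height = 448, seed = 1)
  sc2 <- generateScene(200, width = 448, height = 448, seed = 1)
  expect_identical(sc@cells, sc2@cells)
  expect_identical(sc@markerLevels, sc2@markerLevels)

  counts <- table(sc@cells$phenotype)
  # multinomial sampling error around the 70/30 mix
  expect_gt(counts[["tumor"]], 200 * 0.7 - 3 * sqrt(200 * 0.7 * 0.3))
  expect_lt(counts[["tumor"]], 200 * 0.7 + 3 * sqrt(200 * 0.7 * 0.3))

  # tumor cells express QUAD but never CD45; immune cells the reverse
  tumor <- sc@cells$phenotype == "tumor"
  expect_true(all(sc@markerLevels[tumor, c("HER2", "EpCAM", "MUC1",
                                           "EGFR")] > 0))
  expect_true(all(sc@markerLevels[tumor, "CD45"] == 0))
  expect_true(all(sc@markerLevels[!tumor, "CD45"] > 0))
  expect_true(all(sc@markerLevels[!tumor, "HER2"] == 0))

  # minimum-distance placement honored
  d <- as.matrix(dist(sc@cells[, c("row", "col")]))
  diag(d) <- Inf
  expect_gte(min(d), 20)
})

test_that("impossible placement densities fail with advice", {
  expect_error(generateScene(500, width = 64, height = 64, seed = 1),
               "larger frame")
})

test_that("the ground-truth table mirrors the scene", {
  sc <- generateScene(40, width = 256, height = 256, seed = 2)
  tt <- groundTruthTable(sc)
  expect_equal(nrow(tt), 40L)
  expect_true(all(tt$nucleus_area_px <= tt$cell_area_px))
  expect_true(all(tt$true.CD45[tt$phenotype == "tumor"] == 0))
  expect_equal(nrow(groundTruthTable(generateScene(0, seed = 1))), 0L)
})

test_that("rendering is linear and conserves expected counts", {
  A <- fxFingerprint()
  panel <- defaultPanel()
  sc <- generateScene(12, width = 160, height = 160, seed = 6,
                      autofluorescence = 0)
  nz <- noiselessModel(6)
  r1 <- renderAcquisition(sc, panel, 1, A, nz, quench = FALSE)
  sc2 <- sc
  sc2@markerLevels <- 2 * sc@markerLevels
  r2 <- renderAcquisition(sc2, panel, 1, A, nz, quench = FALSE)
  for (led in names(r1@stained))
    expect_equal(r2@stained[[led]], 2 * r1@stained[[led]],
                 tolerance = 1e-12)

  # conservation: total counts equal the sum of A F over pixels
  labs <- ChromaPlex:::.rasterizeScene(sc)
  map <- panel@cycles[[1L]]
  Fm <- do.call(rbind, lapply(names(map), function(fl)
    as.vector(ChromaPlex:::.markerImage(sc, labs, map[[fl]],
                                        map[[fl]] %in% panel@nuclearMarkers))))
  rownames(Fm) <- names(map)
  S <- fingerprint(A)[, names(map)] %*% Fm
  expect_equal(sum(unlist(r1@stained)), sum(S), tolerance = 1e-9)
})

test_that("an IgG control channel renders as background only", {
  A <- fxFingerprint()
  panel <- defaultPanel()
  sc <- generateScene(12, width = 160, height = 160, seed = 6,
                      autofluorescence = 0)
  stk <- renderAcquisition(sc, panel, 4, A,
                           noiselessModel(6), quench = FALSE)
  # cycle 4 is all-IgG: no cell expresses the IgG markers, so only the
  # DAPI counterstain is visible in its rows
  S <- ChromaPlex:::.stackSignal(stk@stained)
  dapiRows <- fingerprint(A)[, "DAPI"] > 1e-3
  expect_gt(max(S[dapiRows, ]), 100)
  expect_lt(max(S[!dapiRows, ]), 1)
})

test_that("quench residuals carry over and quenched planes scale accordingly", {
  A <- fxFingerprint()
  panel <- defaultPanel()
  sc <- generateScene(10, width = 128, height = 128, seed = 9,
                      autofluorescence = 0)
  res <- 0.1
  nm <- noiseModel(0, 0, FALSE, quenchResidual = res, seed = 9)
  r1 <- renderAcquisition(sc, panel, 1, A, nm)
  r2 <- renderAcquisition(sc, panel, 2, A, nm)
  # cycle 2 stained minus cycle 1 quenched equals cycle 2's fresh stains
  nmClean <- noiseModel(0, 0, FALSE, quenchResidual = 0, seed = 9)
  fresh2 <- renderAcquisition(sc, panel, 2, A, nmClean, quench = FALSE)
  for (led in names(r2@stained))
    expect_equal(r2@stained[[led]] - r1@quenched[[led]],
                 fresh2@stained[[led]], tolerance = 1e-9)
})

test_that("transforms that discard too much frame are rejected", {
  A <- fxFingerprint()
  sc <- generateScene(5, width = 96, height = 96, seed = 3)
  expect_error(renderAcquisition(sc, defaultPanel(), 1, A,
                                 noiselessModel(3),
                                 transform = rigidTransform(0, c(60, 0))),
               "out of bounds")
})

test_that("bead slides are deterministic and carry their truth", {
  A <- fxFingerprint()
  b1 <- generateBeadSlide(30, 300, A, noiseModel(seed = 2), seed = 2)
  b2 <- generateBeadSlide(30, 300, A, noiseModel(seed = 2), seed = 2)
  expect_identical(b1@stained, b2@stained)
  expect_equal(nrow(b1@meta$beads), 30L)
  expect_setequal(unique(b1@meta$beads$fluorochrome),
                  colnames(fingerprint(A)))
})
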