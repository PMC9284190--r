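# synthetic delta-like optics: one LED band, one passband, G-only sensor
.deltaOptics <- function() {
  g <- seq(400, 700, by = 1)
  led <- ledChannel("L470", gaussianSpectrum(g, 470, 5),
                    bandpassSpectrum(g, 460, 480))
  fl <- fluorochrome("FX", gaussianSpectrum(g, 470, 2),
                     gaussianSpectrum(g, 515, 2))
  penta <- pentaFilter(rbind(c(500, 530)),
                       bandpassSpectrum(g, 500, 530, transmission = 1))
  zero <- spectralCurve(g, rep(0, length(g)))
  sensor <- sensorResponse(r = zero, g = spectralCurve(g, rep(1, length(g))),
                           b = zero)
  list(led = led, fl = fl, penta = penta, sensor = sensor)
}

test_that("a narrow-band fluorochrome in one passband yields a single unit entry", {
  o <- .deltaOptics()
  col <- predictFingerprintColumn(o$fl, list(o$led), o$penta, o$sensor)
  expect_equal(unname(col["L470.G"]), 1)
  expect_equal(unname(col[names(col) != "L470.G"]), rep(0, 2))
})

test_that("fingerprint prediction is linear in brightness", {
  cfg <- fxOptics()
  f1 <- cfg@fluorochromes[[3L]]
  f2 <- fluorochrome(f1@name, f1@excitation, f1@emission,
                     2 * f1@brightness)
  c1 <- predictFingerprintColumn(f1, cfg@leds, cfg@penta, cfg@sensor,
                                 scale = FALSE)
  c2 <- predictFingerprintColumn(f2, cfg@leds, cfg@penta, cfg@sensor,
                                 scale = FALSE)
  expect_equal(c2, 2 * c1)
})

test_that("a fluorochrome invisible to the optics raises a named error", {
  o <- .deltaOptics()
  g <- seq(400, 700, by = 1)
  dark <- fluorochrome("GHOST", gaussianSpectrum(g, 470, 2),
                       gaussianSpectrum(g, 650, 2))   # emits between windows
  expect_error(predictFingerprintColumn(dark, list(o$led), o$penta,
                                        o$sensor), "GHOST")
})

test_that("AF555 under L567 shows strong red and green, dark L627/L720 rows", {
  A <- fingerprint(fxFingerprint())
  af555 <- A[, "AF555"]
  expect_gt(af555[["L567.R"]], 0.5)
  expect_gt(af555[["L567.G"]], 0.2)
  expect_lt(max(af555[grep("^L627|^L720", names(af555))]), 0.01)
})

test_that("the fingerprint matrix has the panel geometry and is well conditioned", {
  A <- fxFingerprint()
  expect_identical(dim(fingerprint(A)), c(15L, 6L))
  expect_lt(conditionNumber(A), 100)
  # regression pin for the shipped spectra (recomputed, not asserted
  # to printed precision elsewhere)
  expect_equal(conditionNumber(A), 1.2469, tolerance = 1e-3)
  cfg <- fxOptics()
  A1 <- buildFingerprintMatrix(cfg@fluorochromes[1L], cfg@leds[1L],
                               cfg@penta, cfg@sensor)
  expect_identical(dim(fingerprint(A1)), c(3L, 1L))
  expect_error(buildFingerprintMatrix(cfg@fluorochromes[c(1, 1)],
                                      cfg@leds, cfg@penta, cfg@sensor),
               "duplicate")
})

test_that("shrinking a penta passband never increases a fingerprint entry", {
  cfg <- fxOptics()
  g <- wavelengths(cfg@penta@transmission)
  pbNarrow <- cfg@penta@passbands
  pbNarrow[3L, ] <- c(585, 605)   # shrink the 595 window
  trans <- Reduce(`+`, apply(pbNarrow, 1L, function(w)
    curveValues(bandpassSpectrum(g, w[1], w[2])), simplify = FALSE))
  narrow <- pentaFilter(pbNarrow, spectralCurve(g, pmin(trans, 1)))
  for (fl in cfg@fluorochromes) {
    wide <- predictFingerprintColumn(fl, cfg@leds, cfg@penta,
                                     cfg@sensor, scale = FALSE)
    slim <- predictFingerprintColumn(fl, cfg@leds, narrow, cfg@sensor,
                                     scale = FALSE)
    expect_true(all(slim <= wide + 1e-12), label = fl@name)
  }
})

test_that("fingerprint CSV round-trips with labels and condition number", {
  A <- fxFingerprint()
  path <- withr::local_tempfile(fileext = ".csv")
  writeFingerprintCSV(A, path)
  back <- readFingerprintCSV(path)
  expect_equal(fingerprint(back), fingerprint(A), tolerance = 1e-12)
  expect_equal(conditionNumber(back), conditionNumber(A),
               tolerance = 1e-9)
})

test_that("single-stain estimation reproduces the generating matrix exactly without noise", {
  A <- fxFingerprint()
  fl <- colnames(fingerprint(A))
  stacks <- lapply(fl, fxSingleStain, A = A, noise = noiselessModel(5),
                   nCells = 60, side = 224)
  names(stacks) <- fl
  Ahat <- estimateFingerprint(stacks)
  expect_lt(max(abs(fingerprint(Ahat)[rownames(fingerprint(A)), fl] -
                    fingerprint(A))), 1e-6)
})

test_that("single-stain estimation edge cases error as specified", {
  A <- fxFingerprint()
  stk <- fxSingleStain("AF488", A, noiselessModel(5), nCells = 20,
                       side = 160)
  # all-dark stack: zero out every plane
  darkStk <- stk
  darkStk@stained <- lapply(stk@stained, function(p) p * 0)
  expect_error(estimateFingerprint(list(AF488 = darkStk)),
               "empty foreground|all-dark")
  expect_error(estimateFingerprint(list(stk)), "named list")
})

test_that("bleed-through fractions decompose to one and flag CF750 in the 681 window", {
  bt <- bleedthroughFraction(fxOptics())
  expect_true(all(bt >= 0 & bt <= 1))
  nominal <- attr(bt, "nominalWindow")
  inWin <- bt[cbind(seq_len(nrow(bt)), nominal)]
  expect_equal(unname(inWin + attr(bt, "outside")), rep(1, nrow(bt)))
  # near-infrared dye leaks into the adjacent 681 nm (AF647) window
  expect_gt(bt["CF750", "W681"], 1e-4)
  # a delta-like fluorochrome confined to one window has zero bleed
  o <- .deltaOptics()
  bt1 <- bleedthroughFraction(list(o$fl), o$penta, o$sensor)
  expect_equal(unname(attr(bt1, "outside")), 0, tolerance = 1e-6)
})
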