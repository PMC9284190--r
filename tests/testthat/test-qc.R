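test_that("SNR follows its definition and invariances", {
  img <- matrix(rnorm(10000, 10, 2), 100, 100)
  fg <- matrix(FALSE, 100, 100); fg[1:20, 1:20] <- TRUE
  bg <- matrix(FALSE, 100, 100); bg[60:100, 60:100] <- TRUE
  expect_lt(abs(snr(img, fg, bg)), 0.2)   # fg == bg level -> ~0
  k <- 3.7
  img2 <- img; img2[fg] <- img2[fg] + k * sd(img[bg])
  expect_equal(snr(img2, fg, bg), k, tolerance = 0.05)
  # invariance under an additive constant
  expect_equal(snr(img2 + 100, fg, bg), snr(img2, fg, bg))
  # degenerate background flagged
  flat <- matrix(5, 10, 10); flat[1, 1] <- 9
  fgm <- flat > 5; bgm <- !fgm
  expect_warning(v <- snr(flat, fgm, bgm), "flagged infinite")
  expect_identical(v, Inf)
  expect_error(snr(img, fg, fg), "overlap")
})

test_that("bead SNR matches the closed-form noise-model prediction", {
  A <- fxFingerprint()
  nm <- noiseModel(readNoiseSd = 6, darkOffset = 100, shotNoise = TRUE,
                   quenchResidual = 0, seed = 2)
  bs <- generateBeadSlide(120, 300, A, nm, seed = 2)
  dk <- subtractDarkStack(bs)
  raw <- dk@stained$L385[, , 3L]   # DAPI's brightest plane
  beads <- bs@meta$beads
  h <- nrow(raw); w <- ncol(raw)
  rows <- rep(seq_len(h), times = w); cols <- rep(seq_len(w), each = h)
  fg <- matrix(FALSE, h, w); bg <- matrix(TRUE, h, w)
  for (i in seq_len(nrow(beads))) {
    d2 <- (rows - beads$row[i])^2 + (cols - beads$col[i])^2
    if (beads$fluorochrome[i] == "DAPI")
      fg[d2 <= (bs@meta$radius - 1.2)^2] <- TRUE
    bg[d2 <= (bs@meta$radius + 4)^2] <- FALSE
  }
  measured <- snr(raw, fg, bg)
  # background is the clamped difference of two offset read-noise
  # draws: sd = sqrt(2) * readNoiseSd * sqrt(1/2 - 1/(2*pi))
  sdBg <- sqrt(2) * nm@readNoiseSd * sqrt(0.5 - 1 / (2 * pi))
  predicted <- 300 * fingerprint(A)["L385.B", "DAPI"] / sdBg
  expect_equal(measured, predicted, tolerance = 0.1)
})

test_that("CV uses the sample SD and matches seeded lognormal spread", {
  expect_equal(cvPercent(rep(4, 10)), 0)
  expect_equal(cvPercent(c(9, 11)), 100 * sd(c(9, 11)) / 10)
  expect_equal(round(cvPercent(c(9, 11)), 1), 14.1)
  expect_error(cvPercent(c(-1, 1)), "mean is zero")
  expect_error(cvPercent(3), "two values")
  set.seed(1)
  v <- rlnorm(5000, log(100), 0.04)
  expect_equal(cvPercent(v), 4, tolerance = 0.1)
  expect_equal(cvPercent(3.3 * v), cvPercent(v))
})

test_that("focus scoring is zero for flat fields and decreases under defocus", {
  expect_equal(focusScore(matrix(5, 32, 32)), 0)
  img <- fxNoiselessField()$unmixed$abundances$DAPI
  blurred <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = 2))
  expect_gt(focusScore(img), focusScore(blurred))
  # ranking invariant under linear intensity rescaling
  expect_equal(focusScore(3 * img + 7), focusScore(img),
               tolerance = 1e-9)
})

test_that("the best focal plane is selected from a noisy defocus stack", {
  A <- fxFingerprint()
  sc <- generateScene(60, width = 256, height = 256, seed = 9)
  stk <- renderAcquisition(sc, defaultPanel(), 1, A,
                           noiseModel(seed = 9))
  fs <- simulateFocusStack(dapiComposite(stk), noise = noiseModel(seed = 9))
  sel <- selectFocusPlane(fs)
  truth <- attr(fs, "focusIndex")
  expect_equal(sel$index, truth)
  expect_true(all(diff(sel$scores[seq_len(truth)]) > 0))
  expect_true(all(diff(sel$scores[truth:length(sel$scores)]) < 0))
  # two-plane stack picks the sharper plane; ties resolve low
  two <- new("FocusStack", planes = list(fs@planes[[1]],
                                         fs@planes[[truth]]),
             stepUm = 150)
  expect_equal(selectFocusPlane(two)$index, 2L)
  flat <- new("FocusStack",
              planes = list(matrix(1, 8, 8), matrix(2, 8, 8)),
              stepUm = 150)
  expect_equal(selectFocusPlane(flat)$index, 1L)
})

test_that("bead calibration passes at high SNR and fails per channel", {
  A <- fxFingerprint()
  nm <- noiseModel(readNoiseSd = 6, darkOffset = 100,
                   quenchResidual = 0, seed = 3)
  bs <- generateBeadSlide(90, 400, A, nm, seed = 3)
  rep1 <- calibrationCheck(bs, A)
  expect_true(rep1$pass)
  expect_setequal(names(rep1$channels), colnames(fingerprint(A)))
  for (ch in rep1$channels) expect_true(ch$pass)

  # noise-only slide: no beads
  blank <- generateBeadSlide(1, 0.001, A, nm, seed = 4)
  rep2 <- calibrationCheck(blank, A)
  expect_false(rep2$pass)

  # one LED's power halved: only the fluorochromes read out under that
  # LED lose SNR
  dimIntensity <- setNames(rep(400, 6), colnames(fingerprint(A)))
  dimIntensity["AF647"] <- 20
  bs3 <- generateBeadSlide(90, dimIntensity, A, nm, seed = 5)
  rep3 <- calibrationCheck(bs3, A, thresholds = list(minSnr = 30,
                                                     maxCv = 25))
  expect_false(rep3$channels$AF647$pass)
  expect_true(rep3$channels$AF488$pass)
  expect_true(rep3$channels$DAPI$pass)
})
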