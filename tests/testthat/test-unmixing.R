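.named <- function(m) {
  dimnames(m) <- list(paste0("r", seq_len(nrow(m))),
                      paste0("f", seq_len(ncol(m))))
  m
}

test_that("unmixing solves identity and consistent systems exactly", {
  A <- .named(diag(3))
  fit <- unmixPixel(c(1, 2, 3), A)
  expect_equal(unname(fit$abundance), c(1, 2, 3))
  expect_equal(fit$residual, 0)

  set.seed(7)
  for (i in 1:20) {
    Am <- .named(matrix(runif(12, 0.2, 1), 4, 3))
    fTrue <- runif(3, 0, 5)
    fit <- unmixPixel(as.vector(Am %*% fTrue), Am)
    expect_lt(max(abs(fit$abundance - fTrue)) / max(fTrue), 1e-9)
  }
})

test_that("the zero bound activates on negative signals", {
  A <- .named(matrix(1, 2, 1))
  fit <- unmixPixel(c(-1, -1), A)
  expect_equal(unname(fit$abundance), 0)
  expect_equal(fit$residual, sqrt(2))
})

test_that("unmixing errors on malformed input", {
  A <- .named(diag(3))
  expect_error(unmixPixel(c(1, 2), A), "does not match")
  expect_error(unmixPixel(c(1, NA, 3), A), "non-finite")
})

test_that("abundances are non-negative, optimal and scale-equivariant", {
  set.seed(11)
  for (i in 1:30) {
    A <- .named(matrix(runif(6, 0.1, 1), 3, 2))
    s <- rnorm(3)
    fit <- unmixPixel(s, A)
    f <- unname(fit$abundance)
    expect_true(all(f >= 0))
    # no non-negative perturbation improves the residual
    for (j in 1:20) {
      fp <- pmax(f + rnorm(2, 0, 0.05), 0)
      expect_gte(sqrt(sum((A %*% fp - s)^2)), fit$residual - 1e-10)
    }
    # positive rescaling of the signal rescales the solution
    c3 <- runif(1, 0.5, 3)
    expect_equal(unname(unmixPixel(c3 * s, A)$abundance), c3 * f,
                 tolerance = 1e-10)
  }
})

test_that("the solver agrees with an independent active-set implementation", {
  skip_if_not_installed("pracma")
  set.seed(13)
  for (i in 1:50) {
    A <- .named(matrix(runif(15, 0, 1), 5, 3))
    s <- rnorm(5, 1, 1)
    mine <- unmixPixel(s, A)$abundance
    ref <- pracma::lsqnonneg(A, s)$x
    expect_lt(max(abs(mine - ref)), 1e-8)
  }
})

test_that("image unmixing inverts a noiseless forward render exactly", {
  fx <- fxNoiselessField()
  for (fl in names(fx$panel@cycles[[1L]])) {
    tr <- fxTrueAbundance(fx, fl)
    est <- fx$unmixed$abundances[[fl]]
    sel <- tr > 1e-9
    expect_lt(max(abs(est[sel] - tr[sel]) / tr[sel]), 1e-6, label = fl)
  }
  expect_lt(max(fx$unmixed$residual), 1e-6)
})

test_that("a DAPI-only field leaves other abundance channels at zero", {
  A <- fxFingerprint()
  pan <- cyclePanel(list(c(DAPI = "DAPI")))
  sc <- generateScene(15, width = 160, height = 160, seed = 8,
                      markers = "DAPI", autofluorescence = 0)
  stk <- renderAcquisition(sc, pan, 1, A, noiselessModel(8),
                           quench = FALSE)
  um <- unmixImage(stk@stained, A)
  for (fl in setdiff(names(um$abundances), "DAPI"))
    expect_lt(max(um$abundances[[fl]]), 1e-8, label = fl)
  expect_gt(max(um$abundances$DAPI), 100)
})

test_that("image unmixing names a missing LED plane", {
  fx <- fxNoiselessField()
  planes <- fx$corrected$planes
  planes$L627 <- NULL
  expect_error(unmixImage(planes, fx$A), "L627")
})

test_that("the noise-floor fast path zeroes sub-floor pixels only", {
  fx <- fxNoiselessField()
  um <- unmixImage(fx$corrected$planes, fx$A, noiseFloor = 50)
  full <- fx$unmixed
  tot <- Reduce(`+`, um$abundances)
  totFull <- Reduce(`+`, full$abundances)
  bright <- totFull > 200
  expect_equal(tot[bright], totFull[bright], tolerance = 1e-9)
})
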