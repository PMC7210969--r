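planck <- 6.62607015e-34
muB <- 9.2740100783e-24
oracleField <- function(g, nuGHz) 1e3 * planck * nuGHz * 1e9 / (g * muB)

test_that("resonance fields follow the analytic resonance condition", {
  expect_equal(resonanceField(2.002319, 9.4), oracleField(2.002319, 9.4),
               tolerance = 1e-12)
  expect_equal(round(resonanceField(2.002319, 9.4), 1), 335.4)
  expect_equal(round(resonanceField(2.007, 9.4), 1), 334.6)
  # linear in frequency
  expect_equal(resonanceField(2.0, 18.8), 2 * resonanceField(2.0, 9.4))
  expect_error(resonanceField(-1, 9.4), "positive")
  expect_error(resonanceField(2, 0), "positive")
})

test_that("an isotropic tensor yields a symmetric line crossing at g_iso", {
  p <- acquisitionParams(9.4, linewidthG = 10, fieldStep = 0.005)
  sp <- powderSpectrum(gTensor(2.007), p)
  b0 <- oracleField(2.007, 9.4)
  # derivative zero-crossing at the resonance field within one field step
  ex <- order(intensity(sp))
  cross <- fieldAxis(sp)[which.max(intensity(sp))] +
    (fieldAxis(sp)[which.min(intensity(sp))] -
       fieldAxis(sp)[which.max(intensity(sp))]) / 2
  expect_lt(abs(cross - b0), 2 * p$fieldStep)
  expect_equal(effectiveG(sp), 2.007, tolerance = 5e-4)
})

test_that("simulate-measure round trip recovers g and width across the range", {
  for (g in c(1.95, 2.007, 2.10)) {
    for (lw in c(2, 10, 50)) {
      sp <- powderSpectrum(gTensor(g),
                           acquisitionParams(9.4, linewidthG = lw))
      expect_equal(effectiveG(sp), g, tolerance = 0.001 / g)
      expect_lt(abs(peakToPeakWidth(sp) - lw), 0.5)
    }
  }
  # lorentzian lineshape obeys the same pp-width convention
  spL <- powderSpectrum(gTensor(2.007),
                        acquisitionParams(9.4, linewidthG = 10,
                                          lineshape = "lorentzian"))
  expect_lt(abs(peakToPeakWidth(spL) - 10), 0.5)
})

test_that("axial powder absorption spans the principal-field interval", {
  tens <- gTensor(2.0050, 2.0050, 2.0023)
  p <- acquisitionParams(180, linewidthG = 10, mode = "absorption")
  sp <- powderSpectrum(tens, p)
  expect_true(all(intensity(sp) >= -1e-9))
  bPar <- oracleField(2.0023, 180)
  bPerp <- oracleField(2.0050, 180)
  support <- range(fieldAxis(sp)[intensity(sp) > 0.01])
  expect_gt(support[1], bPerp - 3)
  expect_lt(support[2], bPar + 3)
  # an over-narrow window is refused with the missing edge named
  expect_error(powderSpectrum(tens, acquisitionParams(180, 10,
                                                      fieldRange = c(6414, 6420))),
               "principal resonance")
})

test_that("orientation-grid refinement changes the spectrum by < 1 percent", {
  tens <- gTensor(2.0075, 2.0044, 2.0023)
  s1 <- powderSpectrum(tens, acquisitionParams(180, 10, gridSize = 64L))
  s2 <- powderSpectrum(tens, acquisitionParams(180, 10, gridSize = 128L))
  expect_lt(max(abs(intensity(s1) - intensity(s2))), 0.01)
})

test_that("derivative mode is the field-derivative of absorption mode", {
  tens <- gTensor(2.0050, 2.0050, 2.0023)
  pAbs <- acquisitionParams(94, 10, mode = "absorption")
  pDer <- acquisitionParams(94, 10, mode = "first_derivative")
  a <- powderSpectrum(tens, pAbs)
  d <- powderSpectrum(tens, pDer)
  num <- diff(intensity(a)) / diff(fieldAxis(a))
  numNorm <- num / max(abs(num))
  derAtMid <- (intensity(d)[-1] + intensity(d)[-length(intensity(d))]) / 2
  expect_lt(max(abs(numNorm - derAtMid / max(abs(derAtMid)))), 0.02)
})

test_that("derivative spectra integrate to zero over the sweep", {
  for (tens in list(gTensor(2.007), gTensor(2.0050, 2.0050, 2.0023))) {
    sp <- powderSpectrum(tens, acquisitionParams(9.4, 10))
    b <- fieldAxis(sp); y <- intensity(sp)
    integral <- sum(diff(b) * (y[-1] + y[-length(y)]) / 2)
    expect_lt(abs(integral), 1e-6 * max(abs(y)) * diff(range(b)))
  }
})

test_that("signal size is the max-minus-min intensity and scales linearly", {
  sp <- powderSpectrum(gTensor(2.007), acquisitionParams(9.4, 10))
  expect_equal(signalSize(sp), max(intensity(sp)) - min(intensity(sp)))
  doubled <- sp
  doubled@intensity <- 2 * sp@intensity
  expect_equal(signalSize(doubled), 2 * signalSize(sp))
  flat <- sp
  flat@intensity <- rep(0, length(sp@intensity))
  expect_equal(signalSize(flat), 0)
})

test_that("double integration is translation-invariant and drives spin counts", {
  sp <- powderSpectrum(gTensor(2.007), acquisitionParams(9.4, 10))
  shifted <- sp
  shifted@field <- sp@field + 5
  expect_equal(spinCount(sp, sp, 7), 7)
  expect_equal(spinCount(shifted, shifted, 7), 7)
  doubled <- sp
  doubled@intensity <- 2 * sp@intensity
  expect_equal(spinCount(doubled, sp, 10), 20, tolerance = 1e-9)
  other <- powderSpectrum(gTensor(2.007),
                          acquisitionParams(9.4, 10, fieldStep = 0.01))
  expect_error(spinCount(sp, other, 1), "field axes")
})

test_that("spline smoothing reduces the variance of a noisy constant", {
  set.seed(12)
  y <- rep(3, 200) + rnorm(200, sd = 0.3)
  sm <- smoothSeries(y, stiffness = 0.7)
  expect_lt(stats::var(sm), stats::var(y))
  expect_equal(mean(sm), mean(y), tolerance = 0.05)
})

test_that("spectra round-trip through two-column text", {
  sp <- powderSpectrum(gTensor(2.007), acquisitionParams(9.4, 10))
  f <- file.path(tempdir(), "spec.tsv")
  writeSpectrum(sp, f)
  back <- readSpectrum(f)
  expect_equal(fieldAxis(back), fieldAxis(sp), tolerance = 1e-9)
  expect_equal(intensity(back), intensity(sp), tolerance = 1e-9)
  expect_equal(back@params$frequencyGHz, 9.4)
})

test_that("g-tensor constructors validate and classify axiality", {
  expect_true(isAxial(dopaAnionGTensor()))
  expect_false(isAxial(gTensor(2.0075, 2.0044, 2.0023)))
  expect_false(isAxial(gTensor(2.007)))  # isotropic, not axial
  expect_error(gTensor(3.2), "sanity")
  expect_equal(unname(gValues(gTensor(2.01, 2.02, 2.03))),
               c(2.01, 2.02, 2.03))
})
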