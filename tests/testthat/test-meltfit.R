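makeMeltFile <- function(tC, sig, sep = ",", header = TRUE) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  lines <- paste(tC, sig, sep = sep)
  if (header) lines <- c(paste("temperature_C", "signal", sep = sep), lines)
  writeLines(lines, path)
  path
}

test_that("readMelt parses csv and tab dialects and sorts by temperature", {
  tC <- seq(10, 50, by = 0.1)
  sig <- signalFromFraction(wtModel(), tC)
  expect_equal(length(temperature(readMelt(makeMeltFile(tC, sig)))), 401L)
  tab <- readMelt(makeMeltFile(tC, sig, sep = "\t", header = FALSE))
  expect_equal(cdSignal(tab), sig)
  desc <- readMelt(makeMeltFile(rev(tC), rev(sig)))
  expect_equal(temperature(desc), tC)
  expect_equal(cdSignal(desc), sig)
})

test_that("readMelt rejects malformed input with a line number", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("10,0.1", "11", "12,0.3"), path)
  expect_error(readMelt(path), "line 2")
  writeLines(c("10,0.1", "11,abc", "12,0.3"), path)
  expect_error(readMelt(path), "line 2.*abc")
  writeLines("10,0.1", path)
  expect_error(readMelt(path), "at least 2")
})

test_that("minmax normalization recovers the generating fraction", {
  tC <- seq(10, 50, by = 0.1)
  cv <- MeltCurve(tC, signalFromFraction(wtModel(), tC))
  nm <- normalizeMelt(cv, smoothWindow = 0)
  expect_lt(max(abs(fraction(nm) - fractionUnfolded(wtModel(), tC))), 1e-3)
})

test_that("normalization is idempotent on an already 0-1 sigmoid", {
  tC <- seq(10, 50, by = 0.1)
  f <- fractionUnfolded(UnfoldingModel(tm = 30, dh = -1200), tC)
  f <- (f - min(f)) / (max(f) - min(f))
  nm <- normalizeMelt(MeltCurve(tC, f), smoothWindow = 0)
  expect_equal(fraction(nm), f, tolerance = 1e-12)
})

test_that("flat signal raises a degenerate-curve error", {
  tC <- seq(10, 50, by = 0.1)
  expect_error(normalizeMelt(MeltCurve(tC, rep(-5, length(tC)))),
               "degenerate")
})

test_that("linear baseline mode handles sloped baselines", {
  m <- UnfoldingModel(tm = 30, dh = -800, baselineFolded = c(-10, 0.02),
                      baselineUnfolded = c(-2, 0.01))
  tC <- seq(10, 50, by = 0.1)
  cv <- MeltCurve(tC, signalFromFraction(m, tC))
  nm <- normalizeMelt(cv, baselineMode = "linear", smoothWindow = 0)
  expect_lt(max(abs(fraction(nm) - fractionUnfolded(m, tC))), 0.02)
})

test_that("a melt that does not span the window is rejected", {
  tC <- seq(15, 50, by = 0.1)
  expect_error(normalizeMelt(MeltCurve(tC, tC)), "window")
})

test_that("derivative peaks at Tm for a noise-free single transition", {
  d <- meltToDerivative(wtModel())$deriv
  peakT <- temperature(d)[which.max(dfdT(d))]
  expect_lt(abs(peakT - 34.1), 0.1 + 1e-9)  # within one grid step
})

test_that("derivative of a linear fraction ramp is constant", {
  tC <- seq(10, 50, by = 0.1)
  nm <- new("NormalizedMelt", temperature = tC,
            fraction = (tC - 10) / 40, window = c(10, 50), meta = list())
  d <- firstDerivative(nm, smoothingWindow = 1)
  expect_equal(dfdT(d), rep(1 / 40, length(tC)), tolerance = 1e-9)
})

test_that("well-separated transitions give two derivative maxima", {
  d <- meltToDerivative(acDoubleModel())$deriv
  y <- dfdT(d)
  interior <- 2:(length(y) - 1)
  maxima <- interior[y[interior] > y[interior - 1] & y[interior] >= y[interior + 1]]
  expect_equal(length(maxima), 2L)
})

test_that("oversized smoothing window is a parameter error", {
  nm <- meltToDerivative(wtModel())$norm
  expect_error(firstDerivative(nm, smoothingWindow = 30), "half")
})

test_that("a pure Gaussian derivative is self-fit to high precision", {
  tC <- seq(10, 50, by = 0.1)
  y <- 1 / (3 * sqrt(2 * pi)) * exp(-(tC - 31.7)^2 / (2 * 3^2))
  d <- new("DerivativeCurve", temperature = tC, dfdT = y,
           smoothingWindow = 0, meta = list())
  g <- gaussians(fitGaussians(d, 1))
  expect_equal(g$mean, 31.7, tolerance = 1e-6)
  expect_equal(g$sd, 3, tolerance = 1e-5)
})

test_that("gaussian component areas are normalized to sum to 1", {
  for (model in list(wtModel(), acDoubleModel(), acE129KModel())) {
    d <- meltToDerivative(model)$deriv
    for (n in 1:2)
      expect_equal(sum(gaussians(fitGaussians(d, n))$area), 1,
                   tolerance = 1e-12)
  }
})

test_that("model selection keeps one component for clean single melts", {
  expect_identical(selectNComponents(meltToDerivative(wtModel())$deriv), 1L)
})

test_that("model selection resolves a noisy biphasic acetylated melt", {
  d <- meltToDerivative(acE129KModel(), noiseSd = 0.005, seed = 11)$deriv
  sel <- selectNComponents(d, details = TRUE)
  expect_identical(sel$n, 2L)
  # the criterion margin is decisive, not marginal
  expect_gt(diff(-sel$criterion$aicc), 50)
})

test_that("transitions one degree apart are reported as unresolvable", {
  m <- UnfoldingModel(tm = c(33.5, 34.5), dh = c(-400, -400),
                      amplitude = c(0.5, 0.5))
  d <- meltToDerivative(m)$deriv
  expect_identical(selectNComponents(d), 1L)
  # brute-force check: the two-component fit cannot separate the means
  g2 <- gaussians(fitGaussians(d, 2))
  expect_lt(abs(diff(g2$mean)), 2 * max(g2$sd))
})

test_that("van't Hoff fit is self-consistent on model-generated data", {
  p <- meltToDerivative(wtModel())
  fit <- fitVantHoff(p$norm, fitGaussians(p$deriv, 1))
  expect_lt(fitRSS(fit), 1e-10)
  expect_equal(transitions(fit)$tm, 34.1, tolerance = 1e-6)
  expect_equal(transitions(fit)$dh, -455.8, tolerance = 1e-4)
})

test_that("fits are invariant to the heating direction of the input", {
  tC <- seq(10, 50, by = 0.1)
  sig <- signalFromFraction(wtModel(), tC)
  fwd <- fitMeltCurve(MeltCurve(tC, sig))
  rev <- fitMeltCurve(MeltCurve(rev(tC), rev(sig)))
  expect_identical(transitions(fwd), transitions(rev))
})

test_that("noise-free round trips recover Tm within 0.3 C and dH within 2%", {
  set.seed(3)
  for (i in 1:8) {
    tm1 <- runif(1, 22, 34)
    tm2 <- tm1 + runif(1, 6, 14)
    a <- runif(1, 0.2, 0.8)
    dh <- -runif(2, 200, 600)
    two <- i %% 2 == 0
    m <- if (two) UnfoldingModel(tm = c(tm1, tm2), dh = dh,
                                 amplitude = c(a, 1 - a))
         else UnfoldingModel(tm = tm1, dh = dh[1])
    fit <- fitMeltCurve(simulateMelt(m, noiseSd = 0, seed = i)[[1]],
                        components = if (two) 2 else 1)
    tr <- transitions(fit)
    expect_lt(max(abs(tr$tm - transitions(m)$tm)), 0.3)
    expect_lt(max(abs(abs(tr$dh) - abs(transitions(m)$dh)) /
                    abs(transitions(m)$dh)), 0.02)
  }
})

test_that("median Tm error stays under 0.5 C at noise sd 0.01", {
  errs <- vapply(1:100, function(s) {
    d <- meltToDerivative(wtModel(), noiseSd = 0.01, seed = s)$deriv
    abs(gaussians(fitGaussians(d, 1))$mean[1] - 34.1)
  }, numeric(1))
  expect_lt(median(errs), 0.5)
})

test_that("selection never invents a second transition at noise sd 0.01", {
  picks <- vapply(1:100, function(s) {
    d <- meltToDerivative(wtModel(), noiseSd = 0.01, seed = s)$deriv
    selectNComponents(d)
  }, integer(1))
  expect_true(all(picks == 1L))
})

test_that("replicate averaging interpolates onto the first grid", {
  cvs <- simulateMelt(wtModel(), noiseSd = 0.01, seed = 5, replicates = 3)
  avg <- averageReplicates(cvs)
  expect_equal(temperature(avg), temperature(cvs[[1]]))
  # averaging reduces the residual noise roughly as 1/sqrt(3)
  clean <- signalFromFraction(wtModel(), temperature(avg))
  rAvg <- sd(cdSignal(avg) - clean)
  rOne <- sd(cdSignal(cvs[[1]]) - clean)
  expect_lt(rAvg, rOne)
})
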