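# shared fixtures: generating parameter sets and small pipeline shortcuts

wtModel <- function() UnfoldingModel(tm = 34.1, dh = -455.8)

# acetylated double-mutant: two transitions, 60/40 amplitude split
acDoubleModel <- function()
  UnfoldingModel(tm = c(29.2, 43.2), dh = c(-256.8, -466.2),
                 amplitude = c(0.6, 0.4))

acE129KModel <- function()
  UnfoldingModel(tm = c(29.3, 38.1), dh = c(-481.7, -403.6),
                 amplitude = c(0.6, 0.4))

# the eight single-transition parameter sets (0.5 M salt)
singleTransitionSets <- function() {
  data.frame(
    protein = c("WT", "A18T", "E129K", "E31K", "A18T-E31K",
                "AcWT", "AcA18T", "AcE31K"),
    tm = c(34.1, 29.3, 29.4, 32.2, 27.9, 35.4, 30.5, 35.9),
    dh = c(-455.8, -315.4, -331.1, -447.2, -276.0, -555.7, -342.3, -571.3))
}

# noise-free melt -> normalized + derivative, shared by many tests
meltToDerivative <- function(model, noiseSd = 0, seed = 1L,
                             smoothWindow = 1.0) {
  cv <- simulateMelt(model, noiseSd = noiseSd, seed = seed)[[1]]
  nm <- normalizeMelt(cv, smoothWindow = smoothWindow)
  list(norm = nm, deriv = firstDerivative(nm, smoothingWindow = smoothWindow))
}

# binding series generated at known truth, analysed with the known
# calibration ratio
recoverK50 <- function(k50, nHill = 1.5, densityNoiseCv = 0, seed = 1L,
                       stoichiometry = 4) {
  s <- simulateBinding(k50, nHill = nHill, densityNoiseCv = densityNoiseCv,
                       seed = seed, stoichiometry = stoichiometry)
  s <- saturationFromDensity(s,
         calibrationRatio = s@meta$truth$calibrationRatio)
  s <- freeTpm(s, stoichiometry = stoichiometry)
  fitHill(s)
}

# exhaustive grid search oracle for the Hill fit (thetaMax fixed),
# coarse pass then a fine pass at `step` resolution around the optimum
gridSearchHill <- function(free, theta, thetaMax = 1, step = 0.001) {
  sse <- function(k, n) {
    pred <- thetaMax * outer(free, n, function(f, nn) f^nn) /
      (outer(rep(1, length(free)), n, function(o, nn) k^nn) +
         outer(free, n, function(f, nn) f^nn))
    colSums((theta - pred)^2)
  }
  best <- c(k = NA, n = NA, sse = Inf)
  scan <- function(ks, ns) {
    for (k in ks) {
      s <- sse(k, ns)
      i <- which.min(s)
      if (s[i] < best["sse"]) best <<- c(k = k, n = ns[i], sse = s[i])
    }
  }
  scan(seq(0.05, 2 * max(free), by = 0.05), seq(0.2, 5, by = 0.05))
  ctr <- best
  scan(seq(max(step, ctr["k"] - 0.06), ctr["k"] + 0.06, by = step),
       seq(max(0.2, ctr["n"] - 0.06), ctr["n"] + 0.06, by = step))
  best
}
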