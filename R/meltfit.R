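## Melting-curve analysis: normalization to fraction unfolded, smoothed
## first derivative, Gaussian peak deconvolution, model selection, and the
## direct van't Hoff fit.

#' Read a CD melting trace from a delimited text file
#'
#' Accepts a two-column numeric table (temperature in degrees C, CD signal
#' at 222 nm) with an optional header, in comma-, tab- or
#' whitespace-delimited dialects. Rows are sorted by temperature and
#' duplicate temperatures averaged.
#'
#' @param path file path.
#' @param meta named list of metadata attached to the curve.
#' @return a [MeltCurve()].
#' @export
readMelt <- function(path, meta = list()) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) < 2L) stop("melt file needs at least 2 data rows", call. = FALSE)
  sep <- if (any(grepl(",", lines[keep]))) "," else
    if (any(grepl("\t", lines[keep]))) "\t" else "[[:space:]]+"
  parts <- lapply(strsplit(trimws(lines[keep]), sep), trimws)
  first <- suppressWarnings(as.numeric(parts[[1L]]))
  if (anyNA(first)) keep <- keep[-1L] else NULL  # header row
  parts <- lapply(strsplit(trimws(lines[keep]), sep), trimws)
  tC <- sig <- numeric(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 2L)
      stop(sprintf("line %d: expected 2 columns, found %d", keep[i], length(p)),
           call. = FALSE)
    v <- suppressWarnings(as.numeric(p[1:2]))
    if (anyNA(v))
      stop(sprintf("line %d: non-numeric value '%s'", keep[i],
                   p[1:2][is.na(v)][1L]), call. = FALSE)
    tC[i] <- v[1L]; sig[i] <- v[2L]
  }
  if (length(tC) < 2L) stop("melt file needs at least 2 data rows", call. = FALSE)
  MeltCurve(tC, sig, meta = meta)
}

## centered moving mean; the half-window shrinks symmetrically at the
## edges so linear signals are preserved exactly everywhere; k in points
.movingMean <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  w <- pmin(i - 1L, n - i, k %/% 2L)
  lo <- i - w
  hi <- i + w
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

.windowPoints <- function(temperatureC, windowC) {
  if (windowC <= 0) return(1L)
  dt <- stats::median(diff(temperatureC))
  k <- max(1L, round(windowC / dt))
  if (k %% 2L == 0L) k <- k + 1L
  as.integer(k)
}

## normalization core shared by normalizeMelt and the van't Hoff fitter so
## that model predictions are compared to data in the identical space
.normalizeVector <- function(values, temperatureC, window, mode, smoothWindow) {
  k <- .windowPoints(temperatureC, smoothWindow)
  sm <- .movingMean(values, k)
  inWin <- temperatureC >= window[1] - 1e-9 & temperatureC <= window[2] + 1e-9
  if (mode == "minmax") {
    lo <- min(sm[inWin]); hi <- max(sm[inWin])
    span <- hi - lo
    if (span <= max(abs(values)) * 1e-8 + 1e-300)
      stop("degenerate melt: signal is flat over the normalization window",
           call. = FALSE)
    # folded reference is the low-temperature end of the window
    startVal <- sm[which(inWin)[1L]]
    if (abs(startVal - hi) < abs(startVal - lo)) { tmp <- lo; lo <- hi; hi <- tmp }
    f <- (values - lo) / (hi - lo)
  } else {  # linear pre/post-transition baselines
    span <- window[2] - window[1]
    pre <- inWin & temperatureC <= window[1] + 0.15 * span
    post <- inWin & temperatureC >= window[2] - 0.15 * span
    bf <- stats::lm(values[pre] ~ temperatureC[pre])$coefficients
    bu <- stats::lm(values[post] ~ temperatureC[post])$coefficients
    bfT <- bf[1] + bf[2] * temperatureC
    buT <- bu[1] + bu[2] * temperatureC
    if (max(abs(buT - bfT)) <= max(abs(values)) * 1e-8 + 1e-300)
      stop("degenerate melt: folded and unfolded baselines coincide",
           call. = FALSE)
    f <- (values - bfT) / (buT - bfT)
  }
  pmin(pmax(f, 0), 1)
}

#' Normalize a melting trace to fraction of unfolded protein
#'
#' Rescales the 222 nm signal to the unfolded fraction over a normalization
#' window (default 10-50 degrees C). With \code{baselineMode = "minmax"}
#' the folded/unfolded references are the window extrema of a lightly
#' smoothed copy of the signal, with the low-temperature end taken as
#' folded; with \code{"linear"} they are linear baselines fitted to the
#' first and last 15 percent of the window. The result is clamped to
#' \[0, 1\].
#'
#' @param curve a [MeltCurve()] spanning the window.
#' @param window numeric length-2 normalization window, degrees C.
#' @param baselineMode \code{"minmax"} (default) or \code{"linear"}.
#' @param smoothWindow width (degrees C) of the moving-mean smoother used
#'   to locate the references; 0 disables smoothing.
#' @return a [NormalizedMelt-class] object.
#' @export
normalizeMelt <- function(curve, window = c(10, 50),
                          baselineMode = c("minmax", "linear"),
                          smoothWindow = 1.0) {
  stopifnot(is(curve, "MeltCurve"))
  baselineMode <- match.arg(baselineMode)
  t <- curve@temperature
  if (min(t) > window[1] + 1e-9 || max(t) < window[2] - 1e-9)
    stop(sprintf("melt (%.1f-%.1f C) does not span the %g-%g C window",
                 min(t), max(t), window[1], window[2]), call. = FALSE)
  f <- .normalizeVector(curve@signal, t, window, baselineMode, smoothWindow)
  meta <- curve@meta
  meta$normalization <- list(window = window, mode = baselineMode,
                             smoothWindow = smoothWindow)
  new("NormalizedMelt", temperature = t, fraction = f, window = window,
      meta = meta)
}

#' Smoothed first derivative of a normalized melt
#'
#' Applies a moving-mean smoother of the given width to the unfolded
#' fraction and differentiates by central differences (one-sided at the
#' endpoints). The derivative curve is the substrate for Gaussian
#' deconvolution of the melting transitions.
#'
#' @param norm a [NormalizedMelt-class] with at least 5 points.
#' @param smoothingWindow smoother width, degrees C; must be at least the
#'   grid spacing and no more than half the temperature span.
#' @return a [DerivativeCurve-class] object.
#' @export
firstDerivative <- function(norm, smoothingWindow = 1.0) {
  stopifnot(is(norm, "NormalizedMelt"))
  t <- norm@temperature
  if (length(t) < 5L) stop("need at least 5 points", call. = FALSE)
  span <- max(t) - min(t)
  if (smoothingWindow > span / 2)
    stop("smoothing window exceeds half the temperature span", call. = FALSE)
  sm <- .movingMean(norm@fraction, .windowPoints(t, smoothingWindow))
  n <- length(t)
  d <- numeric(n)
  d[1] <- (sm[2] - sm[1]) / (t[2] - t[1])
  d[n] <- (sm[n] - sm[n - 1]) / (t[n] - t[n - 1])
  i <- 2:(n - 1)
  d[i] <- (sm[i + 1] - sm[i - 1]) / (t[i + 1] - t[i - 1])
  new("DerivativeCurve", temperature = t, dfdT = d,
      smoothingWindow = smoothingWindow, meta = norm@meta)
}

## indices of local maxima, ranked by height; ties break toward lower T
.localMaxima <- function(y) {
  n <- length(y)
  idx <- which(vapply(seq_len(n), function(i) {
    left <- if (i > 1L) y[i] > y[i - 1L] else y[i] > y[i + 1L]
    right <- if (i < n) y[i] >= y[i + 1L] else TRUE
    left && right
  }, logical(1)))
  idx[order(-y[idx], idx)]
}

## greedy peak selection with an exclusion radius so that noise ripples on
## one transition cannot supply two starting means; endpoints are not peaks
.pickPeaks <- function(t, y, m, minSepC) {
  cand <- .localMaxima(y)
  cand <- cand[cand > 1L & cand < length(y)]
  if (!length(cand)) cand <- which.max(y)
  picked <- integer()
  for (i in cand) {
    if (all(abs(t[i] - t[picked]) >= minSepC)) picked <- c(picked, i)
    if (length(picked) == m) break
  }
  picked
}

.gaussSum <- function(tC, means, sds, areas) {
  out <- numeric(length(tC))
  for (i in seq_along(means))
    out <- out + areas[i] / (sds[i] * sqrt(2 * pi)) *
      exp(-(tC - means[i])^2 / (2 * sds[i]^2))
  out
}

#' Fit one or two Gaussian components to a derivative curve
#'
#' Nonlinear least squares of a sum of Gaussians (mean, sd, area per
#' component) to d(fraction)/dT. Initial means are placed on the highest
#' local maxima of the derivative (ties toward lower temperature); fitted
#' components are returned in ascending mean order with areas renormalized
#' to sum to 1. Each component's melting temperature is its mean, and a
#' peak-height enthalpy estimate |dH| = 4 R Tm^2 (height/area) is attached.
#'
#' @param deriv a [DerivativeCurve-class].
#' @param nComponents 1 or 2.
#' @param maxRestarts bounded deterministic restarts on non-convergence.
#' @return a [MeltFitResult-class] with the Gaussian part filled in.
#' @export
fitGaussians <- function(deriv, nComponents, maxRestarts = 4L) {
  stopifnot(is(deriv, "DerivativeCurve"), nComponents %in% 1:2)
  m <- as.integer(nComponents)
  t <- deriv@temperature
  y <- deriv@dfdT
  dt <- stats::median(diff(t))
  totalArea <- sum((y[-1] + y[-length(y)]) / 2 * diff(t))
  ## initial peaks are picked on a re-smoothed copy so that single noise
  ## spikes cannot seed a component; the fit itself uses the raw derivative
  kPick <- .windowPoints(t, max(deriv@smoothingWindow, 1))
  ySm <- .movingMean(y, kPick)
  peaks <- .pickPeaks(t, ySm, m, minSepC = max(2, 2 * deriv@smoothingWindow))
  init <- .gaussInit(t, ySm, peaks, m, totalArea)
  lower <- c(rep(min(t), m), rep(dt, m), rep(1e-6, m))
  upper <- c(rep(max(t), m), rep(max(t) - min(t), m), rep(2, m))
  fit <- NULL
  for (r in 0:maxRestarts) {
    start <- init
    if (r > 0) {  # deterministic spread of the starts
      start$means <- init$means + (r - (maxRestarts + 1) / 2) * dt * 5
      start$means <- pmin(pmax(start$means, min(t)), max(t))
    }
    p0 <- c(start$means, start$sds, start$areas)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0,
        fn = function(p) y - .gaussSum(t, p[1:m], p[m + 1:m], p[2 * m + 1:m]),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$info %in% 1:4) break
  }
  if (is.null(fit))
    stop("Gaussian fit failed to converge after restarts", call. = FALSE)
  p <- fit$par
  means <- p[1:m]; sds <- p[m + 1:m]; areas <- p[2 * m + 1:m]
  o <- order(means)
  means <- means[o]; sds <- sds[o]; areas <- areas[o]
  heights <- areas / (sds * sqrt(2 * pi))
  normArea <- areas / sum(areas)
  gauss <- data.frame(mean = means, sd = sds, area = normArea,
                      height = heights)
  dh <- -.dhFromPeak(means, heights / normArea)
  tr <- data.frame(tm = means, dh = dh, amplitude = normArea)
  new("MeltFitResult", transitions = tr, nComponents = m, gaussians = gauss,
      rss = sum(fit$fvec^2), modelSelection = list(),
      flags = if (any(abs(sds - dt) < 1e-9)) "sd-at-lower-bound" else character(),
      meta = deriv@meta)
}

.gaussInit <- function(t, y, peaks, m, totalArea) {
  dt <- stats::median(diff(t))
  if (length(peaks) >= m) {
    means <- sort(t[peaks[seq_len(m)]])
  } else {
    base <- if (length(peaks)) t[peaks[1L]] else t[which.max(y)]
    means <- sort(c(base, base + 5))[seq_len(m)]
  }
  h <- pmax(stats::approx(t, y, xout = means)$y, max(y) * 0.05)
  areas <- rep(max(totalArea, 0.1) / m, m)
  sds <- pmin(pmax(areas / (h * sqrt(2 * pi)), dt), (max(t) - min(t)) / 4)
  list(means = means, sds = sds, areas = areas)
}

## small-sample-corrected information criterion from a least-squares fit
.aicc <- function(rss, n, k) {
  rss <- max(rss, n * 1e-24)  # floor keeps noise-free fits finite
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

#' Choose between one and two melting transitions
#'
#' Fits one- and two-Gaussian models to the derivative curve and returns 2
#' only when the two-component fit improves a small-sample-corrected
#' information criterion by more than \code{threshold} AND the two fitted
#' means are separated by more than twice the larger component sd;
#' otherwise 1. Both criteria together keep the selector conservative on
#' noisy single-transition melts.
#'
#' @param deriv a [DerivativeCurve-class].
#' @param threshold required criterion improvement (default 10).
#' @param details if TRUE, return a list with the decision, both fits and
#'   the criterion table instead of a bare integer.
#' @return 1 or 2 (or a detail list).
#' @export
selectNComponents <- function(deriv, threshold = 10, details = FALSE) {
  fit1 <- tryCatch(fitGaussians(deriv, 1L), error = function(e) e)
  fit2 <- tryCatch(fitGaussians(deriv, 2L), error = function(e) e)
  if (inherits(fit1, "error") && inherits(fit2, "error"))
    stop("both one- and two-component fits failed", call. = FALSE)
  ## smoothing correlates neighbouring derivative points, so the criterion
  ## is computed at the effective sample size n / (smoothing points)
  n <- length(deriv@temperature)
  k <- .windowPoints(deriv@temperature, deriv@smoothingWindow)
  nEff <- max(round(n / k), 10L)
  a1 <- if (inherits(fit1, "error")) Inf else .aicc(fit1@rss * nEff / n, nEff, 4L)
  a2 <- if (inherits(fit2, "error")) Inf else .aicc(fit2@rss * nEff / n, nEff, 7L)
  sep <- if (inherits(fit2, "error")) 0 else {
    g <- fit2@gaussians
    abs(diff(g$mean)) > 2 * max(g$sd)
  }
  choice <- if (!inherits(fit2, "error") && (a1 - a2) > threshold && sep) 2L else 1L
  if (inherits(fit1, "error") && choice == 1L)
    stop("one-component fit failed and two components are not supported by the data",
         call. = FALSE)
  if (!details) return(choice)
  list(n = choice, fit1 = fit1, fit2 = fit2,
       criterion = data.frame(nComponents = 1:2, aicc = c(a1, a2),
                              rss = c(if (inherits(fit1, "error")) NA else fit1@rss,
                                      if (inherits(fit2, "error")) NA else fit2@rss)),
       separationOK = sep, threshold = threshold)
}

#' Direct van't Hoff fit of a normalized melting curve
#'
#' Fits the amplitude-weighted sum of one or two two-state van't Hoff
#' transitions directly to the unfolded-fraction data by bounded
#' Levenberg-Marquardt least squares, initialized from a Gaussian
#' deconvolution (Tm from the means, amplitudes from the areas, |dH| from
#' the peak heights via |dH| = 4 R Tm^2 height/area). Because the data were
#' min-max normalized over a finite window, the model prediction is passed
#' through the identical normalization before residuals are formed, so a
#' melt generated by the model is recovered exactly. Enthalpies are
#' reported with the negative sign convention used for these CD melts.
#'
#' @param norm the [NormalizedMelt-class] being fitted.
#' @param init a [MeltFitResult-class] from [fitGaussians()] supplying
#'   starting values (and the component count unless overridden).
#' @param nComponents optional override of the component count.
#' @param dhBounds allowed |dH| range, kJ/mol; estimates pinned at a bound
#'   are flagged on the result.
#' @return a [MeltFitResult-class] with the thermodynamic part filled in.
#' @export
fitVantHoff <- function(norm, init, nComponents = NULL,
                        dhBounds = c(50, 1500)) {
  stopifnot(is(norm, "NormalizedMelt"), is(init, "MeltFitResult"))
  m <- if (is.null(nComponents)) init@nComponents else as.integer(nComponents)
  stopifnot(m %in% 1:2)
  t <- norm@temperature
  y <- norm@fraction
  nz <- norm@meta$normalization
  if (is.null(nz))
    nz <- list(window = norm@window, mode = "minmax", smoothWindow = 1.0)
  tr0 <- init@transitions
  tm0 <- tr0$tm[seq_len(min(m, nrow(tr0)))]
  dh0 <- pmin(pmax(abs(tr0$dh[seq_len(min(m, nrow(tr0)))]), dhBounds[1]),
              dhBounds[2])
  if (length(tm0) < m) { tm0 <- c(tm0, tm0 + 8)[1:m]; dh0 <- rep(dh0, m)[1:m] }
  a0 <- if (m == 2L) min(max(tr0$amplitude[1], 0.05), 0.95) else numeric()
  predict <- function(p) {
    o <- order(p[1:m])
    tm <- p[1:m][o]
    dh <- p[m + 1:m][o]
    amp <- if (m == 2L) c(p[2 * m + 1], 1 - p[2 * m + 1])[o] else 1
    if (m == 2L && tm[2] - tm[1] < 1e-6) tm[2] <- tm[1] + 1e-6
    mod <- UnfoldingModel(tm = tm, dh = -dh, amplitude = amp)
    f <- fractionUnfolded(mod, t)
    .normalizeVector(f, t, nz$window, nz$mode, nz$smoothWindow)
  }
  p0 <- c(tm0, dh0, a0)
  lower <- c(rep(min(t), m), rep(dhBounds[1], m), if (m == 2L) 0.02)
  upper <- c(rep(max(t), m), rep(dhBounds[2], m), if (m == 2L) 0.98)
  fit <- minpack.lm::nls.lm(par = p0, fn = function(p) y - predict(p),
                            lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- fit$par
  tm <- p[1:m]; dh <- p[m + 1:m]
  amp <- if (m == 2L) c(p[2 * m + 1], 1 - p[2 * m + 1]) else 1
  o <- order(tm)
  tr <- data.frame(tm = tm[o], dh = -dh[o], amplitude = amp[o])
  flags <- character()
  if (any(dh <= dhBounds[1] + 1e-6) || any(dh >= dhBounds[2] - 1e-6))
    flags <- "dh-at-bound"
  new("MeltFitResult", transitions = tr, nComponents = m,
      gaussians = init@gaussians, rss = sum(fit$fvec^2),
      modelSelection = init@modelSelection, flags = flags, meta = norm@meta)
}

#' Average replicate melting traces onto a common grid
#'
#' Linearly interpolates each replicate onto the first replicate's
#' temperature grid and takes the pointwise mean, mirroring the averaging
#' of repeated unfolding profiles before analysis.
#'
#' @param curves list of [MeltCurve()] replicates.
#' @return a single averaged [MeltCurve()].
#' @export
averageReplicates <- function(curves) {
  stopifnot(length(curves) >= 1L, all(vapply(curves, is, logical(1), "MeltCurve")))
  if (length(curves) == 1L) return(curves[[1L]])
  t0 <- curves[[1L]]@temperature
  sigs <- vapply(curves, function(cv)
    stats::approx(cv@temperature, cv@signal, xout = t0, rule = 2)$y,
    numeric(length(t0)))
  meta <- curves[[1L]]@meta
  meta$replicate <- "average"
  meta$nReplicates <- length(curves)
  MeltCurve(t0, rowMeans(sigs), meta = meta)
}

#' Full melting-curve analysis of one protein
#'
#' Convenience wrapper running replicate averaging, normalization, smoothed
#' differentiation, component-count selection (or a fixed count), Gaussian
#' deconvolution and the direct van't Hoff fit.
#'
#' @param curves a [MeltCurve()] or list of replicate curves.
#' @param window normalization window, degrees C.
#' @param baselineMode passed to [normalizeMelt()].
#' @param smoothWindow smoothing width for normalization references and the
#'   derivative, degrees C.
#' @param components \code{"auto"}, 1 or 2.
#' @param selectionThreshold criterion threshold for [selectNComponents()].
#' @return a [MeltFitResult-class] whose \code{modelSelection} records the
#'   criterion table and options in effect.
#' @examples
#' wt <- UnfoldingModel(tm = 34.1, dh = -455.8)
#' curve <- simulateMelt(wt, noiseSd = 0, seed = 1)[[1]]
#' fitMeltCurve(curve)
#' @export
fitMeltCurve <- function(curves, window = c(10, 50),
                         baselineMode = "minmax", smoothWindow = 1.0,
                         components = "auto", selectionThreshold = 10) {
  if (is(curves, "MeltCurve")) curves <- list(curves)
  avg <- averageReplicates(curves)
  norm <- normalizeMelt(avg, window = window, baselineMode = baselineMode,
                        smoothWindow = smoothWindow)
  deriv <- firstDerivative(norm, smoothingWindow = smoothWindow)
  selInfo <- NULL
  if (identical(components, "auto")) {
    selInfo <- selectNComponents(deriv, threshold = selectionThreshold,
                                 details = TRUE)
    m <- selInfo$n
    g <- if (m == 1L) selInfo$fit1 else selInfo$fit2
    if (inherits(g, "error")) g <- fitGaussians(deriv, m)
  } else {
    m <- as.integer(components)
    g <- fitGaussians(deriv, m)
  }
  fit <- fitVantHoff(norm, g, nComponents = m)
  fit@modelSelection <- list(
    criterion = if (!is.null(selInfo)) selInfo$criterion else NULL,
    threshold = selectionThreshold,
    options = list(window = window, baselineMode = baselineMode,
                   smoothWindow = smoothWindow, components = components))
  fit
}
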