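## Actin-tropomyosin co-sedimentation analysis: densitometry to fractional
## saturation, free-ligand depletion correction, and the Hill fit for K50.

#' Fractional saturation from pellet band densities
#'
#' The ratio of the tropomyosin to the actin pellet band density estimates
#' the fractional saturation of actin; dividing by the ratio at full
#' saturation (the calibration ratio) puts it on a 0-1 scale. With
#' \code{calibrationRatio = "auto"} the mean ratio of the two highest
#' tropomyosin concentrations is used as the apparent plateau.
#'
#' @param series a [BindingSeries()] with band densities.
#' @param calibrationRatio positive number, or \code{"auto"}.
#' @return the series with its \code{theta} slot filled (clamped to
#'   \[0, 1\]).
#' @export
saturationFromDensity <- function(series, calibrationRatio = "auto") {
  stopifnot(is(series, "BindingSeries"))
  dA <- series@densityActin
  dT <- series@densityTpm
  if (!length(dA) || !length(dT))
    stop("band densities are required", call. = FALSE)
  if (any(dA <= 0))
    stop("actin band densities must be positive", call. = FALSE)
  if (any(dT < 0))
    stop("tropomyosin band densities must be non-negative", call. = FALSE)
  ratio <- dT / dA
  if (identical(calibrationRatio, "auto")) {
    top <- order(series@tpmTotal, decreasing = TRUE)[1:2]
    calibrationRatio <- mean(ratio[top])
    if (!is.finite(calibrationRatio) || calibrationRatio <= 0)
      stop("no saturation plateau detectable; supply calibrationRatio",
           call. = FALSE)
  }
  stopifnot(is.numeric(calibrationRatio), calibrationRatio > 0)
  series@theta <- pmin(pmax(ratio / calibrationRatio, 0), 1)
  series@meta$calibrationRatio <- calibrationRatio
  validObject(series)
  series
}

#' Free tropomyosin concentration by bound subtraction
#'
#' Subtracts the actin-bound tropomyosin from the total:
#' \code{free = tpmTotal - theta * actinTotal / stoichiometry}, floored at
#' zero, where \code{stoichiometry} is the number of actin monomers bound
#' per tropomyosin dimer (default 4, appropriate for a short yeast
#' tropomyosin spanning four actin subunits).
#'
#' @param series a [BindingSeries()] with \code{theta} computed.
#' @param stoichiometry actin monomers per bound tropomyosin dimer (>= 1).
#' @return the series with its \code{free} slot filled.
#' @export
freeTpm <- function(series, stoichiometry = 4) {
  stopifnot(is(series, "BindingSeries"), stoichiometry >= 1)
  if (!length(series@theta))
    stop("theta must be computed first (saturationFromDensity)", call. = FALSE)
  capacity <- series@actinTotal / stoichiometry
  free <- series@tpmTotal - series@theta * capacity
  if (any(free < -0.05 * capacity))
    warning("negative free concentrations beyond noise tolerance; ",
            "check the saturation calibration", call. = FALSE)
  series@free <- pmax(free, 0)
  series@meta$stoichiometry <- stoichiometry
  validObject(series)
  series
}

.hillTheta <- function(free, k50, n, thetaMax) {
  thetaMax * free^n / (k50^n + free^n)
}

#' Fit the Hill equation to a binding series
#'
#' Bounded least squares of
#' \eqn{\theta = \theta_{max} \, free^n / (K_{50}^n + free^n)} against the
#' fractional-saturation data, yielding the free tropomyosin concentration
#' at half saturation (K50, uM), the Hill cooperativity coefficient and the
#' plateau. The K50 standard error comes from the fit covariance.
#'
#' @param series a [BindingSeries()] with \code{theta} and \code{free}
#'   computed (at least 5 points sampling both sides of half saturation).
#' @param fixThetaMax optionally fix the plateau instead of fitting it
#'   (bounded at 1.05 when fitted).
#' @return a [HillFit-class] object.
#' @export
fitHill <- function(series, fixThetaMax = NULL) {
  stopifnot(is(series, "BindingSeries"))
  th <- series@theta
  fr <- series@free
  if (!length(th) || !length(fr))
    stop("theta and free must be computed before fitting", call. = FALSE)
  rng <- diff(range(th))
  if (rng < 0.2)
    stop("unidentifiable series: saturation does not traverse a transition",
         call. = FALSE)
  fitMax <- is.null(fixThetaMax)
  halfIdx <- which.min(abs(th - max(th) / 2))
  k0 <- max(fr[halfIdx], 1e-3)
  p0 <- c(log(k0), log(1.2), if (fitMax) min(max(max(th), 0.2), 1.04))
  lower <- c(log(1e-6), log(0.2), if (fitMax) 0.05)
  upper <- c(log(10 * max(fr)), log(10), if (fitMax) 1.05)
  fn <- function(p) {
    tm <- if (fitMax) p[3] else fixThetaMax
    th - .hillTheta(fr, exp(p[1]), exp(p[2]), tm)
  }
  fit <- minpack.lm::nls.lm(par = p0, fn = fn, lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  k50 <- exp(fit$par[1])
  n <- exp(fit$par[2])
  tmax <- if (fitMax) fit$par[3] else fixThetaMax
  ## delta-method SE of k50 from the covariance of log(k50)
  npar <- length(fit$par)
  dof <- max(length(th) - npar, 1L)
  s2 <- sum(fit$fvec^2) / dof
  cov <- tryCatch(s2 * solve(fit$hessian / 2), error = function(e) NULL)
  seK50 <- if (is.null(cov) || !is.finite(cov[1, 1]) || cov[1, 1] < 0) NA_real_
           else k50 * sqrt(cov[1, 1])
  thetaFit <- .hillTheta(fr, k50, n, tmax)
  new("HillFit", k50 = k50, nHill = n, thetaMax = tmax,
      seK50 = seK50, rss = sum(fit$fvec^2),
      curve = data.frame(free = fr, theta = th, thetaFit = thetaFit),
      flags = character())
}

#' Read a co-sedimentation table
#'
#' Reads a CSV with columns \code{tpm_total_uM}, \code{density_tpm_pellet},
#' \code{density_actin_pellet} (or precomputed \code{theta} and
#' \code{free_uM} columns to bypass the densitometry stages).
#'
#' @param path CSV file path.
#' @param actinTotal fixed total actin concentration, uM.
#' @param meta metadata list.
#' @return a [BindingSeries()].
#' @export
readBindingSeries <- function(path, actinTotal = 10, meta = list()) {
  df <- utils::read.csv(path)
  if (!"tpm_total_uM" %in% names(df))
    stop("binding table needs a tpm_total_uM column", call. = FALSE)
  BindingSeries(
    actinTotal = actinTotal,
    tpmTotal = df$tpm_total_uM,
    densityTpm = if ("density_tpm_pellet" %in% names(df))
      df$density_tpm_pellet else numeric(),
    densityActin = if ("density_actin_pellet" %in% names(df))
      df$density_actin_pellet else numeric(),
    theta = if ("theta" %in% names(df)) df$theta else numeric(),
    free = if ("free_uM" %in% names(df)) df$free_uM else numeric(),
    meta = meta)
}
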