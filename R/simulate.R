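## Seeded synthetic-data generators: CD melt traces, co-sedimentation
## densitometry series, and register-bearing coiled-coil sequences with
## known ground truth.

#' Simulate CD melting traces
#'
#' Evaluates the forward van't Hoff model on a temperature grid and adds
#' iid Gaussian noise in raw-signal units. Replicate r is seeded with
#' \code{seed + r}, so each replicate is independent yet the whole set is
#' reproducible from one integer.
#'
#' @param model an [UnfoldingModel()].
#' @param grid numeric \code{c(from, to, by)} temperature grid, degrees C
#'   (default 10-50 at 0.1, emulating a continuously sampled 1 C/min
#'   scan).
#' @param noiseSd Gaussian noise sd in raw-signal units (0 = noise-free).
#' @param seed integer base seed.
#' @param replicates number of replicate curves.
#' @param meta metadata attached to each curve.
#' @return list of [MeltCurve()] objects (replicate id in \code{meta}).
#' @export
simulateMelt <- function(model, grid = c(10, 50, 0.1), noiseSd = 0.005,
                         seed = 1L, replicates = 1L, meta = list()) {
  stopifnot(is(model, "UnfoldingModel"), grid[3] > 0, noiseSd >= 0)
  tC <- seq(grid[1], grid[2], by = grid[3])
  clean <- signalFromFraction(model, tC)
  lapply(seq_len(replicates), function(r) {
    eps <- if (noiseSd > 0) {
      set.seed(as.integer(seed) + r)
      stats::rnorm(length(tC), 0, noiseSd)
    } else 0
    m <- meta
    m$replicate <- r
    MeltCurve(tC, clean + eps, meta = m)
  })
}

## mass-balance fixed point: free + theta(free) * capacity = total,
## monotone in free, solved by bisection
.solveFree <- function(total, capacity, k50, n, thetaMax, tol = 1e-12) {
  lo <- 0; hi <- total
  g <- function(fr) fr + .hillTheta(fr, k50, n, thetaMax) * capacity - total
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Simulate a co-sedimentation binding series
#'
#' For each total tropomyosin concentration the self-consistent free
#' concentration is obtained by solving the mass balance
#' \code{free = total - theta(free) * actinTotal / stoichiometry} (with
#' theta the Hill isotherm) by bisection to 1e-9 uM. Band densities are
#' emitted as a constant actin density and
#' \code{densityTpm = theta * calibrationRatio * densityActin} with
#' multiplicative Gaussian noise of the given coefficient of variation.
#' The noise-free ground truth (\code{theta}, \code{free}) is stored on
#' the returned series.
#'
#' @param k50 generating half-saturation constant, uM.
#' @param nHill generating Hill coefficient.
#' @param thetaMax generating plateau saturation.
#' @param actinTotal total actin, uM.
#' @param stoichiometry actin monomers per bound tropomyosin dimer.
#' @param tpmTotals ascending total tropomyosin concentrations, uM
#'   (default: 10 points log-spaced over 0.2-16 uM).
#' @param densityNoiseCv coefficient of variation of the density noise.
#' @param calibrationRatio tropomyosin/actin density ratio at full
#'   saturation.
#' @param densityActin constant actin band density (arbitrary units).
#' @param seed integer seed for the density noise.
#' @param meta metadata list.
#' @return a [BindingSeries()] carrying noisy densities plus ground-truth
#'   \code{theta} and \code{free} (and the truth parameters in
#'   \code{meta$truth}).
#' @export
simulateBinding <- function(k50, nHill = 1.5, thetaMax = 1, actinTotal = 10,
                            stoichiometry = 4,
                            tpmTotals = exp(seq(log(0.2), log(16),
                                                length.out = 10)),
                            densityNoiseCv = 0, calibrationRatio = 1.2,
                            densityActin = 1000, seed = 1L, meta = list()) {
  stopifnot(k50 > 0, nHill > 0, thetaMax > 0, actinTotal > 0,
            stoichiometry >= 1, all(diff(tpmTotals) > 0), densityNoiseCv >= 0)
  capacity <- actinTotal / stoichiometry
  free <- vapply(tpmTotals, .solveFree, numeric(1), capacity = capacity,
                 k50 = k50, n = nHill, thetaMax = thetaMax)
  theta <- .hillTheta(free, k50, nHill, thetaMax)
  dA <- rep(densityActin, length(tpmTotals))
  noise <- if (densityNoiseCv > 0) {
    set.seed(as.integer(seed))
    stats::rnorm(length(tpmTotals), 0, densityNoiseCv)
  } else 0
  dT <- theta * calibrationRatio * dA * (1 + noise)
  meta$truth <- list(k50 = k50, nHill = nHill, thetaMax = thetaMax,
                     stoichiometry = stoichiometry,
                     calibrationRatio = calibrationRatio)
  BindingSeries(actinTotal = actinTotal, tpmTotal = tpmTotals,
                densityTpm = pmax(dT, 0), densityActin = dA,
                theta = theta, free = free, meta = meta)
}

#' Build a coiled-coil test sequence with a known register
#'
#' Constructs a deterministic sequence from heptad fill rules - core a/d
#' positions get leucine, e/g positions alternate glutamate and lysine
#' (giving chargeable flank positions), all others alanine - then applies
#' explicit residue placements. The true annotation is known by
#' construction, which makes the sequence a ground-truth fixture for the
#' register and pair-detection code.
#'
#' @param length sequence length.
#' @param anchorIndex,anchorLetter the register anchor defining the true
#'   letters.
#' @param placements named list or vector mapping positions to residues,
#'   e.g. \code{c("28" = "K", "31" = "E")}.
#' @param fillRules named character vector mapping heptad letters to fill
#'   residues; entries override the defaults.
#' @return list with \code{sequence} (character) and \code{annotation}
#'   (the true [HeptadAnnotation-class]).
#' @export
simulateSequence <- function(length, anchorIndex, anchorLetter,
                             placements = list(), fillRules = character()) {
  stopifnot(length >= 1L)
  idx <- seq_len(length)
  letters <- .letterAt(anchorIndex, anchorLetter, idx)
  defaults <- c(a = "L", d = "L", b = "A", c = "A", f = "A")
  defaults[names(fillRules)] <- fillRules
  aa <- unname(defaults[letters])
  ## e/g positions alternate E, K along the sequence unless overridden
  eg <- which(letters %in% c("e", "g") & is.na(aa))
  if (length(eg)) aa[eg] <- rep(c("E", "K"), length.out = length(eg))
  aa[is.na(aa)] <- "A"
  if (length(placements)) {
    pos <- as.integer(names(placements))
    if (any(is.na(pos)) || any(pos < 1L | pos > length))
      stop("placement positions must be names within the sequence",
           call. = FALSE)
    if (anyDuplicated(pos)) stop("conflicting placements", call. = FALSE)
    aa[pos] <- unlist(placements, use.names = FALSE)
  }
  seqStr <- paste(aa, collapse = "")
  list(sequence = seqStr,
       annotation = assignRegister(seqStr,
                                   list(c(anchorIndex, anchorLetter))))
}

#' Write a sequence to FASTA
#'
#' @param sequence character sequence.
#' @param path output path.
#' @param name record name.
#' @return the path, invisibly.
#' @export
writeProteinFasta <- function(sequence, path, name = "synthetic") {
  set <- Biostrings::AAStringSet(stats::setNames(sequence, name))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
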