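## Orchestration: the bundled Cdc8 reference parameter set, the
## simulate-then-recover replica run, tolerance comparison, and report
## writers.

#' Reference thermal and binding parameters for Cdc8 tropomyosin variants
#'
#' Literature-reported parameters for fission-yeast Cdc8 tropomyosin and
#' its temperature-sensitive variants at 0.5 M salt: melting temperatures
#' and van't Hoff enthalpies for the unacetylated and Nt-acetylated forms
#' (the acetylated E129K and A18T/E31K proteins unfold in two transitions,
#' with about 60 percent of the CD change in the lower one), and the
#' half-saturation constants of actin binding where measured. These are
#' the generating parameters of the replica run.
#'
#' @return data.frame with one row per protein x acetylation state:
#'   \code{protein}, \code{acetylated}, \code{tm} and \code{dh}
#'   (list-columns, one value per transition, kJ/mol, negative),
#'   \code{amplitude} (list-column), \code{k50} (uM, NA where not
#'   measured).
#' @export
cdc8Parameters <- function() {
  row <- function(protein, ac, tm, dh, amp, k50)
    data.frame(protein = protein, acetylated = ac,
               tm = I(list(tm)), dh = I(list(dh)), amplitude = I(list(amp)),
               k50 = k50)
  rbind(
    row("WT",        FALSE, 34.1, -455.8, 1, 2.54),
    row("WT",        TRUE,  35.4, -555.7, 1, 0.62),
    row("A18T",      FALSE, 29.3, -315.4, 1, NA),
    row("A18T",      TRUE,  30.5, -342.3, 1, NA),
    row("E129K",     FALSE, 29.4, -331.1, 1, 4.69),
    row("E129K",     TRUE,  c(29.3, 38.1), c(-481.7, -403.6), c(0.6, 0.4), 1.65),
    row("E31K",      FALSE, 32.2, -447.2, 1, NA),
    row("E31K",      TRUE,  35.9, -571.3, 1, NA),
    row("A18T-E31K", FALSE, 27.9, -276.0, 1, NA),
    row("A18T-E31K", TRUE,  c(29.2, 43.2), c(-256.8, -466.2), c(0.6, 0.4), NA))
}

#' Run the full simulate-and-recover replica
#'
#' For every configured protein and acetylation state, generates synthetic
#' melting traces from the configured transitions, runs the full melt
#' pipeline (normalize, differentiate, select components, Gaussian
#' deconvolution, van't Hoff fit), and - where a half-saturation constant
#' is configured - generates and refits a co-sedimentation series. The
#' report compares every recovered parameter with its generating value.
#'
#' @param config data.frame as returned by [cdc8Parameters()]; defaults to
#'   the bundled reference set.
#' @param noiseSd melt noise sd in signal units (0 = noise-free).
#' @param densityNoiseCv densitometry noise CV.
#' @param replicates melt replicates per protein.
#' @param seed base seed; each protein row offsets it deterministically.
#' @param components \code{"auto"}, 1 or 2 (passed to [fitMeltCurve()]).
#' @param actinTotal,stoichiometry binding assay configuration.
#' @param outDir optional directory; when given, a JSON report and a tidy
#'   CSV are written there.
#' @return data.frame report with one row per protein/state/transition:
#'   configured and recovered Tm, dH, amplitude, k50, plus the selected
#'   component count. Failures of any stage are recorded per protein, not
#'   raised.
#' @export
runReplica <- function(config = cdc8Parameters(), noiseSd = 0,
                       densityNoiseCv = 0, replicates = 1L, seed = 1L,
                       components = "auto", actinTotal = 10,
                       stoichiometry = 4, outDir = NULL) {
  if (nrow(config) == 0L)
    return(data.frame(protein = character(), acetylated = logical(),
                      transition = integer(), tmTrue = numeric(),
                      tmFit = numeric(), dhTrue = numeric(),
                      dhFit = numeric(), ampTrue = numeric(),
                      ampFit = numeric(), nComponents = integer(),
                      k50True = numeric(), k50Fit = numeric(),
                      error = character()))
  key <- paste(config$protein, config$acetylated)
  if (anyDuplicated(key))
    stop("every protein/state must appear exactly once", call. = FALSE)
  rows <- list()
  for (i in seq_len(nrow(config))) {
    tm <- config$tm[[i]]; dh <- config$dh[[i]]; amp <- config$amplitude[[i]]
    rowSeed <- as.integer(seed) + 1000L * i
    res <- tryCatch({
      model <- UnfoldingModel(tm = tm, dh = dh, amplitude = amp)
      curves <- simulateMelt(model, noiseSd = noiseSd, seed = rowSeed,
                             replicates = replicates)
      fit <- fitMeltCurve(curves, components = components)
      k50Fit <- NA_real_
      if (!is.na(config$k50[i])) {
        series <- simulateBinding(config$k50[i], actinTotal = actinTotal,
                                  stoichiometry = stoichiometry,
                                  densityNoiseCv = densityNoiseCv,
                                  seed = rowSeed)
        series <- saturationFromDensity(
          series, calibrationRatio = series@meta$truth$calibrationRatio)
        series <- freeTpm(series, stoichiometry = stoichiometry)
        k50Fit <- k50(fitHill(series))
      }
      tr <- transitions(fit)
      nT <- max(length(tm), nrow(tr))
      data.frame(protein = config$protein[i],
                 acetylated = config$acetylated[i],
                 transition = seq_len(nT),
                 tmTrue = tm[seq_len(nT)],
                 tmFit = tr$tm[seq_len(nT)],
                 dhTrue = dh[seq_len(nT)],
                 dhFit = tr$dh[seq_len(nT)],
                 ampTrue = amp[seq_len(nT)],
                 ampFit = tr$amplitude[seq_len(nT)],
                 nComponents = nComponents(fit),
                 k50True = config$k50[i], k50Fit = k50Fit,
                 error = NA_character_)
    }, error = function(e) {
      data.frame(protein = config$protein[i],
                 acetylated = config$acetylated[i], transition = 1L,
                 tmTrue = tm[1], tmFit = NA_real_, dhTrue = dh[1],
                 dhFit = NA_real_, ampTrue = amp[1], ampFit = NA_real_,
                 nComponents = NA_integer_, k50True = config$k50[i],
                 k50Fit = NA_real_, error = conditionMessage(e))
    })
    rows[[i]] <- res
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!is.null(outDir)) writeReplicaReport(report, outDir)
  report
}

#' Compare a replica report against a reference table
#'
#' Joins recovered values to a reference keyed by protein, acetylation
#' state and transition index, and reports absolute differences plus pass
#' flags at the supplied tolerances. Keys present in the reference but
#' absent from the report are listed as absent rather than raising.
#'
#' @param report a report from [runReplica()].
#' @param reference data.frame with columns \code{protein},
#'   \code{acetylated}, \code{transition}, and any of \code{tm},
#'   \code{dh}, \code{k50}.
#' @param tolTm Tm tolerance, degrees C.
#' @param tolDhRel relative |dH| tolerance.
#' @param tolK50Rel relative K50 tolerance.
#' @return data.frame of per-value differences and logical pass columns.
#' @export
compareToReference <- function(report, reference, tolTm = 0.3,
                               tolDhRel = 0.02, tolK50Rel = 0.02) {
  out <- merge(reference, report, all.x = TRUE,
               by = c("protein", "acetylated", "transition"))
  if ("tm" %in% names(reference)) {
    out$tmDiff <- abs(out$tm - out$tmFit)
    out$tmPass <- !is.na(out$tmDiff) & out$tmDiff <= tolTm
  }
  if ("dh" %in% names(reference)) {
    out$dhRelDiff <- abs(abs(out$dh) - abs(out$dhFit)) / abs(out$dh)
    out$dhPass <- !is.na(out$dhRelDiff) & out$dhRelDiff <= tolDhRel
  }
  if ("k50" %in% names(reference)) {
    out$k50RelDiff <- abs(out$k50 - out$k50Fit) / out$k50
    out$k50Pass <- !is.na(out$k50RelDiff) & out$k50RelDiff <= tolK50Rel
  }
  out$absent <- is.na(out$tmFit)
  out
}

#' Write a replica report as JSON and tidy CSV
#'
#' Floats are serialized at fixed precision (one decimal for degrees C and
#' kJ/mol, two for uM) with stable row ordering, so identical runs produce
#' byte-identical files.
#'
#' @param report a report from [runReplica()].
#' @param outDir output directory (created if needed).
#' @return invisible named list of the two file paths.
#' @export
writeReplicaReport <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  report <- report[order(report$protein, report$acetylated,
                         report$transition), , drop = FALSE]
  fmt <- report
  for (cl in c("tmTrue", "tmFit", "dhTrue", "dhFit"))
    fmt[[cl]] <- round(fmt[[cl]], 1)
  for (cl in c("ampTrue", "ampFit", "k50True", "k50Fit"))
    fmt[[cl]] <- round(fmt[[cl]], 2)
  csv <- file.path(outDir, "replica_report.csv")
  js <- file.path(outDir, "replica_report.json")
  utils::write.csv(fmt, csv, row.names = FALSE)
  jsonlite::write_json(fmt, js, dataframe = "rows", na = "null", digits = NA,
                       pretty = TRUE)
  invisible(list(csv = csv, json = js))
}

#' Tidy data.frame views of melt objects
#'
#' @param x a [NormalizedMelt-class] or [DerivativeCurve-class].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame of the curve.
#' @export
as.data.frame.NormalizedMelt <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(temperature = x@temperature, fraction = x@fraction)
}

#' @rdname as.data.frame.NormalizedMelt
#' @export
as.data.frame.DerivativeCurve <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(temperature = x@temperature, dfdT = x@dfdT)
}
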