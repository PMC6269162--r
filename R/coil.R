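## Heptad-register annotation of coiled-coil sequences: register
## propagation from anchors, residue classing, core alanine clusters,
## charge-pair detection, and per-mutation structural reports.

.CHARGE_NEG <- c("D", "E")
.CHARGE_POS_DEFAULT <- c("K", "R", "H")
.HYDROPHOBIC <- c("M", "L", "I", "V", "F", "W", "Y")
.SMALL <- c("A", "S", "T", "G")
.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")

.letterAt <- function(anchorIndex, anchorLetter, i) {
  off <- (match(anchorLetter, .HEPTAD) - 1L + (i - anchorIndex)) %% 7L
  .HEPTAD[off + 1L]
}

#' Assign heptad register letters from anchors
#'
#' Propagates a-g register letters cyclically (period 7) from each anchor
#' across its segment. With a single segment (the default) all anchors must
#' imply the same register; contradictory anchors raise a register-conflict
#' error naming the offending pair, since forcing them into one continuous
#' heptad is impossible. Supplying explicit segments allows piecewise
#' registers for coils with local distortions.
#'
#' @param sequence amino-acid string (or an [Biostrings::AAString-class]).
#' @param anchors data.frame with columns \code{index} (1-based residue
#'   position) and \code{letter} (one of a-g), or a list of
#'   \code{c(index, letter)} pairs.
#' @param segments optional data.frame with columns \code{start},
#'   \code{end} tiling the sequence; each anchor must fall in some segment.
#' @return a [HeptadAnnotation-class].
#' @examples
#' ann <- assignRegister(strrep("ABCDEFG", 3), anchors = list(c(1, "a")))
#' registerLetters(ann)[8]  # cyclic: position 8 is again "a"
#' @export
assignRegister <- function(sequence, anchors, segments = NULL) {
  sequence <- as.character(sequence)
  n <- nchar(sequence)
  anchors <- .normalizeAnchors(anchors)
  if (nrow(anchors) < 1L) stop("at least one anchor is required", call. = FALSE)
  if (any(anchors$index < 1L | anchors$index > n))
    stop("anchor index outside the sequence", call. = FALSE)
  if (!all(anchors$letter %in% .HEPTAD))
    stop("anchor letters must be heptad positions a-g", call. = FALSE)
  if (is.null(segments)) segments <- data.frame(start = 1L, end = n)
  segments <- segments[order(segments$start), , drop = FALSE]
  letters <- character(n)
  segAnchor <- integer(nrow(segments))
  for (s in seq_len(nrow(segments))) {
    inSeg <- which(anchors$index >= segments$start[s] &
                   anchors$index <= segments$end[s])
    if (!length(inSeg))
      stop(sprintf("segment %d-%d has no anchor", segments$start[s],
                   segments$end[s]), call. = FALSE)
    a1 <- inSeg[1L]
    for (a2 in inSeg[-1L]) {
      expect <- .letterAt(anchors$index[a1], anchors$letter[a1],
                          anchors$index[a2])
      if (expect != anchors$letter[a2])
        stop(sprintf(paste0(
          "register conflict: anchor %d=%s implies %d=%s, but anchor %d=%s ",
          "was given; the two registers cannot share one continuous heptad"),
          anchors$index[a1], anchors$letter[a1], anchors$index[a2], expect,
          anchors$index[a2], anchors$letter[a2]), call. = FALSE)
    }
    idx <- segments$start[s]:segments$end[s]
    letters[idx] <- .letterAt(anchors$index[a1], anchors$letter[a1], idx)
    segAnchor[s] <- a1
  }
  segments$anchorIndex <- anchors$index[segAnchor]
  segments$anchorLetter <- anchors$letter[segAnchor]
  new("HeptadAnnotation", sequence = sequence, letters = letters,
      segments = segments)
}

.normalizeAnchors <- function(anchors) {
  if (is.data.frame(anchors)) {
    data.frame(index = as.integer(anchors$index),
               letter = as.character(anchors$letter))
  } else {
    data.frame(index = vapply(anchors, function(a) as.integer(a[[1]]), 1L),
               letter = vapply(anchors, function(a) as.character(a[[2]]), ""))
  }
}

#' Classify residues by physico-chemical character
#'
#' Partitions every residue into exactly one of: \code{charged-} (D, E),
#' \code{charged+} (K, R and, by default, H), \code{hydrophobic} (M, L, I,
#' V, F, W, Y), \code{small} (A, S, T, G) or \code{other}.
#'
#' @param annotation a [HeptadAnnotation-class] (or a plain sequence
#'   string).
#' @param histidineCharged treat H as positively charged (default TRUE;
#'   ambiguous at physiological pH).
#' @return character vector of classes, one per residue.
#' @export
classifyResidues <- function(annotation, histidineCharged = TRUE) {
  seq <- if (is(annotation, "HeptadAnnotation")) annotation@sequence
         else as.character(annotation)
  aa <- strsplit(seq, "")[[1L]]
  bad <- setdiff(unique(aa), .AA20)
  if (length(bad))
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  pos <- if (histidineCharged) .CHARGE_POS_DEFAULT else c("K", "R")
  cls <- rep("other", length(aa))
  cls[aa %in% .CHARGE_NEG] <- "charged-"
  cls[aa %in% pos] <- "charged+"
  cls[aa %in% .HYDROPHOBIC] <- "hydrophobic"
  cls[aa %in% .SMALL] <- "small"
  cls
}

.chargeOf <- function(aa, histidineCharged = TRUE) {
  pos <- if (histidineCharged) .CHARGE_POS_DEFAULT else c("K", "R")
  ifelse(aa %in% .CHARGE_NEG, -1L, ifelse(aa %in% pos, 1L, 0L))
}

.chargeClass <- function(c1, c2) {
  if (c1 == 0L || c2 == 0L) "neutral"
  else if (c1 * c2 < 0L) "attractive"
  else "repulsive"
}

#' Find small-residue clusters in the hydrophobic core
#'
#' Walks the core (a/d) positions in sequence order and reports maximal
#' runs occupied by small residues (A, S, T, G) that are flanked on both
#' sides by hydrophobic-occupied core positions; such alanine clusters
#' loosen side-chain packing relative to a leucine-zipper core.
#'
#' @param annotation a [HeptadAnnotation-class].
#' @param classes residue classes from [classifyResidues()] (computed if
#'   missing).
#' @return a list of clusters, each with \code{members} (positions),
#'   \code{residues}, and the flanking hydrophobic core runs.
#' @export
findCoreClusters <- function(annotation, classes = classifyResidues(annotation)) {
  stopifnot(is(annotation, "HeptadAnnotation"))
  core <- which(annotation@letters %in% c("a", "d"))
  if (!length(core)) return(list())
  coreCls <- classes[core]
  runs <- rle(coreCls)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  aa <- strsplit(annotation@sequence, "")[[1L]]
  out <- list()
  for (r in seq_along(runs$values)) {
    if (runs$values[r] != "small") next
    if (r == 1L || r == length(runs$values)) next
    if (runs$values[r - 1L] != "hydrophobic" ||
        runs$values[r + 1L] != "hydrophobic") next
    members <- core[starts[r]:ends[r]]
    out[[length(out) + 1L]] <- list(
      members = members,
      residues = aa[members],
      flankBefore = core[starts[r - 1L]:ends[r - 1L]],
      flankAfter = core[starts[r + 1L]:ends[r + 1L]])
  }
  out
}

#' Detect intra-helix and inter-chain charge pairs
#'
#' Enumerates charged residue pairs at helical spacings i,i+3 and i,i+4
#' within one helix, and, assuming an in-register parallel homodimer, the
#' inter-chain pair between each g-position residue i and the e-position
#' residue i+5 of the partner chain (the next heptad's e). Pairs of
#' opposite charge are attractive (salt bridges), like charges repulsive.
#' For g-e' pairs an uncharged partner is reported as neutral (no bridge
#' possible).
#'
#' @inheritParams findCoreClusters
#' @param histidineCharged passed to the charge assignment.
#' @return data.frame with columns \code{kind}
#'   (\code{intra_helix_i3}, \code{intra_helix_i4}, \code{interchain_g_e}),
#'   \code{i}, \code{j}, \code{aaI}, \code{aaJ}, \code{letterI},
#'   \code{letterJ}, \code{chargeClass}.
#' @export
findPairInteractions <- function(annotation,
                                 classes = classifyResidues(annotation),
                                 histidineCharged = TRUE) {
  stopifnot(is(annotation, "HeptadAnnotation"))
  aa <- strsplit(annotation@sequence, "")[[1L]]
  n <- length(aa)
  ch <- .chargeOf(aa, histidineCharged)
  lt <- annotation@letters
  rows <- list()
  add <- function(kind, i, j) {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, i = i, j = j, aaI = aa[i], aaJ = aa[j],
      letterI = lt[i], letterJ = lt[j],
      chargeClass = .chargeClass(ch[i], ch[j]))
  }
  for (i in seq_len(n)) {
    for (d in 3:4) {
      j <- i + d
      if (j <= n && ch[i] != 0L && ch[j] != 0L)
        add(paste0("intra_helix_i", d), i, j)
    }
  }
  ## inter-chain g-e': g at i pairs with the partner chain's e at i+5
  for (i in which(lt == "g")) {
    j <- i + 5L
    if (j <= n && lt[j] == "e") add("interchain_g_e", i, j)
  }
  if (!length(rows))
    return(data.frame(kind = character(), i = integer(), j = integer(),
                      aaI = character(), aaJ = character(),
                      letterI = character(), letterJ = character(),
                      chargeClass = character()))
  do.call(rbind, rows)
}

#' Structural report on a coiled-coil point substitution
#'
#' Classifies a substitution by its heptad position and its effect on
#' detected charge pairs: \code{core-packing} for a/d positions,
#' \code{intra-helix-pair} when an i,i+3 or i,i+4 charge pair involving the
#' position changes, \code{interchain-bridge} for e/g positions, and
#' \code{surface} otherwise. The report lists pairs gained, lost or
#' flipped between attraction and repulsion, the residue-class change, and
#' notes the local sequence context.
#'
#' @inheritParams findPairInteractions
#' @param position 1-based residue position of the substitution.
#' @param mutAa single-letter replacement residue.
#' @return a [MutationReport-class].
#' @export
annotateMutation <- function(annotation, position, mutAa,
                             classes = classifyResidues(annotation),
                             histidineCharged = TRUE) {
  stopifnot(is(annotation, "HeptadAnnotation"))
  n <- nchar(annotation@sequence)
  position <- as.integer(position)
  if (position < 1L || position > n)
    stop("position outside the sequence", call. = FALSE)
  if (!mutAa %in% .AA20) stop("unknown replacement residue", call. = FALSE)
  aa <- strsplit(annotation@sequence, "")[[1L]]
  wt <- aa[position]
  letter <- annotation@letters[position]
  notes <- character()
  if (mutAa == wt) notes <- c(notes, "synonymous substitution: no-op")
  mutSeq <- annotation
  mutSeq@sequence <- paste0(substr(annotation@sequence, 1, position - 1L),
                            mutAa,
                            substr(annotation@sequence, position + 1L, n))
  before <- findPairInteractions(annotation, classes, histidineCharged)
  after <- findPairInteractions(mutSeq, classifyResidues(mutSeq, histidineCharged),
                                histidineCharged)
  touches <- function(df) df[df$i == position | df$j == position, , drop = FALSE]
  b <- touches(before); a <- touches(after)
  key <- function(df) paste(df$kind, df$i, df$j)
  flipped <- merge(b, a, by = c("kind", "i", "j"), suffixes = c(".wt", ".mut"))
  flipped <- flipped[flipped$chargeClass.wt != flipped$chargeClass.mut, ,
                     drop = FALSE]
  classWt <- classes[position]
  classMut <- classifyResidues(mutSeq, histidineCharged)[position]
  pairChanged <- nrow(flipped) > 0 ||
    length(setdiff(key(b), key(a))) > 0 || length(setdiff(key(a), key(b))) > 0
  classification <-
    if (letter %in% c("a", "d")) "core-packing"
    else if (letter %in% c("e", "g")) "interchain-bridge"
    else if (pairChanged) "intra-helix-pair"
    else "surface"
  ctx <- aa[max(1L, position - 1L):min(n, position + 1L)]
  notes <- c(notes, sprintf("local context: %s",
                            paste0(ctx, max(1L, position - 1L):min(n, position + 1L),
                                   collapse = " ")))
  if (mutAa %in% c("S", "T", "N", "Q") && letter %in% c("a", "d"))
    notes <- c(notes, "introduces polar character into the hydrophobic core")
  new("MutationReport", position = position, wtAa = wt, mutAa = mutAa,
      letter = letter, classification = classification,
      classChange = paste(classWt, "->", classMut),
      pairsBefore = b, pairsAfter = a, notes = notes)
}

#' Per-residue annotation table
#'
#' @param annotation a [HeptadAnnotation-class].
#' @param histidineCharged passed to [classifyResidues()].
#' @return data.frame with columns \code{index}, \code{aa}, \code{letter},
#'   \code{class}.
#' @export
annotationTable <- function(annotation, histidineCharged = TRUE) {
  aa <- strsplit(annotation@sequence, "")[[1L]]
  data.frame(index = seq_along(aa), aa = aa, letter = annotation@letters,
             class = classifyResidues(annotation, histidineCharged))
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper over Biostrings returning plain character sequences named
#' by record id.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
readProteinFasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(set), names(set))
}
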