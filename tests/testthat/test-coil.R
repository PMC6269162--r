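# brute-force register walker used as the oracle for cyclic propagation
walkRegister <- function(n, anchorIndex, anchorLetter) {
  heptad <- c("a", "b", "c", "d", "e", "f", "g")
  out <- character(n)
  out[anchorIndex] <- anchorLetter
  i <- anchorIndex
  while (i < n) {
    nxt <- match(out[i], heptad) %% 7 + 1
    out[i + 1] <- heptad[nxt]
    i <- i + 1
  }
  i <- anchorIndex
  while (i > 1) {
    prv <- (match(out[i], heptad) - 2) %% 7 + 1
    out[i - 1] <- heptad[prv]
    i <- i - 1
  }
  out
}

test_that("register propagation matches the brute-force walker", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(20:160, 1)
    idx <- sample(n, 1)
    letter <- sample(letters[1:7], 1)
    ann <- assignRegister(strrep("A", n), list(c(idx, letter)))
    expect_identical(registerLetters(ann), walkRegister(n, idx, letter))
  }
})

test_that("an A18=d anchor places residue 31 at a c position", {
  ann <- assignRegister(strrep("A", 35), list(c(18, "d")))
  expect_identical(registerLetters(ann)[31], "c")
  # and cyclic period 7: position 1 anchor -> position 8 same letter
  ann2 <- assignRegister(strrep("ABCDEFG", 3), list(c(1, "a")))
  expect_identical(registerLetters(ann2)[8], "a")
})

test_that("contradictory anchors in one segment raise a register conflict", {
  # 18=d forces 129=c by (129-18) mod 7 arithmetic, so 129=g cannot share
  # the same continuous heptad
  expect_identical(walkRegister(130, 18, "d")[129], "c")
  expect_error(
    assignRegister(strrep("A", 140), list(c(18, "d"), c(129, "g"))),
    "register conflict.*129")
  # the same anchors in separate segments are allowed
  ann <- assignRegister(strrep("A", 140), list(c(18, "d"), c(129, "g")),
                        segments = data.frame(start = c(1, 100),
                                              end = c(99, 140)))
  expect_identical(registerLetters(ann)[129], "g")
  expect_identical(registerLetters(ann)[18], "d")
})

test_that("residue classification partitions the twenty amino acids", {
  cls <- classifyResidues("ARNDCQEGHILKMFPSTWYV")
  expect_length(cls, 20)
  expect_true(all(cls %in% c("charged-", "charged+", "hydrophobic",
                             "small", "other")))
  expect_identical(classifyResidues("E"), "charged-")
  expect_identical(classifyResidues("L"), "hydrophobic")
  expect_identical(unique(classifyResidues("MLI")), "hydrophobic")
  expect_identical(classifyResidues("H"), "charged+")
  expect_identical(classifyResidues("H", histidineCharged = FALSE), "other")
  expect_error(classifyResidues("AXB"), "unknown")
})

test_that("the alanine cluster between hydrophobic core runs is found", {
  # core (a/d) positions under an 18=d register: ...4,8,11,15,18,22,25,29,32,36...
  fx <- simulateSequence(40, 18, "d",
                         placements = list("4" = "M", "8" = "L",
                                           "11" = "A", "15" = "T", "18" = "A",
                                           "22" = "A", "25" = "A",
                                           "29" = "L", "32" = "V", "36" = "L"))
  cl <- findCoreClusters(fx$annotation)
  expect_length(cl, 1)
  expect_identical(cl[[1]]$members, c(11L, 15L, 18L, 22L, 25L))
  expect_identical(cl[[1]]$residues, c("A", "T", "A", "A", "A"))
})

test_that("an all-leucine core has no small-residue clusters", {
  fx <- simulateSequence(40, 18, "d")
  expect_length(findCoreClusters(fx$annotation), 0)
})

test_that("a single isolated core alanine forms a cluster of one", {
  fx <- simulateSequence(40, 18, "d", placements = list("18" = "A"))
  cl <- findCoreClusters(fx$annotation)
  expect_length(cl, 1)
  expect_identical(cl[[1]]$members, 18L)
})

test_that("K28-E31 is an attractive i,i+3 pair that E31K makes repulsive", {
  fx <- simulateSequence(35, 18, "d", placements = list("28" = "K", "31" = "E"))
  pairs <- findPairInteractions(fx$annotation)
  p <- pairs[pairs$i == 28 & pairs$j == 31, ]
  expect_identical(p$kind, "intra_helix_i3")
  expect_identical(p$chargeClass, "attractive")
  mut <- simulateSequence(35, 18, "d", placements = list("28" = "K", "31" = "K"))
  pm <- findPairInteractions(mut$annotation)
  expect_identical(pm[pm$i == 28 & pm$j == 31, "chargeClass"], "repulsive")
})

test_that("g-e' pairs across the dimer interface classify by charge", {
  # 129 = g pairs with the partner chain's e at 134
  fx <- simulateSequence(140, 129, "g",
                         placements = list("129" = "E", "134" = "E"))
  pairs <- findPairInteractions(fx$annotation)
  ge <- pairs[pairs$kind == "interchain_g_e" & pairs$i == 129, ]
  expect_identical(ge$j, 134L)
  expect_identical(ge$chargeClass, "repulsive")  # E/E': no bridge possible
  fx2 <- simulateSequence(140, 129, "g",
                          placements = list("129" = "K", "134" = "E"))
  p2 <- findPairInteractions(fx2$annotation)
  expect_identical(p2[p2$kind == "interchain_g_e" & p2$i == 129,
                      "chargeClass"], "attractive")
})

test_that("pair detection is symmetric under chain exchange", {
  # in an in-register homodimer both chains carry the same sequence, so the
  # g-e' list must be identical whichever chain donates the g position
  fx <- simulateSequence(70, 1, "a")
  pairs <- findPairInteractions(fx$annotation)
  ge <- pairs[pairs$kind == "interchain_g_e", ]
  swapped <- findPairInteractions(fx$annotation)  # partner chain = same
  expect_identical(ge, swapped[swapped$kind == "interchain_g_e", ])
})

test_that("mutation reports carry letter, category and flipped pairs", {
  fx <- simulateSequence(35, 18, "d", placements = list("28" = "K", "31" = "E"))
  a18t <- annotateMutation(fx$annotation, 18, "T")
  expect_identical(a18t@letter, "d")
  expect_identical(a18t@classification, "core-packing")
  expect_match(a18t@classChange, "small")
  e31k <- annotateMutation(fx$annotation, 31, "K")
  expect_identical(e31k@classification, "intra-helix-pair")
  flips <- merge(e31k@pairsBefore, e31k@pairsAfter, by = c("kind", "i", "j"))
  expect_true(any(flips$chargeClass.x == "attractive" &
                  flips$chargeClass.y == "repulsive"))
})

test_that("E129K in an R128-E129-R130 context reports an interchain bridge", {
  fx <- simulateSequence(140, 129, "g",
                         placements = list("128" = "R", "129" = "E",
                                           "130" = "R"))
  rep <- annotateMutation(fx$annotation, 129, "K")
  expect_identical(rep@classification, "interchain-bridge")
  expect_match(paste(rep@notes, collapse = " "), "R128 E129 R130")
  # R130 sits at the core a position under this register
  expect_identical(registerLetters(fx$annotation)[130], "a")
})

test_that("a synonymous substitution changes nothing and is flagged", {
  fx <- simulateSequence(35, 18, "d", placements = list("28" = "K", "31" = "E"))
  rep <- annotateMutation(fx$annotation, 31, "E")
  expect_identical(rep@pairsBefore, rep@pairsAfter)
  expect_match(paste(rep@notes, collapse = " "), "no-op")
})

test_that("annotation tables and FASTA io round-trip", {
  fx <- simulateSequence(35, 18, "d")
  tab <- annotationTable(fx$annotation)
  expect_identical(nrow(tab), 35L)
  expect_identical(tab$letter, registerLetters(fx$annotation))
  path <- withr::local_tempfile(fileext = ".fa")
  writeProteinFasta(fx$sequence, path, name = "cdc8_synthetic")
  back <- readProteinFasta(path)
  expect_identical(unname(back), fx$sequence)
})
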