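library(Biostrings)

test_that("alignment reading and reference mapping follow the definitions", {
  f <- file.path(tempdir(), "aln.fasta")
  writeLines(c(">REF", "AC-GT", ">s1", "ACAGT"), f)
  aln <- readAlignment(f)
  map <- mapToReference(aln, "REF")
  expect_equal(as.integer(map), c(1L, 2L, NA, 3L, 4L))

  # gapless alignment gives the identity mapping
  writeLines(c(">REF", "ACDEF", ">s1", "ACDEE"), f)
  mapId <- mapToReference(readAlignment(f), "REF")
  expect_equal(as.integer(mapId), 1:5)

  writeLines(c(">REF", "ACGT", ">s1", "ACG"), f)
  expect_error(readAlignment(f), "ragged")
  expect_error(mapToReference(BStringSet(c(a = "AC")), "missing"),
               "lookup error")
})

test_that("slice counts match direct column tallies", {
  topo <- singleChainTopology(20L)
  # one sequence with Y at position 5 only; slice length 1
  aln <- BStringSet(c(REF = paste(c(rep("A", 4), "Y", rep("A", 15)),
                                  collapse = "")))
  map <- mapToReference(aln, "REF")
  prof <- sliceCounts(aln, map, topo, sliceLen = 1, chainId = "COL1A1")
  zY <- sites(topo)$axial[5]
  hit <- prof$axialStart <= zY & prof$axialEnd > zY
  expect_true(all(prof$Tyr[hit] == 1))
  expect_true(all(prof$Tyr[!hit] == 0))

  # n identical sequences leave the mean unchanged
  aln4 <- BStringSet(setNames(rep(as.character(aln[[1]]), 4),
                              c("REF", "a", "b", "c")))
  prof4 <- sliceCounts(aln4, mapToReference(aln4, "REF"), topo,
                       sliceLen = 1, chainId = "COL1A1")
  expect_equal(prof4$Tyr, prof$Tyr)
})

test_that("non-overlapping slices conserve total class mass", {
  topo <- conservationBundle()
  seqs <- defaultChainSequences()
  spec <- msaSpec(seqs[["COL1A1"]], nSequences = 8,
                  planted = list(Y = c(940, 950)), enrichment = 0.8,
                  backgroundRate = 0.05, seed = 14L)
  aln <- generateMsa(spec)
  map <- mapToReference(aln, "REF")
  prof <- sliceCounts(aln, map, topo, sliceLen = 10, chainId = "COL1A1",
                      step = 10)

  # brute-force oracle: per-site class occurrences over the covered range
  s <- sites(topo)
  cfg <- fibrilConfig(topo)
  covered <- s$axial < max(prof$axialEnd) - 1e-9 &
    cfg@chainComposition[s$chain] == "COL1A1"
  mat <- do.call(rbind, strsplit(as.character(aln), ""))
  perPos <- colSums(mat == "Y")
  oracle <- sum(perPos[s$seqIndex[covered]]) / length(aln)
  expect_equal(sum(prof$Tyr), oracle, tolerance = 1e-9)
})

test_that("profiles are invariant to sequence order in the alignment", {
  topo <- conservationBundle()
  seqs <- defaultChainSequences()
  aln <- generateMsa(msaSpec(seqs[["COL1A1"]], nSequences = 10,
                             planted = list(F = c(104)), seed = 15L))
  prof1 <- sliceCounts(aln, mapToReference(aln, "REF"), topo,
                       chainId = "COL1A1")
  shuffled <- aln[c(5:10, 1:4)]
  prof2 <- sliceCounts(shuffled, mapToReference(shuffled, "REF"), topo,
                       chainId = "COL1A1")
  expect_equal(prof1$Phe, prof2$Phe)
  expect_equal(prof1$redox, prof2$redox)
})

test_that("planted enrichment is recovered at the planted axial position", {
  topo <- conservationBundle()
  seqs <- defaultChainSequences()
  planted <- list(Y = c(940L, 945L, 950L))
  aln <- generateMsa(msaSpec(seqs[["COL1A1"]], nSequences = 24,
                             planted = planted, enrichment = 1.0,
                             backgroundRate = 0.02, seed = 16L))
  map <- mapToReference(aln, "REF")
  prof <- sliceCounts(aln, map, topo, sliceLen = 10, chainId = "COL1A1")

  # brute-force tally locates the same argmax slice
  rise <- fibrilConfig(topo)@axialRise
  argmax <- which.max(prof$Tyr)
  s <- sites(topo)
  plantedZ <- s$axial[s$seqIndex %in% planted$Y &
                        fibrilConfig(topo)@chainComposition[s$chain] ==
                          "COL1A1"]
  mid <- (prof$axialStart[argmax] + prof$axialEnd[argmax]) / 2
  expect_lte(min(abs(mid - plantedZ)), 10 * rise)
})

test_that("crosslink enrichment ratio and permutation null are exact", {
  topo <- conservationBundle()
  # uniform profile: ratio is exactly 1
  seqsU <- defaultChainSequences()
  alnU <- Biostrings::BStringSet(c(REF = chartr("ko", "KP",
                                                seqsU[["COL1A1"]])))
  profU <- sliceCounts(alnU, mapToReference(alnU, "REF"), topo,
                       chainId = "COL1A1")
  profU$flat <- 1
  enrU <- enrichmentNearCrosslinks(profU, topo, radius = 1.5,
                                   column = "flat")
  expect_equal(enrU$ratio, 1)

  # all mass inside the radius: infinity sentinel
  profU$spiky <- 0
  xz <- sites(topo)$axial[crosslinks(topo)$donor[1]]
  mid <- (profU$axialStart + profU$axialEnd) / 2
  profU$spiky[which.min(abs(mid - xz))] <- 5
  enrInf <- enrichmentNearCrosslinks(profU, topo, radius = 1.5,
                                     column = "spiky")
  expect_identical(enrInf$ratio, Inf)

  # p-value equals exhaustive enumeration over all circular shifts
  set.seed(7)
  profU$noisy <- runif(nrow(profU))
  enr <- enrichmentNearCrosslinks(profU, topo, radius = 1.5,
                                  column = "noisy")
  v <- profU$noisy
  n <- length(v)
  xlSites <- c(crosslinks(topo)$donor, crosslinks(topo)$acceptor)
  xlZ <- unique(sites(topo)$axial[xlSites])
  near <- vapply(mid, function(z) min(abs(z - xlZ)) <= 1.5, logical(1))
  ratios <- vapply(0:(n - 1), function(k) {
    vs <- v[((seq_len(n) - 1 + k) %% n) + 1]
    mean(vs[near]) / mean(vs[!near])
  }, numeric(1))
  expect_equal(enr$pValue, mean(ratios >= ratios[1]))

  expect_error(enrichmentNearCrosslinks(profU, topo, radius = -1),
               "no slices")
})

test_that("slice length one with unit step reproduces per-position counts", {
  topo <- singleChainTopology(15L)
  aln <- Biostrings::BStringSet(c(REF = "AYAYAMFAAAYAAAF"))
  map <- mapToReference(aln, "REF")
  prof <- sliceCounts(aln, map, topo, sliceLen = 1, chainId = "COL1A1")
  ref <- strsplit("AYAYAMFAAAYAAAF", "")[[1]]
  # each slice of one residue extent holds exactly one site
  expect_equal(prof$nSites, rep(1, nrow(prof)))
  expect_equal(prof$redox, as.numeric(ref[seq_len(nrow(prof))] %in%
                                        c("Y", "F", "M")))
})
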