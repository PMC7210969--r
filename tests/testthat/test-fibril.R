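test_that("default segment has the expected D-period geometry and crosslinks", {
  topo <- defaultFibril()
  s <- sites(topo)
  x <- crosslinks(topo)

  expect_equal(max(s$axial) - min(s$axial), 67, tolerance = 1e-12)
  expect_equal(nrow(x), 12L)
  expect_equal(sum(x$terminal == "N"), 6L)
  expect_equal(sum(x$terminal == "C"), 6L)
  pairs <- unique(paste(pmin(s$helix[x$donor], s$helix[x$acceptor]),
                        pmax(s$helix[x$donor], s$helix[x$acceptor])))
  expect_length(pairs, 6L)

  # all donors are telopeptide sites; no crosslink within one helix
  expect_true(all(s$region[x$donor] == "telopeptide"))
  expect_true(all(s$helix[x$donor] != s$helix[x$acceptor]))

  # crosslink count = 2 x eligible adjacency pairs, bonds appear once each
  expect_equal(nrow(x), 2L * nrow(fibrilConfig(topo)@adjacency))
  b <- bonds(topo)
  xb <- b[b$type == "crosslink", ]
  expect_equal(nrow(xb), nrow(x))
  expect_false(any(duplicated(paste(pmin(xb$i, xb$j), pmax(xb$i, xb$j)))))
})

test_that("overlap region is denser in molecules than the gap region", {
  topo <- defaultFibril()
  s <- sites(topo)
  cfg <- fibrilConfig(topo)
  lOver <- cfg@overlapFraction * cfg@D
  lGap <- (1 - cfg@overlapFraction) * cfg@D
  # telopeptide sites keep their axial location; count them with their region
  inOver <- sum(s$axial <= lOver)
  inGap <- sum(s$axial > lOver)
  expect_gt(inOver / lOver, inGap / lGap)
})

test_that("building is deterministic and placeCrosslinks is idempotent", {
  cfg <- FibrilConfig(nHelices = 5, staggerClass = 0:4,
                      adjacency = rbind(c(1L, 5L)))
  t1 <- placeCrosslinks(buildTopology(cfg))
  t2 <- placeCrosslinks(buildTopology(cfg))
  expect_identical(as.data.frame(sites(t1)), as.data.frame(sites(t2)))
  expect_identical(as.data.frame(bonds(t1)), as.data.frame(bonds(t2)))
  t3 <- placeCrosslinks(t1)
  expect_identical(as.data.frame(crosslinks(t3)), as.data.frame(crosslinks(t1)))
  expect_equal(nrow(bonds(t3)), nrow(bonds(t1)))
})

test_that("degenerate and invalid configurations behave as contracted", {
  # single helix: no partner, no crosslinks
  cfg1 <- FibrilConfig(nHelices = 1L, staggerClass = 0L,
                       adjacency = matrix(integer(0), 0, 2))
  t1 <- placeCrosslinks(buildTopology(cfg1))
  expect_equal(nrow(crosslinks(t1)), 0L)

  # consecutive residues are one axial rise apart
  s <- sites(t1)
  onechain <- s[s$chain == 1, ]
  expect_equal(diff(onechain$axial[order(onechain$seqIndex)]),
               rep(67 / 234, nrow(onechain) - 1), tolerance = 1e-9)

  # adjacency referencing a missing helix
  expect_error(FibrilConfig(nHelices = 5, staggerClass = 0:4,
                            adjacency = rbind(c(1L, 9L))),
               "adjacency")

  # sequence too short names the offending chain
  shortSeqs <- c(COL1A1 = strrep("G", 100), COL1A2 = strrep("G", 2000))
  expect_error(buildTopology(defaultFibrilConfig(), shortSeqs), "COL1A1")

  # crosslink rule pointing at a non-lysine residue
  rules <- defaultCrosslinkRules()
  rules$N$acceptorSeq <- 946L  # one off the hydroxylysine
  cfgBad <- FibrilConfig(crosslinkRules = rules)
  expect_error(placeCrosslinks(buildTopology(cfgBad)),
               "lysine|hydroxylysine")
})

test_that("bead coordinates respect axial positions, seeds and cutoffs", {
  topo <- conservationBundle()
  xyz <- generateCoordinates(topo, jitter = 0)
  expect_equal(unname(xyz[, 3]), sites(topo)$axial)

  j1 <- generateCoordinates(topo, seed = 9L, jitter = 0.05)
  j2 <- generateCoordinates(topo, seed = 9L, jitter = 0.05)
  expect_identical(j1, j2)
  expect_false(identical(j1, generateCoordinates(topo, seed = 10L,
                                                 jitter = 0.05)))

  # brute-force distance scan: every donor-acceptor pair within the cutoff
  big <- defaultFibril()
  bigXyz <- generateCoordinates(big, jitter = 0)
  x <- crosslinks(big)
  d <- sqrt(rowSums((bigXyz[x$donor, , drop = FALSE] -
                       bigXyz[x$acceptor, , drop = FALSE])^2))
  expect_true(all(d <= fibrilConfig(big)@axialCutoff))
})

test_that("structure and topology tables round-trip through disk", {
  topo <- conservationBundle()
  xyz <- generateCoordinates(topo, jitter = 0)
  dest <- file.path(tempdir(), "bundle")
  writeStructure(xyz, topo, dest)

  pdb <- readLines(paste0(dest, ".pdb"))
  expect_equal(sum(grepl("^ATOM", pdb)), nrow(sites(topo)))

  back <- readStructure(paste0(dest, ".pdb"))
  expect_equal(back$nSites, nrow(sites(topo)))
  expect_equal(nrow(back$crosslinkPairs), nrow(crosslinks(topo)))
  expect_lt(max(abs(back$coords - unname(xyz))), 1e-3)  # PDB prints 0.001 A

  rt <- readTopologyTables(dest)
  expect_equal(nrow(sites(rt)), nrow(sites(topo)))
  expect_equal(nrow(crosslinks(rt)), nrow(crosslinks(topo)))
  expect_equal(nrow(bonds(rt)), nrow(bonds(topo)))

  # coordinate/site count mismatch is a structural error
  expect_error(writeStructure(xyz[-1, ], topo, dest), "mismatch")

  # empty topology still writes a readable file
  empty <- singleChainTopology(2L)
  empty@sites <- sites(empty)[0, ]
  empty@bonds <- bonds(empty)[0, ]
  writeStructure(matrix(numeric(0), 0, 3), empty,
                 file.path(tempdir(), "empty"))
  backE <- readStructure(file.path(tempdir(), "empty.pdb"))
  expect_equal(backE$nSites, 0L)
})

test_that("fibril configuration round-trips through YAML", {
  cfg <- defaultFibrilConfig()
  f <- file.path(tempdir(), "cfg.yaml")
  writeFibrilConfig(cfg, f)
  back <- readFibrilConfig(f)
  expect_equal(back@nHelices, cfg@nHelices)
  expect_equal(back@adjacency, cfg@adjacency)
  expect_equal(back@crosslinkRules$N$acceptorSeq,
               cfg@crosslinkRules$N$acceptorSeq)
  expect_equal(back@overlapFraction, cfg@overlapFraction)
})

test_that("packaged synthetic chains carry the crosslink chemistry", {
  seqs <- defaultChainSequences()
  rules <- defaultCrosslinkRules()
  for (id in c("COL1A1", "COL1A2")) {
    expect_equal(nchar(seqs[[id]]), 1044L)
    expect_equal(substr(seqs[[id]], rules$N$donorSeq, rules$N$donorSeq), "K")
    expect_equal(substr(seqs[[id]], rules$N$acceptorSeq,
                        rules$N$acceptorSeq), "k")
    expect_equal(substr(seqs[[id]], rules$C$acceptorSeq,
                        rules$C$acceptorSeq), "k")
  }
})
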