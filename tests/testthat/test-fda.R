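test_that("static-frame forces match an independent Hooke evaluation", {
  # one bond stretched by a known amount
  cw <- chainWithForces(c(0, 1.5, 0))
  e <- forceEntries(cw$table)
  expect_equal(e$force, c(0, 1.5, 0), tolerance = 1e-9)

  # brute-force oracle on a randomly jittered fibril frame
  topo <- conservationBundle()
  coords <- generateCoordinates(topo, seed = 3L, jitter = 0.02)
  tab <- staticFrameForces(coords, topo, springConstant = 120,
                           crosslinkSpringConstant = 80,
                           interchainSpringConstant = 40)
  b <- bonds(topo)
  kOracle <- ifelse(b$type == "crosslink", 80,
                    ifelse(b$type == "interchain", 40, 120))
  oracle <- vapply(seq_len(nrow(b)), function(r) {
    kOracle[r] * (sqrt(sum((coords[b$i[r], ] - coords[b$j[r], ])^2)) - b$r0[r])
  }, numeric(1))
  expect_equal(forceEntries(tab)$force, oracle, tolerance = 1e-12)
})

test_that("pair forces are symmetric under index exchange", {
  tab <- fixtureSim()$table
  e <- forceEntries(tab)
  pick <- round(seq(1, nrow(e), length.out = 25))
  for (r in pick) {
    expect_identical(pairForce(tab, e$i[r], e$j[r]),
                     pairForce(tab, e$j[r], e$i[r]))
  }
})

test_that("a chain pulled at 1 nN per chain carries 1 nN mean bond force", {
  chain <- singleChainTopology(20L)
  tr <- simulatePulling(chain, SimulationParams(seed = 101L))
  e <- forceEntries(computePairwiseForces(tr))
  expect_true(all(e$type == "backbone"))
  sem <- blockedSemOfMeanForce(tr)
  expect_lt(abs(mean(e$force) - 1), 3 * sem)
})

test_that("unloaded control forces are negligible against the applied scale", {
  # the residual is the documented thermal Jacobian offset 2kT/r0 ~ 0.03 nN
  chain <- singleChainTopology(20L)
  tr <- simulatePulling(chain, SimulationParams(perChainForce = 0,
                                                seed = 102L))
  e <- forceEntries(computePairwiseForces(tr))
  kT <- 1.380649e-5 * 300
  jacobian <- 2 * kT / (67 / 234)
  expect_lt(abs(mean(e$force)), jacobian + 3 * blockedSemOfMeanForce(tr))
  expect_lt(abs(mean(e$force)), 0.1)  # negligible on the 1 nN scale
})

test_that("force-table differences follow hand-computed arithmetic", {
  a <- chainWithForces(c(2, 3, 5))$table
  b <- chainWithForces(c(1, 1, 7))$table
  d <- diffForceTables(a, b)
  expect_equal(forceEntries(d)$force, c(1, 2, -2), tolerance = 1e-9)

  self <- diffForceTables(a, a)
  expect_equal(forceEntries(self)$force, c(0, 0, 0))

  zero <- chainWithForces(c(0, 0, 0))$table
  expect_equal(forceEntries(diffForceTables(a, zero))$force,
               forceEntries(a)$force)

  other <- chainWithForces(c(1, 2))$table
  expect_error(diffForceTables(a, other), "bond sets differ")
})

test_that("windowed profiles reproduce brute-force window means", {
  # 12-residue chain, bond forces 1..11, w = 10 -> (5.5, 6.5)
  cw <- chainWithForces(1:11)
  pr <- windowedProfile(cw$table, cw$topo, w = 10)
  expect_equal(unname(pr@mean), c(mean(1:10), mean(2:11)))
  expect_equal(pr@centers, c(1, 2) + 4.5)

  # w = 1 returns the raw per-bond series
  pr1 <- windowedProfile(cw$table, cw$topo, w = 1)
  expect_equal(unname(pr1@mean), as.numeric(1:11))

  # constant force -> constant profile
  cwc <- chainWithForces(rep(2.5, 11))
  prc <- windowedProfile(cwc$table, cwc$topo, w = 10)
  expect_equal(unname(prc@mean), rep(2.5, length(prc@centers)),
               tolerance = 1e-9)

  expect_error(windowedProfile(cw$table, cw$topo, w = 50), "window")
  expect_error(windowedProfile(cw$table, cw$topo, w = 0), "window")
})

test_that("locateMaxima ranks by force with documented tie-breaking", {
  peak <- chainWithForces(c(0, 0, 0, 0, 4, 0, 0, 0, 0))
  lm <- locateMaxima(windowedProfile(peak$table, peak$topo, w = 1), "N")
  expect_equal(lm$center[1], 5)
  expect_true(is.na(lm$distanceToCrosslink[1]))  # no crosslinks here

  flat <- chainWithForces(rep(0, 9), r0 = 0.25)  # exactly tied values
  lmf <- locateMaxima(windowedProfile(flat$table, flat$topo, w = 3), "N")
  expect_equal(lmf$center, sort(lmf$center))  # ties broken ascending
})

test_that("fixture profile peaks adjacent to a crosslink (brute-force argmax)", {
  fx <- fixtureSim()
  pr <- fx$profile
  expect_equal(ncol(pr@perPair), 2L)  # one series per crosslink-connected pair
  lmN <- locateMaxima(pr, "N")
  lmC <- locateMaxima(pr, "C")
  # brute-force scan agrees with the ranked output
  expect_equal(lmN$center[1], pr@centers[which.max(pr@mean)])
  # the top window sits within one window length of a crosslink
  expect_lte(min(lmN$distanceToCrosslink[1], lmC$distanceToCrosslink[1]),
             pr@window)
})

test_that("crosslink-proximal windows dominate the gap-region level", {
  fx <- fixtureSim()
  pr <- fx$profile
  cfg <- fibrilConfig(fx$topo)
  gapWins <- pr@centers > cfg@overlapFraction * cfg@staggerResidues
  nearX <- vapply(pr@centers, function(c0)
    min(abs(c0 - unlist(pr@crosslinkPositions))) <= 5, logical(1))
  expect_true(any(gapWins) && any(nearX))
  expect_gte(max(pr@mean[nearX]), mean(pr@mean[gapWins]))
})

test_that("telopeptides off the crosslink path carry minimal force", {
  fx <- fixtureSim()
  e <- forceEntries(fx$table)
  s <- sites(fx$topo)
  telo <- e$type == "backbone" &
    s$region[e$i] == "telopeptide" & s$region[e$j] == "telopeptide"
  helical <- e$type == "backbone" &
    s$region[e$i] != "telopeptide" & s$region[e$j] != "telopeptide"
  expect_lt(mean(abs(e$force[telo])), 0.5 * mean(abs(e$force[helical])))
})

test_that("profile standard errors are computed across pairs", {
  pr <- fixtureSim()$profile
  manual <- apply(pr@perPair, 1, stats::sd) / sqrt(ncol(pr@perPair))
  expect_equal(unname(pr@sem), unname(manual))
})
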