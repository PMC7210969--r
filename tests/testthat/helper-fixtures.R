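# Shared fixtures, computed lazily and cached for the whole run.
.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Full default fibril segment (build + crosslinks), deterministic.
defaultFibril <- function() {
  cached("defaultFibril", placeCrosslinks(buildTopology(defaultFibrilConfig())))
}

# Scaled segment + 60 ns loaded run: the trajectory fixture for FDA
# property tests. The scaled segment needs ~40 ns to take up crosslink and
# telopeptide slack, hence production averaging over the final third.
fixtureSim <- function() {
  cached("fixtureSim", {
    topo <- miniFibrilTopology(40L)
    params <- SimulationParams(nSteps = 300000L, recordEvery = 1000L,
                               seed = 11L, equilFraction = 2 / 3)
    traj <- simulatePulling(topo, params)
    table <- computePairwiseForces(traj)
    list(topo = topo, traj = traj, table = table,
         profile = windowedProfile(table, topo, w = 10))
  })
}

# Small one-of-each-stagger-class bundle for conservation mapping.
conservationBundle <- function() {
  cached("conservationBundle", {
    cfg <- FibrilConfig(nHelices = 5, staggerClass = 0:4,
                        adjacency = rbind(c(1L, 5L)))
    placeCrosslinks(buildTopology(cfg))
  })
}

# A straight chain whose static bond forces are exactly `forces`:
# bead spacing r0 + f/k along z.
chainWithForces <- function(forces, k = 300, r0 = 67 / 234) {
  topo <- singleChainTopology(length(forces) + 1L, spacing = r0)
  z <- c(0, cumsum(r0 + forces / k))
  coords <- cbind(0, 0, z)
  list(topo = topo,
       table = staticFrameForces(coords, topo, springConstant = k))
}

# Blocked standard error of the chain-mean bond force over retained frames.
blockedSemOfMeanForce <- function(traj, nBlocks = 10) {
  topo <- traj@topology
  b <- bonds(topo)
  k <- traj@params@springConstant
  fr <- trajectoryFrames(traj)
  perFrame <- apply(fr, 1, function(m) {
    d <- m[b$i, , drop = FALSE] - m[b$j, , drop = FALSE]
    mean(k * (sqrt(rowSums(d * d)) - b$r0))
  })
  bm <- vapply(split(perFrame, cut(seq_along(perFrame), nBlocks)),
               mean, numeric(1))
  stats::sd(bm) / sqrt(length(bm))
}
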