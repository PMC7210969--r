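## fibril_topology: build the D-periodic, crosslinked, coarse-grained
## collagen I segment that every downstream analysis consumes.

.hexLatticePositions <- function(n, a) {
  ## centred hexagonal packing: center, then rings of 6*k sites
  pos <- matrix(0, 0, 2)
  ring <- 0L
  while (nrow(pos) < n) {
    if (ring == 0L) {
      pos <- rbind(pos, c(0, 0))
    } else {
      dirs <- rbind(c(-1, 1), c(-1, 0), c(0, -1), c(1, -1), c(1, 0), c(0, 1))
      q <- ring; r <- 0L
      for (d in seq_len(6L)) for (s in seq_len(ring)) {
        pos <- rbind(pos, c(a * (q + r / 2), a * (sqrt(3) / 2 * r)))
        q <- q + dirs[d, 1]; r <- r + dirs[d, 2]
      }
    }
    ring <- ring + 1L
  }
  pos[seq_len(n), , drop = FALSE]
}

#' Construct a fibril configuration
#'
#' Creates a \linkS4class{FibrilConfig}. All defaults reproduce the packaged
#' one-gap-plus-one-overlap segment of 37 triple helices: D = 67 nm, 234
#' residues per D-stagger (axial rise D/234 ~ 0.2863 nm/residue), overlap
#' fraction 0.46 (Hodge--Petruska convention), helix stagger classes
#' \code{(i-1) mod 5}, and six lattice-neighbour adjacency pairs whose
#' stagger classes differ by 4, the geometry in which both the N- and
#' C-terminal HLKNL rule sites fall inside the segment in axial register.
#'
#' @param nHelices number of triple helices (default 37).
#' @param D axial period, nm (default 67).
#' @param staggerResidues residues per D-stagger (default 234).
#' @param axialRise nm per residue (default \code{D/staggerResidues}).
#' @param overlapFraction overlap fraction of D (default 0.46).
#' @param chainComposition identifiers of the three chains per helix.
#' @param staggerClass integer vector of per-helix stagger classes 0--4.
#' @param adjacency two-column matrix of crosslink-eligible helix pairs.
#' @param crosslinkRules named list (N, C) of HLKNL donor/acceptor rules;
#'   see \linkS4class{FibrilConfig}.
#' @param latticeSpacing lateral helix spacing, nm (default 1.3).
#' @param teloN,teloC integer(2) sequence-index ranges of the telopeptides.
#' @param axialCutoff maximal donor-acceptor axial separation, nm.
#' @param windRadius minor-helix winding radius of the three chains about
#'   the helix axis, nm (0 gives straight chains on the axis).
#' @return a validated \linkS4class{FibrilConfig}.
#' @examples
#' cfg <- FibrilConfig(nHelices = 5,
#'                     staggerClass = 0:4,
#'                     adjacency = rbind(c(1L, 5L)))
#' cfg
#' @export
FibrilConfig <- function(nHelices = 37L,
                         D = 67,
                         staggerResidues = 234L,
                         axialRise = D / staggerResidues,
                         overlapFraction = 0.46,
                         chainComposition = c("COL1A1", "COL1A1", "COL1A2"),
                         staggerClass = (seq_len(nHelices) - 1L) %% 5L,
                         adjacency = NULL,
                         crosslinkRules = defaultCrosslinkRules(),
                         latticeSpacing = 1.3,
                         teloN = c(1L, 16L),
                         teloC = c(1020L, 1044L),
                         axialCutoff = 2.0,
                         windRadius = 0.3) {
  nHelices <- as.integer(nHelices)
  if (is.null(adjacency)) {
    adjacency <- if (nHelices >= 37L) {
      rbind(c(1L, 5L), c(6L, 15L), c(10L, 11L), c(20L, 21L),
            c(25L, 26L), c(35L, 36L))
    } else {
      matrix(integer(0), 0, 2)
    }
  }
  adjacency <- matrix(as.integer(adjacency), ncol = 2)
  if (nrow(adjacency) > 0 &&
      (any(adjacency < 1L) || any(adjacency > nHelices)))
    stop("configuration error: adjacency references helix indices outside 1..",
         nHelices)
  new("FibrilConfig",
      nHelices = nHelices, D = D,
      staggerResidues = as.integer(staggerResidues),
      axialRise = axialRise, overlapFraction = overlapFraction,
      chainComposition = chainComposition,
      staggerClass = as.integer(staggerClass),
      adjacency = adjacency, crosslinkRules = crosslinkRules,
      latticeSpacing = latticeSpacing,
      teloN = as.integer(teloN), teloC = as.integer(teloC),
      axialCutoff = axialCutoff, windRadius = windRadius)
}

#' Default HLKNL crosslink rules
#'
#' N-terminal rule: telopeptide lysine at sequence position 9 donates to the
#' helical hydroxylysine at position 945 (= 9 + 4 x 234, i.e. exact axial
#' register across a 4D stagger) of the partner helix. C-terminal rule:
#' telopeptide lysine at 1041 donates to the helical hydroxylysine at 105
#' (= 1041 - 4 x 234). Donor and acceptor sit on chain 1 (an alpha1 chain)
#' of their helices. These positions are documented conventions; any
#' published telopeptide/helical lysine numbering can be substituted.
#'
#' @return named list with elements \code{N} and \code{C}.
#' @export
defaultCrosslinkRules <- function() {
  list(
    N = list(donorSeq = 9L, acceptorSeq = 945L,
             donorChain = 1L, acceptorChain = 1L,
             donorResidue = "K", acceptorResidue = "k"),
    C = list(donorSeq = 1041L, acceptorSeq = 105L,
             donorChain = 1L, acceptorChain = 1L,
             donorResidue = "K", acceptorResidue = "k")
  )
}

#' @describeIn FibrilConfig the packaged default 37-helix configuration.
#' @export
defaultFibrilConfig <- function() FibrilConfig()

#' Packaged synthetic rat-like collagen I chain sequences
#'
#' Returns the two packaged alpha-chain sequences (synthetic stand-ins for
#' rat COL1A1/COL1A2, generated by \code{\link{syntheticChainSequence}}):
#' 1044 residues each, Gly-X-Y repeats over the helical region (positions
#' 17--1019), N- and C-telopeptides with the donor lysines of
#' \code{\link{defaultCrosslinkRules}}, hydroxylysine (\code{k}) at the
#' acceptor positions, 4-hydroxyproline as \code{o}, and Tyr/Phe/Met
#' enrichment near the crosslink acceptor sites.
#'
#' @return named character vector with elements \code{COL1A1}, \code{COL1A2}.
#' @export
defaultChainSequences <- function() {
  f <- system.file("extdata", "collagenI_chains_synthetic.fasta",
                   package = "colmech", mustWork = TRUE)
  seqs <- Biostrings::readBStringSet(f)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Generate a synthetic collagen-like alpha-chain sequence
#'
#' Deterministic (seeded) generator for the packaged synthetic chains:
#' Gly every third residue of the helical region, X/Y positions drawn from
#' a collagen-like composition with 4-hydroxyproline written as \code{o},
#' hydroxylysine \code{k} fixed at the crosslink acceptor positions, lysine
#' \code{K} fixed at the telopeptide donor positions, and Tyr/Phe/Met
#' probability boosted within \code{enrichRadius} residues of the acceptor
#' positions.
#'
#' @param chainId sequence name.
#' @param nRes chain length (default 1044 = round(4.46 x 234)).
#' @param teloN,teloC telopeptide index ranges.
#' @param rules crosslink rules (for donor/acceptor positions).
#' @param enrichRadius half-width (residues) of the redox-residue enrichment
#'   zone around acceptor positions.
#' @param seed RNG seed.
#' @return a single character string of length \code{nRes}.
#' @export
syntheticChainSequence <- function(chainId = "COL1A1", nRes = 1044L,
                                   teloN = c(1L, 16L), teloC = c(1020L, 1044L),
                                   rules = defaultCrosslinkRules(),
                                   enrichRadius = 12L, seed = 101L) {
  set.seed(seed)
  aa <- rep("A", nRes)
  heloStart <- teloN[2] + 1L
  heloEnd <- teloC[1] - 1L
  ## collagen-like X/Y composition; 'o' = 4-hydroxyproline
  bg <- c(P = 0.18, o = 0.18, A = 0.12, E = 0.07, R = 0.06, S = 0.05,
          D = 0.05, K = 0.05, Q = 0.04, L = 0.04, V = 0.04, N = 0.03,
          T = 0.03, I = 0.02, F = 0.015, Y = 0.01, M = 0.005,
          H = 0.01, W = 0.002, C = 0.001)
  bg <- bg / sum(bg)
  enr <- bg
  enr[c("Y", "F", "M")] <- c(0.14, 0.10, 0.05)
  enr <- enr / sum(enr)
  acceptorPos <- c(rules$N$acceptorSeq, rules$C$acceptorSeq)
  for (j in heloStart:heloEnd) {
    if ((j - heloStart) %% 3L == 0L) {
      aa[j] <- "G"
    } else {
      p <- if (min(abs(j - acceptorPos)) <= enrichRadius) enr else bg
      aa[j] <- sample(names(p), 1L, prob = p)
    }
  }
  telo <- c("Q", "L", "S", "Y", "G", "D", "E", "K", "S", "T", "A", "G", "I",
            "S", "V", "P")
  for (idx in seq(teloN[1], teloN[2]))
    aa[idx] <- telo[((idx - teloN[1]) %% length(telo)) + 1L]
  for (idx in seq(teloC[1], teloC[2]))
    aa[idx] <- telo[((idx - teloC[1] + 3L) %% length(telo)) + 1L]
  ## fix the crosslink chemistry
  aa[rules$N$donorSeq] <- "K"
  aa[rules$C$donorSeq] <- "K"
  aa[rules$N$acceptorSeq] <- "k"
  aa[rules$C$acceptorSeq] <- "k"
  paste(aa, collapse = "")
}

.teloRange <- function(cfg) {
  list(N = seq(cfg@teloN[1], cfg@teloN[2]),
       C = seq(cfg@teloC[1], cfg@teloC[2]))
}

.chainResidues <- function(cfg) {
  as.integer(round((4 + cfg@overlapFraction) * cfg@staggerResidues))
}

#' Build the coarse-grained fibril segment topology
#'
#' Places every helix of the configuration with its D-stagger, truncates
#' residues to the one-D-period axial window [0, D], labels each residue
#' site as telopeptide / overlap / gap, and creates the backbone bead-bead
#' bonds. Fully deterministic. Crosslinks are added by
#' \code{\link{placeCrosslinks}}.
#'
#' A helix with stagger class \code{s} is one collagen molecule whose
#' N-terminus sits at axial coordinate \code{-s * D}; with the chain length
#' \code{round((4 + overlapFraction) * staggerResidues)} this yields five
#' molecules crossing the overlap region and four crossing the gap, the
#' Hodge--Petruska quarter-stagger picture.
#'
#' @param config a \linkS4class{FibrilConfig}.
#' @param sequences named character vector (or \code{BStringSet}) covering
#'   all identifiers of \code{chainComposition}; defaults to the packaged
#'   synthetic chains.
#' @return a \linkS4class{FibrilTopology} (no crosslinks yet).
#' @examples
#' topo <- buildTopology(FibrilConfig(nHelices = 5, staggerClass = 0:4,
#'                                    adjacency = rbind(c(1L, 5L))))
#' topo
#' @export
buildTopology <- function(config, sequences = defaultChainSequences()) {
  validObject(config)
  if (methods::is(sequences, "XStringSet")) {
    nm <- names(sequences)
    sequences <- as.character(sequences)
    names(sequences) <- nm
  }
  missing <- setdiff(unique(config@chainComposition), names(sequences))
  if (length(missing))
    stop("configuration error: no sequence provided for chain(s) ",
         paste(missing, collapse = ", "))
  nRes <- .chainResidues(config)
  telo <- .teloRange(config)
  D <- config@D; rise <- config@axialRise
  eps <- 1e-9
  pieces <- vector("list", config@nHelices * 3L)
  n <- 0L
  for (h in seq_len(config@nHelices)) {
    s <- config@staggerClass[h]
    z0 <- -s * D
    for (c in 1:3) {
      id <- config@chainComposition[c]
      seq <- sequences[[id]]
      if (nchar(seq) < nRes)
        stop("structural error: sequence '", id, "' has ", nchar(seq),
             " residues but the segment requires ", nRes)
      j <- seq_len(nRes)
      z <- z0 + (j - 1) * rise
      keep <- z >= -eps & z <= D + eps
      if (!any(keep)) next
      j <- j[keep]; z <- pmin(pmax(z[keep], 0), D)
      res <- strsplit(substr(seq, 1L, nRes), "")[[1]][j]
      region <- ifelse(z <= config@overlapFraction * D, "overlap", "gap")
      region[j %in% telo$N | j %in% telo$C] <- "telopeptide"
      n <- n + 1L
      pieces[[n]] <- data.frame(helix = h, chain = c, seqIndex = j,
                                residue = res, axial = z, region = region,
                                stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, pieces[seq_len(n)])
  sites <- S4Vectors::DataFrame(df)
  topo <- new("FibrilTopology", config = config, sites = sites,
              crosslinks = .emptyCrosslinks(), bonds = .emptyBonds())
  topo@bonds <- rbind(.backboneBonds(topo), .interchainBonds(topo))
  validObject(topo)
  topo
}

## Soft diagonal springs between the chains of a helix: chain 1 residue j
## to chain 2 residue j+1, chain 2 j to chain 3 j+1, chain 3 j to chain 1
## j+1 -- the one-residue interchain stagger of the triple helix. The
## diagonal geometry matters mechanically: it pre-tilts the springs so
## axial load transfers linearly between chains, letting a molecule that
## terminates inside the segment hand its three-chain load over through a
## crosslink that sits on a single chain.
.interchainBonds <- function(topology) {
  s <- topology@sites
  xyz <- .idealCoordinates(topology)
  out <- .emptyBonds()
  key <- paste(s$helix, s$chain, s$seqIndex)
  pairs <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  for (cc in pairs) {
    a <- which(s$chain == cc[1])
    m <- match(paste(s$helix[a], cc[2], s$seqIndex[a] + 1L), key)
    ok <- !is.na(m)
    i <- a[ok]; j <- m[ok]
    if (!length(i)) next
    r0 <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
    out <- rbind(out, S4Vectors::DataFrame(i = i, j = j,
                                           type = "interchain", r0 = r0))
  }
  out
}

.bondSpringConstants <- function(types, params) {
  ifelse(types == "crosslink", params@crosslinkSpringConstant,
         ifelse(types == "interchain", params@interchainSpringConstant,
                params@springConstant))
}

.emptyCrosslinks <- function() {
  S4Vectors::DataFrame(id = character(0), kind = character(0),
                       terminal = character(0), donor = integer(0),
                       acceptor = integer(0))
}

.emptyBonds <- function() {
  S4Vectors::DataFrame(i = integer(0), j = integer(0), type = character(0),
                       r0 = numeric(0))
}

.backboneBonds <- function(topology) {
  s <- topology@sites
  xyz <- .idealCoordinates(topology)
  ord <- order(s$helix, s$chain, s$seqIndex)
  i <- ord[-length(ord)]; j <- ord[-1]
  ok <- s$helix[i] == s$helix[j] & s$chain[i] == s$chain[j] &
    s$seqIndex[j] == s$seqIndex[i] + 1L
  i <- i[ok]; j <- j[ok]
  r0 <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
  S4Vectors::DataFrame(i = i, j = j, type = "backbone", r0 = r0)
}

## Deterministic jitter-free bead coordinates: helix axes on the hex
## lattice, three chains wound about each axis; z equals the site's axial
## coordinate. windRadius = 0 collapses the winding (straight chains).
.idealCoordinates <- function(topology) {
  cfg <- topology@config
  s <- topology@sites
  centers <- .hexLatticePositions(cfg@nHelices, cfg@latticeSpacing)
  wr <- cfg@windRadius
  pitch <- 8.6
  phi <- 2 * pi * s$axial / pitch + 2 * pi * (s$chain - 1) / 3
  cbind(x = centers[s$helix, 1] + wr * cos(phi),
        y = centers[s$helix, 2] + wr * sin(phi),
        z = s$axial)
}

#' Place HLKNL crosslinks on a built topology
#'
#' For every adjacency pair whose N- and C-terminal rule sites (donor
#' telopeptide lysine, acceptor helical hydroxylysine) both lie inside the
#' segment and within the configured axial cutoff, creates exactly one
#' N-terminal and one C-terminal HLKNL crosslink and appends the
#' corresponding bonds. Idempotent: existing crosslinks are recomputed from
#' scratch.
#'
#' @param topology a \linkS4class{FibrilTopology} from
#'   \code{\link{buildTopology}}.
#' @return the topology with \code{crosslinks} populated and crosslink
#'   bonds appended.
#' @export
placeCrosslinks <- function(topology) {
  cfg <- topology@config
  s <- topology@sites
  xyz <- .idealCoordinates(topology)
  ## idempotence: drop any previous crosslink bonds and records
  topology@bonds <- topology@bonds[topology@bonds$type != "crosslink", ]
  recs <- list(); bnds <- list(); n <- 0L
  findSite <- function(helix, chain, seqIdx) {
    which(s$helix == helix & s$chain == chain & s$seqIndex == seqIdx)
  }
  for (p in seq_len(nrow(cfg@adjacency))) {
    a <- cfg@adjacency[p, 1]; b <- cfg@adjacency[p, 2]
    for (terminal in c("N", "C")) {
      rule <- cfg@crosslinkRules[[terminal]]
      placed <- FALSE
      for (orient in list(c(a, b), c(b, a))) {
        if (placed) next
        dRow <- findSite(orient[1], rule$donorChain, rule$donorSeq)
        aRow <- findSite(orient[2], rule$acceptorChain, rule$acceptorSeq)
        if (length(dRow) != 1L || length(aRow) != 1L) next
        if (abs(s$axial[dRow] - s$axial[aRow]) > cfg@axialCutoff) next
        if (!s$residue[dRow] %in% c("K", "k"))
          stop("validation error: crosslink rule ", terminal,
               " donor position ", rule$donorSeq, " is '", s$residue[dRow],
               "', not a lysine/hydroxylysine")
        if (!s$residue[aRow] %in% c("K", "k"))
          stop("validation error: crosslink rule ", terminal,
               " acceptor position ", rule$acceptorSeq, " is '",
               s$residue[aRow], "', not a lysine/hydroxylysine")
        n <- n + 1L
        recs[[n]] <- data.frame(
          id = sprintf("HLKNL_%s_h%d_h%d", terminal, orient[1], orient[2]),
          kind = "HLKNL", terminal = terminal,
          donor = dRow, acceptor = aRow, stringsAsFactors = FALSE)
        r0 <- sqrt(sum((xyz[dRow, ] - xyz[aRow, ])^2))
        bnds[[n]] <- data.frame(i = dRow, j = aRow, type = "crosslink",
                                r0 = r0, stringsAsFactors = FALSE)
        placed <- TRUE
      }
    }
  }
  if (n > 0) {
    topology@crosslinks <- S4Vectors::DataFrame(do.call(rbind, recs))
    topology@bonds <- rbind(topology@bonds,
                            S4Vectors::DataFrame(do.call(rbind, bnds)))
  } else {
    topology@crosslinks <- .emptyCrosslinks()
  }
  validObject(topology)
  topology
}

#' Generate bead coordinates for a topology
#'
#' One bead per residue: helix axes on the lateral hexagonal lattice, the
#' three chains of a helix wound about the axis with the configured winding
#' radius, and each bead's z equal to its residue's axial coordinate.
#' Optional seeded Gaussian jitter.
#'
#' @param topology a \linkS4class{FibrilTopology}.
#' @param seed RNG seed (only used when \code{jitter > 0}).
#' @param jitter standard deviation (nm) of isotropic Gaussian displacement.
#' @return numeric matrix (nSites x 3), nm.
#' @export
generateCoordinates <- function(topology, seed = 1L, jitter = 0) {
  if (topology@config@latticeSpacing <= 0)
    stop("configuration error: latticeSpacing must be positive")
  xyz <- .idealCoordinates(topology)
  if (jitter > 0) {
    set.seed(seed)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = jitter), ncol = 3)
  }
  xyz
}

#' Build a minimal single-chain topology
#'
#' A straight, un-crosslinked bead-spring chain along z: the fixture used by
#' the force-distribution oracle (a chain pulled at a constant per-chain
#' force develops a uniform mean bond tension equal to the applied force).
#'
#' @param nBeads number of beads.
#' @param spacing bond rest length / bead spacing, nm.
#' @return a \linkS4class{FibrilTopology} with one helix, one chain.
#' @export
singleChainTopology <- function(nBeads = 20L, spacing = 67 / 234) {
  cfg <- FibrilConfig(nHelices = 1L, D = spacing * 234, staggerResidues = 234L,
                      axialRise = spacing, staggerClass = 0L,
                      adjacency = matrix(integer(0), 0, 2),
                      teloN = c(0L, 0L), teloC = c(0L, 0L),
                      windRadius = 0)
  j <- seq_len(as.integer(nBeads))
  sites <- S4Vectors::DataFrame(
    helix = 1L, chain = 1L, seqIndex = j, residue = "G",
    axial = (j - 1) * spacing, region = "overlap")
  topo <- new("FibrilTopology", config = cfg, sites = sites,
              crosslinks = .emptyCrosslinks(), bonds = .emptyBonds())
  topo@bonds <- .backboneBonds(topo)
  topo
}

#' Geometrically scaled fibril segment for affordable simulation
#'
#' Builds a fibril topology with the full default bundle (37 helices, same
#' adjacency and stagger classes) but a reduced D-stagger of
#' \code{staggerResidues} residues, shrinking every chain proportionally
#' while preserving the one-gap-plus-one-overlap geometry, the 12-crosslink
#' count and the crosslink axial-register arithmetic (N acceptor = N donor
#' + 4 x staggerResidues, C acceptor = C donor - 4 x staggerResidues).
#' Sequences are generated on the fly by
#' \code{\link{syntheticChainSequence}} with matching dimensions. Intended
#' as the standard fixture for trajectory-based analyses, where the
#' full-size segment would be needlessly expensive.
#'
#' For trajectory work the default is a 7-helix bundle (the central hexagon
#' of the lattice, one helix per stagger class plus repeats) with two
#' crosslink-eligible class-\{0,4\} neighbour pairs.
#'
#' @param staggerResidues residues per D-stagger (default 60).
#' @param nHelices bundle size (default 7).
#' @param adjacency crosslink-eligible pairs; defaults to the class-\{0,4\}
#'   lattice-neighbour pairs of the chosen bundle size.
#' @param seed seed for the scaled synthetic sequences.
#' @return a crosslinked \linkS4class{FibrilTopology}.
#' @export
miniFibrilTopology <- function(staggerResidues = 60L, nHelices = 7L,
                               adjacency = NULL, seed = 303L) {
  m <- as.integer(staggerResidues)
  rise <- 67 / 234
  nRes <- as.integer(round((4 + 0.46) * m))
  teloN <- c(1L, 4L)
  teloC <- c(nRes - 6L, nRes)
  rules <- list(
    N = list(donorSeq = 2L, acceptorSeq = 2L + 4L * m,
             donorChain = 1L, acceptorChain = 1L,
             donorResidue = "K", acceptorResidue = "k"),
    C = list(donorSeq = nRes - 3L, acceptorSeq = nRes - 3L - 4L * m,
             donorChain = 1L, acceptorChain = 1L,
             donorResidue = "K", acceptorResidue = "k"))
  if (is.null(adjacency)) {
    adjacency <- if (nHelices >= 37L) NULL
    else if (nHelices >= 7L) rbind(c(1L, 5L), c(6L, 5L))
    else matrix(integer(0), 0, 2)
  }
  cfg <- FibrilConfig(nHelices = nHelices, D = m * rise,
                      staggerResidues = m, axialRise = rise,
                      teloN = teloN, teloC = teloC,
                      crosslinkRules = rules,
                      adjacency = adjacency)
  seqs <- c(
    COL1A1 = syntheticChainSequence("COL1A1", nRes = nRes, teloN = teloN,
                                    teloC = teloC, rules = rules,
                                    enrichRadius = 6L, seed = seed),
    COL1A2 = syntheticChainSequence("COL1A2", nRes = nRes, teloN = teloN,
                                    teloC = teloC, rules = rules,
                                    enrichRadius = 6L, seed = seed + 1L))
  placeCrosslinks(buildTopology(cfg, seqs))
}
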