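#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

## Physical constants used across the package (CODATA 2018).
## Internal units: nm, nN, ns, K; energies in nN*nm; fields in mT.
.constants <- list(
  kB        = 1.380649e-5,      # Boltzmann constant, nN*nm/K
  planck    = 6.62607015e-34,   # J*s
  bohrMagneton = 9.2740100783e-24, # J/T
  gravity   = 9.8               # m/s^2; 350 g -> 3.43 N as printed
)

#' FibrilConfig: geometry and chemistry of a D-periodic collagen fibril segment
#'
#' Holds everything needed to build a coarse-grained (one bead per residue)
#' segment of a collagen I fibril spanning exactly one D-period: the number
#' of triple helices in the bundle, the axial period \code{D} (nm), the
#' D-stagger in residues, the overlap fraction of the Hodge--Petruska
#' scheme, the chain composition of each triple helix, the lateral lattice,
#' the helix pairs eligible for crosslinking, and the HLKNL crosslink rules.
#'
#' @slot nHelices number of triple helices in the bundle.
#' @slot D axial period length in nm.
#' @slot staggerResidues residues per D-stagger.
#' @slot axialRise nm of axial rise per residue; must equal
#'   \code{D/staggerResidues}.
#' @slot overlapFraction fraction of the D-period occupied by the overlap
#'   region (all five stagger classes present).
#' @slot chainComposition character(3), sequence identifiers of the three
#'   chains of each helix (two alpha1 + one alpha2 by default).
#' @slot staggerClass integer vector, one D-stagger class (0--4) per helix.
#' @slot adjacency two-column integer matrix of helix index pairs eligible
#'   for crosslinking.
#' @slot crosslinkRules named list with elements \code{N} and \code{C}, each
#'   a list with \code{donorSeq}, \code{acceptorSeq}, \code{donorChain},
#'   \code{acceptorChain}, \code{donorResidue}, \code{acceptorResidue}.
#' @slot latticeSpacing lateral inter-helix distance, nm.
#' @slot teloN,teloC integer(2) 1-based sequence index ranges of the N- and
#'   C-telopeptides.
#' @slot axialCutoff maximal axial donor-acceptor separation for a
#'   crosslink, nm.
#' @exportClass FibrilConfig
setClass("FibrilConfig",
  representation(
    nHelices = "integer",
    D = "numeric",
    staggerResidues = "integer",
    axialRise = "numeric",
    overlapFraction = "numeric",
    chainComposition = "character",
    staggerClass = "integer",
    adjacency = "matrix",
    crosslinkRules = "list",
    latticeSpacing = "numeric",
    teloN = "integer",
    teloC = "integer",
    axialCutoff = "numeric",
    windRadius = "numeric"
  )
)

setValidity("FibrilConfig", function(object) {
  msg <- character(0)
  if (object@nHelices < 1L)
    msg <- c(msg, "nHelices must be >= 1")
  if (!(object@overlapFraction > 0 && object@overlapFraction < 1))
    msg <- c(msg, "overlapFraction must lie strictly between 0 and 1")
  if (abs(object@axialRise * object@staggerResidues - object@D) > 1e-9)
    msg <- c(msg, "axialRise * staggerResidues must equal D within 1e-9 nm")
  if (length(object@staggerClass) != object@nHelices)
    msg <- c(msg, "staggerClass must have one entry per helix")
  if (nrow(object@adjacency) > 0) {
    if (ncol(object@adjacency) != 2L)
      msg <- c(msg, "adjacency must be a two-column matrix")
    else if (any(object@adjacency < 1L) ||
             any(object@adjacency > object@nHelices))
      msg <- c(msg, "adjacency pairs must reference valid helix indices")
  }
  if (length(object@chainComposition) != 3L)
    msg <- c(msg, "chainComposition must name the three chains of a helix")
  if (object@latticeSpacing <= 0)
    msg <- c(msg, "latticeSpacing must be positive")
  if (length(msg)) msg else TRUE
})

#' FibrilTopology: the built coarse-grained fibril segment
#'
#' The central container consumed by every downstream analysis. \code{sites}
#' is one row per residue bead (helix, chain, 1-based sequence index,
#' one-letter residue code with lowercase k = hydroxylysine and o =
#' 4-hydroxyproline, axial coordinate in nm, region label), \code{crosslinks}
#' one row per HLKNL crosslink (donor/acceptor site row indices, terminal
#' N or C), and \code{bonds} the bonded topology (site row indices, type
#' backbone or crosslink, rest length r0 in nm).
#'
#' @slot config the \linkS4class{FibrilConfig} the segment was built from.
#' @slot sites \code{DataFrame} of residue sites.
#' @slot crosslinks \code{DataFrame} of crosslinks (possibly zero rows).
#' @slot bonds \code{DataFrame} of bonds.
#' @exportClass FibrilTopology
setClass("FibrilTopology",
  representation(
    config = "FibrilConfig",
    sites = "DataFrame",
    crosslinks = "DataFrame",
    bonds = "DataFrame"
  )
)

setValidity("FibrilTopology", function(object) {
  msg <- character(0)
  s <- object@sites
  need <- c("helix", "chain", "seqIndex", "residue", "axial", "region")
  if (!all(need %in% colnames(s)))
    msg <- c(msg, paste("sites must have columns:", paste(need, collapse = ", ")))
  b <- object@bonds
  if (nrow(b) > 0 && !all(c("i", "j", "type", "r0") %in% colnames(b)))
    msg <- c(msg, "bonds must have columns i, j, type, r0")
  x <- object@crosslinks
  if (nrow(x) > 0) {
    if (!all(c("id", "kind", "terminal", "donor", "acceptor") %in% colnames(x)))
      msg <- c(msg, "crosslinks must have columns id, kind, terminal, donor, acceptor")
    else {
      if (any(s$region[x$donor] != "telopeptide"))
        msg <- c(msg, "all crosslink donors must be telopeptide sites")
      if (any(s$helix[x$donor] == s$helix[x$acceptor]))
        msg <- c(msg, "crosslinks must join different helices")
    }
  }
  if (length(msg)) msg else TRUE
})

#' SimulationParams: parameters of the overdamped Langevin pulling run
#'
#' @slot springConstant backbone bond spring constant, nN/nm.
#' @slot crosslinkSpringConstant crosslink bond spring constant, nN/nm.
#' @slot interchainSpringConstant intra-helix chain-chain spring constant,
#'   nN/nm.
#' @slot temperature K.
#' @slot friction bead friction coefficient, nN*ns/nm.
#' @slot timestep integration step, ns.
#' @slot nSteps number of integration steps.
#' @slot recordEvery record a frame every this many steps.
#' @slot seed RNG seed.
#' @slot perChainForce average external force per chain, nN.
#' @slot loadingMode "equal" or "shear".
#' @slot shearWeights per-helix force multipliers (mean 1); empty = all 1.
#' @slot equilFraction leading fraction of recorded frames flagged as
#'   equilibration and excluded from downstream averaging.
#' @slot ruptureLength bond length (nm) beyond which the run is flagged.
#' @exportClass SimulationParams
setClass("SimulationParams",
  representation(
    springConstant = "numeric",
    crosslinkSpringConstant = "numeric",
    interchainSpringConstant = "numeric",
    temperature = "numeric",
    friction = "numeric",
    timestep = "numeric",
    nSteps = "integer",
    recordEvery = "integer",
    seed = "integer",
    perChainForce = "numeric",
    loadingMode = "character",
    shearWeights = "numeric",
    equilFraction = "numeric",
    ruptureLength = "numeric"
  )
)

setValidity("SimulationParams", function(object) {
  msg <- character(0)
  if (object@timestep <= 0) msg <- c(msg, "timestep must be > 0")
  if (object@nSteps < 1L) msg <- c(msg, "nSteps must be >= 1")
  if (!object@loadingMode %in% c("equal", "shear"))
    msg <- c(msg, "loadingMode must be 'equal' or 'shear'")
  if (object@loadingMode == "equal" && length(object@shearWeights) &&
      any(abs(object@shearWeights - 1) > 1e-12))
    msg <- c(msg, "equal loading requires all shear weights equal to 1")
  if (length(object@shearWeights) && any(object@shearWeights < 0))
    msg <- c(msg, "shear weights must be >= 0")
  if (!(object@equilFraction >= 0 && object@equilFraction < 1))
    msg <- c(msg, "equilFraction must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' BeadTrajectory: recorded frames of a bead-spring simulation
#'
#' @slot topology the \linkS4class{FibrilTopology} that was simulated.
#' @slot frames numeric array of dimension (nFrames, nSites, 3), nm.
#' @slot params the \linkS4class{SimulationParams} used.
#' @slot ruptured logical flag: some bond exceeded the rupture-check length.
#' @exportClass BeadTrajectory
setClass("BeadTrajectory",
  representation(
    topology = "FibrilTopology",
    frames = "array",
    params = "SimulationParams",
    ruptured = "logical"
  )
)

setValidity("BeadTrajectory", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L || d[3] != 3L)
    return("frames must be an (nFrames, nSites, 3) array")
  if (d[2] != nrow(object@topology@sites))
    return("every frame must have one coordinate per site")
  TRUE
})

#' PairwiseForceTable: time-averaged scalar bond forces
#'
#' One row per bond with the mean signed scalar force (nN, tension
#' positive), its standard deviation over retained frames and the number of
#' frames averaged. Newton-pair symmetry holds by construction: the value
#' attributed to (i, j) is the value of (j, i).
#'
#' @slot entries \code{DataFrame} with columns i, j, type, force, sd, nFrames.
#' @slot topology the underlying \linkS4class{FibrilTopology}.
#' @slot label free-text loading label.
#' @exportClass PairwiseForceTable
setClass("PairwiseForceTable",
  representation(entries = "DataFrame", topology = "FibrilTopology",
                 label = "character")
)

setValidity("PairwiseForceTable", function(object) {
  e <- object@entries
  if (!all(c("i", "j", "type", "force", "sd", "nFrames") %in% colnames(e)))
    return("entries must have columns i, j, type, force, sd, nFrames")
  if (nrow(e) > 0 && any(e$nFrames <= 0))
    return("nFrames must be > 0 for every bond")
  TRUE
})

#' ForceProfile: residue-windowed force profiles along crosslink paths
#'
#' @slot centers window centre positions (sequence index scale).
#' @slot perPair matrix (windows x pairs) of windowed mean forces, nN.
#' @slot mean,sem aggregate mean and standard error across pairs.
#' @slot window window length in residues.
#' @slot crosslinkPositions named list: for terminals "N" and "C", the
#'   sequence positions (profile axis) at which crosslinks attach.
#' @exportClass ForceProfile
setClass("ForceProfile",
  representation(centers = "numeric", perPair = "matrix",
                 mean = "numeric", sem = "numeric", window = "numeric",
                 crosslinkPositions = "list")
)

#' GTensor: principal g-values of an EPR transition
#'
#' @slot gx,gy,gz principal values; axial means two equal components.
#' @exportClass GTensor
setClass("GTensor", representation(gx = "numeric", gy = "numeric",
                                   gz = "numeric"))

setValidity("GTensor", function(object) {
  g <- c(object@gx, object@gy, object@gz)
  if (any(!is.finite(g)) || any(g <= 1.5) || any(g >= 2.5))
    return("g values must lie in the (1.5, 2.5) sanity window")
  TRUE
})

#' EprSpectrum: a simulated or ingested EPR field sweep
#'
#' @slot field magnetic field axis, mT, strictly increasing.
#' @slot intensity signal intensity, arbitrary units.
#' @slot params acquisition provenance (frequency GHz, mode, lineshape,
#'   linewidth G, ...).
#' @exportClass EprSpectrum
setClass("EprSpectrum",
  representation(field = "numeric", intensity = "numeric", params = "list")
)

setValidity("EprSpectrum", function(object) {
  if (length(object@field) != length(object@intensity))
    return("field and intensity must have the same length")
  if (length(object@field) > 1 && any(diff(object@field) <= 0))
    return("field axis must be strictly increasing")
  TRUE
})

#' RdfResult: radial distribution function of target sites around centers
#'
#' @slot breaks bin edges, nm, strictly increasing.
#' @slot g dimensionless g(r) per bin.
#' @slot counts raw (frame-averaged) pair counts per bin.
#' @slot density reference target number density used for normalization,
#'   nm^-3.
#' @slot nCenters,nTargets numbers of center and target sites.
#' @exportClass RdfResult
setClass("RdfResult",
  representation(breaks = "numeric", g = "numeric", counts = "numeric",
                 density = "numeric", nCenters = "integer",
                 nTargets = "integer")
)

setValidity("RdfResult", function(object) {
  if (any(diff(object@breaks) <= 0))
    return("bin edges must be strictly increasing")
  if (length(object@g) != length(object@breaks) - 1L)
    return("g must have one value per bin")
  if (any(object@g < 0)) return("g(r) must be >= 0")
  TRUE
})
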