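## force_distribution: time-averaged scalar pairwise bond forces and their
## residue-windowed profiles along crosslink-connected helix pairs.

#' Compute time-averaged pairwise bond forces from a trajectory
#'
#' For every bond the per-frame scalar force is
#' \code{k (|r_i - r_j| - r0)}, signed with tension positive and
#' compression negative; the table records the mean over retained
#' (post-equilibration) frames, its standard deviation and the frame count.
#' Only bonded pairs (backbone + crosslinks) are evaluated. Newton-pair
#' symmetry holds by construction: the force attributed to (i, j) is the
#' force of (j, i) (see \code{\link{pairForce}}).
#'
#' @param trajectory a \linkS4class{BeadTrajectory}.
#' @param topology the \linkS4class{FibrilTopology} the trajectory was run
#'   on (defaults to the trajectory's own topology).
#' @param includeEquilibration average over all frames instead of dropping
#'   the equilibration fraction.
#' @return a \linkS4class{PairwiseForceTable}.
#' @export
computePairwiseForces <- function(trajectory,
                                  topology = trajectory@topology,
                                  includeEquilibration = FALSE) {
  b <- topology@bonds
  if (nrow(b) == 0) stop("structural error: topology has no bonds")
  if (max(b$i, b$j) > nrow(topology@sites))
    stop("structural error: bond references a missing site")
  fr <- trajectoryFrames(trajectory, retained = !includeEquilibration)
  nf <- dim(fr)[1]
  if (nf == 0) stop("no retained frames to average over")
  p <- trajectory@params
  k <- .bondSpringConstants(b$type, p)
  sum1 <- numeric(nrow(b)); sum2 <- numeric(nrow(b))
  for (f in seq_len(nf)) {
    m <- fr[f, , , drop = TRUE]
    d <- m[b$i, , drop = FALSE] - m[b$j, , drop = FALSE]
    force <- k * (sqrt(rowSums(d * d)) - b$r0)
    sum1 <- sum1 + force
    sum2 <- sum2 + force * force
  }
  mean <- sum1 / nf
  var <- pmax(sum2 / nf - mean^2, 0)
  sd <- sqrt(var * nf / max(nf - 1, 1))
  entries <- S4Vectors::DataFrame(i = b$i, j = b$j, type = b$type,
                                  force = mean, sd = sd, nFrames = nf)
  new("PairwiseForceTable", entries = entries, topology = topology,
      label = sprintf("%g nN/chain, %s", p@perChainForce, p@loadingMode))
}

#' Compute bond forces from a single static frame
#'
#' Direct Hooke evaluation \code{k (|r_i - r_j| - r0)} on one coordinate
#' set; convenience for static checks.
#'
#' @param coords nSites x 3 coordinate matrix, nm.
#' @param topology a \linkS4class{FibrilTopology}.
#' @param springConstant,crosslinkSpringConstant nN/nm.
#' @return a \linkS4class{PairwiseForceTable} with \code{nFrames = 1} and
#'   zero standard deviations.
#' @export
staticFrameForces <- function(coords, topology, springConstant = 300,
                              crosslinkSpringConstant = springConstant,
                              interchainSpringConstant = springConstant) {
  b <- topology@bonds
  k <- ifelse(b$type == "crosslink", crosslinkSpringConstant,
              ifelse(b$type == "interchain", interchainSpringConstant,
                     springConstant))
  d <- coords[b$i, , drop = FALSE] - coords[b$j, , drop = FALSE]
  force <- k * (sqrt(rowSums(d * d)) - b$r0)
  entries <- S4Vectors::DataFrame(i = b$i, j = b$j, type = b$type,
                                  force = force, sd = 0, nFrames = 1L)
  new("PairwiseForceTable", entries = entries, topology = topology,
      label = "static frame")
}

#' Difference of two pairwise force tables
#'
#' Entrywise difference of mean forces (loaded minus control) over the
#' shared bond set; standard deviations are propagated by adding variances.
#'
#' @param loaded,control \linkS4class{PairwiseForceTable}s over the same
#'   topology and bond set.
#' @return a \linkS4class{PairwiseForceTable} of differences.
#' @export
diffForceTables <- function(loaded, control) {
  a <- loaded@entries; b <- control@entries
  keyA <- paste(pmin(a$i, a$j), pmax(a$i, a$j))
  keyB <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
  if (nrow(a) != nrow(b) || !setequal(keyA, keyB)) {
    offenders <- c(setdiff(keyA, keyB), setdiff(keyB, keyA))
    stop("structural error: bond sets differ; offending pairs: ",
         paste(head(offenders, 10), collapse = "; "))
  }
  m <- match(keyA, keyB)
  entries <- S4Vectors::DataFrame(
    i = a$i, j = a$j, type = a$type,
    force = a$force - b$force[m],
    sd = sqrt(a$sd^2 + b$sd[m]^2),
    nFrames = pmin(a$nFrames, b$nFrames[m]))
  new("PairwiseForceTable", entries = entries, topology = loaded@topology,
      label = paste(loaded@label, "-", control@label))
}

## Per-pair force series along the reference chain of each
## crosslink-connected helix pair: the chain spanning the full D-period
## (N-crosslink donor side; for a pair with only a C-crosslink, its
## acceptor side -- the same chain in the default geometry), the chain
## drawn above the profile plot. Backbone bond forces are placed at the
## lower seqIndex of the bond; crosslink bond forces at their attachment
## position on the reference chain.
.pairSeries <- function(table, topology) {
  s <- topology@sites
  e <- table@entries
  x <- topology@crosslinks
  bbKey <- paste(pmin(e$i, e$j), pmax(e$i, e$j))
  lookup <- function(i, j) e$force[match(paste(min(i, j), max(i, j)), bbKey)]
  chainSeries <- function(helix, chain) {
    idx <- which(e$type == "backbone" &
                   s$helix[e$i] == helix & s$chain[e$i] == chain)
    pos <- pmin(s$seqIndex[e$i[idx]], s$seqIndex[e$j[idx]])
    data.frame(pos = pos, force = e$force[idx])
  }
  if (nrow(x) == 0) {
    ## no crosslinks: each chain is its own series
    keys <- unique(paste(s$helix, s$chain))
    out <- lapply(keys, function(k) {
      hc <- as.integer(strsplit(k, " ")[[1]])
      list(series = chainSeries(hc[1], hc[2]),
           xlinks = data.frame(pos = numeric(0), terminal = character(0)))
    })
    names(out) <- keys
    return(out)
  }
  pairKey <- paste(pmin(s$helix[x$donor], s$helix[x$acceptor]),
                   pmax(s$helix[x$donor], s$helix[x$acceptor]))
  out <- list()
  for (pk in unique(pairKey)) {
    rows <- which(pairKey == pk)
    refRow <- rows[match("N", x$terminal[rows])]
    refIsDonor <- TRUE
    if (is.na(refRow)) { refRow <- rows[1]; refIsDonor <- FALSE }
    refSite <- if (refIsDonor) x$donor[refRow] else x$acceptor[refRow]
    refHelix <- s$helix[refSite]; refChain <- s$chain[refSite]
    ser <- chainSeries(refHelix, refChain)
    xl <- data.frame(pos = numeric(0), force = numeric(0),
                     terminal = character(0))
    for (r in rows) {
      site <- if (s$helix[x$donor[r]] == refHelix) x$donor[r] else x$acceptor[r]
      f <- lookup(x$donor[r], x$acceptor[r])
      ser <- rbind(ser, data.frame(pos = s$seqIndex[site], force = f))
      xl <- rbind(xl, data.frame(pos = s$seqIndex[site], force = f,
                                 terminal = x$terminal[r]))
    }
    out[[pk]] <- list(series = ser, xlinks = xl)
  }
  out
}

#' Windowed force profile along crosslink-connected chains
#'
#' For each crosslink-connected helix pair, the backbone bond forces of the
#' chain aligned to the crosslink path are averaged in overlapping sliding
#' windows of \code{w} consecutive residues (step 1); the crosslink bond
#' force enters the windows covering its attachment residue. The profile
#' aggregates the per-pair series into a mean and a standard error computed
#' across the pairs (not across frames). On a topology without crosslinks
#' each chain forms its own series.
#'
#' @param table a \linkS4class{PairwiseForceTable}.
#' @param topology the underlying topology (default: the table's).
#' @param w window length in residues (default 10).
#' @return a \linkS4class{ForceProfile}; window centers are reported at
#'   \code{start + (w - 1)/2} on the sequence-index axis.
#' @export
windowedProfile <- function(table, topology = table@topology, w = 10) {
  if (w < 1) stop("validation error: window length must be >= 1")
  pairs <- .pairSeries(table, topology)
  if (!length(pairs)) stop("profile is empty: no series to window")
  starts <- lapply(pairs, function(p) {
    rng <- range(p$series$pos)
    if (diff(rng) + 1 < w)
      stop("validation error: window of ", w,
           " residues exceeds the chain span ", diff(rng) + 1)
    seq(rng[1], rng[2] - w + 1)
  })
  common <- Reduce(intersect, starts)
  if (!length(common)) stop("no common window positions across pairs")
  mat <- vapply(pairs, function(p) {
    vapply(common, function(c0) {
      inWin <- p$series$pos >= c0 & p$series$pos <= c0 + w - 1
      mean(p$series$force[inWin])
    }, numeric(1))
  }, numeric(length(common)))
  mat <- matrix(mat, nrow = length(common),
                dimnames = list(NULL, names(pairs)))
  aggMean <- rowMeans(mat)
  aggSem <- if (ncol(mat) > 1)
    apply(mat, 1, stats::sd) / sqrt(ncol(mat)) else rep(0, nrow(mat))
  xpos <- list(N = numeric(0), C = numeric(0))
  for (p in pairs) {
    if (nrow(p$xlinks))
      for (r in seq_len(nrow(p$xlinks)))
        xpos[[p$xlinks$terminal[r]]] <- c(xpos[[p$xlinks$terminal[r]]],
                                          p$xlinks$pos[r])
  }
  new("ForceProfile", centers = common + (w - 1) / 2, perPair = mat,
      mean = aggMean, sem = aggSem, window = w,
      crosslinkPositions = lapply(xpos, unique))
}

#' Rank profile windows by aggregate mean force
#'
#' Window centers sorted by descending aggregate mean force (ties broken by
#' ascending position) with the distance of each center to the nearest
#' crosslink attachment of the requested terminal, in residues.
#'
#' @param profile a \linkS4class{ForceProfile}.
#' @param terminal \code{"N"} or \code{"C"}; with no crosslink positions of
#'   that terminal recorded, distances are \code{NA}.
#' @return \code{data.frame} with columns \code{center}, \code{force},
#'   \code{distanceToCrosslink}, ordered by rank.
#' @export
locateMaxima <- function(profile, terminal = c("N", "C")) {
  terminal <- match.arg(terminal)
  if (!length(profile@centers)) stop("profile is empty")
  ord <- order(-profile@mean, profile@centers)
  xp <- profile@crosslinkPositions[[terminal]]
  dist <- if (length(xp))
    vapply(profile@centers[ord],
           function(c0) min(abs(c0 - xp)), numeric(1))
  else rep(NA_real_, length(ord))
  data.frame(center = profile@centers[ord], force = profile@mean[ord],
             distanceToCrosslink = dist)
}
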