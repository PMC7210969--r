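## radical_proximity: radial distribution function of redox-active residue
## sites around crosslink sites.

#' Radial distribution function of target sites around center sites
#'
#' Histograms all center-target distances into bins of \code{binWidth} up
#' to \code{rMax} and normalizes by the ideal-gas expectation:
#' \code{g(r) = count(bin) / (nCenters x shellVolume(bin) x rho)}, with
#' \code{rho} the target number density in the normalization volume. The
#' default normalization volume is the axis-aligned bounding box of all
#' coordinates (centers and targets) inflated by \code{rMax} on each side
#' -- no periodic boundary, the fibril being finite laterally. Passing a
#' \linkS4class{BeadTrajectory} with site index vectors averages counts
#' over the retained frames.
#'
#' @param centers nCenters x 3 coordinate matrix (nm), or a
#'   \linkS4class{BeadTrajectory}.
#' @param targets nTargets x 3 coordinate matrix, or (trajectory case) an
#'   integer vector of target site rows.
#' @param binWidth nm (default 0.05).
#' @param rMax nm (default 3).
#' @param volume normalization volume in nm^3; \code{NULL} = inflated
#'   bounding box.
#' @param centerSites (trajectory case) integer vector of center site rows.
#' @return an \linkS4class{RdfResult}.
#' @export
setGeneric("computeRdf",
  function(centers, targets, binWidth = 0.05, rMax = 3, volume = NULL, ...)
    standardGeneric("computeRdf"))

.crossDistances <- function(a, b) {
  ## Euclidean distances between rows of a (m x 3) and b (n x 3)
  m2 <- rowSums(a^2); n2 <- rowSums(b^2)
  d2 <- outer(m2, n2, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

.rdfFromCounts <- function(counts, breaks, nCenters, nTargets, volume) {
  density <- nTargets / volume
  if (density <= 0) stop("zero normalization density")
  shell <- 4 / 3 * pi * diff(breaks^3)
  g <- counts / (nCenters * shell * density)
  new("RdfResult", breaks = breaks, g = g, counts = counts,
      density = density, nCenters = as.integer(nCenters),
      nTargets = as.integer(nTargets))
}

.boundingVolume <- function(xyz, rMax) {
  prod(apply(xyz, 2, function(v) diff(range(v)) + 2 * rMax))
}

#' @rdname computeRdf
setMethod("computeRdf", signature(centers = "matrix"),
  function(centers, targets, binWidth = 0.05, rMax = 3, volume = NULL, ...) {
    if (nrow(centers) < 1 || nrow(targets) < 1)
      stop("need at least one center and one target")
    if (rMax <= binWidth) stop("rMax must exceed the bin width")
    breaks <- seq(0, rMax, by = binWidth)
    if (breaks[length(breaks)] < rMax) breaks <- c(breaks, rMax)
    d <- .crossDistances(centers, targets)
    counts <- graphics::hist(d[d <= rMax], breaks = breaks,
                             plot = FALSE)$counts
    if (is.null(volume))
      volume <- .boundingVolume(rbind(centers, targets), rMax)
    .rdfFromCounts(counts, breaks, nrow(centers), nrow(targets), volume)
  })

#' @rdname computeRdf
setMethod("computeRdf", signature(centers = "BeadTrajectory"),
  function(centers, targets, binWidth = 0.05, rMax = 3, volume = NULL,
           centerSites, ...) {
    traj <- centers
    fr <- trajectoryFrames(traj)
    nf <- dim(fr)[1]
    breaks <- seq(0, rMax, by = binWidth)
    if (breaks[length(breaks)] < rMax) breaks <- c(breaks, rMax)
    acc <- numeric(length(breaks) - 1L)
    vol <- 0
    for (f in seq_len(nf)) {
      m <- fr[f, , , drop = TRUE]
      a <- m[centerSites, , drop = FALSE]
      b <- m[targets, , drop = FALSE]
      d <- .crossDistances(a, b)
      acc <- acc + graphics::hist(d[d <= rMax], breaks = breaks,
                                  plot = FALSE)$counts
      vol <- vol + if (is.null(volume)) .boundingVolume(rbind(a, b), rMax)
             else volume
    }
    .rdfFromCounts(acc / nf, breaks, length(centerSites), length(targets),
                   vol / nf)
  })

#' Redox-active and crosslink site rows of a topology
#'
#' Convenience selectors: \code{redoxSiteRows} returns the site rows whose
#' residue is in the given class codes; \code{crosslinkSiteRows} the
#' donor/acceptor rows of all crosslinks.
#'
#' @param topology a \linkS4class{FibrilTopology}.
#' @param codes one-letter codes (default Y, F, M).
#' @return integer vector of site row indices.
#' @export
redoxSiteRows <- function(topology, codes = c("Y", "F", "M")) {
  which(topology@sites$residue %in% codes)
}

#' @rdname redoxSiteRows
#' @export
crosslinkSiteRows <- function(topology) {
  x <- topology@crosslinks
  unique(c(x$donor, x$acceptor))
}

#' First contiguous g(r) > threshold shell
#'
#' Scans the bins in order of increasing r and returns the onset and end
#' radii of the first contiguous run with \code{g(r)} strictly above the
#' threshold (strict inequality: a profile exactly at the threshold does
#' not count). Returns \code{NULL} if the threshold is never exceeded.
#'
#' @param result an \linkS4class{RdfResult}.
#' @param threshold default 1.0 (the ideal-gas level).
#' @return \code{c(onset, end)} in nm, or \code{NULL}.
#' @export
firstShell <- function(result, threshold = 1.0) {
  above <- result@g > threshold
  if (!any(above)) return(NULL)
  first <- which(above)[1]
  run <- first
  while (run < length(above) && above[run + 1L]) run <- run + 1L
  c(onset = result@breaks[first], end = result@breaks[run + 1L])
}
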