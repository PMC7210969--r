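## conservation_mapping: MSA-derived counts of redox-active residues in
## 10-residue slices along the fibril axis.

#' Residue classes for conservation mapping
#'
#' Default classes: Tyr = \{Y\}, Phe = \{F\}, Met = \{M\}; their union is
#' reported as the \code{redox} class.
#'
#' @return named list of character vectors of one-letter codes.
#' @export
defaultResidueClasses <- function() {
  list(Tyr = "Y", Phe = "F", Met = "M")
}

#' Read a multiple sequence alignment from FASTA
#'
#' @param source path to an aligned FASTA file.
#' @return a \code{Biostrings::BStringSet}; all records must share one
#'   length (format error otherwise).
#' @export
readAlignment <- function(source) {
  aln <- Biostrings::readBStringSet(source)
  if (length(aln) && length(unique(Biostrings::width(aln))) != 1L)
    stop("format error: ragged alignment (records differ in length)")
  aln
}

#' Map alignment columns to reference sequence positions
#'
#' Sends each non-gap column of the reference record to its 1-based
#' position in the ungapped reference; gap columns map to \code{NA}.
#'
#' @param alignment a \code{BStringSet} (or named character vector) of
#'   aligned sequences.
#' @param referenceId name of the reference record.
#' @return integer vector of length \code{ncol(alignment)} with attribute
#'   \code{referenceId}.
#' @export
mapToReference <- function(alignment, referenceId) {
  nm <- names(alignment)
  if (!referenceId %in% nm)
    stop("lookup error: reference '", referenceId, "' not in alignment")
  ref <- strsplit(as.character(alignment[[match(referenceId, nm)]]), "")[[1]]
  isGap <- ref %in% c("-", ".")
  map <- rep(NA_integer_, length(ref))
  map[!isGap] <- seq_len(sum(!isGap))
  attr(map, "referenceId") <- referenceId
  map
}

.alignmentMatrix <- function(alignment) {
  if (length(alignment) == 0) return(matrix(character(0), 0, 0))
  do.call(rbind, strsplit(as.character(alignment), ""))
}

#' Per-slice mean counts of residue classes along the fibril axis
#'
#' The fibril segment is divided into axial slices spanning
#' \code{sliceLen} residues of axial extent (\code{sliceLen x axialRise}
#' nm), advancing by one residue (overlapping moving-average scheme). For
#' each slice, occurrences of each class are summed across all sequences of
#' the alignment at the columns mapping into the slice, over all sites of
#' the matching chains crossing the slice (all three chains of every helix
#' contribute where their identifier matches \code{chainId}), and divided
#' by the number of sequences.
#'
#' @param alignment a \code{BStringSet} MSA.
#' @param mapping column-to-reference map from \code{\link{mapToReference}}.
#' @param topology a \linkS4class{FibrilTopology}.
#' @param classes named list of one-letter-code vectors (default
#'   \code{\link{defaultResidueClasses}}); a union column \code{redox} is
#'   added.
#' @param sliceLen slice extent in residues (default 10).
#' @param chainId which chain identifier of the topology the MSA describes
#'   (default \code{"COL1A1"}).
#' @param step slice step in residues (default 1; set to \code{sliceLen}
#'   for non-overlapping slices).
#' @return \code{data.frame}: slice index, axial start/end (nm), number of
#'   contributing sites, one mean-count column per class plus \code{redox},
#'   and \code{nSequences} as an attribute.
#' @export
sliceCounts <- function(alignment, mapping, topology,
                        classes = defaultResidueClasses(),
                        sliceLen = 10, chainId = "COL1A1", step = 1) {
  if (sliceLen < 1) stop("validation error: sliceLen must be >= 1")
  nSeq <- length(alignment)
  cfg <- topology@config
  s <- topology@sites
  chainMatch <- cfg@chainComposition[s$chain] == chainId
  s <- s[chainMatch, , drop = FALSE]
  ## per-reference-position class counts across the MSA
  mat <- .alignmentMatrix(alignment)
  nRefPos <- max(c(0L, mapping), na.rm = TRUE)
  colOf <- match(seq_len(nRefPos), mapping)  # reference pos -> column
  classCounts <- matrix(0, nrow = nRefPos, ncol = length(classes),
                        dimnames = list(NULL, names(classes)))
  if (nSeq > 0 && nRefPos > 0) {
    for (cl in names(classes)) {
      isHit <- matrix(mat %in% classes[[cl]], nrow = nrow(mat))
      perCol <- colSums(isHit)
      classCounts[, cl] <- ifelse(is.na(colOf), 0, perCol[colOf])
    }
  }
  rise <- cfg@axialRise
  zmax <- if (nrow(s)) max(s$axial) else cfg@D
  starts <- seq(0, zmax - sliceLen * rise + 1e-9, by = step * rise)
  if (!length(starts)) starts <- 0
  siteCount <- function(z0, z1) {
    inSlice <- s$axial >= z0 - 1e-9 & s$axial < z1 - 1e-9
    pos <- s$seqIndex[inSlice]
    ok <- pos >= 1 & pos <= nRefPos
    list(n = sum(inSlice), pos = pos[ok])
  }
  rows <- lapply(seq_along(starts), function(k) {
    z0 <- starts[k]; z1 <- z0 + sliceLen * rise
    sc <- siteCount(z0, z1)
    counts <- if (nSeq > 0 && length(sc$pos))
      colSums(classCounts[sc$pos, , drop = FALSE]) / nSeq
    else stats::setNames(rep(0, length(classes)), names(classes))
    c(slice = k, axialStart = z0, axialEnd = z1, nSites = sc$n, counts)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out$redox <- rowSums(out[, names(classes), drop = FALSE])
  attr(out, "nSequences") <- nSeq
  attr(out, "sliceLen") <- sliceLen
  out
}

#' Enrichment of a class near crosslinks with a circular-shift null
#'
#' Ratio of the mean per-slice count over slices whose axial midpoint lies
#' within \code{radius} nm of any crosslink site to the mean over all other
#' slices. The p-value comes from a circular-shift permutation of the
#' profile: by default every possible shift is enumerated (a deterministic,
#' exact null); when \code{nPerm} is smaller than the number of available
#' shifts, a seeded random subset of shifts is used. The p-value is the
#' fraction of shifts (the identity included) whose ratio is at least the
#' observed one. This quantification is a device of this package, not a
#' published test.
#'
#' @param profile output of \code{\link{sliceCounts}}.
#' @param topology the \linkS4class{FibrilTopology} providing crosslink
#'   axial positions.
#' @param radius nm (default 1.5).
#' @param column profile column to test (default \code{"redox"}).
#' @param nPerm number of shifts; \code{NULL} (default) enumerates all.
#' @param seed seed used only when subsampling shifts.
#' @return list with \code{ratio} (Inf if the outside mean is 0 while the
#'   near mean is positive), \code{pValue}, \code{nNear}, \code{nFar}.
#' @export
enrichmentNearCrosslinks <- function(profile, topology, radius = 1.5,
                                     column = "redox", nPerm = NULL,
                                     seed = 1L) {
  x <- topology@crosslinks
  if (nrow(x) == 0) stop("topology has no crosslinks")
  s <- topology@sites
  xz <- unique(c(s$axial[x$donor], s$axial[x$acceptor]))
  mid <- (profile$axialStart + profile$axialEnd) / 2
  near <- vapply(mid, function(z) min(abs(z - xz)) <= radius, logical(1))
  if (!any(near)) stop("no slices within radius of any crosslink")
  v <- profile[[column]]
  ratioOf <- function(vals) {
    mNear <- mean(vals[near]); mFar <- mean(vals[!near])
    if (mFar == 0) { if (mNear > 0) Inf else NaN } else mNear / mFar
  }
  obs <- ratioOf(v)
  n <- length(v)
  shifts <- seq_len(n) - 1L
  if (!is.null(nPerm) && nPerm < n) {
    set.seed(seed)
    shifts <- c(0L, sample(shifts[-1], nPerm))
  }
  ratios <- vapply(shifts, function(k) {
    ratioOf(v[((seq_len(n) - 1L + k) %% n) + 1L])
  }, numeric(1))
  p <- mean(ratios >= obs, na.rm = TRUE)
  list(ratio = obs, pValue = p, nNear = sum(near), nFar = sum(!near))
}
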