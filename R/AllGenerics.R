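#' Accessors for colmech classes
#'
#' \code{sites}, \code{crosslinks} and \code{bonds} return the residue-site,
#' crosslink and bond tables of a \linkS4class{FibrilTopology};
#' \code{fibrilConfig} its configuration. \code{trajectoryFrames} returns
#' the coordinate array of a \linkS4class{BeadTrajectory} (optionally only
#' the post-equilibration frames), \code{forceEntries} the per-bond table of
#' a \linkS4class{PairwiseForceTable}, \code{fieldAxis}/\code{intensity} the
#' axes of an \linkS4class{EprSpectrum}, and \code{gValues} the principal
#' values of a \linkS4class{GTensor}.
#'
#' @param x the object.
#' @param ... further arguments passed to methods.
#' @return The corresponding table, array or vector.
#' @name accessors
#' @aliases sites crosslinks bonds fibrilConfig trajectoryFrames
#'   forceEntries fieldAxis intensity gValues
NULL

#' @rdname accessors
#' @export
setGeneric("sites", function(x, ...) standardGeneric("sites"))
#' @rdname accessors
#' @export
setGeneric("crosslinks", function(x, ...) standardGeneric("crosslinks"))
#' @rdname accessors
#' @export
setGeneric("bonds", function(x, ...) standardGeneric("bonds"))
#' @rdname accessors
#' @export
setGeneric("fibrilConfig", function(x, ...) standardGeneric("fibrilConfig"))
#' @rdname accessors
#' @export
setGeneric("trajectoryFrames",
           function(x, ...) standardGeneric("trajectoryFrames"))
#' @rdname accessors
#' @export
setGeneric("forceEntries", function(x, ...) standardGeneric("forceEntries"))
#' @rdname accessors
#' @export
setGeneric("fieldAxis", function(x, ...) standardGeneric("fieldAxis"))
#' @rdname accessors
#' @export
setGeneric("intensity", function(x, ...) standardGeneric("intensity"))
#' @rdname accessors
#' @export
setGeneric("gValues", function(x, ...) standardGeneric("gValues"))

#' @rdname accessors
setMethod("sites", "FibrilTopology", function(x, ...) x@sites)
#' @rdname accessors
setMethod("crosslinks", "FibrilTopology", function(x, ...) x@crosslinks)
#' @rdname accessors
setMethod("bonds", "FibrilTopology", function(x, ...) x@bonds)
#' @rdname accessors
setMethod("fibrilConfig", "FibrilTopology", function(x, ...) x@config)

#' @rdname accessors
#' @param retained logical; drop the equilibration frames (default TRUE).
setMethod("trajectoryFrames", "BeadTrajectory",
  function(x, retained = TRUE, ...) {
    fr <- x@frames
    if (retained) {
      nEq <- floor(dim(fr)[1] * x@params@equilFraction)
      if (nEq > 0) fr <- fr[-seq_len(nEq), , , drop = FALSE]
    }
    fr
  })

#' @rdname accessors
setMethod("forceEntries", "PairwiseForceTable", function(x, ...) x@entries)
#' @rdname accessors
setMethod("fieldAxis", "EprSpectrum", function(x, ...) x@field)
#' @rdname accessors
setMethod("intensity", "EprSpectrum", function(x, ...) x@intensity)
#' @rdname accessors
setMethod("gValues", "GTensor",
          function(x, ...) c(gx = x@gx, gy = x@gy, gz = x@gz))

#' Look up the time-averaged force of a bonded pair
#'
#' Scalar bond forces are symmetric under exchange of the pair: the value
#' returned for \code{(i, j)} equals the value for \code{(j, i)}.
#'
#' @param x a \linkS4class{PairwiseForceTable}.
#' @param i,j site row indices of a bonded pair.
#' @return mean signed scalar force in nN (tension positive).
#' @export
setGeneric("pairForce", function(x, i, j) standardGeneric("pairForce"))

#' @rdname pairForce
setMethod("pairForce", "PairwiseForceTable", function(x, i, j) {
  e <- x@entries
  hit <- which((e$i == i & e$j == j) | (e$i == j & e$j == i))
  if (!length(hit)) stop("no bond between sites ", i, " and ", j)
  e$force[hit[1]]
})

setMethod("show", "FibrilConfig", function(object) {
  cat("FibrilConfig:", object@nHelices, "helices, D =", object@D,
      "nm,", object@staggerResidues, "residues per D-stagger\n")
  cat("  overlap fraction", object@overlapFraction, "| lattice spacing",
      object@latticeSpacing, "nm |", nrow(object@adjacency),
      "adjacency pair(s)\n")
})

setMethod("show", "FibrilTopology", function(object) {
  s <- object@sites
  cat("FibrilTopology:", nrow(s), "residue sites in",
      length(unique(s$helix)), "helices\n")
  if (nrow(s)) {
    cat("  axial span:", signif(max(s$axial) - min(s$axial), 6), "nm |",
        "regions:", paste(names(table(s$region)), table(s$region),
                          collapse = ", "), "\n")
  }
  cat(" ", nrow(object@crosslinks), "crosslink(s),", nrow(object@bonds),
      "bond(s)\n")
})

setMethod("show", "BeadTrajectory", function(object) {
  d <- dim(object@frames)
  cat("BeadTrajectory:", d[1], "frames x", d[2], "beads",
      if (object@ruptured) "[rupture-check flag raised]" else "", "\n")
})

setMethod("show", "PairwiseForceTable", function(object) {
  e <- object@entries
  cat("PairwiseForceTable:", nrow(e), "bonds",
      if (nzchar(object@label)) paste0("(", object@label, ")") else "", "\n")
  if (nrow(e))
    cat("  mean |F| =", signif(mean(abs(e$force)), 4), "nN over",
        e$nFrames[1], "frames\n")
})

setMethod("show", "ForceProfile", function(object) {
  cat("ForceProfile:", length(object@centers), "windows (w =",
      object@window, "residues),", ncol(object@perPair), "series\n")
})

setMethod("show", "GTensor", function(object) {
  g <- gValues(object)
  cat("GTensor: gx =", g[1], "gy =", g[2], "gz =", g[3],
      "| g_iso =", signif(mean(g), 6), "\n")
})

setMethod("show", "EprSpectrum", function(object) {
  cat("EprSpectrum:", length(object@field), "field points,",
      signif(min(object@field), 6), "-", signif(max(object@field), 6),
      "mT,", object@params$mode %||% "?", "mode\n")
})

setMethod("show", "RdfResult", function(object) {
  cat("RdfResult:", length(object@g), "bins to",
      max(object@breaks), "nm;", object@nCenters, "centers x",
      object@nTargets, "targets\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
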