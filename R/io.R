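## Structured-text I/O: CA-only PDB with CONECT crosslink records,
## tab-separated topology tables, YAML configs.

.chainIdPool <- c(LETTERS, letters, 0:9)

#' Write a coarse-grained structure as CA-only PDB plus topology tables
#'
#' Emits one CA ATOM record per bead (coordinates converted nm -> Angstrom,
#' chain identifiers cycled through A-Z a-z 0-9 per helix/chain
#' combination) with crosslink bonds as CONECT records, and the
#' tab-separated topology tables of \code{\link{writeTopologyTables}}.
#' A write/read round trip restores site and crosslink counts exactly.
#'
#' @param coords nSites x 3 coordinate matrix, nm.
#' @param topology the matching \linkS4class{FibrilTopology}.
#' @param destination output prefix; writes \code{<destination>.pdb} and
#'   the \code{<destination>_*.tsv} tables.
#' @return invisibly, the PDB path.
#' @export
writeStructure <- function(coords, topology, destination) {
  s <- topology@sites
  if (nrow(coords) != nrow(s))
    stop("structural error: coordinate/site count mismatch (",
         nrow(coords), " vs ", nrow(s), ")")
  pdbFile <- paste0(destination, ".pdb")
  if (nrow(s) == 0) {
    writeLines("END", pdbFile)
  } else {
    chainKey <- as.integer(factor(paste(s$helix, s$chain),
                                  levels = unique(paste(s$helix, s$chain))))
    chainId <- .chainIdPool[(chainKey - 1L) %% length(.chainIdPool) + 1L]
    n <- nrow(s)
    bio3d::write.pdb(file = pdbFile,
                     xyz = as.numeric(t(coords * 10)),
                     resno = s$seqIndex,
                     resid = rep("GLY", n),
                     chain = chainId,
                     eleno = seq_len(n),
                     elety = rep("CA", n))
    x <- topology@crosslinks
    if (nrow(x) > 0) {
      lines <- readLines(pdbFile)
      conect <- sprintf("CONECT%5d%5d", x$donor, x$acceptor)
      endAt <- grep("^END", lines)
      if (length(endAt)) {
        lines <- append(lines, conect, after = endAt[1] - 1L)
      } else {
        lines <- c(lines, conect)
      }
      writeLines(lines, pdbFile)
    }
  }
  writeTopologyTables(topology, destination)
  invisible(pdbFile)
}

#' Read back a CA-only structure written by \code{writeStructure}
#'
#' @param pdbFile path to the PDB file.
#' @return list with \code{coords} (nm), \code{nSites}, and
#'   \code{crosslinkPairs} (two-column matrix of CONECT bead serials).
#' @export
readStructure <- function(pdbFile) {
  lines <- readLines(pdbFile)
  atomLines <- grepl("^ATOM", lines)
  if (!any(atomLines)) {
    coords <- matrix(numeric(0), 0, 3)
  } else {
    pdb <- bio3d::read.pdb(pdbFile)
    coords <- matrix(pdb$xyz, ncol = 3, byrow = TRUE) / 10
  }
  con <- grep("^CONECT", lines, value = TRUE)
  pairs <- if (length(con)) {
    t(vapply(con, function(l)
      c(as.integer(substr(l, 7, 11)), as.integer(substr(l, 12, 16))),
      integer(2)))
  } else matrix(integer(0), 0, 2)
  dimnames(pairs) <- NULL
  list(coords = coords, nSites = nrow(coords), crosslinkPairs = pairs)
}

#' Write / read the topology tables
#'
#' Three tab-separated tables (\code{<prefix>_sites.tsv},
#' \code{<prefix>_bonds.tsv}, \code{<prefix>_crosslinks.tsv}) plus the
#' configuration as \code{<prefix>_config.yaml}. \code{readTopologyTables}
#' reassembles a validated \linkS4class{FibrilTopology}.
#'
#' @param topology a \linkS4class{FibrilTopology}.
#' @param prefix output path prefix.
#' @return \code{readTopologyTables} returns the restored topology.
#' @export
writeTopologyTables <- function(topology, prefix) {
  wt <- function(df, suffix)
    utils::write.table(as.data.frame(df), paste0(prefix, suffix),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  wt(topology@sites, "_sites.tsv")
  wt(topology@bonds, "_bonds.tsv")
  wt(topology@crosslinks, "_crosslinks.tsv")
  writeFibrilConfig(topology@config, paste0(prefix, "_config.yaml"))
  invisible(prefix)
}

#' @rdname writeTopologyTables
#' @export
readTopologyTables <- function(prefix) {
  rt <- function(suffix, colClasses = NA)
    utils::read.table(paste0(prefix, suffix), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, colClasses = colClasses)
  sites <- rt("_sites.tsv",
              c("integer", "integer", "integer", "character", "numeric",
                "character"))
  bonds <- rt("_bonds.tsv")
  xl <- rt("_crosslinks.tsv")
  cfg <- readFibrilConfig(paste0(prefix, "_config.yaml"))
  topo <- new("FibrilTopology", config = cfg,
              sites = S4Vectors::DataFrame(sites),
              crosslinks = if (nrow(xl)) S4Vectors::DataFrame(xl)
                           else .emptyCrosslinks(),
              bonds = if (nrow(bonds)) S4Vectors::DataFrame(bonds)
                      else .emptyBonds())
  validObject(topo)
  topo
}

#' Write / read a fibril configuration as YAML
#'
#' @param config a \linkS4class{FibrilConfig}.
#' @param file path.
#' @return \code{readFibrilConfig} returns the validated
#'   \linkS4class{FibrilConfig}.
#' @export
writeFibrilConfig <- function(config, file) {
  lst <- list(
    nHelices = config@nHelices, D = config@D,
    staggerResidues = config@staggerResidues,
    axialRise = config@axialRise,
    overlapFraction = config@overlapFraction,
    chainComposition = config@chainComposition,
    staggerClass = config@staggerClass,
    adjacency = apply(config@adjacency, 1, as.list),
    crosslinkRules = config@crosslinkRules,
    latticeSpacing = config@latticeSpacing,
    teloN = config@teloN, teloC = config@teloC,
    axialCutoff = config@axialCutoff,
    windRadius = config@windRadius)
  yaml::write_yaml(lst, file, precision = 15)
  invisible(file)
}

#' @rdname writeFibrilConfig
#' @export
readFibrilConfig <- function(file) {
  lst <- yaml::read_yaml(file)
  adjacency <- if (length(lst$adjacency))
    matrix(as.integer(unlist(lst$adjacency)), ncol = 2, byrow = TRUE)
  else matrix(integer(0), 0, 2)
  rules <- lapply(lst$crosslinkRules, function(r) {
    r$donorSeq <- as.integer(r$donorSeq)
    r$acceptorSeq <- as.integer(r$acceptorSeq)
    r$donorChain <- as.integer(r$donorChain)
    r$acceptorChain <- as.integer(r$acceptorChain)
    r
  })
  FibrilConfig(nHelices = lst$nHelices, D = lst$D,
               staggerResidues = lst$staggerResidues,
               axialRise = lst$axialRise,
               overlapFraction = lst$overlapFraction,
               chainComposition = lst$chainComposition,
               staggerClass = as.integer(lst$staggerClass),
               adjacency = adjacency, crosslinkRules = rules,
               latticeSpacing = lst$latticeSpacing,
               teloN = lst$teloN, teloC = lst$teloC,
               axialCutoff = lst$axialCutoff,
               windRadius = lst$windRadius)
}
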