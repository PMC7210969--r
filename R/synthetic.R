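## synthetic_data (alignments and sweeps): seeded generators for MSAs with
## planted residue-class enrichment and for noisy EPR field sweeps.

#' Specification of a synthetic vertebrate-like MSA
#'
#' @param reference ungapped reference chain sequence (character string);
#'   extended PTM codes are mapped to plain amino acids (k -> K, o -> P).
#' @param nSequences number of aligned sequences (the reference record is
#'   the first of them).
#' @param planted named list of 1-based reference positions per residue
#'   class code, e.g. \code{list(Y = c(104, 945), F = c(106))}.
#' @param enrichment probability that a planted position carries its class
#'   residue in a non-reference sequence.
#' @param backgroundRate probability that a non-planted position is
#'   substituted by a residue drawn from the background composition.
#' @param referenceId name of the reference record.
#' @param seed RNG seed.
#' @return validated plain list.
#' @export
msaSpec <- function(reference, nSequences = 64L,
                    planted = list(), enrichment = 0.9,
                    backgroundRate = 0.05, referenceId = "REF",
                    seed = 1L) {
  if (enrichment < 0 || enrichment > 1 || backgroundRate < 0 ||
      backgroundRate > 1)
    stop("validation error: probabilities must lie in [0, 1]")
  reference <- chartr("ko", "KP", reference)
  n <- nchar(reference)
  for (cl in names(planted))
    if (any(planted[[cl]] < 1 | planted[[cl]] > n))
      stop("validation error: planted position outside sequence length ", n)
  list(reference = reference, nSequences = as.integer(nSequences),
       planted = planted, enrichment = enrichment,
       backgroundRate = backgroundRate, referenceId = referenceId,
       seed = as.integer(seed))
}

.aaBackground <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                   "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Generate a synthetic multiple sequence alignment
#'
#' Produces \code{nSequences} gapless aligned sequences of the reference
#' length: the reference itself first, then sequences in which each planted
#' position carries its class residue with the enrichment probability
#' (otherwise a background draw) and every other position is substituted at
#' the background rate. Seeded and reproducible.
#'
#' @param spec from \code{\link{msaSpec}}.
#' @return a \code{Biostrings::BStringSet}; zero sequences yield an empty
#'   set.
#' @export
generateMsa <- function(spec) {
  set.seed(spec$seed)
  n <- nchar(spec$reference)
  if (spec$nSequences == 0L)
    return(Biostrings::BStringSet(character(0)))
  ref <- strsplit(spec$reference, "")[[1]]
  plantedPos <- unlist(spec$planted, use.names = FALSE)
  plantedClass <- rep(names(spec$planted),
                      lengths(spec$planted))
  seqs <- character(spec$nSequences)
  seqs[1] <- spec$reference
  for (k in seq_len(spec$nSequences - 1L)) {
    aa <- ref
    sub <- stats::runif(n) < spec$backgroundRate
    aa[sub] <- sample(.aaBackground, sum(sub), replace = TRUE)
    if (length(plantedPos)) {
      hit <- stats::runif(length(plantedPos)) < spec$enrichment
      aa[plantedPos[hit]] <- plantedClass[hit]
      miss <- !hit
      aa[plantedPos[miss]] <- sample(.aaBackground, sum(miss),
                                     replace = TRUE)
    }
    seqs[k + 1L] <- paste(aa, collapse = "")
  }
  names(seqs) <- c(spec$referenceId,
                   sprintf("seq%03d", seq_len(spec$nSequences - 1L)))
  Biostrings::BStringSet(seqs)
}

#' Generate a noisy cw-EPR field sweep
#'
#' The noiseless powder spectrum of the tensor (delegated to
#' \code{\link{powderSpectrum}}) plus seeded i.i.d. Gaussian noise of the
#' given standard deviation (on the unit-peak intensity scale).
#'
#' @param tensor a \linkS4class{GTensor}.
#' @param frequencyGHz microwave frequency.
#' @param linewidthG peak-to-peak linewidth, G.
#' @param noiseSd noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @param ... further arguments to \code{\link{acquisitionParams}}.
#' @return an \linkS4class{EprSpectrum}.
#' @export
generateEprSweep <- function(tensor, frequencyGHz = 9.4, linewidthG = 10,
                             noiseSd = 0.01, seed = 1L, ...) {
  if (noiseSd < 0) stop("validation error: noiseSd must be non-negative")
  sp <- powderSpectrum(tensor,
                       acquisitionParams(frequencyGHz = frequencyGHz,
                                         linewidthG = linewidthG, ...))
  if (noiseSd > 0) {
    set.seed(seed)
    sp@intensity <- sp@intensity +
      stats::rnorm(length(sp@intensity), sd = noiseSd)
  }
  sp@params$noiseSd <- noiseSd
  sp
}
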