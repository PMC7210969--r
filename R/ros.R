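## ros_assay: tensile stress/force arithmetic, FOX calibration and
## hydrogen peroxide quantification, and the plate significance test.

#' Tensile stress from force and cross-section
#'
#' \code{stress = force / area}; N over mm^2 is MPa directly.
#'
#' @param forceN force, N.
#' @param areaMm2 cross-sectional area, mm^2 (> 0).
#' @return stress, MPa.
#' @examples
#' stressFromForce(20, 0.5)  # 40 MPa
#' @export
stressFromForce <- function(forceN, areaMm2) {
  if (any(areaMm2 <= 0))
    stop("validation error: cross-sectional area must be positive")
  forceN / areaMm2
}

#' Force from a suspended mass
#'
#' \code{force = mass_kg x g} with the standard gravity constant 9.8
#' m/s^2 (this rounding reproduces 350 g -> 3.43 N exactly; 9.80665 gives
#' 3.432 N, identical at the printed precision).
#'
#' @param massG suspended mass, g (>= 0).
#' @return force, N.
#' @examples
#' forceFromMass(350)  # 3.43 N
#' @export
forceFromMass <- function(massG) {
  if (any(massG < 0)) stop("validation error: mass must be non-negative")
  massG / 1000 * .constants$gravity
}

#' Synthetic FOX absorbance plate
#'
#' Generates paired "pulled"/"untreated" absorbance wells at 595 nm per
#' time point from a linear calibration
#' \code{A = intercept + slope x concentration + noise}, with the pulled
#' concentration offset by \code{trueDeltaUM} over the untreated baseline.
#' Noise is seeded i.i.d. Gaussian at the well level, modelling plate-reader
#' replicate precision.
#'
#' @param trueDeltaUM pulled-minus-untreated H2O2 concentration offset,
#'   micromolar (default 1).
#' @param baselineUM untreated concentration, micromolar.
#' @param calibration numeric c(slope, intercept), absorbance per
#'   micromolar and blank absorbance; slope must be non-zero.
#' @param replicates wells per condition and time point (>= 1).
#' @param timePointsMin time points, minutes.
#' @param noiseSd well-level absorbance noise sd.
#' @param seed RNG seed.
#' @return \code{data.frame} with columns condition, timeMin, well,
#'   absorbance; calibration attached as attribute \code{calibration}.
#' @export
generateFoxPlate <- function(trueDeltaUM = 1, baselineUM = 2,
                             calibration = c(slope = 0.03, intercept = 0.04),
                             replicates = 3L, timePointsMin = c(0, 30, 60),
                             noiseSd = 0.001, seed = 1L) {
  if (replicates < 1) stop("validation error: replicates must be >= 1")
  if (noiseSd < 0) stop("validation error: noiseSd must be non-negative")
  slope <- calibration[[1]]; intercept <- calibration[[2]]
  if (slope == 0)
    stop("validation error: calibration slope of 0 is unrecoverable")
  set.seed(seed)
  grid <- expand.grid(condition = c("untreated", "pulled"),
                      timeMin = timePointsMin,
                      well = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  conc <- ifelse(grid$condition == "pulled",
                 baselineUM + trueDeltaUM, baselineUM)
  grid$absorbance <- intercept + slope * conc +
    stats::rnorm(nrow(grid), sd = noiseSd)
  grid <- grid[order(grid$timeMin, grid$condition, grid$well), ]
  rownames(grid) <- NULL
  attr(grid, "calibration") <- c(slope = slope, intercept = intercept)
  grid
}

#' Estimate the pulled-minus-untreated concentration difference
#'
#' Per time point: condition concentration = (mean absorbance - intercept)
#' / slope; Delta = pulled - untreated, with the standard error propagated
#' from the well-level variances
#' (\code{sqrt(var_p/n_p + var_u/n_u) / |slope|}). Adding a common
#' absorbance offset to both conditions leaves Delta unchanged.
#'
#' @param plate a plate table as from \code{\link{generateFoxPlate}} (or
#'   read from disk) with a \code{calibration} attribute or explicitly
#'   passed calibration.
#' @param calibration numeric c(slope, intercept); default from the plate.
#' @return \code{data.frame}: timeMin, deltaUM, se, nPulled, nUntreated.
#' @export
estimateDeltaConcentration <- function(plate,
                                       calibration = attr(plate, "calibration")) {
  if (is.null(calibration)) stop("calibration (slope, intercept) required")
  slope <- calibration[[1]]; intercept <- calibration[[2]]
  if (slope == 0) stop("validation error: calibration slope is 0")
  out <- lapply(split(plate, plate$timeMin), function(d) {
    p <- d$absorbance[d$condition == "pulled"]
    u <- d$absorbance[d$condition == "untreated"]
    if (!length(p) || !length(u))
      stop("both conditions must be populated at every queried time point")
    varP <- if (length(p) > 1) stats::var(p) else 0
    varU <- if (length(u) > 1) stats::var(u) else 0
    data.frame(timeMin = d$timeMin[1],
               deltaUM = (mean(p) - mean(u)) / slope,
               se = sqrt(varP / length(p) + varU / length(u)) / abs(slope),
               nPulled = length(p), nUntreated = length(u))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$timeMin), ]
}

#' Equal-variance two-tailed t-test with star labels
#'
#' Pooled-variance two-sample t statistic and two-tailed p-value
#' (\code{stats::t.test} with \code{var.equal = TRUE}), plus the plate
#' convention star label: \code{**} for p < 0.01, \code{***} for p <
#' 0.001, empty otherwise. Degenerate zero-variance samples are handled
#' explicitly: equal means give t = 0, p = 1; unequal means give the
#' separation sentinel p = 0 with t = +/- Inf.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return list with \code{t}, \code{p}, \code{stars}.
#' @export
twoTailedTTest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("validation error: each sample needs n >= 2")
  pooled <- ((length(a) - 1) * stats::var(a) +
               (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (pooled == 0) {
    if (mean(a) == mean(b)) {
      t <- 0; p <- 1
    } else {
      t <- sign(mean(a) - mean(b)) * Inf; p <- 0
    }
  } else {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    t <- unname(ht$statistic); p <- ht$p.value
  }
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else ""
  list(t = t, p = p, stars = stars)
}
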