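## epr_spectra: powder EPR simulation from g-tensors and extraction of
## spectral metrics (effective g, peak-to-peak width, signal size, spins).

#' Construct a g-tensor
#'
#' @param gx,gy,gz principal values; an axial tensor has two equal
#'   components (g-perp) and one distinct (g-par).
#' @return a \linkS4class{GTensor}.
#' @examples
#' gTensor(2.007)                    # isotropic
#' gTensor(2.0050, 2.0050, 2.0023)   # axial
#' @export
gTensor <- function(gx, gy = gx, gz = gx) {
  new("GTensor", gx = gx, gy = gy, gz = gz)
}

#' @describeIn gTensor representative axial tensor of a DOPA semiquinone
#'   radical anion (g-perp 2.0050, g-par 2.0023). A placeholder in the
#'   phenoxy-radical range, user-supplied by design: replace with measured
#'   or computed principal values for quantitative work.
#' @export
dopaAnionGTensor <- function() gTensor(2.0050, 2.0050, 2.0023)

#' @describeIn gTensor TRUE if two components coincide within \code{tol}.
#' @param x a \linkS4class{GTensor}.
#' @param tol tolerance on g-value equality.
#' @export
isAxial <- function(x, tol = 1e-4) {
  g <- sort(gValues(x))
  (g[2] - g[1] < tol) != (g[3] - g[2] < tol)
}

#' Resonance field of the EPR condition
#'
#' \code{B = h nu / (g muB)} with CODATA values of h and muB, returned in
#' mT.
#'
#' @param g dimensionless g-value (> 0).
#' @param frequencyGHz microwave frequency, GHz (> 0).
#' @return resonance field, mT.
#' @examples
#' resonanceField(2.002319, 9.4)  # ~335.4 mT
#' @export
resonanceField <- function(g, frequencyGHz) {
  if (any(g <= 0) || any(frequencyGHz <= 0))
    stop("validation error: g and frequency must be positive")
  1e3 * .constants$planck * frequencyGHz * 1e9 /
    (g * .constants$bohrMagneton)
}

.gFromField <- function(fieldMT, frequencyGHz) {
  .constants$planck * frequencyGHz * 1e9 /
    (fieldMT * 1e-3 * .constants$bohrMagneton)
}

#' Acquisition parameters for a simulated sweep
#'
#' @param frequencyGHz microwave frequency (9.4 for X-band, 180 for
#'   G-band).
#' @param linewidthG peak-to-peak linewidth Delta B_pp in Gauss
#'   (1 mT = 10 G).
#' @param mode \code{"first_derivative"} (cw detection) or
#'   \code{"absorption"} (echo-detected).
#' @param lineshape \code{"gaussian"} or \code{"lorentzian"}.
#' @param fieldRange length-2 field window in mT; \code{NULL} spans all
#'   principal resonances of the tensor plus 6 linewidths.
#' @param fieldStep field step, mT (default 0.005).
#' @param gridSize orientation quadrature size per angle (default 64; the
#'   powder average uses a gridSize x gridSize Gauss-Legendre product rule
#'   over one octant).
#' @return a plain list of validated parameters.
#' @export
acquisitionParams <- function(frequencyGHz = 9.4, linewidthG = 10,
                              mode = c("first_derivative", "absorption"),
                              lineshape = c("gaussian", "lorentzian"),
                              fieldRange = NULL, fieldStep = 0.005,
                              gridSize = 64L) {
  if (linewidthG <= 0) stop("validation error: linewidth must be positive")
  if (fieldStep <= 0) stop("validation error: fieldStep must be positive")
  list(frequencyGHz = frequencyGHz, linewidthG = linewidthG,
       mode = match.arg(mode), lineshape = match.arg(lineshape),
       fieldRange = fieldRange, fieldStep = fieldStep,
       gridSize = as.integer(gridSize))
}

.gaussLegendre <- function(n, a, b) {
  ## Golub-Welsch: nodes/weights from the Jacobi matrix eigendecomposition
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- diag(0, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- 2 * e$vectors[1, ]^2
  list(nodes = (b - a) / 2 * nodes + (a + b) / 2,
       weights = (b - a) / 2 * weights)
}

#' Simulate a powder EPR spectrum from a g-tensor
#'
#' Orientation-averages the resonance field of the effective g-value
#' \code{g(theta, phi) = sqrt(gx^2 sin^2 theta cos^2 phi +
#' gy^2 sin^2 theta sin^2 phi + gz^2 cos^2 theta)} over a deterministic
#' Gauss-Legendre product grid in (cos theta, phi) on one octant, bins the
#' weighted stick spectrum onto the field axis, convolves with the chosen
#' lineshape of peak-to-peak width \code{linewidthG}, and normalizes to
#' unit maximum absolute intensity. \code{first_derivative} mode convolves
#' with the analytic derivative of the lineshape.
#'
#' @param tensor a \linkS4class{GTensor}.
#' @param params from \code{\link{acquisitionParams}}.
#' @return an \linkS4class{EprSpectrum}.
#' @examples
#' sp <- powderSpectrum(gTensor(2.007),
#'                      acquisitionParams(9.4, linewidthG = 10))
#' signalSize(sp)
#' @export
powderSpectrum <- function(tensor, params = acquisitionParams()) {
  g <- gValues(tensor)
  bPrincipal <- resonanceField(g, params$frequencyGHz)
  lwMT <- params$linewidthG / 10
  rng <- params$fieldRange
  if (is.null(rng))
    rng <- c(min(bPrincipal) - 6 * lwMT, max(bPrincipal) + 6 * lwMT)
  if (min(bPrincipal) < rng[1])
    stop("field range excludes the low-field principal resonance at ",
         signif(min(bPrincipal), 6), " mT")
  if (max(bPrincipal) > rng[2])
    stop("field range excludes the high-field principal resonance at ",
         signif(max(bPrincipal), 6), " mT")
  field <- seq(rng[1], rng[2], by = params$fieldStep)
  n <- params$gridSize
  qu <- .gaussLegendre(n, 0, 1)        # u = cos(theta)
  qp <- .gaussLegendre(n, 0, pi / 2)   # phi
  u2 <- qu$nodes^2
  s2 <- 1 - u2
  cos2p <- cos(qp$nodes)^2
  gEff2 <- outer(s2 * g["gx"]^2, cos2p) +
    outer(s2 * g["gy"]^2, 1 - cos2p) +
    matrix(u2 * g["gz"]^2, n, n)
  bRes <- resonanceField(sqrt(as.vector(gEff2)), params$frequencyGHz)
  w <- as.vector(outer(qu$weights, qp$weights))
  ## bin sticks onto the field axis
  idx <- round((bRes - field[1]) / params$fieldStep) + 1L
  keep <- idx >= 1L & idx <= length(field)
  hist <- numeric(length(field))
  tab <- tapply(w[keep], idx[keep], sum)
  hist[as.integer(names(tab))] <- tab
  ## lineshape kernel on the same step grid
  half <- ceiling(6 * lwMT / params$fieldStep)
  x <- seq(-half, half) * params$fieldStep
  if (params$lineshape == "gaussian") {
    sigma <- lwMT / 2                       # derivative pp width = 2 sigma
    kernAbs <- exp(-x^2 / (2 * sigma^2))
    kernDer <- -x / sigma^2 * kernAbs
  } else {
    gamma <- sqrt(3) / 2 * lwMT             # derivative pp width = 2 gamma/sqrt(3)
    kernAbs <- gamma^2 / (x^2 + gamma^2)
    kernDer <- -2 * gamma^2 * x / (x^2 + gamma^2)^2
  }
  kern <- if (params$mode == "absorption") kernAbs else kernDer
  y <- stats::convolve(hist, rev(kern), type = "open")
  y <- y[(half + 1L):(half + length(field))]
  if (max(abs(y)) > 0) y <- y / max(abs(y))
  new("EprSpectrum", field = field, intensity = y,
      params = c(params, list(tensor = gValues(tensor))))
}

#' EPR signal size
#'
#' Difference between the maximal and minimal intensity of a sweep, the
#' standard amplitude measure of a field-modulated first-derivative
#' spectrum.
#'
#' @param spectrum an \linkS4class{EprSpectrum}.
#' @return max intensity minus min intensity.
#' @export
signalSize <- function(spectrum) {
  if (!length(spectrum@intensity)) stop("empty spectrum")
  max(spectrum@intensity) - min(spectrum@intensity)
}

.derivativeExtrema <- function(spectrum) {
  iMax <- which.max(spectrum@intensity)
  iMin <- which.min(spectrum@intensity)
  list(iMax = iMax, iMin = iMin,
       lo = min(iMax, iMin), hi = max(iMax, iMin))
}

#' Effective g-factor from a first-derivative spectrum
#'
#' Locates the zero-crossing field between the derivative extrema (linear
#' interpolation between the bracketing points) and converts it to g via
#' the resonance condition.
#'
#' @param spectrum a first-derivative \linkS4class{EprSpectrum} with a
#'   single dominant line.
#' @param frequencyGHz microwave frequency; default from the spectrum's
#'   provenance.
#' @return effective g-value.
#' @export
effectiveG <- function(spectrum,
                       frequencyGHz = spectrum@params$frequencyGHz) {
  ex <- .derivativeExtrema(spectrum)
  y <- spectrum@intensity; b <- spectrum@field
  seg <- ex$lo:ex$hi
  sgn <- sign(y[seg])
  flip <- which(sgn[-1] * sgn[-length(sgn)] <= 0)
  if (!length(flip))
    stop("no zero-crossing between the derivative extrema")
  i <- seg[flip[1]]
  b0 <- b[i] + (0 - y[i]) * (b[i + 1] - b[i]) / (y[i + 1] - y[i])
  .gFromField(b0, frequencyGHz)
}

#' Peak-to-peak linewidth of a first-derivative spectrum
#'
#' Field separation of the derivative extrema, in Gauss (1 mT = 10 G).
#'
#' @param spectrum a first-derivative \linkS4class{EprSpectrum}.
#' @return Delta B_pp in G.
#' @export
peakToPeakWidth <- function(spectrum) {
  ex <- .derivativeExtrema(spectrum)
  abs(spectrum@field[ex$iMax] - spectrum@field[ex$iMin]) * 10
}

.doubleIntegral <- function(field, intensity) {
  ## cumulative trapezoid, then trapezoid of the result
  dx <- diff(field)
  cum <- c(0, cumsum(dx * (intensity[-1] + intensity[-length(intensity)]) / 2))
  sum(dx * (cum[-1] + cum[-length(cum)]) / 2)
}

#' Spin count by double integration against a reference
#'
#' The double integral of a first-derivative spectrum is proportional to
#' the number of spins; the sample count is the reference count scaled by
#' the ratio of double integrals. Both spectra must share the field axis.
#'
#' @param spectrum,reference first-derivative \linkS4class{EprSpectrum}s on
#'   identical field axes.
#' @param referenceSpins known spin count of the reference.
#' @return estimated spin count of the sample.
#' @export
spinCount <- function(spectrum, reference, referenceSpins) {
  if (length(spectrum@field) != length(reference@field) ||
      any(abs(spectrum@field - reference@field) > 1e-9))
    stop("structural error: spectra are not on identical field axes")
  dRef <- .doubleIntegral(reference@field, reference@intensity)
  if (dRef <= 0) stop("reference double integral must be positive")
  referenceSpins * .doubleIntegral(spectrum@field, spectrum@intensity) / dRef
}

#' Cubic smoothing spline for signal-size time series
#'
#' Thin wrapper around \code{stats::smooth.spline}; the stiffness parameter
#' is the spline's \code{spar} in [0, 1] (larger = stiffer).
#'
#' @param values numeric series.
#' @param stiffness spar in [0, 1] (default 0.5).
#' @param x optional abscissa (default index).
#' @return smoothed values at \code{x}.
#' @export
smoothSeries <- function(values, stiffness = 0.5, x = seq_along(values)) {
  fit <- stats::smooth.spline(x, values, spar = stiffness)
  stats::predict(fit, x)$y
}

#' Write / read a spectrum as two-column text
#'
#' Tab-separated (field mT, intensity) with `#`-prefixed metadata header
#' lines (frequency, mode, linewidth).
#'
#' @param spectrum an \linkS4class{EprSpectrum}.
#' @param file path.
#' @return \code{readSpectrum} returns an \linkS4class{EprSpectrum}.
#' @export
writeSpectrum <- function(spectrum, file) {
  p <- spectrum@params
  hdr <- c(sprintf("# frequencyGHz\t%s", p$frequencyGHz %||% NA),
           sprintf("# mode\t%s", p$mode %||% NA),
           sprintf("# linewidthG\t%s", p$linewidthG %||% NA))
  writeLines(hdr, file)
  utils::write.table(data.frame(field = spectrum@field,
                                intensity = spectrum@intensity),
                     file, sep = "\t", row.names = FALSE, col.names = FALSE,
                     append = TRUE)
  invisible(file)
}

#' @rdname writeSpectrum
#' @export
readSpectrum <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^# ", "", hdr), "\t")
  params <- stats::setNames(lapply(kv, function(x) {
    v <- x[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }), vapply(kv, `[`, "", 1))
  body <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t")
  new("EprSpectrum", field = body[[1]], intensity = body[[2]],
      params = params)
}
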