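# Vial-phantom agreement analysis: relative water densities from vial ROIs
# in a central slice, compared with the known concentrations by ordinary
# least squares, Bland-Altman bias, and the intraclass correlation
# coefficient (two-way mixed effects, absolute agreement, single measures).

#' Extract per-vial mean signals and relative water densities
#'
#' Regions of interest are discs concentric with each vial, shrunk by
#' \code{roiShrink} (default 0.8) to stay clear of partial-volume edges,
#' evaluated in the central coronal slice of the vial stack. Relative water
#' density is the ratio of each vial mean to the 100% reference-vial mean,
#' in percent.
#'
#' @param volume the phantom \linkS4class{MRIVolume}.
#' @param layout the \linkS4class{VialLayout} that generated it.
#' @param roiShrink ROI radius as a fraction of the vial radius.
#' @return A data.frame with columns vial, known, meanSignal, relative.
#' @export
extractVialMeans <- function(volume, layout, roiShrink = 0.8) {
  d <- dim(volume@data)
  sp <- volume@spacing
  sr <- .vialSliceRange(layout)
  central <- (sr[1] + sr[2]) %/% 2L
  rMM <- roiShrink * layout@radiusMM
  means <- numeric(nrow(layout@centers))
  plane <- volume@data[central, , ]
  for (v in seq_len(nrow(layout@centers))) {
    cr <- layout@centers[v, 1]; cc <- layout@centers[v, 2]
    if (cr - rMM / sp[2] < 1 || cr + rMM / sp[2] > d[2] ||
        cc - rMM / sp[3] < 1 || cc + rMM / sp[3] > d[3])
      stop("vial ROI leaves the volume (vial ", v, ")")
    rr <- seq(floor(cr - rMM / sp[2]), ceiling(cr + rMM / sp[2]))
    cl <- seq(floor(cc - rMM / sp[3]), ceiling(cc + rMM / sp[3]))
    grd <- expand.grid(row = rr, col = cl)
    inside <- ((grd$row - cr) * sp[2])^2 + ((grd$col - cc) * sp[3])^2 <= rMM^2
    means[v] <- mean(plane[as.matrix(grd[inside, ])])
  }
  ref <- means[layout@reference]
  if (!is.finite(ref) || ref <= 0) stop("reference vial mean is not positive")
  data.frame(vial = seq_along(means), known = layout@concentration,
             meanSignal = means, relative = 100 * means / ref)
}

#' Ordinary-least-squares agreement between measured and known densities
#'
#' @param known,measured paired percent values (length >= 3).
#' @return A list: slope, intercept, r2.
#' @export
linearAgreement <- function(known, measured) {
  if (length(known) != length(measured)) stop("length mismatch")
  if (length(known) < 3) stop("need at least 3 pairs")
  if (var(known) == 0) stop("known values have zero variance")
  fit <- lm(measured ~ known)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = unname(cor(known, measured)^2))
}

#' Bland-Altman bias and limits of agreement
#'
#' @param a,b paired measurements (difference taken as a - b).
#' @return A list: bias (mean difference), sd (sample SD of differences),
#'   loa (bias +/- 1.96 sd).
#' @export
blandAltman <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, sd = s, loa = c(lower = bias - 1.96 * s,
                                    upper = bias + 1.96 * s))
}

#' Intraclass correlation coefficient, absolute agreement, single measures
#'
#' ICC(A,1) of McGraw & Wong: a two-way mixed-effects model on the n x 2
#' table of paired measurements,
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)}
#' with row (subject), column (rater) and error mean squares computed from
#' the two-way layout without replication.
#'
#' @param x,y paired measurements (length n >= 3).
#' @return The ICC (in [-1, 1] for well-posed tables).
#' @export
iccAbsoluteAgreement <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  tab <- cbind(x, y)
  k <- 2
  gm <- mean(tab)
  if (all(tab == gm)) stop("zero total variance")
  rowM <- rowMeans(tab)
  colM <- colMeans(tab)
  ssr <- k * sum((rowM - gm)^2)
  ssc <- n * sum((colM - gm)^2)
  sst <- sum((tab - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Run the simulated vial-phantom validation experiment
#'
#' Generates \code{nRepeats} phantoms (one seed each), extracts relative
#' water densities, pools known-vs-measured pairs across repeats for the
#' overall regression, Bland-Altman and ICC, and reports per-repeat ICCs as
#' well (the repeated-imaging design of the physical experiment).
#'
#' @param nRepeats number of simulated imaging sessions.
#' @param layout a \linkS4class{VialLayout}.
#' @param noiseSD noise SD as a fraction of the reference signal.
#' @param seeds one seed per repeat.
#' @param roiShrink vial ROI shrink factor.
#' @param shadingParams optional coil-shading parameters for the generator.
#' @return A list: \code{perVial} (pooled data.frame with repeat column),
#'   \code{regression} (slope/intercept/r2), \code{blandAltman}
#'   (bias/sd/loa of measured - known), \code{iccPooled},
#'   \code{iccPerRepeat}.
#' @export
runPhantomExperiment <- function(nRepeats = 3, layout = defaultVialLayout(),
                                 noiseSD = 0.02, seeds = seq_len(nRepeats),
                                 roiShrink = 0.8, shadingParams = NULL) {
  if (nRepeats < 1) stop("nRepeats must be >= 1")
  if (length(seeds) != nRepeats) stop("need one seed per repeat")
  perVial <- NULL
  iccRep <- numeric(nRepeats)
  for (r in seq_len(nRepeats)) {
    ph <- generateVialPhantom(layout, shadingParams = shadingParams,
                              noiseSD = noiseSD, seed = seeds[r])
    vm <- extractVialMeans(ph$volume, ph$layout, roiShrink = roiShrink)
    vm$rep <- r
    perVial <- rbind(perVial, vm)
    iccRep[r] <- iccAbsoluteAgreement(vm$relative, vm$known)
  }
  list(perVial = perVial,
       regression = linearAgreement(perVial$known, perVial$relative),
       blandAltman = blandAltman(perVial$relative, perVial$known),
       iccPooled = iccAbsoluteAgreement(perVial$relative, perVial$known),
       iccPerRepeat = iccRep)
}
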