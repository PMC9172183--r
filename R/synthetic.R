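# Digital phantoms with known ground truth. The signal model everywhere is
#   S(x) = C(x) * WD(x)/100 * s0 + eps,   eps ~ N(0, (noiseSD*s0)^2), max(,0)
# i.e. a proton-density-weighted magnitude image with multiplicative coil
# shading C and additive Gaussian noise clipped at zero.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

#' Smooth positive coil-shading field
#'
#' Builds a synthetic surface-coil sensitivity surrogate: a constant offset
#' plus a sum of anisotropic Gaussians, evaluated at voxel centers. The field
#' is guaranteed strictly positive, and its dynamic range is capped: if
#' max/min would exceed \code{params$cap} (default 3) the Gaussian part is
#' rescaled so the ratio equals the cap.
#'
#' @param gridDim integer(3) grid dimensions.
#' @param spacing voxel spacing in mm (scalar or length 3).
#' @param params list with \code{offset} (> 0), \code{cap}, and
#'   \code{gaussians}: a list of \code{list(center, sigma, amplitude)} with
#'   center/sigma in mm per axis.
#' @return A 3D positive array.
#' @export
coilShadingField <- function(gridDim, spacing = 3.5, params = list()) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  offset <- if (is.null(params$offset)) 1 else params$offset
  cap <- if (is.null(params$cap)) 3 else params$cap
  if (offset <= 0) stop("shading offset must be positive")
  gs <- params$gaussians
  G <- array(0, dim = gridDim)
  if (length(gs)) {
    coords <- lapply(1:3, function(d) (seq_len(gridDim[d]) - 1) * spacing[d])
    for (g in gs) {
      v <- lapply(1:3, function(d)
        exp(-(coords[[d]] - g$center[d])^2 / (2 * g$sigma[d]^2)))
      G <- G + g$amplitude * (v[[1]] %o% v[[2]] %o% v[[3]])
    }
  }
  hi <- max(G); lo <- min(G)
  if (offset + lo <= 0 || (offset + hi) / (offset + lo) > cap) {
    s <- offset * (cap - 1) / (hi - cap * lo)
    G <- G * s
  }
  offset + G
}

#' Default 10-vial dilution phantom layout
#'
#' Ten vials with water concentrations 10 to 100% in 10% steps (the rest of
#' the vial volume being deuterium oxide, which gives no MR signal), arranged
#' in two rows of five inside a water-filled container. The 100% vial is the
#' reference.
#'
#' @param spacing voxel spacing in mm (isotropic).
#' @return A \linkS4class{VialLayout}.
#' @export
defaultVialLayout <- function(spacing = 3.5) {
  centers <- cbind(rep(c(29, 53), each = 5), rep(c(12, 28, 44, 60, 76), 2))
  new("VialLayout",
      centers = centers,
      radiusMM = 12,
      concentration = seq(10, 100, by = 10),
      heightSlices = 10L,
      reference = 10L,
      backgroundConc = 100,
      gridDim = c(16L, 80L, 80L),
      spacing = rep(spacing, 3L))
}

.vialSliceRange <- function(layout) {
  S <- layout@gridDim[1]; h <- layout@heightSlices
  s1 <- (S - h) %/% 2 + 1L
  c(s1, s1 + h - 1L)
}

#' Generate the digital vial phantom
#'
#' @param layout a \linkS4class{VialLayout}.
#' @param shadingParams optional parameter list for
#'   \code{\link{coilShadingField}}; NULL (default) means uniform sensitivity.
#' @param noiseSD additive Gaussian noise SD as a fraction of \code{s0}.
#' @param seed RNG seed; the phantom is bit-reproducible given the seed.
#' @param s0 reference signal (signal of 100% water at unit shading).
#' @return \code{list(volume, layout)} where \code{volume} is an
#'   \linkS4class{MRIVolume}.
#' @export
generateVialPhantom <- function(layout = defaultVialLayout(),
                                shadingParams = NULL, noiseSD = 0.02,
                                seed = 1L, s0 = 100) {
  validObject(layout)
  if (noiseSD < 0) stop("noise SD must be nonnegative")
  d <- layout@gridDim
  sp <- layout@spacing
  wd <- array(0, dim = d)
  sr <- .vialSliceRange(layout)
  contSlices <- max(1L, sr[1] - 2L):min(d[1], sr[2] + 2L)
  wd[contSlices, 2:(d[2] - 1), 2:(d[3] - 1)] <- layout@backgroundConc
  rv <- layout@radiusMM / sp[2]
  rowIdx <- matrix(seq_len(d[2]), d[2], d[3])
  colIdx <- matrix(seq_len(d[3]), d[2], d[3], byrow = TRUE)
  for (v in seq_len(nrow(layout@centers))) {
    disc <- (rowIdx - layout@centers[v, 1])^2 +
            (colIdx - layout@centers[v, 2])^2 <= rv^2
    for (s in sr[1]:sr[2]) wd[s, , ][disc] <- layout@concentration[v]
  }
  C <- if (is.null(shadingParams)) 1 else coilShadingField(d, sp, shadingParams)
  signal <- C * wd / 100 * s0
  if (noiseSD > 0)
    signal <- .withSeed(seed,
      pmax(signal + array(rnorm(prod(d), 0, noiseSD * s0), dim = d), 0))
  list(volume = MRIVolume(signal, spacing = sp), layout = layout)
}

#' Describe a digital thorax phantom
#'
#' Defaults reproduce a supine healthy thorax: regional lung water density
#' targets (anterior 21.2, mid 23.5, posterior 28.1%), 70% liver, 85% soft
#' tissue, a posterior-weighted smooth coil-shading field (spine-array
#' surrogate) and 2% additive noise, on a 64 x 96 x 96 grid at 3.5 mm
#' isotropic resolution.
#'
#' @param dim integer(3) grid dimensions (slices, rows, cols).
#' @param spacing isotropic voxel spacing in mm.
#' @param regionalMeans anterior/mid/posterior lung water density targets (%).
#' @param posture "supine" (posterior-dominant gradient) or "prone"
#'   (gradient reversed).
#' @param softTissueWD,liverWD,airwayWD tissue water densities (%).
#' @param s0 reference signal amplitude.
#' @param noiseSD noise SD as a fraction of \code{s0}.
#' @param seed RNG seed.
#' @param coil shading-field parameters (see \code{\link{coilShadingField}});
#'   NULL for a uniform field.
#' @param includeAirway add a central airway tube open to the superior
#'   boundary.
#' @return A \linkS4class{ThoraxTruth}.
#' @export
thoraxTruth <- function(dim = c(64L, 96L, 96L), spacing = 3.5,
                        regionalMeans = c(anterior = 21.2, mid = 23.5,
                                          posterior = 28.1),
                        posture = c("supine", "prone"),
                        softTissueWD = 85, liverWD = 70, airwayWD = 2,
                        s0 = 100, noiseSD = 0.02, seed = 1L,
                        coil = list(offset = 1,
                                    gaussians = list(list(
                                      center = c(320, 290, 168),
                                      sigma = c(160, 160, 220),
                                      amplitude = 0.4)),
                                    cap = 3),
                        includeAirway = TRUE) {
  posture <- match.arg(posture)
  new("ThoraxTruth", dim = as.integer(dim),
      spacing = rep(as.numeric(spacing)[1], 3L),
      regionalMeans = regionalMeans, posture = posture,
      softTissueWD = softTissueWD, liverWD = liverWD, airwayWD = airwayWD,
      s0 = s0, noiseSD = noiseSD, seed = as.integer(seed), coil = coil,
      includeAirway = includeAirway, achieved = list())
}

# split n ordered slices into three contiguous groups with counts differing
# by at most 1; remainder slices go to the mid segment first, then posterior
.splitThirds <- function(slices) {
  n <- length(slices)
  if (n < 3L) stop("fewer than 3 lung-containing slices")
  q <- n %/% 3L; r <- n %% 3L
  counts <- c(q, q + (r >= 1L), q + (r == 2L))
  ends <- cumsum(counts)
  list(anterior = slices[seq_len(counts[1])],
       mid = slices[(ends[1] + 1L):ends[2]],
       posterior = slices[(ends[2] + 1L):ends[3]])
}

.ellipsoid <- function(d, center, semi) {
  a1 <- ((seq_len(d[1]) - 1 - center[1]) / semi[1])^2
  a2 <- ((seq_len(d[2]) - 1 - center[2]) / semi[2])^2
  a3 <- ((seq_len(d[3]) - 1 - center[3]) / semi[3])^2
  outer(outer(a1, a2, "+"), a3, "+") <= 1
}

#' Generate the digital thorax phantom
#'
#' Builds an ellipsoidal body containing two ellipsoidal lungs (the right
#' lung slightly larger and lower), a liver block whose top face lies
#' directly under the right lung's bottom surface, and an optional central
#' airway tube open to the superior boundary. Lung water density varies along
#' the anterior-posterior slice axis as a piecewise-linear profile through
#' the three regional targets (reversed when prone); the signal model adds
#' multiplicative coil shading and clipped Gaussian noise.
#'
#' @param truth a \linkS4class{ThoraxTruth}.
#' @return \code{list(volume, labels, truth)}: the noisy
#'   \linkS4class{MRIVolume}, the ground-truth \linkS4class{LabelMask}, and
#'   the input truth with \code{achieved} filled with the realized noise-free
#'   regional means (computed from the water-density field over the true lung
#'   masks with the same slice-partition rule the pipeline uses).
#' @export
generateThoraxPhantom <- function(truth = thoraxTruth()) {
  validObject(truth)
  d <- truth@dim
  sp <- truth@spacing
  sc <- d / c(64, 96, 96)   # geometry scales with the grid
  body <- .ellipsoid(d, c(32, 50, 48) * sc, c(30, 45, 45) * sc)
  rl <- .ellipsoid(d, c(32, 38, 30) * sc, c(19, 22, 13) * sc)
  ll <- .ellipsoid(d, c(32, 37, 66) * sc, c(19, 20, 12) * sc)
  # keep a closed body shell around the lungs (at least two voxels thick)
  inner <- array(cppErode3D(cppErode3D(body)), dim = d)
  rl <- rl & inner; ll <- ll & inner
  labels <- array(0L, dim = d)
  labels[body] <- 1L
  labels[rl] <- 2L
  labels[ll] <- 3L

  # liver: conforms to the right-lung bottom surface
  depth <- round(16 * sc[2])
  fs <- ((seq_len(d[1]) - 1 - 32 * sc[1]) / (17 * sc[1]))^2
  fc <- ((seq_len(d[3]) - 1 - 30 * sc[3]) / (12 * sc[3]))^2
  foot <- outer(fs, fc, "+") <= 1
  for (s in seq_len(d[1])) for (cc in seq_len(d[3])) {
    if (!foot[s, cc]) next
    rows <- which(rl[s, , cc])
    if (!length(rows)) next
    liverRows <- (max(rows) + 1L):min(max(rows) + depth, d[2])
    liverRows <- liverRows[body[s, liverRows, cc] & !rl[s, liverRows, cc]]
    labels[s, liverRows, cc] <- 4L
  }

  if (truth@includeAirway) {
    ft <- outer(((seq_len(d[1]) - 1 - 32 * sc[1]) / (2.2 * sc[1]))^2,
                ((seq_len(d[3]) - 1 - 48 * sc[3]) / (2.2 * sc[3]))^2,
                "+") <= 1
    airRows <- seq_len(round(41 * sc[2]))
    for (s in seq_len(d[1])) for (cc in seq_len(d[3])) {
      if (!ft[s, cc]) next
      rows <- airRows[body[s, airRows, cc]]
      labels[s, rows, cc] <- 5L
    }
  }

  # water-density field
  wd <- array(0, dim = d)
  wd[labels == 1L] <- truth@softTissueWD
  wd[labels == 4L] <- truth@liverWD
  wd[labels == 5L] <- truth@airwayWD
  lung <- labels == 2L | labels == 3L
  lungSlices <- which(apply(lung, 1, any))
  thirds <- .splitThirds(lungSlices)
  centers <- vapply(thirds, mean, 0)
  vals <- if (truth@posture == "supine") truth@regionalMeans
          else rev(truth@regionalMeans)
  prof <- approx(centers, vals, xout = lungSlices, rule = 2)$y
  for (k in seq_along(lungSlices)) {
    s <- lungSlices[k]
    m <- lung[s, , ]
    w <- wd[s, , ]; w[m] <- prof[k]; wd[s, , ] <- w
  }

  C <- if (is.null(truth@coil)) array(1, dim = d)
       else coilShadingField(d, sp, truth@coil)
  signal <- C * wd / 100 * truth@s0
  if (truth@noiseSD > 0)
    signal <- .withSeed(truth@seed,
      pmax(signal + array(rnorm(prod(d), 0, truth@noiseSD * truth@s0),
                          dim = d), 0))

  regional <- function(sl) {
    m <- lung[sl, , , drop = FALSE]
    mean(wd[sl, , , drop = FALSE][m])
  }
  truth@achieved <- list(
    global = mean(wd[lung]),
    anterior = regional(thirds$anterior),
    mid = regional(thirds$mid),
    posterior = regional(thirds$posterior),
    right = mean(wd[labels == 2L]),
    left = mean(wd[labels == 3L]),
    lungSlices = lungSlices)
  list(volume = MRIVolume(signal, spacing = sp),
       labels = LabelMask(labels, spacing = sp),
       truth = truth)
}

#' Ground-truth lung segmentation of a phantom label mask
#'
#' @param labels a \linkS4class{LabelMask} using the package vocabulary.
#' @return A \linkS4class{LungSegmentation}.
#' @export
truthSegmentation <- function(labels) {
  LungSegmentation(labels@data == 2L, labels@data == 3L,
                   spacing = labels@spacing)
}

#' Generate 2D thorax-like slices for segmentation training
#'
#' Draws random coronal-slice caricatures at segmentation working resolution:
#' an elliptical bright body, zero to two darker elliptical lungs with
#' jittered position/size, a mild random in-plane shading field and additive
#' noise. A fraction of slices contains no lung at all (abdomen-like), so a
#' trained model also learns to emit empty masks.
#'
#' @param nSlices number of image/mask pairs.
#' @param size square slice size in pixels.
#' @param spacingMM in-plane pixel size in mm (the 1-1.5 mm working
#'   resolution of the segmentation model).
#' @param lungFreeFrac fraction of slices without lung tissue.
#' @param noiseSD noise SD as a fraction of the reference signal.
#' @param seed RNG seed.
#' @return \code{list(images, masks, spacingMM)}: arrays of dim
#'   \code{(size, size, nSlices)}; masks are 0/1.
#' @export
generateSegmentationTrainingSet <- function(nSlices = 200, size = 96,
                                            spacingMM = 1.25,
                                            lungFreeFrac = 0.15,
                                            noiseSD = 0.02, seed = 1L) {
  s0 <- 100
  .withSeed(seed, {
    images <- array(0, dim = c(size, size, nSlices))
    masks <- array(0, dim = c(size, size, nSlices))
    ri <- matrix(seq_len(size), size, size)
    ci <- matrix(seq_len(size), size, size, byrow = TRUE)
    for (n in seq_len(nSlices)) {
      bc <- size / 2 + runif(2, -0.05, 0.05) * size
      bs <- runif(2, 0.30, 0.42) * size
      body <- ((ri - bc[1]) / bs[1])^2 + ((ci - bc[2]) / bs[2])^2 <= 1
      wd <- ifelse(body, 85, 0)
      m <- matrix(FALSE, size, size)
      if (runif(1) > lungFreeFrac) {
        lungWD <- runif(1, 15, 35)
        nl <- sample(1:2, 1, prob = c(0.2, 0.8))
        sides <- if (nl == 2) c(-1, 1) else sample(c(-1, 1), 1)
        for (sd1 in sides) {
          lc <- c(bc[1] + runif(1, -0.15, 0.05) * bs[1],
                  bc[2] + sd1 * runif(1, 0.35, 0.55) * bs[2])
          ls <- c(runif(1, 0.45, 0.7) * bs[1], runif(1, 0.28, 0.4) * bs[2])
          lung <- (((ri - lc[1]) / ls[1])^2 + ((ci - lc[2]) / ls[2])^2 <= 1) &
                  body
          wd[lung] <- lungWD
          m <- m | lung
        }
      }
      gc2 <- runif(2, 0.2, 0.8) * size
      amp <- runif(1, 0, 0.4)
      sig <- runif(1, 0.6, 1.2) * size
      shade <- 1 + amp * exp(-(((ri - gc2[1])^2 + (ci - gc2[2])^2) /
                               (2 * sig^2)))
      img <- shade * wd / 100 * s0 +
             matrix(rnorm(size * size, 0, noiseSD * s0), size, size)
      images[, , n] <- pmax(img, 0)
      masks[, , n] <- m
    }
    list(images = images, masks = masks, spacingMM = spacingMM)
  })
}
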