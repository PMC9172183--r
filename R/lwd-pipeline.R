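# The three-step quantification: (1) segmentation + automatic hepatic
# reference ROI, (2) coil-shading normalization by slice-wise
# Tikhonov-regularized least squares with an L-curve-selected smoothing
# parameter, (3) pixel-wise LWD relative to a 70% hepatic water density,
# with global and regional summaries.

#' Body mask for normalization fitting
#'
#' Voxels brighter than the mean intensity of the whole 3D volume, minus the
#' segmented lung voxels, reduced to the largest connected component.
#'
#' @param volume an \linkS4class{MRIVolume}.
#' @param lungs a \linkS4class{LungSegmentation} on the same grid.
#' @return A logical 3D array.
#' @export
computeBodyMask <- function(volume, lungs) {
  if (!identical(dim(volume@data), dim(lungs@right)))
    stop("volume and segmentation grids differ")
  mask <- volume@data > mean(volume@data)
  mask[lungs@right | lungs@left] <- FALSE
  if (!any(mask)) stop("empty body mask after thresholding")
  .largestComponent(mask)
}

# Neumann 5-point Laplacian (rows sum to zero) on an nr x nc grid
.laplacian2d <- function(nr, nc) {
  n <- nr * nc
  idx <- matrix(seq_len(n), nr, nc)
  ii <- list(); jj <- list()
  add <- function(a, b) { ii[[length(ii) + 1]] <<- a
                          jj[[length(jj) + 1]] <<- b }
  add(idx[-nr, ], idx[-1, ])
  add(idx[-1, ], idx[-nr, ])
  add(idx[, -nc], idx[, -1])
  add(idx[, -1], idx[, -nc])
  i <- unlist(ii); j <- unlist(jj)
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  Matrix::Diagonal(x = deg) - A
}

# block-average slice data onto the coarse fitting grid
.normFitPrecompute <- function(volume, bodyMask, downsample) {
  d <- dim(volume@data)
  f <- as.integer(downsample)
  nr <- ceiling(d[2] / f); nc <- ceiling(d[3] / f)
  br <- (seq_len(d[2]) - 1L) %/% f + 1L
  bc <- (seq_len(d[3]) - 1L) %/% f + 1L
  blockOf <- outer(br, (bc - 1L) * nr, "+")   # coarse linear index per pixel
  L <- .laplacian2d(nr, nc)
  LtL <- Matrix::crossprod(L)
  slices <- vector("list", d[1])
  for (s in seq_len(d[1])) {
    S <- volume@data[s, , ]
    w <- bodyMask[s, , ]
    cnt <- numeric(nr * nc)
    ssum <- numeric(nr * nc)
    if (any(w)) {
      bl <- blockOf[w]
      tb <- tapply(S[w], bl, sum)
      ssum[as.integer(names(tb))] <- tb
      tc <- table(bl)
      cnt[as.integer(names(tc))] <- as.numeric(tc)
    }
    slices[[s]] <- list(cnt = cnt, ssum = ssum, S = S, w = w)
  }
  list(slices = slices, L = L, LtL = LtL, nr = nr, nc = nc, d = d, f = f)
}

# solve all slices for one lambda; returns coarse fields + norms
.normFitSolve <- function(pre, lambda) {
  nS <- length(pre$slices)
  coarse <- vector("list", nS)
  fitted <- logical(nS)
  seminorm <- 0
  for (s in seq_len(nS)) {
    sl <- pre$slices[[s]]
    if (sum(sl$cnt) == 0) next
    A <- Matrix::Diagonal(x = sl$cnt) + lambda^2 * pre$LtL
    m <- Matrix::solve(A, sl$ssum)
    coarse[[s]] <- matrix(as.numeric(m), pre$nr, pre$nc)
    fitted[s] <- TRUE
    seminorm <- seminorm + sum(as.numeric(pre$L %*% m)^2)
  }
  if (!any(fitted)) stop("no body voxels in any slice")
  # slices without body voxels copy the nearest fitted slice
  fi <- which(fitted)
  for (s in which(!fitted)) coarse[[s]] <- coarse[[fi[which.min(abs(fi - s))]]]
  residual <- numeric(nS)
  field <- array(0, dim = pre$d)
  for (s in seq_len(nS)) {
    M <- .resize2d(coarse[[s]], pre$d[2], pre$d[3])
    field[s, , ] <- M
    sl <- pre$slices[[s]]
    if (any(sl$w)) residual[s] <- sum((sl$S[sl$w] - M[sl$w])^2)
  }
  list(field = field, residual = residual, seminorm = seminorm)
}

#' Fit the coil-shading normalization map
#'
#' Per coronal slice, minimizes
#' \deqn{\sum_{x \in body} (M(x) - S(x))^2 + \lambda^2 \|\Delta M\|^2}
#' over the full slice grid, where \eqn{\Delta} is the discrete 5-point
#' Laplacian with Neumann boundaries. The quadratic problem is solved on a
#' \code{downsample}-times coarser grid (block-averaged data, weighted by
#' body-voxel count) and interpolated back bilinearly, which leaves the
#' smooth map essentially unchanged while keeping the sparse solve fast.
#' Slices containing no body voxels copy the nearest fitted slice.
#'
#' @param volume an \linkS4class{MRIVolume}.
#' @param bodyMask logical array from \code{\link{computeBodyMask}}.
#' @param lambda smoothing parameter (> 0), typically from
#'   \code{\link{selectLambdaLcurve}}.
#' @param downsample coarse-grid factor for the solve (1 = full resolution).
#' @param floorFrac fraction of the body-median map value used as a
#'   positivity floor at division time.
#' @return A \linkS4class{NormalizationMap}.
#' @export
fitNormalizationMap <- function(volume, bodyMask, lambda, downsample = 4,
                                floorFrac = 1e-3) {
  if (lambda <= 0) stop("lambda must be positive")
  pre <- .normFitPrecompute(volume, bodyMask, downsample)
  sol <- .normFitSolve(pre, lambda)
  new("NormalizationMap", field = sol$field, lambda = lambda,
      sliceResiduals = sol$residual, seminorm = sol$seminorm,
      bodyMedian = median(sol$field[bodyMask]), floorFrac = floorFrac)
}

#' Default smoothing-parameter grid
#'
#' 30 log-spaced values spanning six decades. The Tikhonov trade-off is
#' invariant to global intensity scaling (both terms are quadratic in the
#' signal), so a fixed dimensionless grid serves all inputs on a given grid
#' resolution.
#'
#' @param n grid length.
#' @param range log10 range.
#' @return Numeric vector of lambda values.
#' @export
defaultLambdaGrid <- function(n = 30, range = c(-2, 4)) {
  10^seq(range[1], range[2], length.out = n)
}

#' Select the Tikhonov smoothing parameter by the L-curve method
#'
#' For each lambda on the grid the slice-wise fit is solved and the point
#' (log residual norm over body voxels, log Laplacian seminorm) recorded;
#' the selected lambda maximizes the signed finite-difference curvature of
#' this parametric curve (the L-curve corner). A warning flag is set when
#' the corner lands on the grid boundary.
#'
#' @param volume an \linkS4class{MRIVolume}.
#' @param bodyMask logical body mask.
#' @param grid lambda grid (>= 3 values; default
#'   \code{\link{defaultLambdaGrid}}).
#' @param downsample coarse-grid factor passed to the fit.
#' @return A list: \code{lambda} (the corner), \code{index}, \code{grid},
#'   \code{rho} (residual norms), \code{eta} (seminorms), \code{curvature},
#'   \code{interior} (FALSE if the corner hit the grid edge).
#' @export
selectLambdaLcurve <- function(volume, bodyMask, grid = defaultLambdaGrid(),
                               downsample = 4) {
  if (length(grid) < 3) stop("lambda grid must have at least 3 values")
  grid <- sort(grid)
  pre <- .normFitPrecompute(volume, bodyMask, downsample)
  rho <- eta <- numeric(length(grid))
  for (k in seq_along(grid)) {
    sol <- .normFitSolve(pre, grid[k])
    rho[k] <- sum(sol$residual)
    eta[k] <- sol$seminorm
  }
  x <- log(pmax(rho, 1e-300))
  y <- log(pmax(eta, 1e-12 * max(eta)))
  t <- log(grid)
  d1 <- function(v) (c(v[-1], NA) - c(NA, v[-length(v)])) /
                    (c(t[-1], NA) - c(NA, t[-length(t)]))
  xp <- d1(x); yp <- d1(y)
  xpp <- d1(xp); ypp <- d1(yp)
  speed <- sqrt(xp^2 + yp^2)
  kappa <- (xp * ypp - yp * xpp) / speed^3
  # corner location on range-normalized axes (the two log norms span very
  # different ranges): signed distance of each curve point from the chord
  # joining the curve endpoints. Positive = origin side (the classic
  # L-corner); when the curve is globally concave (anatomy rather than noise
  # dominates the residual and no origin-side corner exists) the strongest
  # far-side bend is taken instead.
  xn <- (x - min(x)) / max(diff(range(x)), 1e-12)
  yn <- (y - min(y)) / max(diff(range(y)), 1e-12)
  v <- c(xn[length(xn)] - xn[1], yn[length(yn)] - yn[1])
  v <- v / sqrt(sum(v^2))
  dchord <- (xn - xn[1]) * v[2] - (yn - yn[1]) * v[1]
  idx <- if (max(dchord) >= 0.05) which.max(dchord) else which.min(dchord)
  interior <- idx > 1 && idx < length(grid)
  list(lambda = grid[idx], index = idx, grid = grid, rho = rho, eta = eta,
       curvature = kappa, chordDistance = dchord, interior = interior)
}

#' Divide a volume by its normalization map
#'
#' The map is floored at \code{floorFrac * median(map over body)} before
#' division so that near-zero extrapolations outside the fitted support
#' cannot blow up the quotient.
#'
#' @param volume an \linkS4class{MRIVolume}.
#' @param map a \linkS4class{NormalizationMap} on the same grid.
#' @return The normalized \linkS4class{MRIVolume}.
#' @export
normalizeVolume <- function(volume, map) {
  if (!identical(dim(volume@data), dim(map@field)))
    stop("volume and normalization map grids differ")
  floorVal <- map@floorFrac * map@bodyMedian
  MRIVolume(volume@data / pmax(map@field, floorVal),
            spacing = volume@spacing)
}

#' Automatically place the circular hepatic reference ROI
#'
#' The disc (area \code{areaCM2}, default 12.5 cm^2, radius
#' \eqn{r = \sqrt{A/\pi} \approx 19.95} mm) is placed in the coronal slice
#' nearest the right-lung 3D centroid, centered in the centroid column, with
#' the center row \code{offsetMM} (default 8.75 mm) below the bottom-most
#' right-lung voxel of that column. Voxels whose centers fall inside the
#' disc are members; lung-labelled voxels are excluded afterwards so the
#' reference mean stays purely hepatic (the disc necessarily grazes the lung
#' above its center).
#'
#' @param lungs a \linkS4class{LungSegmentation} with a nonempty right lung.
#' @param spacing voxel spacing override (defaults to the segmentation's).
#' @param areaCM2 disc area in cm^2.
#' @param offsetMM center offset below the lung bottom in mm.
#' @return A \linkS4class{LiverROI} (mean signal unset; see
#'   \code{\link{roiMean}}).
#' @export
placeLiverROI <- function(lungs, spacing = NULL, areaCM2 = 12.5,
                          offsetMM = 8.75) {
  if (areaCM2 <= 0) stop("ROI area must be positive")
  if (is.null(spacing)) spacing <- lungs@spacing
  rl <- lungs@right
  if (!any(rl)) stop("right lung is empty")
  d <- dim(rl)
  idx <- which(rl, arr.ind = TRUE)
  cen <- colMeans(idx)
  slice <- min(max(round(cen[1]), 1L), d[1])
  col <- min(max(round(cen[3]), 1L), d[3])
  fallback <- FALSE
  rows <- which(rl[slice, , col])
  if (!length(rows)) {
    lungCols <- which(apply(rl[slice, , , drop = FALSE], 3, any))
    if (!length(lungCols)) stop("no right-lung voxels in the centroid slice")
    col <- lungCols[which.min(abs(lungCols - col))]
    rows <- which(rl[slice, , col])
    fallback <- TRUE
  }
  bottom <- max(rows)
  radiusMM <- sqrt(areaCM2 / pi) * 10
  centerRow <- bottom + offsetMM / spacing[2]
  centerCol <- as.numeric(col)
  if (centerRow - radiusMM / spacing[2] < 1 ||
      centerRow + radiusMM / spacing[2] > d[2] ||
      centerCol - radiusMM / spacing[3] < 1 ||
      centerCol + radiusMM / spacing[3] > d[3])
    stop("liver ROI disc exceeds volume bounds")
  rr <- seq(floor(centerRow - radiusMM / spacing[2]),
            ceiling(centerRow + radiusMM / spacing[2]))
  cc <- seq(floor(centerCol - radiusMM / spacing[3]),
            ceiling(centerCol + radiusMM / spacing[3]))
  grd <- expand.grid(row = rr, col = cc)
  inside <- ((grd$row - centerRow) * spacing[2])^2 +
            ((grd$col - centerCol) * spacing[3])^2 <= radiusMM^2
  grd <- grd[inside, ]
  lungPlane <- lungs@right[slice, , ] | lungs@left[slice, , ]
  isLung <- lungPlane[cbind(grd$row, grd$col)]
  members <- as.matrix(grd[!isLung, c("row", "col")])
  storage.mode(members) <- "integer"
  new("LiverROI", slice = as.integer(slice), centerRow = centerRow,
      centerCol = centerCol, radiusMM = radiusMM, members = members,
      preExclusionCount = as.integer(nrow(grd)), meanSignal = NA_real_,
      columnFallback = fallback)
}

#' Mean signal over a liver ROI
#'
#' @param volume the (normalized) \linkS4class{MRIVolume}.
#' @param roi a \linkS4class{LiverROI}.
#' @return The mean intensity over the ROI member voxels.
#' @export
roiMean <- function(volume, roi) {
  mean(volume@data[cbind(roi@slice, roi@members[, 1], roi@members[, 2])])
}

#' Liver ROI area before lung exclusion
#'
#' Member-voxel count times in-plane voxel area, in cm^2.
#'
#' @param roi a \linkS4class{LiverROI}.
#' @param spacing voxel spacing in mm.
#' @return Area in cm^2.
#' @export
roiAreaCM2 <- function(roi, spacing) {
  roi@preExclusionCount * spacing[2] * spacing[3] / 100
}

#' Compute the pixel-wise lung water density map
#'
#' \eqn{LWD(x) = hepaticWD \cdot S(x) / \bar S_{liver}} for lung voxels x on
#' the normalized image; no clipping is applied and non-lung voxels are NA.
#' A lung voxel whose normalized signal equals the liver-ROI mean maps to
#' exactly \code{hepaticWD} (70% by default).
#'
#' @param normVolume the normalized \linkS4class{MRIVolume}.
#' @param lungs a \linkS4class{LungSegmentation}.
#' @param roi the placed \linkS4class{LiverROI}.
#' @param hepaticWD assumed hepatic water density in %.
#' @return An \linkS4class{LWDMap}.
#' @export
computeLwdMap <- function(normVolume, lungs, roi, hepaticWD = 70) {
  liverMean <- roiMean(normVolume, roi)
  if (!is.finite(liverMean) || liverMean <= 0)
    stop("liver ROI mean signal must be positive")
  vals <- array(NA_real_, dim = dim(normVolume@data))
  lung <- lungs@right | lungs@left
  vals[lung] <- hepaticWD * normVolume@data[lung] / liverMean
  new("LWDMap", values = vals, liverMean = liverMean,
      hepaticWD = hepaticWD, spacing = normVolume@spacing)
}

#' Global and regional LWD summaries
#'
#' Lung-containing coronal slices, ordered anterior to posterior, are split
#' into three contiguous segments with equal slice counts (when the count is
#' not divisible by 3, the extra slice goes to the mid segment first, then
#' posterior); means are reported per segment, per lung, and globally, along
#' with the segmented lung volume.
#'
#' @param lwd an \linkS4class{LWDMap}.
#' @param lungs the matching \linkS4class{LungSegmentation}.
#' @return A \linkS4class{RegionalLWD}.
#' @export
summarizeLwd <- function(lwd, lungs) {
  lung <- lungs@right | lungs@left
  if (!any(lung)) stop("empty lung segmentation")
  slices <- which(apply(lung, 1, any))
  thirds <- .splitThirds(slices)
  segMean <- function(sl) {
    m <- lung[sl, , , drop = FALSE]
    mean(lwd@values[sl, , , drop = FALSE][m])
  }
  new("RegionalLWD",
      global = mean(lwd@values[lung]),
      anterior = segMean(thirds$anterior),
      mid = segMean(thirds$mid),
      posterior = segMean(thirds$posterior),
      left = mean(lwd@values[lungs@left]),
      right = mean(lwd@values[lungs@right]),
      sliceRanges = thirds,
      lungVolumeL = lungVolume(lungs))
}

#' Run the full automated LWD pipeline
#'
#' Order of operations: segmentation, liver-ROI placement on the raw-geometry
#' masks, body mask, smoothing-parameter selection (L-curve or fixed),
#' normalization-map fit, division, ROI mean on the normalized image, LWD
#' map, regional summaries. Fully deterministic: a fixed lambda grid and no
#' random numbers.
#'
#' @param volume an \linkS4class{MRIVolume}.
#' @param segmentationMode "classical" (default, weight-free), "unet"
#'   (requires \code{model}), or "provided" (requires \code{lungs}).
#' @param lungs a \linkS4class{LungSegmentation} when
#'   \code{segmentationMode = "provided"}.
#' @param model a trained \code{UNetModel} when
#'   \code{segmentationMode = "unet"}.
#' @param lambda "lcurve" or a fixed positive value.
#' @param lambdaGrid grid for the L-curve search.
#' @param areaCM2,offsetMM,hepaticWD quantification constants (defaults
#'   12.5 cm^2, 8.75 mm, 70%).
#' @param downsample coarse-grid factor of the normalization solve.
#' @return A list: \code{lwd} (\linkS4class{LWDMap}), \code{regional}
#'   (\linkS4class{RegionalLWD}), \code{roi}, \code{map}, \code{lungs},
#'   \code{normalized}, and \code{report} (a plain list ready for JSON
#'   serialization, echoing the full configuration).
#' @export
runPipeline <- function(volume, segmentationMode = c("classical", "unet",
                                                     "provided"),
                        lungs = NULL, model = NULL, lambda = "lcurve",
                        lambdaGrid = defaultLambdaGrid(), areaCM2 = 12.5,
                        offsetMM = 8.75, hepaticWD = 70, downsample = 4) {
  segmentationMode <- match.arg(segmentationMode)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  lungs <- stage("segmentation", switch(segmentationMode,
    classical = segmentLungsClassical(volume),
    unet = {
      if (is.null(model)) stop("segmentationMode 'unet' requires a model")
      predictLungsUnet(model, volume)
    },
    provided = {
      if (is.null(lungs)) stop("segmentationMode 'provided' requires lungs")
      lungs
    }))
  roi <- stage("liver_roi",
    placeLiverROI(lungs, spacing = volume@spacing, areaCM2 = areaCM2,
                  offsetMM = offsetMM))
  body <- stage("body_mask", computeBodyMask(volume, lungs))
  lambdaMode <- if (identical(lambda, "lcurve")) "lcurve" else "fixed"
  lsel <- NULL
  lam <- stage("lambda", {
    if (lambdaMode == "lcurve") {
      lsel <- selectLambdaLcurve(volume, body, grid = lambdaGrid,
                                 downsample = downsample)
      lsel$lambda
    } else {
      lam <- as.numeric(lambda)
      if (!is.finite(lam) || lam <= 0) stop("fixed lambda must be positive")
      lam
    }
  })
  map <- stage("normalization",
    fitNormalizationMap(volume, body, lam, downsample = downsample))
  normVol <- stage("normalization", normalizeVolume(volume, map))
  roi@meanSignal <- stage("liver_roi", roiMean(normVol, roi))
  lwd <- stage("lwd_map", computeLwdMap(normVol, lungs, roi, hepaticWD))
  regional <- stage("summaries", summarizeLwd(lwd, lungs))
  report <- list(
    lwd = list(global = regional@global, anterior = regional@anterior,
               mid = regional@mid, posterior = regional@posterior,
               left = regional@left, right = regional@right),
    lungVolumeL = regional@lungVolumeL,
    lambda = lam, lambdaMode = lambdaMode,
    lambdaInterior = if (is.null(lsel)) NA else lsel$interior,
    roi = list(slice = roi@slice, centerRow = roi@centerRow,
               centerCol = roi@centerCol, radiusMM = roi@radiusMM,
               preExclusionAreaCM2 = roiAreaCM2(roi, volume@spacing),
               memberVoxels = nrow(roi@members),
               meanSignal = roi@meanSignal,
               columnFallback = roi@columnFallback),
    config = list(segmentationMode = segmentationMode, lambda = lambda,
                  areaCM2 = areaCM2, offsetMM = offsetMM,
                  hepaticWD = hepaticWD, downsample = downsample,
                  lambdaGrid = range(lambdaGrid),
                  spacingMM = volume@spacing, dim = dim(volume@data)),
    package = list(name = "lungwater",
                   version = as.character(utils::packageVersion("lungwater"))))
  list(lwd = lwd, regional = regional, roi = roi, map = map, lungs = lungs,
       normalized = normVol, report = report)
}

#' Write an LWD overlay volume
#'
#' The LWD map in percent with non-lung voxels set to a sentinel value.
#'
#' @param lwd an \linkS4class{LWDMap}.
#' @param path destination NIfTI path.
#' @param sentinel value for non-lung voxels (default -1).
#' @return Invisibly, \code{path}.
#' @export
writeLwdOverlay <- function(lwd, path, sentinel = -1) {
  vals <- lwd@values
  vals[is.na(vals)] <- sentinel
  img <- RNifti::asNifti(vals)
  sp <- lwd@spacing
  aff <- rbind(c(0, 0, -sp[3], 0), c(-sp[1], 0, 0, 0),
               c(0, -sp[2], 0, 0), c(0, 0, 0, 1))
  RNifti::`qform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::`pixdim<-`(img, sp) -> img
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
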