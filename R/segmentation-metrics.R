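#' Dice overlap coefficient between two binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; defined as 1 when both masks are empty
#' (two empty predictions agree perfectly, e.g. on a lung-free slice).
#'
#' @param a,b logical/0-1 arrays of identical shape.
#' @return A scalar in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    stop("mask shapes differ")
  a <- as.logical(a); b <- as.logical(b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Soft-Jaccard segmentation loss
#'
#' The differentiable complement of intersection-over-union used to train the
#' segmentation network:
#' \deqn{1 - (\sum p g + \epsilon) / (\sum p + \sum g - \sum p g + \epsilon)}
#' where p are per-pixel probabilities and g the binary truth. The smoothing
#' term \eqn{\epsilon} keeps the loss defined (and its gradient tame) on
#' empty masks.
#'
#' @param probMap numeric array of probabilities in [0, 1].
#' @param truthMask binary array of the same shape.
#' @param epsilon smoothing constant (default 1).
#' @return A scalar loss >= 0.
#' @export
softJaccardLoss <- function(probMap, truthMask, epsilon = 1) {
  if (length(probMap) != length(truthMask) ||
      !identical(dim(probMap), dim(truthMask)))
    stop("shapes differ")
  if (any(probMap < 0 | probMap > 1)) stop("probabilities must lie in [0,1]")
  g <- as.numeric(truthMask)
  p <- as.numeric(probMap)
  i <- sum(p * g)
  u <- sum(p) + sum(g) - i
  1 - (i + epsilon) / (u + epsilon)
}

#' Augmentation configuration for segmentation training
#'
#' Geometric transforms (flips, scaling, rotation) are applied identically to
#' the image and its mask (mask resampled nearest-neighbour so it stays
#' binary); intensity transforms (blur, noise) touch the image only.
#' "Permutations" are realized as axis flips.
#'
#' @param flip enable random horizontal/vertical flips.
#' @param blur enable Gaussian blurring; \code{blurSigmaMax} is the maximum
#'   sigma in pixels.
#' @param scale enable random isotropic scaling within
#'   \code{1 +/- scaleRange}.
#' @param rotate enable random rotation within \code{+/- rotateMaxDeg}
#'   degrees.
#' @param noise enable additive Gaussian noise; \code{noiseSDFrac} scales the
#'   image's intensity range.
#' @param resampleMM target in-plane working resolution in mm; the default
#'   sits inside the 1-1.5 mm band the segmentation model expects.
#' @param blurSigmaMax,scaleRange,rotateMaxDeg,noiseSDFrac numeric ranges,
#'   see above.
#' @return A list of class \code{AugmentationConfig}.
#' @export
augmentationConfig <- function(flip = TRUE, blur = TRUE, scale = TRUE,
                               rotate = TRUE, noise = TRUE,
                               blurSigmaMax = 1.2, scaleRange = 0.1,
                               rotateMaxDeg = 10, noiseSDFrac = 0.03,
                               resampleMM = 1.25) {
  if (resampleMM < 1 || resampleMM > 1.5)
    warning("resampleMM outside the default 1-1.5 mm working band")
  structure(list(flip = flip, blur = blur, scale = scale, rotate = rotate,
                 noise = noise, blurSigmaMax = blurSigmaMax,
                 scaleRange = scaleRange, rotateMaxDeg = rotateMaxDeg,
                 noiseSDFrac = noiseSDFrac, resampleMM = resampleMM),
            class = "AugmentationConfig")
}

.resize2d <- function(m, w, h, nearest = FALSE) {
  out <- EBImage::resize(m, w = w, h = h,
                         filter = if (nearest) "none" else "bilinear")
  as.matrix(out)
}

.centerCropPad <- function(m, size) {
  d <- dim(m)
  out <- matrix(0, size[1], size[2])
  r0 <- max(0, (d[1] - size[1]) %/% 2)
  c0 <- max(0, (d[2] - size[2]) %/% 2)
  ro <- max(0, (size[1] - d[1]) %/% 2)
  co <- max(0, (size[2] - d[2]) %/% 2)
  nr <- min(d[1], size[1]); nc <- min(d[2], size[2])
  out[ro + seq_len(nr), co + seq_len(nc)] <-
    m[r0 + seq_len(nr), c0 + seq_len(nc)]
  out
}

#' Randomly augment an image/mask slice pair
#'
#' @param imageSlice,maskSlice 2D matrices on the same grid.
#' @param config an \code{\link{augmentationConfig}}.
#' @param seed RNG seed; the same seed reproduces the same transform.
#' @return \code{list(image, mask)}; the mask remains binary.
#' @export
augmentPair <- function(imageSlice, maskSlice, config = augmentationConfig(),
                        seed = 1L) {
  if (!identical(dim(imageSlice), dim(maskSlice)))
    stop("image and mask shapes differ")
  .withSeed(seed, {
    img <- imageSlice
    msk <- (maskSlice > 0.5) * 1
    d <- dim(img)
    if (isTRUE(config$flip)) {
      if (runif(1) < 0.5) { img <- img[rev(seq_len(d[1])), , drop = FALSE]
                            msk <- msk[rev(seq_len(d[1])), , drop = FALSE] }
      if (runif(1) < 0.5) { img <- img[, rev(seq_len(d[2])), drop = FALSE]
                            msk <- msk[, rev(seq_len(d[2])), drop = FALSE] }
    }
    if (isTRUE(config$scale)) {
      f <- runif(1, 1 - config$scaleRange, 1 + config$scaleRange)
      nw <- max(4L, round(d[1] * f)); nh <- max(4L, round(d[2] * f))
      img <- .centerCropPad(.resize2d(img, nw, nh), d)
      msk <- .centerCropPad(.resize2d(msk, nw, nh, nearest = TRUE), d)
    }
    if (isTRUE(config$rotate)) {
      ang <- runif(1, -config$rotateMaxDeg, config$rotateMaxDeg)
      img <- as.matrix(EBImage::rotate(img, ang, filter = "bilinear",
                                       output.dim = d, bg.col = 0))
      msk <- as.matrix(EBImage::rotate(msk, ang, filter = "none",
                                       output.dim = d, bg.col = 0))
    }
    if (isTRUE(config$blur)) {
      sg <- runif(1, 0, config$blurSigmaMax)
      if (sg > 0.2) img <- as.matrix(EBImage::gblur(img, sigma = sg))
    }
    if (isTRUE(config$noise)) {
      rng <- diff(range(imageSlice))
      if (rng > 0)
        img <- img + matrix(rnorm(length(img), 0,
                                  config$noiseSDFrac * rng), d[1], d[2])
    }
    list(image = img, mask = (msk > 0.5) * 1)
  })
}
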