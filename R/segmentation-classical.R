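# Weight-free geometric lung segmentation. Serves as the default
# segmentation mode so the quantification pipeline runs without any trained
# model file; the trainable U-Net (unet.R) is the learned alternative.

.largestComponent <- function(mask) {
  lab <- cppLabel3D(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  tb <- tabulate(lab[lab > 0L])
  lab == which.max(tb)
}

#' Classical geometric lung segmentation
#'
#' Pipeline: (1) body mask by thresholding at the mean intensity of the whole
#' volume and keeping the largest connected component; (2) candidate lungs =
#' connected components of the low-intensity complement that do not touch the
#' volume border (cavities enclosed by the body; the background and any
#' airway open to the superior boundary touch the border and are thereby
#' removed); (3) an explicit guard drops residual central narrow tubes
#' (airway); (4) the two largest remaining cavities are the lungs,
#' right/left assigned by centroid column against the volume midline (ties
#' toward right); (5) one-voxel morphological closing smooths each mask.
#'
#' @param volume an \linkS4class{MRIVolume} with body brighter than lungs.
#' @return A \linkS4class{LungSegmentation}.
#' @export
segmentLungsClassical <- function(volume) {
  dat <- volume@data
  d <- dim(dat)
  thr <- mean(dat)
  body <- .largestComponent(dat > thr)
  if (!any(body)) stop("lungs not found: empty body mask")

  low <- dat <= thr
  lab <- cppLabel3D(low)
  nlab <- max(lab)
  if (nlab == 0L) stop("lungs not found: no low-intensity voxels")
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                     lab[, , c(1, d[3])]))
  border <- border[border > 0L]
  sizes <- tabulate(lab, nbins = nlab)
  cand <- setdiff(which(sizes > 0), border)

  if (length(cand)) {
    # guard: drop central narrow tubes (airway remnants fully enclosed)
    keep <- logical(length(cand))
    mid <- (d[3] + 1) / 2
    for (k in seq_along(cand)) {
      idx <- which(lab == cand[k], arr.ind = TRUE)
      cols <- idx[, 3]
      isTube <- abs(mean(cols) - mid) < 0.1 * d[3] &&
        (max(cols) - min(cols) + 1) < 0.2 * d[3]
      keep[k] <- !isTube
    }
    cand <- cand[keep]
  }
  if (length(cand) < 2L) stop("lungs not found: fewer than two lung cavities")

  cand <- cand[order(sizes[cand], decreasing = TRUE)][1:2]
  centroidCol <- vapply(cand, function(cc) {
    mean(which(lab == cc, arr.ind = TRUE)[, 3])
  }, 0)
  rightIdx <- if (centroidCol[1] <= centroidCol[2]) 1L else 2L
  close1 <- function(m) {
    m <- array(cppErode3D(cppDilate3D(m)), dim = d)
    m
  }
  right <- close1(lab == cand[rightIdx])
  left <- close1(lab == cand[3L - rightIdx])
  left[right] <- FALSE   # closing must not create overlap
  LungSegmentation(right, left, spacing = volume@spacing)
}
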