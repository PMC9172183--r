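#' @import methods
#' @importFrom stats rnorm median sd lm coef approx var
#' @importFrom utils head tail
#' @useDynLib lungwater, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' MRIVolume: a 3D proton-density-weighted MR volume
#'
#' Axis convention (fixed across the package): axis 1 indexes coronal slices
#' running anterior to posterior, axis 2 indexes rows running superior to
#' inferior, axis 3 indexes columns running subject-right to subject-left.
#' Voxel indices are interpreted with the voxel center at
#' \code{(i - 1) * spacing} mm along each axis (1-based R indexing; the voxel
#' at index 1 sits at physical coordinate 0).
#'
#' @slot data 3D numeric array of nonnegative, finite intensities (arbitrary
#'   signal units).
#' @slot spacing numeric(3), voxel spacing in mm per axis (slice, row, column).
#'   The acquisition this models uses 3.5 mm isotropic voxels.
#' @export
setClass("MRIVolume",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L)
      return("data must be a 3D array")
    if (!all(is.finite(object@data)))
      return("all intensities must be finite")
    if (any(object@data < 0))
      return("all intensities must be nonnegative")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      return("spacing must be three strictly positive values (mm)")
    TRUE
  })

#' Construct an MRIVolume
#'
#' @param data 3D nonnegative numeric array (slice, row, column).
#' @param spacing voxel spacing in mm, length 3 or a scalar (isotropic);
#'   default 3.5 mm isotropic.
#' @return An \linkS4class{MRIVolume}.
#' @export
MRIVolume <- function(data, spacing = 3.5) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("MRIVolume", data = data, spacing = as.numeric(spacing))
}

#' LabelMask: voxel-wise tissue labels on a volume lattice
#'
#' Label vocabulary: 0 background, 1 body, 2 right lung, 3 left lung,
#' 4 liver, 5 airway.
#'
#' @slot data 3D integer array of labels.
#' @slot spacing numeric(3), voxel spacing in mm.
#' @export
setClass("LabelMask",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L)
      return("data must be a 3D array")
    if (!all(object@data %in% 0:5))
      return("labels must be drawn from {0,...,5}")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be three strictly positive values (mm)")
    TRUE
  })

#' Construct a LabelMask
#' @param data 3D integer array with labels in 0..5.
#' @param spacing voxel spacing in mm (scalar or length 3).
#' @return A \linkS4class{LabelMask}.
#' @export
LabelMask <- function(data, spacing = 3.5) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(data) <- "integer"
  new("LabelMask", data = data, spacing = as.numeric(spacing))
}

#' LungSegmentation: disjoint binary right/left lung masks
#'
#' @slot right,left logical 3D arrays on the volume lattice; subject-right
#'   lung occupies low column indices under the package axis convention.
#' @slot spacing numeric(3), voxel spacing in mm.
#' @export
setClass("LungSegmentation",
  representation(right = "array", left = "array", spacing = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@right), dim(object@left)))
      return("right and left masks must share a lattice")
    if (!is.logical(object@right) || !is.logical(object@left))
      return("masks must be logical arrays")
    if (any(object@right & object@left))
      return("right and left masks must be disjoint")
    TRUE
  })

#' Construct a LungSegmentation
#' @param right,left logical 3D arrays (disjoint).
#' @param spacing voxel spacing in mm (scalar or length 3).
#' @return A \linkS4class{LungSegmentation}.
#' @export
LungSegmentation <- function(right, left, spacing = 3.5) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("LungSegmentation", right = right, left = left,
      spacing = as.numeric(spacing))
}

#' LiverROI: the automatically placed circular hepatic reference region
#'
#' The disc lives in one coronal slice; its center column is the right-lung
#' centroid column and its center row sits a fixed physical offset below the
#' bottom-most right-lung voxel of that column. Lung-labelled voxels are
#' excluded from the member set so the reference mean stays purely hepatic.
#'
#' @slot slice coronal slice index (1-based).
#' @slot centerRow,centerCol disc center in continuous voxel coordinates.
#' @slot radiusMM disc radius in mm.
#' @slot members integer matrix (n x 2) of in-plane (row, col) member voxels
#'   after lung exclusion.
#' @slot preExclusionCount number of voxels whose centers fall inside the
#'   disc before lung exclusion.
#' @slot meanSignal mean normalized signal over members (NA until measured).
#' @slot columnFallback TRUE if the centroid column held no lung voxel in the
#'   centroid slice and the nearest lung-bearing column was used instead.
#' @export
setClass("LiverROI",
  representation(slice = "integer", centerRow = "numeric",
                 centerCol = "numeric", radiusMM = "numeric",
                 members = "matrix", preExclusionCount = "integer",
                 meanSignal = "numeric", columnFallback = "logical"))

#' NormalizationMap: smooth positive coil-shading field
#'
#' @slot field 3D positive array on the volume grid.
#' @slot lambda the Tikhonov smoothing parameter used for the fit.
#' @slot sliceResiduals per-coronal-slice residual sum of squares over body
#'   voxels.
#' @slot seminorm total squared discrete-Laplacian seminorm of the fit.
#' @slot bodyMedian median of the field over body voxels (used for the
#'   division floor).
#' @slot floorFrac fraction of \code{bodyMedian} used as the positivity floor.
#' @export
setClass("NormalizationMap",
  representation(field = "array", lambda = "numeric",
                 sliceResiduals = "numeric", seminorm = "numeric",
                 bodyMedian = "numeric", floorFrac = "numeric"),
  validity = function(object) {
    if (length(dim(object@field)) != 3L)
      return("field must be a 3D array")
    if (object@lambda <= 0) return("lambda must be positive")
    TRUE
  })

#' LWDMap: percent lung water density per lung voxel
#'
#' Values are defined only over lung voxels; all other voxels are NA. No
#' clipping is applied: densities above 100% are reported as computed.
#'
#' @slot values 3D numeric array, NA outside the lungs.
#' @slot liverMean the hepatic reference mean signal used.
#' @slot hepaticWD assumed hepatic water density in % (default 70).
#' @slot spacing voxel spacing in mm.
#' @export
setClass("LWDMap",
  representation(values = "array", liverMean = "numeric",
                 hepaticWD = "numeric", spacing = "numeric"))

#' RegionalLWD: global and regional lung water density summaries
#'
#' @slot global mean LWD (%) over all lung voxels.
#' @slot anterior,mid,posterior mean LWD (%) in three contiguous groups of
#'   lung-containing coronal slices with equal slice counts (within 1).
#' @slot left,right per-lung mean LWD (%).
#' @slot sliceRanges list of the three integer slice-index vectors
#'   (anterior, mid, posterior).
#' @slot lungVolumeL total segmented lung volume in liters.
#' @export
setClass("RegionalLWD",
  representation(global = "numeric", anterior = "numeric", mid = "numeric",
                 posterior = "numeric", left = "numeric", right = "numeric",
                 sliceRanges = "list", lungVolumeL = "numeric"))

#' VialLayout: geometry and truth for the dilution vial phantom
#'
#' Models a water/D2O dilution phantom: vials of known water concentration
#' immersed in a water-filled container, imaged as cylinders along the
#' coronal-slice axis.
#'
#' @slot centers numeric matrix (n x 2) of in-plane (row, col) vial centers in
#'   voxel coordinates of the central coronal slice.
#' @slot radiusMM vial radius in mm.
#' @slot concentration known water concentration per vial in % (default ten
#'   vials, 10 to 100 in steps of 10).
#' @slot heightSlices vial extent in coronal slices.
#' @slot reference index of the 100% reference vial.
#' @slot backgroundConc water concentration of the surrounding container (%).
#' @slot gridDim integer(3) phantom grid dimensions.
#' @slot spacing voxel spacing in mm.
#' @export
setClass("VialLayout",
  representation(centers = "matrix", radiusMM = "numeric",
                 concentration = "numeric", heightSlices = "integer",
                 reference = "integer", backgroundConc = "numeric",
                 gridDim = "integer", spacing = "numeric"),
  validity = function(object) {
    conc <- object@concentration
    if (nrow(object@centers) != length(conc))
      return("one concentration per vial required")
    if (any(conc <= 0 | conc > 100))
      return("concentrations must lie in (0, 100]")
    if (length(object@reference) != 1L ||
        object@reference < 1L || object@reference > length(conc))
      return("exactly one reference vial must be flagged")
    if (conc[object@reference] != 100)
      return("the reference vial must contain 100% water")
    rv <- object@radiusMM / object@spacing[2]
    if (nrow(object@centers) > 1L) {
      d <- as.matrix(dist(object@centers))
      diag(d) <- Inf
      if (min(d) <= 2 * rv) return("vials must not overlap")
    }
    TRUE
  })

#' ThoraxTruth: ground-truth description of the digital thorax phantom
#'
#' @slot dim integer(3) grid dimensions (slices, rows, cols).
#' @slot spacing voxel spacing in mm.
#' @slot regionalMeans named numeric(3): target anterior, mid, posterior lung
#'   water densities in %.
#' @slot posture "supine" or "prone"; supine places the higher densities
#'   posteriorly (gravity-dependent), prone reverses the gradient.
#' @slot softTissueWD,liverWD,airwayWD water densities (%) of body soft
#'   tissue, liver and airway lumen.
#' @slot s0 reference signal amplitude (signal at 100% water, unit shading).
#' @slot noiseSD additive Gaussian noise SD as a fraction of \code{s0}.
#' @slot seed RNG seed making the phantom reproducible.
#' @slot coil list describing the multiplicative shading field (see
#'   \code{\link{coilShadingField}}); NULL for a uniform field.
#' @slot includeAirway logical; add a central low-density airway tube.
#' @slot achieved list filled by the generator with the realized noise-free
#'   regional means (the truth the pipeline is scored against).
#' @export
setClass("ThoraxTruth",
  representation(dim = "integer", spacing = "numeric",
                 regionalMeans = "numeric", posture = "character",
                 softTissueWD = "numeric", liverWD = "numeric",
                 airwayWD = "numeric", s0 = "numeric", noiseSD = "numeric",
                 seed = "integer", coil = "ANY", includeAirway = "logical",
                 achieved = "list"),
  validity = function(object) {
    if (any(object@regionalMeans < 0 | object@regionalMeans > 100))
      return("regional means must lie in [0, 100]")
    if (!object@posture %in% c("supine", "prone"))
      return("posture must be 'supine' or 'prone'")
    if (object@noiseSD < 0) return("noise SD must be nonnegative")
    TRUE
  })
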