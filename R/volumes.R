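#' Read a 3D MR volume from a NIfTI-1 file
#'
#' The image is reoriented (honoring its qform/sform orientation codes) into
#' the package axis convention: axis 1 anterior to posterior (coronal slice
#' index), axis 2 superior to inferior, axis 3 subject-right to subject-left.
#' Files carrying no orientation information (both codes zero) are assumed to
#' be stored in that convention already.
#'
#' @param path path to a readable .nii or .nii.gz file with 3 spatial
#'   dimensions.
#' @return An \linkS4class{MRIVolume} with spacing taken from the file header.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D image, got ", length(dim(img)), " dimensions")
  code <- attr(RNifti::xform(img), "code")
  if (!is.null(code) && code > 0) RNifti::orientation(img) <- "PIL"
  dat <- array(as.vector(img), dim(img))
  if (!all(is.finite(dat)))
    stop("volume contains non-finite voxel values")
  if (any(dat < 0))
    stop("volume contains negative intensities; magnitude images expected")
  MRIVolume(dat, spacing = RNifti::pixdim(img)[1:3])
}

#' Write a volume or label mask to a NIfTI-1 file
#'
#' Volumes are written as float64 so that \code{\link{readVolume}} round-trips
#' them exactly; label masks are written as int16. The qform encodes the
#' package axis convention (PIL) so other tools display them correctly.
#'
#' @param volume an \linkS4class{MRIVolume} or \linkS4class{LabelMask}.
#' @param path destination path (.nii or .nii.gz).
#' @return Invisibly, \code{path}.
#' @export
writeVolume <- function(volume, path) {
  if (!dir.exists(dirname(path)))
    stop("destination directory does not exist: ", dirname(path))
  isMask <- is(volume, "LabelMask")
  if (!isMask && !is(volume, "MRIVolume"))
    stop("volume must be an MRIVolume or LabelMask")
  sp <- volume@spacing
  aff <- rbind(c(0, 0, -sp[3], 0),
               c(-sp[1], 0, 0, 0),
               c(0, -sp[2], 0, 0),
               c(0, 0, 0, 1))
  dat <- volume@data
  storage.mode(dat) <- "double"
  img <- RNifti::asNifti(dat)
  RNifti::`qform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::`pixdim<-`(img, sp) -> img
  RNifti::writeNifti(img, path, datatype = if (isMask) "int16" else "double")
  invisible(path)
}

#' Read a label mask from a NIfTI-1 file
#'
#' @param path path to a NIfTI label volume (labels 0..5).
#' @param spacing optional spacing override (mm); by default taken from the
#'   header.
#' @return A \linkS4class{LabelMask}.
#' @export
readLabelMask <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D label image")
  code <- attr(RNifti::xform(img), "code")
  if (!is.null(code) && code > 0) RNifti::orientation(img) <- "PIL"
  dat <- array(as.vector(img), dim(img))
  if (is.null(spacing)) spacing <- RNifti::pixdim(img)[1:3]
  LabelMask(round(dat), spacing = spacing)
}

#' Reslice an isotropic coronal volume into the sagittal view
#'
#' A pure axis permutation (no interpolation): the output's axis 1 runs
#' subject-right to subject-left (sagittal slice index), axis 2 superior to
#' inferior, axis 3 anterior to posterior. Used to view the
#' anterior-posterior lung water gradient slice-by-slice.
#'
#' @param volume an isotropic \linkS4class{MRIVolume} (spacing equal across
#'   axes within 1%).
#' @return An \linkS4class{MRIVolume} in sagittal orientation.
#' @export
resliceSagittal <- function(volume) {
  sp <- volume@spacing
  if (max(sp) / min(sp) > 1.01)
    stop("sagittal reslicing by permutation requires isotropic voxels")
  MRIVolume(aperm(volume@data, c(3, 2, 1)), spacing = sp[c(3, 2, 1)])
}
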