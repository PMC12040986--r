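#' Create a 3D binary label map
#'
#' A label map is a 3D voxel lattice of 0/1 values together with the
#' physical voxel spacing in mm, identifying one observer's segmentation
#' of one subject's structure (here: a tumor on MRI).
#'
#' @param voxels 3D array; values must be 0/1 (or logical). Foreground = 1.
#' @param spacing numeric length-3, voxel edge lengths (sx, sy, sz) in mm;
#'   all strictly positive.
#' @param subject_id,observer_id identifiers carried through metric tables.
#' @return An object of class `"label_map"`.
#' @seealso [volume_mm3()], [dice()], [assd()], [hd95()], [read_label_map()]
#' @export
label_map <- function(voxels, spacing = c(1, 1, 1),
                      subject_id = NA_character_, observer_id = NA_character_) {
  if (is.logical(voxels)) voxels <- array(as.integer(voxels), dim(voxels))
  if (length(dim(voxels)) != 3L)
    stop("invalid input: 'voxels' must be a 3D array")
  if (!all(voxels %in% c(0, 1)))
    stop("invalid input: label map voxels must all be 0 or 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("invalid input: 'spacing' must be 3 positive mm values")
  structure(
    list(voxels = voxels, spacing = spacing,
         subject_id = as.character(subject_id),
         observer_id = as.character(observer_id)),
    class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<label_map> %dx%dx%d voxels, spacing %.3gx%.3gx%.3g mm, %d foreground (%.4g mm^3)\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    sum(x$voxels), volume_mm3(x)))
  if (!is.na(x$subject_id) || !is.na(x$observer_id))
    cat(sprintf("  subject %s, observer %s\n", x$subject_id, x$observer_id))
  invisible(x)
}

#' Volume of a label map in cubic millimetres
#'
#' @param mask a [label_map()].
#' @return Foreground voxel count times the voxel volume `sx*sy*sz`, mm^3.
#' @export
volume_mm3 <- function(mask) {
  stopifnot(inherits(mask, "label_map"))
  sum(mask$voxels) * prod(mask$spacing)
}

#' Read a binary label map from a NIfTI file
#'
#' Any nonzero voxel is treated as foreground; spacing is taken from the
#' image header (pixdim).
#'
#' @param file path to a `.nii` or `.nii.gz` file.
#' @inheritParams label_map
#' @return A [label_map()].
#' @export
read_label_map <- function(file, subject_id = NA_character_,
                           observer_id = NA_character_) {
  img <- RNifti::readNifti(file)
  vox <- array(as.integer(as.array(img) != 0), dim(img))
  label_map(vox, RNifti::pixdim(img)[1:3],
            subject_id = subject_id, observer_id = observer_id)
}

#' Write a label map to a NIfTI file
#'
#' @param mask a [label_map()].
#' @param file output path (`.nii` or `.nii.gz`).
#' @return `file`, invisibly.
#' @export
write_label_map <- function(mask, file) {
  stopifnot(inherits(mask, "label_map"))
  img <- RNifti::asNifti(mask$voxels)
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, file)
  invisible(file)
}
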