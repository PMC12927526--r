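# NIfTI stores grids x-fastest; internal arrays are (z, y, x). One aperm on
# read and its inverse on write keep a single unambiguous convention for all
# morphology.
nifti_to_internal <- function(a) aperm(a, c(3L, 2L, 1L))
internal_to_nifti <- function(a) aperm(a, c(3L, 2L, 1L))

strip_nii <- function(path) sub("\\.nii(\\.gz)?$", "", basename(path))

read_nifti_array <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path, internal = FALSE)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) { img <- img[, , , 1L]; d <- dim(img) }
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), " dimensions: ", path,
         call. = FALSE)
  sp <- RNifti::pixdim(img)[1:3]
  list(arr = unclass(img)[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE],
       spacing_xyz = sp)
}

#' Read an instance-label volume from NIfTI
#'
#' Reads a `.nii` / `.nii.gz` file of non-negative integer labels. Voxel
#' spacing is taken from the header and preserved exactly; the on-disk
#' (x, y, z) axis order is permuted to the internal (z, y, x) convention.
#'
#' @param path path to a NIfTI file.
#' @param name identifier for the volume; defaults to the file name without
#'   extension.
#' @return An [instance_volume()].
#' @export
read_labels <- function(path, name = strip_nii(path)) {
  r <- read_nifti_array(path)
  a <- r$arr
  if (any(!is.finite(a)) || max(abs(a - round(a))) > 0)
    stop("label file contains non-integer voxel data: ", path, call. = FALSE)
  if (min(a) < 0)
    stop("label file contains negative labels (min ", min(a), "): ", path,
         call. = FALSE)
  storage.mode(a) <- "integer"
  instance_volume(nifti_to_internal(a), spacing = rev(r$spacing_xyz), name = name)
}

#' Write an instance-label volume as NIfTI (uint16, gzip)
#'
#' Labels are stored as 16-bit unsigned integers, the benchmark convention
#' for instance masks; a label above 65535 is an error (reindex first, see
#' [reindex_instances()]). `read_labels(write_labels(v))` reproduces the
#' labels bit-exactly and the spacing to stored precision.
#'
#' @param vol an [instance_volume()].
#' @param path output path; use a `.nii.gz` suffix for gzip compression.
#' @return `path`, invisibly.
#' @export
write_labels <- function(vol, path) {
  stopifnot(inherits(vol, "instance_volume"))
  mx <- max(vol$labels)
  if (mx > 65535L)
    stop("max label ", mx, " exceeds the uint16 range (65535); ",
         "reindex instances before writing", call. = FALSE)
  img <- RNifti::asNifti(internal_to_nifti(vol$labels), internal = FALSE)
  RNifti::pixdim(img) <- rev(vol$spacing)
  RNifti::writeNifti(img, path, datatype = "uint16")
  invisible(path)
}

#' Read a grayscale image volume from NIfTI
#'
#' @inheritParams read_labels
#' @return An [image_volume()].
#' @export
read_image <- function(path, name = strip_nii(path)) {
  r <- read_nifti_array(path)
  a <- r$arr
  if (any(!is.finite(a)))
    stop("image file contains non-finite intensities: ", path, call. = FALSE)
  storage.mode(a) <- "double"
  image_volume(nifti_to_internal(a), spacing = rev(r$spacing_xyz), name = name)
}

#' Write a grayscale image volume as NIfTI (float32)
#'
#' @param img an [image_volume()].
#' @param path output path (`.nii.gz` for gzip).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "image_volume"))
  out <- RNifti::asNifti(internal_to_nifti(img$intensities), internal = FALSE)
  RNifti::pixdim(out) <- rev(img$spacing)
  RNifti::writeNifti(out, path, datatype = "float")
  invisible(path)
}
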