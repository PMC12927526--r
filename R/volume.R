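#' Instance-labeled 3D volume
#'
#' Container for a 3D grid of non-negative integer instance labels plus the
#' physical voxel spacing. Label 0 is background; every positive value marks
#' one instance. The grid is stored in (z, y, x) axis order and spacing is a
#' length-3 numeric (z, y, x) in nanometres.
#'
#' @param labels 3D integer array, all values >= 0 (0 = background).
#' @param spacing numeric length 3, voxel size (z, y, x) in nm; all > 0.
#' @param name identifier string carried into reports.
#' @return An object of class `instance_volume` with elements `labels`,
#'   `spacing` and `name`.
#' @examples
#' a <- array(0L, c(4, 4, 4)); a[2:3, 2:3, 2:3] <- 1L
#' v <- instance_volume(a, spacing = c(30, 8, 8), name = "toy")
#' instance_ids(v)
#' @export
instance_volume <- function(labels, spacing = c(1, 1, 1), name = "volume") {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array", call. = FALSE)
  if (any(dim(labels) < 1L))
    stop("every dimension must be >= 1", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (anyNA(labels))
    stop("labels contain NA", call. = FALSE)
  if (min(labels) < 0L)
    stop("labels must be non-negative integers (0 = background); found ",
         min(labels), call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (z, y, x)", call. = FALSE)
  structure(list(labels = labels, spacing = spacing, name = as.character(name)[1L]),
            class = "instance_volume")
}

#' Single-channel grayscale 3D volume
#'
#' @param intensities 3D numeric array of finite values.
#' @inheritParams instance_volume
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(intensities, spacing = c(1, 1, 1), name = "image") {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3D array", call. = FALSE)
  storage.mode(intensities) <- "double"
  if (any(!is.finite(intensities)))
    stop("intensities must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (z, y, x)", call. = FALSE)
  structure(list(intensities = intensities, spacing = spacing,
                 name = as.character(name)[1L]),
            class = "image_volume")
}

#' Distinct positive instance labels of a volume
#'
#' @param vol an `instance_volume`.
#' @return Sorted integer vector of the distinct positive labels.
#' @export
instance_ids <- function(vol) {
  stopifnot(inherits(vol, "instance_volume"))
  ids <- sort(unique(as.vector(vol$labels)))
  ids[ids > 0L]
}

#' Per-instance voxel counts
#'
#' @param vol an `instance_volume`.
#' @return Named integer vector: names are instance ids, values voxel counts.
#' @export
instance_sizes <- function(vol) {
  stopifnot(inherits(vol, "instance_volume"))
  lab <- as.vector(vol$labels)
  lab <- lab[lab > 0L]
  if (length(lab) == 0L) return(setNames(integer(0), character(0)))
  tab <- tabulate(lab)
  ids <- which(tab > 0L)
  setNames(tab[ids], as.character(ids))
}

#' @export
print.instance_volume <- function(x, ...) {
  d <- dim(x$labels)
  ids <- instance_ids(x)
  cat(sprintf("<instance_volume> %s\n", x$name))
  cat(sprintf("  grid (z,y,x): %d x %d x %d   spacing (nm): %g x %g x %g\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  instances: %d   foreground voxels: %d\n",
              length(ids), sum(x$labels > 0L)))
  invisible(x)
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<image_volume> %s\n", x$name))
  cat(sprintf("  grid (z,y,x): %d x %d x %d   spacing (nm): %g x %g x %g\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

# Binary mask (logical array) of one instance; errors if the id is absent.
instance_mask <- function(vol, instance_id) {
  stopifnot(inherits(vol, "instance_volume"))
  instance_id <- as.integer(instance_id)
  m <- vol$labels == instance_id
  if (instance_id <= 0L || !any(m))
    stop("instance id ", instance_id, " not present in volume '", vol$name, "'",
         call. = FALSE)
  m
}

# Bounding box of TRUE voxels, as list(lo = c(z,y,x), hi = c(z,y,x)),
# optionally padded by `pad` voxels and clipped to the grid.
mask_bbox <- function(mask, pad = 0L) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(NULL)
  coo <- arrayInd(idx, d)
  lo <- pmax(apply(coo, 2L, min) - pad, 1L)
  hi <- pmin(apply(coo, 2L, max) + pad, d)
  list(lo = lo, hi = hi)
}
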