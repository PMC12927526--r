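new_std_log <- function(operation, parameters, before, after, removed = NULL,
                        warnings = character(0)) {
  structure(list(operation = operation, parameters = parameters,
                 instances_before = before, instances_after = after,
                 removed = removed, warnings = warnings),
            class = "standardization_log")
}

#' @export
print.standardization_log <- function(x, ...) {
  cat(sprintf("<standardization_log> %s\n", x$operation))
  cat(sprintf("  instances: %d -> %d\n", x$instances_before, x$instances_after))
  if (!is.null(x$removed) && nrow(x$removed) > 0L)
    cat(sprintf("  removed: %s\n",
                paste(sprintf("%d(%d vox)", x$removed$instance_id,
                              x$removed$voxel_count), collapse = ", ")))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Reindex instance labels to consecutive 1..N
#'
#' Relabels instances deterministically: new ids are assigned in order of
#' each label's first voxel under (z, y, x) lexicographic scan order, so the
#' result is reproducible across runs and platforms. Background and the
#' voxel partition are unchanged.
#'
#' @param vol an [instance_volume()].
#' @return List with `volume` (relabeled) and `id_map` (data.frame old, new).
#' @examples
#' a <- array(0L, c(2, 2, 2)); a[1, 1, 1] <- 42L; a[2, 2, 2] <- 7L
#' reindex_instances(instance_volume(a))$id_map
#' @export
reindex_instances <- function(vol) {
  stopifnot(inherits(vol, "instance_volume"))
  lab <- vol$labels
  d <- dim(lab)
  fg <- which(lab > 0L)
  if (length(fg) == 0L)
    return(list(volume = vol,
                id_map = data.frame(old = integer(0), new = integer(0))))
  coo <- arrayInd(fg, d)
  # scan key: z major, then y, then x
  key <- ((coo[, 1] - 1) * d[2] + (coo[, 2] - 1)) * d[3] + (coo[, 3] - 1)
  old <- lab[fg]
  first_key <- tapply(key, old, min)
  old_ids <- as.integer(names(first_key))
  ord <- order(first_key)
  id_map <- data.frame(old = old_ids[ord], new = seq_along(old_ids))
  lut <- integer(max(old_ids)); lut[id_map$old] <- id_map$new
  lab[fg] <- lut[old]
  list(volume = instance_volume(lab, vol$spacing, vol$name), id_map = id_map)
}

#' Remove instances below a minimum voxel volume
#'
#' Sets every instance whose voxel count is below `min_voxels` to
#' background; survivors are untouched. The boundary is inclusive: an
#' instance of exactly `min_voxels` voxels (500 by default) is kept. The
#' operation is idempotent.
#'
#' @param vol an [instance_volume()].
#' @param min_voxels minimum voxel count to keep (default 500).
#' @return List with `volume` and `log` (a `standardization_log` recording
#'   removed ids and sizes).
#' @export
filter_min_volume <- function(vol, min_voxels = 500L) {
  stopifnot(inherits(vol, "instance_volume"))
  min_voxels <- as.integer(min_voxels)
  if (is.na(min_voxels) || min_voxels < 1L)
    stop("`min_voxels` must be >= 1", call. = FALSE)
  sizes <- instance_sizes(vol)
  small <- sizes[sizes < min_voxels]
  lab <- vol$labels
  if (length(small)) {
    drop_ids <- as.integer(names(small))
    lab[lab %in% drop_ids] <- 0L
  }
  removed <- data.frame(instance_id = as.integer(names(small)),
                        voxel_count = unname(as.integer(small)))
  log <- new_std_log("filter_min_volume",
                     list(min_voxels = min_voxels, spacing_nm = vol$spacing),
                     before = length(sizes),
                     after = length(sizes) - length(small),
                     removed = removed)
  list(volume = instance_volume(lab, vol$spacing, vol$name), log = log)
}

# 1D Gaussian kernel, truncated at 3 sigma, normalized.
gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution along one axis with edge replication.
convolve_axis <- function(a, axis, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  out <- array(0, dim(a))
  n <- dim(a)[axis]
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)  # replicate edges
    sl <- switch(axis,
                 a[idx, , , drop = FALSE],
                 a[, idx, , drop = FALSE],
                 a[, , idx, drop = FALSE])
    out <- out + kernel[j] * sl
  }
  out
}

# Linear interpolation along one axis at fractional source positions `pos`
# (1-based, already clamped to [1, n]).
interp_axis <- function(a, axis, pos) {
  lo <- pmin(floor(pos), dim(a)[axis]); hi <- pmin(lo + 1, dim(a)[axis])
  f <- pos - lo
  take <- function(idx) switch(axis,
                               a[idx, , , drop = FALSE],
                               a[, idx, , drop = FALSE],
                               a[, , idx, drop = FALSE])
  A <- take(lo); B <- take(hi)
  A + sweep(B - A, axis, f, `*`)
}

# voxel-center source positions for resampling one axis
source_positions <- function(n_in, n_out, sp_in, sp_out) {
  pos <- ((seq_len(n_out) - 0.5) * sp_out / sp_in) + 0.5
  pmin(pmax(pos, 1), n_in)
}

#' Resample an image volume to a target voxel spacing
#'
#' Linear (trilinear, separable) interpolation at voxel centers. When
#' downsampling along an axis, a Gaussian anti-aliasing prefilter with
#' `sigma = (factor - 1) / 2` voxels is applied along that axis first, so
#' frequencies above the new Nyquist limit are attenuated before
#' decimation. The output extent per axis is
#' `round(extent * spacing_in / spacing_out)`.
#'
#' @param img an [image_volume()].
#' @param target_spacing numeric length 3 (z, y, x) in nm, all > 0; a
#'   single number is recycled isotropically.
#' @param antialias apply the prefilter when downsampling (default TRUE).
#' @return A resampled [image_volume()] with `spacing = target_spacing`.
#' @export
resample_image <- function(img, target_spacing, antialias = TRUE) {
  stopifnot(inherits(img, "image_volume"))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3L)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0))
    stop("`target_spacing` must be 3 positive numbers (z, y, x)", call. = FALSE)
  a <- img$intensities
  d_in <- dim(a)
  factors <- target_spacing / img$spacing          # > 1 = downsampling
  d_out <- pmax(1L, as.integer(round(d_in * img$spacing / target_spacing)))
  if (antialias) {
    for (axis in 1:3) {
      f <- factors[axis]
      if (f > 1 + 1e-9) {
        sigma <- (f - 1) / 2
        a <- convolve_axis(a, axis, gauss_kernel(sigma))
      }
    }
  }
  for (axis in 1:3) {
    pos <- source_positions(d_in[axis], d_out[axis], img$spacing[axis],
                            target_spacing[axis])
    a <- interp_axis(a, axis, pos)
  }
  image_volume(a, target_spacing, img$name)
}

#' Resample a label volume to a target voxel spacing
#'
#' Nearest-neighbor sampling at voxel centers: every output label value is
#' one of the input values, so no interpolation-created labels can appear
#' (small instances may disappear under coarse resampling). A majority-vote
#' block mode is available for integer downsampling factors.
#'
#' @inheritParams resample_image
#' @param vol an [instance_volume()].
#' @param method "nearest" (default) or "majority" (block-wise modal label;
#'   requires integer downsampling factors along every axis).
#' @return A resampled [instance_volume()].
#' @export
resample_labels <- function(vol, target_spacing, method = c("nearest", "majority")) {
  stopifnot(inherits(vol, "instance_volume"))
  method <- match.arg(method)
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3L)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0))
    stop("`target_spacing` must be 3 positive numbers (z, y, x)", call. = FALSE)
  lab <- vol$labels
  d_in <- dim(lab)
  d_out <- pmax(1L, as.integer(round(d_in * vol$spacing / target_spacing)))
  if (method == "nearest") {
    idx <- lapply(1:3, function(axis) {
      pos <- source_positions(d_in[axis], d_out[axis], vol$spacing[axis],
                              target_spacing[axis])
      pmin(pmax(round(pos), 1L), d_in[axis])
    })
    out <- lab[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  } else {
    f <- target_spacing / vol$spacing
    fi <- as.integer(round(f))
    if (any(abs(f - fi) > 1e-6) || any(fi < 1L))
      stop("majority resampling needs integer downsampling factors", call. = FALSE)
    d_out <- d_in %/% fi
    if (any(d_out < 1L))
      stop("target spacing coarser than the volume extent", call. = FALSE)
    crop <- lab[seq_len(d_out[1] * fi[1]), seq_len(d_out[2] * fi[2]),
                seq_len(d_out[3] * fi[3]), drop = FALSE]
    blk <- array(crop, c(fi[1], d_out[1], fi[2], d_out[2], fi[3], d_out[3]))
    out <- apply(blk, c(2L, 4L, 6L), function(v) {
      t <- table(v); as.integer(names(t)[which.max(t)])
    })
    out <- array(as.integer(out), d_out)
  }
  instance_volume(out, target_spacing, vol$name)
}

#' Report instances with more than one connected component
#'
#' Topological-consistency check: every instance label should form a single
#' connected voxel set. Non-mutating.
#'
#' @param vol an [instance_volume()].
#' @param connectivity component adjacency (default 26).
#' @return data.frame with columns `instance_id`, `n_components`, `flagged`
#'   (TRUE when > 1 component).
#' @export
check_topology <- function(vol, connectivity = 26L) {
  stopifnot(inherits(vol, "instance_volume"))
  ids <- instance_ids(vol)
  n <- vapply(ids, function(id) {
    m <- instance_mask(vol, id)
    bb <- mask_bbox(m)
    sub <- m[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
    count_components(sub, connectivity)
  }, integer(1))
  data.frame(instance_id = ids, n_components = n, flagged = n > 1L)
}

#' Write a standardization log as JSON
#'
#' @param log a `standardization_log`.
#' @param path output path (conventionally a `.json` sidecar next to the
#'   volume it describes).
#' @return `path`, invisibly.
#' @export
write_std_log <- function(log, path) {
  stopifnot(inherits(log, "standardization_log"))
  jsonlite::write_json(unclass(log), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
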