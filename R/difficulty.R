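#' Dilation Collision Index of one instance
#'
#' Number of distinct *other* instances whose masks intersect the instance
#' mask after a small box dilation. With the default 3x3x3 element (radius
#' 1), an instance collides with every instance whose mask lies within
#' Chebyshev distance 1 of its own, so DCI counts 26-adjacent neighbors. A
#' high DCI flags crowding: a small boundary expansion touches many
#' neighbors, the regime where automated segmentation tends to produce
#' false merges.
#'
#' Each neighbor label is counted once however many voxels overlap. The
#' computation is restricted to the instance's bounding box padded by the
#' radius, which is exact because the dilated mask cannot leave that box.
#'
#' @param vol an [instance_volume()].
#' @param instance_id positive integer label present in `vol`.
#' @param se dilation element, a [box_se()] or integer radius (default 1).
#' @return Non-negative integer count of colliding neighbor instances.
#' @seealso [compute_efi()], [difficulty_report()]
#' @export
compute_dci <- function(vol, instance_id, se = box_se(1L)) {
  r <- se_radius(se)
  m <- instance_mask(vol, instance_id)
  bb <- mask_bbox(m, pad = r)
  lab <- vol$labels[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
  sub <- m[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
  dil <- dilate_mask(sub, box_se(r))
  hit <- unique(lab[dil])
  length(hit[hit > 0L & hit != as.integer(instance_id)])
}

#' Erosion Fragility Index of one instance
#'
#' Number of extra connected components created by a mild box erosion of
#' the instance mask: `max(0, N_components(erode(M)) - 1)`. A solid compact
#' instance erodes to a single piece (EFI 0); an instance held together by
#' necks thinner than the structuring element fragments, and EFI counts the
#' newly created pieces. High EFI flags topological fragility — the thin-neck
#' and branched morphologies prone to false splits.
#'
#' An instance that erodes away entirely (everywhere thinner than 2r+1
#' voxels) scores 0: a vanished object creates no fragments. Voxels at the
#' volume border erode, since outside-volume space counts as background.
#'
#' @inheritParams compute_dci
#' @param se erosion element, a [box_se()] or integer radius (default 1).
#' @param connectivity component adjacency for the fragment count (default
#'   26, matching the full-box structuring element).
#' @return Non-negative integer.
#' @seealso [compute_dci()], [difficulty_report()]
#' @export
compute_efi <- function(vol, instance_id, se = box_se(1L), connectivity = 26L) {
  r <- se_radius(se)
  m <- instance_mask(vol, instance_id)
  bb <- mask_bbox(m, pad = 0L)
  sub <- m[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
  # cropping to the tight bounding box is exact: the mask is FALSE beyond it,
  # so the erosion sees the same background there as in the full volume
  ero <- erode_mask(sub, box_se(r))
  max(0L, count_components(ero, connectivity) - 1L)
}

#' Per-instance difficulty report for a labeled volume
#'
#' Computes voxel count, Dilation Collision Index and Erosion Fragility
#' Index for every instance, plus dataset-level arithmetic means. The two
#' indices span a difficulty plane: high-DCI instances are densely packed
#' (merge risk), high-EFI instances are topologically fragile (split risk).
#'
#' @inheritParams compute_dci
#' @param dilation_se,erosion_se structuring elements (default radius 1).
#' @param connectivity fragment adjacency for EFI (default 26).
#' @return An object of class `difficulty_report`: list with `name`,
#'   `records` (data.frame: instance_id, voxel_count, dci, efi),
#'   `n_instances`, `mean_dci`, `mean_efi` (NA for an empty volume) and
#'   `params`.
#' @examples
#' lab <- array(0L, c(4, 8, 4))
#' lab[2:3, 2:4, 2:3] <- 1L; lab[2:3, 5:7, 2:3] <- 2L  # face-abutting slabs
#' difficulty_report(instance_volume(lab))
#' @export
difficulty_report <- function(vol, dilation_se = box_se(1L),
                              erosion_se = box_se(1L), connectivity = 26L) {
  stopifnot(inherits(vol, "instance_volume"))
  ids <- instance_ids(vol)
  sizes <- instance_sizes(vol)
  recs <- data.frame(instance_id = ids,
                     voxel_count = if (length(ids)) unname(sizes[as.character(ids)]) else integer(0),
                     dci = integer(length(ids)),
                     efi = integer(length(ids)))
  for (k in seq_along(ids)) {
    recs$dci[k] <- compute_dci(vol, ids[k], dilation_se)
    recs$efi[k] <- compute_efi(vol, ids[k], erosion_se, connectivity)
  }
  structure(list(
    name = vol$name,
    records = recs,
    n_instances = length(ids),
    mean_dci = if (length(ids)) mean(recs$dci) else NA_real_,
    mean_efi = if (length(ids)) mean(recs$efi) else NA_real_,
    params = list(dilation_radius = se_radius(dilation_se),
                  erosion_radius = se_radius(erosion_se),
                  connectivity = as.integer(connectivity))
  ), class = "difficulty_report")
}

#' @export
print.difficulty_report <- function(x, ...) {
  cat(sprintf("<difficulty_report> %s\n", x$name))
  cat(sprintf("  instances: %d\n", x$n_instances))
  if (x$n_instances > 0) {
    cat(sprintf("  mean DCI: %.3f   mean EFI: %.3f\n", x$mean_dci, x$mean_efi))
    cat(sprintf("  DCI range: [%d, %d]   EFI range: [%d, %d]\n",
                min(x$records$dci), max(x$records$dci),
                min(x$records$efi), max(x$records$efi)))
  }
  invisible(x)
}

#' @export
summary.difficulty_report <- function(object, ...) {
  print(object)
  if (object$n_instances > 0) {
    cat("  per-instance quartiles:\n")
    for (col in c("voxel_count", "dci", "efi")) {
      q <- stats::quantile(object$records[[col]])
      cat(sprintf("    %-11s %s\n", col,
                  paste(names(q), format(q, digits = 3), sep = "=", collapse = " ")))
    }
  }
  invisible(object)
}

#' Difficulty-plane scatter of a report
#'
#' Plots each instance at its (DCI, EFI) coordinates: the lower-left corner
#' is the easy regime, the right edge dense packing, the upper edge
#' topological fragility.
#'
#' @param x a `difficulty_report`.
#' @param jitter_amount uniform jitter applied to the integer coordinates so
#'   coincident instances remain visible; 0 disables.
#' @param ... passed to [graphics::plot()].
#' @export
plot.difficulty_report <- function(x, jitter_amount = 0.15, ...) {
  r <- x$records
  if (nrow(r) == 0L) {
    plot(0, 0, type = "n", xlab = "DCI", ylab = "EFI", main = x$name, ...)
    return(invisible(x))
  }
  jx <- if (jitter_amount > 0) runif(nrow(r), -jitter_amount, jitter_amount) else 0
  jy <- if (jitter_amount > 0) runif(nrow(r), -jitter_amount, jitter_amount) else 0
  plot(r$dci + jx, r$efi + jy, xlab = "DCI (collision neighbors)",
       ylab = "EFI (erosion fragments)", main = x$name,
       pch = 16, col = grDevices::adjustcolor("steelblue", 0.6), ...)
  invisible(x)
}

#' Export difficulty reports as a per-instance CSV
#'
#' One row per instance across all reports, with a fixed header
#' `dataset,instance_id,voxel_count,dci,efi` — the flat form used for
#' difficulty-plane scatter plots across datasets.
#'
#' @param reports a single `difficulty_report` or a list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_difficulty_scatter <- function(reports, path) {
  if (inherits(reports, "difficulty_report")) reports <- list(reports)
  stopifnot(all(vapply(reports, inherits, logical(1), "difficulty_report")))
  rows <- lapply(reports, function(rep) {
    if (rep$n_instances == 0L) return(NULL)
    cbind(dataset = rep$name, rep$records)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(dataset = character(0), instance_id = integer(0),
                      voxel_count = integer(0), dci = integer(0), efi = integer(0))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
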