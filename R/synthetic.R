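# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream, so generation is reproducible per (spec, seed) and side-effect-free.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic phantom volume
#'
#' Describes a seeded 3D phantom of non-overlapping instances built from
#' analytic primitives, emulating the regimes that make real organelle
#' volumes hard to segment: dense packs of near-touching convex bodies
#' (high collision index), thin-necked dumbbells and branched trees that
#' fragment under a 1-voxel erosion (high fragility index), and anisotropic
#' voxel spacing.
#'
#' @param shape grid extent (z, y, x) in voxels.
#' @param spacing voxel size (z, y, x) in nm.
#' @param n_instances number of instances to place.
#' @param primitives mix to sample from: subset of "ball", "tube",
#'   "dumbbell", "tree".
#' @param size_range inclusive range of the primitive size parameter
#'   (ball radius / tube half-length scale / dumbbell head half-width).
#' @param gap minimum pairwise Chebyshev gap between instances in voxels;
#'   0 allows abutting instances.
#' @param neck_radius dumbbell neck half-width; 1 gives a one-voxel-thick
#'   bar that a radius-1 erosion removes.
#' @param arrangement "random" placement, or "abutting_pairs" which places
#'   instances as face-abutting cube pairs (every instance then has a
#'   collision neighbor); `n_instances` must be even for pairs.
#' @param seed RNG seed; identical (spec, seed) gives bit-identical volumes.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48L, 48L, 48L), spacing = c(16, 16, 16),
                         n_instances = 8L,
                         primitives = c("ball", "tube", "dumbbell", "tree"),
                         size_range = c(3L, 5L), gap = 1L, neck_radius = 1L,
                         arrangement = c("random", "abutting_pairs"),
                         seed = 1L) {
  arrangement <- match.arg(arrangement)
  primitives <- match.arg(primitives, several.ok = TRUE)
  stopifnot(length(shape) == 3L, all(shape >= 1L), all(spacing > 0),
            n_instances >= 0L, length(size_range) == 2L,
            all(size_range >= 1L), size_range[1] <= size_range[2],
            gap >= 0L, neck_radius >= 1L)
  if (arrangement == "abutting_pairs" && n_instances %% 2L != 0L)
    stop("abutting_pairs needs an even instance count", call. = FALSE)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 n_instances = as.integer(n_instances),
                 primitives = primitives,
                 size_range = as.integer(size_range), gap = as.integer(gap),
                 neck_radius = as.integer(neck_radius),
                 arrangement = arrangement, seed = as.integer(seed)),
            class = "phantom_spec")
}

# --- analytic rasterizers: local logical arrays built from inequalities ----

raster_ball <- function(R) {
  n <- 2L * R + 1L
  g <- seq_len(n) - (R + 1L)
  d2 <- outer(outer(g^2, g^2, `+`), g^2, `+`)
  array(d2 <= R^2, c(n, n, n))
}

raster_tube <- function(r, half_len, axis) {
  # axis-aligned capsule: distance to the center segment <= r
  L <- 2L * half_len + 1L
  n <- 2L * r + 1L
  d <- c(n, n, n); d[axis] <- L + 2L * r
  grid <- lapply(1:3, function(k) seq_len(d[k]) - (d[k] + 1) / 2)
  along <- grid[[axis]]
  perp <- setdiff(1:3, axis)
  t_clamp <- pmin(pmax(along, -half_len), half_len)
  ax_d2 <- (along - t_clamp)^2
  comp <- vector("list", 3L)
  comp[[axis]] <- ax_d2
  comp[[perp[1]]] <- grid[[perp[1]]]^2
  comp[[perp[2]]] <- grid[[perp[2]]]^2
  d2 <- outer(outer(comp[[1]], comp[[2]], `+`), comp[[3]], `+`)
  array(d2 <= r^2, d)
}

raster_dumbbell <- function(head, neck_radius, neck_len, axis) {
  # two solid cubes of side 2*head+1 joined by a bar of cross-section
  # (2*neck_radius-1)^2 and length neck_len along `axis`
  side <- 2L * head + 1L
  ext <- c(side, side, side); ext[axis] <- 2L * side + neck_len
  m <- array(FALSE, ext)
  idx_all <- lapply(ext, seq_len)
  cube1 <- idx_all; cube1[[axis]] <- 1:side
  cube2 <- idx_all; cube2[[axis]] <- (side + neck_len + 1L):ext[axis]
  m[cube1[[1]], cube1[[2]], cube1[[3]]] <- TRUE
  m[cube2[[1]], cube2[[2]], cube2[[3]]] <- TRUE
  half <- neck_radius - 1L
  ctr <- (side + 1L) %/% 2L
  bar <- idx_all
  bar[[axis]] <- (side + 1L):(side + neck_len)
  for (k in setdiff(1:3, axis)) bar[[k]] <- (ctr - half):(ctr + half)
  m[bar[[1]], bar[[2]], bar[[3]]] <- TRUE
  m
}

raster_tree <- function(r, half_len) {
  # three orthogonal capsules sharing a center: a branched body whose arms
  # are thin enough to fragment under erosion when r = 1
  ext <- rep(2L * (half_len + r) + 1L, 3L)
  m <- array(FALSE, ext)
  for (axis in 1:3) {
    t <- raster_tube(r, half_len, axis)
    off <- (ext - dim(t)) %/% 2L
    sl <- lapply(1:3, function(k) off[k] + seq_len(dim(t)[k]))
    m[sl[[1]], sl[[2]], sl[[3]]] <- m[sl[[1]], sl[[2]], sl[[3]]] | t
  }
  m
}

# Try to place a local mask into the occupancy grid keeping a Chebyshev gap
# to everything already placed. The exclusion zone is the mask dilated by
# `gap` inside a padded frame, so it extends beyond the mask's own bounding
# box (clipped at the volume edge, where there is nothing to collide with).
# Returns the (z,y,x) offset of the mask or NULL.
find_placement <- function(occupied, mask, gap, tries = 200L) {
  d <- dim(occupied)
  local_dim <- dim(mask)
  if (any(local_dim > d)) return(NULL)
  if (gap > 0L) {
    pad_dim <- local_dim + 2L * gap
    padded <- array(FALSE, pad_dim)
    ctr <- lapply(1:3, function(k) gap + seq_len(local_dim[k]))
    padded[ctr[[1]], ctr[[2]], ctr[[3]]] <- mask
    zone <- dilate_mask(padded, box_se(gap))
  } else {
    zone <- mask
  }
  zdim <- dim(zone)
  for (t in seq_len(tries)) {
    off <- vapply(1:3, function(k) sample.int(d[k] - local_dim[k] + 1L, 1L),
                  integer(1))
    zoff <- off - gap  # zone origin in volume coordinates (may be < 1)
    lo <- pmax(zoff, 1L); hi <- pmin(zoff + zdim - 1L, d)
    vol_sl <- lapply(1:3, function(k) lo[k]:hi[k])
    zone_sl <- lapply(1:3, function(k) (lo[k] - zoff[k] + 1L):(hi[k] - zoff[k] + 1L))
    if (!any(zone[zone_sl[[1]], zone_sl[[2]], zone_sl[[3]]] &
             occupied[vol_sl[[1]], vol_sl[[2]], vol_sl[[3]]]))
      return(off)
  }
  NULL
}

#' Generate a seeded phantom instance volume
#'
#' Places `n_instances` analytic primitives without overlap and with
#' pairwise Chebyshev gaps of at least `spec$gap` voxels, labeling them
#' 1..N in placement order. Deterministic for a given spec (the spec's seed
#' drives all randomness; the caller's RNG state is untouched).
#'
#' @param spec a [phantom_spec()].
#' @return An [instance_volume()].
#' @examples
#' v <- generate_phantom(phantom_spec(n_instances = 4, seed = 7))
#' length(instance_ids(v))
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    lab <- array(0L, spec$shape)
    occupied <- array(FALSE, spec$shape)
    placed <- 0L
    if (spec$arrangement == "abutting_pairs") {
      n_pairs <- spec$n_instances %/% 2L
      for (p in seq_len(n_pairs)) {
        s <- sample(spec$size_range[1]:spec$size_range[2], 1L)
        side <- 2L * s + 1L
        axis <- sample.int(3L, 1L)
        ext <- c(side, side, side); ext[axis] <- 2L * side
        pair_local <- array(0L, ext)
        a_idx <- lapply(ext, seq_len); a_idx[[axis]] <- 1:side
        b_idx <- lapply(ext, seq_len); b_idx[[axis]] <- (side + 1L):(2L * side)
        pair_local[a_idx[[1]], a_idx[[2]], a_idx[[3]]] <- 1L
        pair_local[b_idx[[1]], b_idx[[2]], b_idx[[3]]] <- 2L
        mask <- pair_local > 0L
        off <- find_placement(occupied, mask, spec$gap)
        if (is.null(off))
          stop(sprintf("phantom packing infeasible: placed %d of %d instances",
                       placed, spec$n_instances), call. = FALSE)
        sl <- lapply(1:3, function(k) off[k] - 1L + seq_len(dim(mask)[k]))
        sub <- lab[sl[[1]], sl[[2]], sl[[3]]]
        sub[mask] <- placed + pair_local[mask]
        lab[sl[[1]], sl[[2]], sl[[3]]] <- sub
        occ <- occupied[sl[[1]], sl[[2]], sl[[3]]]
        occupied[sl[[1]], sl[[2]], sl[[3]]] <- occ | mask
        placed <- placed + 2L
      }
    } else {
      for (i in seq_len(spec$n_instances)) {
        prim <- sample(spec$primitives, 1L)
        s <- sample(spec$size_range[1]:spec$size_range[2], 1L)
        mask <- switch(prim,
          ball = raster_ball(s),
          tube = raster_tube(max(1L, s %/% 2L), s + 2L, sample.int(3L, 1L)),
          dumbbell = raster_dumbbell(max(2L, s %/% 2L + 1L), spec$neck_radius,
                                     3L, sample.int(3L, 1L)),
          tree = raster_tree(1L, s + 1L))
        off <- find_placement(occupied, mask, spec$gap)
        if (is.null(off))
          stop(sprintf("phantom packing infeasible: placed %d of %d instances",
                       placed, spec$n_instances), call. = FALSE)
        sl <- lapply(1:3, function(k) off[k] - 1L + seq_len(dim(mask)[k]))
        sub <- lab[sl[[1]], sl[[2]], sl[[3]]]
        sub[mask] <- i
        lab[sl[[1]], sl[[2]], sl[[3]]] <- sub
        occ <- occupied[sl[[1]], sl[[2]], sl[[3]]]
        occupied[sl[[1]], sl[[2]], sl[[3]]] <- occ | mask
        placed <- placed + 1L
      }
    }
    instance_volume(lab, spec$spacing,
                    name = sprintf("phantom-seed%d", spec$seed))
  })
}

#' Specification of controlled prediction degradation
#'
#' Error rates for deriving a degraded "prediction" from a ground-truth
#' volume, with every applied event logged so expected instance-level
#' TP/FP/FN at a given IoU threshold can be predicted from the log alone.
#'
#' @param merge_prob probability of merging each 26-adjacent instance pair
#'   (each instance participates in at most one merge).
#' @param split_prob probability of splitting each untouched instance in
#'   two along its longest axis.
#' @param drop_prob probability of deleting each untouched instance.
#' @param spurious_rate expected number of injected background blobs
#'   (Poisson), each placed at Chebyshev distance >= 2 from all foreground.
#' @param boundary_radius per-instance boundary erosion noise radius
#'   (0 = off; boundary noise perturbs IoUs and is logged but not
#'   predictable from the log alone).
#' @param seed RNG seed.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(merge_prob = 0, split_prob = 0, drop_prob = 0,
                              spurious_rate = 0, boundary_radius = 0L,
                              seed = 1L) {
  probs <- c(merge_prob, split_prob, drop_prob)
  stopifnot(all(probs >= 0), all(probs <= 1), spurious_rate >= 0,
            boundary_radius >= 0L)
  structure(list(merge_prob = merge_prob, split_prob = split_prob,
                 drop_prob = drop_prob, spurious_rate = spurious_rate,
                 boundary_radius = as.integer(boundary_radius),
                 seed = as.integer(seed)),
            class = "perturbation_spec")
}

# 26-adjacent instance pairs of a volume (i < j), via radius-1 collisions.
adjacent_pairs <- function(vol) {
  ids <- instance_ids(vol)
  pairs <- list()
  for (id in ids) {
    m <- instance_mask(vol, id)
    bb <- mask_bbox(m, pad = 1L)
    lab <- vol$labels[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
    sub <- m[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
    hit <- unique(lab[dilate_mask(sub)])
    for (j in hit[hit > id]) pairs[[length(pairs) + 1L]] <- c(id, j)
  }
  pairs
}

#' Derive a degraded prediction with a perturbation log
#'
#' Applies merge, split, drop, spurious-blob and boundary-noise events to a
#' ground-truth volume. Prediction labels are freshly assigned (1..M in
#' event order), so the result also exercises label-permutation
#' invariance. Deterministic per (gt, spec).
#'
#' @param gt an [instance_volume()].
#' @param pspec a [perturbation_spec()].
#' @return List with `pred` (an `instance_volume`) and `log` (class
#'   `perturbation_log`): data.frame `events` with one row per event
#'   (type, gt ids, pred id, sizes) plus the spec.
#' @seealso [predict_counts()] for the log-implied TP/FP/FN.
#' @export
perturb_prediction <- function(gt, pspec) {
  stopifnot(inherits(gt, "instance_volume"), inherits(pspec, "perturbation_spec"))
  with_seed(pspec$seed, {
    ids <- instance_ids(gt)
    sizes <- instance_sizes(gt)
    pred <- array(0L, dim(gt$labels))
    events <- list()
    next_id <- 0L
    new_id <- function() { next_id <<- next_id + 1L; next_id }
    touched <- integer(0)

    # merges: each adjacent pair independently, one merge per instance
    for (pair in adjacent_pairs(gt)) {
      if (any(pair %in% touched)) next
      if (runif(1) < pspec$merge_prob) {
        pid <- new_id()
        pred[gt$labels %in% pair] <- pid
        touched <- c(touched, pair)
        events[[length(events) + 1L]] <- data.frame(
          type = "merge", gt_id = pair[1], gt_id2 = pair[2], pred_id = pid,
          size = unname(sizes[as.character(pair[1])]),
          size2 = unname(sizes[as.character(pair[2])]))
      }
    }
    # splits and drops on untouched instances
    for (id in setdiff(ids, touched)) {
      u <- runif(1)
      if (u < pspec$split_prob) {
        m <- gt$labels == id
        coo <- arrayInd(which(m), dim(m))
        ext <- apply(coo, 2L, function(v) diff(range(v)))
        axis <- which.max(ext)
        cut <- stats::median(coo[, axis])
        lo_side <- coo[, axis] <= cut
        if (!any(lo_side) || all(lo_side)) { # degenerate: keep intact
          pid <- new_id(); pred[m] <- pid
          events[[length(events) + 1L]] <- data.frame(
            type = "keep", gt_id = id, gt_id2 = NA, pred_id = pid,
            size = unname(sizes[as.character(id)]), size2 = NA)
        } else {
          p1 <- new_id(); p2 <- new_id()
          vox <- which(m)
          pred[vox[lo_side]] <- p1
          pred[vox[!lo_side]] <- p2
          events[[length(events) + 1L]] <- data.frame(
            type = "split", gt_id = id, gt_id2 = NA, pred_id = p1,
            size = sum(lo_side), size2 = sum(!lo_side))
        }
      } else if (u < pspec$split_prob + pspec$drop_prob) {
        events[[length(events) + 1L]] <- data.frame(
          type = "drop", gt_id = id, gt_id2 = NA, pred_id = NA,
          size = unname(sizes[as.character(id)]), size2 = NA)
      } else {
        pid <- new_id()
        pred[gt$labels == id] <- pid
        events[[length(events) + 1L]] <- data.frame(
          type = "keep", gt_id = id, gt_id2 = NA, pred_id = pid,
          size = unname(sizes[as.character(id)]), size2 = NA)
      }
    }
    # spurious blobs in background, clear of all foreground
    n_blob <- stats::rpois(1L, pspec$spurious_rate)
    if (n_blob > 0L) {
      occ <- gt$labels > 0L | pred > 0L
      blob <- raster_ball(2L)
      for (b in seq_len(n_blob)) {
        off <- find_placement(occ, blob, 2L, tries = 80L)
        if (is.null(off)) next
        pid <- new_id()
        sl <- lapply(1:3, function(k) off[k] - 1L + seq_len(dim(blob)[k]))
        sub <- pred[sl[[1]], sl[[2]], sl[[3]]]
        sub[blob] <- pid
        pred[sl[[1]], sl[[2]], sl[[3]]] <- sub
        o <- occ[sl[[1]], sl[[2]], sl[[3]]]
        occ[sl[[1]], sl[[2]], sl[[3]]] <- o | blob
        events[[length(events) + 1L]] <- data.frame(
          type = "spurious", gt_id = NA, gt_id2 = NA, pred_id = pid,
          size = sum(blob), size2 = NA)
      }
    }
    # boundary noise: erode each kept prediction by a random radius <= b
    if (pspec$boundary_radius > 0L) {
      for (pid in seq_len(next_id)) {
        r <- sample.int(pspec$boundary_radius + 1L, 1L) - 1L
        if (r == 0L) next
        m <- pred == pid
        if (!any(m)) next
        ero <- erode_mask(m, box_se(r))
        pred[m & !ero] <- 0L
        events[[length(events) + 1L]] <- data.frame(
          type = "boundary", gt_id = NA, gt_id2 = NA, pred_id = pid,
          size = sum(ero), size2 = r)
      }
    }
    ev <- if (length(events)) do.call(rbind, events) else
      data.frame(type = character(0), gt_id = integer(0), gt_id2 = integer(0),
                 pred_id = integer(0), size = integer(0), size2 = integer(0))
    log <- structure(list(events = ev, spec = pspec), class = "perturbation_log")
    list(pred = instance_volume(pred, gt$spacing,
                                name = paste0(gt$name, "-perturbed")),
         log = log)
  })
}

#' @export
print.perturbation_log <- function(x, ...) {
  cat("<perturbation_log>\n")
  print(table(x$events$type))
  invisible(x)
}

#' Expected instance TP/FP/FN implied by a perturbation log
#'
#' Bookkeeping for geometrically independent events at IoU threshold
#' `tau`: a kept instance is a TP; a dropped one an FN; a spurious blob an
#' FP; a merged pair yields one TP and one FN when the larger member's IoU
#' with the union (`max(s1, s2) / (s1 + s2)`) reaches `tau`, else two FN
#' and one FP; a split yields one TP and one FP when the larger fragment's
#' IoU (`max(p1, p2) / (p1 + p2)`) reaches `tau`, else one FN and two FP.
#' Undefined in the presence of boundary-noise events.
#'
#' @param log a `perturbation_log`.
#' @param tau IoU threshold (default 0.5).
#' @return List with `tp`, `fp`, `fn`.
#' @export
predict_counts <- function(log, tau = 0.5) {
  stopifnot(inherits(log, "perturbation_log"))
  ev <- log$events
  if (any(ev$type == "boundary"))
    stop("log contains boundary-noise events; counts are not predictable",
         call. = FALSE)
  tp <- fp <- fn <- 0L
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    switch(e$type,
      keep = { tp <- tp + 1L },
      drop = { fn <- fn + 1L },
      spurious = { fp <- fp + 1L },
      merge = {
        if (max(e$size, e$size2) / (e$size + e$size2) >= tau) {
          tp <- tp + 1L; fn <- fn + 1L
        } else { fn <- fn + 2L; fp <- fp + 1L }
      },
      split = {
        if (max(e$size, e$size2) / (e$size + e$size2) >= tau) {
          tp <- tp + 1L; fp <- fp + 1L
        } else { fn <- fn + 1L; fp <- fp + 2L }
      })
  }
  list(tp = tp, fp = fp, fn = fn)
}

#' Write a synthetic benchmark fixture in the standard layout
#'
#' Generates seeded phantom label volumes plus derived intensity volumes
#' (smoothed foreground indicator with Gaussian noise — enough to exercise
#' I/O and layout, with no attempt at EM realism), and writes the full
#' nnU-Net-compatible layout: `imagesTr/`, `labelsTr/`, `imagesTs/`,
#' `labelsTs/`, `dataset.json`, `split.json`, `metadata.csv` and a SHA-256
#' checksum manifest. Validation cases live in the training folders and are
#' marked in `split.json`.
#'
#' @param root output directory (created if needed).
#' @param spec a [phantom_spec()]; case k is generated with seed
#'   `spec$seed + k`.
#' @param n_train,n_val,n_test case counts per split.
#' @param dataset_name short lowercase name used in filenames.
#' @return The validated `dataset_descriptor` of the written layout.
#' @export
make_fixture_dataset <- function(root, spec = phantom_spec(),
                                 n_train = 2L, n_val = 1L, n_test = 1L,
                                 dataset_name = "phantom") {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (d in c("imagesTr", "labelsTr", "imagesTs", "labelsTs"))
    dir.create(file.path(root, d), showWarnings = FALSE)
  n_tr_folder <- n_train + n_val
  cases_tr <- sprintf("me2-%s_train%02d", dataset_name, seq_len(n_tr_folder) - 1L)
  cases_ts <- sprintf("me2-%s_test%02d", dataset_name, seq_len(n_test) - 1L)
  all_cases <- c(cases_tr, cases_ts)
  for (k in seq_along(all_cases)) {
    sp <- spec; sp$seed <- spec$seed + k
    vol <- generate_phantom(sp)
    img <- synth_intensity(vol, seed = sp$seed)
    folder <- if (k <= n_tr_folder) "Tr" else "Ts"
    write_labels(vol, file.path(root, paste0("labels", folder),
                                paste0(all_cases[k], ".nii.gz")))
    write_image(img, file.path(root, paste0("images", folder),
                               paste0(all_cases[k], "_0000.nii.gz")))
  }
  dataset_json <- list(
    name = dataset_name,
    description = "synthetic phantom fixture",
    channel_names = list(`0` = "EM"),
    spacing = spec$spacing,
    labels = list(background = 0),
    numTraining = n_tr_folder,
    numTest = n_test,
    file_ending = ".nii.gz",
    generator = list(seed = spec$seed, n_instances = spec$n_instances,
                     primitives = spec$primitives, gap = spec$gap,
                     arrangement = spec$arrangement)
  )
  jsonlite::write_json(dataset_json, file.path(root, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  split_json <- list(train = cases_tr[seq_len(n_train)],
                     val = if (n_val > 0L) cases_tr[n_train + seq_len(n_val)] else character(0),
                     test = cases_ts)
  jsonlite::write_json(split_json, file.path(root, "split.json"),
                       pretty = TRUE)
  md <- data.frame(dataset = dataset_name, system = "synthetic",
                   tissue = "synthetic", cell_type = "phantom",
                   modality = "synthetic",
                   voxel_size_nm = paste(spec$spacing, collapse = "x"),
                   source = "vemtools generator")
  write.csv(md, file.path(root, "metadata.csv"), row.names = FALSE)
  write_checksum_manifest(root)
  read_dataset_descriptor(root)
}

# Smoothed foreground indicator plus Gaussian noise, as a float image.
synth_intensity <- function(vol, seed = 1L, sigma = 1, noise_sd = 0.1) {
  with_seed(seed + 10000L, {
    a <- array(as.double(vol$labels > 0L), dim(vol$labels))
    k <- gauss_kernel(sigma)
    for (axis in 1:3) a <- convolve_axis(a, axis, k)
    a <- a + rnorm(length(a), sd = noise_sd)
    image_volume(a, vol$spacing, paste0(vol$name, "-img"))
  })
}
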