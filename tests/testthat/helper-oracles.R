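# Brute-force oracles, independent of the package's implementation paths:
# coordinate-set arithmetic for morphology, BFS flood fill for components,
# factorial enumeration for assignment.

all_offsets <- function(radius, connectivity = NULL) {
  g <- expand.grid(dz = -radius:radius, dy = -radius:radius, dx = -radius:radius)
  g <- g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ]
  if (!is.null(connectivity)) {
    manh <- abs(g$dz) + abs(g$dy) + abs(g$dx)
    g <- switch(as.character(connectivity),
                "6" = g[manh == 1, ], "18" = g[manh <= 2, ], "26" = g)
  }
  as.matrix(g)
}

# {p + delta : p in mask, delta in [-r, r]^3} clipped to bounds
oracle_dilate <- function(mask, radius = 1L) {
  d <- dim(mask)
  coo <- arrayInd(which(mask), d)
  out <- array(FALSE, d)
  if (nrow(coo) == 0L) return(out)
  offs <- rbind(c(0L, 0L, 0L), all_offsets(radius))
  for (i in seq_len(nrow(offs))) {
    p <- sweep(coo, 2L, offs[i, ], `+`)
    ok <- p[, 1] >= 1 & p[, 1] <= d[1] & p[, 2] >= 1 & p[, 2] <= d[2] &
      p[, 3] >= 1 & p[, 3] <= d[3]
    out[p[ok, , drop = FALSE]] <- TRUE
  }
  out
}

# voxels whose whole [-r, r]^3 neighborhood lies inside mask AND the grid
oracle_erode <- function(mask, radius = 1L) {
  d <- dim(mask)
  coo <- arrayInd(which(mask), d)
  out <- array(FALSE, d)
  if (nrow(coo) == 0L) return(out)
  keep <- rep(TRUE, nrow(coo))
  offs <- all_offsets(radius)
  for (i in seq_len(nrow(offs))) {
    p <- sweep(coo, 2L, offs[i, ], `+`)
    inside <- p[, 1] >= 1 & p[, 1] <= d[1] & p[, 2] >= 1 & p[, 2] <= d[2] &
      p[, 3] >= 1 & p[, 3] <= d[3]
    val <- rep(FALSE, nrow(coo))
    val[inside] <- mask[p[inside, , drop = FALSE]]
    keep <- keep & val
  }
  out[coo[keep, , drop = FALSE]] <- TRUE
  out
}

# queue-based flood fill over voxel coordinates
oracle_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- all_offsets(1L, connectivity)
  todo <- which(mask)
  seen <- logical(prod(d))
  lin <- function(p) p[, 1] + (p[, 2] - 1L) * d[1] + (p[, 3] - 1L) * d[1] * d[2]
  n <- 0L
  for (s in todo) {
    if (seen[s]) next
    n <- n + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      c0 <- arrayInd(cur, d)
      p <- sweep(offs, 2L, as.integer(c0), `+`)
      ok <- p[, 1] >= 1 & p[, 1] <= d[1] & p[, 2] >= 1 & p[, 2] <= d[2] &
        p[, 3] >= 1 & p[, 3] <= d[3]
      nb <- lin(p[ok, , drop = FALSE])
      nb <- nb[mask[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  n
}

oracle_dci <- function(vol, id, radius = 1L) {
  dil <- oracle_dilate(vol$labels == id, radius)
  hit <- unique(vol$labels[dil])
  length(hit[hit > 0 & hit != id])
}

oracle_efi <- function(vol, id, radius = 1L, connectivity = 26L) {
  ero <- oracle_erode(vol$labels == id, radius)
  if (!any(ero)) return(0L)
  oracle_components(ero, connectivity) - 1L
}

perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# maximum total score over all one-to-one assignments of rows to columns
oracle_best_total <- function(score) {
  nr <- nrow(score); nc <- ncol(score)
  n <- max(nr, nc)
  sq <- matrix(0, n, n)
  sq[seq_len(nr), seq_len(nc)] <- score
  p <- perms(n)
  best <- -Inf
  for (i in seq_len(nrow(p)))
    best <- max(best, sum(sq[cbind(seq_len(n), p[i, ])]))
  best
}

# random labeled volume: k axis-aligned boxes / balls painted in order
# (later labels overwrite), giving irregular and possibly fragmented shapes
random_label_volume <- function(shape = c(20L, 20L, 20L), k = 6L, seed = 1L) {
  set.seed(seed)
  lab <- array(0L, shape)
  for (i in seq_len(k)) {
    if (runif(1) < 0.5) {
      sz <- sample(2:6, 3L, replace = TRUE)
      lo <- vapply(1:3, function(a) sample.int(max(1L, shape[a] - sz[a]), 1L),
                   integer(1))
      lab[lo[1]:(lo[1] + sz[1]), lo[2]:(lo[2] + sz[2]), lo[3]:(lo[3] + sz[3])] <- i
    } else {
      R <- sample(2:4, 1L)
      ctr <- vapply(1:3, function(a) sample.int(shape[a], 1L), integer(1))
      g <- lapply(1:3, function(a) (seq_len(shape[a]) - ctr[a])^2)
      d2 <- outer(outer(g[[1]], g[[2]], `+`), g[[3]], `+`)
      lab[d2 <= R^2] <- i
    }
  }
  instance_volume(lab, name = sprintf("rand-%d", seed))
}

# analytic fixtures reused across tests
make_abutting_cubes <- function() {
  lab <- array(0L, c(8L, 8L, 8L))
  lab[2:4, 2:4, 2:4] <- 1L
  lab[2:4, 5:7, 2:4] <- 2L
  instance_volume(lab, name = "abutting")
}

make_dumbbell_volume <- function(label = 1L, shape = c(7L, 15L, 7L)) {
  lab <- array(0L, shape)
  lab[1:5, 1:5, 1:5] <- label
  lab[3, 6:8, 3] <- label       # 1x1x3 bar: removed by radius-1 erosion
  lab[1:5, 9:13, 1:5] <- label
  instance_volume(lab, name = "dumbbell")
}

make_iou_fixture <- function(iou, gt_sizes = NULL, pred_sizes = NULL) {
  gt_ids <- seq_len(nrow(iou)); pred_ids <- seq_len(ncol(iou))
  structure(list(gt_ids = gt_ids, pred_ids = pred_ids, iou = iou,
                 gt_sizes = setNames(gt_sizes %||% rep(100L, nrow(iou)),
                                     gt_ids),
                 pred_sizes = setNames(pred_sizes %||% rep(100L, ncol(iou)),
                                       pred_ids)),
            class = "iou_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
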