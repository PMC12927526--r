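#' Box structuring element
#'
#' A cubic (2r+1)^3 voxel neighborhood: at radius 1 this is the 3x3x3 box,
#' i.e. the full 26-neighborhood used for both the dilation and erosion
#' steps of the difficulty metrics. Morphology with this element is defined
#' in voxel units regardless of physical anisotropy.
#'
#' @param radius integer >= 1, half-width of the box in voxels.
#' @return An object of class `box_se`.
#' @export
box_se <- function(radius = 1L) {
  radius <- as.integer(radius)
  if (length(radius) != 1L || is.na(radius) || radius < 1L)
    stop("`radius` must be a single integer >= 1", call. = FALSE)
  structure(list(radius = radius), class = "box_se")
}

se_radius <- function(se) {
  if (inherits(se, "box_se")) return(se$radius)
  box_se(se)$radius
}

# Shift a 3D array along one axis by `by` voxels (positive = toward higher
# indices), filling vacated planes with `fill`.
shift_axis <- function(a, axis, by, fill) {
  if (by == 0L) return(a)
  d <- dim(a)
  n <- d[axis]
  out <- array(fill, d)
  if (abs(by) >= n) return(out)
  src <- vector("list", 3L); dst <- vector("list", 3L)
  for (k in 1:3) { src[[k]] <- seq_len(d[k]); dst[[k]] <- seq_len(d[k]) }
  if (by > 0L) { dst[[axis]] <- (by + 1L):n; src[[axis]] <- 1L:(n - by)
  } else       { dst[[axis]] <- 1L:(n + by); src[[axis]] <- (1L - by):n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Separable box morphology: a Chebyshev-ball (box) dilation/erosion is the
# composition of 1D window maxima/minima along each axis. Outside-volume
# voxels count as background in both directions (fill = FALSE), so dilation
# clips at the bounds and border voxels erode away.
box_sweep <- function(mask, radius, op = c("dilate", "erode")) {
  op <- match.arg(op)
  out <- mask
  for (axis in 1:3) {
    acc <- out
    for (k in seq_len(radius)) {
      p <- shift_axis(out, axis,  k, FALSE)
      m <- shift_axis(out, axis, -k, FALSE)
      acc <- if (op == "dilate") acc | p | m else acc & p & m
    }
    out <- acc
  }
  out
}

#' Dilate a binary mask by a box structuring element
#'
#' Returns the set of voxels within Chebyshev distance `radius` of any mask
#' voxel, clipped at the volume bounds. The output always contains the input.
#'
#' @param mask 3D logical array.
#' @param se a [box_se()] or an integer radius (default radius 1, the 3x3x3
#'   box).
#' @return 3D logical array of the same shape.
#' @examples
#' m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
#' sum(dilate_mask(m))  # 27
#' @export
dilate_mask <- function(mask, se = box_se(1L)) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, is.logical(mask))
  box_sweep(mask, se_radius(se), "dilate")
}

#' Erode a binary mask by a box structuring element
#'
#' Keeps the voxels whose full (2r+1)^3 neighborhood lies inside the mask.
#' Outside-volume voxels count as background, so voxels within `radius` of
#' the volume border erode away. The output is always contained in the input;
#' structures thinner than 2r+1 voxels vanish.
#'
#' @inheritParams dilate_mask
#' @return 3D logical array of the same shape.
#' @export
erode_mask <- function(mask, se = box_se(1L)) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, is.logical(mask))
  box_sweep(mask, se_radius(se), "erode")
}

# Half-neighborhood offsets (each unordered voxel pair visited once) for the
# three standard 3D adjacencies.
half_offsets <- function(connectivity) {
  grid <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  grid <- grid[!(grid$dz == 0 & grid$dy == 0 & grid$dx == 0), ]
  manh <- abs(grid$dz) + abs(grid$dy) + abs(grid$dx)
  keep <- switch(as.character(connectivity),
                 "6" = manh == 1, "18" = manh <= 2, "26" = rep(TRUE, nrow(grid)),
                 stop("connectivity must be 6, 18 or 26", call. = FALSE))
  grid <- grid[keep, ]
  # keep one representative of each {+o, -o} pair
  first <- grid$dz > 0 | (grid$dz == 0 & grid$dy > 0) |
    (grid$dz == 0 & grid$dy == 0 & grid$dx > 0)
  as.matrix(grid[first, c("dz", "dy", "dx")])
}

#' Label connected components of a binary mask
#'
#' Components are maximal sets of foreground voxels mutually reachable under
#' the chosen voxel adjacency (6 = faces, 18 = faces+edges, 26 = full box).
#'
#' @param mask 3D logical array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return Integer array of the same shape: 0 on background, components
#'   numbered 1..N in first-voxel scan order. The component count is
#'   `max(result)`.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, is.logical(mask))
  offs <- half_offsets(connectivity)
  d <- dim(mask)
  fg <- which(mask)
  out <- array(0L, d)
  if (length(fg) == 0L) return(out)
  rank <- integer(prod(d)); rank[fg] <- seq_along(fg)
  edges <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    shifted <- shift_axis(shift_axis(shift_axis(mask, 1L, o[1], FALSE),
                                     2L, o[2], FALSE), 3L, o[3], FALSE)
    both <- which(mask & shifted)
    if (length(both) == 0L) next
    # voxel at linear index `both` pairs with its neighbor at -offset
    stride <- c(1L, d[1], d[1] * d[2])
    nb <- both - as.integer(o[1] * stride[1] + o[2] * stride[2] + o[3] * stride[3])
    edges[[i]] <- cbind(rank[both], rank[nb])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # renumber components by first foreground voxel in linear scan order
  first <- match(unique(memb), memb)
  renum <- integer(max(memb)); renum[memb[sort(first)]] <- seq_along(first)
  out[fg] <- renum[memb]
  out
}

#' Count connected components of a binary mask
#'
#' @inheritParams label_components
#' @return Integer >= 0 (0 for an empty mask).
#' @examples
#' m <- array(FALSE, c(3, 3, 3)); m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE
#' count_components(m, 26)  # 1 (diagonal touch)
#' count_components(m, 6)   # 2
#' @export
count_components <- function(mask, connectivity = 26L) {
  max(label_components(mask, connectivity))
}
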