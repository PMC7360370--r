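# Low-level voxel-grid utilities shared by the imaging stages.
#
# Arrays are indexed [z, row, col], 1-based; terminal and nuclei components
# use 26-connectivity in 3D (8-connectivity in 2D), and all dilations use the
# 1-voxel 26-neighbourhood ball, one step at a time.

# out[z,y,x] = arr[z+dz, y+dy, x+dx], `fill` outside bounds
shift_array <- function(arr, dz, dy, dx, fill = 0) {
  d <- dim(arr)
  out <- array(fill, dim = d)
  src_z <- seq_len(d[1]) + dz
  src_y <- seq_len(d[2]) + dy
  src_x <- seq_len(d[3]) + dx
  kz <- src_z >= 1 & src_z <= d[1]
  ky <- src_y >= 1 & src_y <= d[2]
  kx <- src_x >= 1 & src_x <= d[3]
  if (!any(kz) || !any(ky) || !any(kx)) {
    return(out)
  }
  out[which(kz), which(ky), which(kx)] <-
    arr[src_z[kz], src_y[ky], src_x[kx], drop = FALSE]
  out
}

neighbourhood_offsets <- function(ndim = 3, forward_only = FALSE) {
  if (ndim == 3) {
    g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  } else {
    g <- expand.grid(dz = 0L, dy = -1:1, dx = -1:1)
  }
  g <- g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), , drop = FALSE]
  if (forward_only) {
    # keep one of each (o, -o) pair
    key <- g$dz * 9 + g$dy * 3 + g$dx
    g <- g[key > 0, , drop = FALSE]
  }
  as.matrix(g)
}

#' Label connected components of a binary voxel grid
#'
#' 26-connectivity in 3D (8-connectivity when the input is a matrix).
#' Labels are dense from 1 and assigned in scan order (column-major order of
#' the first voxel of each component), so labeling is deterministic.
#'
#' @param mask Logical 3D array (or matrix, treated as a single plane).
#' @return Integer array of the same shape; 0 is background.
#' @export
label_components <- function(mask) {
  was_matrix <- is.matrix(mask)
  if (was_matrix) mask <- array(mask, dim = c(1, dim(mask)))
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  mask <- mask != 0
  d <- dim(mask)
  lab <- array(0L, dim = d)
  fg <- which(mask)
  if (length(fg) == 0) {
    return(if (was_matrix) lab[1, , ] else lab)
  }
  pos <- integer(prod(d))
  pos[fg] <- seq_along(fg)
  co <- arrayInd(fg, d)
  offs <- neighbourhood_offsets(3, forward_only = TRUE)
  from <- integer(0)
  to <- integer(0)
  for (i in seq_len(nrow(offs))) {
    nz <- co[, 1] + offs[i, 1]
    ny <- co[, 2] + offs[i, 2]
    nx <- co[, 3] + offs[i, 3]
    ok <- nz >= 1 & nz <= d[1] & ny >= 1 & ny <= d[2] & nx >= 1 & nx <= d[3]
    if (!any(ok)) next
    nb <- pos[nz[ok] + (ny[ok] - 1L) * d[1] + (nx[ok] - 1L) * d[1] * d[2]]
    hit <- nb != 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, nb[hit])
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(from) > 0) {
    g <- igraph::add_edges(g, rbind(from, to))
  }
  memb <- igraph::components(g)$membership
  # relabel so that components are numbered by first appearance in scan order
  first_seen <- !duplicated(memb)
  relab <- integer(max(memb))
  relab[memb[first_seen]] <- seq_len(sum(first_seen))
  lab[fg] <- relab[memb]
  if (was_matrix) lab[1, , ] else lab
}

#' Dilate a binary grid by the 1-voxel 26-neighbourhood ball
#'
#' @param mask Logical 3D array.
#' @param steps Number of single-voxel dilation steps.
#' @return Logical array of the same shape.
#' @export
dilate_ball <- function(mask, steps = 1L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3, steps >= 0)
  mask <- mask != 0
  offs <- neighbourhood_offsets(3)
  for (s in seq_len(steps)) {
    out <- mask
    for (i in seq_len(nrow(offs))) {
      out <- out | shift_array(mask, offs[i, 1], offs[i, 2], offs[i, 3], fill = FALSE)
    }
    mask <- out
  }
  mask
}

erode_ball <- function(mask, steps = 1L) {
  !dilate_ball(!(mask != 0), steps)
}

#' Morphological closing with a 1-voxel ball
#'
#' @param mask Logical 3D array.
#' @return Logical array.
#' @export
close_ball <- function(mask) {
  erode_ball(dilate_ball(mask, 1L), 1L)
}

# fill holes (background regions not connected to the border) per z-plane
fill_holes <- function(mask) {
  was_matrix <- is.matrix(mask)
  if (was_matrix) mask <- array(mask, dim = c(1, dim(mask)))
  mask <- mask != 0
  d <- dim(mask)
  for (zi in seq_len(d[1])) {
    bg <- !mask[zi, , ]
    lab <- label_components(bg)
    border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    border_labels <- setdiff(border_labels, 0L)
    hole <- bg & !(lab %in% border_labels)
    mask[zi, , ] <- mask[zi, , ] | hole
  }
  if (was_matrix) mask[1, , ] else mask
}

# strict-threshold local maxima (>= all 26 neighbours, > threshold);
# plateaus are collapsed to their first voxel in scan order.
local_maxima <- function(arr, threshold) {
  stopifnot(is.array(arr), length(dim(arr)) == 3)
  ok <- arr > threshold
  offs <- neighbourhood_offsets(3)
  for (i in seq_len(nrow(offs))) {
    if (!any(ok)) break
    ok <- ok & (arr >= shift_array(arr, offs[i, 1], offs[i, 2], offs[i, 3], fill = -Inf))
  }
  idx <- which(ok)
  if (length(idx) <= 1) {
    return(idx)
  }
  # collapse plateau clusters of equal value
  lab <- label_components(ok)
  keep <- !duplicated(lab[idx])
  idx[keep]
}

# linear index -> (z, y, x) tibble
index_to_coords <- function(idx, d) {
  co <- arrayInd(idx, d)
  tibble::tibble(z = co[, 1], y = co[, 2], x = co[, 3])
}

coords_to_index <- function(z, y, x, d) {
  z + (y - 1L) * d[1] + (x - 1L) * d[1] * d[2]
}
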