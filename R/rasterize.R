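#' Rasterize planar contour polygons to a binary mask
#'
#' Structure sets from treatment planning systems store contours as closed
#' planar polygons, one or more per axial slice, in world millimeters. A
#' voxel is set iff its center lies inside a polygon of its slice by the
#' even-odd rule; multiple polygons on one slice are XOR-combined, so holes
#' (e.g. an annulus given as outer plus inner ring) are supported. Voxel
#' centers exactly on a polygon edge follow a half-open convention (inside
#' on the minimum-coordinate edge, outside on the maximum), which makes the
#' rasterization deterministic and tiling-consistent.
#'
#' @param polygons list of contours; each contour is a list with `vertices`
#'   (n x 2 matrix of x, y world mm; the closing edge back to the first
#'   vertex is implicit) and `z` (slice position, world mm).
#' @param frame a `volume_grid` defining the target grid frame.
#' @return binary `volume_grid` on `frame`'s grid.
#' @export
rasterize_contours <- function(polygons, frame) {
  d <- dim(frame$values)
  zs <- axis_coords(frame, 3)
  dz <- frame$spacing[3]
  xs <- axis_coords(frame, 1)
  ys <- axis_coords(frame, 2)
  px <- rep(xs, times = d[2])
  py <- rep(ys, each = d[1])
  m <- array(FALSE, d)
  for (poly in polygons) {
    v <- poly$vertices
    if (is.null(v) || nrow(v) < 3L)
      stop("each contour needs at least 3 vertices", call. = FALSE)
    k <- which(abs(zs - poly$z) <= dz / 2 + 1e-9)
    if (!length(k))
      stop(sprintf("contour at z = %g mm matches no grid slice", poly$z),
           call. = FALSE)
    k <- k[which.min(abs(zs[k] - poly$z))]
    inside <- point_in_polygon(px, py, v)
    m[, , k] <- xor(m[, , k], array(inside, d[1:2]))
  }
  with_values(frame, m)
}

# Even-odd point-in-polygon by ray crossing, vectorized over points.
# Strict comparisons give the half-open edge convention (minimum-coordinate
# edges inside, maximum-coordinate edges outside).
point_in_polygon <- function(px, py, vertices) {
  n <- nrow(vertices)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vertices[j, 1]; y1 <- vertices[j, 2]
    x2 <- vertices[i, 1]; y2 <- vertices[i, 2]
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & px < xint)
    }
    j <- i
  }
  inside
}
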