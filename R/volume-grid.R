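#' Regular axis-aligned 3D volume grid
#'
#' The basic spatial container of the package: a regular, axis-aligned 3D
#' voxel grid with anisotropic spacing, carrying either a binary occupancy
#' mask (a structure) or a scalar dose in Gy. Voxel centers follow the
#' medical-imaging voxel-center convention: the world position (mm) of voxel
#' `(i, j, k)` (1-based array index) is `origin + (index - 1) * spacing`.
#'
#' @param values 3D numeric or logical array. Masks may be logical or 0/1
#'   numeric; dose arrays must be non-negative and finite.
#' @param spacing numeric length-3, voxel edge lengths in mm (strictly
#'   positive, possibly anisotropic).
#' @param origin numeric length-3, world coordinates (mm) of the center of
#'   the first voxel.
#' @param kind `"mask"` or `"dose"`; controls value validation.
#' @return An object of class `volume_grid`.
#' @examples
#' g <- volume_grid(array(0, c(4, 4, 4)), spacing = c(2, 2, 2.5))
#' voxel_volume_cm3(g)
#' @export
volume_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        kind = c("mask", "dose")) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || anyNA(origin))
    stop("'origin' must be 3 finite numbers (mm)", call. = FALSE)
  if (any(dim(values) < 1L))
    stop("grid shape must be strictly positive on all axes", call. = FALSE)
  if (kind == "mask") {
    if (is.logical(values)) {
      if (anyNA(values)) stop("mask contains NA", call. = FALSE)
      storage.mode(values) <- "logical"
    } else {
      if (anyNA(values) || !all(values %in% c(0, 1)))
        stop("binary mask may contain only values {0, 1}", call. = FALSE)
      values <- array(values != 0, dim = dim(values))
    }
  } else {
    if (!is.numeric(values) || anyNA(values) || any(!is.finite(values)) ||
        any(values < 0))
      stop("dose values must be non-negative and finite (Gy)", call. = FALSE)
  }
  structure(list(values = values, spacing = spacing, origin = origin,
                 kind = kind),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %s> dim %s, spacing %s mm, origin %s mm\n",
              x$kind, paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  if (x$kind == "mask") {
    cat(sprintf("  %d voxels set (%.2f cm^3)\n", sum(x$values),
                mask_volume_cm3(x)))
  } else {
    cat(sprintf("  dose range %.3f - %.3f Gy\n", min(x$values), max(x$values)))
  }
  invisible(x)
}

is_volume_grid <- function(x) inherits(x, "volume_grid")

stopifnot_mask <- function(x, what = "mask") {
  if (!is_volume_grid(x)) stop(what, " must be a volume_grid", call. = FALSE)
  if (x$kind != "mask" || !is.logical(x$values))
    stop(what, " must be a binary mask volume_grid", call. = FALSE)
  invisible(x)
}

#' Grid frame accessors and comparison
#'
#' Two grids share a frame when origin, spacing and shape all agree (within
#' 1e-6 mm for the continuous fields).
#'
#' @param a,b `volume_grid` objects.
#' @return `same_frame()` returns a logical scalar.
#' @export
same_frame <- function(a, b) {
  isTRUE(all(dim(a$values) == dim(b$values))) &&
    max(abs(a$spacing - b$spacing)) < 1e-6 &&
    max(abs(a$origin - b$origin)) < 1e-6
}

#' World coordinates of voxel centers along one axis
#' @param grid a `volume_grid`.
#' @param axis 1, 2 or 3.
#' @return numeric vector of world coordinates (mm).
#' @export
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(dim(grid$values)[axis]) - 1) * grid$spacing[axis]
}

#' Volume of one voxel in cubic centimeters
#'
#' @param grid a `volume_grid`.
#' @return Product of the three spacings, converted from mm^3 to cm^3.
#' @examples
#' voxel_volume_cm3(volume_grid(array(0, c(2, 2, 2)), spacing = c(2, 2, 2.5)))
#' @export
voxel_volume_cm3 <- function(grid) {
  if (!is_volume_grid(grid)) stop("'grid' must be a volume_grid", call. = FALSE)
  prod(grid$spacing) / 1000
}

#' Volume of a binary mask in cubic centimeters
#'
#' Count of set voxels times the voxel volume. Additive over disjoint masks
#' and invariant under grid translation.
#'
#' @param mask a binary `volume_grid`.
#' @return volume in cm^3.
#' @export
mask_volume_cm3 <- function(mask) {
  stopifnot_mask(mask)
  sum(mask$values) * voxel_volume_cm3(mask)
}

# Replace the value array, keeping the frame.
with_values <- function(grid, values, kind = grid$kind) {
  volume_grid(values, spacing = grid$spacing, origin = grid$origin,
              kind = kind)
}

# Bounding box (index ranges) of set voxels; NULL for an empty mask.
mask_bbox <- function(mask) {
  idx <- which(mask$values, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  rbind(lo = apply(idx, 2, min), hi = apply(idx, 2, max))
}

# Crop a mask to its bounding box padded by `pad_vox` voxels (clamped to
# the grid); returns the subgrid plus the index window, or NULL if empty.
# Local distance computations on the subgrid are exact as long as the
# relevant range is below the padding.
crop_to_bbox <- function(mask, pad_vox) {
  bb <- mask_bbox(mask)
  if (is.null(bb)) return(NULL)
  d <- dim(mask$values)
  lo <- pmax(bb["lo", ] - pad_vox, 1L)
  hi <- pmin(bb["hi", ] + pad_vox, d)
  sub <- mask$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  list(grid = volume_grid(sub, spacing = mask$spacing,
                          origin = mask$origin + (lo - 1) * mask$spacing),
       lo = lo, hi = hi)
}

# Write subgrid values back into a full-size array of `fill`.
embed_values <- function(full_dim, window, sub_values, fill = FALSE) {
  out <- array(fill, full_dim)
  out[window$lo[1]:window$hi[1], window$lo[2]:window$hi[2],
      window$lo[3]:window$hi[3]] <- sub_values
  out
}

#' Exact Euclidean distance map to a voxel set
#'
#' Distance (mm) from every voxel center to the nearest set-voxel center,
#' respecting anisotropic spacing. Exact (not chamfer) via the separable
#' lower-envelope squared-distance transform.
#'
#' @param mask a binary `volume_grid` with at least one set voxel.
#' @return numeric 3D array of distances in mm (0 on set voxels).
#' @export
distance_map_mm <- function(mask) {
  stopifnot_mask(mask)
  if (!any(mask$values)) stop("distance map of an empty mask", call. = FALSE)
  d <- edt3d_mm(as.vector(mask$values), dim(mask$values), mask$spacing)
  array(d, dim = dim(mask$values))
}

#' Signed distance to a mask boundary
#'
#' Negative inside the mask (distance to the nearest outside-voxel center),
#' positive outside (distance to the nearest inside-voxel center). Used by
#' the level-set contour perturbation and the synthetic dose model.
#'
#' @param mask a binary, non-empty, non-full `volume_grid`.
#' @return numeric 3D array (mm), strictly negative inside, positive outside.
#' @export
signed_distance_mm <- function(mask) {
  stopifnot_mask(mask)
  m <- mask$values
  if (!any(m)) stop("signed distance of an empty mask", call. = FALSE)
  dim3 <- dim(m)
  dout <- array(edt3d_mm(as.vector(m), dim3, mask$spacing), dim = dim3)
  if (all(m)) return(-dout - prod(mask$spacing)) # degenerate: everything inside
  din <- array(edt3d_mm(as.vector(!m), dim3, mask$spacing), dim = dim3)
  sd <- dout
  sd[m] <- -din[m]
  sd
}
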