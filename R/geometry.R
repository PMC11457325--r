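#' Dice similarity coefficient
#'
#' `2 |A n B| / (|A| + |B|)` on voxel counts. Symmetric; 1 for identical
#' masks, 0 for disjoint ones.
#'
#' @param a,b binary `volume_grid`s on the same frame, not both empty.
#' @return ratio in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot_mask(a, "a"); stopifnot_mask(b, "b")
  if (!same_frame(a, b)) stop("masks are on different grid frames",
                              call. = FALSE)
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0L) stop("Dice undefined: both masks empty", call. = FALSE)
  2 * sum(a$values & b$values) / (na + nb)
}

#' Relative volume of the automatic contour
#'
#' `100 * V_auto / V_clin` in percent, where the denominator is the
#' clinically corrected contour.
#'
#' @param auto,clin binary `volume_grid`s; `clin` must be non-empty.
#' @return percent.
#' @export
relative_volume_pct <- function(auto, clin) {
  stopifnot_mask(auto, "auto"); stopifnot_mask(clin, "clin")
  vc <- mask_volume_cm3(clin)
  if (vc == 0) stop("relative volume undefined: clinical mask empty",
                    call. = FALSE)
  100 * mask_volume_cm3(auto) / vc
}

# Logical array of boundary voxels: set voxels with at least one
# face-adjacent neighbor unset or outside the grid.
boundary_array <- function(m) {
  d <- dim(m)
  interior <- array(TRUE, d)
  shift_ok <- function(ax, by) {
    # out[p] = m[p - by] along axis ax, FALSE where p - by falls off the grid
    out <- array(FALSE, d)
    n <- d[ax]
    if (n <= abs(by)) return(out)
    src <- idx_full <- lapply(d, seq_len)
    dst <- idx_full
    src[[ax]] <- if (by > 0) 1:(n - by) else (1 - by):n
    dst[[ax]] <- if (by > 0) (1 + by):n else 1:(n + by)
    vals <- do.call(`[`, c(list(m), src, list(drop = FALSE)))
    do.call(`[<-`, c(list(out), dst, list(vals)))
  }
  for (ax in 1:3) for (by in c(-1L, 1L))
    interior <- interior & shift_ok(ax, by)
  m & !interior
}

#' Boundary points of a mask
#'
#' World-coordinate centers (mm) of the set voxels that have at least one
#' face-adjacent neighbor unset or outside the grid. This voxel-center
#' surface definition underlies the 95% Hausdorff distance and the mean
#' distance to agreement.
#'
#' @param mask a non-empty binary `volume_grid`.
#' @return numeric matrix `n x 3` of world points; the logical boundary
#'   array is attached as attribute `"array"`.
#' @export
boundary_points <- function(mask) {
  stopifnot_mask(mask)
  if (!any(mask$values)) stop("boundary of an empty mask", call. = FALSE)
  b <- boundary_array(mask$values)
  idx <- which(b, arr.ind = TRUE)
  pts <- sweep(sweep(idx - 1, 2, mask$spacing, `*`), 2, mask$origin, `+`)
  dimnames(pts) <- NULL
  structure(pts, array = b)
}

#' Pooled symmetric surface distances
#'
#' For every boundary point of A, the Euclidean distance (mm, anisotropic
#' spacing respected) to the nearest boundary point of B, and vice versa;
#' both directed sets are pooled into one multiset, which serves both the
#' 95% Hausdorff distance and the mean distance to agreement.
#'
#' Implemented with an exact Euclidean distance transform of each boundary
#' sampled at the other boundary's voxels, which equals the all-pairs
#' nearest-neighbour search because all points are voxel centers of one
#' common lattice.
#'
#' @param a,b non-empty binary `volume_grid`s on the same frame.
#' @return numeric vector of distances (mm), length `nA + nB`.
#' @export
pooled_surface_distances <- function(a, b) {
  stopifnot_mask(a, "a"); stopifnot_mask(b, "b")
  if (!same_frame(a, b)) stop("masks are on different grid frames",
                              call. = FALSE)
  if (!any(a$values) || !any(b$values))
    stop("surface distances of an empty mask", call. = FALSE)
  # restrict to the padded union bounding box; boundaries and nearest
  # boundary-to-boundary distances are unchanged by the crop
  un <- with_values(a, a$values | b$values)
  cr <- crop_to_bbox(un, 1L)
  w <- cr
  sub <- function(m) m[w$lo[1]:w$hi[1], w$lo[2]:w$hi[2], w$lo[3]:w$hi[3],
                       drop = FALSE]
  ba <- boundary_array(sub(a$values))
  bb <- boundary_array(sub(b$values))
  dim3 <- dim(ba)
  dmap_b <- edt3d_mm(as.vector(bb), dim3, a$spacing)
  dmap_a <- edt3d_mm(as.vector(ba), dim3, a$spacing)
  c(dmap_b[as.vector(ba)], dmap_a[as.vector(bb)])
}

#' 95th-percentile Hausdorff distance
#'
#' 95th percentile of the pooled surface distances, with linear
#' interpolation between order statistics (rank `1 + (n - 1) * 0.95`).
#'
#' @param distances non-empty numeric vector of distances (mm).
#' @param prob percentile (default 0.95).
#' @return mm.
#' @export
hd95 <- function(distances, prob = 0.95) {
  if (!length(distances)) stop("hd95 of an empty distance set", call. = FALSE)
  unname(stats::quantile(distances, prob, type = 7))
}

#' Mean distance to agreement
#'
#' Arithmetic mean of the pooled surface distances.
#'
#' @param distances non-empty numeric vector of distances (mm).
#' @return mm.
#' @export
mda <- function(distances) {
  if (!length(distances)) stop("mda of an empty distance set", call. = FALSE)
  mean(distances)
}

#' Geometric contour comparison for one structure of one session
#'
#' Compares the automatically proposed against the clinically corrected
#' contour of `role`: Dice similarity coefficient, relative volume
#' (V_auto / V_clin, percent), 95th-percentile Hausdorff distance and mean
#' distance to agreement, plus both absolute volumes.
#'
#' @param session an `rt_session`.
#' @param role structure role present in both arms.
#' @return one-row `data.frame` with columns `patient_id`, `fraction`,
#'   `structure`, `dsc`, `relative_volume`, `hd95`, `mda`, `v_auto`,
#'   `v_clin`.
#' @export
geometric_record <- function(session, role) {
  a <- session$contours_auto$masks[[role]]
  b <- session$contours_clin$masks[[role]]
  if (is.null(a) || is.null(b))
    stop("role ", role, " missing from one arm", call. = FALSE)
  d <- pooled_surface_distances(a, b)
  data.frame(patient_id = session$patient_id, fraction = session$fraction,
             structure = role,
             dsc = dice(a, b),
             relative_volume = relative_volume_pct(a, b),
             hd95 = hd95(d), mda = mda(d),
             v_auto = mask_volume_cm3(a), v_clin = mask_volume_cm3(b),
             stringsAsFactors = FALSE)
}
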