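#' Resample a dose grid onto a structure grid frame
#'
#' Trilinear interpolation of the dose at the voxel centers of the structure
#' frame. Query points outside the dose grid receive 0 Gy; their count is
#' returned so callers can surface a warning (silent extrapolation would
#' corrupt coverage metrics).
#'
#' @param dose a dose `volume_grid`.
#' @param frame a `volume_grid` defining the target frame (values ignored).
#' @return list with `values` (3D array of Gy on the structure frame) and
#'   `n_outside` (number of query points outside the dose grid).
#' @export
resample_dose <- function(dose, frame) {
  if (!is_volume_grid(dose) || dose$kind != "dose")
    stop("'dose' must be a dose volume_grid", call. = FALSE)
  if (same_frame(dose, frame))
    return(list(values = dose$values, n_outside = 0L))
  trilinear_resample(dose$values, dose$spacing, dose$origin, frame)
}

# Trilinear interpolation of a 3D array at the voxel centers of `frame`;
# out-of-grid queries yield `fill` and are counted. Internal workhorse
# shared by dose resampling, mask rescaling and noise-field upsampling.
trilinear_resample <- function(values, spacing, origin, frame, fill = 0) {
  dd <- dim(frame$values)
  # fractional voxel coordinates of the query points in the source grid
  fx <- (axis_coords(frame, 1) - origin[1]) / spacing[1]
  fy <- (axis_coords(frame, 2) - origin[2]) / spacing[2]
  fz <- (axis_coords(frame, 3) - origin[3]) / spacing[3]
  gx <- rep(fx, times = dd[2] * dd[3])
  gy <- rep(rep(fy, each = dd[1]), times = dd[3])
  gz <- rep(fz, each = dd[1] * dd[2])
  nd <- dim(values)
  eps <- 1e-9
  inside <- gx >= -eps & gx <= nd[1] - 1 + eps &
            gy >= -eps & gy <= nd[2] - 1 + eps &
            gz >= -eps & gz <= nd[3] - 1 + eps
  out <- rep(fill, length(gx))
  if (any(inside)) {
    x <- pmin(pmax(gx[inside], 0), nd[1] - 1)
    y <- pmin(pmax(gy[inside], 0), nd[2] - 1)
    z <- pmin(pmax(gz[inside], 0), nd[3] - 1)
    i0 <- pmin(floor(x), nd[1] - 2); i0 <- pmax(i0, 0)
    j0 <- pmin(floor(y), nd[2] - 2); j0 <- pmax(j0, 0)
    k0 <- pmin(floor(z), nd[3] - 2); k0 <- pmax(k0, 0)
    if (nd[1] == 1) i0 <- rep(0, length(x))
    if (nd[2] == 1) j0 <- rep(0, length(y))
    if (nd[3] == 1) k0 <- rep(0, length(z))
    tx <- x - i0; ty <- y - j0; tz <- z - k0
    V <- values
    i1 <- pmin(i0 + 1, nd[1] - 1); j1 <- pmin(j0 + 1, nd[2] - 1)
    k1 <- pmin(k0 + 1, nd[3] - 1)
    at <- function(di, dj, dk) {
      ii <- if (di == 0) i0 else i1
      jj <- if (dj == 0) j0 else j1
      kk <- if (dk == 0) k0 else k1
      V[1 + ii + nd[1] * (jj + nd[2] * kk)]
    }
    out[inside] <-
      at(0, 0, 0) * (1 - tx) * (1 - ty) * (1 - tz) +
      at(1, 0, 0) * tx       * (1 - ty) * (1 - tz) +
      at(0, 1, 0) * (1 - tx) * ty       * (1 - tz) +
      at(1, 1, 0) * tx       * ty       * (1 - tz) +
      at(0, 0, 1) * (1 - tx) * (1 - ty) * tz +
      at(1, 0, 1) * tx       * (1 - ty) * tz +
      at(0, 1, 1) * (1 - tx) * ty       * tz +
      at(1, 1, 1) * tx       * ty       * tz
  }
  list(values = array(out, dd), n_outside = sum(!inside))
}

#' Coverage dose threshold for a target role
#'
#' The coverage threshold is `coverage_fraction` (default 95%) of the
#' prescription at the role's dose level: boost roles (GTV, CTV_boost,
#' PTV_boost) use the boost prescription (elective + SIB), elective roles
#' (CTV_elective, PTV_elective) the elective prescription. On the
#' per-fraction scale the prescriptions are divided by the fraction count.
#'
#' @param role a target role.
#' @param config a [prescription_config()].
#' @return threshold in Gy on the configured evaluation scale.
#' @export
coverage_threshold <- function(role, config) {
  if (role %in% boost_roles()) {
    rx <- config$boost_total
  } else if (role %in% elective_roles()) {
    rx <- config$elective_total
  } else {
    stop(role, " is not a target role", call. = FALSE)
  }
  if (config$evaluation_scale == "per_fraction") rx <- rx / config$fractions
  config$coverage_fraction * rx
}

#' Structure volume at or above a dose threshold
#'
#' Fraction and absolute volume of structure voxels whose dose is at least
#' the threshold (inclusive, matching the "minimum of 95% of the prescribed
#' dose" definition).
#'
#' @param mask non-empty binary `volume_grid`.
#' @param dose_values 3D array of Gy on the mask frame.
#' @param threshold Gy.
#' @return list with `percent` (of structure volume) and `cm3`.
#' @export
v_at_threshold <- function(mask, dose_values, threshold) {
  stopifnot_mask(mask)
  n <- sum(mask$values)
  if (n == 0L) stop("coverage of an empty mask", call. = FALSE)
  hit <- sum(dose_values[mask$values] >= threshold)
  list(percent = 100 * hit / n, cm3 = hit * voxel_volume_cm3(mask))
}

#' Dose spill outside a target
#'
#' Absolute volume of the body at or above the threshold minus the absolute
#' volume of the target at or above the threshold (the `V95,out` equation).
#'
#' @param body,target binary `volume_grid`s with `target` contained in
#'   `body`.
#' @param dose_values 3D array of Gy on the common frame.
#' @param threshold Gy.
#' @return cm^3.
#' @export
v95_out <- function(body, target, dose_values, threshold) {
  stopifnot_mask(body, "body"); stopifnot_mask(target, "target")
  if (any(target$values & !body$values))
    stop("target is not contained in body", call. = FALSE)
  v_at_threshold(body, dose_values, threshold)$cm3 -
    v_at_threshold(target, dose_values, threshold)$cm3
}

#' Dosimetric record for one target, one dose arm
#'
#' Evaluates the clinically corrected contour of `role` (the ground truth
#' for both arms) in the selected dose distribution: relative and absolute
#' V95, body V95, spill outside the target, and the clinical requirement
#' flag (coverage at least `coverage_requirement` percent, inclusive).
#'
#' The spill's body threshold defaults to the elective prescription level
#' (`body_threshold = "elective"`); `"target"` uses each target's own level
#' instead.
#'
#' @param session an `rt_session`.
#' @param role a target role.
#' @param arm `"D_clin"` or `"D_auto"`.
#' @param config a [prescription_config()].
#' @param body_threshold `"elective"` or `"target"`.
#' @param contours evaluate `"clin"` (ground truth, default) or `"auto"`
#'   contours (diagnostics only).
#' @return one-row `data.frame`.
#' @export
dosimetric_record <- function(session, role, arm = c("D_clin", "D_auto"),
                              config = prescription_config(),
                              body_threshold = c("elective", "target"),
                              contours = c("clin", "auto")) {
  arm <- match.arg(arm)
  body_threshold <- match.arg(body_threshold)
  contours <- match.arg(contours)
  ss <- if (contours == "clin") session$contours_clin else
    session$contours_auto
  mask <- ss$masks[[role]]
  body <- ss$masks[["body"]]
  if (is.null(mask)) stop("role ", role, " missing", call. = FALSE)
  if (is.null(body)) stop("body mask missing", call. = FALSE)
  dose <- if (arm == "D_clin") session$dose_clin else session$dose_auto
  rs <- resample_dose(dose, mask)
  thr <- coverage_threshold(role, config)
  thr_body <- if (body_threshold == "elective")
    coverage_threshold("CTV_elective", config) else thr
  v <- v_at_threshold(mask, rs$values, thr)
  vb <- v_at_threshold(body, rs$values, thr_body)
  data.frame(patient_id = session$patient_id, fraction = session$fraction,
             structure = role, arm = arm,
             v95_percent = v$percent, v95_abs = v$cm3,
             v95_body_abs = vb$cm3, v95_out_abs = vb$cm3 - v$cm3,
             meets_requirement = v$percent >= config$coverage_requirement,
             n_outside_dose_grid = rs$n_outside,
             stringsAsFactors = FALSE)
}

#' Cumulative dose-volume histogram
#'
#' Percent of the structure volume receiving at least each dose level, on a
#' regular dose axis from 0 to just above the maximum structure dose. The
#' curve starts at 100% at 0 Gy and is non-increasing; at any grid dose `t`
#' it equals `v_at_threshold(mask, dose, t)$percent`.
#'
#' @param mask non-empty binary `volume_grid`.
#' @param dose_values 3D array of Gy on the mask frame.
#' @param bin_width dose axis step, Gy (> 0).
#' @return `data.frame` with columns `dose_gy`, `volume_pct`.
#' @export
cumulative_dvh <- function(mask, dose_values, bin_width = 0.05) {
  stopifnot_mask(mask)
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  dv <- dose_values[mask$values]
  if (!length(dv)) stop("DVH of an empty mask", call. = FALSE)
  edges <- seq(0, max(dv) + bin_width, by = bin_width)
  pct <- vapply(edges, function(t) 100 * mean(dv >= t), numeric(1))
  data.frame(dose_gy = edges, volume_pct = pct)
}
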