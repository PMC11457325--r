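#' Synthetic pelvic phantom configuration
#'
#' Parameters of the synthetic paired-session cohort that emulates the
#' study conditions of a 17-patient, 20-fraction bladder oART course: a
#' parametric pelvic anatomy (ellipsoidal bladder, curved rectal tube,
#' spherical tumor-bed GTV on the bladder wall), reference-to-online
#' bladder filling at 1-4 ml/min, controllable automatic-vs-clinical
#' contour discrepancies, and a two-level SIB dose model.
#'
#' @param spacing_mm isotropic grid spacing, mm (default 2).
#' @param dim grid shape, voxels (default `c(68, 68, 60)`; the grid is
#'   centered on the world origin).
#' @param body_semiaxes_mm semiaxes of the body ellipsoid.
#' @param bladder_center_mm bladder center, mm.
#' @param bladder_axis_ratio bladder ellipsoid axis ratios (x, y, z).
#' @param bladder_ref_volume_cm3 per-patient reference bladder volume range
#'   sampled uniformly, cm^3.
#' @param prefill_factor per-session range of the online pre-treatment
#'   bladder volume as a multiple of the reference volume.
#' @param filling_rate_ml_min bladder filling rate range, ml/min
#'   (reported clinical range 1-4).
#' @param couch_time_min on-couch time range, minutes.
#' @param rectum_y_mm,rectum_length_mm,rectum_sway_mm rectal tube posterior
#'   offset, cranio-caudal length and lateral centerline amplitude, mm.
#' @param rectum_ref_volume_cm3 per-patient reference rectum volume range.
#' @param rectum_online_scale per-session online/reference rectum volume
#'   factor range.
#' @param gtv_radius_mm tumor-bed radius, mm.
#' @param gtv_direction unit-direction (normalised internally) from the
#'   bladder center to the GTV seat on the bladder wall.
#' @param ctv_boost_margin_mm,ptv_boost_margin_mm isotropic GTV->CTV_boost
#'   and CTV_boost->PTV_boost margins, mm (default 5).
#' @param bladder_ptv_margin_mm bladder PTV margin, mm (default 7).
#' @param perturb_amplitude_mm range of the per-session base contour
#'   perturbation amplitude, mm.
#' @param influencer_coupling growth of the perturbation amplitude with the
#'   bladder volume change: the session amplitude is multiplied by
#'   `1 + influencer_coupling * dV / 100` (dV in cm^3). Emulates the
#'   degradation of influencer-guided target propagation under large
#'   anatomical change.
#' @param boost_amp_factor multiplier of the influencer amplitude for the
#'   GTV/boost chain (target propagation is less accurate than direct organ
#'   segmentation).
#' @param boost_shrink_mm systematic inward bias of the automatic boost
#'   contour, mm (the automatic delineation volume is typically too small);
#'   applied only when the session amplitude is non-zero.
#' @param max_amplitude_mm cap on the effective perturbation amplitude.
#' @param noise_coarse_mm correlation length of the perturbation noise
#'   field, mm.
#' @param dose_halfdist_mm distance outside a PTV at which the synthetic
#'   dose falls to half its prescription, mm.
#' @param correction_probs per-role probability that the session carries a
#'   manual-correction flag (clinically observed frequencies).
#' @param patients,fractions cohort shape (defaults 17 and 20).
#' @param seed master seed; every per-patient and per-session draw derives
#'   from it, so any single session is reproducible in isolation.
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(spacing_mm = 2,
                           dim = c(68, 68, 60),
                           body_semiaxes_mm = c(66, 66, 58),
                           bladder_center_mm = c(0, 15, 0),
                           bladder_axis_ratio = c(1, 0.9, 1.1),
                           bladder_ref_volume_cm3 = c(100, 180),
                           prefill_factor = c(0.7, 1.5),
                           filling_rate_ml_min = c(1, 4),
                           couch_time_min = c(15, 25),
                           rectum_y_mm = -32,
                           rectum_length_mm = 100,
                           rectum_sway_mm = 8,
                           rectum_ref_volume_cm3 = c(30, 60),
                           rectum_online_scale = c(0.5, 2),
                           gtv_radius_mm = 12,
                           gtv_direction = c(0, -0.6, -0.8),
                           ctv_boost_margin_mm = 5,
                           ptv_boost_margin_mm = 5,
                           bladder_ptv_margin_mm = 7,
                           perturb_amplitude_mm = c(0.5, 3),
                           influencer_coupling = 1,
                           boost_amp_factor = 1.5,
                           boost_shrink_mm = 1,
                           max_amplitude_mm = 10,
                           noise_coarse_mm = 16,
                           dose_halfdist_mm = 5,
                           correction_probs = c(bladder = 0.91,
                                                rectum = 0.13, GTV = 0.68),
                           patients = 17, fractions = 20,
                           seed = 1) {
  stopifnot(spacing_mm > 0, length(dim) == 3, all(dim > 0),
            ctv_boost_margin_mm >= 0, ptv_boost_margin_mm >= 0,
            bladder_ptv_margin_mm >= 0,
            all(bladder_ref_volume_cm3 > 0),
            all(filling_rate_ml_min >= 0),
            diff(range(filling_rate_ml_min)) >= 0,
            all(perturb_amplitude_mm >= 0),
            patients >= 1, fractions >= 1, dose_halfdist_mm > 0)
  cfg <- list(spacing = rep(spacing_mm, 3), dim = as.integer(dim),
              origin = -(as.integer(dim) - 1) * rep(spacing_mm, 3) / 2,
              body_semiaxes = body_semiaxes_mm,
              bladder_center = bladder_center_mm,
              bladder_axis_ratio = bladder_axis_ratio,
              bladder_ref_volume = bladder_ref_volume_cm3,
              prefill_factor = prefill_factor,
              filling_rate = filling_rate_ml_min,
              couch_time = couch_time_min,
              rectum_y = rectum_y_mm, rectum_length = rectum_length_mm,
              rectum_sway = rectum_sway_mm,
              rectum_ref_volume = rectum_ref_volume_cm3,
              rectum_online_scale = rectum_online_scale,
              gtv_radius = gtv_radius_mm,
              gtv_direction = gtv_direction / sqrt(sum(gtv_direction^2)),
              ctv_boost_margin = ctv_boost_margin_mm,
              ptv_boost_margin = ptv_boost_margin_mm,
              bladder_ptv_margin = bladder_ptv_margin_mm,
              perturb_amplitude = perturb_amplitude_mm,
              influencer_coupling = influencer_coupling,
              boost_amp_factor = boost_amp_factor,
              boost_shrink = boost_shrink_mm,
              max_amplitude = max_amplitude_mm,
              noise_coarse = noise_coarse_mm,
              dose_halfdist = dose_halfdist_mm,
              correction_probs = correction_probs,
              patients = as.integer(patients),
              fractions = as.integer(fractions),
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  cfg
}

# Deterministic 32-bit child seed; distinct for distinct
# (patient, fraction, salt) under one master seed.
derive_seed <- function(master, patient = 0, fraction = 0, salt = 0) {
  as.integer(((master %% 94906249) * 1103 + patient * 10007 +
                fraction * 101 + salt) %% 2147483629)
}

empty_frame <- function(config) {
  volume_grid(array(FALSE, config$dim), spacing = config$spacing,
              origin = config$origin)
}

ellipsoid_mask <- function(frame, center, semiaxes) {
  ux <- ((axis_coords(frame, 1) - center[1]) / semiaxes[1])^2
  uy <- ((axis_coords(frame, 2) - center[2]) / semiaxes[2])^2
  uz <- ((axis_coords(frame, 3) - center[3]) / semiaxes[3])^2
  q <- outer(outer(ux, uy, `+`), uz, `+`)
  with_values(frame, q <= 1)
}

# Semiaxes of an ellipsoid with the given axis ratios and volume (cm^3).
semiaxes_for_volume <- function(volume_cm3, ratio) {
  r <- (volume_cm3 * 1000 * 3 / (4 * pi * prod(ratio)))^(1 / 3)
  ratio * r
}

# Curved tube: per-slice disk of radius `radius` around a swaying
# centerline x(z) = sway * sin(pi z / length), y = y0.
tube_mask <- function(frame, y0, length_mm, sway, radius) {
  d <- dim(frame$values)
  xs <- axis_coords(frame, 1); ys <- axis_coords(frame, 2)
  zs <- axis_coords(frame, 3)
  m <- array(FALSE, d)
  half <- length_mm / 2
  for (k in seq_len(d[3])) {
    z <- zs[k]
    if (abs(z) > half) next
    xc <- sway * sin(pi * z / length_mm)
    m[, , k] <- outer((xs - xc)^2, (ys - y0)^2, `+`) <= radius^2
  }
  with_values(frame, m)
}

# Any set voxel on the grid border?
touches_border <- function(mask) {
  m <- mask$values
  d <- dim(m)
  any(m[c(1, d[1]), , ]) || any(m[, c(1, d[2]), ]) || any(m[, , c(1, d[3])])
}

#' Isotropic margin expansion
#'
#' Morphological expansion of a mask by a Euclidean margin: the result
#' contains every voxel whose center lies within `margin_mm` of a set voxel
#' center (anisotropic spacing respected); the standard CTV-to-PTV margin
#' operation.
#'
#' @param mask binary `volume_grid`.
#' @param margin_mm margin, mm (>= 0; 0 returns the mask unchanged).
#' @return binary `volume_grid`.
#' @export
expand_margin <- function(mask, margin_mm) {
  stopifnot_mask(mask)
  if (margin_mm < 0) stop("margin must be >= 0", call. = FALSE)
  if (margin_mm == 0 || !any(mask$values)) return(mask)
  pad <- ceiling(margin_mm / min(mask$spacing)) + 1L
  cr <- crop_to_bbox(mask, pad)
  sub <- distance_map_mm(cr$grid) <= margin_mm + 1e-9
  with_values(mask, embed_values(dim(mask$values), cr, sub))
}

# Euclidean erosion by the same metric (used to derive nested structures).
erode_margin <- function(mask, margin_mm) {
  stopifnot_mask(mask)
  if (margin_mm == 0 || !any(mask$values)) return(mask)
  inv <- with_values(mask, !mask$values)
  if (!any(inv$values)) return(mask)
  with_values(mask, mask$values & distance_map_mm(inv) > margin_mm + 1e-9)
}

#' Simulate intrafraction bladder filling
#'
#' Rescales the bladder mask about its centroid so that its volume grows by
#' `rate_ml_min * minutes` ml (1 ml = 1 cm^3), emulating urine inflow
#' during the on-couch time. Works on any mask by trilinear resampling of
#' the occupancy at contracted coordinates.
#'
#' @param bladder non-empty binary `volume_grid`.
#' @param rate_ml_min filling rate, ml/min (>= 0).
#' @param minutes elapsed time, min (>= 0).
#' @return binary `volume_grid` with volume `V0 + rate * minutes` up to
#'   voxelization tolerance; an error if growth reaches the grid border.
#' @export
simulate_filling <- function(bladder, rate_ml_min, minutes) {
  stopifnot_mask(bladder)
  stopifnot(rate_ml_min >= 0, minutes >= 0)
  v0 <- mask_volume_cm3(bladder)
  if (v0 == 0) stop("cannot fill an empty bladder mask", call. = FALSE)
  dv <- rate_ml_min * minutes
  if (dv == 0) return(bladder)
  s <- ((v0 + dv) / v0)^(1 / 3)
  idx <- which(bladder$values, arr.ind = TRUE)
  ctr <- bladder$origin + (colMeans(idx) - 1) * bladder$spacing
  # sampling the source at c + (p - c)/s is a resample from a grid whose
  # origin and spacing are scaled by s about the centroid
  src_origin <- ctr + (bladder$origin - ctr) * s
  rs <- trilinear_resample(bladder$values + 0, bladder$spacing * s,
                           src_origin, bladder, fill = 0)
  out <- with_values(bladder, rs$values >= 0.5)
  if (touches_border(out))
    stop("bladder filling grows the mask beyond the grid extent",
         call. = FALSE)
  out
}

# Smooth noise field in [-1, 1]: iid normal deviates on a coarse lattice,
# Gaussian-smoothed there, trilinearly upsampled to the frame, and
# normalised to unit maximum magnitude.
smooth_noise_field <- function(frame, seed, coarse_mm = 16) {
  d <- dim(frame$values)
  extent <- (d - 1) * frame$spacing
  nc <- pmax(4L, as.integer(ceiling(extent / coarse_mm)) + 3L)
  co <- frame$origin - coarse_mm
  set.seed(seed)
  eta <- array(stats::rnorm(prod(nc)), nc)
  kern <- stats::dnorm(-2:2)
  kern <- kern / sum(kern)
  smooth1 <- function(a, ax) {
    out <- array(0, dim(a))
    n <- dim(a)[ax]
    for (off in -2:2) {
      w <- kern[off + 3]
      src <- pmin(pmax(seq_len(n) + off, 1L), n) # replicate edges
      idx <- lapply(dim(a), seq_len)
      idx[[ax]] <- src
      out <- out + w * do.call(`[`, c(list(a), idx, list(drop = FALSE)))
    }
    out
  }
  for (ax in 1:3) eta <- smooth1(eta, ax)
  rs <- trilinear_resample(eta, rep(coarse_mm, 3), co, frame, fill = 0)
  f <- rs$values
  # zero-mean (a shape perturbation, not a uniform inflate/deflate), unit
  # scale by RMS, clamped to [-1, 1] so the field is unit-bounded
  f <- f - mean(f)
  s <- sqrt(mean(f^2))
  if (s > 0) f <- pmin(pmax(f / (2 * s), -1), 1)
  f
}

#' Level-set contour perturbation
#'
#' Emulates automatic-vs-clinical contour disagreement: the signed distance
#' of the mask is offset by `amplitude_mm` times a smooth, unit-bounded,
#' seeded noise field (plus an optional systematic inward bias) and
#' re-thresholded at zero. Amplitude 0 with bias 0 returns the input
#' exactly.
#'
#' @param mask non-empty binary `volume_grid`.
#' @param amplitude_mm perturbation amplitude, mm (>= 0).
#' @param seed integer seed of the noise field.
#' @param bias_mm systematic offset, mm (positive shrinks the contour).
#' @param noise_coarse_mm correlation length of the noise field, mm.
#' @return perturbed binary `volume_grid`; error if the perturbation
#'   empties the mask.
#' @export
perturb_contour <- function(mask, amplitude_mm, seed, bias_mm = 0,
                            noise_coarse_mm = 16) {
  stopifnot_mask(mask)
  if (amplitude_mm < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (amplitude_mm == 0 && bias_mm == 0) return(mask)
  if (!any(mask$values))
    stop("cannot perturb an empty mask", call. = FALSE)
  # only voxels within amplitude + |bias| of the surface can flip, so work
  # on the padded bounding box of the mask
  reach <- amplitude_mm + abs(bias_mm)
  pad <- ceiling(reach / min(mask$spacing)) + 2L
  cr <- crop_to_bbox(mask, pad)
  # voxel-center signed distance referenced to the implied surface midway
  # between the inner and outer voxel layers, so sub-voxel offsets act
  sd_mm <- signed_distance_mm(cr$grid)
  half <- min(mask$spacing) / 2
  sd_mm <- sd_mm - sign(sd_mm) * half
  offset <- bias_mm
  if (amplitude_mm > 0)
    offset <- offset + amplitude_mm *
      smooth_noise_field(cr$grid, seed, noise_coarse_mm)
  sub <- (sd_mm + offset) < 0
  out <- with_values(mask, embed_values(dim(mask$values), cr, sub))
  if (!any(out$values))
    stop("contour perturbation emptied the mask", call. = FALSE)
  out
}

#' Synthetic two-level SIB dose distribution
#'
#' Geometric (not physics-based) dose model: each prescription level
#' contributes `Rx * 2^(-s / d_half)` where `s` is the Euclidean distance
#' outside that level's PTV (0 inside), and the voxel dose is the maximum
#' over levels. By construction the boost prescription is met everywhere in
#' PTV_boost and the elective prescription everywhere in PTV_elective, with
#' an exponential lateral falloff of half-distance `d_half`.
#'
#' @param ptv_boost,ptv_elective binary `volume_grid`s on one frame.
#' @param prescription a [prescription_config()]; the dose is produced on
#'   its evaluation scale (per-fraction by default).
#' @param d_half_mm falloff half-distance, mm.
#' @return dose `volume_grid` (Gy).
#' @export
synth_dose <- function(ptv_boost, ptv_elective,
                       prescription = prescription_config(),
                       d_half_mm = 5) {
  stopifnot_mask(ptv_boost, "ptv_boost")
  stopifnot_mask(ptv_elective, "ptv_elective")
  if (!same_frame(ptv_boost, ptv_elective))
    stop("PTV masks are on different frames", call. = FALSE)
  nfx <- if (prescription$evaluation_scale == "per_fraction")
    prescription$fractions else 1L
  rx_b <- prescription$boost_total / nfx
  rx_e <- prescription$elective_total / nfx
  sb <- distance_map_mm(ptv_boost)
  se <- distance_map_mm(ptv_elective)
  dose <- pmax(rx_b * 2^(-sb / d_half_mm), rx_e * 2^(-se / d_half_mm))
  with_values(ptv_boost, array(dose, dim(ptv_boost$values)), kind = "dose")
}

# Per-patient anatomy parameters, deterministic under the master seed.
patient_params <- function(config, patient) {
  set.seed(derive_seed(config$seed, patient, 0, 1))
  list(patient_id = sprintf("P%02d", patient),
       bladder_ref_volume = stats::runif(1, config$bladder_ref_volume[1],
                                         config$bladder_ref_volume[2]),
       rectum_ref_volume = stats::runif(1, config$rectum_ref_volume[1],
                                        config$rectum_ref_volume[2]))
}

# Build one arm's anatomy for given organ volumes. Targets are cropped to
# the body, as treatment planning systems crop PTVs to the patient surface.
build_anatomy <- function(config, bladder_volume, rectum_volume,
                          arm = "clin") {
  frame <- empty_frame(config)
  bladder <- ellipsoid_mask(frame, config$bladder_center,
                            semiaxes_for_volume(bladder_volume,
                                                config$bladder_axis_ratio))
  if (touches_border(bladder))
    stop("bladder exceeds the phantom grid extent", call. = FALSE)
  radius <- sqrt(rectum_volume * 1000 / (pi * config$rectum_length))
  rectum <- tube_mask(frame, config$rectum_y, config$rectum_length,
                      config$rectum_sway, radius)
  # GTV seat: intersection of the wall with the configured direction
  semi <- semiaxes_for_volume(bladder_volume, config$bladder_axis_ratio)
  u <- config$gtv_direction
  t <- 1 / sqrt(sum((u / semi)^2))
  gtv_center <- config$bladder_center + u * t
  gtv <- ellipsoid_mask(frame, gtv_center, rep(config$gtv_radius, 3))
  structures_from_organs(config, frame, bladder, rectum, gtv, arm)
}

# Derive the target chain and assemble a validated structure set.
structures_from_organs <- function(config, frame, bladder, rectum, gtv,
                                   arm) {
  body <- ellipsoid_mask(frame, c(0, 0, 0), config$body_semiaxes)
  crop <- function(m) with_values(m, m$values & body$values)
  gtv <- crop(gtv)
  ctv_boost <- crop(expand_margin(gtv, config$ctv_boost_margin))
  ptv_boost <- crop(expand_margin(ctv_boost, config$ptv_boost_margin))
  ctv_elective <- crop(with_values(bladder,
                                   bladder$values | ctv_boost$values))
  ptv_elective <- crop(with_values(
    bladder,
    expand_margin(bladder, config$bladder_ptv_margin)$values |
      ptv_boost$values))
  structure_set(list(bladder = bladder, rectum = rectum, GTV = gtv,
                     CTV_boost = ctv_boost, CTV_elective = ctv_elective,
                     PTV_boost = ptv_boost, PTV_elective = ptv_elective,
                     body = body),
                arm = arm)
}

#' Generate the reference anatomy of one synthetic patient
#'
#' Stands in for the manual reference-CT delineation: an ellipsoidal
#' bladder at the patient's reference volume, a curved rectal tube, a
#' spherical GTV seated on the bladder wall, the margin-derived target
#' chain, and the body. Deterministic under the patient seed.
#'
#' @param config a [phantom_config()].
#' @param patient patient index (1-based).
#' @return list with `structures` (a clin-arm `structure_set`),
#'   `reference_volumes` (named cm^3, analytic targets) and `params`.
#' @export
generate_reference_anatomy <- function(config, patient = 1) {
  p <- patient_params(config, patient)
  ss <- build_anatomy(config, p$bladder_ref_volume, p$rectum_ref_volume)
  list(structures = ss,
       reference_volumes = c(bladder = p$bladder_ref_volume,
                             rectum = p$rectum_ref_volume),
       params = p)
}

#' Generate one synthetic paired session
#'
#' Builds the online (clinically corrected) anatomy of one fraction —
#' pre-fill variation plus on-couch filling for the bladder, volume
#' variation for the rectum, GTV riding on the bladder wall — then derives
#' the automatically proposed arm by level-set perturbation (influencers
#' perturbed directly; the GTV perturbed with the boost amplitude and
#' shrink bias, its margins re-applied, mimicking influencer-guided
#' propagation error), and optimizes one synthetic SIB dose per arm around
#' that arm's PTVs.
#'
#' @param config a [phantom_config()].
#' @param patient,fraction indices (1-based).
#' @param prescription a [prescription_config()].
#' @return list with `session` (a validated `rt_session`) and `truth`
#'   (one-row data.frame of generating parameters).
#' @export
generate_session <- function(config, patient, fraction,
                             prescription = prescription_config()) {
  p <- patient_params(config, patient)
  sseed <- derive_seed(config$seed, patient, fraction, 2)
  set.seed(sseed)
  prefill <- stats::runif(1, config$prefill_factor[1],
                          config$prefill_factor[2])
  rate <- stats::runif(1, config$filling_rate[1], config$filling_rate[2])
  couch <- stats::runif(1, config$couch_time[1], config$couch_time[2])
  rscale <- stats::runif(1, config$rectum_online_scale[1],
                         config$rectum_online_scale[2])
  amp_base <- stats::runif(1, config$perturb_amplitude[1],
                           config$perturb_amplitude[2])
  corr <- stats::runif(length(config$correction_probs)) <
    config$correction_probs
  names(corr) <- names(config$correction_probs)

  v_bladder <- p$bladder_ref_volume * prefill + rate * couch
  v_rectum <- p$rectum_ref_volume * rscale
  clin <- build_anatomy(config, v_bladder, v_rectum, arm = "clin")

  dv_bladder <- abs(v_bladder - p$bladder_ref_volume)
  dv_rectum <- abs(v_rectum - p$rectum_ref_volume)
  amp_inf <- min(config$max_amplitude,
                 amp_base * (1 + config$influencer_coupling *
                               dv_bladder / 100))
  amp_boost <- min(config$max_amplitude, amp_inf * config$boost_amp_factor)
  bias <- if (amp_base > 0) config$boost_shrink else 0

  # deterministic redraw of the noise field on the rare degenerate draw
  # that would empty a small structure entirely
  perturb_retry <- function(mask, amp, seed, bias = 0) {
    for (k in 0:4) {
      out <- tryCatch(
        perturb_contour(mask, amp, seed + 1000L * k, bias_mm = bias,
                        noise_coarse_mm = config$noise_coarse),
        error = function(e) e)
      if (!inherits(out, "error")) return(out)
    }
    stop(out)
  }

  if (amp_base == 0 && bias == 0) {
    auto <- structure_set(clin$masks, arm = "auto", validate = FALSE)
    dose_clin <- synth_dose(clin$masks$PTV_boost, clin$masks$PTV_elective,
                            prescription, config$dose_halfdist)
    dose_auto <- dose_clin
  } else {
    frame <- empty_frame(config)
    bladder_a <- perturb_retry(clin$masks$bladder, amp_inf,
                               derive_seed(config$seed, patient,
                                           fraction, 3))
    rectum_a <- perturb_retry(clin$masks$rectum, amp_inf,
                              derive_seed(config$seed, patient,
                                          fraction, 4))
    gtv_a <- perturb_retry(clin$masks$GTV, amp_boost,
                           derive_seed(config$seed, patient, fraction, 5),
                           bias = bias)
    auto <- structures_from_organs(config, frame, bladder_a, rectum_a,
                                   gtv_a, arm = "auto")
    dose_clin <- synth_dose(clin$masks$PTV_boost, clin$masks$PTV_elective,
                            prescription, config$dose_halfdist)
    dose_auto <- synth_dose(auto$masks$PTV_boost, auto$masks$PTV_elective,
                            prescription, config$dose_halfdist)
  }

  session <- rt_session(p$patient_id, fraction, clin, auto,
                        dose_clin, dose_auto, corrections = corr,
                        reference_volumes = c(
                          bladder = p$bladder_ref_volume,
                          rectum = p$rectum_ref_volume))
  truth <- data.frame(patient_id = p$patient_id, fraction = fraction,
                      seed = sseed,
                      bladder_ref_volume = p$bladder_ref_volume,
                      rectum_ref_volume = p$rectum_ref_volume,
                      bladder_online_volume = v_bladder,
                      rectum_online_volume = v_rectum,
                      dv_bladder_true = dv_bladder,
                      dv_rectum_true = dv_rectum,
                      filling_rate = rate, couch_time = couch,
                      amp_base = amp_base, amp_influencer = amp_inf,
                      amp_boost = amp_boost, boost_bias = bias,
                      stringsAsFactors = FALSE)
  list(session = session, truth = truth)
}

#' Generate a synthetic paired-session cohort
#'
#' Iterates [generate_session()] over the configured patients and
#' fractions. With `out_dir` set, each session is written as an internal
#' bundle (see [write_session()]) and discarded, which keeps memory flat
#' for full-size cohorts; otherwise all sessions are returned in memory
#' (intended for small configurations).
#'
#' @param config a [phantom_config()].
#' @param prescription a [prescription_config()].
#' @param out_dir optional directory for session bundles.
#' @return list with `truth` (data.frame, one row per session, also the
#'   ground-truth log), and either `sessions` (list of `rt_session`) or
#'   `manifests` (character paths).
#' @export
generate_cohort <- function(config, prescription = prescription_config(),
                            out_dir = NULL) {
  truth <- list()
  sessions <- list()
  manifests <- character()
  i <- 0L
  for (pt in seq_len(config$patients)) {
    for (fx in seq_len(config$fractions)) {
      i <- i + 1L
      g <- generate_session(config, pt, fx, prescription)
      truth[[i]] <- g$truth
      if (is.null(out_dir)) {
        sessions[[i]] <- g$session
      } else {
        manifests[i] <- write_session(
          g$session, file.path(out_dir, sprintf("%s_fx%02d",
                                                g$truth$patient_id, fx)))
      }
    }
  }
  out <- list(truth = do.call(rbind, truth))
  if (is.null(out_dir)) out$sessions <- sessions else out$manifests <- manifests
  out
}
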