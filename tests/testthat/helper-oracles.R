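# Independent oracles and small fixture builders, kept deliberately naive.

# All-pairs brute-force pooled surface distances (oracle for the
# distance-transform implementation).
brute_surface_distances <- function(a, b) {
  pa <- boundary_points(a)
  pb <- boundary_points(b)
  d2 <- function(p, q) outer(rowSums(p^2), rowSums(q^2), `+`) -
    2 * p %*% t(q)
  dab <- sqrt(pmax(apply(d2(pa, pb), 1, min), 0))
  dba <- sqrt(pmax(apply(d2(pb, pa), 1, min), 0))
  c(dab, dba)
}

# Full 2^n sign-assignment enumeration of the two-sided signed-rank
# p-value (oracle for the convolution implementation).
enum_wilcoxon_p <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  total <- sum(r)
  hits <- 0L
  for (pat in 0:(2^n - 1)) {
    pos <- as.logical(bitwAnd(pat, 2^(seq_len(n) - 1)))
    w <- min(sum(r[pos]), total - sum(r[pos]))
    if (w <= w_obs + 1e-12) hits <- hits + 1L
  }
  hits / 2^n
}

# Digitized sphere mask on an isotropic grid centered in the array.
sphere_mask <- function(radius_mm, spacing = 1, dim = NULL,
                        center = c(0, 0, 0)) {
  if (is.null(dim)) dim <- rep(2 * ceiling(radius_mm / spacing) + 5, 3)
  origin <- -(dim - 1) * spacing / 2
  g <- volume_grid(array(FALSE, dim), spacing = rep(spacing, 3),
                   origin = origin)
  xs <- axis_coords(g, 1); ys <- axis_coords(g, 2); zs <- axis_coords(g, 3)
  q <- outer(outer((xs - center[1])^2, (ys - center[2])^2, `+`),
             (zs - center[3])^2, `+`)
  volume_grid(q <= radius_mm^2, spacing = rep(spacing, 3), origin = origin)
}

# Analytic volume of the intersection lens of two equal spheres.
sphere_lens_volume <- function(r, d) {
  pi * (2 * r - d)^2 * (d^2 + 4 * d * r) / (12 * d)
}

# Small random blob: union of a few random balls on a compact grid.
random_blob <- function(seed, dim = c(14, 12, 10), spacing = c(1, 1.5, 2)) {
  set.seed(seed)
  g <- volume_grid(array(FALSE, dim), spacing = spacing)
  m <- array(FALSE, dim)
  xs <- axis_coords(g, 1); ys <- axis_coords(g, 2); zs <- axis_coords(g, 3)
  for (i in 1:sample(2:4, 1)) {
    c0 <- c(runif(1, min(xs), max(xs)), runif(1, min(ys), max(ys)),
            runif(1, min(zs), max(zs)))
    r <- runif(1, 2, 5)
    q <- outer(outer((xs - c0[1])^2, (ys - c0[2])^2, `+`),
               (zs - c0[3])^2, `+`)
    m <- m | (q <= r^2)
  }
  if (!any(m)) m[3, 3, 3] <- TRUE
  volume_grid(m, spacing = spacing)
}

# Minimal valid session on a tiny grid: nested box targets, body = large
# box, uniform or caller-supplied doses (Gy per fraction).
make_toy_session <- function(dose_clin_gy = 2.75, dose_auto_gy = 2.75,
                             dim = c(14, 14, 14), spacing = c(2, 2, 2)) {
  box <- function(lo, hi) {
    m <- array(FALSE, dim)
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    volume_grid(m, spacing = spacing)
  }
  masks <- list(
    bladder = box(c(3, 3, 3), c(8, 8, 8)),
    rectum = box(c(10, 10, 3), c(12, 12, 12)),
    GTV = box(c(5, 5, 5), c(6, 6, 6)),
    CTV_boost = box(c(4, 4, 4), c(7, 7, 7)),
    PTV_boost = box(c(3, 3, 3), c(8, 8, 8)),
    CTV_elective = box(c(3, 3, 3), c(8, 8, 8)),
    PTV_elective = box(c(2, 2, 2), c(9, 9, 9)),
    body = box(c(1, 1, 1), c(13, 13, 13)))
  ss_clin <- structure_set(masks, arm = "clin")
  ss_auto <- structure_set(masks, arm = "auto")
  mk_dose <- function(gy) {
    if (length(gy) == 1) gy <- array(gy, dim)
    volume_grid(gy, spacing = spacing, kind = "dose")
  }
  rt_session("T01", 1, ss_clin, ss_auto, mk_dose(dose_clin_gy),
             mk_dose(dose_auto_gy),
             corrections = c(bladder = TRUE, rectum = FALSE, GTV = FALSE),
             reference_volumes = c(bladder = mask_volume_cm3(masks$bladder),
                                   rectum = mask_volume_cm3(masks$rectum)))
}

# Tiny phantom configuration for fast end-to-end tests.
tiny_phantom <- function(seed = 1, patients = 2, fractions = 2, ...) {
  phantom_config(seed = seed, patients = patients, fractions = fractions,
                 ...)
}
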