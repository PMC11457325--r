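#' Influencer volume difference between reference and online anatomy
#'
#' Absolute (default) difference in cm^3 between the influencer volume on
#' the reference CT (session metadata) and its online volume.
#'
#' @param reference_volume cm^3 on the reference CT (> 0).
#' @param online either a binary `volume_grid` (volume computed from the
#'   mask) or a numeric volume in cm^3.
#' @param signed return the signed difference `online - reference` instead.
#' @return cm^3.
#' @export
volume_difference <- function(reference_volume, online, signed = FALSE) {
  if (is.na(reference_volume) || reference_volume <= 0)
    stop("missing or non-positive reference volume", call. = FALSE)
  v_online <- if (is_volume_grid(online)) {
    if (!any(online$values)) stop("online mask is empty", call. = FALSE)
    mask_volume_cm3(online)
  } else {
    as.numeric(online)
  }
  d <- v_online - reference_volume
  if (signed) d else abs(d)
}

bin_edges_for <- function(role, config) {
  w <- bin_width_for(role, config)
  c(seq(0, (config$max_bins - 1) * w, by = w), Inf)
}

bin_labels_for <- function(role, config) {
  e <- bin_edges_for(role, config)
  k <- length(e) - 1
  vapply(seq_len(k), function(i) {
    if (is.infinite(e[i + 1])) sprintf("[%g,Inf)", e[i])
    else sprintf("[%g,%g)", e[i], e[i + 1])
  }, character(1))
}

#' Assign a volume difference to its stratification bin
#'
#' Half-open bins `[0,w), [w,2w), ..., [(max_bins-1)w, Inf)` where `w` is
#' the role's bin width (bladder 50 cm^3, rectum 25 cm^3 by default), so
#' "smaller than 50 cm^3" is the first bin and "larger than 150 cm^3" the
#' open-ended last one.
#'
#' @param diff volume difference, cm^3 (>= 0; signed differences are binned
#'   by magnitude).
#' @param role `"bladder"` or `"rectum"`.
#' @param config a [stratification_config()].
#' @return factor with the full bin-label level set.
#' @export
assign_bin <- function(diff, role, config = stratification_config()) {
  e <- bin_edges_for(role, config)
  labs <- bin_labels_for(role, config)
  cut(abs(diff), breaks = e, labels = labs, right = FALSE,
      include.lowest = FALSE)
}

#' Coverage-failure table by influencer volume change
#'
#' Bins sessions by the influencer's reference-to-online volume difference
#' and tabulates, per bin, the number of sessions and the percent failing
#' the coverage requirement for the chosen target under the automatic dose
#' distribution.
#'
#' @param session_data `data.frame` with one row per session containing the
#'   volume-difference column `dv_<influencer>` (cm^3) and the logical
#'   column `meets_<target>` (requirement met under D_auto).
#' @param target_role `"CTV_boost"` or `"CTV_elective"`.
#' @param influencer_role `"bladder"` or `"rectum"`.
#' @param config a [stratification_config()].
#' @return `data.frame` of class `stratum_table` with columns `bin`,
#'   `n_sessions`, `n_fail`, `pct_fail` (NA for empty bins).
#' @export
failure_table <- function(session_data, target_role, influencer_role,
                          config = stratification_config()) {
  dv_col <- paste0("dv_", influencer_role)
  meet_col <- paste0("meets_", target_role)
  for (col in c(dv_col, meet_col))
    if (!col %in% names(session_data))
      stop("session data lacks column ", col, call. = FALSE)
  bins <- assign_bin(session_data[[dv_col]], influencer_role, config)
  fail <- !session_data[[meet_col]]
  n <- as.integer(table(bins))
  nf <- as.integer(tapply(fail, bins, sum, default = 0L))
  out <- data.frame(bin = bin_labels_for(influencer_role, config),
                    n_sessions = n, n_fail = nf,
                    pct_fail = ifelse(n > 0, 100 * nf / n, NA_real_),
                    stringsAsFactors = FALSE)
  attr(out, "target_role") <- target_role
  attr(out, "influencer_role") <- influencer_role
  class(out) <- c("stratum_table", "data.frame")
  out
}
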