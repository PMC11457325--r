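#' Prescription configuration
#'
#' Dose prescription of the two-level simultaneous-integrated-boost (SIB)
#' scheme: the elective target (bladder plus pelvic lymph nodes) receives
#' `elective_total` Gy and the tumor bed an additional `boost_extra` Gy, in
#' `fractions` fractions. Coverage is judged at `coverage_fraction` of the
#' prescribed dose (V95 for the default 0.95) against the clinical
#' requirement `coverage_requirement` (percent of the structure volume).
#'
#' @param elective_total total elective prescription, Gy (default 40).
#' @param boost_extra additional SIB dose, Gy (default 15); the boost
#'   prescription is `elective_total + boost_extra`.
#' @param fractions number of fractions (default 20).
#' @param evaluation_scale `"per_fraction"` (dose grids hold one fraction,
#'   the default) or `"total"`.
#' @param coverage_fraction fraction of prescription defining the coverage
#'   threshold (default 0.95).
#' @param coverage_requirement minimum percent of the structure volume that
#'   must reach the threshold (default 98, inclusive).
#' @return list of class `prescription_config`.
#' @export
prescription_config <- function(elective_total = 40, boost_extra = 15,
                                fractions = 20,
                                evaluation_scale = c("per_fraction", "total"),
                                coverage_fraction = 0.95,
                                coverage_requirement = 98) {
  evaluation_scale <- match.arg(evaluation_scale)
  stopifnot(elective_total > 0, boost_extra >= 0, fractions >= 1,
            coverage_fraction > 0, coverage_fraction < 1,
            coverage_requirement > 0, coverage_requirement <= 100)
  structure(list(elective_total = elective_total, boost_extra = boost_extra,
                 boost_total = elective_total + boost_extra,
                 fractions = as.integer(fractions),
                 evaluation_scale = evaluation_scale,
                 coverage_fraction = coverage_fraction,
                 coverage_requirement = coverage_requirement),
            class = "prescription_config")
}

#' Statistics configuration
#'
#' Family-wise error control for the paired arm comparisons. The corrected
#' significance level is `family_alpha / family_size` (Bonferroni); the
#' defaults give 0.05 / 10 = 0.005, i.e. a corrected level of 0.5%.
#'
#' @param family_alpha family-wise alpha (default 0.05).
#' @param family_size number of paired comparisons in the family
#'   (default 10: five target structures, two dosimetric metrics each).
#' @param exact_n_max largest number of non-zero paired differences for
#'   which the exact signed-rank null distribution is used (default 20);
#'   above it a tie-corrected normal approximation with continuity
#'   correction is applied.
#' @return list of class `stats_config`.
#' @export
stats_config <- function(family_alpha = 0.05, family_size = 10,
                         exact_n_max = 20) {
  stopifnot(family_alpha > 0, family_alpha < 1, family_size >= 1,
            exact_n_max >= 1)
  corrected <- family_alpha / family_size
  structure(list(family_alpha = family_alpha,
                 family_size = as.integer(family_size),
                 corrected_alpha = corrected,
                 exact_n_max = as.integer(exact_n_max)),
            class = "stats_config")
}

#' Stratification configuration
#'
#' Bin widths for the influencer volume-difference analysis: sessions are
#' binned by the absolute difference between the influencer volume on the
#' reference CT and on the online anatomy, in half-open bins
#' `[0,w), [w,2w), ..., [(max_bins-1)w, Inf)`.
#'
#' @param bladder_bin_width cm^3 (default 50).
#' @param rectum_bin_width cm^3 (default 25).
#' @param max_bins number of bins, last one open-ended (default 4).
#' @param signed use signed differences instead of absolute (default FALSE).
#' @return list of class `stratification_config`.
#' @export
stratification_config <- function(bladder_bin_width = 50,
                                  rectum_bin_width = 25,
                                  max_bins = 4, signed = FALSE) {
  stopifnot(bladder_bin_width > 0, rectum_bin_width > 0, max_bins >= 2)
  structure(list(bladder_bin_width = bladder_bin_width,
                 rectum_bin_width = rectum_bin_width,
                 max_bins = as.integer(max_bins), signed = signed),
            class = "stratification_config")
}

bin_width_for <- function(role, config) {
  switch(role,
         bladder = config$bladder_bin_width,
         rectum = config$rectum_bin_width,
         stop("no bin width defined for role ", role, call. = FALSE))
}
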