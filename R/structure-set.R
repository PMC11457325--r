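#' Structure roles used throughout the pipeline
#'
#' `rt_roles()` returns all recognised structure roles; `target_roles()` the
#' dose-evaluation targets; `influencer_roles()` the organs whose automatic
#' delineation guides target propagation in the adaptive workflow (bladder
#' and rectum); `geometric_roles()` the structures entering the contour
#' comparison.
#'
#' @return character vector of role names.
#' @export
rt_roles <- function() c("bladder", "rectum", "GTV", "CTV_boost",
                         "CTV_elective", "PTV_boost", "PTV_elective", "body")

#' @rdname rt_roles
#' @export
target_roles <- function() c("GTV", "CTV_boost", "PTV_boost",
                             "CTV_elective", "PTV_elective")

#' @rdname rt_roles
#' @export
influencer_roles <- function() c("bladder", "rectum")

#' @rdname rt_roles
#' @export
geometric_roles <- function() c("bladder", "rectum", "CTV_boost")

boost_roles <- function() c("GTV", "CTV_boost", "PTV_boost")
elective_roles <- function() c("CTV_elective", "PTV_elective")

#' One arm's structure set for one session
#'
#' Bundles the named binary masks of one contouring arm (`clin`: clinically
#' corrected contours; `auto`: automatically proposed contours) on a single
#' common grid frame.
#'
#' @param masks named list of binary `volume_grid` objects; names drawn from
#'   [rt_roles()].
#' @param arm `"clin"` or `"auto"`.
#' @param validate run [validate_structure_set()]?
#' @return object of class `structure_set`.
#' @export
structure_set <- function(masks, arm = c("clin", "auto"), validate = TRUE) {
  arm <- match.arg(arm)
  if (is.null(names(masks)) || any(names(masks) == ""))
    stop("'masks' must be a fully named list", call. = FALSE)
  ss <- structure(list(arm = arm, masks = masks), class = "structure_set")
  if (validate) validate_structure_set(ss)
  ss
}

#' Validate a structure set
#'
#' Enforced invariants: all roles recognised; every mask binary, non-empty
#' and on one common grid frame; the body mask is a superset of every target
#' mask; containment chain GTV within CTV_boost within PTV_boost. All
#' violations are collected and reported together.
#'
#' @param ss a `structure_set`.
#' @return `ss`, invisibly; validation failure raises an error listing every
#'   offending role.
#' @export
validate_structure_set <- function(ss) {
  problems <- character()
  masks <- ss$masks
  unknown <- setdiff(names(masks), rt_roles())
  if (length(unknown))
    problems <- c(problems, paste0("unknown roles: ",
                                   paste(unknown, collapse = ", ")))
  for (role in names(masks)) {
    m <- masks[[role]]
    if (!is_volume_grid(m) || m$kind != "mask") {
      problems <- c(problems, paste0(role, ": not a binary mask volume_grid"))
      next
    }
    if (!any(m$values))
      problems <- c(problems, paste0(role, ": empty mask"))
  }
  if (!length(problems)) {
    ref <- masks[[1]]
    for (role in names(masks)[-1])
      if (!same_frame(ref, masks[[role]]))
        problems <- c(problems, paste0(role, ": grid frame differs from ",
                                       names(masks)[1]))
  }
  if (!length(problems)) {
    if (!is.null(masks$body)) {
      for (role in intersect(target_roles(), names(masks)))
        if (any(masks[[role]]$values & !masks$body$values))
          problems <- c(problems, paste0("body does not contain ", role))
    }
    chain <- c("GTV", "CTV_boost", "PTV_boost")
    for (i in 1:2) {
      a <- chain[i]; b <- chain[i + 1]
      if (!is.null(masks[[a]]) && !is.null(masks[[b]]) &&
          any(masks[[a]]$values & !masks[[b]]$values))
        problems <- c(problems, paste0(a, " not contained in ", b))
    }
  }
  if (length(problems))
    stop("invalid structure set (", ss$arm, "): ",
         paste(problems, collapse = "; "), call. = FALSE)
  invisible(ss)
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set arm=%s> roles: %s\n", x$arm,
              paste(names(x$masks), collapse = ", ")))
  invisible(x)
}

#' Paired evaluation session
#'
#' One treatment fraction of one patient: the clinically corrected and the
#' automatically proposed structure sets, the dose distributions optimized
#' on each (`dose_clin`, `dose_auto`, Gy per fraction by default), the
#' manual-correction flags recorded in the clinic, and the influencer
#' volumes on the reference CT.
#'
#' @param patient_id label.
#' @param fraction integer fraction number (1-based).
#' @param contours_clin,contours_auto `structure_set`s with matching arms.
#' @param dose_clin,dose_auto dose `volume_grid`s.
#' @param corrections named logical vector (roles manually adjusted).
#' @param reference_volumes named numeric, cm^3 on the reference CT, for
#'   `bladder` and `rectum`.
#' @param validate run [validate_session()]?
#' @return object of class `rt_session`.
#' @export
rt_session <- function(patient_id, fraction, contours_clin, contours_auto,
                       dose_clin, dose_auto,
                       corrections = c(bladder = FALSE, rectum = FALSE,
                                       GTV = FALSE),
                       reference_volumes = c(bladder = NA_real_,
                                             rectum = NA_real_),
                       validate = TRUE) {
  s <- structure(list(patient_id = as.character(patient_id),
                      fraction = as.integer(fraction),
                      contours_clin = contours_clin,
                      contours_auto = contours_auto,
                      dose_clin = dose_clin, dose_auto = dose_auto,
                      corrections = corrections,
                      reference_volumes = reference_volumes),
                 class = "rt_session")
  if (validate) validate_session(s)
  s
}

# Does the dose grid's world extent cover the mask's bounding box?
dose_covers <- function(dose, mask) {
  bb <- mask_bbox(mask)
  if (is.null(bb)) return(TRUE)
  for (ax in 1:3) {
    w <- mask$origin[ax] + (bb[, ax] - 1) * mask$spacing[ax]
    dlo <- dose$origin[ax]
    dhi <- dose$origin[ax] + (dim(dose$values)[ax] - 1) * dose$spacing[ax]
    if (w[1] < dlo - 1e-6 || w[2] > dhi + 1e-6) return(FALSE)
  }
  TRUE
}

#' Validate a session
#'
#' Checks both structure sets (see [validate_structure_set()]), the arm
#' labels, and that both dose grids cover the bounding box of every target
#' mask of the clinical structure set.
#'
#' @param s an `rt_session`.
#' @return `s` invisibly; raises an informative error otherwise.
#' @export
validate_session <- function(s) {
  id <- sprintf("session %s/fx%02d", s$patient_id, s$fraction)
  if (s$contours_clin$arm != "clin" || s$contours_auto$arm != "auto")
    stop(id, ": structure-set arms are mislabelled", call. = FALSE)
  validate_structure_set(s$contours_clin)
  validate_structure_set(s$contours_auto)
  for (dn in c("dose_clin", "dose_auto")) {
    d <- s[[dn]]
    if (!is_volume_grid(d) || d$kind != "dose")
      stop(id, ": ", dn, " is not a dose volume_grid", call. = FALSE)
    for (role in intersect(target_roles(), names(s$contours_clin$masks)))
      if (!dose_covers(d, s$contours_clin$masks[[role]]))
        stop(id, ": ", dn, " does not cover the bounding box of ", role,
             call. = FALSE)
  }
  invisible(s)
}

#' @export
print.rt_session <- function(x, ...) {
  cat(sprintf("<rt_session %s fx%02d> %d clin / %d auto structures\n",
              x$patient_id, x$fraction, length(x$contours_clin$masks),
              length(x$contours_auto$masks)))
  invisible(x)
}
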