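#' Write a session as an internal bundle
#'
#' Self-contained on-disk form of one paired session: one NIfTI file per
#' structure per arm (uint8) and per dose arm (float32), plus a JSON
#' manifest carrying the grid frames, correction flags, reference volumes
#' and identifiers. Masks round-trip losslessly; dose round-trips bitwise
#' within float32 representation.
#'
#' @param session a validated `rt_session`.
#' @param dir output directory (created if needed).
#' @return path of the manifest file, invisibly usable by
#'   [read_session()].
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frame_of <- function(g) list(origin = g$origin, spacing = g$spacing,
                               dim = dim(g$values))
  files <- list()
  for (arm in c("clin", "auto")) {
    ss <- session[[paste0("contours_", arm)]]
    for (role in names(ss$masks)) {
      fn <- sprintf("%s_%s.nii.gz", arm, role)
      RNifti::writeNifti(array(as.integer(ss$masks[[role]]$values),
                               dim(ss$masks[[role]]$values)),
                         file.path(dir, fn), datatype = "uint8")
      files[[arm]][[role]] <- fn
    }
  }
  for (dn in c("dose_clin", "dose_auto")) {
    fn <- paste0(dn, ".nii.gz")
    RNifti::writeNifti(session[[dn]]$values, file.path(dir, fn),
                       datatype = "float")
    files[[dn]] <- fn
  }
  manifest <- list(
    patient_id = session$patient_id, fraction = session$fraction,
    frames = list(structures = frame_of(session$contours_clin$masks[[1]]),
                  dose_clin = frame_of(session$dose_clin),
                  dose_auto = frame_of(session$dose_auto)),
    files = files,
    corrections = as.list(session$corrections),
    reference_volumes = as.list(session$reference_volumes))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

read_grid <- function(dir, fn, frame, kind) {
  path <- file.path(dir, fn)
  if (!file.exists(path))
    stop("bundle file missing: ", path, call. = FALSE)
  vals <- array(as.vector(RNifti::readNifti(path)),
                unlist(frame$dim))
  volume_grid(vals, spacing = unlist(frame$spacing),
              origin = unlist(frame$origin), kind = kind)
}

#' Read a session bundle
#'
#' Loads and fully validates a session written by [write_session()].
#' Missing roles, frame mismatches or invariant violations raise errors
#' naming the offender.
#'
#' @param manifest path to a bundle `manifest.json` (or its directory).
#' @return a validated `rt_session`.
#' @export
read_session <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.json")
  if (!file.exists(manifest))
    stop("manifest not found: ", manifest, call. = FALSE)
  mf <- jsonlite::read_json(manifest)
  dir <- dirname(manifest)
  need <- c("bladder", "body")
  sets <- list()
  for (arm in c("clin", "auto")) {
    roles <- names(mf$files[[arm]])
    missing <- setdiff(need, roles)
    if (length(missing))
      stop("bundle (", arm, " arm) missing required role(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    masks <- lapply(mf$files[[arm]], function(fn)
      read_grid(dir, fn, mf$frames$structures, "mask"))
    sets[[arm]] <- structure_set(masks, arm = arm, validate = FALSE)
  }
  dose_clin <- read_grid(dir, mf$files$dose_clin, mf$frames$dose_clin,
                         "dose")
  dose_auto <- read_grid(dir, mf$files$dose_auto, mf$frames$dose_auto,
                         "dose")
  rt_session(mf$patient_id, mf$fraction, sets$clin, sets$auto,
             dose_clin, dose_auto,
             corrections = unlist(mf$corrections),
             reference_volumes = unlist(mf$reference_volumes))
}

#' Export a mask as NIfTI
#'
#' Convenience export for external viewing; carries the voxel spacing in
#' the NIfTI header.
#'
#' @param mask a binary `volume_grid`.
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  stopifnot_mask(mask)
  img <- RNifti::asNifti(array(as.integer(mask$values), dim(mask$values)),
                         pixdim = mask$spacing, datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

fmt_summary <- function(s, digits = 3) {
  sprintf("%s [%s-%s]", signif(s[["median"]], digits),
          signif(s[["min"]], digits), signif(s[["max"]], digits))
}

#' Write the evaluation report bundle
#'
#' Emits the cohort tables of a [run_evaluation()] result: per-session CSV
#' tables (`geometric.csv`, `dosimetric.csv`, `sessions.csv`) and a JSON
#' summary (`summary.json`) with median-and-range summaries per structure
#' and metric, paired-test results, manual-correction frequencies,
#' requirement pass rates and the stratification tables. Output is
#' deterministic: identical results give byte-identical files.
#'
#' @param results a `rt_evaluation` object from [run_evaluation()].
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  paths <- c(paths, wr(results$geometric, "geometric.csv"),
             wr(results$dosimetric, "dosimetric.csv"),
             wr(results$sessions, "sessions.csv"))
  jp <- file.path(dir, "summary.json")
  jsonlite::write_json(results$summary, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  paths <- c(paths, jp)
  invisible(paths)
}
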