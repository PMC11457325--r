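#' Evaluate one paired session
#'
#' Runs the full two-arm evaluation of one session: the geometric contour
#' comparison (automatic vs clinically corrected) for the influencers and
#' the boost CTV, and the dosimetric evaluation of the clinically corrected
#' target contours under both dose distributions.
#'
#' @param session a validated `rt_session`.
#' @param prescription a [prescription_config()].
#' @param geometric for which roles to compute contour agreement.
#' @param targets dose-evaluation roles.
#' @param body_threshold see [dosimetric_record()].
#' @return list with `geometric` and `dosimetric` data.frames and
#'   `session_row` (one row of per-session metadata: correction flags,
#'   influencer volume differences, requirement flags under both arms).
#' @export
evaluate_session <- function(session,
                             prescription = prescription_config(),
                             geometric = geometric_roles(),
                             targets = target_roles(),
                             body_threshold = c("elective", "target")) {
  body_threshold <- match.arg(body_threshold)
  geometric <- intersect(geometric, names(session$contours_clin$masks))
  targets <- intersect(targets, names(session$contours_clin$masks))
  geo <- do.call(rbind, lapply(geometric, function(role)
    geometric_record(session, role)))
  dos <- do.call(rbind, unlist(lapply(targets, function(role)
    lapply(c("D_clin", "D_auto"), function(arm)
      dosimetric_record(session, role, arm, prescription,
                        body_threshold = body_threshold))),
    recursive = FALSE))
  row <- data.frame(patient_id = session$patient_id,
                    fraction = session$fraction,
                    stringsAsFactors = FALSE)
  for (role in names(session$corrections))
    row[[paste0("corrected_", role)]] <- unname(session$corrections[[role]])
  for (role in influencer_roles()) {
    rv <- session$reference_volumes[[role]]
    m <- session$contours_clin$masks[[role]]
    row[[paste0("dv_", role)]] <-
      if (!is.null(m) && !is.na(rv)) volume_difference(rv, m) else NA_real_
  }
  for (role in intersect(c("CTV_boost", "CTV_elective"), targets)) {
    for (arm in c("D_clin", "D_auto")) {
      hit <- dos$structure == role & dos$arm == arm
      suffix <- if (arm == "D_auto") role else paste0(role, "_clin")
      row[[paste0("meets_", suffix)]] <- dos$meets_requirement[hit]
    }
  }
  list(geometric = geo, dosimetric = dos, session_row = row)
}

wilcoxon_family <- function(dosimetric, targets, stats_cfg) {
  out <- list()
  for (role in targets) {
    for (metric in c("v95_percent", "v95_out_abs")) {
      sub <- dosimetric[dosimetric$structure == role, ]
      key <- paste(sub$patient_id, sub$fraction)
      clin <- sub[sub$arm == "D_clin", ]
      auto <- sub[sub$arm == "D_auto", ]
      auto <- auto[match(paste(clin$patient_id, clin$fraction),
                         paste(auto$patient_id, auto$fraction)), ]
      res <- tryCatch(
        wilcoxon_signed_rank(clin[[metric]], auto[[metric]], stats_cfg),
        error = function(e) list(statistic = NA_real_, p_value = NA_real_,
                                 n = nrow(clin), n_effective = 0L,
                                 n_zero = nrow(clin), method = "degenerate",
                                 significant = FALSE,
                                 corrected_alpha = stats_cfg$corrected_alpha))
      out[[length(out) + 1L]] <- data.frame(
        structure = role, metric = metric, W = res$statistic,
        p_value = res$p_value, n_effective = res$n_effective,
        n_zero = res$n_zero, method = res$method,
        significant = res$significant, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Run the cohort evaluation
#'
#' Binds the pipeline stages into the two-arm evaluation: per-session
#' geometric and dosimetric records, median-and-range cohort summaries,
#' paired Wilcoxon signed-rank tests between the dose arms at the
#' Bonferroni-corrected level, manual-correction frequencies, requirement
#' pass rates under the automatic dose, and coverage-failure tables
#' stratified by influencer volume change.
#'
#' @param input one of: a list of `rt_session` objects, a character vector
#'   of bundle manifest paths, or a [phantom_config()] (sessions are then
#'   generated on the fly, which keeps memory flat for full cohorts).
#' @param prescription a [prescription_config()].
#' @param stats_cfg a [stats_config()].
#' @param strat_cfg a [stratification_config()].
#' @param body_threshold see [dosimetric_record()].
#' @param skip_invalid drop sessions failing validation (with a warning)
#'   instead of failing fast. Default FALSE: a silently dropped session
#'   would bias the cohort percentages.
#' @param out_dir if set, [write_report()] is called on the result.
#' @return object of class `rt_evaluation`: `geometric`, `dosimetric`,
#'   `sessions` (per-session metadata), `tests`, `summary` (nested list as
#'   written to JSON), `truth` (synthetic runs only).
#' @export
run_evaluation <- function(input,
                           prescription = prescription_config(),
                           stats_cfg = stats_config(),
                           strat_cfg = stratification_config(),
                           body_threshold = c("elective", "target"),
                           skip_invalid = FALSE,
                           out_dir = NULL) {
  body_threshold <- match.arg(body_threshold)
  truth <- NULL
  if (inherits(input, "phantom_config")) {
    cfg <- input
    n <- cfg$patients * cfg$fractions
    getter <- function(i) {
      pt <- (i - 1L) %/% cfg$fractions + 1L
      fx <- (i - 1L) %% cfg$fractions + 1L
      g <- generate_session(cfg, pt, fx, prescription)
      truth[[i]] <<- g$truth
      g$session
    }
    truth <- vector("list", n)
  } else if (is.character(input)) {
    n <- length(input)
    getter <- function(i) read_session(input[i])
  } else {
    n <- length(input)
    # in-memory sessions may have been modified after construction
    getter <- function(i) validate_session(input[[i]])
  }

  geo <- dos <- rows <- vector("list", n)
  kept <- logical(n)
  for (i in seq_len(n)) {
    sess <- tryCatch(getter(i), error = function(e) e)
    if (inherits(sess, "error")) {
      if (skip_invalid) {
        warning("skipping session ", i, ": ", conditionMessage(sess),
                call. = FALSE)
        next
      }
      stop(conditionMessage(sess), call. = FALSE)
    }
    ev <- evaluate_session(sess, prescription,
                           body_threshold = body_threshold)
    geo[[i]] <- ev$geometric
    dos[[i]] <- ev$dosimetric
    rows[[i]] <- ev$session_row
    kept[i] <- TRUE
  }
  geometric <- do.call(rbind, geo[kept])
  dosimetric <- do.call(rbind, dos[kept])
  sessions <- do.call(rbind, rows[kept])
  if (is.null(geometric))
    geometric <- geometric_record_skeleton()
  if (is.null(dosimetric))
    dosimetric <- dosimetric_record_skeleton()
  if (is.null(sessions)) sessions <- data.frame()
  if (!is.null(truth)) truth <- do.call(rbind, truth[kept])

  targets <- unique(dosimetric$structure)
  tests <- if (nrow(dosimetric)) {
    wilcoxon_family(dosimetric, targets, stats_cfg)
  } else {
    data.frame()
  }

  summary <- build_summary(geometric, dosimetric, sessions, tests,
                           prescription, stats_cfg, strat_cfg)
  res <- structure(list(geometric = geometric, dosimetric = dosimetric,
                        sessions = sessions,
                        tests = tests, summary = summary, truth = truth,
                        prescription = prescription,
                        stats_config = stats_cfg,
                        stratification_config = strat_cfg),
                   class = "rt_evaluation")
  if (!is.null(out_dir)) write_report(res, out_dir)
  res
}

geometric_record_skeleton <- function() {
  data.frame(patient_id = character(), fraction = integer(),
             structure = character(), dsc = numeric(),
             relative_volume = numeric(), hd95 = numeric(), mda = numeric(),
             v_auto = numeric(), v_clin = numeric(),
             stringsAsFactors = FALSE)
}

dosimetric_record_skeleton <- function() {
  data.frame(patient_id = character(), fraction = integer(),
             structure = character(), arm = character(),
             v95_percent = numeric(), v95_abs = numeric(),
             v95_body_abs = numeric(), v95_out_abs = numeric(),
             meets_requirement = logical(),
             n_outside_dose_grid = integer(), stringsAsFactors = FALSE)
}

build_summary <- function(geometric, dosimetric, sessions, tests,
                          prescription, stats_cfg, strat_cfg) {
  geo_sum <- list()
  for (role in unique(geometric$structure)) {
    sub <- geometric[geometric$structure == role, ]
    geo_sum[[role]] <- lapply(
      c(dsc = "dsc", relative_volume = "relative_volume",
        hd95 = "hd95", mda = "mda"),
      function(col) {
        s <- summarize_metric(sub[[col]])
        list(median = unname(s[["median"]]), min = unname(s[["min"]]),
             max = unname(s[["max"]]), formatted = fmt_summary(s))
      })
  }
  dos_sum <- list()
  for (role in unique(dosimetric$structure)) {
    dos_sum[[role]] <- list()
    for (arm in c("D_clin", "D_auto")) {
      sub <- dosimetric[dosimetric$structure == role &
                          dosimetric$arm == arm, ]
      if (!nrow(sub)) next
      dos_sum[[role]][[arm]] <- lapply(
        c(v95_percent = "v95_percent", v95_out_abs = "v95_out_abs"),
        function(col) {
          s <- summarize_metric(sub[[col]])
          list(median = unname(s[["median"]]), min = unname(s[["min"]]),
               max = unname(s[["max"]]), formatted = fmt_summary(s))
        })
      dos_sum[[role]][[arm]]$pct_meeting_requirement <-
        100 * mean(sub$meets_requirement)
    }
  }
  corr_cols <- grep("^corrected_", names(sessions), value = TRUE)
  corr <- if (length(corr_cols) && nrow(sessions)) {
    cf <- correction_frequencies(sessions[, corr_cols, drop = FALSE])
    names(cf) <- sub("^corrected_", "", names(cf))
    as.list(cf)
  } else {
    NULL
  }
  strata <- list()
  if (nrow(sessions)) {
    for (target in intersect(c("CTV_boost", "CTV_elective"),
                             unique(dosimetric$structure))) {
      for (inf in influencer_roles()) {
        mc <- paste0("meets_", target)
        dc <- paste0("dv_", inf)
        if (all(c(mc, dc) %in% names(sessions)) &&
            !anyNA(sessions[[dc]])) {
          tb <- failure_table(sessions, target, inf, strat_cfg)
          strata[[paste(target, "by", inf, sep = "_")]] <-
            as.list(as.data.frame(tb))
        }
      }
    }
  }
  test_list <- if (nrow(tests)) as.list(as.data.frame(tests)) else NULL
  list(n_sessions = if (is.null(sessions)) 0L else nrow(sessions),
       prescription = unclass(prescription),
       corrected_alpha = stats_cfg$corrected_alpha,
       geometric = geo_sum, dosimetric = dos_sum,
       correction_frequencies_pct = corr,
       wilcoxon_tests = test_list,
       stratification = strata)
}

#' @export
print.rt_evaluation <- function(x, ...) {
  cat(sprintf("<rt_evaluation> %d sessions\n", x$summary$n_sessions))
  for (role in names(x$summary$geometric)) {
    g <- x$summary$geometric[[role]]
    cat(sprintf("  %-12s DSC %s  relVol%% %s  95%%HD %s mm  MDA %s mm\n",
                role, g$dsc$formatted, g$relative_volume$formatted,
                g$hd95$formatted, g$mda$formatted))
  }
  for (role in names(x$summary$dosimetric)) {
    d <- x$summary$dosimetric[[role]]
    if (!is.null(d$D_auto))
      cat(sprintf("  %-12s V95%% D_auto %s (meets req: %.1f%%)\n",
                  role, d$D_auto$v95_percent$formatted,
                  d$D_auto$pct_meeting_requirement))
  }
  invisible(x)
}
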