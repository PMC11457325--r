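#' Median and range summary
#'
#' The cohort reporting convention: median with the observed range
#' (`median [min-max]`). The median of an even-length sample is the
#' midpoint of the two central order statistics.
#'
#' @param values non-empty numeric vector.
#' @return named numeric `c(median, min, max)`.
#' @export
summarize_metric <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("summary of an empty sample", call. = FALSE)
  c(median = stats::median(values), min = min(values), max = max(values))
}

# Exact null distribution of the positive signed-rank sum, with average
# ranks for ties. Ranks are doubled so tied (half-integer) ranks become
# integers; returns list(support_step = 0.5, probs) where probs[w + 1] is
# P(2*S+ = w) for w = 0..sum(2r), computed by the generating-function
# convolution prod_i (1 + x^{2 r_i}) / 2^n — identical to enumerating all
# 2^n sign assignments.
signed_rank_null <- function(ranks2) {
  total <- sum(ranks2)
  probs <- numeric(total + 1)
  probs[1] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), probs[seq_len(total + 1 - r)])
    probs <- (probs + shifted) / 2
  }
  probs
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired test of `values_auto` against `values_clin`. Zero
#' differences are discarded (classical convention); absolute differences
#' are ranked with average ranks for ties; the statistic `W` is the smaller
#' of the positive and negative rank sums. For at most `exact_n_max`
#' non-zero differences the p-value is exact, from the full null
#' distribution of the rank sum over all sign assignments (computed by
#' convolution, which handles ties exactly); above that a tie-corrected
#' normal approximation with continuity correction is used.
#'
#' @param values_clin,values_auto index-aligned paired measurements.
#' @param config a [stats_config()].
#' @return list of class `signed_rank_test`: `statistic` (W), `p_value`,
#'   `n`, `n_effective`, `n_zero`, `method` (`"exact"` or
#'   `"normal_approx"`), `significant` (at the Bonferroni-corrected alpha),
#'   `corrected_alpha`.
#' @export
wilcoxon_signed_rank <- function(values_clin, values_auto,
                                 config = stats_config()) {
  if (length(values_clin) != length(values_auto))
    stop("paired samples must have equal length", call. = FALSE)
  d <- values_auto - values_clin
  d <- d[!is.na(d)]
  n <- length(d)
  nz <- d[d != 0]
  n_eff <- length(nz)
  if (n_eff == 0L)
    stop("signed-rank test undefined: all differences are zero",
         call. = FALSE)
  r <- rank(abs(nz))
  w_pos <- sum(r[nz > 0])
  w_neg <- sum(r[nz < 0])
  w <- min(w_pos, w_neg)
  total <- n_eff * (n_eff + 1) / 2
  if (n_eff <= config$exact_n_max) {
    method <- "exact"
    ranks2 <- as.integer(round(2 * r))
    probs <- signed_rank_null(ranks2)
    w2 <- as.integer(round(2 * w))
    total2 <- sum(ranks2)
    if (2L * w2 == total2) {
      p <- 1
    } else {
      # two-sided: both tails, symmetric null
      p <- min(1, sum(probs[seq_len(w2 + 1)]) +
                  sum(probs[seq(total2 + 1 - w2, total2 + 1)]))
    }
  } else {
    method <- "normal_approx"
    mu <- total / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (w - mu + 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(z))
  }
  structure(list(statistic = w, p_value = p, n = n, n_effective = n_eff,
                 n_zero = n - n_eff, method = method,
                 significant = p < config$corrected_alpha,
                 corrected_alpha = config$corrected_alpha),
            class = "signed_rank_test")
}

#' @export
print.signed_rank_test <- function(x, ...) {
  cat(sprintf(
    "Paired Wilcoxon signed-rank: W = %g, n_eff = %d (%s), p = %.4g%s\n",
    x$statistic, x$n_effective, x$method, x$p_value,
    if (x$significant) sprintf(" (significant at %.4g)", x$corrected_alpha)
    else ""))
  invisible(x)
}

#' Bonferroni-corrected significance level
#'
#' @param alpha family-wise level, in (0, 1).
#' @param m family size (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni(0.05, 10) # 0.005, i.e. a corrected level of 0.5%
#' @export
bonferroni <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Manual-correction frequencies across sessions
#'
#' Percent of sessions in which each role's automatically proposed contour
#' was manually adjusted in the clinic, plus the percent of sessions with
#' no adjustment to any delineation.
#'
#' @param corrections data.frame or matrix of logicals, one row per session,
#'   one column per role.
#' @return named numeric vector of percentages; the last element `none` is
#'   the no-adjustment share.
#' @export
correction_frequencies <- function(corrections) {
  m <- as.matrix(corrections)
  if (!is.logical(m)) storage.mode(m) <- "logical"
  n <- nrow(m)
  if (n == 0L) stop("no sessions", call. = FALSE)
  per_role <- 100 * colSums(m) / n
  c(per_role, none = 100 * sum(rowSums(m) == 0) / n)
}
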