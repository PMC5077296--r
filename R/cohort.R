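#' Classify a recording as active, silent or excluded
#'
#' Only recordings lasting more than 60 s are included; this duration
#' threshold caps the firing rate still compatible with a "silent" call at
#' 1/60 Hz (about 0.016 Hz, i.e. less than one spike per minute). Included
#' recordings with a mean rate below 1/60 Hz are silent, the rest active —
#' the rule is rate-based, so a long recording with a handful of spikes can
#' still be silent.
#'
#' @param spikes A \code{\link{spike_train}}.
#' @param cfg A \code{\link{run_config}} (field \code{min_duration_s}).
#' @return One of \code{"active"}, \code{"silent"}, \code{"excluded"}.
#' @export
classify_activity <- function(spikes, cfg = run_config()) {
  dur <- spikes$t_end - spikes$t_start
  classify_activity_rate(length(spikes$times), dur, cfg)
}

classify_activity_rate <- function(n_spikes, duration_s, cfg = run_config()) {
  if (duration_s <= cfg$min_duration_s) return("excluded")
  rate <- n_spikes / duration_s
  if (rate < silent_rate_bound_hz(cfg)) "silent" else "active"
}

#' Silent-cell firing-rate bound
#'
#' The largest firing rate still classified as silent: one spike per minimum
#' included duration, 1/60 Hz (0.016 Hz to the precision usually printed).
#'
#' @param cfg A \code{\link{run_config}}.
#' @return Rate bound in Hz.
#' @export
silent_rate_bound_hz <- function(cfg = run_config()) {
  1 / cfg$min_duration_s
}

#' Cohort activity proportions
#'
#' @param table A \code{cohort_table} (see \code{\link{read_cohort_csv}}) or
#'   any data.frame with an \code{activity_class} column.
#' @return List with \code{n_active}, \code{n_silent}, \code{n_excluded},
#'   \code{n_total} (included recordings) and \code{pct_active} (percentage,
#'   one decimal).
#' @export
cohort_proportions <- function(table) {
  if (!nrow(table)) stop("empty cohort table")
  cls <- table$activity_class
  n_act <- sum(cls == "active")
  n_sil <- sum(cls == "silent")
  n_exc <- sum(cls == "excluded")
  tot <- n_act + n_sil
  if (!tot) stop("no included recordings in cohort")
  list(n_active = n_act, n_silent = n_sil, n_excluded = n_exc,
       n_total = tot, pct_active = round(100 * n_act / tot, 1))
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Conditional hypergeometric exact test; the two-sided p-value is the sum
#' of the probabilities of all tables (with the margins fixed) that are no
#' more probable than the observed one.
#'
#' @param a,b,c,d Non-negative integer counts (rows = condition, columns =
#'   active/silent), or a single 2x2 matrix in \code{a}.
#' @return List with \code{odds_ratio} (conditional MLE) and \code{p}
#'   (two-sided). A zero margin yields p = 1 by convention.
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  m <- if (is.matrix(a)) a else matrix(c(a, c, b, d), 2)
  stopifnot(all(m >= 0), sum(m) > 0)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(odds_ratio = NA_real_, p = 1))
  }
  ft <- stats::fisher.test(m)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Two-sided Mann-Whitney test
#'
#' Exact enumeration when both groups have at most 8 observations and no
#' ties are present (matching the group sizes of the identified-cell
#' comparisons); the normal approximation with tie correction otherwise.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_max Largest group size for the exact test (default 8).
#' @return List with \code{U} (statistic for \code{x} vs \code{y}) and
#'   \code{p} (two-sided).
#' @export
mannwhitney_2s <- function(x, y, exact_max = 8) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value)
}
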