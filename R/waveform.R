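#' Centered moving average with shrink-to-valid edges
#'
#' @param x Numeric vector.
#' @param win_samples Window length in samples (coerced to an odd integer).
#' @return Numeric vector of the same length; near the ends the window is
#'   truncated to the valid range (no padding).
#' @keywords internal
moving_average <- function(x, win_samples) {
  n <- length(x)
  half <- max(0L, as.integer(floor(win_samples / 2)))
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

ms_to_samples <- function(ms, dt_ms) max(1L, as.integer(round(ms / dt_ms)))

#' Average peak-aligned spike snippets
#'
#' Pointwise mean of equal-length, peak-aligned spike snippets, then
#' peak-normalized so the maximum equals 1. Shoulder analysis is always
#' performed on such average traces.
#'
#' @param traces A numeric matrix (snippets in rows), a list of equal-length
#'   numeric vectors, or a list of \code{\link{waveform}} objects with a
#'   common \code{dt_ms}.
#' @param dt_ms Sample interval in ms (taken from the waveforms if omitted).
#' @param ... Passed to \code{\link{waveform}} (label, cell_id).
#' @return A peak-normalized \code{\link{waveform}}.
#' @export
average_spikes <- function(traces, dt_ms = NULL, ...) {
  if (is.list(traces) && length(traces) && inherits(traces[[1]], "waveform")) {
    dts <- vapply(traces, `[[`, numeric(1), "dt_ms")
    if (length(unique(dts)) != 1) stop("waveforms have mismatched dt_ms")
    if (is.null(dt_ms)) dt_ms <- dts[1]
    traces <- lapply(traces, `[[`, "samples")
  }
  if (is.list(traces)) {
    if (length(unique(lengths(traces))) != 1) {
      stop("spike snippets have mismatched lengths")
    }
    traces <- do.call(rbind, traces)
  }
  traces <- as.matrix(traces)
  if (is.null(dt_ms)) stop("dt_ms required when traces are raw vectors")
  avg <- colMeans(traces)
  pk <- max(avg)
  if (pk <= 0) stop("average trace has no positive peak")
  waveform(avg / pk, dt_ms = dt_ms, ...)
}

#' Detect a repolarization shoulder on an average spike waveform
#'
#' Implements the moving-average detection of a spike "shoulder" — a
#' transient deceleration on the repolarizing phase of the juxtacellular
#' spike that is a correlate of granule-cell identity. The search window
#' runs from the spike peak to the spike offset (the first sample at or
#' below \code{offset_frac} of the peak). The trace is compared with its
#' centered moving average (window \code{ma_win_ms}); excluding a guard of
#' half the averaging window right after the peak (where the locally concave
#' peak trivially exceeds its average), the first sample at which the trace
#' crosses its moving average from below marks a shoulder. When one is
#' found, the trace and its first derivative are smoothed (window
#' \code{deriv_smooth_ms}) and the local maximum of the derivative nearest
#' the intersection is quantified by its half-width — the width at half of
#' the local maximum's prominence above the surrounding derivative baseline
#' (the derivative is negative throughout the repolarization, so prominence,
#' not raw height, is the meaningful scale).
#'
#' The result is invariant under positive rescaling of the trace amplitude.
#'
#' @param wf A \code{\link{waveform}} with a unique positive global peak and
#'   at least 0.5 ms of samples after the peak.
#' @param cfg A \code{\link{run_config}} (fields \code{ma_win_ms},
#'   \code{offset_frac}, \code{deriv_smooth_ms}).
#'
#' @return An object of class \code{shoulder_result}: list with
#'   \code{detected}, \code{intersection_latency_ms} (spike peak to
#'   trace/moving-average intersection, linearly interpolated),
#'   \code{shoulder_width_ms} and \code{spike_width_ms}. Latency and
#'   shoulder width are \code{NA} when no shoulder is detected.
#' @export
detect_shoulder <- function(wf, cfg = run_config()) {
  stopifnot(inherits(wf, "waveform"))
  x <- wf$samples
  dt <- wf$dt_ms
  if (max(x) <= min(x)) stop("flat trace")
  p <- which(x == max(x))
  if (length(p) > 1) stop("spike peak is not unique")
  if (x[p] <= 0) stop("waveform must have a positive peak")
  if ((length(x) - p) * dt < 0.5) {
    stop("fewer than 0.5 ms of samples after the peak")
  }

  offset_level <- cfg$offset_frac * x[p]
  after <- seq.int(p, length(x))
  off_rel <- which(x[after] <= offset_level)
  if (!length(off_rel)) stop("truncated repolarization: trace never falls to offset")
  off_i <- after[off_rel[1]]

  ma_w <- ms_to_samples(cfg$ma_win_ms, dt)
  ma <- moving_average(x, ma_w)
  guard <- as.integer(ceiling((cfg$ma_win_ms / 2) / dt))
  scan_from <- min(p + guard, off_i)

  d <- x - ma
  cross_i <- NA_integer_
  i <- max(scan_from, p + 1L) + 1L
  while (i <= off_i) {
    if (d[i - 1] < 0 && d[i] >= 0) {
      cross_i <- i
      break
    }
    i <- i + 1L
  }

  sw <- spike_width(wf)
  if (is.na(cross_i)) {
    return(structure(list(detected = FALSE,
                          intersection_latency_ms = NA_real_,
                          shoulder_width_ms = NA_real_,
                          spike_width_ms = sw),
                     class = "shoulder_result"))
  }
  # linear interpolation of the zero crossing of (trace - moving average)
  frac <- if (d[cross_i] == d[cross_i - 1]) 0 else
    -d[cross_i - 1] / (d[cross_i] - d[cross_i - 1])
  t_cross <- (cross_i - 1 - 1 + frac) * dt  # time of sample 1 is 0
  latency <- t_cross - (p - 1) * dt

  width <- shoulder_halfwidth(x, dt, p, off_i, cross_i, cfg)

  structure(list(detected = TRUE,
                 intersection_latency_ms = latency,
                 shoulder_width_ms = width,
                 spike_width_ms = sw),
            class = "shoulder_result")
}

# Half-width of the derivative local maximum in the shoulder region,
# measured at half of its prominence above the surrounding derivative
# baseline (higher of the flanking minima within the search window).
# The central difference of the boxcar-smoothed trace is itself smoothed
# with the same window, so one smoothing pass covers trace and derivative.
shoulder_halfwidth <- function(x, dt, p, off_i, cross_i, cfg) {
  n <- length(x)
  smoothed_deriv <- function(win_samples) {
    xs <- if (win_samples > 1) moving_average(x, win_samples) else x
    der <- c(NA, (xs[3:n] - xs[1:(n - 2)]) / (2 * dt), NA)
    der[1] <- der[2]; der[n] <- der[n - 1]
    der
  }
  win <- seq.int(p, min(off_i + 1L, n))

  width_from <- function(der) {
    dw <- der[win]
    k <- length(dw)
    if (k < 3) return(NULL)
    is_max <- vapply(2:(k - 1), function(j) {
      dw[j] >= dw[j - 1] && dw[j] >= dw[j + 1] &&
        (dw[j] > dw[j - 1] || dw[j] > dw[j + 1])
    }, logical(1))
    cand <- which(is_max) + 1L
    if (!length(cand)) return(NULL)
    m_rel <- cand[which.min(abs(win[cand] - cross_i))]
    left_min <- min(dw[1:m_rel])
    right_min <- min(dw[m_rel:k])
    prominence <- dw[m_rel] - max(left_min, right_min)
    if (prominence <= 0) return(NULL)
    half_level <- dw[m_rel] - prominence / 2
    cross_at <- function(idx_path) {
      # first crossing of half_level walking away from the maximum
      for (a in seq_along(idx_path)[-1]) {
        j0 <- idx_path[a - 1]; j1 <- idx_path[a]
        if ((dw[j0] - half_level) > 0 && (dw[j1] - half_level) <= 0) {
          fr <- (dw[j0] - half_level) / (dw[j0] - dw[j1])
          return((j0 - 1) + fr * (j1 - j0))
        }
      }
      idx_path[length(idx_path)] - 1  # clamp at window edge
    }
    left_pos <- cross_at(seq.int(m_rel, 1L))
    right_pos <- cross_at(seq.int(m_rel, k))
    max((right_pos - left_pos) * dt, dt)
  }

  # local maximum of the smoothed derivative; a shoulder narrower than the
  # smoothing window may leave no resolvable local maximum, in which case
  # the width is reported at the sampling-resolution floor
  w <- width_from(smoothed_deriv(ms_to_samples(cfg$deriv_smooth_ms, dt)))
  if (is.null(w)) w <- dt
  w
}

#' Spike half-width
#'
#' Width of the spike at half of its peak amplitude, with linear
#' interpolation between the samples bracketing the half-maximum crossings
#' on each flank. Fast-spiking interneurons in this preparation are
#' characterized by half-widths below 0.2 ms.
#'
#' @param wf A \code{\link{waveform}} with a unique positive global peak.
#' @return Half-width in ms.
#' @export
spike_width <- function(wf) {
  stopifnot(inherits(wf, "waveform"))
  x <- wf$samples
  dt <- wf$dt_ms
  p <- which(x == max(x))
  if (length(p) > 1) stop("spike peak is not unique")
  if (x[p] <= 0) stop("waveform must have a positive peak")
  half <- x[p] / 2

  left <- NA_real_
  for (i in seq.int(p, 2L)) {
    if (x[i - 1] < half && x[i] >= half) {
      fr <- (half - x[i - 1]) / (x[i] - x[i - 1])
      left <- (i - 1 - 1) + fr
      break
    }
  }
  right <- NA_real_
  for (i in seq.int(p, length(x) - 1L)) {
    if (x[i] >= half && x[i + 1] < half) {
      fr <- (x[i] - half) / (x[i] - x[i + 1])
      right <- (i - 1) + fr
      break
    }
  }
  if (is.na(left) || is.na(right)) {
    stop("half-maximum never crossed on one side of the peak")
  }
  (right - left) * dt
}

#' Correlation between spike width and shoulder width
#'
#' Pearson correlation (with two-sided p-value) between the spike half-width
#' and the shoulder half-width across cells in which a shoulder was
#' detected.
#'
#' @param results List of \code{shoulder_result} objects.
#' @return List with \code{r}, \code{p}, \code{n} and the fitted regression
#'   slope/intercept of shoulder width on spike width.
#' @export
shoulder_width_correlation <- function(results) {
  det <- Filter(function(r) isTRUE(r$detected), results)
  if (length(det) < 3) stop("need at least 3 cells with detected shoulders")
  sw <- vapply(det, `[[`, numeric(1), "spike_width_ms")
  shw <- vapply(det, `[[`, numeric(1), "shoulder_width_ms")
  if (stats::sd(sw) == 0 || stats::sd(shw) == 0) {
    stop("zero variance in spike width or shoulder width")
  }
  ct <- stats::cor.test(sw, shw, method = "pearson")
  fit <- stats::lm(shw ~ sw)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(det),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' @export
print.shoulder_result <- function(x, ...) {
  if (x$detected) {
    cat(sprintf(paste0("<shoulder_result> detected; latency %.3f ms, ",
                       "shoulder width %.3f ms, spike width %.3f ms\n"),
                x$intersection_latency_ms, x$shoulder_width_ms,
                x$spike_width_ms))
  } else {
    cat(sprintf("<shoulder_result> no shoulder; spike width %.3f ms\n",
                x$spike_width_ms))
  }
  invisible(x)
}
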