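#' Analysis configuration
#'
#' Bundles every tunable of the pipeline with its default value. Defaults
#' reproduce the published analysis settings: 2.5 cm rate-map pixels with a
#' sigma = 2.5 cm Gaussian kernel, 20 ms minimum pixel occupancy, a 1 cm/s
#' running-speed threshold computed on 600 ms boxcar-smoothed coordinates,
#' 70% minimum spatial coverage, inclusion thresholds of > 25 spikes and
#' > 0.1 Hz mean rate, place fields of at least 12 contiguous pixels above
#' 20% of the map peak accounting for < 20% of visited pixels when
#' "selective", a 0.25 ms moving-average window and 10%-of-peak spike offset
#' for shoulder detection, > 60 s recording inclusion, a 10-unit hidden layer
#' with early stopping after 6 validation failures for the waveform
#' classifier, and elastic-net mixing values 0.05, 0.1, 0.5, 0.9, 0.95 with
#' 500 permutation runs for the morphology classifier.
#'
#' @param ... Named overrides of any default listed below.
#'
#' @return An object of class \code{gc_config}: a named list with elements
#'   \code{pixel_cm}, \code{sigma_cm}, \code{occ_min_ms},
#'   \code{speed_thresh_cm_s}, \code{speed_win_ms}, \code{coverage_min},
#'   \code{min_spikes}, \code{min_rate_hz}, \code{field_min_pixels},
#'   \code{field_frac_of_peak}, \code{selective_max_field_frac},
#'   \code{field_connectivity}, \code{ma_win_ms}, \code{offset_frac},
#'   \code{deriv_smooth_ms}, \code{min_duration_s}, \code{nn_hidden},
#'   \code{nn_max_val_fail}, \code{nn_val_frac}, \code{nn_max_epochs},
#'   \code{resample_len}, \code{enet_alphas}, \code{enet_nlambda},
#'   \code{enet_lambda_min_ratio}, \code{perm_runs}, \code{perm_alpha},
#'   \code{inner_loo_max_n}, \code{rng_seed}.
#' @export
#' @examples
#' cfg <- run_config(perm_runs = 100, rng_seed = 7)
#' cfg$sigma_cm
run_config <- function(...) {
  cfg <- list(
    # spatial analysis
    pixel_cm = 2.5,
    sigma_cm = 2.5,
    occ_min_ms = 20,
    speed_thresh_cm_s = 1,
    speed_win_ms = 600,
    coverage_min = 0.70,
    min_spikes = 25,
    min_rate_hz = 0.1,
    field_min_pixels = 12,
    field_frac_of_peak = 0.20,
    selective_max_field_frac = 0.20,
    field_connectivity = 8L,
    # shoulder detection
    ma_win_ms = 0.25,
    offset_frac = 0.10,
    deriv_smooth_ms = 0.2,
    # cohort inclusion
    min_duration_s = 60,
    # waveform neural-network classifier
    nn_hidden = 10L,
    nn_max_val_fail = 6L,
    nn_val_frac = 0.15,
    nn_max_epochs = 300L,
    resample_len = 64L,
    # sparse logistic (elastic-net) classifier
    enet_alphas = c(0.05, 0.1, 0.5, 0.9, 0.95),
    enet_nlambda = 100L,
    enet_lambda_min_ratio = 1e-4,
    perm_runs = 500L,
    perm_alpha = 0.1,
    inner_loo_max_n = 20L,
    rng_seed = 0L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) {
      stop("unknown config field(s): ", paste(bad, collapse = ", "))
    }
    cfg[names(over)] <- over
  }
  stopifnot(
    cfg$pixel_cm > 0, cfg$sigma_cm > 0, cfg$occ_min_ms > 0,
    cfg$speed_win_ms > 0, cfg$coverage_min > 0, cfg$coverage_min < 1,
    cfg$field_frac_of_peak > 0, cfg$field_frac_of_peak < 1,
    cfg$selective_max_field_frac > 0, cfg$selective_max_field_frac < 1,
    cfg$ma_win_ms > 0, cfg$offset_frac > 0, cfg$offset_frac < 1,
    cfg$deriv_smooth_ms > 0, cfg$min_duration_s > 0,
    cfg$nn_hidden >= 1, cfg$nn_val_frac > 0, cfg$nn_val_frac < 1,
    all(cfg$enet_alphas > 0), all(cfg$enet_alphas <= 1),
    cfg$perm_runs >= 1,
    cfg$field_connectivity %in% c(4L, 8L)
  )
  class(cfg) <- "gc_config"
  cfg
}

#' @export
print.gc_config <- function(x, ...) {
  cat("<gc_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

#' Average spike waveform
#'
#' Container for a uniformly sampled average spike trace.
#'
#' @param samples Numeric vector of voltage values (arbitrary units),
#'   length >= 16.
#' @param dt_ms Sample interval in milliseconds (> 0).
#' @param label Optional cell-class tag, one of \code{"GC"}, \code{"hilar"},
#'   \code{"CA3c"}, \code{"FS"}, \code{"unknown"}.
#' @param cell_id Optional cell identifier.
#' @param meta Optional list of generator metadata (e.g. ground-truth
#'   shoulder parameters for synthetic traces).
#'
#' @return An object of class \code{waveform}.
#' @export
waveform <- function(samples, dt_ms, label = "unknown", cell_id = "",
                     meta = list()) {
  samples <- as.numeric(samples)
  if (length(samples) < 16) stop("waveform must have at least 16 samples")
  if (!is.finite(dt_ms) || dt_ms <= 0) stop("dt_ms must be > 0")
  label <- match.arg(label, c("unknown", "GC", "hilar", "CA3c", "FS"))
  structure(
    list(samples = samples, dt_ms = dt_ms, label = label,
         cell_id = as.character(cell_id), meta = meta),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf(
    "<waveform> %d samples @ %.4g kHz, %.3g ms span, label=%s%s\n",
    length(x$samples), 1 / x$dt_ms, (length(x$samples) - 1) * x$dt_ms,
    x$label, if (nzchar(x$cell_id)) paste0(", id=", x$cell_id) else ""
  ))
  invisible(x)
}

#' @export
plot.waveform <- function(x, ...) {
  t_ms <- (seq_along(x$samples) - 1) * x$dt_ms
  graphics::plot(t_ms, x$samples, type = "l", xlab = "time (ms)",
                 ylab = "amplitude (a.u.)", ...)
  invisible(x)
}

#' Spike train
#'
#' @param times Strictly increasing spike timestamps in seconds (may be
#'   empty).
#' @param t_start,t_end Recording bounds in seconds, \code{t_end > t_start};
#'   all spike times must lie within them.
#'
#' @return An object of class \code{spike_train}.
#' @export
spike_train <- function(times, t_start, t_end) {
  times <- as.numeric(times)
  if (t_end <= t_start) stop("t_end must exceed t_start")
  if (length(times)) {
    if (is.unsorted(times, strictly = TRUE)) {
      stop("spike times must be strictly increasing")
    }
    if (times[1] < t_start || times[length(times)] > t_end) {
      stop("spike times outside [t_start, t_end]")
    }
  }
  structure(list(times = times, t_start = t_start, t_end = t_end),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  dur <- x$t_end - x$t_start
  cat(sprintf("<spike_train> %d spikes over %.1f s (%.3g Hz)\n",
              length(x$times), dur, length(x$times) / dur))
  invisible(x)
}

#' Arena geometry descriptor
#'
#' @param shape One of \code{"square"} (walled square open field),
#'   \code{"wallless_rect"} (wall-less rectangular platform) or
#'   \code{"o_maze"} (elevated annular maze).
#' @param width_cm,height_cm Outer bounding-box dimensions in cm. Defaults
#'   follow the recording arenas: 70 x 70 cm square, 55 x 65 cm wall-less
#'   platform, 70 x 50 cm O-maze.
#' @param path_width_cm Path width for the O-maze (default 14 cm); ignored
#'   otherwise.
#'
#' @return An object of class \code{arena}.
#' @export
arena <- function(shape = c("square", "wallless_rect", "o_maze"),
                  width_cm = NULL, height_cm = NULL, path_width_cm = 14) {
  shape <- match.arg(shape)
  dims <- switch(shape,
    square = c(70, 70),
    wallless_rect = c(55, 65),
    o_maze = c(70, 50)
  )
  if (!is.null(width_cm)) dims[1] <- width_cm
  if (!is.null(height_cm)) dims[2] <- height_cm
  stopifnot(all(dims > 0))
  structure(list(shape = shape, width_cm = dims[1], height_cm = dims[2],
                 path_width_cm = path_width_cm),
            class = "arena")
}

#' @export
print.arena <- function(x, ...) {
  cat(sprintf("<arena> %s %g x %g cm\n", x$shape, x$width_cm, x$height_cm))
  invisible(x)
}

#' Animal tracking data
#'
#' Positions are in cm in the arena frame, origin at the arena's lower-left
#' bounding-box corner. The animal position is the midpoint of the two
#' head-mounted LEDs where both are valid; frames with any missing LED are
#' flagged invalid and excluded downstream.
#'
#' @param t Strictly increasing frame timestamps in seconds (nominal 25 Hz).
#' @param led1_xy,led2_xy Two-column matrices of LED coordinates in cm;
#'   \code{led2_xy} may be \code{NULL} for single-point tracking.
#' @param arena An \code{\link{arena}} object.
#' @param meta Optional list of generator metadata.
#'
#' @return An object of class \code{tracking} with derived \code{pos_xy} and
#'   logical \code{valid} per frame.
#' @export
tracking_data <- function(t, led1_xy, led2_xy = NULL, arena, meta = list()) {
  t <- as.numeric(t)
  if (is.unsorted(t, strictly = TRUE)) stop("frame times must be strictly increasing")
  led1_xy <- as_xy_matrix(led1_xy, length(t))
  if (!is.null(led2_xy)) {
    led2_xy <- as_xy_matrix(led2_xy, length(t))
    pos <- (led1_xy + led2_xy) / 2
    valid <- stats::complete.cases(led1_xy) & stats::complete.cases(led2_xy)
  } else {
    pos <- led1_xy
    valid <- stats::complete.cases(led1_xy)
  }
  ok <- valid
  tol <- 1  # cm tolerance on arena bounds
  inb <- pos[, 1] >= -tol & pos[, 1] <= arena$width_cm + tol &
    pos[, 2] >= -tol & pos[, 2] <= arena$height_cm + tol
  if (any(ok & !inb)) {
    warning(sum(ok & !inb), " frame(s) outside arena bounds (> 1 cm); marked invalid")
    valid <- ok & inb
  }
  structure(
    list(t = t, led1_xy = led1_xy, led2_xy = led2_xy, pos_xy = pos,
         valid = valid, arena = arena, meta = meta),
    class = "tracking"
  )
}

as_xy_matrix <- function(m, n) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (ncol(m) != 2 || nrow(m) != n) stop("coordinates must be an n x 2 matrix")
  m
}

#' @export
print.tracking <- function(x, ...) {
  cat(sprintf("<tracking> %d frames, %.1f s, %d invalid, arena %s %gx%g cm\n",
              length(x$t), diff(range(x$t)), sum(!x$valid),
              x$arena$shape, x$arena$width_cm, x$arena$height_cm))
  invisible(x)
}
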