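#' Running speed from tracking
#'
#' X and Y coordinates are smoothed with a rectangular (boxcar) sliding
#' window of \code{speed_win_ms} (600 ms default) over the valid frames, and
#' the speed at each frame is the displacement between consecutive smoothed
#' positions divided by the frame interval. Invalid frames get \code{NA}.
#'
#' @param track A \code{\link{tracking_data}}.
#' @param cfg A \code{\link{run_config}}.
#' @return Numeric vector of per-frame speeds in cm/s (\code{NA} at invalid
#'   frames; the first valid frame takes the speed of the second).
#' @export
compute_speed <- function(track, cfg = run_config()) {
  ok <- which(track$valid)
  if (length(ok) < 2) stop("fewer than 2 valid tracking frames")
  t <- track$t[ok]
  dt_med <- stats::median(diff(t))
  win <- max(1L, as.integer(round(cfg$speed_win_ms / 1000 / dt_med)))
  xs <- moving_average(track$pos_xy[ok, 1], win)
  ys <- moving_average(track$pos_xy[ok, 2], win)
  sp <- c(NA, sqrt(diff(xs)^2 + diff(ys)^2) / diff(t))
  sp[1] <- sp[2]
  out <- rep(NA_real_, length(track$t))
  out[ok] <- sp
  out
}

arena_pixel_mask <- function(ar, nx, ny, pixel) {
  cx <- (seq_len(nx) - 0.5) * pixel
  cy <- (seq_len(ny) - 0.5) * pixel
  if (ar$shape == "o_maze") {
    ctr <- c(ar$width_cm / 2, ar$height_cm / 2)
    r_out <- min(ar$width_cm, ar$height_cm) / 2
    r_in <- max(0, r_out - ar$path_width_cm)
    r2 <- outer(cx - ctr[1], cy - ctr[2], function(a, b) a^2 + b^2)
    r2 >= r_in^2 & r2 <= r_out^2
  } else {
    matrix(TRUE, nx, ny)
  }
}

#' Compute an occupancy and firing-rate map
#'
#' Space is discretized into pixels of \code{pixel_cm} (2.5 cm); pixels are
#' half-open intervals with origin at the arena's lower-left corner. The
#' occupancy of pixel x is z(x) = sum_t w(|x - x_t|) dt and the rate
#' r(x) = sum_i w(|x - x_i|) / z(x), where w is an (unnormalized — the
#' normalization cancels between numerator and denominator) Gaussian kernel
#' of sigma \code{sigma_cm} (2.5 cm) evaluated at pixel centers, x_t the
#' animal position in frame t, and x_i the position at spike i (the nearest
#' tracking frame by timestamp). Frames with running speed at or below
#' \code{speed_thresh_cm_s} (1 cm/s) are removed, along with spikes falling
#' in those epochs. Pixels with smoothed occupancy below \code{occ_min_ms}
#' (20 ms) are considered unreliable and masked invalid. The visited mask is
#' taken from the raw (unsmoothed) pixel occupancy, so spatial coverage is
#' the fraction of arena pixels the animal actually entered.
#'
#' @param track A \code{\link{tracking_data}}.
#' @param spikes A \code{\link{spike_train}}.
#' @param cfg A \code{\link{run_config}}.
#' @param speed_filter Apply the running-speed threshold (default TRUE; set
#'   FALSE for controlled inputs such as a stationary test session).
#' @return An object of class \code{rate_map}: list with matrices \code{z}
#'   (s), \code{r} (Hz, \code{NA} off the valid mask), \code{valid_mask},
#'   \code{visited_mask}, \code{arena_mask}, plus \code{pixel_cm},
#'   \code{n_spikes_used}, \code{occupancy_s} and \code{peak_rate_hz}.
#' @export
compute_rate_map <- function(track, spikes, cfg = run_config(),
                             speed_filter = TRUE) {
  ar <- track$arena
  keep <- track$valid
  if (speed_filter) {
    sp <- compute_speed(track, cfg)
    keep <- keep & !is.na(sp) & sp > cfg$speed_thresh_cm_s
  }
  if (!any(keep)) stop("no tracking frames left after speed filtering")
  t_all <- track$t
  dt_frame <- c(diff(t_all), stats::median(diff(t_all)))
  tk <- t_all[keep]
  xk <- track$pos_xy[keep, 1]
  yk <- track$pos_xy[keep, 2]
  dtk <- dt_frame[keep]

  pixel <- cfg$pixel_cm
  nx <- as.integer(ceiling(ar$width_cm / pixel))
  ny <- as.integer(ceiling(ar$height_cm / pixel))
  cx <- (seq_len(nx) - 0.5) * pixel
  cy <- (seq_len(ny) - 0.5) * pixel
  s2 <- 2 * cfg$sigma_cm^2

  gauss <- function(pos, centers) exp(-outer(pos, centers, `-`)^2 / s2)

  # occupancy: separable Gaussian, frames weighted by frame duration
  Gx <- gauss(xk, cx)
  Gy <- gauss(yk, cy)
  z <- t(Gx * dtk) %*% Gy

  # spikes -> position of nearest kept frame
  n_used <- 0L
  spk_sum <- matrix(0, nx, ny)
  if (length(spikes$times)) {
    nearest_all <- findInterval(spikes$times, t_all + c(diff(t_all) / 2, Inf)) + 1L
    nearest_all[nearest_all > length(t_all)] <- length(t_all)
    ok_spk <- keep[nearest_all]
    if (any(ok_spk)) {
      xi <- track$pos_xy[nearest_all[ok_spk], 1]
      yi <- track$pos_xy[nearest_all[ok_spk], 2]
      spk_sum <- t(gauss(xi, cx)) %*% gauss(yi, cy)
      n_used <- sum(ok_spk)
    }
  }

  # raw visited pixels (half-open [i*pixel, (i+1)*pixel))
  ix <- pmin(pmax(floor(xk / pixel) + 1L, 1L), nx)
  iy <- pmin(pmax(floor(yk / pixel) + 1L, 1L), ny)
  visited <- matrix(FALSE, nx, ny)
  visited[cbind(ix, iy)] <- TRUE
  amask <- arena_pixel_mask(ar, nx, ny, pixel)
  visited <- visited & amask

  valid <- visited & (z >= cfg$occ_min_ms / 1000)
  r <- matrix(NA_real_, nx, ny)
  r[valid] <- spk_sum[valid] / z[valid]

  structure(list(z = z, r = r, spike_kernel_sum = spk_sum,
                 valid_mask = valid, visited_mask = visited,
                 arena_mask = amask, pixel_cm = pixel, origin = c(0, 0),
                 arena = ar, n_spikes_used = n_used,
                 occupancy_s = sum(dtk),
                 peak_rate_hz = if (any(valid)) max(r[valid]) else NA_real_),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf(paste0("<rate_map> %d x %d pixels (%.1f cm), %.0f s occupancy, ",
                     "%d spikes, peak %.2f Hz, coverage %.2f\n"),
              nrow(x$z), ncol(x$z), x$pixel_cm, x$occupancy_s,
              x$n_spikes_used, x$peak_rate_hz, spatial_coverage(x)))
  invisible(x)
}

#' @export
plot.rate_map <- function(x, ...) {
  r <- x$r
  graphics::image(
    (seq_len(nrow(r)) - 0.5) * x$pixel_cm,
    (seq_len(ncol(r)) - 0.5) * x$pixel_cm,
    r, xlab = "x (cm)", ylab = "y (cm)", asp = 1,
    col = grDevices::hcl.colors(64, "viridis"), ...
  )
  invisible(x)
}

#' Spatial coverage
#'
#' Fraction of arena pixels visited by the animal.
#'
#' @param map A \code{\link{compute_rate_map}} result.
#' @return Coverage fraction in [0, 1].
#' @export
spatial_coverage <- function(map) {
  sum(map$visited_mask) / sum(map$arena_mask)
}

# connected-component labeling on a logical matrix (4- or 8-connectivity)
label_components <- function(mask, connectivity = 8L) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  nbr <- if (connectivity == 8L) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- matrix(c(i, j), 1)
      lab[i, j] <- cur
      while (nrow(queue)) {
        q <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
        for (k in seq_len(nrow(nbr))) {
          a <- q[1] + nbr[k, 1]; b <- q[2] + nbr[k, 2]
          if (a >= 1 && a <= nx && b >= 1 && b <= ny &&
              mask[a, b] && lab[a, b] == 0L) {
            lab[a, b] <- cur
            queue <- rbind(queue, c(a, b))
          }
        }
      }
    }
  }
  lab
}

#' Detect firing fields in a rate map
#'
#' A firing field is a set of at least \code{field_min_pixels} (12)
#' contiguous pixels whose firing rate exceeds \code{field_frac_of_peak}
#' (20%) of the map's peak rate. Contiguity uses 8-connectivity by default
#' (switchable to 4 via \code{cfg$field_connectivity}).
#'
#' @param map A \code{\link{compute_rate_map}} result with at least one
#'   valid pixel.
#' @param cfg A \code{\link{run_config}}.
#' @return List of fields, each with \code{pixels} (two-column index
#'   matrix), \code{area_pixels}, \code{peak_rate} and
#'   \code{mean_in_field_rate}; empty list when no pixel fires.
#' @export
detect_fields <- function(map, cfg = run_config()) {
  r <- map$r
  valid <- map$valid_mask
  if (!any(valid)) stop("rate map has no valid pixel")
  pk <- max(r[valid])
  if (!is.finite(pk) || pk <= 0) return(list())
  mask <- valid & !is.na(r) & r > cfg$field_frac_of_peak * pk
  lab <- label_components(mask, cfg$field_connectivity)
  out <- list()
  for (l in seq_len(max(lab))) {
    px <- which(lab == l, arr.ind = TRUE)
    if (nrow(px) >= cfg$field_min_pixels) {
      rates <- r[px]
      ctr <- colSums((px - 0.5) * map$pixel_cm * rates) / sum(rates)
      out[[length(out) + 1L]] <- list(pixels = px, area_pixels = nrow(px),
                                      peak_rate = max(rates),
                                      mean_in_field_rate = mean(rates),
                                      center_cm = unname(ctr))
    }
  }
  out
}

#' Spatial-selectivity call
#'
#' A recording is spatially selective when at least one firing field exists
#' and the fields together account for strictly less than
#' \code{selective_max_field_frac} (20%) of the visited pixels.
#'
#' @param map A rate map.
#' @param fields Output of \code{\link{detect_fields}}.
#' @param cfg A \code{\link{run_config}}.
#' @return Logical.
#' @export
classify_selectivity <- function(map, fields, cfg = run_config()) {
  if (!length(fields)) return(FALSE)
  total_area <- sum(vapply(fields, `[[`, numeric(1), "area_pixels"))
  total_area < cfg$selective_max_field_frac * sum(map$visited_mask)
}

#' Lap count on an annular maze
#'
#' Net number of full circuits, from the unwrapped angle of the position
#' around the arena center.
#'
#' @param track A \code{\link{tracking_data}} (O-maze geometry).
#' @return Non-negative number of net laps (continuous).
#' @export
count_laps <- function(track) {
  ok <- track$valid
  ctr <- c(track$arena$width_cm / 2, track$arena$height_cm / 2)
  th <- atan2(track$pos_xy[ok, 2] - ctr[2], track$pos_xy[ok, 1] - ctr[1])
  d <- diff(th)
  d <- ((d + pi) %% (2 * pi)) - pi
  abs(sum(d)) / (2 * pi)
}

#' Inclusion check for spatial analysis
#'
#' A recording enters the spatial analysis when (i) spatial coverage exceeds
#' 70% (square/wall-less arenas) or at least two laps were run (annular
#' maze), and (ii) the average firing rate exceeds 0.1 Hz with more than 25
#' spikes in total (both strict).
#'
#' @param map A rate map (for coverage and arena geometry).
#' @param spikes A \code{\link{spike_train}}.
#' @param cfg A \code{\link{run_config}}.
#' @param laps Lap count for annular arenas (see \code{\link{count_laps}});
#'   required when the arena is an O-maze.
#' @return List with \code{included} (logical) and \code{reason} (name of
#'   the first failed criterion, or \code{"ok"}).
#' @export
inclusion_check <- function(map, spikes, cfg = run_config(), laps = NULL) {
  dur <- spikes$t_end - spikes$t_start
  n <- length(spikes$times)
  rate <- n / dur
  if (map$arena$shape == "o_maze") {
    if (is.null(laps)) stop("lap count required for the annular maze")
    if (laps < 2) return(list(included = FALSE, reason = "laps"))
  } else {
    if (spatial_coverage(map) <= cfg$coverage_min) {
      return(list(included = FALSE, reason = "coverage"))
    }
  }
  if (n <= cfg$min_spikes) return(list(included = FALSE, reason = "n_spikes"))
  if (rate <= cfg$min_rate_hz) return(list(included = FALSE, reason = "rate"))
  list(included = TRUE, reason = "ok")
}

#' Spatial information (Skaggs), bits per spike
#'
#' SI = sum_i p_i (r_i / rbar) log2(r_i / rbar) over valid pixels, with
#' occupancy probabilities p_i = z_i / sum(z) and mean rate
#' rbar = sum_i p_i r_i. Pixels with zero rate contribute zero.
#'
#' @param map A rate map with positive mean rate over the valid pixels.
#' @return Spatial information in bits/spike.
#' @export
spatial_information <- function(map) {
  v <- map$valid_mask
  z <- map$z[v]
  r <- map$r[v]
  p <- z / sum(z)
  rbar <- sum(p * r)
  if (!is.finite(rbar) || rbar <= 0) stop("zero mean rate on the valid pixels")
  pos <- r > 0
  sum(p[pos] * (r[pos] / rbar) * log2(r[pos] / rbar))
}

#' Interspike-interval histogram
#'
#' @param spikes A \code{\link{spike_train}} with >= 2 spikes.
#' @param bin_ms Bin width in ms.
#' @param max_ms Largest interval retained, ms.
#' @return List with \code{breaks_ms}, \code{mid_ms} and \code{counts}.
#' @export
isi_histogram <- function(spikes, bin_ms = 5, max_ms = 500) {
  if (length(spikes$times) < 2) stop("need at least 2 spikes")
  isi <- diff(spikes$times) * 1000
  breaks <- seq(0, max_ms, by = bin_ms)
  counts <- tabulate(findInterval(isi[isi <= max_ms], breaks,
                                  rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  list(breaks_ms = breaks, mid_ms = breaks[-1] - bin_ms / 2, counts = counts)
}

#' Spike-train autocorrelogram
#'
#' Counts of all spike-pair lags within \code{max_lag_ms}, symmetrized
#' around zero with the zero-lag bin excluded. Theta-modulated granule
#' cells show peaks near multiples of ~125 ms (8 Hz).
#'
#' @param spikes A \code{\link{spike_train}} with >= 2 spikes.
#' @param bin_ms Bin width, ms.
#' @param max_lag_ms Largest lag, ms.
#' @return List with \code{lag_ms} (bin midpoints, negative to positive) and
#'   \code{counts}.
#' @export
spike_autocorrelogram <- function(spikes, bin_ms = 5, max_lag_ms = 500) {
  tms <- spikes$times * 1000
  n <- length(tms)
  if (n < 2) stop("need at least 2 spikes")
  lags <- numeric(0)
  for (i in seq_len(n - 1)) {
    d <- tms[(i + 1):n] - tms[i]
    d <- d[d <= max_lag_ms & d > 0]
    if (!length(d)) next
    lags <- c(lags, d)
  }
  nb <- as.integer(ceiling(max_lag_ms / bin_ms))
  pos <- tabulate(pmin(ceiling(lags / bin_ms), nb), nbins = nb)
  list(lag_ms = c(-rev(seq_len(nb) * bin_ms - bin_ms / 2),
                  seq_len(nb) * bin_ms - bin_ms / 2),
       counts = c(rev(pos), pos))
}

#' Full spatial report for one recording
#'
#' Runs the spatial pipeline — rate map, coverage, field detection,
#' selectivity, Skaggs information, in/out-of-field rates and the inclusion
#' check — and returns one structured report.
#'
#' @param track A \code{\link{tracking_data}}.
#' @param spikes A \code{\link{spike_train}}.
#' @param cfg A \code{\link{run_config}}.
#' @return An object of class \code{spatial_report}.
#' @export
spatial_report <- function(track, spikes, cfg = run_config()) {
  map <- compute_rate_map(track, spikes, cfg)
  fields <- if (any(map$valid_mask) &&
                isTRUE(max(map$r[map$valid_mask]) > 0)) {
    detect_fields(map, cfg)
  } else list()
  laps <- if (track$arena$shape == "o_maze") count_laps(track) else NULL
  inc <- inclusion_check(map, spikes, cfg, laps = laps)
  infield <- if (length(fields)) {
    px <- do.call(rbind, lapply(fields, `[[`, "pixels"))
    mean(map$r[px])
  } else NA_real_
  outfield <- {
    v <- map$valid_mask
    if (length(fields)) {
      px <- do.call(rbind, lapply(fields, `[[`, "pixels"))
      vv <- v
      vv[px] <- FALSE
      if (any(vv)) mean(map$r[vv]) else NA_real_
    } else if (any(v)) mean(map$r[v]) else NA_real_
  }
  si <- tryCatch(spatial_information(map), error = function(e) NA_real_)
  structure(list(
    coverage = spatial_coverage(map),
    n_fields = length(fields),
    selective = classify_selectivity(map, fields, cfg),
    spatial_info_bits_per_spike = si,
    in_field_rate = infield, out_field_rate = outfield,
    laps = laps,
    included = inc$included, reason = inc$reason,
    map = map, fields = fields
  ), class = "spatial_report")
}

#' @export
print.spatial_report <- function(x, ...) {
  cat(sprintf(paste0("<spatial_report> coverage %.2f, %d field(s), ",
                     "selective=%s, SI %.2f bits/spike, included=%s (%s)\n"),
              x$coverage, x$n_fields, x$selective,
              x$spatial_info_bits_per_spike, x$included, x$reason))
  invisible(x)
}
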