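# Shared fixtures and independent oracles, all built in code.

# Brute-force shoulder oracle: evaluates the analytic template on a grid 10x
# finer than the sampled trace and searches directly for the first upward
# crossing of the trace over its centered boxcar average (after the
# half-window guard), within the peak-to-offset window. Independent of
# detect_shoulder's implementation.
shoulder_oracle <- function(params, cfg = run_config()) {
  dt <- params$dt_ms / 10
  t <- seq(-params$t_pre_ms, params$t_post_ms, by = dt)
  v <- waveform_template_fun(params)(t)
  v <- v / max(v)
  p <- which.max(v)
  off_rel <- which(v[p:length(v)] <= cfg$offset_frac)
  if (!length(off_rel)) stop("oracle: no spike offset")
  off <- p + off_rel[1] - 1
  half <- floor(round(cfg$ma_win_ms / dt) / 2)
  ma <- vapply(seq_along(v), function(i) {
    mean(v[max(1, i - half):min(length(v), i + half)])
  }, numeric(1))
  d <- v - ma
  guard <- p + ceiling((cfg$ma_win_ms / 2) / dt)
  for (i in seq.int(max(guard, p + 1) + 1, off)) {
    if (d[i - 1] < 0 && d[i] >= 0) {
      return(list(detected = TRUE, latency_ms = (i - p) * dt))
    }
  }
  list(detected = FALSE, latency_ms = NA_real_)
}

# write an SWC file from record lines; returns the path
write_swc_lines <- function(lines) {
  path <- tempfile(fileext = ".swc")
  writeLines(lines, path)
  path
}

# full binary dendritic tree of the given depth (orders 1..depth), every
# segment a straight 50 um piece
binary_tree_swc <- function(depth) {
  lines <- c("1 1 0 0 0 5 -1")
  id <- 1L
  recurse <- function(parent, level, x, y) {
    force(parent)
    if (level > depth) return(invisible(NULL))
    for (side in c(-1, 1)) {
      id <<- id + 1L
      child <- id
      nx <- x + side * 50 / level
      ny <- y + sqrt(max(0, 50^2 - (50 / level)^2))
      lines <<- c(lines, sprintf("%d 3 %.4f %.4f 0 1 %d", child, nx, ny,
                                 parent))
      recurse(child, level + 1, nx, ny)
    }
  }
  # order-1: a single primary (one child of the soma), then bifurcations
  id <- id + 1L
  lines <- c(lines, sprintf("%d 3 0 50 0 1 1", id))
  recurse(2L, 2, 0, 50)
  write_swc_lines(lines)
}

# independent direct-summation Skaggs spatial information
si_oracle <- function(map) {
  v <- which(map$valid_mask)
  z <- map$z[v]; r <- map$r[v]
  tot <- 0
  zs <- sum(z)
  rbar <- sum(z / zs * r)
  for (i in seq_along(v)) {
    p <- z[i] / zs
    if (r[i] > 0) tot <- tot + p * (r[i] / rbar) * log2(r[i] / rbar)
  }
  tot
}

# minimal hand-built rate_map object for closed-form map tests
fake_rate_map <- function(r, z = NULL, valid = NULL, visited = NULL,
                          pixel_cm = 2.5) {
  if (is.null(z)) z <- matrix(1, nrow(r), ncol(r))
  if (is.null(valid)) valid <- matrix(TRUE, nrow(r), ncol(r))
  if (is.null(visited)) visited <- valid
  structure(list(z = z, r = r, valid_mask = valid, visited_mask = visited,
                 arena_mask = matrix(TRUE, nrow(r), ncol(r)),
                 pixel_cm = pixel_cm, origin = c(0, 0),
                 arena = arena("square", nrow(r) * pixel_cm,
                               ncol(r) * pixel_cm),
                 n_spikes_used = NA_integer_, occupancy_s = sum(z),
                 peak_rate_hz = max(r[valid])),
            class = "rate_map")
}

# exact two-sided Mann-Whitney p by full enumeration over group assignments
mw_enum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    rk <- rank(pooled)
    sum(rk[idx]) - nx * (nx + 1) / 2
  }
  u_obs <- u_of(seq_len(nx))
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) {
    rk <- rank(pooled)
    sum(rk[idx]) - nx * (nx + 1) / 2
  })
  mu <- nx * ny / 2
  p <- if (u_obs > mu) 2 * mean(us >= u_obs) else 2 * mean(us <= u_obs)
  min(1, p)
}

# cohort table built directly in memory
make_cohort <- function(n_active, n_silent, n_excluded = 0) {
  n <- n_active + n_silent + n_excluded
  df <- data.frame(
    cell_id = seq_len(n),
    duration_s = rep(120, n),
    n_spikes = c(rep(60, n_active), rep(0, n_silent), rep(0, n_excluded)),
    activity_class = c(rep("active", n_active), rep("silent", n_silent),
                       rep("excluded", n_excluded))
  )
  class(df) <- c("cohort_table", "data.frame")
  df
}
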