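#' Parameters for synthetic average spike waveforms
#'
#' The template emulates the juxtacellular average spike: a positive spike
#' (Gaussian of width \code{w_rise_ms}) minus a delayed after-hyperpolarizing
#' Gaussian (width \code{w_fall_ms}), giving a biphasic shape whose
#' repolarization is strictly monotone from the peak down to the
#' after-hyperpolarization trough. An optional shoulder is an additive
#' Gaussian bump of relative amplitude \code{shoulder_amp} centered
#' \code{shoulder_delay_ms} after the main peak — the analyses here are
#' agnostic about the biophysical origin of the shoulder, so an additive
#' bump is the minimal model. Defaults place the 10%-of-peak spike offset
#' near 0.55 ms after the peak, so the default shoulder delay of 0.4 ms
#' falls inside the detection search window.
#'
#' @param dt_ms Sample interval in ms; default 1/40 (40 kHz, within the
#'   20-50 kHz acquisition range).
#' @param w_rise_ms Width (Gaussian sigma) of the main spike, ms.
#' @param w_fall_ms Width of the after-hyperpolarization Gaussian, ms.
#' @param ahp_amp Relative amplitude of the after-hyperpolarization.
#' @param ahp_delay_ms Center of the after-hyperpolarization after the peak.
#' @param shoulder_amp Relative amplitude s >= 0 of the shoulder bump
#'   (0 = no shoulder).
#' @param shoulder_delay_ms Bump center after the main peak, ms.
#' @param shoulder_sigma_ms Bump width (Gaussian sigma), ms.
#' @param noise_sd Additive white-noise SD relative to the peak.
#' @param t_pre_ms,t_post_ms Time span of the trace before/after the peak.
#' @return An object of class \code{waveform_gen_params}.
#' @export
waveform_gen_params <- function(dt_ms = 1 / 40, w_rise_ms = 0.3,
                                w_fall_ms = 1.0, ahp_amp = 0.2,
                                ahp_delay_ms = 2.0, shoulder_amp = 0,
                                shoulder_delay_ms = 0.4,
                                shoulder_sigma_ms = 0.08, noise_sd = 0,
                                t_pre_ms = 1.5, t_post_ms = 4) {
  stopifnot(dt_ms > 0, w_rise_ms > 0, w_fall_ms > 0, shoulder_amp >= 0,
            shoulder_delay_ms > 0, shoulder_sigma_ms > 0, noise_sd >= 0)
  structure(list(dt_ms = dt_ms, w_rise_ms = w_rise_ms, w_fall_ms = w_fall_ms,
                 ahp_amp = ahp_amp, ahp_delay_ms = ahp_delay_ms,
                 shoulder_amp = shoulder_amp,
                 shoulder_delay_ms = shoulder_delay_ms,
                 shoulder_sigma_ms = shoulder_sigma_ms, noise_sd = noise_sd,
                 t_pre_ms = t_pre_ms, t_post_ms = t_post_ms),
            class = "waveform_gen_params")
}

#' Analytic waveform template
#'
#' Returns the noiseless template as a function of time in ms (peak of the
#' main Gaussian at t = 0), un-normalized. Useful for dense-grid reference
#' computations independent of the sampled trace.
#'
#' @param params A \code{\link{waveform_gen_params}}.
#' @return A vectorized function of time (ms).
#' @export
waveform_template_fun <- function(params) {
  p <- params
  function(t) {
    exp(-t^2 / (2 * p$w_rise_ms^2)) -
      p$ahp_amp * exp(-(t - p$ahp_delay_ms)^2 / (2 * p$w_fall_ms^2)) +
      p$shoulder_amp *
        exp(-(t - p$shoulder_delay_ms)^2 / (2 * p$shoulder_sigma_ms^2))
  }
}

#' Generate a synthetic average spike waveform
#'
#' Samples the analytic template at \code{dt_ms}, adds white noise, and
#' peak-normalizes. Ground truth (shoulder present/absent, bump center) is
#' stored in the waveform's \code{meta}.
#'
#' @param params A \code{\link{waveform_gen_params}}.
#' @param seed Integer RNG seed (only used when \code{noise_sd > 0}).
#' @param label,cell_id Passed to \code{\link{waveform}}.
#' @return A peak-normalized \code{\link{waveform}}.
#' @export
gen_waveform <- function(params, seed = 0L, label = "unknown", cell_id = "") {
  t <- seq(-params$t_pre_ms, params$t_post_ms, by = params$dt_ms)
  if (length(t) < 16) stop("dt_ms implies fewer than 16 samples over the template support")
  v <- waveform_template_fun(params)(t)
  if (params$noise_sd > 0) {
    v <- v + with_seed(seed, stats::rnorm(length(v), 0, params$noise_sd * max(v)))
  }
  v <- v / max(v)
  waveform(v, dt_ms = params$dt_ms, label = label, cell_id = cell_id,
           meta = list(ground_truth_shoulder = params$shoulder_amp > 0,
                       shoulder_amp = params$shoulder_amp,
                       shoulder_delay_ms = params$shoulder_delay_ms,
                       peak_time_offset_ms = params$t_pre_ms))
}

# Evaluate expr with a local RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Parameters for synthetic place-field sessions
#'
#' @param arena An \code{\link{arena}}.
#' @param field_center_cm Length-2 field center in cm (must lie inside the
#'   arena); default the arena center.
#' @param field_sigma_cm Gaussian field width in cm.
#' @param peak_rate_hz Field peak rate above baseline, Hz (>= 0).
#' @param baseline_rate_hz Spatially uniform baseline rate, Hz (>= 0).
#' @param duration_s Session duration in s (>= 60).
#' @param mean_speed_cm_s Target mean running speed of the
#'   Ornstein-Uhlenbeck walk.
#' @param speed_relax_s Velocity relaxation time of the walk, s.
#' @param fs_hz Tracking frame rate, Hz (nominal 25).
#' @return An object of class \code{field_gen_params}.
#' @export
field_gen_params <- function(arena = sparsegc::arena("square"),
                             field_center_cm = NULL, field_sigma_cm = 8,
                             peak_rate_hz = 5, baseline_rate_hz = 0.1,
                             duration_s = 600, mean_speed_cm_s = 15,
                             speed_relax_s = 0.8, fs_hz = 25) {
  if (is.null(field_center_cm)) {
    field_center_cm <- c(arena$width_cm / 2, arena$height_cm / 2)
  }
  stopifnot(peak_rate_hz >= 0, baseline_rate_hz >= 0, duration_s >= 60,
            field_sigma_cm > 0, mean_speed_cm_s > 0, speed_relax_s > 0,
            field_center_cm[1] >= 0, field_center_cm[1] <= arena$width_cm,
            field_center_cm[2] >= 0, field_center_cm[2] <= arena$height_cm)
  structure(list(arena = arena, field_center_cm = field_center_cm,
                 field_sigma_cm = field_sigma_cm,
                 peak_rate_hz = peak_rate_hz,
                 baseline_rate_hz = baseline_rate_hz,
                 duration_s = duration_s,
                 mean_speed_cm_s = mean_speed_cm_s,
                 speed_relax_s = speed_relax_s, fs_hz = fs_hz),
            class = "field_gen_params")
}

#' Generate a synthetic exploration session with place-field spiking
#'
#' The trajectory is an Ornstein-Uhlenbeck random walk (smooth and
#' speed-controllable) reflected at the arena boundary and sampled at the
#' tracking frame rate; for the annular O-maze the walk is reflected at the
#' inner and outer radius of a centered annulus. Two head-LED positions are
#' emitted 3.5 cm apart along the heading so that their midpoint is the true
#' position. Spikes are drawn from an inhomogeneous Poisson process with
#' rate lambda(x) = baseline + peak * exp(-||x - c||^2 / (2 sigma_f^2)) by
#' thinning a homogeneous process at baseline + peak. Ground-truth field
#' parameters are stored in the tracking metadata.
#'
#' @param params A \code{\link{field_gen_params}}.
#' @param seed Integer RNG seed.
#' @return List with \code{tracking} (a \code{\link{tracking_data}}),
#'   \code{spikes} (a \code{\link{spike_train}}) and \code{truth}.
#' @export
gen_session <- function(params, seed = 0L) {
  with_seed(seed, {
    ar <- params$arena
    dt <- 1 / params$fs_hz
    nf <- as.integer(ceiling(params$duration_s * params$fs_hz)) + 1L
    tau <- params$speed_relax_s
    sig_v <- params$mean_speed_cm_s / sqrt(pi / 2)
    a <- exp(-dt / tau)
    b <- sig_v * sqrt(1 - a^2)

    pos <- matrix(0, nf, 2)
    vel <- stats::rnorm(2, 0, sig_v)
    if (ar$shape == "o_maze") {
      cx <- c(ar$width_cm / 2, ar$height_cm / 2)
      r_out <- min(ar$width_cm, ar$height_cm) / 2
      r_in <- max(1, r_out - ar$path_width_cm)
      r0 <- (r_in + r_out) / 2
      pos[1, ] <- cx + c(r0, 0)
    } else {
      pos[1, ] <- c(ar$width_cm / 2, ar$height_cm / 2)
    }
    for (i in 2:nf) {
      vel <- a * vel + b * stats::rnorm(2)
      p <- pos[i - 1, ] + vel * dt
      if (ar$shape == "o_maze") {
        d <- p - cx
        r <- sqrt(sum(d^2))
        if (r > r_out || r < r_in) {
          rr <- if (r > r_out) 2 * r_out - r else 2 * r_in - r
          rr <- min(max(rr, r_in), r_out)
          u <- d / r
          p <- cx + u * rr
          # reflect the radial velocity component
          vel <- vel - 2 * sum(vel * u) * u
        }
      } else {
        for (k in 1:2) {
          lim <- if (k == 1) ar$width_cm else ar$height_cm
          if (p[k] < 0) { p[k] <- -p[k]; vel[k] <- -vel[k] }
          if (p[k] > lim) { p[k] <- 2 * lim - p[k]; vel[k] <- -vel[k] }
          p[k] <- min(max(p[k], 0), lim)
        }
      }
      pos[i, ] <- p
    }
    tt <- (seq_len(nf) - 1) * dt

    # LEDs 3.5 cm apart along the heading, midpoint = position
    head <- rbind(pos[2, ] - pos[1, ], diff(pos))
    hn <- sqrt(rowSums(head^2))
    hn[hn == 0] <- 1
    head <- head / hn
    led1 <- pos + 1.75 * head
    led2 <- pos - 1.75 * head

    # inhomogeneous Poisson spikes by thinning
    lam_max <- params$baseline_rate_hz + params$peak_rate_hz
    times <- numeric(0)
    if (lam_max > 0) {
      n_cand <- stats::rpois(1, lam_max * params$duration_s)
      cand <- sort(stats::runif(n_cand, 0, params$duration_s))
      if (length(cand)) {
        cx_ <- stats::approx(tt, pos[, 1], xout = cand)$y
        cy_ <- stats::approx(tt, pos[, 2], xout = cand)$y
        d2 <- (cx_ - params$field_center_cm[1])^2 +
          (cy_ - params$field_center_cm[2])^2
        lam <- params$baseline_rate_hz +
          params$peak_rate_hz * exp(-d2 / (2 * params$field_sigma_cm^2))
        keep <- stats::runif(length(cand)) < lam / lam_max
        times <- unique(cand[keep])
      }
    }
    truth <- list(field_center_cm = params$field_center_cm,
                  field_sigma_cm = params$field_sigma_cm,
                  peak_rate_hz = params$peak_rate_hz,
                  baseline_rate_hz = params$baseline_rate_hz, seed = seed)
    list(
      tracking = tracking_data(tt, led1, led2, arena = ar, meta = truth),
      spikes = spike_train(times, 0, params$duration_s),
      truth = truth
    )
  })
}

#' Parameters for synthetic dendritic trees
#'
#' Trees are grown as binary trees mimicking mature granule cells: one
#' "deep" primary dendrite carries the high-order arbor — the number of
#' order-(k+1) segments is twice the systematically rounded product of
#' \code{branch_prob[k]} and the order-k segment count, so the skeleton is
#' near-deterministic and the per-order segment counts have low between-cell
#' variance, as real mature granule cells (which reliably reach orders 5-7)
#' do — while any additional primary dendrites stay shallow (they terminate
#' at order 1 or 2). Segment path lengths are Gamma-distributed with
#' per-order means \code{seg_len_mean} (micrometers); the per-segment SD is
#' frozen at \code{seg_len_cv} times the base means. Class structure
#' ("active" vs "silent") enters only through \code{effect_size}: the
#' per-order mean lengths of \code{effect_orders} are shifted so that the
#' class mean of the total length at those orders moves by
#' \code{effect_size} reference standard deviations (the between-cell SD of
#' that order's total length under the base parameters, estimated once from
#' an internal fixed-seed simulation), while the per-segment SD stays at its
#' base value. By default active cells get longer order 5-6 dendrites and
#' silent cells longer order 2-3 dendrites, the directions reported for
#' identified granule cells.
#'
#' @param class \code{"active"} or \code{"silent"}.
#' @param effect_size Class-mean separation in reference SD units (>= 0).
#' @param effect_orders Branch orders receiving the shift; default 5:6 for
#'   active, 2:3 for silent.
#' @param n_primary_probs Probabilities of 1..4 primary dendrites.
#' @param branch_prob Per-order branching probabilities (orders 1..7; order
#'   >= 8 never branches). Defaults make most lineages reach order 5-6, as
#'   mature granule cells do.
#' @param seg_len_mean Per-order mean segment lengths, micrometers.
#' @param seg_len_cv Coefficient of variation of segment lengths under the
#'   base parameters; the per-segment SD is fixed at construction, so an
#'   effect shift moves the mean without inflating within-class variance.
#' @return An object of class \code{morph_gen_params}.
#' @export
morph_gen_params <- function(class = c("silent", "active"), effect_size = 0,
                             effect_orders = NULL,
                             n_primary_probs = c(0.35, 0.45, 0.15, 0.05),
                             branch_prob = c(1, 1, 0.75, 0.5, 1 / 3, 0.125,
                                             0.02),
                             seg_len_mean = c(60, 50, 60, 80, 100, 120, 140),
                             seg_len_cv = 0.4) {
  class <- match.arg(class)
  stopifnot(effect_size >= 0, length(branch_prob) == 7,
            length(seg_len_mean) == 7, all(seg_len_mean > 0),
            all(branch_prob >= 0), all(branch_prob <= 1), seg_len_cv > 0)
  if (is.null(effect_orders)) {
    effect_orders <- if (class == "active") 5:6 else 2:3
  }
  p <- list(class = class, effect_size = effect_size,
            effect_orders = as.integer(effect_orders),
            n_primary_probs = n_primary_probs / sum(n_primary_probs),
            branch_prob = branch_prob, seg_len_mean = seg_len_mean,
            seg_len_sd = seg_len_mean * seg_len_cv,
            seg_len_cv = seg_len_cv)
  if (effect_size > 0) {
    ref <- morph_reference_stats(p)
    for (k in p$effect_orders) {
      if (ref$mean[k] > 0) {
        # shift the class mean of the order-k total length by
        # effect_size reference SDs, holding the per-segment SD fixed
        p$seg_len_mean[k] <- p$seg_len_mean[k] *
          (1 + effect_size * ref$sd[k] / ref$mean[k])
      }
    }
  }
  class(p) <- "morph_gen_params"
  p
}

# Between-cell mean/SD of per-order total length under the base parameters,
# from a fixed-seed internal simulation (cached per parameter signature).
morph_reference_stats <- function(p, n_ref = 150L) {
  key <- paste(c(p$n_primary_probs, p$branch_prob, p$seg_len_mean,
                 p$seg_len_sd, n_ref), collapse = "_")
  hit <- .sparsegc_cache[[key]]
  if (!is.null(hit)) return(hit)
  base <- p
  base$effect_size <- 0
  L <- with_seed(990011L, {
    t(vapply(seq_len(n_ref), function(i) {
      tr <- grow_tree(base)
      f <- morph_features(tr)
      unlist(f[paste0("order", 1:7)])
    }, numeric(7)))
  })
  out <- list(mean = colMeans(L), sd = apply(L, 2, stats::sd))
  .sparsegc_cache[[key]] <- out
  out
}

.sparsegc_cache <- new.env(parent = emptyenv())

# Grow one stochastic dendritic tree (RNG state of the caller is used).
# One deep primary carries the high-order arbor with a variance-reduced
# skeleton; extra primaries terminate at order 1-2.
grow_tree <- function(p) {
  nx <- 0; ny <- 0; nz <- 0
  types <- 1L
  parents <- NA_integer_
  n_nodes <- 1L
  n_primary <- sample.int(length(p$n_primary_probs), 1,
                          prob = p$n_primary_probs)

  add_node <- function(xyz, parent) {
    n_nodes <<- n_nodes + 1L
    nx[n_nodes] <<- xyz[1]; ny[n_nodes] <<- xyz[2]; nz[n_nodes] <<- xyz[3]
    types[n_nodes] <<- 3L
    parents[n_nodes] <<- parent
    n_nodes
  }
  rand_dir <- function(base = NULL, cone = 0.6) {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    if (is.null(base)) return(u)
    v <- base + cone * u
    v / sqrt(sum(v^2))
  }
  # one segment of a given order: noded polyline of Gamma length; returns
  # the id of its distal node
  grow_segment <- function(parent_id, order, dir) {
    k <- min(order, 7L)
    mk <- p$seg_len_mean[k]
    sk <- p$seg_len_sd[k]
    len <- max(stats::rgamma(1, shape = (mk / sk)^2, scale = sk^2 / mk), 1)
    n_pts <- max(1L, as.integer(ceiling(len / 25)))
    start <- c(nx[parent_id], ny[parent_id], nz[parent_id])
    cur <- parent_id
    for (j in seq_len(n_pts)) {
      dir <- rand_dir(dir, cone = 0.15)
      start <- start + dir * (len / n_pts)
      cur <- add_node(start, cur)
    }
    list(end = cur, dir = dir)
  }
  stoch_round <- function(x) {
    fl <- floor(x)
    as.integer(fl + (stats::runif(1) < x - fl))
  }

  # deep primary: per-order segment counts follow the branch probabilities
  # with systematic rounding (low between-tree count variance)
  tips <- list(grow_segment(1L, 1L, rand_dir()))
  order <- 1L
  while (order <= 7L && length(tips) > 0) {
    n_branch <- min(stoch_round(p$branch_prob[order] * length(tips)),
                    length(tips))
    if (n_branch == 0) break
    branching <- sample.int(length(tips), n_branch)
    new_tips <- list()
    for (b in branching) {
      for (side in 1:2) {
        new_tips[[length(new_tips) + 1L]] <-
          grow_segment(tips[[b]]$end, order + 1L,
                       rand_dir(tips[[b]]$dir, cone = 0.9))
      }
    }
    tips <- new_tips
    order <- order + 1L
  }

  # extra primaries stay shallow: branch once with prob branch_prob[1]/2,
  # else terminate unbranched
  for (i in seq_len(n_primary - 1L)) {
    s <- grow_segment(1L, 1L, rand_dir())
    if (stats::runif(1) < p$branch_prob[1] / 2) {
      for (side in 1:2) grow_segment(s$end, 2L, rand_dir(s$dir, cone = 0.9))
    }
  }
  morph_tree(data.frame(id = seq_len(n_nodes), type = types, x = nx, y = ny,
                        z = nz, radius = c(5, rep(0.5, n_nodes - 1L)),
                        parent = parents))
}

#' Generate a cohort of synthetic dendritic trees
#'
#' Generates \code{n_per_class} trees per class whose expected morphometric
#' features differ between classes only through the configured effect sizes.
#'
#' @param params_active,params_silent \code{\link{morph_gen_params}} for the
#'   two classes.
#' @param n_per_class Number of cells per class (>= 2).
#' @param seed Integer RNG seed.
#' @return List with \code{trees} (list of \code{morph_tree}), \code{labels}
#'   (factor \code{silent}/\code{active}) and \code{features} (n x 10
#'   feature matrix from \code{\link{morph_features}}).
#' @export
gen_morph_cohort <- function(params_active, params_silent, n_per_class,
                             seed = 0L) {
  stopifnot(n_per_class >= 2)
  with_seed(seed, {
    trees <- c(
      lapply(seq_len(n_per_class), function(i) grow_tree(params_silent)),
      lapply(seq_len(n_per_class), function(i) grow_tree(params_active))
    )
    labels <- factor(rep(c("silent", "active"), each = n_per_class),
                     levels = c("silent", "active"))
    X <- t(vapply(trees, function(tr) {
      f <- morph_features(tr)
      c(total_length = f$total_length,
        unlist(f[paste0("order", 1:7)]),
        n_primary = f$n_primary, n_endings = f$n_endings)
    }, numeric(10)))
    colnames(X) <- c("total_length", paste0("order", 1:7), "n_primary",
                     "n_endings")
    list(trees = trees, labels = labels, features = X)
  })
}
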