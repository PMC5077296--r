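#' Feature vector from an average spike waveform
#'
#' Resamples the waveform to a fixed length with the spike peak at a fixed
#' position, after amplitude normalization (peak = 1). The time window is
#' expressed relative to the peak so that waveforms recorded at different
#' sampling rates align sample-by-sample; values requested outside the
#' recorded span take the edge value. With \code{segment =
#' "repolarization"} only the stretch from the peak to the spike offset
#' (fraction \code{offset_frac} of the peak) is resampled — the segment
#' where shoulders occur.
#'
#' @param wf A \code{\link{waveform}}.
#' @param resample_len Output length (default 64).
#' @param t_pre_ms,t_post_ms Window before/after the peak, ms.
#' @param segment \code{"full"} or \code{"repolarization"}.
#' @param cfg A \code{\link{run_config}} (for \code{offset_frac}).
#' @return Numeric vector of length \code{resample_len}.
#' @export
waveform_features <- function(wf, resample_len = 64L, t_pre_ms = 0.75,
                              t_post_ms = 2.25,
                              segment = c("full", "repolarization"),
                              cfg = run_config()) {
  segment <- match.arg(segment)
  x <- wf$samples / max(wf$samples)
  t <- (seq_along(x) - which.max(x)) * wf$dt_ms  # time relative to peak
  if (segment == "repolarization") {
    p <- which.max(x)
    off_rel <- which(x[p:length(x)] <= cfg$offset_frac)
    t_end <- if (length(off_rel)) t[p + off_rel[1] - 1] else t[length(t)]
    grid <- seq(0, t_end, length.out = resample_len)
  } else {
    grid <- seq(-t_pre_ms, t_post_ms, length.out = resample_len)
  }
  stats::approx(t, x, xout = grid, rule = 2)$y
}

#' Assemble a labelled waveform dataset
#'
#' @param waveforms List of \code{\link{waveform}} objects.
#' @param labels Optional vector of class labels; defaults to each
#'   waveform's own label collapsed to \code{GC} vs \code{nonGC}.
#' @param cfg A \code{\link{run_config}} (\code{resample_len}).
#' @param segment Passed to \code{\link{waveform_features}}.
#' @return List with \code{features} (items x samples matrix) and
#'   \code{labels} (factor nonGC/GC); both classes must be present.
#' @export
waveform_dataset <- function(waveforms, labels = NULL, cfg = run_config(),
                             segment = "full") {
  if (is.null(labels)) {
    labels <- vapply(waveforms, `[[`, character(1), "label")
    labels <- ifelse(labels == "GC", "GC", "nonGC")
  }
  labels <- factor(labels, levels = c("nonGC", "GC"))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  X <- t(vapply(waveforms, waveform_features, numeric(cfg$resample_len),
                resample_len = cfg$resample_len, segment = segment,
                cfg = cfg))
  list(features = X, labels = labels)
}

#' ADASYN oversampling of the minority class
#'
#' Adaptive synthetic sampling for imbalanced learning: G = (n_maj - n_min)
#' * beta synthetic minority samples are generated, allocated across
#' minority points in proportion to the fraction of majority samples among
#' each point's k nearest neighbours (so harder-to-learn regions receive
#' more synthetic mass), each synthetic point being a convex combination
#' x_i + u (x_z - x_i), u ~ U(0, 1), of a minority point and one of its
#' minority-class k nearest neighbours. All synthetic points therefore lie
#' inside the minority convex hull. The neighbourhood size is shrunk when
#' the minority class is smaller than k + 1.
#'
#' @param features Numeric matrix (samples x features).
#' @param labels Two-class factor/vector; minority class inferred from
#'   counts (balanced input returns zero synthetic samples).
#' @param seed Integer RNG seed.
#' @param k Neighbourhood size (default 5).
#' @param beta Balancing degree in [0, 1]; 1 fully balances.
#' @return List with \code{features}, \code{labels} (originals followed by
#'   synthetic minority rows) and \code{n_synthetic}.
#' @export
adasyn_oversample <- function(features, labels, seed = 0L, k = 5L, beta = 1) {
  X <- as.matrix(features)
  labels <- as.factor(labels)
  cnt <- table(labels)
  if (length(cnt) != 2) stop("exactly two classes required")
  min_cl <- names(cnt)[which.min(cnt)]
  n_min <- min(cnt)
  n_maj <- max(cnt)
  if (n_min < 2) stop("minority class must have at least 2 samples")
  G <- round((n_maj - n_min) * beta)
  if (G == 0 || n_min == n_maj) {
    return(list(features = X, labels = labels, n_synthetic = 0L))
  }
  mi <- which(labels == min_cl)

  with_seed(seed, {
    D <- as.matrix(stats::dist(X))
    k_all <- min(k, nrow(X) - 1L)
    r <- vapply(mi, function(i) {
      others <- setdiff(seq_len(nrow(X)), i)
      nb <- others[order(D[i, others])[seq_len(k_all)]]
      mean(labels[nb] != min_cl)
    }, numeric(1))
    w <- if (sum(r) == 0) rep(1 / length(mi), length(mi)) else r / sum(r)
    # integer allocation summing exactly to G (largest remainder)
    g <- floor(w * G)
    rem <- G - sum(g)
    if (rem > 0) {
      extra <- order(w * G - g, decreasing = TRUE)[seq_len(rem)]
      g[extra] <- g[extra] + 1L
    }

    k_min <- min(k, n_min - 1L)
    Dm <- D[mi, mi, drop = FALSE]
    synth <- matrix(NA_real_, G, ncol(X))
    row <- 0L
    for (ii in seq_along(mi)) {
      if (g[ii] == 0) next
      others_m <- setdiff(seq_along(mi), ii)
      nb_m <- mi[others_m][order(Dm[ii, others_m])[seq_len(k_min)]]
      for (s in seq_len(g[ii])) {
        z <- nb_m[sample.int(k_min, 1)]
        u <- stats::runif(1)
        row <- row + 1L
        synth[row, ] <- X[mi[ii], ] + u * (X[z, ] - X[mi[ii], ])
      }
    }
    list(features = rbind(X, synth),
         labels = factor(c(as.character(labels), rep(min_cl, G)),
                         levels = levels(labels)),
         n_synthetic = G)
  })
}

# Single-hidden-layer feed-forward network (sigmoid hidden units, logistic
# output) trained by full-batch resilient backpropagation with early
# stopping on a held-out validation subset: training stops when the
# validation loss has failed to improve on its best value for more than
# `max_val_fail` consecutive epochs.
nn_train <- function(X, y01, hidden = 10L, val_frac = 0.15,
                     max_val_fail = 6L, max_epochs = 300L) {
  n <- nrow(X)
  d <- ncol(X)
  # stratified validation split
  val <- unlist(lapply(unique(y01), function(cl) {
    rows <- which(y01 == cl)
    rows[sample.int(length(rows), max(1L, round(val_frac * length(rows))))]
  }))
  tr <- setdiff(seq_len(n), val)
  Xtr <- X[tr, , drop = FALSE]; ytr <- y01[tr]
  Xv <- X[val, , drop = FALSE]; yv <- y01[val]

  sig <- function(z) 1 / (1 + exp(-z))
  xent <- function(p, y) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  np <- d * hidden + hidden + hidden + 1L
  theta <- stats::runif(np, -0.5, 0.5)
  unpack <- function(th) {
    W1 <- matrix(th[1:(d * hidden)], d, hidden)
    b1 <- th[d * hidden + 1:hidden]
    w2 <- th[d * hidden + hidden + 1:hidden]
    b2 <- th[np]
    list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
  }
  fwd <- function(th, X_) {
    pr <- unpack(th)
    H <- sig(sweep(X_ %*% pr$W1, 2, pr$b1, `+`))
    list(H = H, p = drop(sig(H %*% pr$w2 + pr$b2)))
  }
  grad <- function(th) {
    pr <- unpack(th)
    f <- fwd(th, Xtr)
    dz2 <- (f$p - ytr) / length(ytr)
    gw2 <- drop(crossprod(f$H, dz2))
    gb2 <- sum(dz2)
    dH <- outer(dz2, pr$w2) * f$H * (1 - f$H)
    gW1 <- crossprod(Xtr, dH)
    gb1 <- colSums(dH)
    c(as.numeric(gW1), gb1, gw2, gb2)
  }

  # iRprop- updates
  delta <- rep(0.02, np)
  g_prev <- rep(0, np)
  best <- list(theta = theta, vloss = Inf, epoch = 0L)
  fails <- 0L
  for (ep in seq_len(max_epochs)) {
    g <- grad(theta)
    s <- g * g_prev
    delta[s > 0] <- pmin(delta[s > 0] * 1.2, 1)
    delta[s < 0] <- pmax(delta[s < 0] * 0.5, 1e-6)
    g[s < 0] <- 0
    theta <- theta - sign(g) * delta
    g_prev <- g
    vloss <- xent(fwd(theta, Xv)$p, yv)
    if (vloss < best$vloss - 1e-12) {
      best <- list(theta = theta, vloss = vloss, epoch = ep)
      fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails > max_val_fail) break
    }
  }
  list(theta = best$theta, epochs = ep, val_loss = best$vloss,
       predict = function(X_) fwd(best$theta, X_)$p)
}

#' Leave-one-out waveform classification
#'
#' For each held-out waveform the remaining items are ADASYN-balanced, a
#' validation subset (fraction \code{nn_val_frac}) is split from the
#' balanced training set, and a feed-forward network with one hidden layer
#' of \code{nn_hidden} (10) sigmoid units and a single logistic output is
#' trained with early stopping after \code{nn_max_val_fail} (6) consecutive
#' validation failures; the held-out item is then predicted. Aggregates
#' accuracy, false positives (non-GC predicted GC) and false negatives (GC
#' predicted non-GC). Fully deterministic given (dataset, cfg, seed).
#'
#' @param ds A \code{\link{waveform_dataset}} (>= 8 items, both classes).
#' @param cfg A \code{\link{run_config}}.
#' @param seed Integer RNG seed.
#' @return An object of class \code{waveclass_report}: list with
#'   \code{predicted} (factor), \code{prob_gc}, \code{accuracy},
#'   \code{false_positive_count}, \code{false_negative_count} and per-fold
#'   \code{folds} metadata.
#' @export
loo_classify_waveforms <- function(ds, cfg = run_config(), seed = 0L) {
  X <- ds$features
  y <- ds$labels
  n <- nrow(X)
  if (n < 8) stop("need at least 8 items")
  with_seed(seed, {
    prob <- numeric(n)
    folds <- vector("list", n)
    for (i in seq_len(n)) {
      ytr <- y[-i]
      if (length(unique(ytr)) < 2) stop("a class is absent from a training fold")
      bal <- adasyn_oversample(X[-i, , drop = FALSE], ytr,
                               seed = sample.int(.Machine$integer.max, 1))
      yb <- as.numeric(bal$labels == "GC")
      net <- nn_train(bal$features, yb, hidden = cfg$nn_hidden,
                      val_frac = cfg$nn_val_frac,
                      max_val_fail = cfg$nn_max_val_fail,
                      max_epochs = cfg$nn_max_epochs)
      prob[i] <- net$predict(X[i, , drop = FALSE])
      folds[[i]] <- list(epochs = net$epochs, val_loss = net$val_loss,
                         n_synthetic = bal$n_synthetic)
    }
    pred <- factor(ifelse(prob >= 0.5, "GC", "nonGC"),
                   levels = c("nonGC", "GC"))
    correct <- pred == y
    structure(list(
      predicted = pred, prob_gc = prob, accuracy = mean(correct),
      false_positive_count = sum(pred == "GC" & y == "nonGC"),
      false_negative_count = sum(pred == "nonGC" & y == "GC"),
      folds = folds, labels = y
    ), class = "waveclass_report")
  })
}

#' @export
print.waveclass_report <- function(x, ...) {
  n <- length(x$predicted)
  cat(sprintf(paste0("<waveclass_report> accuracy %.0f%% (%d/%d), ",
                     "FP %d, FN %d\n"),
              100 * x$accuracy, round(x$accuracy * n), n,
              x$false_positive_count, x$false_negative_count))
  invisible(x)
}
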