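#' Z-score feature columns
#'
#' Centers and scales columns to mean 0 / SD 1, using the population
#' (divide-by-n) standard deviation, so a two-point column {0, 2} maps to
#' {-1, 1}. Constant columns are dropped with a warning. When
#' \code{center}/\code{scale} are supplied (e.g. computed on the training
#' rows of a cross-validation fold) they are applied as-is, so held-out rows
#' are scaled with training statistics only.
#'
#' @param X Numeric matrix, >= 2 rows (unless \code{center} supplied).
#' @param center,scale Optional per-column statistics to apply.
#' @return Scaled matrix with attributes \code{center}, \code{scale} and
#'   \code{kept} (surviving column indices of the input).
#' @export
zscore_features <- function(X, center = NULL, scale = NULL) {
  X <- as.matrix(X)
  if (is.null(center)) {
    stopifnot(nrow(X) >= 2)
    center <- colMeans(X)
    scale <- sqrt(colMeans(sweep(X, 2, center)^2))
    kept <- which(scale > 0)
    if (length(kept) < ncol(X)) {
      warning("dropping constant column(s): ",
              paste(colnames(X)[setdiff(seq_len(ncol(X)), kept)],
                    collapse = ", "))
    }
    center <- center[kept]
    scale <- scale[kept]
  } else {
    kept <- attr(center, "kept")
    if (is.null(kept)) kept <- seq_len(ncol(X))
  }
  Xs <- sweep(sweep(X[, kept, drop = FALSE], 2, center), 2, scale, `/`)
  attr(center, "kept") <- kept
  structure(Xs, center = center, scale = scale, kept = kept)
}

#' Lambda path for the elastic-net
#'
#' 100 log-spaced values (default) from the smallest lambda that zeroes all
#' weights down by a factor of 1e-4.
#'
#' @param X Standardized feature matrix.
#' @param y 0/1 response.
#' @param alpha Elastic-net mixing parameter in (0, 1]; alpha = 1 is the
#'   lasso, small alpha approaches ridge.
#' @param nlambda Path length.
#' @param min_ratio Ratio of the smallest to the largest lambda.
#' @return Decreasing numeric vector of penalties.
#' @export
enet_lambda_path <- function(X, y, alpha, nlambda = 100L, min_ratio = 1e-4) {
  n <- nrow(X)
  lam_max <- max(abs(crossprod(X, y - mean(y)))) / (n * max(alpha, 1e-3))
  lam_max <- max(lam_max, 1e-6)
  exp(seq(log(lam_max), log(lam_max * min_ratio), length.out = nlambda))
}

binomial_deviance <- function(p, y) {
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

as01 <- function(y) {
  if (is.factor(y)) {
    as.numeric(y == levels(y)[2])
  } else if (is.character(y)) {
    as.numeric(y == sort(unique(y))[2])
  } else {
    as.numeric(y)
  }
}

make_folds <- function(y, k) {
  # stratified fold assignment; caller controls RNG state
  id <- integer(length(y))
  for (cl in unique(y)) {
    rows <- which(y == cl)
    id[rows] <- sample(rep_len(seq_len(k), length(rows)))
  }
  id
}

#' Fit a sparse logistic classifier with inner-CV penalty selection
#'
#' Fits the elastic-net penalized logistic regression — penalized deviance
#' with penalty lambda * ((1 - alpha)/2 * ||b||_2^2 + alpha * ||b||_1),
#' intercept unpenalized — along a lambda path by coordinate descent, runs
#' an inner cross-validation to obtain the deviance curve over the path, and
#' selects the penalty by the 1-SE rule: the largest lambda (strongest
#' regularization) whose mean CV deviance is within one standard error of
#' the minimum. Features are z-scored internally; within each inner fold the
#' scaling is computed on that fold's training rows only.
#'
#' @param X Feature matrix (raw scale), both classes present in \code{y}.
#' @param y Labels: 0/1, logical, or a factor whose second level is coded 1.
#' @param alpha Elastic-net mixing parameter.
#' @param cfg A \code{\link{run_config}} (path length, min ratio, inner-fold
#'   policy: leave-one-out when the training set has at most
#'   \code{inner_loo_max_n} rows, 10-fold otherwise).
#' @param lambda Optional explicit lambda path.
#' @return An object of class \code{enet_fit}: list with \code{weights}
#'   (named, on the z-scored feature scale), \code{intercept},
#'   \code{lambda_1se}, \code{lambda_min}, \code{lambda}, \code{cv_mean},
#'   \code{cv_se}, \code{center}, \code{scale} and \code{alpha}. Predict
#'   with \code{\link{predict.enet_fit}}.
#' @export
fit_enet_logistic <- function(X, y, alpha, cfg = run_config(),
                              lambda = NULL) {
  X <- as.matrix(X)
  y01 <- as01(y)
  if (length(unique(y01)) < 2) stop("both classes must be present")
  n <- nrow(X)

  Xs <- zscore_features(X)
  if (is.null(lambda)) {
    lambda <- enet_lambda_path(Xs, y01, alpha, cfg$enet_nlambda,
                               cfg$enet_lambda_min_ratio)
  }

  if (n <= cfg$inner_loo_max_n) {
    foldid <- seq_len(n)
    k <- n
  } else {
    k <- 10L
    foldid <- make_folds(y01, k)
  }

  dev <- enet_cv_deviance_cpp(X, y01, alpha, lambda, as.integer(foldid))
  used <- !is.na(dev[, 1])
  if (!any(used)) stop("all inner folds skipped (a class is too small)")
  if (any(!used)) {
    warning(sum(!used), " inner fold(s) with one class only; skipped")
  }
  cv_mean <- colMeans(dev[used, , drop = FALSE])
  cv_se <- apply(dev[used, , drop = FALSE], 2, stats::sd) / sqrt(sum(used))
  i_min <- which.min(cv_mean)
  ok <- which(cv_mean <= cv_mean[i_min] + cv_se[i_min])
  i_1se <- min(ok)  # lambda is decreasing: smallest index = largest lambda

  B <- enet_logistic_path_cpp(Xs, y01, alpha, lambda)
  w <- B[-1, i_1se]
  names(w) <- colnames(X)[attr(Xs, "kept")]
  structure(list(weights = w, intercept = B[1, i_1se],
                 lambda_1se = lambda[i_1se], lambda_min = lambda[i_min],
                 lambda = lambda, cv_mean = cv_mean, cv_se = cv_se,
                 center = attr(Xs, "center"), scale = attr(Xs, "scale"),
                 alpha = alpha, n = n),
            class = "enet_fit")
}

#' @export
print.enet_fit <- function(x, ...) {
  cat(sprintf("<enet_fit> alpha=%.2g, lambda_1se=%.4g, %d/%d nonzero weights\n",
              x$alpha, x$lambda_1se, sum(x$weights != 0), length(x$weights)))
  invisible(x)
}

#' @export
coef.enet_fit <- function(object, ...) {
  c(intercept = object$intercept, object$weights)
}

#' Predict from a sparse logistic fit
#'
#' @param object An \code{\link{fit_enet_logistic}} result.
#' @param newdata Feature matrix on the raw scale.
#' @param type \code{"response"} (probability of the positive class) or
#'   \code{"class"} (0/1 at threshold 0.5).
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.enet_fit <- function(object, newdata, type = c("response", "class"),
                             ...) {
  type <- match.arg(type)
  Z <- zscore_features(as.matrix(newdata), center = object$center,
                       scale = object$scale)
  eta <- drop(Z %*% object$weights) + object$intercept
  p <- 1 / (1 + exp(-eta))
  if (type == "class") as.numeric(p >= 0.5) else p
}

#' Nested leave-one-out classification of active vs silent cells
#'
#' The outer loop iterates over each cell, training the full inner pipeline
#' (z-scoring on training rows, elastic-net path fit, inner-CV 1-SE penalty
#' choice) on the remaining cells and predicting the held-out cell; the
#' reported accuracy is therefore fully cross-validated. Weight vectors from
#' the n outer fits are summarized as mean +/- SEM per feature, for each
#' mixing parameter alpha.
#'
#' Held-out predictions are thresholded at the training fold's positive-class
#' fraction (equivalently, the linear predictor is compared against the null
#' model's intercept) rather than at probability 0.5. This removes the
#' well-known anti-bias of leave-one-out evaluation with strongly shrunk
#' models: under exact class balance an intercept-only fit would otherwise
#' always predict the training fold's majority class, which is by
#' construction the class opposite to the held-out cell, pushing
#' chance-level accuracy far below 50%.
#'
#' @param X n x 10 matrix of primary dendritic features (total length,
#'   per-order lengths 1-7, number of primary dendrites, number of endings);
#'   any numeric feature matrix is accepted.
#' @param y Labels (factor silent/active, or 0/1 with 1 = active).
#' @param cfg A \code{\link{run_config}}.
#' @param alphas Mixing parameters (default \code{cfg$enet_alphas}).
#' @param seed RNG seed (fold assignment when inner CV is 10-fold).
#' @return An object of class \code{morph_class_report}: per-alpha list with
#'   \code{predicted} (0/1), \code{prob}, \code{accuracy},
#'   \code{weight_mean}, \code{weight_sem} and \code{lambda_1se} per fold;
#'   plus \code{accuracy} (named per-alpha vector), \code{n} and
#'   \code{labels}.
#' @export
nested_loo_classify <- function(X, y, cfg = run_config(),
                                alphas = cfg$enet_alphas,
                                seed = cfg$rng_seed) {
  X <- as.matrix(X)
  y01 <- as01(y)
  n <- nrow(X)
  if (n < 6) stop("need at least 6 cells")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))

  per_alpha <- with_seed(seed, lapply(alphas, function(a) {
    prob <- numeric(n)
    thr <- numeric(n)
    W <- matrix(NA_real_, n, ncol(X), dimnames = list(NULL, colnames(X)))
    lam <- numeric(n)
    for (i in seq_len(n)) {
      fit <- fit_enet_logistic(X[-i, , drop = FALSE], y01[-i], a, cfg)
      prob[i] <- predict(fit, X[i, , drop = FALSE])
      thr[i] <- mean(y01[-i])
      W[i, names(fit$weights)] <- fit$weights
      lam[i] <- fit$lambda_1se
    }
    pred <- as.numeric(prob >= thr - 1e-9)
    list(alpha = a, predicted = pred, prob = prob,
         accuracy = mean(pred == y01),
         weight_mean = colMeans(W, na.rm = TRUE),
         weight_sem = apply(W, 2, stats::sd, na.rm = TRUE) / sqrt(n),
         lambda_1se = lam)
  }))
  names(per_alpha) <- paste0("alpha_", alphas)
  acc <- vapply(per_alpha, `[[`, numeric(1), "accuracy")
  names(acc) <- alphas
  structure(list(per_alpha = per_alpha, accuracy = acc, n = n,
                 labels = y01, alphas = alphas),
            class = "morph_class_report")
}

#' @export
print.morph_class_report <- function(x, ...) {
  cat(sprintf("<morph_class_report> n=%d cells, leave-one-out accuracy:\n",
              x$n))
  for (a in names(x$per_alpha)) {
    pa <- x$per_alpha[[a]]
    cat(sprintf("  alpha=%-5g %.0f%% (%d/%d correct)\n", pa$alpha,
                100 * pa$accuracy, round(pa$accuracy * x$n), x$n))
  }
  invisible(x)
}

#' @export
coef.morph_class_report <- function(object, alpha = object$alphas[1], ...) {
  pa <- object$per_alpha[[paste0("alpha_", alpha)]]
  if (is.null(pa)) stop("alpha not in the report")
  cbind(mean = pa$weight_mean, sem = pa$weight_sem)
}

#' @export
plot.morph_class_report <- function(x, alpha = x$alphas[1], ...) {
  w <- coef(x, alpha = alpha)
  bp <- graphics::barplot(w[, "mean"], las = 2,
                          ylab = "weight (mean over folds)",
                          main = sprintf("alpha = %g", alpha), ...)
  graphics::arrows(bp, w[, "mean"] - w[, "sem"], bp, w[, "mean"] + w[, "sem"],
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Label-permutation significance test for the classifier
#'
#' Shuffles the cell labels and repeats the entire nested cross-validation
#' and classification procedure to build a null distribution of accuracies;
#' the p-value is the fraction of permutation runs with accuracy greater
#' than or equal to the observed one (no +1 correction). Run at a single
#' mixing parameter (\code{cfg$perm_alpha}, default 0.1). An exact zero is
#' flagged as "< 1/perm_runs" via the \code{p_lt} element.
#'
#' @param X,y As in \code{\link{nested_loo_classify}}.
#' @param cfg A \code{\link{run_config}} (\code{perm_runs},
#'   \code{perm_alpha}).
#' @param seed RNG seed.
#' @return List with \code{p}, \code{p_lt} (upper bound when \code{p} is 0),
#'   \code{observed_accuracy}, \code{perm_accuracy} (vector) and
#'   \code{perm_runs}.
#' @export
permutation_test <- function(X, y, cfg = run_config(), seed = cfg$rng_seed) {
  if (cfg$perm_runs < 20) {
    warning("fewer than 20 permutation runs: p-value resolution is coarse")
  }
  y01 <- as01(y)
  obs <- nested_loo_classify(X, y01, cfg, alphas = cfg$perm_alpha,
                             seed = seed)$accuracy[1]
  perm <- with_seed(seed + 1L, {
    vapply(seq_len(cfg$perm_runs), function(r) {
      yp <- sample(y01)
      nested_loo_classify(X, yp, cfg, alphas = cfg$perm_alpha,
                          seed = seed)$accuracy[1]
    }, numeric(1))
  })
  p <- sum(perm >= obs) / cfg$perm_runs
  list(p = p, p_lt = if (p == 0) 1 / cfg$perm_runs else NA_real_,
       observed_accuracy = unname(obs), perm_accuracy = perm,
       perm_runs = cfg$perm_runs)
}
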