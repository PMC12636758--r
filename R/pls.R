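#' Fit a partial least squares regression model
#'
#' Single-response PLSR by NIPALS-style covariance-maximizing deflation
#' (for one response this coincides with SIMPLS). Predictors and
#' response are mean-centered; no variance scaling is applied unless
#' `scale = TRUE`. Each component's weight vector is the normalized
#' covariance `X'y`; scores are mutually orthogonal; `X` and `y` are
#' deflated by the extracted component. The regression vector is
#' `beta = W (P'W)^{-1} q`, giving predictions
#' `yhat = ybar + (x - xbar) beta`.
#'
#' @param X n x p predictor matrix (rows = specimens, columns = spectral
#'   channels).
#' @param y Numeric response vector of length n (T-scores).
#' @param rank Number of latent components A, `1 <= A <= min(n-1, p)`.
#' @param scale Divide predictor columns by their sd before fitting
#'   (default FALSE).
#' @return Object of class `pls_model`: achieved `rank`, centering
#'   means, `weights` (W), `loadings` (P), `scores` (T), `q`,
#'   projection `R = W (P'W)^{-1}`, and coefficient vector `coef`.
#' @export
fit_pls <- function(X, y, rank, scale = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("X and y must be finite", call. = FALSE)
  }
  rank <- as.integer(rank)
  if (rank < 1 || rank > min(n - 1, p)) {
    stop("`rank` must lie in [1, min(n-1, p)] = [1, ", min(n - 1, p), "]",
      call. = FALSE
    )
  }
  x_mean <- colMeans(X)
  x_scale <- if (scale) {
    s <- apply(X, 2, sd)
    s[s == 0] <- 1
    s
  } else {
    rep(1, p)
  }
  y_mean <- mean(y)
  Xc <- sweep(sweep(X, 2, x_mean), 2, x_scale, "/")
  yc <- y - y_mean
  W <- P <- matrix(0, p, rank)
  Tm <- matrix(0, n, rank)
  q <- numeric(rank)
  tol <- .Machine$double.eps^0.5 * sqrt(sum(Xc^2) / p) * max(1, sqrt(sum(yc^2)))
  achieved <- 0L
  for (a in seq_len(rank)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw <= tol) {
      warning("weight vector vanished at component ", a,
        "; model truncated to rank ", achieved,
        call. = FALSE
      )
      break
    }
    w <- w / nw
    t_a <- drop(Xc %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(Xc, t_a)) / tt
    q_a <- sum(yc * t_a) / tt
    Xc <- Xc - tcrossprod(t_a, p_a)
    yc <- yc - q_a * t_a
    W[, a] <- w
    P[, a] <- p_a
    Tm[, a] <- t_a
    q[a] <- q_a
    achieved <- a
  }
  if (achieved == 0L) stop("no PLS component could be extracted", call. = FALSE)
  W <- W[, seq_len(achieved), drop = FALSE]
  P <- P[, seq_len(achieved), drop = FALSE]
  Tm <- Tm[, seq_len(achieved), drop = FALSE]
  q <- q[seq_len(achieved)]
  R <- W %*% solve(crossprod(P, W))
  structure(
    list(
      rank = achieved, x_mean = x_mean, x_scale = x_scale,
      y_mean = y_mean, weights = W, loadings = P, scores = Tm, q = q,
      R = R, coef = drop(R %*% q)
    ),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf(
    "PLS model: rank %d, %d predictors\n", x$rank, length(x$coef)
  ))
  invisible(x)
}

#' Predict responses from a PLS model
#'
#' `yhat = ybar + (x - xbar) beta`, with beta truncated to the first
#' `rank` components when requested.
#'
#' @param model A `pls_model`.
#' @param x Spectrum vector of length p, or an m x p matrix.
#' @param rank Use only the first `rank` components (default: the
#'   model's full rank).
#' @return Numeric vector of predicted T-scores.
#' @export
predict_pls <- function(model, x, rank = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model$x_mean)) {
    stop("predictor length mismatch: expected ", length(model$x_mean),
      call. = FALSE
    )
  }
  beta <- if (is.null(rank) || rank >= model$rank) {
    model$coef
  } else {
    if (rank < 1) stop("`rank` must be >= 1", call. = FALSE)
    drop(model$R[, seq_len(rank), drop = FALSE] %*% model$q[seq_len(rank)])
  }
  Xc <- sweep(sweep(x, 2, model$x_mean), 2, model$x_scale, "/")
  drop(model$y_mean + Xc %*% beta)
}

#' Leave-one-out cross-validated rank selection for PLSR
#'
#' For each candidate rank A, every specimen is predicted by a model
#' fitted to the remaining n-1 (centering recomputed inside each fold,
#' so no statistic of the held-out specimen enters its training), and
#' `RMSE_CV(A)` is the root-mean-square of those errors. The optimal
#' rank minimizes RMSE_CV (ties broken toward the smaller rank); the
#' reported predictions are the LOO predictions at that rank.
#' `per_fold = TRUE` instead selects the rank inside each training fold
#' by a nested LOO sweep.
#'
#' @param X n x p predictor matrix.
#' @param y Length-n response (T-scores).
#' @param ranks Candidate ranks (default 1:9). Ranks exceeding a fold's
#'   admissible maximum are capped with a warning.
#' @param per_fold Select the rank per fold by nested LOO (default
#'   FALSE: one global rank from the full sweep).
#' @param scale Passed to [fit_pls()].
#' @return Object of class `cv_result`: `rmse_cv` (per rank, global
#'   scheme), `optimal_rank`, `predictions` (LOO, one per specimen),
#'   `r`, `rmse`, `true_class`, `predicted_class`, `accuracy`,
#'   `scheme`.
#' @export
loocv_select_rank <- function(X, y, ranks = 1:9, per_fold = FALSE,
                              scale = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("LOOCV needs at least 3 specimens", call. = FALSE)
  ranks <- sort(unique(as.integer(ranks)))
  if (!length(ranks) || any(ranks < 1)) {
    stop("`ranks` must be positive integers", call. = FALSE)
  }
  fold_max <- min(n - 2, ncol(X))
  if (max(ranks) > fold_max) {
    warning("ranks above ", fold_max,
      " capped to the admissible fold maximum",
      call. = FALSE
    )
  }
  preds <- matrix(NA_real_, n, length(ranks))
  for (i in seq_len(n)) {
    m <- fit_pls(X[-i, , drop = FALSE], y[-i], min(max(ranks), fold_max),
      scale = scale
    )
    for (j in seq_along(ranks)) {
      preds[i, j] <- predict_pls(m, X[i, ], rank = min(ranks[j], m$rank))
    }
  }
  rmse_cv <- sqrt(colMeans((preds - y)^2))
  names(rmse_cv) <- as.character(ranks)
  opt <- ranks[which.min(rmse_cv)]

  if (per_fold) {
    pred_final <- numeric(n)
    for (i in seq_len(n)) {
      inner <- loocv_select_rank(X[-i, , drop = FALSE], y[-i],
        ranks = ranks, per_fold = FALSE, scale = scale
      )
      m <- fit_pls(X[-i, , drop = FALSE], y[-i],
        min(inner$optimal_rank, fold_max),
        scale = scale
      )
      pred_final[i] <- predict_pls(m, X[i, ])
    }
    scheme <- "per-fold"
  } else {
    pred_final <- preds[, which.min(rmse_cv)]
    scheme <- "global"
  }
  metrics <- regression_metrics(y, pred_final)
  true_cls <- classify_who(y)
  pred_cls <- classify_who(pred_final)
  structure(
    list(
      rmse_cv = rmse_cv, optimal_rank = opt, predictions = pred_final,
      r = metrics$r, rmse = metrics$rmse,
      true_class = true_cls, predicted_class = pred_cls,
      accuracy = classification_accuracy(true_cls, pred_cls),
      scheme = scheme, ranks = ranks
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "LOOCV PLSR (%s rank selection): optimal rank %d, r = %.3f, RMSE_CV = %.3f, accuracy = %.0f%%\n",
    x$scheme, x$optimal_rank, x$r, x$rmse, 100 * x$accuracy
  ))
  invisible(x)
}

#' Pearson correlation and RMSE of predictions
#'
#' @param y_true,y_pred Numeric vectors of equal length >= 2.
#' @return List with `r` (NA with a warning when `y_true` is constant)
#'   and `rmse`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2) {
    stop("need two equal-length vectors of length >= 2", call. = FALSE)
  }
  r <- if (sd(y_true) == 0) {
    warning("constant y_true: Pearson r undefined", call. = FALSE)
    NA_real_
  } else if (sd(y_pred) == 0) {
    NA_real_
  } else {
    cor(y_true, y_pred)
  }
  list(r = r, rmse = sqrt(mean((y_true - y_pred)^2)))
}

#' Fraction of correctly classified specimens
#'
#' @param true_classes,pred_classes Factors or character vectors of
#'   equal length.
#' @return Fraction of exact class matches in \[0, 1\].
#' @export
classification_accuracy <- function(true_classes, pred_classes) {
  if (length(true_classes) != length(pred_classes) ||
    length(true_classes) < 1) {
    stop("need two equal-length, nonempty class vectors", call. = FALSE)
  }
  mean(as.character(true_classes) == as.character(pred_classes))
}
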