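#' Fit a PLS regression model (NIPALS)
#'
#' Univariate-response NIPALS partial least squares.  X and y are
#' mean-centred on the training set; no autoscaling is applied beyond the
#' block scaling performed upstream.  Initialization is deterministic from
#' the y vector.
#'
#' @param X descriptor matrix (n x p).
#' @param y response vector (length n).
#' @param c number of latent components, `c <= rank of centred X` and
#'   `c < n - 1`.
#' @param block_labels optional per-column block labels; enables per-field
#'   contribution fractions.
#' @return Object of class `qsar_pls`: coefficients and intercept on the
#'   input descriptor scale, fitted values, r2, SEE, F, n_components,
#'   field contributions.
#' @export
fit_pls <- function(X, y, c, block_labels = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (n < 3) stop("need at least 3 training samples")
  if (c >= n - 1) stop("number of components must be < n - 1")
  if (stats::sd(y) == 0) stop("response has zero variance")
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  fit <- nipals_pls(Xc, yc, c)
  beta <- fit$beta
  b0 <- ym - sum(xm * beta)
  fitted <- as.numeric(X %*% beta) + b0
  rss <- sum((y - fitted)^2); tss <- sum((y - ym)^2)
  r2 <- 1 - rss / tss
  see <- sqrt(rss / (n - c - 1))
  fstat <- (r2 / (1 - r2)) * ((n - c - 1) / c)
  contrib <- NULL
  if (!is.null(block_labels)) {
    w <- abs(beta) * apply(X, 2, stats::sd)
    contrib <- tapply(w, block_labels, sum)
    contrib <- contrib / sum(contrib)
  }
  structure(list(n_components = c, coefficients = as.numeric(beta),
                 intercept = b0, fitted = fitted, r2 = r2, SEE = see,
                 F = fstat, q2 = NA_real_, n = n,
                 field_contributions = contrib,
                 x_mean = xm, y_mean = ym),
            class = "qsar_pls")
}

# Core NIPALS on centred data.  With a single response the inner loop
# converges in one pass but is kept (tol 1e-12, max 500 iterations) for
# form's sake; the weight vector is initialised from y.
nipals_pls <- function(Xc, yc, c, tol = 1e-12, max_iter = 500L) {
  p <- ncol(Xc)
  W <- matrix(0, p, c); P <- matrix(0, p, c); Cc <- numeric(c)
  Xa <- Xc; ya <- yc
  for (a in seq_len(c)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14)
      stop("rank exhausted: component ", a, " has zero weight vector")
    w <- w / nw
    for (it in seq_len(max_iter)) {
      t_ <- Xa %*% w
      c_ <- sum(ya * t_) / sum(t_^2)
      w_new <- crossprod(Xa, ya) / nw
      w_new <- w_new / sqrt(sum(w_new^2))
      if (sqrt(sum((w_new - w)^2)) < tol) { w <- w_new; break }
      w <- w_new
    }
    t_ <- as.numeric(Xa %*% w)
    tt <- sum(t_^2)
    p_ <- as.numeric(crossprod(Xa, t_)) / tt
    c_ <- sum(ya * t_) / tt
    W[, a] <- w; P[, a] <- p_; Cc[a] <- c_
    Xa <- Xa - tcrossprod(t_, p_)
    ya <- ya - c_ * t_
  }
  beta <- W %*% solve(crossprod(P, W), Cc)
  list(beta = as.numeric(beta), W = W, P = P, C = Cc)
}

#' @export
print.qsar_pls <- function(x, ...) {
  cat(sprintf("<qsar_pls: %d components, r2=%.3f, SEE=%.3f, F=%.3f%s>\n",
              x$n_components, x$r2, x$SEE, x$F,
              ifelse(is.na(x$q2), "", sprintf(", q2=%.3f", x$q2))))
  if (!is.null(x$field_contributions)) {
    cat("  field contributions:",
        paste(sprintf("%s=%.3f", names(x$field_contributions),
                      x$field_contributions), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict activities from a fitted PLS model
#'
#' @param object `qsar_pls` model.
#' @param newdata descriptor rows built on the training layout (see
#'   [descriptor_rows()]).
#' @param ... unused.
#' @return numeric vector of predicted activities.
#' @export
predict.qsar_pls <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients))
    stop("descriptor column mismatch: model has ",
         length(object$coefficients), ", rows have ", ncol(newdata))
  as.numeric(newdata %*% object$coefficients) + object$intercept
}

#' Leave-one-out cross-validated q2 per component count
#'
#' `q2(c) = 1 - PRESS(c) / sum((y - mean(y))^2)` with PRESS from
#' leave-one-out prediction and the full-training-set mean of y in the
#' denominator (the SAMPLS convention).  The default fast path works in
#' the n x n Gram-matrix (sample-distance) formulation and is numerically
#' identical to refitting each fold; `method = "refit"` does the explicit
#' n-refit and exists as the slow reference route.
#'
#' @param X descriptor matrix.
#' @param y response.
#' @param c_max maximum component count to evaluate.
#' @param method "sampls" (kernel fast path) or "refit".
#' @return numeric vector `q2[1:c_max]`, with attribute "press".
#' @export
loo_q2 <- function(X, y, c_max, method = c("sampls", "refit")) {
  method <- match.arg(method)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 samples for LOO")
  c_max <- min(c_max, n - 3)
  pred <- loo_predictions_all(X, y, c_max, method)
  tss <- sum((y - mean(y))^2)
  press <- colSums((y - pred)^2)
  q2 <- 1 - press / tss
  attr(q2, "press") <- press
  attr(q2, "loo_pred") <- pred
  q2
}

# n x c_max matrix of LOO predictions for each component count
loo_predictions_all <- function(X, y, c_max, method) {
  n <- nrow(X)
  pred <- matrix(NA_real_, n, c_max)
  if (method == "refit") {
    for (i in seq_len(n)) {
      for (cc in seq_len(c_max)) {
        fit <- fit_pls(X[-i, , drop = FALSE], y[-i], cc)
        pred[i, cc] <- predict(fit, X[i, , drop = FALSE])
      }
    }
    return(pred)
  }
  G <- tcrossprod(X)                     # raw Gram, n x n
  for (i in seq_len(n)) {
    T_ <- setdiff(seq_len(n), i)
    m <- length(T_)
    Gtt <- G[T_, T_]; gi <- G[i, T_]
    rm_ <- rowMeans(Gtt); gm <- mean(Gtt)
    K <- sweep(sweep(Gtt, 1, rm_), 2, rm_) + gm       # double centring
    k <- gi - mean(gi) - rm_ + gm                      # centred cross row
    ybar <- mean(y[T_]); ya <- y[T_] - ybar
    Ka <- K; ka <- k
    acc <- ybar
    for (a in seq_len(c_max)) {
      nu2 <- sum(ya * (Ka %*% ya))
      if (nu2 < 1e-14) { pred[i, a:c_max] <- acc; break }
      nu <- sqrt(nu2)
      t_ <- as.numeric(Ka %*% ya) / nu
      tstar <- sum(ka * ya) / nu
      tt <- sum(t_^2)
      c_ <- sum(ya * t_) / tt
      acc <- acc + tstar * c_
      pred[i, a] <- acc
      that <- t_ / sqrt(tt)
      # deflate: X_{a+1} = (I - that that') X_a
      Kt <- Ka %*% that
      ka <- ka - tstar / sqrt(tt) * as.numeric(crossprod(that, Ka))
      ka <- ka - sum(ka * that) * that
      Ka <- Ka - tcrossprod(Kt, that) - tcrossprod(that, Kt) +
        sum(that * Kt) * tcrossprod(that)
      ya <- ya - c_ * t_
    }
  }
  pred
}

#' Leave-one-out predictions at a fixed component count
#'
#' @param X descriptor matrix.
#' @param y response.
#' @param c component count.
#' @param method see [loo_q2()].
#' @return numeric vector of LOO-predicted responses.
#' @export
loo_predictions <- function(X, y, c, method = c("sampls", "refit")) {
  method <- match.arg(method)
  loo_predictions_all(as.matrix(X), as.numeric(y), c, method)[, c]
}

#' Optimal number of components
#'
#' The smallest component count achieving the maximum q2 (ties break to
#' fewer components).
#'
#' @param q2_by_c numeric vector of q2 values indexed by component count.
#' @return integer ONC.
#' @export
select_onc <- function(q2_by_c) {
  if (!length(q2_by_c)) stop("empty q2 vector")
  which.max(q2_by_c)[1]
}

#' Fit a cross-validated QSAR model
#'
#' Convenience wrapper: runs [loo_q2()] up to `c_max`, selects the ONC,
#' refits without cross-validation at that count and attaches q2.
#'
#' @param desc `qsar_descriptors` (training).
#' @param y training activities.
#' @param c_max maximum components (default 10, capped at n - 3).
#' @return `qsar_pls` with `q2`, `onc_q2_curve` and descriptor reference.
#' @export
fit_qsar <- function(desc, y, c_max = 10) {
  q2s <- loo_q2(desc$X, y, c_max)
  onc <- select_onc(q2s)
  model <- fit_pls(desc$X, y, onc, block_labels = desc$block_labels)
  model$q2 <- q2s[onc]
  model$onc_q2_curve <- as.numeric(q2s)
  model$loo_pred <- attr(q2s, "loo_pred")[, onc]
  model
}
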