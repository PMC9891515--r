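#' Center and scale a data block
#'
#' Column-wise autoscaling used by the PLS engine: `"uv"` (unit variance,
#' the chemometrics default) divides each centered column by its sample
#' standard deviation (n - 1 denominator), `"pareto"` by the square root of
#' the standard deviation, `"center"` only subtracts the mean. Zero-variance
#' columns get scale 1 (so they become all-zero) and are flagged rather than
#' made an error; the inverse transform is recoverable from the returned
#' vectors.
#'
#' @param x Numeric matrix with no missing values.
#' @param policy `"uv"`, `"center"`, or `"pareto"`.
#' @return List with `values`, `center`, `scale`, `zero_variance` (logical
#'   per column).
#' @export
autoscale <- function(x, policy = c("uv", "center", "pareto")) {
  policy <- match.arg(policy)
  x <- as.matrix(x)
  if (anyNA(x)) stop("autoscale expects a complete matrix", call. = FALSE)
  ctr <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  zero <- sds < .Machine$double.eps * 1e3
  scl <- switch(policy,
                uv = ifelse(zero, 1, sds),
                pareto = ifelse(zero, 1, sqrt(sds)),
                center = rep(1, ncol(x)))
  vals <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
  list(values = vals, center = ctr, scale = scl, zero_variance = zero)
}

#' Fit a multi-response PLS model by NIPALS
#'
#' Fits partial least squares regression of a response block `Y` on an
#' explanatory block `X`, extracting `ncomp` latent components that maximize
#' the covariance between X-scores and Y-scores. Both blocks are centered and
#' scaled internally according to `scale`. Components are computed by the
#' NIPALS algorithm with deflation of both blocks; the inner loop starts from
#' the (deflated) Y column with the largest variance, a deterministic choice,
#' and each component's weight sign is fixed so that the largest-magnitude
#' X-weight is positive, making the fit invariant to Y column order.
#'
#' Per-component variance shares are Frobenius fractions of the initial
#' scaled blocks: `r2x[a] = ||t_a p_a'||^2 / ||X0||^2` and analogously for
#' `r2y`.
#'
#' @param X Numeric matrix, samples x variables (no missing values).
#' @param Y Numeric matrix or vector, samples x responses.
#' @param ncomp Number of components, at most `min(nrow(X) - 1, ncol(X))`.
#' @param scale Scaling policy for both blocks, see [autoscale()].
#' @param tol Convergence tolerance of the NIPALS inner loop (relative
#'   change of the score vector).
#' @param max_iter Maximum inner-loop iterations per component.
#'
#' @return An object of class `pls_model`: weights `W` (K x A), X-loadings
#'   `P`, Y-weights `C` (M x A), scores `T` and `U` (n x A), cumulative
#'   regression coefficients `B` (K x M, scaled space), per-component `r2x`
#'   and `r2y`, and the centering/scaling vectors of both blocks.
#' @seealso [predict.pls_model()], [compute_vip()], [cross_validate()]
#' @export
fit_pls <- function(X, Y, ncomp, scale = "uv", tol = 1e-10, max_iter = 10000L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("y%d", seq_len(ncol(Y)))
  n <- nrow(X); K <- ncol(X); M <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y disagree on sample count", call. = FALSE)
  if (anyNA(X) || anyNA(Y)) {
    stop("PLS blocks must be complete; impute upstream", call. = FALSE)
  }
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1 || ncomp > min(n - 1, K)) {
    stop("ncomp must lie in 1..min(n-1, K) = 1..", min(n - 1, K),
         call. = FALSE)
  }
  sx <- autoscale(X, scale)
  sy <- autoscale(Y, scale)
  E <- sx$values; F_ <- sy$values
  ssx0 <- sum(E^2); ssy0 <- sum(F_^2)
  if (ssy0 < .Machine$double.eps) {
    stop("response block has no variance", call. = FALSE)
  }
  W <- P <- matrix(0, K, ncomp, dimnames = list(colnames(X), NULL))
  C <- matrix(0, M, ncomp, dimnames = list(colnames(Y), NULL))
  Tm <- U <- matrix(0, n, ncomp, dimnames = list(rownames(X), NULL))
  r2x <- r2y <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    col_var <- apply(F_, 2, stats::var)
    if (max(col_var) < 1e-24) {
      stop("response block exhausted before component ", a,
           "; request fewer components", call. = FALSE)
    }
    u <- F_[, which.max(col_var)]
    t_old <- rep(Inf, n)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      w <- crossprod(E, u)[, 1]
      w <- w / sqrt(sum(w^2))
      t_ <- (E %*% w)[, 1]
      cc <- crossprod(F_, t_)[, 1] / sum(t_^2)
      u <- (F_ %*% cc)[, 1] / sum(cc^2)
      if (sqrt(sum((t_ - t_old)^2)) <= tol * sqrt(sum(t_^2))) break
      if (iter >= max_iter) {
        stop("NIPALS failed to converge for component ", a, call. = FALSE)
      }
      t_old <- t_
    }
    # deterministic sign: dominant X-weight positive
    if (w[which.max(abs(w))] < 0) {
      w <- -w; t_ <- -t_; cc <- -cc; u <- -u
    }
    p <- crossprod(E, t_)[, 1] / sum(t_^2)
    E <- E - tcrossprod(t_, p)
    F_ <- F_ - tcrossprod(t_, cc)
    W[, a] <- w; P[, a] <- p; C[, a] <- cc; Tm[, a] <- t_; U[, a] <- u
    r2x[a] <- sum(t_^2) * sum(p^2) / ssx0
    r2y[a] <- sum(t_^2) * sum(cc^2) / ssy0
  }
  model <- structure(list(
    ncomp = ncomp, W = W, P = P, C = C, T = Tm, U = U,
    r2x = r2x, r2y = r2y,
    x_center = sx$center, x_scale = sx$scale,
    y_center = sy$center, y_scale = sy$scale,
    x_zero_variance = sx$zero_variance, y_zero_variance = sy$zero_variance,
    scale_policy = scale,
    X_names = colnames(X), Y_names = colnames(Y), n = n),
    class = "pls_model")
  model$B <- pls_coefficients(model, ncomp)
  model
}

# cumulative regression coefficients (scaled space) for the first `a` comps:
# B_a = W_a (P_a' W_a)^-1 C_a'
pls_coefficients <- function(model, a) {
  Wa <- model$W[, seq_len(a), drop = FALSE]
  Pa <- model$P[, seq_len(a), drop = FALSE]
  Ca <- model$C[, seq_len(a), drop = FALSE]
  Wa %*% solve(crossprod(Pa, Wa), t(Ca))
}

#' Predict responses from a fitted PLS model
#'
#' Applies the stored centering/scaling of the training X block, the
#' cumulative regression coefficients for the first `ncomp` components, and
#' the inverse Y scaling. Rows are independent; predicting the training X
#' returns the in-sample fitted values, and a row equal to the X center maps
#' to the Y center.
#'
#' @param object A `pls_model`.
#' @param newdata Matrix with the same columns (in order) as the training X.
#' @param ncomp Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return Matrix of predicted responses on the original Y scale.
#' @export
predict.pls_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$X_names)) {
    stop("newdata has ", ncol(newdata), " columns but the model was fitted ",
         "with ", length(object$X_names), call. = FALSE)
  }
  ncomp <- as.integer(ncomp)
  if (ncomp < 1 || ncomp > object$ncomp) {
    stop("ncomp out of fitted range", call. = FALSE)
  }
  B <- if (ncomp == object$ncomp) object$B else pls_coefficients(object, ncomp)
  xs <- sweep(sweep(newdata, 2, object$x_center, "-"), 2, object$x_scale, "/")
  ys <- xs %*% B
  out <- sweep(sweep(ys, 2, object$y_scale, "*"), 2, object$y_center, "+")
  colnames(out) <- object$Y_names
  rownames(out) <- rownames(newdata)
  out
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model>\n")
  cat(sprintf("  %d samples, %d X variables, %d responses, %d components (%s scaling)\n",
              x$n, length(x$X_names), length(x$Y_names), x$ncomp,
              x$scale_policy))
  cat(sprintf("  R2X per component: %s\n",
              paste(sprintf("%.3f", x$r2x), collapse = ", ")))
  cat(sprintf("  R2Y per component: %s\n",
              paste(sprintf("%.3f", x$r2y), collapse = ", ")))
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' Summarizes the contribution of each X variable to the explained
#' Y-variance across all components:
#' `VIP_k = sqrt(K * sum_a(ssy_a * (w_ka / ||w_a||)^2) / sum_a(ssy_a))`,
#' where `ssy_a` is the Y-variance share explained by component `a`. The
#' mean of the squared VIPs equals 1 by construction, so variables with
#' VIP >= 1 contribute more than an average variable.
#'
#' @param model A fitted `pls_model`.
#' @return Named numeric vector of VIP scores over the X variables.
#' @export
compute_vip <- function(model) {
  ssy <- model$r2y
  if (sum(ssy) <= 0) {
    stop("model explains no Y variance; VIP undefined", call. = FALSE)
  }
  W <- model$W
  wn2 <- sweep(W^2, 2, colSums(W^2), "/")
  vip <- sqrt(nrow(W) * as.vector(wn2 %*% ssy) / sum(ssy))
  stats::setNames(vip, model$X_names)
}
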