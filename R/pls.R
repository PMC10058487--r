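#' Fit a PLS regression model by NIPALS
#'
#' From-scratch NIPALS partial least squares regression: PLS1 for a single
#' response, PLS2 for a multivariate response. Predictors and responses are
#' mean-centered internally with the training means; no rescaling is done
#' here (unit-variance scaling is a preprocessing decision, see
#' \code{\link{scale_unit_variance}}). The algorithm is fully deterministic:
#' the score iteration is initialized from the response column with maximal
#' variance and deflates both X (and Y for PLS2) after each component,
#' matching the classical chemometrics NIPALS/kernel family in fitted values.
#'
#' If the residual covariance between X and Y becomes numerically zero
#' (weight norm below \code{tol_zero}) the fit stops early and returns the
#' components extracted so far, with \code{early_stop = TRUE}; bootstrap
#' resamples and degenerate responses are thereby handled without failure.
#'
#' @param X predictor matrix (n x p) or \code{\link{data_block}}.
#' @param Y response matrix (n x q), vector, or \code{\link{data_block}}.
#' @param n_components number of latent components requested; must not
#'   exceed \code{min(n - 1, p)}.
#' @param tol relative convergence tolerance of the inner score iteration.
#' @param max_iter maximal inner iterations per component.
#' @param tol_zero weight-norm threshold below which the residual X'Y
#'   covariance is treated as zero and extraction stops.
#' @return An object of class \code{pls_model} with weights \code{W} (p x a),
#'   scores \code{T} (n x a), loadings \code{P} (p x a), response loadings
#'   \code{Q} (q x a), regression coefficients \code{coefficients} (p x q, at
#'   the realized component count), centering vectors \code{x_means} /
#'   \code{y_means}, per-component captured response variance \code{ssy}, and
#'   the realized \code{n_components}.
#' @export
fit_pls <- function(X, Y, n_components, tol = 1e-12, max_iter = 500L,
                    tol_zero = 1e-12) {
  X <- as_block_matrix(X)
  Y <- as_block_matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  if (n_components < 1) stop("n_components must be >= 1")
  if (n_components > min(n - 1, p))
    stop("n_components exceeds min(n - 1, p) = ", min(n - 1, p))
  x_means <- colMeans(X)
  y_means <- colMeans(Y)
  Xc <- sweep(X, 2, x_means)
  Yc <- sweep(Y, 2, y_means)
  if (all(abs(Xc) < tol_zero)) stop("all predictor columns are constant")

  W <- matrix(0, p, n_components)
  TT <- matrix(0, n, n_components)
  P <- matrix(0, p, n_components)
  Q <- matrix(0, q, n_components)
  ssy <- numeric(n_components)
  a_done <- 0L
  early <- FALSE
  for (a in seq_len(n_components)) {
    u <- Yc[, which.max(apply(Yc, 2, function(col) sum(col^2))), drop = TRUE]
    w_old <- NULL
    wn <- 0; tt <- 0
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xc, u)
      wn <- sqrt(sum(w^2))
      if (wn < tol_zero) break
      w <- w / wn
      tvec <- drop(Xc %*% w)
      tt <- sum(tvec^2)
      if (tt < tol_zero) { wn <- 0; break }
      qvec <- drop(crossprod(Yc, tvec)) / tt
      if (q == 1L) break
      u_new <- drop(Yc %*% qvec) / sum(qvec^2)
      if (!is.null(w_old) && sum((w - w_old)^2) < tol) { u <- u_new; break }
      w_old <- w
      u <- u_new
    }
    if (wn < tol_zero || tt < tol_zero) { early <- TRUE; break }
    pvec <- drop(crossprod(Xc, tvec)) / tt
    Xc <- Xc - tcrossprod(tvec, pvec)
    Yc <- Yc - tcrossprod(tvec, qvec)
    W[, a] <- w; TT[, a] <- tvec; P[, a] <- pvec; Q[, a] <- qvec
    ssy[a] <- sum(qvec^2) * tt
    a_done <- a
  }
  if (a_done == 0L) {
    model <- structure(list(n_components = 0L, n_requested = n_components,
                            W = W[, 0, drop = FALSE], T = TT[, 0, drop = FALSE],
                            P = P[, 0, drop = FALSE], Q = Q[, 0, drop = FALSE],
                            coefficients = matrix(0, p, q),
                            x_means = x_means, y_means = y_means,
                            ssy = numeric(0), early_stop = TRUE,
                            variable_ids = colnames(X),
                            response_ids = colnames(Y)),
                       class = "pls_model")
    return(model)
  }
  keep <- seq_len(a_done)
  W <- W[, keep, drop = FALSE]; TT <- TT[, keep, drop = FALSE]
  P <- P[, keep, drop = FALSE]; Q <- Q[, keep, drop = FALSE]
  ssy <- ssy[keep]
  coef <- pls_coefficients(W, P, Q, a_done)
  structure(list(n_components = a_done, n_requested = n_components,
                 W = W, T = TT, P = P, Q = Q,
                 coefficients = coef,
                 x_means = x_means, y_means = y_means,
                 ssy = ssy, early_stop = early,
                 variable_ids = colnames(X), response_ids = colnames(Y)),
            class = "pls_model")
}

# B_a = W_a (P_a' W_a)^{-1} Q_a' for the leading a components.
pls_coefficients <- function(W, P, Q, a) {
  Wa <- W[, seq_len(a), drop = FALSE]
  Pa <- P[, seq_len(a), drop = FALSE]
  Qa <- Q[, seq_len(a), drop = FALSE]
  Wa %*% solve(crossprod(Pa, Wa), t(Qa))
}

#' Predict from a fitted PLS model
#'
#' Centers new predictors by the stored training means, applies the
#' regression coefficients for the requested number of components, and adds
#' the training response means back.
#'
#' @param object a \code{pls_model}.
#' @param newdata matrix or \code{\link{data_block}} with the same p columns
#'   as the training predictors.
#' @param ncomp number of components to use, capped at the realized
#'   component count of the model; defaults to all realized components.
#' @param ... unused.
#' @return An n_new x q matrix of predictions.
#' @export
predict.pls_model <- function(object, newdata, ncomp = object$n_components,
                              ...) {
  Xn <- as_block_matrix(newdata)
  p <- length(object$x_means)
  if (ncol(Xn) != p)
    stop("newdata has ", ncol(Xn), " columns; model expects ", p)
  ncomp <- min(ncomp, object$n_components)
  Xc <- sweep(Xn, 2, object$x_means)
  if (ncomp == 0L) {
    pred <- matrix(rep(object$y_means, each = nrow(Xn)), nrow = nrow(Xn))
  } else {
    B <- if (ncomp == object$n_components) object$coefficients
         else pls_coefficients(object$W, object$P, object$Q, ncomp)
    pred <- Xc %*% B
    pred <- sweep(pred, 2, object$y_means, "+")
  }
  colnames(pred) <- object$response_ids
  pred
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d component(s), p = %d, q = %d%s\n",
              x$n_components, nrow(x$W), nrow(x$Q),
              if (isTRUE(x$early_stop)) " (early stop)" else ""))
  invisible(x)
}

#' Fraction of response variance explained by predictions
#'
#' Computes \code{1 - ||Y - Yhat||^2 / ||Y - Ybar||^2} with Frobenius norms
#' summed over all response columns, where \code{Ybar} is the reference mean
#' supplied by the caller (full-data column means for cross-validated
#' percentages). For training fits the fitted values are orthogonal to the
#' residuals and the value coincides with the squared-Frobenius ratio
#' \code{||Yhat_c||^2 / ||Y_c||^2}; for out-of-sample predictions it may be
#' negative.
#'
#' @param Y_true observed response matrix or vector.
#' @param Y_pred predicted values of the same shape.
#' @param Y_reference_mean per-column reference means; defaults to the
#'   column means of \code{Y_true}.
#' @return A single number, at most 1.
#' @export
explained_variance_fraction <- function(Y_true, Y_pred,
                                        Y_reference_mean = NULL) {
  Yt <- as_block_matrix(Y_true)
  Yp <- as_block_matrix(Y_pred)
  if (!all(dim(Yt) == dim(Yp))) stop("shape mismatch between Y_true and Y_pred")
  if (is.null(Y_reference_mean)) Y_reference_mean <- colMeans(Yt)
  tss <- sum(sweep(Yt, 2, Y_reference_mean)^2)
  if (tss < 1e-300) stop("zero total variance in Y_true")
  1 - sum((Yt - Yp)^2) / tss
}

#' Variable importance in projection
#'
#' VIP for predictor j over the a components of a fitted PLS model:
#' \deqn{VIP_j = \sqrt{ p \sum_a SSY_a (w_{ja}/\|w_a\|)^2 / \sum_a SSY_a }}
#' where \eqn{SSY_a = \|q_a\|^2 t_a' t_a} is the response variance captured
#' by component a. By construction the mean of the squared VIPs equals 1, so
#' 1 is the natural reference for "more important than average".
#'
#' @param model a fitted \code{pls_model} with at least one component.
#' @return Numeric vector of length p, named by the predictor ids.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  a <- model$n_components
  if (a < 1) stop("vip requires a model with at least one component")
  ssy <- model$ssy
  if (sum(ssy) <= 0) stop("no response variance captured by any component")
  p <- nrow(model$W)
  Wn <- sweep(model$W, 2, sqrt(colSums(model$W^2)), "/")
  v <- sqrt(p * drop(Wn^2 %*% ssy) / sum(ssy))
  names(v) <- model$variable_ids
  v
}
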