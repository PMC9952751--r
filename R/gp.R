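# Gaussian process regression with marginal-likelihood hyperparameter
# optimization. The squared-exponential ARD kernel doubles as the feature
# relevance engine: importance_d = exp(-length_scale_d) on standardized inputs.

# negative log marginal likelihood and analytic gradient in one pass.
# theta = c(log ell (p or 1), log sf, log sn); X standardized, y centered.
.gp_nll_grad <- function(theta, X, y, kernel) {
  n <- nrow(X); p <- ncol(X)
  nell <- if (kernel == "se_ard") p else 1L
  ell <- exp(theta[seq_len(nell)])
  sf2 <- exp(2 * theta[nell + 1])
  sn2 <- exp(2 * theta[nell + 2])

  Xs <- sweep(X, 2, rep(ell, length.out = p), "/")
  sq <- rowSums(Xs^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(Xs)   # scaled squared distances
  D2[D2 < 0] <- 0
  if (kernel == "matern32") {
    R <- sqrt(D2)
    Kf <- sf2 * (1 + sqrt(3) * R) * exp(-sqrt(3) * R)
  } else {
    Kf <- sf2 * exp(-0.5 * D2)
  }
  K <- Kf + diag(sn2 + 1e-10 * sf2, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e10, grad = rep(0, length(theta))))
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  nll <- 0.5 * sum(y * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)

  Kinv <- chol2inv(ch)
  W <- tcrossprod(alpha) - Kinv          # dL/dtheta = 0.5 tr(W dK/dtheta)
  grad <- numeric(length(theta))
  if (kernel == "matern32") {
    V <- W * (sf2 * 3 * D2 * exp(-sqrt(3) * sqrt(D2)))
    grad[1] <- -0.5 * sum(V)             # d/dlog ell (iso)
  } else {
    V <- W * Kf
    if (kernel == "se_ard") {
      # sum_ij V_ij (x_i - x_j)^2 / ell_d^2 per dimension via one matmul
      rs <- rowSums(V)
      VX <- V %*% Xs
      per_dim <- 2 * colSums(Xs^2 * rs) - 2 * colSums(Xs * VX)
      grad[1:p] <- -0.5 * per_dim        # dK/dlog ell_d = Kf * D2_d scaled
    } else {
      grad[1] <- -0.5 * sum(V * D2)
    }
  }
  grad[nell + 1] <- -sum(W * Kf)         # dK/dlog sf = 2 Kf
  grad[nell + 2] <- -sn2 * sum(diag(W))  # dK/dlog sn = 2 sn2 I
  list(value = nll, grad = grad, chol = ch, alpha = alpha)
}

#' Fit a Gaussian process regression model
#'
#' Zero-mean GP with a squared-exponential kernel (isotropic or with per-
#' feature automatic-relevance-determination length scales) or an isotropic
#' Matern-3/2 kernel, plus an additive noise term. Hyperparameters maximize
#' the log marginal likelihood by L-BFGS-B with analytic gradients; on
#' optimizer failure up to `restarts` perturbed restarts are attempted.
#'
#' @param X numeric matrix of predictors (standardize first).
#' @param y numeric response.
#' @param kernel `"se_ard"`, `"se_iso"` or `"matern32"`.
#' @param maxit L-BFGS-B iteration cap (default 80).
#' @param restarts extra restarts on failure (default 3).
#' @return object of class `gp_model` with `length_scales`, `sigma_f`,
#'   `sigma_n`, `loglik`, and the fitted state needed by `predict`.
#' @export
gp_fit <- function(X, y, kernel = c("se_ard", "se_iso", "matern32"),
                   maxit = 80, restarts = 3) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop2("GP fit needs at least 2 rows")
  ymean <- mean(y)
  yc <- y - ymean
  sy <- max(sd(y), 1e-8)
  nell <- if (kernel == "se_ard") p else 1L
  init <- c(rep(log(sqrt(p)), nell), log(sy), log(0.2 * sy))
  # upper bound keeps exp(-ell) above the double underflow threshold so ARD
  # importances stay strictly positive
  lower <- c(rep(-6, nell), log(1e-4 * sy), log(1e-4 * sy))
  upper <- c(rep(6.5, nell), log(100 * sy), log(10 * sy))

  run <- function(par0) {
    env <- new.env()
    fn <- function(th) {
      r <- .gp_nll_grad(th, X, yc, kernel)
      env$last <- r
      r$value
    }
    gr <- function(th) env$last$grad
    o <- tryCatch(
      optim(par0, fn, gr, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(o) || !is.finite(o$value) || o$value >= 1e10) NULL else o
  }
  o <- run(init)
  tries <- 0
  while (is.null(o) && tries < restarts) {
    tries <- tries + 1
    o <- run(init + rnorm(length(init), sd = 0.5))
  }
  if (is.null(o)) stop2("GP hyperparameter optimization failed after %d restarts",
                        restarts)
  fin <- .gp_nll_grad(o$par, X, yc, kernel)
  ell <- exp(o$par[seq_len(nell)])
  structure(list(kernel = kernel, X = X, ymean = ymean,
                 alpha = fin$alpha,
                 length_scales = ell,
                 sigma_f = exp(o$par[nell + 1]),
                 sigma_n = exp(o$par[nell + 2]),
                 loglik = -o$value, convergence = o$convergence),
            class = "gp_model")
}

#' Predict from a fitted GP model
#' @param object a `gp_model`.
#' @param newdata numeric matrix on the same (standardized) scale as training.
#' @param ... unused.
#' @return numeric vector of posterior-mean predictions.
#' @export
predict.gp_model <- function(object, newdata, ...) {
  Xn <- as.matrix(newdata)
  p <- ncol(object$X)
  ell <- rep(object$length_scales, length.out = p)
  A <- sweep(Xn, 2, ell, "/")
  B <- sweep(object$X, 2, ell, "/")
  D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  D2[D2 < 0] <- 0
  Ks <- if (object$kernel == "matern32") {
    R <- sqrt(D2)
    object$sigma_f^2 * (1 + sqrt(3) * R) * exp(-sqrt(3) * R)
  } else {
    object$sigma_f^2 * exp(-0.5 * D2)
  }
  as.numeric(Ks %*% object$alpha) + object$ymean
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf("<gp_model %s>: n=%d, p=%d, sigma_f=%.3g, sigma_n=%.3g, loglik=%.2f\n",
              x$kernel, nrow(x$X), ncol(x$X), x$sigma_f, x$sigma_n, x$loglik))
  invisible(x)
}
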