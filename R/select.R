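# Feature ranking: GP-ARD, RReliefF, LASSO entry order, Laplacian score.

.new_ranking <- function(method, names, scores, extra = list()) {
  ord <- order(scores, decreasing = TRUE)
  structure(c(list(method = method, features = names[ord],
                   scores = scores[ord], n_selected = length(names)), extra),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking %s>: %d features; top 5: %s\n", x$method,
              length(x$features), paste(head(x$features, 5), collapse = ", ")))
  invisible(x)
}

#' Rank features by Gaussian-process automatic relevance determination
#'
#' Fits a GP with an ARD squared-exponential kernel plus noise term by
#' marginal-likelihood maximization; a feature's importance is
#' `exp(-length_scale)`: relevant features learn short length scales (high
#' importance), irrelevant or constant ones drift to long length scales and
#' importances near zero. Importances are strictly positive.
#'
#' @param X numeric matrix, standardized; at least 30 rows.
#' @param y numeric response.
#' @param maxit,restarts passed to [gp_fit()].
#' @return a `feature_ranking`.
#' @export
rank_gp_ard <- function(X, y, maxit = 80, restarts = 3) {
  X <- as.matrix(X)
  if (nrow(X) < 30) stop2("gp_ard ranking needs at least 30 rows")
  nms <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  # constant columns carry no ARD gradient: exclude them from the fit and pin
  # them to the smallest positive importance (effectively last)
  live <- which(apply(X, 2, sd) > 0)
  if (length(live) == 0) stop2("all features are constant")
  fit <- gp_fit(X[, live, drop = FALSE], y, kernel = "se_ard",
                maxit = maxit, restarts = restarts)
  imp <- setNames(rep(.Machine$double.xmin, ncol(X)), nms)
  imp[live] <- pmax(exp(-fit$length_scales), .Machine$double.xmin)
  .new_ranking("gp_ard", nms, imp, list(gp = fit))
}

#' Rank features by RReliefF (regression ReliefF)
#'
#' For every instance and its `k` nearest neighbors (Euclidean distance,
#' rank-based exponential influence decay with parameter `sigma`), the
#' algorithm accumulates the probabilities of a feature differing given that
#' the response differs, and forms the weight
#' `W_f = N_dYdF / N_dY - (N_dF - N_dYdF) / (m - N_dY)`. All instances are
#' used (no subsampling) so the ranking is deterministic.
#'
#' @param X numeric matrix, standardized.
#' @param y continuous response.
#' @param k neighbor count (default 10; reduced to `n - 1` with a warning when
#'   `k >= n`).
#' @param sigma rank-decay scale (default 50).
#' @return a `feature_ranking`.
#' @export
rank_relieff <- function(X, y, k = 10, sigma = 50) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (k >= n) {
    warning(sprintf("k = %d >= n = %d; using k = %d", k, n, n - 1))
    k <- n - 1
  }
  rngf <- apply(X, 2, function(v) diff(range(v)))
  rngf[rngf == 0] <- 1
  rngy <- diff(range(y))
  if (rngy == 0) rngy <- 1
  dmat <- as.matrix(dist(X))
  infl <- exp(-(seq_len(k) / sigma)^2)
  infl <- infl / sum(infl)
  N_dY <- 0
  N_dF <- numeric(p)
  N_dYdF <- numeric(p)
  for (i in seq_len(n)) {
    nb <- order(dmat[i, ])[2:(k + 1)]
    dy <- abs(y[nb] - y[i]) / rngy                       # length k
    dF <- abs(sweep(X[nb, , drop = FALSE], 2, X[i, ], "-"))
    dF <- sweep(dF, 2, rngf, "/")                        # k x p
    N_dY <- N_dY + sum(dy * infl)
    N_dF <- N_dF + colSums(dF * infl)
    N_dYdF <- N_dYdF + colSums(dF * (dy * infl))
  }
  W <- N_dYdF / N_dY - (N_dF - N_dYdF) / (n - N_dY)
  nms <- colnames(X) %||% paste0("f", seq_len(p))
  .new_ranking("relieff", nms, setNames(W, nms))
}

#' Rank features by LASSO regularization-path entry order
#'
#' Fits the L1 path over a log-spaced lambda grid (coordinate descent via
#' glmnet) and ranks features by the lambda at which their coefficient first
#' becomes nonzero: earlier entry = higher rank. Ties are broken by the
#' absolute coefficient at the smallest lambda; features that never enter
#' (including zero-variance columns) rank last with score 0.
#'
#' @param X numeric matrix, standardized.
#' @param y numeric response.
#' @param nlambda path length (default 100).
#' @param lambda optional explicit lambda grid.
#' @return a `feature_ranking` (scores = entry lambda).
#' @export
rank_lasso <- function(X, y, nlambda = 100, lambda = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = 1,
                        nlambda = nlambda, lambda = lambda,
                        standardize = FALSE)
  beta <- as.matrix(fit$beta)                 # p x nlam, lambda decreasing
  lam <- fit$lambda
  entry <- apply(beta != 0, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  last_abs <- abs(beta[, ncol(beta)])
  score <- ifelse(is.na(entry), 0, lam[pmax(entry, 1)])
  # strictly order ties at the same entry lambda by |coef| at the path end
  eps <- ifelse(is.na(entry), 0,
                1e-12 * rank(last_abs, ties.method = "first"))
  nms <- colnames(X) %||% paste0("f", seq_len(p))
  .new_ranking("lasso", nms, setNames(score + eps, nms))
}

#' Rank features by the Laplacian score
#'
#' Unsupervised locality preservation: builds a heat-kernel-weighted k-nearest
#' -neighbor graph (bandwidth = median squared neighbor distance) and scores
#' each feature by how smoothly it varies over the graph relative to its
#' variance, `L_f = (f' L f) / (f' D f)` after degree-centering. Lower
#' Laplacian scores mean better locality preservation; the ranking stores
#' `-L_f` so scores sort non-increasing like the other methods.
#'
#' @param X numeric matrix, standardized.
#' @param k_neighbors neighbors per node (default 5); requires `n > k`.
#' @return a `feature_ranking` (scores = negated Laplacian score).
#' @export
rank_laplacian <- function(X, k_neighbors = 5) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= k_neighbors) stop2("need more rows (%d) than neighbors (%d)",
                              n, k_neighbors)
  d2 <- as.matrix(dist(X))^2
  nn <- t(apply(d2, 1, function(r) order(r)[2:(k_neighbors + 1)]))
  nnd <- vapply(seq_len(n), function(i) d2[i, nn[i, ]], numeric(k_neighbors))
  t_band <- median(nnd)
  if (t_band <= 0) t_band <- 1
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, nn[i, ]] <- exp(-d2[i, nn[i, ]] / t_band)
  W <- pmax(W, t(W))                            # symmetric union graph
  dg <- rowSums(W)
  scores <- vapply(seq_len(p), function(j) {
    f <- X[, j]
    f <- f - sum(f * dg) / sum(dg)              # degree-weighted centering
    den <- sum(dg * f^2)
    if (den <= 0) return(Inf)                   # constant feature: worst
    num <- sum(f * (dg * f)) - sum(f * (W %*% f))  # f' L f with L = D - W
    num / den
  }, 0)
  nms <- colnames(X) %||% paste0("f", seq_len(p))
  .new_ranking("laplacian", nms, setNames(-scores, nms))
}

#' Take the top-n features of a ranking
#'
#' @param ranking a `feature_ranking`.
#' @param n subset size, `1 <= n <= length(ranking$features)`.
#' @return character vector of the first `n` feature names by rank.
#' @export
select_top <- function(ranking, n) {
  stopifnot(inherits(ranking, "feature_ranking"))
  if (n < 1 || n > length(ranking$features))
    stop2("n = %d out of range [1, %d]", n, length(ranking$features))
  ranking$features[seq_len(n)]
}

#' Sweep the selected-feature count on a validation set
#'
#' Utility for choosing `n`: for each candidate size, trains the given model
#' family on the training rows restricted to the top-n features and reports
#' validation RMSE.
#'
#' @param ranking a `feature_ranking` fitted on training rows.
#' @param X_train,y_train,X_val,y_val standardized design matrices and labels.
#' @param n_grid candidate subset sizes.
#' @param family model family (see [train_model()]); default `"linear"` for speed.
#' @return data frame with columns `n` and `val_rmse`.
#' @export
sweep_top_n <- function(ranking, X_train, y_train, X_val, y_val,
                        n_grid = c(5, 8, 11, 15, 20, 30), family = "linear") {
  n_grid <- n_grid[n_grid <= length(ranking$features)]
  res <- lapply(n_grid, function(n) {
    feats <- select_top(ranking, n)
    m <- train_model(family, X_train[, feats, drop = FALSE], y_train,
                     X_val[, feats, drop = FALSE], y_val)
    data.frame(n = n, val_rmse = rmse(predict(m, X_val[, feats, drop = FALSE]),
                                      y_val))
  })
  do.call(rbind, res)
}
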