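# The regression model zoo: five families, 19 documented variant presets.

#' The model zoo
#'
#' Five families with 19 preset variants in total: 3 GPR kernels, 4 SVR
#' presets, 4 ensemble presets (2 bagged, 2 boosted), 4 decision-tree depths,
#' and 4 linear/regularized presets.
#'
#' @return named list: family -> character vector of variant names.
#' @export
model_zoo <- function() {
  list(
    gpr = c("se_ard", "se_iso", "matern32"),
    svr = c("rbf_c1", "rbf_c10", "rbf_wide", "linear_c1"),
    ensemble_tree = c("bag_100", "bag_300", "boost_d3", "boost_d6"),
    decision_tree = c("depth2", "depth4", "depth8", "depth16"),
    linear = c("ols", "ridge", "lasso", "elastic")
  )
}

.fit_variant <- function(family, variant, X, y, X_val = NULL, y_val = NULL) {
  p <- ncol(X)
  fit <- switch(
    family,
    gpr = gp_fit(X, y, kernel = variant),
    svr = {
      cfg <- switch(variant,
                    rbf_c1 = list(kernel = "radial", cost = 1, gamma = 1 / p),
                    rbf_c10 = list(kernel = "radial", cost = 10, gamma = 1 / p),
                    rbf_wide = list(kernel = "radial", cost = 1, gamma = 0.1 / p),
                    linear_c1 = list(kernel = "linear", cost = 1, gamma = 1 / p))
      e1071::svm(X, y, type = "eps-regression", kernel = cfg$kernel,
                 cost = cfg$cost, gamma = cfg$gamma, scale = FALSE)
    },
    ensemble_tree = {
      if (variant %in% c("bag_100", "bag_300")) {
        randomForest::randomForest(X, y,
                                   ntree = if (variant == "bag_100") 100 else 300)
      } else {
        xgboost::xgboost(data = X, label = y, nrounds = 150, eta = 0.1,
                         max_depth = if (variant == "boost_d3") 3 else 6,
                         objective = "reg:squarederror", verbose = 0,
                         nthread = 1)
      }
    },
    decision_tree = {
      depth <- as.integer(sub("depth", "", variant))
      df <- data.frame(y = y, X)
      rpart::rpart(y ~ ., data = df,
                   control = rpart::rpart.control(maxdepth = min(depth, 30),
                                                  cp = 1e-6, minsplit = 5,
                                                  xval = 0))
    },
    linear = {
      if (variant == "ols") {
        df <- data.frame(y = y, X)
        # rank-deficient designs fall back to the least-norm solution with a
        # warning from lm itself
        lm(y ~ ., data = df)
      } else {
        alpha <- switch(variant, ridge = 0, lasso = 1, elastic = 0.5)
        fit <- glmnet::glmnet(X, y, alpha = alpha, standardize = FALSE)
        lam <- if (!is.null(X_val) && nrow(X_val) > 0) {
          pv <- predict(fit, X_val)
          fit$lambda[which.min(colMeans((pv - y_val)^2))]
        } else min(fit$lambda)
        attr(fit, "chosen_lambda") <- lam
        fit
      }
    },
    stop2("unknown model family '%s'", family))
  fit
}

.predict_variant <- function(model, X) {
  fit <- model$fit
  switch(
    model$family,
    gpr = predict(fit, X),
    svr = as.numeric(predict(fit, X)),
    ensemble_tree = {
      if (model$variant %in% c("bag_100", "bag_300")) as.numeric(predict(fit, X))
      else as.numeric(predict(fit, xgboost::xgb.DMatrix(X)))
    },
    decision_tree = as.numeric(predict(fit, data.frame(X))),
    linear = {
      if (model$variant == "ols") as.numeric(predict(fit, data.frame(X)))
      else as.numeric(predict(fit, X, s = attr(fit, "chosen_lambda")))
    })
}

#' Train a regression model
#'
#' Fits the named family on the training rows. When `variant` is `NULL` the
#' family's preset variants are all fitted and the one with the lowest
#' validation RMSE is kept — the validation set is used only for this choice
#' (and for the regularization-path lambda of the penalized linear variants),
#' never for fitting coefficients.
#'
#' @param family one of `names(model_zoo())`.
#' @param X_train,y_train training design (standardized) and labels.
#' @param X_val,y_val validation design and labels (required when
#'   `variant = NULL`).
#' @param variant preset name from [model_zoo()], or `NULL` to select by
#'   validation RMSE.
#' @return object of class `ppg_model` with fields `family`, `variant`,
#'   `fit`, `val_rmse`.
#' @export
train_model <- function(family, X_train, y_train, X_val = NULL, y_val = NULL,
                        variant = NULL) {
  zoo <- model_zoo()
  if (!family %in% names(zoo)) stop2("unknown family '%s'", family)
  X_train <- as.matrix(X_train)
  if (any(!is.finite(y_train))) stop2("training labels must be finite")
  variants <- if (is.null(variant)) zoo[[family]] else variant
  if (length(variants) > 1 && is.null(X_val))
    stop2("variant selection requires a validation set")
  best <- NULL
  for (v in variants) {
    if (!v %in% zoo[[family]]) stop2("unknown variant '%s' for family '%s'", v, family)
    fit <- .fit_variant(family, v, X_train, y_train,
                        if (is.null(X_val)) NULL else as.matrix(X_val), y_val)
    m <- structure(list(family = family, variant = v, fit = fit,
                        val_rmse = NA_real_), class = "ppg_model")
    if (!is.null(X_val)) {
      m$val_rmse <- rmse(.predict_variant(m, as.matrix(X_val)), y_val)
    }
    if (is.null(best) || (is.finite(m$val_rmse) && m$val_rmse < best$val_rmse))
      best <- m
  }
  best
}

#' Predict from a trained model
#' @param object a `ppg_model`.
#' @param newdata matrix on the training (standardized) scale.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.ppg_model <- function(object, newdata, ...) {
  .predict_variant(object, as.matrix(newdata))
}

#' @export
print.ppg_model <- function(x, ...) {
  cat(sprintf("<ppg_model %s/%s>%s\n", x$family, x$variant,
              if (is.finite(x$val_rmse)) sprintf(" val RMSE %.3f", x$val_rmse) else ""))
  invisible(x)
}
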