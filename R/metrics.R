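# The evaluation metric suite: MAE, RMSE, the baseline-relative R statistic,
# Pearson r, 2SD of the error, and Bland-Altman limits of agreement.

.check_pair <- function(pred, truth, min_n = 1) {
  if (length(pred) != length(truth))
    stop2("pred (%d) and truth (%d) differ in length", length(pred), length(truth))
  if (length(pred) < min_n) stop2("need at least %d pairs", min_n)
  if (any(!is.finite(pred)) || any(!is.finite(truth)))
    stop2("pred and truth must be finite")
}

#' Mean absolute error
#' @param pred,truth numeric vectors of equal length.
#' @return `mean(|pred - truth|)`.
#' @export
mae <- function(pred, truth) {
  .check_pair(pred, truth)
  mean(abs(pred - truth))
}

#' Root-mean-squared error
#' @param pred,truth numeric vectors of equal length.
#' @return `sqrt(mean((pred - truth)^2))`.
#' @export
rmse <- function(pred, truth) {
  .check_pair(pred, truth)
  sqrt(mean((pred - truth)^2))
}

#' Baseline-relative R statistic
#'
#' `R = 1 - MSE(model) / MSE(baseline)` where the baseline predicts the mean
#' of the truth — a coefficient-of-determination form. Predicting the truth
#' exactly gives 1; predicting its mean gives 0. Undefined (error) for a
#' constant truth vector.
#'
#' @param pred,truth numeric vectors of equal length.
#' @return scalar, at most 1.
#' @export
r_paper <- function(pred, truth) {
  .check_pair(pred, truth)
  mse_base <- mean((truth - mean(truth))^2)
  if (mse_base == 0) stop2("truth is constant; baseline MSE is zero")
  1 - mean((pred - truth)^2) / mse_base
}

#' Twice the (population) standard deviation of the error
#'
#' `2 * sqrt(mean((e - mean(e))^2))` with `e = pred - truth`; summarizes the
#' 95% spread of the prediction error. `sample = TRUE` switches to the n-1
#' denominator.
#'
#' @param pred,truth numeric vectors of equal length (n >= 2).
#' @param sample use the sample (n-1) SD instead of the population SD.
#' @return scalar.
#' @export
two_sd <- function(pred, truth, sample = FALSE) {
  .check_pair(pred, truth, min_n = 2)
  e <- pred - truth
  if (sample) 2 * sd(e) else 2 * sqrt(mean((e - mean(e))^2))
}

#' Bland-Altman 95% limits of agreement
#'
#' `bias +/- 1.96 * SD(error)` with the population SD convention, plus the
#' per-pair points for plotting: x = mean of prediction and truth, y = error.
#'
#' @param pred,truth numeric vectors of equal length (n >= 3).
#' @param multiplier LOA multiplier (default 1.96 for 95%).
#' @param sample use the sample SD.
#' @return list with `loa_low`, `loa_high`, `bias`, `sd_error`, and `points`
#'   (data frame with columns `mean` and `diff`).
#' @export
limits_of_agreement <- function(pred, truth, multiplier = 1.96, sample = FALSE) {
  .check_pair(pred, truth, min_n = 3)
  e <- pred - truth
  bias <- mean(e)
  sde <- if (sample) sd(e) else sqrt(mean((e - bias)^2))
  list(loa_low = bias - multiplier * sde, loa_high = bias + multiplier * sde,
       bias = bias, sd_error = sde,
       points = data.frame(mean = (pred + truth) / 2, diff = e))
}

#' Full evaluation report
#'
#' Bundles the metric suite for one prediction/truth pair. Both the
#' baseline-relative R statistic ([r_paper()]) and the Pearson correlation are
#' reported, since published "R-values" may refer to either.
#'
#' @param pred,truth numeric vectors of equal length (n >= 3).
#' @param units unit string for printing (e.g. `"breaths/min"`, `"%"`).
#' @return object of class `eval_report` with fields `mae`, `rmse`, `r_paper`,
#'   `pearson_r`, `bias`, `sd_error`, `two_sd`, `loa_low`, `loa_high`, `n`,
#'   `units`, `points`.
#' @export
eval_report <- function(pred, truth, units = "") {
  .check_pair(pred, truth, min_n = 3)
  loa <- limits_of_agreement(pred, truth)
  rp <- if (sd(truth) > 0) r_paper(pred, truth) else NA_real_
  pr <- if (sd(truth) > 0 && sd(pred) > 0) cor(pred, truth) else NA_real_
  structure(list(mae = mae(pred, truth), rmse = rmse(pred, truth),
                 r_paper = rp, pearson_r = pr,
                 bias = loa$bias, sd_error = loa$sd_error,
                 two_sd = 2 * loa$sd_error,
                 loa_low = loa$loa_low, loa_high = loa$loa_high,
                 n = length(pred), units = units, points = loa$points),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  u <- if (nzchar(x$units)) paste0(" ", x$units) else ""
  cat(sprintf("<eval_report> n=%d\n", x$n))
  cat(sprintf("  MAE  %.3f%s   RMSE %.3f%s\n", x$mae, u, x$rmse, u))
  cat(sprintf("  R    %.3f    Pearson r %.3f\n", x$r_paper, x$pearson_r))
  cat(sprintf("  bias %+.3f%s  2SD %.3f%s  LOA [%.3f, %.3f]%s\n",
              x$bias, u, x$two_sd, u, x$loa_low, x$loa_high, u))
  invisible(x)
}
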