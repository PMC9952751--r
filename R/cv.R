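# The 5-fold 60/20/20 cross-validation protocol, the per-fold fitting routine
# (leakage-safe by construction), the experiment grid, and the leakage audit.

#' Build a 5-fold 60/20/20 cross-validation plan
#'
#' Rows are shuffled once by `seed` and split into 5 near-equal contiguous
#' blocks; fold i uses block i as the test set, block `(i mod 5) + 1` as the
#' validation set, and the remaining 3 blocks for training — 60% train / 20%
#' validation / 20% test. Test sets are mutually disjoint and jointly cover
#' all rows.
#'
#' @param n number of rows (>= 10).
#' @param seed integer shuffle seed.
#' @return object of class `cv_plan`: `n`, `seed`, `folds` (list of 5, each
#'   with `train`, `val`, `test` index vectors).
#' @export
make_cv_plan <- function(n, seed = 1) {
  if (n < 10) stop2("cross-validation needs n >= 10 rows, got %d", n)
  set.seed(seed)
  perm <- sample.int(n)
  blocks <- split(perm, cut(seq_len(n), breaks = 5, labels = FALSE))
  folds <- lapply(1:5, function(i) {
    vi <- (i %% 5) + 1
    list(test = sort(blocks[[i]]),
         val = sort(blocks[[vi]]),
         train = sort(unlist(blocks[setdiff(1:5, c(i, vi))], use.names = FALSE)))
  })
  structure(list(n = n, seed = seed, folds = folds), class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  sz <- vapply(x$folds[[1]], length, 0L)
  cat(sprintf("<cv_plan>: n=%d, 5 folds (train %d / val %d / test %d), seed %d\n",
              x$n, sz["train"], sz["val"], sz["test"], x$seed))
  invisible(x)
}

.rank_with <- function(selector, X, y, relieff_k = 10) {
  switch(selector,
         none = {
           nms <- colnames(X)
           .new_ranking("none", nms, setNames(rev(seq_along(nms)), nms))
         },
         gp_ard = rank_gp_ard(X, y),
         relieff = rank_relieff(X, y, k = relieff_k),
         lasso = rank_lasso(X, y),
         laplacian = rank_laplacian(X),
         stop2("unknown selector '%s'", selector))
}

#' Fit and evaluate one fold
#'
#' All fitted state — imputation medians, standardization parameters, the
#' feature ranking, and the model-variant choice — is computed from the fold's
#' training rows only (validation rows are used solely for variant selection),
#' so test rows cannot influence the fitted pipeline.
#'
#' @param fm a `feature_matrix`.
#' @param target `"rr"` or `"spo2"`.
#' @param fold one element of `cv_plan$folds`.
#' @param selector `"none"`, `"gp_ard"`, `"relieff"`, `"lasso"` or `"laplacian"`.
#' @param top_n number of features kept after ranking.
#' @param family model family; `variant` as in [train_model()].
#' @param variant preset name or `NULL` for validation-set selection.
#' @return list with the test-set predictions and truth, an `eval_report`,
#'   and the fitted artifacts (for auditing).
#' @export
fit_fold <- function(fm, target = c("rr", "spo2"), fold, selector = "gp_ard",
                     top_n = 8, family = "gpr", variant = NULL) {
  target <- match.arg(target)
  y_all <- fm$labels[[target]]
  keep <- which(is.finite(y_all))
  tr <- intersect(fold$train, keep)
  va <- intersect(fold$val, keep)
  te <- intersect(fold$test, keep)
  if (length(tr) < 10 || length(te) < 1) stop2("fold has too few labeled rows")

  imp <- fit_imputer(fm$X, tr)
  Xi <- apply_imputer(imp, fm$X)
  std <- fit_standardizer(Xi, tr)
  Xs <- apply_standardizer(std, Xi)

  ranking <- .rank_with(selector, Xs[tr, , drop = FALSE], y_all[tr])
  feats <- select_top(ranking, min(top_n, length(ranking$features)))

  model <- train_model(family,
                       Xs[tr, feats, drop = FALSE], y_all[tr],
                       Xs[va, feats, drop = FALSE], y_all[va],
                       variant = variant)
  pred <- predict(model, Xs[te, feats, drop = FALSE])
  list(pred = pred, truth = y_all[te], test_rows = te,
       report = eval_report(pred, y_all[te],
                            units = if (target == "rr") "breaths/min" else "%"),
       artifacts = list(imputer = imp, standardizer = std,
                        ranking = ranking$features, features = feats,
                        variant = model$variant))
}

#' Run the selector x model experiment grid
#'
#' For every (selector, family) combination, runs all 5 folds and reports the
#' across-fold mean of each metric, in the layout of a results table: one row
#' per combination with RMSE, MAE, R, 2SD and pooled limits of agreement. A
#' fold failure is recorded and the grid continues.
#'
#' @param fm a `feature_matrix`.
#' @param target `"rr"` or `"spo2"`.
#' @param cv_plan a [make_cv_plan()] result.
#' @param selectors character vector of selector names.
#' @param families character vector of family names.
#' @param top_n named numeric (per selector) or single number of features to
#'   keep; ignored for selector `"none"`.
#' @param variant named list or single preset passed through to
#'   [train_model()]; `NULL` selects by validation RMSE.
#' @return object of class `grid_result`: `table` (data frame), `reports`
#'   (pooled `eval_report` per combination), `failures`.
#' @export
run_grid <- function(fm, target = c("rr", "spo2"), cv_plan,
                     selectors = c("none", "gp_ard"),
                     families = c("gpr", "linear"),
                     top_n = 8, variant = NULL) {
  target <- match.arg(target)
  rows <- list(); reports <- list(); failures <- list()
  for (sel in selectors) {
    tn <- if (length(top_n) > 1) top_n[[sel]] else top_n
    if (sel == "none") tn <- ncol(fm$X)
    for (fam in families) {
      vr <- if (is.list(variant)) variant[[fam]] else variant
      per_fold <- list(); pool_pred <- c(); pool_truth <- c()
      for (k in seq_along(cv_plan$folds)) {
        res <- tryCatch(
          fit_fold(fm, target, cv_plan$folds[[k]], selector = sel,
                   top_n = tn, family = fam, variant = vr),
          error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1]] <-
            list(selector = sel, family = fam, fold = k,
                 message = conditionMessage(res))
          next
        }
        per_fold[[length(per_fold) + 1]] <- res$report
        pool_pred <- c(pool_pred, res$pred)
        pool_truth <- c(pool_truth, res$truth)
      }
      if (length(per_fold) == 0) next
      mm <- function(f) mean(vapply(per_fold, `[[`, 0, f))
      pooled <- eval_report(pool_pred, pool_truth,
                            units = if (target == "rr") "breaths/min" else "%")
      key <- paste(sel, fam, sep = "/")
      reports[[key]] <- pooled
      rows[[key]] <- data.frame(
        selector = sel, top_n = tn, family = fam,
        rmse = mm("rmse"), mae = mm("mae"), r = mm("r_paper"),
        pearson_r = mm("pearson_r"), two_sd = mm("two_sd"),
        loa_low = pooled$loa_low, loa_high = pooled$loa_high,
        folds_ok = length(per_fold))
    }
  }
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 reports = reports, failures = failures, target = target,
                 seed = cv_plan$seed),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result target=%s, seed=%d>\n", x$target, x$seed))
  print(x$table, row.names = FALSE, digits = 4)
  if (length(x$failures) > 0)
    cat(sprintf("  (%d fold failures recorded)\n", length(x$failures)))
  invisible(x)
}

#' Audit a fold pipeline for test-set leakage
#'
#' Refits one fold twice: once on the original feature matrix, and once with
#' every test row's features and label replaced by unrelated values. If any
#' fitted state — imputation medians, standardization parameters, feature
#' ranking, selected subset, chosen variant, or the prediction function
#' applied to a fixed probe — differs, test rows influenced fitting and the
#' audit fails.
#'
#' @param fm a `feature_matrix`.
#' @param target `"rr"` or `"spo2"`.
#' @param fold one element of `cv_plan$folds`.
#' @param selector,top_n,family,variant as in [fit_fold()].
#' @param seed seed for the garbage replacement.
#' @return `TRUE` if no leakage is detected, otherwise an error describing the
#'   leaking component.
#' @export
leakage_audit <- function(fm, target = "rr", fold, selector = "relieff",
                          top_n = 8, family = "linear", variant = "ols",
                          seed = 99) {
  a <- fit_fold(fm, target, fold, selector, top_n, family, variant)
  fm2 <- fm
  set.seed(seed)
  te <- fold$test
  fm2$X[te, ] <- matrix(rnorm(length(te) * ncol(fm$X), sd = 100),
                        nrow = length(te))
  fm2$labels[[target]][te] <- runif(length(te), 1000, 2000)
  # the mangled labels stay finite so the same rows remain "labeled"
  b <- fit_fold(fm2, target, fold, selector, top_n, family, variant)
  cmp <- function(u, v, what) {
    if (!isTRUE(all.equal(u, v, tolerance = 0)))
      stop2("leakage detected: %s depends on test rows", what)
  }
  cmp(a$artifacts$imputer$medians, b$artifacts$imputer$medians, "imputation")
  cmp(a$artifacts$standardizer, b$artifacts$standardizer, "standardization")
  cmp(a$artifacts$ranking, b$artifacts$ranking, "feature ranking")
  cmp(a$artifacts$features, b$artifacts$features, "feature subset")
  cmp(a$artifacts$variant, b$artifacts$variant, "variant choice")
  TRUE
}
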