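#' Mean absolute error and its spread
#'
#' `MAE = (1/l) * sum |y_i - yhat_i|`; `sd` is the population SD of the
#' absolute errors (the stability measure used alongside MAE).
#'
#' @param y true labels.
#' @param yhat predictions.
#' @return List with `mae` and `sd`.
#' @export
mae_and_sd <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) != length(yhat)) stop("length mismatch: ", length(y),
                                      " vs ", length(yhat))
  if (length(y) == 0) stop("empty vectors")
  ae <- abs(y - yhat)
  list(mae = mean(ae), sd = pop_sd(ae))
}

#' Discretize a continuous stress value into LS/MS/HS
#'
#' Three equal intervals of the unit scale: low stress `[0, 1/3)`, medium
#' stress `[1/3, 2/3)`, high stress `[2/3, 1]`. Values outside `[0, 1]`
#' are clipped with a warning.
#'
#' @param y numeric value(s) in `[0, 1]`.
#' @return Factor with levels `LS`, `MS`, `HS`.
#' @export
discretize_stress <- function(y) {
  y <- as.numeric(y)
  if (any(y < 0 | y > 1)) {
    warning("values outside [0, 1] clipped before discretization")
    y <- pmin(1, pmax(0, y))
  }
  cls <- ifelse(y < 1 / 3, "LS", ifelse(y < 2 / 3, "MS", "HS"))
  factor(cls, levels = c("LS", "MS", "HS"))
}

#' Three-level stress confusion matrix and per-class F1
#'
#' Discretizes truth and predictions into LS/MS/HS and computes the
#' one-vs-rest precision, recall and F1 per class. A class absent from
#' both truth and predictions gets F1 = 0 with a warning.
#'
#' @param y true labels in `[0, 1]`.
#' @param yhat predictions in `[0, 1]` (clipped if outside).
#' @return List with `confusion` (3 x 3, rows = truth, cols = predicted),
#'   `precision`, `recall`, `f1` (named by class).
#' @export
f1_scores <- function(y, yhat) {
  truth <- discretize_stress(y)
  pred <- discretize_stress(yhat)
  confusion <- table(truth = truth, predicted = pred)
  classes <- c("LS", "MS", "HS")
  precision <- recall <- f1 <- stats::setNames(numeric(3), classes)
  for (cl in classes) {
    tp <- confusion[cl, cl]
    fp <- sum(confusion[, cl]) - tp
    fn <- sum(confusion[cl, ]) - tp
    if (tp + fp + fn == 0) {
      warning("class ", cl, " absent from truth and predictions; F1 set to 0")
      next
    }
    precision[cl] <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall[cl] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[cl] <- if (precision[cl] + recall[cl] > 0) {
      2 * precision[cl] * recall[cl] / (precision[cl] + recall[cl])
    } else 0
  }
  list(confusion = unclass(confusion), precision = precision,
       recall = recall, f1 = f1)
}

#' High/low stress counts at a cut-off
#'
#' Dichotomizes predictions at `cutoff` (high: `yhat > cutoff`; low:
#' `yhat <= cutoff`) and reports the high/low count ratio rounded to two
#' decimals (`Inf` when there are no low-stress predictions).
#'
#' @param yhat numeric predictions.
#' @param cutoff threshold, default 0.5.
#' @return List with `n_high`, `n_low`, `ratio`.
#' @export
high_low_counts <- function(yhat, cutoff = 0.5) {
  yhat <- as.numeric(yhat)
  if (length(yhat) == 0) stop("empty prediction vector")
  n_high <- sum(yhat > cutoff)
  n_low <- sum(yhat <= cutoff)
  list(n_high = n_high, n_low = n_low,
       ratio = if (n_low == 0) Inf else round(n_high / n_low, 2))
}

#' Evaluation report for a batch of predictions
#'
#' @param y true labels.
#' @param yhat predictions.
#' @param subject_id optional per-prediction subject identifiers for the
#'   per-subject breakdown.
#' @return Object of class `evaluation_report`: `mae`, `abs_err_sd`,
#'   `n_predictions`, `confusion`, `f1`, `per_subject` (data.frame), and
#'   the raw `y`/`yhat`.
#' @export
evaluation_report <- function(y, yhat, subject_id = NULL) {
  m <- mae_and_sd(y, yhat)
  fs <- suppressWarnings(f1_scores(y, pmin(1, pmax(0, yhat))))
  per_subject <- NULL
  if (!is.null(subject_id)) {
    per_subject <- do.call(rbind, lapply(unique(subject_id), function(s) {
      i <- subject_id == s
      ms <- mae_and_sd(y[i], yhat[i])
      data.frame(subject_id = s, n = sum(i), mae = ms$mae, sd = ms$sd)
    }))
  }
  structure(
    list(mae = m$mae, abs_err_sd = m$sd, n_predictions = length(y),
         confusion = fs$confusion, f1 = fs$f1, per_subject = per_subject,
         y = as.numeric(y), yhat = as.numeric(yhat)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: n = %d, MAE = %.4f, SD = %.4f\n",
              x$n_predictions, x$mae, x$abs_err_sd))
  cat("  F1 (LS/MS/HS):", paste(sprintf("%.3f", x$f1), collapse = " / "),
      "\n")
  invisible(x)
}

#' Inductive baselines
#'
#' `fit_baseline_esvr` fits a plain (global) epsilon-SVR, i.e. the weighted
#' solver with all weights equal to one. `fit_baseline_lr` fits ordinary
#' least squares with an intercept; a singular design falls back to the
#' minimum-norm solution with a warning.
#'
#' @param train a [labeled_dataset()].
#' @param config a [transductive_config()] supplying C, epsilon, kernel.
#' @return `fit_baseline_esvr`: an `svr_model`. `fit_baseline_lr`: an
#'   object of class `lr_model` with `coefficients` (intercept first).
#' @export
fit_baseline_esvr <- function(train, config = transductive_config()) {
  stopifnot(inherits(train, "labeled_dataset"))
  fit_weighted_svr(train$X, train$y, weights = NULL, C = config$C,
                   epsilon = config$epsilon, kernel = config$kernel)
}

#' @rdname fit_baseline_esvr
#' @export
fit_baseline_lr <- function(train) {
  stopifnot(inherits(train, "labeled_dataset"))
  A <- cbind(1, train$X)
  fit <- tryCatch(qr.solve(A, train$y), error = function(e) NULL)
  if (is.null(fit) || qr(A)$rank < ncol(A)) {
    warning("singular design; using minimum-norm least squares")
    sv <- svd(A)
    pos <- sv$d > max(dim(A)) * .Machine$double.eps * sv$d[1]
    fit <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% train$y) / sv$d[pos])
    fit <- drop(fit)
  }
  structure(list(coefficients = drop(fit)), class = "lr_model")
}

#' @export
predict.lr_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  drop(cbind(1, as.matrix(newdata)) %*% object$coefficients)
}

#' Exhaustive cross-validated grid search
#'
#' Evaluates every combination of the supplied parameter grids by k-fold
#' CV mean MAE and returns the best configuration. The canonical search
#' range for SVR parameters is `2^seq(-8, 8, by = 0.5)` (33 values per
#' parameter). Ties are broken toward the smallest parameter values, in
#' the order the grid lists them.
#'
#' @param dataset a [labeled_dataset()].
#' @param model_kind `"esvr"` (inductive epsilon-SVR), `"st_svr"` or
#'   `"t_svr"` (transductive; CV folds double as the transduction folds).
#' @param grid named list of parameter vectors; recognized names: `C`,
#'   `epsilon`, `gamma`, `rho`, `N`.
#' @param config base [transductive_config()] supplying unsearched values.
#' @param folds CV folds.
#' @param seed fold-assignment seed.
#' @return List with `best` (a `transductive_config`), `best_mae`, and
#'   `cv_table` (one row per combination).
#' @export
grid_search_cv <- function(dataset, model_kind = c("esvr", "st_svr", "t_svr"),
                           grid = list(C = 2^seq(-8, 8, by = 0.5)),
                           config = transductive_config(), folds = 5,
                           seed = 1) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(dataset, "labeled_dataset"), length(grid) >= 1)
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  # row order of expand.grid varies the first column fastest; with each
  # grid vector ascending, the first tie (min index) is the smallest values
  # in documented (listed) order
  n <- n_examples(dataset)
  fold <- make_folds(n, folds, seed)

  eval_combo <- function(pars) {
    cfg <- config
    for (nm in names(pars)) {
      if (nm == "gamma") cfg$kernel$gamma <- pars[[nm]]
      else cfg[[nm]] <- if (nm == "N") as.integer(pars[[nm]]) else pars[[nm]]
    }
    cfg$folds <- as.integer(folds)
    ae <- numeric(0)
    for (f in seq_len(folds)) {
      test_i <- which(fold == f)
      train_d <- subset_dataset(dataset, which(fold != f))
      yh <- switch(model_kind,
        esvr = {
          mod <- fit_baseline_esvr(train_d, cfg)
          predict_svr(mod, dataset$X[test_i, , drop = FALSE])
        },
        st_svr = ,
        t_svr = vapply(test_i, function(i) {
          pool <- if (model_kind == "st_svr") {
            subset_dataset(train_d,
                           which(train_d$subject_id == dataset$subject_id[i]))
          } else train_d
          predict_transductive(pool, dataset$X[i, ], cfg)$yhat
        }, numeric(1))
      )
      ae <- c(ae, abs(dataset$y[test_i] - yh))
    }
    mean(ae)
  }

  maes <- vapply(seq_len(nrow(combos)), function(r) {
    eval_combo(as.list(combos[r, , drop = FALSE]))
  }, numeric(1))
  best_row <- which.min(maes) # which.min takes the first minimum: tie rule
  best <- config
  for (nm in names(combos)) {
    v <- combos[best_row, nm]
    if (nm == "gamma") best$kernel$gamma <- v
    else best[[nm]] <- if (nm == "N") as.integer(v) else v
  }
  cv_table <- cbind(combos, cv_mae = maes)
  list(best = best, best_mae = maes[best_row], cv_table = cv_table)
}

#' Compare transductive and inductive models on a multi-subject dataset
#'
#' Runs LR, epsilon-SVR, ST-SVR and T-SVR under a shared k-fold protocol:
#' per subject and fold, the test set is that subject's fold; the ST-SVR
#' pool is the subject's remaining folds; the T-SVR pool adds all other
#' subjects' examples; the pooled baselines train inductively on the same
#' pool as the T-SVR (`baseline_scope = "per_subject"` restricts them to
#' the subject's remaining folds instead). Absolute errors are pooled over
#' all subjects, then summarized as MAE and the population SD of absolute
#' errors per model.
#'
#' @param dataset a multi-subject [labeled_dataset()].
#' @param config a [transductive_config()].
#' @param seed fold-assignment seed.
#' @param baseline_scope `"pooled"` or `"per_subject"` training data for
#'   the LR and e-SVR baselines.
#' @return List with `table` (data.frame model/mae/sd), and `reports`
#'   (per-model `evaluation_report`s). With a single-subject dataset the
#'   T-SVR row is omitted with a message.
#' @export
compare_models <- function(dataset, config = transductive_config(), seed = 1,
                           baseline_scope = c("pooled", "per_subject")) {
  baseline_scope <- match.arg(baseline_scope)
  stopifnot(inherits(dataset, "labeled_dataset"))
  subjects <- unique(dataset$subject_id)
  multi <- length(subjects) >= 2
  if (!multi) message("single-subject dataset: T-SVR row omitted")

  models <- c("lr", "esvr", "st_svr", if (multi) "t_svr")
  preds <- stats::setNames(
    lapply(models, function(m) numeric(n_examples(dataset))), models)
  truth <- dataset$y

  for (s in subjects) {
    idx <- which(dataset$subject_id == s)
    subj <- subset_dataset(dataset, idx)
    others_idx <- which(dataset$subject_id != s)
    fold <- make_folds(length(idx), config$folds, seed)
    for (f in seq_len(config$folds)) {
      test_loc <- which(fold == f)
      test_i <- idx[test_loc]
      subj_train <- subset_dataset(subj, which(fold != f))
      pooled_train <- if (multi) {
        bind_datasets(subset_dataset(dataset, others_idx), subj_train)
      } else subj_train
      base_train <- if (baseline_scope == "pooled") pooled_train
                    else subj_train

      lr <- fit_baseline_lr(base_train)
      preds$lr[test_i] <- predict(lr, dataset$X[test_i, , drop = FALSE])
      esvr <- fit_baseline_esvr(base_train, config)
      preds$esvr[test_i] <- predict_svr(esvr, dataset$X[test_i, , drop = FALSE])
      for (i in test_i) {
        preds$st_svr[i] <- predict_transductive(subj_train, dataset$X[i, ],
                                                config)$yhat
        if (multi) {
          preds$t_svr[i] <- predict_transductive(pooled_train,
                                                 dataset$X[i, ], config)$yhat
        }
      }
    }
  }

  reports <- lapply(preds, function(p) {
    evaluation_report(truth, p, subject_id = dataset$subject_id)
  })
  table <- data.frame(
    model = c(lr = "LR", esvr = "e-SVR", st_svr = "ST-SVR",
              t_svr = "T-SVR")[models],
    mae = vapply(reports, function(r) r$mae, numeric(1)),
    sd = vapply(reports, function(r) r$abs_err_sd, numeric(1)),
    row.names = NULL
  )
  list(table = table, reports = reports)
}
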