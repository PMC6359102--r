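#' Labeled example sets
#'
#' The atomic training/test container: a feature matrix with one continuous
#' stress label in `[0, 1]` and one subject identifier per row.
#'
#' @param X n x d numeric matrix (rows are examples, features normalized).
#' @param y numeric labels in `[0, 1]`.
#' @param subject_id character vector (recycled if length 1).
#' @return Object of class `labeled_dataset` with elements `X`, `y`,
#'   `subject_id`.
#' @export
labeled_dataset <- function(X, y, subject_id = "s1") {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (any(y < -1e-9 | y > 1 + 1e-9)) stop("labels must lie in [0, 1]")
  subject_id <- rep_len(as.character(subject_id), nrow(X))
  structure(list(X = X, y = y, subject_id = subject_id),
            class = "labeled_dataset")
}

#' Convert a feature table to a labeled dataset
#'
#' @param table feature table (see [extract_feature_table()]) with columns
#'   `subject_id`, `label`, and feature columns.
#' @param feature_cols feature column names; default every numeric column
#'   except `label`, `window_start`, `window_end`.
#' @return A [labeled_dataset()].
#' @export
as_labeled_dataset <- function(table, feature_cols = NULL) {
  table <- as.data.frame(table)
  if (is.null(feature_cols)) {
    num <- names(table)[vapply(table, is.numeric, logical(1))]
    feature_cols <- setdiff(num, c("label", "window_start", "window_end"))
  }
  labeled_dataset(as.matrix(table[feature_cols]), table$label,
                  table$subject_id)
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d examples, %d features, %d subject(s)\n",
              nrow(x$X), ncol(x$X), length(unique(x$subject_id))))
  invisible(x)
}

n_examples <- function(d) nrow(d$X)

subset_dataset <- function(d, idx) {
  labeled_dataset(d$X[idx, , drop = FALSE], d$y[idx], d$subject_id[idx])
}

bind_datasets <- function(a, b) {
  labeled_dataset(rbind(a$X, b$X), c(a$y, b$y),
                  c(a$subject_id, b$subject_id))
}

#' Transductive model configuration
#'
#' @param N neighborhood size (number of training examples selected per
#'   test instance); the operating value established by cross-validation
#'   is 5.
#' @param rho scaling parameter of the label-dispersion penalty (>= 0).
#' @param C,epsilon SVR box penalty and tube half-width (LIBSVM-convention
#'   defaults: C = 1, epsilon = 0.1).
#' @param kernel a [kernel_spec()]; the default RBF kernel resolves gamma
#'   to `1 / n_features`.
#' @param pool_multiplier candidate-pool factor: the neighborhood is chosen
#'   from the `pool_multiplier * N` kernel-nearest training examples.
#' @param folds cross-validation folds for the evaluation harness.
#' @return Object of class `transductive_config`.
#' @export
transductive_config <- function(N = 5, rho = 1, C = 1, epsilon = 0.1,
                                kernel = kernel_spec("rbf"),
                                pool_multiplier = 4, folds = 5) {
  stopifnot(N >= 1, rho >= 0, C > 0, epsilon >= 0, pool_multiplier >= 1,
            folds >= 2)
  structure(list(N = as.integer(N), rho = rho, C = C, epsilon = epsilon,
                 kernel = kernel, pool_multiplier = as.integer(pool_multiplier),
                 folds = as.integer(folds)),
            class = "transductive_config")
}

#' Robust label-dispersion scores
#'
#' Stahel-Donoho-type outlyingness of each label relative to a pool:
#' `|y_i - median(y)| / mad(y)` with the raw (unscaled) median absolute
#' deviation. When `mad(y) = 0` (all labels identical up to a majority tie)
#' every score is defined as 0: identical labels present no outliers to
#' penalize.
#'
#' @param y_pool numeric label vector (non-empty).
#' @return List with `median_y`, `mad_y`, and `scores` (same length as
#'   `y_pool`, all >= 0).
#' @export
dispersion_scores <- function(y_pool) {
  y_pool <- as.numeric(y_pool)
  if (length(y_pool) == 0) stop("empty label pool")
  med <- stats::median(y_pool)
  mad_raw <- stats::median(abs(y_pool - med))
  scores <- if (mad_raw == 0) rep(0, length(y_pool))
            else abs(y_pool - med) / mad_raw
  list(median_y = med, mad_y = mad_raw, scores = scores)
}

#' Select a transductive neighborhood for one test instance
#'
#' Two-stage minimization of the combined objective
#' `sum_{i in sigma} kappa_i + rho * sum_{i in sigma} |y_i - median(y)| /
#' mad(y)`: (1) a candidate pool of the `pool_multiplier * N`
#' kernel-nearest training examples is formed by the feature-space distance
#' `kappa`; (2) the median/MAD statistics are computed on the pool's
#' labels, each candidate is scored `kappa_i + rho * dispersion_i`, and the
#' `N` smallest scores are selected (ties broken toward the lower index).
#' Because the objective is separable given pool-level statistics, stage 2
#' attains the exact subset optimum for that statistic.
#'
#' @param train a [labeled_dataset()].
#' @param test_point feature vector (length d) or 1 x d matrix.
#' @param config a [transductive_config()].
#' @param km optional precomputed [compute_kernel_matrices()] for
#'   `(train, test_point)`.
#' @return Object of class `neighborhood_selection` with `sigma` (selected
#'   indices, size N), `kappa_row` (length L), `dispersion_terms` (length
#'   L, relative to the pool statistics), `pool` (candidate indices),
#'   `stats` (pool median/MAD), `objective_value`, and the 0/1 weight
#'   vector `omega` (length L, `sum(omega) == N`).
#' @export
select_neighborhood <- function(train, test_point, config, km = NULL) {
  stopifnot(inherits(train, "labeled_dataset"),
            inherits(config, "transductive_config"))
  L <- n_examples(train)
  if (config$N > L) stop("neighborhood size N = ", config$N,
                         " exceeds training-set size ", L)
  if (is.null(km)) {
    # kappa needs only the Gram diagonal, not the full training Gram
    z <- matrix(test_point, nrow = 1)
    kcross <- kernel_eval(train$X, z, config$kernel)[, 1]
    kappa <- pmax(kernel_self_diag(train$X, config$kernel) - 2 * kcross +
                    kernel_self_diag(z, config$kernel), 0)
  } else {
    kappa <- kernel_space_distance(km)[, 1]
  }

  pool_size <- min(L, config$pool_multiplier * config$N)
  pool <- order(kappa)[seq_len(pool_size)]
  ds <- dispersion_scores(train$y[pool])
  disp_all <- if (ds$mad_y == 0) rep(0, L)
              else abs(train$y - ds$median_y) / ds$mad_y

  score <- kappa[pool] + config$rho * disp_all[pool]
  sel <- pool[order(score, pool)[seq_len(config$N)]]
  omega <- numeric(L)
  omega[sel] <- 1
  structure(
    list(sigma = sel, kappa_row = kappa, dispersion_terms = disp_all,
         pool = pool, stats = list(median_y = ds$median_y, mad_y = ds$mad_y),
         objective_value = sum(kappa[sel] + config$rho * disp_all[sel]),
         omega = omega),
    class = "neighborhood_selection"
  )
}

#' @export
print.neighborhood_selection <- function(x, ...) {
  cat(sprintf(
    "neighborhood_selection: sigma = {%s}, objective = %.6g (pool %d)\n",
    paste(x$sigma, collapse = ", "), x$objective_value, length(x$pool)))
  invisible(x)
}

#' Transductive prediction for one test instance
#'
#' The full pipeline: select the neighborhood in kernel feature space
#' (penalizing robust label dispersion), build the 0/1 weight vector Omega,
#' fit the instance-weighted epsilon-SVR (whose box constraints collapse to
#' the selected subset), and evaluate the local regression function at the
#' test point.
#'
#' @param train a [labeled_dataset()].
#' @param test_point feature vector.
#' @param config a [transductive_config()].
#' @return List with `yhat`, the `selection`, and the local `model`.
#' @export
predict_transductive <- function(train, test_point, config) {
  sel <- select_neighborhood(train, test_point, config)
  model <- fit_weighted_svr(train$X, train$y, weights = sel$omega,
                            C = config$C, epsilon = config$epsilon,
                            kernel = config$kernel)
  list(yhat = predict_svr(model, test_point), selection = sel,
       model = model)
}

# seeded k-fold assignment, balanced sizes
make_folds <- function(n, folds, seed = 1) {
  stopifnot(folds >= 2, n >= folds)
  r <- sample_with_seed(seed, n)
  fold <- rep(seq_len(folds), length.out = n)
  fold[order(r)]
}

sample_with_seed <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  stats::runif(n)
}

#' Subject-dependent transductive evaluation (ST-SVR)
#'
#' k-fold cross-validation inside one subject's examples: each test point
#' is predicted transductively from the subject's remaining folds.
#'
#' @param dataset a [labeled_dataset()] (may contain several subjects).
#' @param subject_id subject to evaluate.
#' @param config a [transductive_config()].
#' @param seed seed for the fold assignment.
#' @return An [evaluation_report()] for this subject's predictions.
#' @export
run_st_svr <- function(dataset, subject_id, config = transductive_config(),
                       seed = 1) {
  idx <- which(dataset$subject_id == subject_id)
  if (length(idx) == 0) stop("no examples for subject ", subject_id)
  subj <- subset_dataset(dataset, idx)
  n <- n_examples(subj)
  if (n < config$folds * config$N) {
    stop("subject ", subject_id, " has too few examples (", n,
         ") for ", config$folds, "-fold transduction with N = ", config$N)
  }
  fold <- make_folds(n, config$folds, seed)
  yhat <- numeric(n)
  for (f in seq_len(config$folds)) {
    test_i <- which(fold == f)
    pool <- subset_dataset(subj, which(fold != f))
    for (i in test_i) {
      yhat[i] <- predict_transductive(pool, subj$X[i, ], config)$yhat
    }
  }
  evaluation_report(subj$y, yhat, subject_id = subj$subject_id)
}

#' Pooled-subject transductive evaluation (T-SVR)
#'
#' For each test fold of subject i, the training pool is every other
#' subject's examples plus subject i's remaining folds; predictions are
#' transductive as in [run_st_svr()].
#'
#' @inheritParams run_st_svr
#' @return An [evaluation_report()] for this subject's predictions.
#' @export
run_t_svr <- function(dataset, subject_id, config = transductive_config(),
                      seed = 1) {
  if (length(unique(dataset$subject_id)) < 2) {
    stop("T-SVR requires a multi-subject dataset")
  }
  idx <- which(dataset$subject_id == subject_id)
  if (length(idx) == 0) stop("no examples for subject ", subject_id)
  subj <- subset_dataset(dataset, idx)
  others <- subset_dataset(dataset, which(dataset$subject_id != subject_id))
  n <- n_examples(subj)
  if (n < config$folds) stop("subject ", subject_id,
                             " has fewer examples than folds")
  fold <- make_folds(n, config$folds, seed)
  yhat <- numeric(n)
  for (f in seq_len(config$folds)) {
    test_i <- which(fold == f)
    pool <- bind_datasets(others, subset_dataset(subj, which(fold != f)))
    for (i in test_i) {
      yhat[i] <- predict_transductive(pool, subj$X[i, ], config)$yhat
    }
  }
  evaluation_report(subj$y, yhat, subject_id = subj$subject_id)
}
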