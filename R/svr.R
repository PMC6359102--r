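#' Fit an instance-weighted epsilon-SVR
#'
#' Solves the dual of the weighted epsilon-insensitive SVR, in which each
#' example's slack penalty is `C * w_i`, so the dual box constraints become
#' `alpha_i, alpha*_i in [0, C * w_i]`. With 0/1 weights this restricts the
#' support of the solution to the selected neighborhood: examples with
#' `w_i = 0` have `beta_i = 0` exactly and the fit coincides with a plain
#' epsilon-SVR on the `w_i = 1` subset.
#'
#' The dual is solved by sequential minimal optimization (maximal-violating-
#' pair working-set selection) to a KKT gap below `tol`; the bias is the
#' midpoint of the optimality interval, which equals the free-support-vector
#' value whenever free support vectors exist.
#'
#' @param X n x d matrix of (normalized) training features.
#' @param y numeric labels in `[0, 1]`, length n.
#' @param weights per-example weights in `[0, 1]` (the Omega vector);
#'   default all 1 (plain inductive epsilon-SVR).
#' @param C box penalty (positive).
#' @param epsilon half-width of the insensitive tube (>= 0).
#' @param kernel a [kernel_spec()].
#' @param tol KKT stopping tolerance of the dual solver.
#' @param max_iter iteration cap for the solver.
#' @return Object of class `svr_model` with dual coefficients `beta`
#'   (length n; `beta_i = alpha_i - alpha*_i`), bias `b`, `support_indices`
#'   (`|beta| > 1e-10`), the kernel spec, the training features of the
#'   support vectors, and solver diagnostics.
#' @export
fit_weighted_svr <- function(X, y, weights = NULL, C = 1, epsilon = 0.1,
                             kernel = kernel_spec(), tol = 1e-8,
                             max_iter = 1000000L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(length(y) == n, n >= 1, C > 0, epsilon >= 0)
  if (is.null(weights)) weights <- rep(1, n)
  weights <- as.numeric(weights)
  stopifnot(length(weights) == n)
  if (any(weights < 0 | weights > 1)) stop("weights must lie in [0, 1]")
  active <- which(weights > 0)
  if (length(active) == 0) stop("all weights are zero; nothing to fit")

  Xa <- X[active, , drop = FALSE]
  K <- kernel_eval(Xa, Xa, kernel)
  sol <- .smo_svr(K, y[active], C * weights[active], epsilon,
                  tol = tol, max_iter = max_iter)
  if (!sol$converged) {
    stop("SVR dual solver did not converge: KKT gap ",
         format(sol$kkt_gap), " after ", sol$iterations, " iterations")
  }
  beta <- numeric(n)
  beta[active] <- sol$beta
  sv <- which(abs(beta) > 1e-10)
  structure(
    list(beta = beta, b = sol$b, support_indices = sv,
         kernel = kernel, X = X, C = C, epsilon = epsilon,
         weights = weights,
         iterations = sol$iterations, kkt_gap = sol$kkt_gap),
    class = "svr_model"
  )
}

#' @export
print.svr_model <- function(x, ...) {
  cat(sprintf(
    "weighted eps-SVR: %d examples, %d support vectors, %s kernel, C=%g, eps=%g\n",
    nrow(x$X), length(x$support_indices), x$kernel$kind, x$C, x$epsilon))
  invisible(x)
}

#' Predict with a fitted SVR model
#'
#' `f(x) = sum_i beta_i k(x_i, x) + b`, summed over support vectors.
#'
#' @param model an `svr_model`.
#' @param newdata m x d matrix (or single feature vector).
#' @return Numeric vector of m predictions.
#' @export
predict_svr <- function(model, newdata) {
  stopifnot(inherits(model, "svr_model"))
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  sv <- model$support_indices
  if (length(sv) == 0) return(rep(model$b, nrow(newdata)))
  Kx <- kernel_eval(newdata, model$X[sv, , drop = FALSE], model$kernel)
  drop(Kx %*% model$beta[sv]) + model$b
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  predict_svr(object, newdata)
}
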