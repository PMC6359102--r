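#' Kernel specification
#'
#' @param kind `"rbf"`, `"linear"`, or `"polynomial"`.
#' @param gamma RBF width / polynomial scale (positive); `NULL` resolves to
#'   `1 / n_features` at evaluation time (the LIBSVM convention).
#' @param degree,coef0 polynomial parameters.
#' @return Object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("rbf", "linear", "polynomial"),
                        gamma = NULL, degree = 3, coef0 = 1) {
  kind <- match.arg(kind)
  if (kind != "linear" && !is.null(gamma) &&
      (!is.numeric(gamma) || gamma <= 0)) {
    stop("gamma must be positive")
  }
  structure(list(kind = kind, gamma = gamma, degree = degree, coef0 = coef0),
            class = "kernel_spec")
}

#' Evaluate a kernel between two sets of feature vectors
#'
#' @param X n x d matrix (rows are examples).
#' @param Z m x d matrix.
#' @param kernel a [kernel_spec()].
#' @return n x m matrix of kernel values `k(x_i, z_j)`.
#' @export
kernel_eval <- function(X, Z, kernel = kernel_spec()) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  if (ncol(X) != ncol(Z)) stop("feature dimension mismatch: ",
                               ncol(X), " vs ", ncol(Z))
  if (length(kernel$gamma) == 0) kernel$gamma <- 1 / ncol(X)
  G <- X %*% t(Z)
  switch(kernel$kind,
    linear = G,
    polynomial = (kernel$gamma * G + kernel$coef0)^kernel$degree,
    rbf = {
      d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * G
      exp(-kernel$gamma * pmax(d2, 0))
    }
  )
}

# self-kernel values k(x_i, x_i) for each row, without the full Gram matrix
kernel_self_diag <- function(X, kernel) {
  X <- as.matrix(X)
  if (length(kernel$gamma) == 0) kernel$gamma <- 1 / ncol(X)
  switch(kernel$kind,
    rbf = rep(1, nrow(X)),
    linear = rowSums(X^2),
    polynomial = (kernel$gamma * rowSums(X^2) + kernel$coef0)^kernel$degree
  )
}

#' Kernel matrices for one train/test pairing
#'
#' Computes the training Gram matrix, the test self-kernel diagonal
#' `k(z_j, z_j)`, and the L x M cross matrix `K[i, j] = k(x_i, z_j)`.
#'
#' @param train n x d matrix of training features (or data.frame).
#' @param test m x d matrix of test features.
#' @param kernel a [kernel_spec()].
#' @return List of class `kernel_matrices` with `Ktr`, `Kte_diag`,
#'   `Kcross`, and the `kernel` spec.
#' @export
compute_kernel_matrices <- function(train, test, kernel = kernel_spec()) {
  X <- as.matrix(train); Z <- as.matrix(test)
  structure(
    list(Ktr = kernel_eval(X, X, kernel),
         Kte_diag = vapply(seq_len(nrow(Z)), function(j) {
           kernel_eval(Z[j, , drop = FALSE], Z[j, , drop = FALSE], kernel)[1, 1]
         }, numeric(1)),
         Kcross = kernel_eval(X, Z, kernel),
         kernel = kernel),
    class = "kernel_matrices"
  )
}

#' Kernel feature-space squared distances
#'
#' The squared norm of the difference of the (implicit) feature maps,
#' `kappa[i, j] = ||Phi(x_i) - Phi(z_j)||^2 = Ktr[i,i] - 2 K[i,j] +
#' Kte[j,j]`, computable from kernel values alone. It is the distance used
#' to rank training examples by proximity to a test instance in the
#' high-dimensional space.
#'
#' @param km a [compute_kernel_matrices()] result.
#' @return L x M matrix of nonnegative squared distances.
#' @export
kernel_space_distance <- function(km) {
  stopifnot(inherits(km, "kernel_matrices"))
  kap <- outer(diag(km$Ktr), km$Kte_diag, "+") - 2 * km$Kcross
  pmax(kap, 0)
}
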