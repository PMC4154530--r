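#' Kernel specification
#'
#' @param kind `"linear"` (`K = X Z'`) or `"rbf"`
#'   (`K[i,j] = exp(-gamma * ||x_i - z_j||^2)`).
#' @param rbf_gamma positive width parameter of the RBF kernel (default 0.5,
#'   the value used for both kernel classifiers here). The alternative
#'   sigma parameterization `exp(-||.||^2 / (2 sigma^2))` corresponds to
#'   `rbf_gamma = 1 / (2 sigma^2)`.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("linear", "rbf"), rbf_gamma = 0.5) {
  kind <- match.arg(kind)
  if (kind == "rbf" && (!is.numeric(rbf_gamma) || rbf_gamma <= 0))
    stop("`rbf_gamma` must be positive for the rbf kernel")
  structure(list(kind = kind,
                 rbf_gamma = if (kind == "rbf") rbf_gamma else NULL),
            class = "kernel_spec")
}

#' Kernel (Gram) matrix between two sample sets
#'
#' @param X,Z numeric matrices with the same number of columns (`n x d` and
#'   `m x d`).
#' @param kernel a [kernel_spec()].
#' @return The `n x m` kernel matrix.
#' @export
kernel_matrix <- function(X, Z, kernel = kernel_spec("linear")) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  if (ncol(X) != ncol(Z))
    stop(sprintf("dimension mismatch: X has %d columns, Z has %d",
                 ncol(X), ncol(Z)))
  if (kernel$kind == "linear") return(X %*% t(Z))
  d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * tcrossprod(X, Z)
  exp(-kernel$rbf_gamma * pmax(d2, 0))
}
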