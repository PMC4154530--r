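#' Fit a binary relevance vector machine
#'
#' Sparse Bayesian kernel classification: the decision function is
#' `sigma(sum_i w_i K(x, x_i) + b)` with an independent zero-mean Gaussian
#' prior `w_i ~ N(0, 1/alpha_i)` on every weight. Each hyperparameter
#' `alpha_i` is re-estimated by evidence maximization,
#' `alpha_i <- gamma_i / mu_i^2` with `gamma_i = 1 - alpha_i * Sigma_ii`,
#' where `mu` is the posterior mode of the weights under the logistic
#' likelihood (found by iteratively reweighted least squares, i.e. a Laplace
#' approximation) and `Sigma` the posterior covariance at the mode. Basis
#' functions whose `alpha` exceeds `prune_threshold` are removed; the
#' training inputs behind the surviving kernel columns are the relevance
#' vectors. Regularization is thus estimated automatically — there is no
#' penalty parameter to tune.
#'
#' @param X `n x d` numeric feature matrix.
#' @param y binary labels (0/1, logical, or a two-level factor whose second
#'   level is the positive class).
#' @param kernel a [kernel_spec()].
#' @param max_iter maximum number of hyperparameter update cycles.
#' @param tol convergence tolerance on `max |delta log alpha|`.
#' @param prune_threshold `alpha` above which a basis function is removed.
#' @param alpha_init initial `alpha` for all basis functions (and the bias).
#' @param irls_max cap on inner IRLS iterations per cycle (with step halving
#'   whenever a Newton step decreases the posterior).
#' @return An object of class `rvm_binary` with the relevance vectors,
#'   their weights, the bias, retained `alpha`, `iterations_run` and a
#'   `converged` flag (non-convergence is reported here, not raised).
#' @export
rvm_fit_binary <- function(X, y, kernel = kernel_spec("linear"),
                           max_iter = 500L, tol = 1e-3,
                           prune_threshold = 1e9, alpha_init = 1e-2,
                           irls_max = 25L) {
  X <- as.matrix(X)
  y <- as_binary01(y)
  if (!all(is.finite(X))) stop("non-finite feature values")
  n <- nrow(X)
  if (n < 2 || length(unique(y)) < 2)
    stop("training data must contain both classes (n >= 2)")

  Phi <- cbind(bias = 1, kernel_matrix(X, X, kernel))
  keep <- seq_len(n + 1L)            # index 1 is the bias column
  alpha <- rep(alpha_init, n + 1L)
  w <- rep(0, n + 1L)
  iterations <- 0L
  converged <- FALSE

  log_post <- function(Phi, w, alpha, z = Phi %*% w) {
    # Bernoulli log-likelihood written via log1p for numerical safety
    sum(ifelse(y == 1, -log1p(exp(-z)), -log1p(exp(z)))) -
      0.5 * sum(alpha * w^2)
  }

  for (it in seq_len(max_iter)) {
    iterations <- it
    # --- inner IRLS: posterior mode for fixed alpha ---
    f <- log_post(Phi, w, alpha)
    for (j in seq_len(irls_max)) {
      z <- as.numeric(Phi %*% w)
      s <- 1 / (1 + exp(-z))
      g <- crossprod(Phi, y - s) - alpha * w
      if (max(abs(g)) < 1e-6) break
      B <- pmax(s * (1 - s), 1e-12)
      H <- crossprod(Phi * sqrt(B))
      diag(H) <- diag(H) + alpha
      R <- chol_safe(H)
      dw <- backsolve(R, forwardsolve(t(R), g))
      step <- 1
      repeat {
        wn <- w + step * as.numeric(dw)
        fn <- log_post(Phi, wn, alpha)
        if (fn >= f || step < 1e-10) break
        step <- step / 2
      }
      if (fn < f) break      # no ascent possible along the Newton direction
      improved <- fn - f
      w <- wn; f <- fn
      if (improved < 1e-9) break
    }
    # --- evidence update of alpha at the mode ---
    z <- as.numeric(Phi %*% w)
    s <- 1 / (1 + exp(-z))
    B <- pmax(s * (1 - s), 1e-12)
    H <- crossprod(Phi * sqrt(B))
    diag(H) <- diag(H) + alpha
    R <- chol_safe(H)
    Sigma_diag <- colSums(backsolve(R, diag(nrow(H)))^2)
    gam <- pmax(1 - alpha * Sigma_diag, 1e-12)
    alpha_new <- gam / pmax(w^2, .Machine$double.xmin)

    ok <- alpha_new < prune_threshold
    if (!any(ok)) ok[which.min(alpha_new)] <- TRUE   # never drop every basis
    delta <- max(abs(log(alpha_new[ok]) - log(alpha[ok])))
    alpha <- alpha_new[ok]
    w <- w[ok]
    keep <- keep[ok]
    Phi <- Phi[, ok, drop = FALSE]
    if (delta < tol) { converged <- TRUE; break }
  }

  has_bias <- keep[1] == 1L
  rv_idx <- keep[keep != 1L] - 1L
  structure(
    list(relevance_vectors = X[rv_idx, , drop = FALSE],
         rv_index = rv_idx,
         weights = if (has_bias) w[-1] else w,
         bias = if (has_bias) w[1] else 0,
         alpha = alpha,
         kernel = kernel,
         iterations_run = iterations,
         converged = converged,
         n_train = n),
    class = "rvm_binary")
}

#' @export
print.rvm_binary <- function(x, ...) {
  cat(sprintf("<rvm_binary> %d relevance vector(s) of %d training points, %s kernel, %d iteration(s)%s\n",
              nrow(x$relevance_vectors), x$n_train, x$kernel$kind,
              x$iterations_run,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Posterior class-1 probability of a binary sparse model
#'
#' Evaluates `sigma(K(X, RV) w + b)` with `sigma` the logistic function.
#'
#' @param model an [rvm_fit_binary()] result.
#' @param X `m x d` matrix of inputs.
#' @return Numeric vector of `m` probabilities in `(0, 1)`.
#' @export
predict_binary <- function(model, X) {
  stopifnot(inherits(model, "rvm_binary"))
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$relevance_vectors))
    stop(sprintf("dimension mismatch: model expects %d features, got %d",
                 ncol(model$relevance_vectors), ncol(X)))
  z <- model$bias
  if (nrow(model$relevance_vectors) > 0) {
    K <- kernel_matrix(X, model$relevance_vectors, model$kernel)
    z <- as.numeric(K %*% model$weights) + model$bias
  } else {
    z <- rep(z, nrow(X))
  }
  1 / (1 + exp(-z))
}

# internal: labels -> 0/1
as_binary01 <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2) stop("factor labels must have exactly two levels")
    return(as.numeric(y == levels(y)[2]))
  }
  if (is.logical(y)) return(as.numeric(y))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("numeric labels must be 0/1")
  y
}

# internal: Cholesky with jitter fallback for near-singular Hessians
chol_safe <- function(H) {
  tryCatch(chol(H), error = function(e) {
    diag(H) <- diag(H) + 1e-8 * mean(diag(H))
    chol(H)
  })
}
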