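#' Classifier specification for the stage-classification interface
#'
#' Defaults are the fixed operating points of the system: `k = 13`
#' neighbors for k-NN, `cost = 50` for the external margin classifier, and
#' RBF width `gamma = 0.5` where the RBF kernel is selected.
#'
#' @param kind one of `"rvm"`, `"lda"`, `"knn"`, `"svm"`. `"svm"` plugs an
#'   established margin-classifier implementation (package \pkg{e1071})
#'   behind the same interface for comparison runs.
#' @param kernel a [kernel_spec()] (used by `"rvm"` and `"svm"`).
#' @param k neighbor count for `"knn"`.
#' @param cost penalty parameter for `"svm"`.
#' @param ... further arguments stored and passed to [rvm_fit_binary()].
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("rvm", "lda", "knn", "svm"),
                            kernel = kernel_spec("linear"), k = 13L,
                            cost = 50, ...) {
  kind <- match.arg(kind)
  structure(list(kind = kind, kernel = kernel, k = as.integer(k),
                 cost = cost, extra = list(...)),
            class = "classifier_spec")
}

#' Fit / apply a per-feature z-score standardizer
#'
#' Means and standard deviations are estimated on training data only and
#' then applied unchanged to test data; a constant feature gets unit scale.
#' Kernel and distance based classifiers need commensurate feature scales,
#' so standardization sits between feature extraction and every classifier.
#'
#' @param X training feature matrix.
#' @return `fit_standardizer`: a list with `center` and `scale`.
#' @export
fit_standardizer <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

#' @rdname fit_standardizer
#' @param std a standardizer from [fit_standardizer()].
#' @export
apply_standardizer <- function(std, X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

# ---- one-against-all multiclass wrapper ------------------------------------

#' Fit a one-against-all multiclass model over the five sleep stages
#'
#' Trains one binary model per stage (that stage vs. all others) on
#' z-scored features. Prediction takes the stage whose binary model emits
#' the largest probability (RVM) or decision value (SVM); exact ties go to
#' the earliest stage in `c("W","N1","N2","N3","REM")`.
#'
#' @param X `n x d` feature matrix.
#' @param y stage labels; every one of the five stages must be present.
#' @param spec a [classifier_spec()] with `kind` `"rvm"` or `"svm"`.
#' @param class_order fixed stage order of the ensemble.
#' @return An object of class `ova_model`.
#' @export
ova_fit <- function(X, y, spec = classifier_spec("rvm"),
                    class_order = SLEEP_STAGES) {
  X <- as.matrix(X)
  y <- as.character(y)
  check_stages(y, allow_unknown = FALSE)
  absent <- setdiff(class_order, unique(y))
  if (length(absent) > 0)
    stop("stage(s) absent from training data: ",
         paste(absent, collapse = ", "))
  if (!spec$kind %in% c("rvm", "svm"))
    stop("ova_fit supports kinds 'rvm' and 'svm'")
  std <- fit_standardizer(X)
  Xs <- apply_standardizer(std, X)
  members <- lapply(class_order, function(cls) {
    yb <- as.numeric(y == cls)
    if (spec$kind == "rvm") {
      do.call(rvm_fit_binary,
              c(list(X = Xs, y = yb, kernel = spec$kernel), spec$extra))
    } else {
      fit_svm_binary(Xs, yb, spec)
    }
  })
  names(members) <- class_order
  structure(list(class_order = class_order, members = members,
                 feature_standardizer = std, spec = spec),
            class = "ova_model")
}

#' @export
print.ova_model <- function(x, ...) {
  cat(sprintf("<ova_model> %s, stages %s\n", x$spec$kind,
              paste(x$class_order, collapse = "/")))
  if (x$spec$kind == "rvm") {
    nrv <- vapply(x$members, function(m) nrow(m$relevance_vectors), integer(1))
    cat("  relevance vectors:",
        paste(sprintf("%s=%d", names(nrv), nrv), collapse = " "), "\n")
  }
  invisible(x)
}

#' Per-stage scores of a one-against-all model
#'
#' @param model an [ova_fit()] result.
#' @param X feature matrix on the original (unstandardized) scale.
#' @return `n x 5` matrix of member outputs (probabilities for RVM,
#'   decision values for SVM), columns in `model$class_order`.
#' @export
ova_scores <- function(model, X) {
  stopifnot(inherits(model, "ova_model"))
  Xs <- apply_standardizer(model$feature_standardizer, X)
  sc <- vapply(model$members, function(m) {
    if (inherits(m, "rvm_binary")) predict_binary(m, Xs)
    else predict_svm_binary(m, Xs)
  }, numeric(nrow(Xs)))
  sc <- matrix(sc, nrow = nrow(Xs),
               dimnames = list(NULL, model$class_order))
  sc
}

#' Predict stage labels with a one-against-all model
#'
#' @inheritParams ova_scores
#' @return Character vector of stage labels.
#' @export
ova_predict <- function(model, X) {
  sc <- ova_scores(model, X)
  model$class_order[max.col(sc, ties.method = "first")]
}

# external margin classifier (e1071) behind the common interface
fit_svm_binary <- function(Xs, yb, spec) {
  if (!requireNamespace("e1071", quietly = TRUE))
    stop("classifier kind 'svm' requires the e1071 package")
  kern <- if (spec$kernel$kind == "rbf") "radial" else "linear"
  gam <- if (spec$kernel$kind == "rbf") spec$kernel$rbf_gamma else 1 / ncol(Xs)
  yf <- factor(yb, levels = c(0, 1))
  m <- e1071::svm(Xs, yf, kernel = kern, cost = spec$cost, gamma = gam,
                  scale = FALSE)
  # orient decision values so larger means class "1"
  dv <- attr(predict(m, Xs[1:2, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  flip <- grepl("^0/1$", colnames(dv))   # positive side is the first-named class
  list(model = m, flip = flip)
}

predict_svm_binary <- function(m, Xs) {
  dv <- attr(predict(m$model, Xs, decision.values = TRUE), "decision.values")
  d <- as.numeric(dv[, 1])
  if (m$flip) -d else d
}

# ---- baselines -------------------------------------------------------------

#' Linear discriminant analysis (shared-covariance Gaussian classifier)
#'
#' Classes are modeled as Gaussians with a pooled within-class covariance;
#' prediction takes the largest linear discriminant
#' `x' S^-1 m_c - m_c' S^-1 m_c / 2 + log pi_c`. When the pooled covariance
#' is near singular and `ridge = "auto"`, a ridge of
#' `1e-6 * trace(S) / d` is added to its diagonal; with `ridge = "none"` a
#' singular covariance is an error.
#'
#' @param X `n x d` feature matrix.
#' @param y class labels (any set of 2 or more classes, each with at least
#'   2 samples).
#' @param ridge `"auto"`, `"none"`, or a non-negative number added to the
#'   diagonal of the pooled covariance.
#' @return An object of class `lda_model`.
#' @export
lda_fit <- function(X, y, ridge = c("auto", "none")) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- unique(y)
  if (length(classes) < 2) stop("need at least two classes")
  cnt <- table(y)
  if (any(cnt < 2))
    stop("class(es) with fewer than 2 samples: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  d <- ncol(X); n <- nrow(X)
  means <- do.call(rbind, lapply(classes, function(c)
    colMeans(X[y == c, , drop = FALSE])))
  rownames(means) <- classes
  Sw <- matrix(0, d, d)
  for (c in classes) {
    Xc <- scale(X[y == c, , drop = FALSE], center = means[c, ], scale = FALSE)
    Sw <- Sw + crossprod(Xc)
  }
  S <- Sw / (n - length(classes))
  if (is.character(ridge)) {
    ridge <- match.arg(ridge)
    lam <- if (ridge == "auto" && rcond_sym(S) < 1e-10)
      1e-6 * sum(diag(S)) / d else 0
  } else lam <- ridge
  Sr <- S + diag(lam, d)
  Sinv <- tryCatch(solve(Sr), error = function(e)
    stop("pooled within-class covariance is singular (set ridge = 'auto')"))
  priors <- as.numeric(cnt[classes]) / n
  structure(list(classes = classes, means = means, Sinv = Sinv,
                 log_priors = log(priors), ridge_used = lam),
            class = "lda_model")
}

rcond_sym <- function(S) {
  ev <- tryCatch(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) c(0, 1))
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

#' @rdname lda_fit
#' @param model an `lda_model`.
#' @export
lda_predict <- function(model, X) {
  X <- as.matrix(X)
  M <- model$means
  disc <- X %*% model$Sinv %*% t(M)
  disc <- sweep(disc, 2, 0.5 * rowSums((M %*% model$Sinv) * M), "-")
  disc <- sweep(disc, 2, model$log_priors, "+")
  model$classes[max.col(disc, ties.method = "first")]
}

#' k-nearest-neighbor classification
#'
#' Euclidean distance, majority vote among the `k` nearest training points.
#' A vote tie is broken in favor of the tied class containing the single
#' nearest neighbor; equal distances are resolved by training-row order.
#'
#' @param X_train,y_train training features and labels.
#' @param X_test test features.
#' @param k neighbor count (default 13, the fixed operating point).
#' @return Character vector of predicted labels.
#' @export
knn_predict <- function(X_train, y_train, X_test, k = 13L) {
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  y_train <- as.character(y_train)
  n <- nrow(X_train)
  if (k < 1 || k > n) stop(sprintf("`k` must be in 1..%d", n))
  d2 <- outer(rowSums(X_test^2), rowSums(X_train^2), "+") -
    2 * tcrossprod(X_test, X_train)
  apply(d2, 1, function(dist_row) {
    ord <- order(dist_row)               # stable: ties by training index
    nb <- y_train[ord[seq_len(k)]]
    votes <- table(nb)
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) return(top)
    nb[nb %in% top][1]                    # nearest neighbor among tied classes
  })
}

# ---- unified stage-classifier surface --------------------------------------

#' Fit any supported classifier on stage-labeled features
#'
#' Dispatches on `spec$kind`: `"rvm"`/`"svm"` use the one-against-all
#' ensemble ([ova_fit()]); `"lda"` and `"knn"` are inherently multiclass and
#' are fitted directly on z-scored features. All five stages must be
#' present.
#'
#' @inheritParams ova_fit
#' @return An object of class `stage_classifier`.
#' @export
fit_stage_classifier <- function(X, y, spec = classifier_spec("rvm"),
                                 class_order = SLEEP_STAGES) {
  X <- as.matrix(X); y <- as.character(y)
  check_stages(y, allow_unknown = FALSE)
  absent <- setdiff(class_order, unique(y))
  if (length(absent) > 0)
    stop("stage(s) absent from training data: ",
         paste(absent, collapse = ", "))
  fit <- switch(
    spec$kind,
    rvm = ,
    svm = list(model = ova_fit(X, y, spec, class_order), std = NULL),
    lda = {
      std <- fit_standardizer(X)
      list(model = lda_fit(apply_standardizer(std, X), y), std = std)
    },
    knn = {
      std <- fit_standardizer(X)
      list(model = list(X = apply_standardizer(std, X), y = y, k = spec$k),
           std = std)
    })
  structure(list(kind = spec$kind, fit = fit$model, standardizer = fit$std,
                 class_order = class_order, spec = spec),
            class = "stage_classifier")
}

#' Predict stage labels with a fitted [fit_stage_classifier()] model
#'
#' @param model a `stage_classifier`.
#' @param X feature matrix on the original scale.
#' @return Character vector of stage labels.
#' @export
predict_stages <- function(model, X) {
  stopifnot(inherits(model, "stage_classifier"))
  X <- as.matrix(X)
  switch(model$kind,
         rvm = ,
         svm = ova_predict(model$fit, X),
         lda = lda_predict(model$fit, apply_standardizer(model$standardizer, X)),
         knn = {
           Xs <- apply_standardizer(model$standardizer, X)
           knn_predict(model$fit$X, model$fit$y, Xs, model$fit$k)
         })
}

#' @export
print.stage_classifier <- function(x, ...) {
  cat(sprintf("<stage_classifier> kind=%s, stages %s\n", x$kind,
              paste(x$class_order, collapse = "/")))
  invisible(x)
}
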