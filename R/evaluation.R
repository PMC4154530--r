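#' Fisher-criterion separability of a feature set
#'
#' Computes the between-class scatter
#' `S_b = sum_c n_c (m_c - m)(m_c - m)'` and within-class scatter
#' `S_w = sum_c sum_{i in c} (x_i - m_c)(x_i - m_c)'` and returns the two
#' scatter-matrix ratios
#' `J1 = tr(S_b) / tr(S_w)` and `J2 = tr(S_w^-1 S_b)`. Larger values mean
#' larger class separability of the features. `J2` is invariant under any
#' invertible linear map of the feature space; `J1` under orthogonal maps
#' and global scaling.
#'
#' @param X `n x d` feature matrix.
#' @param y class labels (at least two classes, each with >= 2 samples).
#' @param ridge `"auto"` adds `1e-6 * trace(S_w) / d` to the diagonal of a
#'   near-singular `S_w` before inverting; `"none"` raises an error instead;
#'   a number is used directly.
#' @return A list with elements `J1` and `J2` (class `fisher_scores`).
#' @export
fisher_criteria <- function(X, y, ridge = c("auto", "none")) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- unique(y)
  if (length(classes) < 2) stop("need at least two classes")
  cnt <- table(y)
  if (any(cnt < 2))
    stop("class(es) with fewer than 2 samples: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  d <- ncol(X)
  m <- colMeans(X)
  Sb <- matrix(0, d, d); Sw <- matrix(0, d, d)
  for (c in classes) {
    Xc <- X[y == c, , drop = FALSE]
    mc <- colMeans(Xc)
    Sb <- Sb + nrow(Xc) * tcrossprod(mc - m)
    Sw <- Sw + crossprod(sweep(Xc, 2, mc, "-"))
  }
  J1 <- sum(diag(Sb)) / sum(diag(Sw))
  if (is.character(ridge)) {
    ridge <- match.arg(ridge)
    lam <- if (ridge == "auto" && rcond_sym(Sw) < 1e-12)
      1e-6 * sum(diag(Sw)) / d else 0
  } else lam <- ridge
  Swr <- Sw + diag(lam, d)
  J2 <- tryCatch(sum(diag(solve(Swr, Sb))), error = function(e)
    stop("within-class scatter matrix is singular (set ridge = 'auto')"))
  structure(list(J1 = J1, J2 = J2), class = "fisher_scores")
}

#' @export
print.fisher_scores <- function(x, ...) {
  cat(sprintf("<fisher_scores> J1 = %.4g, J2 = %.4g\n", x$J1, x$J2))
  invisible(x)
}

#' Fisher separability of a feature table
#'
#' Convenience wrapper around [fisher_criteria()] for stage-labeled feature
#' tables. By default the features are z-scored first — the representation
#' every classifier in the package consumes. `J1` compares trace ratios and
#' is therefore only meaningful under a fixed per-feature scale convention;
#' `J2` is invariant under any invertible linear map, so standardization
#' does not change it (a useful internal consistency check).
#'
#' @param features a data frame from [feature_table()].
#' @param standardize z-score the feature columns first (default `TRUE`).
#' @param feature_cols feature column names; default all non-metadata columns.
#' @return A `fisher_scores` list with `J1` and `J2`.
#' @export
feature_separability <- function(features, standardize = TRUE,
                                 feature_cols = NULL) {
  if (is.null(feature_cols)) feature_cols <- feature_columns(features)
  keep <- features$stage != "UNKNOWN"
  X <- as.matrix(features[keep, feature_cols, drop = FALSE])
  if (standardize) {
    std <- fit_standardizer(X)
    X <- apply_standardizer(std, X)
  }
  fisher_criteria(X, features$stage[keep])
}

#' Confusion matrix between expert and predicted stages
#'
#' Rows are the expert (truth) labels, columns the predictions.
#'
#' @param truth,predicted equal-length label vectors.
#' @param classes label set fixing the row/column order.
#' @return Integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, predicted, classes = SLEEP_STAGES) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("`truth` and `predicted` must have equal length")
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad) > 0)
    stop("label(s) outside the class set: ", paste(bad, collapse = ", "))
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Overall agreement of a confusion matrix
#' @param cm a square count matrix (rows = truth, columns = predicted).
#' @return Fraction of epochs on the diagonal.
#' @export
overall_accuracy <- function(cm) {
  cm <- unclass(as.matrix(cm))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(cm)) / total
}

#' Per-class sensitivity (recall) of a confusion matrix
#'
#' `sensitivity_c = cm[c, c] / sum(cm[c, ])`; a class never observed in the
#' truth labels gets `NA` (reported as missing, excluded from stage-wise
#' averages).
#'
#' @inheritParams overall_accuracy
#' @return Named numeric vector, one entry per class.
#' @export
per_class_sensitivity <- function(cm) {
  cm <- unclass(as.matrix(cm))
  if (sum(cm) == 0) stop("empty confusion matrix")
  rt <- rowSums(cm)
  out <- ifelse(rt > 0, diag(cm) / rt, NA_real_)
  names(out) <- rownames(cm)
  out
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with
#' `p_o` the observed agreement (diagonal fraction) and
#' `p_e = sum_c row_c * col_c / total^2` the agreement expected by chance
#' from the marginals. Unweighted. The degenerate case `p_e = 1` (all mass
#' in one row and column) is returned as `NA`.
#'
#' @inheritParams overall_accuracy
#' @return A single number in `[-1, 1]`, or `NA` when undefined.
#' @export
cohen_kappa <- function(cm) {
  cm <- unclass(as.matrix(cm))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - pe) < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Two-component PCA projection of a feature matrix
#'
#' Mean-centered projection onto the top-variance orthonormal directions,
#' for scatter-plot inspection of stage separability. Component signs are
#' fixed by making the largest-magnitude loading of each component
#' positive, so projections are reproducible.
#'
#' @param X `n x d` feature matrix (`n >= 2`, `d >= n_components`).
#' @param n_components number of components to keep.
#' @return List with `scores` (`n x n_components`), `loadings`,
#'   `explained_variance` (fraction per component).
#' @export
pca_project <- function(X, n_components = 2L) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least two rows")
  if (ncol(X) < n_components)
    stop("`n_components` exceeds the number of features")
  if (all(apply(X, 2, stats::sd) == 0))
    stop("constant data: zero variance in every feature")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  rot <- p$rotation[, k, drop = FALSE]
  flip <- vapply(k, function(j) {
    v <- rot[, j]; sign(v[which.max(abs(v))]) < 0
  }, logical(1))
  rot[, flip] <- -rot[, flip, drop = FALSE]
  scores <- p$x[, k, drop = FALSE]
  scores[, flip] <- -scores[, flip, drop = FALSE]
  list(scores = scores, loadings = rot,
       explained_variance = (p$sdev^2 / sum(p$sdev^2))[k])
}

#' Leave-one-subject-out evaluation of a classification pipeline
#'
#' One cross-validation fold per subject: the classifier (and its feature
#' standardizer) is fitted on all other subjects' epochs and applied to the
#' held-out subject, so training and test data are always from different
#' people. Epochs labeled `"UNKNOWN"` never enter training or metrics.
#'
#' @param features data frame from [feature_table()] (columns `subject_id`,
#'   `epoch_index`, `stage`, features), covering at least two subjects.
#' @param spec a [classifier_spec()].
#' @param feature_cols feature column names; default all non-metadata
#'   columns.
#' @return An `evaluation_report`: per-subject accuracy, Cohen's kappa,
#'   per-stage sensitivity and confusion matrix; across-subject mean and SD
#'   of accuracy and kappa; pooled confusion matrix with pooled accuracy
#'   and kappa.
#' @export
loso_evaluate <- function(features, spec = classifier_spec("rvm"),
                          feature_cols = NULL) {
  stopifnot(is.data.frame(features),
            all(c("subject_id", "stage") %in% colnames(features)))
  if (is.null(feature_cols)) feature_cols <- feature_columns(features)
  features <- features[features$stage != "UNKNOWN", , drop = FALSE]
  subjects <- unique(features$subject_id)
  if (length(subjects) < 2) stop("need at least two subjects for LOSO")
  X <- as.matrix(features[, feature_cols, drop = FALSE])
  y <- features$stage
  per_subject <- list()
  pooled <- matrix(0L, length(SLEEP_STAGES), length(SLEEP_STAGES),
                   dimnames = list(truth = SLEEP_STAGES,
                                   predicted = SLEEP_STAGES))
  predictions <- data.frame()
  for (s in subjects) {
    test <- features$subject_id == s
    absent <- setdiff(SLEEP_STAGES, unique(y[!test]))
    if (length(absent) > 0)
      stop(sprintf("training fold for subject %s lacks stage(s): %s",
                   s, paste(absent, collapse = ", ")))
    model <- fit_stage_classifier(X[!test, , drop = FALSE], y[!test], spec)
    pred <- predict_stages(model, X[test, , drop = FALSE])
    cm <- confusion_matrix(y[test], pred)
    per_subject[[s]] <- list(accuracy = overall_accuracy(cm),
                             kappa = cohen_kappa(cm),
                             sensitivity = per_class_sensitivity(cm),
                             confusion = cm)
    pooled <- pooled + unclass(cm)
    predictions <- rbind(predictions,
                         data.frame(subject_id = s,
                                    epoch_index = features$epoch_index[test],
                                    truth = y[test], predicted = pred,
                                    stringsAsFactors = FALSE))
  }
  acc <- vapply(per_subject, `[[`, numeric(1), "accuracy")
  kap <- vapply(per_subject, `[[`, numeric(1), "kappa")
  pooled <- structure(pooled, class = c("confusion_matrix", "matrix"))
  structure(list(per_subject = per_subject,
                 mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
                 mean_kappa = mean(kap), sd_kappa = stats::sd(kap),
                 pooled_confusion = pooled,
                 pooled_accuracy = overall_accuracy(pooled),
                 pooled_kappa = cohen_kappa(pooled),
                 predictions = predictions,
                 classifier = spec$kind),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s, %d subject(s)\n", x$classifier,
              length(x$per_subject)))
  cat(sprintf("  accuracy %.1f +/- %.1f %%   kappa %.2f +/- %.2f  (mean +/- SD across subjects)\n",
              100 * x$mean_accuracy, 100 * x$sd_accuracy,
              x$mean_kappa, x$sd_kappa))
  cat(sprintf("  pooled: accuracy %.1f %%, kappa %.2f over %d epochs\n",
              100 * x$pooled_accuracy, x$pooled_kappa,
              sum(x$pooled_confusion)))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an [loso_evaluate()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  per <- lapply(report$per_subject, function(p) {
    list(accuracy = p$accuracy, kappa = p$kappa,
         sensitivity = as.list(p$sensitivity),
         confusion = unclass(p$confusion))
  })
  jsonlite::write_json(
    list(classifier = report$classifier,
         mean_accuracy = report$mean_accuracy,
         sd_accuracy = report$sd_accuracy,
         mean_kappa = report$mean_kappa, sd_kappa = report$sd_kappa,
         pooled_accuracy = report$pooled_accuracy,
         pooled_kappa = report$pooled_kappa,
         pooled_confusion = unclass(report$pooled_confusion),
         per_subject = per),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
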