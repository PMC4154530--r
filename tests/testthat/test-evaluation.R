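# Fisher criteria, agreement metrics, PCA projection, LOSO protocol

# brute-force scatter matrices via explicit double loops
fisher_oracle <- function(X, y) {
  d <- ncol(X); m <- colMeans(X)
  Sb <- matrix(0, d, d); Sw <- matrix(0, d, d)
  for (c in unique(y)) {
    Xc <- X[y == c, , drop = FALSE]
    mc <- colMeans(Xc)
    Sb <- Sb + nrow(Xc) * (mc - m) %*% t(mc - m)
    for (i in seq_len(nrow(Xc)))
      Sw <- Sw + (Xc[i, ] - mc) %*% t(Xc[i, ] - mc)
  }
  list(J1 = sum(diag(Sb)) / sum(diag(Sw)), J2 = sum(diag(solve(Sw) %*% Sb)))
}

test_that("Fisher criteria match the hand-computed 1-D fixture (J1 = J2 = 4)", {
  X <- matrix(c(0, 2, 4, 6), ncol = 1)
  y <- c("A", "A", "B", "B")
  fs <- fisher_criteria(X, y)
  expect_equal(fs$J1, 4)
  expect_equal(fs$J2, 4)
})

test_that("Fisher criteria match the brute-force scatter oracle on random fixtures", {
  set.seed(51)
  for (i in 1:5) {
    X <- matrix(stats::rnorm(30 * 4), 30, 4)
    y <- sample(c("a", "b", "c"), 30, replace = TRUE)
    if (min(table(y)) < 2) next
    fs <- fisher_criteria(X, y)
    or <- fisher_oracle(X, y)
    expect_equal(fs$J1, or$J1, tolerance = 1e-9)
    expect_equal(fs$J2, or$J2, tolerance = 1e-9)
  }
})

test_that("identical class means give zero separability", {
  set.seed(52)
  base <- matrix(stats::rnorm(20), 10, 2)
  X <- rbind(base, base)                     # class means coincide exactly
  y <- rep(c("a", "b"), each = 10)
  fs <- fisher_criteria(X, y)
  expect_equal(fs$J1, 0, tolerance = 1e-12)
  expect_equal(fs$J2, 0, tolerance = 1e-12)
})

test_that("J2 is invariant under invertible linear feature maps; J1 under orthogonal ones", {
  set.seed(53)
  X <- matrix(stats::rnorm(60 * 4), 60, 4)
  y <- rep(c("a", "b", "c"), each = 20)
  f0 <- fisher_criteria(X, y)
  A <- matrix(stats::rnorm(16), 4, 4)        # generic, invertible a.s.
  f1 <- fisher_criteria(X %*% A, y)
  expect_equal(f1$J2, f0$J2, tolerance = 1e-8)
  Q <- qr.Q(qr(A))                           # orthogonal
  f2 <- fisher_criteria(3 * X %*% Q, y)      # orthogonal map + global scale
  expect_equal(f2$J1, f0$J1, tolerance = 1e-8)
  expect_equal(f2$J2, f0$J2, tolerance = 1e-8)
})

test_that("confusion matrix counts, additivity and validation", {
  cm <- confusion_matrix(c("W", "N2"), c("W", "N3"))
  expect_identical(sum(cm), 2L)
  expect_identical(cm["N2", "N3"], 1L)
  truth <- sample(SLEEP_STAGES, 50, replace = TRUE)
  pred <- sample(SLEEP_STAGES, 50, replace = TRUE)
  cm_all <- confusion_matrix(truth, pred)
  cm_sum <- unclass(confusion_matrix(truth[1:20], pred[1:20])) +
    unclass(confusion_matrix(truth[21:50], pred[21:50]))
  expect_equal(unclass(cm_all), cm_sum, ignore_attr = TRUE)
  expect_identical(unname(diag(unclass(confusion_matrix(truth, truth)))),
                   as.integer(table(factor(truth, SLEEP_STAGES))))
  expect_error(confusion_matrix("W", c("W", "N1")), "equal length")
  expect_error(confusion_matrix("W", "S4"), "S4")
})

test_that("accuracy, sensitivity and kappa match hand computations", {
  cm <- matrix(c(45, 5, 15, 35), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(overall_accuracy(cm), 0.8)
  expect_equal(unname(per_class_sensitivity(cm)), c(0.9, 0.7))
  expect_equal(cohen_kappa(cm), 0.6)

  perfect <- diag(c(10, 5, 8, 3, 4))
  expect_equal(overall_accuracy(perfect), 1)
  expect_equal(cohen_kappa(perfect), 1)
  expect_equal(unname(per_class_sensitivity(perfect)), rep(1, 5))

  # all predictions one class, truth split 50/50: kappa exactly 0
  one_sided <- matrix(c(50, 0, 50, 0), 2, 2, byrow = TRUE)
  expect_equal(cohen_kappa(one_sided), 0)

  # empty truth row: sensitivity missing for that class only
  cm0 <- matrix(c(5, 1, 0, 0), 2, 2, byrow = TRUE)
  sens <- per_class_sensitivity(cm0)
  expect_true(is.na(sens[2]) && !is.na(sens[1]))

  # degenerate p_e = 1
  expect_true(is.na(cohen_kappa(matrix(c(7, 0, 0, 0), 2, 2))))
})

test_that("kappa never exceeds accuracy on random confusion matrices", {
  set.seed(54)
  for (i in 1:1000) {
    cm <- matrix(stats::rpois(25, 4), 5, 5)
    if (sum(cm) == 0) next
    k <- cohen_kappa(cm)
    if (is.na(k)) next
    expect_lte(k, overall_accuracy(cm) + 1e-12)
  }
})

test_that("PCA projection: rank structure, distances, orthogonality, sign fixing", {
  set.seed(55)
  # points on a line embedded in 3-D
  t <- stats::rnorm(50)
  X <- cbind(t, 2 * t, -t) + matrix(stats::rnorm(150, 0, 1e-4), 50, 3)
  p <- pca_project(X)
  expect_gte(p$explained_variance[1], 0.999)

  # exact rank-2 data: projection preserves pairwise distances
  B <- matrix(stats::rnorm(10), 2, 5)
  S <- matrix(stats::rnorm(80), 40, 2)
  X2 <- S %*% B
  p2 <- pca_project(X2)
  expect_equal(as.matrix(dist(p2$scores)), as.matrix(dist(X2)),
               tolerance = 1e-8, ignore_attr = TRUE)

  expect_lt(abs(stats::cor(p2$scores[, 1], p2$scores[, 2])), 1e-8)
  # component sign convention: largest-|loading| entry positive
  for (j in 1:2) {
    v <- p2$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_error(pca_project(matrix(1, 5, 3)), "constant")
})

test_that("LOSO runs one fold per subject and respects train/test separation", {
  ft <- toy_feature_table(n_subjects = 3, epochs = 40, seed = 61)
  rep1 <- loso_evaluate(ft, classifier_spec("lda"))
  expect_length(rep1$per_subject, 3)
  expect_setequal(names(rep1$per_subject), unique(ft$subject_id))
  expect_identical(sum(rep1$pooled_confusion), nrow(ft))
  expect_true(rep1$mean_kappa <= rep1$mean_accuracy)

  # relabeling a subject's own test epochs cannot change its predictions
  ft2 <- ft
  s3 <- ft2$subject_id == "S03"
  relabel <- c(W = "N1", N1 = "N2", N2 = "N3", N3 = "REM", REM = "W")
  ft2$stage[s3] <- unname(relabel[ft2$stage[s3]])
  rep2 <- loso_evaluate(ft2, classifier_spec("lda"))
  expect_identical(rep2$predictions$predicted[rep2$predictions$subject_id == "S03"],
                   rep1$predictions$predicted[rep1$predictions$subject_id == "S03"])
})

test_that("LOSO refuses folds whose training part lacks a stage, and UNKNOWN is dropped", {
  ft <- toy_feature_table(n_subjects = 3, epochs = 30, seed = 62)
  # subject S03 holds every REM epoch: folds for S01/S02 still train on it,
  # but the S03 fold trains only on S01+S02, which then lack REM
  drop <- ft$stage == "REM" & ft$subject_id != "S03"
  ft_bad <- ft[!drop, ]
  expect_error(loso_evaluate(ft_bad, classifier_spec("lda")), "REM")

  ft_unk <- ft
  ft_unk$stage[1] <- "UNKNOWN"
  rep_u <- loso_evaluate(ft_unk, classifier_spec("lda"))
  expect_identical(sum(rep_u$pooled_confusion), nrow(ft) - 1L)
})

test_that("evaluation report serializes to JSON", {
  ft <- toy_feature_table(n_subjects = 2, epochs = 25, seed = 63)
  rep <- loso_evaluate(ft, classifier_spec("knn", k = 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_evaluation_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$mean_accuracy, rep$mean_accuracy, tolerance = 1e-12)
  expect_identical(dim(back$pooled_confusion), c(5L, 5L))
})
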