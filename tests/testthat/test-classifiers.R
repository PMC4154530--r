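# Kernels, RVM, one-against-all wrapper, LDA and k-NN baselines

test_that("kernel_matrix matches an element-by-element loop oracle", {
  set.seed(31)
  X <- matrix(stats::rnorm(15), 5, 3)
  Z <- matrix(stats::rnorm(12), 4, 3)
  for (kern in list(kernel_spec("linear"), kernel_spec("rbf", 0.5))) {
    K <- kernel_matrix(X, Z, kern)
    oracle <- matrix(0, 5, 4)
    for (i in 1:5) for (j in 1:4) {
      oracle[i, j] <- if (kern$kind == "linear") sum(X[i, ] * Z[j, ])
      else exp(-kern$rbf_gamma * sum((X[i, ] - Z[j, ])^2))
    }
    expect_equal(K, oracle, tolerance = 1e-12)
  }
  # rbf self-kernel diagonal is 1; linear kernel of orthogonal unit vectors
  expect_equal(diag(kernel_matrix(X, X, kernel_spec("rbf"))), rep(1, 5))
  E <- diag(3)
  expect_equal(kernel_matrix(E, E, kernel_spec("linear")), diag(3))
  expect_error(kernel_matrix(X, matrix(0, 2, 2)), "dimension")
})

test_that("RVM separates Gaussian blobs with a sparse model", {
  fx <- blob_fixture(n = 40, seed = 1)
  m <- rvm_fit_binary(fx$X, fx$y, kernel_spec("linear"))
  p <- predict_binary(m, fx$X)
  expect_equal(mean((p > 0.5) == (fx$y == 1)), 1.0)     # training accuracy
  expect_lt(nrow(m$relevance_vectors), nrow(fx$X) / 2)  # sparsity
  expect_gte(nrow(m$relevance_vectors), 1)
  # probabilities separate the classes around the logistic midpoint
  expect_true(all(p[fx$y == 1] > 0.5) && all(p[fx$y == 0] < 0.5))
  expect_true(all(p > 0 & p < 1))
})

test_that("RVM with RBF kernel represents the XOR pattern", {
  fx <- xor_fixture(n = 80, seed = 2)
  m <- rvm_fit_binary(fx$X, fx$y, kernel_spec("rbf", 0.5))
  p <- predict_binary(m, fx$X)
  expect_gte(mean((p > 0.5) == (fx$y == 1)), 0.9)
  expect_lt(nrow(m$relevance_vectors), nrow(fx$X))
  # decision function evaluated on a grid agrees with the XOR layout
  grid <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1)))
  pg <- predict_binary(m, grid)
  expect_true(all((pg > 0.5) == (grid[, 1] * grid[, 2] > 0)))
})

test_that("predict_binary is the logistic of the kernel score", {
  # a model with no relevance vectors and zero bias scores everything 0.5
  m0 <- structure(list(relevance_vectors = matrix(0, 0, 2), rv_index = integer(0),
                       weights = numeric(0), bias = 0, alpha = numeric(0),
                       kernel = kernel_spec("linear"), iterations_run = 0L,
                       converged = TRUE, n_train = 0L),
                  class = "rvm_binary")
  expect_equal(predict_binary(m0, matrix(stats::rnorm(10), 5, 2)), rep(0.5, 5))
  fx <- blob_fixture()
  m <- rvm_fit_binary(fx$X, fx$y)
  expect_error(predict_binary(m, matrix(0, 2, 5)), "dimension")
})

test_that("RVM input validation", {
  fx <- blob_fixture()
  expect_error(rvm_fit_binary(fx$X, rep(1, nrow(fx$X))), "both classes")
  Xbad <- fx$X; Xbad[1, 1] <- NA
  expect_error(rvm_fit_binary(Xbad, fx$y), "non-finite")
})

test_that("one-against-all ensemble classifies well-separated stage blobs", {
  fx <- five_blob_fixture(n_per = 30, seed = 3)
  idx <- rep(rep(c(TRUE, FALSE), c(20, 10)), 5)   # 20 train / 10 test per blob
  model <- ova_fit(fx$X[idx, ], fx$y[idx], classifier_spec("rvm"))
  pred <- ova_predict(model, fx$X[!idx, ])
  expect_gte(mean(pred == fx$y[!idx]), 0.95)
  # permutation invariance over test rows
  perm <- sample(sum(!idx))
  expect_identical(ova_predict(model, fx$X[!idx, ][perm, ]), pred[perm])
})

test_that("one-against-all ties resolve to the earliest stage in class order", {
  flat <- structure(list(relevance_vectors = matrix(0, 0, 2),
                         rv_index = integer(0), weights = numeric(0),
                         bias = 0, alpha = numeric(0),
                         kernel = kernel_spec("linear"), iterations_run = 0L,
                         converged = TRUE, n_train = 0L),
                    class = "rvm_binary")
  members <- stats::setNames(rep(list(flat), 5), SLEEP_STAGES)
  model <- structure(list(class_order = SLEEP_STAGES, members = members,
                          feature_standardizer = list(center = c(0, 0),
                                                      scale = c(1, 1)),
                          spec = classifier_spec("rvm")),
                     class = "ova_model")
  expect_identical(ova_predict(model, matrix(stats::rnorm(6), 3, 2)),
                   rep("W", 3))
})

test_that("ova_fit reports stages absent from training", {
  fx <- five_blob_fixture()
  keep <- fx$y != "REM"
  expect_error(ova_fit(fx$X[keep, ], fx$y[keep]), "REM")
})

test_that("LDA recovers the midpoint boundary of symmetric Gaussian classes", {
  set.seed(41)
  X <- matrix(c(stats::rnorm(200, -2), stats::rnorm(200, 2)), ncol = 1)
  y <- rep(c("a", "b"), each = 200)
  m <- lda_fit(X, y)
  grid <- matrix(seq(-3, 3, by = 0.01), ncol = 1)
  pred <- lda_predict(m, grid)
  boundary <- grid[max(which(pred == "a"))]
  expect_lt(abs(boundary), 0.3)
  # training points sit on their own side on separable data
  expect_identical(lda_predict(m, matrix(c(-2, 2), ncol = 1)), c("a", "b"))
})

test_that("LDA agrees with the reference implementation on a clean fixture", {
  skip_if_not_installed("MASS")
  set.seed(42)
  fx <- five_blob_fixture(n_per = 40, seed = 5)
  m <- lda_fit(fx$X, fx$y)
  ref <- MASS::lda(fx$X, grouping = fx$y)
  Xnew <- fx$X + matrix(stats::rnorm(length(fx$X), 0, 0.2), nrow(fx$X))
  expect_gte(mean(lda_predict(m, Xnew) ==
                    as.character(predict(ref, Xnew)$class)), 0.99)
})

test_that("LDA errors on singular covariance without ridge, and on tiny classes", {
  set.seed(43)
  X <- cbind(stats::rnorm(20), 0)          # constant second feature
  y <- rep(c("a", "b"), each = 10)
  expect_error(lda_fit(X, y, ridge = "none"), "singular")
  m <- lda_fit(X, y, ridge = "auto")       # ridge fallback succeeds
  expect_gt(m$ridge_used, 0)
  expect_error(lda_fit(matrix(stats::rnorm(6), 3, 2), c("a", "a", "b")),
               "fewer than 2")
})

test_that("k-NN matches an exhaustive-sort brute-force oracle", {
  set.seed(44)
  Xtr <- matrix(stats::rnorm(120), 60, 2)
  ytr <- sample(c("p", "q"), 60, replace = TRUE)
  Xte <- matrix(stats::rnorm(40), 20, 2)
  pred <- knn_predict(Xtr, ytr, Xte, k = 13)
  oracle <- character(20)
  for (i in 1:20) {
    d <- sqrt(colSums((t(Xtr) - Xte[i, ])^2))
    nb <- ytr[order(d)][1:13]
    cnt <- table(nb)
    top <- names(cnt)[cnt == max(cnt)]
    oracle[i] <- if (length(top) == 1) top else nb[nb %in% top][1]
  }
  expect_identical(unname(pred), oracle)
})

test_that("k-NN edge cases: k = 1 self match, k = n global majority, bad k", {
  fx <- five_blob_fixture(n_per = 10, seed = 6)
  expect_identical(unname(knn_predict(fx$X, fx$y, fx$X[7, , drop = FALSE],
                                      k = 1)), fx$y[7])
  majority <- names(which.max(table(c(fx$y, "W"))))  # W wins ties by count
  pred_all <- knn_predict(fx$X, fx$y, fx$X[1:3, ], k = nrow(fx$X))
  expect_true(all(pred_all %in% names(table(fx$y))))
  expect_error(knn_predict(fx$X, fx$y, fx$X, k = 0), "k")
  expect_error(knn_predict(fx$X, fx$y, fx$X, k = nrow(fx$X) + 1), "k")
})

test_that("feature rescaling is absorbed by the standardizer for k-NN and LDA", {
  fx <- five_blob_fixture(n_per = 20, seed = 7)
  colnames(fx$X) <- c("f1", "f2")
  Xte <- fx$X + 0.1
  for (kind in c("knn", "lda")) {
    m1 <- fit_stage_classifier(fx$X, fx$y, classifier_spec(kind))
    p1 <- predict_stages(m1, Xte)
    Xs <- fx$X; Xs[, 2] <- Xs[, 2] * 100
    Xte_s <- Xte; Xte_s[, 2] <- Xte_s[, 2] * 100
    m2 <- fit_stage_classifier(Xs, fx$y, classifier_spec(kind))
    expect_identical(predict_stages(m2, Xte_s), p1)
  }
})

test_that("the external margin classifier plugs in behind the same interface", {
  skip_if_not_installed("e1071")
  fx <- five_blob_fixture(n_per = 20, seed = 8)
  m <- fit_stage_classifier(fx$X, fx$y, classifier_spec("svm"))
  expect_gte(mean(predict_stages(m, fx$X) == fx$y), 0.95)
})
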