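test_that("LDA separates well-separated clouds and matches the shared-covariance Bayes rule", {
  d <- make_clouds(15, d = 2, sep = 4, seed = 10)
  model <- fit_lda(d$X, d$y)
  pred <- predict(model, d$X)
  expect_equal(mean(pred$class == d$y), 1)  # linearly separable
  # posteriors sum to 1
  expect_equal(rowSums(pred[, model$classes]), rep(1, nrow(d$X)),
               tolerance = 1e-9)
  # independent oracle: MASS::lda on the same 30-sample 2-feature instance
  skip_if_not_installed("MASS")
  mass_fit <- MASS::lda(d$X, grouping = d$y)
  mass_pred <- as.character(predict(mass_fit, d$X)$class)
  expect_identical(pred$class, mass_pred)
})

test_that("LDA posteriors are symmetric at the midpoint of class means", {
  d <- make_clouds(50, d = 2, sep = 3, seed = 2)
  model <- fit_lda(d$X, d$y, priors = c(0.5, 0.5))
  mid <- colMeans(model$means)
  p <- predict(model, rbind(mid))
  expect_equal(as.numeric(p[1, model$classes[1]]), 0.5, tolerance = 1e-9)
  # a point at a class mean is assigned to that class with high confidence
  at_mean <- predict(model, rbind(model$means[1, ]))
  expect_identical(at_mean$class, model$classes[1])
  expect_gt(as.numeric(at_mean[1, model$classes[1]]), 0.99)
})

test_that("QDA nests LDA under equal covariances and wins on concentric classes", {
  d <- make_clouds(60, d = 2, sep = 3, seed = 5)
  lda_m <- fit_lda(d$X, d$y)
  qda_m <- fit_qda(d$X, d$y)
  grid <- as.matrix(expand.grid(f1 = seq(-2, 5, 0.5), f2 = seq(-2, 5, 0.5)))
  agree <- mean(predict(lda_m, grid)$class == predict(qda_m, grid)$class)
  expect_gte(agree, 0.95)

  # same mean, very different spread: quadratic boundary required
  withr::with_seed(6, {
    inner <- matrix(rnorm(200, sd = 0.5), 100, 2)
    outer_r <- sqrt(runif(100, 4, 9)); ang <- runif(100, 0, 2 * pi)
    outer <- cbind(outer_r * cos(ang), outer_r * sin(ang)) +
      matrix(rnorm(200, sd = 0.2), 100, 2)
  })
  X <- rbind(inner, outer); colnames(X) <- c("f1", "f2")
  y <- rep(c("viable", "nonviable_abnormal"), each = 100)
  qda_acc <- mean(predict(fit_qda(X, y), X)$class == y)
  lda_acc <- mean(predict(fit_lda(X, y), X)$class == y)
  expect_gt(qda_acc, 0.8)
  expect_lt(abs(lda_acc - 0.5), 0.15)
})

test_that("QDA recovers per-class covariances on large simulated samples", {
  Sigma <- matrix(c(1, 0.6, 0.6, 2), 2)
  withr::with_seed(8, {
    L <- chol(Sigma)
    X1 <- matrix(rnorm(4000), 2000, 2) %*% L
    X2 <- matrix(rnorm(4000), 2000, 2) + 5
  })
  X <- rbind(X1, X2); colnames(X) <- c("f1", "f2")
  y <- rep(c("a", "b"), each = 2000)
  m <- fit_qda(X, y)
  S1_hat <- solve(m$fits[[which(m$classes == "a")]]$cov_inv)
  expect_equal(unname(S1_hat), unname(Sigma), tolerance = 0.1)
})

test_that("KNN equals the brute-force all-pairs oracle and honours tie-breaks", {
  withr::with_seed(3, {
    Xtr <- matrix(runif(100), 50, 2, dimnames = list(NULL, c("f1", "f2")))
    ytr <- sample(c("viable", "nonviable_abnormal"), 50, replace = TRUE)
    Xte <- matrix(runif(40), 20, 2, dimnames = list(NULL, c("f1", "f2")))
  })
  model <- fit_knn(Xtr, ytr, k = 5)
  expect_identical(predict(model, Xte)$class,
                   unname(oracle_knn(Xtr, ytr, Xte, 5)))
  # k = 1 reproduces nearest-neighbour labels
  m1 <- fit_knn(Xtr, ytr, k = 1)
  expect_identical(predict(m1, Xtr)$class, ytr)
  # a query equal to a training point duplicated 5x gets that point's class
  Xdup <- rbind(matrix(0.5, 5, 2), matrix(c(10, 10), 5, 2, byrow = TRUE))
  colnames(Xdup) <- c("f1", "f2")
  ydup <- c(rep("viable", 5), rep("nonviable_abnormal", 5))
  mdup <- fit_knn(Xdup, ydup, k = 5)
  expect_identical(predict(mdup, rbind(c(f1 = 0.5, f2 = 0.5)))$class, "viable")
})

test_that("stratified folds are balanced, disjoint, complete and seed-stable", {
  y <- rep(c("viable", "nonviable_abnormal"), c(53, 47))
  a1 <- seedxray:::stratified_folds(y, 10, rng_seed = 4)
  a2 <- seedxray:::stratified_folds(y, 10, rng_seed = 4)
  expect_identical(a1, a2)
  expect_setequal(unique(a1), 1:10)
  for (f in 1:10) {
    in_fold <- a1 == f
    # per-fold class counts within 1 of proportional
    expect_lte(abs(sum(in_fold & y == "viable") - 5.3), 1)
    expect_lte(abs(sum(in_fold & y == "nonviable_abnormal") - 4.7), 1)
  }
  expect_identical(sum(table(a1)), 100L)
  expect_error(seedxray:::stratified_folds(rep(c("a", "b"), c(5, 95)), 10, 1),
               "fewer samples")
})

test_that("cross-validation reports: perfect separation, closed-form CI, determinism", {
  d <- make_clouds(30, d = 2, sep = 8, seed = 12)
  rep_lda <- cross_validate(d$X, d$y, "lda", folds = 10, rng_seed = 5)
  expect_equal(rep_lda$mean, 100)
  expect_equal(rep_lda$uci, 100)
  expect_equal(rep_lda$lci, 100)
  expect_length(rep_lda$fold_accuracies, 10)

  injected <- cv_report("lda", rep(c(80, 90), 5))
  expect_equal(injected$mean, 85)
  half <- 1.96 * sd(rep(c(80, 90), 5)) / sqrt(10)
  expect_equal(injected$uci, 85 + half)
  expect_equal(injected$lci, 85 - half)
  flat <- cv_report("knn", rep(70, 10))
  expect_equal(flat$uci - flat$lci, 0)

  r1 <- cross_validate(d$X, d$y, "knn", folds = 5, rng_seed = 2)
  r2 <- cross_validate(d$X, d$y, "knn", folds = 5, rng_seed = 2)
  expect_identical(r1$fold_accuracies, r2$fold_accuracies)
  expect_true(r1$lci <= r1$mean && r1$mean <= r1$uci)
})

test_that("standardization is idempotent for KNN orderings", {
  d <- make_clouds(25, d = 3, sep = 2, seed = 9)
  Xs <- scale(d$X)
  attr(Xs, "scaled:center") <- NULL; attr(Xs, "scaled:scale") <- NULL
  sc <- seedxray:::fit_scaler(Xs)
  Xss <- seedxray:::apply_scaler(sc, Xs)
  expect_equal(Xss, Xs, tolerance = 1e-12)
  m1 <- fit_knn(Xs, d$y, k = 5)
  m2 <- fit_knn(Xss, d$y, k = 5)
  expect_identical(predict(m1, Xs)$class, predict(m2, Xss)$class)
})

test_that("schema mismatches are rejected at prediction time", {
  d <- make_clouds(10, d = 2, sep = 3, seed = 1)
  model <- fit_lda(d$X, d$y)
  bad <- matrix(0, 2, 2, dimnames = list(NULL, c("g1", "g2")))
  expect_error(predict(model, bad), class = "seedxray_schema_error")
})
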