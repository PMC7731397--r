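test_that("Fisher score: hand-computed value, null case, affine invariance", {
  X <- cbind(f1 = c(0, 0, 1, 1, 2, 2, 3, 3))
  y <- rep(c("a", "b"), each = 4)
  # class means 0.5 and 2.5, population variances 0.25 each
  expect_equal(unname(fisher_score(X, y)), 8)

  X2 <- cbind(f1 = c(1, 2, 3, 1, 2, 3))
  expect_equal(unname(fisher_score(X2, rep(c("a", "b"), each = 3))), 0)

  withr::with_seed(2, X3 <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("u", "v"))))
  y3 <- rep(c("a", "b"), 10)
  J <- fisher_score(X3, y3)
  J_aff <- fisher_score(sweep(X3 * 3.7, 2, c(-2, 11), "+"), y3)
  expect_equal(unname(J), unname(J_aff))

  expect_error(fisher_score(X, rep("a", 8)), "two classes")
  expect_error(fisher_score(X, c("a", rep("b", 7))), "2 samples")
})

test_that("SFS picks the single best starter feature and grows without repeats", {
  set.seed(30)
  n <- 40
  y <- rep(c("viable", "nonviable_abnormal"), each = n / 2)
  X <- cbind(weak1 = rnorm(n) + (y == "viable") * 0.5,
             strong = rnorm(n, sd = 0.4) + (y == "viable") * 3,
             weak2 = rnorm(n))
  ev <- cv_evaluator("lda", folds = 5, rng_seed = 3)
  # exhaustive first-step scores
  first_scores <- vapply(colnames(X), function(f)
    ev(X[, f, drop = FALSE], y), numeric(1))
  trace <- sfs(X, y, evaluator = ev, max_k = 3, candidate_pool = 3)
  expect_identical(trace$features[1], names(which.max(first_scores)))
  expect_identical(anyDuplicated(trace$features), 0L)
  expect_length(trace$cv_accuracy_at_step, 3)
  expect_identical(trace$best_k, which.max(trace$cv_accuracy_at_step))
})

test_that("every SFS step is optimal against exhaustive candidate re-evaluation", {
  d <- make_informative(n_per_class = 15, n_informative = 2, n_noise = 6,
                        delta = 1.5, seed = 4)
  ev <- cv_evaluator("lda", folds = 5, rng_seed = 7)
  trace <- sfs(d$X, d$y, evaluator = ev, max_k = 4, candidate_pool = 8)
  pool <- colnames(d$X)[order(-fisher_score(d$X, d$y), colnames(d$X))][1:8]
  chosen <- character(0)
  for (step in seq_along(trace$features)) {
    cands <- setdiff(pool, chosen)
    scores <- vapply(cands, function(f)
      ev(d$X[, c(chosen, f), drop = FALSE], d$y), numeric(1))
    expect_equal(trace$cv_accuracy_at_step[step], max(scores))
    expect_gte(scores[trace$features[step]], max(scores) - 1e-12)
    chosen <- c(chosen, trace$features[step])
  }
})

test_that("on informative-plus-noise data the accuracy curve rises then plateaus", {
  d <- make_informative(n_per_class = 30, n_informative = 5, n_noise = 50,
                        delta = 2, seed = 1)
  trace <- sfs(d$X, d$y, evaluator = cv_evaluator("lda", folds = 5, rng_seed = 1),
               max_k = 15, candidate_pool = 20)
  expect_lte(trace$best_k, 15)
  expect_gte(trace$best_accuracy, 90)
  # early gain: accuracy at step 3 already above step-1-of-noise baseline
  expect_gte(max(trace$cv_accuracy_at_step[1:5]), 85)
  # reproducibility: identical rerun
  trace2 <- sfs(d$X, d$y, evaluator = cv_evaluator("lda", folds = 5, rng_seed = 1),
                max_k = 15, candidate_pool = 20)
  expect_identical(trace$cv_accuracy_at_step, trace2$cv_accuracy_at_step)
  expect_identical(trace$features, trace2$features)
})

test_that("selection composition of the bundled 48-name reference listing", {
  nm <- reference_selection_names()
  expect_length(nm, 48)
  comp <- summarize_selection(nm)
  fam <- setNames(comp$by_family$share, comp$by_family$family)
  expect_equal(unname(fam["lbp"]), 87.5)
  expect_equal(unname(fam["gabor"]), 4.2)
  expect_equal(unname(fam["local_fft"]), 6.2)
  st <- setNames(comp$by_set$share, comp$by_set$set)
  expect_equal(unname(st["A"]), 39.6)
  expect_equal(unname(st["B"]), 20.8)
  expect_equal(unname(st["C"]), 39.6)
  expect_equal(sum(comp$by_family$count), 48)

  one <- summarize_selection(c("i-LBP(1,1)[8,u2][A]", "i-LBP(1,2)[8,u2][B]"))
  expect_equal(one$by_family$share, 100)
})

test_that("fold-honest Fisher+LDA reference evaluation is unbiased under the null", {
  withr::with_seed(99, {
    X <- matrix(rnorm(60 * 40), 60, 40,
                dimnames = list(NULL, sprintf("n%02d", 1:40)))
  })
  y <- rep(c("viable", "nonviable_abnormal"), each = 30)
  accs <- vapply(1:3, function(s) fisher_lda_cv(X, y, k = 8, folds = 10,
                                                rng_seed = s), numeric(1))
  expect_gte(mean(accs), 35)
  expect_lte(mean(accs), 65)
})
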