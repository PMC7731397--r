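# Gaussian discriminant and nearest-neighbour classifiers.
#
# LDA: shared (pooled) covariance Gaussian discriminant; QDA: per-class
# covariances. Covariances are ridge-regularized by eps = 1e-6 * trace/p so
# early high-dimensional experiments (p close to or above n) stay solvable;
# a warning is emitted when the unregularized matrix is computationally
# singular. KNN: majority vote over the k nearest Euclidean neighbours, ties
# broken by the nearest neighbour's class.

prep_xy <- function(features, labels) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.character(labels)
  cls <- sort(unique(y))
  if (length(cls) != 2) stop_param("labels must contain exactly two classes")
  if (min(table(y)) < 2) stop_param("each class needs at least 2 samples")
  list(X = X, y = y, classes = cls)
}

regularize <- function(S, p) {
  eps <- 1e-6 * sum(diag(S)) / p
  if (eps <= 0) eps <- 1e-8
  ok <- tryCatch({ solve(S); TRUE }, error = function(e) FALSE)
  if (!ok) warning("singular covariance; applying ridge regularization")
  S + diag(eps, p)
}

#' Fit a linear discriminant (shared-covariance Gaussian) classifier
#'
#' @param features numeric matrix (rows = samples, named columns).
#' @param labels binary class vector.
#' @param priors class priors; defaults to empirical frequencies.
#' @return Model object of class `seed_lda`.
#' @export
fit_lda <- function(features, labels, priors = NULL) {
  d <- prep_xy(features, labels)
  p <- ncol(d$X)
  mu <- do.call(rbind, lapply(d$classes, function(k)
    colMeans(d$X[d$y == k, , drop = FALSE])))
  n <- nrow(d$X)
  Sp <- matrix(0, p, p)
  for (k in d$classes) {
    Xk <- d$X[d$y == k, , drop = FALSE]
    Sp <- Sp + crossprod(sweep(Xk, 2, colMeans(Xk)))
  }
  Sp <- regularize(Sp / (n - 2), p)
  if (is.null(priors)) priors <- as.numeric(table(d$y)[d$classes]) / n
  structure(list(classes = d$classes, means = mu, cov_inv = solve(Sp),
                 priors = priors, feature_names = colnames(d$X)),
            class = c("seed_lda", "seed_classifier"))
}

#' Fit a quadratic discriminant (per-class covariance) classifier
#'
#' @inheritParams fit_lda
#' @return Model object of class `seed_qda`.
#' @export
fit_qda <- function(features, labels, priors = NULL) {
  d <- prep_xy(features, labels)
  p <- ncol(d$X)
  fits <- lapply(d$classes, function(k) {
    Xk <- d$X[d$y == k, , drop = FALSE]
    Sk <- regularize(crossprod(sweep(Xk, 2, colMeans(Xk))) / (nrow(Xk) - 1), p)
    list(mean = colMeans(Xk), cov_inv = solve(Sk),
         logdet = determinant(Sk, logarithm = TRUE)$modulus[1])
  })
  if (is.null(priors)) priors <- as.numeric(table(d$y)[d$classes]) / nrow(d$X)
  structure(list(classes = d$classes, fits = fits, priors = priors,
                 feature_names = colnames(d$X)),
            class = c("seed_qda", "seed_classifier"))
}

#' Fit a k-nearest-neighbour classifier
#'
#' @inheritParams fit_lda
#' @param k neighbourhood size (default 5).
#' @return Model object of class `seed_knn`.
#' @export
fit_knn <- function(features, labels, k = 5L) {
  d <- prep_xy(features, labels)
  if (nrow(d$X) < k) stop_param("need at least k training samples")
  structure(list(X = d$X, y = d$y, k = as.integer(k), classes = d$classes,
                 feature_names = colnames(d$X)),
            class = c("seed_knn", "seed_classifier"))
}

check_newdata <- function(model, newdata) {
  X <- as.matrix(newdata)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(model$feature_names))
      stop_param("feature count mismatch", class = "seedxray_schema_error")
    colnames(X) <- model$feature_names
  }
  if (!all(model$feature_names %in% colnames(X)))
    stop_param("feature names do not match the training schema",
               class = "seedxray_schema_error")
  X[, model$feature_names, drop = FALSE]
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Predict classes and posteriors
#'
#' Discriminant models return Gaussian posterior probabilities (rows sum to
#' 1); KNN returns vote fractions as scores, with ties resolved in favour of
#' the nearest neighbour's class.
#'
#' @param object a fitted `seed_lda`, `seed_qda` or `seed_knn` model.
#' @param newdata numeric matrix or vector of features matching the training
#'   schema.
#' @param ... unused.
#' @return data.frame with a `class` column and one posterior/score column
#'   per class.
#' @export
predict.seed_lda <- function(object, newdata, ...) {
  X <- check_newdata(object, rbind(newdata))
  S <- vapply(seq_along(object$classes), function(k) {
    mu <- object$means[k, ]
    drop(X %*% object$cov_inv %*% mu) - 0.5 * drop(mu %*% object$cov_inv %*% mu) +
      log(object$priors[k])
  }, numeric(nrow(X)))
  S <- matrix(S, nrow = nrow(X))
  post <- softmax_rows(S)
  colnames(post) <- object$classes
  data.frame(class = object$classes[max.col(post, ties.method = "first")],
             post, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname predict.seed_lda
#' @export
predict.seed_qda <- function(object, newdata, ...) {
  X <- check_newdata(object, rbind(newdata))
  S <- vapply(seq_along(object$classes), function(k) {
    f <- object$fits[[k]]
    D <- sweep(X, 2, f$mean)
    -0.5 * rowSums((D %*% f$cov_inv) * D) - 0.5 * f$logdet + log(object$priors[k])
  }, numeric(nrow(X)))
  S <- matrix(S, nrow = nrow(X))
  post <- softmax_rows(S)
  colnames(post) <- object$classes
  data.frame(class = object$classes[max.col(post, ties.method = "first")],
             post, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname predict.seed_lda
#' @export
predict.seed_knn <- function(object, newdata, ...) {
  X <- check_newdata(object, rbind(newdata))
  tr <- object$X
  d2 <- outer(rowSums(X^2), rep(1, nrow(tr))) +
    outer(rep(1, nrow(X)), rowSums(tr^2)) - 2 * X %*% t(tr)
  cls <- object$classes
  votes <- matrix(0, nrow(X), length(cls), dimnames = list(NULL, cls))
  pred <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    ord <- order(d2[i, ])
    nb <- ord[seq_len(object$k)]
    v <- table(factor(object$y[nb], levels = cls))
    votes[i, ] <- as.numeric(v) / object$k
    top <- names(v)[v == max(v)]
    pred[i] <- if (length(top) == 1) top else object$y[nb[1]]
  }
  data.frame(class = pred, votes, check.names = FALSE, stringsAsFactors = FALSE)
}

# deterministic stratified fold assignment: within each class, samples are
# shuffled under the seed and dealt round-robin, so per-fold class counts
# differ by at most 1 from proportionality.
stratified_folds <- function(labels, folds, rng_seed) {
  y <- as.character(labels)
  assign <- integer(length(y))
  with_local_seed(rng_seed, {
    for (k in sort(unique(y))) {
      idx <- which(y == k)
      if (length(idx) < folds)
        stop_param(sprintf("class '%s' has fewer samples than folds", k))
      idx <- sample(idx)
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

# z-score scaler fit on training data only; zero-sd features pass through
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  list(mean = mu, sd = sd)
}
apply_scaler <- function(scaler, X) sweep(sweep(X, 2, scaler$mean), 2, scaler$sd, "/")

#' Stratified k-fold cross-validation
#'
#' Folds are stratified (per-fold class proportions within one sample of the
#' global proportions) and deterministic given `rng_seed`. Features are
#' z-scored using training-fold statistics before fitting. The report gives
#' the per-fold accuracies, their mean, and a 95 percent normal-approximation
#' confidence band `mean +/- 1.96 * sd/sqrt(folds)` (UCI/LCI), clipped to
#' \[0, 100\].
#'
#' @param features numeric matrix.
#' @param labels binary class vector; every class needs >= `folds` samples.
#' @param classifier `"lda"`, `"qda"` or `"knn"`.
#' @param folds number of folds (default 10).
#' @param rng_seed fold-assignment seed.
#' @param k neighbourhood size for KNN.
#' @param standardize z-score features on training-fold statistics.
#' @return A list of class `cv_report`: `classifier`, `fold_accuracies`,
#'   `mean`, `uci`, `lci`, `rng_seed`.
#' @export
cross_validate <- function(features, labels, classifier = c("lda", "qda", "knn"),
                           folds = 10L, rng_seed = 1L, k = 5L,
                           standardize = TRUE) {
  classifier <- match.arg(classifier)
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.character(labels)
  assign <- stratified_folds(y, folds, rng_seed)
  accs <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- assign != f; te <- !tr
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (standardize) {
      sc <- fit_scaler(Xtr)
      Xtr <- apply_scaler(sc, Xtr); Xte <- apply_scaler(sc, Xte)
    }
    model <- switch(classifier,
                    lda = fit_lda(Xtr, y[tr]),
                    qda = fit_qda(Xtr, y[tr]),
                    knn = fit_knn(Xtr, y[tr], k = k))
    pred <- predict(model, Xte)$class
    accs[f] <- 100 * mean(pred == y[te])
  }
  cv_report(classifier, accs, rng_seed)
}

#' Assemble a cross-validation report from fold accuracies
#'
#' Computes the mean and the 95 percent normal-approximation confidence band
#' over the supplied per-fold accuracies. Used internally by
#' [cross_validate()]; exported so the confidence arithmetic can be applied
#' to externally obtained fold accuracies.
#'
#' @param classifier classifier name to record.
#' @param fold_accuracies numeric vector of per-fold accuracies in percent.
#' @param rng_seed fold seed to record.
#' @return A `cv_report` object.
#' @export
cv_report <- function(classifier, fold_accuracies, rng_seed = NA_integer_) {
  m <- mean(fold_accuracies)
  half <- 1.96 * stats::sd(fold_accuracies) / sqrt(length(fold_accuracies))
  if (!is.finite(half)) half <- 0
  structure(list(classifier = classifier, fold_accuracies = fold_accuracies,
                 mean = m, uci = min(100, m + half), lci = max(0, m - half),
                 rng_seed = rng_seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: mean %.1f%%  (LCI %.1f, UCI %.1f) over %d folds\n",
              x$classifier, x$mean, x$lci, x$uci, length(x$fold_accuracies)))
  invisible(x)
}
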