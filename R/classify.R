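#' Fit a quadratic discriminant model
#'
#' Class-conditional Gaussians with class-specific covariance, empirical
#' priors, and a ridge regularization of each covariance,
#' Sigma <- Sigma + eps * (trace(Sigma)/d) * I, which keeps the model
#' defined when low spike counts make a class covariance singular.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Factor of class labels (every level present with >= 2
#'   samples).
#' @param regularization Ridge fraction eps (default 1e-6).
#' @return Object of class `qda_model`.
#' @export
fit_qda <- function(x, y, regularization = 1e-6) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  if (any(table(y) < 2L)) stop("every class needs at least 2 samples")
  d <- ncol(x)
  classes <- levels(y)
  fits <- lapply(classes, function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    S <- stats::cov(xi)
    tr <- sum(diag(S))
    ridge <- regularization * (if (tr > 0) tr / d else 1)
    S <- S + diag(ridge, d)
    R <- chol(S)
    list(mean = colMeans(xi), chol = R,
         logdet = 2 * sum(log(diag(R))),
         prior = nrow(xi) / nrow(x))
  })
  names(fits) <- classes
  structure(list(classes = classes, fits = fits, d = d,
                 regularization = regularization),
            class = "qda_model")
}

#' Per-class quadratic discriminant scores
#'
#' log prior + log Gaussian density (up to the shared constant) for
#' every class and sample.
#'
#' @param model A `qda_model`.
#' @param x Feature matrix with `model$d` columns.
#' @return Numeric matrix (samples x classes).
#' @export
qda_scores <- function(model, x) {
  stopifnot(inherits(model, "qda_model"))
  x <- as.matrix(x)
  if (ncol(x) != model$d)
    stop("feature dimension ", ncol(x), " does not match model (", model$d, ")")
  s <- vapply(model$fits, function(f) {
    z <- backsolve(f$chol, t(x) - f$mean, transpose = TRUE)
    -0.5 * f$logdet - 0.5 * colSums(z^2) + log(f$prior)
  }, numeric(nrow(x)))
  matrix(s, nrow = nrow(x), dimnames = list(NULL, model$classes))
}

#' Predict classes with a quadratic discriminant model
#'
#' Assigns each sample to the class with the largest discriminant
#' score. Exact ties go to the class with the larger prior, then to the
#' first class in level order.
#'
#' @param model A `qda_model`.
#' @param x Feature matrix.
#' @return Factor of predicted labels with the model's class levels.
#' @export
predict_qda <- function(model, x) {
  s <- qda_scores(model, x)
  priors <- vapply(model$fits, `[[`, numeric(1), "prior")
  pick <- apply(s, 1L, function(row) {
    best <- which(row == max(row))
    if (length(best) > 1L) best <- best[order(-priors[best], best)][1L]
    best
  })
  factor(model$classes[pick], levels = model$classes)
}

#' Confusion-matrix performance metrics
#'
#' error = 100 (FN + FP) / (TP + FN + TN + FP),
#' sensitivity = 100 TP / (TP + FN), specificity = 100 TN / (TN + FP),
#' accuracy = 100 - error.
#'
#' @param tp,fn,tn,fp Confusion counts.
#' @return List with `error_pct`, `sensitivity_pct`, `specificity_pct`,
#'   `accuracy_pct`.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  total <- tp + fn + tn + fp
  err <- 100 * (fn + fp) / total
  list(error_pct = err,
       sensitivity_pct = 100 * tp / (tp + fn),
       specificity_pct = 100 * tn / (tn + fp),
       accuracy_pct = 100 - err)
}

#' Stratified five-fold cross-validated evaluation
#'
#' Shuffles each class with the given seed, deals samples into k
#' stratified folds (so every fold trains on about 80% of the data),
#' fits the quadratic discriminant on the training part and scores the
#' held-out part. The first factor level is the positive class.
#'
#' @param x Feature matrix.
#' @param y Factor of labels (>= k samples in every class).
#' @param seed Integer seed for the fold assignment.
#' @param k Number of folds (default 5).
#' @param regularization Passed to [fit_qda()].
#' @return Object of class `eval_result`: `folds` (data frame of
#'   per-fold TP, FN, TN, FP and error), `mean_error_pct`,
#'   `accuracy_pct` (= 100 - mean error), and pooled `sensitivity_pct`
#'   and `specificity_pct`.
#' @export
crossval_5fold <- function(x, y, seed = 1L, k = 5L, regularization = 1e-6) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("two-class evaluation requires 2 classes")
  if (any(table(y) < k))
    stop("need at least ", k, " samples per class for ", k, "-fold CV")
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  pos <- levels(y)[1L]
  neg <- levels(y)[2L]
  folds <- lapply(seq_len(k), function(i) {
    tr <- fold != i
    m <- fit_qda(x[tr, , drop = FALSE], y[tr], regularization)
    pred <- predict_qda(m, x[!tr, , drop = FALSE])
    truth <- y[!tr]
    tp <- sum(pred == pos & truth == pos)
    fn <- sum(pred == neg & truth == pos)
    tn <- sum(pred == neg & truth == neg)
    fp <- sum(pred == pos & truth == neg)
    data.frame(fold = i, TP = tp, FN = fn, TN = tn, FP = fp,
               error_pct = 100 * (fn + fp) / length(truth))
  })
  folds <- do.call(rbind, folds)
  pooled <- confusion_metrics(sum(folds$TP), sum(folds$FN),
                              sum(folds$TN), sum(folds$FP))
  mean_err <- mean(folds$error_pct)
  structure(list(folds = folds, mean_error_pct = mean_err,
                 accuracy_pct = 100 - mean_err,
                 sensitivity_pct = pooled$sensitivity_pct,
                 specificity_pct = pooled$specificity_pct,
                 seed = seed),
            class = "eval_result")
}
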