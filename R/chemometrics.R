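#' Principal component analysis
#'
#' Mean-centered SVD-based PCA (no scaling), returning scores, loadings and
#' the percentage of variance explained per component.
#'
#' @param X samples x features matrix.
#' @param n_components number of components (truncated with a warning when
#'   the matrix rank is lower).
#' @return A list of class `pca_result`: `scores`, `loadings`,
#'   `explained_variance_pct`.
#' @export
pca_fit <- function(X, n_components = 2) {
  X <- as.matrix(X)
  stopifnot(n_components >= 1)
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rank <- sum(pr$sdev > max(pr$sdev) * 1e-12)
  if (n_components > rank) {
    warning("requested ", n_components, " components but rank is ", rank,
            "; truncating")
    n_components <- rank
  }
  ev <- 100 * pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = pr$x[, seq_len(n_components), drop = FALSE],
                 loadings = pr$rotation[, seq_len(n_components),
                                        drop = FALSE],
                 explained_variance_pct = ev[seq_len(n_components)]),
            class = "pca_result")
}

# one NIPALS PLS2 pass on pre-centered E (X) and F (Y); returns the score
# and loading matrices needed for prediction and VIP
.nipals_pls2 <- function(E, F_, n_components, max_iter = 500, tol = 1e-8) {
  n <- nrow(E); p <- ncol(E); k <- ncol(F_)
  W <- matrix(0, p, n_components); P <- matrix(0, p, n_components)
  Q <- matrix(0, k, n_components); Tm <- matrix(0, n, n_components)
  ssy_expl <- numeric(n_components)
  for (a in seq_len(n_components)) {
    if (sum(E^2) < 1e-12 || sum(F_^2) < 1e-12) {
      W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      Q <- Q[, seq_len(a - 1), drop = FALSE]
      Tm <- Tm[, seq_len(a - 1), drop = FALSE]
      ssy_expl <- ssy_expl[seq_len(a - 1)]
      break
    }
    u <- F_[, which.max(colSums(F_^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(E, u)); w <- w / sqrt(sum(w^2))
      t_ <- drop(E %*% w)
      q <- drop(crossprod(F_, t_)) / sum(t_^2)
      u <- drop(F_ %*% q) / sum(q^2)
      if (sqrt(sum((t_ - t_old)^2)) < tol * sqrt(sum(t_^2))) break
      t_old <- t_
      if (it == max_iter)
        stop("NIPALS inner loop failed to converge after ", max_iter,
             " iterations")
    }
    p_ <- drop(crossprod(E, t_)) / sum(t_^2)
    E <- E - tcrossprod(t_, p_)
    F_ <- F_ - tcrossprod(t_, q)
    W[, a] <- w; P[, a] <- p_; Q[, a] <- q; Tm[, a] <- t_
    ssy_expl[a] <- sum(t_^2) * sum(q^2)
  }
  list(W = W, P = P, Q = Q, T = Tm, ssy_expl = ssy_expl, F_res = F_)
}

#' Fit a PLS-DA model (NIPALS PLS2)
#'
#' Partial least squares discriminant analysis on mean-centered features
#' against the centered one-hot class matrix, fitted component-wise by
#' NIPALS. Reports `R2Y` (fraction of class-indicator variance explained),
#' `Q2Y` (its leave-one-out cross-validated counterpart, `1 - PRESS/SSY`)
#' and per-feature VIP scores (variable importance in projection; the
#' squared scores average 1).
#'
#' @param X samples x features matrix.
#' @param labels class labels (>= 2 classes).
#' @param n_components number of latent components (default 2).
#' @param cv compute `Q2Y` by leave-one-out refits (default `TRUE`).
#' @return A list of class `plsda_model` with the NIPALS matrices, `R2Y`,
#'   `Q2Y` (`NA` when `cv = FALSE`), `vip`, the class levels and centering
#'   vectors.
#' @export
plsda_fit <- function(X, labels, n_components = 2, cv = TRUE) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  stopifnot(nrow(X) == length(labels),
            n_components >= 1, n_components <= min(nrow(X) - 1, ncol(X)))
  Y <- diag(length(classes))[match(labels, classes), , drop = FALSE]
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  fit <- .nipals_pls2(sweep(X, 2, x_mean), sweep(Y, 2, y_mean), n_components)
  ssy <- sum(sweep(Y, 2, y_mean)^2)
  r2y <- 1 - sum(fit$F_res^2) / ssy
  a_used <- ncol(fit$W)
  vip <- sqrt(ncol(X) * drop(fit$W^2 %*% fit$ssy_expl) / sum(fit$ssy_expl))
  q2y <- NA_real_
  if (cv) {
    press <- 0
    for (i in seq_len(nrow(X))) {
      xm <- colMeans(X[-i, , drop = FALSE])
      ym <- colMeans(Y[-i, , drop = FALSE])
      f <- .nipals_pls2(sweep(X[-i, , drop = FALSE], 2, xm),
                        sweep(Y[-i, , drop = FALSE], 2, ym),
                        min(a_used, nrow(X) - 2))
      B <- f$W %*% solve(crossprod(f$P, f$W), t(f$Q))
      yhat <- drop((X[i, ] - xm) %*% B) + ym
      press <- press + sum((Y[i, ] - yhat)^2)
    }
    q2y <- 1 - press / ssy
  }
  structure(list(W = fit$W, P = fit$P, Q = fit$Q, scores = fit$T,
                 ssy_expl = fit$ssy_expl, n_components = a_used,
                 R2Y = r2y, Q2Y = q2y, vip = stats::setNames(vip, colnames(X)),
                 classes = classes, x_mean = x_mean, y_mean = y_mean),
            class = "plsda_model")
}

#' Predict with a PLS-DA model
#'
#' Predicted class-indicator values are mapped to a label by argmax and to a
#' confidence by the maximum softmax of the predicted indicators.
#'
#' @param model a `plsda_model`.
#' @param X samples x features matrix.
#' @return A data frame `label`, `confidence`.
#' @export
plsda_predict <- function(model, X) {
  X <- as.matrix(X)
  B <- model$W %*% solve(crossprod(model$P, model$W), t(model$Q))
  Yh <- sweep(sweep(X, 2, model$x_mean) %*% B, 2, model$y_mean, "+")
  S <- exp(Yh - apply(Yh, 1, max))
  S <- S / rowSums(S)
  data.frame(label = model$classes[max.col(S, ties.method = "first")],
             confidence = apply(S, 1, max))
}

#' Fit / predict Gaussian linear discriminant analysis
#'
#' Shared-covariance Gaussian LDA via [MASS::lda()]; the prediction
#' confidence is the maximum posterior class probability.
#'
#' @param X samples x features matrix.
#' @param labels class labels; every class needs >= 2 samples.
#' @return `lda_fit`: a `cr_lda` model object. `lda_predict`: a data frame
#'   `label`, `confidence`.
#' @export
lda_fit <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (any(table(labels) < 2))
    stop("every class needs at least 2 samples for LDA")
  structure(list(fit = MASS::lda(X, grouping = factor(labels))),
            class = "cr_lda")
}

#' @rdname lda_fit
#' @param model a `cr_lda` model.
#' @export
lda_predict <- function(model, X) {
  pr <- stats::predict(model$fit, as.matrix(X))
  data.frame(label = as.character(pr$class),
             confidence = apply(pr$posterior, 1, max))
}

#' Leave-one-out cross-validation
#'
#' Refits the supplied model factory n times, each time leaving one sample
#' out and predicting it; any within-model standardization is recomputed
#' inside each fold, so no information leaks from the held-out sample.
#'
#' @param model_factory `function(X_train, labels_train)` returning a
#'   `function(X_new)` that yields a data frame with `label` and
#'   `confidence` columns (see [nn_factory()], [lda_factory()],
#'   [plsda_factory()]).
#' @param X samples x features matrix (n >= 2).
#' @param labels class labels.
#' @return A `cv_report`: see [cv_report()].
#' @export
loocv <- function(model_factory, X, labels) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  n <- nrow(X)
  stopifnot(n >= 2, length(labels) == n)
  preds <- vector("list", n)
  for (i in seq_len(n)) {
    predict_fn <- model_factory(X[-i, , drop = FALSE], labels[-i])
    preds[[i]] <- predict_fn(X[i, , drop = FALSE])[1, c("label", "confidence")]
  }
  preds <- do.call(rbind, preds)
  cv_report(true = labels, predicted = preds$label,
            confidence = preds$confidence, sample_id = rownames(X))
}

#' Build a cross-validation / external-validation report
#'
#' @param true true labels.
#' @param predicted predicted labels.
#' @param confidence per-sample confidence values.
#' @param sample_id optional sample ids.
#' @return A list of class `cv_report`: `samples` (per-sample data frame),
#'   `confusion` (true x predicted table), `overall_accuracy_pct`,
#'   `min_confidence`, `mean_confidence`.
#' @export
cv_report <- function(true, predicted, confidence, sample_id = NULL) {
  n <- length(true)
  stopifnot(length(predicted) == n, length(confidence) == n)
  if (is.null(sample_id)) sample_id <- paste0("S", seq_len(n))
  lev <- sort(unique(c(true, predicted)))
  confusion <- table(true = factor(true, lev),
                     predicted = factor(predicted, lev))
  structure(list(
    samples = data.frame(sample_id = sample_id, true = true,
                         predicted = predicted, confidence = confidence),
    confusion = confusion,
    overall_accuracy_pct = 100 * mean(predicted == true),
    min_confidence = min(confidence),
    mean_confidence = mean(confidence)), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> accuracy ", round(x$overall_accuracy_pct, 2), "% over ",
      nrow(x$samples), " samples; confidence min ",
      round(x$min_confidence, 4), ", mean ", round(x$mean_confidence, 4),
      "\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' Model factories for cross-validation
#'
#' Each factory returns `function(X_train, labels_train)` producing a
#' predictor closure, for use with [loocv()] and external validation.
#'
#' @param config an [nn_config()] for the neural network.
#' @return A model factory function.
#' @export
nn_factory <- function(config = nn_config()) {
  function(X, labels) {
    model <- nn_train(X, labels, config)
    function(X_new) nn_predict(model, X_new)
  }
}

#' @rdname nn_factory
#' @export
lda_factory <- function() {
  function(X, labels) {
    model <- lda_fit(X, labels)
    function(X_new) lda_predict(model, X_new)
  }
}

#' @rdname nn_factory
#' @param n_components latent components for PLS-DA.
#' @export
plsda_factory <- function(n_components = 2) {
  function(X, labels) {
    model <- plsda_fit(X, labels, n_components, cv = FALSE)
    function(X_new) plsda_predict(model, X_new)
  }
}

#' Stratified batch-level train/validation split
#'
#' Splits a cohort into a training and a validation table, assigning whole
#' batches (so technical replicates never straddle the split) and
#' stratifying by origin: per origin, `round(fraction * n_batches)` batches
#' go to training. On the default 13/16/9-batch cohort with 3 replicates
#' this reproduces 78 training and 36 validation samples (9/11/6 vs 4/5/3
#' batches).
#'
#' @param table a [feature_table()] (QC rows are dropped).
#' @param fraction training fraction (default 2/3).
#' @param seed integer seed for the batch draw.
#' @return A list with `train` and `validation` feature tables.
#' @export
split_train_validate <- function(table, fraction = 2 / 3, seed = 20260218) {
  stopifnot(inherits(table, "feature_table"), fraction > 0, fraction < 1)
  tab <- drop_qc(table)
  set.seed(seed)
  train_batches <- character(0)
  for (g in unique(tab$group)) {
    batches <- unique(tab$batch_id[tab$group == g])
    n_train <- round(fraction * length(batches))
    if (n_train < 1 || n_train >= length(batches))
      stop("group '", g, "' has too few batches to split")
    train_batches <- c(train_batches, sample(batches, n_train))
  }
  idx <- tab$batch_id %in% train_batches
  list(train = subset_samples(tab, idx),
       validation = subset_samples(tab, !idx))
}
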