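#' Neural network configuration
#'
#' A 3-layer feedforward network (input, one hidden layer, output) with
#' logistic-sigmoid units throughout, trained by classic momentum
#' backpropagation on the squared error of the sigmoid outputs against
#' one-hot targets. Updates are applied per pattern (one weight update per
#' training sample, in fixed sample order), the convention of the classic
#' backprop implementations this emulates; one iteration is one pass over
#' the training set.
#'
#' @param hidden_units width of the hidden layer (default 10).
#' @param learning_rate gradient step size (default 0.7).
#' @param momentum momentum coefficient on the previous update (default
#'   0.3).
#' @param iterations training epochs (default 100).
#' @param seed seed for the uniform(-0.5, 0.5) weight initialization.
#' @return A list of class `nn_config`.
#' @export
nn_config <- function(hidden_units = 10, learning_rate = 0.7,
                      momentum = 0.3, iterations = 100, seed = 20260218) {
  stopifnot(hidden_units >= 1, learning_rate > 0, momentum >= 0,
            momentum < 1, iterations >= 1)
  structure(list(hidden_units = hidden_units,
                 learning_rate = learning_rate, momentum = momentum,
                 iterations = iterations, seed = seed), class = "nn_config")
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# gradient of the per-sample squared error 0.5 * ||y - yhat||^2 for a single
# input row; also used by the finite-difference tests
.nn_sample_grad <- function(x, y, W1, b1, W2, b2) {
  h <- .sigmoid(drop(x %*% W1) + b1)
  yh <- .sigmoid(drop(h %*% W2) + b2)
  d_out <- (yh - y) * yh * (1 - yh)
  d_hid <- drop(W2 %*% d_out) * h * (1 - h)
  list(gW1 = outer(x, d_hid), gb1 = d_hid,
       gW2 = outer(h, d_out), gb2 = d_out, yh = yh)
}

#' Train the momentum-backprop neural network
#'
#' Features are standardized internally (z-score with training-set mean and
#' SD; zero-SD features are left centered only), targets are the one-hot
#' class indicators, and weights start uniform(-0.5, 0.5) from
#' `config$seed`. Training runs exactly `config$iterations` passes over the
#' samples with per-pattern momentum updates. Deterministic given the seed.
#'
#' @param X numeric matrix, samples x features.
#' @param labels class labels (>= 2 classes).
#' @param config an [nn_config()].
#' @return An object of class `nn_model`: weights `W1`, `b1`, `W2`, `b2`,
#'   the standardization parameters `center`/`scale`, `classes`, `config`.
#' @export
nn_train <- function(X, labels, config = nn_config()) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  stopifnot(nrow(X) == length(labels))
  center <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scl, "/")
  Y <- diag(length(classes))[match(labels, classes), , drop = FALSE]
  p <- ncol(Z); hdn <- config$hidden_units; k <- length(classes)
  set.seed(config$seed)
  W1 <- matrix(stats::runif(p * hdn, -0.5, 0.5), p, hdn)
  b1 <- stats::runif(hdn, -0.5, 0.5)
  W2 <- matrix(stats::runif(hdn * k, -0.5, 0.5), hdn, k)
  b2 <- stats::runif(k, -0.5, 0.5)
  vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- b2 * 0
  lr <- config$learning_rate; mom <- config$momentum
  for (it in seq_len(config$iterations)) {
    for (i in seq_len(nrow(Z))) {
      g <- .nn_sample_grad(Z[i, ], Y[i, ], W1, b1, W2, b2)
      vW1 <- mom * vW1 - lr * g$gW1; vb1 <- mom * vb1 - lr * g$gb1
      vW2 <- mom * vW2 - lr * g$gW2; vb2 <- mom * vb2 - lr * g$gb2
      W1 <- W1 + vW1; b1 <- b1 + vb1; W2 <- W2 + vW2; b2 <- b2 + vb2
    }
    if (any(!is.finite(W1)) || any(!is.finite(W2)))
      stop("training diverged (non-finite weights); ",
           "try a smaller learning rate")
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, center = center,
                 scale = scl, classes = classes, config = config,
                 features = colnames(X)), class = "nn_model")
}

#' Predict with a trained neural network
#'
#' Class scores are the sigmoid outputs normalized to sum to one; the label
#' is the argmax (ties to the first class in sorted order) and the
#' confidence is the maximum normalized score — the strength of the
#' assignment to the chosen class, in `[0, 1]`.
#'
#' @param model an `nn_model` from [nn_train()].
#' @param X samples x features matrix with the training feature count.
#' @return A data frame `label`, `confidence`, plus one `score_<class>`
#'   column per class (normalized scores summing to 1).
#' @export
nn_predict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$center))
    stop("feature count mismatch: model expects ", length(model$center),
         ", got ", ncol(X))
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  H <- .sigmoid(sweep(Z %*% model$W1, 2, model$b1, "+"))
  Yh <- .sigmoid(sweep(H %*% model$W2, 2, model$b2, "+"))
  S <- Yh / rowSums(Yh)
  out <- data.frame(label = model$classes[max.col(S, ties.method = "first")],
                    confidence = apply(S, 1, max))
  colnames(S) <- paste0("score_", model$classes)
  cbind(out, as.data.frame(S))
}

#' Rank features by input-layer connection weight
#'
#' Scores each input feature by the sum of the absolute values of its
#' input-to-hidden connection weights and ranks features in descending
#' score order (ties to the lower feature index) — the importance measure
#' used to compare the network's decision basis with the ANOVA and VIP
#' rankings.
#'
#' @param model an `nn_model`.
#' @return A data frame `feature`, `score`, `rank`, ordered by rank.
#' @export
weight_importance <- function(model) {
  stopifnot(inherits(model, "nn_model"))
  score <- rowSums(abs(model$W1))
  feature <- model$features
  if (is.null(feature)) feature <- paste0("X", seq_along(score))
  ord <- order(-score, seq_along(score))
  data.frame(feature = feature[ord], score = score[ord],
             rank = seq_along(ord), row.names = NULL)
}
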