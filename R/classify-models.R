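#' The five classification methods
#' @return character vector of method codes
#' @export
classifierMethods <- function() c("nn", "svm", "gnb", "dt", "gbdt")

#' Fit one classifier
#'
#' Dispatches to the method's backend with the study hyperparameters:
#' \describe{
#'   \item{`nn`}{multilayer perceptron (in-package implementation): three
#'     identical rectified-linear hidden layers as wide as the input, softmax
#'     output, cross-entropy loss, Adam optimizer, 800 epochs at batch 80.}
#'   \item{`svm`}{radial-basis-kernel support vector machine, cost 0.2
#'     (\pkg{e1071}).}
#'   \item{`gnb`}{Gaussian naive Bayes (\pkg{e1071}).}
#'   \item{`dt`}{CART decision tree (\pkg{rpart}).}
#'   \item{`gbdt`}{gradient-boosted trees (\pkg{xgboost}; 100 rounds,
#'     learning rate 0.1, depth 3 — the usual gradient-boosting defaults).}
#' }
#'
#' @param method one of [classifierMethods()]
#' @param x numeric training matrix (subjects x features), standardized
#' @param y character class labels
#' @param seed seed for stochastic fitters
#' @param ... method-specific overrides (e.g. `epochs` for `nn`)
#' @return classifier object of class `epClassifier`
#' @export
fitClassifier <- function(method = classifierMethods(), x, y, seed = 1, ...) {
  method <- match.arg(method)
  lv <- diseaseClasses()[diseaseClasses() %in% unique(y)]
  yf <- factor(y, levels = lv)
  fit <- switch(method,
    nn = fitMlp(x, yf, seed = seed, ...),
    svm = {
      set.seed(seed)
      e1071::svm(x, yf, kernel = "radial", cost = 0.2,
                 probability = FALSE, ...)
    },
    gnb = e1071::naiveBayes(as.data.frame(x), yf, ...),
    dt = {
      set.seed(seed)
      df <- data.frame(.y = yf, x, check.names = TRUE)
      # unpruned CART (splits allowed down to single subjects), the usual
      # default of scikit-learn-style decision trees
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(minsplit = 2,
                                                  minbucket = 1, cp = 0),
                   ...)
    },
    gbdt = {
      set.seed(seed)
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(yf) - 1L)
      xgboost::xgb.train(
        params = list(objective = "multi:softmax",
                      num_class = length(lv), eta = 0.1, max_depth = 3,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = 100, verbose = 0, ...)
    })
  structure(list(method = method, fit = fit, levels = lv),
            class = "epClassifier")
}

#' @rdname fitClassifier
#' @param object an `epClassifier`
#' @param newdata matrix of standardized features
#' @export
predict.epClassifier <- function(object, newdata, ...) {
  out <- switch(object$method,
    nn = predictMlp(object$fit, newdata),
    svm = as.character(stats::predict(object$fit, newdata)),
    gnb = as.character(stats::predict(object$fit, as.data.frame(newdata))),
    dt = {
      df <- data.frame(newdata, check.names = TRUE)
      as.character(stats::predict(object$fit, df, type = "class"))
    },
    gbdt = object$levels[
      stats::predict(object$fit, xgboost::xgb.DMatrix(newdata)) + 1L])
  factor(out, levels = object$levels)
}

# ---- multilayer perceptron --------------------------------------------------

relu <- function(z) pmax(z, 0)

softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Multilayer perceptron with Adam
#'
#' Small dense network used for the `nn` method: hidden layers of equal width
#' (defaulting to the input width), rectified-linear activations, softmax
#' output trained by categorical cross-entropy with the Adam optimizer.
#' He-normal weight initialization; minibatches are drawn by shuffling each
#' epoch.
#'
#' @param x training matrix (n x p)
#' @param y factor of class labels
#' @param hidden number of hidden layers
#' @param width hidden width; defaults to `ncol(x)`
#' @param epochs training epochs
#' @param batch minibatch size
#' @param lr learning rate
#' @param beta1,beta2,eps Adam moment parameters
#' @param seed RNG seed for initialization and shuffling
#' @return object of class `epMlp`
#' @export
fitMlp <- function(x, y, hidden = 3, width = ncol(x), epochs = 800,
                   batch = 80, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                   eps = 1e-8, seed = 1) {
  stopifnot(is.factor(y), nrow(x) == length(y))
  set.seed(seed)
  nClass <- nlevels(y)
  sizes <- c(ncol(x), rep(width, hidden), nClass)
  L <- length(sizes) - 1
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(v) v * 0); vb <- mb
  Y <- diag(nClass)[as.integer(y), , drop = FALSE]
  n <- nrow(x)
  step <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- Y[idx, , drop = FALSE]
      # forward
      acts <- vector("list", L + 1)
      acts[[1]] <- xb
      for (l in seq_len(L - 1))
        acts[[l + 1]] <- relu(sweep(acts[[l]] %*% W[[l]], 2, b[[l]], "+"))
      logits <- sweep(acts[[L]] %*% W[[L]], 2, b[[L]], "+")
      probs <- softmaxRows(logits)
      # backward
      delta <- (probs - yb) / nrow(xb)
      step <- step + 1
      for (l in rev(seq_len(L))) {
        gW <- crossprod(acts[[l]], delta)
        gb <- colSums(delta)
        if (l > 1)
          delta <- (delta %*% t(W[[l]])) * (acts[[l]] > 0)
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mhW <- mW[[l]] / (1 - beta1^step)
        vhW <- vW[[l]] / (1 - beta2^step)
        mhb <- mb[[l]] / (1 - beta1^step)
        vhb <- vb[[l]] / (1 - beta2^step)
        W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
        b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
      }
    }
  }
  structure(list(W = W, b = b, levels = levels(y)), class = "epMlp")
}

#' @rdname fitMlp
#' @param fit an `epMlp`
#' @param newdata matrix of features
#' @export
predictMlp <- function(fit, newdata) {
  a <- newdata
  L <- length(fit$W)
  for (l in seq_len(L - 1))
    a <- relu(sweep(a %*% fit$W[[l]], 2, fit$b[[l]], "+"))
  logits <- sweep(a %*% fit$W[[L]], 2, fit$b[[L]], "+")
  fit$levels[max.col(logits, ties.method = "first")]
}
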