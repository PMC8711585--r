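#' @title Linear fatigue classifier on the (A1, A2, A3) triple
#' @name classify
#' @description
#' Optional learning-layer hook: a binary maximum-margin linear classifier
#' separating non-fatigue from fatigue pitches in fatigue-value space.
#' Implemented as an L2-regularised squared-hinge linear model fitted with
#' BFGS (a linear SVM in substance; no external SVM library is required).
NULL

#' Train the fatigue classifier
#'
#' @param A data.frame or matrix with columns `A1`, `A2`, `A3` (rows with
#'   missing values are dropped).
#' @param labels factor/character/logical per-row class labels; exactly two
#'   classes must be present. Conventionally `"nonfatigue"`/`"fatigue"`
#'   interval membership from [split_intervals].
#' @param lambda L2 regularisation strength (default 1e-2).
#' @return An object of class `fatigue_classifier` (weights, intercept,
#'   standardisation constants, class levels).
#' @export
train_fatigue_classifier <- function(A, labels, lambda = 1e-2) {
  X <- as.matrix(as.data.frame(A)[, c("A1", "A2", "A3")])
  keep <- stats::complete.cases(X) & !is.na(labels)
  X <- X[keep, , drop = FALSE]
  labels <- labels[keep]
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2L)
    pf_stop("training_error", "need exactly 2 classes, got %d", length(lev))
  y <- ifelse(as.character(labels) == lev[2], 1, -1)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  obj <- function(par) {
    w <- par[1:3]; b <- par[4]
    m <- 1 - y * (Z %*% w + b)
    sum(pmax(m, 0)^2) / length(y) + lambda / 2 * sum(w^2)
  }
  grad <- function(par) {
    w <- par[1:3]; b <- par[4]
    m <- as.vector(1 - y * (Z %*% w + b))
    act <- m > 0
    gw <- -2 * crossprod(Z[act, , drop = FALSE],
                         (y * m)[act]) / length(y) + lambda * w
    gb <- -2 * sum((y * m)[act]) / length(y)
    c(gw, gb)
  }
  fit <- stats::optim(rep(0, 4), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  structure(list(w = fit$par[1:3], b = fit$par[4], center = ctr,
                 scale = scl, levels = lev, lambda = lambda,
                 converged = fit$convergence == 0),
            class = "fatigue_classifier")
}

#' @export
print.fatigue_classifier <- function(x, ...) {
  cat(sprintf("<fatigue_classifier> linear, classes %s | %s, w = (%.3f, %.3f, %.3f)\n",
              x$levels[1], x$levels[2], x$w[1], x$w[2], x$w[3]))
  invisible(x)
}

#' Predict with a fatigue classifier
#'
#' @param object a `fatigue_classifier`.
#' @param newdata data.frame/matrix with columns `A1`, `A2`, `A3`.
#' @param type `"class"` (default) or `"margin"` (signed distance score,
#'   positive toward the second class level).
#' @param ... unused.
#' @export
predict.fatigue_classifier <- function(object, newdata,
                                       type = c("class", "margin"), ...) {
  type <- match.arg(type)
  X <- as.matrix(as.data.frame(newdata)[, c("A1", "A2", "A3")])
  Z <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  m <- as.vector(Z %*% object$w + object$b)
  if (type == "margin") return(m)
  factor(ifelse(m >= 0, object$levels[2], object$levels[1]),
         levels = object$levels)
}

#' Persist / load a fatigue classifier as JSON
#'
#' @param object a `fatigue_classifier`.
#' @param path JSON file path.
#' @export
write_classifier <- function(object, path) {
  jsonlite::write_json(unclass(object), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$w <- as.numeric(p$w)
  p$center <- as.numeric(p$center)
  p$scale <- as.numeric(p$scale)
  structure(p, class = "fatigue_classifier")
}
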