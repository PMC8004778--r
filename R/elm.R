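#' Moore-Penrose pseudoinverse
#'
#' SVD-based pseudoinverse with the usual relative tolerance on the
#' singular values, giving the minimum-norm least-squares solve used by the
#' extreme learning machine.
#'
#' @param m numeric matrix.
#' @param tol relative singular-value cutoff.
#' @return The pseudoinverse of `m`.
#' @export
pinv <- function(m, tol = max(dim(m)) * .Machine$double.eps) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

elm_activation <- function(tag) {
  switch(tag,
         sigmoid = function(z) 1 / (1 + exp(-z)),
         tanh = base::tanh,
         relu = function(z) pmax(z, 0),
         stop("unknown activation '", tag, "'", call. = FALSE))
}

#' Fit an extreme learning machine
#'
#' A single-hidden-layer feed-forward network whose hidden weights `a`
#' (d x n_hidden) and biases `b` are drawn once from a seeded uniform(-1, 1)
#' and never trained. With hidden output matrix
#' `H[j, i] = f(<a_i, x_j> + b_i)` and one-hot target matrix `T`, the output
#' weights are solved in closed form as the minimum-norm least-squares
#' solution `beta = pinv(H) %*% T`. Classes are the sorted unique labels;
#' prediction takes the argmax output column, ties going to the lowest
#' class index.
#'
#' @param x numeric matrix of training features (n x d).
#' @param y class labels (length n, at least 2 distinct values).
#' @param n_hidden number of hidden nodes (>= 1).
#' @param activation `"sigmoid"` (default), `"tanh"` or `"relu"`.
#' @param seed integer seed for the random hidden layer.
#' @return An object of class `elm` with components `a`, `b`, `beta`,
#'   `activation`, `classes`, `n_hidden`, `seed`.
#' @export
elm <- function(x, y, n_hidden = 100L, activation = "sigmoid", seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 1L || n_hidden < 1L) {
    stop("invalid input: need n_hidden >= 1 and a non-empty x",
         call. = FALSE)
  }
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) {
    stop("invalid input: need at least 2 classes", call. = FALSE)
  }
  d <- ncol(x)
  ab <- with_seed(seed, stats::runif(d * n_hidden + n_hidden, -1, 1))
  a <- matrix(ab[seq_len(d * n_hidden)], d, n_hidden)
  b <- ab[d * n_hidden + seq_len(n_hidden)]
  f <- elm_activation(activation)
  H <- f(sweep(x %*% a, 2L, b, `+`))
  Tmat <- outer(y, classes, `==`) * 1
  beta <- pinv(H) %*% Tmat
  colnames(beta) <- classes
  structure(list(a = a, b = b, beta = beta, activation = activation,
                 classes = classes, n_hidden = as.integer(n_hidden),
                 seed = as.integer(seed), d = d),
            class = "elm")
}

#' Predict from an extreme learning machine
#'
#' Computes the output matrix `O = f(X a + b) beta` and returns either the
#' argmax class per row (ties to the lowest class index) or the raw output
#' scores.
#'
#' @param object an [elm()] fit.
#' @param newdata numeric matrix with the training feature dimension.
#' @param type `"class"` (default) or `"raw"`.
#' @param ... unused.
#' @return Character vector of labels, or the n x M score matrix.
#' @export
predict.elm <- function(object, newdata, type = c("class", "raw"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$d) {
    stop("invalid input: feature dimension mismatch", call. = FALSE)
  }
  f <- elm_activation(object$activation)
  O <- f(sweep(newdata %*% object$a, 2L, object$b, `+`)) %*% object$beta
  if (type == "raw") return(O)
  object$classes[max.col(O, ties.method = "first")]
}

#' @export
coef.elm <- function(object, ...) object$beta

#' @export
print.elm <- function(x, ...) {
  cat(sprintf(
    "<elm: %d hidden nodes (%s), %d features -> %d classes, seed %d>\n",
    x$n_hidden, x$activation, x$d, length(x$classes), x$seed))
  invisible(x)
}
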