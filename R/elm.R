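# Extreme learning machine family: single-hidden-layer networks with
# randomly fixed (or data-constrained) input weights and a closed-form
# regularised least-squares solve for the output weights.

#' Activation functions for the ELM hidden layer
#' @param name `"sigmoid"` (default), `"tanh"`, `"relu"` or `"identity"`.
#' @return A vectorised function of one argument.
#' @export
elm_activation <- function(name = c("sigmoid", "tanh", "relu", "identity")) {
  name <- match.arg(name)
  switch(name,
         sigmoid = function(z) 1 / (1 + exp(-z)),
         tanh = tanh,
         relu = function(z) pmax(z, 0),
         identity = identity)
}

#' Hidden-layer output matrix
#'
#' Computes `H[i, j] = g(w_j' x_i + b_j)` for inputs `X` (rows are
#' samples), hidden weights `W` (rows are hidden nodes) and biases `b`.
#'
#' @param W `L x D` hidden weight matrix.
#' @param b length-`L` bias vector.
#' @param g activation function (see [elm_activation()]).
#' @param X `N x D` input matrix.
#' @return `N x L` matrix.
#' @export
hidden_output <- function(W, b, g, X) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite values in the input matrix")
  stopifnot(ncol(X) == ncol(W), length(b) == nrow(W))
  Z <- tcrossprod(X, W)
  g(Z + rep(b, each = nrow(X)))
}

# +-1 one-vs-rest target coding
encode_targets <- function(y, classes) {
  Ti <- matrix(-1, length(y), length(classes))
  Ti[cbind(seq_along(y), match(as.character(y), classes))] <- 1
  Ti
}

decode_scores <- function(scores, classes) {
  classes[max.col(scores, ties.method = "first")]
}

# SPD solve with a single jitter fallback before failing
spd_solve <- function(A, B) {
  r <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(r)) {
    r <- tryCatch(chol(A + diag(1e-10, nrow(A))), error = function(e) NULL)
    if (is.null(r)) {
      stop("linear system is singular beyond regularisation (condition ",
           "estimate ", format(kappa(A)), ")")
    }
  }
  backsolve(r, backsolve(r, B, transpose = TRUE))
}

# Regularised least-squares output weights: primal when L <= N, dual
# otherwise; the two are algebraically identical.
solve_beta <- function(H, Ti, C) {
  N <- nrow(H); L <- ncol(H)
  if (is.infinite(C)) {
    return(spd_solve(crossprod(H), crossprod(H, Ti)))
  }
  if (L <= N) {
    spd_solve(diag(1 / C, L) + crossprod(H), crossprod(H, Ti))
  } else {
    t(H) %*% spd_solve(diag(1 / C, N) + tcrossprod(H), Ti)
  }
}

#' Fit an extreme learning machine classifier
#'
#' Single-hidden-layer network whose input weights `W` and biases `b` are
#' drawn randomly (uniform on `[-1, 1]`) and whose output weights are the
#' ridge solution `beta = H' (I/C + H H')^-1 T`, where `H` is the hidden
#' output matrix and `T` the `+-1` one-vs-rest target coding.  When the
#' sample count exceeds the hidden-layer width the algebraically
#' equivalent form `(I/C + H'H)^-1 H'T` is solved instead.
#'
#' @param x `N x D` feature matrix.
#' @param y label vector (length `N`).
#' @param n_hidden number of hidden nodes `L`.
#' @param C ridge regularisation constant (> 0).
#' @param activation activation name, see [elm_activation()].
#' @param seed integer seed for the random hidden layer.
#' @return An object of class `elm`: fields `W`, `b`, `beta`, `classes`,
#'   `activation`, `C`.
#' @examples
#' x <- rbind(matrix(rnorm(40, -2), 20), matrix(rnorm(40, 2), 20))
#' fit <- elm(x, rep(c("a", "b"), each = 20), n_hidden = 25, seed = 1)
#' mean(predict(fit, x) == rep(c("a", "b"), each = 20))
#' @export
elm <- function(x, y, n_hidden = 100L, C = 1, activation = "sigmoid",
                seed = 1L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), n_hidden >= 1, C > 0)
  classes <- sort(unique(as.character(y)))
  g <- elm_activation(activation)
  with_seed(seed, {
    W <- matrix(stats::runif(n_hidden * ncol(x), -1, 1), n_hidden, ncol(x))
    b <- stats::runif(n_hidden, -1, 1)
    H <- hidden_output(W, b, g, x)
    beta <- solve_beta(H, encode_targets(y, classes), C)
    structure(list(W = W, b = b, beta = beta, classes = classes,
                   activation = activation, C = C,
                   n_hidden = as.integer(n_hidden)),
              class = "elm")
  })
}

#' @export
print.elm <- function(x, ...) {
  cat("<", class(x)[1], "> ", x$n_hidden, " hidden nodes (",
      x$activation, "), ", length(x$classes), " classes, C = ", x$C,
      "\n", sep = "")
  invisible(x)
}

#' @export
coef.elm <- function(object, ...) object$beta

#' Predict from an ELM-family model
#'
#' @param object a fitted [elm()], [celm()] or [oselm()] model.
#' @param newdata feature matrix (`N x D`).
#' @param type `"class"` for labels, `"score"` for the raw `N x M` output
#'   score matrix `h(x) beta`.
#' @param ... ignored.
#' @export
predict.elm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) {
    return(if (type == "class") character(0)
           else matrix(0, 0, length(object$classes)))
  }
  if (ncol(newdata) != ncol(object$W)) {
    stop("newdata has ", ncol(newdata), " columns but the model expects ",
         ncol(object$W))
  }
  g <- elm_activation(object$activation)
  S <- hidden_output(object$W, object$b, g, newdata) %*% object$beta
  colnames(S) <- object$classes
  if (type == "score") S else decode_scores(S, object$classes)
}

# ---- kernel ELM -----------------------------------------------------------

#' Kernel functions for the kernel ELM
#'
#' @param name `"rbf"` (default, `exp(-gamma |x - y|^2)`), `"linear"`
#'   (`x'y`) or `"poly"` (`(x'y + 1)^degree`).
#' @param gamma RBF width (default `1/D`, resolved at fit time if `NULL`).
#' @param degree polynomial degree.
#' @return A function `k(X, Y)` returning the cross-kernel matrix.
#' @export
elm_kernel <- function(name = c("rbf", "linear", "poly"), gamma = NULL,
                       degree = 2) {
  name <- match.arg(name)
  f <- switch(name,
    rbf = function(X, Y) {
      g <- if (is.null(gamma)) 1 / ncol(X) else gamma
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
      exp(-g * pmax(d2, 0))
    },
    linear = function(X, Y) tcrossprod(X, Y),
    poly = function(X, Y) (tcrossprod(X, Y) + 1)^degree)
  attr(f, "name") <- name
  f
}

#' Fit a kernel extreme learning machine
#'
#' Replaces the random-feature Gram matrix `H H'` with a kernel matrix
#' `K[i, j] = k(x_i, x_j)`; the dual coefficients are
#' `(I/C + K)^-1 T` and prediction scores are `K(Xnew, X)` times the dual
#' coefficients.  With an explicit-feature kernel (e.g. linear) this is
#' algebraically identical to an ELM using those features directly.
#'
#' @param x `N x D` feature matrix.
#' @param y label vector.
#' @param kernel a kernel function from [elm_kernel()], or a kernel name.
#' @param C ridge regularisation constant (> 0).
#' @return An object of class `kelm`: stored training inputs, dual
#'   coefficients, kernel and `C`.
#' @export
kelm <- function(x, y, kernel = elm_kernel("rbf"), C = 1) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), C > 0)
  if (is.character(kernel)) kernel <- elm_kernel(kernel)
  classes <- sort(unique(as.character(y)))
  K <- kernel(x, x)
  if (max(abs(K - t(K))) > 1e-8) stop("kernel matrix is not symmetric")
  dual <- spd_solve(diag(1 / C, nrow(x)) + K, encode_targets(y, classes))
  structure(list(support_inputs = x, dual_coefficients = dual,
                 kernel = kernel, C = C, classes = classes),
            class = "kelm")
}

#' @export
print.kelm <- function(x, ...) {
  cat("<kelm> ", nrow(x$support_inputs), " support inputs, kernel '",
      attr(x$kernel, "name"), "', ", length(x$classes), " classes, C = ",
      x$C, "\n", sep = "")
  invisible(x)
}

#' @rdname predict.elm
#' @export
predict.kelm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) {
    return(if (type == "class") character(0)
           else matrix(0, 0, length(object$classes)))
  }
  S <- object$kernel(newdata, object$support_inputs) %*%
    object$dual_coefficients
  colnames(S) <- object$classes
  if (type == "score") S else decode_scores(S, object$classes)
}

# ---- constrained ELM ------------------------------------------------------

#' Fit a constrained extreme learning machine
#'
#' Like [elm()], but the hidden weight vectors are not free random draws:
#' each `w_j` is built from a randomly drawn pair of samples from two
#' different classes as `w_j = 2 (x_a - x_b) / ||x_a - x_b||^2`, with bias
#' `b_j = (||x_b||^2 - ||x_a||^2) / ||x_a - x_b||^2`, so the node's
#' decision surface passes through the pair midpoint.  Output weights are
#' solved exactly as in [elm()].
#'
#' @inheritParams elm
#' @return An object of class `c("celm", "elm")` with an extra `pairs`
#'   field recording the `(a, b)` sample indices behind each hidden node.
#' @export
celm <- function(x, y, n_hidden = 20L, C = 1, activation = "sigmoid",
                 seed = 1L) {
  x <- as.matrix(x)
  y <- as.character(y)
  stopifnot(nrow(x) == length(y), n_hidden >= 1, C > 0)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("CELM needs at least 2 classes")
  g <- elm_activation(activation)
  with_seed(seed, {
    W <- matrix(0, n_hidden, ncol(x))
    b <- numeric(n_hidden)
    pairs <- matrix(0L, n_hidden, 2L)
    max_tries <- n_hidden * 100L
    tries <- 0L
    for (j in seq_len(n_hidden)) {
      repeat {
        tries <- tries + 1L
        if (tries > max_tries) {
          stop("could not draw distinct between-class sample pairs ",
               "(degenerate data?)")
        }
        a <- sample.int(nrow(x), 1L)
        bidx <- sample(which(y != y[a]), 1L)
        d <- x[a, ] - x[bidx, ]
        nd2 <- sum(d^2)
        if (nd2 > 0) break
      }
      W[j, ] <- 2 * d / nd2
      b[j] <- (sum(x[bidx, ]^2) - sum(x[a, ]^2)) / nd2
      pairs[j, ] <- c(a, bidx)
    }
    H <- hidden_output(W, b, g, x)
    beta <- solve_beta(H, encode_targets(y, classes), C)
    structure(list(W = W, b = b, beta = beta, classes = classes,
                   activation = activation, C = C,
                   n_hidden = as.integer(n_hidden), pairs = pairs),
              class = c("celm", "elm"))
  })
}

# ---- online-sequential ELM ------------------------------------------------

#' Initialise an online-sequential ELM (boosting phase)
#'
#' Fits an unregularised ELM on an initial batch of at least `n_hidden`
#' samples, keeping the inverse accumulator
#' `P = (H0' H0)^-1` needed for later recursive updates; the boosting
#' data themselves are not retained.
#'
#' @param x0,y0 initial batch (`N0 >= n_hidden` samples).
#' @param classes full class universe (later chunks may contain classes
#'   absent from the initial batch); defaults to the classes in `y0`.
#' @inheritParams elm
#' @return An object of class `oselm` with fields `W`, `b`, `beta`, `P`,
#'   `n_seen`.
#' @export
oselm <- function(x0, y0, n_hidden = 50L, activation = "sigmoid",
                  seed = 1L, classes = NULL) {
  x0 <- as.matrix(x0)
  stopifnot(nrow(x0) == length(y0), n_hidden >= 1)
  if (nrow(x0) < n_hidden) {
    stop("the boosting phase needs at least as many samples (", nrow(x0),
         ") as hidden nodes (", n_hidden, ")")
  }
  if (is.null(classes)) classes <- sort(unique(as.character(y0)))
  g <- elm_activation(activation)
  with_seed(seed, {
    W <- matrix(stats::runif(n_hidden * ncol(x0), -1, 1), n_hidden, ncol(x0))
    b <- stats::runif(n_hidden, -1, 1)
    H0 <- hidden_output(W, b, g, x0)
    P <- tryCatch(chol2inv(chol(crossprod(H0))),
                  error = function(e) stop("rank-deficient boosting batch: ",
                                           conditionMessage(e)))
    beta <- P %*% crossprod(H0, encode_targets(y0, classes))
    structure(list(W = W, b = b, beta = beta, P = P, classes = classes,
                   activation = activation, n_hidden = as.integer(n_hidden),
                   n_seen = nrow(x0)),
              class = c("oselm", "elm"))
  })
}

#' Sequential update of an online-sequential ELM
#'
#' Recursive least-squares update absorbing one chunk of data (possibly a
#' single sample) without retaining it:
#' `P <- P - P Hk' (I + Hk P Hk')^-1 Hk P` and
#' `beta <- beta + P Hk' (Tk - Hk beta)`.  Any chunking of a stream
#' yields the same `beta` as a batch unregularised ELM on the
#' concatenated data (with the same hidden layer).
#'
#' @param state an [oselm()] state.
#' @param xk,yk the chunk (zero rows is a no-op).
#' @return The updated `oselm` state.
#' @export
oselm_update <- function(state, xk, yk) {
  stopifnot(inherits(state, "oselm"))
  xk <- as.matrix(xk)
  if (nrow(xk) == 0L) return(state)
  stopifnot(nrow(xk) == length(yk))
  bad <- setdiff(unique(as.character(yk)), state$classes)
  if (length(bad)) {
    stop("chunk contains classes unseen at initialisation: ",
         paste(bad, collapse = ", "))
  }
  g <- elm_activation(state$activation)
  Hk <- hidden_output(state$W, state$b, g, xk)
  Tk <- encode_targets(yk, state$classes)
  PHt <- state$P %*% t(Hk)
  M <- diag(nrow(xk)) + Hk %*% PHt
  P <- state$P - PHt %*% solve(M, t(PHt))
  beta <- state$beta + P %*% t(Hk) %*% (Tk - Hk %*% state$beta)
  if (any(!is.finite(beta))) {
    stop("non-finite values in the sequential update (chunk of ",
         nrow(xk), " samples after ", state$n_seen, " seen)")
  }
  state$P <- P
  state$beta <- beta
  state$n_seen <- state$n_seen + nrow(xk)
  state
}
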