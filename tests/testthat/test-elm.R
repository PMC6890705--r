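ridge_beta <- function(H, Ti, C) {
  L <- ncol(H)
  solve(diag(1 / C, L) + t(H) %*% H, t(H) %*% Ti)
}

pm_targets <- function(y, classes) {
  Ti <- matrix(-1, length(y), length(classes))
  Ti[cbind(seq_along(y), match(y, classes))] <- 1
  Ti
}

test_that("hidden-layer output matches the per-entry definition", {
  # identity activation with an identity-like weight matrix reproduces X
  X <- matrix(rnorm(12), 4, 3)
  H <- hidden_output(diag(3), rep(0, 3), identity, X)
  expect_equal(H, X)

  # sigmoid at zero input is exactly 1/2
  H0 <- hidden_output(matrix(0, 5, 3), rep(0, 5), elm_activation("sigmoid"),
                      X)
  expect_true(all(H0 == 0.5))

  # brute-force entry-by-entry evaluation
  set.seed(21)
  W <- matrix(rnorm(6), 3, 2); b <- rnorm(3)
  X2 <- matrix(rnorm(4), 2, 2)
  g <- elm_activation("sigmoid")
  H2 <- hidden_output(W, b, g, X2)
  for (i in 1:2) for (j in 1:3) {
    expect_equal(H2[i, j], g(sum(W[j, ] * X2[i, ]) + b[j]),
                 tolerance = 1e-12)
  }
  expect_error(hidden_output(W, b, g, matrix(c(1, NA, 1, 1), 2, 2)),
               "non-finite")
})

test_that("the ELM solve matches an independent ridge oracle", {
  set.seed(31)
  for (rep in 1:10) {
    N <- sample(20:60, 1); D <- sample(2:6, 1); L <- sample(5:15, 1)
    C <- 10^runif(1, -2, 2)
    x <- matrix(rnorm(N * D), N, D)
    y <- sample(c("u", "v", "w"), N, replace = TRUE)
    fit <- elm(x, y, n_hidden = L, C = C, seed = rep)
    H <- hidden_output(fit$W, fit$b, elm_activation("sigmoid"), x)
    expect_equal(fit$beta, ridge_beta(H, pm_targets(y, fit$classes), C),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # optimality: gradient of the ridge objective vanishes
    grad <- t(H) %*% H %*% fit$beta + fit$beta / C -
      t(H) %*% pm_targets(y, fit$classes)
    expect_lt(max(abs(grad)), 1e-6)
  }
})

test_that("primal and dual solves agree in both size regimes", {
  set.seed(32)
  x <- matrix(rnorm(30 * 3), 30, 3)
  y <- rep(c("a", "b", "c"), 10)
  for (L in c(10, 60)) {  # L < N and L > N
    fit <- elm(x, y, n_hidden = L, C = 5, seed = 2)
    H <- hidden_output(fit$W, fit$b, elm_activation("sigmoid"), x)
    Ti <- pm_targets(y, fit$classes)
    dual <- t(H) %*% solve(diag(1 / 5, 30) + H %*% t(H), Ti)
    expect_equal(fit$beta, dual, tolerance = 1e-8, ignore_attr = TRUE)
    # prediction via stored beta equals the full dual-form expression
    sc <- predict(fit, x, type = "score")
    expect_equal(sc, H %*% dual, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("an identity-feature ELM reduces to ridge regression on X", {
  set.seed(33)
  x <- matrix(rnorm(40 * 3), 40, 3)
  y <- rep(c("a", "b"), 20)
  fit <- elm(x, y, n_hidden = 3, C = 2, activation = "identity", seed = 1)
  fit$W <- diag(3); fit$b <- rep(0, 3)
  H <- x  # identity map
  Ti <- pm_targets(y, fit$classes)
  beta <- t(x) %*% solve(diag(1 / 2, 40) + x %*% t(x), Ti)
  refit <- myxoclass:::solve_beta(H, Ti, 2)
  expect_equal(refit, beta, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("ELM separates two Gaussians and handles edge cases", {
  task <- gauss2_task(n_per = 100, seed = 41)
  idx <- rep(c(TRUE, FALSE), 100)  # alternating train/test split
  fit <- elm(task$x[idx, ], task$y[idx], n_hidden = 100, C = 1, seed = 5)
  acc <- mean(predict(fit, task$x[!idx, ]) == task$y[!idx])
  expect_gte(acc, 0.95)

  # two-point problem is recovered exactly
  x2 <- rbind(c(-1, 0), c(1, 0))
  f2 <- elm(x2, c("p", "q"), n_hidden = 20, C = 1e6, seed = 1)
  expect_equal(predict(f2, x2), c("p", "q"))

  # empty input: empty output
  expect_identical(predict(fit, task$x[0, , drop = FALSE]), character(0))
  expect_equal(dim(predict(fit, task$x[0, , drop = FALSE], type = "score")),
               c(0L, 2L))
})

test_that("training error is monotone non-increasing in C", {
  set.seed(42)
  x <- matrix(rnorm(60 * 2), 60, 2)
  y <- rep(c("a", "b", "c"), 20)
  classes <- sort(unique(y))
  sse <- sapply(10^seq(-3, 3, by = 1), function(C) {
    fit <- elm(x, y, n_hidden = 25, C = C, seed = 7)  # same W, b each time
    sum((predict(fit, x, type = "score") - pm_targets(y, classes))^2)
  })
  expect_true(all(diff(sse) <= 1e-8))
})

test_that("kernel ELM with explicit-feature kernels equals feature-space ELM", {
  set.seed(51)
  x <- matrix(rnorm(35 * 4), 35, 4)
  y <- sample(c("a", "b", "c"), 35, replace = TRUE)
  kfit <- kelm(x, y, kernel = elm_kernel("linear"), C = 3)
  Ti <- pm_targets(y, kfit$classes)
  # identity feature map h(x) = x: primal ridge scores
  beta <- t(x) %*% solve(diag(1 / 3, 35) + x %*% t(x), Ti)
  xs <- matrix(rnorm(10 * 4), 10, 4)
  expect_equal(predict(kfit, xs, type = "score"), xs %*% beta,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_identical(predict(kfit, xs[0, , drop = FALSE]), character(0))
})

test_that("RBF kernel ELM interpolates training targets as C grows", {
  set.seed(52)
  x <- matrix(rnorm(20 * 2), 20, 2)
  y <- rep(c("a", "b"), 10)
  kfit <- kelm(x, y, kernel = elm_kernel("rbf", gamma = 2), C = 1e8)
  sc <- predict(kfit, x, type = "score")
  expect_equal(sc, pm_targets(y, kfit$classes), tolerance = 1e-3,
               ignore_attr = TRUE)

  # a non-symmetric kernel is rejected
  expect_error(kelm(x, y, kernel = function(a, b) tcrossprod(a, b) +
                      matrix(rnorm(nrow(a) * nrow(b)), nrow(a))),
               "symmetric")
})

test_that("CELM hidden weights are between-class difference vectors", {
  set.seed(61)
  x <- matrix(rnorm(40 * 3), 40, 3)
  y <- rep(c("a", "b", "c", "d"), 10)
  fit <- celm(x, y, n_hidden = 25, seed = 9)
  for (j in 1:25) {
    a <- fit$pairs[j, 1]; b <- fit$pairs[j, 2]
    expect_false(y[a] == y[b])
    d <- x[a, ] - x[b, ]
    expect_equal(fit$W[j, ], 2 * d / sum(d^2), tolerance = 1e-12)
    # node boundary passes through the pair midpoint
    m <- (x[a, ] + x[b, ]) / 2
    expect_equal(sum(fit$W[j, ] * m) + fit$b[j], 0, tolerance = 1e-12)
  }

  # one sample per class: every weight vector is parallel to x1 - x2
  x2 <- rbind(c(2, 1), c(-1, 3))
  f2 <- celm(x2, c("p", "q"), n_hidden = 8, seed = 2)
  d12 <- x2[1, ] - x2[2, ]
  for (j in 1:8) {
    cr <- f2$W[j, 1] * d12[2] - f2$W[j, 2] * d12[1]
    expect_equal(cr, 0, tolerance = 1e-12)
  }

  task <- gauss2_task(n_per = 100, seed = 62)
  idx <- rep(c(TRUE, FALSE), 100)
  cf <- celm(task$x[idx, ], task$y[idx], n_hidden = 20, seed = 3)
  expect_gte(mean(predict(cf, task$x[!idx, ]) == task$y[!idx]), 0.90)

  expect_error(celm(matrix(1, 4, 2), rep("a", 4), n_hidden = 3), "2 classes")
  # identical cross-class points can never yield a difference vector
  same <- rbind(c(1, 1), c(1, 1))
  expect_error(celm(same, c("a", "b"), n_hidden = 3), "degenerate")
})

test_that("online-sequential ELM equals batch ELM for any chunking", {
  set.seed(71)
  x <- matrix(rnorm(100 * 3), 100, 3)
  y <- sample(c("a", "b", "c"), 100, replace = TRUE)
  L <- 20

  st <- oselm(x[1:50, ], y[1:50], n_hidden = L, seed = 8,
              classes = sort(unique(y)))
  # boosting batch with N0 = L solves the system exactly
  st0 <- oselm(x[1:L, ], y[1:L], n_hidden = L, seed = 8,
               classes = sort(unique(y)))
  H0 <- hidden_output(st0$W, st0$b, elm_activation("sigmoid"), x[1:L, ])
  resid <- H0 %*% st0$beta - pm_targets(y[1:L], st0$classes)
  expect_lt(max(abs(resid)), 1e-6)

  # init beta matches unregularised batch ELM on the same batch
  H50 <- hidden_output(st$W, st$b, elm_activation("sigmoid"), x[1:50, ])
  bb <- solve(t(H50) %*% H50, t(H50) %*% pm_targets(y[1:50], st$classes))
  expect_equal(st$beta, bb, tolerance = 1e-8, ignore_attr = TRUE)

  # five chunks of 10 reproduce the batch solution on all 100
  for (s in seq(51, 100, by = 10)) {
    st <- oselm_update(st, x[s:(s + 9), ], y[s:(s + 9)])
  }
  Hall <- hidden_output(st$W, st$b, elm_activation("sigmoid"), x)
  ball <- solve(t(Hall) %*% Hall, t(Hall) %*% pm_targets(y, st$classes))
  expect_lt(max(abs(st$beta - ball)), 1e-6)

  # one-by-one vs chunked: identical result
  st1 <- oselm(x[1:50, ], y[1:50], n_hidden = L, seed = 8,
               classes = sort(unique(y)))
  for (i in 51:100) {
    st1 <- oselm_update(st1, x[i, , drop = FALSE], y[i])
  }
  expect_lt(max(abs(st1$beta - st$beta)), 1e-6)

  # empty chunk is a no-op; seeds are deterministic
  expect_identical(oselm_update(st, x[0, , drop = FALSE], character(0)), st)
  expect_identical(oselm(x[1:50, ], y[1:50], n_hidden = L, seed = 8),
                   oselm(x[1:50, ], y[1:50], n_hidden = L, seed = 8))

  expect_error(oselm(x[1:10, ], y[1:10], n_hidden = 20), "boosting")
})
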