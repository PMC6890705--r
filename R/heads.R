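# Swappable classifier heads over the CNN feature extractor (the hybrid
# "E-CNN" design).  Only the ELM family is bespoke; SVM, MLP and boosted
# trees are thin adapters over established implementations, and the RBF
# network is a small kmeans-centres + ridge-solve classifier since no
# installed package provides one.

head_kinds <- c("softmax_baseline", "mlp", "rbf_network", "svm_linear",
                "gradient_boosted_trees", "elm", "celm", "oselm", "kelm")

#' Specify a classifier head
#'
#' Hyperparameter defaults follow the published head settings: MLP with
#' one hidden layer of 3 nodes (learning rate 0.3 — recorded, though the
#' underlying `nnet` optimiser is BFGS); RBF network with 100 centres;
#' linear-kernel SVM (one-vs-one multiclass); boosted trees with library
#' defaults; ELM with 100 sigmoid nodes; CELM with 20; OSELM with 180
#' nodes, a 300-sample boosting batch and 10 sequential blocks; kernel
#' ELM with an RBF kernel (its "number of nodes" setting is recorded but
#' has no meaning for a kernel method and is ignored).
#'
#' @param kind one of `"softmax_baseline"`, `"mlp"`, `"rbf_network"`,
#'   `"svm_linear"`, `"gradient_boosted_trees"`, `"elm"`, `"celm"`,
#'   `"oselm"`, `"kelm"`.
#' @param ... kind-specific hyperparameter overrides (see Details).
#' @param seed integer seed for stochastic heads.
#' @return An object of class `head_spec`.
#' @export
head_spec <- function(kind, ..., seed = 1L) {
  if (!kind %in% head_kinds) {
    stop("unknown head kind '", kind, "'; expected one of: ",
         paste(head_kinds, collapse = ", "))
  }
  defaults <- switch(kind,
    softmax_baseline = list(),
    mlp = list(learning_rate = 0.3, hidden_layers = 1L, n_nodes = 3L,
               maxit = 200L),
    rbf_network = list(n_centers = 100L, lambda = 1e-6),
    svm_linear = list(cost = 1),
    gradient_boosted_trees = list(nrounds = 50L, max_depth = 6L, eta = 0.3),
    elm = list(n_nodes = 100L, activation = "sigmoid", C = 1),
    celm = list(n_nodes = 20L, activation = "sigmoid", C = 1),
    oselm = list(n_nodes = 180L, n_boost = 300L, n_blocks = 10L,
                 activation = "sigmoid"),
    kelm = list(kernel = "rbf", C = 1, gamma = NULL, n_nodes = NULL))
  override <- list(...)
  bad <- setdiff(names(override), names(defaults))
  if (length(bad)) {
    stop("unknown hyperparameter(s) for ", kind, " head: ",
         paste(bad, collapse = ", "))
  }
  hp <- utils::modifyList(defaults, override)
  if (kind == "mlp" && hp$hidden_layers != 1L) {
    stop("the MLP head supports exactly one hidden layer")
  }
  structure(list(kind = kind, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "head_spec")
}

#' @export
print.head_spec <- function(x, ...) {
  hp <- vapply(x$hyperparameters,
               function(v) if (is.null(v)) "NULL" else paste(v, collapse = ","),
               "")
  cat("<head_spec> ", x$kind,
      if (length(hp)) paste0(" (", paste(names(hp), hp, sep = "=",
                                         collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Instantiate an unfitted classifier head
#'
#' Returns a fit/predict pair shared by every head kind, so the hybrid
#' model can swap heads freely.
#'
#' @param spec a [head_spec()].
#' @return List with `fit = function(x, y)` and
#'   `predict = function(fit, x)` (returns labels).
#' @export
make_head <- function(spec) {
  stopifnot(inherits(spec, "head_spec"))
  hp <- spec$hyperparameters
  seed <- spec$seed
  switch(spec$kind,
    softmax_baseline = list(
      fit = function(x, y) stop("the softmax baseline head is not refitted; ",
                                "it reuses the backbone's own classifier"),
      predict = function(fit, x) stop("not refitted")),
    elm = list(
      fit = function(x, y) elm(x, y, n_hidden = hp$n_nodes, C = hp$C,
                               activation = hp$activation, seed = seed),
      predict = function(fit, x) predict(fit, x)),
    celm = list(
      fit = function(x, y) celm(x, y, n_hidden = hp$n_nodes, C = hp$C,
                                activation = hp$activation, seed = seed),
      predict = function(fit, x) predict(fit, x)),
    kelm = list(
      fit = function(x, y) kelm(x, y,
                                kernel = elm_kernel(hp$kernel,
                                                    gamma = hp$gamma),
                                C = hp$C),
      predict = function(fit, x) predict(fit, x)),
    oselm = list(
      fit = function(x, y) {
        n <- nrow(x)
        n0 <- min(hp$n_boost, n)
        if (n0 < hp$n_nodes) {
          stop("OSELM boosting batch (", n0, ") smaller than the hidden ",
               "layer (", hp$n_nodes, ")")
        }
        st <- oselm(x[seq_len(n0), , drop = FALSE], y[seq_len(n0)],
                    n_hidden = hp$n_nodes, activation = hp$activation,
                    seed = seed, classes = sort(unique(as.character(y))))
        rest <- setdiff(seq_len(n), seq_len(n0))
        if (length(rest)) {
          chunks <- split(rest, cut(seq_along(rest), hp$n_blocks,
                                    labels = FALSE))
          for (ch in chunks) {
            st <- oselm_update(st, x[ch, , drop = FALSE], y[ch])
          }
        }
        st
      },
      predict = function(fit, x) predict(fit, x)),
    mlp = list(
      fit = function(x, y) {
        classes <- sort(unique(as.character(y)))
        Y <- nnet::class.ind(factor(y, levels = classes))
        fit <- with_seed(seed,
          nnet::nnet(as.matrix(x), Y, size = hp$n_nodes, softmax = TRUE,
                     maxit = hp$maxit, trace = FALSE))
        list(fit = fit, classes = classes)
      },
      predict = function(fit, x) {
        p <- predict(fit$fit, as.matrix(x))
        fit$classes[max.col(p, ties.method = "first")]
      }),
    svm_linear = list(
      fit = function(x, y) with_seed(seed,
        e1071::svm(as.matrix(x), factor(y), kernel = "linear",
                   cost = hp$cost, scale = FALSE)),
      predict = function(fit, x) as.character(predict(fit, as.matrix(x)))),
    gradient_boosted_trees = list(
      fit = function(x, y) {
        classes <- sort(unique(as.character(y)))
        yi <- match(as.character(y), classes) - 1L
        dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = yi)
        fit <- with_seed(seed,
          xgboost::xgb.train(params = list(objective = "multi:softmax",
                                           num_class = length(classes),
                                           max_depth = hp$max_depth,
                                           eta = hp$eta),
                             data = dtrain, nrounds = hp$nrounds,
                             verbose = 0))
        list(fit = fit, classes = classes)
      },
      predict = function(fit, x) {
        p <- predict(fit$fit, xgboost::xgb.DMatrix(as.matrix(x)))
        fit$classes[as.integer(p) + 1L]
      }),
    rbf_network = list(
      fit = function(x, y) {
        x <- as.matrix(x)
        classes <- sort(unique(as.character(y)))
        k <- min(hp$n_centers, nrow(unique(x)))
        centers <- with_seed(seed, {
          if (k < nrow(unique(x))) {
            stats::kmeans(x, centers = k, nstart = 1, iter.max = 50)$centers
          } else unique(x)
        })
        d2 <- outer(rowSums(centers^2), rowSums(centers^2), "+") -
          2 * tcrossprod(centers)
        sigma2 <- stats::median(d2[upper.tri(d2)])
        if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- 1
        Phi <- cbind(1, exp(-(outer(rowSums(x^2), rowSums(centers^2), "+") -
                                2 * tcrossprod(x, centers)) / sigma2))
        Ti <- encode_targets(y, classes)
        Wout <- spd_solve(crossprod(Phi) + diag(hp$lambda, ncol(Phi)),
                          crossprod(Phi, Ti))
        list(centers = centers, sigma2 = sigma2, W = Wout, classes = classes)
      },
      predict = function(fit, x) {
        x <- as.matrix(x)
        Phi <- cbind(1, exp(-(outer(rowSums(x^2),
                                    rowSums(fit$centers^2), "+") -
                                2 * tcrossprod(x, fit$centers)) / fit$sigma2))
        decode_scores(Phi %*% fit$W, fit$classes)
      })
  )
}

#' Fit a hybrid CNN + classifier-head model
#'
#' Extracts fully-connected-layer features from the trained backbone for
#' every training image and fits the requested head on them.  The
#' `softmax_baseline` head performs no refit: the hybrid simply reuses
#' the backbone's own fully-connected + softmax classifier, and its
#' predictions are identical to [predict.myxo_cnn()].
#'
#' @param backbone a trained [cnn_fit()] model.
#' @param ds a [labeled_dataset()] (or input tensor with `y` given).
#' @param head a [head_spec()] (or a head kind name).
#' @param labels `"genus"` or `"suborder"`.
#' @param y optional explicit labels.
#' @param standardize standardise features before the head (off by
#'   default: features are fed to the head exactly as extracted).
#' @return An object of class `ecnn`.
#' @export
ecnn <- function(backbone, ds, head = head_spec("elm"),
                 labels = c("genus", "suborder"), y = NULL,
                 standardize = FALSE) {
  stopifnot(inherits(backbone, "myxo_cnn"))
  labels <- match.arg(labels)
  if (is.character(head)) head <- head_spec(head)
  stopifnot(inherits(head, "head_spec"))
  if (is.null(y)) {
    if (!inherits(ds, "myxo_dataset")) stop("y is required for plain arrays")
    y <- ds[[labels]]
  }
  y <- as.character(y)
  center <- NULL; scale <- NULL; head_fit <- NULL
  classes <- sort(unique(y))
  if (head$kind != "softmax_baseline") {
    feats <- extract_features(backbone, ds)
    if (standardize) {
      center <- colMeans(feats)
      scale <- pmax(apply(feats, 2, stats::sd), 1e-12)
      feats <- sweep(sweep(feats, 2, center), 2, scale, "/")
    }
    head_fit <- make_head(head)$fit(feats, y)
  }
  structure(list(backbone = backbone, head_spec = head,
                 head_fit = head_fit, classes = classes,
                 labels = labels, center = center, scale = scale),
            class = "ecnn")
}

#' @export
print.ecnn <- function(x, ...) {
  cat("<ecnn> backbone configuration ", x$backbone$config$table3_config,
      " + ", x$head_spec$kind, " head, ", length(x$classes),
      " classes (", x$labels, ")\n", sep = "")
  invisible(x)
}

#' Predict from a hybrid model
#'
#' @param object an [ecnn()] model.
#' @param newdata images as in [predict.myxo_cnn()].
#' @param ... ignored.
#' @return Character vector of predicted labels.
#' @export
predict.ecnn <- function(object, newdata, ...) {
  if (object$head_spec$kind == "softmax_baseline") {
    p <- predict(object$backbone, newdata, type = "class")
    if (object$labels == "suborder" &&
        object$backbone$label_type == "suborder") return(p)
    return(p)
  }
  feats <- extract_features(object$backbone, newdata)
  if (!is.null(object$center)) {
    feats <- sweep(sweep(feats, 2, object$center), 2, object$scale, "/")
  }
  make_head(object$head_spec)$predict(object$head_fit, feats)
}
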