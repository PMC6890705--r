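# Cross-validation and confusion-matrix metrics.

#' Deterministic k-fold partition
#'
#' Assigns every sample to exactly one of `k` folds.  In stratified mode
#' (the default for classification) each class's samples are spread round-
#' robin over the folds, so per-class fold counts differ by at most one;
#' unstratified mode balances only the total fold sizes.
#'
#' @param labels label vector (used for stratification and length).
#' @param k number of folds.
#' @param seed integer seed; the partition is deterministic given it.
#' @param stratified balance class proportions per fold.
#' @return An object of class `fold_plan`: fields `assignments` (fold id
#'   per sample), `k`, `seed`, `stratified`.
#' @export
kfold_split <- function(labels, k = 10L, seed = 1L, stratified = TRUE) {
  n <- length(labels)
  k <- as.integer(k)
  if (n < k) stop("cannot make ", k, " folds from ", n, " samples")
  assignments <- integer(n)
  with_seed(seed, {
    if (stratified) {
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        if (!length(idx)) stop("stratified split with an empty class")
        idx <- idx[sample.int(length(idx))]
        start <- sample.int(k, 1L)
        assignments[idx] <-
          ((start - 1L + seq_along(idx) - 1L) %% k) + 1L
      }
    } else {
      assignments <- rep_len(seq_len(k), n)[sample.int(n)]
    }
  })
  structure(list(assignments = assignments, k = k, seed = as.integer(seed),
                 stratified = stratified),
            class = "fold_plan")
}

#' Classification accuracy from a confusion matrix
#'
#' The fraction of correctly detected instances over all instances:
#' the diagonal sum of the confusion matrix divided by its grand total.
#'
#' @param confusion square non-negative count matrix, rows = true class,
#'   columns = predicted class.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (!nrow(confusion) || nrow(confusion) != ncol(confusion)) {
    stop("confusion must be a non-empty square matrix")
  }
  if (any(confusion < 0)) stop("confusion counts must be non-negative")
  total <- sum(confusion)
  if (total == 0) stop("confusion matrix is all zero")
  sum(diag(confusion)) / total
}

#' Per-class rates from a confusion matrix
#'
#' True-positive rate (= recall) is the diagonal count over the class's
#' row total; the false-positive count is the class's column total minus
#' the diagonal, and the false-positive rate divides it by the number of
#' samples truly in other classes; precision is the diagonal count over
#' the column total.  Empty denominators yield `NA` rather than errors.
#'
#' @param confusion square count matrix (rows = true, columns = predicted).
#' @return data.frame with one row per class: `class`, `tp`, `fp`,
#'   `tp_rate`, `fp_rate`, `precision`, `recall`.
#' @export
class_rates <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  cls <- rownames(confusion)
  if (is.null(cls)) cls <- as.character(seq_len(nrow(confusion)))
  tp <- diag(confusion)
  row_tot <- rowSums(confusion)
  col_tot <- colSums(confusion)
  grand <- sum(confusion)
  fp <- col_tot - tp
  safe_div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  data.frame(class = cls, tp = as.integer(tp), fp = as.integer(fp),
             tp_rate = safe_div(tp, row_tot),
             fp_rate = safe_div(fp, grand - row_tot),
             precision = safe_div(tp, col_tot),
             recall = safe_div(tp, row_tot),
             row.names = NULL)
}

#' k-fold cross-validation of a classification pipeline
#'
#' For each fold, a fresh pipeline is built by `pipeline_factory`, fitted
#' on the other `k - 1` folds (so any trainable feature extractor is
#' refitted per fold — no leakage), and used to predict the held-out
#' fold.  Results are pooled into one confusion matrix; per-fold
#' accuracies are also reported.
#'
#' @param pipeline_factory `function()` returning a list with elements
#'   `fit = function(ds)` (returns a fitted object) and
#'   `predict = function(fit, ds)` (returns predicted labels).
#' @param ds a [labeled_dataset()].
#' @param k number of folds.
#' @param seed seed for the fold plan.
#' @param labels which labels to evaluate: `"genus"` or `"suborder"`.
#' @param stratified stratify the folds by class (default).
#' @param verbose print per-fold progress.
#' @return An object of class `eval_report`: `confusion` (pooled counts),
#'   `accuracy`, `per_class` (see [class_rates()]), `fold_accuracy`,
#'   `mean_fold_accuracy`, `fold_plan`.
#' @export
cross_validate <- function(pipeline_factory, ds, k = 10L, seed = 1L,
                           labels = c("genus", "suborder"),
                           stratified = TRUE, verbose = FALSE) {
  labels <- match.arg(labels)
  y <- ds[[labels]]
  classes <- sort(unique(y))
  singletons <- names(which(table(y) == 1L))
  if (length(singletons)) {
    warning("classes with a single sample can never be both trained and ",
            "tested: ", paste(singletons, collapse = ", "))
  }
  plan <- kfold_split(y, k = k, seed = seed, stratified = stratified)
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  fold_acc <- numeric(k); fold_n <- integer(k)
  for (f in seq_len(k)) {
    test <- plan$assignments == f
    train_y <- y[!test]
    if (!any(test)) next
    missing <- setdiff(unique(y[test]), unique(train_y))
    if (length(missing)) {
      stop("fold ", f, " training split is missing class(es) ",
           paste(missing, collapse = ", "),
           "; use stratified folds or merge small classes")
    }
    pipe <- pipeline_factory()
    fit <- pipe$fit(ds[!test])
    pred <- pipe$predict(fit, ds[test])
    truth <- y[test]
    for (i in seq_along(pred)) {
      confusion[truth[i], pred[i]] <- confusion[truth[i], pred[i]] + 1L
    }
    fold_acc[f] <- mean(pred == truth)
    fold_n[f] <- sum(test)
    if (verbose) {
      message(sprintf("fold %2d/%d  n=%3d  accuracy %.3f",
                      f, k, fold_n[f], fold_acc[f]))
    }
  }
  structure(list(confusion = confusion,
                 accuracy = accuracy(confusion),
                 per_class = class_rates(confusion),
                 fold_accuracy = fold_acc,
                 fold_n = fold_n,
                 mean_fold_accuracy = sum(fold_acc * fold_n) / sum(fold_n),
                 fold_plan = plan,
                 labels = labels),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", sum(x$confusion), " samples, ",
      nrow(x$confusion), " classes (", x$labels, ")\n",
      "pooled accuracy ", sprintf("%.4f", x$accuracy),
      "; per-fold mean ", sprintf("%.4f", x$mean_fold_accuracy),
      "\n", sep = "")
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits three files under `dir`: `per_class.csv` (per-class metrics),
#' `report.json` (accuracy, per-fold accuracies, fold assignments,
#' confusion matrix) and `confusion.txt` (an aligned plain-text confusion
#' matrix).
#'
#' @param report an [cross_validate()] report.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_class, file.path(dir, "per_class.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(accuracy = report$accuracy,
         mean_fold_accuracy = report$mean_fold_accuracy,
         fold_accuracy = report$fold_accuracy,
         fold_assignments = report$fold_plan$assignments,
         classes = rownames(report$confusion),
         confusion = unname(apply(report$confusion, 1, as.integer,
                                  simplify = FALSE))),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  txt <- utils::capture.output(print(report$confusion))
  writeLines(txt, file.path(dir, "confusion.txt"))
  invisible(dir)
}

#' Plot a pooled confusion matrix
#'
#' Greyscale heat map of the row-normalised confusion matrix, true
#' classes on the vertical axis.
#'
#' @param x an [cross_validate()] report.
#' @param ... ignored.
#' @export
plot.eval_report <- function(x, ...) {
  cm <- x$confusion
  rn <- cm / pmax(rowSums(cm), 1)
  k <- nrow(cm)
  op <- graphics::par(mar = c(6, 6, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(k), seq_len(k), t(rn[k:1, , drop = FALSE]),
                  col = grDevices::grey.colors(64, start = 1, end = 0),
                  axes = FALSE,
                  xlab = "", ylab = "")
  graphics::axis(1, at = seq_len(k), labels = colnames(cm), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(k), labels = rev(rownames(cm)), las = 2,
                 cex.axis = 0.7)
  graphics::title(sprintf("pooled accuracy %.3f", x$accuracy))
  invisible(x)
}
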