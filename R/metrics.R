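#' Confusion matrix of a model on a dataset
#'
#' Rows are true labels, columns predicted labels; prediction is the
#' argmax class score with ties broken toward the lowest class index.
#'
#' @param model an `sresnet_model`.
#' @param ds a labeled [herd_dataset()] with the model's class count.
#' @return integer matrix with class-name dimnames, class
#'   `confusion_matrix`.
#' @export
confusion <- function(model, ds) {
  stopifnot(inherits(ds, "herd_dataset"))
  if (nrow(ds$frames) == 0) stop("empty dataset")
  C <- model$spec$num_classes
  if (length(ds$class_names) != C)
    stop("dataset has ", length(ds$class_names), " classes, model ", C)
  pred <- predict_classes(model, ds)
  cm <- matrix(0L, C, C, dimnames = list(true = ds$class_names,
                                         predicted = ds$class_names))
  for (i in seq_along(pred))
    cm[ds$frames$label[i] + 1L, pred[i] + 1L] <-
      cm[ds$frames$label[i] + 1L, pred[i] + 1L] + 1L
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Classification metrics from a confusion matrix
#'
#' Overall accuracy is the trace over the total count. Per class,
#' one-vs-rest counts give sensitivity `TP / (TP + FN)`, precision
#' `TP / (TP + FP)`, and a per-class one-vs-rest accuracy
#' `(TP + TN) / total` (the per-behavior "accuracy" often reported
#' alongside multiclass accuracy; the two differ in general). A zero
#' denominator yields `NA`, not 0, so undefined values cannot silently
#' distort averages.
#'
#' @param cm a square count matrix, rows = true, columns = predicted.
#' @return a `metrics_report`: `accuracy`, and a `per_class` data.frame
#'   with sensitivity, precision, one-vs-rest accuracy and support.
#' @export
metrics <- function(cm) {
  cm <- unclass(cm)
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), all(cm >= 0))
  total <- sum(cm)
  if (total == 0) stop("confusion matrix is empty")
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  per_class <- data.frame(
    class = if (!is.null(rownames(cm))) rownames(cm)
            else paste0("class", seq_len(nrow(cm)) - 1L),
    sensitivity = safe_div(tp, tp + fn),
    precision = safe_div(tp, tp + fp),
    ovr_accuracy = (tp + tn) / total,
    support = rowSums(cm),
    row.names = NULL)
  structure(list(accuracy = sum(tp) / total, per_class = per_class,
                 total = total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy: %.4f (n = %d)\n", x$accuracy, x$total))
  print(x$per_class, digits = 4)
  invisible(x)
}

#' Cohen's kappa for two label sequences
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with expected
#' agreement from the product of the raters' marginal distributions.
#' When both raters are constant and identical (`p_e = 1`) agreement is
#' perfect by construction and kappa is defined as 1.
#'
#' @param a,b equal-length vectors of labels (any atomic type).
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("label sequences differ in length")
  if (length(a) == 0) stop("empty label sequences")
  lev <- sort(unique(c(a, b)))
  ta <- table(factor(a, lev)) / length(a)
  tb <- table(factor(b, lev)) / length(b)
  po <- mean(a == b)
  pe <- sum(ta * tb)
  if (1 - pe < .Machine$double.eps) return(1)
  (po - pe) / (1 - pe)
}

#' Repeat the full train/evaluate experiment across seeds
#'
#' Re-runs a user-supplied experiment once per seed (each run should
#' re-split and re-train internally from its seed) and aggregates the
#' runs' scalar metrics as mean and standard deviation across repeats,
#' reported in the conventional "x% (+/- y%)" style.
#'
#' @param run_fn function `(seed) -> named numeric vector` of metrics
#'   for one run (e.g. `c(accuracy = ...)`).
#' @param seeds integer vector, one seed per repeat.
#' @return a `repeat_report`: `runs` (matrix, one row per run), `mean`
#'   and `sd` (sample standard deviation across the repeats; 0 for a
#'   single run), `n_repeats`.
#' @export
repeat_experiment <- function(run_fn, seeds) {
  if (length(seeds) < 1) stop("need at least one seed")
  runs <- lapply(seeds, function(s) {
    v <- run_fn(s)
    if (is.null(names(v))) stop("run_fn must return a named numeric vector")
    v
  })
  runs <- do.call(rbind, runs)
  rownames(runs) <- paste0("seed", seeds)
  mu <- colMeans(runs)
  sdv <- if (nrow(runs) > 1) apply(runs, 2, stats::sd) else rep(0, ncol(runs))
  names(sdv) <- colnames(runs)
  structure(list(runs = runs, mean = mu, sd = sdv, seeds = seeds,
                 n_repeats = length(seeds)),
            class = "repeat_report")
}

#' @export
print.repeat_report <- function(x, ...) {
  cat(x$n_repeats, "repeats (seeds:", paste(x$seeds, collapse = ", "), ")\n")
  for (nm in names(x$mean))
    cat(sprintf("  %-12s %.2f%% (+/- %.2f%%)\n", nm,
                100 * x$mean[nm], 100 * x$sd[nm]))
  invisible(x)
}

#' Write a confusion matrix as CSV
#' @param cm a `confusion_matrix`.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  utils::write.csv(as.data.frame(unclass(cm)), path, row.names = TRUE)
  invisible(path)
}
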