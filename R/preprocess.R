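#' SMOTE oversampling of minority behavior classes
#'
#' Synthetic minority oversampling: each synthetic frame is
#' `x + s * (x_nn - x)` with `s ~ U(0, 1)`, where `x` is a random frame
#' of the minority class and `x_nn` one of its `k` nearest same-class
#' neighbors (Euclidean distance on the raw, unstandardized features).
#' Original frames are preserved; synthetic frames are appended until
#' each class reaches its target count.
#'
#' @param ds a [herd_dataset()], raw (pre-standardization) features.
#' @param k number of nearest neighbors considered per source frame.
#' @param target_counts named or ordered integer vector, one entry per
#'   class, each at least the current class count. Default: bring every
#'   class up to the current majority count.
#' @param seed optional integer seed for reproducible draws.
#' @return a [herd_dataset()] whose per-class counts equal
#'   `target_counts`. Attribute `"smote_provenance"` records, for every
#'   synthetic frame, the row indices of `x` and `x_nn` in the returned
#'   frames and the interpolation factor `s`.
#' @export
smote_oversample <- function(ds, k = 5, target_counts = NULL, seed = NULL) {
  stopifnot(inherits(ds, "herd_dataset"))
  if (k <= 0) stop("k must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  cnt <- class_counts(ds)
  if (is.null(target_counts)) target_counts <- rep(max(cnt), length(cnt))
  if (length(target_counts) != length(cnt))
    stop("target_counts must have one entry per class")
  target_counts <- as.integer(target_counts)
  if (any(target_counts < cnt))
    stop("target_counts below current counts for class(es): ",
         paste(ds$class_names[target_counts < cnt], collapse = ", "))
  X <- feature_matrix(ds)
  lab <- ds$frames$label
  new_rows <- list()
  prov <- list()
  for (ci in seq_along(cnt)) {
    deficit <- target_counts[ci] - cnt[ci]
    if (deficit == 0) next
    idx <- which(lab == ci - 1L)
    if (length(idx) < k + 1)
      stop("class '", ds$class_names[ci], "' has ", length(idx),
           " samples; SMOTE with k = ", k, " needs at least ", k + 1)
    Xi <- X[idx, , drop = FALSE]
    D <- as.matrix(stats::dist(Xi))
    diag(D) <- Inf
    # k nearest same-class neighbors of every class member
    nn <- apply(D, 1L, function(dr) order(dr)[seq_len(k)])  # k x n_i
    src <- sample.int(length(idx), deficit, replace = TRUE)
    pick <- sample.int(k, deficit, replace = TRUE)
    nbr <- nn[cbind(pick, src)]
    s <- stats::runif(deficit)
    syn <- Xi[src, , drop = FALSE] +
      s * (Xi[nbr, , drop = FALSE] - Xi[src, , drop = FALSE])
    df <- as.data.frame(syn)
    names(df) <- hp_feature_names()
    df$label <- ci - 1L
    new_rows[[length(new_rows) + 1L]] <- df
    prov[[length(prov) + 1L]] <- data.frame(
      class = ci - 1L, source = idx[src], neighbor = idx[nbr], s = s)
  }
  out <- ds$frames
  if (length(new_rows)) out <- rbind(out, do.call(rbind, new_rows))
  res <- herd_dataset(out, ds$class_names, ds$standardization)
  attr(res, "smote_provenance") <-
    if (length(prov)) do.call(rbind, prov) else NULL
  res
}

#' Standardize feature columns with training-set statistics
#'
#' Each feature i is transformed to `(x - mu_i) / sigma_i` where `mu_i`
#' and `sigma_i` are the mean and *population* standard deviation
#' (divisor n, not n - 1) computed on the training partition only. All
#' other partitions are transformed with the training statistics, so no
#' information leaks from test data into the preprocessing.
#'
#' Constant features (sigma = 0) are mapped to zero by flooring sigma at
#' `1e-8` rather than dividing by zero.
#'
#' @param train training [herd_dataset()].
#' @param others optional list of further [herd_dataset()]s (validation,
#'   test, ...) transformed with the training statistics.
#' @return list with `train`, `others` (same shape as the input list),
#'   `mu`, `sigma`.
#' @export
standardize_features <- function(train, others = list()) {
  stopifnot(inherits(train, "herd_dataset"))
  if (nrow(train$frames) == 0) stop("training partition is empty")
  if (inherits(others, "herd_dataset")) others <- list(others)
  X <- feature_matrix(train)
  n <- nrow(X)
  mu <- colMeans(X)
  sigma <- sqrt(colMeans(X^2) - mu^2)          # population form, divisor n
  sigma <- pmax(sigma, 1e-8)
  std <- list(mu = mu, sigma = sigma)
  apply_std <- function(ds) {
    F <- ds$frames
    F[, hp_feature_names()] <-
      sweep(sweep(feature_matrix(ds), 2, mu), 2, sigma, "/")
    herd_dataset(F, ds$class_names, std)
  }
  list(train = apply_std(train), others = lapply(others, apply_std),
       mu = mu, sigma = sigma)
}

#' Random train/test split of a dataset
#'
#' Frames are partitioned at random in a `ratio : (1 - ratio)` proportion.
#' By default the split is stratified by behavior class so every class is
#' represented in both partitions in proportion to its frequency.
#'
#' @param ds a [herd_dataset()].
#' @param ratio training fraction, strictly between 0 and 1. Default 0.7.
#' @param seed optional integer seed.
#' @param stratified stratify by class (default TRUE).
#' @return list with `train` and `test` datasets; disjoint, union = input.
#' @export
split_dataset <- function(ds, ratio = 0.7, seed = NULL, stratified = TRUE) {
  stopifnot(inherits(ds, "herd_dataset"))
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  n <- nrow(ds$frames)
  if (n < 2) stop("need at least 2 frames to split")
  if (!is.null(seed)) set.seed(seed)
  if (stratified) {
    tr_idx <- integer(0)
    for (ci in seq_along(ds$class_names) - 1L) {
      idx <- which(ds$frames$label == ci)
      if (!length(idx)) next
      n_tr <- round(ratio * length(idx))
      n_tr <- min(max(n_tr, if (length(idx) > 1) 1L else 0L), length(idx))
      tr_idx <- c(tr_idx, sample(idx, n_tr))
    }
  } else {
    tr_idx <- sample.int(n, round(ratio * n))
  }
  mk <- function(i) herd_dataset(ds$frames[i, , drop = FALSE],
                                 ds$class_names, ds$standardization)
  list(train = mk(sort(tr_idx)), test = mk(setdiff(seq_len(n), tr_idx)))
}
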