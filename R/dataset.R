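#' Herd behavior dataset
#'
#' Container for labeled 10-feature behavior frames. Frames live in a
#' data.frame with columns `ax,ay,az,gx,gy,gz,mx,my,mz,d,label`; `label`
#' is a 0-based class index into `class_names`. If the dataset has been
#' standardized, the per-feature training-set mean and standard deviation
#' used for the transform are carried in `standardization`.
#'
#' @param frames data.frame with the ten feature columns and `label`.
#' @param class_names character vector of behavior names; class index i
#'   (0-based) maps to `class_names[i + 1]`.
#' @param standardization optional list with numeric vectors `mu` and
#'   `sigma` of length 10, recording the transform already applied.
#' @return a `herd_dataset` object.
#' @seealso [generate_synthetic_herd()], [smote_oversample()],
#'   [standardize_features()], [split_dataset()]
#' @export
herd_dataset <- function(frames, class_names, standardization = NULL) {
  frames <- as.data.frame(frames)
  need <- c(hp_feature_names(), "label")
  if (!all(need %in% names(frames)))
    stop("frames must have columns ", paste(need, collapse = ","))
  frames <- frames[, need]
  if (nrow(frames) > 0) {
    if (any(!is.finite(as.matrix(frames[, hp_feature_names()]))))
      stop("non-finite feature values")
    lab <- frames$label
    if (any(lab != floor(lab)) || any(lab < 0) || any(lab >= length(class_names)))
      stop("labels must be integers in 0..", length(class_names) - 1)
    frames$label <- as.integer(lab)
  }
  if (!is.null(standardization))
    stopifnot(length(standardization$mu) == 10, length(standardization$sigma) == 10)
  structure(list(frames = frames, class_names = as.character(class_names),
                 standardization = standardization),
            class = "herd_dataset")
}

#' @export
print.herd_dataset <- function(x, ...) {
  cat("herd_dataset:", nrow(x$frames), "frames,",
      length(x$class_names), "classes\n")
  tab <- class_counts(x)
  for (i in seq_along(tab))
    cat(sprintf("  %-20s %d\n", names(tab)[i], tab[i]))
  cat(if (is.null(x$standardization)) "  raw features\n"
      else "  standardized features\n")
  invisible(x)
}

#' Per-class frame counts
#' @param ds a [herd_dataset()].
#' @return named integer vector in class order.
#' @export
class_counts <- function(ds) {
  stopifnot(inherits(ds, "herd_dataset"))
  cnt <- tabulate(ds$frames$label + 1L, nbins = length(ds$class_names))
  names(cnt) <- ds$class_names
  cnt
}

#' Feature matrix of a dataset
#' @param ds a [herd_dataset()].
#' @return numeric matrix, one row per frame, 10 columns.
#' @export
feature_matrix <- function(ds) {
  stopifnot(inherits(ds, "herd_dataset"))
  as.matrix(ds$frames[, hp_feature_names()])
}

#' Read / write behavior frames as CSV
#'
#' The on-disk format is one frame per row with header
#' `ax,ay,az,gx,gy,gz,mx,my,mz,d,label`, UTF-8, `.` decimal separator.
#'
#' @param ds a [herd_dataset()].
#' @param path file path.
#' @param class_names class names for the labels found in the file; when
#'   `NULL`, classes `0..max(label)` are named `class0`, `class1`, ...
#' @return `write_frames_csv` returns `path` invisibly;
#'   `read_frames_csv` returns a [herd_dataset()].
#' @export
write_frames_csv <- function(ds, path) {
  stopifnot(inherits(ds, "herd_dataset"))
  utils::write.csv(ds$frames, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_frames_csv
#' @export
read_frames_csv <- function(path, class_names = NULL) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (is.null(class_names)) {
    ncls <- if (nrow(df)) max(df$label) + 1L else 0L
    class_names <- paste0("class", seq_len(ncls) - 1L)
  }
  herd_dataset(df, class_names)
}

#' Read GPS fixes from CSV
#'
#' Expects header `t,lat,lon` (seconds since epoch, decimal degrees).
#'
#' @param path file path.
#' @return data.frame with columns `t`, `lat`, `lon`.
#' @export
read_gps_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("t", "lat", "lon") %in% names(df)))
    stop("GPS CSV must have columns t,lat,lon")
  if (any(!is.finite(as.matrix(df[, c("t", "lat", "lon")]))))
    stop("non-finite GPS values")
  if (any(abs(df$lat) > 90) || any(df$lon <= -180 | df$lon > 180))
    stop("GPS coordinates out of range")
  df[, c("t", "lat", "lon")]
}
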