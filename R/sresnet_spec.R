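#' @keywords internal
layer_spec <- function(name, kind, in_ch, out_ch, k = 3L, stride = 1L,
                       has_bias = TRUE, has_bn = (kind == "conv1d"),
                       activation = "relu") {
  stopifnot(kind %in% c("conv1d", "fc"), in_ch >= 1, out_ch >= 1,
            stride >= 1, activation %in% c("relu", "none"))
  if (kind == "conv1d" && !k %in% c(1L, 3L))
    stop("conv kernel must be 1 or 3")
  list(name = name, kind = kind, in_ch = as.integer(in_ch),
       out_ch = as.integer(out_ch), k = as.integer(if (kind == "fc") 1L else k),
       stride = as.integer(stride), has_bias = has_bias, has_bn = has_bn,
       activation = activation)
}

#' Build an S-ResNet architecture specification
#'
#' The single-frame residual classifier: an initial 1-D convolution
#' lifting the 1-channel, length-10 feature sequence to `conv1` channels,
#' two residual blocks (two kernel-3 convolutions plus a kernel-1
#' shortcut each, batch-normalized, ReLU-activated), global average
#' pooling over the sequence axis, and a two-layer fully connected head.
#' All convolutions use stride 1 with symmetric zero padding so the
#' sequence length is preserved, which keeps the residual additions
#' shape-compatible.
#'
#' @param widths named integer vector of channel widths:
#'   `conv1`, `b1_conva`, `b1_out`, `b2_conva`, `b2_out`, `fc1`.
#'   `b*_out` is the shared output width of the block's second
#'   convolution and its shortcut (they must match for the residual add).
#'   Default `c(32, 64, 64, 128, 128, 64)`, the 1.0x model.
#' @param input_length number of features along the sequence axis (10).
#' @param num_classes behavior classes in the head.
#' @param head_relu apply ReLU between the two head layers (default
#'   FALSE: the head is a plain affine composition).
#' @return a `model_spec` object (ordered layer list + metadata).
#' @export
build_sresnet <- function(widths = NULL, input_length = 10, num_classes = 4,
                          head_relu = FALSE) {
  def <- c(conv1 = 32L, b1_conva = 64L, b1_out = 64L,
           b2_conva = 128L, b2_out = 128L, fc1 = 64L)
  if (is.null(widths)) widths <- def
  if (is.null(names(widths)) || !all(names(def) %in% names(widths)))
    stop("widths must be named: ", paste(names(def), collapse = ", "))
  w <- as.integer(widths[names(def)])
  if (any(w < 1)) stop("all widths must be >= 1")
  layers <- list(
    layer_spec("conv1",    "conv1d", 1L,   w[1]),
    layer_spec("b1_conva", "conv1d", w[1], w[2]),
    layer_spec("b1_convb", "conv1d", w[2], w[3], activation = "none"),
    layer_spec("b1_short", "conv1d", w[1], w[3], k = 1L, activation = "none"),
    layer_spec("b2_conva", "conv1d", w[3], w[4]),
    layer_spec("b2_convb", "conv1d", w[4], w[5], activation = "none"),
    layer_spec("b2_short", "conv1d", w[3], w[5], k = 1L, activation = "none"),
    layer_spec("fc1", "fc", w[5], w[6], has_bn = FALSE,
               activation = if (head_relu) "relu" else "none"),
    layer_spec("fc2", "fc", w[6], as.integer(num_classes), has_bn = FALSE,
               activation = "none"))
  names(layers) <- vapply(layers, `[[`, "", "name")
  spec <- structure(list(layers = layers,
                         input_length = as.integer(input_length),
                         num_classes = as.integer(num_classes),
                         head_relu = isTRUE(head_relu)),
                    class = "model_spec")
  validate_model_spec(spec)
  spec
}

#' Validate S-ResNet structural invariants
#'
#' Checks the residual wiring: within each block the second convolution
#' and the shortcut must agree in output width (the residual add) and the
#' first convolution and the shortcut must agree in input width; the head
#' must end at `num_classes`.
#'
#' @param spec a `model_spec`.
#' @return `spec` invisibly; errors name the offending layer pair.
#' @export
validate_model_spec <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  L <- spec$layers
  for (blk in c("b1", "b2")) {
    a <- L[[paste0(blk, "_conva")]]; b <- L[[paste0(blk, "_convb")]]
    s <- L[[paste0(blk, "_short")]]
    if (b$out_ch != s$out_ch)
      stop("residual width mismatch: ", b$name, ".out (", b$out_ch,
           ") != ", s$name, ".out (", s$out_ch, ")")
    if (a$in_ch != s$in_ch)
      stop("block input width mismatch: ", a$name, ".in (", a$in_ch,
           ") != ", s$name, ".in (", s$in_ch, ")")
    if (a$out_ch != b$in_ch)
      stop("block internal width mismatch: ", a$name, ".out (", a$out_ch,
           ") != ", b$name, ".in (", b$in_ch, ")")
  }
  if (L$conv1$out_ch != L$b1_conva$in_ch)
    stop("width mismatch: conv1.out != b1_conva.in")
  if (L$b1_convb$out_ch != L$b2_conva$in_ch)
    stop("width mismatch: b1 output != b2_conva.in")
  if (L$b2_convb$out_ch != L$fc1$in_ch)
    stop("width mismatch: b2 output != fc1.in")
  if (L$fc1$out_ch != L$fc2$in_ch)
    stop("width mismatch: fc1.out != fc2.in")
  if (L$fc2$out_ch != spec$num_classes)
    stop("fc2.out must equal num_classes")
  invisible(spec)
}

#' Channel widths of a specification
#' @param spec a `model_spec`.
#' @return named integer vector in `build_sresnet()` width order.
#' @export
spec_widths <- function(spec) {
  L <- spec$layers
  c(conv1 = L$conv1$out_ch, b1_conva = L$b1_conva$out_ch,
    b1_out = L$b1_convb$out_ch, b2_conva = L$b2_conva$out_ch,
    b2_out = L$b2_convb$out_ch, fc1 = L$fc1$out_ch)
}

#' @export
print.model_spec <- function(x, ...) {
  cat("S-ResNet spec: input 1 x", x$input_length, "->",
      x$num_classes, "classes\n")
  for (l in x$layers)
    cat(sprintf("  %-9s %-6s %4d -> %-4d k=%d\n",
                l$name, l$kind, l$in_ch, l$out_ch, l$k))
  invisible(x)
}

#' Multiply-accumulate accounting for an S-ResNet specification
#'
#' Counts one MAC per kernel multiply and one per bias accumulation in
#' every convolutional and fully connected layer. With stride 1 and
#' length-preserving padding, a convolution contributes
#' `out * in * k * L + out * L` MACs and a fully connected layer
#' `out * in + out`. Batch normalization, activations and global average
#' pooling are excluded from the headline total; the convention is
#' recorded in the report. (Deployment toolchains that fold auxiliary
#' ops into their counts report slightly different totals.)
#'
#' @param spec a `model_spec`.
#' @return a `mac_report`: per-layer counts, `total` (raw MACs) and
#'   `millions` (total / 1e6 rounded to 3 decimals).
#' @export
count_macs <- function(spec) {
  validate_model_spec(spec)
  Lout <- spec$input_length
  rows <- lapply(spec$layers, function(l) {
    macs <- if (l$kind == "conv1d")
      l$out_ch * l$in_ch * l$k * Lout + (if (l$has_bias) l$out_ch * Lout else 0)
    else
      l$out_ch * l$in_ch + (if (l$has_bias) l$out_ch else 0)
    data.frame(layer = l$name, kind = l$kind, macs = macs)
  })
  per_layer <- do.call(rbind, rows)
  rownames(per_layer) <- NULL
  total <- sum(per_layer$macs)
  structure(list(per_layer = per_layer, total = total,
                 millions = round(total / 1e6, 3),
                 convention = paste("kernel multiplies + bias accumulations,",
                                    "conv/fc only; BN, activations and GAP",
                                    "excluded; stride 1, same padding")),
            class = "mac_report")
}

#' @export
print.mac_report <- function(x, ...) {
  print(x$per_layer)
  cat(sprintf("total: %d MACs (%.3fM)\n", x$total, x$total / 1e6))
  cat("convention:", x$convention, "\n")
  invisible(x)
}

#' Serialize / restore a model specification as JSON
#' @param spec a `model_spec`.
#' @param path optional file; when NULL the JSON string is returned.
#' @return `spec_to_json`: JSON string or `path`;
#'   `spec_from_json`: a `model_spec`.
#' @export
spec_to_json <- function(spec, path = NULL) {
  validate_model_spec(spec)
  js <- jsonlite::toJSON(list(widths = as.list(spec_widths(spec)),
                              input_length = spec$input_length,
                              num_classes = spec$num_classes,
                              head_relu = spec$head_relu),
                         auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname spec_to_json
#' @param json JSON string or file path produced by [spec_to_json()].
#' @export
spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  build_sresnet(widths = unlist(x$widths), input_length = x$input_length,
                num_classes = x$num_classes, head_relu = isTRUE(x$head_relu))
}
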