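#' Channel coupling groups of an S-ResNet
#'
#' Structured channel pruning must respect the residual wiring: layers
#' that read the same tensor have their input channels pruned together
#' (consumers), and the layers that produce that tensor lose the
#' corresponding output filters (producers). At the residual additions
#' the block's second convolution and its shortcut must keep identical
#' channel sets, so they are pruned jointly. The first convolution's
#' input is the raw sensor frame and is excluded from pruning.
#'
#' For the default architecture this yields five decision groups, in
#' network order:
#' 1. inputs of `b1_conva` + `b1_short` (prunes `conv1` filters);
#' 2. input of `b1_convb` (prunes `b1_conva` filters);
#' 3. inputs of `b2_conva` + `b2_short` (prunes `b1_convb` and
#'    `b1_short` jointly);
#' 4. input of `b2_convb` (prunes `b2_conva` filters);
#' 5. input of `fc1` (prunes `b2_convb` and `b2_short` jointly).
#'
#' @param spec a `model_spec`.
#' @return list of coupling groups, each with `index`, `consumers`,
#'   `producers`, and `c_in` (shared consumer input width).
#' @export
coupling_groups <- function(spec) {
  validate_model_spec(spec)
  g <- list(
    list(index = 1L, consumers = c("b1_conva", "b1_short"),
         producers = "conv1"),
    list(index = 2L, consumers = "b1_convb", producers = "b1_conva"),
    list(index = 3L, consumers = c("b2_conva", "b2_short"),
         producers = c("b1_convb", "b1_short")),
    list(index = 4L, consumers = "b2_convb", producers = "b2_conva"),
    list(index = 5L, consumers = "fc1", producers = c("b2_convb", "b2_short")))
  lapply(g, function(gr) {
    cin <- unique(vapply(spec$layers[gr$consumers], `[[`, 0L, "in_ch"))
    if (length(cin) != 1)
      stop("consumers of group ", gr$index, " disagree on input width")
    cout <- vapply(spec$layers[gr$producers], `[[`, 0L, "out_ch")
    if (any(cout != cin))
      stop("producer output width != consumer input width in group ", gr$index)
    gr$c_in <- cin
    gr
  })
}

# M x p matrix: row m is the flattened concatenation of every consumer
# layer's weight slice for input channel m
channel_slices <- function(model, group) {
  sp <- model$spec
  mats <- lapply(group$consumers, function(nm) {
    l <- sp$layers[[nm]]
    W <- model$weights[[nm]]$W
    if (l$kind == "conv1d") {
      matrix(aperm(W, c(2, 1, 3)), dim(W)[2])  # row m = W[, m, ] flattened
    } else {
      t(W)                                     # fc: slice for input m is column m
    }
  })
  do.call(cbind, mats)
}

#' Channel importance scores for a coupling group
#'
#' The importance of input channel m is the L2 norm of the concatenation
#' of every consumer layer's weight slice for that channel; for joint
#' residual groups the squared norms of both consumers accumulate.
#' Channels are retained in descending score order.
#'
#' @param model an `sresnet_model`.
#' @param group one element of [coupling_groups()].
#' @return numeric vector of length `group$c_in`.
#' @export
channel_importance <- function(model, group) {
  S <- channel_slices(model, group)
  sqrt(rowSums(S^2))
}

#' Prune one coupling group to a channel retention rate
#'
#' Keeps the `ceil(R * c_in)` highest-importance input channels (floored
#' at `ceil(r_min * c_in)`), removing the matching input slices of every
#' consumer and the output filters, biases and batch-norm rows of every
#' producer. Kept channels preserve their original order, so a retention
#' of 1 leaves the model bit-identical.
#'
#' @param model an `sresnet_model`.
#' @param group one element of [coupling_groups()] *for this model's
#'   current spec*.
#' @param R retention rate in `[r_min, 1]`.
#' @param r_min minimum per-layer retention (default 0.2).
#' @return list with `model` (pruned) and `kept` (original channel
#'   indices retained, ascending).
#' @export
prune_group <- function(model, group, R, r_min = 0.2) {
  if (R < 0 || R > 1) stop("retention rate must be in [0, 1]")
  cin <- group$c_in
  n_keep <- min(max(ceiling(R * cin), ceiling(r_min * cin)), cin)
  if (n_keep < 1) stop("pruning would leave 0 channels in group ", group$index)
  score <- channel_importance(model, group)
  kept <- sort(order(score, decreasing = TRUE)[seq_len(n_keep)])
  list(model = .apply_keep(model, group, kept), kept = kept)
}

.apply_keep <- function(model, group, kept) {
  sp <- model$spec
  for (nm in group$consumers) {
    l <- sp$layers[[nm]]
    w <- model$weights[[nm]]
    w$W <- if (l$kind == "conv1d") w$W[, kept, , drop = FALSE]
           else w$W[, kept, drop = FALSE]
    model$weights[[nm]] <- w
    sp$layers[[nm]]$in_ch <- length(kept)
  }
  for (nm in group$producers) {
    w <- model$weights[[nm]]
    w$W <- w$W[kept, , , drop = FALSE]
    for (f in c("b", "gamma", "beta", "rm", "rv")) w[[f]] <- w[[f]][kept]
    model$weights[[nm]] <- w
    sp$layers[[nm]]$out_ch <- length(kept)
  }
  model$spec <- validate_model_spec(sp)
  model
}

#' Prune a trained model with a full retention vector
#'
#' Applies [prune_group()] to the five coupling groups in network order.
#'
#' @param model an `sresnet_model`.
#' @param retentions numeric vector, one retention rate per group.
#' @param r_min minimum per-layer retention.
#' @return list with `model`, `kept` (list of index vectors) and
#'   `retention` (realized kept fractions).
#' @export
prune_model <- function(model, retentions, r_min = 0.2) {
  groups <- coupling_groups(model$spec)
  if (length(retentions) != length(groups))
    stop("need one retention per coupling group (", length(groups), ")")
  kept <- vector("list", length(groups))
  realized <- numeric(length(groups))
  for (i in seq_along(groups)) {
    gr <- coupling_groups(model$spec)[[i]]   # respec after earlier prunes
    pr <- prune_group(model, gr, retentions[i], r_min)
    model <- pr$model
    kept[[i]] <- pr$kept
    realized[i] <- length(pr$kept) / gr$c_in
  }
  list(model = model, kept = kept, retention = realized)
}
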