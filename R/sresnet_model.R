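#' Initialize S-ResNet weights
#'
#' Fan-in-scaled uniform initialization: each weight (and bias) of a
#' layer with fan-in `f` is drawn from `U(-1/sqrt(f), 1/sqrt(f))`. Batch
#' normalization starts at the identity (`gamma = 1`, `beta = 0`) with
#' running statistics (0, 1).
#'
#' @param spec a `model_spec` from [build_sresnet()].
#' @param seed integer seed.
#' @return an `sresnet_model`: `spec`, named `weights` store, empty
#'   training `log`.
#' @export
init_sresnet <- function(spec, seed = 1L) {
  validate_model_spec(spec)
  set.seed(seed)
  weights <- lapply(spec$layers, function(l) {
    fan_in <- l$in_ch * l$k
    bd <- 1 / sqrt(fan_in)
    w <- if (l$kind == "conv1d") {
      list(W = array(stats::runif(l$out_ch * l$in_ch * l$k, -bd, bd),
                     c(l$out_ch, l$in_ch, l$k)),
           b = stats::runif(l$out_ch, -bd, bd),
           gamma = rep(1, l$out_ch), beta = rep(0, l$out_ch),
           rm = rep(0, l$out_ch), rv = rep(1, l$out_ch))
    } else {
      list(W = matrix(stats::runif(l$out_ch * l$in_ch, -bd, bd),
                      l$out_ch, l$in_ch),
           b = stats::runif(l$out_ch, -bd, bd))
    }
    w
  })
  structure(list(spec = spec, weights = weights,
                 log = data.frame(epoch = integer(), loss = numeric(),
                                  acc = numeric(), valid_acc = numeric())),
            class = "sresnet_model")
}

#' @export
print.sresnet_model <- function(x, ...) {
  cat("sresnet_model (", count_macs(x$spec)$millions, "M MACs, ",
      nrow(x$log), " epochs trained)\n", sep = "")
  print(x$spec)
  invisible(x)
}

# conv -> BN -> (relu) unit; conv bias is folded into the BN kernel.
# Returns output, caches, and BN running stats updated in training mode.
.unit_fwd <- function(w, A, training, relu, L, N, momentum = 0.1, eps = 1e-5) {
  cv <- conv1d_fwd(A, w$W, L, N)
  if (training) {
    mo <- cpp_row_moments_bias(cv$Z, w$b)
    mu <- mo$mu; v <- mo$v
    w$rm <- (1 - momentum) * w$rm + momentum * mu
    w$rv <- (1 - momentum) * w$rv + momentum * v
  } else {
    mu <- w$rm; v <- w$rv
  }
  invstd <- 1 / sqrt(v + eps)
  out <- cpp_bn_fwd(cv$Z, w$b, w$gamma, w$beta, mu, invstd, relu)
  list(out = out, col = cv$col, Wmat = cv$Wmat, Z = cv$Z,
       mu = mu, invstd = invstd, w = w)
}

.unit_bwd <- function(dout, cache, w, C_in, k, L, N, relu, need_dA = TRUE) {
  if (relu) dout <- cpp_relu_bwd(dout, cache$out)
  bb <- cpp_bn_bwd(dout, cache$Z, w$b, cache$mu, cache$invstd, w$gamma)
  cb <- conv1d_bwd(bb$dZ, cache, C_in, k, L, N, need_dA)
  list(dA = cb$dA, g = list(W = cb$dW, b = cb$db,
                            gamma = as.numeric(bb$dgamma),
                            beta = as.numeric(bb$dbeta)))
}

# Full forward pass. X: (N x input_length) feature matrix.
# Returns logits (num_classes x N); with keep = TRUE also layer caches,
# and (in training mode) updated BN running statistics.
sres_forward <- function(model, X, training = FALSE, keep = FALSE) {
  sp <- model$spec; W <- model$weights
  L <- sp$input_length; N <- nrow(X)
  if (ncol(X) != L)
    stop("input has ", ncol(X), " features, model expects ", L)
  A0 <- matrix(t(X), 1L)
  u <- .unit_fwd(W$conv1, A0, training, relu = TRUE, L, N)
  W$conv1[c("rm", "rv")] <- u$w[c("rm", "rv")]
  F0 <- u$out
  blk <- function(Fin, pre) {
    a <- .unit_fwd(W[[paste0(pre, "_conva")]], Fin, training, TRUE, L, N)
    b <- .unit_fwd(W[[paste0(pre, "_convb")]], a$out, training, FALSE, L, N)
    s <- .unit_fwd(W[[paste0(pre, "_short")]], Fin, training, FALSE, L, N)
    Fout <- cpp_add_relu(b$out, s$out)
    list(a = a, b = b, s = s, Fout = Fout)
  }
  k1 <- blk(F0, "b1")
  W$b1_conva[c("rm", "rv")] <- k1$a$w[c("rm", "rv")]
  W$b1_convb[c("rm", "rv")] <- k1$b$w[c("rm", "rv")]
  W$b1_short[c("rm", "rv")] <- k1$s$w[c("rm", "rv")]
  k2 <- blk(k1$Fout, "b2")
  W$b2_conva[c("rm", "rv")] <- k2$a$w[c("rm", "rv")]
  W$b2_convb[c("rm", "rv")] <- k2$b$w[c("rm", "rv")]
  W$b2_short[c("rm", "rv")] <- k2$s$w[c("rm", "rv")]
  G <- gap_fwd(k2$Fout, L)
  H <- W$fc1$W %*% G + W$fc1$b
  head_relu <- sp$layers$fc1$activation == "relu"
  Hact <- if (head_relu) relu_fwd(H) else H
  logits <- W$fc2$W %*% Hact + W$fc2$b
  if (!keep) return(list(logits = logits, weights = W))
  list(logits = logits, weights = W,
       cache = list(conv1 = u, F0 = F0, k1 = k1, k2 = k2, G = G,
                    Hact = Hact, head_relu = head_relu, L = L, N = N))
}

sres_backward <- function(model, fw, dlogits) {
  sp <- model$spec; W <- fw$weights; ca <- fw$cache
  L <- ca$L; N <- ca$N
  g <- list()
  g$fc2 <- list(W = tcrossprod(dlogits, ca$Hact), b = rowSums(dlogits))
  dH <- crossprod(W$fc2$W, dlogits)
  if (ca$head_relu) dH <- dH * (ca$Hact > 0)
  g$fc1 <- list(W = tcrossprod(dH, ca$G), b = rowSums(dH))
  dG <- crossprod(W$fc1$W, dH)
  dF2 <- gap_bwd(dG, L)
  blk_bwd <- function(k, pre, dFout) {
    dsum <- cpp_relu_bwd(dFout, k$Fout)
    lb <- sp$layers[[paste0(pre, "_convb")]]
    ls <- sp$layers[[paste0(pre, "_short")]]
    la <- sp$layers[[paste0(pre, "_conva")]]
    ub <- .unit_bwd(dsum, k$b, W[[paste0(pre, "_convb")]], lb$in_ch, lb$k,
                    L, N, relu = FALSE)
    us <- .unit_bwd(dsum, k$s, W[[paste0(pre, "_short")]], ls$in_ch, ls$k,
                    L, N, relu = FALSE)
    ua <- .unit_bwd(ub$dA, k$a, W[[paste0(pre, "_conva")]], la$in_ch, la$k,
                    L, N, relu = TRUE)
    list(gb = ub$g, gs = us$g, ga = ua$g, dFin = ua$dA + us$dA)
  }
  r2 <- blk_bwd(ca$k2, "b2", dF2)
  g$b2_convb <- r2$gb; g$b2_short <- r2$gs; g$b2_conva <- r2$ga
  r1 <- blk_bwd(ca$k1, "b1", r2$dFin)
  g$b1_convb <- r1$gb; g$b1_short <- r1$gs; g$b1_conva <- r1$ga
  u0 <- .unit_bwd(r1$dFin, ca$conv1, W$conv1, 1L, sp$layers$conv1$k, L, N,
                  relu = TRUE, need_dA = FALSE)
  g$conv1 <- u0$g
  g
}

.trainable_names <- function(w)
  if ("gamma" %in% names(w)) c("W", "b", "gamma", "beta") else c("W", "b")

flatten_params <- function(weights) {
  out <- list()
  for (nm in names(weights))
    for (f in .trainable_names(weights[[nm]]))
      out[[paste(nm, f, sep = ".")]] <- weights[[nm]][[f]]
  out
}

unflatten_params <- function(weights, flat) {
  for (key in names(flat)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    weights[[parts[1]]][[parts[2]]] <- flat[[key]]
  }
  weights
}

#' Class scores for behavior frames
#'
#' Runs the network in evaluation mode (batch-norm uses running
#' statistics) and returns pre-softmax logits; apply [softmax_scores()]
#' for probabilities.
#'
#' @param model an `sresnet_model`.
#' @param data a [herd_dataset()] or numeric feature matrix
#'   (frames x features).
#' @return numeric matrix, frames x classes.
#' @export
predict_scores <- function(model, data) {
  X <- if (inherits(data, "herd_dataset")) feature_matrix(data) else as.matrix(data)
  t(sres_forward(model, X, training = FALSE)$logits)
}

#' @rdname predict_scores
#' @return `softmax_scores`: row-stochastic probability matrix.
#' @export
softmax_scores <- function(model, data) {
  s <- predict_scores(model, data)
  t(softmax_cols(t(s)))
}

#' @rdname predict_scores
#' @return `predict_classes`: integer vector of 0-based class indices;
#'   ties resolve to the lowest class index.
#' @export
predict_classes <- function(model, data) {
  s <- predict_scores(model, data)
  max.col(s, ties.method = "first") - 1L
}

#' Overall accuracy of a model on a dataset
#' @param model an `sresnet_model`.
#' @param ds a labeled [herd_dataset()].
#' @return fraction of correctly classified frames.
#' @export
model_accuracy <- function(model, ds) {
  stopifnot(inherits(ds, "herd_dataset"))
  mean(predict_classes(model, ds) == ds$frames$label)
}

#' Training configuration
#'
#' Defaults follow the single-frame classifier's training recipe:
#' Adam, learning rate 0.001, 100 epochs, batch size 128, cross-entropy
#' loss.
#'
#' @param lr learning rate.
#' @param epochs training epochs; 0 returns the initialized model.
#' @param batch_size mini-batch size.
#' @param optimizer only `"adam"` is implemented.
#' @param loss only `"cross_entropy"` is implemented.
#' @param seed integer seed (weight init, shuffling).
#' @param verbose print per-epoch progress.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 0.001, epochs = 100, batch_size = 128,
                         optimizer = "adam", loss = "cross_entropy",
                         seed = 1L, verbose = FALSE) {
  stopifnot(lr >= 0, epochs >= 0, batch_size >= 1)
  if (optimizer != "adam") stop("unsupported optimizer: ", optimizer)
  if (loss != "cross_entropy") stop("unsupported loss: ", loss)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 loss = loss, seed = as.integer(seed), verbose = verbose),
            class = "train_config")
}

#' Train (or continue training) the S-ResNet classifier
#'
#' Mini-batch Adam on softmax cross-entropy. Given a `model_spec`, a
#' fresh model is initialized from `cfg$seed`; given an existing
#' `sresnet_model`, training continues from its weights (this is the
#' fine-tuning path used after pruning, with identical hyperparameters).
#'
#' @param x a `model_spec` or an `sresnet_model`.
#' @param train standardized training [herd_dataset()].
#' @param valid optional validation [herd_dataset()]; its accuracy is
#'   logged per epoch but never used for weight updates.
#' @param cfg a [train_config()].
#' @return an `sresnet_model` with a per-epoch `log`
#'   (epoch, loss, acc, valid_acc).
#' @export
train_classifier <- function(x, train, valid = NULL, cfg = train_config()) {
  stopifnot(inherits(train, "herd_dataset"))
  model <- if (inherits(x, "model_spec")) init_sresnet(x, cfg$seed) else x
  stopifnot(inherits(model, "sresnet_model"))
  y <- train$frames$label + 1L
  if (max(y) > model$spec$num_classes)
    stop("labels exceed the model's ", model$spec$num_classes, " classes")
  X <- feature_matrix(train)
  n <- nrow(X)
  set.seed(cfg$seed)
  opt <- adam_init(flatten_params(model$weights))
  start_epoch <- if (nrow(model$log)) max(model$log$epoch) else 0L
  for (ep in seq_len(cfg$epochs)) {
    idx <- sample.int(n)
    tot_loss <- 0; correct <- 0L
    for (b0 in seq(1L, n, by = cfg$batch_size)) {
      bi <- idx[b0:min(b0 + cfg$batch_size - 1L, n)]
      fw <- sres_forward(model, X[bi, , drop = FALSE], training = TRUE,
                         keep = TRUE)
      model$weights <- fw$weights
      ce <- cross_entropy(fw$logits, y[bi])
      if (!is.finite(ce$loss))
        stop("training diverged (loss = ", ce$loss, ") at epoch ",
             start_epoch + ep, "; lower the learning rate (", cfg$lr, ")")
      tot_loss <- tot_loss + ce$loss * length(bi)
      correct <- correct +
        sum(max.col(t(fw$logits), ties.method = "first") == y[bi])
      grads <- sres_backward(model, fw, ce$dlogits)
      flatg <- flatten_params(grads)
      st <- adam_step(flatten_params(model$weights), flatg, opt, cfg$lr)
      opt <- st$state
      model$weights <- unflatten_params(model$weights, st$params)
    }
    va <- if (is.null(valid)) NA_real_ else model_accuracy(model, valid)
    model$log <- rbind(model$log,
                       data.frame(epoch = start_epoch + ep,
                                  loss = tot_loss / n, acc = correct / n,
                                  valid_acc = va))
    if (cfg$verbose)
      cat(sprintf("epoch %3d  loss %.4f  acc %.4f  valid %.4f\n",
                  start_epoch + ep, tot_loss / n, correct / n, va))
  }
  model
}

#' @rdname train_classifier
#' @param model an `sresnet_model` (possibly pruned).
#' @export
finetune <- function(model, train, valid = NULL, cfg = train_config()) {
  stopifnot(inherits(model, "sresnet_model"))
  train_classifier(model, train, valid = valid, cfg = cfg)
}

#' Save / load an S-ResNet checkpoint directory
#'
#' Writes `spec.json` (architecture), `weights.rds` (named weight
#' arrays) and `log.csv` (per-epoch training log) into `dir`.
#'
#' @param model an `sresnet_model`.
#' @param dir checkpoint directory (created if missing).
#' @return `save_sresnet`: `dir` invisibly; `load_sresnet`: the model.
#' @export
save_sresnet <- function(model, dir) {
  stopifnot(inherits(model, "sresnet_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec_to_json(model$spec, file.path(dir, "spec.json"))
  saveRDS(model$weights, file.path(dir, "weights.rds"))
  utils::write.csv(model$log, file.path(dir, "log.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_sresnet
#' @export
load_sresnet <- function(dir) {
  spec <- spec_from_json(file.path(dir, "spec.json"))
  weights <- readRDS(file.path(dir, "weights.rds"))
  log <- utils::read.csv(file.path(dir, "log.csv"))
  structure(list(spec = spec, weights = weights, log = log),
            class = "sresnet_model")
}
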