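# Independent oracles used across test files. These deliberately use the
# slowest, most literal formulations available so that they share no code
# path with the package implementation.

# MAC count by walking every output element and tallying multiplies and
# bias accumulations (conv and fc layers only).
brute_force_macs <- function(spec) {
  total <- 0
  L <- spec$input_length
  for (l in spec$layers) {
    if (l$kind == "conv1d") {
      for (pos in seq_len(L))           # stride 1, length preserved
        for (oc in seq_len(l$out_ch)) {
          total <- total + l$in_ch * l$k      # kernel multiplies
          if (l$has_bias) total <- total + 1  # bias accumulation
        }
    } else {
      for (oc in seq_len(l$out_ch)) {
        total <- total + l$in_ch
        if (l$has_bias) total <- total + 1
      }
    }
  }
  total
}

# literal per-element eval-mode forward pass of an S-ResNet model
naive_sres_forward <- function(model, x) {
  sp <- model$spec
  L <- sp$input_length
  eps <- 1e-5
  conv_bn <- function(w, A, k, relu) {
    C_out <- dim(w$W)[1]; C_in <- dim(w$W)[2]
    out <- matrix(0, C_out, L)
    p <- (k - 1) / 2
    for (oc in seq_len(C_out)) for (pos in seq_len(L)) {
      acc <- w$b[oc]
      for (ic in seq_len(C_in)) for (kk in seq_len(k)) {
        src <- pos + kk - 1 - p
        if (src >= 1 && src <= L) acc <- acc + w$W[oc, ic, kk] * A[ic, src]
      }
      z <- (acc - w$rm[oc]) / sqrt(w$rv[oc] + eps) * w$gamma[oc] + w$beta[oc]
      out[oc, pos] <- if (relu) max(z, 0) else z
    }
    out
  }
  A0 <- matrix(x, 1, L)
  F0 <- conv_bn(model$weights$conv1, A0, 3, TRUE)
  blk <- function(Fin, pre) {
    a <- conv_bn(model$weights[[paste0(pre, "_conva")]], Fin, 3, TRUE)
    b <- conv_bn(model$weights[[paste0(pre, "_convb")]], a, 3, FALSE)
    s <- conv_bn(model$weights[[paste0(pre, "_short")]], Fin, 1, FALSE)
    pmax(b + s, 0)
  }
  F2 <- blk(blk(F0, "b1"), "b2")
  G <- rowMeans(F2)
  H <- as.numeric(model$weights$fc1$W %*% G) + model$weights$fc1$b
  if (sp$layers$fc1$activation == "relu") H <- pmax(H, 0)
  as.numeric(model$weights$fc2$W %*% H) + model$weights$fc2$b
}

# naive per-node GCN aggregation: H'[i,] = act(sum_j Ahat[i,j] H[j,] W)
naive_gcn <- function(H, Ahat, W, relu = TRUE) {
  M <- nrow(H)
  out <- matrix(0, M, ncol(W))
  for (i in seq_len(M)) {
    agg <- rep(0, ncol(H))
    for (j in seq_len(M)) agg <- agg + Ahat[i, j] * H[j, ]
    out[i, ] <- as.numeric(agg %*% W)
  }
  if (relu) pmax(out, 0) else out
}

# small random S-ResNet spec for property sweeps
random_small_spec <- function(num_classes = sample(2:6, 1)) {
  w <- c(conv1 = sample(2:6, 1), b1_conva = sample(2:8, 1),
         b1_out = sample(2:8, 1), b2_conva = sample(2:8, 1),
         b2_out = sample(2:8, 1), fc1 = sample(2:8, 1))
  build_sresnet(widths = w, num_classes = num_classes)
}

# standardized splits of a small synthetic herd; memoized per test run
tiny_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_synthetic_herd(
        generator_config(n_per_class = c(120, 100, 80, 60), seed = 101))
      sm <- smote_oversample(ds, seed = 102)
      parts <- split_dataset(sm, 0.7, seed = 103)
      inner <- split_dataset(parts$train, 0.8, seed = 104)
      st <- standardize_features(inner$train, list(inner$test, parts$test))
      cache <<- list(train = st$train, valid = st$others[[1]],
                     test = st$others[[2]])
    }
    cache
  }
})

# a lightly trained small-width model on the tiny pipeline; memoized
tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tp <- tiny_pipeline()
      spec <- build_sresnet(num_classes = 4)
      cache <<- train_classifier(spec, tp$train,
                                 cfg = train_config(epochs = 3, seed = 55))
    }
    cache
  }
})
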