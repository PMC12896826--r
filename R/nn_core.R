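# Internal dense primitives for the 1-D CNN and its backward pass.
# Activations are matrices (channels x (length * batch)); column order is
# sequence position fastest, batch slowest. Convolutions use stride 1 and
# symmetric zero padding (kernel 1 or 3), so length is preserved end to
# end. Column unfolding and batch-norm elementwise passes run in C++
# (src/nn_kernels.cpp); all matrix products go through BLAS.

# bias is not added here: it is folded into the batch-norm kernel
conv1d_fwd <- function(M, W, L, N) {
  C_out <- dim(W)[1]; C_in <- dim(W)[2]; k <- dim(W)[3]
  if (nrow(M) != C_in)
    stop("conv input has ", nrow(M), " channels, weight expects ", C_in)
  Wmat <- matrix(W, C_out)
  col <- if (k == 1L) M else cpp_im2col3(M, L, N)
  list(Z = Wmat %*% col, col = col, Wmat = Wmat)
}

conv1d_bwd <- function(dZ, cache, C_in, k, L, N, need_dA = TRUE) {
  dW <- array(tcrossprod(dZ, cache$col), c(nrow(dZ), C_in, k))
  db <- rowSums(dZ)
  dA <- NULL
  if (need_dA) {
    dcol <- crossprod(cache$Wmat, dZ)
    dA <- if (k == 1L) dcol else cpp_col2im3(dcol, C_in, L, N)
  }
  list(dW = dW, db = db, dA = dA)
}

relu_fwd <- function(X) { X[X < 0] <- 0; X }

# (C x L*N) -> (C x N) channel means over the sequence axis
gap_fwd <- function(M, L) {
  C <- nrow(M); N <- ncol(M) %/% L
  dim(M) <- c(C * L, N)
  G <- rowsum(M, group = rep(seq_len(C), times = L), reorder = TRUE) / L
  dimnames(G) <- NULL
  G
}

gap_bwd <- function(dG, L) {
  C <- nrow(dG)
  M <- dG[rep(seq_len(C), times = L), , drop = FALSE] / L
  dim(M) <- c(C, L * ncol(dG))
  M
}

softmax_cols <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# y: 1-based class indices; logits: (C, N)
cross_entropy <- function(logits, y) {
  P <- softmax_cols(logits)
  N <- ncol(logits)
  pick <- pmax(P[cbind(y, seq_len(N))], 1e-12)
  dlogits <- P
  dlogits[cbind(y, seq_len(N))] <- dlogits[cbind(y, seq_len(N))] - 1
  list(loss = -mean(log(pick)), dlogits = dlogits / N)
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
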