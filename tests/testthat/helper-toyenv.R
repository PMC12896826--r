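# A miniature two-decision pruning environment with an analytically known
# reward surface, used to verify that the strategy search recovers the
# optimum. States are genuine channel graphs (6 channels, 11 features);
# the second state carries the first action in its R_prev column, as the
# real environment does. The reward mimics a terminal accuracy peak at
# retentions (0.7, 0.4), scaled by 0.01.
make_toy_env <- function() {
  set.seed(424242)  # fixed geometry, independent of the search seed
  sl1 <- matrix(rnorm(6 * 4), 6, 4)
  sl2 <- matrix(rnorm(6 * 4), 6, 4)
  X1 <- cbind(1, 1, 6, 6, 1, 3, matrix(runif(6 * 2), 6, 2), 0, 0.5, 1)
  X2base <- cbind(2, 1, 6, 6, 1, 3, matrix(runif(6 * 2), 6, 2), 0.3, 0, NA)
  g1 <- build_channel_graph(X1, sl1, k_nn = 3)
  acc_fn <- function(a1, a2)
    0.6 + 0.35 * exp(-((a1 - 0.7)^2 + (a2 - 0.4)^2) / (2 * 0.22^2))
  a <- c(NA, NA); l <- 0; cur <- g1
  clamp <- function(x) min(max(x, 0.2), 1)
  reset <- function() { l <<- 1; a <<- c(NA, NA); cur <<- g1; g1 }
  step <- function(R) {
    R <- clamp(R)
    if (l == 1) {
      a[1] <<- R; l <<- 2
      X2 <- X2base; X2[, 11] <- R
      s2 <- build_channel_graph(X2, sl2, k_nn = 3)
      prev <- cur; cur <<- s2
      list(state = prev, action = R, reward = 0, next_state = s2,
           done = FALSE)
    } else {
      a[2] <<- R; l <<- 3
      list(state = cur, action = R,
           reward = acc_fn(a[1], a[2]) * 0.01, next_state = NULL,
           done = TRUE)
    }
  }
  result <- function() list(retention = a, mac_ratio = mean(a),
                            reward = NA, accuracy = acc_fn(a[1], a[2]))
  list(reset = reset, step = step, result = result, n_groups = 2L,
       acc_fn = acc_fn)
}
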