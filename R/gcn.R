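#' Build a channel dependency graph for one pruning decision
#'
#' Nodes are the input channels of a coupling group; edges connect each
#' channel to its `k_nn` most similar channels by cosine similarity of
#' their flattened weight slices ("closely related channels"), then the
#' edge set is symmetrized and self-loops are added. The normalized
#' adjacency `D^{-1/2} (A + I) D^{-1/2}` is cached for graph
#' convolutions.
#'
#' @param state node feature matrix (one row per channel, e.g. a scaled
#'   [layer_state()]).
#' @param slices per-channel weight slice matrix (rows align with
#'   `state`), used only to define edges.
#' @param k_nn neighbors per node, clipped to `M - 1`.
#' @return a `channel_graph`: `X` (features), `A` (0/1 adjacency with
#'   unit diagonal), `Ahat` (normalized adjacency).
#' @export
build_channel_graph <- function(state, slices, k_nn = 5) {
  state <- as.matrix(state)
  M <- nrow(state)
  stopifnot(M >= 1, nrow(slices) == M)
  A <- diag(1, M)
  if (M > 1) {
    k <- min(k_nn, M - 1)
    nrm <- sqrt(rowSums(slices^2))
    U <- slices / pmax(nrm, 1e-12)
    sim <- tcrossprod(U)
    diag(sim) <- -Inf
    for (m in seq_len(M)) {
      nb <- order(sim[m, ], decreasing = TRUE)[seq_len(k)]
      A[m, nb] <- 1
      A[nb, m] <- 1   # symmetrize
    }
  }
  d <- rowSums(A)
  s <- 1 / sqrt(d)
  structure(list(X = state, A = A, Ahat = A * outer(s, s)),
            class = "channel_graph")
}

#' One graph convolution layer
#'
#' Computes `activation(Ahat %*% H %*% W)`: each node aggregates its
#' neighbors' features through the normalized self-looped adjacency and
#' applies a shared linear transform.
#'
#' @param H node feature matrix (M x d_in).
#' @param Ahat normalized adjacency (M x M).
#' @param W weight matrix (d_in x d_out).
#' @param activation `"relu"` or `"identity"`.
#' @return transformed node features (M x d_out).
#' @export
gcn_layer <- function(H, Ahat, W, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (ncol(Ahat) != nrow(H)) stop("adjacency / feature shape mismatch")
  if (ncol(H) != nrow(W)) stop("feature / weight shape mismatch")
  Z <- Ahat %*% (H %*% W)
  if (activation == "relu") relu_fwd(Z) else Z
}

.glorot <- function(n_in, n_out) {
  bd <- 1 / sqrt(n_in)
  matrix(stats::runif(n_in * n_out, -bd, bd), n_in, n_out)
}

#' Initialize actor and twin-critic networks
#'
#' The actor is a three-layer GCN (feature dim -> 400 -> 300 -> 1) whose
#' node outputs are mean-pooled and squashed by a sigmoid into a
#' retention rate in (0, 1). Each critic embeds the state with one GCN
#' layer mean-pooled to 400 dimensions and the scalar action with an
#' affine map to 400 dimensions, fuses them by elementwise sum, and maps
#' 400 -> 300 -> 1 through fully connected layers. Target copies start
#' as exact clones; the critics are initialized independently.
#'
#' @param seed integer seed.
#' @param in_dim node feature dimension (11 for [layer_state()] rows).
#' @param d1,d2 hidden widths (400 and 300).
#' @param critic_act activation inside the critic head, `"relu"`
#'   (default) or `"identity"`.
#' @return an `agent_nets` list with online and target networks.
#' @export
agent_nets <- function(seed = 1L, in_dim = 11L, d1 = 400L, d2 = 300L,
                       critic_act = "relu") {
  set.seed(seed)
  # output layers start near zero (the classic deterministic-policy-
  # gradient recipe): the actor opens at sigmoid(~0) = 0.5 and the
  # critics at Q ~ 0, so early policy gradients do not chase the noise
  # of an untrained value surface
  out_init <- function(n_in, n_out)
    matrix(stats::runif(n_in * n_out, -3e-3, 3e-3), n_in, n_out)
  actor <- list(W1 = .glorot(in_dim, d1), W2 = .glorot(d1, d2),
                W3 = out_init(d2, 1L))
  fc <- function(n_out, n_in) {
    bd <- 1 / sqrt(n_in)
    matrix(stats::runif(n_out * n_in, -bd, bd), n_out, n_in)
  }
  critic <- function() list(Wg = .glorot(in_dim, d1),
                            wa = stats::runif(d1, -1, 1),
                            ba = stats::runif(d1, -1, 1),
                            W1 = fc(d2, d1), b1 = rep(0, d2),
                            W2 = t(out_init(d2, 1L)), b2 = 0)
  c1 <- critic(); c2 <- critic()
  structure(list(actor = actor, critic1 = c1, critic2 = c2,
                 t_actor = actor, t_critic1 = c1, t_critic2 = c2,
                 critic_act = critic_act),
            class = "agent_nets")
}

#' Actor retention proposal for a channel graph
#'
#' @param nets an [agent_nets()].
#' @param g a [build_channel_graph()] state.
#' @param target use the target actor.
#' @return retention rate strictly inside (0, 1).
#' @export
actor_forward <- function(nets, g, target = FALSE) {
  .actor_fwd(if (target) nets$t_actor else nets$actor, g)$R
}

.actor_fwd <- function(p, g) {
  P <- g$Ahat; H <- g$X
  Z1 <- P %*% (H %*% p$W1); H1 <- relu_fwd(Z1)
  Z2 <- P %*% (H1 %*% p$W2); H2 <- relu_fwd(Z2)
  Z3 <- P %*% (H2 %*% p$W3)
  pool <- mean(Z3)
  list(R = 1 / (1 + exp(-pool)), pool = pool,
       H = H, H1 = H1, H2 = H2, Z1 = Z1, Z2 = Z2, P = P)
}

# gradient of the actor output w.r.t. parameters, scaled by upstream dR
.actor_bwd <- function(p, fw, dR) {
  M <- nrow(fw$H)
  dpool <- dR * fw$R * (1 - fw$R)
  dZ3 <- matrix(dpool / M, M, 1)
  PdZ3 <- fw$P %*% dZ3
  dW3 <- crossprod(fw$H2, PdZ3)
  dH2 <- PdZ3 %*% t(p$W3)
  dZ2 <- dH2 * (fw$Z2 > 0)
  PdZ2 <- fw$P %*% dZ2
  dW2 <- crossprod(fw$H1, PdZ2)
  dH1 <- PdZ2 %*% t(p$W2)
  dZ1 <- dH1 * (fw$Z1 > 0)
  dW1 <- crossprod(fw$H, fw$P %*% dZ1)
  list(W1 = dW1, W2 = dW2, W3 = dW3)
}

#' Critic value for a state graph and action
#'
#' @param nets an [agent_nets()].
#' @param g a [build_channel_graph()] state.
#' @param action scalar retention action.
#' @param which 1 or 2 (twin critics).
#' @param target use the target critic.
#' @return scalar Q value.
#' @export
critic_forward <- function(nets, g, action, which = 1, target = FALSE) {
  p <- nets[[paste0(if (target) "t_critic" else "critic", which)]]
  .critic_fwd(p, g, action, nets$critic_act)$q
}

.critic_fwd <- function(p, g, a, act) {
  P <- g$Ahat; H <- g$X
  Zg <- P %*% (H %*% p$Wg)
  Hg <- relu_fwd(Zg)
  s <- colMeans(Hg)
  u <- s + p$wa * a + p$ba
  h1pre <- as.numeric(p$W1 %*% u) + p$b1
  h1 <- if (act == "relu") pmax(h1pre, 0) else h1pre
  q <- as.numeric(p$W2 %*% h1) + p$b2
  list(q = q, Zg = Zg, Hg = Hg, u = u, h1pre = h1pre, h1 = h1,
       P = P, H = H, a = a)
}

# gradients of q w.r.t. critic parameters and the action, scaled by dq
.critic_bwd <- function(p, fw, dq, act) {
  M <- nrow(fw$H)
  dh1 <- as.numeric(dq * p$W2)
  dW2 <- matrix(dq * fw$h1, 1)
  db2 <- dq
  dh1pre <- if (act == "relu") dh1 * (fw$h1pre > 0) else dh1
  dW1 <- outer(dh1pre, fw$u)
  db1 <- dh1pre
  du <- as.numeric(crossprod(p$W1, dh1pre))
  dwa <- du * fw$a
  dba <- du
  da <- sum(du * p$wa)
  dHg <- matrix(du / M, M, length(du), byrow = TRUE)
  dZg <- dHg * (fw$Zg > 0)
  dWg <- crossprod(fw$H, fw$P %*% dZg)
  list(grads = list(Wg = dWg, wa = dwa, ba = dba, W1 = dW1, b1 = db1,
                    W2 = dW2, b2 = db2),
       da = da)
}
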