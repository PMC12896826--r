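#' Configuration for the TD3 pruning-strategy search
#'
#' Defaults follow the compression recipe: 100 exploration episodes
#' followed by 500 exploitation episodes (600 total), mini-batch 64,
#' soft-update coefficient 0.01, actor/critic learning rates 0.001, and
#' an action range equal to the admissible retention interval
#' `[r_min, 1]`. The discount, noise scales, buffer capacity and noise
#' decay are not pinned down by the recipe; their defaults are
#' conventional TD3 values and all are configurable.
#'
#' @param T total episodes.
#' @param T1 exploration episodes (uniform random actions).
#' @param gamma discount factor.
#' @param delta1 exploration noise standard deviation (decays by
#'   `noise_decay` per post-exploration episode).
#' @param delta2 target-policy smoothing noise standard deviation.
#' @param a,b action bounds (minimum retention, 1).
#' @param tau soft-update coefficient for the target networks.
#' @param N mini-batch size.
#' @param policy_delay actor/target update period in update steps.
#' @param buffer_capacity replay buffer size (FIFO eviction).
#' @param noise_decay multiplicative exploration-noise decay per episode.
#' @param actor_lr,critic_lr Adam learning rates.
#' @param seed integer seed for the whole search.
#' @return a `td3_config` list.
#' @export
td3_config <- function(T = 600L, T1 = 100L, gamma = 0.99, delta1 = 0.25,
                       delta2 = 0.1, a = 0.2, b = 1.0, tau = 0.01, N = 64L,
                       policy_delay = 2L, buffer_capacity = 10000L,
                       noise_decay = 0.99, actor_lr = 0.001,
                       critic_lr = 0.001, seed = 1L) {
  stopifnot(T >= 1, T1 >= 0, T1 <= T, gamma >= 0, gamma <= 1,
            delta1 >= 0, delta2 >= 0, a < b, tau > 0, tau <= 1, N >= 1,
            policy_delay >= 1, buffer_capacity >= N)
  structure(list(T = as.integer(T), T1 = as.integer(T1), gamma = gamma,
                 delta1 = delta1, delta2 = delta2, a = a, b = b, tau = tau,
                 N = as.integer(N), policy_delay = as.integer(policy_delay),
                 buffer_capacity = as.integer(buffer_capacity),
                 noise_decay = noise_decay, actor_lr = actor_lr,
                 critic_lr = critic_lr, seed = as.integer(seed)),
            class = "td3_config")
}

#' Read a TD3 configuration from YAML or JSON
#' @param path `.yaml`/`.yml` or `.json` file of [td3_config()] fields.
#' @return a `td3_config`.
#' @export
read_td3_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path)
  raw <- fix_yaml_bool_keys(raw)
  bad <- setdiff(names(raw), names(formals(td3_config)))
  if (length(bad))
    stop("unknown TD3 config key(s): ", paste(bad, collapse = ", "))
  do.call(td3_config, raw)
}

#' FIFO replay buffer for pruning transitions
#'
#' @param capacity maximum number of stored transitions; the oldest is
#'   evicted first.
#' @return a `replay_buffer` with closures `add(tr)`, `sample_batch(n)`
#'   (without replacement), and `size()`.
#' @export
replay_buffer <- function(capacity = 10000L) {
  store <- vector("list", 0)
  add <- function(tr) {
    store[[length(store) + 1L]] <<- tr
    if (length(store) > capacity) store <<- store[-1L]
    invisible(NULL)
  }
  sample_batch <- function(n) {
    if (length(store) < n)
      stop("replay buffer holds ", length(store), " < ", n, " transitions")
    store[sample.int(length(store), n)]
  }
  structure(list(add = add, sample_batch = sample_batch,
                 size = function() length(store),
                 dump = function() store),
            class = "replay_buffer")
}

# one draw from a truncated normal on [a, b] by inverse-CDF
rtruncnorm1 <- function(a, b, mean, sd) {
  if (sd <= 0) return(min(max(mean, a), b))
  lo <- stats::pnorm(a, mean, sd)
  hi <- stats::pnorm(b, mean, sd)
  x <- stats::qnorm(stats::runif(1, lo, hi), mean, sd)
  min(max(x, a), b)   # guard qnorm edge cases
}

#' Behavior policy: exploration action for an episode
#'
#' During the exploration phase (`episode <= T1`) actions are uniform on
#' `[a, b]`. Afterwards the deterministic actor output is perturbed with
#' truncated Gaussian noise on `[a, b]` whose scale starts at `delta1`
#' and decays exponentially with the episode index, giving a smooth
#' hand-over from exploration to exploitation.
#'
#' @param nets an [agent_nets()].
#' @param g a [build_channel_graph()] state.
#' @param episode 1-based episode index.
#' @param cfg a [td3_config()].
#' @return action in `[a, b]`.
#' @export
explore_action <- function(nets, g, episode, cfg) {
  stopifnot(episode >= 1)
  if (episode <= cfg$T1) return(stats::runif(1, cfg$a, cfg$b))
  mu <- actor_forward(nets, g)
  sd <- cfg$delta1 * cfg$noise_decay^(episode - cfg$T1)
  rtruncnorm1(cfg$a, cfg$b, mu, sd)
}

#' Clipped double-Q regression targets for a batch
#'
#' For each transition the target action is the target actor's proposal
#' for the next state plus Gaussian smoothing noise `N(0, delta2)`,
#' clipped to `[a, b]`; the target value is
#' `r + gamma * min(Q'_1, Q'_2)`, with the bootstrap term dropped at
#' terminal transitions.
#'
#' @param nets an [agent_nets()].
#' @param batch list of transitions (`state`, `action`, `reward`,
#'   `next_state`, `done`).
#' @param cfg a [td3_config()].
#' @param critic_fn optional override `function(g, action, which)`
#'   replacing the target critics (used for diagnostics).
#' @param actor_fn optional override `function(g)` replacing the target
#'   actor.
#' @return numeric vector of targets `y`.
#' @export
td3_targets <- function(nets, batch, cfg, critic_fn = NULL, actor_fn = NULL) {
  vapply(batch, function(tr) {
    if (isTRUE(tr$done) || is.null(tr$next_state)) return(tr$reward)
    mu <- if (is.null(actor_fn)) actor_forward(nets, tr$next_state,
                                               target = TRUE)
          else actor_fn(tr$next_state)
    at <- min(max(mu + stats::rnorm(1, 0, cfg$delta2), cfg$a), cfg$b)
    q <- if (is.null(critic_fn))
      c(critic_forward(nets, tr$next_state, at, 1, target = TRUE),
        critic_forward(nets, tr$next_state, at, 2, target = TRUE))
    else c(critic_fn(tr$next_state, at, 1), critic_fn(tr$next_state, at, 2))
    tr$reward + cfg$gamma * min(q)
  }, 0)
}

#' Soft update of the target networks
#'
#' Every target parameter moves toward its online counterpart:
#' `theta' <- tau * theta + (1 - tau) * theta'`.
#'
#' @param nets an [agent_nets()].
#' @param tau soft-update coefficient; `tau = 1` copies exactly.
#' @return updated `agent_nets`.
#' @export
soft_update <- function(nets, tau) {
  for (pair in list(c("t_actor", "actor"), c("t_critic1", "critic1"),
                    c("t_critic2", "critic2"))) {
    tgt <- nets[[pair[1]]]; src <- nets[[pair[2]]]
    for (nm in names(src)) tgt[[nm]] <- tau * src[[nm]] + (1 - tau) * tgt[[nm]]
    nets[[pair[1]]] <- tgt
  }
  nets
}

#' One TD3 update step from a replay mini-batch
#'
#' Regresses both critics onto the clipped double-Q targets
#' ([td3_targets()]) by mean squared error; every `policy_delay`-th call
#' also ascends the actor along `dQ1/da` (deterministic policy gradient)
#' and soft-updates all target networks.
#'
#' @param nets an [agent_nets()].
#' @param batch list of `cfg$N` transitions.
#' @param cfg a [td3_config()].
#' @param step 1-based update step counter (controls the delayed
#'   updates).
#' @param opt optimizer state from a previous call, or `NULL`.
#' @return list `nets`, `opt`, `losses` (critic1, critic2, actor or NA).
#' @export
td3_update <- function(nets, batch, cfg, step, opt = NULL) {
  if (length(batch) < cfg$N)
    stop("batch has ", length(batch), " transitions; cfg$N = ", cfg$N)
  y <- td3_targets(nets, batch, cfg)
  n <- length(batch)
  if (is.null(opt))
    opt <- list(c1 = adam_init(nets$critic1), c2 = adam_init(nets$critic2),
                actor = adam_init(nets$actor))
  closs <- numeric(2)
  for (ci in 1:2) {
    key <- paste0("critic", ci)
    p <- nets[[key]]
    acc <- lapply(p, function(x) x * 0)
    tot <- 0
    for (i in seq_len(n)) {
      fw <- .critic_fwd(p, batch[[i]]$state, batch[[i]]$action,
                        nets$critic_act)
      err <- fw$q - y[i]
      tot <- tot + err^2
      bw <- .critic_bwd(p, fw, 2 * err / n, nets$critic_act)
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + bw$grads[[nm]]
    }
    st <- adam_step(p, acc, opt[[paste0("c", ci)]], cfg$critic_lr)
    nets[[key]] <- st$params
    opt[[paste0("c", ci)]] <- st$state
    closs[ci] <- tot / n
  }
  aloss <- NA_real_
  if (step %% cfg$policy_delay == 0) {
    acc <- lapply(nets$actor, function(x) x * 0)
    tot <- 0
    for (i in seq_len(n)) {
      afw <- .actor_fwd(nets$actor, batch[[i]]$state)
      cfw <- .critic_fwd(nets$critic1, batch[[i]]$state, afw$R,
                         nets$critic_act)
      tot <- tot + cfw$q
      da <- .critic_bwd(nets$critic1, cfw, 1, nets$critic_act)$da
      g <- .actor_bwd(nets$actor, afw, -da / n)   # ascend Q1
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + g[[nm]]
    }
    st <- adam_step(nets$actor, acc, opt$actor, cfg$actor_lr)
    nets$actor <- st$params
    opt$actor <- st$state
    nets <- soft_update(nets, cfg$tau)
    aloss <- -tot / n
  }
  list(nets = nets, opt = opt,
       losses = c(critic1 = closs[1], critic2 = closs[2], actor = aloss))
}

#' TD3 search for the best pruning strategy
#'
#' Runs `cfg$T` episodes of the environment. The first `cfg$T1` episodes
#' act uniformly at random to fill the replay buffer; afterwards the
#' actor proposes retentions perturbed by decaying truncated Gaussian
#' noise, and one TD3 update is performed per episode at the terminal
#' step. The episode with the highest terminal reward is tracked and its
#' pruning result returned.
#'
#' @param env a [prune_env()] (or any object with the same contract).
#' @param cfg a [td3_config()].
#' @param verbose print per-episode progress.
#' @param checkpoint_dir optional directory; the running best strategy,
#'   networks and RNG state are saved there every `checkpoint_every`
#'   episodes, and an interrupted search can be resumed from it.
#' @param checkpoint_every checkpoint period in episodes.
#' @return list with `best` (a `prune_result`), `best_reward`,
#'   `best_episode`, `log` (per-episode data.frame: episode, reward,
#'   mac_ratio, actions as comma-joined string) and final `nets`.
#' @export
td3_search <- function(env, cfg = td3_config(), verbose = FALSE,
                       checkpoint_dir = NULL, checkpoint_every = 50L) {
  force(env)   # any RNG use in the env constructor must precede the seed
  set.seed(cfg$seed)
  nets <- agent_nets(cfg$seed)
  buf <- replay_buffer(cfg$buffer_capacity)
  opt <- NULL
  step <- 0L
  best <- NULL; best_reward <- -Inf; best_episode <- NA_integer_
  log <- vector("list", cfg$T)
  start_t <- 1L
  if (!is.null(checkpoint_dir) &&
      file.exists(file.path(checkpoint_dir, "search_state.rds"))) {
    ck <- readRDS(file.path(checkpoint_dir, "search_state.rds"))
    nets <- ck$nets; opt <- ck$opt; step <- ck$step
    best <- ck$best; best_reward <- ck$best_reward
    best_episode <- ck$best_episode; log <- ck$log; start_t <- ck$t + 1L
    for (tr in ck$buffer) buf$add(tr)
    .Random.seed <<- ck$rng
  }
  for (t in seq(start_t, cfg$T)) {
    s <- env$reset()
    transitions <- list()
    reward <- 0
    for (l in seq_len(env$n_groups)) {
      prop <- explore_action(nets, s, t, cfg)
      out <- env$step(prop)
      transitions[[l]] <- out
      buf$add(out)
      s <- out$next_state
      if (out$done) reward <- out$reward
    }
    res <- env$result()
    if (reward > best_reward) {
      best_reward <- reward
      best <- res
      best$reward <- reward
      best_episode <- t
    }
    if (t > cfg$T1 && buf$size() >= cfg$N) {
      step <- step + 1L
      up <- td3_update(nets, buf$sample_batch(cfg$N), cfg, step, opt)
      nets <- up$nets; opt <- up$opt
    }
    log[[t]] <- data.frame(
      episode = t, reward = reward, mac_ratio = res$mac_ratio,
      actions = paste(round(res$retention, 4), collapse = ","))
    if (verbose && t %% 10 == 0)
      cat(sprintf("episode %4d  reward %.5f  best %.5f (ep %d)\n",
                  t, reward, best_reward, best_episode))
    if (!is.null(checkpoint_dir) && t %% checkpoint_every == 0) {
      dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      saveRDS(list(nets = nets, opt = opt, step = step, best = best,
                   best_reward = best_reward, best_episode = best_episode,
                   log = log, t = t, rng = .Random.seed,
                   buffer = buf$dump()),
              file.path(checkpoint_dir, "search_state.rds"))
    }
  }
  list(best = best, best_reward = best_reward, best_episode = best_episode,
       log = do.call(rbind, log[!vapply(log, is.null, TRUE)]), nets = nets)
}
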