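rand_graph2 <- function(M, seed = 1) {
  set.seed(seed)
  build_channel_graph(matrix(runif(M * 11), M, 11),
                      matrix(rnorm(M * 6), M, 6), k_nn = 3)
}
mk_tr <- function(seed, reward = 0, done = FALSE) {
  list(state = rand_graph2(5, seed), action = runif(1, 0.2, 1),
       reward = reward,
       next_state = if (done) NULL else rand_graph2(5, seed + 1000),
       done = done)
}

test_that("exploration policy: uniform phase, exact actor at zero noise, bounded", {
  nets <- agent_nets(1)
  cfg <- td3_config(T = 200, T1 = 100, seed = 1)
  g <- rand_graph2(6, 3)
  set.seed(4)
  draws <- replicate(2000, explore_action(nets, g, episode = 50, cfg))
  expect_true(all(draws >= cfg$a & draws <= cfg$b))
  ks <- ks.test(draws, "punif", cfg$a, cfg$b)
  expect_gt(ks$p.value, 0.001)
  cfg0 <- td3_config(T = 200, T1 = 100, delta1 = 0)
  expect_equal(explore_action(nets, g, episode = 150, cfg0),
               actor_forward(nets, g))
  set.seed(5)
  late <- replicate(500, explore_action(nets, g, episode = 101, cfg))
  expect_true(all(late >= cfg$a & late <= cfg$b))
  # noise decays: late-episode draws hug the actor output more tightly
  very_late <- replicate(500, explore_action(nets, g, episode = 500, cfg))
  expect_lt(sd(very_late), sd(late))
})

test_that("targets: gamma = 0 returns rewards; stub critics use the minimum", {
  nets <- agent_nets(2)
  batch <- lapply(1:6, function(i) mk_tr(i, reward = i / 10))
  cfg0 <- td3_config(gamma = 0)
  expect_equal(td3_targets(nets, batch, cfg0), (1:6) / 10)
  cfg <- td3_config(gamma = 0.5, delta2 = 0)
  y <- td3_targets(nets, batch, cfg,
                   critic_fn = function(g, a, which) if (which == 1) 2 else 3)
  expect_equal(y, (1:6) / 10 + 0.5 * 2)
  # terminal transitions never bootstrap
  term <- lapply(1:4, function(i) mk_tr(i, reward = 1, done = TRUE))
  expect_equal(td3_targets(nets, term, cfg), rep(1, 4))
  # clipped double-Q: target never exceeds either single-critic target
  y2 <- td3_targets(nets, batch, td3_config(gamma = 0.9, delta2 = 0))
  y_each <- vapply(batch, function(tr) {
    at <- actor_forward(nets, tr$next_state, target = TRUE)
    tr$reward + 0.9 * min(
      critic_forward(nets, tr$next_state, at, 1, target = TRUE),
      critic_forward(nets, tr$next_state, at, 2, target = TRUE))
  }, 0)
  expect_equal(y2, y_each, tolerance = 1e-12)
})

test_that("soft update: tau = 1 copies, tau < 1 contracts geometrically", {
  nets <- agent_nets(3)
  nets$actor$W1 <- nets$actor$W1 + 1   # desynchronize
  full <- soft_update(nets, 1)
  expect_equal(full$t_actor, full$actor)
  expect_equal(full$t_critic1, full$critic1)
  half <- soft_update(nets, 0.25)
  gap0 <- nets$actor$W1 - nets$t_actor$W1
  gap1 <- nets$actor$W1 - half$t_actor$W1
  expect_equal(gap1, 0.75 * gap0, tolerance = 1e-12)
})

test_that("replay buffer evicts FIFO and samples without replacement", {
  buf <- replay_buffer(5)
  for (i in 1:8) buf$add(list(id = i))
  expect_equal(buf$size(), 5)
  ids <- vapply(buf$dump(), `[[`, 0, "id")
  expect_equal(ids, 4:8)                      # oldest evicted first
  set.seed(1)
  s <- buf$sample_batch(5)
  expect_equal(sort(vapply(s, `[[`, 0, "id")), 4:8)  # no duplicates
  expect_error(buf$sample_batch(6), "holds")
})

test_that("a TD3 update step moves critics toward the targets", {
  set.seed(21)
  nets <- agent_nets(21)
  cfg <- td3_config(N = 8, gamma = 0, policy_delay = 2)
  batch <- lapply(1:8, function(i) mk_tr(i + 50, reward = 0.9, done = TRUE))
  q0 <- mean(vapply(batch, function(tr)
    critic_forward(nets, tr$state, tr$action), 0))
  for (s in 1:30) {
    up <- td3_update(nets, batch, cfg, step = s,
                     opt = if (s == 1) NULL else opt)
    nets <- up$nets; opt <- up$opt
  }
  q1 <- mean(vapply(batch, function(tr)
    critic_forward(nets, tr$state, tr$action), 0))
  expect_lt(abs(q1 - 0.9), abs(q0 - 0.9))
  expect_error(td3_update(nets, batch[1:3], cfg, 1), "transitions")
})

test_that("search on a pruning environment is seeded and tracks its best", {
  m <- tiny_model()
  env <- prune_env(m, prune_budget(0.5, count_macs(m$spec)$total),
                   eval_set = tiny_pipeline()$valid)
  cfg <- td3_config(T = 8, T1 = 8, N = 8, buffer_capacity = 100, seed = 13)
  a <- td3_search(env, cfg)   # pure exploration: no updates performed
  b <- td3_search(env, cfg)
  expect_equal(a$log$reward, b$log$reward)
  expect_equal(a$best_reward, max(a$log$reward))
  expect_equal(a$best$reward, a$best_reward)
  expect_equal(cummax(a$log$reward)[8], a$best_reward)
  expect_lte(a$best$mac_ratio, 0.5)
})
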