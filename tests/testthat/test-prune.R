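test_that("coupling groups partition the prunable layers correctly", {
  spec <- build_sresnet(num_classes = 4)
  g <- coupling_groups(spec)
  expect_length(g, 5)
  expect_equal(vapply(g, `[[`, 0L, "c_in"), c(32L, 64L, 64L, 128L, 128L))
  consumers <- unlist(lapply(g, `[[`, "consumers"))
  expect_false("conv1" %in% consumers)            # excluded from pruning
  expect_false("fc2" %in% consumers)              # head output untouched
  # every other weighted layer appears as a consumer exactly once
  expect_setequal(consumers, c("b1_conva", "b1_short", "b1_convb",
                               "b2_conva", "b2_short", "b2_convb", "fc1"))
  expect_equal(anyDuplicated(consumers), 0L)
  # residual groups tie conv_b and shortcut producers together
  expect_setequal(g[[3]]$producers, c("b1_convb", "b1_short"))
  expect_setequal(g[[5]]$producers, c("b2_convb", "b2_short"))
})

test_that("channel importance is the L2 norm over concatenated slices", {
  m <- init_sresnet(build_sresnet(num_classes = 4), 3)
  g <- coupling_groups(m$spec)
  # single consumer with handpicked weights: 3-4-5 triangle
  m2 <- m
  m2$weights$b1_convb$W[] <- 0
  m2$weights$b1_convb$W[1, 1, 1] <- 3
  m2$weights$b1_convb$W[1, 1, 2] <- 4
  sc <- channel_importance(m2, g[[2]])
  expect_equal(sc[1], 5)
  expect_equal(sc[2], 0)
  # dead channel scores zero and is pruned first
  m3 <- m
  m3$weights$b1_convb$W[, 7, ] <- 0
  pr <- prune_group(m3, g[[2]], R = 0.9)
  expect_false(7 %in% pr$kept)
  # brute-force oracle on random models, joint groups included
  set.seed(19)
  for (i in 1:5) {
    mm <- init_sresnet(random_small_spec(), seed = i + 30)
    for (gr in coupling_groups(mm$spec)) {
      sc <- channel_importance(mm, gr)
      ref <- vapply(seq_len(gr$c_in), function(ch) {
        ss <- 0
        for (nm in gr$consumers) {
          W <- mm$weights[[nm]]$W
          sl <- if (length(dim(W)) == 3) W[, ch, ] else W[, ch]
          ss <- ss + sum(sl^2)
        }
        sqrt(ss)
      }, 0)
      expect_equal(sc, ref, tolerance = 1e-12)
    }
  }
})

test_that("prune_group keeps the top-ranked channels and respects the floor", {
  m <- init_sresnet(build_sresnet(num_classes = 4), 5)
  g <- coupling_groups(m$spec)[[2]]
  sc <- channel_importance(m, g)
  pr <- prune_group(m, g, R = 0.5)
  expect_length(pr$kept, 32)               # ceil(0.5 * 64)
  expect_setequal(pr$kept, order(sc, decreasing = TRUE)[1:32])
  expect_equal(pr$kept, sort(pr$kept))     # original order preserved
  prf <- prune_group(m, g, R = 0.01)       # floored at ceil(0.2 * 64)
  expect_length(prf$kept, 13)
  expect_error(prune_group(m, g, R = 1.5), "retention")
})

test_that("identity retention leaves the network function untouched", {
  m <- tiny_model()
  pr <- prune_model(m, rep(1, 5))
  X <- feature_matrix(tiny_pipeline()$test)[1:100, ]
  expect_equal(predict_scores(pr$model, X), predict_scores(m, X),
               tolerance = 1e-6)
  expect_equal(pr$retention, rep(1, 5))
})

test_that("pruning the head group equals masking the pooled features", {
  m <- tiny_model()
  g5 <- coupling_groups(m$spec)[[5]]
  pr <- prune_group(m, g5, R = 0.4)
  X <- feature_matrix(tiny_pipeline()$test)[1:50, ]
  pruned <- predict_scores(pr$model, X)
  # dense model with the dropped channels zeroed at the pooled layer
  G <- herdprune:::sres_forward(m, X, keep = TRUE)$cache$G
  mask <- rep(0, nrow(G)); mask[pr$kept] <- 1
  H <- m$weights$fc1$W %*% (G * mask) + m$weights$fc1$b
  dense_masked <- t(m$weights$fc2$W %*% H + m$weights$fc2$b)
  expect_equal(pruned, dense_masked, tolerance = 1e-10)
})

test_that("MAC bookkeeping is conserved along an episode", {
  m <- tiny_model()
  total <- count_macs(m$spec)$total
  lg <- herdprune:::.layer_group
  cur <- m
  set.seed(8)
  retained <- runif(5, 0.3, 0.9)
  for (l in 1:5) {
    per <- count_macs(cur$spec)$per_layer
    reduced <- total - sum(per$macs)
    rest <- sum(per$macs[lg[per$layer] > l])
    decided_kept <- sum(per$macs[lg[per$layer] <= l])
    expect_equal(reduced + rest + decided_kept, total)
    if (l == 1) expect_equal(reduced, 0)
    if (l == 5) expect_equal(rest, 0)
    gr <- coupling_groups(cur$spec)[[l]]
    cur <- prune_group(cur, gr, retained[l])$model
  }
})

test_that("feasible_action clamps to the budget and never goes below r_min", {
  spec <- build_sresnet(num_classes = 4)
  total <- count_macs(spec)$total
  # no budget pressure: identity clamp
  b1 <- prune_budget(1.0, total)
  expect_equal(feasible_action(b1, spec, integer(0), 0.9), 0.9)
  expect_equal(feasible_action(b1, spec, integer(0), 0.1), 0.2)  # floor
  # tight budget with all earlier groups kept in full: the final group
  # must absorb the whole reduction
  b2 <- prune_budget(0.6, total)
  a <- feasible_action(b2, spec, c(32L, 64L, 64L, 128L), 1.0)
  expect_lt(a, 1.0)
  expect_gte(a, 0.2)
  # the clamp is exactly the largest feasible kept count
  k <- ceiling(a * 128)
  w_keep <- function(k5) c(32, 64, 64, 128, k5, 64)
  macs_w <- function(w) count_macs(build_sresnet(
    widths = c(conv1 = w[1], b1_conva = w[2], b1_out = w[3],
               b2_conva = w[4], b2_out = w[5], fc1 = w[6]),
    num_classes = 4))$total
  expect_lte(macs_w(w_keep(k)), 0.6 * total)
  expect_gt(macs_w(w_keep(k + 1)), 0.6 * total)
  # a genuinely unachievable budget is rejected up front
  expect_error(feasible_action(prune_budget(0.3, total), spec,
                               c(32L, 64L, 64L, 128L), 1.0), "infeasible")
})

test_that("episodes respect the budget under random policies", {
  m <- init_sresnet(build_sresnet(num_classes = 4), 77)   # weights suffice
  total <- count_macs(m$spec)$total
  set.seed(55)
  for (Rt in c(0.35, 0.6)) {
    env <- prune_env(m, prune_budget(Rt, total), eval_set = NULL)
    for (i in 1:10) {
      ep <- run_prune_episode(env, function(s, l) runif(1, 0.2, 1))
      expect_lte(ep$result$mac_ratio, Rt + 1e-12)
      expect_true(all(ep$result$retention >= 0.2 - 1e-12))
      expect_length(ep$transitions, 5)
    }
  }
  expect_error(prune_env(m, prune_budget(0.01, total)), "infeasible")
})

test_that("episodes are deterministic and serializable", {
  m <- tiny_model()
  env <- prune_env(m, prune_budget(0.5, count_macs(m$spec)$total),
                   eval_set = tiny_pipeline()$valid)
  pol <- function(s, l) c(0.9, 0.8, 0.7, 0.6, 0.5)[l]
  a <- run_prune_episode(env, pol)
  b <- run_prune_episode(env, pol)
  expect_equal(a$result$retention, b$result$retention)
  expect_equal(a$result$reward, b$result$reward)
  js <- jsonlite::fromJSON(prune_result_to_json(a$result))
  expect_equal(js$mac_ratio, a$result$mac_ratio, tolerance = 1e-12)
  expect_equal(unlist(js$retention), a$result$retention)
})
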