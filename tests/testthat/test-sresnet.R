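test_that("default architecture has the expected layers and serializes", {
  spec <- build_sresnet(num_classes = 4)
  expect_length(spec$layers, 9)          # 7 conv + 2 fc weighted layers
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  expect_equal(sum(kinds == "conv1d"), 7)
  expect_equal(sum(kinds == "fc"), 2)
  expect_equal(spec$layers$b1_short$k, 1L)
  expect_equal(spec$layers$b1_conva$k, 3L)
  one <- build_sresnet(num_classes = 1)
  expect_equal(one$layers$fc2$out_ch, 1L)
  js <- spec_to_json(spec)
  expect_equal(spec_from_json(js), spec)
  bad <- spec
  bad$layers$b1_short$out_ch <- 99L
  expect_error(validate_model_spec(bad), "b1_convb.*b1_short")
})

test_that("MAC accounting matches the element-walking oracle and is monotone", {
  expect_equal(count_macs(build_sresnet(num_classes = 6))$millions, 1.040)
  expect_equal(count_macs(build_sresnet(num_classes = 4))$millions, 1.040)
  set.seed(17)
  for (i in 1:10) {
    spec <- random_small_spec()
    mr <- count_macs(spec)
    expect_equal(mr$total, brute_force_macs(spec))
    expect_equal(mr$total, sum(mr$per_layer$macs))
  }
  base <- count_macs(build_sresnet(num_classes = 4))$total
  for (nm in c("conv1", "b1_conva", "b1_out", "b2_conva", "b2_out", "fc1")) {
    w <- c(conv1 = 32, b1_conva = 64, b1_out = 64, b2_conva = 128,
           b2_out = 128, fc1 = 64)
    w[nm] <- w[nm] + 1
    expect_gt(count_macs(build_sresnet(widths = w, num_classes = 4))$total,
              base)
  }
})

test_that("forward pass matches a literal per-element reference", {
  set.seed(23)
  for (i in 1:5) {
    m <- init_sresnet(random_small_spec(), seed = i)
    # make BN statistics non-trivial
    for (nm in names(m$weights))
      if ("rm" %in% names(m$weights[[nm]])) {
        m$weights[[nm]]$rm <- rnorm(length(m$weights[[nm]]$rm), 0, 0.3)
        m$weights[[nm]]$rv <- runif(length(m$weights[[nm]]$rv), 0.5, 2)
      }
    X <- matrix(rnorm(3 * 10), 3, 10)
    fast <- predict_scores(m, X)
    for (r in 1:3)
      expect_equal(unname(fast[r, ]), naive_sres_forward(m, X[r, ]),
                   tolerance = 1e-10)
  }
})

test_that("symmetries: zero weights give equal scores; fc2 permutation permutes", {
  spec <- build_sresnet(widths = c(conv1 = 3, b1_conva = 4, b1_out = 4,
                                   b2_conva = 5, b2_out = 5, fc1 = 4),
                        num_classes = 4)
  m <- init_sresnet(spec, 1)
  for (nm in names(m$weights))
    for (f in intersect(names(m$weights[[nm]]), c("W", "b", "gamma", "beta")))
      m$weights[[nm]][[f]] <- m$weights[[nm]][[f]] * 0
  sc <- predict_scores(m, matrix(rnorm(20), 2, 10))
  expect_true(all(abs(sc - sc[, 1]) < 1e-12))
  m2 <- init_sresnet(spec, 2)
  perm <- c(3, 1, 4, 2)
  m3 <- m2
  m3$weights$fc2$W <- m2$weights$fc2$W[perm, ]
  m3$weights$fc2$b <- m2$weights$fc2$b[perm]
  X <- matrix(rnorm(40), 4, 10)
  expect_equal(predict_scores(m3, X), predict_scores(m2, X)[, perm],
               tolerance = 1e-12)
})

test_that("residual ablation: dead main branch leaves the shortcut path", {
  spec <- build_sresnet(widths = c(conv1 = 3, b1_conva = 4, b1_out = 4,
                                   b2_conva = 5, b2_out = 5, fc1 = 4),
                        num_classes = 3)
  m <- init_sresnet(spec, 4)
  for (f in c("W", "b", "gamma", "beta"))
    m$weights$b2_convb[[f]] <- m$weights$b2_convb[[f]] * 0
  x <- rnorm(10)
  ref <- naive_sres_forward(m, x)   # oracle handles the zeroed branch too
  expect_equal(unname(predict_scores(m, matrix(x, 1))[1, ]), ref,
               tolerance = 1e-10)
  # block output now equals ReLU(shortcut): doubling conv_b weights back in
  # changes the output, zero branch does not react to conv_a changes
  m2 <- m
  m2$weights$b2_conva$W <- m2$weights$b2_conva$W * 2
  expect_equal(predict_scores(m2, matrix(x, 1)),
               predict_scores(m, matrix(x, 1)), tolerance = 1e-12)
})

test_that("training fits a separable toy problem and logs per epoch", {
  set.seed(61)
  n <- 10
  df <- data.frame(matrix(rnorm(20 * 10, 0, 0.2), 20, 10))
  names(df) <- herdprune:::hp_feature_names()
  df$ax <- df$ax + rep(c(-2, 2), each = n)
  df$label <- rep(0:1, each = n)
  ds <- herd_dataset(df, c("a", "b"))
  spec <- build_sresnet(widths = c(conv1 = 4, b1_conva = 6, b1_out = 6,
                                   b2_conva = 8, b2_out = 8, fc1 = 6),
                        num_classes = 2)
  m <- train_classifier(spec, ds, cfg = train_config(epochs = 40,
                                                     batch_size = 8,
                                                     seed = 2))
  expect_equal(nrow(m$log), 40)
  expect_equal(max(m$log$acc), 1)
  expect_equal(mean(predict_classes(m, ds) == ds$frames$label), 1)
})

test_that("epochs = 0 returns the initialized model; lr = 0 finetune is a no-op", {
  spec <- build_sresnet(num_classes = 4)
  tp <- tiny_pipeline()
  m0 <- train_classifier(spec, tp$train, cfg = train_config(epochs = 0, seed = 3))
  expect_equal(nrow(m0$log), 0)
  expect_equal(herdprune:::flatten_params(m0$weights),
               herdprune:::flatten_params(init_sresnet(spec, 3)$weights))
  m1 <- finetune(tiny_model(), tp$train,
                 cfg = train_config(lr = 0, epochs = 1, seed = 4))
  expect_equal(herdprune:::flatten_params(m1$weights),
               herdprune:::flatten_params(tiny_model()$weights))
})

test_that("training is reproducible and improves with fine-tuning hooks", {
  tp <- tiny_pipeline()
  cfg <- train_config(epochs = 2, seed = 9)
  a <- train_classifier(build_sresnet(num_classes = 4), tp$train, cfg = cfg)
  b <- train_classifier(build_sresnet(num_classes = 4), tp$train, cfg = cfg)
  expect_identical(herdprune:::flatten_params(a$weights),
                   herdprune:::flatten_params(b$weights))
  expect_identical(a$log$loss, b$log$loss)
})

test_that("checkpoints round-trip through save/load", {
  m <- tiny_model()
  d <- file.path(tempdir(), "ckpt_test")
  save_sresnet(m, d)
  m2 <- load_sresnet(d)
  expect_equal(m2$spec, m$spec)
  expect_equal(m2$weights, m$weights)
  X <- matrix(rnorm(30), 3, 10)
  expect_equal(predict_scores(m2, X), predict_scores(m, X))
})
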