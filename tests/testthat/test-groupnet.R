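small_cfg <- function(epochs = 10, batch_size = 32, ...) {
  groupnet_config(n_features = 16, n_classes = 2, n_groups = 2,
                  kernels_per_unit = 4, clustered_kernels = 6,
                  fc_units = 24, dropout_rate = 0, epochs = epochs,
                  batch_size = batch_size, learning_rate = 0.02,
                  seed = 5, ...)
}

test_that("forward pass emits valid probability rows", {
  cfg <- small_cfg()
  m <- groupnet_init(cfg)
  X <- matrix(runif(7 * 16), 7, 16)
  p <- groupnet_forward(m, X)
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-6)
  # zero-initialized output layer: exactly uniform probabilities
  expect_true(all(abs(p - 0.5) < 1e-12))
})

test_that("evaluation forward pass is deterministic despite dropout config", {
  cfg <- groupnet_config(n_features = 16, n_classes = 2, n_groups = 2,
                         kernels_per_unit = 4, clustered_kernels = 6,
                         fc_units = 24, dropout_rate = 0.5, seed = 5)
  m <- groupnet_init(cfg)
  X <- matrix(runif(5 * 16), 5, 16)
  expect_identical(groupnet_forward(m, X), groupnet_forward(m, X))
})

test_that("group convolution uses fewer parameters than the dense equivalent", {
  pc <- groupnet_param_count(groupnet_config(100, 8))
  expect_lt(pc$group_conv_params, pc$dense_conv_params)
  # single-group layout coincides with the dense convolution
  pc1 <- groupnet_param_count(groupnet_config(100, 8, n_groups = 1))
  expect_equal(pc1$group_conv_params, pc1$dense_conv_params)
})

test_that("the network memorizes a 64-sample fixture (capacity check)", {
  d <- separable_classes(n = 64, p = 16, shift = 1, seed = 3)
  d <- minmax_apply(d, minmax_fit(d))
  cfg <- small_cfg(epochs = 200, batch_size = 64)
  fit <- groupnet_train(d, "lp_class", mode = "lp", config = cfg)
  expect_lt(min(fit$history$loss), 0.1)
})

test_that("validation accuracy peaks within twice the configured epochs", {
  d <- separable_classes(n = 600, p = 16, seed = 6)
  sp <- split_train_test(d, 0.8, seed = 1)
  pars <- minmax_fit(sp$train)
  tr <- minmax_apply(sp$train, pars)
  te <- minmax_apply(sp$test, pars)
  cfg <- small_cfg(epochs = 20, batch_size = 64)
  fit <- groupnet_train(tr, "lp_class", mode = "lp", config = cfg,
                        validation = te)
  expect_lte(glance(fit)$best_epoch, 2 * 10)
})

test_that("shuffled labels train to chance-level accuracy", {
  d <- separable_classes(n = 600, p = 16, seed = 7)
  withr::with_seed(1, d$lp_class <- sample(d$lp_class))
  sp <- split_train_test(d, 0.8, seed = 2)
  pars <- minmax_fit(sp$train)
  fit <- groupnet_train(minmax_apply(sp$train, pars), "lp_class",
                        mode = "lp", config = small_cfg())
  pred <- groupnet_predict(fit, minmax_apply(sp$test, pars))
  acc <- mean(pred$.pred_class == sp$test$lp_class)
  expect_lt(abs(acc - 0.5), 0.1)
})

test_that("zero-coupling association training equals plain anchor cross-entropy", {
  withr::with_seed(5, {
    d <- separable_classes(n = 200, p = 16, seed = 8)
    d$label_a <- as.integer(d$lp_class == 2)
    d$label_b <- rbinom(200, 1, 0.5)
    d$lp_class <- NULL
  })
  d <- minmax_apply(d, minmax_fit(d))
  cfg <- small_cfg(epochs = 5)
  spec0 <- manual_loss_spec("a", "b", 0)
  fit_cl <- groupnet_train(d, mode = "br", config = cfg,
                           loss_spec = spec0)
  fit_ce <- groupnet_train(d, mode = "br", config = cfg, anchor = "a")
  expect_equal(fit_cl$history$loss, fit_ce$history$loss, tolerance = 1e-12)
  expect_equal(fit_cl$model$W_fc, fit_ce$model$W_fc, tolerance = 1e-12)
  expect_equal(fit_cl$model$heads[[1]]$W, fit_ce$model$heads[[1]]$W,
               tolerance = 1e-12)
})

test_that("binary-relevance prediction thresholds heads at 0.5 inclusive", {
  cfg <- small_cfg()
  fit <- structure(list(model = groupnet_init(cfg, "br"), mode = "br",
                        features = paste0("f", 1:16),
                        head_names = c("a", "b")),
                   class = "groupnet_fit")
  fit$model$trained <- TRUE
  # zero heads give probability exactly 0.5 everywhere -> positive call
  X <- matrix(runif(4 * 16), 4, 16,
              dimnames = list(NULL, paste0("f", 1:16)))
  pred <- groupnet_predict(fit, tibble::as_tibble(X))
  expect_true(all(pred$.prob_a == 0.5))
  expect_true(all(pred$.pred_a == 1L))
})

test_that("predictions are invariant to batch order", {
  d <- separable_classes(n = 120, p = 16, seed = 9)
  d <- minmax_apply(d, minmax_fit(d))
  fit <- groupnet_train(d, "lp_class", mode = "lp",
                        config = small_cfg(epochs = 3))
  perm <- withr::with_seed(2, sample(nrow(d)))
  p1 <- groupnet_predict(fit, d)
  p2 <- groupnet_predict(fit, d[perm, ])
  expect_equal(p2$.pred_class, p1$.pred_class[perm])
  expect_equal(p2$.prob_1, p1$.prob_1[perm])
})

test_that("training is reproducible and rejects empty input", {
  d <- separable_classes(n = 100, p = 16, seed = 10)
  d <- minmax_apply(d, minmax_fit(d))
  f1 <- groupnet_train(d, "lp_class", config = small_cfg(epochs = 2))
  f2 <- groupnet_train(d, "lp_class", config = small_cfg(epochs = 2))
  expect_identical(f1$history, f2$history)
  expect_error(groupnet_train(d[0, ], "lp_class", config = small_cfg()),
               class = "expotox_empty_error")
})
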