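test_that("gru step follows the gate algebra at zero weights", {
  p <- gru_params_init(2, 3, seed = 1)
  for (nm in c("Wr", "Ur", "Wz", "Uz", "U", "W")) p[[nm]][] <- 0
  p$bh[] <- 0
  st <- gru_step(p, c(1, -1), c(2, -4, 6))
  expect_equal(st$r, rep(0.5, 3))
  expect_equal(st$z, rep(0.5, 3))
  expect_equal(st$h_tilde, rep(0, 3))
  expect_equal(st$h, 0.5 * c(2, -4, 6))
})

test_that("a saturated update gate preserves the previous state", {
  p <- gru_params_init(1, 2, seed = 2)
  p$Wz[] <- 50          # z -> 1 for positive input
  h_prev <- c(0.3, -0.7)
  st <- gru_step(p, 1, h_prev)
  expect_equal(st$h, h_prev, tolerance = 1e-8)
})

test_that("gates stay in (0,1) and the state is bounded", {
  withr::with_seed(3, {
    for (i in 1:50) {
      p <- gru_params_init(3, 4, seed = i, init_sd = 0.8)
      x <- rnorm(3, 0, 2); h <- rnorm(4, 0, 2)
      st <- gru_step(p, x, h)
      expect_true(all(st$r > 0 & st$r < 1))
      expect_true(all(st$z > 0 & st$z < 1))
      expect_true(all(abs(st$h_tilde) < 1))
      expect_true(all(abs(st$h) <= pmax(abs(h), 1) + 1e-12))
    }
  })
  expect_error(gru_step(gru_params_init(2, 3), c(1, 2, 3), rep(0, 3)),
               class = "expotox_config_error")
})

test_that("fitness is the mean squared error; population total is the sum", {
  expect_equal(fitness_mse(c(1, 2), c(1, 2)), 0)
  expect_equal(fitness_mse(c(1, 1), c(0, 0)), 1)
  expect_equal(population_fitness(c(0.5, 1.5)), 2)
  expect_error(fitness_mse(numeric(), numeric()),
               class = "expotox_config_error")
})

test_that("roulette selection weights by inverse fitness", {
  expect_equal(roulette_probs(c(1, 3)), c(0.75, 0.25))
  expect_equal(roulette_probs(rep(2, 4)), rep(0.25, 4))
  expect_equal(sum(roulette_probs(runif(10, 0.1, 5))), 1)
  # scale invariance
  e <- c(0.2, 1, 4)
  expect_equal(roulette_probs(e * 17), roulette_probs(e))
  # empirical frequencies over 10,000 draws
  draws <- withr::with_seed(6, roulette_select(c(1, 3), n = 10000))
  freq <- tabulate(draws, 2) / 10000
  expect_lt(max(abs(freq - c(0.75, 0.25))), 0.02)
  expect_error(roulette_probs(numeric()), class = "expotox_empty_error")
})

test_that("real crossover exchanges positions and preserves values", {
  a <- c(1, 2, 3, 4); b <- c(5, 6, 7, 8)
  same <- withr::with_seed(1, real_crossover(a, b, p_swap = 0))
  expect_equal(same$child_a, a)
  expect_equal(same$child_b, b)
  full <- withr::with_seed(1, real_crossover(a, b, p_swap = 1))
  expect_equal(full$child_a, b)
  expect_equal(full$child_b, a)
  withr::with_seed(2, {
    for (i in 1:20) {
      cx <- real_crossover(a, b, p_swap = 0.5)
      for (j in 1:4) {
        expect_setequal(c(cx$child_a[j], cx$child_b[j]), c(a[j], b[j]))
      }
    }
  })
  expect_error(real_crossover(a, b[1:3]), class = "expotox_config_error")
})

test_that("position mutation stays within slot bounds", {
  g <- c(0.5, 10, -2)
  lo <- c(0, 5, -3); hi <- c(1, 20, -1)
  withr::with_seed(4, {
    for (i in 1:1000) {
      out <- position_mutate(g, lo, hi, pv = 0.3)
      expect_true(all(out >= lo & out <= hi))
    }
  })
  # zero-width slot: value unchanged
  expect_equal(withr::with_seed(1, position_mutate(7, 7, 7, pv = 0.2)), 7)
  expect_error(position_mutate(1, 2, 1, pv = 0.1),
               class = "expotox_config_error")
})

test_that("accepted mutation draws are uniform as pv vanishes", {
  vals <- withr::with_seed(5,
    replicate(10000, position_mutate(0, 2, 6, pv = 1e-9)))
  expect_lt(abs(mean(vals) - 4), 0.05)
  # the printed redraw rule biases draws into [pv, 1)
  biased <- withr::with_seed(5,
    replicate(5000, position_mutate(0, 0, 1, pv = 0.5)))
  expect_true(all(biased >= 0.5))
  unbiased <- withr::with_seed(5,
    replicate(5000, position_mutate(0, 0, 1, pv = 0.5, unbiased = TRUE)))
  expect_lt(min(unbiased), 0.5)
})

test_that("selection without crossover or mutation never increases diversity", {
  withr::with_seed(7, {
    pop <- purrr::map(1:8, ~ runif(5))
    fits <- runif(8, 0.1, 2)
    n_distinct <- function(p) length(unique(purrr::map_chr(
      p, ~ paste(round(.x, 12), collapse = ","))))
    div <- n_distinct(pop)
    for (gen in 1:5) {
      idx <- roulette_select(fits, 8)
      children <- purrr::map(seq(1, 8, 2), function(i) {
        real_crossover(pop[[idx[i]]], pop[[idx[i + 1]]], p_swap = 0)
      })
      pop <- purrr::flatten(children)
      fits <- fits[idx]
      expect_lte(n_distinct(pop), div)
      div <- n_distinct(pop)
    }
  })
})

test_that("gru fits a constant series to near-zero error", {
  d <- tibble::tibble(y = rep(5, 200))
  fit <- gru_fit(d, "y", window = 7, epochs = 30, seed = 1)
  pr <- gru_forecast(fit, d)
  expect_lt(fitness_mse(pr$.pred, pr$observed), 1e-3)
  expect_equal(pr$index, 8:200)
})

test_that("gru forecasting is deterministic under a fixed seed", {
  withr::with_seed(2, d <- tibble::tibble(y = cumsum(rnorm(120)),
                                          x = rnorm(120)))
  f1 <- gru_fit(d, "y", "x", window = 5, epochs = 20, seed = 9)
  f2 <- gru_fit(d, "y", "x", window = 5, epochs = 20, seed = 9)
  expect_identical(gru_forecast(f1, d)$.pred, gru_forecast(f2, d)$.pred)
})

test_that("gru recovers a noiseless linear autoregressive target", {
  withr::with_seed(3, {
    x <- sin(2 * pi * (1:300) / 25)
    y <- numeric(300)
    for (t in 2:300) y[t] <- 0.6 * y[t - 1] + 0.4 * x[t - 1]
  })
  d <- tibble::tibble(y = y, x = x)
  tr <- d[1:240, ]; te <- d[221:300, ]   # test windows start fresh
  fit <- gru_fit(tr, "y", "x", window = 7, hidden = 8,
                 learning_rate = 0.02, epochs = 300, patience = 30,
                 seed = 2)
  pr <- gru_forecast(fit, te)
  expect_lt(rmse(pr$.pred, pr$observed), 0.1 * sd(pr$observed))
  expect_error(gru_fit(d[1:5, ], "y", window = 10),
               class = "expotox_config_error")
})

ga_toy_series <- function(seed, T_len = 180, nch = 8) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(T_len * nch), T_len, nch,
                dimnames = list(NULL, paste0("ch", 1:nch)))
    y <- numeric(T_len)
    for (t in 2:T_len) {
      y[t] <- 0.5 * y[t - 1] + 0.8 * X[t - 1, 2] - 0.6 * X[t - 1, 5] +
        rnorm(1, 0, 0.1)
    }
    dplyr::bind_cols(tibble::tibble(y = y), tibble::as_tibble(X))
  })
}

test_that("the GA trace is monotone and a 2-individual run returns the better one", {
  d <- ga_toy_series(1)
  res <- ga_gru_optimize(d, "y", paste0("ch", 1:8),
                         ga = ga_config(num = 6, generations = 3,
                                        seed = 2),
                         window = 5, inner_epochs = 15,
                         inner_patience = 4)
  expect_true(all(diff(res$trace$best_fitness) <= 1e-12))
  tiny <- ga_gru_optimize(d, "y", paste0("ch", 1:8),
                          ga = ga_config(num = 2, generations = 1,
                                         elitism = 1, seed = 3),
                          window = 5, inner_epochs = 10,
                          inner_patience = 3)
  expect_lte(tiny$best_fitness, tiny$trace$best_fitness[1])
})

test_that("the GA mask recovers planted informative channels", {
  hits <- 0
  for (seed in 1:3) {
    d <- ga_toy_series(seed + 10)
    res <- ga_gru_optimize(d, "y", paste0("ch", 1:8),
                           ga = ga_config(num = 10, generations = 5,
                                          seed = seed),
                           window = 5, inner_epochs = 20,
                           inner_patience = 4)
    if (all(c("ch2", "ch5") %in% res$best_decoded$selected)) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 2)
})

test_that("GA-tuned GRU beats the default GRU on a planted panel", {
  wins <- 0
  for (seed in 1:3) {
    d <- ga_toy_series(seed + 20)
    n_train <- floor(nrow(d) * 0.75)
    res <- ga_gru_optimize(d, "y", paste0("ch", 1:8),
                           ga = ga_config(num = 8, generations = 4,
                                          seed = seed),
                           window = 5, inner_epochs = 20,
                           inner_patience = 4)
    plain <- gru_fit(d[seq_len(n_train), ], "y", paste0("ch", 1:8),
                     window = 5, hidden = 8, epochs = 20, patience = 4,
                     seed = seed)
    pr <- gru_forecast(plain, d)
    plain_mse <- fitness_mse(pr$.pred[pr$index > n_train],
                             pr$observed[pr$index > n_train])
    if (res$best_fitness <= plain_mse) wins <- wins + 1
  }
  expect_gte(wins, 2)
})
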