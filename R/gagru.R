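#' Initialize gated-recurrent-unit parameters
#'
#' Reset gate `r_t = sigmoid(Wr x_t + Ur h_{t-1})`, update gate
#' `z_t = sigmoid(Wz x_t + Uz h_{t-1})`, candidate
#' `h~_t = tanh(U x_t + W (r_t * h_{t-1}) + bh)` and state
#' `h_t = z_t * h_{t-1} + (1 - z_t) * h~_t` — with this convention an
#' update gate saturating at 1 preserves the previous state.
#'
#' @param input_dim Input dimension per time step.
#' @param hidden Hidden-state size.
#' @param seed Integer seed.
#' @param init_sd Standard deviation of the Gaussian weight draws.
#'
#' @return A `gru_params` list of weight matrices `Wr`, `Ur`, `Wz`, `Uz`,
#'   `U`, `W`, bias `bh`, and the linear read-out `Wo`, `bo`.
#' @export
gru_params_init <- function(input_dim, hidden, seed = 1L, init_sd = 0.2) {
  withr::with_seed(seed, {
    mk <- function(nr, nc) matrix(rnorm(nr * nc, 0, init_sd), nr, nc)
    structure(list(
      Wr = mk(input_dim, hidden), Ur = mk(hidden, hidden),
      Wz = mk(input_dim, hidden), Uz = mk(hidden, hidden),
      U = mk(input_dim, hidden), W = mk(hidden, hidden),
      bh = rep(0, hidden),
      Wo = mk(hidden, 1), bo = 0,
      input_dim = as.integer(input_dim), hidden = as.integer(hidden)),
      class = "gru_params")
  })
}

#' One gated-recurrent-unit step
#'
#' @param params A `gru_params` object (see [gru_params_init()]).
#' @param x_t Input at time t: a length-`input_dim` vector or an
#'   `n x input_dim` matrix (batched).
#' @param h_prev Previous hidden state: length-`hidden` vector or
#'   `n x hidden` matrix.
#'
#' @return A list with the gate activations `r`, `z` (elementwise in
#'   `(0, 1)`), the candidate `h_tilde` (in `(-1, 1)`) and the new state
#'   `h` (a convex combination of `h_prev` and `h_tilde`).
#' @examples
#' p <- gru_params_init(2, 3)
#' for (nm in c("Wr", "Ur", "Wz", "Uz", "U", "W")) p[[nm]][] <- 0
#' st <- gru_step(p, c(1, 1), c(2, 2, 2))
#' st$r        # 0.5 0.5 0.5
#' st$h        # 1 1 1  (= 0.5 * h_prev)
#' @export
gru_step <- function(params, x_t, h_prev) {
  X <- if (is.matrix(x_t)) x_t else matrix(x_t, 1)
  H <- if (is.matrix(h_prev)) h_prev else matrix(h_prev, 1)
  if (ncol(X) != params$input_dim || ncol(H) != params$hidden) {
    abort("Input or state dimension does not match the parameters.",
          class = "expotox_config_error")
  }
  r <- sigmoid(X %*% params$Wr + H %*% params$Ur)
  z <- sigmoid(X %*% params$Wz + H %*% params$Uz)
  h_tilde <- tanh(X %*% params$U + (r * H) %*% params$W +
                    matrix(params$bh, nrow(X), params$hidden, byrow = TRUE))
  h <- z * H + (1 - z) * h_tilde
  squeeze <- function(m) if (is.matrix(x_t)) m else drop(m)
  list(r = squeeze(r), z = squeeze(z), h_tilde = squeeze(h_tilde),
       h = squeeze(h))
}

# Forward over a window: X_steps is a list of w (n x D) matrices.
gru_forward <- function(params, X_steps, keep_cache = FALSE) {
  n <- nrow(X_steps[[1]])
  H <- matrix(0, n, params$hidden)
  cache <- if (keep_cache) vector("list", length(X_steps))
  for (s in seq_along(X_steps)) {
    st <- gru_step(params, X_steps[[s]], H)
    if (keep_cache) cache[[s]] <- c(st, list(h_prev = H))
    H <- st$h
  }
  yhat <- drop(H %*% params$Wo + params$bo)
  list(yhat = yhat, h = H, cache = cache)
}

# Backpropagation through time for the squared-error loss.
gru_backward <- function(params, fw, X_steps, targets) {
  n <- length(targets)
  dyhat <- matrix(2 * (fw$yhat - targets) / n)
  g <- list(Wr = 0 * params$Wr, Ur = 0 * params$Ur,
            Wz = 0 * params$Wz, Uz = 0 * params$Uz,
            U = 0 * params$U, W = 0 * params$W, bh = 0 * params$bh,
            Wo = t(fw$h) %*% dyhat, bo = sum(dyhat))
  dh <- dyhat %*% t(params$Wo)
  for (s in rev(seq_along(X_steps))) {
    cc <- fw$cache[[s]]
    X <- X_steps[[s]]; Hp <- cc$h_prev
    dz <- dh * (Hp - cc$h_tilde)
    dht <- dh * (1 - cc$z)
    dh_prev <- dh * cc$z
    da <- dht * (1 - cc$h_tilde^2)
    g$U <- g$U + t(X) %*% da
    g$W <- g$W + t(cc$r * Hp) %*% da
    g$bh <- g$bh + colSums(da)
    drh <- da %*% t(params$W)
    dr <- drh * Hp
    dh_prev <- dh_prev + drh * cc$r
    daz <- dz * cc$z * (1 - cc$z)
    g$Wz <- g$Wz + t(X) %*% daz
    g$Uz <- g$Uz + t(Hp) %*% daz
    dh_prev <- dh_prev + daz %*% t(params$Uz)
    dar <- dr * cc$r * (1 - cc$r)
    g$Wr <- g$Wr + t(X) %*% dar
    g$Ur <- g$Ur + t(Hp) %*% dar
    dh_prev <- dh_prev + dar %*% t(params$Ur)
    dh <- dh_prev
  }
  g
}

#' Mean-squared-error fitness
#'
#' The genetic algorithm's fitness is the mean squared error between
#' predictions and targets (lower is fitter); the population total is the
#' plain sum of the individual fitnesses.
#'
#' @param predictions,targets Equal-length numeric vectors.
#' @param fitnesses Numeric vector of individual fitness values.
#'
#' @return A non-negative scalar.
#' @examples
#' fitness_mse(c(1, 1), c(0, 0))     # 1
#' population_fitness(c(0.5, 1.5))   # 2
#' @export
fitness_mse <- function(predictions, targets) {
  check_aligned(predictions, targets)
  mean((predictions - targets)^2)
}

#' @rdname fitness_mse
#' @export
population_fitness <- function(fitnesses) {
  if (!length(fitnesses)) {
    abort("Empty population.", class = "expotox_empty_error")
  }
  sum(fitnesses)
}

#' Roulette-wheel selection probabilities and sampling
#'
#' Selection probability is proportional to inverse fitness,
#' `P(i) = (1/E_i) / sum_j (1/E_j)`, so lower mean squared error makes an
#' individual more likely to be selected. Zero fitnesses are lifted by a
#' tiny epsilon.
#'
#' @param fitnesses Non-negative fitness (MSE) values, one per individual.
#' @param n Number of individuals to draw (with replacement).
#' @param eps Floor added to zero fitnesses.
#'
#' @return `roulette_probs()`: the probability vector (sums to 1);
#'   `roulette_select()`: `n` selected indices.
#' @examples
#' roulette_probs(c(1, 3))  # 0.75 0.25
#' @export
roulette_probs <- function(fitnesses, eps = 1e-12) {
  if (!length(fitnesses)) {
    abort("Empty population.", class = "expotox_empty_error")
  }
  inv <- 1 / pmax(fitnesses, eps)
  inv / sum(inv)
}

#' @rdname roulette_probs
#' @export
roulette_select <- function(fitnesses, n = 1, eps = 1e-12) {
  sample.int(length(fitnesses), n, replace = TRUE,
             prob = roulette_probs(fitnesses, eps))
}

#' Real-coded position-exchange crossover
#'
#' For each genome position independently, with probability `p_swap` the
#' two parents' values are exchanged; the multiset of values at each
#' position is preserved.
#'
#' @param parent_a,parent_b Equal-length numeric genomes.
#' @param p_swap Per-position exchange probability.
#'
#' @return A list with `child_a` and `child_b`.
#' @export
real_crossover <- function(parent_a, parent_b, p_swap = 0.5) {
  if (length(parent_a) != length(parent_b)) {
    abort("Parent genomes differ in length.",
          class = "expotox_config_error")
  }
  swap <- runif(length(parent_a)) < p_swap
  child_a <- ifelse(swap, parent_b, parent_a)
  child_b <- ifelse(swap, parent_a, parent_b)
  list(child_a = child_a, child_b = child_b)
}

#' Position mutation with bounded redrawn values
#'
#' Each element is replaced by `lower + (upper - lower) * u`, where `u` is
#' a uniform draw that is redrawn until it is at least the mutation
#' probability `pv` (so accepted draws are uniform on `[pv, 1)` and the
#' mutated value always stays within its slot bounds). With
#' `unbiased = TRUE` a plain uniform draw on `[0, 1)` is used instead.
#'
#' @param genome Numeric genome.
#' @param lower,upper Per-slot bounds (recycled).
#' @param pv Mutation probability in `(0, 1)` controlling the accepted
#'   draw's lower bound.
#' @param unbiased Use an unbiased uniform draw.
#'
#' @return The mutated genome, elementwise within `[lower, upper]`.
#' @export
position_mutate <- function(genome, lower, upper, pv, unbiased = FALSE) {
  k <- length(genome)
  lower <- rep_len(lower, k); upper <- rep_len(upper, k)
  if (any(lower > upper)) {
    abort("`lower` must not exceed `upper`.",
          class = "expotox_config_error")
  }
  u <- runif(k)
  if (!unbiased) {
    while (any(bad <- u < pv)) u[bad] <- runif(sum(bad))
  }
  lower + (upper - lower) * u
}

#' Genetic-algorithm configuration
#'
#' @param num Population size (at least 2).
#' @param pv Mutation probability in `(0, 1)`.
#' @param p_crossover Per-position crossover (exchange) probability.
#' @param generations Number of generations.
#' @param elitism Number of best individuals copied unchanged.
#' @param seed Integer seed.
#'
#' @return A `ga_config` object.
#' @export
ga_config <- function(num = 12, pv = 0.1, p_crossover = 0.5,
                      generations = 8, elitism = 1, seed = 1L) {
  stopifnot(num >= 2, pv > 0, pv < 1, generations >= 1,
            elitism >= 0, elitism < num)
  structure(list(num = as.integer(num), pv = pv,
                 p_crossover = p_crossover,
                 generations = as.integer(generations),
                 elitism = as.integer(elitism), seed = as.integer(seed)),
            class = "ga_config")
}

#' Fit a GRU forecaster on sliding windows
#'
#' Maps length-`window` histories of the target (daily case counts) and
#' exposure channels to the next day's target value, trained full-batch
#' with Adam on the squared error. Inputs and target are standardized
#' internally (restored at prediction time).
#'
#' @param data Tibble holding the aligned daily series.
#' @param target Name of the target column.
#' @param features Optional exposure/feature columns entering each step's
#'   input alongside the lagged target.
#' @param window History window length `w` (at least 1).
#' @param hidden Hidden-state size.
#' @param learning_rate,epochs Adam step size and maximum epochs.
#' @param patience Early-stopping patience: training stops when the loss
#'   has not improved for this many epochs (`Inf` to disable).
#' @param seed Integer seed.
#'
#' @return A `gru_fit` with the trained `gru_params`, scaling constants
#'   and a per-epoch `history` tibble.
#' @export
gru_fit <- function(data, target, features = NULL, window = 7,
                    hidden = 8, learning_rate = 0.01, epochs = 100,
                    patience = 10, seed = 1L) {
  stopifnot(window >= 1)
  y <- data[[target]]
  if (length(y) <= window) {
    abort("Series shorter than the history window.",
          class = "expotox_config_error")
  }
  Xf <- if (length(features)) as.matrix(data[features]) else NULL
  sc <- function(v) {
    s <- sd(v); if (!is.finite(s) || s == 0) s <- 1
    list(center = mean(v), scale = s)
  }
  y_sc <- sc(y)
  ys <- (y - y_sc$center) / y_sc$scale
  xs <- NULL; x_sc <- NULL
  if (!is.null(Xf)) {
    x_sc <- apply(Xf, 2, sc, simplify = FALSE)
    xs <- vapply(seq_len(ncol(Xf)), function(j)
      (Xf[, j] - x_sc[[j]]$center) / x_sc[[j]]$scale,
      numeric(nrow(Xf)))
  }
  sup <- build_windows(ys, xs, window)
  D <- ncol(sup$steps[[1]])
  params <- gru_params_init(D, hidden, seed = seed)
  popt <- model_params_gru(params)
  state <- adam_init(popt)
  best <- Inf; wait <- 0
  history <- numeric(0)
  for (ep in seq_len(epochs)) {
    params <- set_params_gru(params, popt)
    fw <- gru_forward(params, sup$steps, keep_cache = TRUE)
    loss <- fitness_mse(fw$yhat, sup$targets)
    history <- c(history, loss)
    if (!is.finite(loss)) {
      abort("Non-finite training loss.", class = "expotox_train_error")
    }
    if (loss < best - 1e-10) { best <- loss; wait <- 0 } else {
      wait <- wait + 1
      if (wait >= patience) break
    }
    g <- gru_backward(params, fw, sup$steps, sup$targets)
    upd <- adam_step(popt, g, state, learning_rate)
    popt <- upd$params; state <- upd$state
  }
  params <- set_params_gru(params, popt)
  structure(list(params = params, target = target, features = features,
                 window = window, y_scale = y_sc, x_scale = x_sc,
                 history = tibble(epoch = seq_along(history),
                                  loss = history)),
            class = "gru_fit")
}

model_params_gru <- function(p) {
  p[c("Wr", "Ur", "Wz", "Uz", "U", "W", "bh", "Wo", "bo")]
}

set_params_gru <- function(p, popt) {
  for (nm in names(popt)) p[[nm]] <- popt[[nm]]
  p
}

# Build the sliding-window supervision: for each target index t in
# (window+1)..T the step-s input is [y_{t-window-1+s}, x_{t-window-1+s}].
build_windows <- function(ys, xs, window) {
  T_len <- length(ys)
  targets_idx <- (window + 1):T_len
  n <- length(targets_idx)
  steps <- purrr::map(seq_len(window), function(s) {
    idx <- targets_idx - window - 1 + s
    m <- matrix(ys[idx], n, 1)
    if (!is.null(xs)) m <- cbind(m, xs[idx, , drop = FALSE])
    m
  })
  list(steps = steps, targets = ys[targets_idx], index = targets_idx)
}

#' Forecast with a fitted GRU
#'
#' One-step-ahead predictions for every time point with a full history
#' window, aligned to the input rows.
#'
#' @param fit A `gru_fit` from [gru_fit()].
#' @param data Tibble with the same target/feature columns (defaults to
#'   refusing shorter series than the window).
#'
#' @return A tibble with the row `index` into `data` (and `date` if
#'   present), the observed target and the prediction `.pred`.
#' @export
gru_forecast <- function(fit, data) {
  y <- data[[fit$target]]
  ys <- (y - fit$y_scale$center) / fit$y_scale$scale
  xs <- NULL
  if (length(fit$features)) {
    Xf <- as.matrix(data[fit$features])
    xs <- vapply(seq_along(fit$features), function(j)
      (Xf[, j] - fit$x_scale[[j]]$center) / fit$x_scale[[j]]$scale,
      numeric(nrow(Xf)))
  }
  sup <- build_windows(ys, xs, fit$window)
  fw <- gru_forward(fit$params, sup$steps)
  out <- tibble(index = sup$index,
                observed = y[sup$index],
                .pred = fw$yhat * fit$y_scale$scale + fit$y_scale$center)
  if ("date" %in% names(data)) {
    out <- dplyr::mutate(out, date = data$date[.data$index], .before = 1)
  }
  out
}

#' @export
tidy.gru_fit <- function(x, ...) x$history

#' @export
glance.gru_fit <- function(x, ...) {
  tibble(window = x$window, hidden = x$params$hidden,
         epochs = nrow(x$history), final_loss = dplyr::last(x$history$loss))
}

# Genome layout: one [0,1] mask slot per candidate feature channel
# (threshold 0.5), one hidden-size slot and one log10 learning-rate slot.
genome_bounds <- function(n_channels, hidden_range = c(4, 24),
                          lr_range = c(1e-4, 0.1)) {
  tibble(
    slot = c(paste0("mask_", seq_len(n_channels)), "hidden", "log10_lr"),
    lower = c(rep(0, n_channels), hidden_range[1], log10(lr_range[1])),
    upper = c(rep(1, n_channels), hidden_range[2], log10(lr_range[2]))
  )
}

decode_genome <- function(genome, channels) {
  k <- length(channels)
  list(mask = genome[seq_len(k)] >= 0.5,
       selected = channels[genome[seq_len(k)] >= 0.5],
       hidden = as.integer(round(genome[k + 1])),
       learning_rate = 10^genome[k + 2])
}

#' Optimize GRU inputs and hyperparameters with a genetic algorithm
#'
#' Real-coded GA over a feature-inclusion mask, the hidden size and the
#' learning rate. Each individual is decoded, a GRU is trained briefly on
#' the first part of the series, and the fitness is the mean squared error
#' on the chronological validation fold; selection is roulette-wheel on
#' inverse MSE, followed by position-exchange crossover and bounded
#' position mutation, with elitism. A genome decoding to zero selected
#' features (when `require_features` is set and no lagged target would
#' remain informative) is penalized with infinite fitness.
#'
#' @param data Tibble with the aligned daily series.
#' @param target Target column name.
#' @param channels Candidate feature channels the mask selects from.
#' @param ga A [ga_config()].
#' @param window History window length.
#' @param hidden_range Integer bounds for the hidden size slot.
#' @param lr_range Bounds for the learning-rate slot (log-spaced).
#' @param val_fraction Fraction of the series (chronological tail) used as
#'   the validation fold.
#' @param inner_epochs,inner_patience Training budget per fitness
#'   evaluation.
#'
#' @return A `ga_gru_result`: `best_genome` (raw vector), `best_decoded`,
#'   `best_fitness`, a per-generation `trace` tibble (monotone
#'   non-increasing best fitness, by elitism), the final `population` and
#'   the `bounds`.
#' @export
ga_gru_optimize <- function(data, target, channels, ga = ga_config(),
                            window = 7, hidden_range = c(4, 24),
                            lr_range = c(1e-4, 0.1), val_fraction = 0.25,
                            inner_epochs = 30, inner_patience = 5) {
  bounds <- genome_bounds(length(channels), hidden_range, lr_range)
  n_train <- floor(nrow(data) * (1 - val_fraction))
  if (n_train <= window + 2) {
    abort("Series too short for the requested window and validation fold.",
          class = "expotox_config_error")
  }
  train_fold <- data[seq_len(n_train), , drop = FALSE]
  eval_fitness <- function(genome, eval_seed) {
    dec <- decode_genome(genome, channels)
    if (!any(dec$mask)) return(Inf)
    fit <- tryCatch(
      gru_fit(train_fold, target, features = dec$selected,
              window = window, hidden = dec$hidden,
              learning_rate = dec$learning_rate, epochs = inner_epochs,
              patience = inner_patience, seed = eval_seed),
      error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    pr <- gru_forecast(fit, data)
    val <- pr$index > n_train
    if (!any(val)) return(Inf)
    fitness_mse(pr$.pred[val], pr$observed[val])
  }
  withr::with_seed(ga$seed, {
    pop <- purrr::map(seq_len(ga$num), function(i)
      bounds$lower + (bounds$upper - bounds$lower) * runif(nrow(bounds)))
    fit_vals <- vapply(seq_along(pop), function(i)
      eval_fitness(pop[[i]], substream_seed(ga$seed, i)), numeric(1))
    trace <- tibble(generation = 0L, best_fitness = min(fit_vals),
                    mean_fitness = mean(fit_vals[is.finite(fit_vals)]))
    for (gen in seq_len(ga$generations)) {
      ord <- order(fit_vals)
      elite_idx <- ord[seq_len(ga$elitism)]
      elite <- pop[elite_idx]
      elite_fit <- fit_vals[elite_idx]   # carried unchanged: elitism
      children <- list()
      while (length(children) < ga$num - length(elite)) {
        pa <- roulette_select(fit_vals, 2)
        cx <- real_crossover(pop[[pa[1]]], pop[[pa[2]]], ga$p_crossover)
        for (child in cx) {
          if (runif(1) < ga$pv) {
            child <- position_mutate(child, bounds$lower, bounds$upper,
                                     ga$pv)
          }
          children[[length(children) + 1]] <- child
        }
      }
      children <- children[seq_len(ga$num - length(elite))]
      child_fit <- vapply(seq_along(children), function(i)
        eval_fitness(children[[i]],
                     substream_seed(ga$seed, gen * 100L + i)),
        numeric(1))
      pop <- c(elite, children)
      fit_vals <- c(elite_fit, child_fit)
      trace <- dplyr::bind_rows(trace, tibble(
        generation = gen, best_fitness = min(fit_vals),
        mean_fitness = mean(fit_vals[is.finite(fit_vals)])))
    }
    best_i <- which.min(fit_vals)
    structure(list(
      best_genome = pop[[best_i]],
      best_decoded = decode_genome(pop[[best_i]], channels),
      best_fitness = fit_vals[best_i],
      trace = trace, population = pop, fitnesses = fit_vals,
      bounds = bounds, channels = channels),
      class = "ga_gru_result")
  })
}

#' @export
tidy.ga_gru_result <- function(x, ...) x$trace

#' @export
glance.ga_gru_result <- function(x, ...) {
  d <- x$best_decoded
  tibble(best_fitness = x$best_fitness,
         n_selected = sum(d$mask), hidden = d$hidden,
         learning_rate = d$learning_rate,
         generations = max(x$trace$generation))
}

#' @export
autoplot.ga_gru_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(.data$generation, .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "generation", y = "best validation MSE")
}

#' @export
print.ga_gru_result <- function(x, ...) {
  d <- x$best_decoded
  cat(sprintf(
    "GA-GRU: best validation MSE %.4g; %d/%d channels selected (%s), hidden = %d, lr = %.4g\n",
    x$best_fitness, sum(d$mask), length(x$channels),
    paste(d$selected, collapse = ", "), d$hidden, d$learning_rate))
  invisible(x)
}
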