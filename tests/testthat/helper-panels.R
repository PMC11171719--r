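# Small fixtures built in code, shared across test files.

# A two-channel environmental series with an annual-style cycle compressed
# to `period` days so fixtures stay small.
tiny_env <- function(n_days = 240, period = 60, noise_sd = 4, seed = 1) {
  generate_env(env_config(
    n_days = n_days, channels = c("pm25", "so2"), period = period,
    trend_slope = c(0.01, 0), seasonal_amplitude = c(25, 8),
    noise_sd = noise_sd, baseline = c(55, 12), seed = seed))
}

tiny_panel <- function(n_records = 300, planted_r = 0.5, seed = 2,
                       env = tiny_env(), base_positivity = 0.3,
                       n_features = 6) {
  cfg <- health_config(
    n_records = n_records, n_features = n_features,
    indicators = tibble::tibble(name = "IND", planted_r = planted_r,
                                base_positivity = base_positivity),
    exposure_window_days = 7, seed = seed)
  generate_health(cfg, env)
}

# Multivariate series generated from a known number of random-walk common
# trends, the ground truth for dynamic-factor recovery checks.
factor_panel <- function(n_time = 200, n_channels = 4, m_true = 1,
                         noise_sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    f <- sapply(seq_len(m_true), function(i) cumsum(rnorm(n_time)))
    Z <- matrix(runif(n_channels * m_true, 0.7, 1) *
                  sample(c(-1, 1), n_channels * m_true, TRUE),
                n_channels, m_true)
    Y <- f %*% t(Z) + matrix(rnorm(n_time * n_channels, 0, noise_sd),
                             n_time, n_channels)
    colnames(Y) <- paste0("ch", seq_len(n_channels))
    tibble::as_tibble(Y)
  })
}

# Two-class feature table with a mean shift on the first block of
# features, linearly separable up to noise.
separable_classes <- function(n = 2000, p = 32, shift = 1.5, seed = 2) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    cls <- sample(1:2, n, TRUE)
    X[cls == 2, seq_len(p %/% 4)] <- X[cls == 2, seq_len(p %/% 4)] + shift
    d <- tibble::as_tibble(X, .name_repair = ~ paste0("f", seq_len(p)))
    d$lp_class <- cls
    d
  })
}

# Hand-built association-loss spec (bypasses pearson_alpha for degenerate
# coupling patterns).
manual_loss_spec <- function(anchor, labels, alpha) {
  spec <- tibble::tibble(label = labels, alpha = alpha)
  attr(spec, "anchor") <- anchor
  class(spec) <- c("association_loss_spec", class(spec))
  spec
}
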