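#' Configuration for the synthetic environmental series generator
#'
#' Describes a multichannel sensor panel (pollutants and meteorology) as an
#' additive signal per channel: baseline + linear trend + sinusoidal seasonal
#' cycle + Gaussian noise. Per-channel parameters are recycled across
#' channels.
#'
#' @param n_days Number of daily observations; must be at least `2 * period`.
#' @param channels Character vector of unique channel names.
#' @param period Seasonal cycle length in days (365 for an annual cycle).
#' @param trend_slope Linear trend per day, per channel (channel units/day).
#' @param seasonal_amplitude Amplitude of the sinusoidal seasonal component,
#'   per channel (channel units); non-negative.
#' @param noise_sd Standard deviation of the Gaussian measurement noise, per
#'   channel; non-negative.
#' @param baseline Channel baseline level (channel units).
#' @param start_date First calendar day of the series.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#'
#' @return An object of class `env_config`.
#' @seealso [generate_env()]
#' @export
env_config <- function(n_days,
                       channels = c("pm25", "so2", "temperature",
                                    "humidity", "light", "wind", "wqi"),
                       period = 365,
                       trend_slope = 0,
                       seasonal_amplitude = 0,
                       noise_sd = 1,
                       baseline = 0,
                       start_date = as.Date("2019-01-01"),
                       seed = 1L) {
  if (length(n_days) != 1 || !is.finite(n_days) || n_days < 1 ||
      n_days != floor(n_days)) {
    abort("`n_days` must be a positive integer.", class = "expotox_config_error")
  }
  if (length(period) != 1 || !is.finite(period) || period < 1 ||
      period != floor(period)) {
    abort("`period` must be a positive integer.", class = "expotox_config_error")
  }
  if (n_days < 2 * period) {
    abort("`n_days` must be at least 2 * `period`.",
          class = "expotox_config_error")
  }
  if (anyDuplicated(channels)) {
    abort("Channel names must be unique.", class = "expotox_config_error")
  }
  k <- length(channels)
  rec <- function(x) rep_len(x, k)
  noise_sd <- rec(noise_sd)
  seasonal_amplitude <- rec(seasonal_amplitude)
  if (any(noise_sd < 0)) {
    abort("`noise_sd` must be non-negative.", class = "expotox_config_error")
  }
  if (any(seasonal_amplitude < 0)) {
    abort("`seasonal_amplitude` must be non-negative.",
          class = "expotox_config_error")
  }
  structure(
    list(n_days = as.integer(n_days), channels = channels,
         period = as.integer(period),
         trend_slope = rec(trend_slope),
         seasonal_amplitude = seasonal_amplitude,
         noise_sd = noise_sd, baseline = rec(baseline),
         start_date = as.Date(start_date), seed = as.integer(seed)),
    class = "env_config"
  )
}

#' Generate a synthetic environmental monitoring series
#'
#' Each channel is `baseline + trend_slope * t + seasonal_amplitude *
#' sin(2 * pi * t / period + phase) + N(0, noise_sd)`, with a deterministic
#' per-channel phase spreading the channels around the cycle. The true
#' components are returned alongside the observed series so downstream
#' decompositions can be validated against them.
#'
#' @param cfg An [env_config()] object.
#'
#' @return A tibble with a `date` column and one column per channel. The
#'   true components are attached as attribute `"components"` (a long tibble
#'   with columns `date`, `channel`, `trend`, `seasonal`, `noise`; the trend
#'   column includes the baseline) and the configuration as attribute
#'   `"config"`.
#' @examples
#' env <- generate_env(env_config(n_days = 730, channels = c("pm25", "so2"),
#'                                seasonal_amplitude = 20, noise_sd = 2,
#'                                baseline = c(50, 10), seed = 7))
#' head(env)
#' @export
generate_env <- function(cfg) {
  stopifnot(inherits(cfg, "env_config"))
  t <- seq_len(cfg$n_days)
  k <- length(cfg$channels)
  phases <- 2 * pi * (seq_len(k) - 1) / k
  dates <- cfg$start_date + t - 1L
  comps <- withr::with_seed(cfg$seed, {
    purrr::map(seq_len(k), function(i) {
      trend <- cfg$baseline[i] + cfg$trend_slope[i] * t
      seasonal <- cfg$seasonal_amplitude[i] *
        sin(2 * pi * t / cfg$period + phases[i])
      noise <- rnorm(cfg$n_days, 0, cfg$noise_sd[i])
      tibble(date = dates, channel = cfg$channels[i],
             trend = trend, seasonal = seasonal, noise = noise)
    })
  })
  comps <- dplyr::bind_rows(comps)
  obs <- comps |>
    dplyr::mutate(value = .data$trend + .data$seasonal + .data$noise) |>
    dplyr::select("date", "channel", "value") |>
    tidyr::pivot_wider(names_from = "channel", values_from = "value")
  attr(obs, "components") <- comps
  attr(obs, "config") <- cfg
  obs
}

#' Default indicator panel for the synthetic health generator
#'
#' Five clinical indicators with the sign pattern typical of
#' cardiovascular/respiratory exposure panels: three positively associated
#' markers, one negatively associated, one null. Base positivity rates are
#' in the range observed in large examination cohorts.
#'
#' @return A tibble with columns `name`, `planted_r`, `base_positivity`.
#' @export
default_indicators <- function() {
  tibble(
    name = c("CKMB", "LDH", "CRP", "CYFRA21_1", "NSE"),
    planted_r = c(0.4, 0.25, 0.5, -0.6, 0),
    base_positivity = c(0.09, 0.22, 0.40, 0.14, 0.10)
  )
}

#' Configuration for the synthetic health-examination panel generator
#'
#' @param n_records Number of examination records (at least 100).
#' @param n_features Number of numeric examination features.
#' @param indicators A data frame with columns `name`, `planted_r` (target
#'   Pearson correlation between window-mean exposure and indicator
#'   positivity, in `[-1, 1]`) and `base_positivity` (marginal positivity
#'   rate, in `(0, 1)`).
#' @param label_dependence Strength in `[0, 1]` of a shared latent factor
#'   entering every indicator's logit (inducing cross-label correlation) and
#'   every feature (tying features to health status).
#' @param exposure_channel Name of the environmental channel records are
#'   exposed to.
#' @param exposure_window_days Length of the trailing exposure window whose
#'   mean drives positivity.
#' @param seed Integer seed.
#'
#' @return An object of class `health_config`.
#' @seealso [generate_health()]
#' @export
health_config <- function(n_records,
                          n_features = 100,
                          indicators = default_indicators(),
                          label_dependence = 0.3,
                          exposure_channel = "pm25",
                          exposure_window_days = 7,
                          seed = 1L) {
  indicators <- as_tibble(indicators)
  stopifnot(all(c("name", "planted_r", "base_positivity") %in%
                  names(indicators)))
  if (n_records < 100) {
    abort("`n_records` must be at least 100.", class = "expotox_config_error")
  }
  if (any(abs(indicators$planted_r) > 1)) {
    abort("`planted_r` must lie in [-1, 1].", class = "expotox_config_error")
  }
  if (any(indicators$base_positivity <= 0 | indicators$base_positivity >= 1)) {
    abort("`base_positivity` must lie in (0, 1).",
          class = "expotox_config_error")
  }
  if (label_dependence < 0 || label_dependence > 1) {
    abort("`label_dependence` must lie in [0, 1].",
          class = "expotox_config_error")
  }
  structure(
    list(n_records = as.integer(n_records),
         n_features = as.integer(n_features),
         indicators = indicators,
         label_dependence = label_dependence,
         exposure_channel = exposure_channel,
         exposure_window_days = as.integer(exposure_window_days),
         seed = as.integer(seed)),
    class = "health_config"
  )
}

# Trailing-window mean of a daily series: mean of the `window` values ending
# at (and including) each day. Only positions >= window are valid.
trailing_window_mean <- function(x, window) {
  cs <- cumsum(x)
  n <- length(x)
  idx <- window:n
  (cs[idx] - c(0, cs)[idx - window + 1]) / window
}

# Deterministic expected Pearson correlation between standardized exposure e
# and a Bernoulli outcome whose per-record probability is
# plogis(intercept + beta * e + latent), given the realized latent values.
expected_exposure_r <- function(beta, e, intercept, latent) {
  p <- plogis(intercept + beta * e + latent)
  pbar <- mean(p)
  v <- pbar * (1 - pbar)
  if (v <= 0) return(0)
  (mean(e * p) - mean(e) * pbar) / sqrt(mean((e - mean(e))^2) * v)
}

# Solve for beta such that expected_exposure_r(beta) == target by bisection.
# The map beta -> r is strictly increasing, so bisection is exact up to tol.
calibrate_beta <- function(target, e, intercept, latent,
                           beta_max = 30, tol = 1e-8) {
  r_hi <- expected_exposure_r(beta_max, e, intercept, latent)
  r_lo <- expected_exposure_r(-beta_max, e, intercept, latent)
  if (target > r_hi || target < r_lo) {
    abort(sprintf(
      "planted_r = %.3f is not achievable at this base positivity; achievable range is [%.3f, %.3f].",
      target, r_lo, r_hi), class = "expotox_calibration_error")
  }
  lo <- -beta_max; hi <- beta_max
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (expected_exposure_r(mid, e, intercept, latent) < target) lo <- mid
    else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Generate a synthetic health-examination panel linked to exposure
#'
#' Each record gets a timestamp uniform over the environmental series (with
#' enough history for its exposure window), a trailing window-mean exposure,
#' Gaussian examination features sharing a latent health factor, and binary
#' indicator labels. Positivity is Bernoulli with a logistic dose-response in
#' the standardized window-mean exposure; the slope is calibrated by
#' bisection so the expected Pearson correlation between exposure and
#' positivity matches each indicator's `planted_r`.
#'
#' @param cfg A [health_config()] object.
#' @param env An environmental series from [generate_env()] (or any tibble
#'   with a `date` column and the exposure channel).
#'
#' @return A tibble with columns `record_id`, `date`, features `f1..fK` and
#'   one `label_<name>` column per indicator. Attributes: `"exposure"` (a
#'   tibble with each record's window-mean exposure) and `"calibration"`
#'   (per-indicator fitted logistic slope and achievable correlation range).
#' @examples
#' env <- generate_env(env_config(n_days = 730, channels = "pm25",
#'                                seasonal_amplitude = 30, noise_sd = 10,
#'                                baseline = 50, seed = 1))
#' hx <- generate_health(health_config(n_records = 200, n_features = 10,
#'                                     seed = 2), env)
#' dplyr::count(hx, .data$label_CRP)
#' @export
generate_health <- function(cfg, env) {
  stopifnot(inherits(cfg, "health_config"))
  if (!cfg$exposure_channel %in% names(env)) {
    abort(sprintf("Exposure channel '%s' not found in `env`.",
                  cfg$exposure_channel), class = "expotox_config_error")
  }
  x <- env[[cfg$exposure_channel]]
  w <- cfg$exposure_window_days
  if (length(x) <= w) {
    abort("Environmental series shorter than the exposure window.",
          class = "expotox_config_error")
  }
  wm <- trailing_window_mean(x, w)      # valid for days w .. n_days
  valid_days <- w:length(x)
  n <- cfg$n_records
  inds <- cfg$indicators
  withr::with_seed(cfg$seed, {
    day <- sample(valid_days, n, replace = TRUE)
    e_raw <- wm[day - w + 1L]
    e <- as.numeric(scale(e_raw))
    latent <- rnorm(n)
    lat_term <- cfg$label_dependence * latent
    calib <- purrr::pmap(inds, function(name, planted_r, base_positivity) {
      icept <- qlogis(base_positivity)
      beta <- calibrate_beta(planted_r, e, icept, lat_term)
      p <- plogis(icept + beta * e + lat_term)
      tibble(indicator = name, beta = beta,
             label = list(rbinom(n, 1L, p)))
    }) |> dplyr::bind_rows()
    feats <- matrix(rnorm(n * cfg$n_features), n, cfg$n_features) +
      cfg$label_dependence * latent
    colnames(feats) <- paste0("f", seq_len(cfg$n_features))
    out <- tibble(record_id = seq_len(n), date = env$date[day]) |>
      dplyr::bind_cols(as_tibble(feats))
    for (i in seq_len(nrow(calib))) {
      out[[paste0("label_", calib$indicator[i])]] <- calib$label[[i]]
    }
    attr(out, "exposure") <- tibble(record_id = out$record_id,
                                    exposure_mean = e_raw)
    attr(out, "calibration") <- dplyr::select(calib, "indicator", "beta")
    out
  })
}

#' Identify the feature and label columns of a health panel
#'
#' Health panels follow the column convention `record_id`, `date`,
#' features, `label_<name>`. These helpers return the matching column names.
#'
#' @param data A health-panel tibble.
#' @return A character vector of column names.
#' @export
label_cols <- function(data) {
  grep("^label_", names(data), value = TRUE)
}

#' @rdname label_cols
#' @export
feature_cols <- function(data) {
  setdiff(names(data),
          c("record_id", "date", "lp_class", "attributed",
            label_cols(data)))
}
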