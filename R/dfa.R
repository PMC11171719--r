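#' Classical additive seasonal decomposition
#'
#' Splits each channel into trend + seasonal + remainder: the trend is a
#' centered moving average of window `period` (the usual half-weight ends
#' for even periods, extended to the series edges by a linear fit on the
#' nearest `period` interior trend values so the additive identity holds
#' everywhere); the seasonal component is the period-position mean of the
#' detrended series, re-centered to sum to zero over one cycle; the
#' remainder is the residual, so `observed = trend + seasonal + remainder`
#' holds exactly at every time point.
#'
#' @param data An environmental tibble (`date` plus channel columns) or a
#'   numeric vector.
#' @param period Seasonal cycle length in observations; the series must be
#'   at least twice as long.
#' @param channels Channels to decompose; defaults to all non-`date`
#'   numeric columns.
#'
#' @return A `decomp_result` tibble in long form with columns `date` (or
#'   index `t`), `channel`, `observed`, `trend`, `seasonal`, `remainder`,
#'   `deseasonalized` (= trend + remainder).
#' @examples
#' env <- generate_env(env_config(n_days = 104, channels = "pm25",
#'                                period = 52, seasonal_amplitude = 10,
#'                                baseline = 30, seed = 1))
#' dec <- seasonal_decompose(env, period = 52)
#' @export
seasonal_decompose <- function(data, period, channels = NULL) {
  if (is.numeric(data)) {
    data <- tibble(date = seq_along(data), value = data)
    channels <- "value"
  }
  if (is.null(channels)) {
    channels <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                        c("date", "t"))
  }
  n <- nrow(data)
  if (n < 2 * period) {
    abort("Series must be at least 2 * `period` long.",
          class = "expotox_config_error")
  }
  dates <- if ("date" %in% names(data)) data$date else seq_len(n)
  out <- purrr::map(channels, function(ch) {
    x <- data[[ch]]
    dc <- decompose_channel(x, period)
    tibble(date = dates, channel = ch, observed = x,
           trend = dc$trend, seasonal = dc$seasonal,
           remainder = x - dc$trend - dc$seasonal) |>
      dplyr::mutate(deseasonalized = .data$trend + .data$remainder)
  }) |> dplyr::bind_rows()
  class(out) <- c("decomp_result", class(out))
  attr(out, "period") <- as.integer(period)
  out
}

# Centered moving-average trend with linear edge extension, plus centered
# period-position seasonal means.
decompose_channel <- function(x, period) {
  n <- length(x)
  w <- if (period %% 2 == 0) c(0.5, rep(1, period - 1), 0.5) / period
       else rep(1 / period, period)
  trend <- as.numeric(stats::filter(x, w, sides = 2))
  valid <- which(!is.na(trend))
  extend <- function(trend, idx_fit, idx_fill) {
    fit <- stats::lm.fit(cbind(1, idx_fit), trend[idx_fit])
    trend[idx_fill] <- fit$coefficients[1] + fit$coefficients[2] * idx_fill
    trend
  }
  head_na <- seq_len(min(valid) - 1)
  tail_na <- if (max(valid) < n) (max(valid) + 1):n else integer()
  k <- min(period, length(valid))
  if (length(head_na)) trend <- extend(trend, head(valid, k), head_na)
  if (length(tail_na)) trend <- extend(trend, tail(valid, k), tail_na)
  detr <- x - trend
  pos <- ((seq_len(n) - 1) %% period) + 1
  # positions estimated from interior detrended values only
  interior <- rep(FALSE, n); interior[valid] <- TRUE
  means <- vapply(seq_len(period), function(p) {
    v <- detr[pos == p & interior]
    if (!length(v)) mean(detr[pos == p]) else mean(v)
  }, numeric(1))
  means <- means - mean(means)
  list(trend = trend, seasonal = means[pos])
}

#' Remove the seasonal component
#'
#' Returns the deseasonalized series (trend + remainder) per channel, the
#' series used as the new observations for dynamic factor analysis.
#'
#' @param result A `decomp_result` from [seasonal_decompose()].
#'
#' @return A wide tibble: `date` plus one deseasonalized column per
#'   channel.
#' @export
deseasonalize <- function(result) {
  stopifnot(inherits(result, "decomp_result"))
  result |>
    dplyr::select("date", "channel", "deseasonalized") |>
    tidyr::pivot_wider(names_from = "channel",
                       values_from = "deseasonalized")
}

#' @export
autoplot.decomp_result <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("observed", "trend", "seasonal", "remainder"),
                        names_to = "component", values_to = "value") |>
    dplyr::mutate(component = factor(.data$component,
                                     c("observed", "trend", "seasonal",
                                       "remainder")))
  ggplot2::ggplot(long, ggplot2::aes(.data$date, .data$value,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component),
                        scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, colour = "channel")
}

#' Nash-Sutcliffe model efficiency
#'
#' `1 - sum((obs - sim)^2) / sum((obs - mean(obs))^2)`: 1 for a perfect
#' fit, 0 for a model no better than the observed mean, unbounded below.
#'
#' @param observed,simulated Equal-length numeric vectors; `observed` must
#'   not be constant.
#'
#' @return The efficiency coefficient (scalar, at most 1).
#' @examples
#' nse(c(1, 2, 3), c(3, 2, 1))  # -3
#' @export
nse <- function(observed, simulated) {
  if (length(observed) != length(simulated)) {
    abort("`observed` and `simulated` must have equal length.",
          class = "expotox_config_error")
  }
  if (length(observed) < 2) {
    abort("At least two observations are required.",
          class = "expotox_config_error")
  }
  denom <- sum((observed - mean(observed))^2)
  if (denom == 0) {
    abort("Nash-Sutcliffe efficiency is undefined for a constant observed series.",
          class = "expotox_config_error")
  }
  1 - sum((observed - simulated)^2) / denom
}

#' Akaike information criterion from a fitted likelihood
#'
#' @param m_prime Number of independent model parameters (at least 1).
#' @param log_likelihood Maximized log-likelihood.
#'
#' @return `2 * m_prime - 2 * log_likelihood`.
#' @examples
#' aic(2, -10)  # 24
#' @export
aic <- function(m_prime, log_likelihood) {
  stopifnot(m_prime >= 1)
  2 * m_prime - 2 * log_likelihood
}

#' Dynamic factor analysis by EM on a state-space model
#'
#' Expresses standardized deseasonalized channels as loadings on a small
#' number of random-walk common trends, with diagonal observation noise and
#' optional explanatory regressors:
#' `y_t = Z f_t + D x_t + e_t`, `f_t = f_{t-1} + w_t`, `w_t ~ N(0, I)`.
#' The state noise is fixed to the identity and the upper triangle of `Z`
#' is zeroed for identifiability (the usual dynamic-factor convention);
#' `Z`, `D` and the observation variances are estimated by EM using the
#' Kalman smoother. EM iterations increase the log-likelihood
#' monotonically.
#'
#' @param data Wide tibble (`date` plus channels) or numeric matrix of
#'   deseasonalized response channels; channels are standardized internally.
#' @param m_trends Number of common trends (at least 1, at most the number
#'   of channels).
#' @param response Response channel columns; defaults to all numeric
#'   non-`date` columns not used as explanatory.
#' @param explanatory Optional explanatory channel columns (standardized
#'   and entered as regressors).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#'
#' @return A `dfa_model` with elements `loadings` (channels x trends
#'   tibble), `trends` (long tibble of smoothed common trends), `D`,
#'   `obs_variance`, `logLik`, `m_prime`, `AIC`, `ceff` (per-channel
#'   Nash-Sutcliffe efficiency of the fitted values), `fitted`,
#'   `loglik_trace`, `converged`.
#' @export
fit_dfa <- function(data, m_trends, response = NULL, explanatory = NULL,
                    max_iter = 500, tol = 1e-6) {
  if (is.matrix(data)) data <- as_tibble(data)
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  num <- setdiff(num, c("t"))
  if (is.null(response)) response <- setdiff(num, explanatory)
  stopifnot(m_trends >= 1, m_trends <= length(response))
  y <- scale(as.matrix(data[response]))
  x <- if (length(explanatory)) scale(as.matrix(data[explanatory])) else NULL
  fit <- dfa_em(y, x, m = m_trends, max_iter = max_iter, tol = tol)
  n_ch <- length(response)
  q <- if (is.null(x)) 0 else ncol(x)
  m_prime <- n_ch * m_trends - m_trends * (m_trends - 1) / 2 +
    n_ch * q + n_ch
  ceff <- vapply(seq_len(n_ch), function(i) nse(y[, i], fit$fitted[, i]),
                 numeric(1))
  dates <- if ("date" %in% names(data)) data$date else seq_len(nrow(y))
  loadings <- as_tibble(fit$Z, .name_repair = ~ paste0("trend", seq_len(m_trends)))
  loadings <- dplyr::bind_cols(tibble(channel = response), loadings)
  trends <- as_tibble(fit$f, .name_repair = ~ paste0("trend", seq_len(m_trends)))
  trends$date <- dates
  trends <- tidyr::pivot_longer(trends, -"date", names_to = "trend",
                                values_to = "value")
  structure(list(
    m_trends = m_trends, loadings = loadings, trends = trends,
    D = fit$D, obs_variance = setNames(fit$r, response),
    logLik = fit$loglik, m_prime = m_prime,
    AIC = aic(m_prime, fit$loglik),
    ceff = tibble(channel = response, ceff = ceff),
    fitted = fit$fitted, loglik_trace = fit$trace,
    converged = fit$converged, iterations = fit$iterations,
    response = response, explanatory = explanatory
  ), class = "dfa_model")
}

# EM for the random-walk dynamic factor model on standardized data.
# y: T x N matrix; x: T x q matrix or NULL; m: number of trends.
dfa_em <- function(y, x, m, max_iter = 500, tol = 1e-6, prior_var = 5) {
  T_len <- nrow(y); N <- ncol(y)
  q <- if (is.null(x)) 0 else ncol(x)
  Z <- matrix(0.1, N, m)
  Z[upper.tri(Z)] <- 0
  D <- if (q) matrix(0, N, q) else NULL
  r <- rep(1, N)
  free_cols <- lapply(seq_len(N), function(i) seq_len(min(i, m)))
  trace <- numeric(0)
  prev <- -Inf; converged <- FALSE; it <- 0
  for (it in seq_len(max_iter)) {
    ks <- dfa_smooth(y, x, Z, D, r, prior_var)
    trace <- c(trace, ks$loglik)
    if (is.finite(prev) &&
        abs(ks$loglik - prev) < tol * (abs(prev) + tol)) {
      converged <- TRUE
      break
    }
    prev <- ks$loglik
    # M-step: per-channel regression of y on (constrained f columns, x)
    S_ff <- ks$S_ff            # m x m: sum of E[f f']
    S_fy <- ks$S_fy            # m x N: sum f_hat y'
    f_hat <- ks$f_hat          # T x m
    for (i in seq_len(N)) {
      fc <- free_cols[[i]]
      if (q) {
        A <- rbind(cbind(S_ff[fc, fc, drop = FALSE],
                         t(f_hat[, fc, drop = FALSE]) %*% x),
                   cbind(t(x) %*% f_hat[, fc, drop = FALSE], t(x) %*% x))
        b <- c(S_fy[fc, i], t(x) %*% y[, i])
        beta <- solve(A, b)
        Z[i, ] <- 0; Z[i, fc] <- beta[seq_along(fc)]
        D[i, ] <- beta[-seq_along(fc)]
        resid2 <- sum(y[, i]^2) - 2 * sum(beta * b) +
          drop(t(beta) %*% A %*% beta)
      } else {
        A <- S_ff[fc, fc, drop = FALSE]
        b <- S_fy[fc, i]
        beta <- solve(A, b)
        Z[i, ] <- 0; Z[i, fc] <- beta
        resid2 <- sum(y[, i]^2) - 2 * sum(beta * b) +
          drop(t(beta) %*% A %*% beta)
      }
      r[i] <- max(resid2 / T_len, 1e-8)
    }
  }
  ks <- dfa_smooth(y, x, Z, D, r, prior_var)
  fitted <- ks$f_hat %*% t(Z)
  if (q) fitted <- fitted + x %*% t(D)
  list(Z = Z, D = D, r = r, f = ks$f_hat, fitted = fitted,
       loglik = ks$loglik, trace = c(trace, ks$loglik),
       converged = converged, iterations = it)
}

# Kalman filter + RTS smoother for the random-walk factor model.
# Returns smoothed states, summed second moments and the log-likelihood.
dfa_smooth <- function(y, x, Z, D, r, prior_var) {
  T_len <- nrow(y); N <- ncol(y); m <- ncol(Z)
  Im <- diag(1, m)
  a_pred <- matrix(0, T_len, m); a_filt <- matrix(0, T_len, m)
  P_pred <- array(0, c(m, m, T_len)); P_filt <- array(0, c(m, m, T_len))
  a <- rep(0, m); P <- diag(prior_var, m)
  loglik <- 0
  xb <- if (is.null(D)) matrix(0, T_len, N) else x %*% t(D)
  for (t in seq_len(T_len)) {
    ap <- a
    Pp <- P + Im
    if (t == 1) Pp <- diag(prior_var, m)  # prior covers the first state
    v <- y[t, ] - drop(Z %*% ap) - xb[t, ]
    Fm <- Z %*% Pp %*% t(Z) + diag(r, N)
    cF <- chol(Fm)
    Fi_v <- backsolve(cF, forwardsolve(t(cF), v))
    loglik <- loglik - 0.5 * (N * log(2 * pi) + 2 * sum(log(diag(cF))) +
                                sum(v * Fi_v))
    K <- Pp %*% t(Z) %*% chol2inv(cF)
    a <- ap + drop(K %*% v)
    P <- (Im - K %*% Z) %*% Pp
    P <- (P + t(P)) / 2
    a_pred[t, ] <- ap; P_pred[, , t] <- Pp
    a_filt[t, ] <- a; P_filt[, , t] <- P
  }
  # RTS smoother
  a_sm <- a_filt; V <- P_filt
  if (T_len > 1) {
    for (t in (T_len - 1):1) {
      J <- P_filt[, , t] %*% solve(P_pred[, , t + 1])
      a_sm[t, ] <- a_filt[t, ] +
        drop(J %*% (a_sm[t + 1, ] - a_pred[t + 1, ]))
      V[, , t] <- P_filt[, , t] +
        J %*% (V[, , t + 1] - P_pred[, , t + 1]) %*% t(J)
    }
  }
  S_ff <- t(a_sm) %*% a_sm + apply(V, c(1, 2), sum)
  S_fy <- t(a_sm) %*% y
  list(f_hat = a_sm, S_ff = S_ff, S_fy = S_fy, loglik = loglik)
}

#' @export
print.dfa_model <- function(x, ...) {
  cat(sprintf(
    "Dynamic factor model: %d trend(s), logLik = %.2f, AIC = %.2f (%s)\n",
    x$m_trends, x$logLik, x$AIC,
    if (x$converged) sprintf("converged in %d EM iterations", x$iterations)
    else "did not converge"))
  print(x$ceff)
  invisible(x)
}

#' @export
tidy.dfa_model <- function(x, ...) {
  tidyr::pivot_longer(x$loadings, -"channel", names_to = "trend",
                      values_to = "loading")
}

#' @export
glance.dfa_model <- function(x, ...) {
  tibble(m_trends = x$m_trends, m_prime = x$m_prime, logLik = x$logLik,
         AIC = x$AIC, mean_ceff = mean(x$ceff$ceff),
         converged = x$converged, iterations = x$iterations)
}

#' @export
autoplot.dfa_model <- function(object, ...) {
  ggplot2::ggplot(object$trends,
                  ggplot2::aes(.data$date, .data$value,
                               colour = .data$trend)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "common trend", colour = NULL)
}

#' Select the number of common trends by AIC
#'
#' Fits a dynamic factor model for each candidate trend count and selects
#' the one with the smallest AIC, breaking ties toward fewer trends. The
#' per-channel Nash-Sutcliffe efficiencies are reported alongside.
#'
#' @inheritParams fit_dfa
#' @param m_candidates Positive integer vector of candidate trend counts.
#'
#' @return A list with `best_m`, `report` (one row per candidate with
#'   `m_trends`, `m_prime`, `logLik`, `AIC`, `mean_ceff`) and the fitted
#'   `models`.
#' @export
select_trends <- function(data, m_candidates, response = NULL,
                          explanatory = NULL, ...) {
  stopifnot(length(m_candidates) >= 1)
  m_candidates <- sort(unique(as.integer(m_candidates)))
  models <- purrr::map(m_candidates, function(m) {
    fit_dfa(data, m, response = response, explanatory = explanatory, ...)
  })
  report <- purrr::map(models, glance) |> dplyr::bind_rows()
  best <- m_candidates[which.min(report$AIC)]  # which.min takes first ->
  # smallest m on ties because candidates are sorted increasing
  list(best_m = best, report = report,
       models = setNames(models, paste0("m", m_candidates)))
}
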