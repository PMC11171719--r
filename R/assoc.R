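#' Flag records attributed to exposure
#'
#' An examination record counts as exposure-attributed when the classifier
#' calls it positive and its trailing window-mean exposure exceeds a high
#' quantile of the exposure distribution.
#'
#' @param data A health-panel tibble.
#' @param predicted Logical/binary vector (or column name) of model-positive
#'   calls.
#' @param exposure Numeric vector (or column name) of per-record window-mean
#'   exposure.
#' @param prob_quantile Exposure quantile above which a record counts as
#'   highly exposed (default 0.75).
#'
#' @return `data` with an added logical `attributed` column.
#' @export
flag_attributed <- function(data, predicted, exposure,
                            prob_quantile = 0.75) {
  pv <- if (is.character(predicted) && length(predicted) == 1)
    data[[predicted]] else predicted
  ev <- if (is.character(exposure) && length(exposure) == 1)
    data[[exposure]] else exposure
  thr <- quantile(ev, prob_quantile, na.rm = TRUE)
  data$attributed <- as.logical(pv) & ev > thr
  data
}

#' Quarterly exposure-association counts for one indicator
#'
#' Tabulates, per calendar quarter, the total number of examination
#' records, the number positive for the indicator, and the number of
#' positive records attributed to exposure. Quarters with no records report
#' zero counts; the quarter totals sum to the number of input records.
#'
#' @param data A health-panel tibble with `date`, a `label_<indicator>`
#'   column and a logical attribution column (see [flag_attributed()]).
#' @param indicator Indicator name (without the `label_` prefix).
#' @param year Optional calendar year; records outside it are an error.
#' @param attributed Name of the logical attribution column.
#'
#' @return A tibble with one row per quarter: `quarter`, `total`,
#'   `positive`, `associated`.
#' @export
tabulate_associations <- function(data, indicator, year = NULL,
                                  attributed = "attributed") {
  lab <- paste0("label_", indicator)
  if (!lab %in% names(data)) {
    abort(sprintf("No column '%s' in `data`.", lab),
          class = "expotox_config_error")
  }
  if (!attributed %in% names(data)) {
    abort(sprintf("No attribution column '%s'; see flag_attributed().",
                  attributed), class = "expotox_config_error")
  }
  yrs <- lubridate::year(data$date)
  if (!is.null(year) && any(yrs != year)) {
    abort(sprintf("%d record(s) fall outside year %d.",
                  sum(yrs != year), year), class = "expotox_config_error")
  }
  pos <- data[[lab]] == 1
  att <- as.logical(data[[attributed]])
  tibble(quarter = lubridate::quarter(data$date),
         pos = pos, att = att) |>
    dplyr::group_by(.data$quarter) |>
    dplyr::summarise(total = dplyr::n(),
                     positive = sum(.data$pos),
                     associated = sum(.data$pos & .data$att),
                     .groups = "drop") |>
    tidyr::complete(quarter = 1:4,
                    fill = list(total = 0L, positive = 0L,
                                associated = 0L)) |>
    dplyr::arrange(.data$quarter)
}

#' Percentage of positive cases associated with exposure
#'
#' `100 * associated / positive`, rounded half-up to two decimals.
#' Undefined (returned as `NA`, rendered as an em dash in formatted
#' tables) when there are no positive cases.
#'
#' @param associated,positive Non-negative counts (vectorized);
#'   `associated` must not exceed `positive`.
#'
#' @return Percentages rounded half-up to 2 decimals; `NA` where
#'   `positive` is zero.
#' @examples
#' percent_associated(12, 210)    # 5.71
#' percent_associated(280, 3845)  # 7.28
#' @export
percent_associated <- function(associated, positive) {
  if (any(associated > positive)) {
    abort("`associated` cannot exceed `positive`.",
          class = "expotox_config_error")
  }
  out <- ifelse(positive > 0,
                round_half_up(100 * associated / positive, 2), NA_real_)
  as.numeric(out)
}

#' Correlation between indicator positivity and exposure
#'
#' Bins the examination records into consecutive time bins (weekly by
#' default), computes each bin's positivity rate and mean ambient exposure,
#' and returns the Pearson correlation between the two.
#'
#' @param data Health-panel tibble with `date` and the indicator label.
#' @param indicator Indicator name (without the `label_` prefix).
#' @param env Environmental series tibble (`date` + channels).
#' @param channel Exposure channel name.
#' @param bin_days Bin width in days (default 7, one week).
#'
#' @return The Pearson correlation coefficient.
#' @export
indicator_correlation <- function(data, indicator, env, channel = "pm25",
                                  bin_days = 7) {
  lab <- paste0("label_", indicator)
  origin <- min(env$date)
  bin_of <- function(d) as.integer(floor(as.numeric(d - origin) / bin_days))
  rate <- tibble(bin = bin_of(data$date), pos = data[[lab]]) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(rate = mean(.data$pos), n = dplyr::n(),
                     .groups = "drop")
  expo <- tibble(bin = bin_of(env$date), x = env[[channel]]) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(exposure = mean(.data$x), .groups = "drop")
  d <- dplyr::inner_join(rate, expo, by = "bin")
  if (nrow(d) < 3) {
    abort("Fewer than 3 time bins with records.",
          class = "expotox_config_error")
  }
  if (sd(d$rate) == 0 || sd(d$exposure) == 0) {
    abort("Constant positivity or exposure; correlation undefined.",
          class = "expotox_config_error")
  }
  cor(d$rate, d$exposure)
}

#' Classify an indicator's exposure association
#'
#' An indicator is called positively or negatively associated when the
#' absolute correlation reaches `threshold`, otherwise not associated (in
#' formatted tables a not-associated indicator's attributed-case cells are
#' suppressed).
#'
#' @param r Correlation coefficient(s).
#' @param threshold Absolute-correlation cutoff (default 0.3).
#'
#' @return A factor with levels `positive-associated`,
#'   `negative-associated`, `not-associated`.
#' @examples
#' identify_association(c(0.435, 0.062, -0.597))
#' @export
identify_association <- function(r, threshold = 0.3) {
  lab <- ifelse(abs(r) < threshold, "not-associated",
                ifelse(r > 0, "positive-associated",
                       "negative-associated"))
  factor(lab, levels = c("positive-associated", "negative-associated",
                         "not-associated"))
}

#' Quarterly association table for a set of indicators
#'
#' The full association accounting for a panel: per indicator, quarterly
#' total/positive/attributed counts, the attributed percentage, the
#' positivity-exposure correlation, and the identification call. Counts
#' and percentages of not-associated indicators are suppressed (`NA`).
#'
#' @param data Health-panel tibble with an `attributed` column (see
#'   [flag_attributed()]).
#' @param env Environmental series tibble.
#' @param indicators Indicator names; defaults to all `label_*` columns.
#' @param channel Exposure channel for the correlation.
#' @param threshold Identification cutoff on `|r|`.
#' @param bin_days Bin width for the correlation.
#' @param year Optional year filter passed to [tabulate_associations()].
#'
#' @return An `association_table` tibble with one row per indicator and
#'   quarter: `indicator`, `quarter`, `total`, `positive`, `associated`,
#'   `percent`, `r`, `identified`.
#' @export
association_table <- function(data, env,
                              indicators = sub("^label_", "",
                                               label_cols(data)),
                              channel = "pm25", threshold = 0.3,
                              bin_days = 7, year = NULL) {
  rows <- purrr::map(indicators, function(ind) {
    counts <- tabulate_associations(data, ind, year = year)
    r <- indicator_correlation(data, ind, env, channel = channel,
                               bin_days = bin_days)
    ident <- identify_association(r, threshold)
    counts$percent <- percent_associated(counts$associated,
                                         counts$positive)
    if (ident == "not-associated") {
      counts$associated <- NA_integer_
      counts$percent <- NA_real_
    }
    dplyr::mutate(counts, indicator = ind, r = r, identified = ident,
                  .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("association_table", class(out))
  out
}

#' @export
print.association_table <- function(x, ...) {
  wide <- x |>
    dplyr::mutate(
      associated = ifelse(is.na(.data$associated), "–",
                          as.character(.data$associated)),
      percent = ifelse(is.na(.data$percent), "–",
                       sprintf("%.2f", .data$percent))) |>
    dplyr::select("indicator", "quarter", "total", "positive",
                  "associated", "percent", "r", "identified")
  print(tibble::new_tibble(wide, nrow = nrow(wide)), ...)
  invisible(x)
}

#' @export
autoplot.association_table <- function(object, ...) {
  d <- dplyr::filter(object, !is.na(.data$percent))
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$quarter), .data$percent,
                                  fill = .data$indicator)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "quarter", y = "% of positive cases attributed",
                  fill = NULL)
}
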