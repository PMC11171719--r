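q1_fixture <- function() {
  # 10 records, all in Q1; 4 positive, 1 of them attributed
  tibble::tibble(
    date = as.Date("2021-01-05") + 0:9,
    label_IND = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
    attributed = c(TRUE, rep(FALSE, 9)))
}

test_that("quarterly tabulation counts totals, positives and attributed", {
  counts <- tabulate_associations(q1_fixture(), "IND")
  expect_equal(counts$quarter, 1:4)
  expect_equal(counts$total, c(10L, 0L, 0L, 0L))
  expect_equal(counts$positive, c(4L, 0L, 0L, 0L))
  expect_equal(counts$associated, c(1L, 0L, 0L, 0L))
})

test_that("tabulation conserves records and respects the year filter", {
  withr::with_seed(1, {
    d <- tibble::tibble(
      date = as.Date("2021-01-01") + sample(0:364, 200, TRUE),
      label_IND = rbinom(200, 1, 0.3),
      attributed = runif(200) < 0.2)
  })
  counts <- tabulate_associations(d, "IND", year = 2021)
  expect_equal(sum(counts$total), 200L)
  expect_true(all(counts$associated <= counts$positive))
  expect_true(all(counts$positive <= counts$total))
  d$date[1] <- as.Date("2020-12-31")
  expect_error(tabulate_associations(d, "IND", year = 2021),
               class = "expotox_config_error")
  # attribution flag all false -> no associated cases anywhere
  d$date[1] <- as.Date("2021-01-01")
  d$attributed <- FALSE
  expect_equal(tabulate_associations(d, "IND")$associated, rep(0L, 4))
})

test_that("attributed percentage uses half-up rounding to two decimals", {
  expect_equal(percent_associated(12, 210), 5.71)
  expect_equal(percent_associated(280, 3845), 7.28)
  expect_equal(percent_associated(0, 100), 0)
  expect_true(is.na(percent_associated(0, 0)))
  # exact half rounds up (banker's rounding would give 5.72)
  expect_equal(percent_associated(1145, 20000), 5.73)
  expect_equal(percent_associated(5715, 100000), 5.72)
  # scale-free in the counts
  expect_equal(percent_associated(12 * 7, 210 * 7),
               percent_associated(12, 210))
  expect_error(percent_associated(5, 4), class = "expotox_config_error")
})

test_that("identification thresholds correlations by sign and magnitude", {
  r <- c(0.435, 0.254, 0.481, -0.597, 0.062)
  got <- identify_association(r, threshold = 0.3)
  expect_equal(as.character(got),
               c("positive-associated", "not-associated",
                 "positive-associated", "negative-associated",
                 "not-associated"))
  # monotone in the threshold: raising it never creates an association
  for (thr in c(0.1, 0.3, 0.5, 0.7)) {
    lo <- identify_association(r, thr) != "not-associated"
    hi <- identify_association(r, thr + 0.2) != "not-associated"
    expect_true(all(lo | !hi))
  }
})

test_that("binned positivity-exposure correlation responds to sign flips", {
  env <- tiny_env(n_days = 400, period = 60, seed = 4)
  hx <- tiny_panel(n_records = 4000, planted_r = 0.5, seed = 6,
                   env = env, n_features = 2)
  r <- indicator_correlation(hx, "IND", env, channel = "pm25")
  expect_gt(r, 0.2)
  env_neg <- env
  env_neg$pm25 <- -env_neg$pm25
  r_neg <- indicator_correlation(hx, "IND", env_neg, channel = "pm25")
  expect_equal(r_neg, -r, tolerance = 1e-10)
  # weekly positivity rate exactly linear in weekly exposure -> r = 1
  lab <- unlist(lapply(1:8, function(w) rep(1:0, c(w - 1, 8 - w))))
  lin <- tibble::tibble(date = env$date[1:56], label_IND = lab)
  env_lin <- tibble::tibble(date = env$date[1:56],
                            pm25 = as.numeric(rep(1:8, each = 7)))
  expect_equal(indicator_correlation(lin, "IND", env_lin), 1)
  expect_error(
    indicator_correlation(lin[1:10, ], "IND", env_lin[1:10, ]),
    class = "expotox_config_error")
})

test_that("the full association table suppresses not-associated indicators", {
  env <- tiny_env(n_days = 400, period = 60, seed = 4)
  cfg <- health_config(
    n_records = 4000, n_features = 2,
    indicators = tibble::tibble(
      name = c("POS", "NULLIND"),
      planted_r = c(0.6, 0),
      base_positivity = c(0.3, 0.3)),
    seed = 8)
  hx <- generate_health(cfg, env)
  ex <- attr(hx, "exposure")$exposure_mean
  hx <- flag_attributed(hx, hx$label_POS == 1, ex)
  tab <- association_table(hx, env, threshold = 0.3)
  pos_rows <- dplyr::filter(tab, .data$indicator == "POS")
  null_rows <- dplyr::filter(tab, .data$indicator == "NULLIND")
  expect_equal(as.character(unique(pos_rows$identified)),
               "positive-associated")
  expect_equal(as.character(unique(null_rows$identified)),
               "not-associated")
  expect_true(all(is.na(null_rows$associated)))
  expect_true(all(is.na(null_rows$percent)))
  expect_false(anyNA(pos_rows$percent))
  expect_output(print(tab), "–")
})
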