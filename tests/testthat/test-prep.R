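make_missing_panel <- function() {
  # 10 rows x 10 features; rows 1-3 have 30% missing, the rest 0 or 10%
  withr::with_seed(1, {
    d <- tibble::as_tibble(matrix(rnorm(100), 10, 10),
                           .name_repair = ~ paste0("f", 1:10))
    for (i in 1:3) d[i, sample(10, 3)] <- NA
    d[5, "f2"] <- NA
    d
  })
}

test_that("records above the missingness threshold are dropped, the rest imputed", {
  d <- make_missing_panel()
  out <- clean_records(d, max_missing_fraction = 0.2)
  expect_equal(nrow(out), 7)
  expect_equal(attr(out, "n_dropped"), 3)
  expect_false(anyNA(out))
  # row 5 (second retained row) had f2 missing: imputed with the
  # retained rows' median
  expect_equal(out$f2[2], median(d$f2[4:10], na.rm = TRUE))
  expect_error(clean_records(d, max_missing_fraction = -0.1),
               class = "expotox_empty_error")
})

test_that("min-max normalization follows the rescaling formula", {
  d <- tibble::tibble(f1 = c(1, 3, 5), f2 = c(4, 4, 4))
  p <- minmax_fit(d)
  out <- minmax_apply(d, p)
  expect_equal(out$f1, c(0, 0.5, 1))
  expect_equal(out$f2, c(0, 0, 0))      # constant-feature convention
  # linear extrapolation beyond the training range
  p2 <- minmax_fit(tibble::tibble(f1 = c(0, 10)))
  expect_equal(minmax_apply(tibble::tibble(f1 = 12), p2)$f1, 1.2)
  expect_error(minmax_fit(tibble::tibble(f1 = numeric())),
               class = "expotox_empty_error")
})

test_that("normalization is idempotent on the training split", {
  d <- tibble::as_tibble(matrix(rnorm(60), 20, 3),
                         .name_repair = ~ paste0("f", 1:3))
  once <- minmax_apply(d, minmax_fit(d))
  twice <- minmax_apply(once, minmax_fit(once))
  expect_equal(twice, once)
  expect_true(all(as.matrix(once) >= 0 & as.matrix(once) <= 1))
})

test_that("train/test split is disjoint, exhaustive and seeded", {
  d <- tibble::tibble(id = 1:100, f1 = rnorm(100))
  sp <- split_train_test(d, 0.8, seed = 3)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$test), 20)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  expect_setequal(c(sp$train$id, sp$test$id), d$id)
  sp2 <- split_train_test(d, 0.8, seed = 3)
  expect_identical(sp$train$id, sp2$train$id)
  expect_error(split_train_test(d, 1.2), class = "expotox_config_error")
})

test_that("stratified split keeps per-class proportions within one record", {
  d <- tibble::tibble(id = 1:40,
                      cls = rep(1:4, times = c(17, 11, 7, 5)))
  sp <- split_train_test(d, 0.8, seed = 1, stratify = "cls")
  tab <- table(sp$train$cls)
  glob <- table(d$cls)
  for (k in names(glob)) {
    expect_lte(abs(tab[k] - 0.8 * glob[k]), 1)
  }
})

test_that("binary-relevance transform yields one dataset per label", {
  d <- tibble::tibble(f1 = rnorm(6), f2 = rnorm(6),
                      label_a = c(1, 0, 1, 0, 1, 0),
                      label_b = c(0, 1, 1, 0, 0, 1),
                      label_c = c(0, 0, 0, 1, 1, 1))
  br <- br_transform(d)
  expect_named(br, c("a", "b", "c"))
  expect_equal(br$a$target, d$label_a)
  expect_identical(br$a[c("f1", "f2")], br$c[c("f1", "f2")])
  expect_error(br_transform(dplyr::select(d, f1, f2)),
               class = "expotox_config_error")
})

test_that("label-powerset classes follow first occurrence and invert exactly", {
  d <- tibble::tibble(label_a = c(1, 0, 1), label_b = c(0, 1, 1))
  lp <- lp_transform(d)
  expect_equal(as.integer(lp$lp_class), c(1L, 2L, 3L))
  all_zero <- tibble::tibble(label_a = c(0, 0), label_b = c(0, 0))
  expect_equal(unique(lp_transform(all_zero)$lp_class), 1L)
  # round trip on a larger random label matrix
  withr::with_seed(4, {
    big <- tibble::as_tibble(matrix(rbinom(200, 1, 0.4), 50, 4),
                             .name_repair = ~ paste0("label_", letters[1:4]))
  })
  lp2 <- lp_transform(big)
  rec <- lp_inverse(lp2$lp_class)
  expect_equal(unname(as.matrix(rec)), unname(as.matrix(big)))
})

test_that("pearson coupling coefficients match degenerate label patterns", {
  x <- c(1, 1, 0, 0)
  d <- tibble::tibble(label_anchor = x, label_same = x,
                      label_opp = 1 - x,
                      label_orth = c(1, 0, 1, 0))
  spec <- pearson_alpha(d, "label_anchor")
  expect_s3_class(spec, "association_loss_spec")
  a <- setNames(spec$alpha, spec$label)
  expect_equal(unname(a["label_same"]), 1)
  expect_equal(unname(a["label_opp"]), -1)
  expect_equal(unname(a["label_orth"]), 0)
  d$label_const <- 1
  expect_warning(s2 <- pearson_alpha(d, "label_anchor"),
                 "zero variance")
  expect_equal(s2$alpha[s2$label == "label_const"], 0)
})

test_that("association loss is the coupling-weighted sum of losses", {
  expect_equal(association_loss(1.0, 0.4, spec = 0.5), 1.2)
  expect_equal(association_loss(1.0, 0.4, spec = -0.5), 0.8)
  expect_equal(association_loss(0.7), 0.7)   # no coupled labels
  # linearity in the per-label losses with coefficients (1, alpha)
  withr::with_seed(2, {
    alpha <- runif(4, -1, 1)
    l1 <- runif(4); l2 <- runif(4)
    a1 <- runif(1); a2 <- runif(1)
  })
  expect_equal(
    association_loss(a1 + a2, l1 + l2, spec = alpha),
    association_loss(a1, l1, spec = alpha) +
      association_loss(a2, l2, spec = alpha))
  expect_error(association_loss(1, c(0.1, 0.2), spec = 0.5),
               class = "expotox_config_error")
})
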