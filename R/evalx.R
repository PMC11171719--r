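#' Classification metrics
#'
#' Confusion-count metrics for binary or multi-class predictions. Binary
#' problems use the conventional positive class (the last factor level, so
#' `1` for 0/1 labels); multi-class problems report support-weighted macro
#' precision/recall/F1. Accuracy is reported in percent, the other metrics
#' as fractions. If `scores` are supplied, the area under the ROC curve is
#' computed by the rank (Mann-Whitney) statistic, which equals the
#' trapezoidal area under the empirical ROC.
#'
#' @param truth True class labels.
#' @param predicted Predicted class labels.
#' @param scores Optional scores: for binary problems a numeric vector of
#'   positive-class scores; for multi-class a matrix with one column per
#'   class (one-vs-rest AUC, support-weighted).
#'
#' @return A one-row `classification_report` tibble with columns
#'   `accuracy` (percent), `precision`, `recall`, `f1` and `auc` (`NA` when
#'   no scores are given); the confusion matrix is attached as attribute
#'   `"confusion"`.
#' @examples
#' classification_metrics(c(1, 1, 0, 0), c(1, 0, 1, 0),
#'                        scores = c(0.9, 0.4, 0.6, 0.1))
#' @export
classification_metrics <- function(truth, predicted, scores = NULL) {
  lev <- sort(unique(c(as.character(truth), as.character(predicted))))
  t_f <- factor(as.character(truth), levels = lev)
  p_f <- factor(as.character(predicted), levels = lev)
  cm <- table(truth = t_f, predicted = p_f)
  acc <- 100 * sum(diag(cm)) / sum(cm)
  per_class <- function(cls) {
    tp <- cm[cls, cls]
    fp <- sum(cm[, cls]) - tp
    fn <- sum(cm[cls, ]) - tp
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p = p, r = r, f1 = f1, support = sum(cm[cls, ]))
  }
  if (length(lev) == 2) {
    m <- per_class(lev[2])
    prec <- m[["p"]]; rec <- m[["r"]]; f1 <- m[["f1"]]
  } else {
    ms <- vapply(lev, per_class, numeric(4))
    wts <- ms["support", ] / sum(ms["support", ])
    prec <- sum(ms["p", ] * wts); rec <- sum(ms["r", ] * wts)
    f1 <- sum(ms["f1", ] * wts)
  }
  auc <- NA_real_
  if (!is.null(scores)) {
    if (length(unique(as.character(truth))) < 2) {
      abort("AUC is undefined when the truth contains a single class.",
            class = "expotox_config_error")
    }
    if (is.matrix(scores) || is.data.frame(scores)) {
      scores <- as.matrix(scores)
      supp <- table(t_f)
      aucs <- vapply(lev, function(cls) {
        auc_rank(t_f == cls, scores[, match(cls, colnames(scores) %||% lev)])
      }, numeric(1))
      auc <- sum(aucs * as.numeric(supp[lev])) / sum(supp)
    } else {
      auc <- auc_rank(t_f == lev[length(lev)], scores)
    }
  }
  out <- tibble(accuracy = acc, precision = prec, recall = rec, f1 = f1,
                auc = auc)
  attr(out, "confusion") <- cm
  class(out) <- c("classification_report", class(out))
  out
}

# AUC via the Mann-Whitney rank statistic (ties handled by midranks);
# identical to the trapezoidal area under the empirical ROC curve.
auc_rank <- function(is_pos, scores) {
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Root-mean-square and mean absolute error
#'
#' @param pred,obs Equal-length numeric vectors.
#' @return A non-negative scalar in the target's units.
#' @examples
#' rmse(c(0, 0), c(3, 4))  # sqrt(12.5)
#' mae(c(0, 0), c(3, 4))   # 3.5
#' @export
rmse <- function(pred, obs) {
  check_aligned(pred, obs)
  sqrt(mean((pred - obs)^2))
}

#' @rdname rmse
#' @export
mae <- function(pred, obs) {
  check_aligned(pred, obs)
  mean(abs(pred - obs))
}

check_aligned <- function(pred, obs) {
  if (length(pred) == 0 || length(pred) != length(obs)) {
    abort("`pred` and `obs` must be non-empty and of equal length.",
          class = "expotox_config_error")
  }
}

#' Willmott's index of agreement
#'
#' `d = 1 - sum((obs - pred)^2) / sum((|pred - mean(obs)| +
#' |obs - mean(obs)|)^2)`, bounded in `[0, 1]`; 1 for a perfect fit and 0
#' when the prediction is the observed mean.
#'
#' @inheritParams rmse
#' @return The index of agreement (scalar in `[0, 1]`).
#' @export
index_of_agreement <- function(pred, obs) {
  check_aligned(pred, obs)
  obar <- mean(obs)
  denom <- sum((abs(pred - obar) + abs(obs - obar))^2)
  if (denom == 0) {
    abort("Index of agreement is undefined for constant identical series.",
          class = "expotox_config_error")
  }
  1 - sum((obs - pred)^2) / denom
}

#' Fitting degree between predicted and reference series
#'
#' The agreement score between a model's predictions and a reference
#' (simulated) series: Pearson correlation by default (affine-invariant,
#' in `[-1, 1]`), or Nash-Sutcliffe efficiency with `method = "nse"`.
#'
#' @inheritParams rmse
#' @param method `"pearson"` (default) or `"nse"`.
#' @return A scalar agreement score.
#' @export
fitting_degree <- function(pred, obs, method = c("pearson", "nse")) {
  method <- match.arg(method)
  check_aligned(pred, obs)
  if (sd(pred) == 0 || sd(obs) == 0) {
    abort("Fitting degree is undefined for constant series.",
          class = "expotox_config_error")
  }
  if (method == "pearson") cor(pred, obs) else nse(obs, pred)
}

#' Series prediction report
#'
#' @inheritParams rmse
#' @return A one-row tibble with `rmse`, `mae`, `ia` and `fitting_degree`.
#' @export
series_report <- function(pred, obs) {
  tibble(rmse = rmse(pred, obs), mae = mae(pred, obs),
         ia = index_of_agreement(pred, obs),
         fitting_degree = fitting_degree(pred, obs))
}
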