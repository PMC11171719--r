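#' Drop heavily missing records and impute the remainder
#'
#' Records whose fraction of missing feature values exceeds
#' `max_missing_fraction` are excluded outright; remaining missing values
#' are imputed with the per-feature median computed on the retained rows
#' (pass `reference` to impute from a training split instead).
#'
#' @param data A health-panel tibble (see [generate_health()] for the column
#'   convention).
#' @param max_missing_fraction Maximum tolerated fraction of missing
#'   features per record; rows above it are dropped.
#' @param features Feature columns to consider; defaults to
#'   [feature_cols()].
#' @param reference Optional tibble whose feature medians are used for
#'   imputation (typically the training split).
#'
#' @return The cleaned tibble, with the number of dropped rows in attribute
#'   `"n_dropped"`.
#' @export
clean_records <- function(data, max_missing_fraction = 0.2,
                          features = feature_cols(data),
                          reference = NULL) {
  fm <- as.matrix(data[features])
  frac <- rowMeans(is.na(fm))
  keep <- frac <= max_missing_fraction
  if (!any(keep)) {
    abort("All records exceed the missingness threshold.",
          class = "expotox_empty_error")
  }
  out <- data[keep, , drop = FALSE]
  ref <- if (is.null(reference)) out else reference
  meds <- vapply(features, function(f) median(ref[[f]], na.rm = TRUE),
                 numeric(1))
  for (f in features) {
    miss <- is.na(out[[f]])
    if (any(miss)) out[[f]][miss] <- meds[[f]]
  }
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Min-max normalization
#'
#' `minmax_fit()` records each feature's training-split minimum and maximum;
#' `minmax_apply()` rescales columns as `(x - min) / (max - min)`. Training
#' outputs lie in `[0, 1]`; applying fitted parameters to new data may give
#' values outside that range. A constant feature (max equal to min) maps to
#' 0 by convention.
#'
#' @param data A tibble; only `features` columns are touched.
#' @param features Columns to normalize; defaults to [feature_cols()].
#' @param params Parameters from `minmax_fit()`.
#'
#' @return `minmax_fit()`: a `minmax_params` tibble with columns `feature`,
#'   `min`, `max`. `minmax_apply()`: `data` with the listed columns
#'   rescaled.
#' @examples
#' d <- tibble::tibble(f1 = c(1, 3, 5))
#' minmax_apply(d, minmax_fit(d))$f1  # 0, 0.5, 1
#' @export
minmax_fit <- function(data, features = feature_cols(data)) {
  bad <- features[vapply(features, function(f) all(is.na(data[[f]])) ||
                           nrow(data) == 0, logical(1))]
  if (nrow(data) == 0 || length(bad)) {
    abort("Cannot fit min-max parameters on an empty feature column.",
          class = "expotox_empty_error")
  }
  p <- tibble(
    feature = features,
    min = vapply(data[features], min, numeric(1), na.rm = TRUE,
                 USE.NAMES = FALSE),
    max = vapply(data[features], max, numeric(1), na.rm = TRUE,
                 USE.NAMES = FALSE)
  )
  class(p) <- c("minmax_params", class(p))
  p
}

#' @rdname minmax_fit
#' @export
minmax_apply <- function(data, params) {
  stopifnot(inherits(params, "minmax_params"))
  for (i in seq_len(nrow(params))) {
    f <- params$feature[i]
    rng <- params$max[i] - params$min[i]
    data[[f]] <- if (rng == 0) rep(0, nrow(data)) else
      (data[[f]] - params$min[i]) / rng
  }
  data
}

#' Random train/test split
#'
#' Splits the rows into disjoint, exhaustive training and test sets. With
#' `stratify`, sampling is per class so that each class's training
#' proportion is within one record of the global fraction (used with
#' label-powerset classes).
#'
#' @param data A tibble.
#' @param fraction Training fraction, strictly between 0 and 1 (0.8 for the
#'   conventional 80/20 split).
#' @param seed Integer seed; the same seed reproduces the same split.
#' @param stratify Optional column name (string) or vector of class labels
#'   to stratify on.
#'
#' @return A list with tibbles `train` and `test`.
#' @export
split_train_test <- function(data, fraction = 0.8, seed = 1L,
                             stratify = NULL) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    abort("`fraction` must lie strictly between 0 and 1.",
          class = "expotox_config_error")
  }
  n <- nrow(data)
  strata <- if (is.null(stratify)) rep(1L, n)
  else if (is.character(stratify) && length(stratify) == 1) data[[stratify]]
  else stratify
  idx <- withr::with_seed(seed, {
    unlist(lapply(split(seq_len(n), strata), function(ii) {
      k <- round(length(ii) * fraction)
      if (length(ii) == 1) return(if (runif(1) < fraction) ii else integer())
      sample(ii, k)
    }), use.names = FALSE)
  })
  list(train = data[sort(idx), , drop = FALSE],
       test = data[setdiff(seq_len(n), idx), , drop = FALSE])
}

as_label_matrix <- function(labels) {
  m <- as.matrix(labels)
  if (ncol(m) < 1) {
    abort("At least one label column is required.",
          class = "expotox_config_error")
  }
  if (!all(m %in% c(0, 1))) {
    abort("Label entries must be binary (0/1).",
          class = "expotox_config_error")
  }
  storage.mode(m) <- "integer"
  m
}

#' Binary-relevance transform
#'
#' Decomposes a multi-label panel into one single-label dataset per label:
#' each element holds the identical feature matrix with one binary `target`
#' column.
#'
#' @param data A health-panel tibble with `label_*` columns (or pass
#'   explicit `labels`).
#' @param labels Label columns; defaults to [label_cols()].
#' @param features Feature columns; defaults to [feature_cols()].
#'
#' @return A named list of tibbles, one per label, each `features` plus
#'   `target`.
#' @export
br_transform <- function(data, labels = label_cols(data),
                         features = feature_cols(data)) {
  lm <- as_label_matrix(data[labels])
  out <- purrr::map(seq_along(labels), function(i) {
    d <- data[, features, drop = FALSE]
    d$target <- lm[, i]
    d
  })
  names(out) <- sub("^label_", "", labels)
  out
}

#' Label-powerset transform
#'
#' Maps each observed combination of binary labels to one categorical class,
#' in order of first occurrence. `lp_inverse()` reconstructs the original
#' binary label matrix from the class column.
#'
#' @inheritParams br_transform
#' @param classes An `lp_class` factor produced by `lp_transform()`.
#'
#' @return `lp_transform()`: `data` with an added integer `lp_class` column;
#'   the combination-to-class mapping is attached as attribute `"lp_map"`
#'   (a tibble with the label columns and `lp_class`) and on the column
#'   itself. `lp_inverse()`: a tibble of binary label columns.
#' @export
lp_transform <- function(data, labels = label_cols(data)) {
  lm <- as_label_matrix(data[labels])
  key <- apply(lm, 1, paste, collapse = "")
  lev <- unique(key)                      # first-occurrence order
  cls <- match(key, lev)
  map <- as_tibble(lm[match(lev, key), , drop = FALSE])
  map$lp_class <- seq_along(lev)
  out <- data
  out$lp_class <- cls
  attr(out$lp_class, "lp_map") <- map
  attr(out, "lp_map") <- map
  out
}

#' @rdname lp_transform
#' @export
lp_inverse <- function(classes, map = attr(classes, "lp_map")) {
  if (is.null(map)) {
    abort("No label-powerset mapping found; pass `map`.",
          class = "expotox_config_error")
  }
  map[match(as.integer(classes), map$lp_class),
      setdiff(names(map), "lp_class"), drop = FALSE]
}

#' @rdname lp_transform
#' @param map The combination-to-class mapping tibble.
#' @export
lp_classes <- function(data) attr(data, "lp_map")

#' Pearson coupling coefficients for the association loss
#'
#' For a chosen anchor label, computes the sample Pearson correlation
#' between the anchor's binary label vector and every other label vector on
#' the (training) data. These correlations weight the coupled labels' losses
#' in [association_loss()]. Zero-variance labels get a coefficient of 0 with
#' a warning.
#'
#' @param data A tibble with binary `label_*` columns (or any binary
#'   columns named in `labels`).
#' @param anchor Anchor label: a column name or index into `labels`.
#' @param labels Label columns; defaults to [label_cols()].
#'
#' @return An `association_loss_spec`: a tibble with columns `label` and
#'   `alpha` (one row per non-anchor label, in `labels` order), with the
#'   anchor name in attribute `"anchor"`.
#' @export
pearson_alpha <- function(data, anchor, labels = label_cols(data)) {
  lm <- as_label_matrix(data[labels])
  a_idx <- if (is.character(anchor)) match(anchor, labels) else
    as.integer(anchor)
  if (is.na(a_idx) || a_idx < 1 || a_idx > length(labels)) {
    abort("`anchor` does not name a label column.",
          class = "expotox_config_error")
  }
  av <- lm[, a_idx]
  if (var(av) == 0) {
    abort("Anchor label has zero variance.", class = "expotox_config_error")
  }
  others <- setdiff(seq_along(labels), a_idx)
  alpha <- vapply(others, function(i) {
    if (var(lm[, i]) == 0) {
      warn(sprintf("Label '%s' has zero variance; alpha set to 0.",
                   labels[i]))
      return(0)
    }
    cor(av, lm[, i])
  }, numeric(1))
  spec <- tibble(label = labels[others], alpha = alpha)
  attr(spec, "anchor") <- labels[a_idx]
  class(spec) <- c("association_loss_spec", class(spec))
  spec
}

#' Correlation-weighted association loss
#'
#' Combines per-label cross-entropy losses into the coupled loss
#' `CL = loss_anchor + sum_i alpha_i * loss_i`, where the `alpha_i` are the
#' anchor's Pearson correlations with the coupled labels (from
#' [pearson_alpha()]). With all `alpha_i = 0` this reduces to the anchor's
#' plain cross-entropy. CL is used as-is; strong negative couplings can make
#' it negative.
#'
#' @param anchor_loss Cross-entropy loss of the anchor label's classifier.
#' @param coupled_losses Numeric vector of the coupled labels' losses, in
#'   the order of `spec$label` (or a named vector matched by name).
#' @param spec An `association_loss_spec` from [pearson_alpha()], or a bare
#'   numeric vector of coefficients.
#'
#' @return The combined loss (scalar).
#' @examples
#' association_loss(1.0, 0.4, spec = 0.5)    # 1.2
#' association_loss(1.0, 0.4, spec = -0.5)   # 0.8
#' @export
association_loss <- function(anchor_loss, coupled_losses = numeric(),
                             spec = numeric()) {
  alpha <- if (inherits(spec, "association_loss_spec")) spec$alpha else
    as.numeric(spec)
  if (length(coupled_losses) != length(alpha)) {
    abort("`coupled_losses` and coupling coefficients differ in length.",
          class = "expotox_config_error")
  }
  if (inherits(spec, "association_loss_spec") &&
      !is.null(names(coupled_losses))) {
    coupled_losses <- coupled_losses[spec$label]
  }
  as.numeric(anchor_loss + sum(alpha * coupled_losses))
}
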