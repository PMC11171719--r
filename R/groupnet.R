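#' Group-convolution network configuration
#'
#' Architecture and training hyperparameters for the 1-D group-convolution
#' classifier. The normalized examination features are laid out in column
#' order as a 1-D signal (zero-padded to a multiple of `n_groups`), split
#' into `n_groups` uniform segments convolved independently, fused by a
#' 1x1 "clustered" convolution, max-pooled, regularized by dropout, and
#' classified through a fully connected layer and softmax (or per-label
#' sigmoid heads in binary-relevance mode).
#'
#' @param n_features Length of the input feature vector.
#' @param n_classes Number of output classes (label-powerset mode) or
#'   labels (binary-relevance mode).
#' @param n_groups Number of uniform groups the signal is split into.
#' @param kernels_per_unit Convolution kernels per convolutional unit.
#' @param conv_layers_per_group Stacked convolution layers within each
#'   group.
#' @param kernel_size Odd kernel width (same-padding).
#' @param clustered_kernels Kernels of the 1x1 clustered convolution.
#' @param pool_size Max-pooling width and stride.
#' @param dropout_rate Dropout probability in `[0, 1)` applied after
#'   pooling during training.
#' @param fc_units Neurons in the fully connected layer.
#' @param learning_rate,batch_size,epochs Adam step size, minibatch size
#'   and training cycles.
#' @param seed Integer seed for initialization, shuffling and dropout.
#'
#' @return A `groupnet_config` object.
#' @export
groupnet_config <- function(n_features, n_classes,
                            n_groups = 4, kernels_per_unit = 8,
                            conv_layers_per_group = 2, kernel_size = 3,
                            clustered_kernels = 12, pool_size = 2,
                            dropout_rate = 0.5, fc_units = 372,
                            learning_rate = 0.02, batch_size = 128,
                            epochs = 20, seed = 1L) {
  stopifnot(n_features >= n_groups, n_groups >= 1,
            kernel_size %% 2 == 1, kernel_size >= 1,
            dropout_rate >= 0, dropout_rate < 1, pool_size >= 1,
            conv_layers_per_group >= 1, n_classes >= 1)
  padded <- ceiling(n_features / n_groups) * n_groups
  group_len <- padded %/% n_groups
  if (group_len < pool_size) {
    abort("Group segments shorter than the pooling window.",
          class = "expotox_config_error")
  }
  structure(list(
    n_features = as.integer(n_features), n_classes = as.integer(n_classes),
    n_groups = as.integer(n_groups),
    kernels_per_unit = as.integer(kernels_per_unit),
    conv_layers_per_group = as.integer(conv_layers_per_group),
    kernel_size = as.integer(kernel_size),
    clustered_kernels = as.integer(clustered_kernels),
    pool_size = as.integer(pool_size), dropout_rate = dropout_rate,
    fc_units = as.integer(fc_units), learning_rate = learning_rate,
    batch_size = as.integer(batch_size), epochs = as.integer(epochs),
    padded_len = as.integer(padded), group_len = as.integer(group_len),
    pooled_len = as.integer(group_len %/% pool_size),
    seed = as.integer(seed)), class = "groupnet_config")
}

#' Parameter counts of the group and equivalent dense convolutions
#'
#' The group layout convolves each segment's channels independently, so a
#' layer with `c_in` channels and `k_out` kernels per group costs
#' `n_groups * kernel_size * c_in * k_out` weights, against
#' `kernel_size * (n_groups * c_in) * (n_groups * k_out)` for an ordinary
#' convolution over the undivided channels — a factor `n_groups` saving.
#'
#' @param config A [groupnet_config()].
#' @return A tibble with `group_conv_params` and `dense_conv_params`.
#' @export
groupnet_param_count <- function(config) {
  ks <- config$kernel_size; g <- config$n_groups
  k <- config$kernels_per_unit
  grp <- 0; dense <- 0
  c_in <- 1
  for (l in seq_len(config$conv_layers_per_group)) {
    grp <- grp + g * ks * c_in * k
    dense <- dense + ks * (g * c_in) * (g * k)
    c_in <- k
  }
  tibble(group_conv_params = grp, dense_conv_params = dense)
}

# --- low-level layers -------------------------------------------------
# Activations are stored as (batch, length, channels) arrays; im2col rows
# are ordered batch-fastest then position, matching R's column-major
# flattening.

im2col_1d <- function(X, ks) {
  d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
  p <- (ks - 1) %/% 2
  Xp <- array(0, c(B, L + 2 * p, C))
  Xp[, (p + 1):(p + L), ] <- X
  M <- matrix(0, B * L, C * ks)
  for (c in seq_len(C)) {
    for (o in seq_len(ks)) {
      M[, (c - 1) * ks + o] <- Xp[, o:(o + L - 1), c]
    }
  }
  M
}

col2im_1d <- function(dM, B, L, C, ks) {
  p <- (ks - 1) %/% 2
  dXp <- array(0, c(B, L + 2 * p, C))
  for (c in seq_len(C)) {
    for (o in seq_len(ks)) {
      dXp[, o:(o + L - 1), c] <- dXp[, o:(o + L - 1), c] +
        matrix(dM[, (c - 1) * ks + o], B, L)
    }
  }
  dXp[, (p + 1):(p + L), , drop = FALSE]
}

conv1d_forward <- function(X, W, b, ks) {
  d <- dim(X); B <- d[1]; L <- d[2]
  M <- im2col_1d(X, ks)
  Zm <- sweep(M %*% W, 2, b, "+")
  A <- array(pmax(Zm, 0), c(B, L, length(b)))
  list(A = A, M = M, relu_mask = Zm > 0)
}

conv1d_backward <- function(dA, cache, W, B, L, C_in, ks) {
  dZm <- matrix(dA, B * L, ncol(W)) * cache$relu_mask
  dW <- t(cache$M) %*% dZm
  db <- colSums(dZm)
  dM <- dZm %*% t(W)
  dX <- col2im_1d(dM, B, L, C_in, ks)
  list(dX = dX, dW = dW, db = db)
}

glorot <- function(nr, nc) {
  matrix(rnorm(nr * nc, 0, sqrt(2 / (nr + nc))), nr, nc)
}

#' Initialize a group-convolution network
#'
#' Convolution and fully connected weights get Glorot-normal draws; the
#' output layer is zero-initialized so an untrained network emits uniform
#' class probabilities.
#'
#' @param config A [groupnet_config()].
#' @param mode `"lp"` (single softmax over classes) or `"br"` (one sigmoid
#'   head per label).
#'
#' @return A `groupnet_model`.
#' @export
groupnet_init <- function(config, mode = c("lp", "br")) {
  mode <- match.arg(mode)
  withr::with_seed(config$seed, {
    ks <- config$kernel_size; k <- config$kernels_per_unit
    conv <- purrr::map(seq_len(config$n_groups), function(g) {
      c_in <- 1
      purrr::map(seq_len(config$conv_layers_per_group), function(l) {
        W <- glorot(c_in * ks, k)
        out <- list(W = W, b = rep(0, k), c_in = c_in)
        c_in <<- k
        out
      })
    })
    c_cat <- config$n_groups * k
    W_cl <- glorot(c_cat, config$clustered_kernels)
    flat <- config$pooled_len * config$clustered_kernels
    W_fc <- glorot(flat, config$fc_units)
    heads <- if (mode == "lp") {
      list(list(W = matrix(0, config$fc_units, config$n_classes),
                b = rep(0, config$n_classes)))
    } else {
      purrr::map(seq_len(config$n_classes), function(i)
        list(W = matrix(0, config$fc_units, 1), b = 0))
    }
    structure(list(config = config, mode = mode, conv = conv,
                   W_cl = W_cl, b_cl = rep(0, config$clustered_kernels),
                   W_fc = W_fc, b_fc = rep(0, config$fc_units),
                   heads = heads, trained = FALSE),
              class = "groupnet_model")
  })
}

# Full forward pass. X: (B, n_features) matrix of normalized features.
# Returns head outputs plus (optionally) every cache needed for backprop.
groupnet_forward_full <- function(model, X, train = FALSE,
                                  keep_cache = FALSE) {
  cfg <- model$config
  B <- nrow(X)
  Xp <- matrix(0, B, cfg$padded_len)
  Xp[, seq_len(cfg$n_features)] <- X
  Lg <- cfg$group_len
  caches <- vector("list", cfg$n_groups)
  group_out <- vector("list", cfg$n_groups)
  for (g in seq_len(cfg$n_groups)) {
    A <- array(Xp[, ((g - 1) * Lg + 1):(g * Lg)], c(B, Lg, 1))
    layer_caches <- vector("list", cfg$conv_layers_per_group)
    for (l in seq_len(cfg$conv_layers_per_group)) {
      fw <- conv1d_forward(A, model$conv[[g]][[l]]$W,
                           model$conv[[g]][[l]]$b, cfg$kernel_size)
      if (keep_cache) layer_caches[[l]] <- fw[c("M", "relu_mask")]
      A <- fw$A
    }
    caches[[g]] <- layer_caches
    group_out[[g]] <- A
  }
  # concatenate along the channel axis: (B, Lg, G*k)
  cat_arr <- array(0, c(B, Lg, cfg$n_groups * cfg$kernels_per_unit))
  for (g in seq_len(cfg$n_groups)) {
    idx <- ((g - 1) * cfg$kernels_per_unit + 1):(g * cfg$kernels_per_unit)
    cat_arr[, , idx] <- group_out[[g]]
  }
  # clustered 1x1 convolution + ReLU
  cat_mat <- matrix(cat_arr, B * Lg, dim(cat_arr)[3])
  cl_z <- sweep(cat_mat %*% model$W_cl, 2, model$b_cl, "+")
  cl_mask <- cl_z > 0
  cl_a <- array(pmax(cl_z, 0), c(B, Lg, cfg$clustered_kernels))
  # max-pool (width = stride = pool_size)
  Lp <- cfg$pooled_len
  pool <- array(-Inf, c(B, Lp, cfg$clustered_kernels))
  argmax <- array(1L, c(B, Lp, cfg$clustered_kernels))
  for (o in seq_len(cfg$pool_size)) {
    cand <- cl_a[, (seq_len(Lp) - 1) * cfg$pool_size + o, , drop = FALSE]
    upd <- cand > pool
    argmax[upd] <- o
    pool[upd] <- cand[upd]
  }
  flat <- matrix(pool, B, Lp * cfg$clustered_kernels)
  drop_mask <- NULL
  if (train && cfg$dropout_rate > 0) {
    keep <- 1 - cfg$dropout_rate
    drop_mask <- matrix(rbinom(length(flat), 1, keep) / keep,
                        nrow(flat), ncol(flat))
    flat <- flat * drop_mask
  }
  fc_z <- sweep(flat %*% model$W_fc, 2, model$b_fc, "+")
  fc_mask <- fc_z > 0
  fc_a <- pmax(fc_z, 0)
  if (model$mode == "lp") {
    logits <- sweep(fc_a %*% model$heads[[1]]$W, 2, model$heads[[1]]$b, "+")
    shifted <- logits - apply(logits, 1, max)
    ex <- exp(shifted)
    probs <- ex / rowSums(ex)
  } else {
    probs <- vapply(model$heads, function(h)
      as.numeric(sigmoid(fc_a %*% h$W + h$b)), numeric(B))
    probs <- matrix(probs, B, length(model$heads))
  }
  out <- list(probs = probs, fc_a = fc_a)
  if (keep_cache) {
    out <- c(out, list(caches = caches, group_out = group_out,
                       cat_mat = cat_mat, cl_mask = cl_mask,
                       argmax = argmax, flat = flat,
                       drop_mask = drop_mask, fc_mask = fc_mask, B = B))
  }
  out
}

#' Forward pass of a group-convolution network
#'
#' Evaluation-mode forward pass (dropout disabled, deterministic): rows of
#' the returned matrix are class probabilities summing to 1 in
#' label-powerset mode, or per-label positive probabilities in
#' binary-relevance mode.
#'
#' @param model A `groupnet_model` (or `groupnet_fit`).
#' @param data A tibble or matrix of normalized feature vectors.
#' @param features Feature columns when `data` is a tibble.
#'
#' @return A numeric matrix of probabilities, one row per input record.
#' @export
groupnet_forward <- function(model, data,
                             features = NULL) {
  if (inherits(model, "groupnet_fit")) model <- model$model
  X <- as_feature_matrix(data, features, model$config$n_features)
  groupnet_forward_full(model, X, train = FALSE)$probs
}

as_feature_matrix <- function(data, features, n_features) {
  if (is.matrix(data)) {
    X <- data
  } else {
    if (is.null(features)) features <- feature_cols(data)
    X <- as.matrix(data[features])
  }
  if (ncol(X) != n_features) {
    abort(sprintf("Expected %d features, got %d.", n_features, ncol(X)),
          class = "expotox_config_error")
  }
  unname(X)
}

# Backward pass given per-head logit gradients (B x n_heads for BR, or
# B x n_classes softmax gradient for LP). Returns the gradient list in the
# same structure as the parameters.
groupnet_backward <- function(model, fw, dlogits) {
  cfg <- model$config
  B <- fw$B; Lg <- cfg$group_len; Lp <- cfg$pooled_len
  head_grads <- vector("list", length(model$heads))
  if (model$mode == "lp") {
    h <- model$heads[[1]]
    head_grads[[1]] <- list(W = t(fw$fc_a) %*% dlogits,
                            b = colSums(dlogits))
    dfc_a <- dlogits %*% t(h$W)
  } else {
    dfc_a <- matrix(0, B, cfg$fc_units)
    for (i in seq_along(model$heads)) {
      dz <- dlogits[, i]
      head_grads[[i]] <- list(W = t(fw$fc_a) %*% matrix(dz), b = sum(dz))
      dfc_a <- dfc_a + matrix(dz) %*% t(model$heads[[i]]$W)
    }
  }
  dfc_z <- dfc_a * fw$fc_mask
  dW_fc <- t(fw$flat) %*% dfc_z
  db_fc <- colSums(dfc_z)
  dflat <- dfc_z %*% t(model$W_fc)
  if (!is.null(fw$drop_mask)) dflat <- dflat * fw$drop_mask
  dpool <- array(dflat, c(B, Lp, cfg$clustered_kernels))
  dcl_a <- array(0, c(B, Lg, cfg$clustered_kernels))
  for (o in seq_len(cfg$pool_size)) {
    sel <- fw$argmax == o
    tmp <- array(0, c(B, Lp, cfg$clustered_kernels))
    tmp[sel] <- dpool[sel]
    dcl_a[, (seq_len(Lp) - 1) * cfg$pool_size + o, ] <-
      dcl_a[, (seq_len(Lp) - 1) * cfg$pool_size + o, , drop = FALSE] + tmp
  }
  dcl_z <- matrix(dcl_a, B * Lg, cfg$clustered_kernels) * fw$cl_mask
  dW_cl <- t(fw$cat_mat) %*% dcl_z
  db_cl <- colSums(dcl_z)
  dcat <- array(dcl_z %*% t(model$W_cl),
                c(B, Lg, cfg$n_groups * cfg$kernels_per_unit))
  conv_grads <- vector("list", cfg$n_groups)
  for (g in seq_len(cfg$n_groups)) {
    idx <- ((g - 1) * cfg$kernels_per_unit + 1):(g * cfg$kernels_per_unit)
    dA <- dcat[, , idx, drop = FALSE]
    layer_grads <- vector("list", cfg$conv_layers_per_group)
    for (l in rev(seq_len(cfg$conv_layers_per_group))) {
      layer <- model$conv[[g]][[l]]
      bw <- conv1d_backward(dA, fw$caches[[g]][[l]], layer$W, B, Lg,
                            layer$c_in, cfg$kernel_size)
      layer_grads[[l]] <- list(W = bw$dW, b = bw$db)
      dA <- bw$dX
    }
    conv_grads[[g]] <- layer_grads
  }
  # element order must mirror model_params() exactly: the optimizer walks
  # both structures positionally
  list(conv = conv_grads, W_cl = dW_cl, b_cl = db_cl,
       W_fc = dW_fc, b_fc = db_fc, heads = head_grads)
}

# --- Adam over an arbitrary nested list of numeric parameters ---------

flatten_params <- function(p) {
  out <- list()
  rec <- function(x, path) {
    if (is.list(x)) {
      for (nm in seq_along(x)) rec(x[[nm]], c(path, nm))
    } else if (is.numeric(x)) {
      out[[length(out) + 1]] <<- path
    }
  }
  rec(p, integer())
  out
}

adam_init <- function(params) {
  paths <- flatten_params(params)
  list(paths = paths,
       m = purrr::map(paths, ~ 0), v = purrr::map(paths, ~ 0), t = 0)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (i in seq_along(state$paths)) {
    path <- state$paths[[i]]
    g <- grads[[path]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    params[[path]] <- params[[path]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

model_params <- function(model) {
  list(conv = purrr::map(model$conv, function(g)
    purrr::map(g, function(l) list(W = l$W, b = l$b))),
    W_cl = model$W_cl, b_cl = model$b_cl,
    W_fc = model$W_fc, b_fc = model$b_fc,
    heads = purrr::map(model$heads, function(h) list(W = h$W, b = h$b)))
}

set_model_params <- function(model, params) {
  for (g in seq_along(model$conv)) {
    for (l in seq_along(model$conv[[g]])) {
      model$conv[[g]][[l]]$W <- params$conv[[g]][[l]]$W
      model$conv[[g]][[l]]$b <- params$conv[[g]][[l]]$b
    }
  }
  model$W_cl <- params$W_cl; model$b_cl <- params$b_cl
  model$W_fc <- params$W_fc; model$b_fc <- params$b_fc
  for (i in seq_along(model$heads)) {
    model$heads[[i]]$W <- params$heads[[i]]$W
    model$heads[[i]]$b <- params$heads[[i]]$b
  }
  model
}

#' Train a group-convolution classifier
#'
#' Trains with Adam on minibatches. In label-powerset mode the loss is the
#' softmax cross-entropy over the powerset classes. In binary-relevance
#' mode each label has a sigmoid head sharing the convolutional trunk and
#' per-head binary cross-entropies are combined with weights
#' `(1, alpha_1, ..)`: the anchor's loss plus the Pearson-weighted losses
#' of the coupled labels ([pearson_alpha()]). With all `alpha = 0` (or with
#' `anchor` given and no `loss_spec`) this is exactly plain cross-entropy
#' on the anchor label.
#'
#' @param data Training tibble (normalized features; see [minmax_apply()]).
#' @param labels Label specification: in `"lp"` mode the name of the class
#'   column (e.g. `"lp_class"` from [lp_transform()]); in `"br"` mode the
#'   label columns (default all `label_*` columns).
#' @param mode `"lp"` or `"br"`.
#' @param config A [groupnet_config()]; defaults are built from the data.
#' @param loss_spec Optional `association_loss_spec` from
#'   [pearson_alpha()] (`"br"` mode only).
#' @param anchor Optional anchor label for plain anchor-only cross-entropy
#'   when no `loss_spec` is given.
#' @param validation Optional held-out tibble with the same columns, used
#'   for the per-epoch accuracy in the history.
#' @param features Feature columns; defaults to [feature_cols()].
#'
#' @return A `groupnet_fit`: the trained model plus a `history` tibble
#'   (`epoch`, `loss`, `accuracy`).
#' @export
groupnet_train <- function(data, labels = NULL, mode = c("lp", "br"),
                           config = NULL, loss_spec = NULL, anchor = NULL,
                           validation = NULL, features = NULL) {
  mode <- match.arg(mode)
  if (nrow(data) == 0) {
    abort("Empty training set.", class = "expotox_empty_error")
  }
  if (is.null(features)) features <- feature_cols(data)
  X <- as.matrix(data[features])
  if (mode == "lp") {
    if (is.null(labels)) labels <- "lp_class"
    y <- as.integer(data[[labels]])
    n_out <- max(y)
    head_names <- NULL
  } else {
    if (is.null(labels)) labels <- label_cols(data)
    Y <- as_label_matrix(data[labels])
    n_out <- ncol(Y)
    head_names <- sub("^label_", "", labels)
  }
  if (nrow(X) == 0) {
    abort("Empty training set.", class = "expotox_empty_error")
  }
  if (is.null(config)) {
    config <- groupnet_config(n_features = ncol(X), n_classes = n_out)
  }
  stopifnot(config$n_classes == n_out)
  # per-head loss weights in BR mode: anchor 1, coupled labels alpha
  w_head <- rep(1, n_out)
  if (mode == "br") {
    if (!is.null(loss_spec)) {
      anchor_name <- attr(loss_spec, "anchor")
      w_head <- rep(0, n_out)
      w_head[match(anchor_name, head_names)] <- 1
      w_head[match(loss_spec$label, head_names)] <- loss_spec$alpha
    } else if (!is.null(anchor)) {
      w_head <- rep(0, n_out)
      w_head[match(sub("^label_", "", anchor), head_names)] <- 1
    }
  }
  model <- groupnet_init(config, mode)
  params <- model_params(model)
  state <- adam_init(params)
  n <- nrow(X)
  history <- vector("list", config$epochs)
  withr::with_seed(substream_seed(config$seed, 1L), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      ep_loss <- 0; n_batches <- 0
      for (s in starts) {
        bi <- ord[s:min(s + config$batch_size - 1, n)]
        Xb <- X[bi, , drop = FALSE]
        model <- set_model_params(model, params)
        fw <- groupnet_forward_full(model, Xb, train = TRUE,
                                    keep_cache = TRUE)
        B <- length(bi)
        if (mode == "lp") {
          yb <- y[bi]
          p <- pmax(fw$probs, 1e-12)
          loss <- -mean(log(p[cbind(seq_len(B), yb)]))
          dlogits <- fw$probs
          dlogits[cbind(seq_len(B), yb)] <-
            dlogits[cbind(seq_len(B), yb)] - 1
          dlogits <- dlogits / B
        } else {
          Yb <- Y[bi, , drop = FALSE]
          p <- pmin(pmax(fw$probs, 1e-12), 1 - 1e-12)
          per_head <- -colMeans(Yb * log(p) + (1 - Yb) * log(1 - p))
          loss <- sum(w_head * per_head)
          dlogits <- sweep(fw$probs - Yb, 2, w_head, "*") / B
        }
        if (!is.finite(loss)) {
          abort("Non-finite training loss; lower the learning rate.",
                class = "expotox_train_error")
        }
        grads <- groupnet_backward(model, fw, dlogits)
        upd <- adam_step(params, grads, state, config$learning_rate)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + loss; n_batches <- n_batches + 1
      }
      model <- set_model_params(model, params)
      eval_data <- validation %||% data
      acc <- groupnet_accuracy(model, eval_data, mode, labels, features,
                               w_head)
      history[[ep]] <- tibble(epoch = ep, loss = ep_loss / n_batches,
                              accuracy = acc)
    }
  })
  model$trained <- TRUE
  structure(list(model = model, history = dplyr::bind_rows(history),
                 mode = mode, labels = labels, features = features,
                 head_names = head_names, loss_weights = w_head),
            class = "groupnet_fit")
}

groupnet_accuracy <- function(model, data, mode, labels, features,
                              w_head) {
  X <- as.matrix(data[features])
  probs <- groupnet_forward_full(model, unname(X), train = FALSE)$probs
  if (mode == "lp") {
    pred <- max.col(probs, ties.method = "first")
    mean(pred == as.integer(data[[labels]]))
  } else {
    Y <- as_label_matrix(data[labels])
    active <- which(w_head != 0)
    if (!length(active)) active <- seq_len(ncol(Y))
    mean((probs[, active, drop = FALSE] >= 0.5) ==
           (Y[, active, drop = FALSE] == 1))
  }
}

#' Predict classes or labels from a trained group-convolution network
#'
#' Label-powerset mode returns the arg-max class (ties toward the lower
#' class index); binary-relevance mode thresholds each head at 0.5, with
#' probability exactly 0.5 counting as positive.
#'
#' @param fit A `groupnet_fit` from [groupnet_train()].
#' @param data Tibble or matrix of normalized features.
#'
#' @return A tibble: in LP mode `.pred_class` plus `.prob_<k>` columns; in
#'   BR mode `.pred_<label>` and `.prob_<label>` columns.
#' @export
groupnet_predict <- function(fit, data) {
  if (!inherits(fit, "groupnet_fit") || !fit$model$trained) {
    abort("`fit` must be a trained groupnet_fit.",
          class = "expotox_config_error")
  }
  probs <- groupnet_forward(fit$model, data, features = fit$features)
  if (fit$mode == "lp") {
    out <- tibble(.pred_class = max.col(probs, ties.method = "first"))
    colnames(probs) <- paste0(".prob_", seq_len(ncol(probs)))
    dplyr::bind_cols(out, as_tibble(probs))
  } else {
    pred <- probs >= 0.5
    colnames(pred) <- paste0(".pred_", fit$head_names)
    colnames(probs) <- paste0(".prob_", fit$head_names)
    dplyr::bind_cols(as_tibble(pred * 1L), as_tibble(probs))
  }
}

#' @export
tidy.groupnet_fit <- function(x, ...) x$history

#' @export
glance.groupnet_fit <- function(x, ...) {
  tibble(mode = x$mode, epochs = nrow(x$history),
         final_loss = dplyr::last(x$history$loss),
         final_accuracy = dplyr::last(x$history$accuracy),
         best_epoch = x$history$epoch[which.max(x$history$accuracy)])
}

#' @export
autoplot.groupnet_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$history, c("loss", "accuracy"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}

#' @export
print.groupnet_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "GroupNet fit (%s mode): %d epochs, final loss %.4f, accuracy %.3f\n",
    g$mode, g$epochs, g$final_loss, g$final_accuracy))
  invisible(x)
}
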