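#' Training configuration
#'
#' Optimization settings for the pairwise network: mean squared error loss on
#' the normalized target scale, Adam optimizer, learning rate 1e-4. One
#' training example is a whole dataset (all n individuals); batches group
#' datasets. "Epochs" are full passes over the training split. Early stopping
#' monitors validation loss with the given patience and the best-validation
#' checkpoint is retained.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Datasets per optimization step.
#' @param epochs Maximum passes over the training split.
#' @param k_extract Pairs through which extractor-weight gradients flow,
#'   resampled uniformly each batch (`NULL` = all pairs, no gating).
#' @param validation_fraction Fraction of datasets held out for validation.
#' @param patience Early-stopping patience in epochs (`Inf` disables).
#' @param seed Seed controlling the validation split, batch order and pair
#'   subsampling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 32L, epochs = 50L,
                         k_extract = NULL, validation_fraction = 0.1,
                         patience = 10, seed = 1L) {
  assert_scalar_num(learning_rate, "learning_rate", positive = TRUE)
  batch_size <- assert_count(batch_size, "batch_size")
  epochs <- assert_count(epochs, "epochs")
  if (!is.null(k_extract)) k_extract <- assert_count(k_extract, "k_extract")
  assert_scalar_num(validation_fraction, "validation_fraction", nonneg = TRUE)
  if (validation_fraction >= 1) abort("`validation_fraction` must be < 1.")
  structure(
    list(learning_rate = learning_rate, optimizer = "adam",
         loss = "mse", batch_size = batch_size, epochs = epochs,
         k_extract = k_extract, validation_fraction = validation_fraction,
         patience = patience, seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Mean squared error loss
#'
#' @param pred,true Equal-length numeric vectors (normalized target scale).
#' @return Mean of squared differences.
#' @export
#' @examples
#' loss_mse(c(1, 3), c(2, 2)) # 1
loss_mse <- function(pred, true) {
  if (length(pred) == 0L || length(pred) != length(true)) {
    abort("`pred` and `true` must be non-empty vectors of equal length.")
  }
  mean((pred - true)^2)
}

#' Sample the gated pair subset
#'
#' Uniform random subset of `k` pairs without replacement; during training it is
#' resampled for every batch so all pairs are covered over time. Deterministic
#' given the RNG state (or `seed`).
#'
#' @param pairs Pair matrix from [enumerate_pairs()].
#' @param k Subset size, `1 <= k <= nrow(pairs)`.
#' @param seed Optional seed (otherwise the current RNG state is used).
#' @return A `k`-row subset of `pairs`.
#' @export
select_kextract_pairs <- function(pairs, k, seed = NULL) {
  k <- assert_count(k, "k")
  if (k > nrow(pairs)) abort("`k` cannot exceed the number of pairs.")
  if (!is.null(seed)) set.seed(seed)
  pairs[sort(sample.int(nrow(pairs), k)), , drop = FALSE]
}

# ---- Adam -------------------------------------------------------------------

weight_slots <- function(w) {
  out <- list()
  for (b in seq_along(w$conv_w)) {
    out[[paste0("conv_w", b)]] <- w$conv_w[[b]]
    out[[paste0("conv_b", b)]] <- w$conv_b[[b]]
  }
  out$dense_w <- w$dense_w
  out$dense_b <- w$dense_b
  out$head_w <- w$head_w
  out$head_b <- w$head_b
  out
}

grad_slots <- function(g) {
  out <- list()
  for (b in seq_along(g$conv_w)) {
    out[[paste0("conv_w", b)]] <- g$conv_w[[b]]
    out[[paste0("conv_b", b)]] <- g$conv_b[[b]]
  }
  out$dense_w <- g$dense_w
  out$dense_b <- g$dense_b
  out$head_w <- g$head_w
  out$head_b <- g$head_b
  out
}

set_weight_slots <- function(w, slots) {
  for (b in seq_along(w$conv_w)) {
    w$conv_w[[b]] <- slots[[paste0("conv_w", b)]]
    w$conv_b[[b]] <- slots[[paste0("conv_b", b)]]
  }
  w$dense_w <- slots$dense_w
  w$dense_b <- slots$dense_b
  w$head_w <- slots$head_w
  w$head_b <- slots$head_b
  w
}

adam_init <- function(slots) {
  list(m = lapply(slots, function(x) x * 0),
       v = lapply(slots, function(x) x * 0),
       t = 0L)
}

adam_step <- function(state, slots, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(slots)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    slots[[nm]] <- slots[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(state = state, slots = slots)
}

# ---- training loop ----------------------------------------------------------

as_dataset_list <- function(cache) {
  if (is.character(cache)) cache <- load_training_set(cache)
  if (is.list(cache) && !is.null(cache$datasets)) {
    sig <- vapply(cache$datasets, function(d) d$sigma, numeric(1))
    return(list(datasets = cache$datasets, sigma = sig,
                manifest = cache$manifest))
  }
  # a plain list of sim_result-style datasets
  sig <- vapply(cache, function(d) d$sigma_true %||% d$sigma, numeric(1))
  list(datasets = cache, sigma = sig, manifest = NULL)
}

#' Train the pairwise network
#'
#' Optimizes the network with Adam and mean squared error on z-scored log-sigma
#' targets. Each batch resamples the gated pair subset when `k_extract` is set:
#' the forward pass and the head's gradients use all pairs; extractor-weight
#' gradients flow only through the sampled subset. Training is deterministic
#' given `config$seed`. Divergence (non-finite loss) aborts with a diagnostic.
#'
#' @param spec A [model_spec()].
#' @param cache A directory/manifest written by [pack_training_set()], the list
#'   returned by [load_training_set()], or a plain list of `sim_result`
#'   datasets.
#' @param config A [train_config()].
#' @return A `disp_model`: best-validation weights (with the sigma
#'   normalization used), per-epoch loss history, spec and config.
#' @export
train_model <- function(spec, cache, config = train_config()) {
  stopifnot(inherits(spec, "model_spec"))
  data <- as_dataset_list(cache)
  n_data <- length(data$datasets)
  if (n_data < 2L) abort("need at least 2 datasets to train.")
  d <- dim(data$datasets[[1]]$genotypes)
  if (d[1] != spec$m_snps) {
    abort(sprintf("cache has m = %d SNPs but the spec expects %d.", d[1], spec$m_snps))
  }

  weights <- build_model(spec)
  if (!is.null(data$manifest) && !is.null(data$manifest$sigma_log_mean) &&
      is.finite(data$manifest$sigma_log_sd) && data$manifest$sigma_log_sd > 0) {
    weights$sigma_norm <- list(log_mean = data$manifest$sigma_log_mean,
                               log_sd = data$manifest$sigma_log_sd)
  } else {
    ls <- log(data$sigma)
    sdv <- stats::sd(ls)
    weights$sigma_norm <- list(log_mean = mean(ls),
                               log_sd = if (is.finite(sdv) && sdv > 0) sdv else 1)
  }

  set.seed(derive_seed(config$seed, "train"))
  # validation is split by simulation, not by dataset: draws from one
  # simulation share the same true sigma, and letting them straddle the split
  # would leak simulation identity into early stopping
  sim_of <- match(data$sigma, unique(data$sigma))
  n_sims <- max(sim_of)
  if (n_sims < 2L) sim_of <- seq_len(n_data) # degenerate: split by dataset
  n_sims <- max(sim_of)
  n_val_sims <- max(if (config$validation_fraction > 0) 1L else 0L,
                    round(config$validation_fraction * n_sims))
  val_sims <- if (n_val_sims > 0L) sample.int(n_sims, n_val_sims) else integer(0)
  val_idx <- which(sim_of %in% val_sims)
  train_idx <- setdiff(seq_len(n_data), val_idx)
  if (length(train_idx) == 0L) abort("validation split left no training datasets.")

  pairs <- enumerate_pairs(spec$n_samples)
  k <- config$k_extract %||% spec$k_extract
  use_gate <- !is.null(k) && k < nrow(pairs)

  input_cache <- precompute_pair_inputs(data$datasets, spec)
  slots <- weight_slots(weights)
  opt <- adam_init(slots)
  best_val <- Inf
  best_slots <- slots
  best_epoch <- 0L
  since_best <- 0L
  history <- vector("list", config$epochs)

  val_loss <- function(w) {
    if (length(val_idx) == 0L) return(NA_real_)
    target <- normalize_sigma(data$sigma[val_idx], w$sigma_norm)
    preds <- numeric(length(val_idx))
    starts <- seq(1L, length(val_idx), by = 64L)
    for (s in starts) {
      ids <- val_idx[s:min(s + 63L, length(val_idx))]
      preds[s:(s + length(ids) - 1L)] <-
        nn_forward(w, assemble_inputs(input_cache, ids))$y
    }
    loss_mse(preds, target)
  }

  for (epoch in seq_len(config$epochs)) {
    perm <- sample(train_idx)
    batch_starts <- seq(1L, length(perm), by = config$batch_size)
    epoch_losses <- numeric(length(batch_starts))
    for (s in seq_along(batch_starts)) {
      ids <- perm[batch_starts[s]:min(batch_starts[s] + config$batch_size - 1L, length(perm))]
      gate <- if (use_gate) {
        gate_mask_from_pairs(select_kextract_pairs(pairs, k), spec$n_samples)
      } else NULL
      res <- model_gradients_inputs(weights, assemble_inputs(input_cache, ids),
                                    data$sigma[ids], gate)
      if (!is.finite(res$loss)) {
        abort(sprintf("training diverged (non-finite loss) at epoch %d, batch %d",
                      epoch, s))
      }
      epoch_losses[s] <- res$loss
      upd <- adam_step(opt, slots, grad_slots(res$grads), config$learning_rate)
      opt <- upd$state
      slots <- upd$slots
      weights <- set_weight_slots(weights, slots)
    }
    vl <- val_loss(weights)
    history[[epoch]] <- tibble::tibble(epoch = epoch,
                                       train_loss = mean(epoch_losses),
                                       validation_loss = vl)
    track <- if (is.na(vl)) mean(epoch_losses) else vl
    if (track < best_val) {
      best_val <- track
      best_slots <- slots
      best_epoch <- epoch
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= config$patience) break
    }
  }

  weights <- set_weight_slots(weights, best_slots)
  structure(
    list(weights = weights, spec = spec, config = config,
         history = dplyr::bind_rows(history),
         best_epoch = best_epoch, best_validation_loss = best_val,
         n_train = length(train_idx), n_validation = length(val_idx)),
    class = "disp_model"
  )
}

# batched predictions; normalized = TRUE returns raw network outputs
predict_batches <- function(weights, datasets, batch_size = 32L, normalized = FALSE) {
  starts <- seq(1L, length(datasets), by = batch_size)
  out <- numeric(length(datasets))
  for (s in starts) {
    ids <- s:min(s + batch_size - 1L, length(datasets))
    inputs <- build_pair_inputs(datasets[ids], weights$spec)
    y <- nn_forward(weights, inputs)$y
    out[ids] <- if (normalized) y else denormalize_sigma(y, weights$sigma_norm)
  }
  out
}

#' Predict sigma from genotypes and locations
#'
#' De-normalized sigma estimate in the map units of the training simulations
#' (interpretation of units is the caller's responsibility: a model trained on
#' a simulated habitat returns sigma on that habitat's scale).
#'
#' @param weights A `weight_set` or fitted `disp_model`.
#' @param genotypes Coded genotype matrix (m x n or m x 2n).
#' @param locations Planar coordinates, one row per sample.
#' @return Scalar sigma estimate.
#' @export
predict_sigma <- function(weights, genotypes, locations) {
  if (inherits(weights, "disp_model")) weights <- weights$weights
  forward(genotypes, locations, weights)
}

#' @export
predict.disp_model <- function(object, datasets, ...) {
  sigma_hat <- predict_batches(object$weights, datasets,
                               object$config$batch_size %||% 32L)
  tibble::tibble(dataset = seq_along(datasets), sigma_hat = sigma_hat)
}

#' @export
print.disp_model <- function(x, ...) {
  cat(sprintf("<disp_model> trained %d epoch(s); best epoch %d (validation loss %.4g)\n",
              nrow(x$history), x$best_epoch, x$best_validation_loss))
  print(x$spec)
  invisible(x)
}

#' @export
tidy.disp_model <- function(x, ...) {
  x$history
}

#' @export
glance.disp_model <- function(x, ...) {
  tibble::tibble(
    epochs_trained = nrow(x$history),
    best_epoch = x$best_epoch,
    best_validation_loss = x$best_validation_loss,
    n_train = x$n_train,
    n_validation = x$n_validation,
    n_parameters = n_parameters(x$weights)
  )
}

#' Plot the training history
#'
#' @param object A fitted `disp_model`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss per epoch.
#' @export
autoplot.disp_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"epoch",
                            names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean squared error (normalized scale)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
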