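#' Specify the pairwise feature-extraction network
#'
#' Defines the architecture: per-pair convolutional feature extraction with
#' weights shared across all sample pairs, concatenation of the pair's scaled
#' geographic distance, a fully connected pair-feature layer, and a final
#' linear unit over the stacked features of all pairs producing the scalar
#' sigma estimate. The convolution kernel spans two SNPs (stride 1, valid
#' padding) and each pooling step averages ten SNPs (non-overlapping, remainder
#' dropped); these two constants are fixed. All hidden layers use rectified
#' linear activations; the output unit is linear.
#'
#' @param m_snps Number of SNP rows in the input genotype matrix.
#' @param n_samples Number of individuals n; the head consumes all n(n-1)/2
#'   pairs.
#' @param phased If `TRUE`, each pair contributes 4 haplotype rows instead of 2
#'   genotype rows.
#' @param conv_blocks Number of convolution + average-pooling blocks.
#' @param filters_per_block Integer vector of filter counts, one per block.
#' @param pair_dense_units Width of the per-pair fully connected layer.
#' @param k_extract Number of randomly chosen pairs through which gradients
#'   flow into the extractor weights during training (`NULL` = all pairs). The
#'   forward pass always uses every pair.
#' @param dist_scale Divisor applied to pair distances before they enter the
#'   network (typically the habitat or sample-cloud width); keeps the distance
#'   feature commensurate with convolution outputs.
#' @param seed Seed for weight initialization.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(m_snps, n_samples, phased = FALSE,
                       conv_blocks = 2L, filters_per_block = c(32L, 64L),
                       pair_dense_units = 128L, k_extract = NULL,
                       dist_scale = 1, seed = 1L) {
  m_snps <- assert_count(m_snps, "m_snps", min = 2L)
  n_samples <- assert_count(n_samples, "n_samples", min = 2L)
  conv_blocks <- assert_count(conv_blocks, "conv_blocks")
  filters_per_block <- vapply(filters_per_block, assert_count, integer(1),
                              name = "filters_per_block")
  if (length(filters_per_block) != conv_blocks) {
    abort("`filters_per_block` must have one entry per conv block.")
  }
  pair_dense_units <- assert_count(pair_dense_units, "pair_dense_units")
  n_pairs <- n_samples * (n_samples - 1L) / 2L
  if (!is.null(k_extract)) {
    k_extract <- assert_count(k_extract, "k_extract")
    if (k_extract > n_pairs) abort("`k_extract` cannot exceed the number of pairs.")
  }
  assert_scalar_num(dist_scale, "dist_scale", positive = TRUE)
  spec <- structure(
    list(
      m_snps = m_snps, n_samples = n_samples, phased = isTRUE(phased),
      conv_kernel_snps = 2L, pool_window = 10L,
      conv_blocks = conv_blocks, filters_per_block = filters_per_block,
      pair_dense_units = pair_dense_units,
      k_extract = k_extract, dist_scale = dist_scale,
      seed = as.integer(seed)
    ),
    class = "model_spec"
  )
  model_geometry(spec) # validates m_snps against the conv/pool stack
  spec
}

#' Layer geometry implied by a model specification
#'
#' Computes per-block lengths under the fixed conventions (kernel 2, stride 1,
#' valid padding; average pooling window 10, non-overlapping, remainder
#' dropped) and errors if `m_snps` is too small for the stack, reporting the
#' minimum.
#'
#' @param spec A [model_spec()].
#' @return A tibble with one row per block: input length, post-convolution
#'   length, post-pooling length, input channels and filters.
#' @export
model_geometry <- function(spec) {
  k <- spec$conv_kernel_snps
  w <- spec$pool_window
  min_m <- 1L
  for (b in seq_len(spec$conv_blocks)) min_m <- w * min_m + (k - 1L)
  if (spec$m_snps < min_m) {
    abort(sprintf("m_snps = %d too small for %d conv/pool blocks; minimum is %d",
                  spec$m_snps, spec$conv_blocks, min_m))
  }
  r <- if (spec$phased) 4L else 2L
  len <- spec$m_snps
  ch <- r
  rows <- vector("list", spec$conv_blocks)
  for (b in seq_len(spec$conv_blocks)) {
    l_conv <- len - (k - 1L)
    l_pool <- l_conv %/% w
    rows[[b]] <- tibble::tibble(block = b, len_in = len, channels_in = ch,
                                len_conv = l_conv, len_pool = l_pool,
                                filters = spec$filters_per_block[b])
    len <- l_pool
    ch <- spec$filters_per_block[b]
  }
  dplyr::bind_rows(rows)
}

#' @export
print.model_spec <- function(x, ...) {
  geo <- model_geometry(x)
  flat <- geo$len_pool[nrow(geo)] * geo$filters[nrow(geo)]
  cat(sprintf("<model_spec> m = %d SNPs, n = %d (%d pairs), %s\n",
              x$m_snps, x$n_samples, x$n_samples * (x$n_samples - 1L) / 2L,
              if (x$phased) "phased" else "unphased"))
  cat(sprintf("  extractor: %d conv/pool block(s) [%s filters] -> flatten %d + distance -> dense %d\n",
              x$conv_blocks, paste(x$filters_per_block, collapse = ", "),
              flat, x$pair_dense_units))
  cat(sprintf("  head: linear unit over %d stacked pair features\n",
              (x$n_samples * (x$n_samples - 1L) / 2L) * x$pair_dense_units))
  invisible(x)
}

#' Initialize network weights
#'
#' He-normal initialization for the rectified-linear layers, scaled-normal for
#' the linear head, zero biases; fully determined by `spec$seed`. Extractor
#' weights are shared across pairs, so the extractor parameter count does not
#' depend on the sample size.
#'
#' @param spec A [model_spec()].
#' @return A `weight_set`: conv kernels and biases per block, dense layer,
#'   head, the model specification, and the sigma normalization constants
#'   (identity until set by [train_model()]).
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  geo <- model_geometry(spec)
  set.seed(spec$seed)
  k <- spec$conv_kernel_snps
  conv_w <- vector("list", spec$conv_blocks)
  conv_b <- vector("list", spec$conv_blocks)
  for (b in seq_len(spec$conv_blocks)) {
    fan_in <- geo$channels_in[b] * k
    conv_w[[b]] <- matrix(rnorm(fan_in * geo$filters[b], 0, sqrt(2 / fan_in)),
                          fan_in, geo$filters[b])
    conv_b[[b]] <- numeric(geo$filters[b])
  }
  flat <- geo$len_pool[nrow(geo)] * geo$filters[nrow(geo)]
  dense_in <- flat + 1L # + pair distance
  dense_w <- matrix(rnorm(dense_in * spec$pair_dense_units, 0, sqrt(2 / dense_in)),
                    dense_in, spec$pair_dense_units)
  dense_b <- numeric(spec$pair_dense_units)
  n_pairs <- spec$n_samples * (spec$n_samples - 1L) / 2L
  head_in <- n_pairs * spec$pair_dense_units
  head_w <- matrix(rnorm(head_in, 0, sqrt(1 / head_in)), head_in, 1L)
  structure(
    list(spec = spec, conv_w = conv_w, conv_b = conv_b,
         dense_w = dense_w, dense_b = dense_b,
         head_w = head_w, head_b = 0,
         sigma_norm = list(log_mean = 0, log_sd = 1)),
    class = "weight_set"
  )
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf("<weight_set> %d parameters (%d in the shared extractor)\n",
              n_parameters(x), n_parameters(x, extractor_only = TRUE)))
  print(x$spec)
  invisible(x)
}

#' Count trainable parameters
#'
#' @param weights A `weight_set`.
#' @param extractor_only Count only the shared per-pair extractor (conv blocks
#'   and pair dense layer), excluding the head.
#' @return Integer parameter count.
#' @export
n_parameters <- function(weights, extractor_only = FALSE) {
  n <- sum(vapply(weights$conv_w, length, integer(1))) +
    sum(vapply(weights$conv_b, length, integer(1))) +
    length(weights$dense_w) + length(weights$dense_b)
  if (!extractor_only) n <- n + length(weights$head_w) + 1L
  as.integer(n)
}

# ---- internal batched forward / backward -----------------------------------
#
# A batch of B datasets with P pairs each is unrolled into T = B * P
# pair-instances. Activations are stored as (T * L) x C matrices with rows
# ordered instance-major, position-fastest, so convolution becomes im2col + one
# GEMM and average pooling becomes rowsum() over a precomputed grouping.

# genotype codes are centered before entering the network: 0/1/2 -> -1/0/1
# (unphased) and 0/1 -> -0.5/0.5 (phased); zero-mean inputs condition the
# rectified-linear stack far better than raw counts
genotype_center <- function(spec) if (spec$phased) 0.5 else 1

# stack genotype rows per pair-instance into the (T * m) x r block-1 input
build_pair_inputs <- function(datasets, spec) {
  n <- spec$n_samples
  m <- spec$m_snps
  pairs <- enumerate_pairs(n)
  r <- if (spec$phased) 4L else 2L
  blocks <- vector("list", length(datasets))
  dists <- vector("list", length(datasets))
  for (b in seq_along(datasets)) {
    g <- datasets[[b]]$genotypes
    if (nrow(g) != m) abort(sprintf("dataset %d has %d SNPs; model expects %d", b, nrow(g), m))
    expected_cols <- if (spec$phased) 2L * n else n
    if (ncol(g) != expected_cols) {
      abort(sprintf("dataset %d has %d genotype columns; model expects %d (%s)",
                    b, ncol(g), expected_cols,
                    if (spec$phased) "phased" else "unphased"))
    }
    a <- t(g) # columns are SNPs
    if (spec$phased) {
      rows_i <- 2L * pairs[, 1L]
      rows_j <- 2L * pairs[, 2L]
      lst <- list(a[rows_i - 1L, , drop = FALSE], a[rows_i, , drop = FALSE],
                  a[rows_j - 1L, , drop = FALSE], a[rows_j, , drop = FALSE])
    } else {
      lst <- list(a[pairs[, 1L], , drop = FALSE], a[pairs[, 2L], , drop = FALSE])
    }
    # (P * m) x r, rows pair-major position-fastest
    blocks[[b]] <- vapply(lst, function(x) as.vector(t(x)), numeric(nrow(pairs) * m))
    loc <- datasets[[b]]$locations
    if (is.matrix(loc)) loc <- tibble::tibble(x = loc[, 1], y = loc[, 2])
    if (nrow(loc) != n) abort(sprintf("dataset %d has %d locations; model expects %d", b, nrow(loc), n))
    dists[[b]] <- pair_distances(loc, pairs)
  }
  list(
    a0 = do.call(rbind, blocks) - genotype_center(spec),
    dist = unlist(dists) / spec$dist_scale,
    n_batch = length(datasets),
    n_pairs = nrow(pairs)
  )
}

# per-dataset input blocks built once and reused across epochs; assemble_inputs
# then stacks a batch by row-binding the cached blocks
precompute_pair_inputs <- function(datasets, spec) {
  lapply(datasets, function(d) build_pair_inputs(list(d), spec))
}

assemble_inputs <- function(cache, ids) {
  one <- cache[[ids[1]]]
  list(
    a0 = do.call(rbind, lapply(cache[ids], `[[`, "a0")),
    dist = unlist(lapply(cache[ids], `[[`, "dist"), use.names = FALSE),
    n_batch = length(ids),
    n_pairs = one$n_pairs
  )
}

nn_forward <- function(weights, inputs, keep_cache = FALSE, head = TRUE) {
  spec <- weights$spec
  t_inst <- inputs$n_batch * inputs$n_pairs
  a <- inputs$a0
  block_in <- if (keep_cache) vector("list", spec$conv_blocks) else NULL
  for (b in seq_len(spec$conv_blocks)) {
    if (keep_cache) block_in[[b]] <- a
    a <- conv_pool_fwd(a, weights$conv_w[[b]], weights$conv_b[[b]],
                       t_inst, spec$pool_window)
  }
  len <- nrow(a) / t_inst
  f_last <- ncol(a)
  if (len == 1L) {
    v <- a
  } else {
    v <- do.call(cbind, lapply(seq_len(f_last), function(f) {
      matrix(a[, f], nrow = t_inst, byrow = TRUE)
    }))
  }
  vd <- cbind(v, inputs$dist)
  h <- vd %*% weights$dense_w
  h <- relu(h + rep(weights$dense_b, each = t_inst))
  if (!head) return(list(h = h))
  z <- matrix(c(t(h)), nrow = inputs$n_batch, byrow = TRUE)
  y <- drop(z %*% weights$head_w) + weights$head_b
  out <- list(y = y, h = h, z = z)
  if (keep_cache) {
    out$block_in <- block_in
    out$vd <- vd
    out$v_len <- ncol(v)
    out$len_final <- len
    out$t_inst <- t_inst
  }
  out
}

# dy: dLoss/dy per dataset (length B). gate: logical vector over pairs (length
# P) or NULL; FALSE rows contribute nothing to extractor gradients, while head
# gradients always use every pair.
nn_backward <- function(weights, inputs, fw, dy, gate = NULL) {
  spec <- weights$spec
  b_sz <- inputs$n_batch
  u <- spec$pair_dense_units
  g_head_w <- crossprod(fw$z, dy)
  g_head_b <- sum(dy)
  dz <- tcrossprod(dy, weights$head_w) # B x (P*u)
  dh <- matrix(as.vector(t(dz)), ncol = u, byrow = TRUE) # T x u
  if (!is.null(gate)) {
    dh[rep.int(!gate, b_sz), ] <- 0
  }
  dd1 <- dh * (fw$h > 0)
  g_dense_w <- crossprod(fw$vd, dd1)
  g_dense_b <- colSums(dd1)
  dvd <- tcrossprod(dd1, weights$dense_w)
  dv <- dvd[, seq_len(fw$v_len), drop = FALSE]

  # un-flatten back to (T * len_final) x F
  len <- fw$len_final
  f_last <- fw$v_len / len
  if (len == 1L) {
    dp <- dv
  } else {
    dp <- matrix(0, fw$t_inst * len, f_last)
    for (f in seq_len(f_last)) {
      dp[, f] <- as.vector(t(dv[, (f - 1L) * len + seq_len(len), drop = FALSE]))
    }
  }

  g_conv_w <- vector("list", spec$conv_blocks)
  g_conv_b <- vector("list", spec$conv_blocks)
  for (b in rev(seq_len(spec$conv_blocks))) {
    back <- conv_pool_bwd(fw$block_in[[b]], weights$conv_w[[b]],
                          weights$conv_b[[b]], dp, fw$t_inst,
                          spec$pool_window, need_da = b > 1L)
    g_conv_w[[b]] <- back$gW
    g_conv_b[[b]] <- back$gb
    if (b > 1L) dp <- back$dA
  }
  list(conv_w = g_conv_w, conv_b = g_conv_b,
       dense_w = g_dense_w, dense_b = g_dense_b,
       head_w = g_head_w, head_b = g_head_b)
}

# ---- exported prediction-path operations ------------------------------------

#' Forward pass: predict sigma for one dataset
#'
#' Runs the pairwise extractor over every pair of samples (in canonical
#' lexicographic order), stacks the pair features and applies the linear head.
#' The raw network output is de-normalized through the weight set's sigma
#' normalization (log-scale z-score), so the return value is on the sigma scale
#' in map units. Deterministic given inputs and weights.
#'
#' @param genotypes Coded genotype matrix (m x n, or m x 2n phased).
#' @param locations Data frame of planar x/y coordinates, one row per sample.
#' @param weights A `weight_set`.
#' @param pairs Optional pair matrix; must equal `enumerate_pairs(n)` (supplied
#'   pairs are validated, not reordered).
#' @return The scalar sigma estimate.
#' @export
forward <- function(genotypes, locations, weights, pairs = NULL) {
  spec <- weights$spec
  if (!is.null(pairs)) {
    canon <- enumerate_pairs(spec$n_samples)
    if (nrow(pairs) != nrow(canon) || any(pairs != canon)) {
      abort("`pairs` must be the complete lexicographic pair set for the model's n.")
    }
  }
  inputs <- build_pair_inputs(list(list(genotypes = genotypes, locations = locations)), spec)
  y <- nn_forward(weights, inputs)$y
  denormalize_sigma(y, weights$sigma_norm)
}

#' Forward pass with extractor-gradient gating
#'
#' Identical prediction to [forward()] for any gated pair subset: gating only
#' restricts which pairs' gradients reach the shared extractor weights during
#' optimization (see [model_gradients()]); features are still extracted from
#' the full pair set during the forward pass, and all pairs contribute to the
#' head's gradients.
#'
#' @inheritParams forward
#' @param extract_pairs Matrix of pairs (subset of the full pair set) selected
#'   for extractor-gradient flow.
#' @return The scalar sigma estimate (equal to `forward()`).
#' @export
forward_gated <- function(genotypes, locations, weights, pairs = NULL,
                          extract_pairs = NULL) {
  if (!is.null(extract_pairs)) {
    gate_mask_from_pairs(extract_pairs, weights$spec$n_samples) # validates subset
  }
  forward(genotypes, locations, weights, pairs)
}

#' Per-pair feature extraction
#'
#' Applies the shared extractor to one pair: the stacked genotype block (2 rows
#' unphased, 4 phased), convolution/pooling blocks, flatten, concatenation of
#' the scaled pair distance, and the rectified dense layer.
#'
#' @param genotype_pair The pair's genotype block, a 2 x m (or 4 x m) matrix.
#' @param pair_distance Euclidean distance between the pair, map units (>= 0).
#' @param weights A `weight_set`.
#' @return Numeric feature vector of length `pair_dense_units`.
#' @export
extract_pair_features <- function(genotype_pair, pair_distance, weights) {
  spec <- weights$spec
  r <- if (spec$phased) 4L else 2L
  if (!is.matrix(genotype_pair) || nrow(genotype_pair) != r ||
      ncol(genotype_pair) != spec$m_snps) {
    abort(sprintf("genotype block must be %d x %d for this model.", r, spec$m_snps))
  }
  if (!is.numeric(pair_distance) || length(pair_distance) != 1L || pair_distance < 0) {
    abort("`pair_distance` must be a single non-negative number.")
  }
  a0 <- vapply(seq_len(r), function(k) genotype_pair[k, ], numeric(spec$m_snps))
  inputs <- list(a0 = a0 - genotype_center(spec),
                 dist = pair_distance / spec$dist_scale,
                 n_batch = 1L, n_pairs = 1L)
  drop(nn_forward(weights, inputs, head = FALSE)$h)
}

# validate a pair subset and convert to a logical gate over canonical pairs
gate_mask_from_pairs <- function(extract_pairs, n) {
  canon <- enumerate_pairs(n)
  if (is.null(dim(extract_pairs))) extract_pairs <- matrix(extract_pairs, ncol = 2L)
  key <- extract_pairs[, 1L] * (n + 1L) + extract_pairs[, 2L]
  canon_key <- canon[, 1L] * (n + 1L) + canon[, 2L]
  idx <- match(key, canon_key)
  if (anyNA(idx) || anyDuplicated(idx)) {
    abort("`extract_pairs` must be a subset of the full i<j pair set, without duplicates.")
  }
  gate <- rep(FALSE, nrow(canon))
  gate[idx] <- TRUE
  gate
}

denormalize_sigma <- function(y, sigma_norm) {
  exp(sigma_norm$log_mean + sigma_norm$log_sd * y)
}

normalize_sigma <- function(sigma, sigma_norm) {
  (log(sigma) - sigma_norm$log_mean) / sigma_norm$log_sd
}

#' Loss and gradients for a batch of datasets
#'
#' Computes the mean squared error of the network's raw (normalized-scale)
#' predictions against normalized targets, plus gradients with respect to every
#' weight. When `extract_pairs` is supplied, extractor-weight gradients (conv
#' blocks and pair dense layer) flow only through the selected pairs, while the
#' head's gradients use all pairs; the loss value itself is unaffected by
#' gating.
#'
#' @param weights A `weight_set`.
#' @param datasets List of datasets (`genotypes` + `locations`).
#' @param sigma True sigma per dataset (natural scale).
#' @param extract_pairs Optional pair subset for extractor-gradient gating.
#' @return A list: `loss`, `grads` (same shapes as the weights), `y_hat`
#'   (de-normalized predictions).
#' @export
model_gradients <- function(weights, datasets, sigma, extract_pairs = NULL) {
  if (length(datasets) != length(sigma)) abort("one sigma per dataset required.")
  inputs <- build_pair_inputs(datasets, weights$spec)
  gate <- if (is.null(extract_pairs)) NULL else {
    gate_mask_from_pairs(extract_pairs, weights$spec$n_samples)
  }
  model_gradients_inputs(weights, inputs, sigma, gate)
}

# gradient step on pre-assembled inputs (gate is a logical mask over pairs)
model_gradients_inputs <- function(weights, inputs, sigma, gate = NULL) {
  fw <- nn_forward(weights, inputs, keep_cache = TRUE)
  target <- normalize_sigma(sigma, weights$sigma_norm)
  resid <- fw$y - target
  loss <- mean(resid^2)
  dy <- matrix(2 * resid / length(resid), ncol = 1L)
  grads <- nn_backward(weights, inputs, fw, dy, gate)
  list(loss = loss, grads = grads,
       y_hat = denormalize_sigma(fw$y, weights$sigma_norm))
}

#' Save / load a trained model
#'
#' Serializes the weight set to a single archive with the model specification
#' embedded as JSON alongside the binary weights; loading reproduces
#' predictions bit-exactly on the same hardware.
#'
#' @param weights A `weight_set`.
#' @param path Destination file.
#' @return `path` invisibly (`save_model`); the restored `weight_set`
#'   (`load_model`).
#' @export
save_model <- function(weights, path) {
  stopifnot(inherits(weights, "weight_set"))
  spec_json <- jsonlite::toJSON(unclass(weights$spec), auto_unbox = TRUE, digits = NA)
  saveRDS(list(spec_json = as.character(spec_json), weights = weights), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$weights) || !inherits(obj$weights, "weight_set")) {
    abort("not a dispersr model archive.")
  }
  obj$weights
}
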