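#' Scaled-down validation study: simulate, train, and benchmark
#'
#' Runs the package's end-to-end validation protocol at desk scale: simulate
#' training and held-out datasets over the sigma_f ~ U(0.2, 3) prior on a
#' square habitat, train the pairwise network, apply both the network and the
#' Rousset baseline (given the true simulated density) to the held-out sets,
#' and report MRAE, RMSE and squared correlation per method alongside the
#' analytic prior-mean reference.
#'
#' Defaults follow the package's desk-scale study conditions: a 15 x 15
#' habitat at carrying capacity 5 (about 1,125 individuals), 20 generations of
#' spatial reproduction from a site-frequency-spectrum seeded start, toy
#' 100 kb genome with a 1-Morgan map, 300 training simulations sampled 10
#' times each (n = 10 individuals, m = 200 SNPs), and 50 held-out simulations.
#'
#' @param seed Master seed for simulation, training and evaluation.
#' @param n_train_sims,n_test_sims Numbers of independent simulations.
#' @param draws_per_sim Sample draws per training simulation.
#' @param sample_n,m_snps Dataset dimensions.
#' @param base_params [sim_params()] template for habitat/genome settings.
#' @param spec A [model_spec()]; `NULL` uses the desk-scale default
#'   (2 conv blocks of 16/32 filters, 64 pair-feature units, distances scaled
#'   by the habitat width).
#' @param config A [train_config()]; `NULL` uses 50 epochs maximum, batch
#'   size 32, patience 10.
#' @param progress Print progress dots during simulation.
#' @return A list: `report` (the [run_benchmark()] metrics tibble, including a
#'   `prior_mean` constant-predictor row), `fit` (the trained `disp_model`),
#'   `test_sets`, and `prior_mean_mrae_analytic`.
#' @export
dispersal_benchmark <- function(seed = 1L,
                                n_train_sims = 300L,
                                n_test_sims = 50L,
                                draws_per_sim = 10L,
                                sample_n = 10L,
                                m_snps = 200L,
                                base_params = NULL,
                                spec = NULL,
                                config = NULL,
                                progress = FALSE) {
  if (is.null(base_params)) {
    base_params <- sim_params(habitat_width = 15, k_capacity = 5,
                              n_generations = 20, genome_length = 1e5,
                              recomb_rate = 1e-5, mut_rate = 1e-8,
                              init_sites = 600, seed = seed)
  }
  if (is.null(spec)) {
    spec <- model_spec(m_snps = m_snps, n_samples = sample_n,
                       filters_per_block = c(16L, 32L),
                       pair_dense_units = 64L,
                       dist_scale = base_params$habitat_width,
                       seed = derive_seed(seed, "init-weights"))
  }
  if (is.null(config)) {
    # small batches buy more Adam steps within the epoch budget, which matters
    # at the fixed 1e-4 learning rate
    config <- train_config(epochs = 50L, batch_size = 8L, patience = 15,
                           seed = derive_seed(seed, "train-config"))
  }

  train_sets <- simulate_training_set(
    n_train_sims, base_params, sample_n = sample_n, draws = draws_per_sim,
    m_snps = m_snps, seed = derive_seed(seed, "train-sims"),
    progress = progress
  )
  test_sets <- simulate_training_set(
    n_test_sims, base_params, sample_n = sample_n, draws = 1L,
    m_snps = m_snps, seed = derive_seed(seed, "test-sims"),
    progress = progress
  )

  fit <- train_model(spec, train_sets, config)

  sigma_prior <- c(0.2, 3) * base_params$sigma_factor
  prior_mean <- mean(sigma_prior)
  density <- base_params$k_capacity
  preds_net <- predict(fit, test_sets)$sigma_hat
  methods <- list(
    network = local({
      k <- 0
      function(d) { k <<- k + 1; preds_net[k] }
    }),
    rousset = function(d) {
      rousset_estimate(d$genotypes, d$locations, density)$sigma_hat
    },
    prior_mean = function(d) prior_mean
  )
  report <- run_benchmark(methods, test_sets)
  list(
    report = report,
    fit = fit,
    test_sets = test_sets,
    prior_mean_mrae_analytic = prior_mean_mrae(sigma_prior[1], sigma_prior[2])
  )
}
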