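#' Initialize a spatial population
#'
#' Places approximately `k_capacity * habitat_width^2` individuals uniformly at
#' random on the square habitat and seeds initial standing genetic variation:
#' `init_sites` biallelic sites at unique base-pair positions, with allele
#' frequencies drawn from the neutral site-frequency spectrum (density
#' proportional to 1/p, truncated to \[0.05, 0.95\]) and haplotype alleles drawn
#' independently across sites (linkage equilibrium). Forward generations then
#' build up linkage and spatial structure.
#'
#' @param params A [sim_params()] object.
#' @return A `population_state`: positions, diploid haplotypes over segregating
#'   sites (two rows per individual), site positions, and the generation index.
#' @export
init_population <- function(params) {
  if (!inherits(params, "sim_params")) params <- do.call(sim_params, params)
  n0 <- round(params$k_capacity * params$habitat_width^2)
  if (n0 < 2) abort("habitat_width and k_capacity imply fewer than 2 individuals.")
  set.seed(derive_seed(params$seed, "init"))
  w <- params$habitat_width
  x <- runif(n0, 0, w)
  y <- runif(n0, 0, w)

  s0 <- params$init_sites
  # inverse-CDF draw from f(p) ~ 1/p on [pmin, pmax]
  pmin <- 0.05; pmax <- 0.95
  p <- pmin * (pmax / pmin)^runif(s0)
  positions <- sort(sample.int(params$genome_length, s0))
  # haplotypes stored sites x haplotypes (columns 2i-1, 2i per individual)
  h <- matrix(rbinom(2L * n0 * s0, 1L, rep(p, times = 2L * n0)),
              nrow = s0, ncol = 2L * n0)
  storage.mode(h) <- "integer"
  cs <- rowSums(h)
  keep <- cs >= 1L & cs <= 2L * n0 - 1L
  state <- list(
    x = x, y = y,
    haplotypes = h[keep, , drop = FALSE],
    positions = positions[keep],
    generation = 0L,
    last_displacements = NULL
  )
  class(state) <- "population_state"
  state
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state> %d individuals, %d segregating sites, generation %d\n",
              length(x$x), nrow(x$haplotypes), x$generation))
  invisible(x)
}

#' Advance the population by one non-overlapping generation
#'
#' Applies the spatial life cycle: each individual (as mother) samples a mate
#' with Gaussian weights at scale `sigma_f` truncated at `3 * sigma_f` (no
#' candidate in range means no offspring this generation); expected offspring
#' number follows Beverton-Holt regulation by kernel-estimated local density
#' (edge-corrected), so the census fluctuates around carrying capacity;
#' offspring are displaced from the mother by independent axial Gaussian draws
#' with standard deviation `sigma_f` and reflected at the habitat boundary;
#' gametes recombine with Poisson(`recomb_rate * genome_length`) crossovers and
#' acquire new mutations at `mut_rate`. Sites fixed or lost in the offspring
#' generation are dropped.
#'
#' Pre-reflection offspring displacements are recorded in
#' `state$last_displacements` (one row per birth, columns dx and dy), which is
#' how the dispersal kernel calibration is measured.
#'
#' @param state A `population_state`.
#' @param params A [sim_params()] object.
#' @return The next `population_state`.
#' @export
step_generation <- function(state, params) {
  if (!inherits(state, "population_state")) abort("`state` must be a population_state.")
  n <- length(state$x)
  if (n == 0L) {
    abort("population is extinct", class = "dispersr_extinction")
  }
  sf <- params$sigma_f
  w <- params$habitat_width

  core <- sim_step_core(state$x, state$y, sf, w, params$k_capacity,
                        params$growth_rate)
  n_off_by_mother <- core$n_off
  mothers <- rep.int(seq_len(n), n_off_by_mother)
  n_off <- length(mothers)
  if (n_off == 0L) {
    abort("population went extinct (no offspring produced); retry with a new seed",
          class = "dispersr_extinction")
  }
  fathers <- core$father[mothers]

  disp_x <- rnorm(n_off, 0, sf)
  disp_y <- rnorm(n_off, 0, sf)
  xo <- reflect_into(state$x[mothers] + disp_x, w)
  yo <- reflect_into(state$y[mothers] + disp_y, w)

  genome <- genome_step_core(state$haplotypes, mothers, fathers,
                             state$positions, params$genome_length,
                             params$recomb_rate, params$mut_rate)

  structure(
    list(
      x = xo, y = yo,
      haplotypes = genome$haplotypes,
      positions = genome$positions,
      generation = state$generation + 1L,
      last_displacements = cbind(dx = disp_x, dy = disp_y)
    ),
    class = "population_state"
  )
}

# reflect positions into [0, w] (triangular fold, handles any magnitude)
reflect_into <- function(v, w) {
  v <- v %% (2 * w)
  ifelse(v > w, 2 * w - v, v)
}

#' Extract a minor-allele-coded genotype matrix for a sample
#'
#' Subsets the given individuals, keeps only sites segregating *within the
#' sample*, and codes each site by its minor allele: counts 0/1/2 per individual
#' when unphased, or 0/1 per haplotype (two columns per individual) when phased.
#' A site with minor-allele frequency exactly 0.5 codes the ancestral
#' (index-smaller) allele as minor, for determinism. When more segregating sites
#' are available than `m_snps`, sites are chosen evenly spaced by rank along the
#' genome.
#'
#' @param state A `population_state`.
#' @param sample_ids Indices of the sampled individuals.
#' @param m_snps Number of SNP rows to return.
#' @param phased If `TRUE`, return one 0/1 column per haplotype.
#' @return A list with `genotypes` (an `m_snps` x n (or x 2n) integer matrix
#'   with a `positions` attribute, rows ordered by genomic position) and
#'   `locations` (a tibble of x/y coordinates, row i aligned with the genotype
#'   column(s) of individual i).
#' @export
extract_genotype_matrix <- function(state, sample_ids, m_snps, phased = FALSE) {
  m_snps <- assert_count(m_snps, "m_snps")
  sample_ids <- as.integer(sample_ids)
  if (anyDuplicated(sample_ids) || any(sample_ids < 1L) ||
      any(sample_ids > length(state$x))) {
    abort("`sample_ids` must be unique indices into the population.")
  }
  n <- length(sample_ids)
  hap_cols <- as.vector(rbind(2L * sample_ids - 1L, 2L * sample_ids))
  hs <- state$haplotypes[, hap_cols, drop = FALSE]
  nh <- 2L * n
  cs <- rowSums(hs)
  seg <- which(cs >= 1L & cs <= nh - 1L)
  if (length(seg) < m_snps) {
    abort(sprintf(
      "only %d segregating sites in the sample; %d requested (short by %d)",
      length(seg), m_snps, m_snps - length(seg)
    ))
  }
  pick <- seg[ceiling(seq_len(m_snps) * length(seg) / m_snps)]
  hs <- hs[pick, , drop = FALSE]
  flip <- cs[pick] / nh >= 0.5

  if (phased) {
    geno <- hs
    geno[flip, ] <- 1L - geno[flip, ]
  } else {
    odd <- seq(1L, nh, by = 2L)
    geno <- hs[, odd, drop = FALSE] + hs[, odd + 1L, drop = FALSE]
    geno[flip, ] <- 2L - geno[flip, ]
  }
  storage.mode(geno) <- "integer"
  attr(geno, "positions") <- state$positions[pick]
  attr(geno, "phased") <- phased
  list(
    genotypes = geno,
    locations = tibble::tibble(x = state$x[sample_ids], y = state$y[sample_ids])
  )
}

#' Run a full simulation and sample training datasets from it
#'
#' Runs `n_generations` of the spatial life cycle from a seeded initial
#' population, then takes `draws` independent samples of `sample_n` individuals
#' uniformly at random without replacement from the final generation. Each draw
#' yields one dataset (genotypes + locations) sharing the simulation's true
#' sigma. Extinction during the run is retried with a derived seed up to
#' `max_retries` times.
#'
#' @param params A [sim_params()] object.
#' @param sample_n Individuals per sampled dataset.
#' @param draws Number of independent sample draws from the final generation.
#' @param m_snps SNPs per dataset (see [extract_genotype_matrix()]).
#' @param phased Emit phased (0/1 per haplotype) genotypes.
#' @param max_retries Extinction retries before giving up.
#' @return A list of `sim_result` objects: `genotypes`, `locations`,
#'   `sigma_f_true`, `sigma_true`, `seed`.
#' @export
run_simulation <- function(params, sample_n, draws = 1L, m_snps = 200L,
                           phased = FALSE, max_retries = 3L) {
  sample_n <- assert_count(sample_n, "sample_n", min = 2L)
  draws <- assert_count(draws, "draws")
  attempt <- 0L
  p <- params
  repeat {
    state <- init_population(p)
    set.seed(derive_seed(p$seed, "forward"))
    res <- tryCatch({
      for (g in seq_len(p$n_generations)) {
        state <- step_generation(state, p)
      }
      state
    }, dispersr_extinction = function(e) e)
    if (inherits(res, "population_state")) {
      state <- res
      break
    }
    attempt <- attempt + 1L
    if (attempt > max_retries) {
      abort("simulation went extinct repeatedly; adjust parameters",
            class = "dispersr_extinction")
    }
    p$seed <- derive_seed(p$seed, "extinction-retry")
  }
  census <- length(state$x)
  if (sample_n > census) {
    abort(sprintf("sample_n (%d) exceeds final census (%d)", sample_n, census))
  }
  sigma_true <- effective_sigma(p$sigma_f, p$sigma_factor)
  set.seed(derive_seed(p$seed, "sampling"))
  lapply(seq_len(draws), function(d) {
    ids <- sample.int(census, sample_n)
    ext <- extract_genotype_matrix(state, ids, m_snps, phased = phased)
    structure(
      list(
        genotypes = ext$genotypes,
        locations = ext$locations,
        sigma_f_true = p$sigma_f,
        sigma_true = sigma_true,
        seed = p$seed
      ),
      class = "sim_result"
    )
  })
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d SNPs x %d columns, sigma_true = %.4g (sigma_f = %.4g)\n",
              nrow(x$genotypes), ncol(x$genotypes), x$sigma_true, x$sigma_f_true))
  invisible(x)
}

#' Simulate a training/validation collection over the sigma prior
#'
#' Draws `n_sims` values of `sigma_f` uniformly from `sigma_f_range`, runs one
#' simulation per draw (each with a seed derived from `seed`), and samples
#' `draws` datasets from each, mirroring the benchmark protocol of many
#' simulations each sampled repeatedly.
#'
#' @param n_sims Number of independent parameter draws (simulations).
#' @param base_params A [sim_params()] giving habitat/genome settings; its
#'   `sigma_f` and `seed` are overridden per draw.
#' @param sample_n,draws,m_snps,phased Passed to [run_simulation()].
#' @param sigma_f_range Uniform prior bounds for `sigma_f`.
#' @param seed Master seed.
#' @param progress Print a dot every 25 simulations.
#' @return A flat list of `sim_result` objects (`n_sims * draws` datasets).
#' @export
simulate_training_set <- function(n_sims, base_params, sample_n, draws = 1L,
                                  m_snps = 200L, phased = FALSE,
                                  sigma_f_range = c(0.2, 3), seed = 1L,
                                  progress = FALSE) {
  n_sims <- assert_count(n_sims, "n_sims")
  set.seed(derive_seed(seed, "sigma-prior"))
  sigmas <- runif(n_sims, sigma_f_range[1], sigma_f_range[2])
  out <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    p <- base_params
    p$sigma_f <- sigmas[i]
    p$seed <- derive_seed(seed, paste0("sim-", i))
    out[[i]] <- run_simulation(p, sample_n = sample_n, draws = draws,
                               m_snps = m_snps, phased = phased)
    if (progress && i %% 25L == 0L) cat(".")
  }
  if (progress) cat("\n")
  unlist(out, recursive = FALSE)
}
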