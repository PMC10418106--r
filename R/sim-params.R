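#' Simulation parameters for the spatial forward model
#'
#' Bundles the parameters of the continuous-space individual-based simulation:
#' a square habitat of side `habitat_width`, local carrying capacity `k_capacity`
#' (individuals per square map unit), and a single interaction scale `sigma_f`
#' (map units) shared by the mother-offspring dispersal kernel, the mate-search
#' kernel and the competition (local density) kernel. The genome is a single
#' recombining chromosome represented by its segregating sites.
#'
#' The benchmark prior draws `sigma_f` uniformly on \[0.2, 3\]. The effective
#' dispersal distance to a randomly chosen parent is
#' `sigma = sigma_f * sigma_factor` (see [effective_sigma()]).
#'
#' @param habitat_width Side of the square habitat, map units (benchmark: 50;
#'   desk-scale runs use 10-15).
#' @param k_capacity Local carrying capacity, individuals per square map unit
#'   (benchmark: 5).
#' @param sigma_f Interaction scale in map units; must lie in (0, Inf) and the
#'   benchmark prior restricts it to \[0.2, 3\].
#' @param genome_length Genome length in base pairs.
#' @param recomb_rate Crossovers per base pair per generation. The benchmark
#'   genome (1e8 bp at 1e-8) has total map length 1 Morgan; desk-scale genomes
#'   keep that map length (e.g. 1e5 bp at 1e-5).
#' @param mut_rate Mutations per base pair per generation.
#' @param n_generations Number of non-overlapping generations to run forward.
#' @param init_sites Number of segregating sites seeded as initial standing
#'   variation (site-frequency-spectrum draw at linkage equilibrium).
#' @param growth_rate Mean offspring per mother at zero local density
#'   (Beverton-Holt regulation; 2 gives logistic-style return to carrying
#'   capacity).
#' @param sigma_factor Unitless multiplier converting `sigma_f` to effective
#'   sigma; default `sqrt(3/2)` (the mother-offspring and mating kernels both
#'   contribute to the displacement from a randomly chosen parent).
#' @param seed Integer seed; fully determines the simulation.
#'
#' @return A list of class `sim_params`.
#' @export
#' @examples
#' p <- sim_params(habitat_width = 10, k_capacity = 1, sigma_f = 1,
#'                 n_generations = 5, seed = 1)
#' p$habitat_width
sim_params <- function(habitat_width = 50,
                       k_capacity = 5,
                       sigma_f = 1,
                       genome_length = 1e5,
                       recomb_rate = 1e-5,
                       mut_rate = 1e-8,
                       n_generations = 20,
                       init_sites = 600,
                       growth_rate = 2,
                       sigma_factor = sqrt(3 / 2),
                       seed = 1L) {
  assert_scalar_num(habitat_width, "habitat_width", positive = TRUE)
  assert_scalar_num(k_capacity, "k_capacity", positive = TRUE)
  assert_scalar_num(sigma_f, "sigma_f", positive = TRUE)
  assert_scalar_num(genome_length, "genome_length", positive = TRUE)
  assert_scalar_num(recomb_rate, "recomb_rate", nonneg = TRUE)
  assert_scalar_num(mut_rate, "mut_rate", nonneg = TRUE)
  assert_count(n_generations, "n_generations", min = 0L)
  assert_count(init_sites, "init_sites", min = 1L)
  assert_scalar_num(growth_rate, "growth_rate", positive = TRUE)
  assert_scalar_num(sigma_factor, "sigma_factor", positive = TRUE)
  assert_count(seed, "seed", min = -2147483647)
  structure(
    list(
      habitat_width = habitat_width,
      k_capacity = k_capacity,
      sigma_f = sigma_f,
      genome_length = genome_length,
      recomb_rate = recomb_rate,
      mut_rate = mut_rate,
      n_generations = as.integer(n_generations),
      init_sites = as.integer(init_sites),
      growth_rate = growth_rate,
      sigma_factor = sigma_factor,
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

#' Effective dispersal distance from the simulation interaction scale
#'
#' The simulation's single interaction scale `sigma_f` governs the
#' mother-offspring displacement and the mate-search kernel. The quantity the
#' estimators target is the root-mean-square single-axis displacement between a
#' child and a *randomly chosen* parent, which absorbs both kernels; it is
#' obtained by a multiplicative conversion `sigma = sigma_f * sigma_factor`.
#' The default factor is `sqrt(3/2)`: the displacement to the mother has
#' variance `sigma_f^2` and the displacement to the father adds the mating
#' kernel on top, so the parent-averaged variance is `(3/2) sigma_f^2`.
#'
#' @param sigma_f Interaction scale, map units (> 0).
#' @param sigma_factor Unitless conversion factor (> 0), default `sqrt(3/2)`.
#' @return Effective sigma in map units.
#' @export
#' @examples
#' effective_sigma(1)            # sqrt(1.5)
#' effective_sigma(2, sqrt(1.5)) # 2.4495
effective_sigma <- function(sigma_f, sigma_factor = sqrt(3 / 2)) {
  if (!is.numeric(sigma_f) || any(!is.finite(sigma_f)) || any(sigma_f <= 0)) {
    abort("`sigma_f` must be positive and finite.")
  }
  assert_scalar_num(sigma_factor, "sigma_factor", positive = TRUE)
  sigma_f * sigma_factor
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  habitat: %g x %g, K = %g/unit^2 (expected census %d)\n",
              x$habitat_width, x$habitat_width, x$k_capacity,
              round(x$k_capacity * x$habitat_width^2)))
  cat(sprintf("  sigma_f = %g (effective sigma = %.4g)\n",
              x$sigma_f, effective_sigma(x$sigma_f, x$sigma_factor)))
  cat(sprintf("  genome: %g bp, recomb %g/bp, mut %g/bp, %d generations, seed %d\n",
              x$genome_length, x$recomb_rate, x$mut_rate,
              x$n_generations, x$seed))
  invisible(x)
}
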