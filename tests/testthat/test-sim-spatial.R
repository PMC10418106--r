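test_that("init_population places ~K*area individuals uniformly and is seed-deterministic", {
  p <- sim_params(habitat_width = 10, k_capacity = 1, sigma_f = 1, seed = 3)
  st <- init_population(p)
  expect_equal(length(st$x), 100) # K * area exactly at initialization
  expect_true(all(st$x >= 0 & st$x <= 10 & st$y >= 0 & st$y <= 10))

  p2 <- sim_params(habitat_width = 50, k_capacity = 5, sigma_f = 1, seed = 3,
                   init_sites = 50)
  expect_equal(length(init_population(p2)$x), 12500)

  expect_identical(init_population(p), init_population(p))
  expect_error(sim_params(habitat_width = -1), "habitat_width")
  expect_error(sim_params(k_capacity = 0), "k_capacity")
})

test_that("initial variation is segregating, binary, and position-sorted", {
  st <- init_population(toy_params())
  cs <- rowSums(st$haplotypes)
  expect_true(all(cs >= 1 & cs <= ncol(st$haplotypes) - 1))
  expect_true(all(st$haplotypes %in% 0:1))
  expect_false(is.unsorted(st$positions))
})

test_that("sigma_f = 0 is rejected by the parameter contract", {
  expect_error(sim_params(sigma_f = 0), "sigma_f")
  expect_error(effective_sigma(0), "sigma_f")
})

test_that("mother-offspring displacements follow the Gaussian kernel at scale sigma_f", {
  p <- toy_params(habitat_width = 10, k_capacity = 5, sigma_f = 1, seed = 21)
  st <- init_population(p)
  set.seed(1)
  disp <- c()
  while (length(disp) < 2e4) {
    st <- step_generation(st, p)
    disp <- c(disp, as.vector(st$last_displacements))
  }
  expect_equal(sqrt(mean(disp^2)), 1, tolerance = 0.03)
})

test_that("census is regulated toward K * area", {
  p <- toy_params(habitat_width = 10, k_capacity = 5, sigma_f = 1,
                  n_generations = 12, seed = 5)
  st <- init_population(p)
  set.seed(2)
  for (g in 1:12) st <- step_generation(st, p)
  expect_gt(length(st$x), 0.85 * 500)
  expect_lt(length(st$x), 1.15 * 500)
})

test_that("effective_sigma applies the configurable conversion factor", {
  expect_equal(effective_sigma(1, 1), 1)
  expect_equal(effective_sigma(2), 2 * sqrt(1.5), tolerance = 1e-12)
  expect_equal(effective_sigma(2), 2.4495, tolerance = 1e-4)
  # prior endpoints map monotonically
  expect_lt(effective_sigma(0.2), effective_sigma(3))
  expect_error(effective_sigma(-1), "sigma_f")
  expect_error(effective_sigma(1, -2), "sigma_factor")
})

test_that("run_simulation sampling semantics: shared sigma, distinct draws, census cap", {
  p <- toy_params(seed = 31)
  res <- run_simulation(p, sample_n = 6, draws = 3, m_snps = 30)
  expect_length(res, 3)
  expect_equal(unique(vapply(res, `[[`, numeric(1), "sigma_true")),
               effective_sigma(p$sigma_f))
  expect_equal(res[[1]]$sigma_true, res[[1]]$sigma_f_true * sqrt(1.5))
  # different draws sample different individuals (locations differ)
  expect_false(identical(res[[1]]$locations, res[[2]]$locations))
  # genotype columns align with location rows
  expect_equal(ncol(res[[1]]$genotypes), nrow(res[[1]]$locations))
  expect_error(run_simulation(p, sample_n = 10000, draws = 1, m_snps = 10),
               "exceeds final census")
})

test_that("sampling every individual returns a permutation of all positions", {
  p <- toy_params(n_generations = 2, seed = 41)
  st <- init_population(p)
  set.seed(1)
  for (g in 1:2) st <- step_generation(st, p)
  census <- length(st$x)
  ext <- extract_genotype_matrix(st, seq_len(census), m_snps = 20)
  expect_setequal(round(ext$locations$x, 10), round(st$x, 10))
})

test_that("genotype coding contract: segregating, minor-coded, position-ordered, phased doubling", {
  p <- toy_params(seed = 51)
  res <- run_simulation(p, sample_n = 8, draws = 1, m_snps = 50)[[1]]
  g <- res$genotypes
  expect_true(all(g %in% 0:2))
  n <- ncol(g)
  maf <- rowSums(g) / (2 * n)
  expect_true(all(maf > 0 & maf <= 0.5 + 1e-12))
  expect_false(is.unsorted(attr(g, "positions"), strictly = TRUE))

  res_ph <- run_simulation(p, sample_n = 8, draws = 1, m_snps = 50,
                           phased = TRUE)[[1]]
  expect_equal(ncol(res_ph$genotypes), 2 * ncol(g))
  expect_true(all(res_ph$genotypes %in% 0:1))
})

test_that("too few segregating sites is reported with the shortfall", {
  p <- toy_params(init_sites = 40, seed = 61)
  st <- init_population(p)
  expect_error(extract_genotype_matrix(st, 1:5, m_snps = 500),
               "short by")
})

test_that("fixed seed reproduces the identical simulation output", {
  p <- toy_params(seed = 71)
  expect_identical(run_simulation(p, sample_n = 5, draws = 2, m_snps = 25),
                   run_simulation(p, sample_n = 5, draws = 2, m_snps = 25))
})

test_that("isolation by distance: positive slope, steeper under short-range dispersal", {
  slope_at <- function(sf) {
    p <- sim_params(habitat_width = 12, k_capacity = 5, sigma_f = sf,
                    n_generations = 15, init_sites = 400, seed = 81)
    res <- run_simulation(p, sample_n = 30, draws = 1, m_snps = 150)[[1]]
    a <- genetic_distance_pairs(res$genotypes)
    rousset_regression(a, res$locations)$slope
  }
  s_short <- slope_at(0.3)
  s_long <- slope_at(2.5)
  expect_gt(s_short, 0)
  expect_gt(s_short, s_long)
})

test_that("simulate_training_set draws sigma from the prior and stays reproducible", {
  base <- toy_params(n_generations = 2, seed = 1)
  res <- simulate_training_set(3, base, sample_n = 5, draws = 2, m_snps = 20,
                               seed = 17)
  expect_length(res, 6)
  sig_f <- vapply(res, `[[`, numeric(1), "sigma_f_true")
  expect_true(all(sig_f >= 0.2 & sig_f <= 3))
  expect_equal(unique(sig_f[1:2]), sig_f[1]) # draws share the simulation
  res2 <- simulate_training_set(3, base, sample_n = 5, draws = 2, m_snps = 20,
                                seed = 17)
  expect_identical(res, res2)
})
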