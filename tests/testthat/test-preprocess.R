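test_that("enumerate_pairs matches the brute-force double loop", {
  for (n in c(2, 3, 10, 57)) {
    brute <- NULL
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) brute <- rbind(brute, c(i, j))
    }
    p <- enumerate_pairs(n)
    expect_equal(nrow(p), n * (n - 1) / 2)
    expect_equal(unname(p), unname(brute))
  }
  expect_equal(nrow(enumerate_pairs(100)), 4950)
  expect_equal(unname(enumerate_pairs(2)), matrix(c(1L, 2L), 1))
  expect_error(enumerate_pairs(1), "n")
})

test_that("pairwise_distance is Euclidean, symmetric, and zero iff identical", {
  expect_equal(pairwise_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(pairwise_distance(c(1, 1), c(1, 1)), 0)
  a <- c(0.3, -2); b <- c(5, 1.7)
  expect_equal(pairwise_distance(a, b), pairwise_distance(b, a))
  expect_error(pairwise_distance(c(0, Inf), c(1, 1)), "finite")
})

test_that("read_genotypes codes minor alleles from VCF and respects phasing", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(vcf, list(
    "0/1 0/1 0/1 0/1",   # all het: MAF tie at 0.5, coded as a row of 1s
    "0/0 0/1 1/1 0/1",   # ALT freq 0.5: tie codes REF; counts of REF = 2,1,0,1
    "1/1 1/1 1/1 0/1",   # ALT is major: REF coded -> 0,0,0,1
    "0/0 0/0 0/0 0/0",   # monomorphic: excluded
    "0/0 0/0 0/1 0/0"    # ALT minor: coded directly
  ))
  g <- read_genotypes(vcf)
  expect_equal(nrow(g), 4) # monomorphic row dropped
  expect_equal(unname(g[1, ]), c(1L, 1L, 1L, 1L))
  expect_equal(unname(g[2, ]), c(2L, 1L, 0L, 1L))
  expect_equal(unname(g[3, ]), c(0L, 0L, 0L, 1L))
  expect_equal(unname(g[4, ]), c(0L, 0L, 1L, 0L))
  maf <- rowSums(g) / (2 * ncol(g))
  expect_true(all(maf <= 0.5))

  # phased VCF doubles the column count
  vcf_p <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(vcf_p, list("0|1 1|0 0|0 0|1", "0|0 0|1 0|0 0|0"))
  gp <- read_genotypes(vcf_p, phased = TRUE)
  expect_equal(ncol(gp), 8)
  expect_true(all(gp %in% 0:1))
  expect_error(read_genotypes(vcf, phased = TRUE), "unphased")
})

test_that("read_genotypes subsets to m_snps with increasing positions and rejects missing GT", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  rows <- replicate(12, paste(sample(c("0/0", "0/1", "1/1"), 5, TRUE,
                                     prob = c(.4, .4, .2)), collapse = " "))
  set.seed(4)
  write_test_vcf(vcf, as.list(rows))
  usable <- nrow(read_genotypes(vcf))
  m <- max(2L, usable - 2L)
  g <- read_genotypes(vcf, m_snps = m)
  expect_equal(nrow(g), m)
  expect_false(is.unsorted(attr(g, "positions"), strictly = TRUE))
  expect_error(read_genotypes(vcf, m_snps = 500), "short by")

  vcf_miss <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(vcf_miss, list("0/1 ./. 0/1 0/0"))
  expect_error(read_genotypes(vcf_miss), "missing")
})

test_that("genotype coding is idempotent", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  set.seed(8)
  rows <- replicate(10, paste(sample(c("0/0", "0/1", "1/1"), 6, TRUE), collapse = " "))
  write_test_vcf(vcf, as.list(rows))
  g1 <- read_genotypes(vcf)
  # re-export the coded matrix and read it back: nothing may change
  vcf2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g1, vcf2, sample_names = attr(g1, "samples"))
  g2 <- read_genotypes(vcf2)
  expect_equal(unname(g1), unname(g2), ignore_attr = TRUE)
  expect_equal(attr(g1, "positions"), attr(g2, "positions"))
})

test_that("read_locations parses CSV/TSV, detects headers, validates counts", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,latitude,longitude", "a,1.5,2.5", "b,-3,4"), f)
  loc <- read_locations(f)
  expect_equal(loc$lat, c(1.5, -3))
  expect_equal(loc$lon, c(2.5, 4))
  expect_equal(loc$sample, c("a", "b"))
  expect_silent(read_locations(f, n_expected = 2))
  expect_error(read_locations(f, n_expected = 100), "100 samples expected")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("10.2\t-4", "11\t-4.5"), f2) # headerless two-column
  loc2 <- read_locations(f2)
  expect_equal(loc2$lat, c(10.2, 11))

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,latitude,longitude", "a,xx,2", "b,3,4"), f3)
  expect_error(read_locations(f3), "non-numeric")
})

test_that("project_coordinates is centroid-centered equirectangular on a 6371 km sphere", {
  # one degree of longitude at the equator
  pl <- project_coordinates(data.frame(lat = c(0, 0), lon = c(0, 1)))
  d <- pairwise_distance(c(pl$x[1], pl$y[1]), c(pl$x[2], pl$y[2]))
  expect_equal(d, 6371 * pi / 180, tolerance = 1e-9)
  expect_equal(d, 111.19, tolerance = 1e-4)

  # identical points project to zero distance; single point sits at the origin
  same <- project_coordinates(data.frame(lat = c(12, 12), lon = c(7, 7)))
  expect_equal(pairwise_distance(c(same$x[1], same$y[1]),
                                 c(same$x[2], same$y[2])), 0)
  one <- project_coordinates(data.frame(lat = 45, lon = -120))
  expect_equal(c(one$x, one$y), c(0, 0))

  expect_error(project_coordinates(data.frame(lat = 91, lon = 0)), "latitudes")
  expect_error(project_coordinates(data.frame(lat = 0, lon = 200)), "longitudes")
})

test_that("projection preserves small-scale distance ratios within 1%", {
  # low-latitude cluster: the single-reference-latitude equirectangular scale
  # factor cos(lat0) drifts with latitude, so the 1% contract is a
  # low-to-mid-latitude, sub-2-degree statement
  set.seed(9)
  lat <- 8 + runif(12, 0, 1.5)
  lon <- -60 + runif(12, 0, 1.5)
  pl <- project_coordinates(data.frame(lat = lat, lon = lon))
  pairs <- enumerate_pairs(12)
  planar <- pair_dist <- numeric(nrow(pairs))
  gc_dist <- numeric(nrow(pairs))
  hav <- function(la1, lo1, la2, lo2) {
    # great-circle reference via the haversine formula, R = 6371 km
    to_r <- pi / 180
    a <- sin((la2 - la1) * to_r / 2)^2 +
      cos(la1 * to_r) * cos(la2 * to_r) * sin((lo2 - lo1) * to_r / 2)^2
    2 * 6371 * asin(sqrt(a))
  }
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    planar[k] <- pairwise_distance(c(pl$x[i], pl$y[i]), c(pl$x[j], pl$y[j]))
    gc_dist[k] <- hav(lat[i], lon[i], lat[j], lon[j])
  }
  expect_true(all(abs(planar / gc_dist - 1) < 0.01))
})

test_that("match_sampling is greedy nearest-unchosen and injective", {
  sim <- tibble::tibble(x = c(0, 1, 2, 5, 9), y = c(0, 0, 0, 0, 0))
  # empirical localities equal to a subset of simulated positions
  emp <- tibble::tibble(x = c(5, 1), y = c(0, 0))
  expect_equal(match_sampling(sim, emp), c(4L, 2L))
  # identity when empirical equals simulated
  expect_equal(match_sampling(sim, sim), 1:5)
  # conflict: first locality takes the shared nearest, second takes next-nearest
  emp2 <- tibble::tibble(x = c(0.9, 1.1), y = c(0, 0))
  expect_equal(match_sampling(sim, emp2), c(2L, 3L))
  # injectivity under crowding
  emp3 <- tibble::tibble(x = rep(1, 5), y = rep(0, 5))
  expect_equal(sort(match_sampling(sim, emp3)), 1:5)
  expect_error(match_sampling(sim, tibble::tibble(x = 1:6, y = rep(0, 6))),
               "census")
})

test_that("match_sampling width rescaling aligns the empirical cloud", {
  sim <- tibble::tibble(x = c(0, 5, 10), y = c(0, 5, 10))
  emp <- tibble::tibble(x = c(0, 50, 100), y = c(0, 50, 100)) # same shape, 10x scale
  expect_equal(match_sampling(sim, emp, rescale = TRUE), 1:3)
})

test_that("pack_training_set round-trips bit-exactly and counts datasets", {
  p <- toy_params(seed = 91)
  res <- run_simulation(p, sample_n = 5, draws = 4, m_snps = 25)
  dir <- withr::local_tempdir()
  manifest <- pack_training_set(res, dir)
  expect_equal(manifest$n_datasets, 4)
  expect_equal(manifest$m_snps, 25)
  loaded <- load_training_set(dir)
  expect_equal(loaded$manifest$n_datasets, 4)
  for (k in 1:4) {
    expect_identical(unname(loaded$datasets[[k]]$genotypes),
                     unname(res[[k]]$genotypes))
    expect_identical(loaded$datasets[[k]]$sigma, res[[k]]$sigma_true)
    expect_equal(unname(loaded$datasets[[k]]$locations),
                 unname(as.matrix(res[[k]]$locations)))
  }
  expect_equal(loaded$manifest$sigma_log_mean,
               mean(log(vapply(res, `[[`, numeric(1), "sigma_true"))))
  # dimension mismatch across results is rejected
  res_bad <- c(res, run_simulation(p, sample_n = 6, draws = 1, m_snps = 25))
  expect_error(pack_training_set(res_bad, dir), "dimensions")
})
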