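#' Pairwise genetic differentiation between individuals
#'
#' Computes Rousset's individual-pair statistic a-hat, the individual-level
#' analogue of FST/(1 - FST), from a minor-allele-coded unphased genotype
#' matrix. With per-individual minor-allele dose p_i = g_i / 2 at a locus, the
#' probability of allelic identity between one gene from i and one from j is
#' `Q_b(i,j) = p_i p_j + (1 - p_i)(1 - p_j)`, and within an individual the
#' identity of its two genes is 1 for homozygotes and 0 for heterozygotes.
#' Averaging each over loci (and the within-identity over all individuals)
#' gives `a_hat(i,j) = (Q_w - Q_b(i,j)) / (1 - Q_w)`.
#'
#' Genetically similar pairs have high between-identity, hence low a-hat; the
#' statistic rises with geographic separation under isolation by distance,
#' which is what the regression in [rousset_regression()] exploits.
#'
#' @param genotypes Unphased coded matrix, m SNPs x n individuals (entries
#'   0/1/2), n >= 2.
#' @return An n x n symmetric matrix with zero diagonal.
#' @export
genetic_distance_pairs <- function(genotypes) {
  if (!is.matrix(genotypes) || ncol(genotypes) < 2L) {
    abort("`genotypes` must be a matrix with at least 2 individuals.")
  }
  if (any(!genotypes %in% 0:2)) {
    abort("`genotypes` must be unphased minor-allele counts (0/1/2).")
  }
  m <- nrow(genotypes)
  p <- genotypes / 2
  # per-pair mean over loci of p_i p_j + (1-p_i)(1-p_j)
  q_between <- (crossprod(p) + crossprod(1 - p)) / m
  # two genes within an individual are identical iff the genotype is homozygous
  q_within <- mean(genotypes != 1L)
  a_hat <- (q_within - q_between) / (1 - q_within)
  diag(a_hat) <- 0
  a_hat
}

#' Regression of genetic differentiation on log geographic distance
#'
#' Ordinary least squares of the pairwise a-hat statistic on the natural log of
#' Euclidean distance over all pairs with positive distance (the 2-D habitat
#' convention). Pairs at identical locations are excluded from the fit and
#' counted.
#'
#' @param a_matrix Symmetric pair matrix from [genetic_distance_pairs()].
#' @param locations Data frame of planar x/y coordinates, rows aligned with the
#'   matrix.
#' @return A list: `slope`, `intercept`, `n_pairs_used`, `n_zero_distance`.
#' @export
rousset_regression <- function(a_matrix, locations) {
  n <- nrow(a_matrix)
  if (is.null(n) || n != nrow(locations)) {
    abort("`a_matrix` and `locations` must describe the same individuals.")
  }
  pairs <- enumerate_pairs(n)
  d <- pair_distances(locations, pairs)
  a <- a_matrix[pairs]
  ok <- d > 0
  if (sum(ok) < 2L) abort("need at least 2 pairs with positive distance.")
  x <- log(d[ok])
  yv <- a[ok]
  if (stats::var(x) == 0) abort("all pairwise distances identical; slope undefined.")
  fit <- stats::lm.fit(cbind(1, x), yv)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       n_pairs_used = sum(ok),
       n_zero_distance = sum(!ok))
}

#' Dispersal distance from the Rousset slope
#'
#' Under 2-D isolation by distance the regression slope equals
#' `1 / (4 pi D sigma^2)` (the inverse of Wright's neighborhood size
#' `Nb = 4 pi D sigma^2`), so given the population density D,
#' `sigma = sqrt(1 / (4 pi D slope))`. A non-positive slope carries no
#' isolation-by-distance signal and yields an undefined estimate (`NA`, not an
#' error), which downstream error metrics must exclude.
#'
#' @param slope Regression slope from [rousset_regression()].
#' @param density Population density, individuals per square map unit (> 0).
#' @return Sigma in map units, or `NA_real_` when `slope <= 0`.
#' @export
#' @examples
#' sigma_from_slope(1 / (4 * pi), 1) # exactly 1
sigma_from_slope <- function(slope, density) {
  assert_scalar_num(slope, "slope")
  assert_scalar_num(density, "density", positive = TRUE)
  if (slope <= 0) return(NA_real_)
  sqrt(1 / (4 * pi * density * slope))
}

#' Rousset dispersal estimate for one dataset
#'
#' The full baseline pipeline: pairwise a-hat, OLS on log distance, slope to
#' sigma given density.
#'
#' @param genotypes Unphased coded genotype matrix (m x n).
#' @param locations Planar coordinates, one row per individual.
#' @param density Population density, individuals per square map unit.
#' @return A list of class `rousset_fit`: `slope`, `intercept`, `sigma_hat`
#'   (`NA` when undefined), `neighborhood_size`, `density_used`,
#'   `n_pairs_used`, `n_zero_distance`.
#' @export
rousset_estimate <- function(genotypes, locations, density) {
  a_matrix <- genetic_distance_pairs(genotypes)
  reg <- rousset_regression(a_matrix, locations)
  sigma_hat <- sigma_from_slope(reg$slope, density)
  structure(
    list(slope = reg$slope, intercept = reg$intercept,
         sigma_hat = sigma_hat,
         neighborhood_size = if (reg$slope > 0) 1 / reg$slope else NA_real_,
         density_used = density,
         n_pairs_used = reg$n_pairs_used,
         n_zero_distance = reg$n_zero_distance),
    class = "rousset_fit"
  )
}

#' @export
print.rousset_fit <- function(x, ...) {
  cat(sprintf("<rousset_fit> slope = %.4g, sigma_hat = %s (density %.3g, %d pairs)\n",
              x$slope,
              if (is.na(x$sigma_hat)) "undefined" else sprintf("%.4g", x$sigma_hat),
              x$density_used, x$n_pairs_used))
  invisible(x)
}

#' @export
tidy.rousset_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @export
glance.rousset_fit <- function(x, ...) {
  tibble::tibble(
    sigma_hat = x$sigma_hat,
    neighborhood_size = x$neighborhood_size,
    density_used = x$density_used,
    n_pairs_used = x$n_pairs_used,
    n_zero_distance = x$n_zero_distance
  )
}
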