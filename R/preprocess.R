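#' Read a genotype matrix from a VCF file
#'
#' Parses biallelic SNP records with complete GT fields and returns a
#' minor-allele-coded matrix: counts 0/1/2 per individual (unphased) or one 0/1
#' column per haplotype (phased), rows ordered by genomic position.
#' Multiallelic and monomorphic sites are excluded. Missing genotypes are an
#' error (no imputation is performed). When more usable sites exist than
#' `m_snps`, sites are taken evenly spaced by rank along the genome; ties in
#' minor-allele frequency at exactly 0.5 code the REF allele as minor.
#'
#' @param vcf_path Path to a VCF (v4.x) file.
#' @param phased Expect and use phased genotypes ("|" separators).
#' @param m_snps Number of SNP rows to return; `NULL` keeps all usable sites.
#' @return An integer matrix (`m_snps` x n, or x 2n when phased) with
#'   `positions` and `samples` attributes.
#' @export
read_genotypes <- function(vcf_path, phased = FALSE, m_snps = NULL) {
  if (!file.exists(vcf_path)) abort(sprintf("VCF not found: %s", vcf_path))
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) abort("VCF contains no variant records.")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L, dimnames = list(NULL, names(gt)))
  if (is.null(gt) || ncol(gt) == 0L) abort("VCF has no GT fields.")
  samples <- colnames(gt)

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  biallelic_snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt, fixed = TRUE)
  if (any(is.na(gt))) abort("VCF contains missing genotypes; pre-filter them (no imputation).")

  sep <- if (phased) "|" else "/"
  # accept either separator on read, but phased output requires "|"
  a1 <- substr(gt, 1L, 1L)
  sep_chr <- substr(gt, 2L, 2L)
  a2 <- substr(gt, 3L, 3L)
  if (any(!sep_chr %in% c("/", "|"))) abort("unsupported GT format; expected diploid calls.")
  if (phased && any(sep_chr != "|")) {
    abort("phased = TRUE but VCF contains unphased ('/') genotype separators.")
  }
  if (any(a1 == "." | a2 == ".")) abort("VCF contains missing alleles; pre-filter them.")
  d1 <- matrix(as.integer(a1 == "1"), nrow(gt), ncol(gt))
  d2 <- matrix(as.integer(a2 == "1"), nrow(gt), ncol(gt))

  nh <- 2L * ncol(gt)
  alt_count <- rowSums(d1) + rowSums(d2)
  usable <- biallelic_snp & alt_count >= 1L & alt_count <= nh - 1L
  if (!any(usable)) abort("no usable biallelic segregating SNPs in VCF.")
  pos <- as.numeric(fix[, "POS"])
  ord <- order(pos[usable])
  idx <- which(usable)[ord]

  if (!is.null(m_snps)) {
    m_snps <- assert_count(m_snps, "m_snps")
    if (length(idx) < m_snps) {
      abort(sprintf("only %d usable sites; %d requested (short by %d)",
                    length(idx), m_snps, m_snps - length(idx)))
    }
    idx <- idx[ceiling(seq_len(m_snps) * length(idx) / m_snps)]
  }

  d1 <- d1[idx, , drop = FALSE]
  d2 <- d2[idx, , drop = FALSE]
  f_alt <- (rowSums(d1) + rowSums(d2)) / nh
  flip <- f_alt >= 0.5

  if (phased) {
    g <- matrix(0L, length(idx), nh)
    g[, seq(1L, nh, by = 2L)] <- d1
    g[, seq(2L, nh, by = 2L)] <- d2
    g[flip, ] <- 1L - g[flip, ]
  } else {
    g <- d1 + d2
    g[flip, ] <- 2L - g[flip, ]
  }
  storage.mode(g) <- "integer"
  attr(g, "positions") <- pos[idx]
  attr(g, "samples") <- samples
  attr(g, "phased") <- phased
  g
}

#' Read a sample coordinate table
#'
#' Reads a CSV/TSV table of per-sample coordinates in VCF sample order. A header
#' row is auto-detected (non-numeric fields in the first row) and skipped.
#' Accepts two columns (latitude, longitude) or three (sample_id, latitude,
#' longitude).
#'
#' @param table_path Path to the table.
#' @param n_expected If given, error unless the table has exactly this many rows
#'   (e.g. the VCF sample count).
#' @return A tibble with columns `lat` and `lon` (plus `sample` if present).
#' @export
read_locations <- function(table_path, n_expected = NULL) {
  if (!file.exists(table_path)) abort(sprintf("coordinate table not found: %s", table_path))
  first <- readLines(table_path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  probe <- utils::read.table(table_path, sep = sep, header = FALSE,
                             stringsAsFactors = FALSE, nrows = 1L)
  last2 <- unlist(probe[1, (ncol(probe) - 1L):ncol(probe)])
  has_header <- any(is.na(suppressWarnings(as.numeric(last2))))
  tab <- utils::read.table(table_path, sep = sep, header = has_header,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) abort("coordinate table needs at least latitude and longitude columns.")
  if (ncol(tab) >= 3L) {
    out <- tibble::tibble(sample = as.character(tab[[1]]),
                          lat = tab[[2]], lon = tab[[3]])
  } else {
    out <- tibble::tibble(lat = tab[[1]], lon = tab[[2]])
  }
  if (!is.numeric(out$lat) || !is.numeric(out$lon) ||
      any(!is.finite(out$lat)) || any(!is.finite(out$lon))) {
    abort("non-numeric or missing coordinate fields.")
  }
  if (!is.null(n_expected) && nrow(out) != n_expected) {
    abort(sprintf("coordinate table has %d rows but %d samples expected.",
                  nrow(out), n_expected))
  }
  out
}

#' Project latitude/longitude onto a planar surface
#'
#' Equirectangular projection centered on the sample centroid, spherical Earth
#' of radius 6371 km: `x = R cos(lat0) (lon - lon0)`, `y = R (lat - lat0)` (in
#' radians). Adequate for regional-scale samples; distances between nearby
#' points approximate great-circle distances.
#'
#' @param locations A data frame with `lat` and `lon` columns in degrees.
#' @return A tibble with planar `x` and `y` in kilometers (centroid at the
#'   origin) plus the original `lat`/`lon`.
#' @export
#' @examples
#' project_coordinates(data.frame(lat = c(0, 0), lon = c(0, 1)))
project_coordinates <- function(locations) {
  lat <- locations$lat
  lon <- locations$lon
  if (is.null(lat) || is.null(lon)) abort("`locations` must have lat and lon columns.")
  if (any(lat < -90 | lat > 90)) abort("latitudes must lie in [-90, 90].")
  if (any(lon < -180 | lon > 180)) abort("longitudes must lie in [-180, 180].")
  r_earth <- 6371
  lat0 <- mean(lat)
  lon0 <- mean(lon)
  tibble::tibble(
    x = r_earth * cos(lat0 * pi / 180) * (lon - lon0) * pi / 180,
    y = r_earth * (lat - lat0) * pi / 180,
    lat = lat, lon = lon
  )
}

#' Match empirical sample localities to simulated individuals
#'
#' For each empirical locality (in input order), selects the nearest not yet
#' chosen simulated individual by Euclidean distance (greedy, without
#' replacement), so a training sample mirrors the empirical sampling scheme.
#' When `rescale = TRUE`, the empirical point cloud is first translated and
#' isotropically rescaled so that its widest axis span matches that of the
#' simulated cloud and the centroids coincide.
#'
#' @param sim_locations Data frame of simulated x/y positions.
#' @param empirical_locations Data frame of empirical planar x/y positions.
#' @param rescale Align the empirical cloud onto the simulated habitat by
#'   centroid translation and width matching.
#' @return An integer vector: for each empirical row, the index of the matched
#'   simulated individual (all distinct).
#' @export
match_sampling <- function(sim_locations, empirical_locations, rescale = FALSE) {
  sx <- sim_locations$x; sy <- sim_locations$y
  ex <- empirical_locations$x; ey <- empirical_locations$y
  if (length(sx) < length(ex)) {
    abort(sprintf("simulated census (%d) smaller than locality count (%d).",
                  length(sx), length(ex)))
  }
  if (rescale) {
    width_s <- max(diff(range(sx)), diff(range(sy)))
    width_e <- max(diff(range(ex)), diff(range(ey)))
    scale <- if (width_e > 0) width_s / width_e else 1
    ex <- (ex - mean(ex)) * scale + mean(sx)
    ey <- (ey - mean(ey)) * scale + mean(sy)
  }
  taken <- rep(FALSE, length(sx))
  out <- integer(length(ex))
  for (i in seq_along(ex)) {
    d2 <- (sx - ex[i])^2 + (sy - ey[i])^2
    d2[taken] <- Inf
    j <- which.min(d2)
    out[i] <- j
    taken[j] <- TRUE
  }
  out
}

#' Enumerate all unordered sample pairs
#'
#' All pairs (i, j) with i < j in lexicographic order; with n samples there are
#' n(n-1)/2 pairs (4950 for n = 100).
#'
#' @param n Number of samples (>= 2).
#' @return An integer matrix with columns `i` and `j`, one row per pair.
#' @export
#' @examples
#' enumerate_pairs(4)
enumerate_pairs <- function(n) {
  n <- assert_count(n, "n", min = 2L)
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L:n)
  cbind(i = i, j = j)
}

#' Euclidean distance between two planar points
#'
#' @param p,q Numeric length-2 vectors (x, y) in map units.
#' @return The Euclidean distance.
#' @export
#' @examples
#' pairwise_distance(c(0, 0), c(3, 4)) # 5
pairwise_distance <- function(p, q) {
  if (length(p) != 2L || length(q) != 2L || any(!is.finite(c(p, q)))) {
    abort("`p` and `q` must be finite length-2 coordinate vectors.")
  }
  sqrt(sum((p - q)^2))
}

# all pairwise distances for a location table, in enumerate_pairs() order
pair_distances <- function(locations, pairs) {
  dx <- locations$x[pairs[, 1]] - locations$x[pairs[, 2]]
  dy <- locations$y[pairs[, 1]] - locations$y[pairs[, 2]]
  sqrt(dx * dx + dy * dy)
}

#' Pack simulated datasets into a binary training cache
#'
#' Writes each dataset (genotypes, locations, true sigma) to a binary file and a
#' JSON manifest recording the dataset count, dimensions, sigma targets and the
#' sigma normalization statistics (mean and sd of log sigma) used at training
#' time. The round trip through [load_training_set()] is bit-exact.
#'
#' @param results A list of `sim_result` objects sharing dimensions.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly; written to `out_dir/manifest.json`.
#' @export
pack_training_set <- function(results, out_dir) {
  if (length(results) == 0L) abort("`results` is empty.")
  dims <- vapply(results, function(r) dim(r$genotypes), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("all datasets must share m and n dimensions.")
  }
  phased <- isTRUE(attr(results[[1]]$genotypes, "phased"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sigmas <- vapply(results, function(r) r$sigma_true, numeric(1))
  files <- sprintf("dataset_%06d.rds", seq_along(results))
  for (k in seq_along(results)) {
    r <- results[[k]]
    saveRDS(list(genotypes = r$genotypes,
                 locations = as.matrix(r$locations[, c("x", "y")]),
                 sigma = r$sigma_true),
            file.path(out_dir, files[k]))
  }
  manifest <- list(
    n_datasets = length(results),
    m_snps = dims[1, 1],
    n_columns = dims[2, 1],
    n_samples = if (phased) dims[2, 1] / 2L else dims[2, 1],
    phased = phased,
    files = files,
    sigma = sigmas,
    sigma_log_mean = mean(log(sigmas)),
    sigma_log_sd = stats::sd(log(sigmas))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Load a packed training cache
#'
#' @param dir Directory written by [pack_training_set()] (or the path of its
#'   `manifest.json`).
#' @return A list with the parsed `manifest` and `datasets` (each a list of
#'   `genotypes`, `locations`, `sigma`).
#' @export
load_training_set <- function(dir) {
  manifest_path <- if (grepl("\\.json$", dir)) dir else file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) abort(sprintf("no manifest at %s", manifest_path))
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  base <- dirname(manifest_path)
  datasets <- lapply(manifest$files, function(f) readRDS(file.path(base, f)))
  list(manifest = manifest, datasets = datasets)
}

#' Export a genotype matrix and coordinates as a plain-text VCF
#'
#' Minimal VCF 4.2 writer for interoperability testing: one biallelic SNP
#' record per row of the coded matrix, GT-only FORMAT, "/" or "|" separators
#' according to `phased`. The coded minor allele is written as the REF dose
#' (REF A, ALT T), which makes the coding idempotent under the tie rule that
#' codes the REF allele as minor at minor-allele frequency exactly 0.5:
#' re-reading an exported file reproduces the coded matrix.
#'
#' @param genotypes Coded matrix from [extract_genotype_matrix()] or
#'   [read_genotypes()].
#' @param path Output file path (plain text).
#' @param sample_names Optional sample names (default sample_1..n).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path, sample_names = NULL) {
  phased <- isTRUE(attr(genotypes, "phased"))
  pos <- attr(genotypes, "positions") %||% seq_len(nrow(genotypes))
  n_col <- ncol(genotypes)
  n <- if (phased) n_col / 2L else n_col
  if (is.null(sample_names)) sample_names <- sprintf("sample_%d", seq_len(n))
  sep <- if (phased) "|" else "/"
  if (phased) {
    # coded haplotype 1 = carries the minor (REF) allele -> ALT indicator 0
    a1 <- 1L - genotypes[, seq(1L, n_col, by = 2L), drop = FALSE]
    a2 <- 1L - genotypes[, seq(2L, n_col, by = 2L), drop = FALSE]
  } else {
    alt_dose <- 2L - genotypes
    a1 <- (alt_dose >= 1L) * 1L
    a2 <- (alt_dose == 2L) * 1L
  }
  gt <- matrix(paste0(a1, sep, a2), nrow = nrow(genotypes))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=dispersr",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )
  body <- paste(
    "1", format(pos, scientific = FALSE, trim = TRUE), ".", "A", "T", ".",
    "PASS", ".", "GT",
    apply(gt, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}
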