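# small builders shared across tests; everything is generated in code

toy_params <- function(...) {
  args <- list(habitat_width = 8, k_capacity = 4, sigma_f = 0.8,
               genome_length = 1e5, recomb_rate = 1e-5, mut_rate = 1e-8,
               n_generations = 4, init_sites = 300, seed = 11)
  args[names(list(...))] <- list(...)
  do.call(sim_params, args)
}

toy_spec <- function(...) {
  args <- list(m_snps = 40, n_samples = 4, conv_blocks = 1L,
               filters_per_block = 4L, pair_dense_units = 8L,
               dist_scale = 10, seed = 5)
  args[names(list(...))] <- list(...)
  do.call(model_spec, args)
}

# random dataset in the shape the model consumes
random_dataset <- function(m = 40, n = 4, width = 10, phased = FALSE) {
  vals <- if (phased) 0:1 else 0:2
  cols <- if (phased) 2L * n else n
  list(
    genotypes = matrix(sample(vals, m * cols, replace = TRUE), m, cols),
    locations = tibble::tibble(x = runif(n, 0, width), y = runif(n, 0, width))
  )
}

# move biases off zero so finite differences do not sit on relu kinks
offset_biases <- function(ws, seed = 99) {
  set.seed(seed)
  for (b in seq_along(ws$conv_b)) {
    ws$conv_b[[b]] <- rnorm(length(ws$conv_b[[b]]), 0, 0.1)
  }
  ws$dense_b <- rnorm(length(ws$dense_b), 0, 0.1)
  ws$head_b <- 0.05
  ws
}

# plain-text VCF fixture written in code at test time
write_test_vcf <- function(path, gt_rows, pos = NULL, phased = FALSE,
                           sample_names = NULL) {
  n <- length(strsplit(gt_rows[[1]], " ")[[1]])
  if (is.null(sample_names)) sample_names <- sprintf("s%d", seq_len(n))
  if (is.null(pos)) pos <- seq_along(gt_rows) * 100L
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )
  body <- vapply(seq_along(gt_rows), function(i) {
    gts <- strsplit(gt_rows[[i]], " ")[[1]]
    paste(c("1", pos[i], ".", "A", "T", ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}
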