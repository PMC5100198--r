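# Small fixtures built in code.

# A tiny identified system: M phenotypes, K SNP columns, one QTL per
# phenotype, fixed coefficients. Returns data plus generating parameters.
toy_system <- function(n = 500, M = 3, K = 3, noise_sd = 0.1,
                       gamma_val = 0.6, b_val = 0.8) {
  maf <- seq(0.2, 0.4, length.out = K)
  X <- sapply(maf, function(p) stats::rbinom(n, 2, p) + 2 * p - 2)
  colnames(X) <- paste0("snp", seq_len(K))
  Gamma <- diag(-1, M)
  dimnames(Gamma) <- list(paste0("P", 1:M), paste0("P", 1:M))
  if (M > 1) Gamma[1, 2] <- gamma_val  # edge P1 -> P2
  B <- matrix(0, K, M, dimnames = list(colnames(X), colnames(Gamma)))
  for (i in seq_len(min(M, K))) B[i, i] <- b_val
  ph <- sim_phenotypes(Gamma, B, X, noise_sd = noise_sd)
  list(Y = ph$Y, X = X, Gamma = Gamma, B = B, eps = ph$eps)
}

# Text VCF with the given genotype rows (one string per sample per site).
write_toy_vcf <- function(path, gts, chrom = "1", pos = NULL, ids = NULL,
                          alt = NULL) {
  n_site <- nrow(gts)
  n_samp <- ncol(gts)
  pos <- pos %||% seq_len(n_site) * 100
  ids <- ids %||% paste0("rs", seq_len(n_site))
  alt <- alt %||% rep("T", n_site)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("S", seq_len(n_samp))), collapse = "\t"))
  rows <- vapply(seq_len(n_site), function(i) {
    paste(c(chrom, pos[i], ids[i], "A", alt[i], ".", "PASS", ".", "GT",
            gts[i, ]), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  path
}

`%||%` <- function(x, y) if (is.null(x)) y else x

expect_no_cycles <- function(Gamma) {
  A <- Gamma
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix((A != 0) * 1, mode = "directed")
  expect_true(igraph::is_dag(g))
}
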