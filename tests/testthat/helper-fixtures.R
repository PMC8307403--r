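# Shared small fixtures, built once per test run.

# single-population panel: 500 samples x 200 variants, one gene with
# 3 causal cis variants at h2_cis = 0.3
fx_panel <- local({
  g <- simulate_ld_genotypes(c(P = 500L), 200L, fst = 0, seed = 101L,
                             pos_step = 10000L)
  ann <- data.frame(gene_id = "G1", chrom = "1", start = 1000000L,
                    end = 1020000L, strand = "+")
  cis <- simulate_cis_architecture(g, ann, n_causal_per_gene = 3L,
                                   h2_cis = 0.3, seed = 202L)
  list(genotypes = g, annotation = ann, expression = cis$expression,
       truth = cis$truth)
})

# hand-built genotype matrix with controlled positions / MAF / quality
make_toy_genotypes <- function(n = 60L, pos, maf = NULL, rsq = NULL,
                               seed = 5L, chrom = "1") {
  set.seed(seed)
  m <- length(pos)
  maf <- maf %||% rep(0.3, m)
  rsq <- rsq %||% rep(0.9, m)
  d <- sapply(maf, function(f) rbinom(n, 2L, f))
  # force the exact allele count so empirical MAF is controlled
  for (j in seq_len(m)) {
    cnt <- round(2 * n * maf[j])
    col <- rep(0, n)
    col[seq_len(cnt %/% 2)] <- 2
    if (cnt %% 2 == 1) col[cnt %/% 2 + 1] <- 1
    d[, j] <- sample(col)
  }
  rownames(d) <- sprintf("s%03d", seq_len(n))
  v <- data.frame(id = sprintf("tv%03d", seq_len(m)), chrom = chrom,
                  pos = as.integer(pos), ref = "A", alt = "G",
                  imput_rsq = rsq, stringsAsFactors = FALSE)
  colnames(d) <- v$id
  genotype_matrix(d, v, rep("P", n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal weight_model constructor for plumbing tests
stub_model <- function(gene_id, variant_id, weight, ref = "A", alt = "G",
                       intercept = 0, model_r2 = 0.5, cv_r2 = 0.4,
                       panel = "stub", n_train = 100L) {
  structure(list(gene_id = gene_id, panel = panel, variant_id = variant_id,
                 ref = rep(ref, length(variant_id)),
                 alt = rep(alt, length(variant_id)),
                 weight = weight, intercept = intercept,
                 model_r2 = model_r2, cv_r2 = cv_r2, insample_r2 = model_r2,
                 n_train = n_train, lambda = 0.1, alpha = 0.5,
                 n_folds = 10L, seed = 1L),
            class = "weight_model")
}
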