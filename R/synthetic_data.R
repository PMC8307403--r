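#' Genotype matrix container
#'
#' Bundles per-sample alt-allele dosages with variant metadata and sample
#' population labels. Dosages live in a plain numeric matrix (samples x
#' variants) with sample ids as rownames and variant ids as colnames.
#'
#' @param dosage samples x variants numeric matrix, values in [0, 2].
#' @param variants data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `imput_rsq`, and zero or more `maf_<pop>` columns holding
#'   per-population minor allele frequencies.
#' @param population character vector of per-sample population labels.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants, population) {
  stop_if(is.null(rownames(dosage)), "dosage must have sample ids as rownames")
  stop_if(anyDuplicated(rownames(dosage)) > 0L, "duplicate sample ids")
  stop_if(ncol(dosage) != nrow(variants), "variant metadata does not match dosage columns")
  stop_if(!identical(colnames(dosage), variants$id), "dosage column order must match variant ids")
  stop_if(any(dosage < 0 | dosage > 2), "dosages must lie in [0, 2]")
  stop_if(any(variants$pos < 1L), "positions are 1-based; pos >= 1 required")
  stop_if(length(population) != nrow(dosage), "one population label per sample required")
  structure(
    list(dosage = dosage, variants = variants,
         samples = rownames(dosage), population = population),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%s)\n",
              length(x$samples), nrow(x$variants),
              paste(sprintf("%s=%d", names(table(x$population)),
                            as.integer(table(x$population))), collapse = ", ")))
  invisible(x)
}

#' Subset a genotype matrix by samples and/or variants
#' @param x a `genotype_matrix`.
#' @param samples character or integer index of samples to keep.
#' @param variants character or integer index of variants to keep.
#' @export
subset_genotypes <- function(x, samples = NULL, variants = NULL) {
  d <- x$dosage; v <- x$variants; p <- x$population
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) match(samples, rownames(d)) else samples
    stop_if(anyNA(idx), "unknown sample id in subset")
    d <- d[idx, , drop = FALSE]; p <- p[idx]
  }
  if (!is.null(variants)) {
    jdx <- if (is.character(variants)) match(variants, v$id) else variants
    stop_if(anyNA(jdx), "unknown variant id in subset")
    d <- d[, jdx, drop = FALSE]; v <- v[jdx, , drop = FALSE]
  }
  genotype_matrix(d, v, p)
}

#' Simulate LD-blocked genotypes under Balding-Nichols ancestry divergence
#'
#' Ancestral allele frequencies are drawn uniformly over `maf_range`; each
#' population's frequency is drawn from the Balding-Nichols Beta
#' distribution `Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = fst` (for
#' `fst = 0` all populations share the ancestral frequency). Within-block
#' linkage disequilibrium is induced by a Gaussian-copula AR(1) latent
#' process per haplotype: adjacent variants in a block have latent
#' correlation `ld_rho`, while marginal allele frequencies remain exactly
#' the per-population Balding-Nichols draws. Two haplotypes are summed to
#' a dosage in \{0, 1, 2\}.
#'
#' Per-variant imputation-quality scores are drawn Uniform over
#' `imput_rsq_range` so that downstream quality filters have bite.
#'
#' @param n_samples_by_pop named integer vector of per-population sample
#'   counts (names become population labels).
#' @param n_variants number of variants.
#' @param block_size number of variants per LD block.
#' @param fst Balding-Nichols divergence parameter in [0, 1).
#' @param maf_range ancestral allele-frequency range, subset of (0, 0.5].
#' @param ld_rho latent AR(1) correlation between adjacent in-block
#'   variants, in [0, 1).
#' @param chrom chromosome label for all variants.
#' @param pos_start,pos_step 1-based position of the first variant and
#'   spacing between consecutive variants (bp).
#' @param imput_rsq_range range of simulated imputation quality scores.
#' @param seed integer seed; all randomness flows from it.
#' @return A `genotype_matrix`.
#' @export
simulate_ld_genotypes <- function(n_samples_by_pop, n_variants, block_size = 10L,
                                  fst = 0.1, maf_range = c(0.05, 0.5), ld_rho = 0.6,
                                  chrom = "1", pos_start = 100000L, pos_step = 5000L,
                                  imput_rsq_range = c(0.2, 1.0), seed = 1L) {
  stop_if(any(n_samples_by_pop <= 0L), "non-positive sample count")
  stop_if(n_variants <= 0L, "non-positive variant count")
  stop_if(block_size < 1L, "empty blocks: block_size must be >= 1")
  stop_if(fst < 0 || fst >= 1, "fst must lie in [0, 1)")
  stop_if(maf_range[1] <= 0 || maf_range[2] > 0.5, "maf_range must be within (0, 0.5]")
  stop_if(ld_rho < 0 || ld_rho >= 1, "ld_rho must lie in [0, 1)")
  pops <- names(n_samples_by_pop) %||% paste0("pop", seq_along(n_samples_by_pop))
  if (is.null(names(n_samples_by_pop))) names(n_samples_by_pop) <- pops

  set.seed(seed)
  p_anc <- stats::runif(n_variants, maf_range[1], maf_range[2])
  freq <- sapply(pops, function(pp) {
    if (fst == 0) p_anc
    else stats::rbeta(n_variants, p_anc * (1 - fst) / fst, (1 - p_anc) * (1 - fst) / fst)
  })
  freq <- matrix(pmin(pmax(freq, 1e-4), 1 - 1e-4), nrow = n_variants,
                 dimnames = list(NULL, pops))

  block <- rep(seq_len(ceiling(n_variants / block_size)), each = block_size)[seq_len(n_variants)]
  ar1_latent <- function(n_hap, idx) {
    m <- length(idx)
    Z <- matrix(stats::rnorm(n_hap * m), n_hap, m)
    if (ld_rho > 0 && m > 1L) {
      for (j in 2:m) Z[, j] <- ld_rho * Z[, j - 1L] + sqrt(1 - ld_rho^2) * Z[, j]
    }
    Z
  }

  dosage <- matrix(0, sum(n_samples_by_pop), n_variants)
  pop_lab <- rep(pops, times = n_samples_by_pop)
  row0 <- 0L
  for (pp in pops) {
    n <- n_samples_by_pop[[pp]]
    thr <- stats::qnorm(freq[, pp])
    H <- matrix(0L, 2L * n, n_variants)
    for (b in unique(block)) {
      idx <- which(block == b)
      Z <- ar1_latent(2L * n, idx)
      H[, idx] <- (Z < rep(thr[idx], each = 2L * n)) + 0L
    }
    dosage[row0 + seq_len(n), ] <- H[seq(1L, 2L * n, by = 2L), ] + H[seq(2L, 2L * n, by = 2L), ]
    row0 <- row0 + n
  }

  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, n_variants, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), character(1))
  variants <- data.frame(
    id = sprintf("v%06d", seq_len(n_variants)),
    chrom = chrom,
    pos = as.integer(pos_start + (seq_len(n_variants) - 1L) * pos_step),
    ref = ref, alt = unname(alt),
    imput_rsq = stats::runif(n_variants, imput_rsq_range[1], imput_rsq_range[2]),
    block = block,
    stringsAsFactors = FALSE
  )
  for (pp in pops) variants[[paste0("maf_", pp)]] <- pmin(freq[, pp], 1 - freq[, pp])

  rownames(dosage) <- sprintf("%s_s%05d", pop_lab, stats::ave(seq_along(pop_lab), pop_lab, FUN = seq_along))
  colnames(dosage) <- variants$id
  genotype_matrix(dosage, variants, pop_lab)
}

#' Hudson estimator of FST between two populations
#'
#' Per-variant numerator `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' denominator `p1(1-p2) + p2(1-p1)` over haploid sample sizes, combined as
#' a ratio of sums across variants.
#'
#' @param genotypes a `genotype_matrix` with exactly two population labels
#'   (or `pops` selecting two of them).
#' @param pops optional length-2 character vector of population labels.
#' @return scalar FST estimate.
#' @export
hudson_fst <- function(genotypes, pops = NULL) {
  labs <- pops %||% unique(genotypes$population)
  stop_if(length(labs) != 2L, "hudson_fst requires exactly two populations")
  d1 <- genotypes$dosage[genotypes$population == labs[1], , drop = FALSE]
  d2 <- genotypes$dosage[genotypes$population == labs[2], , drop = FALSE]
  n1 <- 2 * nrow(d1); n2 <- 2 * nrow(d2)
  p1 <- colMeans(d1) / 2; p2 <- colMeans(d2) / 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

#' Place gene annotations along the simulated chromosome
#'
#' @param genotypes a `genotype_matrix` defining the coordinate span.
#' @param n_genes number of genes to place.
#' @param gene_length gene body length (bp).
#' @param seed integer seed.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `strand`.
#' @export
simulate_gene_annotation <- function(genotypes, n_genes, gene_length = 20000L, seed = 1L) {
  stop_if(n_genes <= 0L, "n_genes must be positive")
  set.seed(seed)
  span <- range(genotypes$variants$pos)
  starts <- sort(as.integer(round(seq(span[1], max(span[1], span[2] - gene_length),
                                      length.out = n_genes))))
  data.frame(
    gene_id = sprintf("GENE%03d", seq_len(n_genes)),
    chrom = genotypes$variants$chrom[1],
    start = starts,
    end = starts + as.integer(gene_length) - 1L,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Simulate sparse cis-eQTL architecture with a target cis heritability
#'
#' For each gene, `n_causal_per_gene` causal variants are drawn from its
#' +/- `window_bp` cis window. The genetic value is a linear combination of
#' causal dosages, rescaled so its variance equals `h2_cis`; independent
#' Gaussian noise with variance `1 - h2_cis` is added, so the expected
#' variance fraction explained by the causal set equals `h2_cis`.
#'
#' Causal effect sizes default to equal magnitudes with random signs
#' (`effect_dist = "fixed"`), the usual design in expression-prediction
#' method evaluation so each causal variant carries an equal share of the
#' cis-genetic variance; `"normal"` draws N(0,1) effects instead.
#'
#' @param genotypes a `genotype_matrix` (the expression panel).
#' @param genes gene annotation data.frame (see [simulate_gene_annotation]).
#' @param n_causal_per_gene causal variants per gene.
#' @param h2_cis cis heritability in [0, 1); scalar or per-gene vector.
#' @param effect_dist `"fixed"` or `"normal"` causal effect-size law.
#' @param window_bp cis window half-width around gene start/end.
#' @param seed integer seed.
#' @return list with `expression` (samples x genes matrix) and `truth`
#'   (per-gene causal ids, raw-dosage-scale effects, h2_cis, seed).
#' @export
simulate_cis_architecture <- function(genotypes, genes, n_causal_per_gene = 3L,
                                      h2_cis = 0.3, effect_dist = c("fixed", "normal"),
                                      window_bp = 1e6, seed = 1L) {
  effect_dist <- match.arg(effect_dist)
  h2 <- rep(h2_cis, length.out = nrow(genes))
  stop_if(any(h2 < 0 | h2 >= 1), "h2_cis must lie in [0, 1)")
  set.seed(seed)
  n <- length(genotypes$samples)
  expr <- matrix(NA_real_, n, nrow(genes),
                 dimnames = list(genotypes$samples, genes$gene_id))
  truth_genes <- vector("list", nrow(genes))
  names(truth_genes) <- genes$gene_id
  v <- genotypes$variants
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    cis <- which(v$chrom == g$chrom & v$pos >= g$start - window_bp & v$pos <= g$end + window_bp)
    stop_if(length(cis) == 0L, sprintf("gene %s has no cis variants", g$gene_id))
    nc <- min(n_causal_per_gene, length(cis))
    # draw causal variants from distinct LD blocks where possible, so the
    # sparse architecture is identifiable (independent causal signals rather
    # than intra-block sign-cancelling pairs)
    if (!is.null(v$block) && length(unique(v$block[cis])) >= nc) {
      bks <- sample(unique(v$block[cis]), nc)
      causal <- sort(vapply(bks, function(b) {
        cand <- cis[v$block[cis] == b]
        if (length(cand) == 1L) cand else sample(cand, 1L)
      }, integer(1)))
    } else {
      causal <- sort(sample(cis, nc))
    }
    b <- switch(effect_dist,
                fixed = sample(c(-1, 1), nc, replace = TRUE),
                normal = stats::rnorm(nc))
    Xc <- genotypes$dosage[, causal, drop = FALSE]
    gval <- drop(Xc %*% b)
    sdg <- stats::sd(gval)
    if (h2[k] > 0 && sdg > 0) {
      sc <- sqrt(h2[k]) / sdg
      gval <- (gval - mean(gval)) * sc
      b_raw <- b * sc
      e <- stats::rnorm(n, 0, sqrt(1 - h2[k]))
    } else {
      gval <- rep(0, n); b_raw <- rep(0, nc)
      e <- stats::rnorm(n)
    }
    expr[, k] <- gval + e
    truth_genes[[k]] <- list(gene_id = g$gene_id,
                             causal_ids = v$id[causal],
                             effects = b_raw,
                             h2_cis = h2[k])
  }
  list(expression = expr,
       truth = structure(list(genes = truth_genes, seed = seed,
                              window_bp = window_bp),
                         class = "synthetic_truth"))
}

# Genetic value of each truth gene evaluated on an arbitrary cohort's dosages
# (raw-dosage-scale effects; centered per gene).
#' @export
#' @rdname simulate_cis_architecture
#' @param truth a `synthetic_truth` object.
truth_genetic_values <- function(genotypes, truth) {
  out <- sapply(truth$genes, function(tg) {
    jdx <- match(tg$causal_ids, genotypes$variants$id)
    stop_if(anyNA(jdx), sprintf("causal variant of %s absent from genotypes", tg$gene_id))
    g <- drop(genotypes$dosage[, jdx, drop = FALSE] %*% tg$effects)
    g - mean(g)
  })
  rownames(out) <- genotypes$samples
  out
}

#' Simulate blood-cell traits with expression-mediated genetic effects
#'
#' Each trait's latent (standardized) value combines expression-mediated
#' genetic effects (gene-trait effects applied to the standardized truth
#' genetic values), covariate effects (age, age squared, sex, 10 genotype
#' PCs), and unit-variance Gaussian noise. HGB, HCT and PLT are mapped to
#' natural units on the linear scale; WBC is generated on the log scale and
#' exponentiated, producing the right-skewed distribution typical of
#' leukocyte counts. A designated Duffy-like variant adds
#' `duffy_effect` per alt allele to log WBC. With probability
#' `outlier_rate` a sample receives an extreme value beyond the standard
#' exclusion bounds (WBC > 200, HCT > 60, HGB > 20).
#'
#' @param genotypes cohort `genotype_matrix`.
#' @param truth `synthetic_truth` from [simulate_cis_architecture].
#' @param gene_trait_effects data.frame with columns `gene_id`, `trait`
#'   (HGB/HCT/WBC/PLT) and `effect` (per SD of genetic value, on the
#'   latent residual-SD scale).
#' @param covariate_effects named list with elements `age`, `age2`, `sex`,
#'   `pc` (length-10); defaults are modest realistic effects.
#' @param outlier_rate per-sample probability of an injected extreme value.
#' @param duffy_variant variant id receiving a large WBC effect, or `NULL`.
#' @param duffy_effect per-allele effect on log WBC.
#' @param seed integer seed.
#' @return data.frame: `sample_id`, `HGB`, `HCT`, `WBC`, `PLT`, `age`,
#'   `sex`, `PC1`..`PC10`, `population`.
#' @export
simulate_phenotypes <- function(genotypes, truth, gene_trait_effects,
                                covariate_effects = NULL, outlier_rate = 0,
                                duffy_variant = NULL, duffy_effect = 0, seed = 1L) {
  traits <- c("HGB", "HCT", "WBC", "PLT")
  stop_if(!all(gene_trait_effects$trait %in% traits), "unknown trait in effects")
  stop_if(!all(gene_trait_effects$gene_id %in% names(truth$genes)),
          "unknown gene id in gene_trait_effects")
  if (!is.null(duffy_variant))
    stop_if(!duffy_variant %in% genotypes$variants$id, "unknown Duffy-like variant id")
  ce <- covariate_effects %||% list(age = 0.10, age2 = 0.05, sex = 0.20,
                                    pc = rep(0.05, 10L))
  set.seed(seed)
  n <- length(genotypes$samples)
  age <- round(stats::runif(n, 20, 80))
  sex <- stats::rbinom(n, 1L, 0.5)

  # genotype PCs from a thinned variant set (cheap surrogate for full PCA)
  m <- ncol(genotypes$dosage)
  thin <- sort(sample.int(m, min(m, 500L)))
  Xs <- standardize_columns(genotypes$dosage[, thin, drop = FALSE])
  sv <- svd(Xs, nu = 10L, nv = 0L)
  PC <- sv$u[, seq_len(min(10L, ncol(sv$u))), drop = FALSE] * sqrt(n)
  if (ncol(PC) < 10L) PC <- cbind(PC, matrix(0, n, 10L - ncol(PC)))
  colnames(PC) <- paste0("PC", 1:10)

  gvals <- truth_genetic_values(genotypes, truth)
  gvals_std <- apply(gvals, 2L, function(g) if (stats::sd(g) > 0) g / stats::sd(g) else g)

  zage <- as.numeric(scale(age)); zage2 <- as.numeric(scale(age^2))
  cov_part <- ce$age * zage + ce$age2 * zage2 + ce$sex * (sex - mean(sex)) +
    drop(PC %*% ce$pc)

  latent <- sapply(traits, function(tr) {
    l <- cov_part + stats::rnorm(n)
    eff <- gene_trait_effects[gene_trait_effects$trait == tr, , drop = FALSE]
    if (nrow(eff) > 0L)
      l <- l + drop(gvals_std[, eff$gene_id, drop = FALSE] %*% eff$effect)
    l
  })

  HGB <- 13.5 + 1.3 * latent[, "HGB"]
  HCT <- 41.0 + 3.5 * latent[, "HCT"]
  PLT <- 250 + 60 * latent[, "PLT"]
  log_wbc <- log(6.3) + 0.30 * latent[, "WBC"]
  if (!is.null(duffy_variant) && duffy_effect != 0) {
    dd <- genotypes$dosage[, match(duffy_variant, genotypes$variants$id)]
    log_wbc <- log_wbc + duffy_effect * dd
  }
  WBC <- exp(log_wbc)

  if (outlier_rate > 0) {
    hit <- which(stats::runif(n) < outlier_rate)
    for (i in hit) {
      tr <- sample(c("WBC", "HCT", "HGB"), 1L)
      if (tr == "WBC") WBC[i] <- stats::runif(1, 250, 400)
      if (tr == "HCT") HCT[i] <- stats::runif(1, 62, 75)
      if (tr == "HGB") HGB[i] <- stats::runif(1, 21, 25)
    }
  }

  out <- data.frame(sample_id = genotypes$samples,
                    HGB = HGB, HCT = HCT, WBC = WBC, PLT = PLT,
                    age = age, sex = sex, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(PC))
  out$population <- genotypes$population
  rownames(out) <- NULL
  out
}

#' Emit a synthetic known-variant table (GWAS catalog analog)
#'
#' Builds the conditioning input for the two-step conditional analysis:
#' optionally the truth causal eQTLs of selected gene-trait pairs (tagging
#' the real signals) plus randomly chosen decoy variants, each assigned a
#' source label and a GWAS p-value below or above the genome-wide cutoff.
#'
#' @param truth `synthetic_truth`.
#' @param genotypes `genotype_matrix` supplying variant coordinates.
#' @param gene_trait_effects gene-trait effect table (traits to tag).
#' @param include_causal tag causal eQTLs of affected genes as known hits.
#' @param n_decoys number of random decoy variants per trait.
#' @param source label written to the `source` column.
#' @param seed integer seed.
#' @return data.frame: `chrom`, `pos`, `ref`, `alt`, `variant_id`, `trait`,
#'   `source`, `p`.
#' @export
simulate_known_variants <- function(truth, genotypes, gene_trait_effects,
                                    include_causal = TRUE, n_decoys = 5L,
                                    source = "catalog", seed = 1L) {
  set.seed(seed)
  v <- genotypes$variants
  rows <- list()
  traits <- unique(gene_trait_effects$trait)
  if (include_causal && nrow(gene_trait_effects) > 0L) {
    for (k in seq_len(nrow(gene_trait_effects))) {
      tg <- truth$genes[[gene_trait_effects$gene_id[k]]]
      idx <- match(tg$causal_ids, v$id)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = v$chrom[idx], pos = v$pos[idx], ref = v$ref[idx], alt = v$alt[idx],
        variant_id = v$id[idx], trait = gene_trait_effects$trait[k],
        source = source, p = 10^stats::runif(length(idx), -30, -9),
        stringsAsFactors = FALSE)
    }
  }
  for (tr in traits) {
    idx <- sample.int(nrow(v), min(n_decoys, nrow(v)))
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = v$chrom[idx], pos = v$pos[idx], ref = v$ref[idx], alt = v$alt[idx],
      variant_id = v$id[idx], trait = tr,
      source = source, p = 10^stats::runif(length(idx), -20, -2),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[!duplicated(out[, c("variant_id", "trait")]), , drop = FALSE]
}

#' Simulate a complete multi-cohort TWAS study
#'
#' Convenience generator wiring the individual simulators into the layout
#' the discovery pipeline expects: two expression reference panels (a
#' large European-ancestry whole-blood analog and a smaller
#' ancestry-matched monocyte analog), GWAS cohorts in two ancestry groups
#' sharing the panel's variant set, four blood-cell traits with
#' expression-mediated effects, a Duffy-like WBC variant, and a synthetic
#' known-variant catalog.
#'
#' @param n_panel_big,n_panel_small panel sample sizes.
#' @param cohorts named list: ancestry label -> integer vector of cohort
#'   sizes (names become cohort ids).
#' @param n_variants,block_size,fst,ld_rho genotype simulator parameters.
#' @param n_genes number of genes.
#' @param n_causal_per_gene,h2_cis cis architecture parameters.
#' @param n_causal_gene_traits number of gene-trait pairs given nonzero
#'   trait effects.
#' @param effect_size latent-scale gene-trait effect magnitude.
#' @param outlier_rate extreme-value injection rate in the cohorts.
#' @param duffy_effect per-allele log-WBC effect of the Duffy-like variant.
#' @param known_variants `"causal"`, `"decoys"` or `"none"` for the
#'   synthetic catalog content.
#' @param seed master integer seed.
#' @return list with `panels`, `cohorts`, `annotation`, `truth`,
#'   `gene_trait_effects`, `known_variants`, `duffy_variant`.
#' @export
simulate_twas_study <- function(n_panel_big = 900L, n_panel_small = 300L,
                                cohorts = list(AA = c(AA1 = 600L, AA2 = 600L),
                                               HL = c(HL1 = 800L)),
                                n_variants = 2000L, block_size = 10L, fst = 0.1,
                                ld_rho = 0.6, n_genes = 25L,
                                n_causal_per_gene = 3L, h2_cis = 0.3,
                                n_causal_gene_traits = 10L, effect_size = 0.25,
                                outlier_rate = 0.002, duffy_effect = -0.25,
                                known_variants = c("causal", "decoys", "none"),
                                seed = 1L) {
  known_variants <- match.arg(known_variants)
  n_by_pop <- c(EA = n_panel_big + n_panel_small,
                vapply(names(cohorts), function(a) as.integer(sum(cohorts[[a]])), integer(1)))
  # small panel drawn from EA here; ancestry-matched panels are supported by
  # passing panel genotypes directly to the lower-level simulators
  all_geno <- simulate_ld_genotypes(n_by_pop, n_variants, block_size = block_size,
                                    fst = fst, ld_rho = ld_rho,
                                    seed = derive_seed(seed, 1L))
  annotation <- simulate_gene_annotation(all_geno, n_genes, seed = derive_seed(seed, 2L))

  ea_ids <- all_geno$samples[all_geno$population == "EA"]
  panel_big_g <- subset_genotypes(all_geno, samples = ea_ids[seq_len(n_panel_big)])
  panel_small_src <- names(cohorts)[1]
  src_ids <- all_geno$samples[all_geno$population == panel_small_src]
  panel_small_g <- subset_genotypes(all_geno, samples = src_ids[seq_len(n_panel_small)])

  cis <- simulate_cis_architecture(panel_big_g, annotation,
                                   n_causal_per_gene = n_causal_per_gene,
                                   h2_cis = h2_cis, seed = derive_seed(seed, 3L))
  truth <- cis$truth
  expr_small <- truth_genetic_values(panel_small_g, truth)
  expr_small <- expr_small + matrix(stats::rnorm(length(expr_small), 0,
                                                 sqrt(pmax(1 - vapply(truth$genes, `[[`, 0, "h2_cis"), 1e-6))[col(expr_small)]),
                                    nrow(expr_small))

  panel_cov <- function(g, sd_seed) {
    set.seed(sd_seed)
    n <- length(g$samples)
    data.frame(age = round(stats::runif(n, 20, 80)), sex = stats::rbinom(n, 1L, 0.5),
               row.names = g$samples)
  }
  panels <- list(
    BIGPANEL = list(genotypes = panel_big_g, expression = cis$expression,
                    covariates = panel_cov(panel_big_g, derive_seed(seed, 4L))),
    SMALLPANEL = list(genotypes = panel_small_g, expression = expr_small,
                      covariates = panel_cov(panel_small_g, derive_seed(seed, 5L)))
  )

  set.seed(derive_seed(seed, 6L))
  traits <- c("HGB", "HCT", "WBC", "PLT")
  pick <- sample(annotation$gene_id, min(n_causal_gene_traits, n_genes))
  gte <- data.frame(gene_id = pick,
                    trait = sample(traits, length(pick), replace = TRUE),
                    effect = effect_size * sample(c(-1, 1), length(pick), replace = TRUE),
                    stringsAsFactors = FALSE)
  duffy <- all_geno$variants$id[which.max(all_geno$variants[[paste0("maf_", names(cohorts)[1])]])]

  cohort_list <- list()
  ci <- 0L
  used <- list()
  for (anc in names(cohorts)) {
    anc_ids <- all_geno$samples[all_geno$population == anc]
    if (anc == panel_small_src) anc_ids <- setdiff(anc_ids, panel_small_g$samples)
    off <- 0L
    for (cn in names(cohorts[[anc]])) {
      ci <- ci + 1L
      nn <- cohorts[[anc]][[cn]]
      take <- anc_ids[off + seq_len(min(nn, length(anc_ids) - off))]
      off <- off + length(take)
      g <- subset_genotypes(all_geno, samples = take)
      ph <- simulate_phenotypes(g, truth, gte, outlier_rate = outlier_rate,
                                duffy_variant = duffy, duffy_effect = duffy_effect,
                                seed = derive_seed(seed, 10L + ci))
      cohort_list[[cn]] <- list(name = cn, ancestry = anc, genotypes = g, phenotypes = ph)
    }
  }

  kv <- switch(known_variants,
    none = NULL,
    causal = simulate_known_variants(truth, all_geno, gte, include_causal = TRUE,
                                     n_decoys = 5L, seed = derive_seed(seed, 30L)),
    decoys = simulate_known_variants(truth, all_geno, gte, include_causal = FALSE,
                                     n_decoys = 8L, seed = derive_seed(seed, 30L)))

  list(panels = panels, cohorts = cohort_list, annotation = annotation,
       truth = truth, gene_trait_effects = gte, known_variants = kv,
       duffy_variant = duffy, seed = seed)
}
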