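toy_assoc_setup <- function(n = 400L, seed = 7L) {
  set.seed(seed)
  g <- make_toy_genotypes(n = n, pos = c(1.0e6, 1.1e6, 1.2e6, 2.6e6),
                          maf = c(0.3, 0.4, 0.25, 0.3), seed = seed)
  ids <- rownames(g$dosage)
  # phenotype driven by the first variant
  y <- setNames(0.3 * g$dosage[, 1] + rnorm(n), ids)
  pred <- cbind(GX = 0.8 * g$dosage[, 1] + 0.4 * g$dosage[, 2])
  rownames(pred) <- ids
  ann <- data.frame(gene_id = "GX", chrom = "1", start = 1000000L,
                    end = 1100000L, strand = "+")
  list(g = g, y = y, pred = pred, ann = ann, fit = lmm_null(y, NULL))
}

test_that("conditioning sets respect window, trait, step filter and absent variants", {
  s <- toy_assoc_setup()
  kv <- data.frame(chrom = "1",
                   pos = c(1.0e6, 2.6e6, 1.1e6, 1.2e6),
                   ref = "A", alt = "G",
                   variant_id = c("tv001", "tv004", "tv002", "ghost"),
                   trait = c("HGB", "HGB", "PLT", "HGB"),
                   source = "catalog",
                   p = c(1e-12, 1e-9, 1e-10, 1e-9))
  cs <- build_conditioning_set("GX", "HGB", kv, s$g, s$ann, step = "catalog")
  # tv004 at 2.6 Mb is 1.5 Mb from the gene end: outside the 1 Mb window
  # tv002 is for a different trait; "ghost" is absent from the genotypes
  expect_identical(cs$variant_ids, "tv001")
  expect_identical(cs$skipped, "ghost")

  # step 2 requires genome-wide significance
  kv2 <- data.frame(chrom = "1", pos = c(1.0e6, 1.1e6), ref = "A", alt = "G",
                    variant_id = c("tv001", "tv002"), trait = "HGB",
                    source = "recent_gwas", p = c(1e-7, 1e-9))
  cs2 <- build_conditioning_set("GX", "HGB", kv2, s$g, s$ann, step = "recent_gwas")
  expect_identical(cs2$variant_ids, "tv002")  # 1e-7 >= 5e-8 excluded

  # empty window -> empty set (candidate no_known_variants)
  cs3 <- build_conditioning_set("GX", "HGB", kv[kv$pos > 2e6, ], s$g, s$ann)
  expect_length(cs3$variant_ids, 0L)

  # perfectly correlated conditioning variants are pruned
  g_dup <- s$g
  g_dup$dosage[, "tv002"] <- g_dup$dosage[, "tv001"]
  kv3 <- data.frame(chrom = "1", pos = c(1.0e6, 1.1e6), ref = "A", alt = "G",
                    variant_id = c("tv001", "tv002"), trait = "HGB",
                    source = "catalog", p = 1e-9)
  cs4 <- build_conditioning_set("GX", "HGB", kv3, g_dup, s$ann)
  expect_identical(cs4$variant_ids, "tv001")
})

test_that("conditioning on an orthogonal decoy leaves the signal intact", {
  s <- toy_assoc_setup(n = 500L, seed = 13L)
  marg <- lmm_association(s$pred, s$fit)
  z_marg <- marg$beta / marg$se

  set.seed(14)
  decoy <- matrix(rbinom(500, 2, 0.3), dimnames = list(rownames(s$pred), "d1"))
  # force orthogonality to the predictor
  decoy[, 1] <- residuals(lm(decoy[, 1] ~ s$pred[, 1]))
  cond <- lmm_association(s$pred, s$fit, conditioning = decoy)
  z_cond <- cond$beta / cond$se
  expect_lt(abs(z_cond^2 / z_marg^2 - 1), 0.05)

  # conditioning on the causal variant removes the association
  causal <- s$g$dosage[, 1, drop = FALSE]
  cond2 <- lmm_association(s$pred, s$fit, conditioning = causal)
  expect_gt(cond2$p, 0.01)

  # degenerate: conditioning set equal to the predictor itself
  expect_warning(lmm_association(s$pred, s$fit, conditioning = s$pred),
                 "collinear")
})

test_that("two-step classification keeps the larger conditional p", {
  # step1 p = 0.01 (still significant) -> step 2 runs; final = max = 0.03
  c1 <- classify_two_step(0.01, 0.03, FALSE, FALSE)
  expect_equal(c1$conditional_p, 0.03)
  expect_identical(c1$class, "conditionally_distinct")

  # step1 overturns the signal: final p is step1's, class explained_by_gwas
  c2 <- classify_two_step(0.20, 0.001, FALSE, FALSE)
  expect_equal(c2$conditional_p, 0.20)
  expect_identical(c2$class, "explained_by_gwas")

  # empty catalog -> step 2 alone decides
  c3 <- classify_two_step(NA, 0.2, TRUE, FALSE)
  expect_identical(c3$class, "explained_by_gwas")
  expect_equal(c3$conditional_p, 0.2)

  # both sets empty -> no known variants, no conditional p
  c4 <- classify_two_step(NA, NA, TRUE, TRUE)
  expect_identical(c4$class, "no_known_variants")
  expect_true(is.na(c4$conditional_p))
})

test_that("the two-step driver classifies signals end to end", {
  s <- toy_assoc_setup(n = 500L, seed = 23L)
  cohort_data <- list(c1 = list(predicted = s$pred, null_fit = s$fit,
                                genotypes = s$g))
  catalog <- data.frame(chrom = "1", pos = 1.0e6, ref = "A", alt = "G",
                        variant_id = "tv001", trait = "HGB",
                        source = "catalog", p = 1e-12)
  # conditioning on the causal variant explains the signal
  r1 <- two_step_conditional("GX", "HGB", cohort_data, catalog, NULL, s$ann)
  expect_identical(r1$class, "explained_by_gwas")

  # decoy-only catalog far from the causal signal: conditionally distinct
  decoy_cat <- data.frame(chrom = "1", pos = 1.2e6, ref = "A", alt = "G",
                          variant_id = "tv003", trait = "HGB",
                          source = "catalog", p = 1e-12)
  r2 <- two_step_conditional("GX", "HGB", cohort_data, decoy_cat, NULL, s$ann)
  expect_identical(r2$class, "conditionally_distinct")

  # no known variants anywhere
  r3 <- two_step_conditional("GX", "HGB", cohort_data, NULL, NULL, s$ann)
  expect_identical(r3$class, "no_known_variants")
})

test_that("locus definition is a greedy sentinel-first partition", {
  ann <- data.frame(gene_id = c("A", "B", "C", "D"),
                    chrom = c("1", "1", "1", "2"),
                    start = c(2.0e6, 2.5e6, 9.0e6, 2.0e6),
                    end = c(2.1e6, 2.6e6, 9.1e6, 2.1e6),
                    strand = "+")
  sig <- data.frame(gene_id = c("A", "B", "C", "D"),
                    meta_p = c(1e-8, 1e-5, 1e-6, 1e-7))
  loci <- define_loci(sig, ann)
  # A (sentinel, smallest p) absorbs B 0.5 Mb away; C is its own locus;
  # D sits on another chromosome
  expect_identical(loci$sentinel[loci$gene_id == "A"], "A")
  expect_identical(loci$sentinel[loci$gene_id == "B"], "A")
  expect_identical(loci$sentinel[loci$gene_id == "C"], "C")
  expect_identical(loci$sentinel[loci$gene_id == "D"], "D")
  # partition: every significant gene in exactly one locus
  expect_identical(sort(loci$gene_id), sort(sig$gene_id))
  expect_false(anyDuplicated(loci$gene_id) > 0)
  # single gene -> locus spans +/- 1 Mb of its bounds
  l1 <- define_loci(sig[3, , drop = FALSE], ann)
  expect_equal(l1$start, 9.0e6 - 1e6); expect_equal(l1$end, 9.1e6 + 1e6)
})
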