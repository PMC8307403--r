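make_pheno <- function(n = 200L, seed = 1L) {
  set.seed(seed)
  data.frame(sample_id = sprintf("s%04d", 1:n),
             HGB = rnorm(n, 13.5, 1.3), HCT = rnorm(n, 41, 3.5),
             WBC = exp(rnorm(n, log(6.3), 0.3)), PLT = rnorm(n, 250, 60),
             age = round(runif(n, 20, 80)), sex = rbinom(n, 1, 0.5),
             matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("PC", 1:10))))
}

test_that("phenotype preparation applies the exact exclusion bounds", {
  ph <- make_pheno(200L, seed = 2L)
  ph$WBC[5] <- 250; ph$HCT[6] <- 61; ph$HGB[7] <- 21
  ph$HCT[8] <- 60   # boundary value: retained (strict inequality)

  r_wbc <- suppressWarnings(prepare_phenotype(ph, "WBC"))
  expect_identical(r_wbc$excluded$sample_id, "s0005")
  expect_identical(r_wbc$n_used, 199L)

  r_hct <- prepare_phenotype(ph, "HCT")
  expect_identical(r_hct$excluded$sample_id, "s0006")
  expect_true("s0008" %in% names(r_hct$residuals))

  r_hgb <- prepare_phenotype(ph, "HGB")
  expect_identical(r_hgb$excluded$sample_id, "s0007")

  r_plt <- prepare_phenotype(ph, "PLT")
  expect_identical(nrow(r_plt$excluded), 0L)

  # residuals: mean 0, variance ~ 1, standard normal by construction
  expect_lt(abs(mean(r_hct$residuals)), 1e-8)
  expect_lt(abs(var(r_hct$residuals) - 1), 0.05)
  expect_gt(suppressWarnings(ks.test(r_hct$residuals, "pnorm"))$p.value, 0.01)

  expect_error(prepare_phenotype(ph, "RBC"), "unknown trait")
  expect_warning(prepare_phenotype(ph, "WBC"), "Duffy")
  duffy <- setNames(rbinom(200, 2, 0.4), ph$sample_id)
  expect_silent(prepare_phenotype(ph, "WBC", duffy_dosage = duffy))
})

test_that("kinship matrix matches the naive double-loop computation", {
  g <- simulate_ld_genotypes(c(P = 5L), 50L, fst = 0, seed = 61L)
  K <- compute_kinship(g, maf_min = 0.01)
  # brute-force oracle
  f <- colMeans(g$dosage) / 2
  keep <- which(pmin(f, 1 - f) > 0.01)
  Kbf <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    s <- 0
    for (v in keep)
      s <- s + (g$dosage[i, v] - 2 * f[v]) * (g$dosage[j, v] - 2 * f[v]) /
        (2 * f[v] * (1 - f[v]))
    Kbf[i, j] <- s / length(keep)
  }
  expect_lt(max(abs(K - Kbf)), 1e-10)
  expect_true(isSymmetric(K))

  # duplicated sample: off-diagonal ~ diagonal
  g2 <- g
  g2$dosage[2, ] <- g2$dosage[1, ]
  K2 <- compute_kinship(g2)
  expect_lt(abs(K2[1, 2] - K2[1, 1]), 1e-10)

  # large unrelated panel: mean off-diagonal ~ 0
  gl <- simulate_ld_genotypes(c(P = 150L), 400L, fst = 0, seed = 62L)
  Kl <- compute_kinship(gl)
  expect_lt(abs(mean(Kl[upper.tri(Kl)])), 0.02)

  gm <- g
  gm$dosage[] <- 2
  expect_error(compute_kinship(gm), "polymorphic")
})

test_that("mixed model reduces to OLS under identity kinship", {
  set.seed(71); n <- 200L
  ids <- sprintf("s%03d", 1:n)
  I <- diag(n); dimnames(I) <- list(ids, ids)
  y <- setNames(rnorm(n), ids)
  G <- matrix(rnorm(n * 4), n, 4, dimnames = list(ids, paste0("g", 1:4)))
  r <- lmm_association(G, lmm_null(y, I))
  for (j in 1:4) {
    f <- summary(lm(y ~ scale(G[, j])))$coefficients
    expect_lt(abs(r$beta[j] - f[2, 1]), 1e-6)
    expect_lt(abs(r$se[j] - f[2, 2]), 1e-6)
    expect_lt(abs(r$p[j] - f[2, 4]), 1e-6)
  }

  # phenotype identical to the predictor: essentially perfect association
  y2 <- setNames(as.numeric(scale(G[, 1])), ids)
  r2 <- lmm_association(G[, 1, drop = FALSE], lmm_null(y2, I))
  expect_lt(r2$p[1], 1e-20)
  expect_equal(r2$beta[1], 1, tolerance = 1e-6)

  # zero-variance predictor: flagged, not an error
  Gz <- cbind(G, gz = rep(1, n))
  rz <- lmm_association(Gz, lmm_null(y, I))
  expect_true(rz$skipped[rz$gene_id == "gz"])
})

test_that("mixed model is calibrated under sib-pair relatedness", {
  set.seed(81)
  n <- 600L
  K <- diag(n)
  for (i in 1:40) K[2 * i - 1, 2 * i] <- K[2 * i, 2 * i - 1] <- 0.5
  ids <- sprintf("s%04d", 1:n); dimnames(K) <- list(ids, ids)
  L <- chol(K)
  y <- setNames(drop(crossprod(L, rnorm(n))) * sqrt(0.5) + rnorm(n) * sqrt(0.5), ids)
  G <- crossprod(L, matrix(rnorm(n * 300), n, 300)) * sqrt(0.5) +
    matrix(rnorm(n * 300), n, 300) * sqrt(0.5)
  rownames(G) <- ids; colnames(G) <- paste0("g", 1:300)
  r <- lmm_association(G, lmm_null(y, K))
  rej <- mean(r$p < 0.05)
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
  expect_gt(ks.test(r$p, "punif")$p.value, 0.01)
})

test_that("meta-analysis matches hand-computed inverse-variance forms", {
  res <- data.frame(gene_id = "G1", trait = "HGB",
                    cohort = c("c1", "c2"),
                    beta = c(0.2, -0.1), se = c(0.1, 0.2))
  m <- meta_analyze(res, cohort_order = c("c1", "c2"))
  expect_equal(m$meta_beta, 0.14, tolerance = 1e-10)
  expect_equal(m$meta_se, sqrt(1 / (100 + 25)), tolerance = 1e-10)  # 0.08944...
  expect_identical(m$direction, "+-")

  # symmetric case
  res2 <- data.frame(gene_id = "G1", trait = "HGB", cohort = c("a", "b"),
                     beta = c(0.1, 0.1), se = c(0.1, 0.1))
  m2 <- meta_analyze(res2)
  expect_equal(m2$meta_beta, 0.1, tolerance = 1e-12)
  expect_equal(m2$meta_se, 0.1 / sqrt(2), tolerance = 1e-12)

  # single cohort: passthrough, missing cohorts marked "?"
  res3 <- data.frame(gene_id = "G1", trait = "HGB", cohort = "a",
                     beta = 0.3, se = 0.05)
  m3 <- meta_analyze(res3, cohort_order = c("a", "b"))
  expect_equal(m3$meta_beta, 0.3); expect_equal(m3$meta_se, 0.05)
  expect_identical(m3$direction, "+?")
})

test_that("splitting a homogeneous cohort and meta-analyzing recovers the pooled z", {
  set.seed(91); n <- 2000L
  g <- rnorm(n); y <- 0.1 * g + rnorm(n)
  ids <- sprintf("s%04d", 1:n)
  names(y) <- ids
  G <- matrix(g, n, 1, dimnames = list(ids, "G1"))
  pooled <- lmm_association(G, lmm_null(y, NULL))
  z_pooled <- pooled$beta / pooled$se
  halves <- list(1:(n / 2), (n / 2 + 1):n)
  parts <- lapply(seq_along(halves), function(h) {
    i <- halves[[h]]
    r <- lmm_association(G[i, , drop = FALSE], lmm_null(y[i], NULL))
    r$trait <- "T"; r$cohort <- paste0("c", h); r
  })
  m <- meta_analyze(do.call(rbind, parts))
  z_meta <- m$meta_beta / m$meta_se
  expect_lt(abs(z_meta - z_pooled) / abs(z_pooled), 0.02)
})

test_that("ACAT matches identities, the frozen high-precision oracle, and is monotone", {
  expect_equal(acat_combine(c(0.05, 0.05, 0.05)), 0.05, tolerance = 1e-12)
  expect_equal(acat_combine(0.01), 0.01, tolerance = 1e-12)

  oracle <- read.delim(test_path("fixtures", "acat_oracle.tsv"),
                       colClasses = "character")
  for (i in seq_len(nrow(oracle))) {
    p <- as.numeric(strsplit(oracle$p_values[i], ";")[[1]])
    expected <- as.numeric(oracle$expected[i])
    got <- acat_combine(p)
    expect_lt(abs(got - expected) / expected, 1e-10)
  }

  # monotonicity: decreasing any input p never increases the combined p
  set.seed(11)
  for (r in 1:20) {
    p <- runif(4, 0.001, 0.999)
    j <- sample(4, 1)
    p2 <- p; p2[j] <- p[j] / 2
    expect_lte(acat_combine(p2), acat_combine(p))
  }

  # missing entries dropped with weight renormalization
  expect_equal(acat_combine(c(0.02, NA, 0.02)), acat_combine(c(0.02, 0.02)))
  expect_warning(acat_combine(c(0, 0.5)), "clamped")
  expect_error(acat_combine(numeric(0)), "empty")
})
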