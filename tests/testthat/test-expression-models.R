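test_that("covariate adjustment removes known structure and normalizes", {
  set.seed(61)
  n <- 300L
  cov <- data.frame(age = round(runif(n, 20, 80)), sex = rbinom(n, 1, 0.5))
  # expression exactly linear in covariates -> near-zero residual signal
  E_lin <- outer(cov$age, c(0.1, -0.2)) + outer(cov$sex, c(1, 0.5))
  colnames(E_lin) <- c("gA", "gB"); rownames(E_lin) <- sprintf("s%03d", 1:n)
  adj0 <- adjust_expression(E_lin + matrix(rnorm(2 * n, 0, 1e-8), n),
                            cov, n_hidden_factors = 0L)
  # residuals before the rank transform are ~0; after it they are forced
  # N(0,1), so check instead that covariates explain nothing of the output
  expect_lt(max(abs(cor(adj0, cov$age))), 0.05)
  expect_lt(max(abs(cor(adj0, cov$sex))), 0.05)

  # output columns are standard normal by construction
  E <- matrix(rexp(n * 4), n, dimnames = list(rownames(E_lin), paste0("g", 1:4)))
  adj <- adjust_expression(E, cov, n_hidden_factors = 2L)
  for (j in 1:4) {
    ks <- suppressWarnings(ks.test(adj[, j], "pnorm"))
    expect_gt(ks$p.value, 0.01)
    expect_lt(abs(mean(adj[, j])), 1e-8)
  }

  # hidden batch factor loading on half the genes is absorbed
  batch <- rbinom(n, 1, 0.5)
  G <- 40L
  load <- c(rep(1.5, G / 2), rep(0, G / 2))
  Eb <- matrix(rnorm(n * G), n) + outer(batch, load)
  dimnames(Eb) <- list(rownames(E_lin), paste0("g", 1:G))
  adjb <- adjust_expression(Eb, cov, n_hidden_factors = 5L)
  cors <- abs(cor(adjb, batch))
  expect_lt(max(cors[1:(G / 2)]), 0.1)

  expect_error(adjust_expression(E, cbind(cov, dup = cov$age), 0L), "rank")
  expect_error(adjust_expression(E, cov, n_hidden_factors = n), "n_samples")
})

test_that("cis variant selection applies window, MAF, quality and dedup rules", {
  # gene at [2.0, 2.1] Mb; variants at 1.2 Mb (inside the 1 Mb flank),
  # 0.9 Mb (outside), 3.05 Mb (inside), 3.2 Mb (outside)
  g <- make_toy_genotypes(n = 60L, pos = c(1200000, 900000, 3050000, 3200000,
                                           2050000, 2060000, 2070000),
                          maf = c(0.3, 0.3, 0.3, 0.3, 0.04, 0.3, 0.3),
                          rsq = c(0.9, 0.9, 0.9, 0.9, 0.9, 0.25, 0.9))
  ann <- data.frame(gene_id = "GX", chrom = "1", start = 2000000L,
                    end = 2100000L, strand = "+")
  ids <- select_cis_variants("GX", g, ann)
  expect_true("tv001" %in% ids)            # 1.2 Mb: within +/- 1 Mb of start
  expect_false("tv002" %in% ids)           # 0.9 Mb: outside
  expect_true("tv003" %in% ids)            # 3.05 Mb: within 1 Mb of end
  expect_false("tv004" %in% ids)           # 3.2 Mb: outside
  expect_false("tv005" %in% ids)           # MAF 0.04 <= 0.05
  expect_false("tv006" %in% ids)           # imputation quality 0.25 <= 0.3
  expect_true("tv007" %in% ids)

  # duplicated dosage column: exactly one survivor, first by position
  g2 <- g
  g2$dosage[, "tv003"] <- g2$dosage[, "tv001"]
  ids2 <- select_cis_variants("GX", g2, ann)
  expect_true("tv001" %in% ids2)
  expect_false("tv003" %in% ids2)

  expect_error(select_cis_variants("NOPE", g, ann), "absent")
})

test_that("elastic net recovers a noiseless linear signal", {
  set.seed(71)
  g <- make_toy_genotypes(n = 300L, pos = seq(1e6, 1.9e6, length.out = 10),
                          maf = runif(10, 0.2, 0.5), seed = 71L)
  y <- 0.5 * g$dosage[, 3] - 0.3 * g$dosage[, 7]
  m <- train_elastic_net(y, g$dosage, seed = 1L)
  expect_gt(m$model_r2, 0.99)
  expect_gt(m$insample_r2, 0.99)
  expect_true(all(c("tv003", "tv007") %in% m$variant_id))

  # training sanity: in-sample RSS no worse than the null model
  fitted <- m$intercept + drop(g$dosage[, m$variant_id, drop = FALSE] %*% m$weight)
  expect_lte(sum((y - fitted)^2), sum((y - mean(y))^2))

  # determinism under a fixed seed
  m2 <- train_elastic_net(y, g$dosage, seed = 1L)
  expect_identical(m$weight, m2$weight)
  expect_identical(m$cv_r2, m2$cv_r2)

  expect_error(train_elastic_net(rep(1, 300), g$dosage), "constant")
  expect_error(train_elastic_net(y[1:8], g$dosage[1:8, ]), "folds")
  expect_error(train_elastic_net(y, g$dosage[, 1, drop = FALSE]), "2 cis")
})

test_that("cv_r2 is null-calibrated on pure-noise expression", {
  set.seed(81)
  hits <- 0L
  for (s in 1:30) {
    g <- simulate_ld_genotypes(c(P = 200L), 100L, fst = 0, seed = 3000L + s)
    y <- rnorm(200)
    m <- train_elastic_net(y, g$dosage, seed = s)
    hits <- hits + (m$cv_r2 >= 0.05)
  }
  expect_lte(hits / 30, 0.05)
})

test_that("with vanishing penalty and n >> p the weights approach OLS", {
  set.seed(91)
  n <- 2000L
  g <- make_toy_genotypes(n = n, pos = seq(1e6, 1.9e6, length.out = 10),
                          maf = runif(10, 0.2, 0.5), seed = 91L)
  b <- c(0.8, -0.6, 0.5, 0, 0, 0.7, 0, -0.9, 0, 0.4)
  y <- drop(g$dosage %*% b) + rnorm(n, 0, 0.1)
  m <- train_elastic_net(y, g$dosage, seed = 2L)
  # oracle: normal-equations solve
  X1 <- cbind(1, g$dosage)
  bhat <- solve(crossprod(X1), crossprod(X1, y))[-1]
  w <- setNames(rep(0, 10), colnames(g$dosage))
  w[m$variant_id] <- m$weight
  expect_lt(max(abs(w - bhat)), 0.02)
})

test_that("model retention filter uses an inclusive bound", {
  ms <- list(a = stub_model("a", "tv001", 1, model_r2 = 0.05),
             b = stub_model("b", "tv001", 1, model_r2 = 0.049),
             c = stub_model("c", "tv001", 1, model_r2 = 0.9))
  kept <- filter_models(ms)
  expect_identical(names(kept), c("a", "c"))
  expect_length(filter_models(list()), 0L)
})

test_that("weight tables round-trip through TSV", {
  g <- fx_panel$genotypes
  m <- train_elastic_net(fx_panel$expression[, 1], g$dosage, seed = 4L,
                         gene_id = "G1", panel = "PANEL",
                         variant_meta = g$variants[, c("id", "ref", "alt")])
  path <- tempfile(fileext = ".tsv")
  write_weights(list(G1 = m), path)
  back <- read_weights(path)
  expect_length(back, 1L)
  expect_equal(back$G1$weight, m$weight, tolerance = 1e-10)
  expect_identical(back$G1$variant_id, m$variant_id)
  expect_equal(back$G1$model_r2, m$model_r2, tolerance = 1e-10)
  expect_equal(back$G1$intercept, m$intercept, tolerance = 1e-10)
  s <- read.delim(sub("\\.tsv$", "_summary.tsv", path))
  expect_identical(nrow(s), 1L)
})
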