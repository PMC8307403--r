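random_corr <- function(m, seed) {
  set.seed(seed)
  A <- matrix(rnorm(m * m), m)
  cov2cor(crossprod(A) + diag(m) * 1.5)
}

test_that("expression correlation matches pairwise brute force and guards inputs", {
  set.seed(3)
  n <- 200L
  P <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("G1", "G2", "G3")))
  P[, 2] <- 0.6 * P[, 1] + 0.8 * P[, 2]
  R <- expression_correlation(P, c("G1", "G2", "G3"), ridge_eps = 0)
  for (a in 1:2) for (b in (a + 1):3)
    expect_lt(abs(R[a, b] - cor(P[, a], P[, b])), 1e-12)

  # duplicated gene column: off-diagonal ~ 1 (up to the default ridge)
  P2 <- cbind(P, G4 = P[, 1])
  R2 <- expression_correlation(P2, c("G1", "G4"))
  expect_gt(R2[1, 2], 0.99)

  # independent columns: small off-diagonals
  set.seed(4)
  P3 <- matrix(rnorm(1000 * 3), 1000, dimnames = list(NULL, c("a", "b", "c")))
  R3 <- expression_correlation(P3, c("a", "b", "c"))
  expect_lt(max(abs(R3[upper.tri(R3)])), 0.1)

  Pz <- cbind(P, Gz = rep(1, n))
  expect_error(expression_correlation(Pz, c("G1", "Gz")), "zero-variance")
  expect_error(expression_correlation(P, "G1"), "2 genes")
})

test_that("PIPs equal brute-force configuration enumeration", {
  R <- random_corr(5, seed = 31)
  z <- c(G1 = 5.2, G2 = 1.0, G3 = -0.5, G4 = 3.0, G5 = 0.2)
  n_eff <- 1000; prior_sd <- 0.05; k_max <- 2L
  fm <- finemap_locus(z, R, k_max = k_max, n_eff = n_eff, prior_sd = prior_sd)

  # independent oracle: dense multivariate-normal likelihoods
  s2 <- n_eff * prior_sd^2
  pk <- 1 / 5
  ldmvn <- function(x, S)
    -0.5 * (length(x) * log(2 * pi) +
              as.numeric(determinant(S, logarithm = TRUE)$modulus) +
              drop(crossprod(x, solve(S, x))))
  cfgs <- list(integer(0))
  for (k in 1:k_max) cfgs <- c(cfgs, combn(5, k, simplify = FALSE))
  lps <- vapply(cfgs, function(C) {
    S <- R
    if (length(C)) {
      RC <- R[, C, drop = FALSE]
      S <- R + s2 * RC %*% t(RC)
    }
    ldmvn(z, S) + length(C) * log(pk) + (5 - length(C)) * log(1 - pk)
  }, numeric(1))
  post <- exp(lps - max(lps)); post <- post / sum(post)
  pip_oracle <- vapply(1:5, function(j)
    sum(post[vapply(cfgs, function(C) j %in% C, logical(1))]), numeric(1))
  expect_lt(max(abs(fm$pip - pip_oracle)), 1e-10)

  # posterior normalization
  expect_lt(abs(sum(fm$configs$posterior) - 1), 1e-12)
})

test_that("fine-mapping behaves under symmetry and dominant signals", {
  # single strong gene with near-identity R
  R1 <- diag(2); R1[1, 2] <- R1[2, 1] <- 0.01
  fm1 <- finemap_locus(c(A = 6, B = 0.1), R1, k_max = 1L, n_eff = 1000)
  expect_gt(fm1$pip[["A"]], 0.99)
  expect_true("A" %in% fm1$credible_set)

  # perfectly correlated pair with equal z: exchangeable PIPs, both in set
  R2 <- matrix(c(1, 1 - 1e-9, 1 - 1e-9, 1), 2)
  fm2 <- finemap_locus(c(A = 4, B = 4), R2, k_max = 1L, n_eff = 1000)
  expect_lt(abs(fm2$pip[["A"]] - fm2$pip[["B"]]), 1e-6)
  expect_setequal(fm2$credible_set, c("A", "B"))

  # PIP is monotone in |z| under identity R
  pips <- vapply(c(2, 4, 6, 8), function(zz)
    finemap_locus(c(A = zz, B = 0), diag(2), k_max = 1L, n_eff = 1000)$pip[["A"]],
    numeric(1))
  expect_true(all(diff(pips) > 0))

  expect_error(finemap_locus(c(A = 1, B = 2), diag(2), k_max = 0L), "k_max")
  expect_error(finemap_locus(rnorm(25), random_corr(25, 1)), "20 genes")
})

test_that("95% credible sets cover the causal gene across simulated loci", {
  set.seed(7)
  s2 <- 1000 * 0.05^2
  cover <- 0L
  n_loci <- 200L
  for (r in seq_len(n_loci)) {
    m <- 6L
    R <- random_corr(m, seed = 1000L + r)
    cj <- sample(m, 1)
    lam <- rnorm(1, 0, sqrt(s2))
    zz <- drop(R[, cj] * lam + crossprod(chol(R), rnorm(m)))
    names(zz) <- paste0("G", 1:m)
    fm <- finemap_locus(zz, R, k_max = 3L, n_eff = 1000)
    cover <- cover + (paste0("G", cj) %in% fm$credible_set)
  }
  expect_gte(cover / n_loci, 0.90)
})

test_that("locus diagnostics report weight overlap and anomalies", {
  shared <- sprintf("v%03d", 1:5)
  mA <- stub_model("A", c(shared, "v101"), rep(0.1, 6))
  mB <- stub_model("B", c(shared, "v201"), rep(0.1, 6))
  mC <- stub_model("C", c("v301", "v302"), c(0.2, 0.2))
  R <- diag(3); dimnames(R) <- list(c("A", "B", "C"), c("A", "B", "C"))
  R[1, 2] <- R[2, 1] <- 0.8
  fm <- list(pip = c(A = 0.9, B = 0.5, C = 0.4), credible_set = c("A", "C"))
  class(fm) <- "finemap_result"
  d <- diagnose_locus(fm, R, list(A = mA, B = mB, C = mC))
  expect_equal(d$jaccard["A", "B"], 5 / 7)
  expect_equal(d$jaccard["A", "A"], 1)
  expect_equal(d$jaccard["A", "C"], 0)
  # C is in the credible set but uncorrelated with the top gene A
  expect_true(d$anomaly_flag)
  expect_identical(d$uncorrelated_in_credible_set, "C")

  # 50% of each weight set shared -> Jaccard 1/3
  mD <- stub_model("D", c("s1", "s2", "u1", "u2"), rep(0.1, 4))
  mE <- stub_model("E", c("s1", "s2", "u3", "u4"), rep(0.1, 4))
  R2 <- diag(2); dimnames(R2) <- list(c("D", "E"), c("D", "E"))
  fm2 <- list(pip = c(D = 0.9, E = 0.8), credible_set = c("D", "E"))
  class(fm2) <- "finemap_result"
  d2 <- diagnose_locus(fm2, R2, list(D = mD, E = mE))
  expect_equal(d2$jaccard["D", "E"], 1 / 3)
})
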