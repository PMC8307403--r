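#' Prepare a blood-cell trait for association testing
#'
#' Applies the standard extreme-value exclusions (WBC > 200 x 10^9/L,
#' HCT > 60%, HGB > 20 g/dL; none for PLT; all strict inequalities),
#' log-transforms WBC, residualizes on age, age squared, sex and the 10
#' genotype PCs (plus the Duffy-like variant dosage for WBC when
#' supplied), and applies a rank-based inverse-normal transform to the
#' residuals.
#'
#' @param raw phenotype data.frame with `sample_id`, the trait columns and
#'   covariates `age`, `sex`, `PC1`..`PC10`.
#' @param trait one of `"HGB"`, `"HCT"`, `"WBC"`, `"PLT"`.
#' @param covariates covariate column names (age squared is added from
#'   `age` automatically).
#' @param duffy_dosage named numeric vector of Duffy-variant dosages; used
#'   for WBC only. A missing Duffy adjustment for WBC raises a warning,
#'   not an error.
#' @return list: `residuals` (named, inverse-normalized), `excluded`
#'   (data.frame sample_id, value, reason), `n_used`.
#' @export
prepare_phenotype <- function(raw, trait, covariates = c("age", "sex", paste0("PC", 1:10)),
                              duffy_dosage = NULL) {
  stop_if(!trait %in% c("HGB", "HCT", "WBC", "PLT"), sprintf("unknown trait %s", trait))
  bounds <- c(WBC = 200, HCT = 60, HGB = 20, PLT = Inf)
  y <- raw[[trait]]
  excl_hi <- !is.na(y) & y > bounds[[trait]]
  excluded <- data.frame(sample_id = raw$sample_id[excl_hi], value = y[excl_hi],
                         reason = rep(sprintf("%s > %g", trait, bounds[[trait]]), sum(excl_hi)))
  keep <- !is.na(y) & !excl_hi
  d <- raw[keep, , drop = FALSE]
  yv <- d[[trait]]
  if (trait == "WBC") {
    yv <- log(yv)
    if (is.null(duffy_dosage)) {
      warning("WBC analysis without Duffy-variant adjustment")
    } else {
      d$duffy <- unname(duffy_dosage[d$sample_id])
      covariates <- c(covariates, "duffy")
    }
  }
  cv <- d[, covariates, drop = FALSE]
  if ("age" %in% covariates) cv$age2 <- cv$age^2
  fit <- stats::lm.fit(stats::model.matrix(~ ., data = cv), yv)
  res <- inverse_normal_transform(fit$residuals)
  names(res) <- d$sample_id
  list(residuals = res, excluded = excluded, n_used = length(res))
}

#' Genetic relationship (kinship) matrix from genome-wide dosages
#'
#' Standard GRM: dosages centered by twice the allele frequency and scaled
#' by `sqrt(2 p (1 - p))`, cross-product averaged over variants with minor
#' allele frequency above `maf_min`.
#'
#' @param genotypes `genotype_matrix`.
#' @param maf_min minor-allele-frequency cutoff (default 0.01).
#' @return n x n symmetric PSD matrix with sample ids as dimnames.
#' @export
compute_kinship <- function(genotypes, maf_min = 0.01) {
  f <- colMeans(genotypes$dosage) / 2
  keep <- pmin(f, 1 - f) > maf_min
  stop_if(sum(keep) == 0L, "no polymorphic variants above maf_min")
  X <- genotypes$dosage[, keep, drop = FALSE]
  p <- f[keep]
  Xs <- sweep(sweep(X, 2L, 2 * p, "-"), 2L, sqrt(2 * p * (1 - p)), "/")
  K <- tcrossprod(Xs) / ncol(Xs)
  K <- (K + t(K)) / 2
  dimnames(K) <- list(genotypes$samples, genotypes$samples)
  K
}

#' Fit the null mixed model once per trait (EMMAX approximation)
#'
#' Estimates the variance-component ratio of the model
#' `y = X b + u + e`, `u ~ N(0, sg^2 K)`, `e ~ N(0, se^2 I)` by REML on
#' the null model (no gene term), via the spectral decomposition of `K`.
#' The returned object carries the rotated data so that per-gene tests are
#' single generalized-least-squares solves.
#'
#' @param y named phenotype residual vector (from [prepare_phenotype]).
#' @param kinship kinship matrix covering the samples of `y`.
#' @param covariates optional samples x q matrix of extra fixed effects.
#' @return list of class `lmm_null_fit`: eigen pair, `h2` (sg^2 fraction),
#'   rotated response/design, sample ids.
#' @export
lmm_null <- function(y, kinship, covariates = NULL) {
  if (is.null(kinship)) {
    # unrelated-samples shortcut: K = I, so the model is ordinary least squares
    samples <- names(y)
    stop_if(length(samples) < 30L, "fewer than 30 samples")
    lambda <- rep(1, length(samples))
    U <- NULL
  } else {
    samples <- intersect(names(y), rownames(kinship))
    stop_if(length(samples) < 30L, "fewer than 30 shared samples")
    K <- kinship[samples, samples]
    ev <- eigen(K, symmetric = TRUE)
    stop_if(min(ev$values) < -1e-6 * max(ev$values), "kinship not PSD")
    lambda <- pmax(ev$values, 0)
    U <- ev$vectors
  }
  X <- cbind(intercept = rep(1, length(samples)))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates)[samples, , drop = FALSE])
  rot <- function(M) if (is.null(U)) M else crossprod(U, M)
  ys <- drop(rot(cbind(y[samples])))
  Xs <- rot(X)
  n <- length(ys); q <- ncol(Xs)

  reml_nll <- function(h2) {
    d <- h2 * lambda + (1 - h2)
    w <- 1 / d
    XtWX <- crossprod(Xs, Xs * w)
    XtWy <- crossprod(Xs, ys * w)
    b <- solve(XtWX, XtWy)
    r <- ys - drop(Xs %*% b)
    rss <- sum(r^2 * w)
    s2 <- rss / (n - q)
    0.5 * ((n - q) * log(s2) + sum(log(d)) + determinant(XtWX, logarithm = TRUE)$modulus)
  }
  opt <- stats::optimize(reml_nll, interval = c(1e-6, 1 - 1e-6))
  h2 <- opt$minimum
  structure(list(samples = samples, U = U, lambda = lambda, h2 = h2,
                 d = h2 * lambda + (1 - h2), y_rot = ys, X_rot = Xs),
            class = "lmm_null_fit")
}

#' Kinship-adjusted association of predicted expression with a trait
#'
#' EMMAX-style test: the variance-ratio from [lmm_null] is held fixed and
#' each gene's (standardized) predicted expression is tested by
#' generalized least squares in the rotated space, with the residual scale
#' re-estimated per gene and a t-test on the gene coefficient. With
#' `kinship = I` this reduces exactly to ordinary least squares.
#'
#' @param predicted samples x genes matrix of predicted expression.
#' @param null_fit an `lmm_null_fit`.
#' @param conditioning optional samples x k dosage matrix entering as
#'   fixed covariates (conditional analysis). Collinear columns are
#'   dropped to a full-rank basis with a warning.
#' @param gene_ids optional subset of genes to test.
#' @return data.frame: `gene_id`, `beta` (per SD of predicted expression),
#'   `se`, `p`, `n`, `skipped` (zero-variance flag).
#' @export
lmm_association <- function(predicted, null_fit, conditioning = NULL, gene_ids = NULL) {
  samples <- null_fit$samples
  stop_if(!all(samples %in% rownames(predicted)),
          "predicted expression missing phenotyped samples")
  P <- predicted[samples, , drop = FALSE]
  if (!is.null(gene_ids)) P <- P[, intersect(gene_ids, colnames(P)), drop = FALSE]
  w <- 1 / null_fit$d
  sw <- sqrt(w)
  rot <- function(M) if (is.null(null_fit$U)) M else crossprod(null_fit$U, M)
  Xbase <- null_fit$X_rot
  if (!is.null(conditioning)) {
    Cn <- as.matrix(conditioning)
    if (!is.null(rownames(Cn))) {
      Cn <- Cn[samples, , drop = FALSE]
    } else {
      stop_if(nrow(Cn) != length(samples),
              "conditioning rows must match phenotyped samples")
    }
    Cr <- rot(Cn)
    qq <- qr(cbind(Xbase, Cr) * sw)
    if (qq$rank < ncol(Xbase) + ncol(Cr)) {
      warning("collinear conditioning set; dropped to a full-rank basis")
      keep <- qq$pivot[seq_len(qq$rank)]
      keep <- keep[keep > ncol(Xbase)] - ncol(Xbase)
      stop_if(length(keep) == 0L, "conditioning set collinear with base covariates")
      Cr <- Cr[, keep, drop = FALSE]
    }
    Xbase <- cbind(Xbase, Cr)
  }
  n <- length(samples)
  sds <- apply(P, 2L, stats::sd)
  Pstd <- sweep(sweep(P, 2L, colMeans(P), "-"), 2L,
                ifelse(sds > 0, sds, Inf), "/")
  Prot <- rot(Pstd)
  out <- lapply(colnames(P), function(gid) {
    if (sds[[gid]] == 0) {
      return(data.frame(gene_id = gid, beta = NA_real_, se = NA_real_,
                        p = NA_real_, n = n, skipped = TRUE))
    }
    gs <- Prot[, gid]
    Xg <- cbind(Xbase, gene = gs)
    fit <- stats::lm.wfit(Xg, null_fit$y_rot, w)
    pcol <- ncol(Xg)
    beta <- fit$coefficients[pcol]
    if (fit$rank < pcol || is.na(beta)) {
      warning(sprintf("gene %s collinear with covariates/conditioning set", gid))
      return(data.frame(gene_id = gid, beta = NA_real_, se = NA_real_,
                        p = NA_real_, n = n, skipped = TRUE))
    }
    df <- n - fit$rank
    sigma2 <- sum(w * fit$residuals^2) / df
    XtXinv <- chol2inv(qr.R(fit$qr))
    pos <- match(pcol, fit$qr$pivot)
    se <- sqrt(sigma2 * XtXinv[pos, pos])
    tval <- beta / se
    data.frame(gene_id = gid, beta = unname(beta), se = se,
               p = 2 * stats::pt(-abs(tval), df), n = n, skipped = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Fixed-effect inverse-variance meta-analysis with direction strings
#'
#' METAL-style combination: `meta_beta = sum(b/se^2) / sum(1/se^2)`,
#' `meta_se = sqrt(1 / sum(1/se^2))`, two-sided normal p-value, and a
#' direction string with one `+`/`-`/`?` per cohort in `cohort_order`.
#'
#' @param results data.frame with columns `gene_id`, `trait`, `cohort`,
#'   `beta`, `se` (rows with missing beta/se are treated as absent).
#' @param cohort_order fixed cohort ordering for the direction string
#'   (default: sorted unique cohorts).
#' @return data.frame: `gene_id`, `trait`, `meta_beta`, `meta_se`,
#'   `meta_p`, `direction`, `n_cohorts`.
#' @export
meta_analyze <- function(results, cohort_order = NULL) {
  cohort_order <- cohort_order %||% sort(unique(results$cohort))
  keys <- unique(results[, c("gene_id", "trait"), drop = FALSE])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    ri <- results[results$gene_id == keys$gene_id[i] & results$trait == keys$trait[i], ]
    ri <- ri[!is.na(ri$beta) & !is.na(ri$se) & ri$se > 0, , drop = FALSE]
    stop_if(nrow(ri) == 0L, "all cohorts missing for a gene-trait pair")
    w <- 1 / ri$se^2
    mb <- sum(w * ri$beta) / sum(w)
    ms <- sqrt(1 / sum(w))
    dirs <- vapply(cohort_order, function(cc) {
      j <- match(cc, ri$cohort)
      if (is.na(j)) "?" else if (ri$beta[j] >= 0) "+" else "-"
    }, character(1))
    data.frame(gene_id = keys$gene_id[i], trait = keys$trait[i],
               meta_beta = mb, meta_se = ms,
               meta_p = 2 * stats::pnorm(-abs(mb / ms)),
               direction = paste(dirs, collapse = ""),
               n_cohorts = nrow(ri))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Cauchy combination (ACAT) of p-values
#'
#' Combines p-values as `T = sum(w_i tan((0.5 - p_i) pi)) / sum(w_i)` and
#' returns the standard-Cauchy upper-tail probability of `T`. For
#' `p < 1e-15` the tangent term is replaced by its small-p linearization
#' `1/(p pi)` to avoid overflow. Missing entries are dropped with weight
#' renormalization; p-values of exactly 0 or 1 are clamped to
#' `[1e-300, 1 - 1e-16]` with a warning.
#'
#' @param p numeric vector of p-values in (0, 1).
#' @param weights optional non-negative weights (default equal).
#' @return combined p-value.
#' @export
acat_combine <- function(p, weights = NULL) {
  w <- weights %||% rep(1, length(p))
  keep <- !is.na(p)
  p <- p[keep]; w <- w[keep]
  stop_if(length(p) == 0L, "empty p-value set")
  stop_if(any(w < 0) || sum(w) == 0, "invalid weights")
  if (any(p <= 0 | p >= 1)) {
    warning("p-values clamped to [1e-300, 1 - 1e-16]")
    p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  }
  w <- w / sum(w)
  small <- p < 1e-15
  terms <- numeric(length(p))
  terms[small] <- 1 / (p[small] * pi)
  terms[!small] <- tan((0.5 - p[!small]) * pi)
  t_stat <- sum(w * terms)
  if (t_stat > 1e15) return(1 / (t_stat * pi))
  stats::pcauchy(t_stat, lower.tail = FALSE)
}
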