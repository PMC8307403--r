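#' Covariate adjustment and normalization of panel expression
#'
#' Residualizes each gene on the supplied covariates (sex, age, age
#' squared, genotype PCs, ...), estimates `n_hidden_factors` latent
#' factors as the leading principal components of the covariate-residual
#' matrix (a PCA stand-in for PEER-style hidden-confounder estimation),
#' residualizes again on covariates plus factors, and finally applies a
#' rank-based inverse-normal transform per gene.
#'
#' Hidden factors are estimated from expression alone, so strong cis
#' signals shared across many genes could in principle leak into the
#' factors; with sparse per-gene cis architecture this effect is
#' negligible, but it is a known caveat of expression-only factor methods.
#'
#' @param expression samples x genes numeric matrix.
#' @param covariates data.frame/matrix of per-sample covariates (an
#'   `age2 = age^2` column is added automatically when `age` is present
#'   and `age2` is not).
#' @param n_hidden_factors number of latent expression factors (default 10).
#' @return samples x genes matrix of adjusted, inverse-normalized
#'   expression.
#' @export
adjust_expression <- function(expression, covariates, n_hidden_factors = 10L) {
  n <- nrow(expression)
  stop_if(n_hidden_factors < 0L, "n_hidden_factors must be >= 0")
  stop_if(n_hidden_factors >= n, "n_hidden_factors must be < n_samples")
  cov <- as.data.frame(covariates)
  if ("age" %in% names(cov) && !"age2" %in% names(cov)) cov$age2 <- cov$age^2
  C <- stats::model.matrix(~ ., data = cov)
  stop_if(qr(C)$rank < ncol(C), "rank-deficient covariate matrix")
  resid_on <- function(E, X) {
    Q <- qr.Q(qr(X))
    E - Q %*% (t(Q) %*% E)
  }
  R1 <- resid_on(expression, C)
  X <- C
  if (n_hidden_factors > 0L) {
    sv <- svd(scale(R1, scale = FALSE), nu = n_hidden_factors, nv = 0L)
    X <- cbind(C, sv$u[, seq_len(n_hidden_factors), drop = FALSE])
  }
  R2 <- resid_on(expression, X)
  out <- apply(R2, 2L, inverse_normal_transform)
  dimnames(out) <- dimnames(expression)
  out
}

#' Select cis predictor variants for a gene
#'
#' Candidate variants lie within +/- `window_bp` of the gene's start and
#' end, have empirical minor allele frequency strictly above `maf_min` in
#' the panel, and imputation quality strictly above `rsq_min`. Among any
#' group of perfectly correlated dosage columns (|r| = 1 within 1e-12)
#' only the first by position is retained; no other LD pruning is applied
#' (the elastic net handles collinearity).
#'
#' @param gene_id gene identifier present in `annotation`.
#' @param genotypes panel `genotype_matrix`.
#' @param annotation gene annotation data.frame.
#' @param window_bp cis window half-width (default 1 Mb).
#' @param maf_min minor-allele-frequency cutoff (exclusive).
#' @param rsq_min imputation-quality cutoff (exclusive).
#' @return character vector of retained variant ids (possibly empty: the
#'   gene is then untrainable, not an error).
#' @export
select_cis_variants <- function(gene_id, genotypes, annotation,
                                window_bp = 1e6, maf_min = 0.05, rsq_min = 0.3) {
  g <- annotation[annotation$gene_id == gene_id, , drop = FALSE]
  stop_if(nrow(g) == 0L, sprintf("gene %s absent from annotation", gene_id))
  v <- genotypes$variants
  maf <- empirical_maf(genotypes$dosage)
  keep <- v$chrom == g$chrom &
    v$pos >= g$start - window_bp & v$pos <= g$end + window_bp &
    maf > maf_min & v$imput_rsq > rsq_min
  idx <- which(keep)
  if (length(idx) <= 1L) return(v$id[idx])
  idx <- idx[order(v$pos[idx])]
  cc <- suppressWarnings(stats::cor(genotypes$dosage[, idx, drop = FALSE]))
  cc[is.na(cc)] <- 0
  drop <- rep(FALSE, length(idx))
  for (j in seq_along(idx)[-1]) {
    if (any(abs(cc[seq_len(j - 1L), j]) >= 1 - 1e-12 & !drop[seq_len(j - 1L)])) drop[j] <- TRUE
  }
  v$id[idx[!drop]]
}

#' Train an elastic-net expression prediction model for one gene
#'
#' Fits `glmnet` with mixing parameter `mixing_alpha` (default 0.5, the
#' PrediXcan convention); the penalty strength is chosen by `n_folds`-fold
#' cross-validation minimizing mean squared error, with fold assignment by
#' seeded permutation.
#'
#' Reported fit statistics follow the PredictDB convention: `model_r2` is
#' the cross-validated prediction R2 — the squared Pearson correlation of
#' the pooled out-of-fold predictions with the observed expression, both
#' centered within fold (per-fold intercepts otherwise induce a spurious
#' anti-correlation under the null) — and `cv_r2` is the squared average
#' of the per-fold out-of-fold correlations (negative averages clamped to
#' zero), a systematically more conservative estimate. The in-sample
#' squared correlation of the full-data refit is kept as `insample_r2`.
#'
#' @param y adjusted expression vector for the gene.
#' @param X samples x cis-variants dosage matrix (>= 2 columns).
#' @param mixing_alpha elastic-net mixing parameter in [0, 1].
#' @param n_folds number of CV folds (default 10).
#' @param seed integer seed controlling fold assignment.
#' @param gene_id,panel labels stored in the model record.
#' @param variant_meta optional data.frame with `id`, `ref`, `alt` used to
#'   annotate weights.
#' @return an object of class `weight_model`: `gene_id`, `panel`,
#'   `variant_id`, `ref`, `alt`, `weight` (nonzero only), `intercept`,
#'   `model_r2`, `cv_r2`, `n_train`, `lambda`, `alpha`, `n_folds`, `seed`.
#' @export
train_elastic_net <- function(y, X, mixing_alpha = 0.5, n_folds = 10L, seed = 1L,
                              gene_id = NA_character_, panel = NA_character_,
                              variant_meta = NULL) {
  stop_if(ncol(X) < 2L, "need >= 2 cis variants to train")
  n <- length(y)
  stop_if(n <= n_folds, "fewer samples than folds")
  stop_if(stats::sd(y) == 0, "all-constant expression")
  set.seed(seed)
  foldid <- sample(rep(seq_len(n_folds), length.out = n))
  cv <- glmnet::cv.glmnet(X, y, alpha = mixing_alpha, foldid = foldid,
                          keep = TRUE, standardize = TRUE)
  ilam <- which.min(cv$cvm)
  co <- as.matrix(stats::coef(cv, s = "lambda.min"))
  fitted <- drop(stats::predict(cv, newx = X, s = "lambda.min"))
  preval <- cv$fit.preval[, ilam]
  pv_fc <- preval - stats::ave(preval, foldid)
  y_fc <- y - stats::ave(y, foldid)
  r2 <- function(a, b) if (stats::sd(a) > 0 && stats::sd(b) > 0) stats::cor(a, b)^2 else 0
  fold_cors <- vapply(seq_len(n_folds), function(f) {
    i <- foldid == f
    if (stats::sd(preval[i]) == 0 || stats::sd(y[i]) == 0) 0
    else stats::cor(preval[i], y[i])
  }, numeric(1))
  rho_avg <- max(mean(fold_cors), 0)
  nz <- which(co[-1, 1] != 0)
  vm <- variant_meta
  if (is.null(vm)) vm <- data.frame(id = colnames(X), ref = NA_character_,
                                    alt = NA_character_, stringsAsFactors = FALSE)
  mi <- match(colnames(X)[nz], vm$id)
  structure(list(
    gene_id = gene_id, panel = panel,
    variant_id = colnames(X)[nz],
    ref = vm$ref[mi], alt = vm$alt[mi],
    weight = unname(co[-1, 1][nz]),
    intercept = unname(co[1, 1]),
    model_r2 = r2(pv_fc, y_fc), cv_r2 = rho_avg^2,
    insample_r2 = r2(fitted, y),
    n_train = n, lambda = cv$lambda.min, alpha = mixing_alpha,
    n_folds = n_folds, seed = seed
  ), class = "weight_model")
}

#' @export
print.weight_model <- function(x, ...) {
  cat(sprintf("weight_model %s [%s]: %d variants, model R2 = %.3f, CV R2 = %.3f (n = %d)\n",
              x$gene_id, x$panel, length(x$variant_id), x$model_r2, x$cv_r2, x$n_train))
  invisible(x)
}

#' Train elastic-net models for every gene in a panel
#'
#' Runs [select_cis_variants] and [train_elastic_net] per gene with
#' per-gene seeds derived deterministically from `seed`.
#'
#' @inheritParams select_cis_variants
#' @inheritParams train_elastic_net
#' @param adjusted_expression output of [adjust_expression] (or any
#'   samples x genes matrix aligned with the panel genotypes).
#' @param panel panel label stored in the models.
#' @return list with `models` (named list of `weight_model`) and `skipped`
#'   (data.frame of untrainable genes with reasons).
#' @export
train_panel_models <- function(genotypes, adjusted_expression, annotation,
                               window_bp = 1e6, maf_min = 0.05, rsq_min = 0.3,
                               mixing_alpha = 0.5, n_folds = 10L, seed = 1L,
                               panel = "panel") {
  genes <- intersect(annotation$gene_id, colnames(adjusted_expression))
  models <- list(); skipped <- list()
  for (k in seq_along(genes)) {
    gid <- genes[k]
    ids <- select_cis_variants(gid, genotypes, annotation,
                               window_bp = window_bp, maf_min = maf_min,
                               rsq_min = rsq_min)
    if (length(ids) < 2L) {
      skipped[[gid]] <- data.frame(gene_id = gid, reason = "fewer than 2 cis variants")
      next
    }
    X <- genotypes$dosage[, match(ids, genotypes$variants$id), drop = FALSE]
    models[[gid]] <- train_elastic_net(
      adjusted_expression[, gid], X, mixing_alpha = mixing_alpha,
      n_folds = n_folds, seed = derive_seed(seed, k),
      gene_id = gid, panel = panel,
      variant_meta = genotypes$variants[, c("id", "ref", "alt")])
  }
  list(models = models,
       skipped = if (length(skipped)) do.call(rbind, skipped)
                 else data.frame(gene_id = character(), reason = character()))
}

#' Retain models meeting the prediction-quality filter
#'
#' Keeps models with model R2 (cross-validated prediction R2) at or above
#' `model_r2_min` (inclusive bound).
#'
#' @param models list of `weight_model`.
#' @param model_r2_min retention threshold (default 0.05).
#' @return filtered named list of `weight_model`.
#' @export
filter_models <- function(models, model_r2_min = 0.05) {
  keep <- vapply(models, function(m) m$model_r2 >= model_r2_min, logical(1))
  models[keep]
}

#' Write / read weight models as PredictDB-style TSV tables
#'
#' `write_weights` emits a long weights table (`gene_id`, `variant_id`,
#' `ref`, `alt`, `weight`) at `path` and a per-gene summary
#' (`gene_id`, `panel`, `n_variants`, `intercept`, `model_r2`, `cv_r2`,
#' `n_train`) at `path` with a `_summary.tsv` suffix. `read_weights`
#' inverts the pair.
#'
#' @param models list of `weight_model`.
#' @param path weights TSV path.
#' @return `read_weights` returns a named list of `weight_model`.
#' @export
write_weights <- function(models, path) {
  w <- data.table::rbindlist(lapply(models, function(m)
    data.table::data.table(gene_id = m$gene_id,
                           variant_id = if (length(m$variant_id)) m$variant_id else character(0),
                           ref = m$ref, alt = m$alt, weight = m$weight)))
  s <- data.table::rbindlist(lapply(models, function(m)
    data.table::data.table(gene_id = m$gene_id, panel = m$panel,
                           n_variants = length(m$variant_id),
                           intercept = m$intercept, model_r2 = m$model_r2,
                           cv_r2 = m$cv_r2, insample_r2 = m$insample_r2,
                           n_train = m$n_train,
                           lambda = m$lambda, alpha = m$alpha,
                           n_folds = m$n_folds, seed = m$seed)))
  data.table::fwrite(w, path, sep = "\t")
  data.table::fwrite(s, weights_summary_path(path), sep = "\t")
  invisible(c(weights = path, summary = weights_summary_path(path)))
}

#' @keywords internal
weights_summary_path <- function(path) {
  sub("\\.tsv$", "", path) |> paste0("_summary.tsv")
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  w <- as.data.frame(data.table::fread(path))
  s <- as.data.frame(data.table::fread(weights_summary_path(path)))
  req <- c("gene_id", "variant_id", "ref", "alt", "weight")
  stop_if(!all(req %in% names(w)), "malformed weights table")
  models <- lapply(seq_len(nrow(s)), function(i) {
    wi <- w[w$gene_id == s$gene_id[i], , drop = FALSE]
    structure(list(gene_id = s$gene_id[i], panel = s$panel[i],
                   variant_id = wi$variant_id, ref = wi$ref, alt = wi$alt,
                   weight = wi$weight, intercept = s$intercept[i],
                   model_r2 = s$model_r2[i], cv_r2 = s$cv_r2[i],
                   insample_r2 = s$insample_r2[i],
                   n_train = s$n_train[i], lambda = s$lambda[i],
                   alpha = s$alpha[i], n_folds = s$n_folds[i], seed = s$seed[i]),
              class = "weight_model")
  })
  names(models) <- s$gene_id
  models
}
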