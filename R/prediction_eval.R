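#' Predict expression in a target cohort from weight models
#'
#' For each gene, computes intercept + sum of weight x dosage over the
#' model's variants found in the target genotypes. Allele orientation is
#' reconciled by REF/ALT string match: when the model's effect allele is
#' the target's REF (alleles swapped), the dosage is flipped to
#' `2 - dosage` before weighting. Variants whose alleles match neither
#' orientation, or which are absent from the target, are dropped (not
#' imputed) and counted. Genes with no matched variants are omitted with a
#' logged reason.
#'
#' @param models named list of `weight_model`.
#' @param genotypes target `genotype_matrix`.
#' @return list: `predictions` (samples x genes matrix), `info`
#'   (data.frame gene_id, n_found, n_missing), `dropped` (data.frame of
#'   omitted genes and reasons).
#' @export
predict_expression <- function(models, genotypes) {
  v <- genotypes$variants
  n <- length(genotypes$samples)
  cols <- list(); info <- list(); dropped <- list()
  for (m in models) {
    idx <- match(m$variant_id, v$id)
    use <- !is.na(idx)
    flip <- rep(FALSE, length(idx))
    if (any(use) && !all(is.na(m$ref))) {
      same <- use & m$ref == v$ref[idx] & m$alt == v$alt[idx]
      swapped <- use & m$ref == v$alt[idx] & m$alt == v$ref[idx]
      flip <- swapped & !same
      use <- same | swapped
    }
    nf <- sum(use)
    info[[m$gene_id]] <- data.frame(gene_id = m$gene_id, n_found = nf,
                                    n_missing = length(idx) - nf)
    if (nf == 0L) {
      dropped[[m$gene_id]] <- data.frame(gene_id = m$gene_id,
                                         reason = "no weight variants matched in target")
      next
    }
    D <- genotypes$dosage[, idx[use], drop = FALSE]
    if (any(flip[use])) D[, flip[use]] <- 2 - D[, flip[use]]
    cols[[m$gene_id]] <- m$intercept + drop(D %*% m$weight[use])
  }
  stop_if(length(cols) == 0L, "no overlapping variants for any gene")
  pred <- do.call(cbind, cols)
  rownames(pred) <- genotypes$samples
  list(predictions = pred,
       info = do.call(rbind, c(info, list(make.row.names = FALSE))),
       dropped = if (length(dropped)) do.call(rbind, c(dropped, list(make.row.names = FALSE)))
                 else data.frame(gene_id = character(), reason = character()))
}

#' Evaluate prediction accuracy against measured expression (true R2)
#'
#' Squared Pearson correlation of predicted vs measured expression per
#' gene over the shared samples. Genes with zero-variance prediction get
#' `true_r2 = 0` and a flag.
#'
#' @param predicted samples x genes matrix of predicted expression.
#' @param measured samples x genes matrix of measured expression.
#' @return data.frame: `gene_id`, `true_r2`, `n`, `zero_variance`.
#' @export
evaluate_true_r2 <- function(predicted, measured) {
  samples <- intersect(rownames(predicted), rownames(measured))
  stop_if(length(samples) < 3L, "fewer than 3 shared samples")
  genes <- intersect(colnames(predicted), colnames(measured))
  stop_if(length(genes) == 0L, "no shared genes")
  P <- predicted[samples, genes, drop = FALSE]
  M <- measured[samples, genes, drop = FALSE]
  zv <- apply(P, 2L, stats::sd) == 0 | apply(M, 2L, stats::sd) == 0
  r2 <- rep(0, length(genes))
  r2[!zv] <- vapply(which(!zv), function(j) stats::cor(P[, j], M[, j])^2, numeric(1))
  data.frame(gene_id = genes, true_r2 = r2, n = length(samples),
             zero_variance = zv, row.names = NULL)
}

#' Panel-overlap report of well-predicted genes
#'
#' Venn-style counts of genes exceeding the true-R2 threshold in each
#' panel, in both/all, and in at least one, plus a threshold sweep.
#'
#' @param true_r2_by_panel named list of [evaluate_true_r2] outputs.
#' @param threshold true-R2 cutoff (exclusive, default 0.05).
#' @param sweep thresholds for the sweep table.
#' @return list: `counts` (named integer vector with one entry per panel
#'   plus `both` and `either`), `sweep` (data.frame threshold x counts).
#' @export
overlap_report <- function(true_r2_by_panel, threshold = 0.05,
                           sweep = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.3)) {
  stop_if(length(true_r2_by_panel) < 2L, "need >= 2 panels")
  well <- function(th) lapply(true_r2_by_panel, function(d) d$gene_id[d$true_r2 > th])
  count_at <- function(th) {
    w <- well(th)
    c(vapply(w, length, integer(1)),
      both = length(Reduce(intersect, w)),
      either = length(Reduce(union, w)))
  }
  list(counts = count_at(threshold),
       sweep = data.frame(threshold = sweep,
                          t(vapply(sweep, count_at,
                                   numeric(length(true_r2_by_panel) + 2L)))))
}

#' Panel subsampling experiment
#'
#' Retrains expression models on `n_reps` seeded subsamples of the panel
#' at `target_n`, evaluates each model set in a held-out cohort, and
#' compares the per-gene mean true R2 with the full-panel models'. This
#' reproduces the design used to separate reference-panel sample size from
#' ancestry matching.
#'
#' @param panel_genotypes,panel_expression panel data (expression already
#'   adjusted/normalized).
#' @param annotation gene annotation.
#' @param eval_genotypes,eval_expression held-out evaluation cohort.
#' @param target_n subsample size (< panel size).
#' @param n_reps number of subsamplings (default 5).
#' @param seed integer seed; rep r uses a seed derived from it.
#' @param ... passed to [train_panel_models].
#' @return list: `full` (models + true_r2), `reps` (per-rep models),
#'   `true_r2_sub` (per-gene mean over reps), `summary` (mean true R2
#'   full vs subsampled over shared genes).
#' @export
subsample_experiment <- function(panel_genotypes, panel_expression, annotation,
                                 eval_genotypes, eval_expression,
                                 target_n, n_reps = 5L, seed = 1L, ...) {
  n <- length(panel_genotypes$samples)
  stop_if(target_n > n, "target_n exceeds panel size")
  dots <- list(...)
  n_folds <- dots$n_folds %||% 10L
  stop_if(target_n <= n_folds, "target_n too small to train (<= folds)")

  run <- function(g, e, sd) {
    tr <- train_panel_models(g, e, annotation, seed = sd, ...)
    if (length(tr$models) == 0L) return(NULL)
    pe <- predict_expression(tr$models, eval_genotypes)
    list(models = tr$models, true_r2 = evaluate_true_r2(pe$predictions, eval_expression))
  }
  full <- run(panel_genotypes, panel_expression, seed)

  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(derive_seed(seed, 100L + r))
    take <- if (target_n == n) seq_len(n) else sort(sample.int(n, target_n))
    reps[[r]] <- run(subset_genotypes(panel_genotypes, samples = take),
                     panel_expression[take, , drop = FALSE], seed)
  }
  r2_tabs <- lapply(reps, function(x) x$true_r2)
  genes <- Reduce(intersect, c(list(full$true_r2$gene_id),
                               lapply(r2_tabs, `[[`, "gene_id")))
  sub_mean <- rowMeans(matrix(
    unlist(lapply(r2_tabs, function(d) d$true_r2[match(genes, d$gene_id)])),
    nrow = length(genes)))
  true_r2_sub <- data.frame(gene_id = genes, mean_true_r2 = sub_mean)
  full_mean <- full$true_r2$true_r2[match(genes, full$true_r2$gene_id)]
  list(full = full, reps = reps, true_r2_sub = true_r2_sub,
       summary = data.frame(n_full = n, n_sub = target_n, n_reps = n_reps,
                            mean_true_r2_full = mean(full_mean),
                            mean_true_r2_sub = mean(sub_mean)))
}
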