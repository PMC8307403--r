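#' Build the conditioning set of known variants around a gene
#'
#' Collects trait-matched known variants within +/- `window_bp` of the
#' gene's start/end, extracts their dosages, and LD-prunes the set at
#' `|r| > prune_r` (keeping the first of each correlated pair by position)
#' so the downstream generalized-least-squares solve stays stable. For the
#' `recent_gwas` step, only entries with source p-value below
#' `gwas_p_max` (genome-wide significance) are eligible.
#'
#' @param gene_id gene identifier.
#' @param trait trait name matched against the table's `trait` column.
#' @param known_variants data.frame with `chrom`, `pos`, `trait`,
#'   `source`, `p` and optionally `variant_id`.
#' @param genotypes cohort `genotype_matrix` supplying dosages.
#' @param annotation gene annotation.
#' @param step `"catalog"` (no p filter) or `"recent_gwas"`
#'   (p < `gwas_p_max` required).
#' @param window_bp window half-width (default 1 Mb).
#' @param gwas_p_max significance cutoff for step 2 entries.
#' @param prune_r LD-pruning |r| threshold.
#' @return list of class `conditioning_set`: `gene_id`, `trait`, `step`,
#'   `variant_ids`, `dosages` (samples x k or NULL), `window`, `skipped`
#'   (ids listed but absent from genotypes).
#' @export
build_conditioning_set <- function(gene_id, trait, known_variants, genotypes,
                                   annotation, step = c("catalog", "recent_gwas"),
                                   window_bp = 1e6, gwas_p_max = 5e-8,
                                   prune_r = 0.95) {
  step <- match.arg(step)
  g <- annotation[annotation$gene_id == gene_id, , drop = FALSE]
  stop_if(nrow(g) == 0L, sprintf("gene %s absent from annotation", gene_id))
  lo <- g$start - window_bp; hi <- g$end + window_bp
  kv <- known_variants
  kv <- kv[kv$trait == trait & kv$chrom == g$chrom & kv$pos >= lo & kv$pos <= hi, , drop = FALSE]
  if (step == "recent_gwas") kv <- kv[kv$p < gwas_p_max, , drop = FALSE]
  empty <- function(skipped = character(0)) structure(
    list(gene_id = gene_id, trait = trait, step = step,
         variant_ids = character(0), dosages = NULL,
         window = c(lo, hi), skipped = skipped),
    class = "conditioning_set")
  if (nrow(kv) == 0L) return(empty())

  v <- genotypes$variants
  idx <- if ("variant_id" %in% names(kv)) match(kv$variant_id, v$id)
         else match(paste(kv$chrom, kv$pos), paste(v$chrom, v$pos))
  skipped <- kv$variant_id[is.na(idx)] %||% character(0)
  idx <- unique(idx[!is.na(idx)])
  if (length(idx) == 0L) return(empty(skipped))
  idx <- idx[order(v$pos[idx])]
  if (length(idx) > 1L) {
    cc <- suppressWarnings(stats::cor(genotypes$dosage[, idx, drop = FALSE]))
    cc[is.na(cc)] <- 0
    drop <- rep(FALSE, length(idx))
    for (j in seq_along(idx)[-1])
      if (any(abs(cc[seq_len(j - 1L), j]) > prune_r & !drop[seq_len(j - 1L)])) drop[j] <- TRUE
    idx <- idx[!drop]
  }
  structure(list(gene_id = gene_id, trait = trait, step = step,
                 variant_ids = v$id[idx],
                 dosages = genotypes$dosage[, idx, drop = FALSE],
                 window = c(lo, hi), skipped = skipped),
            class = "conditioning_set")
}

#' Conditional association of one gene given a conditioning set
#'
#' Re-tests the gene's predicted expression with the conditioning dosages
#' entering the mixed model as fixed covariates (per cohort); multi-cohort
#' results are meta-analyzed exactly as marginal results are.
#'
#' @param predicted samples x genes predicted expression (one cohort).
#' @param null_fit `lmm_null_fit` for the trait in that cohort.
#' @param conditioning_set a `conditioning_set` (non-empty).
#' @return one-row data.frame as from [lmm_association].
#' @export
conditional_association <- function(predicted, null_fit, conditioning_set) {
  stop_if(length(conditioning_set$variant_ids) == 0L, "conditioning set is empty")
  stop_if(length(null_fit$samples) <= ncol(conditioning_set$dosages) + 10L,
          "too few samples for the conditioning set")
  lmm_association(predicted, null_fit,
                  conditioning = conditioning_set$dosages,
                  gene_ids = conditioning_set$gene_id)
}

#' Classify a signal from its two-step conditional p-values
#'
#' Decision rule: Step 1 conditions on the GWAS-catalog set; if the signal
#' stays significant (conditional p < `alpha`) or the catalog set is
#' empty, Step 2 conditions on the recent-GWAS genome-wide-significant
#' set. The final conditional p is the larger (less significant) of the
#' step p-values that were run; the signal is `conditionally_distinct` iff
#' the final p < `alpha`, and `no_known_variants` iff both sets are empty.
#'
#' @param step1_p,step2_p step p-values (`NA` when the step did not run).
#' @param step1_empty,step2_empty whether each conditioning set was empty.
#' @param alpha lenient conditional-significance threshold (default 0.05).
#' @return list: `class`, `conditional_p` (NA for no_known_variants),
#'   `step1_p`, `step2_p`.
#' @export
classify_two_step <- function(step1_p, step2_p, step1_empty, step2_empty,
                              alpha = 0.05) {
  if (step1_empty && step2_empty) {
    return(list(class = "no_known_variants", conditional_p = NA_real_,
                step1_p = NA_real_, step2_p = NA_real_))
  }
  ps <- c(if (!step1_empty) step1_p, if (!step2_empty) step2_p)
  # Step 2 only runs when step 1 passed (or had no variants); when step 1
  # already overturned the signal its p stands alone.
  if (!step1_empty && !is.na(step1_p) && step1_p >= alpha) ps <- step1_p
  final_p <- max(ps, na.rm = TRUE)
  list(class = if (final_p < alpha) "conditionally_distinct" else "explained_by_gwas",
       conditional_p = final_p,
       step1_p = if (step1_empty) NA_real_ else step1_p,
       step2_p = if (step2_empty) NA_real_ else step2_p)
}

#' Two-step conditional analysis of one gene-trait pair across cohorts
#'
#' Runs Step 1 (GWAS catalog) and, when required by [classify_two_step]'s
#' rule, Step 2 (recent genome-wide-significant variants) in every cohort,
#' meta-analyzes each step's per-cohort conditional results, and classifies
#' the signal.
#'
#' @param gene_id,trait the marginally significant pair.
#' @param cohort_data named list; each element holds `predicted`
#'   (samples x genes), `null_fit` (`lmm_null_fit`) and `genotypes`.
#' @param catalog,recent_gwas known-variant tables for the two steps
#'   (either may be NULL/empty).
#' @param annotation gene annotation.
#' @param alpha conditional significance threshold (default 0.05).
#' @param window_bp,gwas_p_max,prune_r passed to [build_conditioning_set].
#' @return list of class `signal_class`: `gene_id`, `trait`, `class`,
#'   `conditional_p`, `step1_p`, `step2_p`.
#' @export
two_step_conditional <- function(gene_id, trait, cohort_data, catalog, recent_gwas,
                                 annotation, alpha = 0.05, window_bp = 1e6,
                                 gwas_p_max = 5e-8, prune_r = 0.95) {
  run_step <- function(kv, step) {
    if (is.null(kv) || nrow(kv) == 0L) return(list(empty = TRUE, p = NA_real_))
    rows <- list(); any_set <- FALSE
    for (cn in names(cohort_data)) {
      cd <- cohort_data[[cn]]
      cs <- build_conditioning_set(gene_id, trait, kv, cd$genotypes, annotation,
                                   step = step, window_bp = window_bp,
                                   gwas_p_max = gwas_p_max, prune_r = prune_r)
      if (length(cs$variant_ids) == 0L) next
      any_set <- TRUE
      r <- conditional_association(cd$predicted, cd$null_fit, cs)
      r$trait <- trait; r$cohort <- cn
      rows[[cn]] <- r
    }
    if (!any_set) return(list(empty = TRUE, p = NA_real_))
    res <- do.call(rbind, rows)
    res <- res[!res$skipped, , drop = FALSE]
    if (nrow(res) == 0L) return(list(empty = TRUE, p = NA_real_))
    list(empty = FALSE, p = meta_analyze(res)$meta_p)
  }
  s1 <- run_step(catalog, "catalog")
  need_step2 <- s1$empty || (!is.na(s1$p) && s1$p < alpha)
  s2 <- if (need_step2) run_step(recent_gwas, "recent_gwas")
        else list(empty = is.null(recent_gwas) || nrow(recent_gwas) == 0L, p = NA_real_)
  cls <- classify_two_step(s1$p, s2$p, s1$empty, s2$empty, alpha = alpha)
  structure(c(list(gene_id = gene_id, trait = trait), cls), class = "signal_class")
}

#' Define TWAS loci by greedy sentinel assignment
#'
#' Significant gene-trait results are sorted by marginal p ascending; each
#' still-unassigned gene founds a locus spanning its start - `window_bp`
#' to end + `window_bp`, and all remaining genes inside those bounds (same
#' chromosome) join it. The result is a partition: every significant gene
#' belongs to exactly one locus, and the sentinel has the smallest
#' marginal p among its members.
#'
#' @param significant data.frame with `gene_id` and `meta_p` (one row per
#'   significant gene for the trait under consideration).
#' @param annotation gene annotation.
#' @param window_bp locus half-width (default 1 Mb).
#' @return data.frame: `locus`, `sentinel`, `chrom`, `start`, `end`,
#'   `gene_id` (one row per member gene).
#' @export
define_loci <- function(significant, annotation, window_bp = 1e6) {
  stop_if(nrow(significant) == 0L, "no significant genes")
  d <- merge(significant, annotation, by = "gene_id")
  d <- d[order(d$meta_p), , drop = FALSE]
  assigned <- rep(NA_integer_, nrow(d))
  loci <- list(); li <- 0L
  for (i in seq_len(nrow(d))) {
    if (!is.na(assigned[i])) next
    li <- li + 1L
    lo <- d$start[i] - window_bp; hi <- d$end[i] + window_bp
    member <- is.na(assigned) & d$chrom == d$chrom[i] & d$start >= lo & d$end <= hi
    member[i] <- TRUE
    assigned[member] <- li
    loci[[li]] <- data.frame(locus = li, sentinel = d$gene_id[i],
                             chrom = d$chrom[i], start = lo, end = hi,
                             gene_id = d$gene_id[member])
  }
  do.call(rbind, c(loci, list(make.row.names = FALSE)))
}
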