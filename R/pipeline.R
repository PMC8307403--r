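#' Default discovery-pipeline configuration
#'
#' All thresholds default to the standard values of the blood-cell TWAS
#' workflow: training variant filters MAF > 0.05 and imputation R2 > 0.3
#' (0.8 for replication retraining), model retention at model R2 >= 0.05,
#' suggestive meta-analysis screen p < 1e-4, lenient conditional
#' significance 0.05, tier-2 replication fallthrough at model R2 < 0.01.
#'
#' @param outdir directory for stage outputs.
#' @param seed master integer seed.
#' @param ... overrides for any config field.
#' @return named list of class `pipeline_config`.
#' @export
default_config <- function(outdir = tempfile("twas_run_"), seed = 1L, ...) {
  cfg <- list(outdir = outdir, seed = seed,
              window_bp = 1e6, maf_min = 0.05,
              rsq_min_train = 0.3, rsq_min_replication = 0.8,
              model_r2_min = 0.05, suggestive_p = 1e-4,
              conditional_alpha = 0.05, tier2_model_r2 = 0.01,
              gwas_p_max = 5e-8, prune_r = 0.95,
              mixing_alpha = 0.5, n_folds = 10L, n_hidden_factors = 10L,
              kinship_maf_min = 0.01,
              k_max = 3L, prior_sd = 0.05, alpha = 0.05)
  ov <- list(...)
  cfg[names(ov)] <- ov
  for (f in c("maf_min", "rsq_min_train", "rsq_min_replication", "model_r2_min",
              "suggestive_p", "conditional_alpha", "tier2_model_r2"))
    stop_if(cfg[[f]] <= 0 || cfg[[f]] >= 1, sprintf("threshold %s outside (0,1)", f))
  structure(cfg, class = "pipeline_config")
}

#' @keywords internal
stage_record <- function(stage, path, rows, seed) {
  data.frame(stage = stage,
             output = basename(path),
             md5 = unname(tools::md5sum(path)),
             rows = rows, seed = seed, stringsAsFactors = FALSE)
}

#' Run the full TWAS discovery pipeline on a study bundle
#'
#' Orchestrates the seven discovery stages — panel model training,
#' expression prediction in the GWAS cohorts, kinship-adjusted
#' association per cohort and trait, within-ancestry meta-analysis,
#' cross-panel ACAT aggregation, two-step conditional analysis of
#' suggestive signals, and gene-level fine-mapping of multi-gene loci —
#' writing every stage's table plus a manifest (stage, output file, md5,
#' row count, seed) under `config$outdir`. Identical study + config +
#' seed yields byte-identical outputs.
#'
#' @param study a study bundle as produced by [simulate_twas_study] (or
#'   assembled from the `read_*` fixture readers with the same shape).
#' @param config a [default_config] list.
#' @return list: `weights` (per panel), `predictions`, `cohort_results`,
#'   `meta_results`, `acat_results`, `conditional_results`,
#'   `finemap_results`, `loci`, `manifest`, `context` (null fits and
#'   adjusted phenotypes, reused by replication).
#' @export
run_discovery <- function(study, config = default_config()) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  manifest <- list()
  traits <- c("HGB", "HCT", "WBC", "PLT")

  ## stage 1: train expression models per panel
  weights <- list()
  for (pn in names(study$panels)) {
    pa <- study$panels[[pn]]
    # latent-factor estimation needs many more genes than factors; with few
    # genes the factors absorb per-gene cis signal, so cap at genes/10
    nh <- min(config$n_hidden_factors, nrow(pa$expression) - 1L,
              ncol(pa$expression) %/% 10L)
    adj <- adjust_expression(pa$expression, pa$covariates, n_hidden_factors = nh)
    tr <- train_panel_models(pa$genotypes, adj, study$annotation,
                             window_bp = config$window_bp, maf_min = config$maf_min,
                             rsq_min = config$rsq_min_train,
                             mixing_alpha = config$mixing_alpha,
                             n_folds = config$n_folds,
                             seed = derive_seed(seed, 1000L + match(pn, names(study$panels))),
                             panel = pn)
    weights[[pn]] <- filter_models(tr$models, config$model_r2_min)
    write_weights(weights[[pn]], file.path(config$outdir, sprintf("weights_%s.tsv", pn)))
  }
  wpath <- file.path(config$outdir, sprintf("weights_%s.tsv", names(study$panels)[1]))
  manifest[["train"]] <- stage_record("train", wpath,
                                      sum(vapply(weights, length, integer(1))), seed)

  ## stage 2: predict expression in every cohort with every panel
  predictions <- list(); pred_info <- list()
  for (cn in names(study$cohorts)) {
    for (pn in names(weights)) {
      if (length(weights[[pn]]) == 0L) next
      pe <- predict_expression(weights[[pn]], study$cohorts[[cn]]$genotypes)
      predictions[[cn]][[pn]] <- pe$predictions
      ii <- pe$info; ii$cohort <- cn; ii$panel <- pn
      pred_info[[paste(cn, pn)]] <- ii
    }
  }
  pred_info <- do.call(rbind, c(pred_info, list(make.row.names = FALSE)))
  pip_path <- file.path(config$outdir, "prediction_info.tsv")
  data.table::fwrite(pred_info, pip_path, sep = "\t")
  manifest[["predict"]] <- stage_record("predict", pip_path, nrow(pred_info), seed)

  ## stage 3: per-cohort kinship LMM association
  context <- list()
  rows <- list()
  for (cn in names(study$cohorts)) {
    co <- study$cohorts[[cn]]
    K <- compute_kinship(co$genotypes, maf_min = config$kinship_maf_min)
    duffy <- NULL
    if (!is.null(study$duffy_variant) &&
        study$duffy_variant %in% co$genotypes$variants$id) {
      duffy <- co$genotypes$dosage[, match(study$duffy_variant, co$genotypes$variants$id)]
      names(duffy) <- co$genotypes$samples
    }
    for (tr in traits) {
      ph <- prepare_phenotype(co$phenotypes, tr,
                              duffy_dosage = if (tr == "WBC") duffy else NULL)
      nf <- lmm_null(ph$residuals, K)
      context[[cn]][[tr]] <- list(null_fit = nf, excluded = ph$excluded)
      for (pn in names(predictions[[cn]])) {
        r <- lmm_association(predictions[[cn]][[pn]], nf)
        r$trait <- tr; r$cohort <- cn; r$panel <- pn; r$ancestry <- co$ancestry
        rows[[paste(cn, tr, pn)]] <- r
      }
    }
  }
  cohort_results <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  cr_path <- file.path(config$outdir, "cohort_results.tsv")
  data.table::fwrite(cohort_results, cr_path, sep = "\t")
  manifest[["associate"]] <- stage_record("associate", cr_path, nrow(cohort_results), seed)

  ## stage 4: within-ancestry fixed-effect meta-analysis per panel
  metas <- list()
  for (anc in unique(cohort_results$ancestry)) {
    for (pn in unique(cohort_results$panel)) {
      sub <- cohort_results[cohort_results$ancestry == anc &
                              cohort_results$panel == pn & !cohort_results$skipped, ]
      if (nrow(sub) == 0L) next
      mm <- meta_analyze(sub, cohort_order = sort(unique(sub$cohort)))
      mm$ancestry <- anc; mm$panel <- pn
      metas[[paste(anc, pn)]] <- mm
    }
  }
  meta_results <- do.call(rbind, c(metas, list(make.row.names = FALSE)))
  mr_path <- file.path(config$outdir, "meta_results.tsv")
  data.table::fwrite(meta_results, mr_path, sep = "\t")
  manifest[["meta"]] <- stage_record("meta", mr_path, nrow(meta_results), seed)

  ## stage 5: ACAT aggregation across panel x ancestry sets
  keys <- unique(meta_results[, c("gene_id", "trait")])
  acat_results <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    ps <- meta_results$meta_p[meta_results$gene_id == keys$gene_id[i] &
                                meta_results$trait == keys$trait[i]]
    data.frame(gene_id = keys$gene_id[i], trait = keys$trait[i],
               acat_p = acat_combine(ps), n_sets = length(ps))
  }))
  ac_path <- file.path(config$outdir, "acat_results.tsv")
  data.table::fwrite(acat_results, ac_path, sep = "\t")
  manifest[["acat"]] <- stage_record("acat", ac_path, nrow(acat_results), seed)

  ## stage 6: two-step conditional analysis of suggestive signals
  kv <- study$known_variants
  catalog <- if (!is.null(kv)) kv[kv$source == "catalog", , drop = FALSE]
  recent <- if (!is.null(kv)) kv[kv$source == "recent_gwas", , drop = FALSE]
  sugg <- meta_results[meta_results$meta_p < config$suggestive_p, , drop = FALSE]
  cond_rows <- list()
  if (nrow(sugg) > 0L) for (i in seq_len(nrow(sugg))) {
    anc <- sugg$ancestry[i]; pn <- sugg$panel[i]
    tr <- sugg$trait[i]; gid <- sugg$gene_id[i]
    cohort_data <- list()
    for (cn in names(study$cohorts)) {
      if (study$cohorts[[cn]]$ancestry != anc) next
      if (is.null(predictions[[cn]][[pn]])) next
      cohort_data[[cn]] <- list(predicted = predictions[[cn]][[pn]],
                                null_fit = context[[cn]][[tr]]$null_fit,
                                genotypes = study$cohorts[[cn]]$genotypes)
    }
    sc <- two_step_conditional(gid, tr, cohort_data, catalog, recent,
                               study$annotation, alpha = config$conditional_alpha,
                               window_bp = config$window_bp,
                               gwas_p_max = config$gwas_p_max,
                               prune_r = config$prune_r)
    cond_rows[[i]] <- data.frame(
      gene_id = gid, trait = tr, ancestry = anc, panel = pn,
      meta_beta = sugg$meta_beta[i], meta_se = sugg$meta_se[i],
      direction = sugg$direction[i], marginal_p = sugg$meta_p[i],
      conditional_p = sc$conditional_p, step1_p = sc$step1_p,
      step2_p = sc$step2_p, class = sc$class)
  }
  conditional_results <- if (length(cond_rows)) do.call(rbind, cond_rows)
    else data.frame(gene_id = character(), trait = character(), ancestry = character(),
                    panel = character(), meta_beta = numeric(), meta_se = numeric(),
                    direction = character(), marginal_p = numeric(),
                    conditional_p = numeric(), step1_p = numeric(),
                    step2_p = numeric(), class = character())
  co_path <- file.path(config$outdir, "conditional_results.tsv")
  data.table::fwrite(conditional_results, co_path, sep = "\t")
  manifest[["conditional"]] <- stage_record("conditional", co_path,
                                            nrow(conditional_results), seed)

  ## stage 7: loci and gene-level fine-mapping of multi-gene loci
  fm_rows <- list(); loci_all <- list()
  if (nrow(sugg) > 0L) {
    combos <- unique(sugg[, c("ancestry", "panel", "trait")])
    for (i in seq_len(nrow(combos))) {
      ss <- sugg[sugg$ancestry == combos$ancestry[i] & sugg$panel == combos$panel[i] &
                   sugg$trait == combos$trait[i], ]
      loci <- define_loci(ss, study$annotation, window_bp = config$window_bp)
      loci$ancestry <- combos$ancestry[i]; loci$panel <- combos$panel[i]
      loci$trait <- combos$trait[i]
      loci_all[[i]] <- loci
      ref_cohort <- names(study$cohorts)[vapply(study$cohorts, function(x)
        x$ancestry == combos$ancestry[i], logical(1))][1]
      pred_ref <- predictions[[ref_cohort]][[combos$panel[i]]]
      for (L in unique(loci$locus)) {
        genes <- loci$gene_id[loci$locus == L]
        genes <- intersect(genes, colnames(pred_ref))
        if (length(genes) < 2L) next
        R <- expression_correlation(pred_ref, genes)
        zz <- ss$meta_beta / ss$meta_se
        names(zz) <- ss$gene_id
        fm <- finemap_locus(zz[genes], R, k_max = config$k_max,
                            n_eff = round(mean(cohort_results$n)),
                            prior_sd = config$prior_sd)
        fm_rows[[paste(i, L)]] <- data.frame(
          ancestry = combos$ancestry[i], panel = combos$panel[i],
          trait = combos$trait[i], locus = L,
          gene_id = genes, z = unname(zz[genes]), pip = unname(fm$pip),
          in_credible_set = genes %in% fm$credible_set)
      }
    }
  }
  finemap_results <- if (length(fm_rows)) do.call(rbind, c(fm_rows, list(make.row.names = FALSE)))
    else data.frame(ancestry = character(), panel = character(), trait = character(),
                    locus = integer(), gene_id = character(), z = numeric(),
                    pip = numeric(), in_credible_set = logical())
  fm_path <- file.path(config$outdir, "finemap_results.tsv")
  data.table::fwrite(finemap_results, fm_path, sep = "\t")
  manifest[["finemap"]] <- stage_record("finemap", fm_path, nrow(finemap_results), seed)

  manifest <- do.call(rbind, c(manifest, list(make.row.names = FALSE)))
  data.table::fwrite(manifest, file.path(config$outdir, "manifest.tsv"), sep = "\t")

  list(weights = weights, predictions = predictions,
       cohort_results = cohort_results, meta_results = meta_results,
       acat_results = acat_results, conditional_results = conditional_results,
       finemap_results = finemap_results,
       loci = if (length(loci_all)) do.call(rbind, c(loci_all, list(make.row.names = FALSE))) else NULL,
       manifest = manifest, context = context, config = config)
}

#' Retrain panel models on the replication-grade variant set
#'
#' Restricts the panel to variants present in both the panel and the
#' replication cohort that are common (MAF > `maf_min`) and well-imputed
#' (imputation R2 > `rsq_min`, the stricter replication-grade cutoff) in
#' both, then reruns elastic-net training.
#'
#' @param panel_genotypes,panel_adjusted_expression,annotation panel data.
#' @param replication_genotypes replication cohort `genotype_matrix`.
#' @param maf_min,rsq_min replication-grade filters (defaults 0.05 / 0.8).
#' @param ... passed to [train_panel_models].
#' @return as [train_panel_models].
#' @export
retrain_for_replication <- function(panel_genotypes, panel_adjusted_expression,
                                    annotation, replication_genotypes,
                                    maf_min = 0.05, rsq_min = 0.8, ...) {
  shared <- intersect(panel_genotypes$variants$id, replication_genotypes$variants$id)
  stop_if(length(shared) == 0L, "panel and replication cohort share no variants")
  ok <- function(g) {
    j <- match(shared, g$variants$id)
    empirical_maf(g$dosage[, j, drop = FALSE]) > maf_min & g$variants$imput_rsq[j] > rsq_min
  }
  keep <- shared[ok(panel_genotypes) & ok(replication_genotypes)]
  stop_if(length(keep) == 0L, "no variants pass the replication-grade filters")
  train_panel_models(subset_genotypes(panel_genotypes, variants = keep),
                     panel_adjusted_expression, annotation,
                     maf_min = maf_min, rsq_min = rsq_min, ...)
}

#' Bonferroni-corrected significance threshold
#' @param alpha family-wise error rate (default 0.05).
#' @param n_tests number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  stop_if(n_tests < 1L, "n_tests must be >= 1")
  alpha / n_tests
}

#' Two-tier replication of conditionally distinct signals
#'
#' Tier 1 tests each signal with the replication-grade retrained panel
#' models. A signal falls through to tier 2 (ancestry-matched panel
#' models) when its tier-1 model is absent, its tier-1 association is not
#' significant at the Bonferroni-adjusted threshold, or the tier-1 model
#' predicts poorly (model R2 < `tier2_model_r2`). Every input signal
#' yields exactly one record.
#'
#' @param signals data.frame with `gene_id` and `trait` (conditionally
#'   distinct or no-known-variant pairs).
#' @param tier1_models named list of replication-retrained `weight_model`.
#' @param ancestry_models named list of ancestry-panel `weight_model`.
#' @param replication_genotypes,replication_phenotypes replication cohort.
#' @param n_tests number of replication tests for the Bonferroni
#'   threshold.
#' @param alpha family-wise error rate (default 0.05).
#' @param tier2_model_r2 tier-2 fallthrough model-quality cutoff.
#' @param kinship optional replication kinship matrix (NULL = unrelated).
#' @param duffy_dosage optional named Duffy dosages for WBC adjustment.
#' @return data.frame: `gene_id`, `trait`, `tier`, `beta`, `se`, `p`,
#'   `model_r2`, `threshold`, `replicated` (NA when untestable), `reason`.
#' @export
replication_tiers <- function(signals, tier1_models, ancestry_models,
                              replication_genotypes, replication_phenotypes,
                              n_tests, alpha = 0.05, tier2_model_r2 = 0.01,
                              kinship = NULL, duffy_dosage = NULL) {
  thr <- bonferroni_threshold(alpha, n_tests)
  nf_cache <- list()
  get_fit <- function(trait) {
    if (is.null(nf_cache[[trait]])) {
      ph <- prepare_phenotype(replication_phenotypes, trait,
                              duffy_dosage = if (trait == "WBC") duffy_dosage else NULL)
      nf_cache[[trait]] <<- lmm_null(ph$residuals, kinship)
    }
    nf_cache[[trait]]
  }
  test_one <- function(model, trait) {
    pe <- tryCatch(predict_expression(list(model), replication_genotypes),
                   error = function(e) NULL)
    if (is.null(pe)) return(NULL)
    r <- lmm_association(pe$predictions, get_fit(trait))
    if (r$skipped[1]) NULL else r
  }
  out <- lapply(seq_len(nrow(signals)), function(i) {
    gid <- signals$gene_id[i]; tr <- signals$trait[i]
    rec <- data.frame(gene_id = gid, trait = tr, tier = NA_integer_,
                      beta = NA_real_, se = NA_real_, p = NA_real_,
                      model_r2 = NA_real_, threshold = thr,
                      replicated = NA, reason = "")
    m1 <- tier1_models[[gid]]
    r1 <- if (!is.null(m1)) test_one(m1, tr)
    tier1_ok <- !is.null(r1) && !is.null(m1) && m1$model_r2 >= tier2_model_r2 &&
      r1$p[1] < thr
    if (tier1_ok) {
      rec$tier <- 1L; rec$beta <- r1$beta[1]; rec$se <- r1$se[1]; rec$p <- r1$p[1]
      rec$model_r2 <- m1$model_r2; rec$replicated <- TRUE
      rec$reason <- "tier-1 significant"
      return(rec)
    }
    m2 <- ancestry_models[[gid]]
    r2 <- if (!is.null(m2)) test_one(m2, tr)
    if (!is.null(r2)) {
      rec$tier <- 2L; rec$beta <- r2$beta[1]; rec$se <- r2$se[1]; rec$p <- r2$p[1]
      rec$model_r2 <- m2$model_r2; rec$replicated <- r2$p[1] < thr
      rec$reason <- if (is.null(m1)) "no tier-1 model"
                    else if (!is.null(r1) && m1$model_r2 < tier2_model_r2)
                      "tier-1 model poorly predictive"
                    else "tier-1 not significant"
      return(rec)
    }
    if (!is.null(r1)) {
      rec$tier <- 1L; rec$beta <- r1$beta[1]; rec$se <- r1$se[1]; rec$p <- r1$p[1]
      rec$model_r2 <- m1$model_r2; rec$replicated <- FALSE
      rec$reason <- "tier-1 not significant; no ancestry model"
      return(rec)
    }
    rec$reason <- "no usable model in either tier"
    rec
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
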