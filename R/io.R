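#' Write synthetic study fixtures to disk
#'
#' Emits the on-disk interchange formats the pipeline readers consume:
#' genotypes as either a dosage TSV triplet (`dosages.tsv`, `variants.tsv`,
#' `samples.tsv`) or a VCF 4.2 with FORMAT `DS` (plus `samples.tsv`),
#' expression and phenotype TSVs, a BED-like gene annotation TSV
#' (1-based inclusive coordinates, stated in the header comment), and the
#' ground-truth JSON. All tables round-trip losslessly through the
#' corresponding `read_*` functions (VCF dosages at 6-decimal precision).
#'
#' @param genotypes `genotype_matrix`.
#' @param expression samples x genes matrix.
#' @param phenotypes phenotype/covariate data.frame (see
#'   [simulate_phenotypes]).
#' @param annotation gene annotation data.frame.
#' @param truth optional `synthetic_truth` written as JSON.
#' @param outdir output directory (created if absent).
#' @param format `"tsv"` or `"vcf"` genotype representation.
#' @return invisibly, named character vector of file paths.
#' @export
write_fixtures <- function(genotypes, expression, phenotypes, annotation,
                           truth = NULL, outdir, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  stop_if(!identical(rownames(expression), genotypes$samples),
          "expression sample ids do not match genotypes")
  stop_if(!identical(phenotypes$sample_id, genotypes$samples),
          "phenotype sample ids do not match genotypes")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()

  smp <- data.table::data.table(sample_id = genotypes$samples,
                                population = genotypes$population)
  paths["samples"] <- file.path(outdir, "samples.tsv")
  data.table::fwrite(smp, paths["samples"], sep = "\t")

  if (format == "tsv") {
    paths["variants"] <- file.path(outdir, "variants.tsv")
    data.table::fwrite(genotypes$variants, paths["variants"], sep = "\t")
    dt <- data.table::data.table(sample_id = genotypes$samples)
    dt <- cbind(dt, data.table::as.data.table(genotypes$dosage))
    paths["dosages"] <- file.path(outdir, "dosages.tsv")
    data.table::fwrite(dt, paths["dosages"], sep = "\t")
  } else {
    paths["vcf"] <- file.path(outdir, "genotypes.vcf")
    write_vcf_dosage(genotypes, paths["vcf"])
  }

  ex <- data.table::data.table(sample_id = rownames(expression))
  ex <- cbind(ex, data.table::as.data.table(expression))
  paths["expression"] <- file.path(outdir, "expression.tsv")
  data.table::fwrite(ex, paths["expression"], sep = "\t")

  paths["phenotypes"] <- file.path(outdir, "phenotypes.tsv")
  data.table::fwrite(phenotypes, paths["phenotypes"], sep = "\t")

  paths["annotation"] <- file.path(outdir, "genes.tsv")
  writeLines("# coordinates: 1-based inclusive (chrom, start, end, gene_id, strand)",
             paths["annotation"])
  data.table::fwrite(annotation[, c("chrom", "start", "end", "gene_id", "strand")],
                     paths["annotation"], sep = "\t", append = TRUE, col.names = TRUE)

  if (!is.null(truth)) {
    paths["truth"] <- file.path(outdir, "truth.json")
    jsonlite::write_json(
      list(seed = truth$seed, window_bp = truth$window_bp,
           genes = lapply(truth$genes, function(tg)
             list(gene_id = tg$gene_id, causal_ids = tg$causal_ids,
                  effects = tg$effects, h2_cis = tg$h2_cis))),
      paths["truth"], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

# Serialize a genotype_matrix as plain-text VCF 4.2 with FORMAT DS.
# Positions are emitted sorted within chromosome; coordinates 1-based.
#' @keywords internal
write_vcf_dosage <- function(genotypes, path) {
  v <- genotypes$variants
  ord <- order(v$chrom, v$pos)
  v <- v[ord, , drop = FALSE]
  d <- genotypes$dosage[, ord, drop = FALSE]
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                   "FORMAT", genotypes$samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i], ".", "PASS",
            sprintf("R2=%.4f", v$imput_rsq[i]), "DS",
            sprintf("%.6f", d[, i])), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
}

#' Read genotype fixtures
#'
#' `read_dosage_tsv` reconstructs a [genotype_matrix] from the TSV triplet
#' written by [write_fixtures]; `read_vcf_dosage` parses a VCF with FORMAT
#' `DS` via \pkg{vcfR} (per-population minor allele frequencies are then
#' recomputed empirically from the dosages, since VCF carries no
#' generating-frequency sidecar).
#'
#' @param dir fixture directory (TSV layout).
#' @return a `genotype_matrix`.
#' @export
read_dosage_tsv <- function(dir) {
  v <- as.data.frame(data.table::fread(file.path(dir, "variants.tsv")))
  smp <- as.data.frame(data.table::fread(file.path(dir, "samples.tsv")))
  dt <- data.table::fread(file.path(dir, "dosages.tsv"))
  d <- as.matrix(dt[, -1, with = FALSE])
  rownames(d) <- dt[[1]]
  stop_if(!identical(colnames(d), v$id), "dosage columns do not match variants.tsv")
  genotype_matrix(d, v, smp$population[match(rownames(d), smp$sample_id)])
}

#' @rdname read_dosage_tsv
#' @param vcf_path path to a VCF with a DS FORMAT field.
#' @param samples_path optional samples.tsv providing population labels.
#' @export
read_vcf_dosage <- function(vcf_path, samples_path = NULL) {
  stop_if(!requireNamespace("vcfR", quietly = TRUE),
          "vcfR is required to read VCF genotypes")
  vr <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  ds <- vcfR::extract.gt(vr, element = "DS", as.numeric = TRUE)
  fix <- as.data.frame(vr@fix, stringsAsFactors = FALSE)
  r2 <- suppressWarnings(as.numeric(sub(".*R2=([0-9.eE+-]+).*", "\\1", fix$INFO)))
  d <- t(ds)
  variants <- data.frame(id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         imput_rsq = r2, stringsAsFactors = FALSE)
  colnames(d) <- variants$id
  pop <- rep("unknown", nrow(d))
  if (!is.null(samples_path)) {
    smp <- as.data.frame(data.table::fread(samples_path))
    pop <- smp$population[match(rownames(d), smp$sample_id)]
  }
  for (pp in unique(pop)) {
    f <- colMeans(d[pop == pp, , drop = FALSE]) / 2
    variants[[paste0("maf_", pp)]] <- pmin(f, 1 - f)
  }
  genotype_matrix(d, variants, pop)
}

#' Read expression / phenotype / annotation / truth fixtures
#' @param path file path.
#' @return matrix, data.frame, or `synthetic_truth` respectively.
#' @export
read_expression_tsv <- function(path) {
  dt <- data.table::fread(path)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt[[1]]
  m
}

#' @rdname read_expression_tsv
#' @export
read_phenotype_tsv <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' @rdname read_expression_tsv
#' @export
read_annotation_tsv <- function(path) {
  as.data.frame(data.table::fread(path, skip = "chrom"))
}

#' @rdname read_expression_tsv
#' @export
read_truth_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  genes <- lapply(j$genes, function(g)
    list(gene_id = g$gene_id, causal_ids = unlist(g$causal_ids),
         effects = unlist(g$effects), h2_cis = g$h2_cis))
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  structure(list(genes = genes, seed = j$seed, window_bp = j$window_bp),
            class = "synthetic_truth")
}
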