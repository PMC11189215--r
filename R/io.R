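## Readers and writers for the plain-text interchange formats: dosage TSV
## (+ variant metadata sidecar), VCF, SV TSV, count TSV, covariate TSV, TE
## annotation TSV, gene-model GTF, GMT gene sets, trait maps and whole
## simulated cohorts.

.write_tsv <- function(df, path, row_names = FALSE) {
  # doubles are written with 17 significant digits so stored tables
  # round-trip exactly (threshold comparisons stay re-derivable)
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
}

.read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

#' Write genotype dosages as TSV with a variant-metadata sidecar
#'
#' @param g \code{\link{genotype_matrix}}
#' @param path dosage TSV (first column \code{sample}, then one column per
#'   variant ID)
#' @param meta_path variant metadata TSV (id, chrom, pos, ref, alt, maf,
#'   hwe_p); default \code{<path>.variants.tsv}
#' @export
write_dosage_tsv <- function(g, path,
                             meta_path = paste0(path, ".variants.tsv")) {
  stopifnot(inherits(g, "genotype_matrix"))
  df <- data.frame(sample = rownames(g$dosage), g$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
  .write_tsv(g$variants, meta_path)
  invisible(c(path, meta_path))
}

#' Read genotype dosages from TSV (+ variant metadata sidecar)
#'
#' @inheritParams write_dosage_tsv
#' @param impute_mean passed to \code{\link{genotype_matrix}}
#' @return \code{\link{genotype_matrix}}
#' @export
read_dosage_tsv <- function(path, meta_path = paste0(path, ".variants.tsv"),
                            impute_mean = FALSE) {
  df <- .read_tsv(path)
  meta <- .read_tsv(meta_path)
  dos <- as.matrix(df[, -1, drop = FALSE])
  rownames(dos) <- df$sample
  if (!identical(colnames(dos), meta$id))
    stop("dosage columns do not match variant metadata")
  genotype_matrix(dos, meta, impute_mean = impute_mean)
}

#' Write genotypes as a minimal VCF (v4.2, GT only)
#'
#' @param g \code{\link{genotype_matrix}}
#' @param path output path (plain text)
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(g$dosage)),
                     collapse = "\t")), con)
  gt <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(g$dosage))) {
    v <- g$variants[j, ]
    writeLines(paste(c(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".",
                       "GT", gt[g$dosage[, j] + 1L]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read biallelic SNV genotypes from VCF
#'
#' Parses FORMAT/GT of a VCF (via vcfR) into additive ALT-allele dosages.
#' Multiallelic records and records with missing genotypes are rejected
#' unless \code{impute_mean = TRUE}.
#'
#' @param path VCF path (plain or gzipped)
#' @param impute_mean passed to \code{\link{genotype_matrix}}
#' @return \code{\link{genotype_matrix}}
#' @export
read_vcf_genotypes <- function(path, impute_mean = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_count <- function(x) {
    ifelse(is.na(x), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", x), "/", fixed = FALSE),
                  function(al) sum(al == "1"), integer(1)))
  }
  dos <- t(apply(gt, 1, alt_count))
  dimnames(dos) <- dimnames(gt)
  variants <- data.frame(id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  genotype_matrix(t(dos), variants, impute_mean = impute_mean)
}

#' Write / read structural-variant dosages (rows = SVs)
#'
#' TSV columns: \code{id}, \code{sv_class}, then one column per sample.
#'
#' @param svs \code{\link{sv_set}}
#' @param path TSV path
#' @export
write_sv_tsv <- function(svs, path) {
  stopifnot(inherits(svs, "sv_set"))
  df <- data.frame(id = colnames(svs$dosage), sv_class = svs$sv_class,
                   t(svs$dosage), check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
  invisible(path)
}

#' @rdname write_sv_tsv
#' @return \code{\link{sv_set}}
#' @export
read_sv_tsv <- function(path) {
  df <- .read_tsv(path)
  dos <- t(as.matrix(df[, -(1:2), drop = FALSE]))
  colnames(dos) <- df$id
  sv_set(dos, df$sv_class)
}

#' Write / read feature counts (rows = features)
#'
#' TSV columns: \code{feature_id}, \code{kind}, then one column per sample.
#' Library sizes are recomputed as column sums at read time.
#'
#' @param c \code{\link{count_matrix}}
#' @param path TSV path
#' @export
write_counts_tsv <- function(c, path) {
  stopifnot(inherits(c, "count_matrix"))
  df <- data.frame(feature_id = rownames(c$counts), kind = c$features$kind,
                   c$counts, check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @return \code{\link{count_matrix}}
#' @export
read_counts_tsv <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$feature_id
  count_matrix(m, df$kind)
}

#' Write / read a per-sample covariate table
#'
#' TSV keyed by a \code{sample} column; remaining columns are covariates.
#'
#' @param cov data.frame with sample IDs as row names
#' @param path TSV path
#' @export
write_covariates_tsv <- function(cov, path) {
  .write_tsv(data.frame(sample = rownames(cov), cov, check.names = FALSE),
             path)
  invisible(path)
}

#' @rdname write_covariates_tsv
#' @return data.frame with sample IDs as row names
#' @export
read_covariates_tsv <- function(path) {
  df <- .read_tsv(path)
  rownames(df) <- df$sample
  df$sample <- NULL
  df
}

#' Write / read TE locus annotation
#'
#' TSV columns: \code{locus_id}, \code{chrom}, \code{start}, \code{end}
#' (1-based inclusive), \code{subfamily}, \code{family}, \code{te_class},
#' optional \code{region}.
#'
#' @param te TE annotation data.frame
#' @param path TSV path
#' @export
write_te_annotation_tsv <- function(te, path) {
  .write_tsv(te, path)
  invisible(path)
}

#' @rdname write_te_annotation_tsv
#' @return data.frame
#' @export
read_te_annotation_tsv <- function(path) .read_tsv(path)

#' Write gene models as GTF
#'
#' Emits one \code{gene} feature per gene and one \code{exon} feature per
#' exon, 1-based inclusive, with \code{gene_id} attributes.
#'
#' @param gm \code{\link{gene_models}}
#' @param path GTF path
#' @export
write_gene_models_gtf <- function(gm, path) {
  stopifnot(inherits(gm, "gene_models"))
  line <- function(chrom, feat, s, e, gid)
    paste(chrom, "teqtl", feat, s, e, ".", "+", ".",
          sprintf('gene_id "%s";', gid), sep = "\t")
  lines <- c(
    mapply(line, gm$genes$chrom, "gene", gm$genes$start, gm$genes$end,
           gm$genes$gene_id),
    mapply(line, gm$exons$chrom, "exon", gm$exons$start, gm$exons$end,
           gm$exons$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GTF
#'
#' Uses rtracklayer's GTF parser; \code{gene} rows define gene spans and
#' \code{exon} rows define exons (grouped by \code{gene_id}). When no
#' \code{gene} rows exist, gene spans are the union of each gene's exons.
#'
#' @param path GTF path
#' @return \code{\link{gene_models}}
#' @export
read_gene_models_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   type = as.character(gr$type),
                   gene_id = gr$gene_id, stringsAsFactors = FALSE)
  ex <- df[df$type == "exon", c("gene_id", "chrom", "start", "end")]
  gn <- df[df$type == "gene", c("gene_id", "chrom", "start", "end")]
  if (nrow(gn) == 0) {
    gn <- do.call(rbind, lapply(split(ex, ex$gene_id), function(d)
      data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
                 start = min(d$start), end = max(d$end))))
  }
  rownames(gn) <- rownames(ex) <- NULL
  gene_models(gn, ex)
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name, description (the collection kind), then member
#' IDs, tab-separated.
#'
#' @param sets \code{\link{gene_set_collection}}
#' @param path GMT path
#' @export
write_gmt <- function(sets, path) {
  kind <- attr(sets, "kind")
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, kind, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @param kind collection kind override; defaults to the description field of
#'   the first line when it is a known kind, else \code{"pathway"}
#' @return \code{\link{gene_set_collection}}
#' @export
read_gmt <- function(path, kind = NULL) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  if (is.null(kind)) {
    desc <- parts[[1]][2]
    kind <- if (desc %in% c("te_family", "l1_age", "region_stratified",
                            "pathway")) desc else "pathway"
  }
  gene_set_collection(sets, kind)
}

#' Write / read a trait map
#'
#' Long-format TSV with columns \code{snv_id}, \code{category}; universe
#' SNVs without any trait mapping are written with an empty category so the
#' universe round-trips.
#'
#' @param tm \code{\link{trait_map}}
#' @param path TSV path
#' @export
write_trait_map_tsv <- function(tm, path) {
  stopifnot(inherits(tm, "trait_map"))
  unmapped <- setdiff(tm$universe, tm$mapping$snv_id)
  df <- rbind(tm$mapping,
              if (length(unmapped))
                data.frame(snv_id = unmapped, category = ""))
  .write_tsv(df, path)
  invisible(path)
}

#' @rdname write_trait_map_tsv
#' @return \code{\link{trait_map}}
#' @export
read_trait_map_tsv <- function(path) {
  df <- .read_tsv(path, colClasses = "character")
  df$category[is.na(df$category)] <- ""
  trait_map(df[df$category != "", , drop = FALSE], unique(df$snv_id))
}

#' Write an expression matrix with a provenance sidecar
#'
#' Values go to a TSV (feature_id, kind, samples); the state and provenance
#' metadata go to a JSON-lines sidecar \code{<path>.provenance.json}.
#'
#' @param e \code{\link{expression_matrix}}
#' @param path TSV path
#' @export
write_expression_tsv <- function(e, path) {
  stopifnot(inherits(e, "expression_matrix"))
  df <- data.frame(feature_id = rownames(e$values), kind = e$features$kind,
                   e$values, check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
  prov <- c(list(state = e$state), e$provenance)
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, digits = NA),
             paste0(path, ".provenance.json"))
  invisible(path)
}

#' Write a complete simulated cohort to disk
#'
#' Writes VCF + dosage TSV (and variant sidecar), SV TSV, count TSV, gene
#' GTF, TE annotation TSV, covariate TSV, TE-family GMT, a null trait-map
#' TSV over the SNV universe, and the ground-truth JSON. Re-reading the
#' files reproduces the in-memory objects.
#'
#' @param cohort \code{\link{simulate_cohort}} result
#' @param dir output directory (created if needed)
#' @return invisible named vector of paths
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    dosage = file.path(dir, "dosage.tsv"),
    sv = file.path(dir, "sv.tsv"),
    counts = file.path(dir, "counts.tsv"),
    gtf = file.path(dir, "genes.gtf"),
    te = file.path(dir, "te_annotation.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    gmt = file.path(dir, "te_family_sets.gmt"),
    trait_map = file.path(dir, "trait_map.tsv"),
    truth = file.path(dir, "truth.json"))
  write_vcf(cohort$genotypes, paths["vcf"])
  write_dosage_tsv(cohort$genotypes, paths["dosage"])
  write_sv_tsv(cohort$svs, paths["sv"])
  write_counts_tsv(cohort$counts, paths["counts"])
  write_gene_models_gtf(cohort$genes, paths["gtf"])
  write_te_annotation_tsv(cohort$te, paths["te"])
  write_covariates_tsv(cohort$covariates, paths["covariates"])
  write_gmt(build_te_family_sets(cohort$te), paths["gmt"])
  write_trait_map_tsv(trait_map(data.frame(snv_id = character(0),
                                           category = character(0)),
                                cohort$genotypes$variants$id),
                      paths["trait_map"])
  writeLines(jsonlite::toJSON(list(seed = cohort$seed,
                                   trios = cohort$truth$trios),
                              auto_unbox = TRUE, digits = NA),
             paths["truth"])
  invisible(paths)
}
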