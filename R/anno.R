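## Gene / TE coordinate handling: genomic-context stratification of TE loci,
## subfamily aggregation, TE gene sets, and L1 density near SNVs.
## Intervals are GTF-style 1-based inclusive throughout.

#' Gene models container
#'
#' @param genes data.frame with \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive)
#' @param exons data.frame with \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end}; every exon must lie within its gene span
#' @return object of class \code{gene_models}
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)),
            all(c("gene_id", "chrom", "start", "end") %in% names(exons)),
            all(genes$start <= genes$end))
  m <- match(exons$gene_id, genes$gene_id)
  if (anyNA(m)) stop("exon references unknown gene")
  if (any(exons$start < genes$start[m] | exons$end > genes$end[m]))
    stop("exon outside its gene span")
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

.genes_gr <- function(gm) {
  GenomicRanges::GRanges(gm$genes$chrom,
                         IRanges::IRanges(gm$genes$start, gm$genes$end))
}

.exons_gr <- function(gm) {
  GenomicRanges::GRanges(gm$exons$chrom,
                         IRanges::IRanges(gm$exons$start, gm$exons$end))
}

#' Classify TE loci by genomic context
#'
#' Assigns each TE locus exactly one region label with precedence
#' exonic > intronic > nearby_intergenic > distal_intergenic:
#' \emph{exonic} if it overlaps any annotated exon by at least 1 bp,
#' \emph{intronic} if it overlaps a gene body but no exon,
#' \emph{nearby_intergenic} if its nearest gene-boundary distance is at most
#' \code{near_bp} (5 kb default), else \emph{distal_intergenic}. Distance is
#' measured between nearest edges, strand-ignored.
#'
#' @param te data.frame of TE loci with \code{chrom}, \code{start}, \code{end}
#' @param genes a \code{\link{gene_models}} object
#' @param near_bp nearby-intergenic distance cutoff (default 5000)
#' @return character vector of region labels, one per locus
#' @export
classify_te_locus_region <- function(te, genes, near_bp = 5000) {
  stopifnot(all(c("chrom", "start", "end") %in% names(te)))
  n <- nrow(te)
  if (n == 0) return(character(0))
  if (nrow(genes$genes) == 0) return(rep("distal_intergenic", n))
  lev <- unique(c(te$chrom, genes$genes$chrom, genes$exons$chrom))
  te_gr <- GenomicRanges::GRanges(factor(te$chrom, lev),
                                  IRanges::IRanges(te$start, te$end))
  ex_gr <- GenomicRanges::GRanges(factor(genes$exons$chrom, lev),
                                  IRanges::IRanges(genes$exons$start,
                                                   genes$exons$end))
  gn_gr <- GenomicRanges::GRanges(factor(genes$genes$chrom, lev),
                                  IRanges::IRanges(genes$genes$start,
                                                   genes$genes$end))
  exonic <- GenomicRanges::countOverlaps(te_gr, ex_gr) > 0
  genic <- GenomicRanges::countOverlaps(te_gr, gn_gr) > 0
  out <- rep("distal_intergenic", n)
  rest <- which(!genic)
  if (length(rest)) {
    g <- genes$genes
    d <- vapply(rest, function(i) {
      same <- g$chrom == te$chrom[i]
      if (!any(same)) return(Inf)
      min(pmax(0, g$start[same] - te$end[i], te$start[i] - g$end[same]))
    }, numeric(1))
    out[rest[d <= near_bp]] <- "nearby_intergenic"
  }
  out[genic] <- "intronic"
  out[exonic] <- "exonic"
  out
}

#' Aggregate TE locus counts to subfamily level
#'
#' Sums locus-level counts within each subfamily per sample. With
#' \code{by_region = TRUE} the output features are
#' \code{subfamily:region} pairs, whose per-sample regional totals partition
#' the unstratified subfamily totals exactly.
#'
#' @param loci a \code{\link{count_matrix}} whose rows are \code{te_locus}
#'   features
#' @param annotation data.frame with \code{locus_id}, \code{subfamily} and
#'   (for \code{by_region}) \code{region}
#' @param by_region stratify by genomic-context label?
#' @return \code{count_matrix} of \code{te_subfamily} rows (library sizes
#'   inherited from \code{loci})
#' @export
aggregate_te_counts <- function(loci, annotation, by_region = FALSE) {
  stopifnot(inherits(loci, "count_matrix"))
  ids <- rownames(loci$counts)
  m <- match(ids, annotation$locus_id)
  if (anyNA(m))
    stop("unannotated TE locus: ", paste(ids[is.na(m)], collapse = ", "))
  grp <- if (by_region) {
    if (is.null(annotation$region) || anyNA(annotation$region[m]))
      stop("region labels required for by_region aggregation")
    paste(annotation$subfamily[m], annotation$region[m], sep = ":")
  } else annotation$subfamily[m]
  agg <- rowsum(loci$counts, grp)
  count_matrix(agg, "te_subfamily", loci$library_size)
}

#' Gene-set collection
#'
#' @param sets named list of character vectors (feature IDs); empty sets are
#'   dropped
#' @param kind one of \code{te_family}, \code{l1_age}, \code{region_stratified},
#'   \code{pathway}
#' @return object of class \code{gene_set_collection}
#' @export
gene_set_collection <- function(sets, kind) {
  kind <- match.arg(kind,
                    c("te_family", "l1_age", "region_stratified", "pathway"))
  sets <- lapply(sets, unique)
  sets <- sets[vapply(sets, length, integer(1)) > 0]
  structure(sets, class = "gene_set_collection", kind = kind)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection [%s]: %d sets (sizes %s)\n",
              attr(x, "kind"), length(x),
              paste(range(vapply(x, length, integer(1))), collapse = "-")))
  invisible(x)
}

#' Build TE family gene sets
#'
#' One set per TE family containing its subfamily IDs (families with a single
#' subfamily are retained), using the family designations from the TE
#' annotation.
#'
#' @param annotation data.frame with \code{subfamily} and \code{family}
#' @return \code{\link{gene_set_collection}} of kind \code{te_family}
#' @export
build_te_family_sets <- function(annotation) {
  stopifnot(all(c("subfamily", "family") %in% names(annotation)))
  u <- unique(annotation[, c("subfamily", "family")])
  gene_set_collection(split(u$subfamily, u$family), "te_family")
}

#' Build evolutionary-age L1 gene sets
#'
#' Partitions L1 subfamily names into three age strata: \code{L1PA_young}
#' (prefix \code{L1PA}, plus \code{L1HS}, the youngest human subfamily),
#' \code{L1P_intermediate} (prefix \code{L1P} excluding \code{L1PA}) and
#' \code{L1M_old} (prefix \code{L1M}). Names matching no rule fall into an
#' \code{unclassified} bucket with a warning.
#'
#' @param l1_subfamilies character vector of L1 subfamily names
#' @return \code{\link{gene_set_collection}} of kind \code{l1_age}
#' @export
build_l1_age_sets <- function(l1_subfamilies) {
  stopifnot(all(startsWith(l1_subfamilies, "L1")))
  x <- unique(l1_subfamilies)
  young <- grepl("^L1PA", x) | x == "L1HS"
  old <- !young & grepl("^L1M", x)
  inter <- !young & !old & grepl("^L1P", x)
  other <- !(young | old | inter)
  if (any(other))
    warning("unclassified L1 subfamilies: ", paste(x[other], collapse = ", "))
  sets <- list(L1PA_young = x[young], L1P_intermediate = x[inter],
               L1M_old = x[old], unclassified = x[other])
  gene_set_collection(sets, "l1_age")
}

#' L1 fragment density around SNVs
#'
#' Counts L1-family TE loci overlapping the window \code{[pos - flank_bp,
#' pos + flank_bp]} around each SNV (5 kb on either side by default).
#'
#' @param snvs data.frame with \code{id}, \code{chrom}, \code{pos}
#' @param annotation TE locus data.frame with \code{chrom}, \code{start},
#'   \code{end}, \code{family}; restricted to \code{family == "L1"} internally
#' @param flank_bp one-sided flank (default 5000)
#' @return named integer vector of per-SNV L1 counts
#' @export
l1_density_near_snvs <- function(snvs, annotation, flank_bp = 5000) {
  stopifnot(all(c("id", "chrom", "pos") %in% names(snvs)))
  l1 <- annotation[annotation$family == "L1", , drop = FALSE]
  lev <- unique(c(snvs$chrom, l1$chrom))
  win <- GenomicRanges::GRanges(
    factor(snvs$chrom, lev),
    IRanges::IRanges(pmax(1, snvs$pos - flank_bp), snvs$pos + flank_bp))
  if (nrow(l1) == 0)
    return(stats::setNames(integer(nrow(snvs)), snvs$id))
  l1_gr <- GenomicRanges::GRanges(factor(l1$chrom, lev),
                                  IRanges::IRanges(l1$start, l1$end))
  stats::setNames(GenomicRanges::countOverlaps(win, l1_gr), snvs$id)
}

#' Compare L1 density at index SNVs against background SNVs
#'
#' Two-sample (rank-sum) Wilcoxon comparison of per-SNV L1 fragment counts
#' between an index set and a background set (e.g. 1000 random SNVs).
#'
#' @param index_counts,background_counts integer vectors from
#'   \code{\link{l1_density_near_snvs}}
#' @return list with \code{p} (two-sided rank-sum p), \code{median_index},
#'   \code{median_background}
#' @export
l1_density_test <- function(index_counts, background_counts) {
  if (length(background_counts) == 0) stop("empty background set")
  p <- suppressWarnings(
    stats::wilcox.test(index_counts, background_counts)$p.value)
  list(p = p,
       median_index = stats::median(index_counts),
       median_background = stats::median(background_counts))
}
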