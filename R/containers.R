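#' Construct a genotype matrix
#'
#' Bundles a complete sample-by-variant additive dosage matrix (counts of the
#' ALT allele, values 0/1/2) with per-variant metadata. Missing genotypes are
#' rejected unless \code{impute_mean = TRUE}, in which case missing entries are
#' replaced by the variant mean dosage (rounded to the nearest integer); the
#' default mirrors a complete-sites-only filter.
#'
#' @param dosage integer matrix, samples in rows, variants in columns; values
#'   in \{0, 1, 2\}. Row names are sample IDs, column names variant IDs.
#' @param variants data.frame with columns \code{id}, \code{chrom}, \code{pos}
#'   (1-based), \code{ref}, \code{alt}; optional \code{maf}, \code{hwe_p}.
#'   Row order must match the dosage columns.
#' @param impute_mean replace missing dosages with the variant mean? Default
#'   \code{FALSE} (missing data is an error).
#' @return object of class \code{genotype_matrix}: list with elements
#'   \code{dosage} and \code{variants}.
#' @export
genotype_matrix <- function(dosage, variants, impute_mean = FALSE) {
  dosage <- as.matrix(dosage)
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants)),
            ncol(dosage) == nrow(variants))
  if (anyNA(dosage)) {
    if (!impute_mean)
      stop("missing genotypes present; sites must be complete (or set impute_mean = TRUE)")
    for (j in which(colSums(is.na(dosage)) > 0L)) {
      mu <- mean(dosage[, j], na.rm = TRUE)
      dosage[is.na(dosage[, j]), j] <- as.integer(round(mu))
    }
  }
  if (!all(dosage %in% 0:2))
    stop("dosages must be additive 0/1/2 counts of the ALT allele")
  storage.mode(dosage) <- "integer"
  if (any(variants$pos < 1L)) stop("positions are 1-based; pos >= 1 required")
  colnames(dosage) <- variants$id
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  variants$maf <- if (is.null(variants$maf)) NA_real_
                  else as.numeric(variants$maf)
  variants$hwe_p <- if (is.null(variants$hwe_p)) NA_real_
                    else as.numeric(variants$hwe_p)
  rownames(variants) <- NULL
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              nrow(x$dosage), ncol(x$dosage)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$variants$chrom), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Sample IDs of a container
#' @param x a \code{genotype_matrix}, \code{count_matrix} or
#'   \code{expression_matrix}
#' @return character vector of sample IDs
#' @export
samples <- function(x) {
  if (inherits(x, "genotype_matrix")) rownames(x$dosage)
  else if (inherits(x, "count_matrix")) colnames(x$counts)
  else if (inherits(x, "expression_matrix")) colnames(x$values)
  else stop("unsupported class")
}

#' Construct a count matrix
#'
#' Feature-by-sample nonnegative integer read counts. Each feature carries a
#' kind: \code{gene}, \code{te_subfamily}, \code{te_locus} or \code{viral}.
#' Library sizes are the column sums at load time and are carried along so
#' that CPM thresholds stay anchored to the original sequencing depth even
#' after features are dropped.
#'
#' @param counts numeric matrix, features in rows, samples in columns
#' @param kind character vector, one entry per feature
#' @param library_size per-sample totals; defaults to \code{colSums(counts)}
#' @return object of class \code{count_matrix}
#' @export
count_matrix <- function(counts, kind, library_size = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  kind <- rep_len(as.character(kind), nrow(counts))
  bad <- setdiff(unique(kind), c("gene", "te_subfamily", "te_locus", "viral"))
  if (length(bad)) stop("unknown feature kind: ", paste(bad, collapse = ", "))
  if (nrow(counts) > 0 && is.null(rownames(counts)))
    stop("counts must have feature IDs as row names")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  if (is.null(library_size)) library_size <- colSums(counts)
  structure(list(counts = counts,
                 features = data.frame(id = rownames(counts), kind = kind,
                                       stringsAsFactors = FALSE),
                 library_size = library_size),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  tab <- table(x$features$kind)
  cat(sprintf("count_matrix: %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Construct an expression matrix
#'
#' Real-valued feature-by-sample expression in one of three forward-only
#' states: \code{transformed} (variance-stabilized), \code{residualized}
#' (covariates regressed out) or \code{inverse_normal} (rank-based normal
#' scores). State transitions are enforced by the preparation functions.
#'
#' @param values numeric matrix, features x samples, with dimnames
#' @param kind per-feature kind (as in \code{\link{count_matrix}})
#' @param state one of \code{"transformed"}, \code{"residualized"},
#'   \code{"inverse_normal"}
#' @param provenance named list describing how the values were produced
#' @return object of class \code{expression_matrix}
#' @export
expression_matrix <- function(values, kind, state, provenance = list()) {
  values <- as.matrix(values)
  state <- match.arg(state, c("transformed", "residualized", "inverse_normal"))
  if (is.null(rownames(values))) stop("values must have feature IDs as row names")
  kind <- rep_len(as.character(kind), nrow(values))
  structure(list(values = values,
                 features = data.frame(id = rownames(values), kind = kind,
                                       stringsAsFactors = FALSE),
                 state = state,
                 provenance = provenance),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d features x %d samples\n",
              x$state, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by feature kind
#' @param e expression_matrix
#' @param kind kinds to keep
#' @return expression_matrix restricted to the requested kinds
#' @export
subset_kind <- function(e, kind) {
  stopifnot(inherits(e, "expression_matrix"))
  keep <- e$features$kind %in% kind
  expression_matrix(e$values[keep, , drop = FALSE], e$features$kind[keep],
                    e$state, e$provenance)
}
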