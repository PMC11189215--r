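## Trait-category enrichment of hit SNV sets against random equal-size SNV
## combinations, via per-category empirical cumulative distributions.

#' Trait-map container
#'
#' Maps SNVs to trait categories (e.g. 14 age-related disease categories)
#' within a defined universe of scannable SNVs. Built from a long-format
#' table; SNVs in the universe without any category simply map to none.
#'
#' @param mapping data.frame with columns \code{snv_id}, \code{category}
#' @param universe character vector of all scannable SNV IDs; must contain
#'   every mapped SNV
#' @return object of class \code{trait_map}
#' @export
trait_map <- function(mapping, universe) {
  stopifnot(all(c("snv_id", "category") %in% names(mapping)))
  extra <- setdiff(mapping$snv_id, universe)
  if (length(extra))
    stop("mapped SNV(s) outside universe: ", paste(extra, collapse = ", "))
  mapping <- unique(mapping[, c("snv_id", "category")])
  structure(list(mapping = mapping, universe = unique(universe),
                 categories = sort(unique(mapping$category))),
            class = "trait_map")
}

#' @export
print.trait_map <- function(x, ...) {
  cat(sprintf("trait_map: %d SNVs mapped to %d categories (universe %d)\n",
              length(unique(x$mapping$snv_id)), length(x$categories),
              length(x$universe)))
  invisible(x)
}

#' Count SNVs mapping to each trait category
#'
#' @param snvs character vector of SNV IDs (must lie in the universe)
#' @param tm a \code{\link{trait_map}}
#' @return named integer vector, one count per category in the map (an SNV
#'   with several categories counts once in each)
#' @export
count_category_mappings <- function(snvs, tm) {
  stopifnot(inherits(tm, "trait_map"))
  out <- setdiff(snvs, tm$universe)
  if (length(out))
    stop("SNV(s) outside universe: ", paste(out, collapse = ", "))
  hit <- tm$mapping[tm$mapping$snv_id %in% snvs, , drop = FALSE]
  counts <- table(factor(hit$category, levels = tm$categories))
  stats::setNames(as.integer(counts), tm$categories)
}

#' Trait-category enrichment against random SNV combinations
#'
#' Draws \code{n_combos} random SNV sets of the same size as the observed set
#' from the universe (without replacement within each set), builds the
#' empirical cumulative distribution of per-category mapping counts, and
#' reports for each category the literal enrichment p
#' \code{1 - ecdf(observed)}, a conservative add-one alternative
#' \code{(1 + #\{random >= observed\}) / (1 + n_combos)}, the enrichment score
#' \code{ES = observed / median(random)}, BH FDR over categories, and the
#' significance call \code{ES > 1 & FDR < 0.05}.
#'
#' @param observed character vector of hit SNV IDs
#' @param tm a \code{\link{trait_map}}
#' @param n_combos number of random combinations (default 500; >= 10)
#' @param seed integer seed
#' @return data.frame: \code{category}, \code{observed_count},
#'   \code{median_random}, \code{es}, \code{p_ecdf}, \code{p_conservative},
#'   \code{fdr}, \code{significant}
#' @export
category_enrichment <- function(observed, tm, n_combos = 500, seed = 1L) {
  stopifnot(inherits(tm, "trait_map"), n_combos >= 10)
  observed <- unique(observed)
  if (length(observed) > length(tm$universe))
    stop("observed set larger than universe")
  obs_counts <- count_category_mappings(observed, tm)
  set.seed(seed)
  rand <- matrix(0L, n_combos, length(tm$categories),
                 dimnames = list(NULL, tm$categories))
  for (b in seq_len(n_combos)) {
    draw <- sample(tm$universe, length(observed))
    rand[b, ] <- count_category_mappings(draw, tm)
  }
  med <- apply(rand, 2, stats::median)
  p_ecdf <- vapply(seq_along(tm$categories), function(j) {
    1 - stats::ecdf(rand[, j])(obs_counts[j])
  }, numeric(1))
  p_cons <- vapply(seq_along(tm$categories), function(j) {
    (1 + sum(rand[, j] >= obs_counts[j])) / (1 + n_combos)
  }, numeric(1))
  es <- ifelse(med > 0, obs_counts / med,
               ifelse(obs_counts > 0, Inf, NA_real_))
  # the literal ecdf formula can return exactly 0; BH is computed on the
  # conservative add-one p so the adjustment stays well defined
  fdr <- bh_fdr(p_cons)
  data.frame(category = tm$categories,
             observed_count = unname(obs_counts),
             median_random = unname(med),
             es = unname(es),
             p_ecdf = p_ecdf,
             p_conservative = p_cons,
             fdr = fdr,
             significant = !is.na(es) & es > 1 & fdr < 0.05,
             row.names = NULL, stringsAsFactors = FALSE)
}
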