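## Synthetic cohort generator: population-structured LD-blocked genotypes,
## gene/TE annotations spanning all four genomic strata, covariates, and
## negative-binomial counts with planted cis, trans and mediated effects,
## plus a ground-truth table for recovery testing.

#' Simulation configuration
#'
#' Defaults describe the reference synthetic cohort used throughout the
#' package's validation: 200 samples from 2 Balding-Nichols populations
#' (Fst 0.1), 2,000 LD-blocked SNVs on 2 chromosomes, 200 genes, 400 TE loci
#' (100 per genomic stratum) in 20 subfamilies across 7 TE families, and 3
#' planted mediated SNV-gene-TE trios with a = b = 0.6 and no direct effect.
#'
#' @param n_samples samples (default 200)
#' @param n_populations populations (default 2)
#' @param fst Balding-Nichols divergence in [0, 1) (default 0.1)
#' @param n_chrom autosomes (default 2)
#' @param chrom_length chromosome length in bp (default 5e7)
#' @param n_snvs SNVs in total (default 2000)
#' @param ld_block_size SNVs per LD block (default 10)
#' @param ld_rho within-block haplotype copy probability (default 0.8)
#' @param n_genes genes (default 200)
#' @param n_te_loci named vector of loci per region stratum (default 100 each
#'   of intronic, nearby_intergenic, distal_intergenic, exonic)
#' @param n_subfamilies TE subfamilies to use, up to the 20 built-in
#'   subfamily/family labels (default 20)
#' @param nb_dispersion negative-binomial dispersion (default 0.05)
#' @param library_size_range uniform range of library sizes (default 1e6-2e6)
#' @param n_planted_trios planted mediated trios (default 3)
#' @param planted_a,planted_b,planted_c_direct planted effect sizes on the
#'   latent log scale (defaults 0.6, 0.6, 0)
#' @param batch_effect,sex_effect,viral_effect covariate loading SDs on the
#'   latent log scale (defaults 0.3, 0.2, 0.2)
#' @param n_svs structural variants (default 40)
#' @return list of class \code{sim_config}
#' @export
sim_config <- function(n_samples = 200, n_populations = 2, fst = 0.1,
                       n_chrom = 2, chrom_length = 5e7, n_snvs = 2000,
                       ld_block_size = 10, ld_rho = 0.8,
                       n_genes = 200,
                       n_te_loci = c(intronic = 100, nearby_intergenic = 100,
                                     distal_intergenic = 100, exonic = 100),
                       nb_dispersion = 0.05,
                       library_size_range = c(1e6, 2e6),
                       n_subfamilies = 20,
                       n_planted_trios = 3, planted_a = 0.6, planted_b = 0.6,
                       planted_c_direct = 0,
                       batch_effect = 0.3, sex_effect = 0.2,
                       viral_effect = 0.2, n_svs = 40) {
  stopifnot(n_samples > 0, n_populations > 0, fst >= 0, fst < 1,
            ld_rho >= 0, ld_rho < 1, nb_dispersion > 0,
            all(n_te_loci >= 0), n_planted_trios >= 0)
  structure(as.list(environment()), class = "sim_config")
}

# the 20 default TE subfamilies with family and (for L1) age-informative names
.default_subfamilies <- function(n_subfamilies = 20) {
  tab <- data.frame(
    subfamily = c("L1HS", "L1PA2", "L1PA3", "L1P1", "L1P4a", "L1MEb",
                  "L1M5", "L1MA4", "AluY", "AluSx", "AluJb", "HERVH-int",
                  "MER41B", "MLT1B", "THE1C", "MER5A", "Charlie1",
                  "Tigger1", "MIR", "MIRb"),
    family = c(rep("L1", 8), rep("Alu", 3), rep("ERV1", 2),
               rep("ERVL-MaLR", 2), rep("hAT-Charlie", 2), "TcMar-Tigger",
               rep("MIR", 2)),
    te_class = c(rep("LINE", 8), rep("SINE", 3), rep("LTR", 4),
                 rep("DNA", 3), rep("SINE", 2)),
    stringsAsFactors = FALSE)
  tab[seq_len(min(n_subfamilies, nrow(tab))), ]
}

#' Simulate population-structured genotypes
#'
#' Ancestral allele frequencies are Uniform(0.05, 0.5); each population's
#' frequencies follow the Balding-Nichols Beta(p(1-F)/F, (1-p)(1-F)/F)
#' model. Linkage disequilibrium is induced by block-copying: within an LD
#' block each SNV's haplotype allele copies the previous SNV's with
#' probability \code{ld_rho}, else is drawn fresh. Genotypes are the sum of
#' two haplotypes. Structural variants are generated analogously
#' (unstructured) with L1/Alu insertion/deletion class labels.
#'
#' @param cfg a \code{\link{sim_config}}
#' @param seed integer seed
#' @return list: \code{genotypes} (\code{\link{genotype_matrix}}),
#'   \code{svs} (\code{\link{sv_set}}), \code{sample_info} (sample,
#'   population), \code{ancestral_freq}
#' @export
simulate_genotypes <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  n <- cfg$n_samples
  m <- cfg$n_snvs
  pops <- rep_len(paste0("POP", seq_len(cfg$n_populations)), n)
  sample_ids <- sprintf("S%03d", seq_len(n))
  p0 <- stats::runif(m, 0.05, 0.5)
  pf <- matrix(p0, cfg$n_populations, m, byrow = TRUE)
  if (cfg$fst > 0 && cfg$n_populations > 1) {
    F <- cfg$fst
    for (k in seq_len(cfg$n_populations))
      pf[k, ] <- stats::rbeta(m, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
    # keep sites segregating so QC retains most of the panel
    pf <- pmin(pmax(pf, 0.01), 0.99)
  }
  per_chrom <- diff(round(seq(0, m, length.out = cfg$n_chrom + 1)))
  chrom <- rep(paste0("chr", seq_len(cfg$n_chrom)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(k)
    sort(sample.int(cfg$chrom_length - 1000, k))), use.names = FALSE)
  block_start <- unlist(lapply(per_chrom, function(k) {
    s <- rep(FALSE, k); s[seq(1, k, by = cfg$ld_block_size)] <- TRUE; s
  }), use.names = FALSE)
  pop_idx <- match(pops, paste0("POP", seq_len(cfg$n_populations)))
  make_hap <- function() {
    H <- matrix(0L, n, m)
    fresh <- matrix(stats::rbinom(n * m, 1L, pf[pop_idx, ]), n, m)
    copy <- matrix(stats::rbinom(n * m, 1L, cfg$ld_rho), n, m)
    copy[, block_start] <- 0L
    H[, 1] <- fresh[, 1]
    for (j in 2:m) H[, j] <- ifelse(copy[, j] == 1L, H[, j - 1], fresh[, j])
    H
  }
  dosage <- make_hap() + make_hap()
  rownames(dosage) <- sample_ids
  variants <- data.frame(id = sprintf("snv%05d", seq_len(m)),
                         chrom = chrom, pos = pos,
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  g <- genotype_matrix(dosage, variants)
  sv_class <- rep(c("L1_insertion", "L1_deletion", "Alu_insertion",
                    "Alu_deletion", "other"), length.out = cfg$n_svs)
  sv_freq <- stats::runif(cfg$n_svs, 0.05, 0.5)
  sv_dos <- matrix(stats::rbinom(n * cfg$n_svs, 2L,
                                 rep(sv_freq, each = n)), n, cfg$n_svs)
  rownames(sv_dos) <- sample_ids
  colnames(sv_dos) <- sprintf("sv%03d", seq_len(cfg$n_svs))
  list(genotypes = g, svs = sv_set(sv_dos, sv_class),
       sample_info = data.frame(sample = sample_ids, population = pops,
                                stringsAsFactors = FALSE),
       ancestral_freq = p0)
}

#' Simulate gene models and TE locus annotations
#'
#' Places non-overlapping genes (1-5 exons each) along each chromosome, then
#' places TE loci so that each requested genomic stratum (exonic, intronic,
#' nearby-intergenic at <= 5 kb, distal-intergenic at > 5 kb) is realized
#' exactly; the placement is verified by a
#' \code{\link{classify_te_locus_region}} round trip and fails loudly if any
#' stratum cannot be realized.
#'
#' @param cfg a \code{\link{sim_config}}
#' @param seed integer seed
#' @return list: \code{genes} (\code{\link{gene_models}}), \code{te}
#'   (TE locus data.frame with subfamily, family, te_class, region)
#' @export
simulate_annotations <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed + 1000L)
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chrom + 1)))
  genes <- list(); exons <- list()
  gi <- 0
  for (ci in seq_along(chroms)) {
    # genes occupy the first ~60% of the chromosome; the tail is reserved
    # for distal-intergenic TE placement
    cursor <- 50000
    limit <- 0.6 * cfg$chrom_length
    for (k in seq_len(per_chrom[ci])) {
      gi <- gi + 1
      glen <- round(stats::runif(1, 20000, 60000))
      if (cursor + glen > limit)
        stop("infeasible gene placement; increase chrom_length")
      gid <- sprintf("gene%04d", gi)
      gstart <- cursor
      gend <- gstart + glen - 1
      n_ex <- sample(1:5, 1)
      # exons at the gene's 5' end, each 1-2 kb with 2-4 kb introns between,
      # leaving the 3' half exon-free so intronic TEs always fit
      ex_cursor <- gstart
      ex_limit <- gstart + glen / 2 - 3000
      for (e in seq_len(n_ex)) {
        elen <- round(stats::runif(1, 1000, 2000))
        if (ex_cursor + elen - 1 >= ex_limit) break
        exons[[length(exons) + 1]] <-
          data.frame(gene_id = gid, chrom = chroms[ci],
                     start = ex_cursor, end = ex_cursor + elen - 1)
        ex_cursor <- ex_cursor + elen + round(stats::runif(1, 2000, 4000))
      }
      genes[[gi]] <- data.frame(gene_id = gid, chrom = chroms[ci],
                                start = gstart, end = gend)
      cursor <- gend + round(stats::runif(1, 25000, 50000))
    }
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)
  gm <- gene_models(genes, exons)

  strata <- cfg$n_te_loci
  subfam <- .default_subfamilies(cfg$n_subfamilies)
  te_rows <- list()
  place_in_stratum <- function(stratum, count) {
    out <- vector("list", count)
    for (i in seq_len(count)) {
      gene_row <- genes[1 + (i - 1) %% nrow(genes), ]
      if (stratum == "exonic") {
        ex <- exons[exons$gene_id == gene_row$gene_id, ][1, ]
        s <- ex$start + 100
        e <- min(s + 300, ex$end)
      } else if (stratum == "intronic") {
        # 3' half of the gene body is exon-free by construction
        s <- round((gene_row$start + gene_row$end) / 2) + 3000 + (i %% 40) * 100
        e <- s + 400
      } else if (stratum == "nearby_intergenic") {
        s <- gene_row$end + 500 + (i %% 8) * 500   # <= 5 kb from gene end
        e <- s + 300
      } else {                                     # distal_intergenic
        base <- 0.7 * cfg$chrom_length
        s <- round(base) + i * 10000
        e <- s + 500
        gene_row$chrom <- chroms[1 + (i - 1) %% length(chroms)]
      }
      out[[i]] <- data.frame(chrom = gene_row$chrom, start = s, end = e,
                             requested = stratum)
    }
    do.call(rbind, out)
  }
  for (st in names(strata))
    if (strata[[st]] > 0) te_rows[[st]] <- place_in_stratum(st, strata[[st]])
  te <- do.call(rbind, te_rows)
  rownames(te) <- NULL
  te$locus_id <- sprintf("te_locus%04d", seq_len(nrow(te)))
  # balanced subfamily assignment, shuffled so every subfamily spans strata
  sfi <- sample(rep_len(seq_len(nrow(subfam)), nrow(te)))
  te$subfamily <- subfam$subfamily[sfi]
  te$family <- subfam$family[sfi]
  te$te_class <- subfam$te_class[sfi]
  te$region <- classify_te_locus_region(te, gm)
  bad <- te$region != te$requested
  if (any(bad))
    stop(sprintf("infeasible TE placement: %d locus/loci misclassified (%s)",
                 sum(bad),
                 paste(utils::head(te$locus_id[bad]), collapse = ", ")))
  te$requested <- NULL
  list(genes = gm, te = te[, c("locus_id", "chrom", "start", "end",
                               "subfamily", "family", "te_class", "region")])
}

#' Simulate gene, TE-locus and viral counts with planted effects
#'
#' Latent per-gene log-means are baseline + a * dosage (for planted cis
#' effects) + covariate loadings; each TE locus adds b * (centered latent
#' value of its subfamily's planted mediator gene) + c_direct * dosage +
#' covariate loadings, so subfamily-level trans effects are distributed
#' across that subfamily's loci and the true indirect effect on the latent
#' scale is exactly a * b. Counts are negative binomial with the configured
#' dispersion, scaled by each sample's library-size factor. One viral
#' expression feature (EBV-like) is generated with its own loadings.
#'
#' @param cfg a \code{\link{sim_config}}
#' @param geno result of \code{\link{simulate_genotypes}}
#' @param anno result of \code{\link{simulate_annotations}}
#' @param seed integer seed
#' @return list: \code{counts} (\code{\link{count_matrix}} of gene + te_locus
#'   + viral rows), \code{covariates} (data.frame: lab, population, sex),
#'   \code{truth} (planted trios with a, b, c_direct; per-feature covariate
#'   loadings)
#' @export
simulate_counts <- function(cfg, geno, anno, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed + 2000L)
  g <- geno$genotypes
  n <- nrow(g$dosage)
  genes <- anno$genes$genes
  te <- anno$te
  lab <- sample(c("lab1", "lab2"), n, replace = TRUE)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  lib <- stats::runif(n, cfg$library_size_range[1], cfg$library_size_range[2])
  libf <- lib / mean(lib)
  labv <- as.numeric(lab == "lab2")
  sexv <- as.numeric(sex == "male")

  # choose planted trios: distinct genes, an SNV within the cis window of
  # each, and distinct TE subfamilies
  n_tr <- cfg$n_planted_trios
  truth_trios <- data.frame(snv_id = character(0), gene_id = character(0),
                            te_subfamily = character(0), a = numeric(0),
                            b = numeric(0), c_direct = numeric(0))
  if (n_tr > 0) {
    subfams <- unique(te$subfamily)
    pick_sub <- sample(subfams, n_tr)
    # genes are only eligible if a common SNV sits within the cis window
    gene_pool <- sample(genes$gene_id)
    pick_gene <- character(n_tr); pick_snv <- character(n_tr)
    k <- 0
    for (gid in gene_pool) {
      if (k == n_tr) break
      gr <- genes[genes$gene_id == gid, ]
      cand <- which(g$variants$chrom == gr$chrom &
                      g$variants$pos >= gr$start - 5e5 &
                      g$variants$pos <= gr$end + 5e5)
      cand <- cand[apply(g$dosage[, cand, drop = FALSE], 2,
                         .variant_maf) >= 0.1]
      if (length(cand) == 0) next
      k <- k + 1
      pick_gene[k] <- gid
      pick_snv[k] <- g$variants$id[cand[sample.int(length(cand), 1)]]
    }
    if (k < n_tr)
      stop("could not place all planted trios: no usable SNV near enough genes")
    truth_trios <- data.frame(snv_id = pick_snv, gene_id = pick_gene,
                              te_subfamily = pick_sub,
                              a = cfg$planted_a, b = cfg$planted_b,
                              c_direct = cfg$planted_c_direct,
                              stringsAsFactors = FALSE)
  }

  # viral (EBV-like) latent expression, with a lab loading
  viral_lat <- log(200) + 0.3 * labv + stats::rnorm(n, 0, 0.4)
  viral_centered <- viral_lat - mean(viral_lat)

  gene_load <- data.frame(
    feature = genes$gene_id,
    lab = stats::rnorm(nrow(genes), 0, cfg$batch_effect),
    sex = stats::rnorm(nrow(genes), 0, cfg$sex_effect),
    viral = stats::rnorm(nrow(genes), 0, cfg$viral_effect))
  gene_lat <- matrix(stats::runif(nrow(genes), log(50), log(500)),
                     nrow(genes), n)
  gene_lat <- gene_lat + outer(gene_load$lab, labv) +
    outer(gene_load$sex, sexv) + outer(gene_load$viral, viral_centered)
  rownames(gene_lat) <- genes$gene_id
  for (i in seq_len(nrow(truth_trios))) {
    dos <- g$dosage[, truth_trios$snv_id[i]]
    gene_lat[truth_trios$gene_id[i], ] <-
      gene_lat[truth_trios$gene_id[i], ] + truth_trios$a[i] * dos
  }

  te_load <- data.frame(
    feature = te$locus_id,
    lab = stats::rnorm(nrow(te), 0, cfg$batch_effect),
    sex = stats::rnorm(nrow(te), 0, cfg$sex_effect),
    viral = stats::rnorm(nrow(te), 0, cfg$viral_effect))
  te_lat <- matrix(stats::runif(nrow(te), log(20), log(200)), nrow(te), n)
  te_lat <- te_lat + outer(te_load$lab, labv) + outer(te_load$sex, sexv) +
    outer(te_load$viral, viral_centered)
  rownames(te_lat) <- te$locus_id
  for (i in seq_len(nrow(truth_trios))) {
    rows <- which(te$subfamily == truth_trios$te_subfamily[i])
    glat <- gene_lat[truth_trios$gene_id[i], ]
    add <- truth_trios$b[i] * (glat - mean(glat)) +
      truth_trios$c_direct[i] * g$dosage[, truth_trios$snv_id[i]]
    te_lat[rows, ] <- sweep(te_lat[rows, , drop = FALSE], 2, add, "+")
  }

  lat <- rbind(gene_lat, te_lat, EBV = viral_lat)
  mu <- sweep(exp(lat), 2, libf, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / cfg$nb_dispersion),
                   nrow(mu), ncol(mu), dimnames = list(rownames(mu),
                                                       rownames(g$dosage)))
  kind <- c(rep("gene", nrow(gene_lat)), rep("te_locus", nrow(te_lat)),
            "viral")
  cm <- count_matrix(counts, kind)
  covariates <- data.frame(lab = lab, population = geno$sample_info$population,
                           sex = sex, row.names = rownames(g$dosage),
                           stringsAsFactors = FALSE)
  list(counts = cm, covariates = covariates,
       truth = list(trios = truth_trios,
                    gene_loadings = gene_load, te_loadings = te_load))
}

#' Generate a complete synthetic cohort
#'
#' Runs \code{\link{simulate_genotypes}}, \code{\link{simulate_annotations}}
#' and \code{\link{simulate_counts}} under a single seed and assembles the
#' pieces a pipeline run needs.
#'
#' @param cfg a \code{\link{sim_config}} (default: reference cohort)
#' @param seed integer seed
#' @return list of class \code{sim_cohort}: \code{genotypes}, \code{svs},
#'   \code{counts}, \code{covariates}, \code{genes}, \code{te},
#'   \code{truth}, \code{config}, \code{seed}
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = 1L) {
  geno <- simulate_genotypes(cfg, seed)
  anno <- simulate_annotations(cfg, seed)
  cnt <- simulate_counts(cfg, geno, anno, seed)
  structure(list(genotypes = geno$genotypes, svs = geno$svs,
                 sample_info = geno$sample_info,
                 counts = cnt$counts, covariates = cnt$covariates,
                 genes = anno$genes, te = anno$te, truth = cnt$truth,
                 config = cfg, seed = seed),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "sim_cohort (seed %d): %d samples, %d SNVs, %d genes, %d TE loci, %d planted trios\n",
    x$seed, nrow(x$genotypes$dosage), ncol(x$genotypes$dosage),
    nrow(x$genes$genes), nrow(x$te), nrow(x$truth$trios)))
  invisible(x)
}
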