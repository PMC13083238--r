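#' Simulate a founder haplotype pool
#'
#' Draws per-site allele frequencies log-uniformly from the configured MAF
#' spectrum, assigns each site to a gene and a consequence class (with CADD /
#' PolyPhen-2 / SIFT surrogates for missense sites), and realizes
#' `2 * n_samples` founder haplotypes by independent Bernoulli draws. A
#' haplotype may carry several rare alleles of one gene; such multi-variant
#' haplotypes are permitted and detectable downstream.
#'
#' @param config A [sim_config()].
#' @return A list with `haps` (0/1 matrix, `2 n_samples x n_sites`), `sites`
#'   (tibble with gene assignment, consequence annotation and true MAF) and
#'   `config`.
#' @examples
#' pool <- simulate_haplotype_pool(sim_config(n_samples = 100, n_genes = 5, seed = 7))
#' dim(pool$haps)
#' @export
simulate_haplotype_pool <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_hap <- 2L * config$n_samples
  n_per_gene <- pmax(1L, stats::rpois(config$n_genes, config$variants_per_gene))
  gene_ids <- sprintf("GENE%04d", seq_len(config$n_genes))
  gene <- rep(gene_ids, n_per_gene)
  m <- length(gene)
  # log-uniform AF spectrum: rare variants dominate, as in exome data
  maf <- exp(runif(m, log(config$maf_lower), log(config$maf_upper)))
  cons_class <- sample(names(config$prop_consequence), m, replace = TRUE,
                       prob = config$prop_consequence)
  consequence <- c(plof_hc = "pLoF-HC", plof_lc = "pLoF-LC",
                   missense = "missense", synonymous = "synonymous")[cons_class]
  is_mis <- consequence == "missense"
  cadd <- ifelse(is_mis, runif(m, 0, 40), NA_real_)
  polyphen <- ifelse(is_mis, runif(m), NA_real_)
  sift_call <- ifelse(is_mis,
                      sample(c("deleterious", "tolerated"), m, replace = TRUE),
                      NA_character_)
  pos <- seq_len(m) * 100L
  sites <- tibble(
    variant_key = sprintf("1:%d:A:T", pos),
    chrom = "1", pos = pos, ref = "A", alt = "T",
    gene = gene, consequence = unname(consequence),
    cadd = cadd, polyphen = polyphen, sift_call = sift_call,
    true_maf = maf)
  haps <- matrix(rbinom(n_hap * m, 1L, rep(maf, each = n_hap)),
                 nrow = n_hap, ncol = m)
  list(haps = haps, sites = sites, config = config)
}

#' Simulate individuals with per-sample autozygosity
#'
#' Assigns each sample an inbreeding coefficient F from the two-point
#' consanguineous/background mixture, then builds its two haplotypes gene by
#' gene: with probability F the second haplotype of the gene is copied
#' identical-by-descent from the first, otherwise it is drawn independently
#' from the founder pool. This yields the classic autozygous homozygote excess
#' `q^2 + q (1 - q) F` at a site of frequency `q`, and depletes
#' compound-heterozygous (two distinct variants in trans) configurations as F
#' grows. True phase is stored in `truth`; the reported phase is initialized to
#' the truth with phasing probability 1 (see [inject_phase_noise()]).
#'
#' @param pool Result of [simulate_haplotype_pool()].
#' @param config A [sim_config()] (defaults to the pool's).
#' @return A [rare_cohort()] with `truth$f`, `truth$hap1`, `truth$hap2`,
#'   `truth$consanguineous`.
#' @export
simulate_individuals <- function(pool, config = pool$config) {
  stopifnot(is.list(pool), !is.null(pool$haps), nrow(pool$haps) > 0)
  set.seed(config$seed + 1L)
  n <- config$n_samples
  n_hap <- nrow(pool$haps)
  consang <- runif(n) < config$consanguinity_fraction
  f <- ifelse(consang, config$f_consang, config$f_background)
  genes <- unique(pool$sites$gene)
  m <- nrow(pool$sites)
  hap1 <- matrix(0L, n, m)
  hap2 <- matrix(0L, n, m)
  for (g in genes) {
    cols <- which(pool$sites$gene == g)
    i1 <- sample.int(n_hap, n, replace = TRUE)
    i2 <- sample.int(n_hap, n, replace = TRUE)
    ibd <- runif(n) < f
    i2[ibd] <- i1[ibd]
    hap1[, cols] <- pool$haps[i1, cols, drop = FALSE]
    hap2[, cols] <- pool$haps[i2, cols, drop = FALSE]
  }
  gt <- hap1 + hap2
  if (config$missing_rate > 0) {
    miss <- runif(length(gt)) < config$missing_rate
    gt[miss] <- NA_integer_
  }
  samples <- sprintf("S%05d", seq_len(n))
  pp <- matrix(NA_real_, n, m)
  pp[!is.na(gt) & gt == 1L] <- 1
  r_hap1 <- hap1; r_hap2 <- hap2
  r_hap1[is.na(gt)] <- NA_integer_; r_hap2[is.na(gt)] <- NA_integer_
  rare_cohort(samples, pool$sites, gt, hap1 = r_hap1, hap2 = r_hap2, pp = pp,
              truth = list(f = setNames(f, samples),
                           consanguineous = setNames(consang, samples),
                           hap1 = hap1, hap2 = hap2,
                           maf = pool$sites$true_maf))
}

#' Inject phase errors and reported phasing probabilities
#'
#' Flips the reported haplotype assignment of each heterozygous genotype with
#' probability `phase_error_rate` and draws a reported phasing probability from
#' a Beta distribution whose parameters differ between correctly phased and
#' flipped genotypes, so that the reported probability is informative about
#' correctness (as the output of a statistical phaser is). Homozygous and
#' missing genotypes are untouched (phase is degenerate there). The true phase
#' is retained in `truth` for evaluation. A zero error rate models a perfect
#' phaser: the reported phase equals the truth and every reported probability
#' is 1.
#'
#' @param cohort A [rare_cohort()] carrying true phase.
#' @param config A [sim_config()]; uses `phase_error_rate` and
#'   `phase_prob_shape`.
#' @return The cohort with `hap1`/`hap2`/`pp` replaced by reported values.
#' @export
inject_phase_noise <- function(cohort, config) {
  stopifnot(inherits(cohort, "rare_cohort"), !is.null(cohort$truth$hap1))
  set.seed(config$seed + 2L)
  gt <- cohort$gt
  het <- which(!is.na(gt) & gt == 1L)
  hap1 <- cohort$truth$hap1
  hap2 <- cohort$truth$hap2
  hap1[is.na(gt)] <- NA_integer_
  hap2[is.na(gt)] <- NA_integer_
  flip <- runif(length(het)) < config$phase_error_rate
  if (any(flip)) {
    idx <- het[flip]
    tmp <- hap1[idx]
    hap1[idx] <- hap2[idx]
    hap2[idx] <- tmp
  }
  sh <- config$phase_prob_shape
  pp_val <- numeric(length(het))
  if (config$phase_error_rate == 0) {
    # a perfect phaser: all reported probabilities are 1
    pp_val[] <- 1
  } else {
    pp_val[!flip] <- rbeta(sum(!flip), sh$correct[1], sh$correct[2])
    pp_val[flip] <- rbeta(sum(flip), sh$flipped[1], sh$flipped[2])
  }
  # reported to 4 decimals, matching the VCF PP representation
  pp <- matrix(NA_real_, nrow(gt), ncol(gt))
  pp[het] <- round(pp_val, 4)
  out <- cohort
  out$hap1 <- hap1; out$hap2 <- hap2; out$pp <- pp
  dimnames(out$hap1) <- dimnames(out$hap2) <- dimnames(out$pp) <- dimnames(gt)
  out$truth$phase_flipped <- {
    fl <- matrix(FALSE, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    fl[het] <- flip
    fl
  }
  out
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper chaining [simulate_haplotype_pool()],
#' [simulate_individuals()] and [inject_phase_noise()].
#'
#' @param config A [sim_config()].
#' @return A [rare_cohort()].
#' @export
simulate_cohort <- function(config = sim_config()) {
  pool <- simulate_haplotype_pool(config)
  cohort <- simulate_individuals(pool, config)
  inject_phase_noise(cohort, config)
}

#' True per-gene genotype classes
#'
#' From the retained true haplotypes, classifies each sample x gene as 0 (no
#' qualifying allele), 1 (alleles on one haplotype only) or 2 (biallelic: both
#' haplotypes carry at least one qualifying allele, i.e. a true homozygote or
#' true compound heterozygote). Used by the phenotype simulator and as truth
#' for comp-het evaluation.
#'
#' @param cohort A [rare_cohort()] with truth haplotypes.
#' @param keys Optional subset of variant keys to count as qualifying.
#' @return Integer matrix `n_samples x n_genes`.
#' @export
true_gene_genotypes <- function(cohort, keys = NULL) {
  stopifnot(!is.null(cohort$truth$hap1))
  sites <- cohort$sites
  use <- if (is.null(keys)) rep(TRUE, nrow(sites)) else sites$variant_key %in% keys
  genes <- unique(sites$gene)
  out <- matrix(0L, length(cohort$samples), length(genes),
                dimnames = list(cohort$samples, genes))
  for (j in seq_along(genes)) {
    cols <- which(sites$gene == genes[j] & use)
    if (!length(cols)) next
    a1 <- rowSums(cohort$truth$hap1[, cols, drop = FALSE]) > 0
    a2 <- rowSums(cohort$truth$hap2[, cols, drop = FALSE]) > 0
    out[, j] <- a1 + a2
  }
  out
}
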