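#' Simulation configuration for a synthetic autozygous cohort
#'
#' Bundles and validates the parameters of the synthetic cohort generator.
#' The defaults describe a consanguinity-enriched cohort: about a third of
#' participants are modelled as offspring of consanguineous unions (second
#' cousins or closer), and the two-point mixture of inbreeding coefficients is
#' chosen so that the cohort-mean autozygous genome fraction is close to 1.8%.
#'
#' @param n_samples Number of diploid individuals.
#' @param n_genes Number of genes carrying rare variation.
#' @param variants_per_gene Mean number of variant sites per gene (Poisson with
#'   a minimum of one site).
#' @param maf_lower,maf_upper Bounds of the allele-frequency spectrum from which
#'   per-site frequencies are drawn (log-uniform), as fractions within
#'   `[1e-6, 0.05]`.
#' @param consanguinity_fraction Fraction of samples drawn as consanguineous
#'   offspring.
#' @param f_consang Inbreeding coefficient F for consanguineous samples
#'   (first-cousin offspring would be 0.0625, second-cousin 0.015625).
#' @param f_background Inbreeding coefficient for the remaining samples.
#' @param phase_error_rate Fraction of heterozygous genotypes whose reported
#'   haplotype assignment is flipped by [inject_phase_noise()].
#' @param phase_prob_shape Named list with Beta shape pairs `correct` and
#'   `flipped` for reported phasing probabilities; correctly phased
#'   heterozygotes draw higher reported probabilities on average.
#' @param prop_consequence Named numeric vector of probabilities over the
#'   consequence classes `plof_hc`, `plof_lc`, `missense`, `synonymous` used to
#'   annotate simulated sites; must sum to 1.
#' @param missing_rate Per-genotype missingness rate.
#' @param seed Integer seed; a fixed seed makes the whole cohort (haplotype
#'   pool, genotypes, phase noise) reproducible.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_samples = 200, n_genes = 20, seed = 1)
#' cfg$f_consang
#' @export
sim_config <- function(n_samples = 2000,
                       n_genes = 100,
                       variants_per_gene = 8,
                       maf_lower = 1e-4,
                       maf_upper = 0.05,
                       consanguinity_fraction = 0.33,
                       f_consang = 0.05,
                       f_background = 0.002,
                       phase_error_rate = 0.05,
                       phase_prob_shape = list(correct = c(30, 1.5),
                                               flipped = c(6, 3)),
                       prop_consequence = c(plof_hc = 0.15, plof_lc = 0.02,
                                            missense = 0.53, synonymous = 0.30),
                       missing_rate = 0,
                       seed = 1L) {
  stopifnot(is.numeric(n_samples), length(n_samples) == 1, n_samples >= 1)
  stopifnot(n_genes >= 1, variants_per_gene > 0)
  if (maf_lower <= 0 && maf_upper <= 0) {
    abort("no polymorphism: allele-frequency spectrum is degenerate (both bounds zero)")
  }
  stopifnot(maf_lower > 0, maf_upper >= maf_lower, maf_upper <= 0.05,
            maf_lower >= 1e-6)
  for (f in c(consanguinity_fraction, f_consang, f_background,
              phase_error_rate, missing_rate)) {
    stopifnot(is.numeric(f), f >= 0, f <= 1)
  }
  stopifnot(setequal(names(prop_consequence),
                     c("plof_hc", "plof_lc", "missense", "synonymous")),
            abs(sum(prop_consequence) - 1) < 1e-8)
  stopifnot(is.list(phase_prob_shape),
            all(c("correct", "flipped") %in% names(phase_prob_shape)))
  structure(
    list(n_samples = as.integer(n_samples),
         n_genes = as.integer(n_genes),
         variants_per_gene = variants_per_gene,
         maf_lower = maf_lower, maf_upper = maf_upper,
         consanguinity_fraction = consanguinity_fraction,
         f_consang = f_consang, f_background = f_background,
         phase_error_rate = phase_error_rate,
         phase_prob_shape = phase_prob_shape,
         prop_consequence = prop_consequence,
         missing_rate = missing_rate,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' True phenotype-generating model for the synthetic cohort
#'
#' Describes how phenotypes are generated from gene genotypes: per-gene additive
#' effects act on the 0/1/2 gene genotype, dominance-deviation effects on its
#' 0/1/0 recoding, and recessive effects only on biallelic (genotype 2)
#' carriers. Exactly one of the additive/dominance pair or the recessive effect
#' should be non-zero for a given gene.
#'
#' @param genes Character vector of gene ids the effects refer to.
#' @param beta Per-gene additive effect (trait units per allele, or log-odds).
#' @param gamma Per-gene dominance-deviation effect.
#' @param rec_beta Per-gene recessive effect applied to biallelic carriers only.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param prevalence Target prevalence for binary traits, in (0, 1).
#' @param noise_sd Residual standard deviation for quantitative traits.
#' @param n_pcs Number of standard-normal principal-component surrogates to
#'   simulate as covariates.
#' @param covar_effects Named numeric effects for `age`, `sex`, `age2` and PCs
#'   on the trait scale (linear predictor scale for binary traits).
#'
#' @return An object of class `true_model`.
#' @export
true_model <- function(genes,
                       beta = 0,
                       gamma = 0,
                       rec_beta = 0,
                       trait_type = c("quantitative", "binary"),
                       prevalence = 0.1,
                       noise_sd = 1,
                       n_pcs = 4,
                       covar_effects = c(age = 0.01, sex = 0.2, age2 = 0)) {
  trait_type <- arg_match(trait_type)
  g <- length(genes)
  recycle <- function(x) if (length(x) == 1) rep(x, g) else x
  beta <- recycle(beta); gamma <- recycle(gamma); rec_beta <- recycle(rec_beta)
  stopifnot(length(beta) == g, length(gamma) == g, length(rec_beta) == g)
  both <- (beta != 0 | gamma != 0) & rec_beta != 0
  if (any(both)) {
    abort(paste0("genes with both additive/dominance and recessive effects: ",
                 paste(genes[both], collapse = ", ")))
  }
  stopifnot(prevalence > 0, prevalence < 1, noise_sd >= 0, n_pcs >= 0)
  structure(
    list(effects = tibble(gene = genes, beta = beta, gamma = gamma,
                          rec_beta = rec_beta),
         trait_type = trait_type, prevalence = prevalence,
         noise_sd = noise_sd, n_pcs = as.integer(n_pcs),
         covar_effects = covar_effects),
    class = "true_model")
}
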