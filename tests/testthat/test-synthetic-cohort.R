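test_that("haplotype pool realizes the configured allele-frequency spectrum", {
  cfg <- sim_config(n_samples = 500, n_genes = 1, variants_per_gene = 1e-9,
                    maf_lower = 0.01, maf_upper = 0.01, seed = 42)
  pool <- simulate_haplotype_pool(cfg)
  expect_equal(nrow(pool$haps), 1000)
  expect_equal(ncol(pool$haps), 1)
  af <- mean(pool$haps[, 1])
  # binomial sampling error around 0.01 with 1000 haplotypes
  expect_lt(abs(af - 0.01), 4 * sqrt(0.01 * 0.99 / 1000))
})

test_that("a fixed seed reproduces the cohort end to end; the empty cohort errors", {
  cfg <- sim_config(n_samples = 60, n_genes = 8, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$gt, b$gt)
  expect_identical(a$hap1, b$hap1)
  expect_identical(a$pp, b$pp)
  expect_identical(a$truth$f, b$truth$f)
  expect_error(sim_config(n_samples = 0), "n_samples")
  expect_error(sim_config(maf_lower = 0, maf_upper = 0), "no polymorphism")
})

test_that("full autozygosity makes every called genotype homozygous", {
  cfg <- sim_config(n_samples = 80, n_genes = 10, consanguinity_fraction = 1,
                    f_consang = 1, f_background = 1, seed = 3,
                    maf_lower = 0.01)
  co <- simulate_cohort(cfg)
  expect_true(all(co$gt %in% c(0L, 2L)))
})

test_that("homozygote rate matches q^2 + q(1-q)F across seeds", {
  # one site at q = 0.01; empirical mean over >= 10 seeds vs the closed form
  hom_rate <- function(f, seeds, n = 4000) {
    mean(vapply(seeds, function(s) {
      cfg <- sim_config(n_samples = n, n_genes = 1, variants_per_gene = 1e-9,
                        maf_lower = 0.01, maf_upper = 0.01,
                        consanguinity_fraction = 1, f_consang = f,
                        f_background = f, seed = s)
      pool <- simulate_haplotype_pool(cfg)
      co <- simulate_individuals(pool, cfg)
      q <- mean(pool$haps[, 1])   # realized pool frequency is what is copied
      mean(co$gt[, 1] == 2L) - (q^2 + q * (1 - q) * f)
    }, numeric(1)))
  }
  n_tot <- 4000 * 12
  tol0 <- 3 * sqrt(1e-4 / n_tot)
  expect_lt(abs(hom_rate(0, 1:12)), tol0)
  exp_f <- 1e-4 + 0.0099 * 0.0625
  tol_f <- 3 * sqrt(exp_f / n_tot)
  expect_lt(abs(hom_rate(0.0625, 21:32)), tol_f)
})

test_that("phase noise controls flip rate, probabilities and hom immunity", {
  cfg <- sim_config(n_samples = 400, n_genes = 25, maf_lower = 5e-3,
                    phase_error_rate = 0.2, seed = 5)
  co <- simulate_cohort(cfg)
  het <- !is.na(co$gt) & co$gt == 1L
  # flips happen only at hets, at about the configured rate
  flips <- co$truth$phase_flipped
  expect_true(all(!flips[!het]))
  rate <- mean(flips[het])
  expect_lt(abs(rate - 0.2), 4 * sqrt(0.2 * 0.8 / sum(het)))
  # reported probability is informative: flipped pairs lower on average
  expect_gt(mean(co$pp[het & !flips]), mean(co$pp[het & flips]))
  # homozygous genotypes keep their trivial phase
  hom <- !is.na(co$gt) & co$gt == 2L
  expect_true(all(co$hap1[hom] == 1L & co$hap2[hom] == 1L))
  # zero error rate: reported phase identical to truth, probabilities 1
  cfg0 <- sim_config(n_samples = 200, n_genes = 10, phase_error_rate = 0,
                     maf_lower = 5e-3, seed = 6)
  co0 <- simulate_cohort(cfg0)
  expect_identical(co0$hap1[!is.na(co0$gt)], co0$truth$hap1[!is.na(co0$gt)])
  expect_true(all(co0$pp[!is.na(co0$pp)] == 1))
})

test_that("compound-het rate decreases as F increases", {
  rate_at <- function(f) {
    mean(vapply(1:6, function(s) {
      cfg <- sim_config(n_samples = 800, n_genes = 40, maf_lower = 5e-3,
                        consanguinity_fraction = 1, f_consang = f,
                        f_background = f, phase_error_rate = 0, seed = s)
      co <- simulate_cohort(cfg)
      nrow(true_comphet_pairs(co))
    }, numeric(1)))
  }
  r <- c(rate_at(0), rate_at(0.1), rate_at(0.5))
  expect_true(all(diff(r) < 0))
})

test_that("phenotype generator honors the additive, recessive and null models", {
  cfg <- sim_config(n_samples = 600, n_genes = 10, maf_lower = 0.02, seed = 8)
  co <- simulate_cohort(cfg)
  genes <- unique(co$sites$gene)
  # beta = 1, no noise: trait exactly linear in the gene genotype
  m1 <- true_model(genes = genes[1], beta = 1, noise_sd = 0, n_pcs = 0,
                   covar_effects = c(age = 0))
  s1 <- simulate_phenotypes(co, m1, seed = 2)
  g <- s1$gene_genotypes[, genes[1]]
  expect_equal(s1$phenotypes$trait, as.numeric(unname(g)), tolerance = 1e-12)
  # recessive-only effect: het carriers indistinguishable from noncarriers
  m2 <- true_model(genes = genes[2], rec_beta = 5, noise_sd = 0, n_pcs = 0,
                   covar_effects = c(age = 0))
  s2 <- simulate_phenotypes(co, m2, seed = 2)
  g2 <- s2$gene_genotypes[, genes[2]]
  expect_true(all(s2$phenotypes$trait[g2 == 1] == 0))
  expect_true(all(s2$phenotypes$trait[g2 == 2] == 5))
  # binary trait calibrated to target prevalence
  m3 <- true_model(genes = genes[3], beta = 0, trait_type = "binary",
                   prevalence = 0.2, n_pcs = 2)
  s3 <- simulate_phenotypes(co, m3, seed = 3)
  prev <- mean(s3$phenotypes$trait)
  expect_lt(abs(prev - 0.2), 4 * sqrt(0.2 * 0.8 / 600))
  # a gene cannot carry both parameterizations
  expect_error(true_model(genes = "G", beta = 1, rec_beta = 1), "both")
})
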