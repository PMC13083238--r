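#' Simulate phenotypes and covariates
#'
#' Generates one trait under the joint additive / dominance-deviation /
#' recessive model
#' `y = sum_g beta_g g_add + gamma_g g_domdev + rec_g 1[biallelic] + covariates + e`,
#' where `g_add` is the 0/1/2 gene genotype, `g_domdev` its 0/1/0 recoding and
#' the recessive indicator is 1 only for biallelic carriers. Quantitative
#' traits add Gaussian noise; binary traits are drawn from a logistic model
#' whose intercept is solved numerically so the expected prevalence matches the
#' target.
#'
#' @param cohort A [rare_cohort()] (truth haplotypes required).
#' @param model A [true_model()].
#' @param seed Integer seed for noise and covariates.
#' @param trait_name Column name for the trait.
#' @return A list with `phenotypes` (tibble `sample_id`, trait),
#'   `covariates` (tibble `sample_id`, `age`, `sex`, `age2`, `PC1..K`) and
#'   `gene_genotypes` (the true 0/1/2 matrix used).
#' @export
simulate_phenotypes <- function(cohort, model, seed = 1L, trait_name = "trait") {
  stopifnot(inherits(cohort, "rare_cohort"), inherits(model, "true_model"))
  if (!all(model$effects$gene %in% cohort$sites$gene)) {
    abort("model refers to genes absent from the cohort")
  }
  set.seed(seed)
  n <- length(cohort$samples)
  age <- runif(n, 18, 80)
  sex <- rbinom(n, 1L, 0.5)
  covars <- tibble(sample_id = cohort$samples, age = age, sex = sex,
                   age2 = age^2)
  if (model$n_pcs > 0) {
    pcs <- matrix(rnorm(n * model$n_pcs), n, model$n_pcs)
    colnames(pcs) <- paste0("PC", seq_len(model$n_pcs))
    covars <- bind_cols(covars, as_tibble(pcs))
  }
  ce <- model$covar_effects
  eta_cov <- 0
  for (nm in names(ce)) {
    if (nm %in% names(covars)) eta_cov <- eta_cov + ce[[nm]] * covars[[nm]]
  }
  gg <- true_gene_genotypes(cohort)
  eff <- model$effects
  eta_gene <- rep(0, n)
  for (k in seq_len(nrow(eff))) {
    g <- gg[, eff$gene[k]]
    eta_gene <- eta_gene +
      eff$beta[k] * g +
      eff$gamma[k] * as.numeric(g == 1L) +
      eff$rec_beta[k] * as.numeric(g == 2L)
  }
  eta <- eta_cov + eta_gene
  if (model$trait_type == "quantitative") {
    y <- eta + rnorm(n, sd = model$noise_sd)
  } else {
    # solve the intercept so that mean(plogis(c + eta)) = prevalence
    fr <- function(c0) mean(plogis(c0 + eta)) - model$prevalence
    lo <- qlogis(model$prevalence) - max(abs(eta)) - 10
    hi <- qlogis(model$prevalence) + max(abs(eta)) + 10
    c0 <- tryCatch(uniroot(fr, c(lo, hi))$root, error = function(e) NA_real_)
    if (is.na(c0)) {
      warn("target prevalence unreachable; using logit(prevalence) intercept")
      c0 <- qlogis(model$prevalence)
    }
    pr <- plogis(c0 + eta)
    y <- rbinom(n, 1L, pr)
    achieved <- mean(y)
    if (abs(achieved - model$prevalence) > 5 * sqrt(model$prevalence * (1 - model$prevalence) / n)) {
      warn(sprintf("achieved prevalence %.4f differs from target %.4f",
                   achieved, model$prevalence))
    }
  }
  pheno <- tibble(sample_id = cohort$samples)
  pheno[[trait_name]] <- unname(y)
  list(phenotypes = pheno, covariates = covars, gene_genotypes = gg)
}
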