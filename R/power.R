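#' Expected biallelic carriers under autozygosity
#'
#' `n (Q^2 + Q (1 - Q) F)` for gene-level qualifying haplotype frequency `Q`,
#' inbreeding coefficient `F` and sample size `n` (the same closed form as
#' [expected_biallelic_hwe()], re-exported on the power grid's axes).
#'
#' @param q Gene-level qualifying frequency Q (scalar or vector).
#' @param f Inbreeding coefficient.
#' @param n Sample size.
#' @export
expected_carriers <- function(q, f, n) {
  stopifnot(all(q >= 0), all(q <= 0.5))
  n * (q^2 + q * (1 - q) * f)
}

#' Analytic power for a recessive association test
#'
#' Non-centrality approximation for the 1-df Wald test of a 0/1 biallelic
#' carrier indicator with carrier fraction `p_c = Q^2 + Q (1 - Q) F`. For a
#' quantitative trait with residual standard deviation `sd`, the
#' non-centrality is `ncp = n p_c (1 - p_c) effect^2 / sd^2`; for a binary
#' trait with baseline prevalence `K` and log-odds effect,
#' `ncp = n p_c (1 - p_c) K (1 - K) effect^2`. Power at two-sided level
#' `alpha` is `P(|Z + sqrt(ncp)| > z_{1-alpha/2})`.
#'
#' @param q Gene-level qualifying frequency Q.
#' @param f Inbreeding coefficient F.
#' @param n Sample size.
#' @param effect Effect size (trait units for quantitative; log-odds for
#'   binary).
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param alpha Two-sided significance level.
#' @param sd Residual standard deviation (quantitative).
#' @param prevalence Baseline prevalence (binary).
#' @return Power in `[0, 1]` (vectorized over the inputs).
#' @export
analytic_power <- function(q, f, n, effect, trait_type = c("quantitative", "binary"),
                           alpha = 0.05, sd = 1, prevalence = NULL) {
  trait_type <- arg_match(trait_type)
  p_c <- q^2 + q * (1 - q) * f
  stopifnot(all(p_c > 0), all(p_c < 1))
  ncp <- if (trait_type == "quantitative") {
    n * p_c * (1 - p_c) * effect^2 / sd^2
  } else {
    if (is.null(prevalence)) abort("binary traits need a baseline prevalence")
    n * p_c * (1 - p_c) * prevalence * (1 - prevalence) * effect^2
  }
  z <- qnorm(1 - alpha / 2)
  pnorm(sqrt(ncp) - z) + pnorm(-sqrt(ncp) - z)
}

#' Empirical power of the recessive scan by simulation
#'
#' Simulates cohorts with a single gene carrying one qualifying variant at
#' frequency `Q`, every individual at inbreeding coefficient `F`, and a
#' recessive phenotype effect; runs the recessive burden scan and reports the
#' rejection rate at level `alpha`. Replicates in which the gene fails the
#' minimum-carrier filter count as non-rejections, exactly as the pipeline
#' would behave.
#'
#' @inheritParams analytic_power
#' @param n_reps Simulation replicates.
#' @param seed Integer seed.
#' @param min_carriers Testability filter (default 4).
#' @param noise_sd Residual standard deviation of the simulated trait.
#' @return One-row tibble: `q`, `f`, `n`, `effect`, `power`, `mc_se`,
#'   `n_reps`, `n_untestable`.
#' @export
empirical_power <- function(q, f, n, effect, alpha = 0.05, n_reps = 100L,
                            seed = 1L, min_carriers = 4L, noise_sd = 1) {
  rejections <- 0L
  untestable <- 0L
  for (r in seq_len(n_reps)) {
    rs <- seed + r
    cfg <- sim_config(n_samples = n, n_genes = 1, variants_per_gene = 1e-9,
                      maf_lower = q, maf_upper = q,
                      consanguinity_fraction = 1, f_consang = f,
                      f_background = f, phase_error_rate = 0, seed = rs)
    cohort <- simulate_cohort(cfg)
    sim <- simulate_phenotypes(
      cohort, true_model(genes = cohort$sites$gene[1], rec_beta = effect,
                         noise_sd = noise_sd, n_pcs = 0),
      seed = rs)
    g <- as.numeric(sim$gene_genotypes[, 1] == 2L)
    if (sum(g) < min_carriers) { untestable <- untestable + 1L; next }
    res <- tryCatch(
      linear_assoc(sim$phenotypes$trait, g, sim$covariates),
      error = function(e) NULL)
    if (!is.null(res) && !is.na(res$p) && res$p < alpha) {
      rejections <- rejections + 1L
    }
  }
  pw <- rejections / n_reps
  tibble(q = q, f = f, n = n, effect = effect, power = pw,
         mc_se = sqrt(pw * (1 - pw) / n_reps),
         n_reps = as.integer(n_reps), n_untestable = untestable)
}

#' Analytic + empirical power grid
#'
#' Evaluates [analytic_power()] and [empirical_power()] on the Cartesian grid
#' of the supplied axes.
#'
#' @param q,f,n,effect Grid axes.
#' @param alpha Significance level.
#' @param n_reps Replicates per empirical cell.
#' @param seed Integer seed.
#' @param noise_sd Residual standard deviation.
#' @return A `power_grid` tibble with `analytic` and `power` (empirical)
#'   columns.
#' @export
power_grid <- function(q, f, n, effect, alpha = 0.05, n_reps = 100L,
                       seed = 1L, noise_sd = 1) {
  grid <- tidyr::expand_grid(q = q, f = f, n = n, effect = effect)
  out <- pmap(grid, function(q, f, n, effect) {
    cell_seed <- seed + as.integer(1e4 * q * 1e3 + f * 1e6) %% 10000L
    emp <- empirical_power(q, f, n, effect, alpha, n_reps, cell_seed,
                           noise_sd = noise_sd)
    mutate(emp, analytic = analytic_power(q, f, n, effect, alpha = alpha,
                                          sd = noise_sd))
  }) |> list_rbind()
  structure(out, class = c("power_grid", class(out)))
}

#' ggplot2 methods for result objects
#'
#' `autoplot()` methods for the package's result classes: the permutation-FDR
#' curve, the knockout accrual curve and the power grid.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name autoplot_methods
NULL

#' @rdname autoplot_methods
#' @export
autoplot.power_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$f)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$analytic, linetype = "analytic")) +
    ggplot2::geom_point(ggplot2::aes(y = .data$power)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$power - 2 * .data$mc_se,
                                        ymax = .data$power + 2 * .data$mc_se),
                           width = 0) +
    ggplot2::facet_grid(n ~ q, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "inbreeding coefficient F", y = "power",
                  linetype = NULL,
                  title = "Recessive association power vs autozygosity") +
    ggplot2::theme_minimal()
}
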