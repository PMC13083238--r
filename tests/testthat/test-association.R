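test_that("linear association recovers an exact linear relationship", {
  set.seed(1)
  g <- rbinom(500, 2, 0.2)
  cv <- data.frame(age = rnorm(500))
  res <- linear_assoc(2 * g, g, cv)
  expect_equal(res$beta, 2, tolerance = 1e-10)
  expect_equal(res$p, 0)
  expect_error(linear_assoc(rnorm(500), rep(1, 500), cv), "monomorphic")
})

test_that("the OLS fast path agrees with lm() exactly", {
  set.seed(2)
  n <- 300
  G <- cbind(rbinom(n, 2, 0.1), rbinom(n, 2, 0.3), rbinom(n, 1, 0.05))
  cv <- data.frame(a = rnorm(n), b = runif(n))
  y <- 0.3 * G[, 1] + cv$a + rnorm(n)
  for (j in 1:3) {
    mine <- linear_assoc(y, G[, j], cv)
    ref <- summary(lm(y ~ G[, j] + a + b, data = cv))$coefficients[2, ]
    expect_equal(mine$beta, unname(ref["Estimate"]), tolerance = 1e-12)
    expect_equal(mine$se, unname(ref["Std. Error"]), tolerance = 1e-12)
    expect_equal(mine$p, unname(ref["Pr(>|t|)"]), tolerance = 1e-12)
  }
})

test_that("null linear P values are uniform (KS at alpha 0.01, 1000 reps)", {
  set.seed(3)
  n <- 150
  cv <- data.frame(a = rnorm(n))
  y <- cv$a + rnorm(n)
  g0 <- rbinom(n, 2, 0.2)
  ps <- vapply(1:1000, function(i) {
    linear_assoc(y, sample(g0), cv)$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("intercept-only Firth fit matches the Jeffreys closed form", {
  for (k in c(0, 1, 7)) {
    y <- c(rep(1, k), rep(0, 25 - k))
    fit <- firth_fit(matrix(1, 25, 1), y)
    expect_equal(plogis(fit$beta), (k + 0.5) / 26, tolerance = 1e-7)
  }
})

test_that("Firth fallback returns finite estimates under complete separation", {
  set.seed(4)
  g <- c(rep(0, 40), rep(1, 10))
  y <- as.integer(g == 1)
  res <- logistic_assoc(y, g, NULL)
  expect_true(res$firth_applied)
  expect_true(is.finite(res$beta) && is.finite(res$se))
  expect_true(res$p > 0 && res$p < 1e-4)
})

test_that("logistic ML path agrees with glm when no Firth trigger", {
  set.seed(5)
  n <- 800
  g <- rbinom(n, 2, 0.3)
  cv <- data.frame(a = rnorm(n))
  y <- rbinom(n, 1, plogis(-1 + 0.1 * g))
  res <- logistic_assoc(y, g, cv, firth_trigger_p = 1e-12)
  ref <- summary(glm(y ~ g + a, data = cv, family = binomial()))$coefficients["g", ]
  expect_false(res$firth_applied)
  expect_equal(res$beta, unname(ref["Estimate"]), tolerance = 1e-6)
  expect_equal(res$p, unname(ref["Pr(>|z|)"]), tolerance = 1e-5)
})

test_that("Firth logistic maximum matches an independent Nelder-Mead maximizer", {
  # pure recessive binary outcome: y = 1 iff g = 2 on a noisy background
  set.seed(6)
  g <- rbinom(300, 2, 0.3)
  y <- as.integer(g == 2)
  y[sample(300, 15)] <- 1 - y[sample(300, 15)]  # break perfect separation a bit
  X <- cbind(1, g_add = g, g_dom = as.numeric(g == 1))
  fit <- firth_fit(X, y)
  pen_ll <- function(b) {
    eta <- drop(X %*% b); pr <- plogis(eta)
    w <- pmax(pr * (1 - pr), 1e-12)
    sum(y * eta - log1p(exp(eta))) +
      0.5 * as.numeric(determinant(crossprod(X, X * w), TRUE)$modulus)
  }
  alt <- optim(c(0, 0, 0), function(b) -pen_ll(b), method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  expect_equal(unname(fit$beta), alt$par, tolerance = 1e-3)
  expect_gte(fit$loglik_pen, -alt$value - 1e-6)
})

test_that("dominance deviation is zero under an exact additive signal", {
  set.seed(7)
  g <- rbinom(400, 2, 0.3)
  cv <- data.frame(a = rnorm(400))
  res <- dominance_deviation_test(3 * g + cv$a, g, cv)
  expect_equal(res$gamma, 0, tolerance = 1e-10)
  expect_lt(res$p_joint2df, 1e-10)
})

test_that("pure recessive binary signal yields negative gamma via Firth", {
  set.seed(8)
  g <- rbinom(2000, 2, 0.25)
  y <- rbinom(2000, 1, plogis(-3 + 3 * (g == 2)))
  res <- dominance_deviation_test(y, g, trait_type = "binary")
  expect_lt(res$gamma, 0)
  expect_lt(res$p_domdev, 0.01)
  expect_true(res$gamma_estimable)
  # no heterozygotes: gamma flagged inestimable
  g2 <- ifelse(g == 1, 0, g)
  res2 <- dominance_deviation_test(rbinom(2000, 1, 0.2), g2,
                                   trait_type = "binary")
  expect_false(res2$gamma_estimable)
})

test_that("Wald and LRT dominance P values agree to first order", {
  set.seed(9)
  reps <- replicate(40, {
    g <- rbinom(1500, 2, 0.3)
    y <- 0.15 * g - 0.12 * (g == 1) + rnorm(1500)
    r <- dominance_deviation_test(y, g)
    c(r$p_domdev, r$p_domdev_lrt)
  })
  sel <- reps[1, ] > 1e-6 & reps[1, ] < 0.05
  skip_if(sum(sel) < 5)
  expect_true(all(abs(log10(reps[1, sel] / reps[2, sel])) < 0.3))
})

test_that("genomic lambda has its defining closed-form behavior", {
  med <- qchisq(0.5, 1)
  expect_equal(genomic_lambda(chi2 = rep(med, 5)), 1)
  expect_equal(genomic_lambda(chi2 = rep(2 * med, 5)), 2)
  set.seed(10)
  expect_equal(genomic_lambda(p = runif(10000)), 1, tolerance = 0.05)
  expect_error(genomic_lambda(), "no statistics")
})

test_that("additive scan applies the MAC filter and finds a planted burden", {
  cfg <- sim_config(n_samples = 1500, n_genes = 30, maf_lower = 2e-3,
                    maf_upper = 0.03, seed = 31)
  st <- sim_stage(cfg)
  co <- st$cohort
  mac <- pmin(co$sites$ac, co$sites$an - co$sites$ac)
  target <- co$sites$gene[which.max(co$sites$af)]
  sim <- simulate_phenotypes(co, true_model(genes = target, beta = 0.8),
                             seed = 1)
  scan <- run_additive_scan(co, sim$phenotypes, sim$covariates, st$masks,
                            use_masks = "C", af_cutoffs = list(0.01),
                            quant_min_n = 0)
  sv <- dplyr::filter(scan, unit_type == "variant")
  expect_true(all(sv$mac >= 5))
  expect_false(any(co$sites$variant_key[mac == 4] %in% sv$unit))
  hit <- dplyr::filter(scan, unit_type == "burden", gene == target)
  if (nrow(hit)) expect_lt(min(hit$p), 1e-4)
})

test_that("synonymous-mask burdens on a null phenotype are well calibrated", {
  cfg <- sim_config(n_samples = 1200, n_genes = 60, maf_lower = 2e-3,
                    maf_upper = 0.03, seed = 32)
  st <- sim_stage(cfg)
  sim <- simulate_phenotypes(st$cohort,
                             true_model(genes = unique(st$cohort$sites$gene)[1],
                                        beta = 0), seed = 2)
  scan <- run_additive_scan(st$cohort, sim$phenotypes, sim$covariates,
                            st$masks, min_mac = 1e9,   # burden arm only
                            use_masks = "D", af_cutoffs = list(0.01),
                            quant_min_n = 0)
  lam <- genomic_lambda(p = scan$p[!is.na(scan$p)])
  expect_lt(abs(lam - 1), 0.35)
})

test_that("a planted recessive effect is stronger under the recessive model", {
  cfg <- sim_config(n_samples = 2500, n_genes = 30, maf_lower = 5e-3,
                    seed = 33, phase_error_rate = 0)
  st <- sim_stage(cfg)
  co <- st$cohort
  b <- build_recessive_burden(st$calls, co$samples)
  testable <- dplyr::filter(b$genes, testable)
  skip_if(nrow(testable) < 1)
  target <- testable$gene[which.max(testable$n_carriers)]
  sim <- simulate_phenotypes(co, true_model(genes = target, rec_beta = 2),
                             seed = 3)
  add_b <- build_additive_burden(co, st$masks, "C", 0.01)
  rs <- run_recessive_scan(b, sim$phenotypes, sim$covariates,
                           additive_burden = add_b, quant_min_n = 0)
  row <- dplyr::filter(rs, gene == target)
  expect_lt(row$p, 1e-3)
  expect_lt(row$p, row$p_add)
  # genes below the carrier minimum are not scanned
  expect_true(all(rs$gene %in% testable$gene))
})
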