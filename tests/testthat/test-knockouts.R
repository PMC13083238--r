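ko_masks <- function() {
  tibble::tibble(
    variant_key = c("v1", "v2", "v3", "v4"),
    gene = c("G1", "G1", "G2", "G3"),
    consequence = c("pLoF-HC", "pLoF-HC", "pLoF-HC", "missense"),
    pdm = c(FALSE, FALSE, FALSE, TRUE),
    mask_a = c(TRUE, TRUE, TRUE, FALSE),
    mask_b = TRUE, mask_c = TRUE, mask_d = FALSE,
    mac = c(3L, 2L, 5L, 4L),
    maf = c(0.005, 0.004, 0.02, 0.005),
    af_flipped = FALSE,
    bin_singleton = FALSE, bin_lt_0001 = FALSE, bin_lt_001 = FALSE,
    bin_lt_01 = c(TRUE, TRUE, FALSE, TRUE))
}

test_that("knockout catalog keeps only pLoF-HC below 1% MAF, deduplicated", {
  calls <- tibble::tibble(
    sample_id = c("s1", "s2", "s3", "s4"),
    gene = c("G1", "G2", "G1", "G3"),
    class = c("hom", "hom", "comp-het", "hom"),
    var1 = c("v1", "v3", "v1", "v4"),
    var2 = c(NA, NA, "v2", NA),
    pp = c(NA, NA, 0.99, NA))
  cat <- build_catalog(calls, ko_masks())
  # v3 (MAF 2%) and v4 (missense) records are excluded
  expect_equal(cat$n_genes, 1)
  expect_equal(sort(unique(cat$records$gene)), "G1")
  expect_equal(cat$n_hom, 1)
  expect_equal(cat$n_comphet, 1)
  expect_equal(glance(cat)$n_genotypes, 2)
})

test_that("accrual is monotone, exact at full size, and degenerate cases hold", {
  set.seed(61)
  samples <- paste0("s", 1:200)
  carriers <- sample(samples, 50)
  rec <- tibble::tibble(sample_id = carriers,
                        gene = sample(paste0("G", 1:12), 50, replace = TRUE),
                        class = "hom", var1 = "v", var2 = NA, pp = NA)
  cat <- structure(list(records = rec,
                        gene_summary = dplyr::count(rec, gene),
                        n_genes = dplyr::n_distinct(rec$gene)),
                   class = "knockout_catalog")
  ac <- accrual_curve(cat, samples, grid = c(10, 50, 100, 200), n_repeats = 8,
                      seed = 1)
  expect_true(all(diff(ac$mean_genes) >= 0))
  expect_equal(ac$mean_genes[ac$n == 200], cat$n_genes)
  expect_equal(ac$sd_genes[ac$n == 200], 0)
  # one gene knocked out in every sample: curve identically 1
  rec1 <- tibble::tibble(sample_id = samples, gene = "G1", class = "hom",
                         var1 = "v", var2 = NA, pp = NA)
  cat1 <- structure(list(records = rec1, gene_summary = dplyr::count(rec1, gene),
                         n_genes = 1L), class = "knockout_catalog")
  ac1 <- accrual_curve(cat1, samples, grid = c(1, 100, 200), n_repeats = 3)
  expect_true(all(ac1$mean_genes == 1))
})

test_that("carrier phenotype review: z-test and rank-sum behave as defined", {
  set.seed(62)
  nc <- exp(rnorm(500, mean = 2, sd = 0.4))
  # single carrier at the noncarrier mean (log scale): z = 0, P = 1
  x0 <- exp(mean(log(nc)))
  r0 <- carrier_phenotype_test(x0, nc)
  expect_equal(r0$method, "z")
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1, tolerance = 1e-12)
  # single carrier at mean + 1.96 sd: P close to 0.05
  x1 <- exp(mean(log(nc)) + 1.96 * sd(log(nc)))
  expect_equal(carrier_phenotype_test(x1, nc)$p, 0.05, tolerance = 0.001)
  # >= 2 carriers switch to the rank-sum path, same direction as z
  rs <- carrier_phenotype_test(c(x1, x1 * 1.1), nc)
  expect_equal(rs$method, "wilcoxon")
  expect_lt(rs$p, 0.2)
  # non-positive values skip the log transform with a warning
  expect_warning(carrier_phenotype_test(-1, rnorm(100)), "log")
})

test_that("percent difference reproduces a 62% triglyceride reduction", {
  expect_equal(round(percent_difference(49.6, 131.1)), 62)
})

test_that("noncarrier matching windows apply with a safe fallback", {
  nc <- tibble::tibble(age = c(30, 32, 60, 31, 29), sex = c(1, 1, 1, 0, 1),
                       trait = 1:5)
  got <- match_noncarriers(list(age = 30, sex = 1), nc, min_matches = 2)
  expect_equal(got$trait, c(1, 2, 5))
  expect_warning(all_back <- match_noncarriers(list(age = 90, sex = 1), nc,
                                               min_matches = 2),
                 "falling back")
  expect_equal(nrow(all_back), 5)
})

test_that("drug phase-transition enrichment: Fisher cross-product and logistic", {
  # 2x2 from the spec of the method: KO 30/10 vs no-KO 50/50 -> OR 3
  drugs <- tibble::tibble(
    drug_id = paste0("d", 1:140),
    target_genes = c(rep("KO1", 40), rep("NN1", 100)),
    max_phase = c(rep(4L, 30), rep(1L, 10), rep(4L, 50), rep(1L, 50)),
    action_type = "inhibitor", indication_class = "hypertension")
  res <- drug_transition_enrichment(drugs, c("KO1"), transition_phase = 1)
  expect_equal(res$or_fisher, 3)
  expect_false(res$logistic_skipped)
  # with all drugs single-target the logistic OR is close to Fisher's
  expect_equal(log(res$or), log(3), tolerance = 0.25)
  # single-class outcome: logistic skipped, Fisher still reported
  drugs2 <- dplyr::mutate(drugs, max_phase = 4L)
  res2 <- drug_transition_enrichment(drugs2, c("KO1"))
  expect_true(res2$logistic_skipped)
})

test_that("exposure is null-calibrated when knockouts are independent of phase", {
  set.seed(63)
  ps <- replicate(200, {
    drugs <- tibble::tibble(
      drug_id = paste0("d", 1:300),
      target_genes = sample(paste0("G", 1:50), 300, replace = TRUE),
      max_phase = sample(1:4, 300, replace = TRUE),
      action_type = "inhibitor", indication_class = "pain")
    ko <- paste0("G", sample(50, 20))
    drug_transition_enrichment(drugs, ko)$p
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.001)
})

test_that("action classes and oncology indications follow the printed rules", {
  expect_equal(classify_action(c("inhibitor", "agonist", "inverse agonist",
                                 "positive modulator", "chelator")),
               c("antagonistic", "agonistic", "antagonistic", "agonistic",
                 "other"))
  expect_equal(is_oncology_indication(c("breast cancer", "melanoma",
                                        "glaucoma", "hypertension",
                                        "acute leukemia")),
               c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_false(is_oncology_indication("glaucoma", stop_list = "glaucoma"))
})

test_that("stratified enrichment runs per action class and oncology flag", {
  set.seed(64)
  drugs <- tibble::tibble(
    drug_id = paste0("d", 1:200),
    target_genes = sample(paste0("G", 1:30), 200, replace = TRUE),
    max_phase = sample(1:4, 200, replace = TRUE),
    action_type = sample(c("inhibitor", "agonist"), 200, replace = TRUE),
    indication_class = sample(c("lung cancer", "asthma"), 200, replace = TRUE))
  st <- drug_transition_strata(drugs, paste0("G", 1:10))
  expect_true(all(c("all", "antagonistic", "agonistic", "oncology",
                    "non_oncology") %in% st$stratum))
})
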