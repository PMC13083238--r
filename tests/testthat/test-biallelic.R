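test_that("homozygote calls respect genotype, mask and AF cutoff", {
  co <- toy_cohort()
  m <- toy_masks(co)
  hom <- find_homozygotes(co, m, "A", 0.01)
  expect_equal(nrow(hom), 1)
  expect_equal(hom$sample_id, "C")
  expect_equal(hom$var1, "1:100:A:T")
  # AF filter: push the site over the cutoff and the call disappears
  m2 <- m; m2$bin_lt_01[1] <- FALSE
  expect_equal(nrow(find_homozygotes(co, m2, "A", 0.01)), 0)
  # het genotypes never produce hom calls
  expect_false("A" %in% hom$sample_id)
})

test_that("comp-het calling needs trans configuration and high phasing probability", {
  co <- toy_cohort(pp_default = 0.95)
  m <- toy_masks(co)
  ch <- call_compound_hets(co, m, "A", 0.01)
  expect_equal(ch$sample_id, "A")           # trans pair, PP 0.95 > 0.9
  expect_equal(sort(c(ch$var1, ch$var2)), c("1:100:A:T", "1:200:A:T"))
  expect_false("B" %in% ch$sample_id)       # cis pair: both alts on hap 1
  # threshold is strict: PP 0.85 is refused
  co2 <- toy_cohort(pp_default = 0.85)
  expect_equal(nrow(call_compound_hets(co2, m, "A", 0.01)), 0)
  expect_equal(nrow(call_compound_hets(co2, m, "A", 0.01,
                                       phase_prob_threshold = 0.8)), 1)
})

test_that("recessive burden is 0/1 with hom precedence and a carrier minimum", {
  co <- toy_cohort()
  m <- toy_masks(co)
  calls <- combine_biallelic_calls(find_homozygotes(co, m, "A", 0.01),
                                   call_compound_hets(co, m, "A", 0.01))
  b <- build_recessive_burden(calls, co$samples, min_carriers = 4)
  bm <- burden_matrix(b)
  expect_equal(unname(bm["G1", ]), c(1, 0, 1))   # A comp-het, C hom; B cis only
  expect_false(b$genes$testable[b$genes$gene == "G1"])  # 2 carriers < 4
  b2 <- build_recessive_burden(calls, co$samples, min_carriers = 2)
  expect_true(b2$genes$testable)
  # hom precedence in provenance when a sample is both
  dup <- dplyr::bind_rows(calls,
                          tibble::tibble(sample_id = "C", gene = "G1",
                                         class = "comp-het", var1 = "x",
                                         var2 = "y", pp = 0.99))
  cc <- combine_biallelic_calls(dup)
  expect_equal(cc$class[cc$sample_id == "C"], "hom")
  # carrier counts sum to distinct (sample, gene) pairs
  expect_equal(sum(b$genes$n_carriers), nrow(dplyr::distinct(calls, sample_id, gene)))
})

test_that("additive burden collapses by max or capped sum", {
  co <- toy_cohort()
  m <- toy_masks(co)
  bmax <- build_additive_burden(co, m, "C", 0.01, collapse = "max")
  bsum <- build_additive_burden(co, m, "C", 0.01, collapse = "sum")
  # sample A: het at two qualifying sites of G1
  expect_equal(bmax$matrix["G1", "A"], 1)
  expect_equal(bsum$matrix["G1", "A"], 2)
  # sample C: hom at one site -> 2 under both collapses
  expect_equal(bmax$matrix["G1", "C"], 2)
  expect_equal(bsum$matrix["G1", "C"], 2)
  # mask D has no qualifying G1 site: gene absent
  bd <- build_additive_burden(co, m, "D", 0.01)
  expect_false("G1" %in% rownames(bd$matrix))
})

test_that("Hardy-Weinberg expectation closed form and its guard", {
  expect_equal(expected_biallelic_hwe(0.01, 1e4), 1)
  expect_equal(expected_biallelic_hwe(0.01, 1e4, f = 0.0625),
               1e4 * (1e-4 + 0.0099 * 0.0625))
  expect_equal(expected_biallelic_hwe(0.001, 44028, f = 0.02),
               44028 * (1e-6 + 0.001 * 0.999 * 0.02))
  # the printed-scale sanity values: ~0.924 vs ~0.044
  expect_equal(round(expected_biallelic_hwe(0.001, 44028, f = 0.02), 3), 0.924)
  expect_equal(round(expected_biallelic_hwe(0.001, 44028), 3), 0.044)
  expect_error(expected_biallelic_hwe(c(0.3, 0.3), 100), "0.5")
})

test_that("enrichment ratio is the ratio of sums and handles empty expectation", {
  calls <- tibble::tibble(sample_id = paste0("s", 1:5), gene = "G1",
                          class = "hom", var1 = "v", var2 = NA, pp = NA)
  res <- autozygosity_enrichment_ratio(calls, list(G1 = 0.01414214), n = 1e4)
  expect_equal(res$ratio, 5 / (1e4 * 0.01414214^2), tolerance = 1e-6)
  expect_error(autozygosity_enrichment_ratio(calls, list(G1 = 0), n = 10),
               "zero")
})

test_that("comp-het truth recovery is perfect without phase noise", {
  st <- sim_stage(sim_config(n_samples = 1200, n_genes = 40, maf_lower = 5e-3,
                             phase_error_rate = 0, seed = 21))
  rec <- comphet_recovery(st$cohort, st$masks, "C", 0.01)
  expect_gt(rec$n_true, 5)
  expect_equal(rec$precision, 1)
  expect_equal(rec$recall, 1)
})
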