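# shared fixture builders (all fixtures are generated in code)

# cohort + masks + biallelic calls for a simulated configuration
sim_stage <- function(cfg, mask = "C", af_cutoff = 0.01,
                      phase_prob_threshold = 0.9) {
  co <- simulate_cohort(cfg)
  ann <- annotation_table(co)
  afs <- dplyr::bind_cols(co$sites["variant_key"], cohort_allele_counts(co))
  m <- suppressMessages(assign_masks(ann, afs))
  calls <- combine_biallelic_calls(
    find_homozygotes(co, m, mask, af_cutoff),
    call_compound_hets(co, m, mask, af_cutoff, phase_prob_threshold))
  list(cohort = co, masks = m, calls = calls, annotation = ann)
}

# a hand-built 3-sample, 4-site cohort in one gene plus one second-gene site,
# with explicit phase, for call-level unit tests
toy_cohort <- function(pp_default = 0.95) {
  sites <- tibble::tibble(
    variant_key = c("1:100:A:T", "1:200:A:T", "1:300:A:T", "2:100:A:T"),
    chrom = c("1", "1", "1", "2"), pos = c(100L, 200L, 300L, 100L),
    ref = "A", alt = "T",
    gene = c("G1", "G1", "G1", "G2"),
    consequence = c("pLoF-HC", "pLoF-HC", "missense", "synonymous"),
    cadd = c(NA, NA, 30, NA), polyphen = c(NA, NA, 0.9, NA),
    sift_call = c(NA, NA, "deleterious", NA))
  samples <- c("A", "B", "C")
  gt <- rbind(c(1L, 1L, 0L, 0L),   # A: trans pair at sites 1,2
              c(1L, 1L, 0L, 1L),   # B: cis pair at sites 1,2
              c(2L, 0L, 1L, 0L))   # C: hom at site 1
  h1 <- rbind(c(1L, 0L, NA, NA),
              c(1L, 1L, NA, 0L),
              c(1L, NA, 1L, NA))
  h2 <- rbind(c(0L, 1L, NA, NA),
              c(0L, 0L, NA, 1L),
              c(1L, NA, 0L, NA))
  pp <- matrix(NA_real_, 3, 4)
  pp[1, 1:2] <- pp_default
  pp[2, 1:2] <- pp_default
  pp[2, 4] <- pp_default
  pp[3, 3] <- pp_default
  rare_cohort(samples, sites, gt, hap1 = h1, hap2 = h2, pp = pp)
}

# hand-built mask assignment for the toy cohort (its 3-sample AFs are not
# meaningful, so mask membership is stated directly; every AF bin qualifies)
toy_masks <- function(co = toy_cohort(), maf = 0.004) {
  cons <- co$sites$consequence
  pdm <- !is.na(co$sites$cadd) & cons == "missense" &
    co$sites$cadd > 20 & co$sites$polyphen > 0.445 &
    co$sites$sift_call == "deleterious"
  tibble::tibble(
    variant_key = co$sites$variant_key,
    gene = co$sites$gene,
    consequence = cons,
    pdm = pdm,
    mask_a = cons == "pLoF-HC",
    mask_b = cons == "pLoF-HC" | pdm,
    mask_c = cons %in% c("pLoF-HC", "pLoF-LC", "missense"),
    mask_d = cons == "synonymous",
    mac = co$sites$ac,
    maf = maf,
    af_flipped = FALSE,
    bin_singleton = TRUE, bin_lt_0001 = TRUE, bin_lt_001 = TRUE,
    bin_lt_01 = TRUE)
}
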