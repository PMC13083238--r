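#' Assign consequence masks and allele-frequency bins
#'
#' Classifies annotated variants into the four nested/complementary burden
#' masks used throughout the pipeline:
#' \itemize{
#'   \item Mask A: high-confidence predicted loss-of-function (pLoF-HC);
#'   \item Mask B: pLoF-HC plus predicted damaging missense (pDM: CADD > 20,
#'     PolyPhen-2 > 0.445 and SIFT call "deleterious", all three required);
#'   \item Mask C: all pLoF (HC and LC) plus all missense;
#'   \item Mask D: synonymous (negative control, disjoint from A-C).
#' }
#' and the four nested minor-allele-frequency bins (singleton, <0.01%, <0.1%,
#' <1%; strict inequalities, a singleton belongs to every bin). The MAF is the
#' cohort minor-allele frequency: sites with alt frequency above 0.5 are
#' minor-allele flipped for binning only and flagged.
#'
#' @param annotation Annotation tibble ([read_annotation()] schema).
#' @param afs Tibble with `variant_key`, `ac`, `an` (cohort counts), e.g.
#'   `dplyr::bind_cols(cohort$sites["variant_key"], cohort_allele_counts(cohort))`.
#' @return A tibble with per-variant class, `pdm` flag, `mask_a`..`mask_d`
#'   memberships, `mac`, `maf`, nested bin flags `bin_singleton`,
#'   `bin_lt_0001`, `bin_lt_001`, `bin_lt_01` and `af_flipped`.
#' @export
assign_masks <- function(annotation, afs) {
  known <- c("pLoF-HC", "pLoF-LC", "missense", "synonymous")
  tab <- inner_join(annotation, afs, by = "variant_key")
  unknown <- !tab$consequence %in% known
  if (any(unknown)) {
    warn(sprintf("%d variant(s) with unknown consequence class; set to 'other'",
                 sum(unknown)))
    tab$consequence[unknown] <- "other"
  }
  mis <- tab$consequence == "missense"
  score_na <- mis & (is.na(tab$cadd) | is.na(tab$polyphen) | is.na(tab$sift_call))
  if (any(score_na)) {
    inform(sprintf("%d missense variant(s) missing damage scores; not pDM",
                   sum(score_na)))
  }
  pdm <- mis & !score_na &
    tab$cadd > 20 & tab$polyphen > 0.445 & tab$sift_call == "deleterious"
  alt_af <- ifelse(tab$an > 0, tab$ac / tab$an, NA_real_)
  flipped <- !is.na(alt_af) & alt_af > 0.5
  if (any(flipped)) {
    inform(sprintf("%d site(s) with alt AF > 0.5 minor-allele flipped for binning",
                   sum(flipped)))
  }
  mac <- ifelse(flipped, tab$an - tab$ac, tab$ac)
  maf <- ifelse(flipped, 1 - alt_af, alt_af)
  out <- tibble(
    variant_key = tab$variant_key,
    gene = tab$gene,
    consequence = tab$consequence,
    pdm = pdm,
    mask_a = tab$consequence == "pLoF-HC",
    mask_b = tab$consequence == "pLoF-HC" | pdm,
    mask_c = tab$consequence %in% c("pLoF-HC", "pLoF-LC", "missense"),
    mask_d = tab$consequence == "synonymous",
    mac = as.integer(mac),
    maf = maf,
    af_flipped = flipped,
    bin_singleton = mac == 1L,
    bin_lt_0001 = mac == 1L | maf < 1e-4,
    bin_lt_001 = mac == 1L | maf < 1e-3,
    bin_lt_01 = mac == 1L | maf < 1e-2)
  out
}

#' Mask membership counts
#'
#' @param masks Output of [assign_masks()].
#' @return One-row tibble of per-mask and per-class counts.
#' @export
mask_counts <- function(masks) {
  summarise(masks,
            n_total = n(),
            n_mask_a = sum(.data$mask_a),
            n_mask_b = sum(.data$mask_b),
            n_mask_c = sum(.data$mask_c),
            n_mask_d = sum(.data$mask_d),
            n_plof_hc = sum(.data$consequence == "pLoF-HC"),
            n_plof_lc = sum(.data$consequence == "pLoF-LC"),
            n_missense = sum(.data$consequence == "missense"),
            n_pdm = sum(.data$pdm),
            n_synonymous = sum(.data$consequence == "synonymous"),
            n_other = sum(!.data$consequence %in%
                            c("pLoF-HC", "pLoF-LC", "missense", "synonymous")))
}

af_bin_column <- function(cutoff) {
  switch(as.character(cutoff),
         "singleton" = "bin_singleton",
         "1e-04" = "bin_lt_0001",
         "0.001" = "bin_lt_001",
         "0.01" = "bin_lt_01",
         abort(sprintf("unknown AF cutoff '%s' (use 'singleton', 1e-4, 1e-3 or 1e-2)",
                       cutoff)))
}

mask_column <- function(mask) {
  mask <- toupper(mask)
  if (!mask %in% c("A", "B", "C", "D")) abort("mask must be one of A, B, C, D")
  paste0("mask_", tolower(mask))
}

#' Variant keys qualifying under a mask and AF cutoff
#'
#' @param masks Output of [assign_masks()].
#' @param mask One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param af_cutoff `"singleton"` or one of `1e-4`, `1e-3`, `1e-2`.
#' @return Character vector of variant keys.
#' @export
qualifying_variants <- function(masks, mask = "A", af_cutoff = 0.01) {
  sel <- masks[[mask_column(mask)]] & masks[[af_bin_column(af_cutoff)]]
  masks$variant_key[sel]
}

#' Cohort-versus-reference allele-frequency enrichment
#'
#' For each variant, tests whether the alt allele is more frequent in the
#' cohort than in a reference panel using the two-sided Fisher exact test on
#' the 2x2 allele-count table (alt/ref x cohort/reference). The reported odds
#' ratio is the sample cross-product (with a 0.5 continuity correction for
#' display only when a cell is zero); the P value is exact. Significance is
#' flagged at the Bonferroni level `0.05 / n_tests`.
#'
#' @param counts Tibble with `variant_key`, `ac`, `an`, `ref_panel_ac`,
#'   `ref_panel_an`.
#' @param n_tests Number of tests for the Bonferroni threshold (default
#'   `nrow(counts)`).
#' @param alpha Family-wise error rate.
#' @return Tibble with `or`, `p`, `bonferroni_significant`.
#' @export
reference_enrichment <- function(counts, n_tests = nrow(counts), alpha = 0.05) {
  stopifnot(all(c("ac", "an", "ref_panel_ac", "ref_panel_an") %in% names(counts)),
            all(counts$an > 0), all(counts$ref_panel_an > 0))
  a <- counts$ac                       # cohort alt
  b <- counts$an - counts$ac           # cohort ref
  c_ <- counts$ref_panel_ac            # reference alt
  d <- counts$ref_panel_an - counts$ref_panel_ac
  or <- (a * d) / (b * c_)
  zero <- a == 0 | b == 0 | c_ == 0 | d == 0
  or[zero] <- ((a + 0.5) * (d + 0.5) / ((b + 0.5) * (c_ + 0.5)))[zero]
  p <- vapply(seq_len(nrow(counts)), function(i) {
    fisher.test(matrix(c(a[i], b[i], c_[i], d[i]), 2))$p.value
  }, numeric(1))
  tibble(variant_key = counts$variant_key, or = or, p = p,
         bonferroni_significant = p < alpha / n_tests)
}
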