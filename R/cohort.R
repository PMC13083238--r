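#' Cohort genotype container
#'
#' Central data model for the pipeline: sample ids, a variant site table and
#' dense genotype / haplotype / phasing-probability matrices. Genotypes are
#' alt-allele dosages in `{0, 1, 2}` with `NA` for missing; `hap1`/`hap2` give
#' the reported alt-allele carriage of the two haplotypes where phase is known;
#' `pp` holds the reported phasing probability for phased heterozygous
#' genotypes (NA elsewhere).
#'
#' @param samples Character vector of sample ids.
#' @param sites Tibble with columns `variant_key`, `chrom`, `pos`, `ref`,
#'   `alt`, `gene` (site keys must be unique).
#' @param gt Integer matrix `n_samples x n_sites`.
#' @param hap1,hap2 Optional 0/1 matrices of reported phase.
#' @param pp Optional numeric matrix of phasing probabilities.
#' @param truth Optional list of generator truth (per-sample `f`, true
#'   haplotype matrices, true site MAFs) retained for evaluation only.
#'
#' @return An object of class `rare_cohort`.
#' @export
rare_cohort <- function(samples, sites, gt, hap1 = NULL, hap2 = NULL,
                        pp = NULL, truth = list()) {
  samples <- as.character(samples)
  stopifnot(is_tibble(sites) || is.data.frame(sites))
  sites <- as_tibble(sites)
  need <- c("variant_key", "chrom", "pos", "ref", "alt", "gene")
  missing_cols <- setdiff(need, names(sites))
  if (length(missing_cols)) {
    abort(paste("site table missing column(s):", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(sites$variant_key)) abort("duplicate variant keys in site table")
  stopifnot(is.matrix(gt), nrow(gt) == length(samples), ncol(gt) == nrow(sites))
  dimnames(gt) <- list(samples, sites$variant_key)
  for (m in list(hap1, hap2, pp)) {
    if (!is.null(m)) stopifnot(all(dim(m) == dim(gt)))
  }
  if (!is.null(hap1)) dimnames(hap1) <- dimnames(gt)
  if (!is.null(hap2)) dimnames(hap2) <- dimnames(gt)
  if (!is.null(pp)) dimnames(pp) <- dimnames(gt)
  obj <- structure(list(samples = samples, sites = sites, gt = gt,
                        hap1 = hap1, hap2 = hap2, pp = pp, truth = truth),
                   class = "rare_cohort")
  obj$sites <- bind_cols(sites[setdiff(names(sites), c("ac", "an", "af"))],
                         cohort_allele_counts(obj))
  obj
}

#' Per-site allele counts from the genotype matrix
#'
#' Recomputes alt-allele count (AC), called allele number (AN, excluding
#' missing genotypes) and alt-allele frequency per site.
#'
#' @param cohort A [rare_cohort()].
#' @return Tibble with `ac`, `an`, `af` (one row per site).
#' @export
cohort_allele_counts <- function(cohort) {
  gt <- cohort$gt
  ac <- colSums(gt, na.rm = TRUE)
  an <- 2L * colSums(!is.na(gt))
  tibble(ac = as.integer(ac), an = as.integer(an),
         af = ifelse(an > 0, ac / an, NA_real_))
}

#' @export
print.rare_cohort <- function(x, ...) {
  n_phased <- if (is.null(x$pp)) 0L else sum(!is.na(x$pp))
  cat(sprintf("<rare_cohort> %d samples x %d sites (%d genes); %d phased het genotypes\n",
              length(x$samples), nrow(x$sites),
              length(unique(x$sites$gene)), n_phased))
  invisible(x)
}

#' Long-format view of cohort genotypes
#'
#' Returns one row per non-reference, non-missing genotype (a sparse view,
#' appropriate for rare variation) with reported phase and phasing probability
#' where available.
#'
#' @param x A `rare_cohort`.
#' @param ... Unused.
#' @export
as_tibble.rare_cohort <- function(x, ...) {
  idx <- which(x$gt != 0 & !is.na(x$gt), arr.ind = TRUE)
  out <- tibble(
    sample_id = x$samples[idx[, 1]],
    variant_key = x$sites$variant_key[idx[, 2]],
    gt = x$gt[idx],
    hap1 = if (is.null(x$hap1)) NA_integer_ else x$hap1[idx],
    hap2 = if (is.null(x$hap2)) NA_integer_ else x$hap2[idx],
    pp = if (is.null(x$pp)) NA_real_ else x$pp[idx])
  left_join(out, select(x$sites, "variant_key", "gene"), by = "variant_key") |>
    arrange(.data$variant_key, .data$sample_id)
}

site_cols <- function(cohort, keys) match(keys, cohort$sites$variant_key)
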