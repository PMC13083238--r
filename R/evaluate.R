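#' True compound-heterozygous pairs from generator truth
#'
#' A sample x gene is a true compound heterozygote when, restricted to the
#' given qualifying variants, both true haplotypes carry at least one
#' qualifying allele and no single qualifying site is homozygous (otherwise
#' the sample is a homozygote for that gene).
#'
#' @param cohort A simulated [rare_cohort()] with truth haplotypes.
#' @param keys Qualifying variant keys (default: all sites).
#' @return Tibble `sample_id`, `gene`.
#' @export
true_comphet_pairs <- function(cohort, keys = NULL) {
  sites <- cohort$sites
  use <- if (is.null(keys)) rep(TRUE, nrow(sites)) else sites$variant_key %in% keys
  h1 <- cohort$truth$hap1; h2 <- cohort$truth$hap2
  out <- list()
  for (g in unique(sites$gene)) {
    cols <- which(sites$gene == g & use)
    if (length(cols) < 2) next
    a1 <- rowSums(h1[, cols, drop = FALSE]) > 0
    a2 <- rowSums(h2[, cols, drop = FALSE]) > 0
    hom <- rowSums(h1[, cols, drop = FALSE] * h2[, cols, drop = FALSE]) > 0
    ch <- which(a1 & a2 & !hom)
    if (length(ch)) {
      out[[g]] <- tibble(sample_id = cohort$samples[ch], gene = g)
    }
  }
  if (length(out)) bind_rows(out) else tibble(sample_id = character(),
                                              gene = character())
}

#' Compound-heterozygote precision and recall against truth
#'
#' Compares the calls of [call_compound_hets()] (made from the reported,
#' possibly noisy phase) with the true trans pairs retained by the generator.
#'
#' @param cohort A simulated [rare_cohort()].
#' @param masks Output of [assign_masks()].
#' @param mask,af_cutoff,phase_prob_threshold As in [call_compound_hets()].
#' @return One-row tibble: `n_true`, `n_called`, `n_correct`, `precision`,
#'   `recall` (NA when undefined).
#' @export
comphet_recovery <- function(cohort, masks, mask = "A", af_cutoff = 0.01,
                             phase_prob_threshold = 0.9) {
  keys <- qualifying_variants(masks, mask, af_cutoff)
  truth <- true_comphet_pairs(cohort, keys)
  # homozygote precedence applies on the called side exactly as in the truth
  # classification: a sample hom at a qualifying site is not a comp-het
  called <- combine_biallelic_calls(
    find_homozygotes(cohort, masks, mask, af_cutoff),
    call_compound_hets(cohort, masks, mask, af_cutoff,
                       phase_prob_threshold)) |>
    filter(.data$class == "comp-het")
  key <- function(d) paste(d$sample_id, d$gene)
  n_correct <- sum(key(called) %in% key(truth))
  tibble(n_true = nrow(truth), n_called = nrow(called), n_correct = n_correct,
         precision = if (nrow(called)) n_correct / nrow(called) else NA_real_,
         recall = if (nrow(truth)) n_correct / nrow(truth) else NA_real_)
}
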