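#' Homozygous biallelic calls
#'
#' Emits one call per genotype-2 entry at a qualifying site (mask and MAF
#' cutoff applied to the site annotation).
#'
#' @param cohort A [rare_cohort()].
#' @param masks Output of [assign_masks()].
#' @param mask Mask letter (`"A"`..`"D"`).
#' @param af_cutoff `"singleton"` or a strict MAF cutoff (1e-4, 1e-3, 1e-2).
#' @return Tibble of calls: `sample_id`, `gene`, `class = "hom"`, `var1`,
#'   `var2 = NA`, `pp = NA`.
#' @export
find_homozygotes <- function(cohort, masks, mask = "A", af_cutoff = 0.01) {
  keys <- qualifying_variants(masks, mask, af_cutoff)
  cols <- site_cols(cohort, keys)
  cols <- cols[!is.na(cols)]
  if (!length(cols)) return(empty_calls())
  sub <- cohort$gt[, cols, drop = FALSE]
  idx <- which(!is.na(sub) & sub == 2L, arr.ind = TRUE)
  if (!nrow(idx)) return(empty_calls())
  tibble(sample_id = cohort$samples[idx[, 1]],
         gene = cohort$sites$gene[cols[idx[, 2]]],
         class = "hom",
         var1 = cohort$sites$variant_key[cols[idx[, 2]]],
         var2 = NA_character_,
         pp = NA_real_)
}

empty_calls <- function() {
  tibble(sample_id = character(), gene = character(), class = character(),
         var1 = character(), var2 = character(), pp = numeric())
}

#' Compound-heterozygote calls from reported phase
#'
#' For each sample and gene, looks for two distinct qualifying heterozygous
#' variants reported on opposite haplotypes (in trans). The pair's phasing
#' probability is the minimum of the two genotypes' reported probabilities and
#' must exceed `phase_prob_threshold` (strictly). If several trans pairs
#' qualify, the best-supported pair (largest pair probability, then smallest
#' positions) is reported, so each sample contributes at most one
#' compound-heterozygote call per gene. Cis pairs and unphased heterozygotes
#' never produce calls; unphasable pairs are tallied per gene in the
#' `"unphasable"` attribute.
#'
#' @inheritParams find_homozygotes
#' @param phase_prob_threshold Minimum (exclusive) pair phasing probability.
#' @return Tibble of calls (`class = "comp-het"`, `var1`/`var2` the trans
#'   pair, `pp` the pair probability).
#' @export
call_compound_hets <- function(cohort, masks, mask = "A", af_cutoff = 0.01,
                               phase_prob_threshold = 0.9) {
  keys <- qualifying_variants(masks, mask, af_cutoff)
  cols <- site_cols(cohort, keys)
  cols <- cols[!is.na(cols)]
  unphasable <- integer(0)
  if (length(cols) < 2) {
    return(structure(empty_calls(), unphasable = unphasable))
  }
  gt <- cohort$gt[, cols, drop = FALSE]
  h1 <- cohort$hap1[, cols, drop = FALSE]
  pp <- if (is.null(cohort$pp)) matrix(NA_real_, nrow(gt), ncol(gt)) else
    cohort$pp[, cols, drop = FALSE]
  genes <- cohort$sites$gene[cols]
  pos <- cohort$sites$pos[cols]
  vkey <- cohort$sites$variant_key[cols]
  het <- !is.na(gt) & gt == 1L
  phased <- het & !is.na(h1)
  res <- list()
  unph_tally <- c()
  for (g in unique(genes)) {
    jj <- which(genes == g)
    if (length(jj) < 2) next
    hsub <- phased[, jj, drop = FALSE]
    # samples with >=2 phased qualifying hets in this gene
    cand <- which(rowSums(het[, jj, drop = FALSE]) >= 2)
    n_unph <- 0L
    for (i in cand) {
      on1 <- jj[hsub[i, ] & h1[i, jj] == 1L]
      on2 <- jj[hsub[i, ] & h1[i, jj] == 0L]
      n_unph <- n_unph + sum(het[i, jj] & !hsub[i, ])
      if (!length(on1) || !length(on2)) next
      # best pair = argmax per haplotype of the genotype PP (pair pp = min)
      b1 <- on1[order(-pp[i, on1], pos[on1])][1]
      b2 <- on2[order(-pp[i, on2], pos[on2])][1]
      pair_pp <- min(pp[i, b1], pp[i, b2])
      if (is.na(pair_pp) || pair_pp <= phase_prob_threshold) next
      v <- sort(c(vkey[b1], vkey[b2]))
      res[[length(res) + 1L]] <- tibble(
        sample_id = cohort$samples[i], gene = g, class = "comp-het",
        var1 = v[1], var2 = v[2], pp = pair_pp)
    }
    if (n_unph > 0) unph_tally[g] <- n_unph
  }
  out <- if (length(res)) bind_rows(res) else empty_calls()
  structure(out, unphasable = unph_tally)
}

#' Combine biallelic calls with hom-precedence deduplication
#'
#' @param ... Call tibbles ([find_homozygotes()], [call_compound_hets()]).
#' @return Deduplicated calls: one row per (sample, gene), homozygous calls
#'   taking precedence over compound-heterozygous ones.
#' @export
combine_biallelic_calls <- function(...) {
  calls <- bind_rows(...)
  if (!nrow(calls)) return(empty_calls())
  calls |>
    mutate(.rank = if_else(.data$class == "hom", 1L, 2L)) |>
    arrange(.data$sample_id, .data$gene, .data$.rank, dplyr::desc(.data$pp)) |>
    distinct(.data$sample_id, .data$gene, .keep_all = TRUE) |>
    select(-".rank")
}

#' Recessive 0/1 gene burden
#'
#' Collapses biallelic calls to a per-gene, per-sample 0/1 burden (1 if the
#' sample carries any biallelic genotype in the gene). Genes below the carrier
#' minimum are retained but flagged untestable.
#'
#' @param calls Combined biallelic calls.
#' @param samples Cohort sample ids (defines the 0 rows).
#' @param min_carriers Minimum carriers for a gene to be testable (default 4).
#' @return A list of class `gene_burden`: `carriers` (tibble `gene`,
#'   `sample_id`, `class`), `genes` (tibble `gene`, `n_carriers`, `n_hom`,
#'   `n_comphet`, `testable`), `samples`, `mode = "recessive"`.
#' @export
build_recessive_burden <- function(calls, samples, min_carriers = 4L) {
  calls <- combine_biallelic_calls(calls)
  genes <- calls |>
    group_by(.data$gene) |>
    summarise(n_carriers = dplyr::n_distinct(.data$sample_id),
              n_hom = sum(.data$class == "hom"),
              n_comphet = sum(.data$class == "comp-het"),
              .groups = "drop") |>
    mutate(testable = .data$n_carriers >= min_carriers)
  structure(list(carriers = select(calls, "gene", "sample_id", "class"),
                 genes = genes, samples = samples, mode = "recessive",
                 min_carriers = min_carriers),
            class = "gene_burden")
}

#' Additive gene burden
#'
#' Collapses qualifying-site genotypes per gene, by default as the maximum
#' genotype across sites (in `{0,1,2}`); `collapse = "sum"` sums alt alleles
#' and caps at 2. Genes with no qualifying site are absent.
#'
#' @inheritParams find_homozygotes
#' @param collapse `"max"` (default) or `"sum"` (capped at 2).
#' @return A `gene_burden` list with `matrix` (genes x samples) and `genes`
#'   summary; `mode = "additive"`.
#' @export
build_additive_burden <- function(cohort, masks, mask = "A", af_cutoff = 0.01,
                                  collapse = c("max", "sum")) {
  collapse <- arg_match(collapse)
  keys <- qualifying_variants(masks, mask, af_cutoff)
  cols <- site_cols(cohort, keys)
  cols <- cols[!is.na(cols)]
  genes_all <- cohort$sites$gene[cols]
  mats <- list()
  for (g in unique(genes_all)) {
    sub <- cohort$gt[, cols[genes_all == g], drop = FALSE]
    v <- if (collapse == "max") {
      suppressWarnings(apply(sub, 1, max, na.rm = TRUE))
    } else {
      pmin(rowSums(sub, na.rm = TRUE), 2)
    }
    v[!is.finite(v)] <- NA_real_   # all sites missing for the sample
    all_na <- rowSums(!is.na(sub)) == 0
    v[all_na] <- NA_real_
    mats[[g]] <- v
  }
  bm <- do.call(rbind, mats)
  if (is.null(bm)) bm <- matrix(numeric(0), 0, length(cohort$samples))
  colnames(bm) <- cohort$samples
  genes <- tibble(gene = rownames(bm) %||% character(0),
                  n_carriers = if (nrow(bm)) rowSums(bm > 0, na.rm = TRUE) else integer(0))
  structure(list(matrix = bm, genes = genes, samples = cohort$samples,
                 mode = "additive", collapse = collapse),
            class = "gene_burden")
}

#' Recessive burden as a genes x samples 0/1 matrix
#' @param burden A recessive `gene_burden`.
#' @param testable_only Drop untestable genes.
#' @return Numeric matrix genes x samples.
#' @export
burden_matrix <- function(burden, testable_only = FALSE) {
  if (burden$mode == "additive") return(burden$matrix)
  genes <- burden$genes
  if (testable_only) genes <- filter(genes, .data$testable)
  bm <- matrix(0, nrow(genes), length(burden$samples),
               dimnames = list(genes$gene, burden$samples))
  cc <- filter(burden$carriers, .data$gene %in% genes$gene)
  bm[cbind(match(cc$gene, genes$gene), match(cc$sample_id, burden$samples))] <- 1
  bm
}

#' @export
print.gene_burden <- function(x, ...) {
  cat(sprintf("<gene_burden> mode=%s, %d genes, %d samples\n",
              x$mode, nrow(x$genes), length(x$samples)))
  invisible(x)
}

#' Expected biallelic genotype count under Hardy-Weinberg with inbreeding
#'
#' With gene-level qualifying haplotype frequency `Q = sum(q_i)` (assuming at
#' most one qualifying allele per haplotype), the expected number of biallelic
#' carriers among `n` individuals with inbreeding coefficient `F` is
#' `n (Q^2 + Q (1 - Q) F)`; `F = 0` gives the Hardy-Weinberg reference used
#' for the enrichment ratio.
#'
#' @param q Vector of qualifying-variant allele frequencies in the gene.
#' @param n Number of individuals.
#' @param f Inbreeding coefficient (scalar or mean over the cohort).
#' @return Expected count (numeric scalar).
#' @examples
#' expected_biallelic_hwe(0.01, 1e4)            # 1
#' expected_biallelic_hwe(0.01, 1e4, f = 0.0625) # 7.1875
#' @export
expected_biallelic_hwe <- function(q, n, f = 0) {
  bq <- sum(q)
  if (bq > 0.5) {
    abort(sprintf("gene-level qualifying frequency Q = %.3f > 0.5; the one-qualifying-allele-per-haplotype assumption is violated", bq))
  }
  n * (bq^2 + bq * (1 - bq) * f)
}

#' Per-gene qualifying allele frequencies
#'
#' Named list of cohort allele-frequency vectors for the qualifying variants
#' of each gene (the `gene_afs` input of [autozygosity_enrichment_ratio()]).
#'
#' @inheritParams find_homozygotes
#' @return Named list, one numeric vector per gene with qualifying sites.
#' @export
gene_qualifying_afs <- function(cohort, masks, mask = "A", af_cutoff = 0.01) {
  keys <- qualifying_variants(masks, mask, af_cutoff)
  sites <- filter(cohort$sites, .data$variant_key %in% keys)
  split(sites$af, sites$gene)
}

#' Autozygosity-driven biallelic enrichment over Hardy-Weinberg
#'
#' Compares the observed number of biallelic genotypes per gene with the count
#' expected under Hardy-Weinberg equilibrium (F = 0) at the genes' qualifying
#' allele frequencies. The headline ratio is the ratio of sums across genes
#' (robust to genes with tiny expectations); per-gene ratios and the mean of
#' per-gene ratios are also returned.
#'
#' @param calls Combined biallelic calls.
#' @param gene_afs Named list (or tibble with `gene`, `af` list-column) of
#'   qualifying allele-frequency vectors per gene. Genes with observed calls
#'   but no frequencies are an error.
#' @param n Number of individuals.
#' @return List with `ratio` (ratio of sums), `mean_gene_ratio`, and
#'   `per_gene` tibble (`gene`, `observed`, `expected`, `ratio`).
#' @export
autozygosity_enrichment_ratio <- function(calls, gene_afs, n) {
  calls <- combine_biallelic_calls(calls)
  if (is.data.frame(gene_afs)) {
    gene_afs <- setNames(gene_afs$af, gene_afs$gene)
  }
  obs <- calls |> count(.data$gene, name = "observed")
  missing_genes <- setdiff(obs$gene, names(gene_afs))
  if (length(missing_genes)) {
    abort(paste("no allele frequencies for gene(s):",
                paste(head(missing_genes, 5), collapse = ", ")))
  }
  per_gene <- tibble(gene = names(gene_afs)) |>
    left_join(obs, by = "gene") |>
    mutate(observed = dplyr::coalesce(.data$observed, 0L),
           expected = map_dbl(gene_afs[.data$gene],
                              ~ expected_biallelic_hwe(.x, n, f = 0)),
           ratio = .data$observed / .data$expected)
  tot_exp <- sum(per_gene$expected)
  if (tot_exp <= 0) abort("total Hardy-Weinberg expectation is zero")
  list(ratio = sum(per_gene$observed) / tot_exp,
       mean_gene_ratio = mean(per_gene$ratio[is.finite(per_gene$ratio)]),
       per_gene = per_gene)
}
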