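#' Additive association scan: single variants and gene burdens
#'
#' Runs the covariate-adjusted additive scan over (i) every variant with minor
#' allele count at or above `min_mac` and (ii) gene burdens for each requested
#' mask x AF-cutoff combination. Quantitative traits use exact OLS (vectorized
#' across units); binary traits use logistic regression with the Firth
#' fallback of [logistic_assoc()]. Trait inclusion thresholds default to at
#' least 5,000 measured values (quantitative) and 100 cases (binary). Genes in
#' `exclude_genes` (e.g. olfactory receptors, the MHC region) are removed from
#' both arms.
#'
#' @param cohort A [rare_cohort()].
#' @param phenotypes Tibble `sample_id` + one column per trait.
#' @param covariates Tibble `sample_id` + numeric covariates.
#' @param masks Output of [assign_masks()].
#' @param traits Traits to test (default: all phenotype columns).
#' @param min_mac Minimum minor allele count for the single-variant arm.
#' @param use_masks Mask letters for the burden arm.
#' @param af_cutoffs AF cutoffs for the burden arm (`"singleton"`, 1e-4, 1e-3,
#'   1e-2).
#' @param exclude_genes Genes excluded from testing.
#' @param quant_min_n,binary_min_cases Trait inclusion thresholds.
#' @param collapse Burden collapse rule (see [build_additive_burden()]).
#' @param rint Rank-inverse-normalize quantitative traits.
#' @param firth_trigger_p Firth trigger for binary traits.
#' @return An `assoc_scan` tibble: `unit`, `unit_type`, `gene`, `mask`,
#'   `af_cutoff`, `trait`, `model`, `beta`, `se`, `p`, `n`, `n_cases`, `mac`,
#'   `firth_applied`.
#' @export
run_additive_scan <- function(cohort, phenotypes, covariates, masks,
                              traits = NULL, min_mac = 5L,
                              use_masks = c("A", "B", "C", "D"),
                              af_cutoffs = list("singleton", 1e-4, 1e-3, 1e-2),
                              exclude_genes = NULL,
                              quant_min_n = 5000L, binary_min_cases = 100L,
                              collapse = "max", rint = FALSE,
                              firth_trigger_p = 0.01) {
  traits <- traits %||% setdiff(names(phenotypes), "sample_id")
  units <- scan_units(cohort, masks, min_mac, use_masks, af_cutoffs,
                      exclude_genes, collapse)
  run_scan_units(units, cohort$samples, phenotypes, covariates, traits,
                 quant_min_n, binary_min_cases, rint, firth_trigger_p)
}

# assemble the dosage matrix and metadata of all scan units
scan_units <- function(cohort, masks, min_mac, use_masks, af_cutoffs,
                       exclude_genes, collapse) {
  sites <- cohort$sites
  mac <- pmin(sites$ac, sites$an - sites$ac)
  sv_keep <- mac >= min_mac & !sites$gene %in% exclude_genes
  G <- list(); meta <- list()
  if (any(sv_keep)) {
    G$sv <- cohort$gt[, sv_keep, drop = FALSE]
    meta$sv <- tibble(unit = sites$variant_key[sv_keep], unit_type = "variant",
                      gene = sites$gene[sv_keep], mask = NA_character_,
                      af_cutoff = NA_character_,
                      mac = as.integer(mac[sv_keep]))
  }
  for (mk in use_masks) {
    for (co in af_cutoffs) {
      b <- build_additive_burden(cohort, masks, mask = mk, af_cutoff = co,
                                 collapse = collapse)
      bm <- b$matrix
      bm <- bm[!rownames(bm) %in% exclude_genes, , drop = FALSE]
      if (!nrow(bm)) next
      key <- paste(mk, co, sep = "_")
      G[[key]] <- t(bm)
      meta[[key]] <- tibble(unit = paste(rownames(bm), mk, as.character(co),
                                         sep = ":"),
                            unit_type = "burden", gene = rownames(bm),
                            mask = mk, af_cutoff = as.character(co),
                            mac = as.integer(colSums(t(bm) > 0, na.rm = TRUE)))
    }
  }
  list(G = do.call(cbind, G), meta = bind_rows(meta))
}

run_scan_units <- function(units, samples, phenotypes, covariates, traits,
                           quant_min_n, binary_min_cases, rint,
                           firth_trigger_p) {
  G <- units$G
  meta <- units$meta
  if (is.null(G) || !ncol(G)) abort("no testable units")
  ph <- as_tibble(phenotypes)[match(samples, phenotypes$sample_id), , drop = FALSE]
  cv <- covar_matrix(covariates, samples)
  eligible <- keep(traits, function(tr) {
    y <- ph[[tr]]
    if (all(na.omit(y) %in% c(0, 1))) sum(y == 1, na.rm = TRUE) >= binary_min_cases
    else sum(!is.na(y)) >= quant_min_n
  })
  if (!length(eligible)) abort("no eligible traits at the inclusion thresholds")
  out <- list()
  for (tr in eligible) {
    y <- ph[[tr]]
    binary <- all(na.omit(y) %in% c(0, 1))
    ok <- complete.cases(y, cv)
    Xc <- cbind(1, cv[ok, , drop = FALSE])
    if (!binary) {
      yy <- if (rint) rank_inverse_normal(y[ok]) else y[ok]
      res <- ols_scan(yy, Xc, G[ok, , drop = FALSE])
      res <- bind_cols(meta, res) |>
        mutate(trait = tr, model = "additive", n = sum(ok),
               n_cases = NA_integer_, firth_applied = FALSE)
    } else {
      res <- map(seq_len(ncol(G)), function(j) {
        g <- G[ok, j]
        r <- tryCatch(
          logistic_assoc(y[ok], g, covariates = as.data.frame(cv[ok, , drop = FALSE]),
                         firth_trigger_p = firth_trigger_p),
          error = function(e) tibble(model = "additive", beta = NA_real_,
                                     se = NA_real_, p = NA_real_,
                                     n = sum(ok),
                                     n_cases = as.integer(sum(y[ok] == 1)),
                                     firth_applied = FALSE))
        r
      }) |> list_rbind()
      res <- bind_cols(meta, select(res, -"model")) |>
        mutate(trait = tr, model = "additive")
    }
    out[[tr]] <- res
  }
  structure(bind_rows(out) |>
              select("unit", "unit_type", "gene", "mask", "af_cutoff",
                     "trait", "model", "beta", "se", "p", "n", "n_cases",
                     "mac", "firth_applied"),
            class = c("assoc_scan", "tbl_df", "tbl", "data.frame"))
}

#' Recessive burden association scan
#'
#' Tests each testable gene's 0/1 recessive burden against the supplied
#' traits with covariate adjustment (linear or logistic with Firth fallback
#' according to the trait). If an additive burden is supplied, the additive P
#' for the same gene/trait is reported alongside for comparison.
#'
#' @param burden Recessive [build_recessive_burden()] result.
#' @param phenotypes,covariates As in [run_additive_scan()].
#' @param traits Traits to test (default all).
#' @param additive_burden Optional additive `gene_burden` for the side-by-side
#'   additive P.
#' @param quant_min_n,binary_min_cases Trait-inclusion thresholds (defaults
#'   5,000 measured / 120 cases).
#' @param rint,firth_trigger_p See [run_additive_scan()].
#' @return An `assoc_scan` tibble with `model = "recessive"` and, when the
#'   additive burden is given, `p_add`/`beta_add` columns.
#' @export
run_recessive_scan <- function(burden, phenotypes, covariates, traits = NULL,
                               additive_burden = NULL,
                               quant_min_n = 5000L, binary_min_cases = 120L,
                               rint = FALSE, firth_trigger_p = 0.01) {
  stopifnot(inherits(burden, "gene_burden"), burden$mode == "recessive")
  bm <- burden_matrix(burden, testable_only = TRUE)
  if (!nrow(bm)) abort("no testable genes (carrier minimum not met)")
  samples <- burden$samples
  units <- list(G = t(bm),
                meta = tibble(unit = rownames(bm), unit_type = "recessive_burden",
                              gene = rownames(bm), mask = NA_character_,
                              af_cutoff = NA_character_,
                              mac = as.integer(rowSums(bm))))
  traits <- traits %||% setdiff(names(phenotypes), "sample_id")
  res <- run_scan_units(units, samples, phenotypes, covariates, traits,
                        quant_min_n, binary_min_cases, rint, firth_trigger_p) |>
    mutate(model = "recessive")
  if (!is.null(additive_burden)) {
    am <- burden_matrix(additive_burden)
    common <- intersect(rownames(am), res$gene)
    if (length(common)) {
      add_units <- list(G = t(am[common, , drop = FALSE]),
                        meta = tibble(unit = common, unit_type = "burden",
                                      gene = common, mask = NA_character_,
                                      af_cutoff = NA_character_,
                                      mac = as.integer(rowSums(am[common, , drop = FALSE]))))
      add <- run_scan_units(add_units, additive_burden$samples, phenotypes,
                            covariates, traits, quant_min_n, binary_min_cases,
                            rint, firth_trigger_p) |>
        select("gene", "trait", beta_add = "beta", p_add = "p")
      res <- left_join(res, add, by = c("gene", "trait"))
    }
  }
  structure(res, class = c("assoc_scan", "tbl_df", "tbl", "data.frame"))
}

#' @export
glance.assoc_scan <- function(x, ...) {
  tibble(n_units = dplyr::n_distinct(x$unit),
         n_traits = dplyr::n_distinct(x$trait),
         n_tests = sum(!is.na(x$p)),
         lambda = genomic_lambda(p = x$p[!is.na(x$p)]),
         min_p = suppressWarnings(min(x$p, na.rm = TRUE)))
}

#' @export
tidy.assoc_scan <- function(x, ...) as_tibble(x)
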