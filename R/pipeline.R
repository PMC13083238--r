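#' Run the synthetic end-to-end pipeline from a configuration
#'
#' Orchestrates the stages on a simulated cohort: simulate, write/read the
#' VCF and tables, assign masks, call biallelic genotypes, build burdens, run
#' the additive and recessive scans, optionally derive the permutation-FDR
#' threshold and build the knockout catalog. Writes every stage artifact as
#' TSV/VCF under `output_dir` plus a JSON run manifest with seeds, row counts
#' and file checksums; a rerun with the same config reproduces identical
#' checksums.
#'
#' @param config A YAML file path or a list. Recognized keys (with defaults):
#'   `output_dir` (required), `seed` (1), `sim` (list passed to
#'   [sim_config()]), `trait` (list passed to [true_model()] minus genes),
#'   `n_causal_recessive` (3), `rec_effect` (1),
#'   `mask` ("A"), `af_cutoff` (0.01), `phase_prob_threshold` (0.9),
#'   `min_mac` (5), `min_carriers` (4), `firth_trigger_p` (0.01),
#'   `quant_min_n` (0), `binary_min_cases` (0), `run_permfdr` (FALSE),
#'   `n_permutations` (100), `target_fdr` (0.05).
#' @return A list of stage results (`cohort`, `masks`, `calls`, `burden`,
#'   `additive_scan`, `recessive_scan`, `fdr`, `catalog`, `manifest`),
#'   invisibly writing the artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$output_dir)) abort("config needs an output_dir")
  defaults <- list(seed = 1L, sim = list(), n_causal_recessive = 3L,
                   rec_effect = 1, mask = "A", af_cutoff = 0.01,
                   phase_prob_threshold = 0.9, min_mac = 5L, min_carriers = 4L,
                   firth_trigger_p = 0.01, quant_min_n = 0L,
                   binary_min_cases = 0L, run_permfdr = FALSE,
                   n_permutations = 100L, target_fdr = 0.05)
  config <- modifyList(defaults, config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out_path <- function(f) file.path(config$output_dir, f)

  cfg <- do.call(sim_config, modifyList(list(seed = config$seed), config$sim))
  cohort <- simulate_cohort(cfg)
  ann <- annotation_table(cohort)
  genes <- unique(cohort$sites$gene)
  causal <- head(genes, config$n_causal_recessive)
  model <- true_model(genes = causal, rec_beta = config$rec_effect)
  sim <- simulate_phenotypes(cohort, model, seed = config$seed)

  write_vcf(cohort, out_path("cohort.vcf"))
  readr::write_tsv(ann, out_path("annotation.tsv"))
  readr::write_tsv(sim$phenotypes, out_path("phenotypes.tsv"))
  readr::write_tsv(sim$covariates, out_path("covariates.tsv"))
  readr::write_tsv(tibble(sample_id = cohort$samples, f = cohort$truth$f),
                   out_path("sample_f.tsv"))
  readr::write_tsv(model$effects, out_path("true_effects.tsv"))

  afs <- bind_cols(cohort$sites["variant_key"], cohort_allele_counts(cohort))
  masks <- assign_masks(ann, afs)
  readr::write_tsv(masks, out_path("masks.tsv"))

  hom <- find_homozygotes(cohort, masks, config$mask, config$af_cutoff)
  ch <- call_compound_hets(cohort, masks, config$mask, config$af_cutoff,
                           config$phase_prob_threshold)
  calls <- combine_biallelic_calls(hom, ch)
  readr::write_tsv(calls, out_path("biallelic_calls.tsv"))

  burden <- build_recessive_burden(calls, cohort$samples, config$min_carriers)
  readr::write_tsv(burden$genes, out_path("recessive_burden_genes.tsv"))
  add_burden <- build_additive_burden(cohort, masks, config$mask,
                                      config$af_cutoff)

  additive_scan <- run_additive_scan(
    cohort, sim$phenotypes, sim$covariates, masks,
    min_mac = config$min_mac, use_masks = config$mask,
    af_cutoffs = list(config$af_cutoff),
    quant_min_n = config$quant_min_n,
    binary_min_cases = config$binary_min_cases,
    firth_trigger_p = config$firth_trigger_p)
  readr::write_tsv(as_tibble(additive_scan), out_path("additive_scan.tsv"))

  recessive_scan <- tryCatch(
    run_recessive_scan(burden, sim$phenotypes, sim$covariates,
                       additive_burden = add_burden,
                       quant_min_n = config$quant_min_n,
                       binary_min_cases = config$binary_min_cases,
                       firth_trigger_p = config$firth_trigger_p),
    error = function(e) NULL)
  if (!is.null(recessive_scan)) {
    readr::write_tsv(as_tibble(recessive_scan), out_path("recessive_scan.tsv"))
  }

  fdr <- NULL
  if (isTRUE(config$run_permfdr) && !is.null(recessive_scan)) {
    scan_fun <- function(co) {
      b <- build_recessive_burden(
        combine_biallelic_calls(
          find_homozygotes(co, masks, config$mask, config$af_cutoff),
          call_compound_hets(co, masks, config$mask, config$af_cutoff,
                             config$phase_prob_threshold)),
        co$samples, config$min_carriers)
      res <- tryCatch(
        run_recessive_scan(b, sim$phenotypes, sim$covariates,
                           quant_min_n = config$quant_min_n,
                           binary_min_cases = config$binary_min_cases),
        error = function(e) NULL)
      if (is.null(res)) numeric(0) else res$p
    }
    fdr <- permutation_fdr(cohort, scan_fun, config$n_permutations,
                           seed = config$seed, target_fdr = config$target_fdr)
    readr::write_tsv(glance(fdr), out_path("fdr_threshold.tsv"))
  }

  catalog <- build_catalog(calls, masks)
  readr::write_tsv(catalog$gene_summary, out_path("knockout_catalog.tsv"))

  files <- list.files(config$output_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("autoburden")),
    seed = config$seed,
    n_samples = length(cohort$samples),
    n_sites = nrow(cohort$sites),
    n_biallelic_calls = nrow(calls),
    n_testable_genes = sum(burden$genes$testable),
    n_scan_rows = nrow(additive_scan),
    n_knockout_genes = catalog$n_genes,
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort = cohort, masks = masks, calls = calls,
                 burden = burden, additive_scan = additive_scan,
                 recessive_scan = recessive_scan, fdr = fdr,
                 catalog = catalog, manifest = manifest,
                 truth = list(model = model, sim = sim)))
}
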