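#' Build the human-knockout catalog
#'
#' A human knockout is a homozygous or compound-heterozygous carrier of
#' high-confidence predicted loss-of-function variants with cohort MAF < 1%
#' in a gene. Calls are restricted to mask A at the < 1% cutoff and
#' deduplicated per (sample, gene) with homozygous precedence.
#'
#' @param calls Biallelic calls (from [find_homozygotes()] /
#'   [call_compound_hets()] run on mask `"A"`, cutoff 0.01, or broader; the
#'   mask restriction is re-applied here).
#' @param masks Output of [assign_masks()].
#' @param maf_cutoff Strict MAF cutoff (default 0.01).
#' @return An object of class `knockout_catalog`: `records` tibble,
#'   `gene_summary` tibble and scalar counts.
#' @export
build_catalog <- function(calls, masks, maf_cutoff = 0.01) {
  qualifying <- masks$variant_key[masks$mask_a & masks$maf < maf_cutoff]
  records <- combine_biallelic_calls(calls) |>
    filter(.data$var1 %in% qualifying,
           is.na(.data$var2) | .data$var2 %in% qualifying)
  gene_summary <- records |>
    group_by(.data$gene) |>
    summarise(n_carriers = dplyr::n_distinct(.data$sample_id),
              n_hom = sum(.data$class == "hom"),
              n_comphet = sum(.data$class == "comp-het"),
              .groups = "drop")
  structure(list(records = records, gene_summary = gene_summary,
                 n_genes = nrow(gene_summary),
                 n_hom = sum(records$class == "hom"),
                 n_comphet = sum(records$class == "comp-het")),
            class = "knockout_catalog")
}

#' @export
print.knockout_catalog <- function(x, ...) {
  cat(sprintf("<knockout_catalog> %d genes; %d homozygous and %d compound-heterozygous genotypes\n",
              x$n_genes, x$n_hom, x$n_comphet))
  invisible(x)
}

#' @export
tidy.knockout_catalog <- function(x, ...) x$records

#' @export
glance.knockout_catalog <- function(x, ...) {
  tibble(n_genes = x$n_genes, n_genotypes = nrow(x$records),
         n_hom = x$n_hom, n_comphet = x$n_comphet)
}

#' Knockout gene accrual under downsampling
#'
#' Estimates the expected number of genes with at least one knockout carrier
#' as a function of sample size, by repeatedly sampling subsets of individuals
#' without replacement.
#'
#' @param catalog A [build_catalog()] result.
#' @param samples All cohort sample ids (carriers and noncarriers).
#' @param grid Sample sizes (each at most `length(samples)`).
#' @param n_repeats Downsampling repeats per grid point.
#' @param seed Integer seed.
#' @return An `accrual_curve` tibble: `n`, `mean_genes`, `sd_genes`,
#'   `n_repeats`.
#' @export
accrual_curve <- function(catalog, samples, grid, n_repeats = 10L, seed = 1L) {
  stopifnot(all(grid <= length(samples)), all(grid >= 0))
  set.seed(seed)
  rec <- catalog$records
  reps <- map(seq_len(n_repeats), function(r) {
    ord <- sample(samples)   # one shuffle per repeat => nested subsets, monotone
    pos <- match(rec$sample_id, ord)
    vapply(grid, function(k) dplyr::n_distinct(rec$gene[pos <= k]), integer(1))
  })
  mat <- do.call(cbind, reps)
  out <- tibble(n = as.integer(grid),
                mean_genes = rowMeans(mat),
                sd_genes = apply(mat, 1, sd),
                n_repeats = as.integer(n_repeats))
  structure(out, class = c("accrual_curve", class(out)))
}

#' @rdname autoplot_methods
#' @export
autoplot.accrual_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data$mean_genes)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_genes - .data$sd_genes,
                                      ymax = .data$mean_genes + .data$sd_genes),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sample size", y = "genes with >= 1 knockout",
                  title = "Knockout gene accrual") +
    ggplot2::theme_minimal()
}

#' Carrier-level phenotype review statistic
#'
#' Compares trait values of knockout carriers with a noncarrier reference.
#' With a single carrier, a z-test on the log scale:
#' `z = (x - mean(log noncarriers)) / sd(log noncarriers)`, two-sided normal
#' P. With two or more carriers, the Wilcoxon rank-sum test on log-transformed
#' values. The log transform is skipped (with a flag) when any value is
#' non-positive. Noncarrier matching (age, sex, ancestry, BMI windows) is the
#' caller's responsibility via [match_noncarriers()].
#'
#' @param carrier_values Trait values of carriers (length >= 1).
#' @param noncarrier_values Trait values of the (matched) noncarrier set.
#' @return One-row tibble: `method` ("z" or "wilcoxon"), `statistic`, `p`,
#'   `log_scale`, `n_carriers`, `n_noncarriers`,
#'   `percent_difference` (of carrier median vs noncarrier median, raw scale).
#' @export
carrier_phenotype_test <- function(carrier_values, noncarrier_values) {
  stopifnot(length(carrier_values) >= 1, length(noncarrier_values) >= 2)
  log_ok <- all(c(carrier_values, noncarrier_values) > 0)
  cv <- if (log_ok) log(carrier_values) else carrier_values
  nv <- if (log_ok) log(noncarrier_values) else noncarrier_values
  if (!log_ok) warn("non-positive trait values; log transform skipped")
  pct <- percent_difference(median(carrier_values), median(noncarrier_values))
  if (length(carrier_values) == 1) {
    z <- (cv - mean(nv)) / sd(nv)
    tibble(method = "z", statistic = z, p = 2 * pnorm(-abs(z)),
           log_scale = log_ok, n_carriers = 1L,
           n_noncarriers = length(noncarrier_values),
           percent_difference = pct)
  } else {
    wt <- wilcox.test(cv, nv)
    tibble(method = "wilcoxon", statistic = unname(wt$statistic), p = wt$p.value,
           log_scale = log_ok, n_carriers = length(carrier_values),
           n_noncarriers = length(noncarrier_values),
           percent_difference = pct)
  }
}

#' Percent difference of a carrier value relative to a reference
#'
#' `100 * (reference - value) / reference`; positive when the carrier value is
#' lower (e.g. a 62% reduction).
#'
#' @param value Carrier value (or median).
#' @param reference Noncarrier reference value (or median).
#' @export
percent_difference <- function(value, reference) {
  100 * (reference - value) / reference
}

#' Matched noncarrier selection
#'
#' Selects noncarriers within the matching windows (age within `age_window`
#' years, same sex, same ancestry when given, BMI within `bmi_window`). If
#' fewer than `min_matches` noncarriers qualify, all noncarriers are returned
#' with a warning.
#'
#' @param carrier One-row tibble/list with the carrier's `age`, `sex` and
#'   optionally `ancestry`, `bmi`.
#' @param noncarriers Tibble of noncarriers with the same columns plus the
#'   trait.
#' @param age_window,bmi_window Matching half-widths.
#' @param min_matches Fallback threshold.
#' @return The matched noncarrier tibble.
#' @export
match_noncarriers <- function(carrier, noncarriers, age_window = 5,
                              bmi_window = 5, min_matches = 20L) {
  sel <- rep(TRUE, nrow(noncarriers))
  if (!is.null(carrier$age) && "age" %in% names(noncarriers)) {
    sel <- sel & abs(noncarriers$age - carrier$age) <= age_window
  }
  if (!is.null(carrier$sex) && "sex" %in% names(noncarriers)) {
    sel <- sel & noncarriers$sex == carrier$sex
  }
  if (!is.null(carrier$ancestry) && "ancestry" %in% names(noncarriers)) {
    sel <- sel & noncarriers$ancestry == carrier$ancestry
  }
  if (!is.null(carrier$bmi) && "bmi" %in% names(noncarriers)) {
    sel <- sel & abs(noncarriers$bmi - carrier$bmi) <= bmi_window
  }
  if (sum(sel) < min_matches) {
    warn(sprintf("only %d matched noncarriers (< %d); falling back to all noncarriers",
                 sum(sel), min_matches))
    return(noncarriers)
  }
  noncarriers[sel, , drop = FALSE]
}
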