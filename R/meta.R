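#' Genomic-control adjustment of association results
#'
#' Divides each 1-df chi-squared statistic by lambda (equivalently inflates
#' the standard error by sqrt(lambda)) and recomputes P values. Applied only
#' when lambda > 1; deflation is never applied.
#'
#' @param results Tibble with `beta`, `se`, `p`.
#' @param lambda Genomic inflation factor (from [genomic_lambda()] on the
#'   study's null-calibration statistics).
#' @return The results with adjusted `se` and `p` and a `gc_lambda` column.
#' @export
genomic_control_adjust <- function(results, lambda) {
  if (lambda <= 1) {
    return(mutate(results, gc_lambda = lambda))
  }
  mutate(results,
         se = .data$se * sqrt(lambda),
         p = 2 * pnorm(-abs(.data$beta / .data$se)),
         gc_lambda = lambda)
}

#' Inverse-variance fixed-effects meta-analysis of two cohorts
#'
#' Joins the two studies' results by `unit` (exact key match; alleles are part
#' of the key, so no strand/allele rescue is attempted), computes the
#' fixed-effects estimate with weights `1/se^2`, Cochran's Q heterogeneity
#' statistic and a direction string. Units with opposite effect directions are
#' flagged `included = FALSE` (filtered from meta-analysis claims); units
#' present in one study only pass through with `included = FALSE`.
#'
#' @param study1,study2 Tibbles with `unit`, `beta`, `se` (and optionally `p`).
#' @param names Length-2 study labels for the direction string.
#' @return A `meta_result` tibble: per-study estimates, `beta`, `se`, `p`
#'   (meta), `q`, `df`, `p_het`, `direction`, `included`.
#' @export
fixed_effects_meta <- function(study1, study2, names = c("study1", "study2")) {
  s1 <- select(study1, "unit", beta1 = "beta", se1 = "se")
  s2 <- select(study2, "unit", beta2 = "beta", se2 = "se")
  both <- inner_join(s1, s2, by = "unit")
  only1 <- anti_join(s1, s2, by = "unit")
  only2 <- anti_join(s2, s1, by = "unit")
  res <- both |>
    mutate(w1 = 1 / .data$se1^2, w2 = 1 / .data$se2^2,
           beta = (.data$w1 * .data$beta1 + .data$w2 * .data$beta2) /
             (.data$w1 + .data$w2),
           se = 1 / sqrt(.data$w1 + .data$w2),
           p = 2 * pnorm(-abs(.data$beta / .data$se)),
           q = .data$w1 * (.data$beta1 - .data$beta)^2 +
             .data$w2 * (.data$beta2 - .data$beta)^2,
           df = 1L,
           p_het = pchisq(.data$q, df = 1, lower.tail = FALSE),
           direction = paste0(ifelse(.data$beta1 >= 0, "+", "-"),
                              ifelse(.data$beta2 >= 0, "+", "-")),
           included = sign(.data$beta1) == sign(.data$beta2)) |>
    select(-"w1", -"w2")
  pass <- bind_rows(
    mutate(only1, beta = .data$beta1, se = .data$se1,
           direction = paste0(ifelse(.data$beta1 >= 0, "+", "-"), "?")),
    mutate(only2, beta = .data$beta2, se = .data$se2,
           direction = paste0("?", ifelse(.data$beta2 >= 0, "+", "-")))) |>
    mutate(p = 2 * pnorm(-abs(.data$beta / .data$se)),
           q = NA_real_, df = NA_integer_, p_het = NA_real_,
           included = FALSE)
  out <- bind_rows(res, pass) |> arrange(.data$unit)
  structure(out, class = c("meta_result", class(out)),
            study_names = names)
}

#' Meta-analysis significance thresholds
#'
#' Default exome-wide meta significance thresholds by trait type and unit
#' type: binary 3.3e-8 (single variant) / 3.5e-8 (gene-based); quantitative
#' 7.5e-9 / 4.5e-7.
#'
#' @param meta A [fixed_effects_meta()] result.
#' @param trait_type `"binary"` or `"quantitative"`.
#' @param unit_type `"variant"` or `"gene"`.
#' @param thresholds Named list overriding the defaults.
#' @return The tibble filtered to included, threshold-passing units.
#' @export
meta_significant <- function(meta, trait_type = c("binary", "quantitative"),
                             unit_type = c("variant", "gene"),
                             thresholds = list(
                               binary = c(variant = 3.3e-8, gene = 3.5e-8),
                               quantitative = c(variant = 7.5e-9, gene = 4.5e-7))) {
  trait_type <- arg_match(trait_type)
  unit_type <- arg_match(unit_type)
  thr <- thresholds[[trait_type]][[unit_type]]
  filter(meta, .data$included, !is.na(.data$p), .data$p < thr)
}
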