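#' Permute genotypes against fixed phenotypes
#'
#' Reassigns whole genotype rows (all sites of a sample move together, so the
#' within-genotype correlation structure is preserved) by a uniform random
#' permutation of sample ids; phenotypes and covariates stay attached to their
#' original samples. Per-site allele frequencies are invariant by
#' construction. Permuting genotypes rather than phenotypes keeps the
#' phenotype-covariate relationship (including any confounding structure)
#' intact under the null.
#'
#' @param cohort A [rare_cohort()].
#' @param seed Integer seed; `identity = TRUE` returns the cohort unchanged.
#' @param identity Return the identity permutation (for reproducing the
#'   observed scan through the same code path).
#' @return The cohort with permuted genotype/haplotype/probability rows.
#' @export
permute_genotypes <- function(cohort, seed, identity = FALSE) {
  if (identity) return(cohort)
  set.seed(seed)
  idx <- sample.int(length(cohort$samples))
  out <- cohort
  perm_rows <- function(m) {
    if (is.null(m)) return(NULL)
    m <- m[idx, , drop = FALSE]
    rownames(m) <- cohort$samples
    m
  }
  out$gt <- perm_rows(cohort$gt)
  out$hap1 <- perm_rows(cohort$hap1)
  out$hap2 <- perm_rows(cohort$hap2)
  out$pp <- perm_rows(cohort$pp)
  out
}

#' Empirical FDR threshold from permutation P values
#'
#' Plug-in permutation estimator: at candidate threshold `t`,
#' `FDR(t) = mean_k #\{P_perm_k <= t\} / max(1, #\{P_obs <= t\})`. The curve is
#' made non-decreasing in `t` by isotonic regression before thresholding, and
#' `t*` is the largest observed P value whose smoothed FDR is at or below the
#' target. When no threshold attains the target, `threshold` is `NA` and
#' `attainable` is `FALSE`.
#'
#' @param observed_p Observed P values (the real scan).
#' @param perm_p List of per-permutation P-value vectors (or a matrix with one
#'   column per permutation) from the same test grid.
#' @param target_fdr Target false discovery rate (default 0.05).
#' @return An object of class `perm_fdr`: list with `threshold`,
#'   `achieved_fdr`, `attainable`, `n_discoveries`, `target_fdr`,
#'   `n_permutations` and the smoothed `curve` tibble (`t`, `n_obs`,
#'   `mean_null`, `fdr_raw`, `fdr`).
#' @export
empirical_fdr_threshold <- function(observed_p, perm_p, target_fdr = 0.05) {
  observed_p <- observed_p[!is.na(observed_p)]
  if (!length(observed_p)) abort("no observed P values")
  if (is.matrix(perm_p)) perm_p <- lapply(seq_len(ncol(perm_p)), function(j) perm_p[, j])
  if (!length(perm_p)) abort("at least one permutation required")
  perm_all <- sort(unlist(lapply(perm_p, function(x) x[!is.na(x)])))
  n_perm <- length(perm_p)
  ts <- sort(unique(observed_p))
  n_obs <- findInterval(ts, sort(observed_p))
  mean_null <- findInterval(ts, perm_all) / n_perm
  fdr_raw <- mean_null / pmax(1, n_obs)
  fdr <- if (length(ts) > 1) isoreg(ts, fdr_raw)$yf else fdr_raw
  fdr <- pmin(fdr, 1)
  ok <- fdr <= target_fdr
  if (any(ok)) {
    i <- max(which(ok))
    threshold <- ts[i]
    achieved <- fdr[i]
    n_disc <- n_obs[i]
    attainable <- TRUE
  } else {
    threshold <- NA_real_; achieved <- NA_real_; n_disc <- 0L
    attainable <- FALSE
  }
  structure(list(threshold = threshold, achieved_fdr = achieved,
                 attainable = attainable, n_discoveries = as.integer(n_disc),
                 target_fdr = target_fdr, n_permutations = n_perm,
                 curve = tibble(t = ts, n_obs = n_obs, mean_null = mean_null,
                                fdr_raw = fdr_raw, fdr = fdr)),
            class = "perm_fdr")
}

#' Genotype-permutation FDR for an association scan
#'
#' Reruns a user-supplied scan on `n_permutations` genotype-permuted copies of
#' the cohort and derives the empirical FDR threshold for the observed P
#' values.
#'
#' @param cohort A [rare_cohort()].
#' @param scan_fun Function `cohort -> numeric vector of P values` (the same
#'   test grid every call).
#' @param n_permutations Number of permutations (default 100).
#' @param seed Base seed; permutation `k` uses `seed + k`.
#' @param target_fdr Target FDR.
#' @return A `perm_fdr` object (see [empirical_fdr_threshold()]) with the
#'   observed P values attached as `observed_p`.
#' @export
permutation_fdr <- function(cohort, scan_fun, n_permutations = 100L,
                            seed = 1L, target_fdr = 0.05) {
  observed <- scan_fun(cohort)
  perms <- map(seq_len(n_permutations), function(k) {
    scan_fun(permute_genotypes(cohort, seed = seed + k))
  })
  out <- empirical_fdr_threshold(observed, perms, target_fdr)
  out$observed_p <- observed
  out$seed <- seed
  out
}

#' @export
print.perm_fdr <- function(x, ...) {
  if (x$attainable) {
    cat(sprintf("<perm_fdr> t* = %.3g (achieved FDR %.3f <= target %.3f), %d discoveries, %d permutations\n",
                x$threshold, x$achieved_fdr, x$target_fdr, x$n_discoveries,
                x$n_permutations))
  } else {
    cat(sprintf("<perm_fdr> no threshold attains FDR <= %.3f (%d permutations)\n",
                x$target_fdr, x$n_permutations))
  }
  invisible(x)
}

#' @export
tidy.perm_fdr <- function(x, ...) x$curve

#' @export
glance.perm_fdr <- function(x, ...) {
  tibble(threshold = x$threshold, achieved_fdr = x$achieved_fdr,
         attainable = x$attainable, n_discoveries = x$n_discoveries,
         target_fdr = x$target_fdr, n_permutations = x$n_permutations)
}

#' @rdname autoplot_methods
#' @export
autoplot.perm_fdr <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$t, y = .data$fdr)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$target_fdr, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "P-value threshold t", y = "estimated FDR(t)",
                  title = "Permutation FDR curve") +
    ggplot2::theme_minimal()
}
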