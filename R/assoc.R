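#' Rank-based inverse-normal transform
#'
#' Blom offset (c = 3/8); ties share the average rank.
#'
#' @param y Numeric vector (NAs preserved).
#' @return Transformed vector.
#' @export
rank_inverse_normal <- function(y) {
  out <- rep(NA_real_, length(y))
  ok <- !is.na(y)
  r <- rank(y[ok], ties.method = "average")
  out[ok] <- qnorm((r - 3 / 8) / (sum(ok) + 1 / 4))
  out
}

covar_matrix <- function(covariates, sample_ids = NULL) {
  if (is.null(covariates)) return(NULL)
  cv <- as_tibble(covariates)
  if ("sample_id" %in% names(cv) && !is.null(sample_ids)) {
    cv <- cv[match(sample_ids, cv$sample_id), , drop = FALSE]
  }
  cv <- cv[setdiff(names(cv), "sample_id")]
  as.matrix(cv)
}

#' Covariate-adjusted linear association
#'
#' Ordinary least squares of a quantitative trait on a dosage with covariate
#' adjustment; Wald test on the dosage term.
#'
#' @param y Quantitative trait.
#' @param g Dosage (any numeric coding; constant dosage is an error).
#' @param covariates Data frame of numeric covariates (optional `sample_id`
#'   column is dropped), or `NULL`.
#' @param rint Apply [rank_inverse_normal()] to `y` first.
#' @return One-row tibble: `beta`, `se`, `p`, `n`, `model = "additive"`.
#' @export
linear_assoc <- function(y, g, covariates = NULL, rint = FALSE) {
  cv <- covar_matrix(covariates)
  ok <- complete.cases(y, g, if (is.null(cv)) rep(0, length(y)) else cv)
  if (sum(ok) < 10) abort("insufficient complete cases (< 10)")
  y <- y[ok]; g <- g[ok]
  if (rint) y <- rank_inverse_normal(y)
  if (var(g) == 0) abort("monomorphic in analyzed subset")
  X <- if (is.null(cv)) matrix(1, length(y), 1) else cbind(1, cv[ok, , drop = FALSE])
  fit <- ols_fit(y, X, g)
  tibble(model = "additive", beta = fit$beta, se = fit$se, p = fit$p,
         n = length(y), n_cases = NA_integer_, firth_applied = FALSE)
}

# exact OLS slope test for g given covariates X, by Frisch-Waugh projection
ols_fit <- function(y, X, g) {
  qx <- qr(X)
  ry <- qr.resid(qx, y)
  rg <- qr.resid(qx, g)
  gss <- sum(rg^2)
  df <- length(y) - qx$rank - 1L
  if (gss < 1e-12 || df < 1) {
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_))
  }
  beta <- sum(rg * ry) / gss
  rss <- sum(ry^2) - beta^2 * gss
  if (rss < 0) rss <- 0
  sigma2 <- rss / df
  se <- sqrt(sigma2 / gss)
  tval <- if (se > 0) beta / se else sign(beta) * Inf
  p <- 2 * stats::pt(-abs(tval), df)
  if (se == 0) p <- 0
  list(beta = beta, se = se, p = p, df = df)
}

# vectorized version over the columns of G; exact match to per-column OLS.
# Columns with missing genotypes fall back to the scalar path.
ols_scan <- function(y, X, G) {
  qx <- qr(X)
  ry <- qr.resid(qx, y)
  has_na <- colSums(is.na(G)) > 0
  beta <- se <- p <- rep(NA_real_, ncol(G))
  if (any(!has_na)) {
    Gc <- G[, !has_na, drop = FALSE]
    RG <- qr.resid(qx, Gc)
    gss <- colSums(RG^2)
    df <- length(y) - qx$rank - 1L
    b <- colSums(RG * ry) / gss
    rss <- pmax(sum(ry^2) - b^2 * gss, 0)
    s <- sqrt(rss / df / gss)
    tt <- b / s
    pp <- 2 * stats::pt(-abs(tt), df)
    bad <- gss < 1e-12
    b[bad] <- s[bad] <- pp[bad] <- NA_real_
    beta[!has_na] <- b; se[!has_na] <- s; p[!has_na] <- pp
  }
  for (j in which(has_na)) {
    ok <- !is.na(G[, j])
    if (sum(ok) < 10 || var(G[ok, j]) == 0) next
    f <- ols_fit(y[ok], X[ok, , drop = FALSE], G[ok, j])
    beta[j] <- f$beta; se[j] <- f$se; p[j] <- f$p
  }
  tibble(beta = beta, se = se, p = p)
}

#' Firth penalized logistic regression
#'
#' Maximum penalized likelihood with the Jeffreys-prior penalty
#' `0.5 log det I(beta)`, fitted by Newton-Raphson on the modified score
#' `U*(beta) = X' (y - p + h (1/2 - p))` with step-halving on the penalized
#' likelihood. Estimates are finite even under complete separation.
#'
#' @param X Design matrix (including the intercept column).
#' @param y 0/1 response.
#' @param tol Convergence tolerance on the modified-score max norm.
#' @param maxit Maximum Newton iterations.
#' @return List: `beta`, `se` (from the inverse Fisher information at the
#'   penalized maximum), `loglik_pen`, `converged`, `iter`.
#' @export
firth_fit <- function(X, y, tol = 1e-8, maxit = 100) {
  X <- as.matrix(X)
  k <- ncol(X)
  beta <- numeric(k)
  beta[1] <- qlogis(pmin(pmax(mean(y), 0.01), 0.99))
  pen_ll <- function(b) {
    eta <- drop(X %*% b)
    pr <- plogis(eta)
    w <- pmax(pr * (1 - pr), 1e-12)
    info <- crossprod(X, X * w)
    ld <- determinant(info, logarithm = TRUE)$modulus
    sum(y * eta - log1p(exp(eta))) + 0.5 * as.numeric(ld)
  }
  ll_old <- pen_ll(beta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    pr <- plogis(eta)
    w <- pmax(pr * (1 - pr), 1e-12)
    info <- crossprod(X, X * w)
    inv <- solve(info)
    h <- rowSums((X %*% inv) * X) * w
    score <- drop(crossprod(X, y - pr + h * (0.5 - pr)))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    delta <- drop(inv %*% score)
    # cap the step, then halve until the penalized likelihood improves
    if (max(abs(delta)) > 5) delta <- delta * 5 / max(abs(delta))
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- pen_ll(cand)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-10) break
      step <- step / 2
      if (step < 1e-6) break
    }
    beta <- beta + step * delta
    ll_old <- pen_ll(beta)
  }
  eta <- drop(X %*% beta)
  pr <- plogis(eta)
  w <- pmax(pr * (1 - pr), 1e-12)
  inv <- solve(crossprod(X, X * w))
  list(beta = beta, se = sqrt(diag(inv)), loglik_pen = pen_ll(beta),
       converged = converged, iter = iter)
}

# penalized-likelihood-ratio P for dropping column set `drop` from X
firth_lrt <- function(X, y, drop) {
  full <- firth_fit(X, y)
  red <- firth_fit(X[, -drop, drop = FALSE], y)
  stat <- 2 * (full$loglik_pen - red$loglik_pen)
  list(full = full, p = pchisq(pmax(stat, 0), df = length(drop),
                               lower.tail = FALSE))
}

#' Covariate-adjusted logistic association with Firth fallback
#'
#' Fits standard maximum-likelihood logistic regression first. If the Wald P
#' on the dosage is below `firth_trigger_p`, or the fit fails to converge
#' (including separation), the model is refitted by Firth penalized likelihood
#' and the penalized estimate with its likelihood-ratio P is reported
#' (`firth_applied = TRUE`).
#'
#' @inheritParams linear_assoc
#' @param firth_trigger_p Refit with Firth when the ML Wald P is below this.
#' @return One-row tibble: `beta`, `se`, `p`, `n`, `n_cases`, `firth_applied`.
#' @export
logistic_assoc <- function(y, g, covariates = NULL, firth_trigger_p = 0.01) {
  cv <- covar_matrix(covariates)
  ok <- complete.cases(y, g, if (is.null(cv)) rep(0, length(y)) else cv)
  y <- y[ok]; g <- g[ok]
  if (length(unique(y)) < 2) abort("single-class response")
  if (var(g) == 0) abort("monomorphic in analyzed subset")
  X <- if (is.null(cv)) matrix(1, length(y), 1) else cbind(1, cv[ok, , drop = FALSE])
  Xg <- cbind(X, g = g)
  ml <- suppressWarnings(glm.fit2(Xg, y))
  need_firth <- !ml$converged || !is.finite(ml$p) || ml$p < firth_trigger_p
  if (need_firth) {
    fl <- firth_lrt(Xg, y, drop = ncol(Xg))
    j <- ncol(Xg)
    tibble(model = "additive", beta = fl$full$beta[j], se = fl$full$se[j],
           p = fl$p, n = length(y), n_cases = as.integer(sum(y)),
           firth_applied = TRUE)
  } else {
    tibble(model = "additive", beta = ml$beta, se = ml$se, p = ml$p,
           n = length(y), n_cases = as.integer(sum(y)), firth_applied = FALSE)
  }
}

# ML logistic fit reporting the last column's Wald test; flags separation
glm.fit2 <- function(Xg, y) {
  fit <- tryCatch(
    stats::glm.fit(Xg, y, family = binomial()),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(converged = FALSE, beta = NA_real_, se = NA_real_, p = NA_real_))
  }
  j <- ncol(Xg)
  beta <- fit$coefficients[j]
  pr <- fit$fitted.values
  w <- pr * (1 - pr)
  info <- crossprod(Xg, Xg * w)
  se <- tryCatch(sqrt(diag(solve(info)))[j], error = function(e) NA_real_)
  conv <- isTRUE(fit$converged) && is.finite(beta) && is.finite(se) &&
    abs(beta) < 15 && se < 100
  z <- beta / se
  list(converged = conv, beta = unname(beta), se = unname(se),
       p = unname(2 * pnorm(-abs(z))))
}

#' Joint additive and dominance-deviation test
#'
#' Jointly fits `y ~ beta * g_add + gamma * g_domdev + covariates` with
#' `g_add` the 0/1/2 genotype and `g_domdev` its 0/1/0 recoding, by linear or
#' logistic regression according to the trait. Reports the additive and
#' dominance-deviation estimates, a 1-df P for the dominance deviation (Wald
#' and likelihood-ratio) and the 2-df likelihood-ratio P for the joint
#' (beta, gamma) hypothesis. Binary traits fall back to Firth penalized fits
#' under the same trigger as [logistic_assoc()].
#'
#' @param y Trait (quantitative, or 0/1 binary).
#' @param g Genotypes in `{0, 1, 2}`.
#' @param covariates Optional covariate data frame.
#' @param trait_type `"auto"` (binary iff y has only 0/1), `"quantitative"`
#'   or `"binary"`.
#' @param firth_trigger_p Firth trigger for binary traits.
#' @return One-row tibble: `beta`, `gamma`, `se_beta`, `se_gamma`, `p_add`,
#'   `p_domdev` (Wald), `p_domdev_lrt`, `p_joint2df`, `n`, `n_cases`,
#'   `firth_applied`, `gamma_estimable`.
#' @export
dominance_deviation_test <- function(y, g, covariates = NULL,
                                     trait_type = c("auto", "quantitative", "binary"),
                                     firth_trigger_p = 0.01) {
  trait_type <- arg_match(trait_type)
  cv <- covar_matrix(covariates)
  ok <- complete.cases(y, g, if (is.null(cv)) rep(0, length(y)) else cv)
  y <- y[ok]; g <- g[ok]
  if (trait_type == "auto") {
    trait_type <- if (all(y %in% c(0, 1))) "binary" else "quantitative"
  }
  g_add <- as.numeric(g)
  g_dom <- as.numeric(g == 1)
  if (!any(g == 1)) {
    return(tibble(beta = NA_real_, gamma = NA_real_, se_beta = NA_real_,
                  se_gamma = NA_real_, p_add = NA_real_, p_domdev = NA_real_,
                  p_domdev_lrt = NA_real_, p_joint2df = NA_real_,
                  n = length(y), n_cases = NA_integer_,
                  firth_applied = FALSE, gamma_estimable = FALSE))
  }
  X0 <- if (is.null(cv)) matrix(1, length(y), 1) else cbind(1, cv[ok, , drop = FALSE])
  Xf <- cbind(X0, g_add = g_add, g_dom = g_dom)
  ja <- ncol(Xf) - 1L; jd <- ncol(Xf)
  if (trait_type == "quantitative") {
    fit <- stats::lm.fit(Xf, y)
    df <- length(y) - fit$rank
    rss1 <- sum(fit$residuals^2)
    sigma2 <- rss1 / df
    XtXinv <- chol2inv(chol(crossprod(Xf)))
    se <- sqrt(diag(XtXinv) * sigma2)
    tstat <- fit$coefficients / se
    pwald <- 2 * stats::pt(-abs(tstat), df)
    rss_d <- sum(stats::lm.fit(Xf[, -jd, drop = FALSE], y)$residuals^2)
    rss_0 <- sum(stats::lm.fit(X0, y)$residuals^2)
    n <- length(y)
    lrt1 <- n * log(rss_d / rss1)
    lrt2 <- n * log(rss_0 / rss1)
    tibble(beta = unname(fit$coefficients[ja]),
           gamma = unname(fit$coefficients[jd]),
           se_beta = se[ja], se_gamma = se[jd],
           p_add = unname(pwald[ja]), p_domdev = unname(pwald[jd]),
           p_domdev_lrt = pchisq(pmax(lrt1, 0), 1, lower.tail = FALSE),
           p_joint2df = pchisq(pmax(lrt2, 0), 2, lower.tail = FALSE),
           n = n, n_cases = NA_integer_,
           firth_applied = FALSE, gamma_estimable = TRUE)
  } else {
    ml <- tryCatch(stats::glm.fit(Xf, y, family = binomial()),
                   error = function(e) NULL)
    use_firth <- is.null(ml) || !isTRUE(ml$converged) ||
      any(abs(ml$coefficients[c(ja, jd)]) > 15)
    if (!use_firth) {
      pr <- ml$fitted.values
      info <- crossprod(Xf, Xf * pmax(pr * (1 - pr), 1e-12))
      se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, ncol(Xf)))
      z <- ml$coefficients / se
      pw <- 2 * pnorm(-abs(z))
      use_firth <- !all(is.finite(pw[c(ja, jd)])) || min(pw[c(ja, jd)]) < firth_trigger_p
    }
    if (use_firth) {
      full <- firth_fit(Xf, y)
      red_d <- firth_fit(Xf[, -jd, drop = FALSE], y)
      red_0 <- firth_fit(X0, y)
      z <- full$beta / full$se
      pw <- 2 * pnorm(-abs(z))
      lrt1 <- 2 * (full$loglik_pen - red_d$loglik_pen)
      lrt2 <- 2 * (full$loglik_pen - red_0$loglik_pen)
      tibble(beta = full$beta[ja], gamma = full$beta[jd],
             se_beta = full$se[ja], se_gamma = full$se[jd],
             p_add = pw[ja], p_domdev = pw[jd],
             p_domdev_lrt = pchisq(pmax(lrt1, 0), 1, lower.tail = FALSE),
             p_joint2df = pchisq(pmax(lrt2, 0), 2, lower.tail = FALSE),
             n = length(y), n_cases = as.integer(sum(y)),
             firth_applied = TRUE, gamma_estimable = TRUE)
    } else {
      dev1 <- ml$deviance
      dev_d <- stats::glm.fit(Xf[, -jd, drop = FALSE], y, family = binomial())$deviance
      dev_0 <- stats::glm.fit(X0, y, family = binomial())$deviance
      tibble(beta = unname(ml$coefficients[ja]), gamma = unname(ml$coefficients[jd]),
             se_beta = se[ja], se_gamma = se[jd],
             p_add = unname(pw[ja]), p_domdev = unname(pw[jd]),
             p_domdev_lrt = pchisq(pmax(dev_d - dev1, 0), 1, lower.tail = FALSE),
             p_joint2df = pchisq(pmax(dev_0 - dev1, 0), 2, lower.tail = FALSE),
             n = length(y), n_cases = as.integer(sum(y)),
             firth_applied = FALSE, gamma_estimable = TRUE)
    }
  }
}

#' Genomic inflation factor
#'
#' `lambda = median(chi2_observed) / median(chi2_1)`, with P values converted
#' to 1-df chi-squared statistics through the quantile function.
#'
#' @param p P values (used if `chi2` missing).
#' @param chi2 1-df chi-squared statistics.
#' @return Scalar lambda.
#' @export
genomic_lambda <- function(p = NULL, chi2 = NULL) {
  if (is.null(chi2)) {
    if (is.null(p) || !length(p)) abort("no statistics supplied")
    chi2 <- qchisq(p, df = 1, lower.tail = FALSE)
  }
  if (!length(chi2)) abort("no statistics supplied")
  median(chi2, na.rm = TRUE) / qchisq(0.5, df = 1)
}
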