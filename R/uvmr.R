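#' @noRd
new_mr_result <- function(method, beta, se, n_snp, dist = "normal",
                          df = NULL, outcome_type = "binary", extra = list()) {
  crit <- if (dist == "t") qt(0.975, df) else qnorm(0.975)
  pvalue <- if (dist == "t") 2 * pt(-abs(beta / se), df)
            else 2 * pnorm(-abs(beta / se))
  out <- c(list(method = method, beta = beta, se = se,
                ci_low = beta - crit * se, ci_high = beta + crit * se,
                pvalue = max(pvalue, .Machine$double.xmin),
                n_snp = n_snp, outcome_type = outcome_type),
           extra)
  structure(out, class = "mr_result")
}

#' @export
print.mr_result <- function(x, digits = 4, ...) {
  cat("<mr_result>", x$method, "| nsnp =", x$n_snp, "\n")
  cat("  beta =", signif(x$beta, digits), " se =", signif(x$se, digits),
      " 95% CI [", signif(x$ci_low, digits), ",", signif(x$ci_high, digits),
      "] p =", signif(x$pvalue, 3), "\n")
  if (!is.null(x$or_)) {
    cat("  OR =", signif(x$or_, digits), " [", signif(x$or_low, digits),
        ",", signif(x$or_high, digits), "]\n")
  }
  if (!is.null(x$q_stat)) {
    cat("  Q =", signif(x$q_stat, digits), " p_Q =",
        signif(x$q_pvalue, 3), "\n")
  }
  if (!is.null(x$egger_intercept)) {
    cat("  intercept =", signif(x$egger_intercept, digits), " p_intercept =",
        signif(x$intercept_pvalue, 3), "\n")
  }
  invisible(x)
}

#' @method tidy mr_result
#' @export
tidy.mr_result <- function(x, ...) {
  tibble::tibble(method = x$method, n_snp = x$n_snp, beta = x$beta,
                 se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
                 pvalue = x$pvalue,
                 or_ = x$or_ %||% NA_real_,
                 or_low = x$or_low %||% NA_real_,
                 or_high = x$or_high %||% NA_real_)
}

#' @method glance mr_result
#' @export
glance.mr_result <- function(x, ...) {
  tibble::tibble(method = x$method, n_snp = x$n_snp,
                 q_stat = x$q_stat %||% NA_real_,
                 q_pvalue = x$q_pvalue %||% NA_real_,
                 egger_intercept = x$egger_intercept %||% NA_real_,
                 intercept_se = x$intercept_se %||% NA_real_,
                 intercept_pvalue = x$intercept_pvalue %||% NA_real_)
}

#' Wald ratio estimate for a single instrument
#'
#' `beta = by / bx` with first-order standard error `|sy / bx|` (the
#' exposure-side error is ignored; a second-order option propagates it).
#'
#' @param bx,sx Exposure effect and standard error.
#' @param by,sy Outcome effect and standard error.
#' @param second_order If `TRUE`, use the second-order delta standard error
#'   `sqrt(sy^2/bx^2 + by^2 sx^2 / bx^4)`.
#' @return An `mr_result`.
#' @export
wald_ratio <- function(bx, sx, by, sy, second_order = FALSE) {
  if (bx == 0) abort("wald_ratio undefined for a null exposure effect")
  beta <- by / bx
  se <- if (second_order) sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
        else abs(sy / bx)
  new_mr_result("wald_ratio", beta, se, 1L)
}

# IVW weights on the ratio scale: w_j = bx_j^2 / sy_j^2
ivw_weights <- function(h) h_bx(h)^2 / h_sy(h)^2

# weighted least squares with multiplicative residual inflation floored at 1;
# the fixed-effect covariance is computed analytically so exact fits
# (zero residual variance) remain well defined
wls_fit <- function(X, y, w) {
  XtWX <- crossprod(X * sqrt(w))
  V <- solve(XtWX)
  coefs <- unname(drop(V %*% crossprod(X * w, y)))
  resid <- y - drop(X %*% coefs)
  rss <- sum(w * resid^2)
  df <- nrow(X) - ncol(X)
  sigma <- if (df > 0) sqrt(rss / df) else 0
  list(coef = coefs, se = unname(sqrt(diag(V))) * max(1, sigma),
       se_fixed = unname(sqrt(diag(V))), sigma = sigma, rss = rss, df = df)
}

#' Inverse-variance weighted (IVW) estimate
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights `1/sy^2`; equivalently the inverse-variance
#' meta-analysis of per-variant Wald ratios. The random-effects model
#' inflates the fixed-effect standard error by the multiplicative residual
#' factor `sqrt(max(1, Q/(n_snp - 1)))`, where Q is Cochran's Q of the Wald
#' ratios under IVW weights.
#'
#' @param h A single-exposure `mr_harmonized` set.
#' @param model `"random_multiplicative"` (default, the primary model) or
#'   `"fixed"`.
#' @return An `mr_result` carrying `q_stat` and `q_pvalue` when at least two
#'   instruments are available.
#' @export
mr_ivw <- function(h, model = c("random_multiplicative", "fixed")) {
  model <- match.arg(model)
  J <- n_snp(h)
  if (J < 1 || (model == "random_multiplicative" && J < 2)) {
    abort("too few instruments for the requested IVW model")
  }
  bx <- h_bx(h); by <- h_by(h); sy <- h_sy(h)
  w <- 1 / sy^2
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- sqrt(1 / sum(w * bx^2))
  q_stat <- q_pvalue <- NULL
  se <- se_fixed
  if (J >= 2) {
    q <- cochran_q(h)
    q_stat <- q$q_stat; q_pvalue <- q$q_pvalue
    if (model == "random_multiplicative") {
      se <- se_fixed * sqrt(max(1, q_stat / (J - 1)))
    }
  }
  new_mr_result(paste0("ivw_", sub("_multiplicative", "", model)),
                beta, se, J, outcome_type = h$outcome_type,
                extra = list(q_stat = q_stat, q_pvalue = q_pvalue))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with an intercept
#' (weights `1/sy^2`) after orienting every instrument so its exposure
#' effect is non-negative. The slope is the causal estimate; the intercept
#' estimates the average directional pleiotropy, with a two-sided t test on
#' `n_snp - 2` degrees of freedom. Standard errors carry the multiplicative
#' residual inflation floored at 1.
#'
#' @param h A single-exposure `mr_harmonized` set with at least 3
#'   instruments.
#' @return An `mr_result` with `egger_intercept`, `intercept_se`,
#'   `intercept_pvalue` and the heterogeneity of the Egger fit (`q_stat`,
#'   `q_pvalue`, on `n_snp - 2` df).
#' @export
mr_egger <- function(h) {
  J <- n_snp(h)
  if (J < 3) abort("mr_egger requires at least 3 instruments")
  flip <- sign(h_bx(h))
  flip[flip == 0] <- 1
  bx <- h_bx(h) * flip; by <- h_by(h) * flip
  sy <- h_sy(h)
  w <- 1 / sy^2
  fit <- wls_fit(cbind(1, bx), by, w)
  beta <- fit$coef[2]
  se <- fit$se[2]
  a <- fit$coef[1]
  a_se <- fit$se[1]
  df <- J - 2
  rss <- fit$rss
  new_mr_result(
    "mr_egger", beta, se, J, dist = "t", df = df,
    outcome_type = h$outcome_type,
    extra = list(
      egger_intercept = a, intercept_se = a_se,
      intercept_pvalue = 2 * pt(-abs(a / a_se), df),
      q_stat = rss, q_pvalue = pchisq(rss, df, lower.tail = FALSE))
  )
}

#' Weighted median estimate
#'
#' The weighted median of per-variant Wald ratios under IVW weights
#' normalized to sum 1, located by linear interpolation of the cumulative
#' weight at 0.5. Consistent when instruments carrying at least half the
#' weight are valid. The standard error comes from a seeded parametric
#' bootstrap that redraws each variant's exposure and outcome effects from
#' their sampling distributions.
#'
#' @param h A single-exposure `mr_harmonized` set with at least 3
#'   instruments.
#' @param n_boot Bootstrap draws for the standard error, default 1000.
#' @param seed Integer seed (mandatory; the estimate is deterministic, the
#'   bootstrap is seeded).
#' @return An `mr_result`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed) {
  J <- n_snp(h)
  if (J < 3) abort("mr_weighted_median requires at least 3 instruments")
  bx <- h_bx(h); sx <- h_sx(h); by <- h_by(h); sy <- h_sy(h)
  beta <- weighted_median_point(by / bx, ivw_weights(h))
  boots <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bxi <- rnorm(J, bx, sx)
      byi <- rnorm(J, by, sy)
      weighted_median_point(byi / bxi, bxi^2 / sy^2)
    }, numeric(1))
  })
  new_mr_result("weighted_median", beta, sd(boots), J,
                outcome_type = h$outcome_type)
}

# interpolated weighted median: cumulative weight (midpoint convention) vs 0.5
weighted_median_point <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(x[1])
  if (cum[length(cum)] <= 0.5) return(x[length(x)])
  stats::approx(cum, x, xout = 0.5, ties = "ordered")$y
}

# evaluate seeded code without disturbing the caller's RNG stream
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Maximum-likelihood estimate
#'
#' Maximizes the bivariate normal likelihood in which each variant's true
#' exposure effect is a nuisance parameter: `bx_j ~ N(xi_j, sx_j^2)`,
#' `by_j ~ N(theta xi_j, sy_j^2)`. The nuisance effects are profiled out in
#' closed form and `theta` is optimized numerically from the IVW starting
#' point; the standard error comes from the curvature (observed information)
#' of the profile likelihood.
#'
#' @param h A single-exposure `mr_harmonized` set.
#' @return An `mr_result`.
#' @export
mr_max_likelihood <- function(h) {
  J <- n_snp(h)
  if (J < 1) abort("mr_max_likelihood requires at least one instrument")
  bx <- h_bx(h); sx <- h_sx(h); by <- h_by(h); sy <- h_sy(h)
  nll <- function(theta) {
    # profile xi_j for fixed theta, then the exact -2 log likelihood
    xi <- (bx / sx^2 + theta * by / sy^2) / (1 / sx^2 + theta^2 / sy^2)
    sum((bx - xi)^2 / sx^2 + (by - theta * xi)^2 / sy^2)
  }
  start <- sum(bx * by / sy^2) / sum(bx^2 / sy^2)
  opt <- optim(start, nll, method = "BFGS", hessian = TRUE)
  if (opt$convergence != 0) {
    abort(paste0("maximum-likelihood optimizer failed to converge ",
                 "(code ", opt$convergence,
                 if (!is.null(opt$message)) paste0(": ", opt$message), ")"))
  }
  # nll is -2 logL, so information = hessian / 2
  se <- sqrt(2 / opt$hessian[1, 1])
  new_mr_result("max_likelihood", opt$par, se, J,
                outcome_type = h$outcome_type)
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_j (ratio_j - theta_ivw)^2` with IVW weights
#' `w_j = bx_j^2 / sy_j^2`; p-value from chi-square on `n_snp - 1` degrees
#' of freedom. A Q p-value below 0.05 indicates heterogeneity across
#' instruments.
#'
#' @param h A single-exposure `mr_harmonized` set with at least 2
#'   instruments.
#' @return Tibble with `q_stat`, `df`, `q_pvalue`.
#' @export
cochran_q <- function(h) {
  J <- n_snp(h)
  if (J < 2) abort("cochran_q requires at least 2 instruments")
  w <- ivw_weights(h)
  ratio <- h_by(h) / h_bx(h)
  theta <- sum(w * ratio) / sum(w)
  q <- sum(w * (ratio - theta)^2)
  tibble::tibble(q_stat = q, df = J - 1,
                 q_pvalue = pchisq(q, J - 1, lower.tail = FALSE))
}

#' Express an estimate as an odds ratio
#'
#' For binary outcomes the causal estimate is a log odds ratio; this
#' populates `or_ = exp(beta)` and exponentiated confidence bounds.
#'
#' @param r An `mr_result`.
#' @return The same `mr_result` with `or_`, `or_low`, `or_high` populated.
#' @export
or_from_result <- function(r) {
  r$or_ <- exp(r$beta)
  r$or_low <- exp(r$ci_low)
  r$or_high <- exp(r$ci_high)
  r
}

#' Dual significance criterion
#'
#' Causal inference is declared only when the primary (IVW) p-value clears
#' the (typically Bonferroni-corrected) threshold and every method agrees on
#' the direction of effect.
#'
#' @param primary The primary `mr_result` (IVW).
#' @param others List of supplementary `mr_result`s.
#' @param p_threshold Significance threshold, e.g. `0.05 / 4` for four
#'   exposures.
#' @return Logical scalar.
#' @export
significance_gate <- function(primary, others = list(), p_threshold = 0.05) {
  signs <- vapply(c(list(primary), others), function(r) sign(r$beta),
                  numeric(1))
  primary$pvalue < p_threshold && length(unique(signs)) == 1
}

#' Bonferroni-corrected family threshold
#'
#' @param alpha Family-wise error rate, default 0.05.
#' @param m Number of tests in the family.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(m >= 1)
  alpha / m
}

#' P-value implied by an odds ratio and its confidence interval
#'
#' Recovers the two-sided normal p-value from a printed `OR (low, high)`
#' triplet: the log-scale standard error is the CI width divided by
#' `2 * qnorm(0.975)` and the z statistic is `log(or) / se`. Useful as an
#' internal-consistency check on reported results.
#'
#' @param or_,or_low,or_high Odds ratio and 95 percent bounds.
#' @return Two-sided p-value.
#' @export
p_from_or_ci <- function(or_, or_low, or_high) {
  se <- (log(or_high) - log(or_low)) / (2 * qnorm(0.975))
  2 * pnorm(-abs(log(or_) / se))
}
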