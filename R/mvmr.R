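#' @noRd
new_mvmr_result <- function(method, estimates, n_snp, extra = list()) {
  structure(c(list(method = method, estimates = estimates, n_snp = n_snp),
              extra),
            class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat("<mvmr_result>", x$method, "| nsnp =", x$n_snp, "\n")
  print(x$estimates)
  if (!is.null(x$intercept)) {
    cat("  intercept =", signif(x$intercept, 4), " p_intercept =",
        signif(x$intercept_pvalue, 3), "\n")
  }
  invisible(x)
}

#' @method tidy mvmr_result
#' @export
tidy.mvmr_result <- function(x, ...) {
  dplyr::mutate(x$estimates, method = x$method, n_snp = x$n_snp,
                .before = 1)
}

#' @method glance mvmr_result
#' @export
glance.mvmr_result <- function(x, ...) {
  tibble::tibble(method = x$method, n_snp = x$n_snp,
                 intercept = x$intercept %||% NA_real_,
                 intercept_pvalue = x$intercept_pvalue %||% NA_real_,
                 n_valid = length(x$selected_valid %||% character(0)))
}

mv_design <- function(h) {
  X <- h$exposure_betas
  if (anyNA(X) || anyNA(h$outcome_betas)) {
    abort("harmonized set contains missing effects; re-harmonize jointly")
  }
  w <- 1 / h$outcome_ses^2
  qrX <- qr(sqrt(w) * X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    abort(paste0("exposure-effect matrix is rank deficient; collinear ",
                 "column(s): ", paste(bad, collapse = ", ")))
  }
  list(X = X, y = h$outcome_betas, w = w, k = ncol(X))
}

mv_estimates_table <- function(fit_coefs, ses, exposure_ids, dist = "normal",
                               df = NULL) {
  crit <- if (dist == "t") qt(0.975, df) else qnorm(0.975)
  pv <- if (dist == "t") 2 * pt(-abs(fit_coefs / ses), df)
        else 2 * pnorm(-abs(fit_coefs / ses))
  tibble::tibble(exposure = exposure_ids, beta = unname(fit_coefs),
                 se = unname(ses),
                 ci_low = unname(fit_coefs - crit * ses),
                 ci_high = unname(fit_coefs + crit * ses),
                 pvalue = unname(pmax(pv, .Machine$double.xmin)))
}

#' Multivariable IVW estimate
#'
#' Weighted multivariable regression of outcome effects on the matrix of
#' exposure effects through the origin, weights `1/sy^2`, giving each
#' exposure's direct effect conditional on the others. Standard errors carry
#' the multiplicative residual inflation floored at 1; p-values are normal.
#'
#' @param h An `mr_harmonized` set (any number of exposure columns) with
#'   more instruments than exposures.
#' @return An `mvmr_result` with one row per exposure.
#' @export
mv_ivw <- function(h) {
  d <- mv_design(h)
  J <- n_snp(h)
  if (J <= d$k) abort("mv_ivw needs more instruments than exposures")
  fit <- wls_fit(d$X, d$y, d$w)
  new_mvmr_result(
    "mv_ivw",
    mv_estimates_table(fit$coef, fit$se, h$exposure_ids),
    J,
    extra = list(q_stat = fit$rss, q_df = J - d$k)
  )
}

#' Multivariable MR-Egger
#'
#' As [mv_ivw()] plus an intercept capturing average directional
#' pleiotropy. Rows are oriented so the first exposure's effects are
#' non-negative; the intercept p-value uses a t reference with
#' `n_snp - k - 1` degrees of freedom.
#'
#' @param h An `mr_harmonized` set with at least `k + 2` instruments.
#' @return An `mvmr_result` with `intercept`, `intercept_se`,
#'   `intercept_pvalue`.
#' @export
mvmr_egger <- function(h) {
  d <- mv_design(h)
  J <- n_snp(h)
  if (J <= d$k + 1) {
    abort("mvmr_egger needs more instruments than exposures plus one")
  }
  flip <- sign(d$X[, 1]); flip[flip == 0] <- 1
  X <- d$X * flip; y <- d$y * flip
  fit <- wls_fit(cbind(1, X), y, d$w)
  df <- J - d$k - 1
  a <- fit$coef[1]
  a_se <- fit$se[1]
  slopes <- fit$coef[-1]
  slope_se <- fit$se[-1]
  new_mvmr_result(
    "mvmr_egger",
    mv_estimates_table(slopes, slope_se, h$exposure_ids, dist = "t",
                       df = df),
    J,
    extra = list(intercept = a, intercept_se = a_se,
                 intercept_pvalue = 2 * pt(-abs(a / a_se), df))
  )
}

#' Multivariable median estimate
#'
#' Minimizes the weighted sum of absolute residuals (weights `1/sy`) of the
#' no-intercept multivariable model, a robust alternative to [mv_ivw()]
#' tolerant of a minority of pleiotropic instruments. Standard errors come
#' from a seeded parametric bootstrap.
#'
#' @param h An `mr_harmonized` set.
#' @param n_boot Bootstrap draws, default 1000.
#' @param seed Integer seed (mandatory).
#' @return An `mvmr_result`.
#' @export
mvmr_median <- function(h, n_boot = 1000, seed) {
  d <- mv_design(h)
  J <- n_snp(h)
  if (J <= d$k) abort("mvmr_median needs more instruments than exposures")
  l1_fit <- function(X, y, w_abs, start) {
    obj <- function(theta) sum(w_abs * abs(y - drop(X %*% theta)))
    if (length(start) == 1) {
      optimize(obj, interval = start + c(-10, 10) * max(abs(start), 1))$minimum
    } else {
      opt <- optim(start, obj, method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-10))
      if (opt$convergence != 0) abort("mvmr_median optimizer failed")
      opt$par
    }
  }
  start <- coef(lm(d$y ~ 0 + d$X, weights = d$w))
  w_abs <- 1 / h$outcome_ses
  theta <- l1_fit(d$X, d$y, w_abs, start)
  boots <- withr_seed(seed, {
    t(vapply(seq_len(n_boot), function(i) {
      Xi <- d$X + matrix(rnorm(length(d$X)), J) * h$exposure_ses
      yi <- rnorm(J, d$y, h$outcome_ses)
      l1_fit(Xi, yi, w_abs, theta)
    }, numeric(d$k)))
  })
  ses <- apply(boots, 2, sd)
  new_mvmr_result(
    "mvmr_median",
    mv_estimates_table(theta, ses, h$exposure_ids),
    J
  )
}

#' Multivariable Lasso: instrument selection then IVW
#'
#' Augments the multivariable design with one indicator (variant-specific
#' intercept) per instrument and applies an L1 penalty to the indicators
#' only. Variants whose indicator is shrunk to zero are treated as valid.
#' The penalty is chosen by a heterogeneity criterion: among grid values
#' whose post-selection Cochran's Q over the valid set stays below the
#' chi-square 95th percentile of its degrees of freedom, the value retaining
#' the most valid instruments is used (falling back to the minimal-Q value
#' when none qualifies). The final estimate is [mv_ivw()] on the valid set.
#'
#' @param h An `mr_harmonized` set.
#' @param lambda_grid Optional decreasing penalty grid; default 50
#'   log-spaced values chosen by `glmnet`.
#' @return An `mvmr_result` carrying `selected_valid` and `lambda`.
#' @export
mvmr_lasso <- function(h, lambda_grid = NULL) {
  d <- mv_design(h)
  J <- n_snp(h)
  if (J <= d$k) abort("mvmr_lasso needs more instruments than exposures")
  design <- cbind(d$X, diag(J))
  fit <- glmnet::glmnet(
    design, d$y, weights = d$w, intercept = FALSE, standardize = FALSE,
    penalty.factor = c(rep(0, d$k), rep(1, J)),
    lambda = lambda_grid, nlambda = 50
  )
  lambdas <- fit$lambda          # decreasing
  coefs <- as.matrix(fit$beta)   # (k + J) x n_lambda
  best <- NULL
  fallback <- NULL
  for (i in seq_along(lambdas)) {
    valid <- which(abs(coefs[d$k + seq_len(J), i]) < 1e-12)
    if (length(valid) <= d$k) next
    hv <- subset_harmonized(h, valid)
    mv <- mv_ivw(hv)
    ok <- mv$q_stat < qchisq(0.95, mv$q_df)
    cand <- list(lambda = lambdas[i], valid = valid, mv = mv,
                 q = mv$q_stat, n_valid = length(valid))
    if (is.null(fallback) || cand$q < fallback$q) fallback <- cand
    if (ok && (is.null(best) || cand$n_valid > best$n_valid ||
               (cand$n_valid == best$n_valid && cand$lambda > best$lambda))) {
      best <- cand
    }
  }
  chosen <- best %||% fallback
  if (is.null(chosen)) {
    abort("mvmr_lasso found no usable valid set at any penalty value")
  }
  new_mvmr_result(
    "mvmr_lasso", chosen$mv$estimates, J,
    extra = list(selected_valid = h$variant_ids[chosen$valid],
                 lambda = chosen$lambda, q_stat = chosen$mv$q_stat,
                 q_df = chosen$mv$q_df)
  )
}

#' Joint instrument selection and harmonization for multivariable MR
#'
#' Takes the union of each exposure's independent genome-wide-significant
#' instruments, re-clumps the union jointly (ranked by each variant's
#' minimum p-value across exposures), and harmonizes all datasets to a
#' single effect-allele frame. With `instrument_policy = "first_exposure"`
#' only the first exposure's instruments are used, which keeps adjusted
#' effects on the same instrument frame as the corresponding univariable
#' fit.
#'
#' @param exposures List of [mr_sumstats()] datasets (at least 2 for a
#'   multivariable fit; the first defines the allele frame).
#' @param outcome An [mr_sumstats()] dataset.
#' @param ld An [mr_ld()] table.
#' @param p_threshold,r2_max,window_kb Selection and clumping parameters.
#' @param instrument_policy `"union"` (default) or `"first_exposure"`.
#' @param ... Passed to [harmonize()].
#' @return An `mr_harmonized` set with one exposure column per dataset.
#' @export
align_multi <- function(exposures, outcome, ld = mr_ld(),
                        p_threshold = 5e-8, r2_max = 0.001,
                        window_kb = 10000,
                        instrument_policy = c("union", "first_exposure"),
                        ...) {
  instrument_policy <- match.arg(instrument_policy)
  stopifnot(length(exposures) >= 1)
  per_exposure <- lapply(exposures, function(e) {
    sig <- select_by_pvalue(e, p_threshold)
    clump(e[e$variant_id %in% sig, ], ld, r2_max = r2_max,
          window_kb = window_kb)
  })
  ids <- if (instrument_policy == "first_exposure") {
    per_exposure[[1]]
  } else {
    unique(unlist(per_exposure))
  }
  if (length(ids) == 0) abort("no instruments for any exposure")
  # joint re-clump, ranking by the minimum p-value across exposures
  pmin_tbl <- purrr::map_dfr(exposures, function(e) {
    tibble::as_tibble(e)[, c("variant_id", "pvalue")]
  })
  pmin_tbl <- dplyr::summarise(
    dplyr::group_by(pmin_tbl[pmin_tbl$variant_id %in% ids, ],
                    .data$variant_id),
    pvalue = min(.data$pvalue), .groups = "drop")
  ids <- clump(pmin_tbl, ld, r2_max = r2_max, window_kb = window_kb)
  ids <- ids[ids %in% exposures[[1]]$variant_id]
  if (length(ids) == 0) {
    abort("no joint instruments present in the first exposure dataset")
  }
  harmonize(exposures, outcome, instrument_ids = ids, ...)
}
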