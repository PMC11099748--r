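#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' The global test compares the observed leave-one-out residual sum of
#' squares (each variant's outcome effect against the IVW prediction from
#' all other variants, weighted by `1/sy^2`) with its parametric-bootstrap
#' null distribution. Per-variant outlier p-values compare each variant's
#' observed RSS contribution with its simulated contributions, Bonferroni
#' adjusted across instruments at `alpha`. The distortion test compares the
#' difference between the raw and outlier-corrected IVW estimates against
#' the bootstrap distribution of the difference obtained by removing equally
#' many variants at random. The corrected estimate is the random-effects IVW
#' on non-outliers.
#'
#' @param h A single-exposure `mr_harmonized` set with at least 4
#'   instruments.
#' @param n_sim Bootstrap draws, default 1000.
#' @param seed Integer seed (mandatory; results are bit-reproducible given
#'   the seed).
#' @param alpha Outlier significance level before Bonferroni adjustment,
#'   default 0.05.
#' @return Object of class `mr_presso`: `global_rss_observed`,
#'   `global_pvalue`, `outlier_indices`, `outlier_ids`, `outlier_pvalues`,
#'   `distortion_pvalue`, `raw_estimate` and `corrected_estimate`
#'   (`mr_result`s), `n_sim`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, seed, alpha = 0.05) {
  J <- n_snp(h)
  if (J < 4) abort("mr_presso requires at least 4 instruments")
  bx <- h_bx(h); sx <- h_sx(h); by <- h_by(h); sy <- h_sy(h)
  w <- 1 / sy^2

  loo_theta <- function(bx, by) {
    sxy <- sum(w * bx * by); sxx <- sum(w * bx^2)
    (sxy - w * bx * by) / (sxx - w * bx^2)
  }
  contrib <- function(bx, by) {
    w * (by - loo_theta(bx, by) * bx)^2
  }

  obs_contrib <- contrib(bx, by)
  rss_obs <- sum(obs_contrib)
  theta_loo <- loo_theta(bx, by)

  sim <- withr_seed(seed, {
    sim_contrib <- matrix(NA_real_, n_sim, J)
    sim_dist <- rep(NA_real_, n_sim)
    n_out_guess <- NULL
    for (i in seq_len(n_sim)) {
      bxi <- rnorm(J, bx, sx)
      byi <- rnorm(J, theta_loo * bx, sy)
      sim_contrib[i, ] <- contrib(bxi, byi)
    }
    list(contrib = sim_contrib)
  })
  rss_sim <- rowSums(sim$contrib)
  global_pvalue <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  outlier_pvalues <- vapply(seq_len(J), function(j) {
    (1 + sum(sim$contrib[, j] >= obs_contrib[j])) / (n_sim + 1)
  }, numeric(1))
  outliers <- which(outlier_pvalues * J < alpha)

  raw <- mr_ivw(h)
  if (length(outliers) > 0 && J - length(outliers) >= 2) {
    corrected <- mr_ivw(subset_harmonized(h, -outliers))
  } else {
    corrected <- raw
  }

  distortion_pvalue <- NA_real_
  if (length(outliers) > 0 && J - length(outliers) >= 2) {
    d_obs <- raw$beta - corrected$beta
    d_sim <- withr_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(i) {
        bxi <- rnorm(J, bx, sx)
        byi <- rnorm(J, theta_loo * bx, sy)
        keep <- sample.int(J, J - length(outliers))
        t_all <- sum(bxi * byi * w) / sum(bxi^2 * w)
        t_sub <- sum((bxi * byi * w)[keep]) / sum((bxi^2 * w)[keep])
        t_all - t_sub
      }, numeric(1))
    })
    distortion_pvalue <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_sim + 1)
  }

  structure(
    list(global_rss_observed = rss_obs, global_pvalue = global_pvalue,
         outlier_indices = outliers,
         outlier_ids = h$variant_ids[outliers],
         outlier_pvalues = outlier_pvalues,
         distortion_pvalue = distortion_pvalue,
         raw_estimate = raw, corrected_estimate = corrected,
         n_sim = n_sim, seed = seed),
    class = "mr_presso"
  )
}

#' @export
print.mr_presso <- function(x, ...) {
  cat("<mr_presso> global RSS =", signif(x$global_rss_observed, 4),
      " global p =", signif(x$global_pvalue, 3), "\n")
  cat("  outliers:", if (length(x$outlier_ids)) {
    paste(x$outlier_ids, collapse = ", ")
  } else "none", "\n")
  cat("  raw beta =", signif(x$raw_estimate$beta, 4),
      " corrected beta =", signif(x$corrected_estimate$beta, 4), "\n")
  invisible(x)
}

#' @method tidy mr_presso
#' @export
tidy.mr_presso <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$raw_estimate), method = "mr_presso_raw"),
    dplyr::mutate(tidy(x$corrected_estimate), method = "mr_presso_corrected")
  )
}

#' @method glance mr_presso
#' @export
glance.mr_presso <- function(x, ...) {
  tibble::tibble(global_rss_observed = x$global_rss_observed,
                 global_pvalue = x$global_pvalue,
                 n_outliers = length(x$outlier_indices),
                 distortion_pvalue = x$distortion_pvalue,
                 n_sim = x$n_sim, seed = x$seed)
}

#' Radial MR with modified second-order weights
#'
#' Fits the radial IVW regression: response `ratio_j * sqrt(w_j)` on
#' predictor `sqrt(w_j)` through the origin, with modified second-order
#' weights `w_j = (sy_j^2/bx_j^2 + by_j^2 sx_j^2 / bx_j^4)^{-1}`. Each
#' variant contributes `Q_j = w_j (ratio_j - theta)^2`, which sums to the
#' total radial Q; variants whose `Q_j` exceeds the chi-square(1) upper-tail
#' critical value at `alpha` are flagged as outliers, and the post-removal
#' estimate is the random-effects IVW on the survivors. One detection pass
#' is performed by default; `iterate = TRUE` repeats removal until no
#' outlier remains.
#'
#' @param h A single-exposure `mr_harmonized` set with at least 2
#'   instruments.
#' @param alpha Per-variant outlier significance level, default 0.05.
#' @param iterate Repeat detection after each removal, default `FALSE`.
#' @return Object of class `mr_radial`: `radial_q`, `per_variant_q`,
#'   `outliers` (variant ids), `estimate` (radial slope, `mr_result`) and
#'   `post_removal` (`mr_result`).
#' @export
radial_ivw <- function(h, alpha = 0.05, iterate = FALSE) {
  J <- n_snp(h)
  if (J < 2) abort("radial_ivw requires at least 2 instruments")

  radial_pass <- function(hh) {
    bx <- h_bx(hh); sx <- h_sx(hh); by <- h_by(hh); sy <- h_sy(hh)
    ratio <- by / bx
    w <- 1 / (sy^2 / bx^2 + by^2 * sx^2 / bx^4)
    theta <- sum(w * ratio) / sum(w)
    qj <- w * (ratio - theta)^2
    list(theta = theta, se = sqrt(1 / sum(w)), qj = qj,
         out = hh$variant_ids[pchisq(qj, 1, lower.tail = FALSE) < alpha])
  }

  first <- radial_pass(h)
  outliers <- first$out
  if (iterate) {
    hh <- h
    repeat {
      hh <- subset_harmonized(hh, setdiff(hh$variant_ids, outliers))
      if (n_snp(hh) < 2) break
      nxt <- radial_pass(hh)
      if (length(nxt$out) == 0) break
      outliers <- c(outliers, nxt$out)
    }
  }

  survivors <- setdiff(h$variant_ids, outliers)
  post <- if (length(survivors) >= 2) {
    mr_ivw(subset_harmonized(h, survivors))
  } else {
    mr_ivw(h)
  }
  bx <- h_bx(h); sx <- h_sx(h); by <- h_by(h); sy <- h_sy(h)
  w <- 1 / (sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  structure(
    list(radial_q = sum(first$qj),
         per_variant_q = setNames(first$qj, h$variant_ids),
         outliers = outliers,
         data = tibble::tibble(
           variant_id = h$variant_ids, sqrt_w = sqrt(w),
           product = (by / bx) * sqrt(w),
           outlier = h$variant_ids %in% outliers),
         estimate = new_mr_result("radial_ivw", first$theta, first$se, J,
                                  outcome_type = h$outcome_type),
         post_removal = post),
    class = "mr_radial"
  )
}

#' @export
print.mr_radial <- function(x, ...) {
  cat("<mr_radial> Q =", signif(x$radial_q, 4), "|",
      length(x$outliers), "outlier(s)\n")
  cat("  post-removal beta =", signif(x$post_removal$beta, 4),
      " p =", signif(x$post_removal$pvalue, 3), "\n")
  invisible(x)
}

#' @method tidy mr_radial
#' @export
tidy.mr_radial <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$estimate), method = "radial_ivw"),
    dplyr::mutate(tidy(x$post_removal), method = "radial_post_removal")
  )
}

#' @method glance mr_radial
#' @export
glance.mr_radial <- function(x, ...) {
  tibble::tibble(radial_q = x$radial_q, n_outliers = length(x$outliers))
}
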