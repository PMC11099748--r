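#' Select variants by association p-value
#'
#' @param dataset An [mr_sumstats()] dataset.
#' @param p_threshold Genome-wide significance threshold; variants with
#'   `pvalue < p_threshold` are returned. The conventional threshold is
#'   5e-8; a lenient 5e-7 is common when instruments are scarce (e.g.
#'   reverse-direction analyses).
#' @return Character vector of variant ids, sorted by ascending p-value.
#' @export
select_by_pvalue <- function(dataset, p_threshold = 5e-8) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  hits <- dataset[dataset$pvalue < p_threshold, c("variant_id", "pvalue")]
  hits <- hits[order(hits$pvalue, hits$variant_id), ]
  hits$variant_id
}

#' Greedy LD clumping
#'
#' Repeatedly retains the remaining candidate with the smallest p-value and
#' discards all remaining candidates in linkage disequilibrium with it
#' (r-squared at or above `r2_max`), optionally restricted to a genomic
#' window when positions are available. Ties in p-value are broken by
#' lexicographic variant id, so the result is deterministic and independent
#' of input order.
#'
#' @param candidates Data frame with columns `variant_id` and `pvalue`
#'   (an [mr_sumstats()] dataset works directly).
#' @param ld An [mr_ld()] table; absent pairs count as r-squared 0.
#' @param r2_max LD pruning threshold, default 0.001.
#' @param window_kb Clumping window in kb, default 10000; only applied when
#'   the LD table carries positions, otherwise all pairs are considered
#'   in-window.
#' @return Character vector of retained (index) variant ids.
#' @export
clump <- function(candidates, ld = mr_ld(), r2_max = 0.001,
                  window_kb = 10000) {
  cand <- tibble::as_tibble(candidates)[, c("variant_id", "pvalue")]
  cand <- cand[order(cand$pvalue, cand$variant_id), ]
  lookup <- ld_lookup(ld)
  pos <- attr(ld, "positions")
  keep <- character(0)
  remaining <- cand$variant_id
  while (length(remaining)) {
    top <- remaining[1]
    keep <- c(keep, top)
    remaining <- remaining[-1]
    if (length(remaining)) {
      r2 <- lookup(rep(top, length(remaining)), remaining)
      in_window <- rep(TRUE, length(remaining))
      if (!is.null(pos) && top %in% names(pos)) {
        d <- abs(pos[remaining] - pos[[top]])
        in_window <- is.na(d) | d <= window_kb
      }
      remaining <- remaining[!(r2 >= r2_max & in_window)]
    }
  }
  keep
}

#' Variance in a trait explained by a single variant
#'
#' Computed from summary statistics as
#' \deqn{R^2 = \frac{\beta^2\,2f(1-f)}{\beta^2\,2f(1-f) + se^2\,n\,2f(1-f)},}
#' with `f` the effect-allele frequency; when `f` is missing the equivalent
#' z-score form `z^2 / (z^2 + n)` is used.
#'
#' @param beta,se,eaf,n Per-variant effect, standard error, effect-allele
#'   frequency (may be `NA`) and sample size. Vectorized.
#' @return Per-variant R-squared values in `[0, 1)`.
#' @export
variance_explained <- function(beta, se, eaf = NA_real_, n) {
  stopifnot(all(se > 0), all(n > 2))
  f <- eaf
  num <- ifelse(is.na(f), beta^2, beta^2 * 2 * f * (1 - f))
  den <- ifelse(is.na(f), beta^2 + se^2 * n,
                beta^2 * 2 * f * (1 - f) + se^2 * n * 2 * f * (1 - f))
  num / den
}

#' Instrument-strength F-statistic
#'
#' `F = R2 (n - 2) / (1 - R2)`. Instruments with F below 10 are
#' conventionally considered weak.
#'
#' @param r2 Variance explained, in `[0, 1)`.
#' @param n Sample size (> 2).
#' @return F-statistic (vectorized).
#' @export
f_statistic <- function(r2, n) {
  if (any(r2 >= 1) || any(r2 < 0)) abort("r2 must lie in [0, 1)")
  stopifnot(all(n > 2))
  r2 * (n - 2) / (1 - r2)
}

#' Exclude candidates directly associated with the outcome
#'
#' Instruments whose outcome-GWAS p-value falls below `p_threshold` violate
#' the exclusivity assumption and are removed. Candidates absent from the
#' outcome dataset are untouched by this filter.
#'
#' @param candidates Character vector of variant ids.
#' @param outcome An [mr_sumstats()] dataset.
#' @param p_threshold Default 5e-8.
#' @return List with `keep` (surviving ids) and `excluded` (tibble of
#'   `variant_id`, `reason`).
#' @export
exclude_outcome_associated <- function(candidates, outcome,
                                       p_threshold = 5e-8) {
  p_out <- outcome$pvalue[match(candidates, outcome$variant_id)]
  bad <- !is.na(p_out) & p_out < p_threshold
  list(keep = candidates[!bad],
       excluded = tibble::tibble(variant_id = candidates[bad],
                                 reason = "outcome_associated"))
}

#' Find LD proxies for instruments missing from the outcome GWAS
#'
#' For each missing instrument, returns the outcome-present variant with the
#' highest r-squared at or above `r2_min`; ties are broken by lexicographic
#' variant id.
#'
#' @param missing Character vector of instrument ids absent from the outcome.
#' @param ld An [mr_ld()] table.
#' @param outcome An [mr_sumstats()] dataset.
#' @param r2_min Minimum acceptable proxy r-squared, default 0.8.
#' @return List with `proxies` (named character vector, instrument ->
#'   proxy) and `failed` (tibble of `variant_id`, `reason`).
#' @export
proxy_substitute <- function(missing, ld, outcome, r2_min = 0.8) {
  proxies <- character(0)
  failed <- character(0)
  present <- outcome$variant_id
  for (v in missing) {
    partners <- dplyr::bind_rows(
      tibble::tibble(id = ld$variant_b[ld$variant_a == v],
                     r2 = ld$r2[ld$variant_a == v]),
      tibble::tibble(id = ld$variant_a[ld$variant_b == v],
                     r2 = ld$r2[ld$variant_b == v])
    )
    partners <- partners[partners$id %in% present & partners$r2 >= r2_min, ]
    if (nrow(partners) == 0) {
      failed <- c(failed, v)
    } else {
      partners <- partners[order(-partners$r2, partners$id), ]
      proxies[v] <- partners$id[1]
    }
  }
  list(proxies = proxies,
       failed = tibble::tibble(variant_id = failed,
                               reason = "missing_proxy_failed"))
}

#' Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure with the
#' variance they explain in the outcome. The causal direction is
#' exposure-to-outcome when the exposure R-squared exceeds the outcome
#' R-squared; the p-value is the two-sided z-test comparing the Fisher-z
#' transformed correlation magnitudes with variance
#' `1/(n_exp - 3) + 1/(n_out - 3)`.
#'
#' @param h A single-exposure `mr_harmonized` set.
#' @param n_exposure,n_outcome Sample sizes; defaults taken from `h`.
#' @return Tibble with `direction`, `r2_exposure`, `r2_outcome`, `pvalue`.
#' @export
steiger_test <- function(h, n_exposure = NULL, n_outcome = NULL) {
  if (n_snp(h) == 0) abort("steiger_test requires at least one instrument")
  n_exposure <- n_exposure %||% unname(h$n_exposure[1])
  n_outcome <- n_outcome %||% h$n_outcome
  if (is.null(n_exposure) || is.null(n_outcome) ||
      is.na(n_exposure) || is.na(n_outcome)) {
    abort("sample sizes are required for the Steiger test")
  }
  r2_exp <- sum(variance_explained(h_bx(h), h_sx(h), h$eaf, n_exposure))
  r2_out <- sum(variance_explained(h_by(h), h_sy(h), h$outcome_eaf,
                                   n_outcome))
  r2_exp <- min(r2_exp, 1 - 1e-12)
  r2_out <- min(r2_out, 1 - 1e-12)
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  tibble::tibble(
    direction = ifelse(r2_exp > r2_out, "exposure_to_outcome",
                       "outcome_to_exposure"),
    r2_exposure = r2_exp, r2_outcome = r2_out,
    pvalue = 2 * pnorm(-abs(z))
  )
}

#' Full instrument-selection workflow for one exposure
#'
#' Applies, in order: the p-value threshold, greedy LD clumping, the weak
#' instrument filter (F below `f_min` dismissed), and — when an outcome is
#' supplied — exclusion of variants directly associated with the outcome and
#' proxy substitution for instruments the outcome GWAS lacks.
#'
#' @param exposure An [mr_sumstats()] dataset.
#' @param outcome Optional [mr_sumstats()] outcome dataset.
#' @param ld An [mr_ld()] table.
#' @param p_threshold Instrument significance threshold, default 5e-8.
#' @param r2_max,window_kb Clumping parameters, defaults 0.001 and 10000 kb.
#' @param f_min Weak-instrument cutoff, default 10 (strictly below is
#'   dismissed).
#' @param outcome_p Outcome-association exclusion threshold, default 5e-8.
#' @param proxy_r2 Minimum proxy r-squared, default 0.8.
#' @return List of class `instrument_report`: `selected` ids, `proxies`
#'   (named vector), and a `report` tibble (variant, status, reason, r2, F).
#' @export
select_instruments <- function(exposure, outcome = NULL, ld = mr_ld(),
                               p_threshold = 5e-8, r2_max = 0.001,
                               window_kb = 10000, f_min = 10,
                               outcome_p = 5e-8, proxy_r2 = 0.8) {
  sig <- select_by_pvalue(exposure, p_threshold)
  excluded <- tibble::tibble(
    variant_id = setdiff(exposure$variant_id, sig),
    reason = "above_p_threshold")

  kept <- clump(exposure[exposure$variant_id %in% sig, ], ld,
                r2_max = r2_max, window_kb = window_kb)
  excluded <- dplyr::bind_rows(
    excluded,
    tibble::tibble(variant_id = setdiff(sig, kept), reason = "clumped"))

  rows <- exposure[match(kept, exposure$variant_id), ]
  r2 <- variance_explained(rows$beta, rows$se, rows$eaf, rows$n)
  f <- f_statistic(r2, rows$n)
  weak <- f < f_min
  excluded <- dplyr::bind_rows(
    excluded,
    tibble::tibble(variant_id = kept[weak], reason = "weak_instrument"))
  kept <- kept[!weak]
  r2 <- setNames(r2[!weak], kept)
  f <- setNames(f[!weak], kept)

  proxies <- character(0)
  if (!is.null(outcome)) {
    oa <- exclude_outcome_associated(kept, outcome, outcome_p)
    kept <- oa$keep
    excluded <- dplyr::bind_rows(excluded, oa$excluded)
    missing <- kept[!kept %in% outcome$variant_id]
    if (length(missing)) {
      px <- proxy_substitute(missing, ld, outcome, r2_min = proxy_r2)
      proxies <- px$proxies
      excluded <- dplyr::bind_rows(excluded, px$failed)
      kept <- setdiff(kept, px$failed$variant_id)
    }
  }

  report <- dplyr::bind_rows(
    tibble::tibble(variant_id = kept, status = "selected",
                   reason = NA_character_,
                   r2 = unname(r2[kept]), f_stat = unname(f[kept])),
    dplyr::mutate(excluded, status = "excluded", r2 = NA_real_,
                  f_stat = NA_real_)
  )
  structure(list(selected = kept, proxies = proxies, report = report),
            class = "instrument_report")
}

#' @export
print.instrument_report <- function(x, ...) {
  cat("<instrument_report>", length(x$selected), "selected,",
      sum(x$report$status == "excluded"), "excluded\n")
  invisible(x)
}

#' @method tidy instrument_report
#' @export
tidy.instrument_report <- function(x, ...) x$report
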