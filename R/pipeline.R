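#' Analysis configuration
#'
#' Collects every tunable threshold of the workflow in one list. Defaults
#' follow standard two-sample MR practice: genome-wide instrument
#' significance 5e-8 (lenient 5e-7 for reverse-direction analyses where
#' instruments are scarce), clumping at r-squared 0.001 within 10,000 kb,
#' weak instruments dismissed below F = 10, outcome-associated instruments
#' removed at 5e-8, proxies accepted at r-squared 0.8 or higher, palindromic
#' variants dropped at effect-allele frequency 0.42-0.58, and a Bonferroni
#' family of 4 primary exposures giving a 0.0125 significance gate.
#'
#' @param p_instrument Instrument p-value threshold, default `5e-8`.
#' @param p_reverse Lenient threshold for reverse-direction instrument
#'   selection, default `5e-7`.
#' @param clump_r2,window_kb Clumping parameters, defaults 0.001 / 10000.
#' @param f_min Weak-instrument F cutoff, default 10.
#' @param outcome_p Outcome-association exclusion threshold, default 5e-8.
#' @param proxy_r2 Minimum proxy r-squared, default 0.8.
#' @param palindrome_eaf_window Intermediate-frequency window, default
#'   `c(0.42, 0.58)`.
#' @param alpha Nominal significance level for diagnostics, default 0.05.
#' @param family_size Bonferroni family size for the primary significance
#'   gate, default 4.
#' @param alpha_screen Mediator-screen significance level, default 0.05.
#' @param n_boot Bootstrap draws for median-type estimators, default 1000.
#' @param presso_n_sim MR-PRESSO bootstrap draws, default 1000.
#' @param mvmr_policy Instrument policy for multivariable fits: `"union"`
#'   or `"first_exposure"`.
#' @param seed Integer seed for all stochastic methods, default 1.
#' @return A list of class `mr_config`.
#' @export
mr_config <- function(p_instrument = 5e-8, p_reverse = 5e-7,
                      clump_r2 = 0.001, window_kb = 10000, f_min = 10,
                      outcome_p = 5e-8, proxy_r2 = 0.8,
                      palindrome_eaf_window = c(0.42, 0.58), alpha = 0.05,
                      family_size = 4, alpha_screen = 0.05, n_boot = 1000,
                      presso_n_sim = 1000,
                      mvmr_policy = c("union", "first_exposure"),
                      seed = 1) {
  stopifnot(family_size >= 1)
  structure(
    list(p_instrument = p_instrument, p_reverse = p_reverse,
         clump_r2 = clump_r2, window_kb = window_kb, f_min = f_min,
         outcome_p = outcome_p, proxy_r2 = proxy_r2,
         palindrome_eaf_window = palindrome_eaf_window, alpha = alpha,
         family_size = family_size, alpha_screen = alpha_screen,
         n_boot = n_boot, presso_n_sim = presso_n_sim,
         mvmr_policy = match.arg(mvmr_policy), seed = as.integer(seed)),
    class = "mr_config"
  )
}

# all univariable methods + diagnostics on one harmonized pair
uvmr_all_methods <- function(h, config, gate_threshold) {
  J <- n_snp(h)
  fits <- list(mr_ivw(h))
  if (J >= 3) fits <- c(fits, list(mr_egger(h)))
  if (J >= 3) {
    fits <- c(fits, list(mr_weighted_median(h, n_boot = config$n_boot,
                                            seed = config$seed)))
  }
  fits <- c(fits, list(mr_max_likelihood(h)))
  presso <- if (J >= 4) {
    mr_presso(h, n_sim = config$presso_n_sim, seed = config$seed,
              alpha = config$alpha)
  } else {
    NULL
  }
  binary <- identical(h$outcome_type, "binary")
  if (binary) fits <- lapply(fits, or_from_result)

  rows <- purrr::map_dfr(fits, function(f) {
    dplyr::bind_cols(tidy(f), glance(f)[, c("q_stat", "q_pvalue",
                                            "egger_intercept",
                                            "intercept_pvalue")])
  })
  if (!is.null(presso)) {
    pr <- tidy(presso)
    if (binary) {
      pr <- dplyr::mutate(pr, or_ = exp(.data$beta),
                          or_low = exp(.data$ci_low),
                          or_high = exp(.data$ci_high))
    }
    pr$q_stat <- NA_real_; pr$q_pvalue <- NA_real_
    pr$egger_intercept <- NA_real_; pr$intercept_pvalue <- NA_real_
    rows <- dplyr::bind_rows(rows, pr)
  }

  ivw <- fits[[1]]
  others <- c(fits[-1],
              if (!is.null(presso)) list(presso$corrected_estimate))
  rows$gate_passed <- NA
  rows$gate_passed[1] <- significance_gate(ivw, others, gate_threshold)

  steiger <- tryCatch(steiger_test(h), error = function(e) NULL)
  rows$steiger_direction <- if (is.null(steiger)) NA_character_ else
    steiger$direction
  rows$steiger_pvalue <- if (is.null(steiger)) NA_real_ else steiger$pvalue

  # radial re-analysis only when heterogeneity is detected
  if (!is.null(ivw$q_pvalue) && ivw$q_pvalue < config$alpha) {
    rad <- radial_ivw(h, alpha = config$alpha)
    rr <- tidy(rad$post_removal)
    rr$method <- "radial_post_removal"
    if (binary) {
      rr <- dplyr::mutate(rr, or_ = exp(.data$beta),
                          or_low = exp(.data$ci_low),
                          or_high = exp(.data$ci_high))
    }
    rows <- dplyr::bind_rows(rows, rr)
  }
  rows
}

#' Bidirectional univariable MR across exposures
#'
#' For every exposure: instrument selection (p-value threshold, clumping,
#' weak-instrument and outcome-association filters), harmonization, all
#' univariable estimators with heterogeneity/pleiotropy/directionality
#' diagnostics, a radial MR re-analysis when Cochran's Q flags
#' heterogeneity, and the dual significance gate at the Bonferroni
#' threshold `alpha / family_size`. The reverse direction (outcome as
#' exposure) is run with the lenient instrument threshold. Failures on a
#' single pair are logged and skipped.
#'
#' @param exposures List of [mr_sumstats()] datasets (or a single one).
#' @param outcome An [mr_sumstats()] dataset.
#' @param ld An [mr_ld()] table.
#' @param config An [mr_config()] list.
#' @param reverse Run the reverse direction too, default `TRUE`.
#' @return Tibble with one row per (pair, direction, method).
#' @export
run_uvmr_phase <- function(exposures, outcome, ld = mr_ld(),
                           config = mr_config(), reverse = TRUE) {
  if (inherits(exposures, "mr_sumstats")) exposures <- list(exposures)
  gate <- bonferroni_threshold(config$alpha, config$family_size)

  one_pair <- function(exp_ds, out_ds, direction, p_sel) {
    sel <- select_instruments(
      exp_ds, outcome = out_ds, ld = ld, p_threshold = p_sel,
      r2_max = config$clump_r2, window_kb = config$window_kb,
      f_min = config$f_min, outcome_p = config$outcome_p,
      proxy_r2 = config$proxy_r2)
    h <- harmonize(exp_ds, out_ds, instrument_ids = sel$selected,
                   palindrome_eaf_window = config$palindrome_eaf_window)
    rows <- uvmr_all_methods(h, config, gate)
    dplyr::mutate(rows, exposure = trait_id(exp_ds),
                  outcome = trait_id(out_ds), direction = direction,
                  .before = 1)
  }

  purrr::map_dfr(exposures, function(e) {
    fwd <- tryCatch(
      one_pair(e, outcome, "forward", config$p_instrument),
      error = function(err) {
        inform(paste0("skipping ", trait_id(e), " -> ", trait_id(outcome),
                      ": ", conditionMessage(err)))
        tibble::tibble()
      })
    rev <- if (reverse) {
      tryCatch(
        one_pair(outcome, e, "reverse", config$p_reverse),
        error = function(err) {
          inform(paste0("skipping reverse ", trait_id(outcome), " -> ",
                        trait_id(e), ": ", conditionMessage(err)))
          tibble::tibble()
        })
    } else {
      tibble::tibble()
    }
    dplyr::bind_rows(fwd, rev)
  })
}

#' Confounder-adjusted multivariable MR
#'
#' For each confounder, fits the multivariable models (MV-IVW primary;
#' Egger, median and Lasso supplementary) of the outcome on the exposure
#' plus that confounder, reporting the exposure's adjusted effect alongside
#' the unadjusted univariable estimate. Confounders are adjusted one at a
#' time by default; pass `joint = TRUE` to adjust for all simultaneously.
#'
#' @param exposure An [mr_sumstats()] dataset.
#' @param confounders List of [mr_sumstats()] datasets.
#' @param outcome An [mr_sumstats()] dataset.
#' @param ld An [mr_ld()] table.
#' @param config An [mr_config()] list.
#' @param joint Adjust for all confounders jointly, default `FALSE`.
#' @return Tibble with one row per (adjustment, method, exposure term).
#' @export
run_mvmr_phase <- function(exposure, confounders, outcome, ld = mr_ld(),
                           config = mr_config(), joint = FALSE) {
  if (inherits(confounders, "mr_sumstats")) confounders <- list(confounders)

  unadjusted <- tryCatch({
    sel <- select_instruments(
      exposure, outcome = outcome, ld = ld,
      p_threshold = config$p_instrument, r2_max = config$clump_r2,
      window_kb = config$window_kb, f_min = config$f_min,
      outcome_p = config$outcome_p, proxy_r2 = config$proxy_r2)
    h <- harmonize(exposure, outcome, instrument_ids = sel$selected,
                   palindrome_eaf_window = config$palindrome_eaf_window)
    fit <- or_from_result(mr_ivw(h))
    dplyr::mutate(tidy(fit), adjustment = "none",
                  exposure = trait_id(exposure),
                  intercept_pvalue = NA_real_, .before = 1)
  }, error = function(e) tibble::tibble())

  sets <- if (joint) list(confounders) else lapply(confounders, list)
  adjusted <- purrr::map_dfr(sets, function(confs) {
    label <- paste(vapply(confs, trait_id, character(1)), collapse = "+")
    tryCatch({
      h <- align_multi(c(list(exposure), confs), outcome, ld = ld,
                       p_threshold = config$p_instrument,
                       r2_max = config$clump_r2,
                       window_kb = config$window_kb,
                       instrument_policy = config$mvmr_policy,
                       palindrome_eaf_window = config$palindrome_eaf_window)
      fits <- list(mv_ivw(h), mvmr_egger(h),
                   mvmr_median(h, n_boot = config$n_boot,
                               seed = config$seed),
                   mvmr_lasso(h))
      purrr::map_dfr(fits, function(f) {
        dplyr::mutate(tidy(f), adjustment = label,
                      intercept_pvalue = f$intercept_pvalue %||% NA_real_,
                      .before = 1)
      })
    }, error = function(e) {
      inform(paste0("skipping adjustment for ", label, ": ",
                    conditionMessage(e)))
      tibble::tibble()
    })
  })
  dplyr::bind_rows(unadjusted, adjusted)
}

#' Full two-phase workflow: bidirectional UVMR, MVMR, mediation
#'
#' Phase 1 runs bidirectional univariable MR for each exposure against the
#' outcome and confounder-adjusted multivariable MR for the first exposure.
#' Phase 2 screens the candidate mediators and quantifies mediating effects
#' and proportions by two-step MR. Optionally writes the result tables
#' (TSV), a machine-readable JSON summary and a plain-text log to
#' `out_dir`; all outputs are deterministic given the config seed.
#'
#' @param exposures List of [mr_sumstats()] datasets (first is the primary
#'   exposure used for MVMR and mediation).
#' @param outcome An [mr_sumstats()] dataset.
#' @param confounders,mediators Lists of [mr_sumstats()] datasets (may be
#'   empty).
#' @param ld An [mr_ld()] table.
#' @param config An [mr_config()] list.
#' @param out_dir Optional output directory.
#' @return Object of class `mr_report`: `uvmr`, `mvmr`, `screen`,
#'   `mediation` tibbles plus the `config` used.
#' @export
run_full <- function(exposures, outcome, confounders = list(),
                     mediators = list(), ld = mr_ld(),
                     config = mr_config(), out_dir = NULL) {
  if (inherits(exposures, "mr_sumstats")) exposures <- list(exposures)
  uvmr <- run_uvmr_phase(exposures, outcome, ld = ld, config = config)
  mvmr <- if (length(confounders)) {
    run_mvmr_phase(exposures[[1]], confounders, outcome, ld = ld,
                   config = config)
  } else {
    tibble::tibble()
  }
  med <- if (length(mediators)) {
    run_mediation(exposures[[1]], mediators, outcome, ld = ld,
                  config = config)
  } else {
    NULL
  }

  report <- structure(
    list(uvmr = uvmr, mvmr = mvmr,
         screen = if (is.null(med)) tibble::tibble() else med$screen,
         mediation = if (is.null(med)) tibble::tibble() else med$results,
         config = config),
    class = "mr_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.mr_report <- function(x, ...) {
  cat("<mr_report>\n")
  cat("  uvmr rows:", nrow(x$uvmr), "| mvmr rows:", nrow(x$mvmr),
      "| mediators passed:",
      if (nrow(x$screen)) sum(x$screen$passed) else 0, "\n")
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("uvmr", "mvmr", "screen", "mediation")) {
    if (nrow(report[[nm]])) {
      readr::write_tsv(report[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                       progress = FALSE)
    }
  }
  jsonlite::write_json(
    list(uvmr = report$uvmr, mvmr = report$mvmr, screen = report$screen,
         mediation = report$mediation,
         config = unclass(report$config)),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  writeLines(
    c(paste("mrmediate", as.character(utils::packageVersion("mrmediate"))),
      paste("seed:", report$config$seed),
      paste("instrument p threshold:", report$config$p_instrument),
      paste("reverse p threshold:", report$config$p_reverse),
      paste("clump r2:", report$config$clump_r2),
      paste("Bonferroni gate:",
            bonferroni_threshold(report$config$alpha,
                                 report$config$family_size))),
    file.path(out_dir, "run.log"))
  invisible(out_dir)
}
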