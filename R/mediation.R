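#' Product-of-coefficients mediating effect with delta-method error
#'
#' The mediating (indirect) effect of an exposure on an outcome through one
#' mediator is `beta1 * beta2`, where `beta1` is the exposure-to-mediator
#' effect and `beta2` the mediator-to-outcome effect adjusted for the
#' exposure. The first-order delta-method standard error, treating the two
#' steps as independent, is `sqrt(beta1^2 se2^2 + beta2^2 se1^2)`.
#'
#' @param beta1,se1 Exposure-to-mediator estimate and standard error.
#' @param beta2,se2 Adjusted mediator-to-outcome estimate and standard
#'   error.
#' @return Tibble with `indirect` and `indirect_se`.
#' @export
two_step_effect <- function(beta1, se1, beta2, se2) {
  stopifnot(all(se1 > 0), all(se2 > 0))
  tibble::tibble(indirect = beta1 * beta2,
                 indirect_se = sqrt(beta1^2 * se2^2 + beta2^2 * se1^2))
}

#' Mediated proportion with delta-method error
#'
#' The proportion of the total effect carried through a mediator is the
#' mediating effect divided by the total effect, `indirect / beta0`. The
#' standard error propagates both components as independent:
#' `|proportion| * sqrt((indirect_se/indirect)^2 + (se0/beta0)^2)` (reducing
#' to `indirect_se / |beta0|` when the indirect effect is 0). The 95 percent
#' interval is reported both raw and truncated to `[0, 1]`; truncation is a
#' reporting convention only.
#'
#' @param indirect,indirect_se Mediating effect and its standard error.
#' @param beta0,se0 Total effect (non-zero) and its standard error.
#' @return Tibble with `proportion`, `proportion_se`, `ci_low`, `ci_high`
#'   (raw) and `ci_low_trunc`, `ci_high_trunc`.
#' @export
mediated_proportion <- function(indirect, indirect_se, beta0, se0) {
  if (any(beta0 == 0)) abort("total effect beta0 must be non-zero")
  prop <- indirect / beta0
  prop_se <- ifelse(
    indirect == 0,
    indirect_se / abs(beta0),
    abs(prop) * sqrt((indirect_se / indirect)^2 + (se0 / beta0)^2)
  )
  z <- qnorm(0.975)
  tibble::tibble(
    proportion = prop, proportion_se = prop_se,
    ci_low = prop - z * prop_se, ci_high = prop + z * prop_se,
    ci_low_trunc = pmin(pmax(prop - z * prop_se, 0), 1),
    ci_high_trunc = pmin(pmax(prop + z * prop_se, 0), 1)
  )
}

#' Monte-Carlo interval for the mediated proportion
#'
#' Sensitivity alternative to the delta method: draws
#' `(beta1, beta2, beta0)` from their sampling distributions and takes
#' percentile bounds of `beta1 beta2 / beta0`.
#'
#' @param beta1,se1,beta2,se2,beta0,se0 Step and total estimates with
#'   standard errors.
#' @param n_draws Number of draws, default 1e5.
#' @param seed Integer seed.
#' @return Tibble with `proportion`, `ci_low`, `ci_high` (2.5/97.5
#'   percentiles).
#' @export
mediated_proportion_mc <- function(beta1, se1, beta2, se2, beta0, se0,
                                   n_draws = 1e5, seed) {
  draws <- withr_seed(seed, {
    rnorm(n_draws, beta1, se1) * rnorm(n_draws, beta2, se2) /
      rnorm(n_draws, beta0, se0)
  })
  qs <- quantile(draws, c(0.025, 0.975), names = FALSE)
  tibble::tibble(proportion = beta1 * beta2 / beta0,
                 ci_low = qs[1], ci_high = qs[2])
}

#' Five-criterion mediator screen
#'
#' Evaluates one candidate mediator on the pathway from exposure to
#' outcome:
#' * `c1_exposure_to_mediator` — the exposure causally affects the mediator
#'   (univariable IVW p below `alpha_screen`); the Egger intercept of this
#'   fit also sets `pleiotropy_flag`;
#' * `c2_mediator_to_outcome_uvmr` — the mediator affects the outcome
#'   without adjustment;
#' * `c3_mediator_to_outcome_mvmr` — the mediator affects the outcome after
#'   adjusting for the exposure (multivariable IVW);
#' * `c4_no_reverse_causation` — the mediator does not causally affect the
#'   exposure (reverse univariable IVW p at or above `alpha_screen`);
#' * `c5_sign_consistent` — the mediating effect `beta1 * beta2` shares the
#'   sign of the total effect `beta0`.
#'
#' A candidate passes only when all five criteria hold and no directional
#' pleiotropy is flagged on the exposure-to-mediator fit.
#'
#' @param exposure,mediator,outcome [mr_sumstats()] datasets.
#' @param ld An [mr_ld()] table.
#' @param config An [mr_config()] list (uses `alpha_screen`,
#'   `p_instrument`, clumping and harmonization settings).
#' @param beta0 Optional precomputed total-effect `mr_result`
#'   (exposure-to-outcome IVW); computed when `NULL`.
#' @return One-row tibble (`screen_decision`): the five criteria,
#'   `pleiotropy_flag`, `passed`, `exclusion_reason`, and the step
#'   estimates (`beta1`, `se1`, `beta2`, `se2`).
#' @export
screen_mediator <- function(exposure, mediator, outcome, ld = mr_ld(),
                            config = mr_config(), beta0 = NULL) {
  med_id <- trait_id(mediator)
  res <- tryCatch(
    screen_mediator_impl(exposure, mediator, outcome, ld, config, beta0),
    error = function(e) {
      abort(paste0("screening failed for mediator '", med_id, "': ",
                   conditionMessage(e)))
    }
  )
  res
}

screen_mediator_impl <- function(exposure, mediator, outcome, ld, config,
                                 beta0) {
  alpha <- config$alpha_screen
  sel_exp <- select_instruments(
    exposure, ld = ld, p_threshold = config$p_instrument,
    r2_max = config$clump_r2, window_kb = config$window_kb,
    f_min = config$f_min)

  if (is.null(beta0)) {
    h0 <- harmonize(exposure, outcome, instrument_ids = sel_exp$selected,
                    palindrome_eaf_window = config$palindrome_eaf_window)
    beta0 <- mr_ivw(h0)
  }

  # c1: exposure -> mediator, with Egger pleiotropy flag
  h1 <- harmonize(exposure, mediator, instrument_ids = sel_exp$selected,
                  palindrome_eaf_window = config$palindrome_eaf_window)
  fit1 <- mr_ivw(h1)
  c1 <- fit1$pvalue < alpha
  pleio <- if (n_snp(h1) >= 3) {
    mr_egger(h1)$intercept_pvalue < alpha
  } else {
    FALSE
  }

  sel_med <- select_instruments(
    mediator, ld = ld, p_threshold = config$p_instrument,
    r2_max = config$clump_r2, window_kb = config$window_kb,
    f_min = config$f_min)

  # c2: mediator -> outcome, unadjusted
  h2 <- harmonize(mediator, outcome, instrument_ids = sel_med$selected,
                  palindrome_eaf_window = config$palindrome_eaf_window)
  fit2 <- mr_ivw(h2)
  c2 <- fit2$pvalue < alpha

  # c3: mediator -> outcome adjusted for the exposure (MV-IVW)
  h3 <- align_multi(list(mediator, exposure), outcome, ld = ld,
                    p_threshold = config$p_instrument,
                    r2_max = config$clump_r2, window_kb = config$window_kb,
                    instrument_policy = config$mvmr_policy,
                    palindrome_eaf_window = config$palindrome_eaf_window)
  fit3 <- mv_ivw(h3)
  row3 <- fit3$estimates[fit3$estimates$exposure == trait_id(mediator), ]
  c3 <- row3$pvalue < alpha

  # c4: no reverse causation (mediator -> exposure must be null)
  h4 <- harmonize(mediator, exposure, instrument_ids = sel_med$selected,
                  palindrome_eaf_window = config$palindrome_eaf_window)
  fit4 <- mr_ivw(h4)
  c4 <- fit4$pvalue >= alpha

  # c5: mediating and total effects point the same way
  c5 <- sign(fit1$beta * row3$beta) == sign(beta0$beta)

  reasons <- c(
    pleiotropy_flag = "exposure_mediator_pleiotropy",
    c1_exposure_to_mediator = "no_exposure_to_mediator_effect",
    c2_mediator_to_outcome_uvmr = "no_mediator_to_outcome_effect",
    c3_mediator_to_outcome_mvmr = "no_adjusted_mediator_to_outcome_effect",
    c4_no_reverse_causation = "reverse_causation_with_exposure",
    c5_sign_consistent = "sign_inconsistent_with_total_effect"
  )
  flags <- c(pleiotropy_flag = !pleio, c1_exposure_to_mediator = c1,
             c2_mediator_to_outcome_uvmr = c2,
             c3_mediator_to_outcome_mvmr = c3,
             c4_no_reverse_causation = c4, c5_sign_consistent = c5)
  passed <- all(flags)
  exclusion_reason <- if (passed) NA_character_ else {
    unname(reasons[names(which(!flags))[1]])
  }

  tibble::tibble(
    mediator_id = trait_id(mediator),
    c1_exposure_to_mediator = c1,
    c2_mediator_to_outcome_uvmr = c2,
    c3_mediator_to_outcome_mvmr = c3,
    c4_no_reverse_causation = c4,
    c5_sign_consistent = c5,
    pleiotropy_flag = pleio,
    passed = passed,
    exclusion_reason = exclusion_reason,
    beta1 = fit1$beta, se1 = fit1$se, p1 = fit1$pvalue,
    beta2 = row3$beta, se2 = row3$se, p2 = row3$pvalue
  )
}

#' Two-step MR mediation across a set of candidate mediators
#'
#' Screens every candidate with [screen_mediator()]; for survivors computes
#' the total effect `beta0` (univariable IVW, exposure instruments), the
#' step estimates `beta1` (univariable IVW exposure-to-mediator) and `beta2`
#' (multivariable IVW of the outcome on mediator plus exposure), then the
#' mediating effect and mediated proportion with delta-method errors.
#' Candidates whose screening errors out (e.g. no usable instruments) are
#' recorded as failed rather than aborting the run.
#'
#' @param exposure An [mr_sumstats()] dataset.
#' @param mediators List of [mr_sumstats()] candidate mediator datasets.
#' @param outcome An [mr_sumstats()] dataset.
#' @param ld An [mr_ld()] table.
#' @param config An [mr_config()] list.
#' @return Object of class `mr_mediation`: `total` (the `mr_result` for
#'   `beta0`), `screen` (one row per candidate) and `results` (one row per
#'   passing mediator, ranked by mediated proportion, largest first).
#' @export
run_mediation <- function(exposure, mediators, outcome, ld = mr_ld(),
                          config = mr_config()) {
  stopifnot(length(mediators) >= 1)
  sel_exp <- select_instruments(
    exposure, outcome = outcome, ld = ld,
    p_threshold = config$p_instrument, r2_max = config$clump_r2,
    window_kb = config$window_kb, f_min = config$f_min,
    outcome_p = config$outcome_p, proxy_r2 = config$proxy_r2)
  h0 <- harmonize(exposure, outcome, instrument_ids = sel_exp$selected,
                  palindrome_eaf_window = config$palindrome_eaf_window)
  beta0 <- mr_ivw(h0)

  screen <- purrr::map_dfr(mediators, function(m) {
    tryCatch(
      screen_mediator(exposure, m, outcome, ld = ld, config = config,
                      beta0 = beta0),
      error = function(e) {
        tibble::tibble(mediator_id = trait_id(m),
                       passed = FALSE,
                       exclusion_reason = conditionMessage(e))
      }
    )
  })

  passing <- screen[which(screen$passed), ]
  total_beta <- beta0$beta
  total_se <- beta0$se
  results <- if (nrow(passing)) {
    step <- two_step_effect(passing$beta1, passing$se1, passing$beta2,
                            passing$se2)
    prop <- mediated_proportion(step$indirect, step$indirect_se,
                                beta0$beta, beta0$se)
    dplyr::arrange(
      dplyr::bind_cols(
        passing[, c("mediator_id", "beta1", "se1", "beta2", "se2")],
        tibble::tibble(beta0 = total_beta, se0 = total_se),
        step, prop),
      dplyr::desc(.data$proportion))
  } else {
    tibble::tibble()
  }

  structure(list(total = beta0, screen = screen, results = results,
                 exposure_id = trait_id(exposure),
                 outcome_id = trait_id(outcome)),
            class = "mr_mediation")
}

#' @export
print.mr_mediation <- function(x, ...) {
  cat("<mr_mediation>", x$exposure_id, "->", x$outcome_id, "| total beta =",
      signif(x$total$beta, 4), "\n")
  cat(" ", sum(x$screen$passed), "of", nrow(x$screen),
      "candidate mediator(s) passed screening\n")
  if (nrow(x$results)) {
    print(x$results[, c("mediator_id", "indirect", "proportion",
                        "ci_low_trunc", "ci_high_trunc")])
  }
  invisible(x)
}

#' @method tidy mr_mediation
#' @export
tidy.mr_mediation <- function(x, ...) x$results

#' @method glance mr_mediation
#' @export
glance.mr_mediation <- function(x, ...) {
  tibble::tibble(exposure = x$exposure_id, outcome = x$outcome_id,
                 beta0 = x$total$beta, se0 = x$total$se,
                 n_candidates = nrow(x$screen),
                 n_passed = sum(x$screen$passed))
}
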