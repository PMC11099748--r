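#' Configuration for the synthetic summary-statistic generator
#'
#' Defines the generative model: a causal chain exposure -> mediator ->
#' outcome with a direct exposure-to-outcome path, observed through
#' two-sample GWAS summary statistics. Defaults mirror a UK-Biobank-scale
#' continuous exposure (appendicular lean mass, n = 450,243), a large
#' binary mediator GWAS (coronary heart disease, n = 184,305) and a
#' MEGASTROKE-scale binary outcome (ischemic stroke, n = 440,328); the
#' default path coefficients reproduce a total effect of about -0.078 on
#' the log-odds scale with roughly 40 percent mediated.
#'
#' @param n_snps Number of exposure instruments, default 50.
#' @param n_mediator_snps Number of mediator-specific instruments (variants
#'   affecting the mediator but not the exposure), default 50.
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes.
#' @param maf_range Uniform range for minor-allele frequencies, within
#'   `(0, 0.5]`; default `c(0.05, 0.5)`.
#' @param gamma_sd Standard deviation of true per-variant effects, default
#'   0.03 (most instruments reach genome-wide significance at these sample
#'   sizes).
#' @param theta_direct Direct exposure-to-outcome effect, default -0.047.
#' @param beta1_true Exposure-to-mediator effect, default -0.176.
#' @param beta2_true Mediator-to-outcome effect, default 0.177.
#' @param pleiotropy `"none"`, `"balanced"` (zero-mean direct effects on
#'   the outcome) or `"directional"` (non-zero mean).
#' @param pleiotropy_mean,pleiotropy_sd Parameters of the pleiotropic
#'   effects (exposure instruments only).
#' @param n_outliers Number of exposure instruments whose true outcome
#'   effect is shifted by `outlier_shift`.
#' @param outlier_shift Additive shift on the outcome effect of outlier
#'   variants.
#' @param ld_blocks Optional `list(block_size =, r2 =)`: variants are tiled
#'   into blocks with constant within-block r-squared (0 between blocks).
#' @param seed Integer seed; mandatory.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 50, n_mediator_snps = 50,
                       n_exposure = 450243, n_mediator = 184305,
                       n_outcome = 440328, maf_range = c(0.05, 0.5),
                       gamma_sd = 0.03, theta_direct = -0.047,
                       beta1_true = -0.176, beta2_true = 0.177,
                       pleiotropy = c("none", "balanced", "directional"),
                       pleiotropy_mean = 0, pleiotropy_sd = 0,
                       n_outliers = 0, outlier_shift = 0,
                       ld_blocks = NULL, seed) {
  pleiotropy <- match.arg(pleiotropy)
  problems <- character(0)
  if (missing(seed)) problems <- c(problems, "seed is mandatory")
  if (n_snps < 1) problems <- c(problems, "n_snps must be >= 1")
  if (n_mediator_snps < 0) {
    problems <- c(problems, "n_mediator_snps must be >= 0")
  }
  for (nm in c("n_exposure", "n_mediator", "n_outcome")) {
    if (get(nm) <= 3) problems <- c(problems, paste(nm, "must exceed 3"))
  }
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    problems <- c(problems, "maf_range must be an interval within (0, 0.5]")
  }
  if (n_outliers < 0 || n_outliers > n_snps) {
    problems <- c(problems, "n_outliers must lie in [0, n_snps]")
  }
  if (!is.null(ld_blocks) &&
      (is.null(ld_blocks$block_size) || is.null(ld_blocks$r2))) {
    problems <- c(problems, "ld_blocks needs block_size and r2")
  }
  if (length(problems)) {
    abort(paste0("invalid simulation config: ",
                 paste(problems, collapse = "; ")))
  }
  structure(
    list(n_snps = n_snps, n_mediator_snps = n_mediator_snps,
         n_exposure = n_exposure, n_mediator = n_mediator,
         n_outcome = n_outcome, maf_range = maf_range, gamma_sd = gamma_sd,
         theta_direct = theta_direct, beta1_true = beta1_true,
         beta2_true = beta2_true, pleiotropy = pleiotropy,
         pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
         n_outliers = n_outliers, outlier_shift = outlier_shift,
         ld_blocks = ld_blocks, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# non-palindromic allele pairs so that harmonization is lossless by design
sim_allele_pairs <- function() {
  list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
       c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
}

#' Simulate an exposure/mediator/outcome summary-statistic triplet
#'
#' Draws minor-allele frequencies uniformly, true per-variant exposure
#' effects from `N(0, gamma_sd^2)`, mediator effects `beta1_true * gamma`
#' plus mediator-specific instruments, and outcome effects
#' `(theta_direct + beta1_true * beta2_true) * gamma + beta2_true * delta`
#' plus optional pleiotropy and outlier shifts. Observed effects add
#' independent noise with `se = 1 / sqrt(2 maf (1 - maf) n_trait)` per
#' trait; the three noise draws are independent, matching the two-sample
#' (no overlap) design. Fully reproducible from the config seed.
#'
#' @param config A [sim_config()].
#' @return List of class `mr_sim`: `exposure`, `mediator`, `outcome`
#'   ([mr_sumstats()] datasets), `ld` ([mr_ld()]) and `truth` (realized
#'   effects, outlier ids, implied `beta0`/`beta1`/`beta2` and mediated
#'   proportion).
#' @export
simulate_triplet <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  J <- cfg$n_snps; M <- cfg$n_mediator_snps
  total <- J + M
  withr_seed(cfg$seed, {
    ids <- sprintf("rs%05d", seq_len(total))
    maf <- runif(total, cfg$maf_range[1], cfg$maf_range[2])
    pair_idx <- sample.int(length(sim_allele_pairs()), total, replace = TRUE)
    ea <- vapply(sim_allele_pairs()[pair_idx], `[`, character(1), 1)
    oa <- vapply(sim_allele_pairs()[pair_idx], `[`, character(1), 2)

    gamma <- c(rnorm(J, 0, cfg$gamma_sd), rep(0, M))
    delta <- c(rep(0, J), rnorm(M, 0, cfg$gamma_sd))
    alpha <- rep(0, total)
    if (cfg$pleiotropy == "balanced") {
      alpha[seq_len(J)] <- rnorm(J, 0, cfg$pleiotropy_sd)
    } else if (cfg$pleiotropy == "directional") {
      alpha[seq_len(J)] <- rnorm(J, cfg$pleiotropy_mean, cfg$pleiotropy_sd)
    }
    beta0_true <- cfg$theta_direct + cfg$beta1_true * cfg$beta2_true
    true_exp <- gamma
    true_med <- cfg$beta1_true * gamma + delta
    true_out <- beta0_true * gamma + cfg$beta2_true * delta + alpha
    outlier_idx <- integer(0)
    if (cfg$n_outliers > 0) {
      outlier_idx <- sample.int(J, cfg$n_outliers)
      true_out[outlier_idx] <- true_out[outlier_idx] + cfg$outlier_shift
    }

    mk <- function(true_beta, n_trait, trait, type, unit) {
      se <- 1 / sqrt(2 * maf * (1 - maf) * n_trait)
      b <- rnorm(total, true_beta, se)
      mr_sumstats(
        tibble::tibble(
          variant_id = ids, effect_allele = ea, other_allele = oa,
          eaf = maf, beta = b, se = se,
          pvalue = pmax(2 * pnorm(-abs(b / se)), .Machine$double.xmin),
          n = n_trait),
        trait_id = trait, trait_type = type, unit = unit)
    }
    exposure <- mk(true_exp, cfg$n_exposure, "exposure", "continuous",
                   "1-SD")
    mediator <- mk(true_med, cfg$n_mediator, "mediator", "binary", "event")
    outcome <- mk(true_out, cfg$n_outcome, "outcome", "binary", "event")

    ld <- if (is.null(cfg$ld_blocks)) {
      mr_ld()
    } else {
      bs <- cfg$ld_blocks$block_size
      block <- ceiling(seq_len(total) / bs)
      pairs <- purrr::map_dfr(unique(block), function(bl) {
        members <- ids[block == bl]
        if (length(members) < 2) return(tibble::tibble())
        cmb <- utils::combn(members, 2)
        tibble::tibble(variant_a = cmb[1, ], variant_b = cmb[2, ],
                       r2 = cfg$ld_blocks$r2)
      })
      mr_ld(pairs)
    }

    structure(
      list(exposure = exposure, mediator = mediator, outcome = outcome,
           ld = ld,
           truth = list(
             gamma = setNames(gamma, ids), delta = setNames(delta, ids),
             pleiotropy = setNames(alpha, ids),
             outlier_ids = ids[outlier_idx],
             beta0 = beta0_true, beta1 = cfg$beta1_true,
             beta2 = cfg$beta2_true,
             proportion = if (beta0_true != 0) {
               cfg$beta1_true * cfg$beta2_true / beta0_true
             } else {
               NA_real_
             }),
           config = cfg),
      class = "mr_sim"
    )
  })
}

#' @export
print.mr_sim <- function(x, ...) {
  cat("<mr_sim>", x$config$n_snps, "exposure +", x$config$n_mediator_snps,
      "mediator instruments | true beta0 =", signif(x$truth$beta0, 4),
      " proportion =", signif(x$truth$proportion, 4), "\n")
  invisible(x)
}

#' Shift the observed effects of selected variants
#'
#' Adds `shift` to the observed beta of the given variants, leaving every
#' other field untouched. Used to plant outliers for testing the outlier
#' diagnostics.
#'
#' @param dataset An [mr_sumstats()] dataset.
#' @param variant_ids Variants to shift; all must exist in `dataset`.
#' @param shift Additive shift.
#' @return The modified dataset.
#' @export
inject_outliers <- function(dataset, variant_ids, shift) {
  idx <- match(variant_ids, dataset$variant_id)
  if (anyNA(idx)) {
    abort(paste0("unknown variant(s): ",
                 paste(variant_ids[is.na(idx)], collapse = ", ")))
  }
  dataset$beta[idx] <- dataset$beta[idx] + shift
  dataset
}

#' Simulate individual-level genotype and trait data for one variant
#'
#' Validation helper for [variance_explained()]: genotypes are
#' `Binomial(2, maf)` and the trait is `beta * g` plus standard normal
#' noise, so the regression R-squared has expectation
#' `beta^2 2f(1-f) / (beta^2 2f(1-f) + 1)`.
#'
#' @param n Sample size.
#' @param maf Minor-allele frequency.
#' @param beta Per-allele effect in trait-SD units.
#' @param seed Integer seed.
#' @return Tibble with columns `g`, `y`.
#' @export
simulate_individual <- function(n, maf, beta, seed) {
  withr_seed(seed, {
    g <- rbinom(n, 2, maf)
    tibble::tibble(g = g, y = beta * g + rnorm(n))
  })
}
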