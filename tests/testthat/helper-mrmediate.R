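# shared fixture builders; everything is generated in code under fixed seeds

# canonical 3-variant summary table
base_tbl <- function() {
  tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "C", "T"),
    other_allele = c("G", "A", "C"),
    eaf = c(0.30, 0.20, 0.45),
    beta = c(0.10, -0.05, 0.02),
    se = c(0.010, 0.020, 0.015),
    pvalue = c(1e-9, 0.0124, 0.182),
    n = 10000
  )
}

# flat generative model for a single harmonized exposure-outcome pair:
# true instrument effects gamma (optionally oriented positive), causal
# slope theta, optional directional/balanced pleiotropy and planted
# outliers; returns a ready mr_harmonized set
sim_pair <- function(J, theta = 0, seed, n_exp = 5e4, n_out = 5e4,
                     gamma_sd = 0.1, maf = NULL, orient = FALSE,
                     pleio_mean = 0, pleio_sd = 0, n_outliers = 0,
                     outlier_shift = 0, gamma_fixed = NULL) {
  set.seed(seed)
  maf <- maf %||% runif(J, 0.1, 0.5)
  if (length(maf) == 1) maf <- rep(maf, J)
  sx <- 1 / sqrt(2 * maf * (1 - maf) * n_exp)
  sy <- 1 / sqrt(2 * maf * (1 - maf) * n_out)
  gamma <- gamma_fixed %||% rnorm(J, 0, gamma_sd)
  if (orient) gamma <- abs(gamma)
  alpha <- if (pleio_mean != 0 || pleio_sd > 0) {
    rnorm(J, pleio_mean, pleio_sd)
  } else {
    rep(0, J)
  }
  true_out <- theta * gamma + alpha
  if (n_outliers > 0) {
    true_out[seq_len(n_outliers)] <- true_out[seq_len(n_outliers)] +
      outlier_shift
  }
  harmonized_set(rnorm(J, gamma, sx), sx, rnorm(J, true_out, sy), sy,
                 eaf = maf, n_exposure = n_exp, n_outcome = n_out)
}

`%||%` <- rlang::`%||%`

# Deterministic, noise-free summary-statistic triplets isolating one
# screening mechanism each. Observed effects equal the structural values
# exactly, so every p-value, flag and exclusion reason is fully
# reproducible; `scale` varies instrument strength to generate distinct
# fixtures. Effect sizes are kept such that exposure-shared variants stay
# below genome-wide significance in the mediator (and vice versa), as in
# real data where the mediator's instrument set is its own.
archetype_datasets <- function(type = c("clean", "pleiotropy",
                                        "sign_inconsistent", "reverse"),
                               scale = 1) {
  type <- match.arg(type)
  J <- 30; M <- 30
  gamma <- seq(0.03, 0.10, length.out = J) * scale
  delta <- seq(0.03, 0.10, length.out = M) * scale
  b1 <- -0.176
  b2 <- if (type == "sign_inconsistent") -0.2 else 0.177
  thd <- if (type == "sign_inconsistent") -0.15 else -0.047
  beta0 <- thd + b1 * b2
  se_x <- 0.003; se_m <- 0.004; se_o <- 0.004
  maf <- 0.3
  n_for <- function(se) round(1 / (2 * maf * (1 - maf) * se^2))
  ids <- sprintf("fx%04d", seq_len(J + M))
  mk <- function(beta, se, trait, type_tr = "continuous") {
    mr_sumstats(tibble::tibble(
      variant_id = ids, effect_allele = "A", other_allele = "G",
      eaf = maf, beta = beta, se = se,
      pvalue = pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin),
      n = n_for(se)), trait_id = trait, trait_type = type_tr)
  }
  exp_beta <- c(gamma, rep(0, M))
  med_beta <- c(b1 * gamma, delta)
  out_beta <- c(beta0 * gamma, b2 * delta)
  if (type == "pleiotropy") med_beta[1:J] <- med_beta[1:J] + 0.02
  if (type == "reverse") exp_beta[J + seq_len(M)] <- 0.1 * delta
  list(exposure = mk(exp_beta, se_x, "exposure"),
       mediator = mk(med_beta, se_m, "mediator"),
       outcome = mk(out_beta, se_o, "outcome", "binary"))
}

# sim_config shorthand for a pure exposure -> outcome chain (no mediator)
chain_cfg <- function(theta, seed, J = 50, n = 5e4, gamma_sd = 0.1, ...) {
  sim_config(n_snps = J, n_mediator_snps = 0, n_exposure = n,
             n_mediator = n, n_outcome = n, gamma_sd = gamma_sd,
             theta_direct = theta, beta1_true = 0, beta2_true = 0,
             seed = seed, ...)
}
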