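# two-exposure harmonized set with known direct effects
sim_mv <- function(J = 50, effects = c(0.2, 0), seed, n = 1e5,
                   contaminate = 0, contam_shift = 0, invalid = 0,
                   invalid_intercept = 0) {
  set.seed(seed)
  maf <- runif(J, 0.1, 0.5)
  s <- 1 / sqrt(2 * maf * (1 - maf) * n)
  G <- cbind(rnorm(J, 0, 0.1), rnorm(J, 0, 0.1))
  X <- G + matrix(rnorm(2 * J), J) * s
  SX <- cbind(s, s)
  true_y <- drop(G %*% effects)
  if (contaminate > 0) {
    idx <- seq_len(ceiling(contaminate * J))
    true_y[idx] <- true_y[idx] + contam_shift
  }
  if (invalid > 0) {
    true_y[seq_len(invalid)] <- true_y[seq_len(invalid)] + invalid_intercept
  }
  harmonized_set(X, SX, rnorm(J, true_y, s), s,
                 exposure_ids = c("x1", "x2"))
}

test_that("multivariable IVW with one exposure reduces to univariable IVW", {
  h <- sim_pair(J = 20, theta = 0.1, seed = 21)
  mv <- mv_ivw(h)
  uv <- mr_ivw(h, "random_multiplicative")
  expect_equal(mv$estimates$beta, uv$beta, tolerance = 1e-10)
  expect_equal(mv$estimates$se, uv$se, tolerance = 1e-10)
  e_mv <- mvmr_egger(h)
  e_uv <- mr_egger(h)
  expect_equal(e_mv$estimates$beta, e_uv$beta, tolerance = 1e-10)
  expect_equal(e_mv$intercept, e_uv$egger_intercept, tolerance = 1e-10)
  expect_equal(e_mv$intercept_pvalue, e_uv$intercept_pvalue,
               tolerance = 1e-10)
})

test_that("multivariable IVW recovers joint direct effects with coverage", {
  res <- t(vapply(1:200, function(i) {
    h <- sim_mv(J = 50, effects = c(0.2, 0), seed = 9000 + i)
    est <- mv_ivw(h)$estimates
    c(est$beta,
      est$ci_low[1] <= 0.2 && est$ci_high[1] >= 0.2,
      est$ci_low[2] <= 0 && est$ci_high[2] >= 0)
  }, numeric(4)))
  expect_lt(abs(mean(res[, 1]) - 0.2), 0.02)
  expect_lt(abs(mean(res[, 2]) - 0), 0.02)
  expect_gt(mean(res[, 3]), 0.92); expect_lt(mean(res[, 3]), 0.98)
  expect_gt(mean(res[, 4]), 0.92); expect_lt(mean(res[, 4]), 0.98)
})

test_that("a duplicated exposure column raises a collinearity error", {
  h <- sim_pair(J = 20, theta = 0.1, seed = 23)
  h2 <- harmonized_set(cbind(h$exposure_betas[, 1], h$exposure_betas[, 1]),
                       cbind(h$exposure_ses[, 1], h$exposure_ses[, 1]),
                       h$outcome_betas, h$outcome_ses,
                       exposure_ids = c("a", "a_copy"))
  expect_error(mv_ivw(h2), "a_copy")
})

test_that("estimates are invariant to exposure column order", {
  h <- sim_mv(J = 40, effects = c(0.2, -0.1), seed = 31)
  mv <- mv_ivw(h)
  h_swap <- harmonized_set(h$exposure_betas[, 2:1], h$exposure_ses[, 2:1],
                           h$outcome_betas, h$outcome_ses,
                           exposure_ids = c("x2", "x1"))
  mv_swap <- mv_ivw(h_swap)
  expect_equal(mv_swap$estimates$beta[2:1], mv$estimates$beta,
               tolerance = 1e-10)
})

test_that("multivariable Egger recovers an exact intercept", {
  set.seed(41)
  J <- 20
  X <- cbind(abs(rnorm(J, 0, 0.1)), rnorm(J, 0, 0.1))
  y <- 0.02 + drop(X %*% c(0.2, -0.1))
  h <- harmonized_set(X, matrix(0.005, J, 2), y, rep(0.01, J),
                      exposure_ids = c("x1", "x2"))
  e <- mvmr_egger(h)
  expect_equal(e$intercept, 0.02, tolerance = 1e-10)
  expect_equal(e$estimates$beta, c(0.2, -0.1), tolerance = 1e-10)
})

test_that("multivariable Egger intercept holds its size without pleiotropy", {
  rej <- vapply(1:200, function(i) {
    h <- sim_mv(J = 50, effects = c(0.2, 0.1), seed = 10000 + i)
    h$exposure_betas[, 1] <- abs(h$exposure_betas[, 1])
    mvmr_egger(h)$intercept_pvalue < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.11)
})

test_that("multivariable median agrees on clean data and resists outliers", {
  h <- sim_mv(J = 50, effects = c(0.2, 0), seed = 51)
  med <- mvmr_median(h, n_boot = 100, seed = 3)
  ivw <- mv_ivw(h)
  expect_lt(max(abs(med$estimates$beta - ivw$estimates$beta)), 0.03)
  med2 <- mvmr_median(h, n_boot = 100, seed = 3)
  expect_identical(med$estimates$se, med2$estimates$se)

  wins <- vapply(1:50, function(i) {
    h <- sim_mv(J = 50, effects = c(0.2, 0), seed = 11000 + i,
                contaminate = 0.3, contam_shift = 0.05)
    m <- mvmr_median(h, n_boot = 2, seed = 1)$estimates$beta[1]
    v <- mv_ivw(h)$estimates$beta[1]
    abs(m - 0.2) < abs(v - 0.2)
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("multivariable Lasso keeps clean data intact and drops invalids", {
  h <- sim_mv(J = 40, effects = c(0.2, 0), seed = 61)
  ls <- mvmr_lasso(h)
  expect_setequal(ls$selected_valid, h$variant_ids)
  expect_equal(ls$estimates$beta, mv_ivw(h)$estimates$beta,
               tolerance = 1e-10)
  # the no-penalty limit keeps every instrument by construction
  ls_inf <- mvmr_lasso(h, lambda_grid = c(10, 1))
  expect_setequal(ls_inf$selected_valid, h$variant_ids)

  hit <- vapply(1:50, function(i) {
    h <- sim_mv(J = 40, effects = c(0.2, 0), seed = 12000 + i,
                invalid = 5, invalid_intercept = 0.1)
    ls <- mvmr_lasso(h)
    excluded <- setdiff(h$variant_ids, ls$selected_valid)
    sum(h$variant_ids[1:5] %in% excluded) >= 4
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("joint alignment unions, re-clumps and shares one allele frame", {
  sim <- simulate_triplet(sim_config(seed = 71))
  # identical exposure datasets give the univariable instrument set
  ids_uni <- select_instruments(sim$exposure, ld = sim$ld)$selected
  h_dup <- harmonized_set(cbind(1, 1), cbind(1, 1), 1, 1)  # placeholder
  expect_error(mv_ivw(h_dup), "collinear|instruments")

  h <- align_multi(list(sim$exposure, sim$mediator), sim$outcome,
                   ld = sim$ld)
  expect_true(all(ids_uni %in% h$variant_ids))
  expect_equal(ncol(h$exposure_betas), 2)
  expect_true(!anyNA(h$exposure_betas))

  # strand flips across datasets still produce sign-consistent effects
  flip_strand <- function(ds) {
    x <- tibble::as_tibble(ds)
    comp <- c(A = "T", T = "A", C = "G", G = "C")
    x$effect_allele <- unname(comp[x$effect_allele])
    x$other_allele <- unname(comp[x$other_allele])
    mr_sumstats(x, trait_id = trait_id(ds))
  }
  h_flip <- align_multi(list(sim$exposure, flip_strand(sim$mediator)),
                        flip_strand(sim$outcome), ld = sim$ld)
  expect_equal(h_flip$exposure_betas, h$exposure_betas)
  expect_equal(h_flip$outcome_betas, h$outcome_betas)

  # a variant missing from one exposure is dropped with a reason
  med_sub <- tibble::as_tibble(sim$mediator)
  med_sub <- med_sub[med_sub$variant_id != h$variant_ids[1], ]
  h_miss <- align_multi(list(sim$exposure,
                             mr_sumstats(med_sub, trait_id = "mediator")),
                        sim$outcome, ld = sim$ld)
  expect_true(h$variant_ids[1] %in%
                h_miss$dropped$variant_id[h_miss$dropped$reason ==
                                            "missing_in_exposure"])
})
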