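test_that("Wald ratio follows the first-order formula", {
  r <- wald_ratio(bx = 0.1, sx = 0.005, by = 0.02, sy = 0.01)
  expect_equal(r$beta, 0.2)
  expect_equal(r$se, 0.1)
  r0 <- wald_ratio(bx = 0.1, sx = 0.005, by = 0, sy = 0.01)
  expect_equal(r0$beta, 0)
  expect_equal(r0$pvalue, 1)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.01), "null exposure")
  # second-order se agrees within 5% for strong instruments (|bx/sx| > 20)
  r1 <- wald_ratio(0.1, 0.004, 0.02, 0.01)
  r2 <- wald_ratio(0.1, 0.004, 0.02, 0.01, second_order = TRUE)
  expect_equal(r2$se / r1$se, 1, tolerance = 0.05)
})

test_that("IVW equals the explicit weighted-least-squares solution", {
  h <- sim_pair(J = 5, theta = 0.1, seed = 101)
  f <- mr_ivw(h, model = "fixed")
  # independent oracle: normal equations of by ~ bx through the origin
  w <- 1 / h$outcome_ses^2
  bx <- h$exposure_betas[, 1]
  theta_wls <- solve(t(bx) %*% (w * bx), t(bx) %*% (w * h$outcome_betas))
  expect_equal(f$beta, drop(theta_wls), tolerance = 1e-10)
  # algebraic identity: weight-normalized sum of Wald ratios
  wr <- bx^2 / h$outcome_ses^2
  expect_equal(f$beta,
               sum(wr * h$outcome_betas / bx) / sum(wr),
               tolerance = 1e-10)
})

test_that("IVW degenerate and homogeneous cases behave as meta-analysis", {
  h1 <- harmonized_set(0.1, 0.005, 0.02, 0.01)
  expect_equal(mr_ivw(h1, model = "fixed")$beta,
               wald_ratio(0.1, 0.005, 0.02, 0.01)$beta)
  expect_equal(mr_ivw(h1, model = "fixed")$se,
               wald_ratio(0.1, 0.005, 0.02, 0.01)$se)
  # identical ratios: fixed and random coincide, Q = 0
  bx <- c(0.1, 0.2, 0.3)
  h <- harmonized_set(bx, rep(0.005, 3), 0.2 * bx, rep(0.01, 3))
  expect_equal(mr_ivw(h, "fixed")$beta, mr_ivw(h, "random_multiplicative")$beta)
  expect_equal(mr_ivw(h, "random_multiplicative")$q_stat, 0, tolerance = 1e-20)
  q <- cochran_q(h)
  expect_equal(q$q_stat, 0, tolerance = 1e-20)
  expect_equal(q$q_pvalue, 1)
  expect_error(mr_ivw(h1, model = "random_multiplicative"), "too few")
})

test_that("random-effects se never falls below the fixed-effects se", {
  for (s in 1:20) {
    h <- sim_pair(J = 15, theta = 0.05, seed = 300 + s,
                  pleio_sd = ifelse(s %% 2, 0, 0.01))
    expect_gte(mr_ivw(h, "random_multiplicative")$se,
               mr_ivw(h, "fixed")$se * (1 - 1e-12))
  }
})

test_that("Egger recovers an exact line and flags directional pleiotropy", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h <- harmonized_set(bx, rep(0.01, 4), 0.03 + 0.2 * bx, rep(0.01, 4))
  e <- mr_egger(h)
  expect_equal(e$beta, 0.2, tolerance = 1e-10)
  expect_equal(e$egger_intercept, 0.03, tolerance = 1e-10)
  expect_error(mr_egger(harmonized_set(bx[1:2], rep(0.01, 2), bx[1:2],
                                       rep(0.01, 2))),
               "at least 3")
})

test_that("Egger intercept test holds its size under balanced pleiotropy", {
  rej <- vapply(1:200, function(i) {
    h <- sim_pair(J = 50, theta = 0.1, seed = 1200 + i, orient = TRUE,
                  pleio_mean = 0, pleio_sd = 0.01)
    mr_egger(h)$intercept_pvalue < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.11)
})

test_that("Egger slope tolerates InSIDE directional pleiotropy that biases IVW", {
  est <- t(vapply(1:200, function(i) {
    h <- sim_pair(J = 50, theta = 0.1, seed = 2200 + i, orient = TRUE,
                  pleio_mean = 0.01, pleio_sd = 0.005)
    c(mr_egger(h)$beta, mr_ivw(h)$beta)
  }, numeric(2)))
  expect_lt(abs(mean(est[, 1]) - 0.1), 0.02)  # Egger approximately unbiased
  expect_gt(abs(mean(est[, 2]) - 0.1), 0.04)  # IVW visibly biased
})

test_that("weighted median interpolates the cumulative weight at one half", {
  h <- harmonized_set(c(1, 1, 1), rep(1e-6, 3), c(0.1, 0.2, 0.9),
                      rep(1, 3))
  wm <- mr_weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(wm$beta, 0.2)
  # permutation invariance of the estimate
  h2 <- harmonized_set(c(1, 1, 1), rep(1e-6, 3), c(0.9, 0.1, 0.2),
                       rep(1, 3))
  expect_equal(mr_weighted_median(h2, n_boot = 50, seed = 1)$beta, wm$beta)
  # invariance to doubling all weights (halve sy: w = bx^2/sy^2 quadruples)
  h3 <- harmonized_set(c(1, 1, 1), rep(1e-6, 3), c(0.1, 0.2, 0.9),
                       rep(1 / sqrt(2), 3))
  expect_equal(mr_weighted_median(h3, n_boot = 50, seed = 1)$beta, wm$beta)
})

test_that("the weighted median balances the weight on either side", {
  # independent characterization: at the interpolated estimate, the
  # normalized weight strictly below it is within half the largest single
  # weight of one half
  for (s in 1:10) {
    set.seed(7000 + s)
    J <- 25
    bx <- runif(J, 0.05, 0.3)
    sy <- runif(J, 0.005, 0.02)
    by <- rnorm(J, 0.1 * bx, sy)
    h <- harmonized_set(bx, rep(1e-8, J), by, sy)
    m <- mr_weighted_median(h, n_boot = 2, seed = 1)$beta
    w <- bx^2 / sy^2
    wn <- w / sum(w)
    below <- sum(wn[by / bx < m])
    expect_gte(below, 0.5 - max(wn) / 2 - 1e-9)
    expect_lte(below, 0.5 + max(wn) / 2 + 1e-9)
  }
})

test_that("weighted median resists up to half the weight being invalid", {
  est <- vapply(1:100, function(i) {
    set.seed(4200 + i)
    J <- 100
    se_u <- rep(1 / sqrt(2 * 0.3 * 0.7 * 1e6), J)
    g <- rep(0.3, J)
    a <- c(rep(0.15, 49), rep(0, 51))
    h <- harmonized_set(rnorm(J, g, se_u), se_u,
                        rnorm(J, 0.1 * g + a, se_u), se_u)
    mr_weighted_median(h, n_boot = 2, seed = i)$beta
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.1), 0.02)
})

test_that("maximum likelihood matches its limits and beats the IVW likelihood", {
  # no-measurement-error limit: equals fixed-effect IVW
  h <- sim_pair(J = 10, theta = 0.1, seed = 55)
  h$exposure_ses[] <- 1e-9
  expect_equal(mr_max_likelihood(h)$beta, mr_ivw(h, "fixed")$beta,
               tolerance = 1e-5)
  # single instrument equals the Wald ratio
  h1 <- harmonized_set(0.1, 0.005, 0.02, 0.01)
  expect_equal(mr_max_likelihood(h1)$beta, 0.2, tolerance = 1e-6)
  # profile likelihood at the optimum dominates a grid (incl. IVW point)
  h5 <- sim_pair(J = 5, theta = 0.1, seed = 66)
  bx <- h5$exposure_betas[, 1]; sx <- h5$exposure_ses[, 1]
  by <- h5$outcome_betas; sy <- h5$outcome_ses
  nll <- function(theta) {
    xi <- (bx / sx^2 + theta * by / sy^2) / (1 / sx^2 + theta^2 / sy^2)
    sum((bx - xi)^2 / sx^2 + (by - theta * xi)^2 / sy^2)
  }
  opt <- mr_max_likelihood(h5)$beta
  grid <- seq(opt - 0.5, opt + 0.5, length.out = 401)
  expect_lte(nll(opt), min(vapply(grid, nll, numeric(1))) + 1e-8)
  expect_lte(nll(opt), nll(mr_ivw(h5, "fixed")$beta) + 1e-10)
})

test_that("Cochran's Q follows its null distribution and grows with outliers", {
  frac_central <- mean(vapply(1:200, function(i) {
    h <- sim_pair(J = 50, theta = 0.1, seed = 3200 + i)
    q <- cochran_q(h)$q_stat
    q > qchisq(0.025, 49) && q < qchisq(0.975, 49)
  }, logical(1)))
  expect_gt(frac_central, 0.90)
  expect_lt(frac_central, 0.995)

  h <- sim_pair(J = 20, theta = 0.1, seed = 77)
  q0 <- cochran_q(h)$q_stat
  h_out <- h
  h_out$outcome_betas[1] <- h_out$outcome_betas[1] + 10 * h_out$outcome_ses[1]
  expect_gt(cochran_q(h_out)$q_stat, q0)
})

test_that("MR-PRESSO is quiet on homogeneous data and seed-reproducible", {
  h <- sim_pair(J = 15, theta = 0.1, seed = 88)
  p1 <- mr_presso(h, n_sim = 400, seed = 5)
  expect_gt(p1$global_pvalue, 0.05)
  expect_length(p1$outlier_indices, 0)
  expect_equal(p1$corrected_estimate$beta, p1$raw_estimate$beta)
  p2 <- mr_presso(h, n_sim = 400, seed = 5)
  expect_identical(p1$global_rss_observed, p2$global_rss_observed)
  expect_identical(p1$outlier_pvalues, p2$outlier_pvalues)
  expect_identical(p1$global_pvalue, p2$global_pvalue)
  expect_error(mr_presso(harmonized_set(1:3 / 10, rep(0.01, 3),
                                        1:3 / 50, rep(0.01, 3)),
                         n_sim = 100, seed = 1),
               "at least 4")
})

test_that("MR-PRESSO flags a planted outlier and corrects the estimate", {
  hits <- vapply(1:20, function(i) {
    h <- sim_pair(J = 30, theta = 0.1, seed = 5200 + i, n_outliers = 1,
                  outlier_shift = 0.15)
    pr <- mr_presso(h, n_sim = 1000, seed = i)
    1L %in% pr$outlier_indices
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("radial MR decomposes Q exactly and removes planted outliers", {
  h <- sim_pair(J = 20, theta = 0.1, seed = 99)
  r <- radial_ivw(h)
  expect_equal(sum(r$per_variant_q), r$radial_q, tolerance = 1e-12)
  expect_length(setdiff(r$outliers, character(0)), length(r$outliers))
  expect_equal(r$post_removal$beta, mr_ivw(h)$beta, tolerance = 0.05)

  closer <- vapply(1:50, function(i) {
    sim <- simulate_triplet(chain_cfg(theta = 0.1, seed = 6200 + i, J = 30))
    sel <- select_instruments(sim$exposure, ld = sim$ld)
    v <- sel$selected[ceiling(length(sel$selected) / 2)]
    j <- match(v, sim$outcome$variant_id)
    out2 <- inject_outliers(sim$outcome, v, 30 * sim$outcome$se[j])
    h <- harmonize(sim$exposure, out2, instrument_ids = sel$selected)
    r <- radial_ivw(h)
    raw <- mr_ivw(h)$beta
    (v %in% r$outliers) && abs(r$post_removal$beta - 0.1) <= abs(raw - 0.1)
  }, logical(1))
  expect_gte(mean(closer), 0.9)
})

test_that("odds-ratio conversion and the reported-triplet check agree", {
  r <- new_result <- mr_ivw(sim_pair(J = 10, theta = 0, seed = 1))
  r$beta <- 0
  r$ci_low <- -0.1; r$ci_high <- 0.1
  r <- or_from_result(r)
  expect_equal(r$or_, 1)
  expect_true(r$or_low < r$or_ && r$or_ < r$or_high)
  # reported OR/CI triplet implies its printed p-value
  expect_equal(round(p_from_or_ci(0.925, 0.879, 0.974), 3), 0.003)
})

test_that("the dual significance gate needs both p and sign agreement", {
  mk <- function(beta, p) {
    r <- mr_ivw(sim_pair(J = 10, theta = 0.1, seed = 2))
    r$beta <- beta; r$pvalue <- p
    r
  }
  others <- list(mk(-0.05, 0.2), mk(-0.08, 0.01))
  expect_true(significance_gate(mk(-0.078, 0.003), others, 0.0125))
  expect_false(significance_gate(mk(-0.078, 0.017), others, 0.0125))
  expect_false(significance_gate(mk(-0.078, 0.003),
                                 c(others, list(mk(0.01, 0.9))), 0.0125))
})
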