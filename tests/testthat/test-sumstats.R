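test_that("construction enforces row invariants and clamps zero p-values", {
  tbl <- base_tbl()
  ds <- mr_sumstats(tbl, trait_id = "t")
  expect_s3_class(ds, "mr_sumstats")
  expect_equal(nrow(ds), 3)
  expect_equal(trait_id(ds), "t")

  bad <- dplyr::bind_rows(
    tbl,
    tibble::tibble(variant_id = "rs4", effect_allele = "A",
                   other_allele = "G", eaf = 0.5, beta = 0.1, se = 0,
                   pvalue = 0.5, n = 10000),
    tibble::tibble(variant_id = "rs5", effect_allele = "I",
                   other_allele = "G", eaf = 0.5, beta = 0.1, se = 0.01,
                   pvalue = 0.5, n = 10000))
  expect_message(ds2 <- mr_sumstats(bad, trait_id = "t"), "2 malformed")
  expect_equal(ds2$variant_id, tbl$variant_id)

  zp <- tbl
  zp$pvalue[1] <- 0
  expect_warning(ds3 <- mr_sumstats(zp, trait_id = "t"), "clamped")
  expect_gt(ds3$pvalue[1], 0)
})

test_that("missing mandatory columns are hard errors naming the column", {
  tbl <- base_tbl()
  expect_error(mr_sumstats(tbl[, setdiff(names(tbl), "se")], "t"), "se")
  expect_error(mr_sumstats(tbl[, setdiff(names(tbl), "effect_allele")], "t"),
               "effect_allele")
})

test_that("write/read round-trips a dataset field for field", {
  ds <- mr_sumstats(base_tbl(), trait_id = "t")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(ds, path)
  expect_equal(length(readLines(path)), 4)  # header + 3 rows
  back <- read_sumstats(path, trait_id = "t")
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(ds),
               tolerance = 1e-12)
  expect_error(write_sumstats(ds[0, ], withr::local_tempfile()), "empty")
})

test_that("column maps translate arbitrary header dialects", {
  tbl <- base_tbl()
  names(tbl) <- c("SNP", "A1", "A2", "FRQ", "b", "SE", "P", "N")
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tbl, path)
  ds <- read_sumstats(
    path,
    column_map = c(variant_id = "SNP", effect_allele = "A1",
                   other_allele = "A2", eaf = "FRQ", beta = "b", se = "SE",
                   pvalue = "P", n = "N"),
    trait_id = "t")
  expect_equal(ds$beta, base_tbl()$beta)
  expect_error(
    read_sumstats(path, column_map = c(variant_id = "nope"),
                  trait_id = "t"),
    "nope")
})

make_pair <- function(exp_rows, out_rows) {
  list(exposure = mr_sumstats(exp_rows, trait_id = "exp"),
       outcome = mr_sumstats(out_rows, trait_id = "out"))
}

test_that("harmonization aligns swapped and strand-flipped alleles", {
  exp_rows <- tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "A", "A"),
    other_allele = c("G", "G", "G"),
    eaf = 0.3, beta = 0.1, se = 0.01, pvalue = 1e-10, n = 1e5)
  out_rows <- tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("G", "T", "C"),   # swap; complement; complement+swap
    other_allele = c("A", "C", "T"),
    eaf = c(0.7, 0.3, 0.7),
    beta = c(0.05, 0.02, 0.03), se = 0.01, pvalue = 0.5, n = 1e5)
  p <- make_pair(exp_rows, out_rows)
  h <- harmonize(p$exposure, p$outcome)
  expect_equal(n_snp(h), 3)
  expect_equal(unname(h$outcome_betas), c(-0.05, 0.02, -0.03))
  expect_equal(unname(h$outcome_eaf), c(0.3, 0.3, 0.3))
})

test_that("palindromic and incompatible variants are dropped with reasons", {
  exp_rows <- tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "A", "C"),
    other_allele = c("T", "G", "G"),
    eaf = c(0.50, 0.30, 0.20),
    beta = 0.1, se = 0.01, pvalue = 1e-10, n = 1e5)
  out_rows <- tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "A", "C"),
    other_allele = c("T", "C", "G"),
    eaf = c(0.50, 0.30, 0.20),
    beta = 0.05, se = 0.01, pvalue = 0.5, n = 1e5)
  p <- make_pair(exp_rows, out_rows)
  h <- harmonize(p$exposure, p$outcome,
                 palindrome_eaf_window = c(0.42, 0.58))
  expect_setequal(h$dropped$variant_id, c("rs1", "rs2"))
  expect_equal(
    h$dropped$reason[h$dropped$variant_id == "rs1"],
    "palindromic_intermediate_eaf")
  expect_equal(
    h$dropped$reason[h$dropped$variant_id == "rs2"],
    "incompatible_alleles")
  # rs3 is palindromic C/G with clear eaf: retained
  expect_equal(h$variant_ids, "rs3")
})

test_that("palindromic variants with clear frequencies orient by eaf side", {
  exp_rows <- tibble::tibble(
    variant_id = c("rs1", "rs2"),
    effect_allele = c("A", "A"), other_allele = c("T", "G"),
    eaf = 0.20, beta = 0.1, se = 0.01, pvalue = 1e-10, n = 1e5)
  # the outcome reports rs1 on the other strand: eaf lands on the
  # opposite side of 0.5
  out_rows <- tibble::tibble(
    variant_id = c("rs1", "rs2"),
    effect_allele = c("A", "A"), other_allele = c("T", "G"),
    eaf = c(0.80, 0.20), beta = 0.05, se = 0.01, pvalue = 0.5, n = 1e5)
  p <- make_pair(exp_rows, out_rows)
  h <- harmonize(p$exposure, p$outcome)
  expect_equal(unname(h$outcome_betas), c(-0.05, 0.05))
  # missing eaf on a palindromic variant: dropped under the default policy
  out_na <- out_rows
  out_na$eaf[1] <- NA_real_
  h2 <- harmonize(p$exposure, mr_sumstats(out_na, trait_id = "out"))
  expect_equal(h2$dropped$reason, "palindromic_missing_eaf")
  h3 <- harmonize(p$exposure, mr_sumstats(out_na, trait_id = "out"),
                  action_on_missing_eaf = "keep")
  expect_equal(unname(h3$outcome_betas), c(0.05, 0.05))
})

test_that("harmonization is idempotent and sign-consistent", {
  sim <- simulate_triplet(sim_config(seed = 11))
  h1 <- harmonize(sim$exposure, sim$outcome)
  # rebuild the outcome from the harmonized frame and harmonize again
  exp_frame <- tibble::as_tibble(sim$exposure)
  out2 <- exp_frame[match(h1$variant_ids, exp_frame$variant_id), ]
  out2$beta <- unname(h1$outcome_betas)
  out2$se <- unname(h1$outcome_ses)
  out2$eaf <- unname(h1$outcome_eaf)
  h2 <- harmonize(sim$exposure, mr_sumstats(out2, trait_id = "out"),
                  instrument_ids = h1$variant_ids)
  expect_equal(h2$outcome_betas, h1$outcome_betas)
  expect_equal(h2$outcome_ses, h1$outcome_ses)

  # flipping outcome alleles and negating beta leaves the result unchanged
  flipped <- tibble::as_tibble(sim$outcome)
  flipped <- dplyr::mutate(flipped,
                           tmp = effect_allele,
                           effect_allele = other_allele,
                           other_allele = tmp,
                           beta = -beta, eaf = 1 - eaf)
  flipped$tmp <- NULL
  h3 <- harmonize(sim$exposure, mr_sumstats(flipped, trait_id = "outcome"))
  expect_equal(h3$outcome_betas, h1$outcome_betas)
  expect_equal(h3$variant_ids, h1$variant_ids)
})

test_that("retained plus dropped account for every instrument", {
  sim <- simulate_triplet(sim_config(seed = 12))
  out_sub <- tibble::as_tibble(sim$outcome)[-c(3, 9), ]
  h <- harmonize(sim$exposure, mr_sumstats(out_sub, trait_id = "out"))
  expect_equal(n_snp(h) + nrow(h$dropped), nrow(sim$exposure))
  expect_true(all(c("rs00003", "rs00009") %in%
                    h$dropped$variant_id[h$dropped$reason ==
                                           "missing_in_outcome"]))
  expect_error(
    harmonize(sim$exposure,
              mr_sumstats(tibble::as_tibble(sim$outcome)[1, ],
                          trait_id = "out"),
              instrument_ids = sim$exposure$variant_id[5:10]),
    "no usable instruments")
})
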