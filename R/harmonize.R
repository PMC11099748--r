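#' Harmonize exposure and outcome summary statistics
#'
#' Aligns every instrument's outcome (and additional-exposure) association to
#' the effect-allele frame of the first exposure dataset. For each variant:
#' if the effect/other alleles are swapped relative to the exposure, the beta
#' sign is flipped and the effect-allele frequency replaced by its
#' complement; if alleles match only after strand complementation (A/T, C/G),
#' they are complemented first; palindromic variants (allele pair A/T or C/G)
#' with intermediate effect-allele frequency in any contributing dataset are
#' dropped, as are variants whose allele sets cannot be reconciled. Every
#' removal is recorded with its reason in `dropped`.
#'
#' Palindromic variants outside the intermediate window are oriented by
#' effect-allele frequency: when the frequency falls on opposite sides of 0.5
#' in the two datasets, a strand flip is assumed and the association is
#' reoriented.
#'
#' @param exposures An [mr_sumstats()] dataset or a list of them (the first
#'   defines the allele frame).
#' @param outcome An [mr_sumstats()] dataset.
#' @param instrument_ids Variants to harmonize; default all variants of the
#'   first exposure. All must be present in the first exposure.
#' @param palindrome_eaf_window Numeric length-2; palindromic variants with
#'   effect-allele frequency inside this closed interval (in any dataset) are
#'   dropped. Default `c(0.42, 0.58)`.
#' @param action_on_missing_eaf Policy for palindromic variants lacking a
#'   frequency: `"drop"` (conservative default) or `"keep"` (assume both
#'   datasets report the forward strand).
#' @return An object of class `mr_harmonized`: instrument-aligned effect
#'   matrices (`exposure_betas`, `exposure_ses`), outcome vectors
#'   (`outcome_betas`, `outcome_ses`), per-variant metadata, and the
#'   `dropped` table.
#' @export
harmonize <- function(exposures, outcome, instrument_ids = NULL,
                      palindrome_eaf_window = c(0.42, 0.58),
                      action_on_missing_eaf = c("drop", "keep")) {
  action_on_missing_eaf <- match.arg(action_on_missing_eaf)
  if (inherits(exposures, "mr_sumstats")) exposures <- list(exposures)
  stopifnot(length(exposures) >= 1, inherits(outcome, "mr_sumstats"))
  ref <- exposures[[1]]
  if (is.null(instrument_ids)) instrument_ids <- ref$variant_id
  if (!all(instrument_ids %in% ref$variant_id)) {
    abort("all instrument_ids must be present in the first exposure dataset")
  }

  k <- length(exposures)
  exposure_ids <- vapply(exposures, trait_id, character(1))
  others <- c(exposures[-1], list(outcome))
  other_is_outcome <- c(rep(FALSE, k - 1), TRUE)

  ref_rows <- ref[match(instrument_ids, ref$variant_id), ]
  J <- length(instrument_ids)
  exposure_betas <- matrix(NA_real_, J, k,
                           dimnames = list(instrument_ids, exposure_ids))
  exposure_ses <- exposure_betas
  exposure_betas[, 1] <- ref_rows$beta
  exposure_ses[, 1] <- ref_rows$se
  outcome_betas <- rep(NA_real_, J)
  outcome_ses <- rep(NA_real_, J)
  outcome_eaf <- rep(NA_real_, J)
  drop_reason <- rep(NA_character_, J)

  win <- sort(palindrome_eaf_window)
  is_pal <- function(a, b) (a == comp_allele(b))
  in_win <- function(f) !is.na(f) & f >= win[1] & f <= win[2]

  ref_ea <- ref_rows$effect_allele; ref_oa <- ref_rows$other_allele
  ref_eaf <- ref_rows$eaf
  for (d in seq_along(others)) {
    ds <- others[[d]]
    idx <- match(instrument_ids, ds$variant_id)
    ds_beta <- ds$beta; ds_se <- ds$se; ds_eaf <- ds$eaf
    ds_ea <- ds$effect_allele; ds_oa <- ds$other_allele
    for (j in seq_len(J)) {
      if (!is.na(drop_reason[j])) next
      ea <- ref_ea[j]; oa <- ref_oa[j]
      f_ref <- ref_eaf[j]
      pal <- is_pal(ea, oa)

      if (is.na(idx[j])) {
        drop_reason[j] <- if (other_is_outcome[d]) "missing_in_outcome"
                          else "missing_in_exposure"
        next
      }
      b <- ds_beta[idx[j]]; s <- ds_se[idx[j]]; f <- ds_eaf[idx[j]]
      ea_d <- ds_ea[idx[j]]; oa_d <- ds_oa[idx[j]]

      if (pal) {
        if (!setequal(c(ea_d, oa_d), c(ea, oa))) {
          drop_reason[j] <- "incompatible_alleles"; next
        }
        if (in_win(f_ref) || in_win(f)) {
          drop_reason[j] <- "palindromic_intermediate_eaf"; next
        }
        if (is.na(f_ref) || is.na(f)) {
          if (action_on_missing_eaf == "drop") {
            drop_reason[j] <- "palindromic_missing_eaf"; next
          }
          # keep: assume forward strand, literal allele match below
          if (ea_d != ea) { b <- -b; f <- 1 - f }
        } else {
          if (ea_d != ea) { b <- -b; f <- 1 - f }
          # frequencies on opposite sides of 0.5 imply a strand flip
          if ((f < 0.5) != (f_ref < 0.5)) { b <- -b; f <- 1 - f }
        }
      } else {
        if (ea_d == ea && oa_d == oa) {
          # aligned as-is
        } else if (ea_d == oa && oa_d == ea) {
          b <- -b; f <- 1 - f
        } else {
          cea <- comp_allele(ea_d); coa <- comp_allele(oa_d)
          if (cea == ea && coa == oa) {
            # strand flip only
          } else if (cea == oa && coa == ea) {
            b <- -b; f <- 1 - f
          } else {
            drop_reason[j] <- "incompatible_alleles"; next
          }
        }
      }

      if (other_is_outcome[d]) {
        outcome_betas[j] <- b; outcome_ses[j] <- s; outcome_eaf[j] <- f
      } else {
        exposure_betas[j, d + 1] <- b; exposure_ses[j, d + 1] <- s
      }
    }
  }

  keep <- is.na(drop_reason)
  if (!any(keep)) abort("no usable instruments after harmonization")
  dropped <- tibble::tibble(variant_id = instrument_ids[!keep],
                            reason = drop_reason[!keep])

  new_mr_harmonized(
    variant_ids = instrument_ids[keep],
    exposure_betas = exposure_betas[keep, , drop = FALSE],
    exposure_ses = exposure_ses[keep, , drop = FALSE],
    outcome_betas = outcome_betas[keep],
    outcome_ses = outcome_ses[keep],
    exposure_ids = exposure_ids,
    outcome_id = trait_id(outcome),
    outcome_type = attr(outcome, "trait_type"),
    eaf = ref_rows$eaf[keep],
    outcome_eaf = outcome_eaf[keep],
    n_exposure = setNames(
      vapply(exposures, function(e) median(e$n, na.rm = TRUE), numeric(1)),
      exposure_ids),
    n_outcome = median(outcome$n, na.rm = TRUE),
    dropped = dropped
  )
}

comp_allele <- function(a) {
  unname(c(A = "T", T = "A", C = "G", G = "C")[a])
}

new_mr_harmonized <- function(variant_ids, exposure_betas, exposure_ses,
                              outcome_betas, outcome_ses, exposure_ids,
                              outcome_id, outcome_type = "binary",
                              eaf = NULL, outcome_eaf = NULL,
                              n_exposure = NULL, n_outcome = NULL,
                              dropped = tibble::tibble(variant_id = character(),
                                                       reason = character())) {
  structure(
    list(variant_ids = variant_ids,
         exposure_betas = exposure_betas, exposure_ses = exposure_ses,
         outcome_betas = outcome_betas, outcome_ses = outcome_ses,
         exposure_ids = exposure_ids, outcome_id = outcome_id,
         outcome_type = outcome_type,
         eaf = eaf %||% rep(NA_real_, length(variant_ids)),
         outcome_eaf = outcome_eaf %||% rep(NA_real_, length(variant_ids)),
         n_exposure = n_exposure, n_outcome = n_outcome,
         dropped = dropped),
    class = "mr_harmonized"
  )
}

#' Build a harmonized set directly from effect vectors
#'
#' Convenience constructor for already-aligned effects (e.g. simulation
#' output), bypassing allele bookkeeping.
#'
#' @param exposure_betas,exposure_ses Numeric vector (single exposure) or
#'   matrix with one column per exposure.
#' @param outcome_betas,outcome_ses Numeric vectors.
#' @param variant_ids Optional variant identifiers.
#' @param exposure_ids,outcome_id Trait labels.
#' @param outcome_type `"binary"` or `"continuous"`.
#' @param eaf,n_exposure,n_outcome Optional allele frequencies / sample sizes
#'   (needed by [steiger_test()]).
#' @return An `mr_harmonized` object.
#' @export
harmonized_set <- function(exposure_betas, exposure_ses, outcome_betas,
                           outcome_ses, variant_ids = NULL,
                           exposure_ids = NULL, outcome_id = "outcome",
                           outcome_type = "binary", eaf = NULL,
                           n_exposure = NULL, n_outcome = NULL) {
  if (!is.matrix(exposure_betas)) exposure_betas <- cbind(exposure_betas)
  if (!is.matrix(exposure_ses)) exposure_ses <- cbind(exposure_ses)
  k <- ncol(exposure_betas)
  exposure_ids <- exposure_ids %||% colnames(exposure_betas) %||%
    paste0("exposure", seq_len(k))
  colnames(exposure_betas) <- colnames(exposure_ses) <- exposure_ids
  variant_ids <- variant_ids %||% paste0("rs", seq_len(nrow(exposure_betas)))
  stopifnot(nrow(exposure_betas) == length(outcome_betas),
            all(exposure_ses > 0), all(outcome_ses > 0))
  new_mr_harmonized(variant_ids, exposure_betas, exposure_ses,
                    outcome_betas, outcome_ses, exposure_ids, outcome_id,
                    outcome_type = outcome_type, eaf = eaf,
                    n_exposure = n_exposure, n_outcome = n_outcome)
}

#' @export
print.mr_harmonized <- function(x, ...) {
  cat("<mr_harmonized>", paste(x$exposure_ids, collapse = " + "), "->",
      x$outcome_id, "|", n_snp(x), "instruments,",
      nrow(x$dropped), "dropped\n")
  invisible(x)
}

#' Number of instruments in a harmonized set
#' @param h An `mr_harmonized` object.
#' @return Integer count of retained instruments.
#' @export
n_snp <- function(h) length(h$variant_ids)

# single-exposure accessors
h_bx <- function(h) {
  if (ncol(h$exposure_betas) != 1) abort("a single-exposure set is required")
  h$exposure_betas[, 1]
}
h_sx <- function(h) h$exposure_ses[, 1]
h_by <- function(h) h$outcome_betas
h_sy <- function(h) h$outcome_ses

#' Restrict a harmonized set to a subset of instruments
#'
#' @param h An `mr_harmonized` object.
#' @param keep Character vector of variant ids, or logical/integer index.
#' @return The restricted `mr_harmonized` object.
#' @export
subset_harmonized <- function(h, keep) {
  if (is.character(keep)) keep <- h$variant_ids %in% keep
  new_mr_harmonized(
    variant_ids = h$variant_ids[keep],
    exposure_betas = h$exposure_betas[keep, , drop = FALSE],
    exposure_ses = h$exposure_ses[keep, , drop = FALSE],
    outcome_betas = h$outcome_betas[keep],
    outcome_ses = h$outcome_ses[keep],
    exposure_ids = h$exposure_ids, outcome_id = h$outcome_id,
    outcome_type = h$outcome_type,
    eaf = h$eaf[keep], outcome_eaf = h$outcome_eaf[keep],
    n_exposure = h$n_exposure, n_outcome = h$n_outcome,
    dropped = h$dropped
  )
}

#' @method tidy mr_harmonized
#' @export
tidy.mr_harmonized <- function(x, ...) {
  wide <- tibble::tibble(variant_id = x$variant_ids, eaf = x$eaf)
  for (i in seq_along(x$exposure_ids)) {
    wide[[paste0("beta_", x$exposure_ids[i])]] <- x$exposure_betas[, i]
    wide[[paste0("se_", x$exposure_ids[i])]] <- x$exposure_ses[, i]
  }
  wide$beta_outcome <- x$outcome_betas
  wide$se_outcome <- x$outcome_ses
  wide
}
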