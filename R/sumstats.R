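#' Construct a GWAS summary-statistics dataset
#'
#' A summary-statistics dataset is a tibble with one row per variant and the
#' canonical columns `variant_id`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pvalue`, `n`, carrying trait metadata (`trait_id`,
#' `trait_type`, `unit`) as attributes. `beta` is the per-allele effect on the
#' trait: log-odds for binary traits, standard-deviation units for continuous
#' traits.
#'
#' Rows violating basic invariants (non-positive standard error, alleles
#' outside A/C/G/T, identical alleles, non-finite effect size) are dropped
#' with a message; p-values of exactly zero are clamped to the smallest
#' positive double with a warning.
#'
#' @param data Data frame with at least `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`. Missing `eaf`, `pvalue`, `n` columns are
#'   filled with `NA` (`pvalue` is recomputed from `beta/se` when absent).
#' @param trait_id Character scalar naming the trait.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param unit Unit of the effect estimate (e.g. `"1-SD"`, `"event"`).
#' @return A tibble of class `mr_sumstats`.
#' @examples
#' mr_sumstats(
#'   data.frame(
#'     variant_id = "rs1", effect_allele = "A", other_allele = "G",
#'     eaf = 0.3, beta = 0.02, se = 0.005, pvalue = 6e-5, n = 10000
#'   ),
#'   trait_id = "trait"
#' )
#' @export
mr_sumstats <- function(data, trait_id, trait_type = c("continuous", "binary"),
                        unit = "1-SD") {
  trait_type <- match.arg(trait_type)
  mandatory <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(mandatory, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- tibble::as_tibble(data)
  for (col in c("eaf", "pvalue", "n")) {
    if (!col %in% names(x)) x[[col]] <- NA_real_
  }
  x <- dplyr::select(x, dplyr::all_of(sumstats_cols()))
  x <- dplyr::mutate(
    x,
    variant_id = as.character(.data$variant_id),
    effect_allele = toupper(as.character(.data$effect_allele)),
    other_allele = toupper(as.character(.data$other_allele)),
    dplyr::across(c("eaf", "beta", "se", "pvalue", "n"), as.numeric)
  )

  ok <- is.finite(x$beta) & is.finite(x$se) & x$se > 0 &
    x$effect_allele %in% c("A", "C", "G", "T") &
    x$other_allele %in% c("A", "C", "G", "T") &
    x$effect_allele != x$other_allele &
    (is.na(x$eaf) | (x$eaf >= 0 & x$eaf <= 1))
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    inform(paste0("dropped ", n_bad, " malformed row(s) for trait '",
                  trait_id, "'"))
    x <- x[ok, , drop = FALSE]
  }

  no_p <- is.na(x$pvalue)
  if (any(no_p)) {
    x$pvalue[no_p] <- 2 * pnorm(-abs(x$beta[no_p] / x$se[no_p]))
  }
  zero_p <- x$pvalue <= 0
  if (any(zero_p)) {
    warn(paste0(sum(zero_p), " p-value(s) of 0 clamped to smallest positive",
                " double"))
    x$pvalue[zero_p] <- .Machine$double.xmin
  }
  if (anyDuplicated(x$variant_id)) {
    abort(paste0("duplicated variant_id in trait '", trait_id, "'"))
  }

  structure(
    x,
    trait_id = trait_id,
    trait_type = trait_type,
    unit = unit,
    class = c("mr_sumstats", class(tibble::tibble()))
  )
}

sumstats_cols <- function() {
  c("variant_id", "effect_allele", "other_allele", "eaf", "beta", "se",
    "pvalue", "n")
}

#' @export
print.mr_sumstats <- function(x, ...) {
  cat("<mr_sumstats> trait:", trait_id(x),
      paste0("(", attr(x, "trait_type"), ", ", attr(x, "unit"), "),"),
      nrow(x), "variants\n")
  NextMethod()
}

#' Trait metadata accessors
#'
#' @param x An `mr_sumstats` object.
#' @return `trait_id()` the trait identifier; `trait_type()` `"continuous"`
#'   or `"binary"`.
#' @export
trait_id <- function(x) attr(x, "trait_id")

#' @rdname trait_id
#' @export
trait_type <- function(x) attr(x, "trait_type")

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab-separated (or other delimited) table with a header row and maps
#' arbitrary source column names onto the canonical fields via `column_map`.
#' Source GWAS rarely share a header dialect, so the map is explicit:
#' `c(variant_id = "SNP", beta = "b", ...)`.
#'
#' @param path Path to a delimited text file with a header.
#' @param column_map Named character vector, `standard_field = source_column`.
#'   Fields absent from the map are assumed to already use canonical names.
#' @param trait_id,trait_type,unit Trait metadata, see [mr_sumstats()].
#' @param delim Field delimiter, default tab.
#' @return An [mr_sumstats()] tibble.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_id,
                          trait_type = c("continuous", "binary"),
                          unit = "1-SD", delim = "\t") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!is.null(column_map)) {
    src_missing <- setdiff(unname(column_map), names(raw))
    if (length(src_missing)) {
      abort(paste0("column(s) named in column_map not found in file: ",
                   paste(src_missing, collapse = ", ")))
    }
    raw <- dplyr::rename(raw, !!!setNames(column_map, names(column_map)))
  }
  mandatory <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols)) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  mr_sumstats(raw, trait_id = trait_id, trait_type = match.arg(trait_type),
              unit = unit)
}

#' Write summary statistics as canonical TSV
#'
#' Writes the canonical column order (`variant_id`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`) at full float
#' precision, so that [read_sumstats()] round-trips the dataset exactly.
#'
#' @param dataset An [mr_sumstats()] object; must be non-empty.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(dataset, path) {
  if (nrow(dataset) == 0) abort("refusing to write an empty dataset")
  out <- tibble::as_tibble(dataset)[, sumstats_cols()]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a pairwise LD table
#'
#' Three tab-separated columns: `variant_a`, `variant_b`, `r2`. Pairs are
#' unordered; absent pairs are treated as r-squared 0 and self pairs as 1.
#'
#' @param path Path to the LD TSV.
#' @return A tibble of class `mr_ld`.
#' @export
read_ld <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1:3] <- c("variant_a", "variant_b", "r2")
  mr_ld(x)
}

#' Construct a pairwise LD table
#'
#' @param pairs Data frame with columns `variant_a`, `variant_b`, `r2`
#'   (r-squared in `[0, 1]`), or `NULL` for complete linkage equilibrium.
#' @param positions Optional named numeric vector of variant positions in kb,
#'   used by windowed [clump()].
#' @return A tibble of class `mr_ld` with a `positions` attribute.
#' @export
mr_ld <- function(pairs = NULL, positions = NULL) {
  if (is.null(pairs)) {
    pairs <- tibble::tibble(variant_a = character(), variant_b = character(),
                            r2 = numeric())
  }
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("variant_a", "variant_b", "r2") %in% names(pairs)))
  if (any(pairs$r2 < 0 | pairs$r2 > 1)) abort("r2 values must lie in [0, 1]")
  structure(pairs, positions = positions,
            class = c("mr_ld", class(tibble::tibble())))
}

# fast unordered-pair lookup closure; absent pair -> 0, self pair -> 1
ld_lookup <- function(ld) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  tab <- setNames(ld$r2, key(ld$variant_a, ld$variant_b))
  function(a, b) {
    out <- unname(tab[key(a, b)])
    out[is.na(out)] <- 0
    out[a == b] <- 1
    out
  }
}
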