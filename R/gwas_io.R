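#' @importFrom stats approx coef median pchisq pnorm pt qnorm rnorm runif sd setNames var
#' @importFrom utils head
NULL

# Canonical per-variant fields. Optional fields absent from an input table are
# filled with NA rather than invented.
.variant_fields <- c(
  "snp_id", "chrom", "pos", "gene", "effect_allele", "other_allele",
  "eaf", "beta", "se", "n", "pvalue", "trait", "ancestry", "source"
)

.valid_bases <- c("A", "C", "G", "T")

#' Construct an instrument set
#'
#' An instrument set bundles the per-variant summary associations for one
#' exposure trait with trait-level metadata. Variants are stored as a tibble
#' with one row per SNP; missing optional fields are `NA`.
#'
#' @param trait Trait label (e.g. `"VPA"`).
#' @param variants Data frame of variant associations; must contain at least
#'   `snp_id`, `effect_allele`, `beta`, `se`.
#' @param exposure_type `"continuous"` or `"binary"`. For binary exposures
#'   (e.g. vigorous physical activity yes/no) downstream causal estimates are
#'   on the "per 1 unit higher log odds" scale.
#' @param source Study or consortium label.
#'
#' @return An object of class `instrument_set`: a list with elements `trait`,
#'   `exposure_type`, `source` and `variants` (tibble).
#' @export
instrument_set <- function(trait, variants, exposure_type = c("continuous", "binary"),
                           source = NA_character_) {
  exposure_type <- match.arg(exposure_type)
  variants <- validate_variants(tibble::as_tibble(variants))
  dup <- variants$snp_id[duplicated(variants$snp_id)]
  if (length(dup) > 0) {
    stop("duplicate snp_id in instrument set: ", paste(unique(dup), collapse = ", "))
  }
  structure(
    list(trait = trait, exposure_type = exposure_type, source = source,
         variants = variants),
    class = "instrument_set"
  )
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> trait=%s (%s exposure), %d variant(s), source=%s\n",
              x$trait, x$exposure_type, nrow(x$variants),
              ifelse(is.na(x$source), "?", x$source)))
  print(x$variants, ...)
  invisible(x)
}

#' @export
length.instrument_set <- function(x) nrow(x$variants)

# Validate a variant table against the per-field invariants: se > 0, eaf in
# [0,1], single-base alleles, effect != other allele, pvalue in (0,1].
validate_variants <- function(tbl) {
  for (f in .variant_fields) {
    if (!f %in% names(tbl)) {
      tbl[[f]] <- if (f %in% c("pos", "n")) NA_integer_ else if (f %in% c("eaf", "beta", "se", "pvalue")) NA_real_ else NA_character_
    }
  }
  tbl <- tbl[, .variant_fields]
  if (nrow(tbl) == 0) return(tbl)
  bad_row <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx) > 0) stop(sprintf("row %s: %s", paste(idx, collapse = ","), msg))
  }
  bad_row(is.na(tbl$snp_id) | tbl$snp_id == "", "missing snp_id")
  bad_row(!is.finite(tbl$beta), "beta must be numeric")
  bad_row(!is.finite(tbl$se), "se must be numeric")
  bad_row(tbl$se <= 0, "se must be > 0")
  bad_row(!is.na(tbl$eaf) & (tbl$eaf < 0 | tbl$eaf > 1), "eaf must lie in [0,1]")
  bad_row(!is.na(tbl$pvalue) & (tbl$pvalue <= 0 | tbl$pvalue > 1), "pvalue must lie in (0,1]")
  bad_row(!is.na(tbl$effect_allele) & !tbl$effect_allele %in% .valid_bases,
          "effect_allele must be a single base A/C/G/T (multi-allelic input rejected)")
  bad_row(!is.na(tbl$other_allele) & !tbl$other_allele %in% .valid_bases,
          "other_allele must be a single base A/C/G/T (multi-allelic input rejected)")
  bad_row(!is.na(tbl$effect_allele) & !is.na(tbl$other_allele) &
            tbl$effect_allele == tbl$other_allele,
          "effect_allele and other_allele must differ")
  tbl
}

#' Read summary associations from a delimited text table
#'
#' Reads a headered TSV or CSV of GWAS summary statistics into an
#' [instrument_set()], renaming source columns to the canonical fields via a
#' column mapping. Only `snp_id`, `effect_allele`, `beta` and `se` are
#' required; any canonical field without a mapped column is stored as missing.
#'
#' @param file Path to a tab- or comma-delimited file with a header row.
#' @param column_map Named character vector or list mapping canonical field
#'   names (`snp_id`, `chrom`, `pos`, `gene`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `n`, `pvalue`, `ancestry`) to column names in the
#'   file.
#' @param trait Trait label attached to every variant.
#' @param exposure_type,source Passed to [instrument_set()].
#' @param delim Field delimiter. Default `NULL` auto-detects tab vs comma from
#'   the header line; any other delimiter must be given explicitly.
#'
#' @return An [instrument_set()].
#' @export
read_associations <- function(file, column_map, trait,
                              exposure_type = c("continuous", "binary"),
                              source = NA_character_, delim = NULL) {
  exposure_type <- match.arg(exposure_type)
  column_map <- unlist(column_map)
  required <- c("snp_id", "effect_allele", "beta", "se")
  missing_req <- setdiff(required, names(column_map))
  if (length(missing_req) > 0) {
    stop("column_map must cover: ", paste(missing_req, collapse = ", "))
  }
  unknown <- setdiff(names(column_map), .variant_fields)
  if (length(unknown) > 0) {
    stop("unknown canonical field(s) in column_map: ", paste(unknown, collapse = ", "))
  }
  if (is.null(delim)) {
    header <- readLines(file, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else
      stop("cannot auto-detect delimiter (only tab and comma are detected); pass `delim`")
  }
  raw <- readr::read_delim(file, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  absent <- setdiff(unname(column_map), names(raw))
  if (length(absent) > 0) {
    stop("mapped column(s) not found in file: ", paste(absent, collapse = ", "))
  }
  tbl <- tibble::tibble(.rows = nrow(raw))
  for (f in names(column_map)) tbl[[f]] <- raw[[column_map[[f]]]]

  num_field <- function(x, f) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad) > 0) {
      stop(sprintf("row %s: non-numeric value in %s ('%s')",
                   paste(bad, collapse = ","), f, x[bad[1]]))
    }
    v
  }
  for (f in intersect(c("eaf", "beta", "se", "pvalue"), names(tbl))) {
    tbl[[f]] <- num_field(tbl[[f]], f)
  }
  for (f in intersect(c("pos", "n"), names(tbl))) {
    tbl[[f]] <- as.integer(round(num_field(gsub(",", "", tbl[[f]]), f)))
  }
  for (f in intersect(c("effect_allele", "other_allele"), names(tbl))) {
    tbl[[f]] <- toupper(trimws(tbl[[f]]))
  }
  tbl$trait <- trait
  if (!"source" %in% names(column_map)) tbl$source <- source
  instrument_set(trait, tbl, exposure_type = exposure_type, source = source)
}

#' Write an instrument set back to TSV at full precision
#'
#' Inverse of [read_associations()] for round-tripping: numeric fields are
#' written with enough digits that reading the file back reproduces them
#' exactly.
#'
#' @param set An [instrument_set()].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_associations <- function(set, file) {
  stopifnot(inherits(set, "instrument_set"))
  tbl <- set$variants
  for (f in c("eaf", "beta", "se", "pvalue")) {
    tbl[[f]] <- formatC(tbl[[f]], digits = 17, format = "g")
    tbl[[f]][tbl[[f]] %in% c("NA", " NA")] <- NA
  }
  readr::write_tsv(tbl, file, progress = FALSE)
  invisible(file)
}

.fixture_traits <- c("MVPA", "VPA", "sedentary", "sleep_duration")

#' Load a packaged lifestyle instrument set
#'
#' Returns the genome-wide-significant instruments packaged with lifestyleMR
#' for one of four lifestyle exposures: moderate-to-vigorous physical activity
#' (MVPA, 9 SNPs, continuous), vigorous physical activity (VPA, 5 SNPs,
#' binary), sedentary behaviours (4 SNPs, continuous) and sleep duration
#' (7 SNPs, continuous, betas in minutes/night per allele as published).
#' The source GWAS tables report no non-effect allele, so `other_allele` is
#' missing and allele resolution is deferred to harmonization, which falls
#' back on effect-allele frequencies.
#'
#' @param trait One of `"MVPA"`, `"VPA"`, `"sedentary"`, `"sleep_duration"`.
#' @return An [instrument_set()].
#' @export
load_instrument_fixture <- function(trait) {
  if (!is.character(trait) || length(trait) != 1 || !trait %in% .fixture_traits) {
    stop("unknown trait '", paste(trait, collapse = ","), "'; valid traits: ",
         paste(.fixture_traits, collapse = ", "))
  }
  path <- system.file("extdata", "lifestyle_instruments.tsv", package = "lifestyleMR",
                      mustWork = TRUE)
  all <- readr::read_tsv(path, col_types = readr::cols(
    trait = "c", snp_id = "c", ancestry = "c", chrom = "c", pos = "i",
    gene = "c", effect_allele = "c", eaf = "d", beta = "d", se = "d",
    n = "i", pvalue = "d", source = "c"
  ), progress = FALSE)
  rows <- all[all$trait == trait, ]
  instrument_set(
    trait, rows,
    exposure_type = if (trait == "VPA") "binary" else "continuous",
    source = rows$source[1]
  )
}

#' Filter instruments by significance and keep the lead SNP per locus
#'
#' Drops variants whose p-value is at or above `p_threshold`, then, among the
#' retained variants, groups same-chromosome variants lying closer than
#' `locus_window_bp` (single-linkage along the chromosome) and keeps only the
#' lowest-p variant per group as the locus lead. Ties are broken by smaller
#' standard error, then lexicographic rsID. This is a positional stand-in for
#' LD-based clumping: no linkage-disequilibrium reference panel is consulted.
#'
#' @param set An [instrument_set()] whose variants carry `pvalue`, `chrom`, `pos`.
#' @param p_threshold Significance threshold; default genome-wide `5e-8`.
#' @param locus_window_bp Positional window defining a locus; default 500 kb.
#' @return The filtered [instrument_set()] (possibly with zero variants).
#' @export
apply_selection_filters <- function(set, p_threshold = 5e-8, locus_window_bp = 5e5) {
  stopifnot(inherits(set, "instrument_set"))
  v <- set$variants
  v <- v[!is.na(v$pvalue) & v$pvalue < p_threshold, ]
  if (nrow(v) > 1) {
    keep <- logical(0)
    kept_ids <- character(0)
    for (ch in unique(v$chrom)) {
      sub <- v[v$chrom == ch, ]
      sub <- sub[order(sub$pos), ]
      gap <- c(Inf, diff(sub$pos))
      cluster <- cumsum(gap >= locus_window_bp)
      for (cl in unique(cluster)) {
        grp <- sub[cluster == cl, ]
        grp <- grp[order(grp$pvalue, grp$se, grp$snp_id), ]
        kept_ids <- c(kept_ids, grp$snp_id[1])
      }
    }
    v <- v[v$snp_id %in% kept_ids, ]
  }
  instrument_set(set$trait, v, exposure_type = set$exposure_type, source = set$source)
}

#' Outcome dataset metadata
#'
#' @param outcome Outcome label.
#' @param outcome_type `"binary"` (reported as odds ratios) or `"continuous"`
#'   (reported as effect sizes).
#' @param n_cases,n_controls Case/control counts; required for binary outcomes.
#' @param n Total sample size; required for continuous outcomes.
#' @param source Consortium label.
#' @param year Publication year.
#' @return An object of class `outcome_meta`.
#' @export
outcome_meta <- function(outcome, outcome_type = c("binary", "continuous"),
                         n_cases = NA_integer_, n_controls = NA_integer_,
                         n = NA_integer_, source = NA_character_, year = NA_integer_) {
  outcome_type <- match.arg(outcome_type)
  if (outcome_type == "binary" && (is.na(n_cases) || is.na(n_controls))) {
    stop("binary outcomes must carry n_cases and n_controls")
  }
  if (outcome_type == "continuous" && is.na(n)) {
    stop("continuous outcomes must carry total n")
  }
  structure(
    list(outcome = outcome, outcome_type = outcome_type, n_cases = n_cases,
         n_controls = n_controls, n = n, source = source, year = year),
    class = "outcome_meta"
  )
}

#' Write MR results as a tab-separated table
#'
#' Emits one row per (exposure-outcome pair, method): exposure, outcome,
#' method, number of SNPs, the estimate on its reporting scale (odds ratio for
#' binary outcomes, effect size for continuous ones) with its confidence
#' interval, the p-value, and the significance label. Formatting is
#' deterministic so repeated runs are byte-identical.
#'
#' @param results List of `pair_result` objects from [run_pair()]/[run_grid()].
#' @param file Output path or connection.
#' @param decimals Decimal places for estimates and CI bounds (default 2,
#'   matching the usual "OR 0.65 (0.47-0.90)" display).
#' @return Invisibly, the formatted tibble that was written.
#' @export
write_results_table <- function(results, file, decimals = 2) {
  if (length(results) == 0) stop("no results")
  if (inherits(results, "pair_result")) results <- list(results)
  rows <- list()
  for (pr in results) {
    if (!inherits(pr, "pair_result")) stop("results must be pair_result objects")
    for (m in names(pr$estimates)) {
      est <- pr$estimates[[m]]
      binary <- identical(pr$outcome_type, "binary")
      if (binary) {
        tr <- to_or(est)
        point <- tr$or; lo <- tr$ci_low; hi <- tr$ci_high
      } else {
        point <- est$theta; lo <- est$ci_low; hi <- est$ci_high
      }
      fmt <- function(x) sprintf(paste0("%.", decimals, "f"), x)
      rows[[length(rows) + 1]] <- tibble::tibble(
        exposure = pr$exposure, outcome = pr$outcome, method = m,
        n_snps = est$n_snps,
        estimate = fmt(point), se = fmt(est$se),
        ci_low = fmt(lo), ci_high = fmt(hi),
        pvalue = formatC(est$pvalue, digits = 3, format = "g"),
        scale = if (binary) "OR" else "ES",
        significance = pr$significance
      )
    }
  }
  out <- do.call(rbind, rows)
  readr::write_tsv(out, file, progress = FALSE)
  invisible(out)
}
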