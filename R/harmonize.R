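# Allele harmonization: express exposure and outcome effects for each SNP on
# a common effect allele before any causal estimation.

complement_allele <- function(a) chartr("ACGT", "TGCA", a)

is_palindromic_pair <- function(ea, oa) {
  !is.na(ea) && !is.na(oa) && identical(complement_allele(ea), oa)
}

.harm_actions <- c("as_is", "flipped_sign", "strand_complemented",
                   "palindromic_kept", "dropped")

#' Align one SNP's exposure and outcome records on a common effect allele
#'
#' Applies the standard two-sample MR allele-matching rules, in order:
#' palindromic SNPs (A/T or G/C pairs, strand unresolvable from alleles) are
#' dropped when either effect-allele frequency falls inside
#' `palindrome_eaf_window`, and otherwise oriented by frequency concordance;
#' non-palindromic records are kept as-is when effect alleles agree, have the
#' outcome beta negated when the outcome's effect allele is the exposure's
#' other allele (or, with the other allele missing, when the outcome EAF
#' matches 1 minus the exposure EAF within `eaf_tol`), and are
#' strand-complemented then re-matched when the alleles only agree after
#' A<->T / C<->G complementation. Irreconcilable alleles yield
#' `action = "dropped"` with a logged reason, never an error.
#'
#' @param exp_v,out_v Single-variant records (one-row data frames or named
#'   lists) for the same rsID, carrying `snp_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`.
#' @param palindrome_eaf_window Length-2 numeric `[lo, hi]`: palindromic SNPs
#'   with either EAF inside this window are dropped as ambiguous. Default
#'   `c(0.42, 0.58)`; `c(0.5, 0.5)` disables dropping.
#' @param eaf_tol Tolerance for frequency-based flip detection when the
#'   exposure's other allele is unrecorded (default 0.08).
#'
#' @return A one-row tibble: `snp_id`, `effect_allele`, `beta_exp`, `se_exp`,
#'   `eaf_exp`, `beta_out`, `se_out`, `eaf_out`, `action`, `reason`.
#' @export
align_alleles <- function(exp_v, out_v, palindrome_eaf_window = c(0.42, 0.58),
                          eaf_tol = 0.08) {
  tibble::as_tibble(align_one(as.list(exp_v), as.list(out_v),
                              palindrome_eaf_window, eaf_tol))
}

# Scalar worker behind align_alleles/harmonize_set; returns a plain list to
# keep per-SNP overhead low on simulation-sized inputs.
align_one <- function(exp_v, out_v, palindrome_eaf_window, eaf_tol) {
  if (!identical(exp_v$snp_id, out_v$snp_id)) {
    stop("align_alleles: snp_id mismatch (", exp_v$snp_id, " vs ", out_v$snp_id, ")")
  }
  ea_x <- exp_v$effect_allele; oa_x <- exp_v$other_allele
  ea_y <- out_v$effect_allele; oa_y <- out_v$other_allele
  f_x <- exp_v$eaf; f_y <- out_v$eaf
  if (is.null(oa_x)) oa_x <- NA_character_
  if (is.null(oa_y)) oa_y <- NA_character_
  if (is.null(f_x)) f_x <- NA_real_
  if (is.null(f_y)) f_y <- NA_real_

  result <- function(action, flip = FALSE, reason = NA_character_) {
    beta_out <- out_v$beta
    eaf_out <- f_y
    if (flip) {
      beta_out <- -beta_out
      if (!is.na(eaf_out)) eaf_out <- 1 - eaf_out
    }
    list(
      snp_id = exp_v$snp_id,
      effect_allele = if (is.na(ea_x)) NA_character_ else ea_x,
      beta_exp = exp_v$beta, se_exp = exp_v$se, eaf_exp = f_x,
      beta_out = beta_out, se_out = out_v$se, eaf_out = eaf_out,
      action = action, reason = reason
    )
  }

  in_window <- function(f) {
    !is.na(f) && f >= palindrome_eaf_window[1] && f <= palindrome_eaf_window[2]
  }

  # Palindromic pairs are checked first: their alleles always "match" under
  # the plain rules, so the plain rules would silently mis-orient them.
  if (is_palindromic_pair(ea_x, oa_x) || is_palindromic_pair(ea_y, oa_y)) {
    if (in_window(f_x) || in_window(f_y)) {
      return(result("dropped",
                    reason = "palindromic SNP with EAF inside the ambiguity window"))
    }
    if (is.na(f_x) || is.na(f_y)) {
      return(result("dropped",
                    reason = "palindromic SNP without both EAFs; cannot orient"))
    }
    flip <- abs(f_y - f_x) > abs(f_y - (1 - f_x))
    return(result("palindromic_kept", flip = flip,
                  reason = if (flip) "oriented by EAF (flipped)" else "oriented by EAF"))
  }

  match_plain <- function(ea_y, oa_y, f_y) {
    # "same" / "flip" / "none" under the given outcome allele labels
    if (!is.na(ea_y) && !is.na(ea_x) && ea_y == ea_x &&
        (is.na(oa_x) || is.na(oa_y) || oa_y == oa_x)) {
      return("same")
    }
    if (!is.na(oa_x) && !is.na(ea_y) && ea_y == oa_x &&
        (is.na(oa_y) || oa_y == ea_x)) {
      return("flip")
    }
    if (is.na(oa_x) && !is.na(oa_y) && !is.na(ea_x) && oa_y == ea_x &&
        (is.na(ea_y) || ea_y != ea_x)) {
      return("flip")
    }
    if (is.na(oa_x) && is.na(oa_y) && !is.na(ea_y) && !is.na(ea_x) && ea_y != ea_x &&
        !is.na(f_x) && !is.na(f_y) && abs(f_y - (1 - f_x)) <= eaf_tol) {
      return("flip")
    }
    "none"
  }

  if (is.na(ea_x) || is.na(ea_y)) {
    return(result("dropped", reason = "missing effect allele"))
  }

  m <- match_plain(ea_y, oa_y, f_y)
  if (m == "same") {
    reason <- if (is.na(oa_x) && is.na(oa_y) && is.na(f_y)) {
      "kept as_is; orientation unverifiable (no other allele or outcome EAF)"
    } else NA_character_
    return(result("as_is", reason = reason))
  }
  if (m == "flip") return(result("flipped_sign", flip = TRUE))

  # strand complementation, then re-apply the same rules
  m2 <- match_plain(complement_allele(ea_y),
                    if (is.na(oa_y)) NA_character_ else complement_allele(oa_y), f_y)
  if (m2 == "same") return(result("strand_complemented"))
  if (m2 == "flip") {
    return(result("strand_complemented", flip = TRUE,
                  reason = "complemented and sign-flipped"))
  }
  result("dropped", reason = sprintf(
    "irreconcilable alleles (exposure %s/%s vs outcome %s/%s)",
    ea_x, ifelse(is.na(oa_x), "?", oa_x), ea_y, ifelse(is.na(oa_y), "?", oa_y)))
}

#' Harmonize an exposure instrument set against an outcome association table
#'
#' Intersects on rsID and applies [align_alleles()] per SNP. Instruments
#' dropped during harmonization never reach the estimators; instruments absent
#' from the outcome table are recorded in the log.
#'
#' @param exp_set An [instrument_set()].
#' @param out_assocs Outcome associations: an [instrument_set()] or a data
#'   frame of variant records.
#' @inheritParams align_alleles
#'
#' @return A list of class `harmonized_set`:
#'   * `instruments`: tibble of retained harmonized instruments (one row per
#'     SNP; columns as in [align_alleles()], `action != "dropped"`),
#'   * `log`: tibble (`snp_id`, `action`, `reason`) covering every exposure SNP,
#'   * `counts`: named integer vector
#'     (`matched`, `flipped`, `complemented`, `palindromic_kept`, `dropped`,
#'     `absent_from_outcome`).
#' @export
harmonize_set <- function(exp_set, out_assocs, palindrome_eaf_window = c(0.42, 0.58),
                          eaf_tol = 0.08) {
  exp_tbl <- if (inherits(exp_set, "instrument_set")) exp_set$variants else
    tibble::as_tibble(exp_set)
  out_tbl <- if (inherits(out_assocs, "instrument_set")) out_assocs$variants else
    tibble::as_tibble(out_assocs)
  shared <- intersect(exp_tbl$snp_id, out_tbl$snp_id)
  if (length(shared) == 0) stop("no overlapping instruments")

  ei <- match(shared, exp_tbl$snp_id)
  oi <- match(shared, out_tbl$snp_id)
  exp_rows <- lapply(exp_tbl, function(col) col[ei])
  out_rows <- lapply(out_tbl, function(col) col[oi])
  rows <- vector("list", length(shared))
  for (i in seq_along(shared)) {
    rows[[i]] <- align_one(
      lapply(exp_rows, `[`, i), lapply(out_rows, `[`, i),
      palindrome_eaf_window, eaf_tol
    )
  }
  harm <- tibble::as_tibble(do.call(
    Map, c(list(f = c), rows)
  ))
  absent <- setdiff(exp_tbl$snp_id, shared)
  log <- tibble::tibble(
    snp_id = c(harm$snp_id, absent),
    action = c(harm$action, rep("absent_from_outcome", length(absent))),
    reason = c(harm$reason, rep("instrument not present in outcome table", length(absent)))
  )
  n_unverified <- sum(!is.na(harm$reason) & grepl("unverifiable", harm$reason))
  if (n_unverified > 0) {
    warning(n_unverified, " instrument(s) kept as_is with unverifiable orientation ",
            "(no other allele or outcome EAF)")
  }
  counts <- c(
    matched = sum(harm$action == "as_is"),
    flipped = sum(harm$action == "flipped_sign"),
    complemented = sum(harm$action == "strand_complemented"),
    palindromic_kept = sum(harm$action == "palindromic_kept"),
    dropped = sum(harm$action == "dropped"),
    absent_from_outcome = length(absent)
  )
  structure(
    list(instruments = harm[harm$action != "dropped", ], log = log, counts = counts),
    class = "harmonized_set"
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("<harmonized_set>", nrow(x$instruments), "instrument(s) retained\n")
  print(x$counts)
  invisible(x)
}
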