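# Orchestration of the exposure x outcome analysis grid with
# multiple-testing-aware significance labelling.

#' Bonferroni-corrected significance threshold for an analysis grid
#'
#' @param alpha Family-wise error level (default 0.05).
#' @param n_exposures,n_outcomes Grid dimensions; the number of tests is their
#'   product.
#' @return `alpha / (n_exposures * n_outcomes)`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_exposures, n_outcomes) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) stop("alpha must be in (0,1]")
  if (!is.numeric(n_exposures) || n_exposures <= 0 ||
      !is.numeric(n_outcomes) || n_outcomes <= 0) {
    stop("n_exposures and n_outcomes must be positive")
  }
  alpha / (n_exposures * n_outcomes)
}

#' Analysis configuration
#'
#' Bundles every tunable of the pipeline: which estimators to run, the
#' family-wise alpha and number of tests (from which the Bonferroni threshold
#' `alpha / n_tests` follows), the palindrome ambiguity window and EAF flip
#' tolerance for harmonization, the bootstrap size and seed for the median
#' estimators, and the display precision for result tables.
#'
#' @param methods Ordered estimator labels; the first is the primary method
#'   used for significance labelling.
#' @param alpha Family-wise level (default 0.05).
#' @param n_tests Number of tests for Bonferroni correction; `NULL` (default)
#'   lets [run_grid()] set it to exposures x outcomes.
#' @param palindrome_eaf_window,eaf_tol See [align_alleles()].
#' @param n_boot,seed Bootstrap replicates and seed for the median methods.
#' @param decimals Display decimals for [write_results_table()].
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(methods = c("ivw_fe", "simple_median", "weighted_median", "egger"),
                            alpha = 0.05, n_tests = NULL,
                            palindrome_eaf_window = c(0.42, 0.58), eaf_tol = 0.08,
                            n_boot = 5000, seed = 1L, decimals = 2) {
  known <- c("ivw_fe", "simple_median", "weighted_median", "egger")
  bad <- setdiff(methods, known)
  if (length(bad) > 0) stop("unknown method(s): ", paste(bad, collapse = ", "))
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0,1]")
  if (!is.null(n_tests) && n_tests < 1) stop("n_tests must be >= 1")
  structure(
    list(methods = methods, alpha = alpha, n_tests = n_tests,
         palindrome_eaf_window = palindrome_eaf_window, eaf_tol = eaf_tol,
         n_boot = n_boot, seed = seed, decimals = decimals),
    class = "analysis_config"
  )
}

#' Run all configured estimators for one exposure-outcome pair
#'
#' Harmonizes the instruments against the outcome table, runs every
#' configured estimator that can run at the available number of instruments J
#' (the median methods and MR-Egger need J >= 3 and are skipped with a logged
#' reason below that), computes heterogeneity of the per-SNP ratios around the
#' IVW estimate (J >= 2), and labels the pair from the primary (first
#' configured) method's p-value: `"significant"` below `alpha / n_tests`,
#' `"suggestive"` for p < 0.05 but above the Bonferroni threshold, `"null"`
#' otherwise.
#'
#' @param exp_set An [instrument_set()].
#' @param out_assocs Outcome association table ([instrument_set()] or data
#'   frame of variant records).
#' @param meta An [outcome_meta()] or `NULL`; supplies the outcome label and
#'   binary/continuous type (default binary, labelled from the table's trait).
#' @param cfg An [analysis_config()].
#' @return An object of class `pair_result`: list with `exposure`, `outcome`,
#'   `outcome_type`, `estimates` (named list of [mr_estimate()]), `egger`
#'   ([mr_egger()] result or `NULL`), `het` ([heterogeneity()] result or
#'   `NULL`), `n_snps_used`, `harmonization`, `skipped` (named reasons),
#'   `significance`.
#' @export
run_pair <- function(exp_set, out_assocs, meta = NULL, cfg = analysis_config()) {
  stopifnot(inherits(cfg, "analysis_config"))
  outcome_type <- if (!is.null(meta)) meta$outcome_type else "binary"
  outcome_label <- if (!is.null(meta)) meta$outcome else {
    if (inherits(out_assocs, "instrument_set")) out_assocs$trait else
      if ("trait" %in% names(out_assocs)) out_assocs$trait[1] else "outcome"
  }
  harm <- harmonize_set(exp_set, out_assocs,
                        palindrome_eaf_window = cfg$palindrome_eaf_window,
                        eaf_tol = cfg$eaf_tol)
  hs <- harm$instruments
  J <- nrow(hs)
  estimates <- list()
  skipped <- character(0)
  egger <- NULL

  run_one <- function(m) {
    if (m == "ivw_fe") {
      if (J < 1) return("no instruments after harmonization")
      estimates[["ivw_fe"]] <<- ivw_fixed(hs, outcome_type = outcome_type)
    } else if (m %in% c("simple_median", "weighted_median")) {
      if (J < 3) return(sprintf("insufficient instruments for %s (J=%d < 3)", m, J))
      fn <- if (m == "simple_median") simple_median else weighted_median
      estimates[[m]] <<- fn(hs, n_boot = cfg$n_boot, seed = cfg$seed,
                            outcome_type = outcome_type)
    } else if (m == "egger") {
      if (J < 3) return(sprintf("insufficient instruments for MR-Egger (J=%d < 3)", J))
      egger <<- mr_egger(hs, outcome_type = outcome_type)
      estimates[["egger_slope"]] <<- egger$slope
    }
    NA_character_
  }
  for (m in cfg$methods) {
    reason <- tryCatch(run_one(m), error = function(e) conditionMessage(e))
    if (!is.na(reason)) skipped[m] <- reason
  }

  het <- NULL
  if (J >= 2 && !is.null(estimates[["ivw_fe"]])) {
    het <- heterogeneity(hs, estimates[["ivw_fe"]]$theta)
  }

  primary <- cfg$methods[1]
  primary_key <- if (primary == "egger") "egger_slope" else primary
  n_tests <- if (is.null(cfg$n_tests)) 1L else cfg$n_tests
  alpha_bonf <- cfg$alpha / n_tests
  significance <- "null"
  if (!is.null(estimates[[primary_key]])) {
    p <- estimates[[primary_key]]$pvalue
    significance <- if (p < alpha_bonf) "significant"
      else if (p < 0.05) "suggestive" else "null"
  }

  structure(
    list(exposure = exp_set$trait, outcome = outcome_label,
         outcome_type = outcome_type, estimates = estimates, egger = egger,
         het = het, n_snps_used = J, harmonization = harm,
         skipped = skipped, significance = significance),
    class = "pair_result"
  )
}

#' @export
print.pair_result <- function(x, ...) {
  cat(sprintf("<pair_result> %s -> %s (%s outcome), J=%d, %s\n",
              x$exposure, x$outcome, x$outcome_type, x$n_snps_used, x$significance))
  for (est in x$estimates) print(est)
  if (!is.null(x$het)) print(x$het)
  if (length(x$skipped) > 0) {
    cat("  skipped:", paste(names(x$skipped), x$skipped, sep = ": ", collapse = "; "), "\n")
  }
  invisible(x)
}

#' Run the full exposure-by-outcome grid
#'
#' Runs [run_pair()] over the Cartesian product of exposures and outcomes in
#' exposure-major order. The number of Bonferroni tests defaults to the size
#' of the grid; a user-supplied `cfg$n_tests` overrides it with a warning.
#' Per-pair failures (e.g. no overlapping instruments) are captured as
#' entries of class `pair_failure` carrying the reason; the grid aborts only
#' if every pair fails.
#'
#' @param exposures List of [instrument_set()] objects.
#' @param outcomes Named list; each element is a list with `assocs` (outcome
#'   association table) and optionally `meta` (an [outcome_meta()]).
#' @param cfg An [analysis_config()].
#' @return List of `pair_result` (or `pair_failure`) objects, exposure-major.
#' @export
run_grid <- function(exposures, outcomes, cfg = analysis_config()) {
  if (length(exposures) == 0 || length(outcomes) == 0) {
    stop("exposures and outcomes must be non-empty")
  }
  n_grid <- length(exposures) * length(outcomes)
  if (is.null(cfg$n_tests)) {
    cfg$n_tests <- n_grid
  } else if (cfg$n_tests != n_grid) {
    warning(sprintf("n_tests=%d overrides the grid size %d", cfg$n_tests, n_grid))
  }
  results <- list()
  for (exp_set in exposures) {
    for (oname in names(outcomes)) {
      o <- outcomes[[oname]]
      meta <- o$meta
      if (!is.null(meta) && is.na(meta$outcome)) meta$outcome <- oname
      res <- tryCatch(
        run_pair(exp_set, o$assocs, meta = meta, cfg = cfg),
        error = function(e) structure(
          list(exposure = exp_set$trait, outcome = oname,
               reason = conditionMessage(e)),
          class = "pair_failure")
      )
      results[[paste(exp_set$trait, oname, sep = ".")]] <- res
    }
  }
  if (all(vapply(results, inherits, logical(1), "pair_failure"))) {
    stop("every exposure-outcome pair failed; first reason: ", results[[1]]$reason)
  }
  results
}
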