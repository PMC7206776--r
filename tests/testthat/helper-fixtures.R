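# Small builders shared across test files.

# A harmonized-instrument table built directly (bypassing harmonization) for
# estimator unit tests.
make_harm <- function(beta_exp, beta_out, se_out, se_exp = rep(0.01, length(beta_exp)),
                      snp_id = sprintf("rs%d", seq_along(beta_exp))) {
  tibble::tibble(
    snp_id = snp_id, effect_allele = "A",
    beta_exp = beta_exp, se_exp = se_exp,
    beta_out = beta_out, se_out = se_out,
    action = "as_is"
  )
}

# One variant record as a named list (align_alleles input).
make_variant <- function(snp_id = "rs1", effect_allele = "A", other_allele = NA,
                         eaf = NA, beta = 0.1, se = 0.01) {
  list(snp_id = snp_id, effect_allele = effect_allele,
       other_allele = if (is.na(other_allele)) NA_character_ else other_allele,
       eaf = as.numeric(eaf), beta = beta, se = se)
}

# Write a small association TSV and return its path.
write_assoc_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# Default column map matching the packaged fixture's header.
fixture_map <- c(snp_id = "snp_id", chrom = "chrom", pos = "pos", gene = "gene",
                 effect_allele = "effect_allele", eaf = "eaf", beta = "beta",
                 se = "se", n = "n", pvalue = "pvalue", ancestry = "ancestry")
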