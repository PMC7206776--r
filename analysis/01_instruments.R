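#!/usr/bin/env Rscript
# Step 1 — instrument bookkeeping.
#
# Loads the packaged instrument sets for the four lifestyle exposures,
# re-applies the published inclusion rule (genome-wide significance, lowest-p
# variant per locus within 500 kb), and writes the instrument table plus a
# per-trait summary. Of note: the seven sleep-duration SNPs sit in two tight
# clusters (four within ~40 kb of PAX8 on chr2, three within ~1 kb of IER3 on
# chr6), so positional lead-SNP pruning collapses them to two independent
# loci; the published set keeps all seven, which we preserve as the fixture
# and report both ways here. Two further published instruments (rs149943 for
# MVPA, p = 5.6e-8; rs2764261 for VPA, p = 5.3e-8) sit just above the
# genome-wide threshold their selection nominally required, so strict
# re-application of the rule also removes those.

suppressPackageStartupMessages(library(lifestyleMR))
dir.create("results", showWarnings = FALSE)

traits <- c("MVPA", "VPA", "sedentary", "sleep_duration")
all_rows <- list()
summary_rows <- list()
for (trait in traits) {
  set <- load_instrument_fixture(trait)
  pruned <- apply_selection_filters(set, p_threshold = 5e-8, locus_window_bp = 5e5)
  all_rows[[trait]] <- set$variants
  summary_rows[[trait]] <- tibble::tibble(
    trait = trait, exposure_type = set$exposure_type,
    n_published = nrow(set$variants), n_after_locus_pruning = nrow(pruned$variants),
    min_p = min(set$variants$pvalue), max_p = max(set$variants$pvalue)
  )
  cat(sprintf("%-15s %d instrument(s) published, %d independent locus lead(s)\n",
              trait, nrow(set$variants), nrow(pruned$variants)))
}
readr::write_tsv(do.call(rbind, all_rows), "results/instruments.tsv")
readr::write_tsv(do.call(rbind, summary_rows), "results/instruments_summary.tsv")
cat("wrote results/instruments.tsv and results/instruments_summary.tsv\n")
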