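#!/usr/bin/env Rscript
# Stage 5: low-frequency branch — grouped Student's t-tests per ceM.
#
# Samples are split by whether any LF mutation perturbs a given ceM
# through the ceRNA mechanism; ceM expression differences are tested
# with the pooled-variance t-test on log2(FPKM+1), fold change is
# reported on raw FPKM, and the predicted tendency (sign of the summed
# mutation scores) annotates each ceM.

suppressMessages(library(smilm))

bundle <- read_bundle("results/bundle")
lf_units <- utils::read.delim("results/03_units_lf.tsv",
                              stringsAsFactors = FALSE)

res <- lf_test_cems(lf_units, bundle$expr_mrna, bundle$sample_cancers)
write_tsv(res, "results/05_lf_cem_tests.tsv")
write_tsv(attr(res, "skipped"), "results/05_lf_skipped.tsv")

cat("ceM groups tested:", nrow(res), "; skipped:",
    nrow(attr(res, "skipped")), "\n")
sig <- res[res$significant, ]
cat("Significant ceMs (p < 0.05):", nrow(sig), "\n")
if (nrow(sig) > 0)
  print(sig[, c("ceM", "cancer_type", "tendency", "n_mut", "n_ctl",
                "t_stat", "p_value", "fold_change")], row.names = FALSE)
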