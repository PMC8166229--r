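#!/usr/bin/env Rscript
# Stage 6: gene-set enrichment of the perturbed ceMs.
#
# Over-representation (hypergeometric, BH-adjusted, universe = all
# genes in the cancer's expression matrix) of the significant ceMs,
# plus rank-based enrichment weighted by log2 fold change over all
# tested ceMs.

suppressMessages(library(smilm))

bundle <- read_bundle("results/bundle")
lf <- utils::read.delim("results/05_lf_cem_tests.tsv",
                        stringsAsFactors = FALSE)
hf <- utils::read.delim("results/04_hf_regression.tsv",
                        stringsAsFactors = FALSE)

universe <- rownames(bundle$expr_mrna)
query <- union(lf$ceM[lf$significant],
               hf$ceM[hf$passes_step1 & hf$passes_step2 %in% TRUE])
cat("Query:", length(query), "perturbed ceMs against",
    length(bundle$gene_sets), "gene sets (universe", length(universe),
    "genes)\n")

ora_res <- ora(query, bundle$gene_sets, universe)
write_tsv(ora_res, "results/06_ora.tsv")
print(ora_res, row.names = FALSE)

ranked <- data.frame(gene = lf$ceM, stat = log2(lf$fold_change))
gsea_res <- gsea_lite(ranked, bundle$gene_sets, n_perm = 1000, seed = 7)
write_tsv(gsea_res, "results/06_gsea.tsv")
cat("Rank-based enrichment (weighted by log2 fold change):\n")
print(gsea_res, row.names = FALSE)
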