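#!/usr/bin/env Rscript
# Stage 3: affinity states, functional scores and SMILM units.
#
# Control-vs-mutant score changes become one of the four affinity
# states (gain +1, up +0.5, loss -1, down -0.5); per-mutation
# functional scores sum the states over affected miRNAs; each affected
# miRNA fans out over its experimentally validated target mRNAs to
# form somatic mutation-miRNA-ceL-ceM (SMILM) units, split into
# high-frequency (>= 2 carriers in a cancer) and low-frequency sets.

suppressMessages(library(smilm))

bundle <- read_bundle("results/bundle")
cfg <- predictor_config()
sites <- utils::read.delim("results/02_binding_sites.tsv",
                           stringsAsFactors = FALSE)

changes <- collapse_changes_to_gene(classify_affinities(sites, cfg))
write_tsv(changes, "results/03_affinity_changes.tsv")
cat("Affinity changes:", nrow(changes), "(",
    paste(names(table(changes$state)), table(changes$state),
          collapse = ", "), ")\n")

fscores <- functional_score(changes)
write_tsv(fscores, "results/03_functional_scores.tsv")

units <- assemble_units(changes, bundle$interactions, bundle$mutations)
split <- split_hf_lf(units)
write_tsv(split$hf, "results/03_units_hf.tsv")
write_tsv(split$lf, "results/03_units_lf.tsv")
invisible(export_network(units, "results/03_network_edges.tsv"))

cat("SMILM units:", nrow(units), "->", nrow(split$hf), "HF +",
    nrow(split$lf), "LF\n")
cat("Network edge list written with",
    nrow(utils::read.delim("results/03_network_edges.tsv")), "edges\n")
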