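#' Read a bundle directory written by [write_bundle()]
#'
#' Loads every standard-format input back through the package readers.
#'
#' @param dir Directory containing the bundle files.
#' @return A list shaped like a `smilm_bundle` (without ground truth
#'   unless `truth_*.tsv` files are present).
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  genome_ss <- Biostrings::readDNAStringSet(p("genome.fa"))
  genome <- as.character(genome_ss)
  names(genome) <- sub("\\s.*$", "", names(genome_ss))
  mutations <- read_mutations(p("mutations.tsv"), dialect = "simple_tsv")
  clinical <- read_clinical(p("clinical.tsv"))
  sample_cancers <- tapply(mutations$cancer_type, mutations$sample_id,
                           function(x) x[1])
  expr_mir <- read_expression(p("expr_mir.tsv"))
  # samples without mutations only appear in the expression matrices;
  # infer their cancer from the sample-id prefix written by the generator
  all_samples <- colnames(expr_mir)
  sc <- sub("_S[0-9]+$", "", all_samples)
  names(sc) <- all_samples
  sc[names(sample_cancers)] <- sample_cancers
  truth_files <- list.files(dir, pattern = "^truth_.*\\.tsv$")
  truth <- if (length(truth_files) > 0)
    stats::setNames(lapply(truth_files, function(f)
      utils::read.delim(p(f), stringsAsFactors = FALSE)),
      sub("^truth_(.*)\\.tsv$", "\\1", truth_files)) else NULL
  list(genome = genome,
       transcripts = read_gtf(p("annotation.gtf"), biotype_filter = "lncRNA"),
       mirnas = read_mirna_fasta(p("mirnas.fa")),
       interactions = read_interactions(p("interactions.tsv")),
       mutations = mutations,
       expr_lnc = read_expression(p("expr_lnc.tsv")),
       expr_mir = expr_mir,
       expr_mrna = read_expression(p("expr_mrna.tsv")),
       clinical = clinical,
       gene_sets = read_gmt(p("sets.gmt")),
       sample_cancers = sc,
       truth = truth)
}

#' Run the full SMILM pipeline on a bundle
#'
#' End-to-end: context-window extraction around every mutation on every
#' lncRNA transcript, dual-predictor site calling on control and mutant
#' windows, affinity-change classification, per-mutation functional
#' scores, SMILM unit assembly against the validated interaction table,
#' the high/low-frequency split, the bivariate regression branch with
#' both filters for HF units, the grouped t-test branch for LF ceMs,
#' and survival analysis over the ceMs that pass either branch.
#'
#' @param bundle A `smilm_bundle` (from [simulate_bundle()] or
#'   [read_bundle()]).
#' @param pred_cfg A [predictor_config()].
#' @param alpha Significance level for both branches.
#' @param flank,upstream_ext Window geometry (see [build_context()]).
#' @param min_carriers HF threshold (see [split_hf_lf()]).
#' @return List with `contexts`, `sites`, `changes` (gene level),
#'   `fscores`, `units`, `hf_units`, `lf_units`, `hf_results`,
#'   `lf_results`, `survival_results`, and `counts` (a named vector of
#'   stage tallies).
#' @export
run_pipeline <- function(bundle, pred_cfg = predictor_config(),
                         alpha = 0.05, flank = 7L, upstream_ext = 14L,
                         min_carriers = 2L) {
  txs <- bundle$transcripts
  lnc_txs <- Filter(function(t) is.null(t$biotype) || t$biotype == "lncRNA",
                    txs)
  contexts <- build_contexts(bundle$mutations, lnc_txs, bundle$genome,
                             flank = flank, upstream_ext = upstream_ext)
  sites <- do.call(rbind, lapply(contexts, call_sites,
                                 mirnas = bundle$mirnas, cfg = pred_cfg))
  if (is.null(sites) || nrow(sites) == 0)
    stop("no miRNA binding sites called on any window")
  changes_tx <- classify_affinities(sites, pred_cfg)
  changes <- collapse_changes_to_gene(changes_tx)
  fscores <- functional_score(changes)
  units <- assemble_units(changes, bundle$interactions, bundle$mutations)
  split <- split_hf_lf(units, min_carriers)

  hf_results <- if (nrow(split$hf) > 0)
    hf_test_units(split$hf, bundle$expr_lnc, bundle$expr_mir,
                  bundle$expr_mrna, fscores, bundle$sample_cancers,
                  alpha = alpha)
  else NULL
  lf_results <- lf_test_cems(split$lf, bundle$expr_mrna,
                             bundle$sample_cancers, alpha = alpha)

  sig_hf <- if (!is.null(hf_results))
    hf_results[hf_results$passes_step1 & hf_results$passes_step2 %in% TRUE, ]
  else NULL
  sig_lf_cems <- lf_results$ceM[lf_results$significant]
  sig_units <- units[
    (paste(units$ceM, units$cancer_type) %in%
       paste(sig_lf_cems, lf_results$cancer_type[lf_results$significant])) |
    (!is.null(sig_hf) &
       paste(units$mutation_key, units$ceM, units$cancer_type) %in%
         paste(sig_hf$mutation_key, sig_hf$ceM, sig_hf$cancer_type)), ,
    drop = FALSE]
  survival_results <- if (nrow(sig_units) > 0)
    survival_by_cem(sig_units, bundle$expr_mrna, bundle$clinical,
                    bundle$sample_cancers)
  else NULL

  counts <- c(n_mutations = nrow(bundle$mutations),
              n_sites = length(unique(bundle$mutations$mutation_key)),
              n_contexts = length(contexts),
              n_called = nrow(sites),
              n_changes = nrow(changes),
              n_units = nrow(units),
              n_hf_units = nrow(split$hf),
              n_lf_units = nrow(split$lf),
              n_hf_pass = if (is.null(sig_hf)) 0L else nrow(sig_hf),
              n_lf_sig = sum(lf_results$significant))
  list(contexts = contexts, sites = sites, changes = changes,
       fscores = fscores, units = units,
       hf_units = split$hf, lf_units = split$lf,
       hf_results = hf_results, lf_results = lf_results,
       survival_results = survival_results, counts = counts)
}
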