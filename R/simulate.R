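comp_base <- function(b) COMPLEMENT[[b]]

rand_seq <- function(n, at_frac = 0.5) {
  p_at <- at_frac / 2; p_gc <- (1 - at_frac) / 2
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(p_at, p_at, p_gc, p_gc)), collapse = "")
}

#' Generator configuration
#'
#' Study conditions for the synthetic bundle: per-cancer cohort size,
#' planted effect sizes for the high-frequency (HF) regression branch
#' and the low-frequency (LF) t-test branch, expression noise, and the
#' survival log-hazard attached to the planted ceM direction. Defaults
#' are the conditions used throughout the package's validation: 60
#' samples, 20 HF carriers, planted (eta_l, eta_m) magnitudes (2, 1) in
#' log2 units, noise sigma = 1, LF effect 1.5 log2 units over 5
#' single-carrier mutations per ceM, survival log-hazard 0.7.
#'
#' @param cancers Cancer-type labels (one cohort per label).
#' @param n_samples Samples per cancer.
#' @param n_hf_units Planted HF mutations (states cycle
#'   gain/loss/up/down).
#' @param hf_carriers Carrier samples per HF mutation.
#' @param eta_l_mag,eta_m_mag Planted genotype-effect magnitudes on ceL
#'   and ceM (log2 FPKM units); signs follow the planted state so that
#'   `sign(eta_l) = -sign(event_score)` and `eta_l * eta_m < 0`.
#' @param gamma,delta miRNA-covariate loadings on ceL and ceM.
#' @param sigma Gaussian noise standard deviation (log2 units).
#' @param mir_sigma Between-sample spread of miRNA expression (log2
#'   units); kept separate from `sigma` because the miRNA enters the
#'   model as a covariate, not as noise.
#' @param n_lf_cems Planted LF-perturbed ceMs per cancer.
#' @param lf_units_per_cem Single-carrier LF mutations per planted ceM.
#' @param lf_effect Planted ceM expression shift (log2 units).
#' @param n_decoy_hf HF mutations with a real affinity change but no
#'   expression effect.
#' @param n_bg_mrna,n_bg_lnc Background genes without planted effects.
#' @param mirna_len Mature miRNA length.
#' @param surv_beta Survival log-hazard added to samples of the planted
#'   up-regulated class of the first HF ceM.
#' @param surv_base_hazard Baseline exponential hazard (per day).
#' @param censor_time Administrative censoring time (days).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(cancers = "COAD", n_samples = 60L,
                       n_hf_units = 4L, hf_carriers = 20L,
                       eta_l_mag = 2, eta_m_mag = 1,
                       gamma = 0.2, delta = 0.2, sigma = 1, mir_sigma = 1,
                       n_lf_cems = 2L, lf_units_per_cem = 5L, lf_effect = 1.5,
                       n_decoy_hf = 2L, n_bg_mrna = 8L, n_bg_lnc = 2L,
                       mirna_len = 22L,
                       surv_beta = 0.7, surv_base_hazard = 0.002,
                       censor_time = 2000) {
  stopifnot(n_samples > 0, hf_carriers >= 2, hf_carriers < n_samples,
            sigma >= 0, mirna_len >= 17)
  structure(as.list(environment()), class = "sim_config")
}

# miRNA engineered so the planted site geometry works:
# position 1 = U (target A1 pairs), position 9 = U (up/down mutation site
# toggles A/T), positions 10-13 A/U (AU-rich seed-adjacent flank).
make_mirna <- function(len) {
  m <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  m[1] <- "T"; m[9] <- "T"
  m[10:13] <- sample(c("A", "T"), 4, replace = TRUE)
  # guarantee some GC in the paired region for duplex energy headroom
  m[c(3, 6, 14)] <- sample(c("G", "C"), 3, replace = TRUE)
  paste(m, collapse = "")
}

# target-space site, 5'->3': supp (pairs m16..m9) + m8 pair + 6mer + A1.
# Returns the site string and the 1-based offsets of the two mutable
# positions (m8 pair at 9, m9 pair at 8).
make_site <- function(mirna) {
  m <- strsplit(mirna, "")[[1]]
  paste0(revcomp(paste(m[9:16], collapse = "")),
         comp_base(m[8]),
         revcomp(paste(m[2:7], collapse = "")),
         "A")
}

non_pairing_base <- function(mirna_base) {
  wc <- comp_base(mirna_base)
  wob <- if (mirna_base == "G") "T" else if (mirna_base == "T") "G" else NA
  setdiff(c("A", "C", "G", "T"), c(wc, wob))[1]
}

# control/mutant base at the mutation offset for each intended state
state_edit <- function(mirna, state) {
  m <- strsplit(mirna, "")[[1]]
  switch(state,
    loss = list(offset = 9L, control = comp_base(m[8]),
                mutant = non_pairing_base(m[8])),
    gain = list(offset = 9L, control = non_pairing_base(m[8]),
                mutant = comp_base(m[8])),
    # m9 is fixed to U, so WC partner is A and T is a non-pairing AU base
    down = list(offset = 8L, control = "A", mutant = "T"),
    up = list(offset = 8L, control = "T", mutant = "A"))
}

# Build one planted lncRNA transcript carrying the control-version site,
# verify the intended state with the actual predictors, retrying flanks.
plant_transcript <- function(id, gene_id, mirna_id, mirna, state, strand,
                             cfg_pred, max_tries = 40L) {
  edit <- state_edit(mirna, state)
  site <- make_site(mirna)
  substr(site, edit$offset, edit$offset) <- edit$control
  for (try in seq_len(max_tries)) {
    exon1 <- rand_seq(30, at_frac = 0.8)
    left <- rand_seq(10, at_frac = 0.9)
    right <- rand_seq(10, at_frac = 0.9)
    exon2 <- paste0(left, site, right)
    tx_center <- nchar(exon1) + nchar(left) + edit$offset - 1L  # 0-based
    tx <- list(transcript_id = id, gene_id = gene_id,
               gene_name = gene_id, biotype = "lncRNA",
               chrom = NA, strand = strand,
               exon_seqs = c(exon1, exon2),
               spliced = paste0(exon1, exon2),
               spliced_length = nchar(exon1) + nchar(exon2),
               tx_center = tx_center,
               ref_tx = edit$control, alt_tx = edit$mutant,
               mirna_id = mirna_id, state = state,
               site_tx_start = nchar(exon1) + nchar(left))
    if (verify_planted_state(tx, mirna_id, mirna, cfg_pred)) return(tx)
  }
  stop("could not plant a ", state, " site for ", mirna_id,
       " (sequence space infeasible for these predictor settings)")
}

verify_planted_state <- function(tx, mirna_id, mirna, cfg_pred) {
  L <- tx$spliced_length
  ctr <- tx$tx_center
  w_start <- max(0L, ctr - 7L); w_end <- min(L, ctr + 1L + 7L)
  e_start <- max(0L, ctr - 14L)
  control <- substr(tx$spliced, w_start + 1L, w_end)
  ext_control <- substr(tx$spliced, e_start + 1L, w_end)
  edit_at <- function(win, start0) {
    off <- ctr - start0
    paste0(substr(win, 1, off), tx$alt_tx,
           substr(win, off + 2L, nchar(win)))
  }
  ctx <- list(mutation_key = "probe", transcript_id = tx$transcript_id,
              gene_id = tx$gene_id, control_seq = control,
              mutant_seq = edit_at(control, w_start),
              extended_control_seq = ext_control,
              extended_mutant_seq = edit_at(ext_control, e_start))
  mir <- c(mirna); names(mir) <- mirna_id
  sites <- call_sites(ctx, mir, cfg_pred)
  if (nrow(sites) != 1) return(FALSE)
  chg <- classify_affinity(sites[1, ], cfg_pred)
  !is.null(chg) && chg$state == tx$state
}

# lay transcripts onto one chromosome: spacer + exon + intron + exon ...
layout_chromosome <- function(txs, chrom, spacer = 25L, intron = 20L) {
  seq_parts <- character(0); pos <- 0L
  models <- list()
  for (tx in txs) {
    g_exons <- tx$exon_seqs
    if (tx$strand == "-") g_exons <- rev(vapply(g_exons, revcomp, character(1)))
    sp <- rand_seq(spacer, at_frac = 0.6)
    seq_parts <- c(seq_parts, sp); pos <- pos + spacer
    exons <- matrix(0L, nrow = length(g_exons), ncol = 2,
                    dimnames = list(NULL, c("start", "end")))
    for (k in seq_along(g_exons)) {
      if (k > 1) {
        seq_parts <- c(seq_parts, rand_seq(intron, at_frac = 0.6))
        pos <- pos + intron
      }
      exons[k, ] <- c(pos + 1L, pos + nchar(g_exons[k]))
      seq_parts <- c(seq_parts, g_exons[k])
      pos <- pos + nchar(g_exons[k])
    }
    tx$chrom <- chrom
    tx$exons <- exons
    models[[tx$transcript_id]] <- tx
  }
  list(seq = paste(seq_parts, collapse = ""), models = models)
}

#' Generate a complete synthetic input bundle with ground truth
#'
#' Emits every input the pipeline consumes -- genome, lncRNA/mRNA
#' annotation, mature miRNAs, validated interactions, per-sample somatic
#' mutations, FPKM expression matrices for lncRNA/miRNA/mRNA, clinical
#' follow-up and a gene-set collection -- with planted miRNA response
#' elements, mutations of known affinity-change state, SMILM units of
#' known effect size, LF-perturbed ceMs of known direction, and survival
#' hazard tied to the planted ceM class. All randomness flows from
#' `seed`; the same seed yields an identical bundle.
#'
#' Expression is generated on the log2 scale as
#' `E = mu + eta * Gt + loading * (MIr - mean(MIr)) + noise` and stored
#' as FPKM via `2^E - 1` (floored at 0), so the pipeline's
#' log2(FPKM+1) transform recovers the planted linear model exactly up
#' to the floor.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param pred_cfg Predictor configuration used to verify planted
#'   states at build time.
#' @return A list of class `smilm_bundle`: `genome` (named character),
#'   `transcripts`, `mirnas`, `interactions`, `mutations`,
#'   `expr_lnc`/`expr_mir`/`expr_mrna`, `clinical`, `gene_sets`,
#'   `sample_cancers`, `truth` (planted MREs, mutations, units, ceMs,
#'   survival), and `config`.
#' @export
simulate_bundle <- function(config = sim_config(), seed = 1L,
                            pred_cfg = predictor_config()) {
  set.seed(seed)
  cf <- config
  states <- rep(c("gain", "loss", "up", "down"), length.out = cf$n_hf_units)

  samples <- unlist(lapply(cf$cancers, function(ca)
    paste0(ca, "_S", sprintf("%02d", seq_len(cf$n_samples)))))
  sample_cancers <- rep(cf$cancers, each = cf$n_samples)
  names(sample_cancers) <- samples

  # --- sequences: miRNAs, planted lncRNA transcripts -------------------
  n_planted_mirna <- cf$n_hf_units + cf$n_lf_cems + cf$n_decoy_hf
  mirna_ids <- sprintf("hsa-miR-sim%02d", seq_len(n_planted_mirna + 2L))
  mirnas <- vapply(mirna_ids, function(i) make_mirna(cf$mirna_len),
                   character(1))

  txs <- list(); plant_rows <- list()
  strands <- rep(c("+", "-"), length.out = cf$n_hf_units)
  for (i in seq_len(cf$n_hf_units)) {
    id <- sprintf("LNC%02d-T1", i); gid <- sprintf("LNC%02d", i)
    txs[[id]] <- plant_transcript(id, gid, mirna_ids[i], mirnas[[i]],
                                  states[i], strands[i], pred_cfg)
    plant_rows[[id]] <- list(class = "hf", unit_index = i)
  }
  k <- cf$n_hf_units
  for (j in seq_len(cf$n_lf_cems)) {
    mir_id <- mirna_ids[k + j]
    lf_state <- if (j %% 2 == 1) "gain" else "loss"
    for (u in seq_len(cf$lf_units_per_cem)) {
      idx <- length(txs) + 1L
      id <- sprintf("LNC%02d-T1", idx); gid <- sprintf("LNC%02d", idx)
      txs[[id]] <- plant_transcript(id, gid, mir_id, mirnas[[mir_id]],
                                    lf_state, sample(c("+", "-"), 1), pred_cfg)
      plant_rows[[id]] <- list(class = "lf", lf_cem = j)
    }
  }
  for (d in seq_len(cf$n_decoy_hf)) {
    mir_id <- mirna_ids[cf$n_hf_units + cf$n_lf_cems + d]
    idx <- length(txs) + 1L
    id <- sprintf("LNC%02d-T1", idx); gid <- sprintf("LNC%02d", idx)
    txs[[id]] <- plant_transcript(id, gid, mir_id, mirnas[[mir_id]],
                                  "loss", "+", pred_cfg)
    plant_rows[[id]] <- list(class = "decoy")
  }
  # background lncRNAs without planted sites
  bg_lnc_ids <- character(0)
  for (b in seq_len(cf$n_bg_lnc)) {
    idx <- length(txs) + 1L
    id <- sprintf("LNC%02d-T1", idx); gid <- sprintf("LNC%02d", idx)
    txs[[id]] <- list(transcript_id = id, gene_id = gid, gene_name = gid,
                      biotype = "lncRNA", chrom = NA, strand = "+",
                      exon_seqs = c(rand_seq(40, 0.8), rand_seq(30, 0.8)),
                      spliced_length = 70L)
    bg_lnc_ids <- c(bg_lnc_ids, gid)
  }

  chr1 <- layout_chromosome(txs, "chr1")
  tx_models <- chr1$models
  genome <- c(chr1 = chr1$seq, chr2 = rand_seq(200, 0.5))

  # --- mutations and carriers -----------------------------------------
  mut_rows <- list(); truth_mut <- list()
  add_mutation <- function(tx, carriers, cancer, class, unit_index = NA) {
    model <- tx_models[[tx$transcript_id]]
    gpos <- transcript_to_genomic(model, model$tx_center)
    ref_g <- if (model$strand == "-") comp_base(model$ref_tx) else model$ref_tx
    alt_g <- if (model$strand == "-") comp_base(model$alt_tx) else model$alt_tx
    key <- mutation_key(model$chrom, gpos, ref_g, alt_g)
    mut_rows[[length(mut_rows) + 1L]] <<- data.frame(
      sample_id = carriers, cancer_type = cancer, chrom = model$chrom,
      pos = gpos, ref = ref_g, alt = alt_g, stringsAsFactors = FALSE)
    truth_mut[[length(truth_mut) + 1L]] <<- data.frame(
      mutation_key = key, transcript_id = model$transcript_id,
      gene_id = model$gene_id, mirna_id = model$mirna_id,
      state = model$state, class = class, cancer_type = cancer,
      n_carriers = length(carriers), stringsAsFactors = FALSE)
    key
  }

  # genes: each planted miRNA targets one effect ceM and one bystander
  n_cem <- cf$n_hf_units + cf$n_lf_cems + cf$n_decoy_hf
  cem_ids <- sprintf("CEM%02d", seq_len(n_cem))
  bystander_ids <- sprintf("BYS%02d", seq_len(n_planted_mirna))
  bg_mrna_ids <- sprintf("MRNA%02d", seq_len(cf$n_bg_mrna))
  mrna_ids <- c(cem_ids, bystander_ids, bg_mrna_ids)
  interactions <- rbind(
    data.frame(mirna_id = mirna_ids[seq_len(n_cem)], target_gene_id = cem_ids,
               evidence = "Luciferase", stringsAsFactors = FALSE),
    data.frame(mirna_id = mirna_ids[seq_len(n_planted_mirna)],
               target_gene_id = bystander_ids,
               evidence = "Western", stringsAsFactors = FALSE))

  truth_units <- list(); truth_cems <- list()
  hf_carrier_sets <- list(); lf_carrier_sets <- list()
  for (ca in cf$cancers) {
    ca_samples <- samples[sample_cancers == ca]
    hf_ids <- names(Filter(function(p) identical(p$class, "hf"), plant_rows))
    for (i in seq_along(hf_ids)) {
      carriers <- sample(ca_samples, cf$hf_carriers)
      key <- add_mutation(txs[[hf_ids[i]]], carriers, ca, "hf", i)
      s <- sign(c(gain = 1, loss = -1, up = 1, down = -1)[[states[i]]])
      eta_l <- -s * cf$eta_l_mag; eta_m <- s * cf$eta_m_mag
      model <- tx_models[[hf_ids[i]]]
      truth_units[[length(truth_units) + 1L]] <- data.frame(
        mutation_key = key, cancer_type = ca, mirna_id = model$mirna_id,
        ceL = model$gene_id, ceM = cem_ids[i], state = states[i],
        eta_l = eta_l, eta_m = eta_m, stringsAsFactors = FALSE)
      hf_carrier_sets[[paste(ca, i)]] <- list(
        carriers = carriers, ceL = model$gene_id, ceM = cem_ids[i],
        mirna = model$mirna_id, eta_l = eta_l, eta_m = eta_m)
    }
    lf_ids <- names(Filter(function(p) identical(p$class, "lf"), plant_rows))
    for (j in seq_len(cf$n_lf_cems)) {
      ids_j <- lf_ids[vapply(plant_rows[lf_ids], function(p)
        p$lf_cem == j, logical(1))]
      carriers_j <- sample(ca_samples, length(ids_j))
      direction <- if (j %% 2 == 1) 1 else -1
      for (u in seq_along(ids_j)) {
        add_mutation(txs[[ids_j[u]]], carriers_j[u], ca, "lf")
      }
      cem <- cem_ids[cf$n_hf_units + j]
      truth_cems[[length(truth_cems) + 1L]] <- data.frame(
        ceM = cem, cancer_type = ca,
        direction = if (direction > 0) "up" else "down",
        effect = direction * cf$lf_effect,
        n_carriers = length(carriers_j),
        carriers = paste(sort(carriers_j), collapse = ","),
        stringsAsFactors = FALSE)
      lf_carrier_sets[[paste(ca, j)]] <- list(
        carriers = carriers_j, cem = cem, direction = direction,
        lnc_genes = vapply(ids_j, function(id) tx_models[[id]]$gene_id,
                           character(1)))
    }
    decoy_ids <- names(Filter(function(p) identical(p$class, "decoy"),
                              plant_rows))
    for (id in decoy_ids)
      add_mutation(txs[[id]], sample(ca_samples, 2L), ca, "decoy")
  }

  mutations <- do.call(rbind, mut_rows)
  mutations$mutation_key <- mutation_key(mutations$chrom, mutations$pos,
                                         mutations$ref, mutations$alt)
  names(mutations)[names(mutations) == "ref"] <- "ref_allele"
  names(mutations)[names(mutations) == "alt"] <- "alt_allele"
  mutations$variant_class <- infer_variant_class(mutations$ref_allele,
                                                 mutations$alt_allele)

  # --- expression -----------------------------------------------------
  lnc_ids <- unique(vapply(tx_models, function(t) t$gene_id, character(1)))
  n_s <- length(samples)
  log_mat <- function(ids, sd) {
    mu <- stats::runif(length(ids), 5, 7)
    matrix(stats::rnorm(length(ids) * n_s, mean = mu, sd = sd),
           nrow = length(ids), dimnames = list(ids, samples))
  }
  mir_log <- log_mat(mirna_ids, cf$mir_sigma)
  lnc_log <- log_mat(lnc_ids, cf$sigma)
  mrna_log <- log_mat(mrna_ids, cf$sigma)

  for (hc in hf_carrier_sets) {
    gt <- as.numeric(samples %in% hc$carriers)
    mi_c <- mir_log[hc$mirna, ] - mean(mir_log[hc$mirna, ])
    lnc_log[hc$ceL, ] <- lnc_log[hc$ceL, ] + hc$eta_l * gt + cf$gamma * mi_c
    mrna_log[hc$ceM, ] <- mrna_log[hc$ceM, ] + hc$eta_m * gt + cf$delta * mi_c
  }
  for (lc in lf_carrier_sets) {
    ind <- as.numeric(samples %in% lc$carriers)
    mrna_log[lc$cem, ] <- mrna_log[lc$cem, ] +
      lc$direction * cf$lf_effect * ind
    for (u in seq_along(lc$lnc_genes)) {
      ind_u <- as.numeric(samples %in% lc$carriers[u])
      lnc_log[lc$lnc_genes[u], ] <- lnc_log[lc$lnc_genes[u], ] -
        lc$direction * cf$lf_effect * ind_u
    }
  }
  to_fpkm <- function(m) pmax(2^m - 1, 0)

  # --- clinical: hazard tied to the planted class of the first HF ceM -
  surv_cem <- cem_ids[1]
  up_samples <- unique(unlist(lapply(hf_carrier_sets, function(hc)
    if (hc$ceM == surv_cem && hc$eta_m > 0) hc$carriers else NULL)))
  z <- as.numeric(samples %in% up_samples)
  hazard <- cf$surv_base_hazard * exp(cf$surv_beta * z)
  t_raw <- stats::rexp(n_s, rate = hazard)
  event <- as.integer(t_raw <= cf$censor_time)
  time <- pmin(t_raw, cf$censor_time)
  clinical <- data.frame(sample_id = samples, time = round(time, 1),
                         event = event,
                         stage = sample(paste0("Stage", c("I", "II", "III", "IV")),
                                        n_s, replace = TRUE),
                         stringsAsFactors = FALSE)

  # --- gene sets ------------------------------------------------------
  gene_sets <- list(
    PLANTED_CEMS = cem_ids,
    HALLMARK_RANDOM_A = sample(mrna_ids, min(6, length(mrna_ids))),
    HALLMARK_RANDOM_B = sample(mrna_ids, min(6, length(mrna_ids))))

  truth <- list(
    mres = do.call(rbind, lapply(tx_models, function(t) {
      if (is.null(t$mirna_id)) return(NULL)
      data.frame(transcript_id = t$transcript_id, gene_id = t$gene_id,
                 mirna_id = t$mirna_id, state = t$state,
                 site_tx_start = t$site_tx_start,
                 center_tx_pos = t$tx_center, stringsAsFactors = FALSE)
    })),
    mutations = do.call(rbind, truth_mut),
    units = do.call(rbind, truth_units),
    cems = do.call(rbind, truth_cems),
    survival = data.frame(ceM = surv_cem, beta = cf$surv_beta,
                          stringsAsFactors = FALSE))
  rownames(truth$mres) <- NULL

  structure(list(genome = genome, transcripts = tx_models,
                 mirnas = mirnas, interactions = interactions,
                 mutations = mutations,
                 expr_lnc = to_fpkm(lnc_log), expr_mir = to_fpkm(mir_log),
                 expr_mrna = to_fpkm(mrna_log), clinical = clinical,
                 gene_sets = gene_sets, sample_cancers = sample_cancers,
                 truth = truth, config = cf),
            class = "smilm_bundle")
}

#' Generate a bundle with no planted expression or survival effects
#'
#' Same structure as [simulate_bundle()] -- planted sites and mutations
#' remain, so the pipeline still assembles units -- but expression is
#' independent of genotype and the hazard is flat. Used to calibrate
#' type-I error of the statistical branches.
#'
#' @inheritParams simulate_bundle
#' @return A `smilm_bundle`.
#' @export
null_bundle <- function(config = sim_config(), seed = 1L,
                        pred_cfg = predictor_config()) {
  config$eta_l_mag <- 0; config$eta_m_mag <- 0
  config$lf_effect <- 0; config$surv_beta <- 0
  config$gamma <- 0; config$delta <- 0
  simulate_bundle(config, seed, pred_cfg)
}

#' Simulate expression for one SMILM regression unit
#'
#' Draws (El, Em, Gt, MIr) under the planted bivariate model on the
#' log2 scale, pushes values through the FPKM representation
#' (`2^x - 1`, floored at 0) and back through `log2(FPKM + 1)`, i.e.
#' the exact path pipeline data take. Setting both effects to zero
#' gives a null unit.
#'
#' @param n Samples; `n_carriers` of them have `Gt = 1`.
#' @param n_carriers Carrier count.
#' @param eta_l,eta_m Planted genotype effects (log2 units).
#' @param gamma,delta miRNA loadings.
#' @param sigma Noise standard deviation.
#' @param mu_l,mu_m,mu_mir Baseline log2 expression levels.
#' @return List with `El`, `Em`, `Gt`, `MIr` ready for
#'   [fit_bivariate()].
#' @export
simulate_regression_input <- function(n = 60L, n_carriers = 20L,
                                      eta_l = -2, eta_m = 1,
                                      gamma = 0.2, delta = 0.2, sigma = 1,
                                      mu_l = 6, mu_m = 6, mu_mir = 6) {
  Gt <- as.numeric(seq_len(n) <= n_carriers)
  mir <- stats::rnorm(n, mu_mir, sigma)
  mi_c <- mir - mean(mir)
  el <- mu_l + eta_l * Gt + gamma * mi_c + stats::rnorm(n, 0, sigma)
  em <- mu_m + eta_m * Gt + delta * mi_c + stats::rnorm(n, 0, sigma)
  round_trip <- function(x) log2(pmax(2^x - 1, 0) + 1)
  list(El = round_trip(el), Em = round_trip(em), Gt = Gt,
       MIr = round_trip(mir))
}

#' Simulate survival times under a proportional-hazards model
#'
#' Exponential event times with hazard
#' `base_hazard * exp(beta * x)`, administratively censored.
#'
#' @param x Covariate vector (one value per sample).
#' @param beta Log-hazard coefficient.
#' @param base_hazard Baseline hazard per day.
#' @param censor_time Administrative censoring time.
#' @return Clinical-style data frame (`sample_id`, `time`, `event`,
#'   `stage`).
#' @export
simulate_survival <- function(x, beta = 0.7, base_hazard = 0.002,
                              censor_time = 2000) {
  n <- length(x)
  t_raw <- stats::rexp(n, rate = base_hazard * exp(beta * x))
  data.frame(sample_id = if (is.null(names(x)))
               paste0("S", seq_len(n)) else names(x),
             time = pmin(t_raw, censor_time),
             event = as.integer(t_raw <= censor_time),
             stage = NA_character_, stringsAsFactors = FALSE)
}

#' Write a synthetic bundle to disk in standard formats
#'
#' Genome and miRNAs as FASTA, annotation as GTF, gene sets as GMT, all
#' tables as TSV (mutations in the `simple_tsv` dialect of
#' [read_mutations()]), ground truth as `truth_*.tsv`.
#'
#' @param bundle A `smilm_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(bundle$genome), p("genome.fa"))
  mir_rna <- chartr("T", "U", unlist(bundle$mirnas))
  writeLines(as.vector(rbind(paste0(">", names(bundle$mirnas)), mir_rna)),
             p("mirnas.fa"))
  gtf <- unlist(lapply(bundle$transcripts, function(t) {
    apply_rows <- apply(t$exons, 1, function(e) {
      attrs <- sprintf(
        'gene_id "%s"; transcript_id "%s"; gene_name "%s"; gene_type "%s"; transcript_type "%s";',
        t$gene_id, t$transcript_id, t$gene_name, t$biotype, t$biotype)
      paste(t$chrom, "sim", "exon", e[1], e[2], ".", t$strand, ".", attrs,
            sep = "\t")
    })
    apply_rows
  }))
  writeLines(gtf, p("annotation.gtf"))
  write_tsv(bundle$interactions, p("interactions.tsv"))
  mut_out <- bundle$mutations[, c("sample_id", "cancer_type", "chrom", "pos",
                                  "ref_allele", "alt_allele")]
  names(mut_out) <- c("sample_id", "cancer_type", "chrom", "pos", "ref", "alt")
  write_tsv(mut_out, p("mutations.tsv"))
  wm <- function(m, f) {
    df <- data.frame(gene_id = rownames(m), as.data.frame(m),
                     check.names = FALSE)
    write_tsv(df, p(f))
  }
  wm(round(bundle$expr_lnc, 4), "expr_lnc.tsv")
  wm(round(bundle$expr_mir, 4), "expr_mir.tsv")
  wm(round(bundle$expr_mrna, 4), "expr_mrna.tsv")
  write_tsv(bundle$clinical, p("clinical.tsv"))
  writeLines(vapply(names(bundle$gene_sets), function(nm)
    paste(c(nm, "synthetic", bundle$gene_sets[[nm]]), collapse = "\t"),
    character(1)), p("sets.gmt"))
  for (nm in names(bundle$truth))
    write_tsv(bundle$truth[[nm]], p(paste0("truth_", nm, ".tsv")))
  invisible(dir)
}

#' Read mature miRNA sequences from FASTA
#'
#' @param path miRBase-style FASTA (RNA or DNA letters); header up to
#'   the first whitespace becomes the miRNA id.
#' @return Named character vector of sequences (U preserved).
#' @export
read_mirna_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}
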