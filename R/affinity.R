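#' Classify the affinity change of one miRNA site
#'
#' The four states of altered lncRNA-miRNA binding affinity:
#' \describe{
#'   \item{gain (+1)}{site absent in control, present in mutant}
#'   \item{loss (-1)}{site present in control, absent in mutant}
#'   \item{up (+0.5)}{present in both, binding strengthened by at least
#'     the score margin}
#'   \item{down (-0.5)}{present in both, binding weakened by at least
#'     the margin}
#' }
#' Direction for up/down is taken from the alignment-score change when
#' it clears `delta_align_min`, otherwise from the context-score change
#' (more negative context = stronger) when it clears
#' `delta_context_min`; sites present in both windows without a margin,
#' or absent from both, yield no change.
#'
#' @param site_row One row of the [call_sites()] output.
#' @param cfg A [predictor_config()] (margins are read from it).
#' @return A one-row data frame with `state`, `event_score`,
#'   `delta_align`, `delta_context` appended to the site key columns,
#'   or `NULL` when there is no affinity change.
#' @export
classify_affinity <- function(site_row, cfg = predictor_config()) {
  ctl <- site_row$control_present; mut <- site_row$mutant_present
  d_align <- site_row$mutant_align - site_row$control_align
  d_ctx <- site_row$mutant_context - site_row$control_context
  state <- if (!ctl && mut) "gain"
    else if (ctl && !mut) "loss"
    else if (ctl && mut) {
      if (d_align >= cfg$delta_align_min) "up"
      else if (d_align <= -cfg$delta_align_min) "down"
      else if (d_ctx <= -cfg$delta_context_min) "up"
      else if (d_ctx >= cfg$delta_context_min) "down"
      else NA_character_
    } else NA_character_
  if (is.na(state)) return(NULL)
  score <- c(gain = 1, up = 0.5, loss = -1, down = -0.5)[[state]]
  data.frame(mutation_key = site_row$mutation_key,
             transcript_id = site_row$transcript_id,
             gene_id = site_row$gene_id,
             mirna_id = site_row$mirna_id,
             state = state, event_score = score,
             delta_align = d_align, delta_context = d_ctx,
             stringsAsFactors = FALSE)
}

#' Classify affinity changes for a whole site table
#'
#' @param sites [call_sites()] output (possibly row-bound over contexts).
#' @param cfg A [predictor_config()].
#' @return Data frame of affinity changes (zero rows if none).
#' @export
classify_affinities <- function(sites, cfg = predictor_config()) {
  rows <- lapply(seq_len(nrow(sites)),
                 function(i) classify_affinity(sites[i, ], cfg))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(mutation_key = character(0), transcript_id = character(0),
                      gene_id = character(0), mirna_id = character(0),
                      state = character(0), event_score = numeric(0),
                      delta_align = numeric(0), delta_context = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Per-mutation functional score
#'
#' Sum of the state scores (+1, +0.5, -1, -0.5) over all miRNAs whose
#' binding affinity the mutation alters; order-invariant.
#'
#' @param changes Affinity-change data frame for one or more mutations
#'   (gene-level; see [collapse_changes_to_gene()]).
#' @return Data frame with one row per mutation key: `functional_score`
#'   and `n_events`.
#' @export
functional_score <- function(changes) {
  if (nrow(changes) == 0)
    return(data.frame(mutation_key = character(0),
                      functional_score = numeric(0), n_events = integer(0),
                      stringsAsFactors = FALSE))
  agg <- stats::aggregate(event_score ~ mutation_key, data = changes, FUN = sum)
  n <- stats::aggregate(event_score ~ mutation_key, data = changes, FUN = length)
  out <- data.frame(mutation_key = agg$mutation_key,
                    functional_score = agg$event_score,
                    n_events = n$event_score, stringsAsFactors = FALSE)
  out
}

#' Collapse transcript-level affinity changes to gene level
#'
#' A mutation may hit several overlapping transcripts of one lncRNA
#' gene. The gene-level state per (mutation, miRNA, gene) is resolved by
#' the transcript change with the largest absolute alignment-score
#' delta; exact ties with conflicting sign of the event score are
#' discarded (logged in attribute `n_conflicts`).
#'
#' @param changes Transcript-level affinity-change data frame.
#' @return Gene-level affinity-change data frame.
#' @export
collapse_changes_to_gene <- function(changes) {
  if (nrow(changes) == 0) { attr(changes, "n_conflicts") <- 0L; return(changes) }
  key <- paste(changes$mutation_key, changes$mirna_id, changes$gene_id,
               sep = "\r")
  n_conflicts <- 0L
  keep <- unlist(lapply(split(seq_len(nrow(changes)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    sub <- changes[idx, ]
    best <- which(abs(sub$delta_align) == max(abs(sub$delta_align)))
    if (length(best) > 1 && length(unique(sign(sub$event_score[best]))) > 1) {
      n_conflicts <<- n_conflicts + 1L
      return(integer(0))
    }
    idx[best[1]]
  }))
  out <- changes[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_conflicts") <- n_conflicts
  out
}

#' Assemble somatic mutation-miRNA-ceL-ceM (SMILM) units
#'
#' For each gene-level affinity change, every experimentally validated
#' target mRNA of the affected miRNA becomes the ceM of one unit;
#' carrier samples are attached per cancer type from the mutation table.
#' miRNAs with no validated targets produce no units (counted).
#'
#' @param changes Gene-level affinity changes
#'   (see [collapse_changes_to_gene()]).
#' @param interactions Interaction table from [read_interactions()].
#' @param mutations Mutation data frame (all carrier rows).
#' @return Data frame of SMILM units: `mutation_key`, `cancer_type`,
#'   `mirna_id`, `ceL`, `ceM`, `state`, `event_score`, `carriers`
#'   (comma-separated sample ids), `n_carriers`. Attribute
#'   `n_untargeted_mirnas` counts affected miRNAs absent from the
#'   interaction table.
#' @export
assemble_units <- function(changes, interactions, mutations) {
  stopifnot(nrow(interactions) > 0)
  empty <- data.frame(mutation_key = character(0), cancer_type = character(0),
                      mirna_id = character(0), ceL = character(0),
                      ceM = character(0), state = character(0),
                      event_score = numeric(0), carriers = character(0),
                      n_carriers = integer(0), stringsAsFactors = FALSE)
  if (nrow(changes) == 0) { attr(empty, "n_untargeted_mirnas") <- 0L; return(empty) }
  n_untargeted <- length(setdiff(unique(changes$mirna_id),
                                 unique(interactions$mirna_id)))
  merged <- merge(changes, interactions, by = "mirna_id")
  merged <- merged[merged$target_gene_id != merged$gene_id, , drop = FALSE]
  if (nrow(merged) == 0) { attr(empty, "n_untargeted_mirnas") <- n_untargeted; return(empty) }
  carrier_map <- stats::aggregate(
    sample_id ~ mutation_key + cancer_type, data = mutations,
    FUN = function(s) paste(sort(unique(s)), collapse = ","))
  out <- merge(merged, carrier_map, by = "mutation_key")
  out <- data.frame(mutation_key = out$mutation_key,
                    cancer_type = out$cancer_type,
                    mirna_id = out$mirna_id,
                    ceL = out$gene_id,
                    ceM = out$target_gene_id,
                    state = out$state,
                    event_score = out$event_score,
                    carriers = out$sample_id,
                    stringsAsFactors = FALSE)
  out$n_carriers <- lengths(strsplit(out$carriers, ",", fixed = TRUE))
  out <- out[order(out$mutation_key, out$cancer_type, out$mirna_id, out$ceM), ]
  rownames(out) <- NULL
  attr(out, "n_untargeted_mirnas") <- n_untargeted
  out
}

#' Split SMILM units into high- and low-frequency classes
#'
#' A mutation site is high-frequency (HF) in a cancer type when at
#' least `min_carriers` distinct samples of that cancer carry the exact
#' same (chrom, pos, ref, alt) variant; the remainder are low-frequency
#' (LF). The split is per cancer type: the same site can be HF in one
#' cancer and LF in another.
#'
#' @param units SMILM unit data frame from [assemble_units()].
#' @param min_carriers Carrier-count threshold (default 2).
#' @return List with data frames `hf` and `lf`.
#' @export
split_hf_lf <- function(units, min_carriers = 2L) {
  hf <- units$n_carriers >= min_carriers
  list(hf = units[hf, , drop = FALSE], lf = units[!hf, , drop = FALSE])
}

#' Expression tendency of a ceM
#'
#' Sign of the sum of event scores over all units that regulate one ceM
#' in one cancer type: `"up"` when the sum is positive, `"down"` when
#' negative, `"none"` when zero.
#'
#' @param units_for_cem SMILM units sharing one ceM and cancer type.
#' @return `"up"`, `"down"` or `"none"`.
#' @export
cem_tendency <- function(units_for_cem) {
  s <- sum(units_for_cem$event_score)
  if (s > 0) "up" else if (s < 0) "down" else "none"
}

#' Split carrier strings into sample vectors
#' @param units SMILM unit data frame.
#' @return List of character vectors, one per unit row.
#' @export
carrier_list <- function(units) {
  strsplit(units$carriers, ",", fixed = TRUE)
}
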