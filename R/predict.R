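#' Predictor configuration
#'
#' Thresholds and scoring parameters for the two built-in miRNA target
#' predictors. The pass thresholds are strict inequalities: alignment
#' score > 160 and duplex energy < -20 kcal/mol for the alignment-based
#' predictor, context score < -0.4 for the seed/context predictor.
#'
#' @param score_min Alignment-score pass threshold (exclusive).
#' @param energy_max Duplex-energy pass threshold in kcal/mol (exclusive).
#' @param context_max Context-score pass threshold (exclusive).
#' @param seed_scale Multiplier applied to substitution scores at miRNA
#'   seed positions 2-8.
#' @param match_score,wobble_score,mismatch Substitution scores for
#'   Watson-Crick pairs, G:U wobbles and non-pairs.
#' @param gap_open,gap_extend Affine gap penalties.
#' @param pair_energies Stacking energies (kcal/mol) per paired
#'   `GC`/`AU`/`GU`.
#' @param gap_energy Energy penalty per gap run in the duplex.
#' @param combine_rule `"both"` requires both predictors to pass for a
#'   site to be called present; `"either"` accepts one.
#' @param delta_align_min,delta_context_min Minimum score margins for
#'   calling a directional (up/down) affinity change.
#' @return A list of class `predictor_config`.
#' @export
predictor_config <- function(score_min = 160, energy_max = -20,
                             context_max = -0.4, seed_scale = 4.0,
                             match_score = 5, wobble_score = 1, mismatch = -3,
                             gap_open = -9, gap_extend = -4,
                             pair_energies = c(GC = -3.0, AU = -2.0, GU = -1.0),
                             gap_energy = 0.5,
                             combine_rule = c("both", "either"),
                             delta_align_min = 1.0, delta_context_min = 0.01) {
  stopifnot(score_min > 0, energy_max < 0, context_max < 0, seed_scale > 0)
  structure(list(score_min = score_min, energy_max = energy_max,
                 context_max = context_max, seed_scale = seed_scale,
                 match_score = match_score, wobble_score = wobble_score,
                 mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, pair_energies = pair_energies,
                 gap_energy = gap_energy,
                 combine_rule = match.arg(combine_rule),
                 delta_align_min = delta_align_min,
                 delta_context_min = delta_context_min),
            class = "predictor_config")
}

norm_seq <- function(s) toupper(chartr("Uu", "Tt", s))

is_wc <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}
is_wobble <- function(a, b) (a == "G" & b == "T") | (a == "T" & b == "G")

# substitution score for miRNA base (at 5'->3' position mpos) vs target base
pair_sub_score <- function(mb, tb, mpos, cfg) {
  s <- if (is_wc(mb, tb)) cfg$match_score
       else if (is_wobble(mb, tb)) cfg$wobble_score
       else cfg$mismatch
  if (mpos >= 2 && mpos <= 8) s * cfg$seed_scale else s
}

pair_energy <- function(mb, tb, cfg) {
  if ((mb == "G" && tb == "C") || (mb == "C" && tb == "G"))
    cfg$pair_energies[["GC"]]
  else if ((mb == "A" && tb == "T") || (mb == "T" && tb == "A"))
    cfg$pair_energies[["AU"]]
  else if (is_wobble(mb, tb)) cfg$pair_energies[["GU"]]
  else 0
}

#' Alignment-based binding score
#'
#' Local alignment of the reversed miRNA (3'->5', so both sequences read
#' left to right in antiparallel register) against a target window on a
#' complementarity substitution matrix with affine gaps. Substitution
#' scores at miRNA seed positions 2-8 are multiplied by `seed_scale`.
#' The duplex energy is the sum of per-pair stacking energies over
#' aligned complementary (including wobble) pairs plus `gap_energy` per
#' gap run. Ties are broken deterministically: highest score, then
#' leftmost window end, then 5'-most miRNA end, with diagonal moves
#' preferred in the traceback (shortest alignment).
#'
#' @param mirna_seq Mature miRNA sequence, 5'->3' (RNA or DNA letters).
#' @param window Target sequence window, 5'->3'.
#' @param cfg A [predictor_config()].
#' @return List with `align_score`, `duplex_energy`, and `trace`, a data
#'   frame of aligned (miRNA position, window position) pairs with their
#'   pair class.
#' @export
miranda_like_score <- function(mirna_seq, window, cfg = predictor_config()) {
  q <- strsplit(norm_seq(mirna_seq), "")[[1]]
  t <- strsplit(norm_seq(window), "")[[1]]
  n <- length(q); m <- length(t)
  stopifnot(n >= 6, m >= 6)
  qr <- rev(q)                       # index i -> miRNA position n - i + 1
  mpos_of <- n - seq_len(n) + 1L

  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)    # gap in miRNA (consume target)
  F <- matrix(NEG, n + 1, m + 1)    # gap in target (consume miRNA)
  sub <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m))
    sub[i, j] <- pair_sub_score(qr[i], t[j], mpos_of[i], cfg)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] + cfg$gap_open, E[i, j - 1] + cfg$gap_extend)
      F[i, j] <- max(H[i - 1, j] + cfg$gap_open, F[i - 1, j] + cfg$gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub[i - 1, j - 1], E[i, j], F[i, j])
    }
  }
  best <- max(H)
  if (best <= 0)
    return(list(align_score = 0, duplex_energy = 0,
                trace = data.frame(mirna_pos = integer(0),
                                   window_pos = integer(0),
                                   pair = character(0))))
  hits <- which(H == best, arr.ind = TRUE)
  hits <- hits[order(hits[, 2], hits[, 1]), , drop = FALSE]
  i <- hits[1, 1]; j <- hits[1, 2]

  # traceback, diagonal preferred
  pairs <- list(); n_gap_runs <- 0L
  state <- "H"
  while (i > 1 || j > 1) {
    if (state == "H") {
      if (H[i, j] == 0) break
      if (i > 1 && j > 1 && H[i, j] == H[i - 1, j - 1] + sub[i - 1, j - 1]) {
        pairs[[length(pairs) + 1L]] <- c(i - 1L, j - 1L)
        i <- i - 1L; j <- j - 1L
      } else if (H[i, j] == E[i, j]) state <- "E"
      else if (H[i, j] == F[i, j]) state <- "F"
      else break
    } else if (state == "E") {
      n_gap_runs_add <- if (E[i, j] == H[i, j - 1] + cfg$gap_open) 1L else 0L
      if (n_gap_runs_add) { n_gap_runs <- n_gap_runs + 1L; state <- "H" }
      j <- j - 1L
    } else {
      n_gap_runs_add <- if (F[i, j] == H[i - 1, j] + cfg$gap_open) 1L else 0L
      if (n_gap_runs_add) { n_gap_runs <- n_gap_runs + 1L; state <- "H" }
      i <- i - 1L
    }
  }
  pr <- do.call(rbind, rev(pairs))
  mb <- qr[pr[, 1]]; tb <- t[pr[, 2]]
  cls <- ifelse(is_wc(mb, tb), "wc", ifelse(is_wobble(mb, tb), "gu", "mm"))
  energy <- sum(mapply(pair_energy, mb, tb, MoreArgs = list(cfg = cfg))) +
    cfg$gap_energy * n_gap_runs
  list(align_score = best, duplex_energy = unname(energy),
       trace = data.frame(mirna_pos = mpos_of[pr[, 1]],
                          window_pos = pr[, 2], pair = cls,
                          stringsAsFactors = FALSE))
}

SEED_BASELINE <- c(`8mer` = -0.31, `7mer-m8` = -0.16,
                   `7mer-A1` = -0.10, `6mer` = -0.03)

#' Seed-match and context-style binding score
#'
#' Finds canonical seed matches (6mer = complement of miRNA positions
#' 2-7; 7mer-m8 adds the position-8 pair on the target 5' side; 7mer-A1
#' adds an A opposite position 1 on the target 3' side; 8mer has both)
#' and scores the best site as
#' `baseline(seed_type) + au_term + pairing3p_term`, where `au_term` is
#' -0.25 times the A/U fraction of the up-to-10 window bases flanking
#' the seed match and `pairing3p_term` is -0.02 per base of the longest
#' complementary run between miRNA positions 13-17 and the window 5' of
#' the site. More negative means stronger. Among equally strong seed
#' types the 5'-most site is taken.
#'
#' @param mirna_seq Mature miRNA sequence, 5'->3'.
#' @param extended_window Target window with upstream padding, 5'->3'.
#' @return List with `seed_type` (`"8mer"`, `"7mer-m8"`, `"7mer-A1"`,
#'   `"6mer"` or `"none"`) and `context_score` (0 when no seed match).
#' @export
targetscan_like_score <- function(mirna_seq, extended_window) {
  m <- strsplit(norm_seq(mirna_seq), "")[[1]]
  W <- norm_seq(extended_window)
  wb <- strsplit(W, "")[[1]]
  L <- length(wb)
  if (length(m) < 8 || L < 6)
    return(list(seed_type = "none", context_score = 0))
  seed6 <- revcomp(paste(m[2:7], collapse = ""))
  m8c <- COMPLEMENT[[m[8]]]

  starts <- c(); k <- 1L
  repeat {
    p <- regexpr(seed6, substr(W, k, L), fixed = TRUE)
    if (p < 0) break
    starts <- c(starts, k + as.integer(p) - 1L)
    k <- k + as.integer(p)
    if (k > L) break
  }
  if (length(starts) == 0)
    return(list(seed_type = "none", context_score = 0))

  strength <- c(`6mer` = 1, `7mer-A1` = 2, `7mer-m8` = 3, `8mer` = 4)
  best <- NULL
  for (p in starts) {   # p = 1-based start of the 6mer match in W
    has_m8 <- p >= 2 && wb[p - 1] == m8c
    has_a1 <- p + 6 <= L && wb[p + 6] == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
            else if (has_a1) "7mer-A1" else "6mer"
    if (is.null(best) || strength[[type]] > strength[[best$type]])
      best <- list(p = p, type = type, has_m8 = has_m8)
  }
  p <- best$p
  site_start <- if (best$has_m8) p - 1L else p
  site_end <- if (best$type %in% c("7mer-A1", "8mer")) p + 6L else p + 5L
  up_idx <- if (site_start > 1)
    seq(max(1L, site_start - 5L), site_start - 1L) else integer(0)
  dn_idx <- if (site_end < L)
    seq(site_end + 1L, min(L, site_end + 5L)) else integer(0)
  flank_idx <- c(up_idx, dn_idx)
  au_frac <- if (length(flank_idx) == 0) 0 else
    mean(wb[flank_idx] %in% c("A", "T"))
  up_region <- if (site_start > 1) substr(W, 1, site_start - 1L) else ""
  p3 <- longest_complementary_run(paste(m[13:min(17, length(m))],
                                        collapse = ""), up_region)
  score <- SEED_BASELINE[[best$type]] - 0.25 * au_frac - 0.02 * p3
  list(seed_type = best$type, context_score = unname(score))
}

# length of the longest contiguous substring of revcomp(mir_part)
# occurring in region (0 when either side is empty)
longest_complementary_run <- function(mir_part, region) {
  if (nchar(mir_part) == 0 || nchar(region) == 0) return(0L)
  rc <- revcomp(mir_part)
  n <- nchar(rc)
  for (len in seq(n, 1)) {
    for (s in seq_len(n - len + 1)) {
      if (grepl(substr(rc, s, s + len - 1), region, fixed = TRUE))
        return(len)
    }
  }
  0L
}

score_window <- function(mirna_seq, window, extended_window, cfg) {
  al <- miranda_like_score(mirna_seq, window, cfg)
  ts <- targetscan_like_score(mirna_seq, extended_window)
  passes_miranda <- al$align_score > cfg$score_min &&
    al$duplex_energy < cfg$energy_max
  passes_targetscan <- ts$seed_type != "none" &&
    ts$context_score < cfg$context_max
  present <- if (cfg$combine_rule == "both")
    passes_miranda && passes_targetscan else passes_miranda || passes_targetscan
  list(align_score = al$align_score, duplex_energy = al$duplex_energy,
       context_score = ts$context_score, seed_type = ts$seed_type,
       passes_miranda = passes_miranda, passes_targetscan = passes_targetscan,
       present = present)
}

#' Score all miRNAs against a control/mutant window pair
#'
#' Both windows of a context pair are scored for every miRNA in the
#' catalog; miRNAs whose site is absent from both windows are omitted.
#'
#' @param ctx A context pair from [build_context()].
#' @param mirnas Named character vector of mature miRNA sequences.
#' @param cfg A [predictor_config()].
#' @return Data frame, one row per retained miRNA, with control_* and
#'   mutant_* score columns, pass flags and presence flags.
#' @export
call_sites <- function(ctx, mirnas, cfg = predictor_config()) {
  stopifnot(length(mirnas) > 0)
  rows <- lapply(names(mirnas), function(id) {
    ctl <- score_window(mirnas[[id]], ctx$control_seq,
                        ctx$extended_control_seq, cfg)
    mut <- score_window(mirnas[[id]], ctx$mutant_seq,
                        ctx$extended_mutant_seq, cfg)
    if (!ctl$present && !mut$present) return(NULL)
    data.frame(mutation_key = ctx$mutation_key,
               transcript_id = ctx$transcript_id,
               gene_id = ctx$gene_id,
               mirna_id = id,
               control_align = ctl$align_score, control_energy = ctl$duplex_energy,
               control_context = ctl$context_score, control_seed = ctl$seed_type,
               control_present = ctl$present,
               mutant_align = mut$align_score, mutant_energy = mut$duplex_energy,
               mutant_context = mut$context_score, mutant_seed = mut$seed_type,
               mutant_present = mut$present,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(mutation_key = character(0), transcript_id = character(0),
                      gene_id = character(0), mirna_id = character(0),
                      control_align = numeric(0), control_energy = numeric(0),
                      control_context = numeric(0), control_seed = character(0),
                      control_present = logical(0),
                      mutant_align = numeric(0), mutant_energy = numeric(0),
                      mutant_context = numeric(0), mutant_seed = character(0),
                      mutant_present = logical(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Import externally produced prediction tables
#'
#' Adapter so real alignment-based or seed/context-based predictor
#' output can replace the built-in scorers. Thresholds from `cfg` are
#' applied identically to imported scores. Rows are keyed by
#' `(mutation_key, window_kind, mirna_id)`; a missing mutant (or
#' control) row is treated as site absent in that window.
#'
#' @param path TSV file. Dialect `"miranda_tab"` needs columns
#'   `mutation_key`, `window_kind` (control/mutant), `mirna_id`,
#'   `align_score`, `duplex_energy`; dialect `"targetscan_tab"` needs
#'   `mutation_key`, `window_kind`, `mirna_id`, `seed_type`,
#'   `context_score`.
#' @param dialect One of `"miranda_tab"`, `"targetscan_tab"`.
#' @param cfg A [predictor_config()].
#' @return Data frame keyed by (mutation_key, mirna_id) with control_*
#'   and mutant_* columns for the imported predictor plus pass flags.
#' @export
import_external_predictions <- function(path,
                                        dialect = c("miranda_tab",
                                                    "targetscan_tab"),
                                        cfg = predictor_config()) {
  dialect <- match.arg(dialect)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- switch(dialect,
    miranda_tab = c("mutation_key", "window_kind", "mirna_id",
                    "align_score", "duplex_energy"),
    targetscan_tab = c("mutation_key", "window_kind", "mirna_id",
                       "seed_type", "context_score"))
  if (!all(need %in% names(raw)))
    stop("missing column(s) for dialect ", dialect, ": ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  stopifnot(all(raw$window_kind %in% c("control", "mutant")))
  keys <- unique(raw[c("mutation_key", "mirna_id")])
  get <- function(k, kind, col, default) {
    i <- which(raw$mutation_key == k[1] & raw$mirna_id == k[2] &
                 raw$window_kind == kind)
    if (length(i) == 0) default else raw[[col]][i[1]]
  }
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(r) {
    k <- c(keys$mutation_key[r], keys$mirna_id[r])
    if (dialect == "miranda_tab") {
      ca <- get(k, "control", "align_score", 0)
      ce <- get(k, "control", "duplex_energy", 0)
      ma <- get(k, "mutant", "align_score", 0)
      me <- get(k, "mutant", "duplex_energy", 0)
      data.frame(mutation_key = k[1], mirna_id = k[2],
                 control_align = ca, control_energy = ce,
                 mutant_align = ma, mutant_energy = me,
                 control_passes = ca > cfg$score_min & ce < cfg$energy_max,
                 mutant_passes = ma > cfg$score_min & me < cfg$energy_max,
                 stringsAsFactors = FALSE)
    } else {
      cs <- get(k, "control", "context_score", 0)
      ct <- get(k, "control", "seed_type", "none")
      ms <- get(k, "mutant", "context_score", 0)
      mt <- get(k, "mutant", "seed_type", "none")
      data.frame(mutation_key = k[1], mirna_id = k[2],
                 control_context = cs, control_seed = ct,
                 mutant_context = ms, mutant_seed = mt,
                 control_passes = ct != "none" & cs < cfg$context_max,
                 mutant_passes = mt != "none" & ms < cfg$context_max,
                 stringsAsFactors = FALSE)
    }
  }))
  rownames(out) <- NULL
  out
}
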