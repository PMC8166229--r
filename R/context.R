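COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", U = "A", N = "N")

#' Reverse complement of a DNA/RNA string
#'
#' U is treated as T; output is in DNA letters.
#' @param s Single sequence string.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(s) {
  if (nchar(s) == 0) return(s)
  chars <- rev(strsplit(toupper(chartr("U", "T", s)), "")[[1]])
  paste(COMPLEMENT[chars], collapse = "")
}

#' Spliced transcript sequence
#'
#' Concatenates exon sequences 5'->3' in transcript orientation; minus
#' strand transcripts are reverse-complemented.
#'
#' @param tx A transcript model (see [read_gtf()]).
#' @param genome Named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences.
#' @return The spliced sequence as an uppercase DNA string.
#' @export
spliced_sequence <- function(tx, genome) {
  chrom_seq <- genome_chrom(genome, tx$chrom)
  parts <- apply(tx$exons, 1, function(e) substr(chrom_seq, e[1], e[2]))
  s <- toupper(paste(parts, collapse = ""))
  if (tx$strand == "-") revcomp(s) else s
}

genome_chrom <- function(genome, chrom) {
  if (inherits(genome, "DNAStringSet")) {
    if (!chrom %in% names(genome)) stop("chromosome ", chrom, " absent from genome")
    return(as.character(genome[[chrom]]))
  }
  if (!chrom %in% names(genome)) stop("chromosome ", chrom, " absent from genome")
  as.character(genome[[chrom]])
}

#' Map a genomic position into transcript coordinates
#'
#' @param tx Transcript model.
#' @param chrom Chromosome name.
#' @param pos 1-based genomic position.
#' @return 0-based offset into the spliced transcript, or `NA` when the
#'   position is intronic, intergenic or on another chromosome.
#' @export
genomic_to_transcript <- function(tx, chrom, pos) {
  if (chrom != tx$chrom) return(NA_integer_)
  ex <- tx$exons
  hit <- which(pos >= ex[, "start"] & pos <= ex[, "end"])
  if (length(hit) == 0) return(NA_integer_)
  hit <- hit[1]
  lens <- ex[, "end"] - ex[, "start"] + 1L
  before <- if (hit > 1) sum(lens[seq_len(hit - 1)]) else 0L
  plus_off <- as.integer(before + (pos - ex[hit, "start"]))
  if (tx$strand == "-") tx$spliced_length - 1L - plus_off else plus_off
}

#' Inverse of [genomic_to_transcript()]
#'
#' @param tx Transcript model.
#' @param tx_pos 0-based transcript offset.
#' @return 1-based genomic position.
#' @export
transcript_to_genomic <- function(tx, tx_pos) {
  if (tx$strand == "-") tx_pos <- tx$spliced_length - 1L - tx_pos
  ex <- tx$exons
  lens <- ex[, "end"] - ex[, "start"] + 1L
  cum <- cumsum(lens)
  hit <- which(tx_pos < cum)[1]
  before <- if (hit > 1) cum[hit - 1] else 0L
  as.integer(ex[hit, "start"] + (tx_pos - before))
}

#' Build control/mutant sequence windows around one mutation
#'
#' Extracts the wild-type (control) transcript-space window of `flank`
#' nucleotides on either side of the mutated span and the corresponding
#' mutant window with the edit applied, plus extended windows padded
#' upstream to `upstream_ext` nucleotides for the context-style scorer.
#' Alleles in the mutation record are on the + genomic strand and are
#' reverse-complemented for minus-strand transcripts. Windows are
#' truncated (and flagged) at transcript ends.
#'
#' @param tx Transcript model whose exons contain the mutation.
#' @param genome Genome accessor as in [spliced_sequence()].
#' @param m One-row mutation record (data frame row or list).
#' @param flank Flank width per side in nt (default 7).
#' @param upstream_ext Upstream padding in nt for the extended window
#'   (default 14).
#' @return A context pair (list) with fields `mutation_key`,
#'   `transcript_id`, `gene_id`, `center_tx_pos`, `control_seq`,
#'   `mutant_seq`, `extended_control_seq`, `extended_mutant_seq`,
#'   `truncated_5p`, `truncated_3p`, `ref_tx`, `alt_tx`; or, when the
#'   mutation cannot be placed on this transcript, a list with
#'   `dropped = TRUE` and `reason` (`"unmapped"` or `"ref_mismatch"`).
#' @export
build_context <- function(tx, genome, m, flank = 7L, upstream_ext = 14L) {
  stopifnot(flank >= 1L, upstream_ext >= flank)
  ref <- if (m$ref_allele == "-") "" else m$ref_allele
  alt <- if (m$alt_allele == "-") "" else m$alt_allele
  txseq <- spliced_sequence(tx, genome)
  L <- nchar(txseq)

  dropped <- function(reason) list(dropped = TRUE, reason = reason)

  if (nchar(ref) > 0) {
    g_positions <- m$pos + seq_len(nchar(ref)) - 1L
    t_positions <- vapply(g_positions, function(p)
      genomic_to_transcript(tx, m$chrom, p), integer(1))
    if (anyNA(t_positions)) return(dropped("unmapped"))
    t_positions <- sort(t_positions)
    if (!all(diff(t_positions) == 1L)) return(dropped("unmapped"))
    center <- t_positions[1]
    ref_tx <- if (tx$strand == "-") revcomp(ref) else ref
    alt_tx <- if (tx$strand == "-") revcomp(alt) else alt
    if (substr(txseq, center + 1L, center + nchar(ref_tx)) != ref_tx)
      return(dropped("ref_mismatch"))
    ref_len <- nchar(ref_tx)
  } else {
    # insertion: pos is the base immediately 5' (on + strand) of the insert
    t_anchor <- genomic_to_transcript(tx, m$chrom, m$pos)
    if (is.na(t_anchor)) return(dropped("unmapped"))
    # insert goes 3' of pos on + strand; in transcript space that is
    # after t(pos) on +, before t(pos) on - (i.e. after t(pos+1))
    center <- if (tx$strand == "-") t_anchor else t_anchor + 1L
    ref_tx <- ""
    alt_tx <- if (tx$strand == "-") revcomp(alt) else alt
    ref_len <- 0L
  }

  w_start <- max(0L, center - flank)               # 0-based half-open
  w_end <- min(L, center + ref_len + flank)
  e_start <- max(0L, center - upstream_ext)
  control <- substr(txseq, w_start + 1L, w_end)
  ext_control <- substr(txseq, e_start + 1L, w_end)
  edit <- function(win, start0) {
    off <- center - start0
    paste0(substr(win, 1L, off), alt_tx,
           substr(win, off + ref_len + 1L, nchar(win)))
  }
  list(mutation_key = m$mutation_key,
       transcript_id = tx$transcript_id,
       gene_id = tx$gene_id,
       center_tx_pos = center,
       control_seq = control,
       mutant_seq = edit(control, w_start),
       extended_control_seq = ext_control,
       extended_mutant_seq = edit(ext_control, e_start),
       truncated_5p = w_start > center - flank,
       truncated_3p = w_end < center + ref_len + flank,
       ref_tx = ref_tx, alt_tx = alt_tx)
}

#' Build context pairs for all mutation x transcript combinations
#'
#' Maps every mutation onto every transcript whose exons contain it; one
#' context pair per (mutation, transcript). Unmappable mutations and
#' reference mismatches are dropped and tallied.
#'
#' @param mutations Mutation data frame from [read_mutations()];
#'   duplicate carrier rows of the same site are collapsed first.
#' @param transcripts List of transcript models.
#' @param genome Genome accessor.
#' @inheritParams build_context
#' @return List of context pairs with attribute `drop_counts`, a named
#'   integer vector over drop reasons.
#' @export
build_contexts <- function(mutations, transcripts, genome,
                           flank = 7L, upstream_ext = 14L) {
  sites <- mutations[!duplicated(mutations$mutation_key), , drop = FALSE]
  out <- list()
  drops <- c(unmapped = 0L, ref_mismatch = 0L)
  for (i in seq_len(nrow(sites))) {
    m <- sites[i, ]
    mapped <- FALSE; mismatched <- FALSE
    for (tx in transcripts) {
      ctx <- build_context(tx, genome, m, flank, upstream_ext)
      if (isTRUE(ctx$dropped)) {
        if (identical(ctx$reason, "ref_mismatch")) mismatched <- TRUE
        next
      }
      mapped <- TRUE
      out[[length(out) + 1L]] <- ctx
    }
    if (!mapped) {
      reason <- if (mismatched) "ref_mismatch" else "unmapped"
      drops[reason] <- drops[reason] + 1L
    }
  }
  attr(out, "drop_counts") <- drops
  out
}
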