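#' @keywords internal
"_PACKAGE"

ALLELE_RE <- "^([ACGT]+|-)$"

#' Read a somatic mutation table
#'
#' Reads a MAF-style or simple TSV mutation table into a validated
#' data frame of mutation records. Coordinates are kept 1-based genomic;
#' a `"-"` allele denotes the absent allele of an insertion or deletion
#' (MAF convention; for insertions `pos` is the base immediately 5' of
#' the inserted sequence).
#'
#' Malformed rows (non-numeric position, illegal allele characters, both
#' alleles `"-"`) are skipped and counted rather than aborting the read.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect `"simple_tsv"` expects columns `sample_id`,
#'   `cancer_type`, `chrom`, `pos`, `ref`, `alt`; `"maf_min"` expects the
#'   minimal MAF columns `Tumor_Sample_Barcode`, `Chromosome`,
#'   `Start_Position`, `Reference_Allele`, `Tumor_Seq_Allele2` plus a
#'   `Cancer_Type` column.
#' @return A data frame with columns `sample_id`, `cancer_type`, `chrom`,
#'   `pos`, `ref_allele`, `alt_allele`, `variant_class` (SNV/INS/DEL/MNV)
#'   and `mutation_key`; attribute `n_dropped` counts skipped rows.
#' @export
read_mutations <- function(path, dialect = c("simple_tsv", "maf_min")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  # force character columns: an allele column of all T/F letters would
  # otherwise be read as logical
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  cols <- switch(dialect,
    simple_tsv = c(sample_id = "sample_id", cancer_type = "cancer_type",
                   chrom = "chrom", pos = "pos", ref = "ref", alt = "alt"),
    maf_min = c(sample_id = "Tumor_Sample_Barcode", cancer_type = "Cancer_Type",
                chrom = "Chromosome", pos = "Start_Position",
                ref = "Reference_Allele", alt = "Tumor_Seq_Allele2"))
  missing_cols <- setdiff(unname(cols), names(raw))
  if (length(missing_cols) > 0)
    stop("mutation table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- data.frame(
    sample_id   = as.character(raw[[cols["sample_id"]]]),
    cancer_type = as.character(raw[[cols["cancer_type"]]]),
    chrom       = as.character(raw[[cols["chrom"]]]),
    pos         = suppressWarnings(as.integer(raw[[cols["pos"]]])),
    ref_allele  = toupper(as.character(raw[[cols["ref"]]])),
    alt_allele  = toupper(as.character(raw[[cols["alt"]]])),
    stringsAsFactors = FALSE)
  ok <- !is.na(df$pos) & df$pos >= 1 &
    grepl(ALLELE_RE, df$ref_allele) & grepl(ALLELE_RE, df$alt_allele) &
    !(df$ref_allele == "-" & df$alt_allele == "-") &
    nzchar(df$sample_id) & nzchar(df$chrom)
  n_dropped <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0) stop("no valid mutation rows in ", path)
  df$variant_class <- infer_variant_class(df$ref_allele, df$alt_allele)
  df$mutation_key <- mutation_key(df$chrom, df$pos, df$ref_allele, df$alt_allele)
  rownames(df) <- NULL
  attr(df, "n_dropped") <- n_dropped
  df
}

infer_variant_class <- function(ref, alt) {
  ifelse(ref == "-", "INS",
    ifelse(alt == "-", "DEL",
      ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV", "MNV")))
}

#' Canonical mutation site key
#'
#' `chrom:pos:ref:alt`; used both as a row identifier and as the
#' per-cancer recurrence unit for the high/low-frequency split.
#' @param chrom,pos,ref,alt Vectors describing mutation sites.
#' @return Character vector of keys.
#' @export
mutation_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Read transcript models from a GTF file
#'
#' Parses exon features of a GENCODE-dialect GTF into per-transcript
#' models. Exons are stored sorted by genomic start regardless of strand;
#' orientation is handled downstream.
#'
#' @param path Path to a GTF file with `exon` features carrying
#'   `transcript_id` and `gene_id` attributes.
#' @param biotype_filter Optional character vector; only transcripts whose
#'   biotype (from `transcript_type`, `gene_type`, `transcript_biotype` or
#'   `gene_biotype`) is in this set are kept.
#' @return Named list of transcript models, each a list with
#'   `transcript_id`, `gene_id`, `gene_name`, `biotype`, `chrom`,
#'   `strand`, `exons` (2-column matrix of 1-based inclusive start/end,
#'   sorted) and `spliced_length`.
#' @export
read_gtf <- function(path, biotype_filter = NULL) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) stop("no exon features in ", path)
  meta <- as.data.frame(gr)
  pick <- function(nms) {
    for (nm in nms) if (nm %in% names(meta)) return(as.character(meta[[nm]]))
    rep(NA_character_, nrow(meta))
  }
  meta$..biotype <- pick(c("transcript_type", "transcript_biotype",
                           "gene_type", "gene_biotype"))
  meta$..gene_name <- pick("gene_name")
  keep <- if (is.null(biotype_filter)) rep(TRUE, nrow(meta)) else
    meta$..biotype %in% biotype_filter
  meta <- meta[keep, , drop = FALSE]
  if (nrow(meta) == 0) return(structure(list(), names = character(0)))
  split_idx <- split(seq_len(nrow(meta)), meta$transcript_id)
  txs <- lapply(split_idx, function(i) {
    sub <- meta[i, , drop = FALSE]
    exons <- cbind(start = sub$start, end = sub$end)
    exons <- exons[order(exons[, "start"]), , drop = FALSE]
    list(transcript_id = sub$transcript_id[1],
         gene_id = as.character(sub$gene_id[1]),
         gene_name = sub$..gene_name[1],
         biotype = sub$..biotype[1],
         chrom = as.character(sub$seqnames[1]),
         strand = as.character(sub$strand[1]),
         exons = exons,
         spliced_length = sum(exons[, "end"] - exons[, "start"] + 1L))
  })
  txs
}

#' Read an FPKM expression matrix
#'
#' First column holds gene/miRNA identifiers, remaining columns samples.
#' Duplicate identifier rows are collapsed by their mean (TCGA-style
#' matrices contain duplicated symbols); negative values violate the
#' FPKM invariant and abort.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix (rows = entities, columns = samples) with an
#'   `n_collapsed` attribute giving the number of duplicate rows merged.
#' @export
read_expression <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(raw[[1]])
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(raw[-1], is.numeric, logical(1)))
    stop("non-numeric expression values in column(s): ",
         paste(names(raw)[-1][bad], collapse = ", "))
  }
  if (anyNA(vals)) stop("missing expression values in ", path)
  if (any(vals < 0)) stop("negative expression values violate FPKM units")
  n_collapsed <- sum(duplicated(ids))
  if (n_collapsed > 0) {
    sums <- rowsum(vals, group = ids)
    vals <- sums / as.vector(table(ids)[rownames(sums)])
  } else {
    rownames(vals) <- ids
  }
  attr(vals, "n_collapsed") <- n_collapsed
  vals
}

#' Read a validated miRNA-target interaction table
#'
#' @param path TSV with columns `mirna_id`, `target_gene_id` and
#'   optionally `evidence`.
#' @return Data frame with unique `(mirna_id, target_gene_id)` pairs;
#'   attribute `n_duplicates` counts removed duplicates.
#' @export
read_interactions <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("mirna_id", "target_gene_id") %in% names(raw)))
  if (!"evidence" %in% names(raw)) raw$evidence <- NA_character_
  dup <- duplicated(raw[c("mirna_id", "target_gene_id")])
  out <- raw[!dup, c("mirna_id", "target_gene_id", "evidence"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_duplicates") <- sum(dup)
  out
}

#' Read a clinical follow-up table
#'
#' @param path TSV with columns `sample_id`, `time` (days), `event`
#'   (0 = censored, 1 = death) and optionally `stage`.
#' @return Data frame of valid rows; rows with negative time or
#'   non-binary event are skipped and counted in attribute `n_dropped`.
#' @export
read_clinical <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "time", "event") %in% names(raw)))
  if (!"stage" %in% names(raw)) raw$stage <- NA_character_
  time <- suppressWarnings(as.numeric(raw$time))
  event <- suppressWarnings(as.integer(raw$event))
  ok <- !is.na(time) & time >= 0 & !is.na(event) & event %in% c(0L, 1L)
  out <- data.frame(sample_id = as.character(raw$sample_id[ok]),
                    time = time[ok], event = event[ok],
                    stage = as.character(raw$stage[ok]),
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Read a GMT gene-set file
#'
#' Each line: set name, description, then member genes, tab-separated.
#' @param path Path to a GMT file.
#' @return Named list of character vectors of unique member genes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Write a data frame as a TSV output table
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a ceRNA network edge list
#'
#' Emits ceL--miRNA and miRNA--ceM edges of SMILM units as a 3-column
#' edge list loadable by graph viewers.
#'
#' @param units SMILM unit data frame (see [assemble_units()]).
#' @param path Output TSV path.
#' @return The edge-list data frame, invisibly.
#' @export
export_network <- function(units, path = NULL) {
  e1 <- unique(data.frame(source = units$ceL, target = units$mirna_id,
                          edge_type = "ceL-miRNA", stringsAsFactors = FALSE))
  e2 <- unique(data.frame(source = units$mirna_id, target = units$ceM,
                          edge_type = "miRNA-ceM", stringsAsFactors = FALSE))
  edges <- rbind(e1, e2)
  if (!is.null(path)) write_tsv(edges, path)
  invisible(edges)
}
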