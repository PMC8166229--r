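# toy locus: chrT = 5' pad (10) + exon1 (pos 11-13 "ACG") + intron +
# exon2 (pos 17-18 "TT") + 3' pad
toy_genome <- c(chrT = "AAAAAAAAAAACGXXXTTAAAAAAA")

test_that("spliced sequence concatenates exons and honours strand", {
  tx_p <- toy_tx(list(c(11, 13), c(17, 18)), "+")
  tx_m <- toy_tx(list(c(11, 13), c(17, 18)), "-")
  expect_equal(spliced_sequence(tx_p, toy_genome), "ACGTT")
  expect_equal(spliced_sequence(tx_m, toy_genome), "AACGT")
  expect_equal(nchar(spliced_sequence(tx_p, toy_genome)),
               tx_p$spliced_length)
  expect_error(spliced_sequence(toy_tx(list(c(1, 3)), chrom = "chrZ"),
                                toy_genome), "absent")
})

test_that("genomic positions map to transcript offsets with orientation", {
  tx_p <- toy_tx(list(c(11, 13), c(17, 18)), "+")
  tx_m <- toy_tx(list(c(11, 13), c(17, 18)), "-")
  expect_equal(genomic_to_transcript(tx_p, "chrT", 11), 0L)
  expect_equal(genomic_to_transcript(tx_p, "chrT", 17), 3L)
  expect_equal(genomic_to_transcript(tx_m, "chrT", 11), 4L)  # spliced_len-1
  expect_true(is.na(genomic_to_transcript(tx_p, "chrT", 15))) # intronic
  expect_true(is.na(genomic_to_transcript(tx_p, "chrQ", 11)))
  # inverse mapping round-trips every exonic offset on both strands
  for (tx in list(tx_p, tx_m)) {
    for (off in 0:4)
      expect_equal(genomic_to_transcript(tx, "chrT",
                                         transcript_to_genomic(tx, off)), off)
  }
})

make_locus <- function(seq20, strand = "+") {
  # single-exon 20-nt transcript at genomic 1..20
  genome <- c(chrT = if (strand == "+") seq20 else smilm::revcomp(seq20))
  list(tx = toy_tx(list(c(1, 20)), strand), genome = genome)
}

test_that("SNV windows have the documented geometry", {
  s <- "ACGTACGTACGTACGTACGT"
  loc <- make_locus(s)
  m <- toy_mutation("chrT", 10, substr(s, 10, 10), "A")
  ctx <- build_context(loc$tx, loc$genome, m, flank = 7)
  expect_equal(nchar(ctx$control_seq), 15)
  expect_equal(nchar(ctx$mutant_seq), 15)
  diffs <- which(strsplit(ctx$control_seq, "")[[1]] !=
                   strsplit(ctx$mutant_seq, "")[[1]])
  expect_equal(diffs, 8)  # offset 7, 1-based 8
  expect_false(ctx$truncated_5p || ctx$truncated_3p)
  # the 20-nt transcript only offers 9 upstream bases at position 10
  expect_equal(nchar(ctx$extended_control_seq), 9 + 1 + 7)
  # with room, the extended window adds exactly upstream_ext - flank bases
  s40 <- paste(rep("ACGT", 10), collapse = "")
  loc40 <- list(tx = toy_tx(list(c(1, 40))), genome = c(chrT = s40))
  m25 <- toy_mutation("chrT", 25, substr(s40, 25, 25), "T")
  ctx40 <- build_context(loc40$tx, loc40$genome, m25)
  expect_equal(nchar(ctx40$extended_control_seq), 14 + 1 + 7)
})

test_that("deletion and insertion windows keep length bookkeeping", {
  s <- "ACGTACGTACGTACGTACGT"
  loc <- make_locus(s)
  del <- toy_mutation("chrT", 10, substr(s, 10, 10), "-")
  ctx <- build_context(loc$tx, loc$genome, del)
  expect_equal(nchar(ctx$control_seq), 15)
  expect_equal(nchar(ctx$mutant_seq), 14)
  ins <- toy_mutation("chrT", 10, "-", "GG")
  ctx2 <- build_context(loc$tx, loc$genome, ins)
  expect_equal(nchar(ctx2$control_seq), 14)  # no ref base in the window
  expect_equal(nchar(ctx2$mutant_seq), 16)
})

test_that("windows truncate (and flag) at transcript ends", {
  s <- "ACGTACGTACGTACGTACGT"
  loc <- make_locus(s)
  m <- toy_mutation("chrT", 4, substr(s, 4, 4), "A")  # 3 nt of 5' flank
  ctx <- build_context(loc$tx, loc$genome, m)
  expect_equal(nchar(ctx$control_seq), 3 + 1 + 7)
  expect_true(ctx$truncated_5p)
  expect_false(ctx$truncated_3p)
})

test_that("reference mismatches are dropped with a reason", {
  loc <- make_locus("ACGTACGTACGTACGTACGT")
  m <- toy_mutation("chrT", 10, "A", "G")  # true base is C
  ctx <- build_context(loc$tx, loc$genome, m)
  expect_true(ctx$dropped)
  expect_equal(ctx$reason, "ref_mismatch")
})

test_that("applying the reverse edit to the mutant window restores the control", {
  set.seed(11)
  for (r in 1:25) {
    s <- rand_dna(20)
    loc <- make_locus(s)
    pos <- sample(8:13, 1)
    kind <- sample(c("snv", "del", "ins"), 1)
    ref <- substr(s, pos, pos)
    m <- switch(kind,
      snv = toy_mutation("chrT", pos, ref, sample(setdiff(c("A","C","G","T"), ref), 1)),
      del = toy_mutation("chrT", pos, ref, "-"),
      ins = toy_mutation("chrT", pos, "-", rand_dna(2)))
    ctx <- build_context(loc$tx, loc$genome, m)
    off <- ctx$center_tx_pos - max(0, ctx$center_tx_pos - 7)
    rebuilt <- paste0(substr(ctx$mutant_seq, 1, off), ctx$ref_tx,
                      substr(ctx$mutant_seq, off + nchar(ctx$alt_tx) + 1,
                             nchar(ctx$mutant_seq)))
    expect_equal(rebuilt, ctx$control_seq)
  }
})

test_that("minus-strand windows equal plus-strand windows of the mirrored locus", {
  set.seed(12)
  for (r in 1:20) {
    s <- rand_dna(20)
    pos <- sample(8:13, 1)
    ref <- substr(s, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    # plus-strand locus with the transcript sequence s
    plus <- make_locus(s, "+")
    ctx_p <- build_context(plus$tx, plus$genome,
                           toy_mutation("chrT", pos, ref, alt))
    # minus-strand locus: genome holds revcomp(s); the same transcript-space
    # edit is the complementary allele at the mirrored genomic position
    minus <- make_locus(s, "-")
    gpos <- 20 - pos + 1
    ctx_m <- build_context(minus$tx, minus$genome,
                           toy_mutation("chrT", gpos, smilm::revcomp(ref),
                                        smilm::revcomp(alt)))
    expect_equal(ctx_m$control_seq, ctx_p$control_seq)
    expect_equal(ctx_m$mutant_seq, ctx_p$mutant_seq)
    expect_equal(ctx_m$center_tx_pos, ctx_p$center_tx_pos)
  }
})

test_that("batch context building tallies dropped and retained mutations", {
  s <- "ACGTACGTACGTACGTACGT"
  loc <- make_locus(s)
  muts <- rbind(toy_mutation("chrT", 10, "C", "A"),      # ref ok (C at 10)
                toy_mutation("chrT", 12, "A", "C"),      # ref mismatch (T at 12)
                toy_mutation("chrT", 100, "A", "C"))     # off transcript
  ctxs <- build_contexts(muts, list(loc$tx), loc$genome)
  drops <- attr(ctxs, "drop_counts")
  expect_equal(length(ctxs) + sum(drops), nrow(muts))
})
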