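write_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("mutation reader infers variant classes and keeps 1-based coordinates", {
  f <- write_tmp(c("sample_id\tcancer_type\tchrom\tpos\tref\talt",
                   "S1\tCOAD\tchr17\t80340219\tC\t-",
                   "S2\tCOAD\tchr1\t100\tA\tG",
                   "S3\tLUSC\tchr1\t200\t-\tTT",
                   "S4\tCOAD\tchr1\t300\tAC\tGT"))
  mut <- read_mutations(f)
  expect_equal(nrow(mut), 4)
  expect_equal(mut$variant_class, c("DEL", "SNV", "INS", "MNV"))
  expect_equal(mut$pos[1], 80340219L)
  expect_equal(mut$mutation_key[1], "chr17:80340219:C:-")
  expect_equal(attr(mut, "n_dropped"), 0L)
})

test_that("malformed mutation rows are skipped and counted, not fatal", {
  f <- write_tmp(c("sample_id\tcancer_type\tchrom\tpos\tref\talt",
                   "S1\tCOAD\tchr1\tx\tA\tG",      # bad position
                   "S2\tCOAD\tchr1\t10\tZ\tG",     # bad allele
                   "S3\tCOAD\tchr1\t10\t-\t-",     # double dash
                   "S4\tCOAD\tchr1\t10\tA\tG"))
  mut <- read_mutations(f)
  expect_equal(nrow(mut), 1)
  expect_equal(attr(mut, "n_dropped"), 3L)
  expect_equal(nrow(mut) + attr(mut, "n_dropped"), 4L)
})

test_that("mutation reader fails fast on missing columns or no valid rows", {
  f <- write_tmp(c("sample_id\tchrom\tpos", "S1\tchr1\t5"))
  expect_error(read_mutations(f), "missing required column")
  f2 <- write_tmp(c("sample_id\tcancer_type\tchrom\tpos\tref\talt",
                    "S1\tCOAD\tchr1\tx\tA\tG"))
  expect_error(read_mutations(f2), "no valid mutation rows")
})

test_that("maf_min dialect maps MAF column names", {
  f <- write_tmp(paste(
    c("Tumor_Sample_Barcode\tCancer_Type\tChromosome\tStart_Position\tReference_Allele\tTumor_Seq_Allele2",
      "TCGA-01\tCOAD\tchr2\t500\tG\tT")))
  mut <- read_mutations(f, dialect = "maf_min")
  expect_equal(mut$sample_id, "TCGA-01")
  expect_equal(mut$variant_class, "SNV")
})

test_that("GTF reader builds sorted exon models and honours the biotype filter", {
  gtf <- c(
    paste("chr1\tsim\texon\t201\t230\t.\t+\t.",
          'gene_id "G1"; transcript_id "T1"; gene_type "lncRNA"; transcript_type "lncRNA";',
          sep = "\t"),
    paste("chr1\tsim\texon\t101\t150\t.\t+\t.",
          'gene_id "G1"; transcript_id "T1"; gene_type "lncRNA"; transcript_type "lncRNA";',
          sep = "\t"),
    paste("chr1\tsim\texon\t301\t400\t.\t-\t.",
          'gene_id "G2"; transcript_id "T2"; gene_type "protein_coding"; transcript_type "protein_coding";',
          sep = "\t"))
  f <- write_tmp(gtf, ".gtf")
  txs <- read_gtf(f)
  expect_equal(sort(names(txs)), c("T1", "T2"))
  expect_equal(txs$T1$exons[, "start"], c(101, 150 + 51))
  expect_true(all(diff(txs$T1$exons[, "start"]) > 0))
  expect_equal(txs$T1$spliced_length, 50L + 30L)
  expect_equal(txs$T2$strand, "-")
  only_lnc <- read_gtf(f, biotype_filter = "lncRNA")
  expect_equal(names(only_lnc), "T1")
})

test_that("expression reader collapses duplicates by mean and enforces FPKM sign", {
  f <- write_tmp(c("gene_id\tS1\tS2", "G1\t1\t10", "G1\t3\t20", "G2\t5\t6"))
  m <- read_expression(f)
  expect_equal(m["G1", ], c(S1 = 2, S2 = 15))
  expect_equal(attr(m, "n_collapsed"), 1L)
  f2 <- write_tmp(c("gene_id\tS1", "G1\t-1"))
  expect_error(read_expression(f2), "negative")
  f3 <- write_tmp(c("gene_id\tS1", "G1\tabc"))
  expect_error(read_expression(f3), "non-numeric")
})

test_that("interaction, clinical and GMT readers enforce their invariants", {
  fi <- write_tmp(c("mirna_id\ttarget_gene_id", "miR-1\tG1", "miR-1\tG1",
                    "miR-1\tG2"))
  ia <- read_interactions(fi)
  expect_equal(nrow(ia), 2)
  expect_equal(attr(ia, "n_duplicates"), 1L)

  fc <- write_tmp(c("sample_id\ttime\tevent", "S1\t100\t1", "S2\t-1\t0",
                    "S3\t50\t2"))
  cl <- read_clinical(fc)
  expect_equal(cl$sample_id, "S1")
  expect_equal(attr(cl, "n_dropped"), 2L)

  fg <- write_tmp(c("SET_A\tdesc\tG1\tG2", "SET_B\tdesc\tG3"), ".gmt")
  gs <- read_gmt(fg)
  expect_equal(gs, list(SET_A = c("G1", "G2"), SET_B = "G3"))
})

test_that("tables round-trip through write_tsv and their reader", {
  f <- tempfile(fileext = ".tsv")
  df <- data.frame(mirna_id = c("miR-1", "miR-2"),
                   target_gene_id = c("G1", "G2"),
                   evidence = c("Luciferase", "PCR"), stringsAsFactors = FALSE)
  write_tsv(df, f)
  back <- read_interactions(f)
  attr(back, "n_duplicates") <- NULL
  expect_equal(back, df)
})

test_that("network export emits both edge layers", {
  units <- data.frame(ceL = c("L1", "L1"), mirna_id = c("m1", "m1"),
                      ceM = c("M1", "M2"), stringsAsFactors = FALSE)
  edges <- export_network(units)
  expect_equal(nrow(edges), 3)  # 1 ceL-miRNA + 2 miRNA-ceM
  expect_setequal(unique(edges$edge_type), c("ceL-miRNA", "miRNA-ceM"))
})
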