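cfg <- predictor_config()

test_that("a perfect complement of miRNA bases 1-15 scores 7*5*4 + 8*5 = 180", {
  set.seed(3)
  for (r in 1:5) {
    m <- rand_dna(22)
    window <- revcomp(substr(m, 1, 15))
    res <- miranda_like_score(m, window, cfg)
    expect_equal(res$align_score, 180)
    expect_equal(nrow(res$trace), 15)
    expect_true(all(res$trace$pair == "wc"))
    # duplex energy is the per-pair sum with no gaps
    counts <- table(strsplit(substr(m, 1, 15), "")[[1]] %in% c("G", "C"))
    expected <- -3 * sum(strsplit(substr(m, 1, 15), "")[[1]] %in% c("G", "C")) -
      2 * sum(!strsplit(substr(m, 1, 15), "")[[1]] %in% c("G", "C"))
    expect_equal(res$duplex_energy, expected)
  }
})

test_that("windows with no complementary stretch stay far below the pass threshold", {
  m <- paste(rep("A", 22), collapse = "")
  window <- paste(rep("A", 15), collapse = "")   # A:A never pairs
  res <- miranda_like_score(m, window, cfg)
  expect_lt(res$align_score, cfg$score_min)
})

test_that("alignment equals the matched-pair-chain oracle on random cases", {
  set.seed(101)
  for (r in 1:200) {
    m <- rand_dna(sample(8:22, 1))
    w <- rand_dna(sample(6:12, 1))
    expect_equal(miranda_like_score(m, w, cfg)$align_score,
                 oracle_align_score(m, w, cfg))
  }
})

test_that("the chain oracle itself matches full recursion on tiny cases", {
  set.seed(102)
  for (r in 1:10) {
    m <- rand_dna(6); w <- rand_dna(6)
    expect_equal(oracle_align_score(m, w, cfg),
                 bruteforce_align_score(m, w, cfg))
  }
})

test_that("scores are invariant to T/U representation", {
  set.seed(103)
  m <- rand_dna(22); w <- rand_dna(15)
  m_rna <- chartr("T", "U", m); w_rna <- chartr("T", "U", w)
  expect_equal(miranda_like_score(m, w, cfg)$align_score,
               miranda_like_score(m_rna, w_rna, cfg)$align_score)
  expect_equal(targetscan_like_score(m, w)$context_score,
               targetscan_like_score(m_rna, w_rna)$context_score)
})

test_that("replacing a mismatch with a Watson-Crick pair never lowers the score", {
  set.seed(104)
  for (r in 1:60) {
    m <- rand_dna(22)
    w <- rand_dna(12)
    base <- miranda_like_score(m, w, cfg)
    if (nrow(base$trace) == 0) next
    mm <- base$trace[base$trace$pair == "mm", , drop = FALSE]
    if (nrow(mm) == 0) next
    pick <- mm[1, ]
    mb <- substr(chartr("U", "T", toupper(m)), pick$mirna_pos, pick$mirna_pos)
    w2 <- w
    substr(w2, pick$window_pos, pick$window_pos) <-
      c(A = "T", C = "G", G = "C", T = "A")[[mb]]
    expect_gte(miranda_like_score(m, w2, cfg)$align_score, base$align_score)
  }
})

test_that("seed matches are typed canonically and scored by the context formula", {
  # miRNA chosen so seed complement is unambiguous
  m <- "UGAGGUAGUAGGUUGUAUAGUU"  # let-7-like
  seed6 <- revcomp(substr(chartr("U", "T", m), 2, 7))   # complement of 2-7
  m8c <- revcomp(substr(chartr("U", "T", m), 8, 8))
  none <- targetscan_like_score(m, paste(rep("C", 20), collapse = ""))
  expect_equal(none$seed_type, "none")
  expect_equal(none$context_score, 0)

  # 8mer in all-AU flanks with a planted 4-nt 3' pairing run:
  # -0.31 - 0.25*1 - 0.02*4 = -0.64
  p3run <- revcomp(substr(chartr("U", "T", m), 13, 16))
  win <- paste0("ATA", p3run, "TTA", m8c, seed6, "A", "TATTA")
  res <- targetscan_like_score(m, win)
  expect_equal(res$seed_type, "8mer")
  expect_equal(res$context_score, -0.31 - 0.25 * 1 - 0.02 * 4)

  # 6mer with GC-rich flanks and no 3' pairing cannot clear -0.4
  win6 <- paste0("GGCGG", seed6, "GCGCG")
  res6 <- targetscan_like_score(m, win6)
  expect_equal(res6$seed_type, "6mer")
  expect_gte(res6$context_score, -0.28)
})

test_that("context score is monotone in seed-type strength at fixed flanks", {
  m <- "UGAGGUAGUAGGUUGUAUAGUU"
  md <- chartr("U", "T", m)
  seed6 <- revcomp(substr(md, 2, 7))
  m8c <- revcomp(substr(md, 8, 8))
  other <- setdiff(c("A", "C", "G", "T"), m8c)[1]
  flank <- "TTATT"
  wins <- list(
    `6mer`    = paste0(flank, other, seed6, "G", flank),
    `7mer-A1` = paste0(flank, other, seed6, "A", flank),
    `7mer-m8` = paste0(flank, m8c, seed6, "G", flank),
    `8mer`    = paste0(flank, m8c, seed6, "A", flank))
  scores <- vapply(names(wins), function(k) {
    r <- targetscan_like_score(m, wins[[k]])
    expect_equal(r$seed_type, k)
    r$context_score
  }, numeric(1))
  expect_true(all(diff(scores[c("6mer", "7mer-A1", "7mer-m8", "8mer")]) < 0))
})

test_that("call_sites detects a planted seed destroyed by an SNV", {
  set.seed(7)
  b <- simulate_bundle(sim_config(), seed = 7)
  loss <- b$truth$mutations[b$truth$mutations$state == "loss" &
                              b$truth$mutations$class == "hf", ][1, ]
  tx <- b$transcripts[[loss$transcript_id]]
  msub <- b$mutations[b$mutations$mutation_key == loss$mutation_key, ][1, ]
  ctx <- build_context(tx, b$genome, msub)
  sites <- call_sites(ctx, b$mirnas, cfg)
  row <- sites[sites$mirna_id == loss$mirna_id, ]
  expect_true(row$control_present)
  expect_false(row$mutant_present)
})

test_that("a mutation outside any pairing region leaves scores identical", {
  set.seed(105)
  m <- rand_dna(22)
  w <- paste0(revcomp(substr(m, 1, 15)), "AAAAA")
  w2 <- paste0(revcomp(substr(m, 1, 15)), "AACAA")  # edit in unpaired tail
  expect_equal(miranda_like_score(m, w, cfg)$align_score,
               miranda_like_score(m, w2, cfg)$align_score)
})

test_that("combine_rule either admits single-predictor sites", {
  ctx <- list(mutation_key = "k", transcript_id = "T", gene_id = "G",
              control_seq = "x", mutant_seq = "x",
              extended_control_seq = "x", extended_mutant_seq = "x")
  # craft scores directly through score_window via a miranda-only site:
  set.seed(106)
  m <- rand_dna(22)
  win <- revcomp(substr(m, 1, 15))          # passes alignment thresholds
  gc_ext <- paste0("GCGCG", win)            # GC flanks push context above -0.4?
  s_both <- smilm:::score_window(m, win, gc_ext, predictor_config())
  s_either <- smilm:::score_window(m, win, gc_ext,
                                   predictor_config(combine_rule = "either"))
  expect_true(s_either$passes_miranda)
  expect_true(s_either$present)
  expect_equal(s_both$present,
               s_both$passes_miranda && s_both$passes_targetscan)
})

test_that("imported predictions get identical strict thresholds", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("mutation_key\twindow_kind\tmirna_id\talign_score\tduplex_energy",
               "k1\tcontrol\tmiR-1\t161\t-21",
               "k1\tmutant\tmiR-1\t160\t-21",
               "k2\tcontrol\tmiR-2\t200\t-19"), f)
  imp <- import_external_predictions(f, "miranda_tab")
  r1 <- imp[imp$mutation_key == "k1", ]
  expect_true(r1$control_passes)          # 161 > 160 strictly
  expect_false(r1$mutant_passes)          # 160 fails the strict >
  r2 <- imp[imp$mutation_key == "k2", ]
  expect_false(r2$control_passes)         # energy -19 fails < -20
  expect_false(r2$mutant_passes)          # missing mutant row => absent
  expect_error(import_external_predictions(f, "targetscan_tab"),
               "missing column")
})
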