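cfg <- predictor_config()

site_row <- function(cp, mp, ca = 170, ma = 170, cc = -0.5, mc = -0.5) {
  data.frame(mutation_key = "k", transcript_id = "T1", gene_id = "L1",
             mirna_id = "miR-1", control_present = cp, mutant_present = mp,
             control_align = ca, mutant_align = ma,
             control_context = cc, mutant_context = mc,
             stringsAsFactors = FALSE)
}

test_that("the four affinity states partition the presence/margin grid", {
  expect_equal(classify_affinity(site_row(FALSE, TRUE), cfg)$state, "gain")
  expect_equal(classify_affinity(site_row(TRUE, FALSE), cfg)$state, "loss")
  expect_equal(classify_affinity(site_row(TRUE, TRUE, ma = 176), cfg)$state, "up")
  expect_equal(classify_affinity(site_row(TRUE, TRUE, ma = 164), cfg)$state, "down")
  expect_null(classify_affinity(site_row(FALSE, FALSE), cfg))
  expect_null(classify_affinity(site_row(TRUE, TRUE), cfg))  # no margin
  # context margin decides when the alignment change is sub-threshold
  expect_equal(classify_affinity(site_row(TRUE, TRUE, mc = -0.55), cfg)$state, "up")
  expect_equal(classify_affinity(site_row(TRUE, TRUE, mc = -0.45), cfg)$state, "down")
})

test_that("states carry the published scores and are mutually exclusive", {
  scores <- c(gain = 1, up = 0.5, loss = -1, down = -0.5)
  rows <- list(site_row(FALSE, TRUE), site_row(TRUE, TRUE, ma = 176),
               site_row(TRUE, FALSE), site_row(TRUE, TRUE, ma = 164))
  got <- vapply(rows, function(r) {
    ch <- classify_affinity(r, cfg)
    expect_equal(ch$event_score, scores[[ch$state]])
    ch$state
  }, character(1))
  expect_equal(sort(got), sort(names(scores)))
  # exhaustive grid: every (presence, margin) combination maps to at most
  # one state
  set.seed(9)
  for (r in 1:50) {
    row <- site_row(sample(c(TRUE, FALSE), 1), sample(c(TRUE, FALSE), 1),
                    ca = 170, ma = 170 + runif(1, -10, 10),
                    cc = -0.5, mc = -0.5 + runif(1, -0.2, 0.2))
    ch <- classify_affinity(row, cfg)
    if (!is.null(ch))
      expect_true(ch$state %in% names(scores))
  }
})

test_that("functional scores sum event scores and ignore order", {
  ch <- function(states) data.frame(
    mutation_key = "k", transcript_id = "T", gene_id = "G",
    mirna_id = paste0("m", seq_along(states)), state = states,
    event_score = c(gain = 1, up = 0.5, loss = -1, down = -0.5)[states],
    delta_align = 0, delta_context = 0, stringsAsFactors = FALSE)
  expect_equal(functional_score(ch(c("gain", "down")))$functional_score, 0.5)
  expect_equal(functional_score(ch(c("loss", "loss")))$functional_score, -2)
  expect_equal(functional_score(ch(c("gain", "loss")))$functional_score, 0)
  perm <- ch(c("gain", "down", "loss", "up"))
  expect_equal(functional_score(perm)$functional_score,
               functional_score(perm[sample(4), ])$functional_score)
  fs <- functional_score(ch(c("gain", "down")))
  expect_lte(abs(fs$functional_score), fs$n_events)
  empty <- functional_score(ch("gain")[0, ])
  expect_equal(nrow(empty), 0)
})

toy_changes <- function() data.frame(
  mutation_key = "chr1:10:A:G", transcript_id = "L1-T1", gene_id = "L1",
  mirna_id = "miR-1", state = "gain", event_score = 1,
  delta_align = 20, delta_context = -0.1, stringsAsFactors = FALSE)

toy_carriers <- function(samples, cancer = "COAD")
  do.call(rbind, lapply(samples, function(s)
    toy_mutation("chr1", 10, "A", "G", sample_id = s, cancer_type = cancer)))

test_that("unit assembly fans out over validated targets and attaches carriers", {
  ia <- data.frame(mirna_id = "miR-1", target_gene_id = c("M1", "M2", "M3"),
                   evidence = NA, stringsAsFactors = FALSE)
  units <- assemble_units(toy_changes(), ia, toy_carriers(c("S1", "S2")))
  expect_equal(nrow(units), 3)
  expect_setequal(units$ceM, c("M1", "M2", "M3"))
  expect_true(all(units$n_carriers == 2))
  expect_true(all(units$carriers == "S1,S2"))
  # miRNA without validated targets yields no units but is counted
  ia2 <- data.frame(mirna_id = "miR-9", target_gene_id = "M1",
                    evidence = NA, stringsAsFactors = FALSE)
  units2 <- assemble_units(toy_changes(), ia2, toy_carriers("S1"))
  expect_equal(nrow(units2), 0)
  expect_equal(attr(units2, "n_untargeted_mirnas"), 1L)
  # self-regulation ceL == ceM is excluded
  ia3 <- data.frame(mirna_id = "miR-1", target_gene_id = "L1",
                    evidence = NA, stringsAsFactors = FALSE)
  expect_equal(nrow(assemble_units(toy_changes(), ia3, toy_carriers("S1"))), 0)
})

test_that("HF/LF split counts carriers per cancer type", {
  ia <- data.frame(mirna_id = "miR-1", target_gene_id = "M1",
                   evidence = NA, stringsAsFactors = FALSE)
  # two carriers in the same cancer -> HF
  u_same <- assemble_units(toy_changes(), ia, toy_carriers(c("S1", "S2")))
  sp <- split_hf_lf(u_same)
  expect_equal(nrow(sp$hf), 1); expect_equal(nrow(sp$lf), 0)
  # same site carried once in each of two cancers -> LF in both
  muts <- rbind(toy_carriers("S1", "COAD"), toy_carriers("S2", "LUSC"))
  u_split <- assemble_units(toy_changes(), ia, muts)
  sp2 <- split_hf_lf(u_split)
  expect_equal(nrow(sp2$hf), 0); expect_equal(nrow(sp2$lf), 2)
  # single carrier -> LF; partition is exact and disjoint
  u_one <- assemble_units(toy_changes(), ia, toy_carriers("S1"))
  sp3 <- split_hf_lf(u_one)
  expect_equal(nrow(sp3$hf) + nrow(sp3$lf), nrow(u_one))
})

test_that("ceM tendency follows the sign of the summed mutation scores", {
  mk <- function(scores) data.frame(event_score = scores)
  expect_equal(cem_tendency(mk(c(1, -0.5))), "up")
  expect_equal(cem_tendency(mk(c(1, -1))), "none")
  expect_equal(cem_tendency(mk(-0.5)), "down")
})

test_that("gene-level collapse keeps the dominant transcript change", {
  ch2 <- rbind(toy_changes(), toy_changes())
  ch2$transcript_id <- c("L1-T1", "L1-T2")
  ch2$state <- c("gain", "loss"); ch2$event_score <- c(1, -1)
  ch2$delta_align <- c(20, -5)
  out <- collapse_changes_to_gene(ch2)
  expect_equal(nrow(out), 1)
  expect_equal(out$state, "gain")
  # exact-tie conflict is discarded and logged
  ch2$delta_align <- c(20, -20)
  out2 <- collapse_changes_to_gene(ch2)
  expect_equal(nrow(out2), 0)
  expect_equal(attr(out2, "n_conflicts"), 1L)
})
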