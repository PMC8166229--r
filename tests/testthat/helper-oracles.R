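# Independent oracles used to validate the package implementations.

# ---- local alignment oracle -------------------------------------------
# Maximizes over all chains of matched positions (i1<i2<..., j1<j2<...),
# charging each skipped run in either sequence as one affine gap. This is
# the matched-pair-graph formulation of local alignment, structurally
# different from the cell-wise match/insert/delete recursion used by the
# implementation.
oracle_sub_score <- function(qb, tb, mpos, cfg) {
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  s <- if (!is.na(wc[qb]) && wc[[qb]] == tb) cfg$match_score
  else if ((qb == "G" && tb == "T") || (qb == "T" && tb == "G"))
    cfg$wobble_score
  else cfg$mismatch
  if (mpos >= 2 && mpos <= 8) s * cfg$seed_scale else s
}

oracle_align_score <- function(mirna_seq, window, cfg = predictor_config()) {
  q <- rev(strsplit(toupper(chartr("U", "T", mirna_seq)), "")[[1]])
  t <- strsplit(toupper(chartr("U", "T", window)), "")[[1]]
  n <- length(q); m <- length(t)
  mpos <- n - seq_len(n) + 1L
  gapcost <- function(g) ifelse(g <= 0, 0, cfg$gap_open + (g - 1) * cfg$gap_extend)
  gq <- gapcost(0:n); gt <- gapcost(0:m)   # gq[g+1] = cost of skipping g
  B <- matrix(-Inf, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- oracle_sub_score(q[i], t[j], mpos[i], cfg)
      ext <- 0
      if (i > 1 && j > 1) {
        ii <- seq_len(i - 1); jj <- seq_len(j - 1)
        prev <- B[ii, jj, drop = FALSE] +
          outer(gq[i - ii], gt[j - jj], `+`)
        ext <- max(0, max(prev))
      }
      B[i, j] <- s + ext
    }
  }
  max(0, max(B))
}

# Fully exhaustive recursion over matched-pair chains (no memoization);
# only feasible for very small sequences. Used to validate the oracle.
bruteforce_align_score <- function(mirna_seq, window, cfg = predictor_config()) {
  q <- rev(strsplit(toupper(chartr("U", "T", mirna_seq)), "")[[1]])
  t <- strsplit(toupper(chartr("U", "T", window)), "")[[1]]
  n <- length(q); m <- length(t)
  mpos <- n - seq_len(n) + 1L
  gapcost <- function(g) if (g <= 0) 0 else cfg$gap_open + (g - 1) * cfg$gap_extend
  best <- 0
  extend <- function(i, j, score) {
    best <<- max(best, score)
    if (i >= n || j >= m) return()
    for (i2 in (i + 1):n) for (j2 in (j + 1):m) {
      extend(i2, j2, score +
               gapcost(i2 - i - 1) + gapcost(j2 - j - 1) +
               oracle_sub_score(q[i2], t[j2], mpos[i2], cfg))
    }
  }
  for (i in seq_len(n)) for (j in seq_len(m))
    extend(i, j, oracle_sub_score(q[i], t[j], mpos[i], cfg))
  best
}

# ---- bivariate regression oracle --------------------------------------
# Explicit normal equations plus SSCP-based Pillai test of the genotype
# term, independent of stats::lm / stats::anova.
oracle_bivariate <- function(El, Em, Gt, MIr) {
  n <- length(El)
  X <- cbind(1, MIr, Gt)
  Y <- cbind(El, Em)
  XtX <- crossprod(X)
  B <- solve(XtX, crossprod(X, Y))
  R <- Y - X %*% B
  E <- crossprod(R)
  X0 <- cbind(1, MIr)
  B0 <- solve(crossprod(X0), crossprod(X0, Y))
  R0 <- Y - X0 %*% B0
  H <- crossprod(R0) - E
  V <- sum(diag(H %*% solve(H + E)))          # Pillai trace, q = 1 df
  Fstat <- (n - 4) / 2 * V / (1 - V)
  p_joint <- stats::pf(Fstat, 2, n - 4, lower.tail = FALSE)
  se <- sqrt(diag(solve(XtX))[3] * diag(E) / (n - 3))
  tval <- B[3, ] / se
  list(eta_l = unname(B[3, 1]), eta_m = unname(B[3, 2]),
       p_joint = unname(p_joint),
       p_l = unname(2 * stats::pt(abs(tval[1]), n - 3, lower.tail = FALSE)),
       p_m = unname(2 * stats::pt(abs(tval[2]), n - 3, lower.tail = FALSE)))
}

# ---- hypergeometric enumeration oracle --------------------------------
oracle_hyper_upper <- function(k, K, N, n) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# ---- toy transcript/genome builders -----------------------------------
toy_tx <- function(exons, strand = "+", chrom = "chrT",
                   transcript_id = "TX1", gene_id = "G1",
                   biotype = "lncRNA") {
  ex <- matrix(as.integer(unlist(exons)), ncol = 2, byrow = TRUE,
               dimnames = list(NULL, c("start", "end")))
  list(transcript_id = transcript_id, gene_id = gene_id,
       gene_name = gene_id, biotype = biotype, chrom = chrom,
       strand = strand, exons = ex,
       spliced_length = sum(ex[, 2] - ex[, 1] + 1L))
}

toy_mutation <- function(chrom, pos, ref, alt, sample_id = "S1",
                         cancer_type = "COAD") {
  data.frame(sample_id = sample_id, cancer_type = cancer_type,
             chrom = chrom, pos = as.integer(pos), ref_allele = ref,
             alt_allele = alt,
             variant_class = smilm:::infer_variant_class(ref, alt),
             mutation_key = mutation_key(chrom, pos, ref, alt),
             stringsAsFactors = FALSE)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
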