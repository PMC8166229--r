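#' Group samples by LF-mutation status for one ceM
#'
#' Mutated samples are the union of carrier samples over all LF units
#' that perturb the ceM in one cancer type; controls are the remaining
#' samples with expression data.
#'
#' @param units_for_cem LF SMILM units sharing a ceM and cancer type.
#' @param all_samples Samples with expression data in that cancer.
#' @return List with `mutated` and `control` character vectors.
#' @export
group_samples <- function(units_for_cem, all_samples) {
  mutated <- unique(unlist(carrier_list(units_for_cem)))
  mutated <- intersect(mutated, all_samples)
  list(mutated = mutated, control = setdiff(all_samples, mutated))
}

#' Test one ceM for expression change between mutated and control groups
#'
#' Classic pooled-variance (Student) two-sided t-test on log2(FPKM+1)
#' values; Welch's correction is available for unbalanced groups. The
#' fold change compares raw FPKM group means with a 0.01 pseudo-count:
#' `(mean_mut + 0.01) / (mean_ctl + 0.01)`, so identical groups give
#' exactly 1.
#'
#' @param expr_row Named numeric vector of raw FPKM values per sample.
#' @param mutated,control Sample id vectors.
#' @param min_group Minimum group size (default 2).
#' @param welch Use Welch's t-test instead of pooled variance.
#' @param log_transform Apply log2(FPKM+1) before testing.
#' @return One-row data frame with `n_mut`, `n_ctl`, `t_stat`,
#'   `p_value`, `fold_change`; or `NULL` with a skip handled by the
#'   caller when a group is below `min_group`.
#' @export
test_cem <- function(expr_row, mutated, control, min_group = 2L,
                     welch = FALSE, log_transform = TRUE) {
  mutated <- intersect(mutated, names(expr_row))
  control <- intersect(control, names(expr_row))
  if (length(mutated) < min_group || length(control) < min_group) return(NULL)
  tf <- if (log_transform) function(x) log2(x + 1) else identity
  x <- tf(expr_row[mutated]); y <- tf(expr_row[control])
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    # degenerate (e.g. noiseless) input: exact difference or exact tie
    d <- mean(x) - mean(y)
    t_stat <- if (d == 0) 0 else sign(d) * Inf
    p <- if (d == 0) 1 else 0
  } else {
    ht <- stats::t.test(x, y, var.equal = !welch)
    t_stat <- unname(ht$statistic); p <- ht$p.value
  }
  fc <- (mean(expr_row[mutated]) + 0.01) / (mean(expr_row[control]) + 0.01)
  data.frame(n_mut = length(mutated), n_ctl = length(control),
             t_stat = t_stat, p_value = p, fold_change = fc,
             stringsAsFactors = FALSE)
}

#' Run the LF branch over a unit table
#'
#' Units are grouped per (ceM, cancer type); each group is tested with
#' [test_cem()] and annotated with its predicted expression tendency
#' ([cem_tendency()]) and regulating ceLs. Groups skipped for
#' insufficient carriers or missing expression are reported in the
#' attached audit table.
#'
#' @param lf_units LF unit data frame (see [split_hf_lf()]).
#' @param expr_mrna Raw FPKM matrix (genes x samples).
#' @param sample_cancers Named character vector sample id -> cancer type.
#' @param alpha Significance level (default 0.05).
#' @inheritParams test_cem
#' @return Data frame of ceM test results with a `significant` flag;
#'   attribute `skipped` is a data frame of skipped (ceM, cancer,
#'   reason) rows.
#' @export
lf_test_cems <- function(lf_units, expr_mrna, sample_cancers, alpha = 0.05,
                         min_group = 2L, welch = FALSE, log_transform = TRUE) {
  key <- paste(lf_units$ceM, lf_units$cancer_type, sep = "\r")
  groups <- split(seq_len(nrow(lf_units)), key)
  rows <- list(); skipped <- list()
  for (g in groups) {
    sub <- lf_units[g, ]
    cem <- sub$ceM[1]; cancer <- sub$cancer_type[1]
    skip <- function(reason)
      data.frame(ceM = cem, cancer_type = cancer, reason = reason,
                 stringsAsFactors = FALSE)
    if (!cem %in% rownames(expr_mrna)) {
      skipped[[length(skipped) + 1L]] <- skip("missing_expression"); next
    }
    samples <- intersect(names(sample_cancers)[sample_cancers == cancer],
                         colnames(expr_mrna))
    grp <- group_samples(sub, samples)
    if (length(grp$mutated) == 0) {
      skipped[[length(skipped) + 1L]] <- skip("no_mutated_samples"); next
    }
    if (length(grp$control) == 0) {
      skipped[[length(skipped) + 1L]] <- skip("no_controls"); next
    }
    res <- test_cem(expr_mrna[cem, samples], grp$mutated, grp$control,
                    min_group, welch, log_transform)
    if (is.null(res)) {
      skipped[[length(skipped) + 1L]] <- skip("insufficient_carriers"); next
    }
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(ceM = cem, cancer_type = cancer,
                 tendency = cem_tendency(sub),
                 ceLs = paste(sort(unique(sub$ceL)), collapse = ","),
                 stringsAsFactors = FALSE),
      res)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(ceM = character(0), cancer_type = character(0),
               tendency = character(0), ceLs = character(0),
               n_mut = integer(0), n_ctl = integer(0), t_stat = numeric(0),
               p_value = numeric(0), fold_change = numeric(0),
               stringsAsFactors = FALSE)
  if (nrow(out) > 0) out$significant <- out$p_value < alpha
  else out$significant <- logical(0)
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped) > 0) do.call(rbind, skipped) else
    data.frame(ceM = character(0), cancer_type = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  out
}
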