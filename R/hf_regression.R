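#' Bivariate genotype regression for one HF SMILM unit
#'
#' Fits the two-response linear model `(El, Em) ~ MIr + Gt`, where `El`
#' and `Em` are ceL and ceM expression (log2(FPKM+1) upstream of this
#' function), `Gt` is the 0/1 carrier genotype and `MIr` the miRNA
#' expression covariate. Coefficients are the per-response least-squares
#' solutions (identical to the multivariate solution); the joint
#' significance of the genotype across both responses is the
#' Pillai-trace test of the `Gt` term (fitted last, i.e. adjusted for
#' the covariate); per-response two-sided t-tests on the `Gt`
#' coefficient are reported alongside.
#'
#' Degenerate inputs: if the fit is exact (all residuals numerically
#' zero) the test statistics are undefined; by convention the joint and
#' per-response p-values are set to 0 when the corresponding genotype
#' coefficient is nonzero and to 1 otherwise.
#'
#' @param El,Em Numeric response vectors (ceL and ceM expression).
#' @param Gt 0/1 genotype indicator.
#' @param MIr miRNA expression covariate.
#' @return List of class `hf_regression` with `eta_l`, `eta_m`,
#'   `p_joint`, `p_l`, `p_m`, `residual_cov`, `n`, `n_carriers`; or a
#'   list with `ok = FALSE` and a `reason` code (`"too_few_samples"`,
#'   `"no_carriers"`, `"all_carriers"`, `"rank_deficient"`) when the
#'   unit cannot be fitted.
#' @export
fit_bivariate <- function(El, Em, Gt, MIr) {
  n <- length(El)
  fail <- function(reason) list(ok = FALSE, reason = reason)
  if (!(length(Em) == n && length(Gt) == n && length(MIr) == n) || n < 4)
    return(fail("too_few_samples"))
  if (all(Gt == 0)) return(fail("no_carriers"))
  if (all(Gt == 1)) return(fail("all_carriers"))
  X <- cbind(1, MIr, Gt)
  if (qr(X)$rank < 3) return(fail("rank_deficient"))

  fit <- stats::lm(cbind(El, Em) ~ MIr + Gt)
  co <- stats::coef(fit)
  eta_l <- co["Gt", "El"]; eta_m <- co["Gt", "Em"]
  res <- stats::residuals(fit)
  residual_cov <- crossprod(res) / (n - 3)

  if (max(abs(res)) < 1e-10) {
    # exact fit: snap numerically-zero coefficients so sign filters
    # cannot be driven by rounding noise
    if (abs(eta_l) < 1e-10) eta_l <- 0
    if (abs(eta_m) < 1e-10) eta_m <- 0
    p_l <- if (eta_l != 0) 0 else 1
    p_m <- if (eta_m != 0) 0 else 1
    p_joint <- min(p_l, p_m)
  } else {
    a <- stats::anova(fit, test = "Pillai")
    p_joint <- a["Gt", "Pr(>F)"]
    sm <- summary(fit)
    p_l <- sm[[1]]$coefficients["Gt", "Pr(>|t|)"]
    p_m <- sm[[2]]$coefficients["Gt", "Pr(>|t|)"]
  }
  structure(list(ok = TRUE, eta_l = unname(eta_l), eta_m = unname(eta_m),
                 p_joint = unname(p_joint), p_l = unname(p_l),
                 p_m = unname(p_m), residual_cov = residual_cov,
                 n = n, n_carriers = sum(Gt)),
            class = "hf_regression")
}

#' Step-1 filter: opposite genotype effects, jointly significant
#'
#' Competing transcripts must move in opposite directions with
#' genotype: the unit passes when `eta_l * eta_m < 0` and the joint
#' genotype p-value is below `alpha`.
#'
#' @param res A fitted [fit_bivariate()] result.
#' @param alpha Significance level (default 0.05).
#' @return Logical flag.
#' @export
step1_filter <- function(res, alpha = 0.05) {
  isTRUE(res$ok) && res$eta_l * res$eta_m < 0 && res$p_joint < alpha
}

#' Step-2 filter: direction consistency with the predicted score change
#'
#' A net gain of miRNA binding on the lncRNA (positive functional
#' score) is expected to decrease ceL expression in carriers (the
#' sponge is degraded/captured) and increase ceM expression; so the
#' unit passes when `sign(eta_l) == -sign(functional_score)`.
#'
#' @param res A fitted [fit_bivariate()] result.
#' @param fscore Functional score of the unit's mutation.
#' @return Logical flag, or `NA` when `fscore == 0` (direction
#'   undefined; the unit is excluded).
#' @export
step2_filter <- function(res, fscore) {
  if (!isTRUE(res$ok)) return(FALSE)
  if (fscore == 0) return(NA)
  sign(res$eta_l) == -sign(fscore)
}

#' One-sample t-test of non-mutant expression against the mutant mean
#'
#' @param expr_nonmutant Numeric vector of non-mutant sample values
#'   (length >= 2).
#' @param mutant_mean Mean expression of the mutant samples.
#' @return List with `t` and two-sided `p`. Zero variance in the
#'   non-mutant values is handled by convention: p = 0 when the means
#'   differ, p = 1 otherwise (t is +/-Inf or 0 accordingly).
#' @export
one_sample_check <- function(expr_nonmutant, mutant_mean) {
  stopifnot(length(expr_nonmutant) >= 2)
  if (stats::sd(expr_nonmutant) == 0) {
    d <- mean(expr_nonmutant) - mutant_mean
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                p = if (d == 0) 1 else 0))
  }
  ht <- stats::t.test(expr_nonmutant, mu = mutant_mean)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Run the HF regression branch over a unit table
#'
#' For every HF unit, builds the genotype vector over the samples
#' shared by the three expression matrices and the clinical cancer
#' label, fits [fit_bivariate()] on log2(FPKM+1) values and applies the
#' two filters.
#'
#' @param hf_units HF unit data frame (see [split_hf_lf()]).
#' @param expr_lnc,expr_mir,expr_mrna FPKM matrices (genes x samples).
#' @param fscores Functional-score table from [functional_score()].
#' @param sample_cancers Named character vector mapping sample id to
#'   cancer type; only samples of the unit's cancer enter the fit.
#' @param alpha Significance level for step 1.
#' @param log_transform Apply log2(FPKM+1) (default TRUE).
#' @return Data frame with one row per unit: coefficients, p-values,
#'   filter flags and a `reason` code for unfitted units.
#' @export
hf_test_units <- function(hf_units, expr_lnc, expr_mir, expr_mrna, fscores,
                          sample_cancers, alpha = 0.05, log_transform = TRUE) {
  tf <- if (log_transform) function(x) log2(x + 1) else identity
  carriers <- carrier_list(hf_units)
  rows <- lapply(seq_len(nrow(hf_units)), function(i) {
    u <- hf_units[i, ]
    base <- data.frame(mutation_key = u$mutation_key,
                       cancer_type = u$cancer_type, mirna_id = u$mirna_id,
                       ceL = u$ceL, ceM = u$ceM, state = u$state,
                       event_score = u$event_score,
                       eta_l = NA_real_, eta_m = NA_real_,
                       p_joint = NA_real_, p_l = NA_real_, p_m = NA_real_,
                       passes_step1 = FALSE, passes_step2 = NA,
                       reason = NA_character_, stringsAsFactors = FALSE)
    samples <- names(sample_cancers)[sample_cancers == u$cancer_type]
    samples <- Reduce(intersect, list(samples, colnames(expr_lnc),
                                      colnames(expr_mir), colnames(expr_mrna)))
    ok_rows <- u$ceL %in% rownames(expr_lnc) &&
      u$mirna_id %in% rownames(expr_mir) && u$ceM %in% rownames(expr_mrna)
    if (!ok_rows || length(samples) < 4) {
      base$reason <- if (!ok_rows) "missing_expression" else "too_few_samples"
      return(base)
    }
    Gt <- as.integer(samples %in% carriers[[i]])
    res <- fit_bivariate(tf(expr_lnc[u$ceL, samples]),
                         tf(expr_mrna[u$ceM, samples]),
                         Gt, tf(expr_mir[u$mirna_id, samples]))
    if (!isTRUE(res$ok)) { base$reason <- res$reason; return(base) }
    fs <- fscores$functional_score[match(u$mutation_key, fscores$mutation_key)]
    base$eta_l <- res$eta_l; base$eta_m <- res$eta_m
    base$p_joint <- res$p_joint; base$p_l <- res$p_l; base$p_m <- res$p_m
    base$passes_step1 <- step1_filter(res, alpha)
    base$passes_step2 <- step2_filter(res, fs)
    if (is.na(base$passes_step2)) base$reason <- "zero_functional_score"
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
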