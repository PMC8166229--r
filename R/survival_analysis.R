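#' Classify samples by predicted ceM regulatory direction
#'
#' Each sample is assigned one of four classes for a given ceM:
#' `"None"` (carries no mutation perturbing the ceM), `"Up-regulated"`
#' (only positive-score mutations), `"Down-regulated"` (only negative),
#' `"Unknown"` (both up- and down-directed mutations present).
#'
#' @param units_for_cem SMILM units sharing one ceM (and cancer type).
#' @param samples Character vector of sample ids to classify.
#' @return Named character vector of classes over `samples`.
#' @export
classify_samples <- function(units_for_cem, samples) {
  carr <- carrier_list(units_for_cem)
  cls <- vapply(samples, function(s) {
    in_unit <- vapply(carr, function(cs) s %in% cs, logical(1))
    if (!any(in_unit)) return("None")
    scores <- units_for_cem$event_score[in_unit]
    has_up <- any(scores > 0); has_down <- any(scores < 0)
    if (has_up && has_down) "Unknown"
    else if (has_up) "Up-regulated"
    else if (has_down) "Down-regulated"
    else "None"
  }, character(1))
  names(cls) <- samples
  cls
}

#' Single-covariate Cox proportional-hazards fit
#'
#' Proportional-hazards regression of survival on one continuous
#' covariate (typically log2(FPKM+1) ceM expression), with Efron tie
#' handling. HR < 1 with p < 0.05 indicates association with reduced
#' risk of death.
#'
#' @param x Numeric covariate per sample (named by sample id when
#'   `clinical` must be matched by id).
#' @param clinical Clinical data frame (see [read_clinical()]); rows are
#'   matched to `x` by `sample_id` when `x` is named, else by position.
#' @param min_samples,min_events Minimum sample and event counts.
#' @return List with `hr`, `coef`, `p` (Wald), `n`, `n_events`; or
#'   `ok = FALSE` with a `reason` code (`"too_few_samples"`,
#'   `"no_events"`, `"no_convergence"`).
#' @export
cox_fit <- function(x, clinical, min_samples = 10L, min_events = 3L) {
  if (!is.null(names(x))) {
    common <- intersect(names(x), clinical$sample_id)
    clinical <- clinical[match(common, clinical$sample_id), , drop = FALSE]
    x <- x[common]
  }
  fail <- function(reason) list(ok = FALSE, reason = reason)
  if (length(x) < min_samples) return(fail("too_few_samples"))
  if (sum(clinical$event) < min_events) return(fail("no_events"))
  fit <- tryCatch(
    survival::coxph(survival::Surv(clinical$time, clinical$event) ~ x,
                    ties = "efron",
                    control = survival::coxph.control(iter.max = 50)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit) || is.na(stats::coef(fit))) return(fail("no_convergence"))
  sm <- summary(fit)
  list(ok = TRUE, hr = unname(exp(stats::coef(fit))),
       coef = unname(stats::coef(fit)),
       p = unname(sm$coefficients[1, "Pr(>|z|)"]),
       n = length(x), n_events = sum(clinical$event))
}

#' Kaplan-Meier curves and log-rank test across mutation classes
#'
#' Product-limit survival estimate per class plus the multi-group
#' log-rank chi-square test. Classes with fewer than `min_class`
#' samples are merged into `"other"` (logged in the result).
#'
#' @param classing Named character vector of per-sample classes
#'   (see [classify_samples()]).
#' @param clinical Clinical data frame.
#' @param min_class Minimum class size before merging (default 3).
#' @return List with `km` (data frame: class, time, surv, n_risk,
#'   n_event), `logrank_chisq`, `logrank_p` (NA with a single class),
#'   `classes` (retained class labels), `n_merged`.
#' @export
km_logrank <- function(classing, clinical, min_class = 3L) {
  common <- intersect(names(classing), clinical$sample_id)
  cl <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  grp <- classing[common]
  tab <- table(grp)
  small <- names(tab)[tab < min_class]
  n_merged <- sum(grp %in% small)
  if (length(small) > 0) grp[grp %in% small] <- "other"
  grp <- factor(grp)
  surv <- survival::Surv(cl$time, cl$event)
  sf <- survival::survfit(surv ~ grp)
  strata_names <- if (is.null(sf$strata)) levels(grp)[1] else
    sub("^grp=", "", names(sf$strata))
  km <- data.frame(
    class = rep(strata_names,
                if (is.null(sf$strata)) length(sf$time) else sf$strata),
    time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
    n_event = sf$n.event, stringsAsFactors = FALSE)
  if (nlevels(droplevels(grp)) < 2) {
    return(list(km = km, logrank_chisq = NA_real_, logrank_p = NA_real_,
                classes = levels(droplevels(grp)), n_merged = n_merged))
  }
  sd <- survival::survdiff(surv ~ grp)
  df <- length(sd$n) - 1
  list(km = km, logrank_chisq = unname(sd$chisq),
       logrank_p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       classes = levels(droplevels(grp)), n_merged = n_merged)
}

#' Survival analysis over all ceMs of a unit table
#'
#' For each (ceM, cancer type): Cox PH on continuous ceM expression and
#' a log-rank test across the four mutation-direction classes.
#'
#' @param units SMILM unit data frame (typically the units that passed
#'   the HF/LF statistical filters).
#' @param expr_mrna Raw FPKM matrix (genes x samples).
#' @param clinical Clinical data frame.
#' @param sample_cancers Named character vector sample id -> cancer.
#' @param log_transform Apply log2(FPKM+1) to the Cox covariate.
#' @return Data frame with one row per (ceM, cancer): `hr`, `cox_p`,
#'   `logrank_p`, class counts and a `reason` code for skipped fits.
#' @export
survival_by_cem <- function(units, expr_mrna, clinical, sample_cancers,
                            log_transform = TRUE) {
  tf <- if (log_transform) function(x) log2(x + 1) else identity
  key <- paste(units$ceM, units$cancer_type, sep = "\r")
  groups <- split(seq_len(nrow(units)), key)
  rows <- lapply(groups, function(g) {
    sub <- units[g, ]
    cem <- sub$ceM[1]; cancer <- sub$cancer_type[1]
    base <- data.frame(ceM = cem, cancer_type = cancer,
                       hr = NA_real_, cox_p = NA_real_,
                       logrank_p = NA_real_, n = NA_integer_,
                       n_events = NA_integer_, reason = NA_character_,
                       stringsAsFactors = FALSE)
    if (!cem %in% rownames(expr_mrna)) {
      base$reason <- "missing_expression"; return(base)
    }
    samples <- intersect(names(sample_cancers)[sample_cancers == cancer],
                         colnames(expr_mrna))
    samples <- intersect(samples, clinical$sample_id)
    x <- tf(expr_mrna[cem, samples]); names(x) <- samples
    cx <- cox_fit(x, clinical)
    if (!isTRUE(cx$ok)) { base$reason <- cx$reason; return(base) }
    classing <- classify_samples(sub, samples)
    kl <- km_logrank(classing, clinical)
    base$hr <- cx$hr; base$cox_p <- cx$p
    base$logrank_p <- kl$logrank_p
    base$n <- cx$n; base$n_events <- cx$n_events
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
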