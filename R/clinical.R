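#' Kaplan-Meier curves, log-rank test and Cox hazard ratio
#'
#' Product-limit survival estimates for the mutated and reference groups, a
#' two-group log-rank test, and a Cox proportional-hazards fit on the group
#' indicator (Breslow tie handling) to give the direction of the effect as
#' a hazard ratio with confidence interval.
#'
#' @param samples sample table with `sample_id`, `os_time` (days),
#'   `os_event` (1 = death).
#' @param mutated,reference sample id vectors.
#' @return list(n_mut, n_ref, logrank_chisq, p, hr, hr_ci, curves).
#' @export
km_logrank <- function(samples, mutated, reference) {
  assert_columns(samples, c("sample_id", "os_time", "os_event"), "clinical")
  d <- samples[samples$sample_id %in% c(mutated, reference), , drop = FALSE]
  d$group <- ifelse(d$sample_id %in% mutated, "mutated", "reference")
  if (!any(d$group == "mutated") || !any(d$group == "reference")) {
    stop("both survival groups must be non-empty")
  }
  fit <- survival::survfit(survival::Surv(os_time, os_event) ~ group, data = d)
  strata <- rep(names(fit$strata) %||% "all", fit$strata %||% length(fit$time))
  curves <- split(data.frame(time = fit$time, surv = fit$surv), strata)
  names(curves) <- sub("^group=", "", names(curves))
  if (sum(d$os_event) == 0) {
    warning("no events in either group; log-rank p unavailable")
    return(list(n_mut = sum(d$group == "mutated"),
                n_ref = sum(d$group == "reference"),
                logrank_chisq = NA_real_, p = NA_real_,
                hr = NA_real_, hr_ci = c(NA_real_, NA_real_),
                curves = curves))
  }
  sd <- survival::survdiff(survival::Surv(os_time, os_event) ~ group, data = d)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  d$mut01 <- as.integer(d$group == "mutated")
  cx <- survival::coxph(survival::Surv(os_time, os_event) ~ mut01, data = d,
                        ties = "breslow")
  ci <- exp(stats::confint(cx))
  list(n_mut = sum(d$group == "mutated"),
       n_ref = sum(d$group == "reference"),
       logrank_chisq = unname(sd$chisq), p = p,
       hr = unname(exp(stats::coef(cx))),
       hr_ci = c(lower = ci[1], upper = ci[2]),
       curves = curves)
}

normalize_stage <- function(stage) {
  s <- toupper(trimws(stage))
  s <- sub("^STAGE\\s*", "", s)
  s <- sub("[ABC][12]?$", "", s) # collapse sub-stages (IIIA -> III)
  ifelse(s %in% c("I", "II", "III", "IV"), s, NA_character_)
}

#' Mutation occurrence across tumor stages, stratified by cancer type
#'
#' Dichotomizes stage into early (I-II) versus late (III-IV), builds one
#' 2x2 table (mutation presence x stage class) per cancer type, and tests
#' the common association with the Cochran-Mantel-Haenszel test (continuity
#' correction off). Per-cancer Fisher's exact tests are reported alongside.
#'
#' @param samples sample table with `sample_id`, `cancer_type`, `stage`.
#' @param mutated sample ids with the mutation of interest.
#' @param early,late stage labels forming the dichotomy.
#' @return list(statistic, p, tables (2x2xS array), per_cancer data.frame).
#' @export
cmh_stage_test <- function(samples, mutated, early = c("I", "II"),
                           late = c("III", "IV")) {
  assert_columns(samples, c("sample_id", "cancer_type", "stage"), "clinical")
  d <- samples
  d$stage_n <- normalize_stage(d$stage)
  d <- d[!is.na(d$stage_n) & d$stage_n %in% c(early, late), , drop = FALSE]
  d$late <- d$stage_n %in% late
  d$mut <- d$sample_id %in% mutated
  strata <- sort(unique(d$cancer_type))
  tabs <- vapply(strata, function(cn) {
    s <- d[d$cancer_type == cn, ]
    c(sum(s$mut & s$late), sum(!s$mut & s$late),
      sum(s$mut & !s$late), sum(!s$mut & !s$late))
  }, numeric(4))
  arr <- array(tabs, dim = c(2, 2, length(strata)),
               dimnames = list(mutation = c("mutated", "unmutated"),
                               stage = c("late", "early"),
                               cancer = strata))
  if (sum(arr) == 0) stop("no informative stratum for the CMH test")
  if (length(strata) == 1L) {
    # single stratum: the CMH statistic is the (n-1)/n-scaled Pearson
    # chi-square of that table (agreeing with it asymptotically)
    t1 <- arr[, , 1]
    if (any(rowSums(t1) == 0) || any(colSums(t1) == 0)) {
      stop("degenerate strata for the CMH test")
    }
    n <- sum(t1)
    stat <- unname(suppressWarnings(
      stats::chisq.test(t1, correct = FALSE)$statistic)) * (n - 1) / n
    mh <- list(statistic = stat,
               p.value = stats::pchisq(stat, 1, lower.tail = FALSE))
  } else {
    mh <- tryCatch(stats::mantelhaen.test(arr, correct = FALSE),
                   error = function(e) stop(sprintf(
                     "degenerate strata for the CMH test: %s",
                     conditionMessage(e))))
  }
  per_cancer <- do.call(rbind, lapply(strata, function(cn) {
    t <- arr[, , cn]
    p <- if (any(rowSums(t) == 0) || any(colSums(t) == 0)) NA_real_ else
      stats::fisher.test(t)$p.value
    data.frame(cancer = cn, n = sum(t), p = p, stringsAsFactors = FALSE)
  }))
  list(statistic = unname(mh$statistic), p = mh$p.value, tables = arr,
       per_cancer = per_cancer)
}

#' Copy-number alterations across mutation classes of a gene
#'
#' Groups samples by their mutation class in the gene (`none`, `hotspot`,
#' `deleterious`, `other`; a sample with both a hotspot and another
#' mutation counts as hotspot), reports the proportion with a thresholded
#' deletion call (<= -1) and amplification call (>= +1), and tests deletion
#' x mutation-presence with Fisher's exact test.
#'
#' @param cnv long table sample_id/gene/call with calls in -2..2.
#' @param muts classified mutation table.
#' @param gene gene symbol.
#' @param hotspot_positions residues treated as hotspot (optional).
#' @param samples optional sample table restricting the cohort.
#' @return list(by_class data.frame, fisher_p, n_missing_cnv).
#' @export
cnv_cooccurrence <- function(cnv, muts, gene, hotspot_positions = NULL,
                             samples = NULL) {
  cg <- cnv[cnv$gene == gene, , drop = FALSE]
  ids <- if (!is.null(samples)) samples$sample_id else unique(cg$sample_id)
  n_missing <- sum(!ids %in% cg$sample_id)
  if (n_missing > 0.5 * length(ids)) {
    warning(sprintf("copy-number calls missing for %d of %d samples",
                    n_missing, length(ids)))
  }
  m <- muts[muts$gene == gene & muts$sample_id %in% ids, , drop = FALSE]
  hs <- if (is.null(hotspot_positions)) rep(FALSE, nrow(m)) else
    m$consequence == "missense" & m$protein_pos %in% hotspot_positions
  del_cls <- m$consequence %in% DELETERIOUS_CLASSES
  cls <- rep("none", length(ids)); names(cls) <- ids
  cls[unique(m$sample_id)] <- "other"
  cls[unique(m$sample_id[del_cls])] <- "deleterious"
  cls[unique(m$sample_id[hs])] <- "hotspot"
  call <- cg$call[match(ids, cg$sample_id)]
  by_class <- do.call(rbind, lapply(c("none", "hotspot", "deleterious", "other"),
                                    function(k) {
    sel <- cls == k & !is.na(call)
    n <- sum(sel)
    data.frame(class = k, n = n,
               prop_deleted = if (n) mean(call[sel] <= -1) else NA_real_,
               prop_amplified = if (n) mean(call[sel] >= 1) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  ok <- !is.na(call)
  mutated <- cls != "none"
  tab <- matrix(c(sum(ok & mutated & call <= -1), sum(ok & mutated & call > -1),
                  sum(ok & !mutated & call <= -1), sum(ok & !mutated & call > -1)),
                2, byrow = TRUE)
  fisher_p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1 else
    stats::fisher.test(tab)$p.value
  list(by_class = by_class, fisher_p = fisher_p, table = tab,
       n_missing_cnv = n_missing)
}
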