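#' Define mutated and reference sample groups for a gene
#'
#' The mutated group holds samples with at least one mutation of the
#' requested class in the gene; the reference group holds samples with no
#' mutation of *any* class in that gene. Samples carrying only other-class
#' mutations in the gene belong to neither group.
#'
#' @param muts classified mutation table.
#' @param samples sample table (`sample_id`).
#' @param gene gene symbol.
#' @param class_filter NULL (any mutation), a character vector of
#'   consequence classes, or a predicate function on the gene's mutation
#'   rows returning a logical vector. The helpers [class_hotspot()] and
#'   [class_deleterious()] build common predicates.
#' @return list(mutated, reference) of sample id vectors.
#' @export
define_groups <- function(muts, samples, gene, class_filter = NULL) {
  g <- muts[muts$gene == gene, , drop = FALSE]
  sel <- if (is.null(class_filter)) rep(TRUE, nrow(g))
  else if (is.function(class_filter)) class_filter(g)
  else g$consequence %in% class_filter
  mutated <- unique(g$sample_id[sel])
  if (!length(mutated)) {
    stop(sprintf("no samples with the requested mutation class in %s", gene))
  }
  any_mut <- unique(g$sample_id)
  reference <- setdiff(samples$sample_id, any_mut)
  list(mutated = mutated, reference = reference)
}

#' Predicate: missense mutations at hotspot residues
#' @param positions hotspot residues (integer protein positions).
#' @return Function usable as `class_filter` in [define_groups()].
#' @export
class_hotspot <- function(positions) {
  function(g) g$consequence == "missense" & g$protein_pos %in% positions
}

#' Predicate: definitive deleterious mutations
#' @return Function usable as `class_filter` in [define_groups()].
#' @export
class_deleterious <- function() {
  function(g) g$consequence %in% DELETERIOUS_CLASSES
}

#' Differential miRNA analysis between mutation groups
#'
#' Per miRNA, a two-sided Wilcoxon rank-sum comparison of the mutated
#' versus reference samples (exact enumeration when the smaller group has
#' at most 8 untied values, normal approximation with tie correction
#' otherwise). The effect is the difference of medians on normalized
#' scales and the log2 fold change of medians on the raw RPM scale.
#' P-values are reported nominally (volcano counts use p < 0.05);
#' Benjamini-Hochberg adjusted values are appended as an extra column.
#'
#' @param expr an `expr_matrix`.
#' @param mutated,reference sample id vectors (non-empty, present in the
#'   matrix).
#' @param pseudocount used for the RPM-scale fold change.
#' @return data.frame mirna, arm, n_mut, n_ref, effect, p, p_adjusted,
#'   direction.
#' @export
diff_test <- function(expr, mutated, reference, pseudocount = 1) {
  v <- expr$values
  mutated <- intersect(mutated, colnames(v))
  reference <- intersect(reference, colnames(v))
  if (!length(mutated) || !length(reference)) {
    stop("both groups must contain samples present in the expression matrix")
  }
  xm <- v[, mutated, drop = FALSE]
  xr <- v[, reference, drop = FALSE]
  n <- nrow(v)
  eff <- p <- numeric(n)
  for (i in seq_len(n)) {
    a <- xm[i, ]; b <- xr[i, ]
    if (stats::sd(c(a, b)) == 0) {
      p[i] <- 1; eff[i] <- 0
      next
    }
    exact <- min(length(a), length(b)) <= 8
    p[i] <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact)$p.value)
    eff[i] <- if (expr$dialect == "rpm") {
      log2((stats::median(a) + pseudocount) / (stats::median(b) + pseudocount))
    } else {
      stats::median(a) - stats::median(b)
    }
  }
  out <- data.frame(
    mirna = rownames(v),
    arm = unname(expr$arm),
    n_mut = length(mutated), n_ref = length(reference),
    effect = eff, p = p,
    p_adjusted = stats::p.adjust(p, "BH"),
    direction = ifelse(eff > 0, "up", ifelse(eff < 0, "down", "none")),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' 5p/3p arm asymmetry among significantly altered miRNAs
#'
#' Among miRNAs significant at `alpha`, counts 5p and 3p members separately
#' for the down- and upregulated sets (arm-unspecified miRNAs are excluded)
#' and tests the arm x direction association with a two-sided Fisher's
#' exact test.
#'
#' @param results a [diff_test()] table.
#' @param alpha significance cutoff on the nominal p-value.
#' @return list(counts 2x2 matrix, proportions (within direction), p,
#'   n_significant).
#' @export
arm_asymmetry <- function(results, alpha = 0.05) {
  sig <- results$p < alpha & results$arm %in% c("5p", "3p") &
    results$direction %in% c("down", "up")
  counts <- matrix(0L, 2, 2, dimnames = list(arm = c("5p", "3p"),
                                             direction = c("down", "up")))
  if (!any(sig)) {
    warning("no significant arm-annotated miRNAs")
    return(list(counts = counts, proportions = counts, p = NA_real_,
                n_significant = 0L))
  }
  tab <- table(factor(results$arm[sig], levels = c("5p", "3p")),
               factor(results$direction[sig], levels = c("down", "up")))
  counts[] <- as.integer(tab)
  props <- sweep(counts, 2, pmax(1, colSums(counts)), "/")
  p <- stats::fisher.test(counts)$p.value
  list(counts = counts, proportions = props, p = p,
       n_significant = sum(sig))
}

#' Restrict differential results to high-confidence miRNAs
#'
#' High confidence here means curated annotation of mature versus passenger
#' strands (MirGeneDB-style flags supplied as input).
#'
#' @param results a [diff_test()] table.
#' @param flags named logical vector keyed by miRNA id.
#' @return Filtered copy of `results`.
#' @export
highconf_subset <- function(results, flags) {
  keep <- results$mirna %in% names(flags)[flags %in% TRUE]
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
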