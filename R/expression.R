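#' Infer the miRNA arm from the identifier suffix
#'
#' Canonical `-5p` / `-3p` suffixes map to the corresponding arm; other
#' identifiers are `unspecified` (such miRNAs are excluded from arm
#' statistics).
#'
#' @param ids miRNA identifiers.
#' @return Character vector in {"5p","3p","unspecified"}.
#' @export
mirna_arm <- function(ids) {
  ifelse(grepl("-5p$", ids), "5p",
         ifelse(grepl("-3p$", ids), "3p", "unspecified"))
}

#' Construct an expression matrix object
#'
#' A light container for a miRNA x sample matrix with its dialect
#' (`batch_normalized` levels may be negative; `rpm` values are
#' non-negative; `reference_normalized` is the log2-ratio scale produced by
#' [reference_normalize()]) plus arm and high-confidence annotations.
#'
#' @param values numeric matrix, rows = miRNAs, columns = samples.
#' @param dialect one of `"batch_normalized"`, `"rpm"`,
#'   `"reference_normalized"`.
#' @param arm named vector (default: parsed from rownames).
#' @param high_confidence named logical vector (default: all FALSE).
#' @return An `expr_matrix` object.
#' @export
expression_matrix <- function(values,
                              dialect = c("batch_normalized", "rpm",
                                          "reference_normalized"),
                              arm = NULL, high_confidence = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression values need miRNA rownames and sample colnames")
  }
  if (dialect == "rpm" && any(values < 0, na.rm = TRUE)) {
    stop("rpm expression values must be non-negative")
  }
  ids <- rownames(values)
  arm <- arm %||% stats::setNames(mirna_arm(ids), ids)
  high_confidence <- high_confidence %||%
    stats::setNames(rep(FALSE, length(ids)), ids)
  structure(list(values = values, dialect = dialect,
                 arm = arm[ids], high_confidence = high_confidence[ids]),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d miRNAs x %d samples (%s dialect)\n",
              nrow(x$values), ncol(x$values), x$dialect))
  invisible(x)
}

subset_expr <- function(expr, keep) {
  expression_matrix(expr$values[keep, , drop = FALSE], expr$dialect,
                    expr$arm[keep], expr$high_confidence[keep])
}

#' Read an expression TSV (rows = miRNAs, columns = samples)
#'
#' @param path TSV whose first column (`mirna`) carries identifiers.
#' @param dialect expression dialect (see [expression_matrix()]).
#' @param annotation optional annotation data.frame
#'   (mirna/arm/high_confidence).
#' @return An `expr_matrix`.
#' @export
read_expression <- function(path, dialect = "batch_normalized",
                            annotation = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  arm <- hc <- NULL
  if (!is.null(annotation)) {
    assert_columns(annotation, c("mirna", "arm"), "annotation")
    arm <- stats::setNames(annotation$arm, annotation$mirna)
    if (!is.null(annotation$high_confidence)) {
      hc <- stats::setNames(as.logical(annotation$high_confidence),
                            annotation$mirna)
    }
  }
  expression_matrix(mat, dialect, arm, hc)
}

#' Remove miRNAs with frequently undetectable signal
#'
#' Drops miRNAs whose level is exactly 0 in more than 30% of samples for
#' pan-cancer analyses, or more than 10% for single-cancer analyses.
#'
#' @param expr an `expr_matrix`.
#' @param scope `"pan_cancer"` (30% cutoff) or `"single_cancer"` (10%).
#' @return Filtered `expr_matrix`.
#' @export
filter_expressed <- function(expr, scope = c("pan_cancer", "single_cancer")) {
  scope <- match.arg(scope)
  cutoff <- if (scope == "pan_cancer") 0.30 else 0.10
  zero_frac <- rowMeans(expr$values == 0)
  subset_expr(expr, zero_frac <= cutoff)
}

#' Equalize per-cancer median and variation of miRNA levels
#'
#' To make levels comparable across cancer types, each miRNA is centered on
#' its per-cancer median and scaled by its per-cancer maximal absolute
#' deviation from that median, giving per-cancer median exactly 0 and range
#' within [-1, 1] (constant miRNAs map to 0). The transform is idempotent.
#'
#' @param expr an `expr_matrix` (batch_normalized dialect).
#' @param cancer_labels cancer type per sample (named by sample or in
#'   column order); every cancer needs at least 2 samples.
#' @return Normalized `expr_matrix`.
#' @export
pan_cancer_normalize <- function(expr, cancer_labels) {
  v <- expr$values
  if (!is.null(names(cancer_labels))) cancer_labels <- cancer_labels[colnames(v)]
  if (length(cancer_labels) != ncol(v) || anyNA(cancer_labels)) {
    stop("every sample needs a cancer label")
  }
  counts <- table(cancer_labels)
  if (any(counts < 2)) {
    stop(sprintf("cancer type(s) with fewer than 2 samples: %s",
                 paste(names(counts)[counts < 2], collapse = ", ")))
  }
  out <- v
  for (cn in names(counts)) {
    idx <- which(cancer_labels == cn)
    sub <- v[, idx, drop = FALSE]
    med <- apply(sub, 1, stats::median)
    dev <- sub - med
    scale <- apply(abs(dev), 1, max)
    scale[scale == 0] <- 1 # constant miRNA: 0/0 -> 0
    out[, idx] <- dev / scale
  }
  expression_matrix(out, expr$dialect, expr$arm, expr$high_confidence)
}

#' Re-normalize RPM levels against a reference miRNA
#'
#' Expresses every miRNA as a per-sample log2 ratio to a reference miRNA
#' whose biogenesis is DICER1-independent (default miR-451a), removing any
#' artifact of normalizing against the total miRNA read count:
#' `x' = log2(x + pc) - log2(x_ref + pc)`. The transform is invariant to
#' per-sample global rescaling; the reference row becomes identically 0.
#'
#' @param expr an `expr_matrix` with `rpm` dialect.
#' @param reference_mirna reference identifier (error if absent; warning if
#'   zero in more than 10% of samples).
#' @param pseudocount added before taking logs (RPM units).
#' @param log use the log2-ratio form (`FALSE` gives the plain ratio).
#' @return `expr_matrix` with dialect `reference_normalized`.
#' @export
reference_normalize <- function(expr, reference_mirna = "hsa-miR-451a",
                                pseudocount = 1, log = TRUE) {
  if (expr$dialect != "rpm") {
    stop("reference_normalize expects the rpm dialect")
  }
  if (!reference_mirna %in% rownames(expr$values)) {
    stop(sprintf("reference miRNA %s absent from matrix", reference_mirna))
  }
  ref <- expr$values[reference_mirna, ]
  if (mean(ref == 0) > 0.10) {
    warning(sprintf("reference miRNA %s undetectable in %.0f%% of samples",
                    reference_mirna, 100 * mean(ref == 0)))
  }
  v <- expr$values
  out <- if (log) {
    sweep(log2(v + pseudocount), 2, log2(ref + pseudocount), "-")
  } else {
    sweep(v + pseudocount, 2, ref + pseudocount, "/")
  }
  expression_matrix(out, "reference_normalized", expr$arm,
                    expr$high_confidence)
}
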