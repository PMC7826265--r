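#' Read an isomiR table
#'
#' Long table of per-sample 5'-end isoform abundances: one record per
#' (sample, miRNA, offset), where `offset` is the signed distance (nt) of
#' the isoform 5' end from the annotated 5' end and `rpm` its abundance.
#'
#' @param path TSV with columns sample_id, mirna, offset, rpm.
#' @return data.frame.
#' @export
read_isomirs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_columns(df, c("sample_id", "mirna", "offset", "rpm"), "isomiR table")
  if (any(df$rpm < 0)) stop("isomiR rpm values must be >= 0")
  df
}

#' Select highly expressed 3p-miRNAs
#'
#' Reliable isomiR fractions need high expression; keeps 3p-annotated
#' miRNAs whose median total RPM (summed over offsets, per sample) across
#' the analyzed cohort is at least `min_rpm`.
#'
#' @param isomirs isomiR table ([read_isomirs()]).
#' @param arm named arm vector keyed by miRNA id.
#' @param min_rpm expression cutoff (default 100 RPM).
#' @param samples optional subset of samples defining the cohort.
#' @return Character vector of selected miRNA ids.
#' @export
select_high_expression_3p <- function(isomirs, arm, min_rpm = 100,
                                      samples = NULL) {
  if (!is.null(samples)) isomirs <- isomirs[isomirs$sample_id %in% samples, ]
  totals <- stats::aggregate(rpm ~ mirna + sample_id, isomirs, sum)
  med <- tapply(totals$rpm, totals$mirna, stats::median)
  ids <- names(med)[med >= min_rpm]
  ids[arm[ids] %in% "3p"]
}

#' Main-isoform fraction of a miRNA per sample
#'
#' The main 5' end is the offset with the highest summed per-sample read
#' share across the reference samples (a cohort-wide definition, so group
#' comparisons address the same isoform, and scale-free, so per-sample
#' library-size factors cannot change it). Per sample, the main fraction is
#' that offset's RPM over the total; upstream and downstream minor
#' fractions are the shares of offsets below and above the main offset.
#' Samples where the miRNA is entirely absent are excluded and counted.
#'
#' @param isomirs isomiR table.
#' @param mirna miRNA id.
#' @param reference_samples samples defining the main offset (default: all).
#' @return list(mirna, main_offset, fractions data.frame(sample_id, main,
#'   upstream, downstream), n_excluded).
#' @export
main_fraction <- function(isomirs, mirna, reference_samples = NULL) {
  sub <- isomirs[isomirs$mirna == mirna, , drop = FALSE]
  if (nrow(sub) == 0 || all(sub$rpm == 0)) {
    stop(sprintf("no positive isomiR signal for %s", mirna))
  }
  ref <- if (is.null(reference_samples)) sub else
    sub[sub$sample_id %in% reference_samples, , drop = FALSE]
  if (nrow(ref) == 0 || all(ref$rpm == 0)) ref <- sub
  ref_tot <- tapply(ref$rpm, ref$sample_id, sum)
  ref_share <- ref$rpm / as.numeric(ref_tot[ref$sample_id])
  ref_share[!is.finite(ref_share)] <- 0
  by_off <- tapply(ref_share, ref$offset, sum)
  main_offset <- as.integer(names(by_off)[which.max(by_off)])
  totals <- tapply(sub$rpm, sub$sample_id, sum)
  main <- tapply(sub$rpm * (sub$offset == main_offset), sub$sample_id, sum)
  up <- tapply(sub$rpm * (sub$offset < main_offset), sub$sample_id, sum)
  down <- tapply(sub$rpm * (sub$offset > main_offset), sub$sample_id, sum)
  ok <- totals > 0
  fr <- data.frame(sample_id = names(totals)[ok],
                   main = as.numeric(main[ok] / totals[ok]),
                   upstream = as.numeric(up[ok] / totals[ok]),
                   downstream = as.numeric(down[ok] / totals[ok]),
                   stringsAsFactors = FALSE)
  rownames(fr) <- NULL
  list(mirna = mirna, main_offset = main_offset, fractions = fr,
       n_excluded = sum(!ok))
}

#' Compare main-isoform fractions between mutation groups
#'
#' Per miRNA, a two-sided rank-sum comparison of the per-sample main
#' fractions between mutated and reference samples, plus a pooled test on
#' per-sample median fractions across the analyzed miRNAs. Groups with
#' fewer than 3 informative samples for a miRNA give `NA` with a warning.
#'
#' @param results list of [main_fraction()] outputs (or one such output).
#' @param mutated,reference sample id vectors.
#' @return list(per_mirna data.frame(mirna, main_offset, n_mut, n_ref,
#'   median_mut, median_ref, effect, p), pooled p).
#' @export
compare_fractions <- function(results, mutated, reference) {
  if (!is.null(results$fractions)) results <- list(results)
  rows <- lapply(results, function(r) {
    fr <- r$fractions
    a <- fr$main[fr$sample_id %in% mutated]
    b <- fr$main[fr$sample_id %in% reference]
    if (length(a) < 3 || length(b) < 3) {
      warning(sprintf("%s: fewer than 3 informative samples in a group",
                      r$mirna))
      p <- NA_real_
    } else {
      p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    }
    data.frame(mirna = r$mirna, main_offset = r$main_offset,
               n_mut = length(a), n_ref = length(b),
               median_mut = stats::median(a), median_ref = stats::median(b),
               effect = stats::median(a) - stats::median(b), p = p,
               stringsAsFactors = FALSE)
  })
  per_mirna <- do.call(rbind, rows)
  # pooled: per-sample median main fraction across miRNAs
  all_fr <- do.call(rbind, lapply(results, function(r) r$fractions))
  per_sample <- tapply(all_fr$main, all_fr$sample_id, stats::median)
  a <- per_sample[names(per_sample) %in% mutated]
  b <- per_sample[names(per_sample) %in% reference]
  pooled <- if (length(a) >= 3 && length(b) >= 3) {
    suppressWarnings(stats::wilcox.test(a, b)$p.value)
  } else NA_real_
  list(per_mirna = per_mirna, pooled = pooled)
}
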