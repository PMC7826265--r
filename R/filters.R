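#' Apply the somatic-call reliability filters
#'
#' Retains a call iff every applicable criterion holds:
#'
#' 1. at least 2 alt-allele-supporting reads in the tumor, enforced when no
#'    alt read was detected in the matched normal;
#' 2. tumor alt-allele frequency at least 5x the normal alt-allele frequency,
#'    enforced when the normal frequency is > 0 (boundary inclusive);
#' 3. somatic score SSC > 30, for callers reporting it (VarScan2,
#'    SomaticSniper);
#' 4. tumor alt-allele base quality BQ > 20, for callers reporting it (MuSE,
#'    MuTect2).
#'
#' Absent SSC/BQ fields are not grounds for rejection. Filtering is total:
#' no input raises an error.
#'
#' @param calls caller variant data.frame (see [read_caller_file()]).
#' @return The subset of `calls` passing all applicable criteria.
#' @export
apply_reliability_filters <- function(calls) {
  if (nrow(calls) == 0) return(calls)
  keep <- reliability_pass(calls)
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-call reliability predicate
#'
#' Vectorized conjunction underlying [apply_reliability_filters()]; exposed
#' so callers can inspect which records pass.
#'
#' @param calls caller variant data.frame.
#' @return Logical vector, one element per call.
#' @export
reliability_pass <- function(calls) {
  crit_alt <- calls$n_alt_reads != 0 | calls$t_alt_reads >= 2
  crit_freq <- calls$n_alt_freq <= 0 | calls$t_alt_freq >= 5 * calls$n_alt_freq
  crit_ssc <- is.na(calls$ssc) | calls$ssc > 30
  crit_bq <- is.na(calls$bq) | calls$bq > 20
  crit_alt & crit_freq & crit_ssc & crit_bq
}
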