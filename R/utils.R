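#' @keywords internal
"_PACKAGE"

#' Somatic variant callers recognized by the package
#'
#' The four caller dialects the consensus layer understands. SSC (somatic
#' score) is reported by VarScan2 and SomaticSniper; BQ (alt-allele base
#' quality in the tumor) by MuSE and MuTect2.
#'
#' @format Character vector of caller names.
#' @export
CALLERS <- c("MuSE", "MuTect2", "VarScan2", "SomaticSniper")

SSC_CALLERS <- c("VarScan2", "SomaticSniper")
BQ_CALLERS <- c("MuSE", "MuTect2")

CONSEQUENCE_CLASSES <- c("missense", "synonymous", "nonsense", "frameshift",
                         "inframe_indel", "splice_site", "start_stop", "other")

#' Mutation classes treated as definitively deleterious
#'
#' Frameshift, nonsense and splice-site mutations, i.e. classes expected to
#' abolish protein function.
#'
#' @export
DELETERIOUS_CLASSES <- c("frameshift", "nonsense", "splice_site")

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-up (base round() is banker's rounding; printed percentages in
# atlas summaries use the conventional half-up rule)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

assert_columns <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

variant_key <- function(sample_id, chrom, pos, ref, alt) {
  paste(sample_id, chrom, pos, ref, alt, sep = "|")
}

empty_caller_variants <- function() {
  data.frame(
    caller = character(0), sample_id = character(0), chrom = character(0),
    pos = integer(0), ref = character(0), alt = character(0),
    filter_status = character(0),
    t_alt_reads = integer(0), n_alt_reads = integer(0),
    t_alt_freq = numeric(0), n_alt_freq = numeric(0),
    ssc = numeric(0), bq = numeric(0),
    stringsAsFactors = FALSE
  )
}
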