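#' Caller VCF dialects
#'
#' The four supported caller outputs share the VCF 4.2 container but differ in
#' where the fields used by the reliability filters live. The dialect contract
#' implemented (and emitted by the synthetic generator) is:
#'
#' * **MuSE** — `FORMAT GT:DP:AD:BQ`; `AD` = "ref,alt" read counts, allele
#'   frequency derived as alt/DP, `BQ` = alt-allele base quality (tumor).
#' * **MuTect2** — `FORMAT GT:AD:AF:BQ`; `AF` carries the allele frequency
#'   directly.
#' * **VarScan2** — `INFO SSC=<somatic score>`; `FORMAT GT:DP:RD:AD:FREQ`
#'   with `AD` = alt reads, `RD` = ref reads; frequency derived as alt/DP
#'   (the percent-formatted `FREQ` field is emitted for display fidelity).
#' * **SomaticSniper** — `FORMAT GT:DP:AD:SSC`; `AD` = alt reads, per-sample
#'   somatic score in `SSC`.
#'
#' Each file holds one tumor/normal pair with sample columns `NORMAL` and
#' `TUMOR`; the tumor sample identifier is carried in a `##tumor_sample=`
#' header line.
#'
#' @name caller-dialects
NULL

DIALECT_FORMAT <- list(
  MuSE = "GT:DP:AD:BQ",
  MuTect2 = "GT:AD:AF:BQ",
  VarScan2 = "GT:DP:RD:AD:FREQ",
  SomaticSniper = "GT:DP:AD:SSC"
)

check_dialect <- function(dialect) {
  if (length(dialect) != 1 || !dialect %in% CALLERS) {
    stop(sprintf("unknown caller dialect: %s (expected one of %s)",
                 paste(dialect, collapse = ","),
                 paste(CALLERS, collapse = ", ")), call. = FALSE)
  }
  dialect
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

ad_split <- function(x, which) {
  # "ref,alt" -> requested component as numeric
  parts <- strsplit(ifelse(is.na(x), "NA,NA", x), ",", fixed = TRUE)
  vapply(parts, function(p) num_or_na(p[which]), numeric(1))
}

#' Read one caller's somatic calls for one tumor/normal pair
#'
#' Parses a caller VCF (see [caller-dialects]) and returns the calls with
#' `PASS` filter status only, with read support and quality fields mapped
#' from the dialect-specific locations. Coordinates are kept 1-based as in
#' the source.
#'
#' @param path VCF path.
#' @param dialect one of `CALLERS`.
#' @param sample_id tumor sample identifier; defaults to the
#'   `##tumor_sample=` header line.
#' @return data.frame of caller variants (one row per PASS record) with
#'   columns caller, sample_id, chrom, pos, ref, alt, filter_status,
#'   t_alt_reads, n_alt_reads, t_alt_freq, n_alt_freq, ssc, bq.
#' @export
read_caller_file <- function(path, dialect, sample_id = NULL) {
  check_dialect(dialect)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  nfield <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  if (any(nfield != 11L)) {
    bad <- body[which(nfield != 11L)[1]]
    stop(sprintf("parse error in %s at line %d: expected 11 tab-separated fields",
                 path, bad))
  }
  if (is.null(sample_id)) {
    m <- grep("^##tumor_sample=", lines, value = TRUE)
    if (length(m)) sample_id <- sub("^##tumor_sample=", "", m[1])
  }
  if (length(body) == 0) return(empty_caller_variants())
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop(sprintf("parse error in %s: %s",
                                                   path, conditionMessage(e))))
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) return(empty_caller_variants())
  el <- function(element, sample) {
    m <- vcfR::extract.gt(vcf, element = element)
    if (nrow(fix) == 1 && is.null(dim(m))) m <- matrix(m, nrow = 1,
                                                       dimnames = list(NULL, names(m)))
    m[, sample]
  }
  if (dialect == "MuSE") {
    t_alt <- ad_split(el("AD", "TUMOR"), 2); t_dp <- num_or_na(el("DP", "TUMOR"))
    n_alt <- ad_split(el("AD", "NORMAL"), 2); n_dp <- num_or_na(el("DP", "NORMAL"))
    t_freq <- ifelse(t_dp > 0, t_alt / t_dp, 0)
    n_freq <- ifelse(n_dp > 0, n_alt / n_dp, 0)
    ssc <- rep(NA_real_, nrow(fix)); bq <- num_or_na(el("BQ", "TUMOR"))
  } else if (dialect == "MuTect2") {
    t_alt <- ad_split(el("AD", "TUMOR"), 2); n_alt <- ad_split(el("AD", "NORMAL"), 2)
    t_freq <- num_or_na(el("AF", "TUMOR")); n_freq <- num_or_na(el("AF", "NORMAL"))
    ssc <- rep(NA_real_, nrow(fix)); bq <- num_or_na(el("BQ", "TUMOR"))
  } else if (dialect == "VarScan2") {
    t_alt <- num_or_na(el("AD", "TUMOR")); t_dp <- num_or_na(el("DP", "TUMOR"))
    n_alt <- num_or_na(el("AD", "NORMAL")); n_dp <- num_or_na(el("DP", "NORMAL"))
    t_freq <- ifelse(t_dp > 0, t_alt / t_dp, 0)
    n_freq <- ifelse(n_dp > 0, n_alt / n_dp, 0)
    ssc <- num_or_na(vcfR::extract.info(vcf, element = "SSC"))
    bq <- rep(NA_real_, nrow(fix))
  } else { # SomaticSniper
    t_alt <- num_or_na(el("AD", "TUMOR")); t_dp <- num_or_na(el("DP", "TUMOR"))
    n_alt <- num_or_na(el("AD", "NORMAL")); n_dp <- num_or_na(el("DP", "NORMAL"))
    t_freq <- ifelse(t_dp > 0, t_alt / t_dp, 0)
    n_freq <- ifelse(n_dp > 0, n_alt / n_dp, 0)
    ssc <- num_or_na(el("SSC", "TUMOR")); bq <- rep(NA_real_, nrow(fix))
  }
  out <- data.frame(
    caller = dialect,
    sample_id = sample_id %||% NA_character_,
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    filter_status = fix[, "FILTER"],
    t_alt_reads = as.integer(t_alt),
    n_alt_reads = as.integer(n_alt),
    t_alt_freq = t_freq,
    n_alt_freq = n_freq,
    ssc = ssc,
    bq = bq,
    stringsAsFactors = FALSE
  )
  out <- out[out$filter_status == "PASS", , drop = FALSE]
  rownames(out) <- NULL
  out
}

depth_for <- function(alt, freq, default = 60L) {
  ifelse(freq > 0, as.integer(round(alt / freq)), default)
}

#' Write caller variants as a dialect VCF
#'
#' Used by the synthetic cohort generator; also handy for building test
#' fixtures. See [caller-dialects] for the field layout.
#'
#' @param records data.frame of caller variants (as from
#'   [read_caller_file()]; `filter_status` defaults to PASS).
#' @param path output path.
#' @param dialect one of `CALLERS`.
#' @param sample_id tumor sample identifier written to the header.
#' @export
write_caller_vcf <- function(records, path, dialect, sample_id) {
  check_dialect(dialect)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=mutatlas synthetic cohort (%s dialect)", dialect),
    sprintf("##tumor_sample=%s", sample_id),
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FILTER=<ID=REJECT,Description=\"Rejected call\">",
    "##INFO=<ID=SSC,Number=1,Type=Float,Description=\"Somatic score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=.,Type=Integer,Description=\"Allele read counts\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
    "##FORMAT=<ID=RD,Number=1,Type=Integer,Description=\"Reference read count\">",
    "##FORMAT=<ID=FREQ,Number=1,Type=String,Description=\"Allele frequency (percent)\">",
    "##FORMAT=<ID=BQ,Number=1,Type=Float,Description=\"Alt base quality\">",
    "##FORMAT=<ID=SSC,Number=1,Type=Float,Description=\"Somatic score\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNORMAL\tTUMOR"
  )
  if (nrow(records) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  r <- records[order(records$chrom, records$pos, records$ref, records$alt), ,
               drop = FALSE]
  if (is.null(r$filter_status)) r$filter_status <- "PASS"
  td <- depth_for(r$t_alt_reads, r$t_alt_freq)
  nd <- depth_for(r$n_alt_reads, r$n_alt_freq)
  tr <- td - r$t_alt_reads; nr <- nd - r$n_alt_reads
  fmt_q <- function(x) ifelse(is.na(x), ".", formatC(x, format = "g", digits = 6))
  info <- rep(".", nrow(r))
  if (dialect == "MuSE") {
    fmtline <- DIALECT_FORMAT$MuSE
    normal <- sprintf("0/0:%d:%d,%d:.", nd, nr, r$n_alt_reads)
    tumor <- sprintf("0/1:%d:%d,%d:%s", td, tr, r$t_alt_reads, fmt_q(r$bq))
  } else if (dialect == "MuTect2") {
    fmtline <- DIALECT_FORMAT$MuTect2
    normal <- sprintf("0/0:%d,%d:%.6f:.", nr, r$n_alt_reads, r$n_alt_freq)
    tumor <- sprintf("0/1:%d,%d:%.6f:%s", tr, r$t_alt_reads, r$t_alt_freq,
                     fmt_q(r$bq))
  } else if (dialect == "VarScan2") {
    fmtline <- DIALECT_FORMAT$VarScan2
    info <- sprintf("SSC=%s;SOMATIC", fmt_q(r$ssc))
    normal <- sprintf("0/0:%d:%d:%d:%.4f%%", nd, nr, r$n_alt_reads,
                      100 * r$n_alt_freq)
    tumor <- sprintf("0/1:%d:%d:%d:%.4f%%", td, tr, r$t_alt_reads,
                     100 * r$t_alt_freq)
  } else {
    fmtline <- DIALECT_FORMAT$SomaticSniper
    normal <- sprintf("0/0:%d:%d:.", nd, r$n_alt_reads)
    tumor <- sprintf("0/1:%d:%d:%s", td, r$t_alt_reads, fmt_q(r$ssc))
  }
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s\t%s\t%s\t%s",
                  r$chrom, r$pos, r$ref, r$alt, r$filter_status, info,
                  fmtline, normal, tumor)
  writeLines(c(hdr, body), path)
  invisible(path)
}
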