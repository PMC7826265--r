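#' Left-normalize an indel representation
#'
#' Trims shared suffix then shared prefix bases from a ref/alt pair (keeping
#' the VCF anchor base), adjusting the position, so that the same indel
#' reported with different padding by two callers reduces to one canonical
#' key before deduplication.
#'
#' @param pos,ref,alt vectors describing variants (1-based VCF convention).
#' @return data.frame with normalized `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  for (i in seq_along(pos)) {
    r <- ref[i]; a <- alt[i]
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1, nchar(r) - 1)
      a <- substr(a, 1, nchar(a) - 1)
    }
    while (nchar(r) > 1 && nchar(a) > 1 && substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r))
      a <- substr(a, 2, nchar(a))
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- r; alt[i] <- a
  }
  data.frame(pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
}

#' Merge filter-passing calls across callers without duplication
#'
#' Variants detected by more than one algorithm are collapsed to a single
#' consensus record keyed by (sample, chrom, pos, ref, alt) after indel
#' left-normalization; the `callers` field records the union of supporting
#' callers. Cancer type is joined from the clinical table.
#'
#' @param per_caller a data.frame of filter-passing caller variants, or a
#'   list of such data.frames (one per caller).
#' @param clinical sample table with columns `sample_id`, `cancer_type`.
#' @return Consensus mutation data.frame: sample_id, cancer_type, chrom,
#'   pos, ref, alt, callers (comma-joined, caller order as in `CALLERS`),
#'   n_callers.
#' @export
merge_callers <- function(per_caller, clinical) {
  calls <- if (is.data.frame(per_caller)) per_caller else
    do.call(rbind, unname(per_caller))
  assert_columns(clinical, c("sample_id", "cancer_type"), "clinical table")
  if (is.null(calls) || nrow(calls) == 0) {
    return(data.frame(sample_id = character(0), cancer_type = character(0),
                      chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      callers = character(0), n_callers = integer(0),
                      stringsAsFactors = FALSE))
  }
  missing <- setdiff(unique(calls$sample_id), clinical$sample_id)
  if (length(missing)) {
    stop(sprintf("sample(s) absent from clinical table: %s",
                 paste(missing, collapse = ", ")))
  }
  norm <- normalize_variant(calls$pos, calls$ref, calls$alt)
  calls$pos <- norm$pos; calls$ref <- norm$ref; calls$alt <- norm$alt
  key <- variant_key(calls$sample_id, calls$chrom, calls$pos, calls$ref, calls$alt)
  first <- !duplicated(key)
  out <- calls[first, c("sample_id", "chrom", "pos", "ref", "alt"), drop = FALSE]
  caller_sets <- split(calls$caller, key)[key[first]]
  out$callers <- vapply(caller_sets, function(cs) {
    paste(CALLERS[CALLERS %in% cs], collapse = ",")
  }, character(1))
  out$n_callers <- vapply(caller_sets, function(cs) length(unique(cs)), integer(1))
  out$cancer_type <- clinical$cancer_type[match(out$sample_id, clinical$sample_id)]
  out <- out[, c("sample_id", "cancer_type", "chrom", "pos", "ref", "alt",
                 "callers", "n_callers")]
  out <- out[order(out$sample_id, out$chrom, out$pos, out$ref, out$alt), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
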