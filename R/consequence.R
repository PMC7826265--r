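#' Simplified transcript (CDS) models
#'
#' A CDS model holds, per gene, the genomic exon intervals of the coding
#' sequence (1-based, inclusive), the strand and the spliced CDS sequence.
#' It supports the simplified consequence classifier: codon translation for
#' SNVs, frame arithmetic for indels, and the 2-nt exon extensions as the
#' splice-site territory.
#'
#' @param model_path TSV with columns gene, chrom, strand, exon, start, end
#'   (1-based inclusive, exon = rank along the genome).
#' @param genome_path FASTA of the reference sequence.
#' @return Named list of CDS models.
#' @export
read_cds_models <- function(model_path, genome_path) {
  tab <- utils::read.delim(model_path, stringsAsFactors = FALSE)
  assert_columns(tab, c("gene", "chrom", "strand", "start", "end"), "CDS model")
  genome <- Biostrings::readDNAStringSet(genome_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  models <- lapply(split(tab, tab$gene), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    chrom <- g$chrom[1]; strand <- g$strand[1]
    if (!chrom %in% names(genome)) {
      stop(sprintf("chromosome %s absent from genome FASTA", chrom))
    }
    pieces <- substring(as.character(genome[[chrom]]), g$start, g$end)
    cds <- paste(pieces, collapse = "")
    if (strand == "-") {
      cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    }
    list(gene = g$gene[1], chrom = chrom, strand = strand,
         exons = data.frame(start = g$start, end = g$end), cds = cds)
  })
  models
}

# 1-based CDS index of a genomic position, NA if not exonic
genomic_to_cds <- function(model, pos) {
  ex <- model$exons
  i <- which(pos >= ex$start & pos <= ex$end)
  if (length(i) == 0) return(NA_integer_)
  if (model$strand == "+") {
    before <- if (i > 1) sum(ex$end[seq_len(i - 1)] - ex$start[seq_len(i - 1)] + 1L) else 0L
    before + (pos - ex$start[i] + 1L)
  } else {
    n <- nrow(ex)
    after <- if (i < n) sum(ex$end[(i + 1):n] - ex$start[(i + 1):n] + 1L) else 0L
    after + (ex$end[i] - pos + 1L)
  }
}

in_splice_window <- function(model, pos) {
  ex <- model$exons
  any((pos >= ex$start - 2L & pos <= ex$start - 1L) |
      (pos >= ex$end + 1L & pos <= ex$end + 2L))
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

classify_one <- function(model, pos, ref, alt) {
  res <- list(consequence = "other", protein_pos = NA_integer_,
              protein_ref = NA_character_, protein_alt = NA_character_,
              protein_label = NA_character_)
  ex <- model$exons
  exonic <- any(pos >= ex$start & pos <= ex$end)
  if (!exonic) {
    if (in_splice_window(model, pos)) {
      res$consequence <- "splice_site"
      res$protein_label <- "splice"
      return(res)
    }
    stop(sprintf("mutation at %s:%d outside transcript model of %s",
                 model$chrom, pos, model$gene))
  }
  is_snv <- nchar(ref) == 1 && nchar(alt) == 1
  if (!is_snv) {
    # anchored indel: changed bases start at pos + 1
    del_span <- if (nchar(ref) > 1) (pos + 1L):(pos + nchar(ref) - 1L) else integer(0)
    off_exon <- del_span[!vapply(del_span, function(p) any(p >= ex$start & p <= ex$end),
                                 logical(1))]
    if (length(off_exon)) {
      # deletion running past the exon boundary removes splice territory
      res$consequence <- "splice_site"
      res$protein_label <- "splice"
      return(res)
    }
    cds_i <- genomic_to_cds(model, if (length(del_span)) del_span[1] else pos)
    aa <- if (is.na(cds_i)) NA_integer_ else as.integer(ceiling(cds_i / 3))
    ref_aa <- if (!is.na(aa)) translate_codon(substr(model$cds, 3 * aa - 2, 3 * aa)) else NA_character_
    delta <- nchar(alt) - nchar(ref)
    if (delta %% 3 != 0) {
      res$consequence <- "frameshift"
      res$protein_label <- sprintf("p.%s%dfs", ref_aa %||% "X", aa)
    } else {
      res$consequence <- "inframe_indel"
      res$protein_label <- sprintf("p.%s%d_inframe", ref_aa %||% "X", aa)
    }
    res$protein_pos <- aa; res$protein_ref <- ref_aa
    return(res)
  }
  cds_i <- genomic_to_cds(model, pos)
  aa <- as.integer(ceiling(cds_i / 3))
  frame <- cds_i - 3L * (aa - 1L)
  codon <- substr(model$cds, 3 * aa - 2, 3 * aa)
  base <- if (model$strand == "+") alt else unname(COMPLEMENT[alt])
  cds_ref <- substr(model$cds, cds_i, cds_i)
  expected_ref <- if (model$strand == "+") ref else unname(COMPLEMENT[ref])
  if (!identical(cds_ref, expected_ref)) {
    stop(sprintf("reference allele mismatch at %s:%d in %s (model %s, call %s)",
                 model$chrom, pos, model$gene, cds_ref, expected_ref))
  }
  new_codon <- codon
  substr(new_codon, frame, frame) <- base
  ref_aa <- translate_codon(codon)
  alt_aa <- translate_codon(new_codon)
  n_aa <- nchar(model$cds) %/% 3
  res$protein_pos <- aa; res$protein_ref <- ref_aa; res$protein_alt <- alt_aa
  res$protein_label <- sprintf("p.%s%d%s", ref_aa, aa, alt_aa)
  res$consequence <-
    if (aa == 1L && !identical(alt_aa, "M")) "start_stop"
    else if (aa == n_aa && identical(ref_aa, "*")) {
      if (identical(alt_aa, "*")) "synonymous" else "start_stop"
    }
    else if (identical(alt_aa, "*")) "nonsense"
    else if (identical(alt_aa, ref_aa)) "synonymous"
    else "missense"
  res
}

#' Classify mutation consequences against simplified CDS models
#'
#' SNVs are classified by codon translation (missense / synonymous /
#' nonsense, with start- and stop-codon hits as `start_stop`), indels by
#' frame arithmetic (frameshift when the length change is not a multiple of
#' 3, inframe otherwise), and positions within the 2-nt exon extensions as
#' `splice_site`. The deleterious classes are `DELETERIOUS_CLASSES`.
#'
#' @param muts consensus mutation data.frame with `gene`, `chrom`, `pos`,
#'   `ref`, `alt`.
#' @param models list of CDS models from [read_cds_models()].
#' @return `muts` with columns consequence, protein_pos, protein_ref,
#'   protein_alt, protein_label appended.
#' @export
classify_consequence <- function(muts, models) {
  n <- nrow(muts)
  cons <- character(n); ppos <- integer(n)
  pref <- character(n); palt <- character(n); plab <- character(n)
  for (i in seq_len(n)) {
    g <- muts$gene[i]
    model <- models[[g]]
    if (is.null(model)) {
      stop(sprintf("no transcript model for gene %s", g))
    }
    r <- classify_one(model, muts$pos[i], muts$ref[i], muts$alt[i])
    cons[i] <- r$consequence
    ppos[i] <- r$protein_pos %||% NA_integer_
    pref[i] <- r$protein_ref %||% NA_character_
    palt[i] <- r$protein_alt %||% NA_character_
    plab[i] <- r$protein_label %||% NA_character_
  }
  muts$consequence <- cons
  muts$protein_pos <- ppos
  muts$protein_ref <- pref
  muts$protein_alt <- palt
  muts$protein_label <- plab
  muts
}
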