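#' Validate a table of analyzed gene regions
#'
#' Gene regions are the coding exons of each analyzed gene extended by 2 nt on
#' each side (so that definitive splice-site mutations fall inside the
#' analyzed territory). Coordinates are 0-based half-open, as in BED.
#' Intervals belonging to the same gene are merged; intervals of different
#' genes must not overlap, and overlapping input is rejected at load time.
#'
#' @param df data.frame with columns `gene`, `chrom`, `start`, `end` and
#'   optionally `strand` (0-based half-open coordinates).
#' @return The validated (merged, sorted) regions data.frame with class
#'   `gene_regions`.
#' @export
gene_regions <- function(df) {
  if (inherits(df, "gene_regions")) return(df)
  assert_columns(df, c("gene", "chrom", "start", "end"), "gene regions")
  if (is.null(df$strand)) df$strand <- "+"
  if (!is.numeric(df$start) || !is.numeric(df$end)) {
    stop("gene region start/end must be numeric")
  }
  if (any(df$start < 0) || any(df$end <= df$start)) {
    stop("gene regions must satisfy 0 <= start < end (0-based half-open)")
  }
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  # merge intervals within each gene
  pieces <- lapply(split(seq_len(nrow(df)), df$gene), function(idx) {
    red <- GenomicRanges::reduce(gr[idx])
    data.frame(gene = df$gene[idx][1],
               chrom = as.character(GenomicRanges::seqnames(red)),
               start = GenomicRanges::start(red) - 1L,
               end = GenomicRanges::end(red),
               strand = df$strand[idx][1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  mgr <- GenomicRanges::GRanges(out$chrom, IRanges::IRanges(out$start + 1L, out$end))
  hits <- GenomicRanges::findOverlaps(mgr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(hits) > 0) {
    i <- S4Vectors::queryHits(hits)[1]; j <- S4Vectors::subjectHits(hits)[1]
    stop(sprintf("overlapping regions from different genes: %s and %s",
                 out$gene[i], out$gene[j]))
  }
  class(out) <- c("gene_regions", "data.frame")
  out
}

#' Total analyzed coding length per gene
#'
#' @param regions a [gene_regions()] table.
#' @return Named integer vector: sum of interval lengths (bp) per gene.
#' @export
coding_lengths <- function(regions) {
  regions <- gene_regions(regions)
  lens <- tapply(regions$end - regions$start, regions$gene, sum)
  stats::setNames(as.integer(lens), names(lens))
}

#' Read gene regions from a BED file
#'
#' @param path BED file; the name field carries the gene symbol.
#' @return A validated [gene_regions()] table.
#' @export
read_gene_regions <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  gene_regions(data.frame(
    gene = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = "+",
    stringsAsFactors = FALSE
  ))
}

#' Write gene regions to a BED file
#'
#' @param regions a [gene_regions()] table.
#' @param path output BED path.
#' @export
write_gene_regions <- function(regions, path) {
  regions <- gene_regions(regions)
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L, regions$end),
                               name = regions$gene)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Restrict consensus mutations to the analyzed gene regions
#'
#' Keeps mutations whose (1-based) position falls inside any analyzed
#' interval and annotates each retained mutation with the containing gene.
#' Because cross-gene overlaps are rejected at load time, a position maps to
#' at most one gene.
#'
#' @param muts consensus mutation data.frame (columns `chrom`, `pos`, ...).
#' @param regions a [gene_regions()] table.
#' @return `muts` subset with a `gene` column filled in.
#' @export
restrict_to_regions <- function(muts, regions) {
  regions <- gene_regions(regions)
  if (nrow(muts) == 0) {
    muts$gene <- character(0)
    return(muts)
  }
  q <- GenomicRanges::GRanges(muts$chrom, IRanges::IRanges(muts$pos, muts$pos))
  s <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start + 1L, regions$end))
  hits <- GenomicRanges::findOverlaps(q, s, select = "first")
  keep <- !is.na(hits)
  out <- muts[keep, , drop = FALSE]
  out$gene <- regions$gene[hits[keep]]
  rownames(out) <- NULL
  out
}
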