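#' Flag hypermutated samples
#'
#' A sample is hypermutated when its whole-exome mutation burden strictly
#' exceeds the threshold (default 10,000). Hypermutated samples (and their
#' mutations) are excluded from downstream atlas statistics to limit
#' passenger noise.
#'
#' @param samples sample table with `exome_mutation_total`.
#' @param threshold integer burden cutoff (strictly-greater comparison).
#' @return `samples` with a logical `hypermutated` column.
#' @export
flag_hypermutated <- function(samples, threshold = 10000L) {
  assert_columns(samples, "exome_mutation_total", "sample table")
  samples$hypermutated <- samples$exome_mutation_total > threshold
  samples
}

#' Drop hypermutated samples and their mutations
#'
#' @param muts consensus mutation table.
#' @param samples sample table (run through [flag_hypermutated()] first, or
#'   it is flagged here with the default threshold).
#' @return list(muts, samples) with flagged samples removed.
#' @export
exclude_hypermutated <- function(muts, samples) {
  if (is.null(samples$hypermutated)) samples <- flag_hypermutated(samples)
  keep <- samples$sample_id[!samples$hypermutated]
  list(muts = muts[muts$sample_id %in% keep, , drop = FALSE],
       samples = samples[!samples$hypermutated, , drop = FALSE])
}

#' Mutation classification summary
#'
#' Counts per consequence class, printed-style percentages (half-up to the
#' nearest integer) and the definitive-deleterious total
#' (frameshift + nonsense + splice-site).
#'
#' @param muts mutation table with a `consequence` column.
#' @return list(counts, percentages, total, deleterious_total).
#' @export
classification_summary <- function(muts) {
  counts <- stats::setNames(integer(length(CONSEQUENCE_CLASSES)),
                            CONSEQUENCE_CLASSES)
  if (nrow(muts) > 0) {
    tab <- table(factor(muts$consequence, levels = CONSEQUENCE_CLASSES))
    counts[names(tab)] <- as.integer(tab)
  }
  total <- sum(counts)
  pct <- if (total > 0) round_half_up(100 * counts / total) else counts * 0
  list(counts = counts, percentages = pct, total = total,
       deleterious_total = sum(counts[DELETERIOUS_CLASSES]))
}

#' Mutation density in mutations per kilobase
#'
#' Number of detected mutations divided by the analyzed gene length (total
#' length of all analyzed coding intervals), scaled to mut/kbp.
#'
#' @param count mutation count.
#' @param coding_length_bp analyzed length in bp (> 0).
#' @return Density in mutations per kbp.
#' @export
mutation_density <- function(count, coding_length_bp) {
  if (any(coding_length_bp <= 0)) stop("coding_length_bp must be > 0")
  1000 * count / coding_length_bp
}

#' Per-gene per-cancer mutated-sample frequency
#'
#' Percentage of samples of each cancer type carrying at least one mutation
#' in each gene (a sample with several mutations in a gene counts once),
#' plus a pan-cancer column. Hypermutated samples should be excluded first.
#'
#' @param muts mutation table (`sample_id`, `gene`).
#' @param samples sample table (`sample_id`, `cancer_type`).
#' @param genes genes to tabulate (default: those present in `muts`).
#' @return Matrix genes x (cancers, pan_cancer), in percent.
#' @export
sample_mutation_frequency <- function(muts, samples, genes = NULL) {
  genes <- genes %||% sort(unique(muts$gene))
  cancers <- sort(unique(samples$cancer_type))
  out <- matrix(0, length(genes), length(cancers) + 1L,
                dimnames = list(genes, c(cancers, "pan_cancer")))
  n_c <- table(factor(samples$cancer_type, levels = cancers))
  for (g in genes) {
    carr <- unique(muts$sample_id[muts$gene == g])
    cc <- samples$cancer_type[samples$sample_id %in% carr]
    hits <- table(factor(cc, levels = cancers))
    out[g, cancers] <- 100 * as.numeric(hits) / pmax(1, as.numeric(n_c))
    out[g, "pan_cancer"] <- 100 * length(carr) / nrow(samples)
  }
  out
}

#' Overmutation enrichment of genes in specific cancers
#'
#' For each gene and cancer, tests whether the gene's share of panel
#' mutations in that cancer exceeds its share in the pan-cancer background
#' (one-sided Fisher's exact test on the 2x2 table mutation counts
#' \{gene, other panel genes\} x \{cancer, pan-cancer\}). By default the
#' background excludes the tested cancer (no self-comparison) and counts
#' mutations, not mutated samples; both choices are configurable. P-values
#' are Bonferroni-adjusted over genes x cancers, so with 29 genes and 33
#' cancers adjusted significance at 0.05 corresponds to a nominal p below
#' about 5e-5.
#'
#' @param muts mutation table (post hypermutation exclusion).
#' @param samples sample table.
#' @param genes,cancers levels to test (defaults: all present).
#' @param include_self keep the tested cancer inside the background.
#' @param count_unit `"mutations"` or `"samples"` (mutated samples).
#' @return data.frame gene, cancer, a, b, c, d, odds_ratio, p, p_adjusted.
#' @export
overmutation_test <- function(muts, samples, genes = NULL, cancers = NULL,
                              include_self = FALSE,
                              count_unit = c("mutations", "samples")) {
  count_unit <- match.arg(count_unit)
  genes <- genes %||% sort(unique(muts$gene))
  cancers <- cancers %||% sort(unique(samples$cancer_type))
  if (count_unit == "samples") {
    muts <- muts[!duplicated(paste(muts$sample_id, muts$gene)), , drop = FALSE]
  }
  n_tests <- length(genes) * length(cancers)
  res <- vector("list", n_tests)
  i <- 0L
  for (g in genes) {
    for (cn in cancers) {
      in_c <- muts$cancer_type == cn
      in_g <- muts$gene == g
      bg <- if (include_self) rep(TRUE, nrow(muts)) else !in_c
      a <- sum(in_c & in_g); b <- sum(in_c & !in_g)
      cc <- sum(bg & in_g & (include_self | !in_c))
      d <- sum(bg & !in_g & (include_self | !in_c))
      i <- i + 1L
      if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0) {
        warning(sprintf("empty margin for %s in %s; p set to 1", g, cn))
        res[[i]] <- data.frame(gene = g, cancer = cn, a = a, b = b, c = cc,
                               d = d, odds_ratio = NA_real_, p = 1,
                               stringsAsFactors = FALSE)
        next
      }
      ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                               alternative = "greater")
      res[[i]] <- data.frame(gene = g, cancer = cn, a = a, b = b, c = cc,
                             d = d, odds_ratio = unname(ft$estimate),
                             p = ft$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$p_adjusted <- pmin(1, out$p * n_tests)
  out
}

#' Detect recurrently mutated amino-acid residues (hotspots)
#'
#' Point mutations with a protein position are grouped by (gene, residue);
#' indels are grouped by identical protein-level label. Residues reaching
#' the recurrence threshold are reported, sorted by count (descending),
#' then gene, then position.
#'
#' @param muts classified mutation table (needs `protein_pos`,
#'   `protein_label`, `consequence`).
#' @param min_recurrence smallest count called a hotspot (default 3).
#' @return data.frame gene, protein_pos, label, count, per-consequence
#'   breakdown columns, cancers (comma-joined multiset).
#' @export
detect_hotspots <- function(muts, min_recurrence = 3L) {
  empty <- data.frame(gene = character(0), protein_pos = integer(0),
                      label = character(0), count = integer(0),
                      cancers = character(0), stringsAsFactors = FALSE)
  if (nrow(muts) == 0) return(empty)
  point <- muts$consequence %in% c("missense", "synonymous", "nonsense", "start_stop") &
    !is.na(muts$protein_pos)
  indel <- muts$consequence %in% c("frameshift", "inframe_indel") &
    !is.na(muts$protein_label)
  key <- character(nrow(muts))
  key[point] <- paste(muts$gene[point], muts$protein_pos[point], sep = "|")
  key[indel] <- paste(muts$gene[indel], muts$protein_label[indel], sep = "#")
  use <- point | indel
  if (!any(use)) return(empty)
  groups <- split(which(use), key[use])
  rows <- lapply(groups, function(idx) {
    m <- muts[idx, , drop = FALSE]
    breakdown <- table(factor(m$consequence, levels = CONSEQUENCE_CLASSES))
    df <- data.frame(gene = m$gene[1],
                     protein_pos = m$protein_pos[1],
                     label = m$protein_label[1],
                     count = nrow(m),
                     cancers = paste(sort(m$cancer_type %||% character(0)),
                                     collapse = ","),
                     stringsAsFactors = FALSE)
    for (cl in CONSEQUENCE_CLASSES) df[[paste0("n_", cl)]] <- as.integer(breakdown[[cl]])
    df
  })
  out <- do.call(rbind, rows)
  out <- out[out$count >= min_recurrence, , drop = FALSE]
  out <- out[order(-out$count, out$gene, out$protein_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hotspot versus deleterious mutation proportions within a gene
#'
#' Splits a gene's hotspot-missense and deleterious mutations per cancer
#' type, reports the split with printed-style percentages, and tests each
#' cancer's split against the pan-cancer split of the remaining cancers
#' with a two-sided Fisher's exact test. Cancers with no relevant mutations
#' are omitted.
#'
#' @param muts classified mutation table.
#' @param gene gene to analyze.
#' @param hotspot_positions residues counted as hotspot (e.g. from
#'   [detect_hotspots()]).
#' @return list(pan = data.frame, per_cancer = data.frame).
#' @export
hotspot_vs_deleterious <- function(muts, gene, hotspot_positions) {
  m <- muts[muts$gene == gene, , drop = FALSE]
  hs <- m$consequence == "missense" & m$protein_pos %in% hotspot_positions
  del <- m$consequence %in% DELETERIOUS_CLASSES
  split_of <- function(sel) {
    h <- sum(hs & sel); d <- sum(del & sel); tot <- h + d
    data.frame(n_hotspot = h, n_deleterious = d,
               pct_hotspot = if (tot) round_half_up(100 * h / tot) else NA_real_,
               pct_deleterious = if (tot) round_half_up(100 * d / tot) else NA_real_)
  }
  pan <- split_of(rep(TRUE, nrow(m)))
  cancers <- sort(unique(m$cancer_type[hs | del]))
  rows <- lapply(cancers, function(cn) {
    sel <- m$cancer_type == cn
    s <- split_of(sel)
    rest <- split_of(!sel)
    p <- if ((s$n_hotspot + s$n_deleterious) == 0) NA_real_ else
      stats::fisher.test(matrix(c(s$n_hotspot, s$n_deleterious,
                                  rest$n_hotspot, rest$n_deleterious),
                                2, byrow = TRUE))$p.value
    cbind(data.frame(cancer = cn, stringsAsFactors = FALSE), s, p = p)
  })
  list(pan = pan,
       per_cancer = if (length(rows)) do.call(rbind, rows) else NULL)
}
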