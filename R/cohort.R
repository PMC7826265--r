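#' Default synthetic gene panel
#'
#' Four genes named after prominent miRNA biogenesis genes, with synthetic
#' coordinates and down-scaled coding lengths (real CDS lengths would only
#' slow the generator without adding information; mutation planting and
#' recovery are length-independent).
#'
#' @return data.frame with gene, cds_length (bp, multiple of 3 incl. the
#'   stop codon) and n_exons.
#' @export
default_gene_panel <- function() {
  data.frame(
    gene = c("SMAD4", "SMAD2", "DICER1", "TNRC6A"),
    cds_length = c(450L, 420L, 900L, 600L),
    n_exons = c(3L, 3L, 5L, 4L),
    stringsAsFactors = FALSE
  )
}

#' Default hotspot plan
#'
#' Recurrent missense mutations planted at single amino-acid residues,
#' echoing the recurrence structure seen in real tumor cohorts (an
#' SMAD4-style MH2 hotspot concentrated in gastrointestinal cancers and a
#' DICER1 RNase-domain hotspot concentrated in endometrial cancer).
#'
#' @return list of hotspot specs (gene, residue, count, cancers).
#' @export
default_hotspot_spec <- function() {
  list(
    list(gene = "SMAD4", residue = 50L, count = 10L, cancers = c("PAAD", "COAD")),
    list(gene = "DICER1", residue = 250L, count = 8L, cancers = "UCEC")
  )
}

#' Build and validate a synthetic cohort configuration
#'
#' Defaults define the study conditions of the package's validation cohort:
#' three cancer types of 60 samples each, a four-gene panel, planted
#' hotspots, a DICER1-like arm effect (5p down / 3p up sparing the
#' DICER1-independent reference miRNA miR-451a) and a survival hazard for
#' mutated samples.
#'
#' @param n_samples_per_cancer samples per cancer type.
#' @param cancer_types cancer type labels.
#' @param genes gene panel ([default_gene_panel()]).
#' @param hotspot_spec list of planted hotspots ([default_hotspot_spec()]).
#' @param deleterious_rate,missense_rate,synonymous_rate per-gene per-sample
#'   probabilities of planting one mutation of the class.
#' @param noise_call_rate expected false calls per sample per caller; each
#'   noise call is constructed to fail exactly one reliability filter.
#' @param hypermutated_fraction proportion of samples given an exome burden
#'   above the hypermutation threshold (such samples also carry extra
#'   passenger panel mutations).
#' @param arm_effect list(gene, class, shift_5p, shift_3p): samples carrying
#'   a mutation of `class` in `gene` have 5p-/3p-annotated miRNA levels
#'   shifted additively (normalized scale) and by the same amount in log2
#'   units (RPM scale), sparing `reference_mirna`.
#' @param reference_mirna DICER1-independent reference miRNA identifier.
#' @param survival_gene gene whose hotspot/deleterious carriers form the
#'   at-risk survival group (default: the arm-effect gene).
#' @param survival_hr hazard ratio (mutated vs unmutated), > 0.
#' @param n_mirna_pairs number of 5p/3p miRNA pairs simulated.
#' @param n_unspecified_mirna miRNAs without an arm suffix.
#' @param cnv_del_rate_mutated,cnv_del_rate_unmutated probability of a
#'   copy-number deletion call (<= -1) given mutation status in the gene.
#' @param seed integer; fully determines the emitted bundle.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_samples_per_cancer = 60L,
                          cancer_types = c("PAAD", "COAD", "UCEC"),
                          genes = default_gene_panel(),
                          hotspot_spec = default_hotspot_spec(),
                          deleterious_rate = 0.03,
                          missense_rate = 0.02,
                          synonymous_rate = 0.02,
                          noise_call_rate = 1,
                          hypermutated_fraction = 0.02,
                          arm_effect = list(gene = "DICER1", class = "hotspot",
                                            shift_5p = -0.5, shift_3p = 0.5),
                          reference_mirna = "hsa-miR-451a",
                          survival_gene = NULL,
                          survival_hr = 2,
                          n_mirna_pairs = 30L,
                          n_unspecified_mirna = 5L,
                          cnv_del_rate_mutated = 0.5,
                          cnv_del_rate_unmutated = 0.1,
                          seed = 1L) {
  bad <- function(field, why) {
    stop(sprintf("invalid cohort configuration: %s (%s)", field, why),
         call. = FALSE)
  }
  if (!is.numeric(n_samples_per_cancer) || n_samples_per_cancer < 1) {
    bad("n_samples_per_cancer", "must be a positive integer")
  }
  if (!length(cancer_types)) bad("cancer_types", "must be non-empty")
  assert_columns(genes, c("gene", "cds_length", "n_exons"), "genes")
  if (any(genes$cds_length %% 3 != 0)) bad("genes", "cds_length must be a multiple of 3")
  for (p in c("deleterious_rate", "missense_rate", "synonymous_rate",
              "hypermutated_fraction", "cnv_del_rate_mutated",
              "cnv_del_rate_unmutated")) {
    v <- get(p)
    if (!is.numeric(v) || v < 0 || v > 1) bad(p, "must be a probability in [0,1]")
  }
  if (!is.numeric(noise_call_rate) || noise_call_rate < 0) {
    bad("noise_call_rate", "must be >= 0")
  }
  if (!is.numeric(survival_hr) || survival_hr <= 0) {
    bad("survival_hr", "hazard ratio must be > 0")
  }
  if (!is.list(arm_effect) ||
      !all(c("gene", "class", "shift_5p", "shift_3p") %in% names(arm_effect))) {
    bad("arm_effect", "needs gene, class, shift_5p, shift_3p")
  }
  if (!is.finite(arm_effect$shift_5p) || !is.finite(arm_effect$shift_3p)) {
    bad("arm_effect", "shift parameters must be finite")
  }
  for (h in hotspot_spec) {
    if (!all(c("gene", "residue", "count", "cancers") %in% names(h))) {
      bad("hotspot_spec", "each entry needs gene, residue, count, cancers")
    }
    if (!h$gene %in% genes$gene) bad("hotspot_spec", sprintf("unknown gene %s", h$gene))
    if (h$residue < 2 || h$residue >= genes$cds_length[genes$gene == h$gene] / 3) {
      bad("hotspot_spec", sprintf("residue %d outside CDS of %s", h$residue, h$gene))
    }
    if (!all(h$cancers %in% cancer_types)) bad("hotspot_spec", "unknown cancer type")
  }
  if (!is.numeric(seed) || is.na(seed)) bad("seed", "must be an integer")
  cfg <- list(
    n_samples_per_cancer = as.integer(n_samples_per_cancer),
    cancer_types = cancer_types,
    genes = genes,
    hotspot_spec = hotspot_spec,
    deleterious_rate = deleterious_rate,
    missense_rate = missense_rate,
    synonymous_rate = synonymous_rate,
    noise_call_rate = noise_call_rate,
    hypermutated_fraction = hypermutated_fraction,
    arm_effect = arm_effect,
    reference_mirna = reference_mirna,
    survival_gene = survival_gene %||% arm_effect$gene,
    survival_hr = survival_hr,
    n_mirna_pairs = as.integer(n_mirna_pairs),
    n_unspecified_mirna = as.integer(n_unspecified_mirna),
    cnv_del_rate_mutated = cnv_del_rate_mutated,
    cnv_del_rate_unmutated = cnv_del_rate_unmutated,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  cfg
}

famseed <- function(seed, offset) {
  set.seed((as.integer(seed) %% 21474836L) * 100L + offset)
}

NONSTOP_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
})

# ---- genome and gene synthesis ------------------------------------------

synth_genome <- function(genes) {
  bases <- c("A", "C", "G", "T")
  chrom <- "chr1"
  cursor <- 1000L
  models <- list()
  exon_rows <- list()
  total_span <- 1000L +
    sum(genes$cds_length + (genes$n_exons - 1L) * 150L + 500L) + 1000L
  seqv <- sample(bases, total_span, replace = TRUE)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    n_codons <- g$cds_length %/% 3
    cds <- paste0("ATG",
                  paste(sample(NONSTOP_CODONS, n_codons - 2L, replace = TRUE),
                        collapse = ""),
                  "TAA")
    base_len <- g$cds_length %/% g$n_exons
    lens <- rep(base_len, g$n_exons)
    lens[g$n_exons] <- g$cds_length - base_len * (g$n_exons - 1L)
    starts <- integer(g$n_exons); ends <- integer(g$n_exons)
    pos <- cursor
    off <- 0L
    for (e in seq_len(g$n_exons)) {
      starts[e] <- pos
      ends[e] <- pos + lens[e] - 1L
      piece <- substr(cds, off + 1L, off + lens[e])
      seqv[starts[e]:ends[e]] <- strsplit(piece, "")[[1]]
      off <- off + lens[e]
      pos <- ends[e] + 150L + 1L
    }
    cursor <- ends[g$n_exons] + 500L
    models[[g$gene]] <- list(gene = g$gene, chrom = chrom, strand = "+",
                             exons = data.frame(start = starts, end = ends),
                             cds = cds)
    exon_rows[[g$gene]] <- data.frame(gene = g$gene, chrom = chrom, strand = "+",
                                      exon = seq_len(g$n_exons),
                                      start = starts, end = ends,
                                      stringsAsFactors = FALSE)
  }
  genome <- paste(seqv, collapse = "")
  # re-extract CDS from the assembled genome so models and genome agree
  list(chrom = chrom, genome = genome, models = models,
       exon_table = do.call(rbind, exon_rows))
}

regions_from_models <- function(models) {
  rows <- lapply(models, function(m) {
    data.frame(gene = m$gene, chrom = m$chrom,
               start = m$exons$start - 2L - 1L, # extend 2 nt, 0-based
               end = m$exons$end + 2L,
               strand = m$strand, stringsAsFactors = FALSE)
  })
  gene_regions(do.call(rbind, rows))
}

cds_to_genomic <- function(model, cds_i) {
  ex <- model$exons
  off <- 0L
  for (e in seq_len(nrow(ex))) {
    len <- ex$end[e] - ex$start[e] + 1L
    if (cds_i <= off + len) return(ex$start[e] + (cds_i - off - 1L))
    off <- off + len
  }
  stop("CDS index outside model")
}

genome_base <- function(genome, pos) substr(genome, pos, pos)

# ---- mutation planting ---------------------------------------------------

plant_substitution <- function(model, target = c("missense", "nonsense", "synonymous"),
                               residue = NULL) {
  target <- match.arg(target)
  n_aa <- nchar(model$cds) %/% 3
  residues <- if (!is.null(residue)) residue else sample(2:(n_aa - 1L))
  for (r in residues) {
    codon <- substr(model$cds, 3 * r - 2, 3 * r)
    ref_aa <- translate_codon(codon)
    if (ref_aa == "*") next
    for (fr in sample(1:3)) {
      refb <- substr(codon, fr, fr)
      for (b in sample(setdiff(c("A", "C", "G", "T"), refb))) {
        nc <- codon; substr(nc, fr, fr) <- b
        aa <- translate_codon(nc)
        ok <- switch(target,
                     missense = aa != ref_aa && aa != "*",
                     nonsense = aa == "*",
                     synonymous = aa == ref_aa)
        if (ok) {
          cds_i <- 3L * (r - 1L) + fr
          return(list(pos = cds_to_genomic(model, cds_i), ref = refb, alt = b,
                      consequence = if (target == "nonsense") "nonsense" else target,
                      protein_pos = r,
                      protein_label = sprintf("p.%s%d%s", ref_aa, r, aa)))
        }
      }
    }
    if (!is.null(residue)) break
  }
  NULL
}

plant_frameshift <- function(model, genome) {
  ex <- model$exons
  e <- sample(nrow(ex), 1)
  # keep the changed base well inside the exon
  pos <- sample((ex$start[e] + 2L):(ex$end[e] - 3L), 1)
  anchor <- genome_base(genome, pos)
  if (stats::runif(1) < 0.5) {
    ref <- anchor
    alt <- paste0(anchor, sample(c("A", "C", "G", "T"), 1))
  } else {
    ref <- paste0(anchor, genome_base(genome, pos + 1L))
    alt <- anchor
  }
  cds_i <- genomic_to_cds(model, pos + 1L)
  r <- as.integer(ceiling(cds_i / 3))
  ref_aa <- translate_codon(substr(model$cds, 3 * r - 2, 3 * r))
  list(pos = pos, ref = ref, alt = alt, consequence = "frameshift",
       protein_pos = r, protein_label = sprintf("p.%s%dfs", ref_aa, r))
}

plant_splice <- function(model, genome) {
  ex <- model$exons
  e <- sample(nrow(ex), 1)
  side <- sample(c("donor", "acceptor"), 1)
  pos <- if (side == "donor") ex$end[e] + sample(1:2, 1) else
    ex$start[e] - sample(1:2, 1)
  refb <- genome_base(genome, pos)
  alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
  list(pos = pos, ref = refb, alt = alt, consequence = "splice_site",
       protein_pos = NA_integer_, protein_label = "splice")
}

plant_deleterious <- function(model, genome) {
  k <- sample(c("frameshift", "nonsense", "splice_site"), 1,
              prob = c(0.55, 0.35, 0.10))
  switch(k,
         frameshift = plant_frameshift(model, genome),
         nonsense = plant_substitution(model, "nonsense"),
         splice_site = plant_splice(model, genome))
}

support_fields <- function(caller_set) {
  depth <- sample(c(40L, 50L, 80L, 100L, 200L), 1)
  alt <- sample(8:round(0.6 * depth), 1)
  list(t_alt_reads = alt, n_alt_reads = 0L,
       t_alt_freq = alt / depth, n_alt_freq = 0,
       ssc = round(stats::runif(1, 40, 150), 1),
       bq = round(stats::runif(1, 25, 40), 1))
}

#' Construct a caller record violating exactly one reliability filter
#'
#' Returns a single caller-variant row whose field values fail the named
#' criterion of [apply_reliability_filters()] while satisfying the other
#' three (criteria that do not apply to the chosen caller are satisfied
#' vacuously). Coordinates are left `NA` for the caller of this function to
#' fill in.
#'
#' @param failing_filter one of `"alt_reads"`, `"freq_ratio"`, `"ssc"`,
#'   `"bq"`.
#' @param caller caller dialect; defaults to one for which the failing field
#'   is applicable.
#' @return One-row caller variant data.frame.
#' @export
emit_noise_call <- function(failing_filter, caller = NULL) {
  filters <- c("alt_reads", "freq_ratio", "ssc", "bq")
  if (length(failing_filter) != 1 || !failing_filter %in% filters) {
    stop(sprintf("unknown filter id: %s (expected one of %s)",
                 paste(failing_filter, collapse = ","),
                 paste(filters, collapse = ", ")))
  }
  caller <- caller %||% switch(failing_filter,
                               ssc = "VarScan2", bq = "MuSE",
                               alt_reads = "MuTect2", freq_ratio = "MuSE")
  check_dialect(caller)
  if (failing_filter == "ssc" && !caller %in% SSC_CALLERS) {
    stop(sprintf("caller %s does not report SSC", caller))
  }
  if (failing_filter == "bq" && !caller %in% BQ_CALLERS) {
    stop(sprintf("caller %s does not report BQ", caller))
  }
  f <- list(t_alt_reads = 20L, n_alt_reads = 0L,
            t_alt_freq = 20 / 100, n_alt_freq = 0,
            ssc = if (caller %in% SSC_CALLERS) 60 else NA_real_,
            bq = if (caller %in% BQ_CALLERS) 30 else NA_real_)
  if (failing_filter == "alt_reads") {
    f$t_alt_reads <- 1L; f$t_alt_freq <- 1 / 100
  } else if (failing_filter == "freq_ratio") {
    # normal carries alt reads, so the >=2-read rule does not apply;
    # tumor/normal frequency ratio is 4 (< 5)
    f$n_alt_reads <- 5L; f$n_alt_freq <- 5 / 100
    f$t_alt_reads <- 20L; f$t_alt_freq <- 20 / 100
  } else if (failing_filter == "ssc") {
    f$ssc <- 29
  } else {
    f$bq <- 19
  }
  data.frame(caller = caller, sample_id = NA_character_, chrom = NA_character_,
             pos = NA_integer_, ref = NA_character_, alt = NA_character_,
             filter_status = "PASS",
             t_alt_reads = f$t_alt_reads, n_alt_reads = f$n_alt_reads,
             t_alt_freq = f$t_alt_freq, n_alt_freq = f$n_alt_freq,
             ssc = f$ssc, bq = f$bq, stringsAsFactors = FALSE)
}

# ---- component simulators -----------------------------------------------

#' Simulate miRNA expression matrices with an arm-asymmetric mutation effect
#'
#' Per-miRNA baselines are log-normal on the RPM scale; noise is additive
#' Gaussian on the normalized scale and multiplicative log-normal on the RPM
#' scale. Samples in `mutated_ids` have 5p-annotated miRNAs shifted by
#' `shift_5p` and 3p-annotated ones by `shift_3p` (additively on the
#' normalized scale, by the same amount in log2 units on the RPM scale);
#' the reference miRNA and arm-unspecified miRNAs are untouched. Dropout
#' zeros model undetectable signals.
#'
#' @param sample_ids,mutated_ids sample identifiers (mutated subset).
#' @param annot data.frame mirna/arm/high_confidence ([mirna_panel()]).
#' @param shift_5p,shift_3p additive shifts (normalized scale units / log2
#'   RPM units).
#' @param reference_mirna identifier excluded from shifting and dropout.
#' @param sigma_norm Gaussian noise SD on the normalized scale.
#' @param noise_sdlog log-normal noise SD on the RPM scale.
#' @param dropout per-miRNA zero probability (scalar or vector).
#' @return list with `normalized` and `rpm` miRNA x sample matrices.
#' @export
simulate_expression <- function(sample_ids, mutated_ids, annot,
                                shift_5p = 0, shift_3p = 0,
                                reference_mirna = "hsa-miR-451a",
                                sigma_norm = 0.25, noise_sdlog = 0.5,
                                dropout = 0.02) {
  m <- nrow(annot); n <- length(sample_ids)
  mu <- stats::rnorm(m, 0, 0.2)
  b <- stats::rlnorm(m, log(200), 1)
  is_ref <- annot$mirna == reference_mirna
  b[is_ref] <- 1000
  drop_p <- rep(dropout, length.out = m)
  drop_p[is_ref] <- 0
  shift <- ifelse(annot$arm == "5p", shift_5p,
                  ifelse(annot$arm == "3p", shift_3p, 0))
  shift[is_ref] <- 0
  mut <- as.numeric(sample_ids %in% mutated_ids)
  shift_mat <- outer(shift, mut)
  normalized <- mu + shift_mat + matrix(stats::rnorm(m * n, 0, sigma_norm), m, n)
  rpm <- b * 2^shift_mat * matrix(stats::rlnorm(m * n, 0, noise_sdlog), m, n)
  zero <- matrix(stats::runif(m * n) < drop_p, m, n)
  normalized[zero] <- 0
  rpm[zero] <- 0
  dimnames(normalized) <- dimnames(rpm) <- list(annot$mirna, sample_ids)
  list(normalized = normalized, rpm = rpm)
}

#' Simulate exponential survival with proportional hazards
#'
#' Exponential event times with baseline median `baseline_median` days; the
#' hazard of subjects with `group = TRUE` is multiplied by `hr`. Censoring is
#' uniform over `[0, follow_up]`.
#'
#' @param group logical vector (TRUE = at-risk group).
#' @param hr hazard ratio, > 0.
#' @param baseline_median median survival of the baseline group (days).
#' @param follow_up maximal follow-up (days).
#' @return data.frame with `os_time` (days) and `os_event` (1 = death).
#' @export
simulate_survival <- function(group, hr = 2, baseline_median = 1095,
                              follow_up = 3650) {
  lambda0 <- log(2) / baseline_median
  lambda <- lambda0 * ifelse(group, hr, 1)
  t_event <- stats::rexp(length(group), lambda)
  t_cens <- stats::runif(length(group), 0, follow_up)
  data.frame(os_time = pmin(t_event, t_cens),
             os_event = as.integer(t_event <= t_cens))
}

#' Simulate 5'-end isomiR tables
#'
#' For every miRNA x sample cell with positive total RPM, distributes reads
#' over 5' offsets (-1, 0, +1); offset 0 is the annotated (main) 5' end,
#' whose fraction is Beta-distributed with median ~0.95. Samples in
#' `mutated_ids` have the main fraction reduced by `main_shift`.
#'
#' @param totals miRNA x sample RPM matrix (e.g. the `rpm` component of
#'   [simulate_expression()], subset to 3p miRNAs).
#' @param mutated_ids samples whose main fraction is shifted.
#' @param main_shift reduction of the main-isoform fraction in mutated
#'   samples.
#' @param beta_shape1,beta_shape2 Beta parameters of the main fraction.
#' @return Long data.frame: sample_id, mirna, offset, rpm.
#' @export
simulate_isomirs <- function(totals, mutated_ids = character(),
                             main_shift = 0,
                             beta_shape1 = 57, beta_shape2 = 3) {
  mirnas <- rownames(totals); samples <- colnames(totals)
  m <- length(mirnas); n <- length(samples)
  f <- matrix(stats::rbeta(m * n, beta_shape1, beta_shape2), m, n)
  mut <- samples %in% mutated_ids
  f[, mut] <- pmax(0, f[, mut] - main_shift)
  up_share <- matrix(stats::runif(m * n), m, n)
  rows <- list(
    data.frame(sample_id = rep(samples, each = m),
               mirna = rep(mirnas, n), offset = -1L,
               rpm = as.vector(totals * (1 - f) * up_share)),
    data.frame(sample_id = rep(samples, each = m),
               mirna = rep(mirnas, n), offset = 0L,
               rpm = as.vector(totals * f)),
    data.frame(sample_id = rep(samples, each = m),
               mirna = rep(mirnas, n), offset = 1L,
               rpm = as.vector(totals * (1 - f) * (1 - up_share)))
  )
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, out$mirna, out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Synthetic miRNA panel
#'
#' `n_pairs` 5p/3p pairs, `n_unspecified` miRNAs without an arm suffix, and
#' the reference miRNA. High-confidence flags are drawn Bernoulli(0.6).
#'
#' @param n_pairs,n_unspecified panel sizes.
#' @param reference_mirna reference miRNA id (always high-confidence).
#' @return data.frame mirna/arm/high_confidence.
#' @export
mirna_panel <- function(n_pairs = 30L, n_unspecified = 5L,
                        reference_mirna = "hsa-miR-451a") {
  ids <- c(
    sprintf("hsa-miR-%d-5p", 100 + seq_len(n_pairs)),
    sprintf("hsa-miR-%d-3p", 100 + seq_len(n_pairs)),
    if (n_unspecified > 0) sprintf("hsa-miR-%d", 400 + seq_len(n_unspecified)),
    reference_mirna
  )
  annot <- data.frame(mirna = ids, arm = mirna_arm(ids),
                      high_confidence = stats::runif(length(ids)) < 0.6,
                      stringsAsFactors = FALSE)
  annot$high_confidence[annot$mirna == reference_mirna] <- TRUE
  annot
}
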