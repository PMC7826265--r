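#' Samples carrying a mutation class in a gene (ground-truth view)
#' @noRd
carriers_of <- function(muts, gene, class) {
  if (nrow(muts) == 0) return(character(0))
  sel <- muts$gene == gene & switch(class,
                                    any = TRUE,
                                    muts$class == class)
  unique(muts$sample_id[sel])
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

matrix_to_tsv <- function(mat, path) {
  df <- data.frame(mirna = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Generate a synthetic cohort file bundle with known ground truth
#'
#' Emits, for each sample, four caller-dialect VCFs in which every planted
#' true mutation appears in at least one caller with field values passing
#' all four reliability filters, plus noise calls constructed to fail
#' exactly one named filter; a synthetic genome, CDS models and extended
#' gene regions; normalized and RPM expression matrices in which carriers
#' of the configured arm-effect mutation have 5p/3p miRNA levels shifted
#' (sparing the reference miRNA); isomiR tables; clinical data with
#' exponential survival at the configured hazard ratio; and thresholded
#' copy-number calls with deletion enrichment in mutated samples. The
#' bundle is fully determined by `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, list(dir, files, ground_truth). The ground truth is
#'   also written to `ground_truth.json`.
#' @export
generate_cohort <- function(config, out_dir) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "vcf"), showWarnings = FALSE)
  bases <- c("A", "C", "G", "T")

  ## reference sequence, transcript models, analyzed regions
  famseed(config$seed, 1L)
  gen <- synth_genome(config$genes)
  models <- gen$models
  regions <- regions_from_models(models)
  genome_path <- file.path(out_dir, "genome.fa")
  gseq <- Biostrings::DNAStringSet(stats::setNames(gen$genome, gen$chrom))
  Biostrings::writeXStringSet(gseq, genome_path)
  model_path <- write_tsv(gen$exon_table, file.path(out_dir, "cds_models.tsv"))
  bed_path <- write_gene_regions(regions, file.path(out_dir, "regions.bed"))

  ## samples
  famseed(config$seed, 2L)
  samples <- data.frame(
    cancer_type = rep(config$cancer_types, each = config$n_samples_per_cancer),
    stringsAsFactors = FALSE
  )
  samples$sample_id <- sprintf("S-%s-%03d", samples$cancer_type,
                               sequence(rep(config$n_samples_per_cancer,
                                            length(config$cancer_types))))
  N <- nrow(samples)
  samples$exome_mutation_total <- pmax(1L, as.integer(round(stats::rlnorm(N, log(150), 1))))
  n_h <- round(config$hypermutated_fraction * N)
  hyper_idx <- if (n_h > 0) sample(N, n_h) else integer(0)
  if (n_h > 0) {
    samples$exome_mutation_total[hyper_idx] <-
      sample(12000:30000, n_h, replace = TRUE)
  }
  samples$stage <- sample(c("I", "II", "III", "IV"), N, replace = TRUE,
                          prob = c(0.3, 0.3, 0.25, 0.15))
  hyper_ids <- samples$sample_id[hyper_idx]

  ## planted mutations
  famseed(config$seed, 3L)
  mut_rows <- list()
  used_keys <- character(0)
  add_mut <- function(sample_id, gene, plant, class) {
    if (is.null(plant)) return(FALSE)
    key <- paste(sample_id, plant$pos, sep = "|")
    if (key %in% used_keys) return(FALSE)
    used_keys <<- c(used_keys, key)
    cs <- CALLERS[stats::runif(4) < 0.8]
    if (!length(cs)) cs <- sample(CALLERS, 1)
    sup <- support_fields(cs)
    mut_rows[[length(mut_rows) + 1L]] <<- data.frame(
      sample_id = sample_id,
      cancer_type = samples$cancer_type[match(sample_id, samples$sample_id)],
      gene = gene, chrom = gen$chrom, pos = plant$pos,
      ref = plant$ref, alt = plant$alt,
      consequence = plant$consequence, class = class,
      protein_pos = plant$protein_pos, protein_label = plant$protein_label,
      callers = paste(CALLERS[CALLERS %in% cs], collapse = ","),
      t_alt_reads = sup$t_alt_reads, n_alt_reads = sup$n_alt_reads,
      t_alt_freq = sup$t_alt_freq, n_alt_freq = sup$n_alt_freq,
      ssc = sup$ssc, bq = sup$bq, stringsAsFactors = FALSE
    )
    TRUE
  }
  non_hyper <- setdiff(samples$sample_id, hyper_ids)
  for (h in config$hotspot_spec) {
    eligible <- intersect(
      samples$sample_id[samples$cancer_type %in% h$cancers], non_hyper)
    if (length(eligible) < h$count) {
      stop(sprintf("hotspot_spec for %s requests %d carriers but only %d eligible samples",
                   h$gene, h$count, length(eligible)))
    }
    for (sid in sample(eligible, h$count)) {
      plant <- plant_substitution(models[[h$gene]], "missense", h$residue)
      add_mut(sid, h$gene, plant, "hotspot")
    }
  }
  rates <- c(deleterious = config$deleterious_rate,
             missense = config$missense_rate,
             synonymous = config$synonymous_rate)
  for (g in config$genes$gene) {
    for (sid in samples$sample_id) {
      for (cls in names(rates)) {
        if (stats::runif(1) >= rates[[cls]]) next
        for (attempt in 1:5) {
          plant <- switch(cls,
                          deleterious = plant_deleterious(models[[g]], gen$genome),
                          missense = plant_substitution(models[[g]], "missense"),
                          synonymous = plant_substitution(models[[g]], "synonymous"))
          if (!is.null(plant) && add_mut(sid, g, plant, cls)) break
        }
      }
    }
  }
  # hypermutated samples carry extra passenger mutations
  for (sid in hyper_ids) {
    k <- 3L + stats::rpois(1, 3)
    for (j in seq_len(k)) {
      g <- sample(config$genes$gene, 1)
      cls <- sample(c("missense", "synonymous"), 1)
      for (attempt in 1:5) {
        plant <- plant_substitution(models[[g]], cls)
        if (!is.null(plant) && add_mut(sid, g, plant, cls)) break
      }
    }
  }
  muts <- if (length(mut_rows)) do.call(rbind, mut_rows) else
    data.frame(sample_id = character(0), cancer_type = character(0),
               gene = character(0), chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0),
               consequence = character(0), class = character(0),
               protein_pos = integer(0), protein_label = character(0),
               callers = character(0), t_alt_reads = integer(0),
               n_alt_reads = integer(0), t_alt_freq = numeric(0),
               n_alt_freq = numeric(0), ssc = numeric(0), bq = numeric(0))
  muts <- muts[order(muts$sample_id, muts$chrom, muts$pos, muts$ref, muts$alt), ,
               drop = FALSE]
  rownames(muts) <- NULL

  ## noise calls failing exactly one filter each
  famseed(config$seed, 4L)
  noise_rows <- list()
  for (sid in samples$sample_id) {
    for (cl in CALLERS) {
      k <- stats::rpois(1, config$noise_call_rate)
      applicable <- c("alt_reads", "freq_ratio",
                      if (cl %in% SSC_CALLERS) "ssc",
                      if (cl %in% BQ_CALLERS) "bq")
      for (j in seq_len(k)) {
        for (attempt in 1:10) {
          ri <- sample(nrow(regions), 1)
          pos <- sample((regions$start[ri] + 1L):regions$end[ri], 1)
          key <- paste(sid, pos, sep = "|")
          if (key %in% used_keys) next
          used_keys <- c(used_keys, key)
          rec <- emit_noise_call(sample(applicable, 1), cl)
          rec$sample_id <- sid
          rec$chrom <- regions$chrom[ri]
          rec$pos <- pos
          rec$ref <- genome_base(gen$genome, pos)
          rec$alt <- sample(setdiff(bases, rec$ref), 1)
          noise_rows[[length(noise_rows) + 1L]] <- rec
          break
        }
      }
    }
  }
  noise <- if (length(noise_rows)) do.call(rbind, noise_rows) else NULL

  ## non-PASS decoy records (dropped at extraction)
  famseed(config$seed, 5L)
  decoy_rows <- list()
  for (sid in samples$sample_id) {
    for (cl in CALLERS) {
      if (stats::runif(1) >= 0.25) next
      ri <- sample(nrow(regions), 1)
      pos <- sample((regions$start[ri] + 1L):regions$end[ri], 1)
      sup <- support_fields(cl)
      decoy_rows[[length(decoy_rows) + 1L]] <- data.frame(
        caller = cl, sample_id = sid, chrom = regions$chrom[ri], pos = pos,
        ref = genome_base(gen$genome, pos),
        alt = sample(setdiff(bases, genome_base(gen$genome, pos)), 1),
        filter_status = "REJECT",
        t_alt_reads = sup$t_alt_reads, n_alt_reads = sup$n_alt_reads,
        t_alt_freq = sup$t_alt_freq, n_alt_freq = sup$n_alt_freq,
        ssc = if (cl %in% SSC_CALLERS) sup$ssc else NA_real_,
        bq = if (cl %in% BQ_CALLERS) sup$bq else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  decoys <- if (length(decoy_rows)) do.call(rbind, decoy_rows) else NULL

  ## write per-sample per-caller VCFs
  vcf_files <- character(0)
  for (sid in samples$sample_id) {
    smuts <- muts[muts$sample_id == sid, , drop = FALSE]
    for (cl in CALLERS) {
      recs <- list()
      if (nrow(smuts)) {
        has <- vapply(strsplit(smuts$callers, ",", fixed = TRUE),
                      function(x) cl %in% x, logical(1))
        if (any(has)) {
          sm <- smuts[has, , drop = FALSE]
          recs[[length(recs) + 1L]] <- data.frame(
            caller = cl, sample_id = sid, chrom = sm$chrom, pos = sm$pos,
            ref = sm$ref, alt = sm$alt, filter_status = "PASS",
            t_alt_reads = sm$t_alt_reads, n_alt_reads = sm$n_alt_reads,
            t_alt_freq = sm$t_alt_freq, n_alt_freq = sm$n_alt_freq,
            ssc = ifelse(cl %in% SSC_CALLERS, sm$ssc, NA_real_),
            bq = ifelse(cl %in% BQ_CALLERS, sm$bq, NA_real_),
            stringsAsFactors = FALSE)
        }
      }
      if (!is.null(noise)) {
        nn <- noise[noise$sample_id == sid & noise$caller == cl, , drop = FALSE]
        if (nrow(nn)) recs[[length(recs) + 1L]] <- nn
      }
      if (!is.null(decoys)) {
        dd <- decoys[decoys$sample_id == sid & decoys$caller == cl, , drop = FALSE]
        if (nrow(dd)) recs[[length(recs) + 1L]] <- dd
      }
      rec_df <- if (length(recs)) do.call(rbind, recs) else empty_caller_variants()
      f <- file.path(out_dir, "vcf", sprintf("%s_%s.vcf", sid, cl))
      write_caller_vcf(rec_df, f, cl, sid)
      vcf_files <- c(vcf_files, f)
    }
  }

  ## expression
  famseed(config$seed, 6L)
  annot <- mirna_panel(config$n_mirna_pairs, config$n_unspecified_mirna,
                       config$reference_mirna)
  dropv <- rep(0.02, nrow(annot))
  unspec <- which(annot$arm == "unspecified" & annot$mirna != config$reference_mirna)
  if (length(unspec) >= 2) dropv[unspec[1:2]] <- 0.35
  arm_carriers <- carriers_of(muts, config$arm_effect$gene, config$arm_effect$class)
  expr <- simulate_expression(samples$sample_id, arm_carriers, annot,
                              shift_5p = config$arm_effect$shift_5p,
                              shift_3p = config$arm_effect$shift_3p,
                              reference_mirna = config$reference_mirna,
                              dropout = dropv)
  annot_path <- write_tsv(annot, file.path(out_dir, "mirna_annotation.tsv"))
  norm_path <- matrix_to_tsv(expr$normalized,
                             file.path(out_dir, "expression_normalized.tsv"))
  rpm_path <- matrix_to_tsv(expr$rpm, file.path(out_dir, "expression_rpm.tsv"))

  ## isomiRs (3p miRNAs; null 5'-end composition)
  famseed(config$seed, 7L)
  totals <- expr$rpm[annot$arm == "3p", , drop = FALSE]
  isomirs <- simulate_isomirs(totals)
  isomir_path <- write_tsv(isomirs, file.path(out_dir, "isomir.tsv"))

  ## survival + clinical
  famseed(config$seed, 8L)
  surv_carriers <- union(carriers_of(muts, config$survival_gene, "hotspot"),
                         carriers_of(muts, config$survival_gene, "deleterious"))
  os <- simulate_survival(samples$sample_id %in% surv_carriers,
                          hr = config$survival_hr)
  clinical <- cbind(samples[, c("sample_id", "cancer_type",
                                "exome_mutation_total", "stage")], os)
  clinical$os_time <- round(clinical$os_time, 3)
  clin_path <- write_tsv(clinical, file.path(out_dir, "clinical.tsv"))

  ## thresholded copy number with deletion enrichment in mutated samples
  famseed(config$seed, 9L)
  cnv_rows <- lapply(config$genes$gene, function(g) {
    mutated <- samples$sample_id %in% carriers_of(muts, g, "any")
    p_del <- ifelse(mutated, config$cnv_del_rate_mutated,
                    config$cnv_del_rate_unmutated)
    del <- stats::runif(N) < p_del
    call <- integer(N)
    call[del] <- sample(c(-2L, -1L), sum(del), replace = TRUE, prob = c(0.3, 0.7))
    call[!del] <- sample(c(0L, 1L, 2L), sum(!del), replace = TRUE,
                         prob = c(0.85, 0.10, 0.05))
    data.frame(sample_id = samples$sample_id, gene = g, call = call,
               stringsAsFactors = FALSE)
  })
  cnv <- do.call(rbind, cnv_rows)
  cnv_path <- write_tsv(cnv, file.path(out_dir, "cnv.tsv"))

  ground_truth <- list(
    seed = config$seed,
    mutations = muts,
    hypermutated = hyper_ids,
    noise_calls = if (is.null(noise)) 0L else nrow(noise),
    arm_effect = c(config$arm_effect,
                   list(carriers = arm_carriers,
                        shifted_5p = annot$mirna[annot$arm == "5p"],
                        shifted_3p = annot$mirna[annot$arm == "3p"],
                        reference_mirna = config$reference_mirna)),
    survival = list(gene = config$survival_gene, hr = config$survival_hr,
                    group = sort(surv_carriers))
  )
  gt_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(ground_truth, gt_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  files <- c(genome = genome_path, cds_models = model_path, regions = bed_path,
             mirna_annotation = annot_path, expression_normalized = norm_path,
             expression_rpm = rpm_path, isomir = isomir_path,
             clinical = clin_path, cnv = cnv_path, ground_truth = gt_path)
  invisible(list(dir = out_dir, files = files, vcf_files = vcf_files,
                 ground_truth = ground_truth))
}
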