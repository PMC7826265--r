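#' Build a pipeline run configuration
#'
#' Single source of truth for an end-to-end run: input/output paths, stage
#' toggles and all thresholds. `cohort` holds overrides for
#' [cohort_config()] when the generate stage is on.
#'
#' @param input_dir directory holding (or receiving) the cohort bundle.
#' @param out_dir directory for pipeline outputs.
#' @param generate,merge,stats,mirna,isomir,clinical stage toggles.
#' @param hypermutation_threshold exome burden cutoff (default 10000).
#' @param alpha nominal significance level (default 0.05).
#' @param overmutation_cut nominal overmutation significance after
#'   Bonferroni logic (default 5e-5).
#' @param min_rpm isomiR expression cutoff (default 100).
#' @param hotspot_recurrence hotspot threshold (default 3).
#' @param mirna_gene,mirna_class mutation group analyzed by the expression
#'   stages (class: hotspot / deleterious / any).
#' @param cohort list of [cohort_config()] overrides.
#' @param seed integer seed for the generate stage.
#' @return A `run_config` list.
#' @export
run_config <- function(input_dir, out_dir,
                       generate = TRUE, merge = TRUE, stats = TRUE,
                       mirna = TRUE, isomir = TRUE, clinical = TRUE,
                       hypermutation_threshold = 10000L,
                       alpha = 0.05, overmutation_cut = 5e-5,
                       min_rpm = 100, hotspot_recurrence = 3L,
                       mirna_gene = "DICER1", mirna_class = "hotspot",
                       cohort = list(), seed = 1L) {
  stopifnot(hypermutation_threshold > 0, alpha > 0, alpha < 1,
            overmutation_cut > 0, overmutation_cut < 1,
            min_rpm >= 0, hotspot_recurrence >= 2)
  cfg <- list(input_dir = input_dir, out_dir = out_dir,
              stages = list(generate = generate, merge = merge, stats = stats,
                            mirna = mirna, isomir = isomir,
                            clinical = clinical),
              hypermutation_threshold = as.integer(hypermutation_threshold),
              alpha = alpha, overmutation_cut = overmutation_cut,
              min_rpm = min_rpm,
              hotspot_recurrence = as.integer(hotspot_recurrence),
              mirna_gene = mirna_gene, mirna_class = mirna_class,
              cohort = cohort, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#' @param path YAML path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  stages <- y$stages %||% list()
  do.call(run_config, c(
    list(input_dir = y$input_dir, out_dir = y$out_dir),
    stages,
    y[setdiff(names(y), c("input_dir", "out_dir", "stages"))]
  ))
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  y <- unclass(config)
  yaml::write_yaml(y, path)
  invisible(path)
}

stage_fail <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[E_%s] stage %s failed: %s", toupper(stage), stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

class_filter_for <- function(class, hotspots, gene) {
  switch(class,
         hotspot = class_hotspot(hotspots$protein_pos[hotspots$gene == gene]),
         deleterious = class_deleterious(),
         any = NULL,
         stop(sprintf("unknown mutation class: %s", class)))
}

#' Run the full analysis pipeline
#'
#' Executes (optionally) generate, then merge, stats, mirna, isomir and
#' clinical stages on the bundle in `config$input_dir`, writing outputs and
#' a manifest (seed, effective config, per-stage row counts, md5 content
#' hash of every output file) under `config$out_dir`. A rerun with the same
#' config and inputs is bit-identical for the deterministic stages. A stage
#' error halts the run with the stage name and a machine-readable code.
#'
#' @param config a [run_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- config$stages
  counts <- list()
  outputs <- character(0)
  add_out <- function(path) outputs <<- c(outputs, path)
  idir <- config$input_dir

  if (isTRUE(st$generate)) {
    stage_fail("generate", {
      cc <- do.call(cohort_config, c(config$cohort, list(seed = config$seed)))
      gen <- generate_cohort(cc, idir)
      counts$generate <- list(samples = nrow(utils::read.delim(gen$files["clinical"])),
                               planted_mutations = nrow(gen$ground_truth$mutations))
    })
  }

  need <- function(f) {
    p <- file.path(idir, f)
    if (!file.exists(p)) stop(sprintf("required input %s missing", f))
    p
  }

  muts <- NULL
  clinical <- NULL
  if (isTRUE(st$merge)) {
    stage_fail("merge", {
      clinical <- utils::read.delim(need("clinical.tsv"), stringsAsFactors = FALSE)
      regions <- read_gene_regions(need("regions.bed"))
      models <- read_cds_models(need("cds_models.tsv"), need("genome.fa"))
      vcfs <- sort(list.files(file.path(idir, "vcf"), pattern = "\\.vcf$",
                              full.names = TRUE))
      calls <- lapply(vcfs, function(f) {
        caller <- sub("^.*_([A-Za-z0-9]+)\\.vcf$", "\\1", basename(f))
        apply_reliability_filters(read_caller_file(f, caller))
      })
      muts <- merge_callers(do.call(rbind, calls), clinical)
      muts <- restrict_to_regions(muts, regions)
      muts <- classify_consequence(muts, models)
      f <- file.path(config$out_dir, "mutations.tsv")
      write_tsv(muts, f); add_out(f)
      counts$merge <- list(consensus_mutations = nrow(muts))
    })
  }

  samples_x <- NULL
  hotspots <- NULL
  if (isTRUE(st$stats)) {
    stage_fail("stats", {
      if (is.null(muts)) stop("merge outputs unavailable (stage toggled off?)")
      sdir <- file.path(config$out_dir, "stats")
      dir.create(sdir, showWarnings = FALSE)
      flagged <- flag_hypermutated(clinical, config$hypermutation_threshold)
      ex <- exclude_hypermutated(muts, flagged)
      samples_x <- ex$samples
      cls <- classification_summary(ex$muts)
      jsonlite::write_json(cls, file.path(sdir, "classification_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      add_out(file.path(sdir, "classification_summary.json"))
      freq <- sample_mutation_frequency(ex$muts, ex$samples)
      matrix_to_tsv(freq, file.path(sdir, "frequency.tsv"))
      add_out(file.path(sdir, "frequency.tsv"))
      om <- suppressWarnings(overmutation_test(ex$muts, ex$samples))
      write_tsv(om, file.path(sdir, "overmutation.tsv"))
      add_out(file.path(sdir, "overmutation.tsv"))
      hotspots <- detect_hotspots(ex$muts, config$hotspot_recurrence)
      write_tsv(hotspots, file.path(sdir, "hotspots.tsv"))
      add_out(file.path(sdir, "hotspots.tsv"))
      muts <- ex$muts
      counts$stats <- list(retained_mutations = nrow(ex$muts),
                            retained_samples = nrow(ex$samples),
                            hotspots = nrow(hotspots))
    })
  }

  groups <- NULL
  if (isTRUE(st$mirna)) {
    stage_fail("mirna", {
      if (is.null(muts) || is.null(samples_x)) {
        stop("stats outputs unavailable (stage toggled off?)")
      }
      mdir <- file.path(config$out_dir, "mirna")
      dir.create(mdir, showWarnings = FALSE)
      annot <- utils::read.delim(need("mirna_annotation.tsv"),
                                 stringsAsFactors = FALSE)
      expr <- read_expression(need("expression_normalized.tsv"),
                              "batch_normalized", annot)
      expr$values <- expr$values[, samples_x$sample_id, drop = FALSE]
      expr <- filter_expressed(expr, "pan_cancer")
      labels <- stats::setNames(samples_x$cancer_type, samples_x$sample_id)
      norm <- pan_cancer_normalize(expr, labels)
      cf <- class_filter_for(config$mirna_class, hotspots, config$mirna_gene)
      groups <- define_groups(muts, samples_x, config$mirna_gene, cf)
      res <- diff_test(norm, groups$mutated, groups$reference)
      write_tsv(res, file.path(mdir, "diff_normalized.tsv"))
      add_out(file.path(mdir, "diff_normalized.tsv"))
      arm <- arm_asymmetry(res, config$alpha)
      rpm <- read_expression(need("expression_rpm.tsv"), "rpm", annot)
      rpm$values <- rpm$values[, samples_x$sample_id, drop = FALSE]
      refn <- reference_normalize(rpm)
      res_ref <- diff_test(refn, groups$mutated, groups$reference)
      write_tsv(res_ref, file.path(mdir, "diff_reference_normalized.tsv"))
      add_out(file.path(mdir, "diff_reference_normalized.tsv"))
      arm_ref <- arm_asymmetry(res_ref, config$alpha)
      jsonlite::write_json(
        list(normalized = list(counts = arm$counts, p = arm$p),
             reference_normalized = list(counts = arm_ref$counts,
                                         p = arm_ref$p)),
        file.path(mdir, "arm_asymmetry.json"), auto_unbox = TRUE, digits = NA,
        matrix = "rowmajor")
      add_out(file.path(mdir, "arm_asymmetry.json"))
      counts$mirna <- list(mirnas_tested = nrow(res),
                            n_mutated = length(groups$mutated),
                            n_reference = length(groups$reference))
    })
  }

  if (isTRUE(st$isomir)) {
    stage_fail("isomir", {
      if (is.null(groups)) stop("mirna outputs unavailable (stage toggled off?)")
      odir <- file.path(config$out_dir, "isomir")
      dir.create(odir, showWarnings = FALSE)
      iso <- read_isomirs(need("isomir.tsv"))
      iso <- iso[iso$sample_id %in% samples_x$sample_id, , drop = FALSE]
      annot <- utils::read.delim(need("mirna_annotation.tsv"),
                                 stringsAsFactors = FALSE)
      armv <- stats::setNames(annot$arm, annot$mirna)
      sel <- select_high_expression_3p(iso, armv, config$min_rpm)
      fr <- lapply(sel, function(mi) main_fraction(iso, mi, groups$reference))
      cmp <- suppressWarnings(compare_fractions(fr, groups$mutated,
                                                groups$reference))
      write_tsv(cmp$per_mirna, file.path(odir, "comparison.tsv"))
      add_out(file.path(odir, "comparison.tsv"))
      counts$isomir <- list(mirnas_analyzed = length(sel),
                             pooled_p = cmp$pooled)
    })
  }

  if (isTRUE(st$clinical)) {
    stage_fail("clinical", {
      if (is.null(groups)) stop("mirna outputs unavailable (stage toggled off?)")
      cdir <- file.path(config$out_dir, "clinical")
      dir.create(cdir, showWarnings = FALSE)
      km <- km_logrank(samples_x, groups$mutated, groups$reference)
      jsonlite::write_json(km[c("n_mut", "n_ref", "logrank_chisq", "p",
                                "hr", "hr_ci")],
                           file.path(cdir, "survival.json"),
                           auto_unbox = TRUE, digits = NA)
      add_out(file.path(cdir, "survival.json"))
      cmh <- tryCatch(cmh_stage_test(samples_x, groups$mutated),
                      error = function(e) NULL)
      if (!is.null(cmh)) {
        write_tsv(data.frame(statistic = cmh$statistic, p = cmh$p),
                  file.path(cdir, "stage_cmh.tsv"))
        add_out(file.path(cdir, "stage_cmh.tsv"))
      }
      cnv <- utils::read.delim(need("cnv.tsv"), stringsAsFactors = FALSE)
      cooc <- suppressWarnings(cnv_cooccurrence(
        cnv, muts, config$mirna_gene,
        hotspot_positions = hotspots$protein_pos[hotspots$gene == config$mirna_gene],
        samples = samples_x))
      write_tsv(cooc$by_class, file.path(cdir, "cnv_cooccurrence.tsv"))
      add_out(file.path(cdir, "cnv_cooccurrence.tsv"))
      counts$clinical <- list(logrank_p = km$p, hr = km$hr,
                               cnv_fisher_p = cooc$fisher_p)
    })
  }

  manifest <- list(
    package = "mutatlas",
    version = as.character(utils::packageVersion("mutatlas")),
    seed = config$seed,
    config = unclass(config),
    stage_counts = counts,
    files = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

report_section <- function(title, body) {
  c(sprintf("## %s", title), "", body, "")
}

#' Render a human-readable run report
#'
#' Collates pipeline outputs into one markdown document: classification
#' summary, gene x cancer frequency table, hotspot list, differential
#' tables, arm proportions and survival summaries. Missing stage outputs
#' produce an explicit gap rather than an error.
#'
#' @param run_dir pipeline output directory (with `manifest.json`).
#' @return Invisibly, the report path (`report.md` in `run_dir`).
#' @export
render_report <- function(run_dir) {
  mf_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in run_dir")
  mf <- jsonlite::read_json(mf_path)
  lines <- c("# mutatlas run report", "",
             sprintf("seed: %s", mf$seed), "")
  tsv_or_gap <- function(rel, title, max_rows = 15L) {
    p <- file.path(run_dir, rel)
    if (!file.exists(p)) {
      return(report_section(title, "*stage output absent*"))
    }
    df <- utils::read.delim(p, stringsAsFactors = FALSE)
    df <- utils::head(df, max_rows)
    body <- c(paste(names(df), collapse = " | "),
              paste(rep("---", ncol(df)), collapse = " | "),
              apply(df, 1, function(r) paste(r, collapse = " | ")))
    report_section(title, body)
  }
  cls_p <- file.path(run_dir, "stats", "classification_summary.json")
  if (file.exists(cls_p)) {
    cls <- jsonlite::read_json(cls_p)
    body <- c(sprintf("total mutations: %s", cls$total),
              sprintf("deleterious (frameshift+nonsense+splice): %s",
                      cls$deleterious_total),
              sprintf("- %s: %s (%s%%)", names(cls$counts),
                      unlist(cls$counts), unlist(cls$percentages)))
    lines <- c(lines, report_section("Mutation classification", body))
  } else {
    lines <- c(lines, report_section("Mutation classification",
                                     "*stage output absent*"))
  }
  lines <- c(lines,
             tsv_or_gap("stats/frequency.tsv", "Mutated-sample frequency [%]"),
             tsv_or_gap("stats/hotspots.tsv", "Hotspot residues"),
             tsv_or_gap("stats/overmutation.tsv", "Overmutation tests"),
             tsv_or_gap("mirna/diff_normalized.tsv",
                        "Differential miRNAs (pan-cancer normalized)"),
             tsv_or_gap("mirna/diff_reference_normalized.tsv",
                        "Differential miRNAs (reference re-normalized)"),
             tsv_or_gap("isomir/comparison.tsv", "isomiR main-fraction comparison"),
             tsv_or_gap("clinical/cnv_cooccurrence.tsv", "CNV co-occurrence"))
  surv_p <- file.path(run_dir, "clinical", "survival.json")
  if (file.exists(surv_p)) {
    sv <- jsonlite::read_json(surv_p)
    lines <- c(lines, report_section("Survival", c(
      sprintf("groups: %s mutated vs %s reference", sv$n_mut, sv$n_ref),
      sprintf("log-rank p = %s; Cox HR = %s", format(sv$p), format(sv$hr)))))
  } else {
    lines <- c(lines, report_section("Survival", "*stage output absent*"))
  }
  out <- file.path(run_dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}
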