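# hand-written MuSE-dialect fixture: 3 PASS + 2 non-PASS records
muse_fixture <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##tumor_sample=S-TEST-001",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNORMAL\tTUMOR",
    "chr1\t101\t.\tA\tG\t.\tPASS\t.\tGT:DP:AD:BQ\t0/0:50:50,0:.\t0/1:50:40,10:32",
    "chr1\t150\t.\tC\tT\t.\tREJECT\t.\tGT:DP:AD:BQ\t0/0:50:50,0:.\t0/1:50:40,10:32",
    "chr1\t202\t.\tG\tA\t.\tPASS\t.\tGT:DP:AD:BQ\t0/0:40:39,1:.\t0/1:80:60,20:35",
    "chr1\t250\t.\tT\tC\t.\tTier5\t.\tGT:DP:AD:BQ\t0/0:50:50,0:.\t0/1:50:40,10:28",
    "chr1\t303\t.\tT\tA\t.\tPASS\t.\tGT:DP:AD:BQ\t0/0:50:50,0:.\t0/1:100:75,25:19"
  ), path)
  path
}

test_that("read_caller_file keeps only PASS records and maps dialect fields", {
  f <- muse_fixture(withr::local_tempfile(fileext = ".vcf"))
  cv <- read_caller_file(f, "MuSE")
  expect_equal(nrow(cv), 3)
  expect_equal(cv$sample_id, rep("S-TEST-001", 3))
  expect_equal(cv$pos, c(101L, 202L, 303L))
  expect_equal(cv$t_alt_reads, c(10L, 20L, 25L))
  expect_equal(cv$t_alt_freq, c(10 / 50, 20 / 80, 25 / 100))
  expect_equal(cv$n_alt_freq, c(0, 1 / 40, 0))
  expect_equal(cv$bq, c(32, 35, 19))
  expect_true(all(is.na(cv$ssc)))
})

test_that("a header-only file yields an empty call list and bad input errors", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNORMAL\tTUMOR"),
             f)
  expect_equal(nrow(read_caller_file(f, "MuSE")), 0)
  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNORMAL\tTUMOR",
               "chr1\t100\t.\tA\tG\tPASS"), bad)
  expect_error(read_caller_file(bad, "MuSE"), "line 3")
  expect_error(read_caller_file(f, "Strelka"), "unknown caller dialect")
})

test_that("every dialect round-trips records through write + read", {
  rec <- data.frame(
    caller = NA_character_, sample_id = "S1", chrom = "chr1",
    pos = c(120L, 340L), ref = c("A", "CT"), alt = c("G", "C"),
    filter_status = "PASS",
    t_alt_reads = c(20L, 13L), n_alt_reads = c(0L, 2L),
    t_alt_freq = c(20 / 80, 13 / 50), n_alt_freq = c(0, 2 / 40),
    ssc = c(55.5, 80), bq = c(31, 25.5), stringsAsFactors = FALSE)
  for (cl in CALLERS) {
    r <- rec
    r$ssc <- if (cl %in% c("VarScan2", "SomaticSniper")) rec$ssc else NA_real_
    r$bq <- if (cl %in% c("MuSE", "MuTect2")) rec$bq else NA_real_
    f <- withr::local_tempfile(fileext = ".vcf")
    write_caller_vcf(r, f, cl, "S1")
    back <- read_caller_file(f, cl)
    expect_equal(back$pos, r$pos, label = cl)
    expect_equal(back$ref, r$ref)
    expect_equal(back$alt, r$alt)
    expect_equal(back$t_alt_reads, r$t_alt_reads)
    expect_equal(back$n_alt_reads, r$n_alt_reads)
    expect_equal(back$t_alt_freq, r$t_alt_freq, tolerance = 1e-12)
    expect_equal(back$n_alt_freq, r$n_alt_freq, tolerance = 1e-12)
    expect_equal(back$ssc, r$ssc)
    expect_equal(back$bq, r$bq)
  }
})

test_that("parsed synthetic bundle records equal the generator's ground truth", {
  bundle <- shared_bundle()
  gt <- bundle$ground_truth$mutations
  raw <- read_bundle_calls(bundle, filtered = TRUE)
  idx <- match(paste(raw$sample_id, raw$pos), paste(gt$sample_id, gt$pos))
  expect_false(anyNA(idx)) # filters removed all noise
  expect_equal(raw$ref, gt$ref[idx])
  expect_equal(raw$alt, gt$alt[idx])
  expect_equal(raw$t_alt_reads, gt$t_alt_reads[idx])
  expect_equal(raw$t_alt_freq, gt$t_alt_freq[idx], tolerance = 1e-12)
})

test_that("reliability filters implement the four criteria at their boundaries", {
  mk <- function(t_alt = 10L, n_alt = 0L, t_f = 0.25, n_f = 0,
                 ssc = NA_real_, bq = NA_real_) {
    data.frame(caller = "x", sample_id = "s", chrom = "c", pos = 1L,
               ref = "A", alt = "G", filter_status = "PASS",
               t_alt_reads = t_alt, n_alt_reads = n_alt,
               t_alt_freq = t_f, n_alt_freq = n_f, ssc = ssc, bq = bq)
  }
  # (i) >=2 tumor alt reads, only when the normal has none
  expect_false(reliability_pass(mk(t_alt = 1L, n_alt = 0L)))
  expect_true(reliability_pass(mk(t_alt = 2L, n_alt = 0L)))
  expect_true(reliability_pass(mk(t_alt = 1L, n_alt = 1L, t_f = 0.25, n_f = 0.01)))
  # (ii) 5x frequency ratio, inclusive boundary, only when normal freq > 0
  expect_false(reliability_pass(mk(t_f = 0.20, n_f = 0.05)))
  expect_true(reliability_pass(mk(t_f = 0.25, n_f = 0.05)))
  expect_true(reliability_pass(mk(t_f = 0.01, n_f = 0)))
  # (iii) SSC > 30 strictly, when present
  expect_false(reliability_pass(mk(ssc = 30)))
  expect_false(reliability_pass(mk(ssc = 29)))
  expect_true(reliability_pass(mk(ssc = 30.5)))
  # (iv) BQ > 20 strictly, when present
  expect_false(reliability_pass(mk(bq = 20)))
  expect_true(reliability_pass(mk(bq = 20.5)))
})

test_that("filtering agrees with the brute-force conjunction oracle", {
  set.seed(11)
  n <- 2000
  calls <- data.frame(
    caller = sample(CALLERS, n, TRUE), sample_id = "s", chrom = "c",
    pos = seq_len(n), ref = "A", alt = "G", filter_status = "PASS",
    t_alt_reads = sample(0:6, n, TRUE), n_alt_reads = sample(0:3, n, TRUE),
    t_alt_freq = round(runif(n, 0, 0.5), 3),
    n_alt_freq = round(runif(n, 0, 0.12), 3),
    ssc = ifelse(runif(n) < 0.5, NA, sample(25:35, n, TRUE)),
    bq = ifelse(runif(n) < 0.5, NA, sample(15:25, n, TRUE)))
  expect_identical(reliability_pass(calls), oracle_filter(calls))
  kept <- apply_reliability_filters(calls)
  expect_equal(nrow(kept), sum(oracle_filter(calls)))
})

clin2 <- data.frame(sample_id = c("s1", "s2"), cancer_type = c("PAAD", "UCEC"))

cv_row <- function(caller, sample, pos, ref = "A", alt = "G") {
  data.frame(caller = caller, sample_id = sample, chrom = "chr1", pos = pos,
             ref = ref, alt = alt, filter_status = "PASS",
             t_alt_reads = 10L, n_alt_reads = 0L, t_alt_freq = 0.2,
             n_alt_freq = 0, ssc = NA_real_, bq = NA_real_)
}

test_that("merge_callers deduplicates across callers and joins cancer type", {
  calls <- rbind(cv_row("MuTect2", "s1", 100L), cv_row("VarScan2", "s1", 100L),
                 cv_row("MuSE", "s2", 100L))
  m <- merge_callers(calls, clin2)
  expect_equal(nrow(m), 2)
  expect_equal(m$callers[m$sample_id == "s1"], "MuTect2,VarScan2")
  expect_equal(m$n_callers[m$sample_id == "s1"], 2L)
  expect_equal(m$cancer_type, c("PAAD", "UCEC"))
  # single-caller input: output count equals input count
  single <- rbind(cv_row("MuSE", "s1", 1L), cv_row("MuSE", "s1", 2L))
  expect_equal(nrow(merge_callers(single, clin2)), 2)
  expect_error(merge_callers(cv_row("MuSE", "s9", 5L), clin2), "s9")
})

test_that("merge count equals the number of distinct keys on random fixtures", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    calls <- do.call(rbind, lapply(seq_len(n), function(i) {
      cv_row(sample(CALLERS, 1), sample(c("s1", "s2"), 1),
             sample(1:12, 1), sample(c("A", "C"), 1), "G")
    }))
    expected <- length(unique(mut_key(calls)))
    expect_equal(nrow(merge_callers(calls, clin2)), expected)
  }
})

test_that("merging is idempotent and monotone in added callers", {
  calls <- rbind(cv_row("MuTect2", "s1", 100L), cv_row("VarScan2", "s1", 100L),
                 cv_row("MuSE", "s2", 150L), cv_row("MuSE", "s1", 300L))
  m1 <- merge_callers(calls, clin2)
  # split merged records back into per-caller rows and re-merge
  resplit <- do.call(rbind, lapply(seq_len(nrow(m1)), function(i) {
    do.call(rbind, lapply(strsplit(m1$callers[i], ",")[[1]], function(cl) {
      cv_row(cl, m1$sample_id[i], m1$pos[i], m1$ref[i], m1$alt[i])
    }))
  }))
  m2 <- merge_callers(resplit, clin2)
  expect_equal(m2[, c("sample_id", "pos", "ref", "alt", "callers")],
               m1[, c("sample_id", "pos", "ref", "alt", "callers")])
  # adding a caller's list never decreases the count or changes existing keys
  extra <- rbind(calls, cv_row("SomaticSniper", "s2", 150L),
                 cv_row("SomaticSniper", "s2", 999L))
  m3 <- merge_callers(extra, clin2)
  expect_gte(nrow(m3), nrow(m1))
  expect_true(all(mut_key(m1) %in% mut_key(m3)))
})

test_that("differently padded indels merge to one canonical record", {
  a <- cv_row("MuSE", "s1", 10L, ref = "AT", alt = "A")
  b <- cv_row("MuTect2", "s1", 10L, ref = "ATT", alt = "AT") # same deletion, padded
  m <- merge_callers(rbind(a, b), clin2)
  expect_equal(nrow(m), 1)
  expect_equal(m$callers, "MuSE,MuTect2")
  norm <- normalize_variant(7L, "TACG", "TG")
  expect_equal(norm$pos, 7L) # anchored minimal form: delete AC after the T
  expect_equal(norm$ref, "TAC")
  expect_equal(norm$alt, "T")
})

test_that("region restriction respects interval boundaries and the 2-nt extension", {
  regions <- gene_regions(data.frame(
    gene = c("G1", "G2"), chrom = "chr1",
    start = c(10L, 100L), end = c(20L, 130L)))
  muts <- data.frame(sample_id = "s1", chrom = "chr1",
                     pos = c(10L, 11L, 20L, 21L, 99L, 130L),
                     ref = "A", alt = "G")
  kept <- restrict_to_regions(muts, regions)
  expect_equal(kept$pos, c(11L, 20L, 130L))
  expect_equal(kept$gene, c("G1", "G1", "G2"))
  # overlapping regions of different genes rejected at load
  expect_error(gene_regions(data.frame(gene = c("A", "B"), chrom = "chr1",
                                       start = c(0L, 5L), end = c(10L, 15L))),
               "overlapping")
})

test_that("region restriction matches a linear point-in-interval scan", {
  set.seed(31)
  regions <- gene_regions(data.frame(
    gene = c("G1", "G2", "G3"), chrom = c("chr1", "chr1", "chr2"),
    start = c(50L, 200L, 10L), end = c(120L, 260L, 90L)))
  muts <- data.frame(sample_id = "s1",
                     chrom = sample(c("chr1", "chr2"), 300, TRUE),
                     pos = sample(1:300, 300, TRUE), ref = "A", alt = "G")
  expected <- oracle_in_regions(muts$chrom, muts$pos, regions)
  kept <- restrict_to_regions(muts, regions)
  expect_equal(nrow(kept), sum(!is.na(expected)))
  expect_equal(kept$gene, expected[!is.na(expected)])
})

test_that("a planted splice mutation 2 nt past the exon end survives the pipeline", {
  bundle <- shared_bundle()
  gt <- bundle$ground_truth$mutations
  regions <- read_gene_regions(bundle$files["regions"])
  kept <- restrict_to_regions(gt, regions)
  expect_setequal(mut_key(kept), mut_key(gt))
})
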