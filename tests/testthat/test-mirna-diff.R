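mk_expr <- function(values, dialect = "batch_normalized") {
  expression_matrix(values, dialect)
}

test_that("detectability filtering uses the 30% / 10% zero-fraction cutoffs", {
  v <- matrix(1, 4, 100,
              dimnames = list(c("hsa-miR-1-5p", "hsa-miR-2-5p",
                                "hsa-miR-3-3p", "hsa-miR-4-3p"),
                              sprintf("s%d", 1:100)))
  v[1, 1:31] <- 0 # 31% zeros
  v[2, 1:30] <- 0 # 30% zeros
  v[3, 1:11] <- 0 # 11% zeros
  e <- mk_expr(v)
  expect_setequal(rownames(filter_expressed(e, "pan_cancer")$values),
                  c("hsa-miR-2-5p", "hsa-miR-3-3p", "hsa-miR-4-3p"))
  expect_setequal(rownames(filter_expressed(e, "single_cancer")$values),
                  "hsa-miR-4-3p")
})

test_that("per-cancer normalization gives median 0, range in [-1,1]", {
  v <- matrix(c(1, 2, 3, 10), 1, 4,
              dimnames = list("hsa-miR-9-5p", sprintf("s%d", 1:4)))
  out <- pan_cancer_normalize(mk_expr(v), rep("PAAD", 4))
  expect_equal(unname(out$values[1, ]), c(-0.2, -1 / 15, 1 / 15, 1),
               tolerance = 1e-12)
  # property on random input, two cancers
  set.seed(12)
  v2 <- matrix(rnorm(50 * 40), 50, 40,
               dimnames = list(sprintf("hsa-miR-%d-3p", 1:50), sprintf("s%d", 1:40)))
  labels <- rep(c("PAAD", "UCEC"), each = 20)
  n2 <- pan_cancer_normalize(mk_expr(v2), labels)
  for (cn in c("PAAD", "UCEC")) {
    sub <- n2$values[, labels == cn]
    expect_equal(unname(apply(sub, 1, median)), rep(0, 50), tolerance = 1e-12)
    expect_true(all(abs(sub) <= 1 + 1e-12))
  }
  # idempotence and the constant-miRNA degenerate case
  n3 <- pan_cancer_normalize(n2, labels)
  expect_equal(n3$values, n2$values, tolerance = 1e-12)
  vc <- matrix(5, 1, 4, dimnames = list("m", sprintf("s%d", 1:4)))
  expect_true(all(pan_cancer_normalize(mk_expr(vc), rep("A", 4))$values == 0))
  expect_error(pan_cancer_normalize(mk_expr(v2), c(rep("A", 39), "B")),
               "fewer than 2")
})

test_that("group definition excludes other-class carriers from both groups", {
  muts <- data.frame(sample_id = c("s1", "s1", "s2", "s3"),
                     gene = c("SMAD4", "SMAD4", "SMAD4", "OTHER"),
                     consequence = c("missense", "synonymous", "synonymous",
                                     "missense"),
                     protein_pos = c(361L, 100L, 90L, 5L))
  samples <- data.frame(sample_id = sprintf("s%d", 1:5))
  g <- define_groups(muts, samples, "SMAD4", class_hotspot(361L))
  expect_equal(g$mutated, "s1") # hotspot + synonymous counts as hotspot
  expect_setequal(g$reference, c("s3", "s4", "s5")) # s2 in neither group
  expect_error(define_groups(muts, samples, "SMAD4", class_deleterious()),
               "no samples")
  g2 <- define_groups(muts, samples, "SMAD4", NULL)
  expect_setequal(g2$mutated, c("s1", "s2"))
})

test_that("rank-sum p-values match exact enumeration on a small two-sample case", {
  v <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
              dimnames = list("m", sprintf("s%d", 1:6)))
  r <- diff_test(mk_expr(v), mutated = c("s1", "s2", "s3"),
                 reference = c("s4", "s5", "s6"))
  expect_equal(r$p, oracle_ranksum_p(c(1, 2, 3), c(4, 5, 6)), tolerance = 1e-12)
  expect_equal(r$effect, 2 - 5)
  expect_equal(r$direction, "down")
  # constant miRNA: p = 1, effect = 0
  vc <- matrix(7, 1, 6, dimnames = dimnames(v))
  rc <- diff_test(mk_expr(vc), c("s1", "s2", "s3"), c("s4", "s5", "s6"))
  expect_equal(rc$p, 1)
  expect_equal(rc$effect, 0)
  expect_equal(rc$direction, "none")
})

test_that("effects follow the dialect rule (difference vs log2 fold change)", {
  v <- matrix(c(8, 8, 8, 2, 2, 2), 1, 6,
              dimnames = list("m", sprintf("s%d", 1:6)))
  mut <- c("s1", "s2", "s3"); ref <- c("s4", "s5", "s6")
  r_norm <- diff_test(mk_expr(v, "batch_normalized"), mut, ref)
  expect_equal(r_norm$effect, 6)
  r_rpm <- diff_test(mk_expr(v, "rpm"), mut, ref)
  expect_equal(r_rpm$effect, log2((8 + 1) / (2 + 1)))
  expect_equal(r_rpm$direction, "up")
})

test_that("reference re-normalization zeroes the reference and is scale-invariant", {
  set.seed(14)
  v <- matrix(rlnorm(8 * 6, log(100), 1), 8, 6,
              dimnames = list(c(sprintf("hsa-miR-%d-5p", 1:7), "hsa-miR-451a"),
                              sprintf("s%d", 1:6)))
  e <- mk_expr(v, "rpm")
  rn <- reference_normalize(e)
  expect_true(all(rn$values["hsa-miR-451a", ] == 0))
  expect_equal(rn$dialect, "reference_normalized")
  # multiplying one sample's values by 8 leaves its normalized column unchanged
  # up to the pseudocount; with pseudocount 0 the invariance is exact
  v2 <- v; v2[, 3] <- v2[, 3] * 8
  rn0 <- reference_normalize(mk_expr(v, "rpm"), pseudocount = 0)
  rn2 <- reference_normalize(mk_expr(v2, "rpm"), pseudocount = 0)
  expect_equal(rn2$values[, 3], rn0$values[, 3], tolerance = 1e-12)
  # hand value: x = 100, ref = 25, pc = 1
  vh <- matrix(c(100, 25), 2, 1, dimnames = list(c("m", "hsa-miR-451a"), "s1"))
  rh <- reference_normalize(mk_expr(vh, "rpm"), pseudocount = 1)
  expect_equal(rh$values["m", 1], log2(101 / 26), tolerance = 1e-12)
  expect_equal(rh$values["m", 1], 1.958, tolerance = 1e-3)
  # guards
  expect_error(reference_normalize(mk_expr(v, "batch_normalized")), "rpm")
  expect_error(reference_normalize(e, reference_mirna = "hsa-miR-999"), "absent")
  vz <- v; vz["hsa-miR-451a", 1:2] <- 0
  expect_warning(reference_normalize(mk_expr(vz, "rpm")), "undetectable")
})

test_that("arm asymmetry summarizes significant miRNAs by arm and direction", {
  res <- data.frame(
    mirna = c(sprintf("hsa-miR-%d-5p", 1:6), sprintf("hsa-miR-%d-3p", 1:6),
              "hsa-miR-451a"),
    arm = c(rep("5p", 6), rep("3p", 6), "unspecified"),
    effect = c(rep(-1, 6), rep(1, 6), -1),
    p = c(rep(0.01, 12), 0.001),
    direction = c(rep("down", 6), rep("up", 6), "down"))
  a <- arm_asymmetry(res)
  expect_equal(unname(a$counts["5p", "down"]), 6L)
  expect_equal(unname(a$counts["3p", "up"]), 6L)
  expect_equal(unname(a$proportions["5p", "down"]), 1)
  expect_equal(unname(a$proportions["3p", "up"]), 1)
  expect_equal(a$n_significant, 12L) # arm-unspecified miRNA excluded
  expect_equal(a$p, fisher.test(matrix(c(6, 0, 0, 6), 2))$p.value)
  res$p <- 0.5
  expect_warning(a0 <- arm_asymmetry(res), "no significant")
  expect_true(is.na(a0$p))
})

test_that("the high-confidence subset is a simple flag mask", {
  res <- data.frame(mirna = c("a", "b", "c"), p = c(0.1, 0.2, 0.3))
  flags <- c(a = TRUE, b = FALSE, c = TRUE)
  expect_equal(highconf_subset(res, flags)$mirna, c("a", "c"))
  expect_equal(nrow(highconf_subset(res, c(a = FALSE, b = FALSE, c = FALSE))), 0)
  expect_equal(highconf_subset(res, c(a = TRUE, b = TRUE, c = TRUE)), res)
})

test_that("type-I error is calibrated at nominal 0.05 under the null", {
  set.seed(15)
  n_mirna <- 1500
  v <- matrix(rnorm(n_mirna * 80), n_mirna, 80,
              dimnames = list(sprintf("hsa-miR-%d-5p", seq_len(n_mirna)),
                              sprintf("s%d", 1:80)))
  r <- diff_test(mk_expr(v), sprintf("s%d", 1:40), sprintf("s%d", 41:80))
  expect_lte(mean(r$p < 0.05), 0.06)
  expect_gte(mean(r$p < 0.05), 0.03)
})
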