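test_that("hypermutation flagging is a strictly-greater comparison", {
  s <- data.frame(sample_id = c("a", "b", "c"),
                  exome_mutation_total = c(10001L, 10000L, 0L))
  f <- flag_hypermutated(s)
  expect_equal(f$hypermutated, c(TRUE, FALSE, FALSE))
  m <- data.frame(sample_id = c("a", "a", "b"), gene = "G")
  ex <- exclude_hypermutated(m, f)
  expect_equal(nrow(ex$muts), 1)
  expect_equal(ex$samples$sample_id, c("b", "c"))
})

test_that("exactly the planted hypermutated samples are flagged in the bundle", {
  bundle <- shared_bundle()
  clin <- read.delim(bundle$files["clinical"])
  f <- flag_hypermutated(clin)
  expect_setequal(f$sample_id[f$hypermutated], bundle$ground_truth$hypermutated)
})

test_that("classification summary reproduces tallies and the deleterious total", {
  cons <- c(rep("missense", 2196), rep("synonymous", 774), rep("frameshift", 341),
            rep("nonsense", 222), rep("splice_site", 62), rep("start_stop", 30),
            rep("other", 24))
  s <- classification_summary(data.frame(consequence = cons))
  expect_equal(s$deleterious_total, 625)
  expect_equal(s$total, 3649)
  expect_equal(unname(s$percentages["missense"]), 60)
  expect_equal(unname(s$percentages["synonymous"]), 21)
  expect_equal(unname(s$percentages["frameshift"] + s$percentages["nonsense"] +
                        s$percentages["splice_site"]), 9 + 6 + 2)
  z <- classification_summary(data.frame(consequence = character(0)))
  expect_true(all(z$counts == 0) && z$deleterious_total == 0)
  set.seed(3)
  rnd <- sample(CONSEQUENCE_CLASSES, 500, TRUE)
  s2 <- classification_summary(data.frame(consequence = rnd))
  expect_equal(unname(s2$counts), unname(table(factor(rnd, CONSEQUENCE_CLASSES))),
               ignore_attr = TRUE)
})

test_that("mutation density is count per kilobase of analyzed sequence", {
  expect_equal(mutation_density(0, 1234), 0)
  expect_equal(mutation_density(46, 1000), 46)
  set.seed(4)
  for (i in 1:20) {
    cnt <- sample(0:400, 1); len <- sample(500:8000, 1)
    expect_equal(mutation_density(cnt, len), 1000 * cnt / len)
  }
  expect_error(mutation_density(5, 0), "coding_length_bp")
})

test_that("mutated-sample frequency counts samples once and is order-invariant", {
  samples <- data.frame(sample_id = sprintf("s%d", 1:10),
                        cancer_type = rep(c("PAAD", "UCEC"), each = 5))
  muts <- data.frame(sample_id = c("s1", "s1", "s1", "s6"),
                     gene = c("G1", "G1", "G1", "G1"))
  fr <- sample_mutation_frequency(muts, samples)
  expect_equal(fr["G1", "PAAD"], 20) # s1 counts once despite 3 mutations
  expect_equal(fr["G1", "UCEC"], 20)
  expect_equal(fr["G1", "pan_cancer"], 20)
  fr2 <- sample_mutation_frequency(muts, samples[sample(10), ])
  expect_equal(fr, fr2)
  expect_equal(sample_mutation_frequency(muts, samples, genes = c("G1", "G2"))["G2", "PAAD"], 0)
})

test_that("overmutation test matches the hypergeometric enumeration oracle", {
  # table (20,80 / 10,890): gene share 20% in the cancer vs ~1% elsewhere
  muts <- data.frame(
    gene = c(rep("G", 20), rep("other", 80), rep("G", 10), rep("other", 890)),
    cancer_type = c(rep("BRCA", 100), rep("LUAD", 900)),
    sample_id = sprintf("s%d", 1:1000))
  samples <- data.frame(sample_id = muts$sample_id, cancer_type = muts$cancer_type)
  res <- overmutation_test(muts, samples, genes = "G", cancers = "BRCA")
  expect_equal(unname(unlist(res[1, c("a", "b", "c", "d")])), c(20, 80, 10, 890))
  expect_equal(res$p, oracle_fisher_greater(20, 80, 10, 890), tolerance = 1e-12)
  expect_equal(res$p_adjusted, min(1, res$p * 2)) # genes x cancers = 1 x 2
  # identical shares in the cancer and the background: no enrichment
  null_muts <- data.frame(
    gene = rep(c("G", "other"), times = c(50, 450)),
    cancer_type = rep(c("BRCA", "LUAD"), length.out = 500),
    sample_id = sprintf("n%d", 1:500))
  null_samples <- data.frame(sample_id = null_muts$sample_id,
                             cancer_type = null_muts$cancer_type)
  r0 <- overmutation_test(null_muts, null_samples, genes = "G", cancers = "BRCA")
  expect_gte(r0$p, 0.4)
  # empty margins: p = 1 with a warning
  expect_warning(
    r1 <- overmutation_test(data.frame(gene = "G", cancer_type = "BRCA",
                                       sample_id = "s1"),
                            samples, genes = "G", cancers = "BRCA"),
    "empty margin")
  expect_equal(r1$p, 1)
})

hot_fixture <- function() {
  set.seed(8)
  base <- data.frame(
    sample_id = sprintf("s%d", 1:200),
    cancer_type = sample(c("PAAD", "COAD", "READ"), 200, TRUE),
    gene = "SMAD4", consequence = "missense",
    protein_pos = NA_integer_, protein_label = NA_character_)
  base$protein_pos <- c(rep(361L, 37), rep(351L, 5), rep(352L, 3),
                        sample(2:340, 155, replace = FALSE))
  base$protein_label <- sprintf("p.X%d Y", base$protein_pos)
  base
}

test_that("hotspot detection recovers recurrences above the threshold, sorted", {
  hs <- detect_hotspots(hot_fixture(), min_recurrence = 3)
  expect_equal(hs$protein_pos[1], 361L)
  expect_equal(hs$count[1], 37L)
  expect_setequal(hs$protein_pos, c(361L, 351L, 352L))
  expect_true(all(diff(hs$count) <= 0))
  expect_equal(unname(hs$n_missense), hs$count)
  # all-distinct residues: no hotspot
  distinct <- data.frame(sample_id = "s", cancer_type = "PAAD", gene = "G",
                         consequence = "missense", protein_pos = 1:50,
                         protein_label = sprintf("p.A%dV", 1:50))
  expect_equal(nrow(detect_hotspots(distinct)), 0)
})

test_that("hotspot counts equal a group-by tally on random fixtures", {
  set.seed(9)
  for (rep in 1:10) {
    m <- data.frame(sample_id = "s", cancer_type = "PAAD",
                    gene = sample(c("A", "B"), 120, TRUE),
                    consequence = sample(c("missense", "synonymous", "nonsense"),
                                         120, TRUE),
                    protein_pos = sample(1:15, 120, TRUE))
    m$protein_label <- sprintf("p.X%d", m$protein_pos)
    hs <- detect_hotspots(m, min_recurrence = 4)
    tally <- table(paste(m$gene, m$protein_pos))
    expect_setequal(paste(hs$gene, hs$protein_pos),
                    names(tally)[tally >= 4])
    expect_equal(hs$count,
                 unname(as.integer(tally[paste(hs$gene, hs$protein_pos)])))
  }
})

test_that("indel hotspots are keyed by identical protein label", {
  m <- data.frame(sample_id = sprintf("s%d", 1:7), cancer_type = "COAD",
                  gene = "ZCCHC11", consequence = "frameshift",
                  protein_pos = 58L,
                  protein_label = c(rep("p.N58fs", 4), rep("p.N58del", 3)))
  m$consequence[5:7] <- "inframe_indel"
  hs <- detect_hotspots(m, min_recurrence = 3)
  expect_equal(nrow(hs), 2)
  expect_setequal(hs$count, c(4L, 3L))
})

test_that("hotspot vs deleterious split reproduces printed-style percentages", {
  m <- data.frame(
    sample_id = sprintf("s%d", 1:162),
    cancer_type = c(rep("READ", 22), rep("PAAD", 40), rep("COAD", 100)),
    gene = "SMAD4",
    consequence = c(rep("missense", 71), rep(c("frameshift", "nonsense"), length.out = 91)),
    protein_pos = c(rep(361L, 71), rep(NA_integer_, 91)),
    protein_label = "x")
  out <- hotspot_vs_deleterious(m, "SMAD4", hotspot_positions = 361L)
  expect_equal(out$pan$n_hotspot, 71)
  expect_equal(out$pan$n_deleterious, 91)
  expect_equal(out$pan$pct_hotspot, 44)
  expect_equal(out$pan$pct_deleterious, 56)
  # an all-hotspot cancer splits 100 / 0
  m2 <- m
  m2$consequence[m2$cancer_type == "READ"] <- "missense"
  m2$protein_pos[m2$cancer_type == "READ"] <- 361L
  out2 <- hotspot_vs_deleterious(m2, "SMAD4", 361L)
  pc <- out2$per_cancer
  expect_equal(pc$pct_hotspot[pc$cancer == "READ"], 100)
  expect_equal(pc$pct_deleterious[pc$cancer == "READ"], 0)
  # per-cancer Fisher p agrees with the enumeration oracle (two-sided
  # checked against fisher.test separately below on small tables)
  expect_true(all(pc$p >= 0 & pc$p <= 1))
})
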