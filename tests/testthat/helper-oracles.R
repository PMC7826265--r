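# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (and library calls) they verify.

# literal one-record-at-a-time evaluation of the four reliability criteria
oracle_filter <- function(calls) {
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    r <- calls[i, ]
    ok <- TRUE
    if (r$n_alt_reads == 0) {
      if (r$t_alt_reads < 2) ok <- FALSE
    }
    if (r$n_alt_freq > 0) {
      if (r$t_alt_freq < 5 * r$n_alt_freq) ok <- FALSE
    }
    if (!is.na(r$ssc)) {
      if (!(r$ssc > 30)) ok <- FALSE
    }
    if (!is.na(r$bq)) {
      if (!(r$bq > 20)) ok <- FALSE
    }
    keep[i] <- ok
  }
  keep
}

# one-sided (greater) Fisher p by direct hypergeometric enumeration:
# for table (a b / c d), sum P(X = x) over x >= a with margins fixed,
# probabilities from log-binomial coefficients (not dhyper/fisher.test)
oracle_fisher_greater <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  sum(exp(logp[xs >= a]))
}

# two-sided exact rank-sum p by full enumeration of group assignments
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(pooled), n1)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# linear point-in-interval scan (0-based half-open regions, 1-based pos)
oracle_in_regions <- function(chrom, pos, regions) {
  hit <- rep(NA_character_, length(pos))
  for (i in seq_along(pos)) {
    for (j in seq_len(nrow(regions))) {
      if (chrom[i] == regions$chrom[j] &&
          (pos[i] - 1) >= regions$start[j] && (pos[i] - 1) < regions$end[j]) {
        hit[i] <- regions$gene[j]
        break
      }
    }
  }
  hit
}

# log-rank chi-square by explicit risk-set arithmetic
oracle_logrank <- function(time, event, group) {
  g1 <- unique(group)[1]
  times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Cochran-Mantel-Haenszel chi-square (no continuity correction), closed form
oracle_cmh <- function(arr) {
  S <- dim(arr)[3]
  num <- 0; den <- 0
  for (s in seq_len(S)) {
    t <- arr[, , s]
    n <- sum(t)
    if (n == 0) next
    a <- t[1, 1]
    e <- sum(t[1, ]) * sum(t[, 1]) / n
    v <- sum(t[1, ]) * sum(t[2, ]) * sum(t[, 1]) * sum(t[, 2]) / (n^2 * (n - 1))
    num <- num + (a - e)
    den <- den + v
  }
  num^2 / den
}

# small fast cohort configuration for generator round-trip tests
tiny_config <- function(seed, ...) {
  defaults <- list(
    n_samples_per_cancer = 4L,
    cancer_types = c("PAAD", "UCEC"),
    genes = data.frame(gene = c("SMAD4", "DICER1"),
                       cds_length = c(300L, 450L), n_exons = c(2L, 3L)),
    hotspot_spec = list(list(gene = "DICER1", residue = 60L, count = 3L,
                             cancers = "UCEC")),
    deleterious_rate = 0.15, missense_rate = 0.1, synonymous_rate = 0.1,
    noise_call_rate = 0, hypermutated_fraction = 0,
    n_mirna_pairs = 6L, n_unspecified_mirna = 2L,
    seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

# shared generated bundle for tests that only read it
shared_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "mutatlas-shared-bundle")
      cache <<- generate_cohort(
        tiny_config(42, n_samples_per_cancer = 10L, noise_call_rate = 1,
                    hypermutated_fraction = 0.1),
        dir)
    }
    cache
  }
})

read_bundle_calls <- function(bundle, filtered = TRUE) {
  calls <- lapply(bundle$vcf_files, function(f) {
    caller <- sub("^.*_([A-Za-z0-9]+)\\.vcf$", "\\1", basename(f))
    cv <- read_caller_file(f, caller)
    if (filtered) apply_reliability_filters(cv) else cv
  })
  do.call(rbind, calls)
}

mut_key <- function(d) paste(d$sample_id, d$chrom, d$pos, d$ref, d$alt)
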