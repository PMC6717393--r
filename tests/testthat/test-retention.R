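mk_evidence <- function(intron = "i1", sample = "t1_r1", tissue = "t1",
                        b5 = 5, b3 = 5, s = 50, cov = 1, lib = 3e6) {
  data.frame(intron_id = intron, sample_id = sample, tissue = tissue,
             boundary_reads_5 = b5, boundary_reads_3 = b3, spliced_reads = s,
             covered_fraction = cov, library_unique_reads = lib,
             stringsAsFactors = FALSE)
}

test_that("the mis-splicing index follows the mean-of-boundaries formula", {
  expect_equal(compute_msi(0, 0, 10), 0)
  expect_equal(compute_msi(5, 5, 0), 100)
  expect_equal(compute_msi(6, 3, 6), 100 * 0.5 * (6 / 12 + 3 / 9))
  expect_true(is.na(compute_msi(0, 0, 0)))
  ## pooled alternative
  expect_equal(compute_msi(6, 3, 6, method = "pooled"), 100 * 9 / 21)
})

test_that("MSI is monotone: boundary reads raise it, spliced reads lower it", {
  set.seed(10)
  for (i in 1:200) {
    b5 <- sample(0:30, 1); b3 <- sample(0:30, 1); s <- sample(1:50, 1)
    m <- compute_msi(b5, b3, s)
    expect_gte(compute_msi(b5 + 1, b3, s), m)
    expect_gte(compute_msi(b5, b3 + 1, s), m)
    expect_lte(compute_msi(b5, b3, s + 1), m)
  }
})

test_that("replicate filters enforce the boundary, per-splice-site and coverage rules", {
  ## 2+2 = 4 boundary reads is not > 4
  r <- filter_retention(mk_evidence(b5 = 2, b3 = 2))
  expect_false(r$per_replicate$passed_filters)
  expect_match(r$per_replicate$fail_reasons, "boundary_reads")
  ## coverage must exceed 95%
  r <- filter_retention(mk_evidence(cov = 0.90))
  expect_false(r$per_replicate$passed_filters)
  expect_match(r$per_replicate$fail_reasons, "coverage")
  ## a splice site with zero boundary reads fails even when totals pass
  r <- filter_retention(mk_evidence(b5 = 6, b3 = 0))
  expect_match(r$per_replicate$fail_reasons, "no_3ss_read")
  ## passing row
  r <- filter_retention(mk_evidence(b5 = 3, b3 = 2, cov = 0.96))
  expect_true(r$per_replicate$passed_filters)
  ## all-zero evidence is undefined, reason no_reads
  r <- filter_retention(mk_evidence(b5 = 0, b3 = 0, s = 0))
  expect_true(is.na(r$per_replicate$msi))
  expect_match(r$per_replicate$fail_reasons, "no_reads")
})

test_that("tissue calls require all replicates (or >= 3 in min3 mode)", {
  ev <- rbind(
    mk_evidence(sample = "thymus_r1", tissue = "thymus"),
    mk_evidence(sample = "thymus_r2", tissue = "thymus"),
    mk_evidence(sample = "thymus_r3", tissue = "thymus"),
    mk_evidence(sample = "liver_r1", tissue = "liver", b5 = 0, b3 = 0),
    mk_evidence(sample = "liver_r2", tissue = "liver"),
    mk_evidence(sample = "liver_r3", tissue = "liver"))
  r <- filter_retention(ev)
  tc <- r$tissue_calls
  expect_true(tc$retained[tc$tissue == "thymus"])
  expect_false(tc$retained[tc$tissue == "liver"])
  expect_equal(r$replicate_class$class, "retained_all_replicates")
  ## min3 mode: 3 of 4 replicates suffice
  ev4 <- rbind(
    mk_evidence(sample = paste0("bm_r", 1:3), tissue = "bm"),
    mk_evidence(sample = "bm_r4", tissue = "bm", b5 = 0, b3 = 0))
  expect_false(filter_retention(ev4)$tissue_calls$retained)
  expect_true(filter_retention(ev4, mode = "min3")$tissue_calls$retained)
  ## with three replicates min3 falls back to all-replicates
  ev3 <- ev[4:6, ]
  expect_false(filter_retention(ev3, mode = "min3")$tissue_calls$retained)
})

test_that("retained calls are conservative: audit trail re-asserts every filter", {
  cfg <- sim_config(seed = 12, n_genes = 10)
  sim <- simulate_genome_annotation(cfg)
  reads <- simulate_reads(cfg, sim)
  res <- filter_retention(reads$evidence)
  retained <- res$tissue_calls[res$tissue_calls$retained, ]
  for (i in seq_len(nrow(retained))) {
    reps <- res$per_replicate[
      res$per_replicate$intron_id == retained$intron_id[i] &
      res$per_replicate$tissue == retained$tissue[i], ]
    expect_true(all(reps$boundary_reads_5 >= 1))
    expect_true(all(reps$boundary_reads_3 >= 1))
    expect_true(all(reps$boundary_reads_5 + reps$boundary_reads_3 >= 5))
    expect_true(all(reps$covered_fraction > 0.95))
  }
})

test_that("flanking retention bins follow the six-way table", {
  expect_equal(as.character(flanking_bin(TRUE, FALSE, FALSE)), "I")
  expect_equal(as.character(flanking_bin(TRUE, TRUE, FALSE)), "II")
  expect_equal(as.character(flanking_bin(TRUE, TRUE, TRUE)), "III")
  expect_equal(as.character(flanking_bin(FALSE, FALSE, FALSE)), "IV")
  expect_equal(as.character(flanking_bin(FALSE, FALSE, TRUE)), "V")
  expect_equal(as.character(flanking_bin(FALSE, TRUE, TRUE)), "VI")
})

test_that("group tests match closed-form oracles and flag degenerate input", {
  ## identical groups: p ~ 1, no stars
  r <- msi_group_tests(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3),
                       test = "rank")
  expect_gt(r$p_value, 0.9)
  expect_equal(r$stars, "")
  ## two well-separated groups: closed-form one-way ANOVA F statistic
  x <- c(1, 2, 3, 101, 102, 103); g <- rep(c("a", "b"), each = 3)
  r <- msi_group_tests(x, g, test = "anova")
  grand <- mean(x)
  ssb <- 3 * ((mean(x[1:3]) - grand)^2 + (mean(x[4:6]) - grand)^2)
  ssw <- sum((x[1:3] - mean(x[1:3]))^2) + sum((x[4:6] - mean(x[4:6]))^2)
  f_oracle <- (ssb / 1) / (ssw / 4)
  expect_equal(r$statistic, f_oracle)
  expect_lt(r$p_value, 0.01)
  expect_true(nchar(r$stars) >= 2)
  ## planted length difference: two-group rank test rejects
  set.seed(13)
  short <- rlnorm(40, log(120), 0.3); long <- rlnorm(40, log(300), 0.3)
  r <- msi_group_tests(c(short, long), rep(c("s", "l"), each = 40),
                       test = "two_group_rank")
  expect_lt(r$p_value, 0.001)
  ## degenerate: zero variance everywhere
  r <- msi_group_tests(c(1, 1, 2, 2), c("a", "a", "b", "b"), test = "anova")
  expect_true(is.na(r$p_value))
  expect_true(isTRUE(r$degenerate))
  expect_error(msi_group_tests(1:3, c("a", "a", "a")), ">= 2 groups")
})

test_that("the Dunn post-hoc ranks groups like the omnibus test expects", {
  set.seed(14)
  x <- c(rnorm(20, 0), rnorm(20, 0), rnorm(20, 5))
  g <- rep(c("a", "b", "c"), each = 20)
  ph <- dunn_posthoc(x, g)
  expect_equal(nrow(ph), 3)
  sig <- ph[ph$group2 == "c" | ph$group1 == "c", ]
  expect_true(all(sig$p_adj < 0.01))
  ns <- ph[ph$group1 == "a" & ph$group2 == "b", ]
  expect_gt(ns$p_adj, 0.05)
})

test_that("alignment-based evidence counting matches the generator truth", {
  cfg <- sim_config(seed = 15, n_genes = 6)
  sim <- simulate_genome_annotation(cfg)
  introns <- sim$truth$introns
  picks <- introns[c(which(introns$strand == "+")[1],
                     which(introns$strand == "-")[1]), ]
  for (k in seq_len(nrow(picks))) {
    counts <- list(boundary_reads_5 = 6L, boundary_reads_3 = 4L,
                   spliced_reads = 15L)
    sam <- tempfile(fileext = ".sam")
    simulate_sam(sim, picks[k, ], counts, sam)
    ev <- count_intron_evidence(sam, picks[k, ])
    expect_equal(ev$boundary_reads_5, counts$boundary_reads_5)
    expect_equal(ev$boundary_reads_3, counts$boundary_reads_3)
    expect_equal(ev$spliced_reads, counts$spliced_reads)
    expect_gt(ev$covered_fraction, 0.95)
  }
  ## a read with too little anchor on the intron side is not a boundary read
  one <- picks[1, ]
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", one$chrom,
                       nchar(as.character(sim$annotation$seqs[[one$chrom]]))),
               sprintf("r1\t0\t%s\t%d\t50\t7M\t*\t0\t0\t%s\t*", one$chrom,
                       one$start - 5L,
                       strrep("A", 7))), sam)
  ev <- count_intron_evidence(sam, one, anchor = 3L)
  expect_equal(ev$boundary_reads_5 + ev$boundary_reads_3, 0)
})
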