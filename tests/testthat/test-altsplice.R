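mk_junc <- function(gap_start, gap_end, read_id = "r1", sample_id = "t1_r1",
                    oh_l = 10L, oh_r = 10L, unique = TRUE) {
  data.frame(read_id = read_id, sample_id = sample_id, tissue = "t1",
             gap_start = gap_start, gap_end = gap_end,
             overhang_left = oh_l, overhang_right = oh_r, unique = unique,
             stringsAsFactors = FALSE)
}

test_that("read collection drops 1-nt overhangs, multimappers and far junctions", {
  locus <- toy_locus()
  Is <- locus$minor[1]; Ie <- locus$minor[2]
  juncs <- rbind(
    mk_junc(Is, Ie, "keep"),
    mk_junc(Is, Ie, "oh1", oh_l = 1L),
    mk_junc(Is, Ie, "multi", unique = FALSE),
    mk_junc(5000L, 6000L, "far"))
  kept <- collect_spliced_reads(juncs, locus)
  expect_equal(kept$read_id, "keep")
})

test_that("cryptic junction detection applies the >2 nt rule and pass-2 bait rescue", {
  locus <- toy_locus()
  Is <- locus$minor[1]; Ie <- locus$minor[2]
  juncs <- rbind(
    mk_junc(Is, Ie + 1L, "shift1"),          # 1 nt off: not cryptic
    mk_junc(Is, Ie - 30L, "cr1"),            # cryptic acceptor inside intron
    mk_junc(Is, Ie - 30L, "cr2"),
    mk_junc(Is + 10L, Ie - 30L, "rescued"))  # pass-2: shares the cryptic acceptor
  cr <- detect_cryptic_junctions(juncs, locus)
  expect_equal(nrow(cr), 1)
  expect_equal(cr$side, "3ss")
  nl <- minorintron:::norm_locus(locus)
  expect_equal(cr$coord, nl$minor[2] - 30L)
  expect_equal(cr$n_reads, 3)                # two pass-1 + one rescued
})

test_that("junction binning reproduces the worked category examples", {
  locus <- toy_locus()
  Is <- locus$minor[1]; Ie <- locus$minor[2]
  Us <- locus$up_exon[1]; Ue <- locus$up_exon[2]
  Ds <- locus$down_exon[1]; De <- locus$down_exon[2]
  U2e <- locus$up2_exon[2]; D2s <- locus$down2_exon[1]
  expect_equal(bin_junction(Is, Ie, locus), "CAT1")
  expect_setequal(bin_junction(U2e + 1L, D2s - 1L, locus), "CAT2")
  expect_setequal(bin_junction(U2e + 1L, Ie, locus), "CAT3")
  expect_setequal(bin_junction(Is, D2s - 1L, locus), "CAT4")
  expect_setequal(bin_junction(Ue - 10L, Ie, locus), "CAT5")
  expect_setequal(bin_junction(Is + 20L, Ie, locus), c("CAT6", "CAT9"))
  expect_setequal(bin_junction(Is, Ds + 10L, locus), "CAT7")
  expect_setequal(bin_junction(Is, Ie - 20L, locus), c("CAT8", "CAT9"))
  ## acceptor one nt off is neither canonical nor cryptic
  expect_equal(bin_junction(Is, Ie + 1L, locus), "unassigned")
})

test_that("binning equals the brute-force predicate oracle on 1000 random junctions", {
  locus <- toy_locus()
  set.seed(16)
  lo <- locus$up2_exon[1] - 20L
  hi <- locus$down2_exon[2] + 20L
  for (i in 1:1000) {
    a <- sort(sample(lo:hi, 2))
    got <- sort(bin_junction(a[1], a[2], locus))
    want <- sort(oracle_bin(a[1], a[2], locus))
    expect_identical(got, want)
  }
})

test_that("binning is invariant under reverse-complementing the locus", {
  locus <- toy_locus()
  L <- 2000L
  mirrored <- mirror_locus(locus, L)
  set.seed(17)
  lo <- locus$up2_exon[1] - 20L
  hi <- locus$down2_exon[2] + 20L
  for (i in 1:200) {
    a <- sort(sample(lo:hi, 2))
    fwd <- sort(bin_junction(a[1], a[2], locus))
    rev <- sort(bin_junction(L + 1L - a[2], L + 1L - a[1], mirrored))
    expect_identical(fwd, rev)
  }
})

test_that("event MSI uses the distinct-read denominator and strict filters", {
  locus <- toy_locus()
  Is <- locus$minor[1]; Ie <- locus$minor[2]
  U2e <- locus$up2_exon[2]
  samples <- data.frame(sample_id = "t1_r1", tissue = "t1",
                        library_unique_reads = 3e6)
  ## 5 CAT3 reads among 50 total: MSI exactly 10.0 fails the strict > 10 rule
  juncs <- rbind(
    mk_junc(rep(U2e + 1L, 5), rep(Ie, 5), paste0("e", 1:5)),
    mk_junc(rep(Is, 45), rep(Ie, 45), paste0("c", 1:45)))
  q <- quantify_as_events(juncs, locus, samples)
  cat3 <- q$tissue_calls[q$tissue_calls$category == "CAT3", ]
  expect_equal(cat3$mean_msi, 10)
  expect_false(cat3$passed)
  expect_match(cat3$fail_reasons, "msi_below_threshold")
  ## 2 supporting reads in a 3M library: normalized support 2 > 1 passes depth
  expect_equal(cat3$mean_reads * 3e6 / 3e6, 5)
  juncs2 <- rbind(
    mk_junc(rep(U2e + 1L, 2), rep(Ie, 2), paste0("e", 1:2)),
    mk_junc(rep(Is, 8), rep(Ie, 8), paste0("c", 1:8)))
  q2 <- quantify_as_events(juncs2, locus, samples)
  cat3b <- q2$tissue_calls[q2$tissue_calls$category == "CAT3", ]
  expect_equal(cat3b$mean_norm_reads, 2)
  expect_true(cat3b$passed)        # MSI 20 > 10 and depth 2 > 1
  ## zero supporting reads: event not reported as passing
  catx <- q2$tissue_calls[q2$tissue_calls$category == "CAT2", ]
  expect_equal(catx$mean_msi, 0)
  expect_false(catx$passed)
  ## CAT1 is never reported as an AS event
  expect_false("CAT1" %in% q2$tissue_calls$category)
})

test_that("multi-gap reads contribute each junction but count once in the denominator", {
  locus <- toy_locus()
  Is <- locus$minor[1]; Ie <- locus$minor[2]
  samples <- data.frame(sample_id = "t1_r1", tissue = "t1",
                        library_unique_reads = 3e6)
  ## one read with two gaps flanking a cryptic exon, plus 3 canonical reads
  e1 <- Is + 15L; e2 <- e1 + 23L
  juncs <- rbind(
    mk_junc(Is, e1 - 1L, "both"),
    mk_junc(e2 + 1L, Ie, "both"),
    mk_junc(rep(Is, 3), rep(Ie, 3), paste0("c", 1:3)))
  q <- quantify_as_events(juncs, locus, samples)
  ps <- q$per_sample
  expect_equal(unique(ps$total_spliced), 4)   # distinct reads
  expect_equal(ps$reads[ps$category == "CAT9"], 1)
  ## category support can exceed distinct reads in total (multi-assignment)
  expect_gte(sum(ps$reads), length(unique(juncs$read_id)))
})

test_that("every collected read lands in at least one category or unassigned", {
  cfg <- sim_config(seed = 18, n_genes = 10, tissues = c("t1", "t2"))
  sim <- simulate_genome_annotation(cfg)
  reads <- simulate_reads(cfg, sim)
  ta <- reads$truth$as_events
  expect_false(is.null(ta))   # this seed plants events
  for (i in seq_len(min(2, nrow(ta)))) {
    mi <- sim$truth$introns[sim$truth$introns$intron_id == ta$intron_id[i], ]
    tx <- sim$annotation$genes[[mi$gene_id]]$transcripts[[mi$transcript_id]]
    locus <- as_locus(tx, mi)
    sub <- collect_spliced_reads(
      reads$junctions[reads$junctions$intron_id == ta$intron_id[i], ], locus)
    for (j in seq_len(min(nrow(sub), 50))) {
      cats <- bin_junction(sub$gap_start[j], sub$gap_end[j], locus)
      expect_gte(length(cats), 1)
    }
  }
})

test_that("annotated isoforms bin into the four classes in the quoted order", {
  t <- toy_transcript()
  minor <- t$minor
  base <- t$tx
  expect_equal(unname(bin_annotated_isoforms(list(base), minor$start,
                                             minor$end)), "constitutive")
  trunc <- base; trunc$exons <- base$exons[1:2, ]
  expect_equal(unname(bin_annotated_isoforms(list(trunc), minor$start,
                                             minor$end)), "truncated_before")
  term <- base
  term$exons <- rbind(data.frame(start = minor$start + 5L,
                                 end = minor$start + 30L),
                      base$exons[3:5, ])
  expect_equal(unname(bin_annotated_isoforms(list(term), minor$start,
                                             minor$end)), "terminal_exon_within")
  skipper <- base; skipper$exons <- base$exons[c(1, 2, 4, 5), ]
  expect_equal(unname(bin_annotated_isoforms(list(skipper), minor$start,
                                             minor$end)), "AS_across")
})
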