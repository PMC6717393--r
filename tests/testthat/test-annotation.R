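gtf_line <- function(chrom, type, start, end, strand, attrs, src = "ensembl") {
  sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, src, type, start, end,
          strand, attrs)
}

test_that("GTF/FASTA parsing builds gene models and validates chromosomes", {
  fa <- write_toy_fasta(c(chr1 = strrep("ACGT", 500)))
  at <- function(tx, extra = "") {
    sprintf('gene_id "g1"; transcript_id "%s"; gene_biotype "protein_coding";%s',
            tx, extra)
  }
  gtf <- write_toy_gtf(c(
    gtf_line("chr1", "exon", 101, 200, "+", at("t1")),
    gtf_line("chr1", "exon", 301, 400, "+", at("t1")),
    gtf_line("chr1", "exon", 501, 600, "+", at("t1")),
    gtf_line("chr1", "exon", 101, 200, "+", at("t2")),
    gtf_line("chr1", "exon", 501, 600, "+", at("t2"))))
  ann <- parse_annotation(gtf, fa)
  expect_length(ann$genes, 1)
  expect_length(ann$genes$g1$transcripts, 2)
  expect_equal(nrow(ann$genes$g1$transcripts$t1$exons), 3)

  gtf_bad <- write_toy_gtf(gtf_line("chrMISSING", "exon", 1, 50, "+", at("t1")))
  expect_error(parse_annotation(gtf_bad, fa), "chrMISSING")

  empty <- write_toy_gtf(character(0))
  expect_length(parse_annotation(empty, fa)$genes, 0)
})

test_that("canonical transcript follows the CCDS/longest-CDS ladder with id tie-break", {
  mk <- function(id, cds_len, ccds = FALSE, ehav = FALSE, exonic = 1000L) {
    list(transcript_id = id, gene_id = "g", chrom = "c", strand = "+",
         exons = data.frame(start = 1L, end = exonic), cds = NULL,
         cds_len = cds_len, exonic_length = exonic, has_ccds = ccds,
         has_ensembl_havana = ehav)
  }
  gene <- function(...) list(gene_id = "g", gene_type = "protein_coding",
                             transcripts = list(...))
  ## CCDS beats a longer untagged CDS
  g <- gene(a = mk("a", 300L, ccds = TRUE), b = mk("b", 600L))
  expect_equal(select_canonical_transcript(g)$transcript_id, "a")
  ## Ensembl/Havana beats plain coding
  g <- gene(a = mk("a", 300L, ehav = TRUE), b = mk("b", 600L))
  expect_equal(select_canonical_transcript(g)$transcript_id, "a")
  ## no CDS anywhere: longest exonic
  g <- gene(a = mk("a", 0L, exonic = 500L), b = mk("b", 0L, exonic = 800L))
  expect_equal(select_canonical_transcript(g)$transcript_id, "b")
  ## equal CDS, same tags: lexicographically smaller id
  g <- gene(zz = mk("zz", 300L), aa = mk("aa", 300L))
  expect_equal(select_canonical_transcript(g)$transcript_id, "aa")
})

test_that("introns are derived with transcript-orientation ordinals and dinucleotides", {
  t <- toy_transcript()
  introns <- derive_introns(t$tx, t$seqs)
  expect_equal(nrow(introns), 4)
  expect_equal(introns$ordinal, 1:4)
  expect_equal(introns$length,
               t$exon_starts[-1] - t$exon_ends[-5] - 1L)
  ## single-exon transcript
  tx1 <- t$tx; tx1$exons <- tx1$exons[1, , drop = FALSE]
  expect_equal(nrow(derive_introns(tx1, t$seqs)), 0)
  ## abutting exons error
  tx2 <- t$tx; tx2$exons$start[2] <- tx2$exons$end[1] + 1L
  expect_error(derive_introns(tx2, t$seqs), "abutting")
})

test_that("minus-strand dinucleotides are the reverse complement of the forward slice", {
  chrom <- strrep("A", 400)
  ## forward intron 151..250 reads GT...AG; on the minus strand the
  ## transcript-orientation intron is its reverse complement CT...AC
  substring(chrom, 151, 152) <- "GT"
  substring(chrom, 249, 250) <- "AG"
  seqs <- Biostrings::DNAStringSet(c(c1 = chrom))
  tx <- list(transcript_id = "t", gene_id = "g", chrom = "c1", strand = "-",
             exons = data.frame(start = c(101L, 251L), end = c(150L, 300L)),
             cds = NULL, cds_len = 0L, exonic_length = 100L,
             has_ccds = FALSE, has_ensembl_havana = FALSE)
  introns <- derive_introns(tx, seqs)
  expect_equal(introns$dinuc_5, "CT")
  expect_equal(introns$dinuc_3, "AC")
  tx$strand <- "+"
  introns <- derive_introns(tx, seqs)
  expect_equal(introns$dinuc_5, "GT")
  expect_equal(introns$dinuc_3, "AG")
})

test_that("splice windows have the documented geometry", {
  t <- toy_transcript()
  introns <- derive_introns(t$tx, t$seqs)
  win <- extract_splice_windows(introns[1, ], t$seqs)
  expect_equal(nchar(win$donor12), 12)
  expect_equal(nchar(win$acceptor14), 14)
  ## donor holds the intron's first dinucleotide at positions 4-5, the
  ## acceptor its last dinucleotide at positions 12-13
  expect_equal(substring(win$donor12, 4, 5), introns$dinuc_5[1])
  expect_equal(substring(win$acceptor14, 12, 13), introns$dinuc_3[1])
  ## 100-nt intron: full -40..-1 region, 29 windows
  expect_length(win$bps_windows, 29)
  expect_false(win$flag_short)
})

test_that("short introns get clipped branch-point regions matching a brute-force slicer", {
  for (len in c(35L, 45L, 60L, 100L)) {
    chrom <- paste(rep("ACGT", 200), collapse = "")
    seqs <- Biostrings::DNAStringSet(c(c1 = chrom))
    intron <- data.frame(chrom = "c1", start = 101L, end = 100L + len,
                         strand = "+")
    win <- extract_splice_windows(intron, seqs, min_scorable_length = 30L)
    usable <- min(40L, len - 9L)
    expected_n <- max(0L, usable - 12L + 1L)
    ## brute-force slicer over the -usable..-1 region
    region <- substring(chrom, 100L + len - usable + 1L, 100L + len)
    brute <- if (nchar(region) >= 12) {
      vapply(seq_len(nchar(region) - 11L), function(i) {
        substring(region, i, i + 11L)
      }, character(1))
    } else character(0)
    expect_equal(win$bps_windows, brute)
    expect_length(win$bps_windows, expected_n)
    expect_equal(win$flag_short, len < 49L)
  }
  ## below the minimum scorable length: no windows, flagged
  seqs <- Biostrings::DNAStringSet(c(c1 = strrep("ACGT", 100)))
  intron <- data.frame(chrom = "c1", start = 101L, end = 125L, strand = "+")
  win <- extract_splice_windows(intron, seqs)
  expect_length(win$bps_windows, 0)
  expect_true(win$flag_short)
})

test_that("windows are strand symmetric: a mirrored minus-strand gene scores identically", {
  sim <- simulate_genome_annotation(sim_config(seed = 4, n_genes = 5))
  introns <- sim$truth$introns
  L <- nchar(as.character(sim$annotation$seqs[[1]]))
  mirrored <- Biostrings::DNAStringSet(
    setNames(as.character(Biostrings::reverseComplement(sim$annotation$seqs[[1]])),
             "chrS"))
  for (i in seq_len(min(nrow(introns), 8))) {
    a <- extract_splice_windows(introns[i, ], sim$annotation$seqs)
    m <- introns[i, ]
    m$start <- L + 1L - introns$end[i]
    m$end <- L + 1L - introns$start[i]
    m$strand <- if (introns$strand[i] == "+") "-" else "+"
    b <- extract_splice_windows(m, mirrored)
    expect_equal(a$donor12, b$donor12)
    expect_equal(a$acceptor14, b$acceptor14)
    expect_equal(a$bps_windows, b$bps_windows)
  }
})

test_that("exon+intron slices reconcatenate to the contiguous genomic sequence", {
  sim <- simulate_genome_annotation(sim_config(seed = 6, n_genes = 4))
  for (gene in sim$annotation$genes) {
    tx <- select_canonical_transcript(gene)
    ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
    if (nrow(ex) < 2) next
    whole <- as.character(Biostrings::subseq(sim$annotation$seqs[[tx$chrom]],
                                             min(ex$start), max(ex$end)))
    introns <- derive_introns(tx, sim$annotation$seqs)
    introns <- introns[order(introns$start), ]
    parts <- character(0)
    for (i in seq_len(nrow(ex))) {
      parts <- c(parts, as.character(Biostrings::subseq(
        sim$annotation$seqs[[tx$chrom]], ex$start[i], ex$end[i])))
      if (i < nrow(ex)) {
        parts <- c(parts, as.character(Biostrings::subseq(
          sim$annotation$seqs[[tx$chrom]], introns$start[i], introns$end[i])))
      }
    }
    expect_equal(paste(parts, collapse = ""), whole)
  }
})
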