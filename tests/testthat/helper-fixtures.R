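# In-code fixtures and independent oracles shared across the suite.

# A deterministic toy transcript: five exons on a hand-built chromosome, with
# the minor intron between exons 2 and 3. Exonic sequence carries an intact
# ORF (ATG ... TAA) so fate predictions are decidable by construction.
toy_transcript <- function(strand = "+") {
  exon_len <- c(60L, 60L, 60L, 60L, 60L)     # 300 exonic nt = 100 codons
  intron_len <- c(100L, 140L, 100L, 100L)
  starts <- integer(5); ends <- integer(5)
  pos <- 101L
  for (i in 1:5) {
    starts[i] <- pos; ends[i] <- pos + exon_len[i] - 1L
    pos <- ends[i] + 1L + if (i < 5) intron_len[i] else 0L
  }
  mrna <- paste0("ATG", strrep("GCT", 98), "TAA")  # exactly 300 exonic nt
  chrom_len <- ends[5] + 100L
  set.seed(42)
  s <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  idx <- unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))
  s[idx] <- strsplit(mrna, "")[[1]]
  chrom <- paste(s, collapse = "")
  if (strand == "-") chrom_name <- "chrM" else chrom_name <- "chrT"
  seqs <- Biostrings::DNAStringSet(setNames(chrom, chrom_name))
  ex <- data.frame(start = starts, end = ends)
  tx <- list(transcript_id = "toy1", gene_id = "toyG", chrom = chrom_name,
             strand = "+", exons = ex, cds = ex, cds_len = 300L,
             exonic_length = 300L, has_ccds = TRUE, has_ensembl_havana = TRUE)
  minor <- data.frame(chrom = chrom_name, start = ends[2] + 1L,
                      end = starts[3] - 1L, strand = "+")
  list(tx = tx, minor = minor, seqs = seqs,
       exon_starts = starts, exon_ends = ends)
}

toy_locus <- function() {
  t <- toy_transcript()
  as_locus(t$tx, t$minor)
}

# mirror of a locus model: same gene drawn on the minus strand of a mirrored
# chromosome of length L (position x maps to L + 1 - x)
mirror_locus <- function(locus, L) {
  fl <- function(iv) if (is.null(iv)) NULL else c(L + 1L - iv[2], L + 1L - iv[1])
  structure(list(chrom = locus$chrom,
                 strand = if (locus$strand == "+") "-" else "+",
                 minor = fl(locus$minor),
                 up_exon = fl(locus$up_exon), down_exon = fl(locus$down_exon),
                 up2_exon = fl(locus$up2_exon),
                 down2_exon = fl(locus$down2_exon)), class = "as_locus")
}

# Independent brute-force evaluator of the four minor-intron criteria,
# written directly from the threshold rules over plain score lists.
oracle_classify <- function(atac5, mgt5, majgt5, majgc5, bps, x3_atac, x3_gtag) {
  others <- function(x, rest) all(x - rest >= 10)
  c1 <- atac5 > 50 && others(atac5, c(mgt5, majgt5, majgc5))
  c2 <- mgt5 > 50 && (mgt5 - majgt5) >= 25 && (mgt5 - atac5) >= 10 &&
    (mgt5 - majgc5) >= 10
  c3 <- mgt5 > 50 && others(mgt5, c(atac5, majgt5, majgc5)) &&
    !is.na(bps) && bps > 65
  best5 <- max(atac5, mgt5)
  x3 <- if (atac5 >= mgt5) x3_atac else x3_gtag
  c4 <- !is.na(bps) && !is.na(x3) && (best5 + bps + x3) > 150
  crit <- which(c(c1, c2, c3, c4))
  list(call = if (length(crit)) "minor" else "major",
       criterion = if (length(crit)) crit[1] else NA_integer_)
}

# Independent brute-force category classifier: predicates expressed through
# the set of removed bases rather than coordinate comparisons.
oracle_bin <- function(gap_start, gap_end, locus,
                       cryptic_map = c(exonic_5 = "CAT5", intronic_5 = "CAT6",
                                       exonic_3 = "CAT7", intronic_3 = "CAT8"),
                       min_dist = 2L) {
  nl <- minorintron:::norm_locus(locus)
  nj <- minorintron:::norm_junc(gap_start, gap_end, locus)
  removed <- seq(nj$jd, nj$ja)
  intron <- seq(nl$minor[1], nl$minor[2])
  up_ex <- seq(nl$up_exon[1], nl$up_exon[2])
  down_ex <- seq(nl$down_exon[1], nl$down_exon[2])
  left_flank <- min(removed) - 1L   # last retained base before the gap
  right_flank <- max(removed) + 1L  # first retained base after the gap
  cats <- character(0)
  if (setequal(removed, intron)) cats <- c(cats, "CAT1")
  covers <- function(b) all(b %in% removed)
  if (covers(up_ex) && covers(down_ex)) cats <- c(cats, "CAT2")
  if (covers(up_ex) && !covers(down_ex) && right_flank <= max(down_ex))
    cats <- c(cats, "CAT3")
  if (covers(down_ex) && !covers(up_ex) && left_flank >= min(up_ex))
    cats <- c(cats, "CAT4")
  d <- min(removed)  # cryptic donor position
  a <- max(removed)  # cryptic acceptor position
  if (d %in% up_ex && d != min(up_ex) && (min(intron) - d) > min_dist &&
      a >= min(intron)) cats <- c(cats, cryptic_map[["exonic_5"]])
  if (d %in% intron && d != min(intron) && (d - min(intron)) > min_dist)
    cats <- c(cats, cryptic_map[["intronic_5"]])
  if (a %in% down_ex && a != max(down_ex) && (a - max(intron)) > min_dist &&
      d <= max(intron)) cats <- c(cats, cryptic_map[["exonic_3"]])
  if (a %in% intron && a != max(intron) && (max(intron) - a) > min_dist)
    cats <- c(cats, cryptic_map[["intronic_3"]])
  left_inside <- d %in% intron && d != min(intron)
  right_inside <- a %in% intron && a != max(intron)
  left_anchor <- left_flank %in% c(up_ex, min(intron) - 1L) &&
    d <= min(intron)
  right_anchor <- right_flank %in% c(down_ex, max(intron) + 1L) &&
    a >= max(intron)
  if ((left_inside && right_inside) || (left_inside && right_anchor) ||
      (right_inside && left_anchor)) cats <- c(cats, "CAT9")
  if (length(cats) == 0L) cats <- "unassigned"
  unique(cats)
}

# tiny GTF writer for annotation parsing tests
write_toy_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

write_toy_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  path
}
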