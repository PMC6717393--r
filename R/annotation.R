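#' Parse a genome annotation and its sequence
#'
#' Reads an Ensembl-dialect GTF (via rtracklayer) and a multi-record FASTA
#' (via Biostrings) into the gene/transcript model used by the classifier.
#' Exon coordinates are kept exactly as annotated (1-based, inclusive).
#'
#' @param gtf_path path to a GTF file with `exon` (and optionally `CDS`)
#'   records carrying `gene_id` and `transcript_id` attributes.
#' @param fasta_path path to the genome FASTA; every chromosome referenced by
#'   an exon must be present.
#' @return list with `genes` (named list of gene models) and `seqs`
#'   (`DNAStringSet`), class `annotation_set`.
#' @export
parse_annotation <- function(gtf_path, fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  raw <- readLines(gtf_path, warn = FALSE)
  if (!any(nzchar(raw) & !startsWith(raw, "#"))) {
    return(structure(list(genes = list(), seqs = seqs),
                     class = "annotation_set"))
  }
  gr <- tryCatch(rtracklayer::import(gtf_path, format = "gtf"),
                 error = function(e) stopf("malformed GTF '%s': %s",
                                           gtf_path, conditionMessage(e)))
  if (length(gr) == 0L) {
    return(structure(list(genes = list(), seqs = seqs),
                     class = "annotation_set"))
  }
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS")
  gr <- gr[keep]; md <- md[keep, , drop = FALSE]
  chroms <- as.character(GenomicRanges::seqnames(gr))
  missing <- setdiff(unique(chroms), names(seqs))
  if (length(missing)) {
    stopf("GTF references chromosome(s) absent from FASTA: %s",
          paste(missing, collapse = ", "))
  }
  attr_or_na <- function(field) {
    if (field %in% colnames(md)) as.character(md[[field]]) else
      rep(NA_character_, length(gr))
  }
  df <- data.frame(
    type = as.character(md$type),
    chrom = chroms,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    source = attr_or_na("source"),
    gene_id = attr_or_na("gene_id"),
    transcript_id = attr_or_na("transcript_id"),
    gene_biotype = attr_or_na("gene_biotype"),
    ccds_id = attr_or_na("ccds_id"),
    tag = attr_or_na("tag"),
    stringsAsFactors = FALSE)
  if (anyNA(df$transcript_id) || anyNA(df$gene_id)) {
    stopf("GTF exon/CDS record missing gene_id or transcript_id")
  }
  genes <- build_gene_models(df)
  structure(list(genes = genes, seqs = seqs), class = "annotation_set")
}

## collapse the flat GTF record table into nested gene -> transcript models
build_gene_models <- function(df) {
  genes <- list()
  for (gid in unique(df$gene_id)) {
    gdf <- df[df$gene_id == gid, , drop = FALSE]
    biotype <- gdf$gene_biotype[!is.na(gdf$gene_biotype)][1]
    gene_type <- if (is.na(biotype)) "other"
      else if (grepl("pseudogene", biotype)) "pseudogene"
      else if (grepl("lincRNA|lncRNA", biotype)) "lincRNA"
      else if (biotype == "protein_coding") "protein_coding"
      else "other"
    txs <- list()
    for (tid in unique(gdf$transcript_id)) {
      tdf <- gdf[gdf$transcript_id == tid, , drop = FALSE]
      ex <- tdf[tdf$type == "exon", , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      cds <- tdf[tdf$type == "CDS", , drop = FALSE]
      txs[[tid]] <- list(
        transcript_id = tid, gene_id = gid,
        chrom = ex$chrom[1], strand = ex$strand[1],
        exons = data.frame(start = ex$start, end = ex$end),
        cds = if (nrow(cds)) {
          ord <- order(cds$start)
          data.frame(start = cds$start[ord], end = cds$end[ord])
        } else NULL,
        cds_len = if (nrow(cds)) sum(cds$end - cds$start + 1L) else 0L,
        exonic_length = sum(ex$end - ex$start + 1L),
        has_ccds = any(!is.na(tdf$ccds_id) & nzchar(tdf$ccds_id)),
        has_ensembl_havana = any(tdf$source %in% "ensembl_havana") ||
          any(!is.na(tdf$tag) & grepl("basic", tdf$tag)))
    }
    genes[[gid]] <- list(gene_id = gid, gene_type = gene_type,
                         transcripts = txs)
  }
  genes
}

#' Select a gene's canonical transcript
#'
#' Priority ladder: (1) among CCDS-tagged coding transcripts, the longest
#' coding sequence; (2) else among Ensembl/Havana-tagged coding transcripts,
#' the longest CDS; (3) else among all coding transcripts, the longest CDS;
#' (4) else (no CDS anywhere) the longest transcript by summed exonic length.
#' Ties are broken by the lexicographically smallest transcript identifier.
#'
#' @param gene a gene model as produced by [parse_annotation()].
#' @return the selected transcript model.
#' @export
select_canonical_transcript <- function(gene) {
  txs <- gene$transcripts
  if (length(txs) == 0L) stopf("gene '%s' has no transcripts", gene$gene_id)
  pick_longest <- function(cands, len_field) {
    lens <- vapply(cands, function(t) as.numeric(t[[len_field]]), numeric(1))
    ids <- vapply(cands, function(t) t$transcript_id, character(1))
    cands[[order(-lens, ids)[1]]]
  }
  coding <- Filter(function(t) t$cds_len > 0L, txs)
  if (length(coding)) {
    ccds <- Filter(function(t) t$has_ccds, coding)
    if (length(ccds)) return(pick_longest(ccds, "cds_len"))
    ehav <- Filter(function(t) t$has_ensembl_havana, coding)
    if (length(ehav)) return(pick_longest(ehav, "cds_len"))
    return(pick_longest(coding, "cds_len"))
  }
  pick_longest(txs, "exonic_length")
}

#' Derive the introns of a transcript
#'
#' One intron per adjacent exon pair, numbered 1-based 5'->3' in transcript
#' orientation. Terminal dinucleotides are reported in transcript orientation
#' (reverse-complemented on the minus strand), so the first pair is always
#' the donor side.
#'
#' @param tx a transcript model.
#' @param seqs genome `DNAStringSet`.
#' @return data.frame with columns intron_id, gene_id, transcript_id, chrom,
#'   start, end, strand, ordinal, length, dinuc_5, dinuc_3. Empty for
#'   single-exon transcripts.
#' @export
derive_introns <- function(tx, seqs) {
  ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
  n <- nrow(ex)
  empty <- data.frame(intron_id = character(), gene_id = character(),
                      transcript_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      ordinal = integer(), length = integer(),
                      dinuc_5 = character(), dinuc_3 = character(),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  istart <- ex$end[-n] + 1L
  iend <- ex$start[-1] - 1L
  if (any(iend < istart)) {
    stopf("transcript '%s': abutting or overlapping exons leave a zero-length intron",
          tx$transcript_id)
  }
  k <- n - 1L
  ordinal <- if (tx$strand == "-") rev(seq_len(k)) else seq_len(k)
  d5 <- character(k); d3 <- character(k)
  for (i in seq_len(k)) {
    left <- seq_slice(seqs, tx$chrom, istart[i], istart[i] + 1L)
    right <- seq_slice(seqs, tx$chrom, iend[i] - 1L, iend[i])
    if (tx$strand == "-") {
      d5[i] <- revcomp(right); d3[i] <- revcomp(left)
    } else {
      d5[i] <- left; d3[i] <- right
    }
  }
  out <- data.frame(
    intron_id = sprintf("%s_i%d", tx$transcript_id, ordinal),
    gene_id = tx$gene_id, transcript_id = tx$transcript_id,
    chrom = tx$chrom, start = istart, end = iend, strand = tx$strand,
    ordinal = ordinal, length = iend - istart + 1L,
    dinuc_5 = d5, dinuc_3 = d3, stringsAsFactors = FALSE)
  out[order(out$ordinal), , drop = FALSE]
}

#' Extract the splice-site windows of an intron
#'
#' Returns the 12-nt donor window (positions -3..+9 around the 5' splice
#' site: three exonic plus nine intronic bases), the 14-nt acceptor window
#' (-13..+1: thirteen intronic plus one exonic base), and the sliding 12-nt
#' branch-point windows over the region up to 40 nt upstream of the 3' splice
#' site (-40..-1), all in transcript orientation. Position numbering skips
#' zero: -1 is the last base before a boundary and +1 the first after it.
#'
#' The branch-point region is clipped so it never reaches into the nine
#' intronic donor bases; a full-length region yields 29 windows. Introns
#' shorter than `min_scorable_length` get no branch-point windows and are
#' flagged, so they are classified on donor/acceptor evidence alone. Introns
#' whose exonic context would run past a chromosome end are flagged
#' unscorable.
#'
#' @param intron one-row data.frame as returned by [derive_introns()].
#' @param seqs genome `DNAStringSet`.
#' @param min_scorable_length minimum intron length (nt) for branch-point
#'   scoring.
#' @return list with `donor12`, `acceptor14`, `bps_windows`, `flag_short`,
#'   `flag_boundary`, class `splice_windows`.
#' @export
extract_splice_windows <- function(intron, seqs, min_scorable_length = 30L) {
  chrom <- intron$chrom; s <- intron$start; e <- intron$end
  len <- e - s + 1L
  minus <- intron$strand == "-"
  grab <- function(a, b) tryCatch(seq_slice(seqs, chrom, a, b),
                                  error = function(err) NA_character_)
  if (minus) {
    donor12 <- grab(e - 8L, e + 3L)
    acceptor14 <- grab(s - 1L, s + 12L)
    if (!is.na(donor12)) donor12 <- revcomp(donor12)
    if (!is.na(acceptor14)) acceptor14 <- revcomp(acceptor14)
  } else {
    donor12 <- grab(s - 3L, s + 8L)
    acceptor14 <- grab(e - 12L, e + 1L)
  }
  flag_boundary <- is.na(donor12) || is.na(acceptor14)
  if (len < 13L) {
    acceptor14 <- NA_character_
  }
  bps_windows <- character(0)
  flag_short <- len < min_scorable_length
  if (!flag_short) {
    ## region -usable..-1 upstream of the 3'SS, never reaching the donor bases
    usable <- min(40L, len - 9L)
    region <- if (minus) {
      r <- grab(s, s + usable - 1L)
      if (!is.na(r)) revcomp(r) else r
    } else {
      grab(e - usable + 1L, e)
    }
    if (!is.na(region) && usable >= 12L) {
      starts <- seq_len(usable - 11L)
      bps_windows <- substring(region, starts, starts + 11L)
    }
    if (usable < 40L) flag_short <- TRUE
  }
  structure(list(donor12 = donor12, acceptor14 = acceptor14,
                 bps_windows = bps_windows, flag_short = flag_short,
                 flag_boundary = flag_boundary),
            class = "splice_windows")
}
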