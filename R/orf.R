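STOP_CODONS <- c("TAA", "TAG", "TGA")

## cumulative transcript-coordinate map of an exon chain
## returns per-exon transcript start/end (orientation-aware)
chain_tmap <- function(chain, strand) {
  ord <- order(chain$start, decreasing = (strand == "-"))
  ex <- chain[ord, , drop = FALSE]
  widths <- ex$end - ex$start + 1L
  tend <- cumsum(widths)
  tstart <- tend - widths + 1L
  list(exons = ex, tstart = tstart, tend = tend)
}

## genomic position -> transcript coordinate under a chain (NA if excised)
g2t <- function(pos, chain, strand) {
  tm <- chain_tmap(chain, strand)
  for (i in seq_len(nrow(tm$exons))) {
    s <- tm$exons$start[i]; e <- tm$exons$end[i]
    if (pos >= s && pos <= e) {
      off <- if (strand == "-") e - pos else pos - s
      return(tm$tstart[i] + off)
    }
  }
  NA_integer_
}

chain_sequence <- function(chain, chrom, strand, seqs) {
  tm <- chain_tmap(chain, strand)
  parts <- vapply(seq_len(nrow(tm$exons)), function(i) {
    s <- seq_slice(seqs, chrom, tm$exons$start[i], tm$exons$end[i])
    if (strand == "-") revcomp(s) else s
  }, character(1))
  paste(parts, collapse = "")
}

#' Apply an alternative-splicing event to a canonical transcript
#'
#' Edits the canonical exon chain according to the event category: retention
#' turns the minor intron exonic (merging the flanking exons); exon skipping
#' removes the skipped exon(s); a cryptic splice site moves an exon boundary
#' to the cryptic coordinate; a cryptic exon inserts an internal exon within
#' the minor intron. Junction positions and the transcript coordinate of the
#' annotated start codon are recomputed on the edited chain.
#'
#' Events whose read support only passes the filters as a sum over several
#' distinct junction coordinates, with no single coordinate passing on its
#' own, must be excluded upstream (see [single_coordinate_pass()]).
#'
#' @param tx canonical transcript model (with `cds`).
#' @param intron one-row minor-intron data.frame (genomic start/end).
#' @param category one of "RET", "CAT2".."CAT9".
#' @param gap genomic `c(start, end)` of the spliced-out interval for cryptic
#'   categories (CAT5-CAT8); ignored otherwise.
#' @param cryptic_exon genomic `c(start, end)` of the inserted exon (CAT9).
#' @return list with `exon_chain`, `junction_positions` (transcript coords of
#'   the last base of each exon but the final one), `annotated_start`
#'   (transcript coordinate, `NA` if lost), `chrom`, `strand`, `start_lost`,
#'   class `modified_transcript`.
#' @export
apply_as_event <- function(tx, intron, category, gap = NULL,
                           cryptic_exon = NULL) {
  ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
  li <- which(ex$end == intron$start - 1L)
  ri <- which(ex$start == intron$end + 1L)
  if (length(li) != 1L || length(ri) != 1L) {
    stopf("minor intron does not sit between adjacent exons of '%s'",
          tx$transcript_id)
  }
  minus <- tx$strand == "-"
  up_i <- if (minus) ri else li      # upstream flanking exon (transcript sense)
  down_i <- if (minus) li else ri
  chain <- ex
  if (category == "RET") {
    chain$end[li] <- chain$end[ri]
    chain <- chain[-ri, , drop = FALSE]
  } else if (category == "CAT1") {
    ## constitutive: chain unchanged
  } else if (category == "CAT2") {
    chain <- chain[-c(li, ri), , drop = FALSE]
  } else if (category == "CAT3") {
    chain <- chain[-up_i, , drop = FALSE]
  } else if (category == "CAT4") {
    chain <- chain[-down_i, , drop = FALSE]
  } else if (category %in% c("CAT5", "CAT6", "CAT7", "CAT8")) {
    if (is.null(gap)) stopf("cryptic category '%s' needs gap coordinates", category)
    ## the spliced-out interval replaces the canonical intron: the exon left
    ## of the gap ends at gap[1]-1, the exon right of it starts at gap[2]+1
    chain$end[li] <- gap[1] - 1L
    chain$start[ri] <- gap[2] + 1L
    chain <- chain[chain$end >= chain$start, , drop = FALSE]
  } else if (category == "CAT9") {
    if (is.null(cryptic_exon)) stopf("CAT9 needs cryptic exon coordinates")
    chain <- rbind(chain, data.frame(start = cryptic_exon[1],
                                     end = cryptic_exon[2]))
    chain <- chain[order(chain$start), , drop = FALSE]
  } else {
    stopf("unknown event category '%s'", category)
  }
  rownames(chain) <- NULL
  tm <- chain_tmap(chain, tx$strand)
  junctions <- if (nrow(chain) > 1L) tm$tend[-length(tm$tend)] else integer(0)
  start_g <- annotated_start_genomic(tx)
  t_start <- if (is.na(start_g)) NA_integer_ else g2t(start_g, chain, tx$strand)
  structure(list(
    transcript_id = tx$transcript_id, category = category,
    exon_chain = tm$exons, junction_positions = junctions,
    annotated_start = t_start, chrom = tx$chrom, strand = tx$strand,
    start_lost = !is.na(start_g) && is.na(t_start)
  ), class = "modified_transcript")
}

## genomic position of the first base of the annotated start codon
annotated_start_genomic <- function(tx) {
  if (is.null(tx$cds) || nrow(tx$cds) == 0L) return(NA_integer_)
  if (tx$strand == "-") max(tx$cds$end) else min(tx$cds$start)
}

#' Predict the protein / NMD / NSD fate of a modified transcript
#'
#' Translates from the annotated start codon in the standard genetic code
#' and locates the first in-frame stop. A transcript with no stop codon
#' before its end is predicted to undergo non-stop decay (NSD); a stop more
#' than `nmd_distance` nt upstream of the final exon-exon junction triggers
#' nonsense-mediated decay (NMD); anything else yields protein, classified
#' as truncated, extended or unchanged by comparing the new open reading
#' frame with the canonical one. With `junction_rule = "any"` the NMD
#' distance is tested against every downstream junction instead of only the
#' last one.
#'
#' @param mt a `modified_transcript` from [apply_as_event()].
#' @param tx the canonical transcript model (for the reference ORF).
#' @param seqs genome `DNAStringSet`.
#' @param nmd_distance the premature-stop distance rule (default 50 nt).
#' @param junction_rule "last" (default) or "any".
#' @return list with `fate` ("protein"/"NMD"/"NSD", or NA when the start
#'   codon was lost), `protein_change` ("truncated"/"extended"/"unchanged"/
#'   NA), `new_stop_position` (transcript coordinate of the stop codon's last
#'   base), `orf_codons`, `flag`.
#' @export
predict_fate <- function(mt, tx, seqs, nmd_distance = 50L,
                         junction_rule = c("last", "any")) {
  junction_rule <- match.arg(junction_rule)
  if (mt$start_lost || is.na(mt$annotated_start)) {
    return(list(fate = NA_character_, protein_change = NA_character_,
                new_stop_position = NA_integer_, orf_codons = NA_integer_,
                flag = "start_lost"))
  }
  seq <- chain_sequence(mt$exon_chain, mt$chrom, mt$strand, seqs)
  stop_at <- first_stop(seq, mt$annotated_start)
  if (is.na(stop_at)) {
    return(list(fate = "NSD", protein_change = NA_character_,
                new_stop_position = NA_integer_,
                orf_codons = (nchar(seq) - mt$annotated_start + 1L) %/% 3L,
                flag = ""))
  }
  stop_last <- stop_at + 2L   # transcript coordinate of the stop codon's last base
  juncs <- mt$junction_positions
  nmd <- if (junction_rule == "last") {
    length(juncs) > 0L && (max(juncs) - stop_last) > nmd_distance
  } else {
    any((juncs - stop_last) > nmd_distance)
  }
  n_codons <- (stop_at - mt$annotated_start) %/% 3L  # codons before the stop
  if (nmd) {
    return(list(fate = "NMD", protein_change = NA_character_,
                new_stop_position = stop_last, orf_codons = n_codons,
                flag = ""))
  }
  ref_codons <- canonical_orf_codons(tx, seqs)
  change <- if (is.na(ref_codons)) NA_character_
    else if (n_codons < ref_codons) "truncated"
    else if (n_codons > ref_codons) "extended"
    else "unchanged"
  list(fate = "protein", protein_change = change,
       new_stop_position = stop_last, orf_codons = n_codons, flag = "")
}

## transcript coordinate of the first in-frame stop codon (start of codon)
first_stop <- function(seq, t_start) {
  n <- nchar(seq)
  if (t_start > n - 2L) return(NA_integer_)
  pos <- seq(t_start, n - 2L, by = 3L)
  if (length(pos) == 0L) return(NA_integer_)
  codons <- substring(seq, pos, pos + 2L)
  hit <- which(codons %in% STOP_CODONS)
  if (length(hit) == 0L) NA_integer_ else pos[hit[1]]
}

canonical_orf_codons <- function(tx, seqs) {
  start_g <- annotated_start_genomic(tx)
  if (is.na(start_g)) return(NA_integer_)
  chain <- tx$exons
  t_start <- g2t(start_g, chain, tx$strand)
  seq <- chain_sequence(chain, tx$chrom, tx$strand, seqs)
  stop_at <- first_stop(seq, t_start)
  if (is.na(stop_at)) return(NA_integer_)
  (stop_at - t_start) %/% 3L
}

#' Single-coordinate read-filter check for aggregate events
#'
#' An event whose read filter only passes as a sum over several distinct
#' junction coordinates, with no single coordinate passing on its own, is
#' excluded from the fate analysis.
#'
#' @param coord_reads named numeric vector: reads per distinct junction
#'   coordinate supporting one event.
#' @param library_unique_reads library size for the depth normalization.
#' @param depth_norm see [quantify_as_events()].
#' @return TRUE when at least one single coordinate passes the depth filter.
#' @export
single_coordinate_pass <- function(coord_reads, library_unique_reads,
                                   depth_norm = 3e6) {
  any(coord_reads * depth_norm / library_unique_reads > 1)
}

#' Translate a modified transcript to its predicted protein
#'
#' @param mt a `modified_transcript`.
#' @param seqs genome `DNAStringSet`.
#' @return an `AAString` of the predicted protein (up to, not including, the
#'   stop), or `NULL` if the start was lost.
#' @export
predicted_protein <- function(mt, seqs) {
  if (mt$start_lost || is.na(mt$annotated_start)) return(NULL)
  seq <- chain_sequence(mt$exon_chain, mt$chrom, mt$strand, seqs)
  cds <- substring(seq, mt$annotated_start, nchar(seq))
  cds <- substring(cds, 1L, (nchar(cds) %/% 3L) * 3L)
  if (nchar(cds) < 3L) return(NULL)
  aa <- Biostrings::translate(Biostrings::DNAString(cds))
  star <- regexpr("*", as.character(aa), fixed = TRUE)
  if (star > 0) aa <- Biostrings::subseq(aa, 1L, star - 1L)
  aa
}
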