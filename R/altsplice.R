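#' Build the interrogation locus around a minor intron
#'
#' The locus model resolves the coordinates needed to bin spliced reads: the
#' minor intron, its two flanking exons and (when present) their neighbouring
#' exons, all in genomic coordinates with the strand recorded.
#'
#' @param tx transcript model (see [parse_annotation()]).
#' @param intron one-row data.frame for the minor intron (genomic start/end).
#' @return list with `chrom`, `strand`, `minor`, `up_exon`, `down_exon`,
#'   `up2_exon`, `down2_exon` (each `c(start, end)` or `NULL`), class
#'   `as_locus`. "Up"/"down" are in transcript orientation.
#' @export
as_locus <- function(tx, intron) {
  ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
  left_idx <- which(ex$end == intron$start - 1L)
  right_idx <- which(ex$start == intron$end + 1L)
  if (length(left_idx) != 1L || length(right_idx) != 1L) {
    stopf("intron %d-%d does not sit between two exons of transcript '%s'",
          intron$start, intron$end, tx$transcript_id)
  }
  get <- function(i) if (i >= 1L && i <= nrow(ex)) c(ex$start[i], ex$end[i]) else NULL
  minus <- tx$strand == "-"
  structure(list(
    chrom = tx$chrom, strand = tx$strand,
    minor = c(intron$start, intron$end),
    up_exon = if (minus) get(right_idx) else get(left_idx),
    down_exon = if (minus) get(left_idx) else get(right_idx),
    up2_exon = if (minus) get(right_idx + 1L) else get(left_idx - 1L),
    down2_exon = if (minus) get(left_idx - 1L) else get(right_idx + 1L)
  ), class = "as_locus")
}

## flip a locus (and junctions) into plus-like "transcript space" so binning
## predicates are written once; the flip x -> -x reverses order, so upstream
## is always left of the minor intron afterwards
norm_locus <- function(locus) {
  if (locus$strand != "-") return(locus)
  fl <- function(iv) if (is.null(iv)) NULL else c(-iv[2], -iv[1])
  locus$minor <- fl(locus$minor)
  locus$up_exon <- fl(locus$up_exon)
  locus$down_exon <- fl(locus$down_exon)
  locus$up2_exon <- fl(locus$up2_exon)
  locus$down2_exon <- fl(locus$down2_exon)
  locus
}

norm_junc <- function(jd, ja, locus) {
  if (locus$strand == "-") list(jd = -ja, ja = -jd) else list(jd = jd, ja = ja)
}

#' Collect uniquely mapped spliced reads around a minor intron
#'
#' Keeps junction reads that are uniquely mapped, have at least
#' `min_overhang` aligned nt on both sides of the junction, and have either
#' junction end within the interrogation window spanning from the
#' neighbouring exons through the minor intron.
#'
#' @param juncs data.frame of junction reads with columns `read_id`,
#'   `gap_start`, `gap_end` (the removed interval, 1-based inclusive, genomic
#'   plus-strand coordinates), `overhang_left`, `overhang_right`, `unique`.
#' @param locus an `as_locus`.
#' @param min_overhang minimum aligned nt on each side (reads with only one
#'   nucleotide on either side of the junction are excluded).
#' @return the filtered junction data.frame.
#' @export
collect_spliced_reads <- function(juncs, locus, min_overhang = 2L) {
  if (nrow(juncs) == 0L) return(juncs)
  win_left <- (locus$up2_exon %||% locus$up_exon %||% locus$minor)[1]
  win_right <- (locus$down2_exon %||% locus$down_exon %||% locus$minor)[2]
  if (locus$strand == "-") {
    win_left <- (locus$down2_exon %||% locus$down_exon %||% locus$minor)[1]
    win_right <- (locus$up2_exon %||% locus$up_exon %||% locus$minor)[2]
  }
  keep <- juncs$unique &
    juncs$overhang_left >= min_overhang &
    juncs$overhang_right >= min_overhang &
    ((juncs$gap_start >= win_left & juncs$gap_start <= win_right) |
     (juncs$gap_end >= win_left & juncs$gap_end <= win_right))
  juncs[keep, , drop = FALSE]
}

#' Detect cryptic splice junctions around a minor intron
#'
#' Pass 1 keeps junctions with one end exactly at a canonical splice site of
#' the minor intron and the other end more than `min_dist` nt away from its
#' canonical counterpart; those novel coordinates are then used as bait in
#' pass 2 to rescue reads sharing a cryptic coordinate even when their other
#' end is not anchored at a canonical site.
#'
#' @param juncs collected junction reads (see [collect_spliced_reads()]).
#' @param locus an `as_locus`.
#' @param min_dist minimum distance (nt) from the canonical splice site.
#' @return data.frame with `side` ("5ss"/"3ss"), `coord` (normalized
#'   transcript-space coordinate of the cryptic gap end), `n_reads` (pooled
#'   pass-1 + pass-2 support).
#' @export
detect_cryptic_junctions <- function(juncs, locus, min_dist = 2L) {
  nl <- norm_locus(locus)
  Is <- nl$minor[1]; Ie <- nl$minor[2]
  if (nrow(juncs) == 0L) {
    return(data.frame(side = character(), coord = integer(),
                      n_reads = integer(), stringsAsFactors = FALSE))
  }
  nj <- norm_junc(juncs$gap_start, juncs$gap_end, locus)
  jd <- nj$jd; ja <- nj$ja
  p1_donor <- unique(jd[ja == Ie & abs(jd - Is) > min_dist])
  p1_accept <- unique(ja[jd == Is & abs(ja - Ie) > min_dist])
  count_support <- function(side, coord) {
    if (side == "5ss") sum(jd == coord) else sum(ja == coord)
  }
  out <- rbind(
    if (length(p1_donor))
      data.frame(side = "5ss", coord = p1_donor, stringsAsFactors = FALSE),
    if (length(p1_accept))
      data.frame(side = "3ss", coord = p1_accept, stringsAsFactors = FALSE))
  if (is.null(out)) {
    return(data.frame(side = character(), coord = integer(),
                      n_reads = integer(), stringsAsFactors = FALSE))
  }
  out$n_reads <- vapply(seq_len(nrow(out)), function(i) {
    count_support(out$side[i], out$coord[i])
  }, numeric(1))
  out
}

DEFAULT_CRYPTIC_MAP <- c(exonic_5 = "CAT5", intronic_5 = "CAT6",
                         exonic_3 = "CAT7", intronic_3 = "CAT8")

#' Bin one junction into splicing categories
#'
#' Categories around a minor intron (multi-assignment is allowed; a single
#' read can support several events): CAT1 the exact canonical junction; CAT2
#' both flanking exons skipped; CAT3 upstream exon skipped; CAT4 downstream
#' exon skipped; four cryptic splice-site classes generated as side x
#' location (5'/3' x exonic/intronic) and mapped to CAT5-CAT8 through
#' `cryptic_map` (defaults: CAT5 cryptic 5'SS within the upstream exon, CAT6
#' cryptic 5'SS within the minor intron, CAT7 cryptic 3'SS within the
#' downstream exon, CAT8 cryptic 3'SS within the minor intron); and CAT9,
#' cryptic-exon support, a junction end strictly inside the minor intron with
#' the other end inside the intron or anchored in a flanking exon.
#'
#' @param gap_start,gap_end the removed interval (genomic, 1-based
#'   inclusive).
#' @param locus an `as_locus`.
#' @param cryptic_map named character vector mapping the four cryptic
#'   geometries to category labels.
#' @param min_dist cryptic sites must be more than this many nt from the
#'   canonical splice site.
#' @return character vector of categories, or "unassigned".
#' @export
bin_junction <- function(gap_start, gap_end, locus,
                         cryptic_map = DEFAULT_CRYPTIC_MAP, min_dist = 2L) {
  nl <- norm_locus(locus)
  nj <- norm_junc(gap_start, gap_end, locus)
  jd <- nj$jd; ja <- nj$ja
  Is <- nl$minor[1]; Ie <- nl$minor[2]
  Us <- nl$up_exon[1]; Ue <- nl$up_exon[2]
  Ds <- nl$down_exon[1]; De <- nl$down_exon[2]
  cats <- character(0)
  if (jd == Is && ja == Ie) cats <- c(cats, "CAT1")
  if (jd <= Us && ja >= De) cats <- c(cats, "CAT2")
  if (jd <= Us && ja >= Ue && ja <= De - 1L) cats <- c(cats, "CAT3")
  if (ja >= De && jd >= Us + 1L && jd <= Ds) cats <- c(cats, "CAT4")
  if (jd > Us && jd <= Ue && (Is - jd) > min_dist && ja >= Is)
    cats <- c(cats, cryptic_map[["exonic_5"]])
  if (jd > Is && jd <= Ie && (jd - Is) > min_dist)
    cats <- c(cats, cryptic_map[["intronic_5"]])
  if (ja >= Ds && ja <= De - 1L && (ja - Ie) > min_dist && jd <= Ie)
    cats <- c(cats, cryptic_map[["exonic_3"]])
  if (ja >= Is && ja < Ie && (Ie - ja) > min_dist)
    cats <- c(cats, cryptic_map[["intronic_3"]])
  left_inside <- jd > Is && jd <= Ie
  right_inside <- ja >= Is && ja < Ie
  left_exon <- jd >= Us + 1L && jd <= Is
  right_exon <- ja >= Ie && ja <= De - 1L
  if ((left_inside && right_inside) || (left_inside && right_exon) ||
      (right_inside && left_exon)) cats <- c(cats, "CAT9")
  if (length(cats) == 0L) cats <- "unassigned"
  unique(cats)
}

#' Quantify alternative-splicing events around a minor intron
#'
#' Bins every collected junction read of every sample, computes a per-event
#' mis-splicing index (MSI) as the percentage of distinct spliced reads at
#' the locus supporting the event, and applies the tissue-level acceptance
#' filters: mean MSI over replicates above `msi_threshold` percent and mean
#' supporting reads above 1 per 3 million uniquely mapped reads. CAT1
#' (constitutive splicing) contributes to the denominator but is never
#' reported as an alternative-splicing event.
#'
#' @param juncs junction read data.frame (as in [collect_spliced_reads()])
#'   with an additional `sample_id` column.
#' @param locus an `as_locus`.
#' @param samples data.frame with `sample_id`, `tissue`,
#'   `library_unique_reads`.
#' @param cryptic_map,min_dist passed to [bin_junction()].
#' @param min_overhang passed to [collect_spliced_reads()].
#' @param msi_threshold tissue-level mean MSI must exceed this (percent).
#' @param depth_norm reads are normalized to this many uniquely mapped reads
#'   (default 3e6) and the mean normalized support must exceed 1.
#' @return list with `per_sample` (intronless long table: sample, category,
#'   reads, msi) and `tissue_calls` (category x tissue: mean values and pass
#'   flag with reasons).
#' @export
quantify_as_events <- function(juncs, locus, samples,
                               cryptic_map = DEFAULT_CRYPTIC_MAP,
                               min_dist = 2L, min_overhang = 2L,
                               msi_threshold = 10, depth_norm = 3e6) {
  per_sample <- list()
  for (sid in samples$sample_id) {
    sub <- juncs[juncs$sample_id == sid, , drop = FALSE]
    sub <- collect_spliced_reads(sub, locus, min_overhang = min_overhang)
    denom <- length(unique(sub$read_id))
    cats_by_read <- if (nrow(sub)) {
      ## bin each distinct junction once; reads mostly share coordinates
      key <- paste(sub$gap_start, sub$gap_end)
      uniq <- !duplicated(key)
      cat_map <- setNames(lapply(which(uniq), function(i) {
        bin_junction(sub$gap_start[i], sub$gap_end[i], locus,
                     cryptic_map = cryptic_map, min_dist = min_dist)
      }), key[uniq])
      tapply(key, sub$read_id, function(ks) unique(unlist(cat_map[unique(ks)])))
    } else list()
    all_cats <- c(paste0("CAT", 1:9), "unassigned")
    counts <- vapply(all_cats, function(cc) {
      sum(vapply(cats_by_read, function(cs) cc %in% cs, logical(1)))
    }, numeric(1))
    per_sample[[sid]] <- data.frame(
      sample_id = sid,
      tissue = samples$tissue[samples$sample_id == sid][1],
      category = all_cats, reads = unname(counts),
      total_spliced = denom,
      msi = if (denom > 0) 100 * unname(counts) / denom else NA_real_,
      library_unique_reads =
        samples$library_unique_reads[samples$sample_id == sid][1],
      stringsAsFactors = FALSE)
  }
  ps <- do.call(rbind, per_sample)
  rownames(ps) <- NULL
  event_cats <- paste0("CAT", 2:9)
  combos <- expand.grid(tissue = unique(samples$tissue),
                        category = event_cats, stringsAsFactors = FALSE)
  tissue_calls <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sub <- ps[ps$tissue == combos$tissue[i] &
              ps$category == combos$category[i], , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    no_denominator <- all(sub$total_spliced == 0)
    mean_msi <- mean(sub$msi, na.rm = TRUE)
    mean_norm <- mean(sub$reads * depth_norm / sub$library_unique_reads)
    reasons <- character(0)
    if (no_denominator) reasons <- "no_spliced_reads"
    else {
      if (!(mean_msi > msi_threshold)) reasons <- c(reasons, "msi_below_threshold")
      if (!(mean_norm > 1)) reasons <- c(reasons, "read_depth")
    }
    data.frame(tissue = combos$tissue[i], category = combos$category[i],
               mean_msi = if (no_denominator) NA_real_ else mean_msi,
               mean_reads = mean(sub$reads),
               mean_norm_reads = mean_norm,
               passed = length(reasons) == 0L,
               fail_reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(tissue_calls) <- NULL
  list(per_sample = ps, tissue_calls = tissue_calls)
}

#' Bin annotated transcript isoforms against a minor intron
#'
#' Every annotated transcript of a minor intron-containing gene is assigned
#' exactly one category, tested in order: `constitutive` (two adjacent exons
#' exactly flank the minor intron), `truncated_before` (the transcript does
#' not reach the minor intron coordinates), `terminal_exon_within` (the
#' transcript's first or last exon starts or ends inside the minor intron)
#' and `AS_across` (any other configuration).
#'
#' @param transcripts list of transcript models.
#' @param minor_start,minor_end minor-intron genomic coordinates.
#' @return character vector of categories, named by transcript id.
#' @export
bin_annotated_isoforms <- function(transcripts, minor_start, minor_end) {
  vapply(transcripts, function(tx) {
    ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
    n <- nrow(ex)
    constitutive <- n >= 2L &&
      any(ex$end[-n] == minor_start - 1L & ex$start[-1] == minor_end + 1L)
    if (constitutive) return("constitutive")
    span <- c(min(ex$start), max(ex$end))
    if (span[2] < minor_start || span[1] > minor_end) return("truncated_before")
    terminal <- ex[c(1L, n), , drop = FALSE]
    inside <- function(p) p >= minor_start & p <= minor_end
    if (any(inside(terminal$start) | inside(terminal$end)))
      return("terminal_exon_within")
    "AS_across"
  }, character(1))
}
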