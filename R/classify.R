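#' Score the splice-site windows of one intron
#'
#' Computes rescaled (0-100) scores of the donor window against all four 5'SS
#' PWMs, of the acceptor window against both minor 3'SS PWMs, and the best
#' branch-point score over all windows and both branch-point variants.
#'
#' @param windows a `splice_windows` object from [extract_splice_windows()].
#' @param pwms a `pwm_set` from [build_pwm_set()].
#' @return list with `x_5ss` (named length-4 vector), `x_3ss` (named length-2
#'   vector), `x_bps`, `bps_window_index`, `bps_variant`, class
#'   `intron_scores`.
#' @export
score_intron <- function(windows, pwms) {
  stopifnot(all(FIVE_SS_NAMES %in% names(pwms)))
  x5 <- vapply(FIVE_SS_NAMES, function(n) {
    if (is.na(windows$donor12)) NA_real_ else score_window(windows$donor12, pwms[[n]])
  }, numeric(1))
  x3 <- vapply(c("minor_3ss_ATAC", "minor_3ss_GTAG"), function(n) {
    if (is.na(windows$acceptor14)) NA_real_ else score_window(windows$acceptor14, pwms[[n]])
  }, numeric(1))
  bps <- best_bps_score(windows$bps_windows, pwms[["bps_A9"]], pwms[["bps_A10"]])
  structure(list(x_5ss = x5, x_3ss = x3, x_bps = bps$score,
                 bps_window_index = bps$window_index,
                 bps_variant = bps$variant),
            class = "intron_scores")
}

#' Call an intron minor or major from its rescaled splice-site scores
#'
#' An intron is called minor if it satisfies any of four criteria, evaluated
#' in order (the first satisfied criterion is the one reported):
#' \enumerate{
#'   \item minor AT-AC 5'SS score over 50 and at least 10 points higher than
#'     every other 5'SS score;
#'   \item minor GT-AG 5'SS score over 50, at least 25 points above the major
#'     GT-AG 5'SS score and at least 10 above the two remaining 5'SS scores;
#'   \item minor GT-AG 5'SS score over 50 and at least 10 above every other
#'     5'SS score, with a branch-point score over 65;
#'   \item the sum of the minor 5'SS score (the larger of the two minor
#'     variants), the branch-point score and the minor 3'SS score of the
#'     matching subtype over 150.
#' }
#' Margins are read as written ("at least 10" is >= 10; "over 50" is > 50).
#' Missing branch-point or 3'SS scores simply disable the criteria that need
#' them.
#'
#' @param scores an `intron_scores` object (or list with the same fields).
#' @return list with `call` ("minor"/"major") and `criterion` (1:4 or NA).
#' @export
classify_intron <- function(scores) {
  x5 <- scores$x_5ss
  atac <- x5[["minor_5ss_ATAC"]]
  mgt <- x5[["minor_5ss_GTAG"]]
  majgt <- x5[["major_5ss_GTAG"]]
  majgc <- x5[["major_5ss_GCAG"]]
  bps <- scores$x_bps
  ok <- function(x) !is.na(x)

  crit1 <- ok(atac) && atac > 50 &&
    all(atac - c(mgt, majgt, majgc) >= 10, na.rm = FALSE)
  crit2 <- ok(mgt) && mgt > 50 && ok(majgt) && mgt - majgt >= 25 &&
    all(mgt - c(atac, majgc) >= 10)
  crit3 <- ok(mgt) && mgt > 50 && all(mgt - c(atac, majgt, majgc) >= 10) &&
    ok(bps) && bps > 65
  crit4 <- FALSE
  if (ok(atac) || ok(mgt)) {
    win5 <- which.max(c(ATAC = atac, GTAG = mgt))
    x5_best <- max(c(atac, mgt), na.rm = TRUE)
    x3_match <- scores$x_3ss[[c("minor_3ss_ATAC", "minor_3ss_GTAG")[win5]]]
    crit4 <- ok(bps) && ok(x3_match) && (x5_best + bps + x3_match) > 150
  }
  fired <- which(c(isTRUE(crit1), isTRUE(crit2), isTRUE(crit3), isTRUE(crit4)))
  if (length(fired)) {
    list(call = "minor", criterion = fired[1])
  } else {
    list(call = "major", criterion = NA_integer_)
  }
}

#' Terminal-dinucleotide subtype of an intron
#'
#' @param first2,last2 first and last two intronic bases in transcript
#'   orientation.
#' @return "GT-AG", "AT-AC" or "other".
#' @export
subtype_terminal_dinucleotide <- function(first2, last2) {
  ifelse(first2 == "GT" & last2 == "AG", "GT-AG",
         ifelse(first2 == "AT" & last2 == "AC", "AT-AC", "other"))
}

#' Positional context of minor introns within a transcript
#'
#' Labels each minor intron of a transcript by its neighbourhood:
#' `only_intron` (the transcript's single intron), `first_or_last`,
#' `adjacent_to_minor` (a neighbouring intron is also minor) or
#' `flanked_by_two_major`, applied in that order of precedence.
#'
#' @param calls character vector of "minor"/"major" in transcript 5'->3'
#'   intron order.
#' @return character vector the same length; `NA` for major introns.
#' @export
assign_context <- function(calls) {
  n <- length(calls)
  out <- rep(NA_character_, n)
  for (i in which(calls == "minor")) {
    neighbours <- calls[setdiff(c(i - 1L, i + 1L), c(0L, n + 1L))]
    out[i] <- if (n == 1L) "only_intron"
      else if (i == 1L || i == n) "first_or_last"
      else if (any(neighbours == "minor")) "adjacent_to_minor"
      else "flanked_by_two_major"
  }
  out
}

#' Classify every intron of an annotation set
#'
#' Runs the full classification pipeline: canonical-transcript selection per
#' gene, intron derivation, splice-site window extraction, PWM scoring, the
#' four-criteria call, terminal-dinucleotide subtyping and positional context
#' assignment.
#'
#' @param annotation an `annotation_set` from [parse_annotation()] or
#'   [simulate_genome_annotation()].
#' @param ppms a `ppm_set`.
#' @param min_scorable_length introns shorter than this (nt) are classified on
#'   donor/acceptor evidence only and flagged.
#' @return data.frame (class `intron_catalog`) with one row per intron of
#'   every canonical transcript: coordinates, ordinal, dinucleotides, all
#'   rescaled scores, criterion, call, subtype and context.
#' @export
#' @examples
#' sim <- simulate_genome_annotation(sim_config(seed = 1, n_genes = 8))
#' cat <- classify_introns(sim$annotation, sim$ppms)
#' table(cat$call)
classify_introns <- function(annotation, ppms, min_scorable_length = 30L) {
  pwms <- build_pwm_set(ppms)
  rows <- list()
  for (gene in annotation$genes) {
    tx <- select_canonical_transcript(gene)
    introns <- derive_introns(tx, annotation$seqs)
    if (nrow(introns) == 0L) next
    per <- lapply(seq_len(nrow(introns)), function(i) {
      win <- extract_splice_windows(introns[i, ], annotation$seqs,
                                    min_scorable_length = min_scorable_length)
      sc <- score_intron(win, pwms)
      cl <- classify_intron(sc)
      data.frame(
        intron_id = introns$intron_id[i], gene_id = gene$gene_id,
        gene_type = gene$gene_type, transcript_id = tx$transcript_id,
        chrom = introns$chrom[i], start = introns$start[i],
        end = introns$end[i], strand = introns$strand[i],
        ordinal = introns$ordinal[i], length = introns$length[i],
        dinuc_5 = introns$dinuc_5[i], dinuc_3 = introns$dinuc_3[i],
        subtype = subtype_terminal_dinucleotide(introns$dinuc_5[i],
                                                introns$dinuc_3[i]),
        x_atac_5ss = sc$x_5ss[["minor_5ss_ATAC"]],
        x_minor_gtag_5ss = sc$x_5ss[["minor_5ss_GTAG"]],
        x_major_gtag_5ss = sc$x_5ss[["major_5ss_GTAG"]],
        x_major_gcag_5ss = sc$x_5ss[["major_5ss_GCAG"]],
        x_minor_3ss_atac = sc$x_3ss[["minor_3ss_ATAC"]],
        x_minor_3ss_gtag = sc$x_3ss[["minor_3ss_GTAG"]],
        x_bps = sc$x_bps,
        bps_window_index = sc$bps_window_index %||% NA_integer_,
        bps_variant = sc$bps_variant %||% NA_character_,
        short_intron = isTRUE(win$flag_short),
        criterion = cl$criterion, call = cl$call,
        stringsAsFactors = FALSE)
    })
    block <- do.call(rbind, per)
    block$context <- assign_context(block$call)
    rows[[length(rows) + 1L]] <- block
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_catalog()
  rownames(out) <- NULL
  class(out) <- c("intron_catalog", "data.frame")
  out
}

empty_catalog <- function() {
  data.frame(intron_id = character(), gene_id = character(),
             gene_type = character(), transcript_id = character(),
             chrom = character(), start = integer(), end = integer(),
             strand = character(), ordinal = integer(), length = integer(),
             dinuc_5 = character(), dinuc_3 = character(),
             subtype = character(), x_atac_5ss = numeric(),
             x_minor_gtag_5ss = numeric(), x_major_gtag_5ss = numeric(),
             x_major_gcag_5ss = numeric(), x_minor_3ss_atac = numeric(),
             x_minor_3ss_gtag = numeric(), x_bps = numeric(),
             bps_window_index = integer(), bps_variant = character(),
             short_intron = logical(), criterion = integer(),
             call = character(), context = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.intron_catalog <- function(x, ...) {
  n_minor <- sum(x$call == "minor")
  cat(sprintf("Intron catalog: %d introns in %d genes; %d minor (%d MIGs)\n",
              nrow(x), length(unique(x$gene_id)), n_minor,
              length(unique(x$gene_id[x$call == "minor"]))))
  if (n_minor > 0) {
    cat("Minor-intron subtypes:\n")
    print(table(x$subtype[x$call == "minor"]))
  }
  invisible(x)
}

#' Compare a classification against a prior minor-intron list
#'
#' Coordinate intersection of called minor introns with a prior catalog
#' (U12DB-style table of chrom/start/end/strand), with configurable slack
#' (default 0 nt, i.e. exact boundary agreement).
#'
#' @param catalog an `intron_catalog`.
#' @param prior data.frame with columns chrom, start, end, strand.
#' @param slack maximum per-boundary coordinate difference tolerated.
#' @return list with `shared`, `new` (called here, absent from prior) and
#'   `missed` (prior introns not called) counts plus row indices.
#' @export
compare_prior_list <- function(catalog, prior, slack = 0L) {
  minors <- catalog[catalog$call == "minor", , drop = FALSE]
  key <- function(df) paste(df$chrom, df$strand)
  matched_prior <- rep(FALSE, nrow(prior))
  matched_cat <- rep(FALSE, nrow(minors))
  for (i in seq_len(nrow(minors))) {
    cand <- which(prior$chrom == minors$chrom[i] &
                  prior$strand == minors$strand[i] &
                  abs(prior$start - minors$start[i]) <= slack &
                  abs(prior$end - minors$end[i]) <= slack)
    if (length(cand)) {
      matched_cat[i] <- TRUE
      matched_prior[cand[1]] <- TRUE
    }
  }
  list(shared = sum(matched_cat), new = sum(!matched_cat),
       missed = sum(!matched_prior),
       shared_idx = which(matched_cat), missed_idx = which(!matched_prior))
}
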