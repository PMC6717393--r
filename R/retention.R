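#' Read a per-intron read-evidence table
#'
#' The tab-separated evidence format (also emitted by [simulate_reads()]) has
#' one row per intron per sample: `intron_id`, `sample_id`, `tissue`,
#' `boundary_reads_5`, `boundary_reads_3`, `spliced_reads`,
#' `covered_fraction`, `library_unique_reads`.
#'
#' @param path path to the TSV.
#' @return data.frame of evidence rows.
#' @export
read_evidence_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("intron_id", "sample_id", "tissue", "boundary_reads_5",
            "boundary_reads_3", "spliced_reads", "covered_fraction",
            "library_unique_reads")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("evidence table missing column(s): %s",
                          paste(miss, collapse = ", "))
  df
}

#' Count retention evidence for one intron from aligned reads
#'
#' A boundary read is an unspliced read aligned contiguously across an
#' exon-intron junction with at least `anchor` nt on each side; a spliced
#' read has a gap whose coordinates match the intron exactly. Only uniquely
#' mapped reads (mapq > 0 and no secondary flag) are counted. The covered
#' fraction is the fraction of intron bases overlapped by at least one
#' aligned read base (gaps of spliced reads do not contribute).
#'
#' @param alignments path to a SAM or BAM file (SAM is converted on the fly).
#' @param intron one-row data.frame with chrom, start, end (1-based,
#'   inclusive).
#' @param anchor minimum contiguous nt on each side of the junction.
#' @return list with `boundary_reads_5`, `boundary_reads_3`, `spliced_reads`,
#'   `covered_fraction`, `library_unique_reads`.
#' @export
count_intron_evidence <- function(alignments, intron, anchor = 3L) {
  bam <- alignments
  if (grepl("\\.sam$", alignments, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(alignments,
                            destination = tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  }
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE),
      what = "mapq"))
  ga <- ga[!is.na(S4Vectors::mcols(ga)$mapq) & S4Vectors::mcols(ga)$mapq > 0]
  lib <- length(ga)
  if (!intron$chrom %in% GenomeInfoDb::seqlevels(ga) && lib > 0L) {
    stopf("intron contig '%s' absent from alignment targets", intron$chrom)
  }
  on_chrom <- ga[as.character(GenomicAlignments::seqnames(ga)) == intron$chrom]
  blocks <- GenomicAlignments::grglist(on_chrom)
  ## spliced support: a gap identical to the intron
  junc <- GenomicAlignments::junctions(on_chrom)
  spliced <- sum(vapply(seq_along(junc), function(i) {
    j <- junc[[i]]
    any(GenomicRanges::start(j) == intron$start &
        GenomicRanges::end(j) == intron$end)
  }, logical(1)))
  ## boundary support: one contiguous block covering the junction +/- anchor
  covers <- function(pos) {
    want <- IRanges::IRanges(pos - anchor + 1L, pos + anchor)
    sum(vapply(seq_along(blocks), function(i) {
      any(IRanges::start(blocks[[i]]) <= IRanges::start(want) &
          IRanges::end(blocks[[i]]) >= IRanges::end(want))
    }, logical(1)))
  }
  ## 5' junction sits between start-1 | start; 3' between end | end+1
  b5 <- covers(intron$start - 1L)
  b3 <- covers(intron$end)
  cov <- IRanges::coverage(unlist(blocks))
  intron_cov <- if (intron$chrom %in% names(cov)) {
    v <- cov[[intron$chrom]]
    win <- IRanges::IRanges(intron$start, intron$end)
    mean(as.integer(IRanges::Views(v, win)[[1]]) > 0)
  } else 0
  if (intron$strand == "-") { tmp <- b5; b5 <- b3; b3 <- tmp }
  list(boundary_reads_5 = b5, boundary_reads_3 = b3, spliced_reads = spliced,
       covered_fraction = intron_cov, library_unique_reads = lib)
}

#' Mis-splicing index from boundary and spliced read counts
#'
#' The default (`method = "mean"`) MSI is the mean of the two per-boundary
#' retention ratios, as a percentage:
#' \deqn{MSI = 100 \cdot \tfrac{1}{2}\left(\frac{b_5}{b_5+s} +
#'   \frac{b_3}{b_3+s}\right)}
#' where \eqn{b_5, b_3} are the exon-intron boundary read counts and \eqn{s}
#' the count of reads spliced exactly across the intron.
#' `method = "pooled"` uses \eqn{100 (b_5+b_3) / (b_5+b_3+2s)} instead. With
#' no reads at all the MSI is undefined (`NA`).
#'
#' @param b5,b3 boundary read counts at the 5' and 3' splice sites.
#' @param s spliced read count.
#' @param method "mean" (default) or "pooled".
#' @return MSI percentage in \[0, 100\], or `NA` when undefined.
#' @export
#' @examples
#' compute_msi(6, 3, 6)  # 100 * 0.5 * (6/12 + 3/9) = 41.67
compute_msi <- function(b5, b3, s, method = c("mean", "pooled")) {
  method <- match.arg(method)
  tot <- b5 + b3 + s
  if (method == "pooled") {
    out <- ifelse(tot == 0, NA_real_, 100 * (b5 + b3) / (b5 + b3 + 2 * s))
    return(out)
  }
  r5 <- ifelse(b5 + s == 0, NA_real_, b5 / (b5 + s))
  r3 <- ifelse(b3 + s == 0, NA_real_, b3 / (b3 + s))
  out <- 100 * rowMeans(cbind(r5, r3), na.rm = TRUE)
  out[tot == 0] <- NA_real_
  unname(out)
}

#' Apply the retention evidence filters and call retained introns per tissue
#'
#' A replicate passes for an intron when the total boundary reads exceed 4,
#' each splice site has at least one boundary read, and more than 95% of the
#' intron is covered. A tissue-level retention call requires a pass in all
#' replicates (`mode = "all_replicates"`, the default used for the
#' three-replicate mouse design) or in at least three replicates
#' (`mode = "min3"`, used for designs with more than three replicates; with
#' three or fewer it falls back to all replicates).
#'
#' @param evidence data.frame in the format of [read_evidence_tsv()].
#' @param mode "all_replicates" or "min3".
#' @param min_boundary_total total boundary reads must exceed this.
#' @param min_coverage covered fraction must exceed this.
#' @param msi_method passed to [compute_msi()].
#' @return list with `per_replicate` (evidence plus msi, pass, reasons),
#'   `tissue_calls` (intron x tissue: retained flag and mean MSI over
#'   replicates) and `replicate_class` (per intron: retained in all
#'   replicates of >= 1 tissue / in 1-2 replicates / in none).
#' @export
filter_retention <- function(evidence, mode = c("all_replicates", "min3"),
                             min_boundary_total = 4L, min_coverage = 0.95,
                             msi_method = "mean") {
  mode <- match.arg(mode)
  ev <- evidence
  ev$msi <- compute_msi(ev$boundary_reads_5, ev$boundary_reads_3,
                        ev$spliced_reads, method = msi_method)
  reasons <- vapply(seq_len(nrow(ev)), function(i) {
    r <- character(0)
    if (ev$boundary_reads_5[i] + ev$boundary_reads_3[i] +
        ev$spliced_reads[i] == 0) r <- c(r, "no_reads")
    if (ev$boundary_reads_5[i] + ev$boundary_reads_3[i] <=
        min_boundary_total) r <- c(r, "boundary_reads")
    if (ev$boundary_reads_5[i] < 1) r <- c(r, "no_5ss_read")
    if (ev$boundary_reads_3[i] < 1) r <- c(r, "no_3ss_read")
    if (ev$covered_fraction[i] <= min_coverage) r <- c(r, "coverage")
    paste(r, collapse = ";")
  }, character(1))
  ev$passed_filters <- !nzchar(reasons)
  ev$fail_reasons <- reasons

  combos <- unique(ev[, c("intron_id", "tissue")])
  tissue_calls <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sub <- ev[ev$intron_id == combos$intron_id[i] &
              ev$tissue == combos$tissue[i], , drop = FALSE]
    n_rep <- nrow(sub)
    n_pass <- sum(sub$passed_filters)
    retained <- if (mode == "min3" && n_rep > 3L) n_pass >= 3L
                else n_pass == n_rep
    data.frame(intron_id = combos$intron_id[i], tissue = combos$tissue[i],
               n_replicates = n_rep, n_pass = n_pass, retained = retained,
               mean_msi = mean(sub$msi, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))

  rep_class <- vapply(unique(ev$intron_id), function(id) {
    tc <- tissue_calls[tissue_calls$intron_id == id, , drop = FALSE]
    if (any(tc$retained)) "retained_all_replicates"
    else if (any(tc$n_pass >= 1L)) "retained_1_2_replicates"
    else "not_retained"
  }, character(1))

  list(per_replicate = ev, tissue_calls = tissue_calls,
       replicate_class = data.frame(intron_id = unique(ev$intron_id),
                                    class = unname(rep_class),
                                    stringsAsFactors = FALSE))
}

#' Retention bin of a minor intron and its flanking major introns
#'
#' For minor introns flanked by two major introns, the joint retention status
#' in a tissue falls into six bins: I minor retained, neither major; II minor
#' plus exactly one major; III minor plus both majors; IV none retained; V
#' minor not retained, exactly one major; VI minor not retained, both majors.
#'
#' @param minor_retained,upstream_retained,downstream_retained logicals.
#' @return factor level "I".."VI".
#' @export
flanking_bin <- function(minor_retained, upstream_retained,
                         downstream_retained) {
  n_major <- as.integer(upstream_retained) + as.integer(downstream_retained)
  bins_minor <- c("I", "II", "III")
  bins_not <- c("IV", "V", "VI")
  out <- ifelse(minor_retained, bins_minor[n_major + 1L],
                bins_not[n_major + 1L])
  factor(out, levels = c("I", "II", "III", "IV", "V", "VI"))
}

#' Dunn post-hoc test after a Kruskal-Wallis rank test
#'
#' All-pairs z statistics on mean ranks with tie correction, with p-values
#' adjusted for multiplicity (Bonferroni by default, the conventional choice
#' for the Dunn procedure).
#'
#' @param x numeric response.
#' @param g grouping factor.
#' @param p_adjust_method passed to [stats::p.adjust()].
#' @return data.frame with one row per pair: groups, z, p, p_adj, stars.
#' @export
dunn_posthoc <- function(x, g, p_adjust_method = "bonferroni") {
  g <- factor(g)
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  n <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(r, g, mean)
  sizes <- tapply(r, g, length)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  res <- apply(pairs, 2, function(p) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
               (1 / sizes[[p[1]]] + 1 / sizes[[p[2]]]))
    z <- (mean_rank[[p[1]]] - mean_rank[[p[2]]]) / se
    c(z = z, p = 2 * pnorm(-abs(z)))
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = res["z", ], p = res["p", ],
                    stringsAsFactors = FALSE)
  out$p_adj <- p.adjust(out$p, method = p_adjust_method)
  out$stars <- p_stars(out$p_adj)
  rownames(out) <- NULL
  out
}

#' Group comparisons of MSI and intron-length distributions
#'
#' Bundles the statistical comparisons used across the retention and
#' alternative-splicing analyses: `"rank"` runs a Kruskal-Wallis rank-sum
#' test with a Dunn post-hoc (for, e.g., intron length across retention
#' classes), `"anova"` a one-way ANOVA with Tukey HSD post-hoc (for MSI of
#' one intron across tissues, or minor versus flanking major introns), and
#' `"two_group_rank"` a Mann-Whitney U test (for, e.g., length of
#' alternatively spliced versus canonically spliced introns). Significance
#' stars follow *<0.05, **<0.01, ***<0.001.
#'
#' @param x numeric response values.
#' @param g group labels.
#' @param test one of "rank", "anova", "two_group_rank".
#' @return list with `statistic`, `p_value`, `stars` and (for the K-group
#'   tests) a `posthoc` data.frame.
#' @export
msi_group_tests <- function(x, g, test = c("rank", "anova", "two_group_rank")) {
  test <- match.arg(test)
  g <- factor(g)
  by_g <- split(x, g)
  if (length(by_g) < 2L || any(lengths(by_g) < 2L)) {
    stopf("need >= 2 groups with >= 2 observations each")
  }
  if (all(vapply(by_g, function(v) stats::var(v) == 0, logical(1)))) {
    return(list(statistic = NA_real_, p_value = NA_real_, stars = "",
                posthoc = NULL, degenerate = TRUE))
  }
  if (test == "rank") {
    kt <- kruskal.test(x, g)
    list(statistic = unname(kt$statistic), p_value = kt$p.value,
         stars = p_stars(kt$p.value), posthoc = dunn_posthoc(x, g))
  } else if (test == "anova") {
    fit <- aov(x ~ g)
    sm <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$g
    ph <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                     p_adj = tk[, "p adj"], stars = p_stars(tk[, "p adj"]),
                     stringsAsFactors = FALSE)
    rownames(ph) <- NULL
    list(statistic = sm[["F value"]][1], p_value = sm[["Pr(>F)"]][1],
         stars = p_stars(sm[["Pr(>F)"]][1]), posthoc = ph)
  } else {
    if (length(by_g) != 2L) stopf("two_group_rank needs exactly 2 groups")
    wt <- wilcox.test(by_g[[1]], by_g[[2]])
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         stars = p_stars(wt$p.value), posthoc = NULL)
  }
}
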