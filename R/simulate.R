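#' Simulation configuration
#'
#' Bundles every knob of the synthetic genome, read and expression generator
#' with the defaults used throughout the package's tests: a multi-tissue
#' bulk RNA-seq design (eleven tissues, three replicates, as in the mouse
#' tissue panel the pipeline is aimed at), genes of 4-8 exons with one to
#' three minor introns in a minor intron-containing gene, log-normal intron
#' lengths with a shorter median for minor introns, binomially sampled
#' boundary/spliced/junction reads around planted mis-splicing indices, and
#' log-normal TPM replicates with planted tissue-enriched and silent genes.
#'
#' @param seed integer seed; every downstream generator derives its
#'   randomness from it.
#' @param n_genes number of genes.
#' @param mig_fraction fraction of genes carrying minor introns.
#' @param minor_per_mig_probs probabilities of 1, 2 or 3 minor introns per
#'   minor intron-containing gene.
#' @param p_atac probability a planted minor intron is of the AT-AC subtype.
#' @param pseudogene_frac,lincrna_frac gene-type fractions.
#' @param exons_per_gene inclusive range of exon counts.
#' @param exon_length inclusive range of exon lengths (nt).
#' @param intron_meanlog_major,intron_meanlog_minor,intron_sdlog log-normal
#'   intron length parameters (separate medians support the
#'   "retained introns are shorter" scenario).
#' @param min_intron_length floor on intron length (nt).
#' @param information_content splice-site information content, bits/position
#'   in (0, 2]; 2 gives one-hot consensus matrices.
#' @param tissues tissue labels.
#' @param replicates replicates per tissue.
#' @param depth boundary/spliced read depth per intron per replicate.
#' @param as_locus_reads spliced reads per minor-intron locus per replicate.
#' @param library_size uniquely mapped reads per library.
#' @param read_overhang aligned nt on each side of simulated junctions.
#' @param retained_frac fraction of minor introns with planted retention.
#' @param retention_msi_values planted retention MSI values (percent) drawn
#'   for retained minor introns.
#' @param major_retained_frac,major_retention_msi retention planting for
#'   flanking major introns.
#' @param as_event_frac fraction of minor introns with a planted
#'   alternative-splicing event.
#' @param as_msi planted alternative-splicing event MSI (percent).
#' @param n_signature_per_tissue planted tissue-enriched genes per tissue.
#' @param signature_fold fold factor of planted signature genes.
#' @param n_silent genes planted silent in `silent_tissue`.
#' @param silent_tpm true mean TPM of silent genes in their silent tissue.
#' @param noise_sd replicate noise, standard deviation of log2 TPM.
#' @param base_log2_mean,base_log2_sd distribution of baseline log2 TPM.
#' @return list of settings, class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 30L,
                       mig_fraction = 0.3,
                       minor_per_mig_probs = c(0.88, 0.09, 0.03),
                       p_atac = 0.25,
                       pseudogene_frac = 0.05,
                       lincrna_frac = 0.05,
                       exons_per_gene = c(4L, 8L),
                       exon_length = c(90L, 180L),
                       intron_meanlog_major = log(300),
                       intron_meanlog_minor = log(120),
                       intron_sdlog = 0.35,
                       min_intron_length = 60L,
                       information_content = 1.9,
                       tissues = c("bone", "bone_marrow", "cerebrum", "heart",
                                   "kidney", "liver", "lung",
                                   "skeletal_muscle", "spleen", "testis",
                                   "thymus"),
                       replicates = 3L,
                       depth = 200L,
                       as_locus_reads = 60L,
                       library_size = 3e6,
                       read_overhang = 20L,
                       retained_frac = 0.4,
                       retention_msi_values = c(20, 40, 60),
                       major_retained_frac = 0.1,
                       major_retention_msi = 20,
                       as_event_frac = 0.5,
                       as_msi = 25,
                       n_signature_per_tissue = 2L,
                       signature_fold = 8,
                       n_silent = 3L,
                       silent_tpm = 0.3,
                       noise_sd = 0.3,
                       base_log2_mean = 3,
                       base_log2_sd = 1.2) {
  cfg <- as.list(environment())
  stopifnot(cfg$information_content > 0, cfg$information_content <= 2,
            cfg$mig_fraction >= 0, cfg$mig_fraction <= 1,
            all(cfg$retention_msi_values >= 0),
            all(cfg$retention_msi_values <= 100),
            cfg$as_msi >= 0, cfg$as_msi <= 100)
  structure(cfg, class = "sim_config")
}

## consensus sequences of the simulated splice-site models; donor windows are
## 3 exonic + 9 intronic nt, acceptors 13 intronic + 1 exonic, branch points
## 12 nt with the branch adenosine at position 9 (A9) or 10 (A10)
SIM_CONSENSUS <- list(
  minor_5ss_ATAC = "AAGATATCCTTT",
  minor_5ss_GTAG = "AAGGTATCCTTT",
  major_5ss_GTAG = "CAGGTAAGTATT",
  major_5ss_GCAG = "CAGGCAAGTATT",
  minor_3ss_ATAC = "TTCCTTAACTTACG",
  minor_3ss_GTAG = "TTCCTTAACTTAGG",
  bps_A9  = "CTTTCCTTAACT",
  bps_A10 = "TCTTTCCTTAAC")

## major-intron acceptor used only while writing sequence (the classifier has
## no major 3'SS model); chosen distinct from the minor acceptor model at the
## non-terminal positions, as the minor/major consensus sequences are
SIM_MAJOR_3SS <- "CTCCTCTCTCCAGG"

ppm_from_consensus <- function(consensus, p) {
  bases <- strsplit(consensus, "")[[1]]
  m <- matrix((1 - p) / 3, nrow = 4, ncol = length(bases),
              dimnames = list(DNA_BASES, NULL))
  for (j in seq_along(bases)) m[bases[j], j] <- p
  m
}

#' Simulate the full named splice-site PPM set
#'
#' Emits the eight matrices the classifier consumes (four 5'SS, two minor
#' 3'SS, two branch-point variants) at a chosen per-position information
#' content: the consensus base carries probability
#' `0.25 + 0.75 * information_content / 2` and the remainder is spread
#' uniformly, so an information content of 2 yields one-hot columns.
#'
#' @param seed kept for interface symmetry; the matrices are deterministic.
#' @param information_content bits per position, in (0, 2].
#' @return a `ppm_set`.
#' @export
simulate_ppms <- function(seed = 1L, information_content = 1.9) {
  stopifnot(information_content > 0, information_content <= 2)
  p <- 0.25 + 0.75 * information_content / 2
  out <- lapply(SIM_CONSENSUS, ppm_from_consensus, p = p)
  structure(out, class = "ppm_set")
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

sample_from_ppm <- function(ppm) {
  paste(vapply(seq_len(ncol(ppm)), function(j) {
    sample(DNA_BASES, 1L, prob = ppm[, j])
  }, character(1)), collapse = "")
}

str_assign <- function(s, at, replacement) {
  substring(s, at, at + nchar(replacement) - 1L) <- replacement
  s
}

#' Simulate a genome, annotation and classification truth
#'
#' Lays genes with planted minor and major introns on one synthetic
#' chromosome (both strands represented). Minor-intron donor, acceptor and
#' branch-point sequences are sampled from the minor PPMs; major introns
#' from the major donor models and a polypyrimidine acceptor. Protein-coding
#' genes get a CDS spanning their exons (ATG first codon, TAA last); a
#' pseudogene and lincRNA fraction is included. A fraction of genes gains a
#' second, untagged transcript so canonical-transcript selection is
#' exercised.
#'
#' @param cfg a `sim_config`.
#' @return list with `annotation` (`annotation_set`, same structure as
#'   [parse_annotation()] returns), `ppms`, and `truth` (data.frames
#'   `introns` — per-intron class/subtype/context/coords — and `genes`).
#' @export
simulate_genome_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ppms <- simulate_ppms(cfg$seed, cfg$information_content)
  p <- 0.25 + 0.75 * cfg$information_content / 2
  major3 <- ppm_from_consensus(SIM_MAJOR_3SS, p)

  chrom <- "chrS"
  chrom_parts <- list(random_dna(300L))
  cursor <- 301L
  genes <- list()
  truth_introns <- list()
  truth_genes <- list()

  for (g in seq_len(cfg$n_genes)) {
    gene_id <- sprintf("GENE%03d", g)
    tx_id <- sprintf("TX%03d.1", g)
    u <- runif(1)
    gene_type <- if (u < cfg$pseudogene_frac) "pseudogene"
      else if (u < cfg$pseudogene_frac + cfg$lincrna_frac) "lincRNA"
      else "protein_coding"
    is_mig <- runif(1) < cfg$mig_fraction
    n_minor <- if (is_mig) sample(1:3, 1L, prob = cfg$minor_per_mig_probs) else 0L
    n_exons <- sample(seq(cfg$exons_per_gene[1], cfg$exons_per_gene[2]), 1L)
    n_exons <- max(n_exons, n_minor + 1L)
    n_introns <- n_exons - 1L
    minor_at <- if (n_minor > 0L) sort(sample(seq_len(n_introns), n_minor)) else integer(0)
    strand <- sample(c("+", "-"), 1L)

    exon_len <- sample(seq(cfg$exon_length[1], cfg$exon_length[2]), n_exons,
                       replace = TRUE)
    is_minor <- seq_len(n_introns) %in% minor_at
    intron_len <- pmax(cfg$min_intron_length, round(rlnorm(
      n_introns,
      meanlog = ifelse(is_minor, cfg$intron_meanlog_minor,
                       cfg$intron_meanlog_major),
      sdlog = cfg$intron_sdlog)))

    exon_seq <- vapply(exon_len, random_dna, character(1))
    if (gene_type == "protein_coding") {
      exon_seq[1] <- str_assign(exon_seq[1], 1L, "ATG")
      exon_seq[n_exons] <- str_assign(exon_seq[n_exons],
                                      exon_len[n_exons] - 2L, "TAA")
    }
    intron_seq <- character(n_introns)
    subtype <- rep(NA_character_, n_introns)
    for (i in seq_len(n_introns)) {
      s <- random_dna(intron_len[i])
      if (is_minor[i]) {
        st <- if (runif(1) < cfg$p_atac) "ATAC" else "GTAG"
        subtype[i] <- st
        donor <- sample_from_ppm(ppms[[paste0("minor_5ss_", st)]])
        acceptor <- sample_from_ppm(ppms[[paste0("minor_3ss_", st)]])
        bps <- sample_from_ppm(ppms[[sample(c("bps_A9", "bps_A10"), 1L)]])
        ## branch-point window occupies -25..-14, clear of the acceptor region
        s <- str_assign(s, intron_len[i] - 24L, bps)
      } else {
        dn <- if (runif(1) < 0.1) "major_5ss_GCAG" else "major_5ss_GTAG"
        donor <- sample_from_ppm(ppms[[dn]])
        acceptor <- sample_from_ppm(major3)
      }
      s <- str_assign(s, 1L, substring(donor, 4L, 12L))
      s <- str_assign(s, intron_len[i] - 12L, substring(acceptor, 1L, 13L))
      intron_seq[i] <- s
      exon_seq[i] <- str_assign(exon_seq[i], exon_len[i] - 2L,
                                substring(donor, 1L, 3L))
      exon_seq[i + 1L] <- str_assign(exon_seq[i + 1L], 1L,
                                     substring(acceptor, 14L, 14L))
    }

    ## transcript-orientation gene sequence and segment offsets
    segs <- character(2L * n_exons - 1L)
    segs[seq(1L, by = 2L, length.out = n_exons)] <- exon_seq
    if (n_introns > 0L) segs[seq(2L, by = 2L, length.out = n_introns)] <- intron_seq
    gene_seq <- paste(segs, collapse = "")
    G <- nchar(gene_seq)
    seg_len <- nchar(segs)
    seg_end <- cumsum(seg_len)
    seg_start <- seg_end - seg_len + 1L

    placed <- if (strand == "-") revcomp(gene_seq) else gene_seq
    O <- cursor
    chrom_parts[[length(chrom_parts) + 1L]] <- placed
    chrom_parts[[length(chrom_parts) + 1L]] <- random_dna(300L)
    cursor <- cursor + G + 300L

    t2g <- function(a, b) {
      if (strand == "-") c(O + G - b, O + G - a) else c(O + a - 1L, O + b - 1L)
    }
    exon_idx <- seq(1L, by = 2L, length.out = n_exons)
    exon_coords <- t(vapply(exon_idx, function(i) {
      t2g(seg_start[i], seg_end[i])
    }, numeric(2)))
    exons_df <- data.frame(start = as.integer(exon_coords[, 1]),
                           end = as.integer(exon_coords[, 2]))
    exons_df <- exons_df[order(exons_df$start), , drop = FALSE]

    cds_df <- if (gene_type == "protein_coding") exons_df else NULL
    tx1 <- list(transcript_id = tx_id, gene_id = gene_id, chrom = chrom,
                strand = strand, exons = exons_df, cds = cds_df,
                cds_len = if (is.null(cds_df)) 0L else
                  sum(cds_df$end - cds_df$start + 1L),
                exonic_length = sum(exons_df$end - exons_df$start + 1L),
                has_ccds = gene_type == "protein_coding",
                has_ensembl_havana = TRUE)
    txs <- setNames(list(tx1), tx_id)
    if (n_exons >= 3L && runif(1) < 0.25) {
      ## shorter, untagged isoform: drops the transcript-last exon
      drop_idx <- if (strand == "-") 1L else n_exons
      ex2 <- exons_df[-drop_idx, , drop = FALSE]
      tx2_id <- sprintf("TX%03d.2", g)
      txs[[tx2_id]] <- list(transcript_id = tx2_id, gene_id = gene_id,
                            chrom = chrom, strand = strand, exons = ex2,
                            cds = NULL, cds_len = 0L,
                            exonic_length = sum(ex2$end - ex2$start + 1L),
                            has_ccds = FALSE, has_ensembl_havana = FALSE)
    }
    genes[[gene_id]] <- list(gene_id = gene_id, gene_type = gene_type,
                             transcripts = txs)

    if (n_introns > 0L) {
      intron_idx <- seq(2L, by = 2L, length.out = n_introns)
      g_coords <- t(vapply(intron_idx, function(i) {
        t2g(seg_start[i], seg_end[i])
      }, numeric(2)))
      cls <- ifelse(is_minor, "minor", "major")
      truth_introns[[gene_id]] <- data.frame(
        intron_id = sprintf("%s_i%d", tx_id, seq_len(n_introns)),
        gene_id = gene_id, transcript_id = tx_id, chrom = chrom,
        start = as.integer(g_coords[, 1]), end = as.integer(g_coords[, 2]),
        strand = strand, ordinal = seq_len(n_introns),
        length = intron_len, class = cls,
        subtype = ifelse(is_minor, subtype, NA_character_),
        context = assign_context(cls), stringsAsFactors = FALSE)
    }
    truth_genes[[gene_id]] <- data.frame(
      gene_id = gene_id, gene_type = gene_type, is_mig = is_mig,
      n_minor = n_minor, strand = strand, stringsAsFactors = FALSE)
  }

  seqs <- Biostrings::DNAStringSet(setNames(paste(unlist(chrom_parts),
                                                  collapse = ""), chrom))
  annotation <- structure(list(genes = genes, seqs = seqs),
                          class = "annotation_set")
  ti <- do.call(rbind, truth_introns); rownames(ti) <- NULL
  tg <- do.call(rbind, truth_genes); rownames(tg) <- NULL
  list(annotation = annotation, ppms = ppms,
       truth = list(introns = ti, genes = tg))
}

## the spliced-out interval of a planted AS event, genomic coordinates
event_gap <- function(locus, category) {
  nl <- norm_locus(locus)
  Is <- nl$minor[1]; Ie <- nl$minor[2]
  Us <- nl$up_exon[1]; Ue <- nl$up_exon[2]
  Ds <- nl$down_exon[1]; De <- nl$down_exon[2]
  U2e <- if (!is.null(nl$up2_exon)) nl$up2_exon[2] else NA
  D2s <- if (!is.null(nl$down2_exon)) nl$down2_exon[1] else NA
  gap <- switch(category,
    CAT1 = c(Is, Ie),
    CAT2 = c(U2e + 1L, D2s - 1L),
    CAT3 = c(U2e + 1L, Ie),
    CAT4 = c(Is, D2s - 1L),
    CAT5 = c(Ue - 10L, Ie),
    CAT6 = c(Is + 20L, Ie),
    CAT7 = c(Is, Ds + 10L),
    CAT8 = c(Is, Ie - 20L),
    CAT9 = NULL)
  if (category == "CAT9") {
    ## cryptic exon 24 nt inside the intron; reads alternate between the two
    ## junctions that flank it
    e1 <- Is + 15L; e2 <- e1 + 23L
    gap <- rbind(c(Is, e1 - 1L), c(e2 + 1L, Ie))
  } else {
    gap <- rbind(gap)
  }
  if (anyNA(gap)) return(NULL)
  ## map back from normalized transcript space to genomic coordinates
  if (locus$strand == "-") {
    gap <- cbind(-gap[, 2], -gap[, 1])
  }
  gap
}

#' Simulate retention evidence and junction reads
#'
#' For every intron, tissue and replicate, boundary and spliced read counts
#' are drawn binomially around the planted retention MSI (retained introns
#' are planted in a random subset of tissues, making retention
#' tissue-specific). For every minor intron with a planted
#' alternative-splicing event, per-replicate locus junction reads are drawn
#' with the event supported at the planted category MSI and the remainder
#' supporting the canonical junction. A few non-unique and 1-nt-overhang
#' reads are included per locus so that read filters are exercised.
#'
#' @param cfg a `sim_config`.
#' @param sim output of [simulate_genome_annotation()].
#' @return list with `samples`, `evidence` (boundary/spliced read table),
#'   `junctions` (junction read table), and truth tables
#'   `retention` (intron x tissue planted MSI) and `as_events`.
#' @export
simulate_reads <- function(cfg, sim) {
  set.seed(cfg$seed + 1L)
  tissues <- cfg$tissues
  samples <- data.frame(
    sample_id = as.vector(t(outer(tissues, seq_len(cfg$replicates),
                                  function(t, r) sprintf("%s_r%d", t, r)))),
    tissue = rep(tissues, each = cfg$replicates),
    replicate = rep(seq_len(cfg$replicates), times = length(tissues)),
    library_unique_reads = cfg$library_size, stringsAsFactors = FALSE)

  introns <- sim$truth$introns
  ## planted retention: tissue-specific MSI per intron
  msi_mat <- matrix(0, nrow = nrow(introns), ncol = length(tissues),
                    dimnames = list(introns$intron_id, tissues))
  for (i in seq_len(nrow(introns))) {
    retain <- if (introns$class[i] == "minor") {
      runif(1) < cfg$retained_frac
    } else {
      runif(1) < cfg$major_retained_frac
    }
    if (retain) {
      in_tissue <- runif(length(tissues)) < 0.5
      if (!any(in_tissue)) in_tissue[sample(length(tissues), 1L)] <- TRUE
      vals <- cfg$retention_msi_values
      val <- if (introns$class[i] == "minor") {
        vals[sample.int(length(vals), 1L)]
      } else cfg$major_retention_msi
      msi_mat[i, in_tissue] <- val
    }
  }

  ev <- vector("list", nrow(introns) * nrow(samples))
  k <- 0L
  for (i in seq_len(nrow(introns))) {
    for (s in seq_len(nrow(samples))) {
      r <- msi_mat[i, samples$tissue[s]] / 100
      u5 <- rbinom(1L, cfg$depth, r)
      u3 <- rbinom(1L, cfg$depth, r)
      spl <- cfg$depth - as.integer(round((u5 + u3) / 2))
      k <- k + 1L
      ev[[k]] <- data.frame(
        intron_id = introns$intron_id[i], sample_id = samples$sample_id[s],
        tissue = samples$tissue[s], boundary_reads_5 = u5,
        boundary_reads_3 = u3, spliced_reads = spl,
        covered_fraction = if (u5 + u3 > 0) 1 else round(runif(1, 0, 0.4), 3),
        library_unique_reads = cfg$library_size, stringsAsFactors = FALSE)
    }
  }
  evidence <- do.call(rbind, ev)

  ## planted AS events on minor introns with available geometry
  minors <- introns[introns$class == "minor", , drop = FALSE]
  truth_as <- list(); junc <- list()
  for (i in seq_len(nrow(minors))) {
    if (runif(1) >= cfg$as_event_frac) next
    tx <- sim$annotation$genes[[minors$gene_id[i]]]$transcripts[[minors$transcript_id[i]]]
    locus <- as_locus(tx, minors[i, ])
    cats <- paste0("CAT", 2:9)
    if (is.null(locus$up2_exon)) cats <- setdiff(cats, c("CAT2", "CAT3"))
    if (is.null(locus$down2_exon)) cats <- setdiff(cats, c("CAT2", "CAT4"))
    category <- sample(cats, 1L)
    gap <- event_gap(locus, category)
    if (is.null(gap)) next
    truth_as[[length(truth_as) + 1L]] <- data.frame(
      intron_id = minors$intron_id[i], gene_id = minors$gene_id[i],
      category = category, msi = cfg$as_msi,
      gap_start = gap[1, 1], gap_end = gap[1, 2], stringsAsFactors = FALSE)
    can <- event_gap(locus, "CAT1")
    for (s in seq_len(nrow(samples))) {
      L <- cfg$as_locus_reads
      kk <- rbinom(1L, L, cfg$as_msi / 100)
      n_can <- L - kk
      gap_rows <- gap[rep_len(seq_len(nrow(gap)), kk), , drop = FALSE]
      df <- data.frame(
        read_id = sprintf("%s_%s_e%d", minors$intron_id[i],
                          samples$sample_id[s], seq_len(kk + n_can)),
        sample_id = samples$sample_id[s], tissue = samples$tissue[s],
        intron_id = minors$intron_id[i], chrom = minors$chrom[i],
        gap_start = c(gap_rows[, 1], rep(can[1, 1], n_can)),
        gap_end = c(gap_rows[, 2], rep(can[1, 2], n_can)),
        overhang_left = cfg$read_overhang,
        overhang_right = cfg$read_overhang,
        unique = TRUE, stringsAsFactors = FALSE)
      ## reads the collector must drop: 1-nt overhang and multimapping
      extra <- df[rep(1L, 2L), , drop = FALSE]
      extra$read_id <- paste0(extra$read_id, c("_oh1", "_multi"))
      extra$gap_start <- can[1, 1]; extra$gap_end <- can[1, 2]
      extra$overhang_left[1] <- 1L
      extra$unique[2] <- FALSE
      junc[[length(junc) + 1L]] <- rbind(df, extra)
    }
  }
  junctions <- if (length(junc)) do.call(rbind, junc) else
    data.frame(read_id = character(), sample_id = character(),
               tissue = character(), intron_id = character(),
               chrom = character(), gap_start = integer(),
               gap_end = integer(), overhang_left = integer(),
               overhang_right = integer(), unique = logical(),
               stringsAsFactors = FALSE)
  rownames(evidence) <- rownames(junctions) <- NULL
  list(samples = samples, evidence = evidence, junctions = junctions,
       truth = list(
         retention = msi_mat,
         as_events = if (length(truth_as)) do.call(rbind, truth_as) else NULL))
}

#' Simulate a replicate TPM expression matrix with planted signatures
#'
#' Baseline expression is log-normal per gene (clamped to at least 2 TPM so
#' baseline genes count as expressed); per tissue, planted signature genes
#' are multiplied by the configured fold factor, planted silent genes drop
#' to a sub-threshold mean in their silent tissue, and replicates add
#' log-normal noise.
#'
#' @param cfg a `sim_config`.
#' @param gene_ids genes to simulate; defaults to synthetic identifiers.
#' @return list with `expr` (genes x samples TPM matrix), `samples`, and
#'   `truth` (`means` gene x tissue true mean TPM, `signature` data.frame,
#'   `silent` gene ids).
#' @export
simulate_expression <- function(cfg, gene_ids = sprintf("GENE%03d",
                                                        seq_len(cfg$n_genes))) {
  set.seed(cfg$seed + 2L)
  tissues <- cfg$tissues
  samples <- data.frame(
    sample_id = as.vector(t(outer(tissues, seq_len(cfg$replicates),
                                  function(t, r) sprintf("%s_r%d", t, r)))),
    tissue = rep(tissues, each = cfg$replicates), stringsAsFactors = FALSE)
  n <- length(gene_ids)
  base <- pmax(1, rnorm(n, cfg$base_log2_mean, cfg$base_log2_sd))
  means <- matrix(rep(2^base, length(tissues)), nrow = n,
                  dimnames = list(gene_ids, tissues))

  n_sig <- cfg$n_signature_per_tissue * length(tissues)
  sig_genes <- if (n_sig > 0 && n >= n_sig + cfg$n_silent) {
    sample(gene_ids, n_sig)
  } else character(0)
  signature <- if (length(sig_genes)) {
    data.frame(gene_id = sig_genes,
               tissue = rep(tissues, each = cfg$n_signature_per_tissue),
               stringsAsFactors = FALSE)
  } else data.frame(gene_id = character(), tissue = character())
  for (i in seq_len(nrow(signature))) {
    means[signature$gene_id[i], signature$tissue[i]] <-
      means[signature$gene_id[i], signature$tissue[i]] * cfg$signature_fold
  }
  silent_pool <- setdiff(gene_ids, sig_genes)
  silent <- if (cfg$n_silent > 0 && length(silent_pool) >= cfg$n_silent) {
    sample(silent_pool, cfg$n_silent)
  } else character(0)
  means[silent, tissues[1]] <- cfg$silent_tpm

  expr <- matrix(0, nrow = n, ncol = nrow(samples),
                 dimnames = list(gene_ids, samples$sample_id))
  for (s in seq_len(nrow(samples))) {
    mu <- means[, samples$tissue[s]]
    expr[, s] <- mu * 2^rnorm(n, 0, cfg$noise_sd)
  }
  list(expr = expr, samples = samples,
       truth = list(means = means, signature = signature, silent = silent,
                    silent_tissue = tissues[1]))
}

#' Write a simulated dataset to a run directory
#'
#' Serializes the genome (FASTA), annotation (Ensembl-dialect GTF), PPMs
#' (SpliceRack-style text), evidence/junction/expression tables (TSV), the
#' sample sheet and all truth tables, plus the configuration as JSON. All
#' outputs are plain text and byte-stable under a fixed seed.
#'
#' @param cfg a `sim_config`.
#' @param dir output directory (created if needed).
#' @return (invisibly) a named list of written paths; also returns the
#'   in-memory simulation in attribute-free list form.
#' @export
write_simulation <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_genome_annotation(cfg)
  reads <- simulate_reads(cfg, sim)
  exprs <- simulate_expression(cfg)
  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    ppms = file.path(dir, "ppms.txt"),
    evidence = file.path(dir, "evidence.tsv"),
    junctions = file.path(dir, "junctions.tsv"),
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.tsv"),
    truth_introns = file.path(dir, "truth_introns.tsv"),
    truth_retention = file.path(dir, "truth_retention.tsv"),
    truth_as = file.path(dir, "truth_as_events.tsv"),
    truth_expression = file.path(dir, "truth_expression.tsv"),
    config = file.path(dir, "config.json"))
  Biostrings::writeXStringSet(sim$annotation$seqs, paths$fasta)
  writeLines(gtf_lines(sim$annotation), paths$gtf)
  write_ppms(sim$ppms, paths$ppms)
  wtsv <- function(df, p) write.table(df, p, sep = "\t", quote = FALSE,
                                      row.names = FALSE)
  wtsv(reads$evidence, paths$evidence)
  wtsv(reads$junctions, paths$junctions)
  wtsv(data.frame(gene_id = rownames(exprs$expr), exprs$expr,
                  check.names = FALSE), paths$expression)
  wtsv(merge(reads$samples, exprs$samples,
             by = c("sample_id", "tissue"), all = TRUE), paths$samples)
  wtsv(sim$truth$introns, paths$truth_introns)
  wtsv(data.frame(intron_id = rownames(reads$truth$retention),
                  reads$truth$retention, check.names = FALSE),
       paths$truth_retention)
  if (!is.null(reads$truth$as_events)) wtsv(reads$truth$as_events, paths$truth_as)
  wtsv(data.frame(gene_id = rownames(exprs$truth$means), exprs$truth$means,
                  check.names = FALSE), paths$truth_expression)
  jsonlite::write_json(unclass(cfg), paths$config, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(paths, list(sim = sim, reads = reads, expression = exprs)))
}

## Ensembl-dialect GTF serialization of an annotation_set
gtf_lines <- function(annotation) {
  out <- character(0)
  line <- function(chrom, src, type, start, end, strand, attrs) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, src, type,
            start, end, strand, attrs)
  }
  for (gene in annotation$genes) {
    txs <- gene$transcripts
    chrom <- txs[[1]]$chrom; strand <- txs[[1]]$strand
    span <- range(unlist(lapply(txs, function(t) c(t$exons$start, t$exons$end))))
    gattr <- sprintf('gene_id "%s"; gene_biotype "%s";', gene$gene_id,
                     if (gene$gene_type == "protein_coding") "protein_coding"
                     else if (gene$gene_type == "lincRNA") "lincRNA"
                     else "processed_pseudogene")
    out <- c(out, line(chrom, "sim", "gene", span[1], span[2], strand, gattr))
    for (tx in txs) {
      src <- if (tx$has_ensembl_havana) "ensembl_havana" else "havana"
      tattr <- sprintf('%s transcript_id "%s";%s', gattr, tx$transcript_id,
                       if (tx$has_ccds)
                         sprintf(' ccds_id "CCDS%s";', sub("^TX", "", tx$transcript_id))
                       else "")
      out <- c(out, line(chrom, src, "transcript", min(tx$exons$start),
                         max(tx$exons$end), strand, tattr))
      for (i in seq_len(nrow(tx$exons))) {
        out <- c(out, line(chrom, src, "exon", tx$exons$start[i],
                           tx$exons$end[i], strand, tattr))
      }
      if (!is.null(tx$cds)) {
        for (i in seq_len(nrow(tx$cds))) {
          out <- c(out, line(chrom, src, "CDS", tx$cds$start[i],
                             tx$cds$end[i], strand, tattr))
        }
      }
    }
  }
  out
}

#' Write simulated alignments for one intron as a SAM file
#'
#' Emits gapped alignments reproducing a given evidence row: spliced reads
#' with an N-gap exactly matching the intron, contiguous boundary reads with
#' `overhang` nt on each side of each junction, and, for retained introns,
#' unspliced reads tiling the intron body so the coverage filter is
#' satisfiable. Intended for cross-checking the alignment-based evidence
#' counter against the tabular generator truth.
#'
#' @param sim output of [simulate_genome_annotation()].
#' @param intron one-row data.frame with chrom/start/end/strand.
#' @param counts list with `boundary_reads_5`, `boundary_reads_3`,
#'   `spliced_reads`.
#' @param path output SAM path.
#' @param overhang aligned nt on each side of a junction.
#' @return the path, invisibly.
#' @export
simulate_sam <- function(sim, intron, counts, path, overhang = 20L) {
  seqs <- sim$annotation$seqs
  chrom <- intron$chrom
  chrom_len <- nchar(as.character(seqs[[chrom]]))
  ilen <- intron$end - intron$start + 1L
  recs <- character(0)
  add <- function(qname, pos, cigar) {
    ## reconstruct the read sequence from the reference so SEQ is consistent
    ops <- regmatches(cigar, gregexpr("\\d+[MN]", cigar))[[1]]
    p <- pos; parts <- character(0)
    for (op in ops) {
      n <- as.integer(sub("[MN]", "", op))
      if (grepl("M", op)) parts <- c(parts, seq_slice(seqs, chrom, p, p + n - 1L))
      p <- p + n
    }
    s <- paste(parts, collapse = "")
    recs <<- c(recs, sprintf("%s\t0\t%s\t%d\t50\t%s\t*\t0\t0\t%s\t*",
                             qname, chrom, pos, cigar, s))
  }
  b5 <- counts$boundary_reads_5; b3 <- counts$boundary_reads_3
  s5_junc <- intron$start; s3_junc <- intron$end
  if (intron$strand == "-") { tmp <- b5; b5 <- b3; b3 <- tmp }
  for (i in seq_len(b5)) {
    add(sprintf("b5_%d", i), s5_junc - overhang, sprintf("%dM", 2L * overhang))
  }
  for (i in seq_len(b3)) {
    add(sprintf("b3_%d", i), s3_junc - overhang + 1L, sprintf("%dM", 2L * overhang))
  }
  for (i in seq_len(counts$spliced_reads)) {
    add(sprintf("sp_%d", i), intron$start - overhang,
        sprintf("%dM%dN%dM", overhang, ilen, overhang))
  }
  if (b5 + b3 > 0) {
    ## tile the intron body for coverage
    starts <- seq(intron$start, intron$end, by = 40L)
    for (i in seq_along(starts)) {
      ## clipped to the intron so tiles never masquerade as boundary reads
      w <- min(60L, intron$end - starts[i] + 1L)
      add(sprintf("cov_%d", i), starts[i], sprintf("%dM", w))
    }
  }
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  writeLines(c(header, recs), path)
  invisible(path)
}
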