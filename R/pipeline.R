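#' Export MIDB-style catalog tables
#'
#' Builds the reporting tables of a classification run: the minor-intron
#' table, the per-gene rollup of minor-intron counts (how many genes carry
#' one, two or three minor introns), the terminal-dinucleotide distribution,
#' the positional-context distribution and, when a prior minor-intron list
#' is supplied, the overlap columns against it.
#'
#' @param catalog an `intron_catalog` from [classify_introns()].
#' @param prior optional prior minor-intron list (chrom/start/end/strand) for
#'   overlap reporting.
#' @param slack coordinate slack for the prior comparison, nt.
#' @return named list of data.frames: `minor_introns`, `mig_rollup`,
#'   `dinucleotides`, `contexts`, and optionally `prior_overlap`.
#' @export
export_catalog <- function(catalog, prior = NULL, slack = 0L) {
  minors <- catalog[catalog$call == "minor", , drop = FALSE]
  per_gene <- table(minors$gene_id)
  rollup_tab <- table(factor(as.integer(per_gene), levels = 1:3))
  mig_rollup <- data.frame(n_minor_introns = as.integer(names(rollup_tab)),
                           n_genes = as.integer(rollup_tab))
  dn <- table(minors$subtype)
  dinucleotides <- data.frame(subtype = names(dn), n = as.integer(dn),
                              fraction = as.numeric(dn) / max(1L, nrow(minors)))
  cx <- table(minors$context)
  contexts <- data.frame(context = names(cx), n = as.integer(cx))
  out <- list(minor_introns = minors, mig_rollup = mig_rollup,
              dinucleotides = dinucleotides, contexts = contexts)
  if (!is.null(prior)) {
    ov <- compare_prior_list(catalog, prior, slack = slack)
    out$prior_overlap <- data.frame(shared = ov$shared, new = ov$new,
                                    missed = ov$missed)
  }
  out
}

#' Run the pipeline end to end on a run directory
#'
#' Subcommands: `simulate` writes a seeded synthetic dataset into `out_dir`;
#' `classify`, `retention`, `altsplice`, `signature` and `orf_fate` run the
#' corresponding stage on the files in the run directory; `all` runs
#' everything in order. Every stage writes TSV reports plus a provenance
#' entry (seed, configuration hash) into `run_log.json`. Outputs are
#' deterministic under a fixed seed.
#'
#' @param subcommand one of "simulate", "classify", "retention", "altsplice",
#'   "signature", "orf_fate", "all".
#' @param out_dir the run directory.
#' @param config a `sim_config` (for `simulate`/`all`); defaults to
#'   `sim_config(seed = seed)`.
#' @param seed integer seed.
#' @param retention_mode passed to [filter_retention()].
#' @return (invisibly) named list of report paths written by the stage(s).
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "classify",
                                        "retention", "altsplice", "signature",
                                        "orf_fate"),
                         out_dir, config = NULL, seed = 1L,
                         retention_mode = "all_replicates") {
  subcommand <- match.arg(subcommand)
  if (missing(out_dir)) stopf("out_dir is required")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  config <- config %||% sim_config(seed = seed)
  written <- list()
  need <- function(p) {
    if (!file.exists(p)) stopf("required input missing: %s", p)
    p
  }
  wtsv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written[[name]] <<- p
    p
  }

  stages <- if (subcommand == "all") {
    c("simulate", "classify", "retention", "altsplice", "signature",
      "orf_fate")
  } else subcommand

  for (stage in stages) {
    if (stage == "simulate") {
      write_simulation(config, out_dir)
      written[["simulate"]] <- out_dir
    } else if (stage == "classify") {
      gtf <- need(file.path(out_dir, "annotation.gtf"))
      ann <- parse_annotation(gtf, need(file.path(out_dir, "genome.fa")))
      ppms <- read_ppms(need(file.path(out_dir, "ppms.txt")))
      catalog <- classify_introns(ann, ppms)
      wtsv(catalog, "catalog.tsv")
      tabs <- export_catalog(catalog)
      wtsv(tabs$mig_rollup, "mig_rollup.tsv")
      wtsv(tabs$dinucleotides, "dinucleotides.tsv")
      wtsv(tabs$contexts, "contexts.tsv")
    } else if (stage == "retention") {
      ev <- read_evidence_tsv(need(file.path(out_dir, "evidence.tsv")))
      res <- filter_retention(ev, mode = retention_mode)
      wtsv(res$per_replicate, "msi.tsv")
      wtsv(res$tissue_calls, "retention_calls.tsv")
      wtsv(res$replicate_class, "retention_classes.tsv")
    } else if (stage == "altsplice") {
      juncs <- read.delim(need(file.path(out_dir, "junctions.tsv")),
                          stringsAsFactors = FALSE)
      samples <- read.delim(need(file.path(out_dir, "samples.tsv")),
                            stringsAsFactors = FALSE)
      catalog <- read.delim(need(file.path(out_dir, "catalog.tsv")),
                            stringsAsFactors = FALSE)
      ann <- parse_annotation(need(file.path(out_dir, "annotation.gtf")),
                              need(file.path(out_dir, "genome.fa")))
      minors <- catalog[catalog$call == "minor", , drop = FALSE]
      out <- list()
      for (i in seq_len(nrow(minors))) {
        sub <- juncs[juncs$intron_id == minors$intron_id[i], , drop = FALSE]
        if (nrow(sub) == 0L) next
        tx <- ann$genes[[minors$gene_id[i]]]$transcripts[[minors$transcript_id[i]]]
        locus <- as_locus(tx, minors[i, ])
        q <- quantify_as_events(sub, locus, samples)
        tc <- q$tissue_calls
        if (!is.null(tc) && nrow(tc)) {
          tc$intron_id <- minors$intron_id[i]
          tc$gene_id <- minors$gene_id[i]
          out[[length(out) + 1L]] <- tc
        }
      }
      as_calls <- if (length(out)) do.call(rbind, out) else
        data.frame(tissue = character(), category = character(),
                   mean_msi = numeric(), passed = logical(),
                   intron_id = character(), gene_id = character())
      wtsv(as_calls, "as_events.tsv")
    } else if (stage == "signature") {
      exprs <- read.delim(need(file.path(out_dir, "expression.tsv")),
                          check.names = FALSE, stringsAsFactors = FALSE)
      mat <- as.matrix(exprs[, -1, drop = FALSE])
      rownames(mat) <- exprs$gene_id
      samples <- read.delim(need(file.path(out_dir, "samples.tsv")),
                            stringsAsFactors = FALSE)
      bad <- setdiff(samples$sample_id, colnames(mat))
      if (length(bad)) stopf("sample sheet lists sample(s) absent from the expression matrix: %s",
                             paste(bad, collapse = ", "))
      tissues <- unique(samples$tissue)
      pairs <- utils::combn(tissues, 2)
      de <- list()
      for (k in seq_len(ncol(pairs))) {
        de[[paste(pairs[1, k], pairs[2, k], sep = "|")]] <-
          pairwise_de(mat, samples, pairs[1, k], pairs[2, k],
                      seed = seed + k)
      }
      sig <- compute_signatures(de, tissues)
      wtsv(sig$summary, "signature_summary.tsv")
      long <- do.call(rbind, lapply(tissues, function(tt) {
        s <- sig$signatures[[tt]]
        rbind(
          if (length(s$up_signature))
            data.frame(tissue = tt, direction = "up", gene_id = s$up_signature),
          if (length(s$down_signature))
            data.frame(tissue = tt, direction = "down", gene_id = s$down_signature))
      }))
      wtsv(long %||% data.frame(tissue = character(), direction = character(),
                                gene_id = character()), "signatures.tsv")
    } else if (stage == "orf_fate") {
      as_path <- need(file.path(out_dir, "as_events.tsv"))
      as_calls <- read.delim(as_path, stringsAsFactors = FALSE)
      catalog <- read.delim(need(file.path(out_dir, "catalog.tsv")),
                            stringsAsFactors = FALSE)
      truth_as <- file.path(out_dir, "truth_as_events.tsv")
      coords <- if (file.exists(truth_as)) {
        read.delim(truth_as, stringsAsFactors = FALSE)
      } else NULL
      ann <- parse_annotation(need(file.path(out_dir, "annotation.gtf")),
                              need(file.path(out_dir, "genome.fa")))
      passing <- unique(as_calls[as_calls$passed,
                                 c("intron_id", "gene_id", "category")])
      fates <- list()
      for (i in seq_len(nrow(passing))) {
        row <- passing[i, ]
        intron <- catalog[catalog$intron_id == row$intron_id, , drop = FALSE][1, ]
        tx <- ann$genes[[row$gene_id]]$transcripts[[intron$transcript_id]]
        gap <- NULL; cexon <- NULL
        if (row$category %in% paste0("CAT", 5:8)) {
          cr <- coords[coords$intron_id == row$intron_id &
                       coords$category == row$category, , drop = FALSE]
          if (nrow(cr) == 0L) next
          gap <- c(cr$gap_start[1], cr$gap_end[1])
        } else if (row$category == "CAT9") {
          cr <- coords[coords$intron_id == row$intron_id &
                       coords$category == "CAT9", , drop = FALSE]
          if (nrow(cr) == 0L) next
          cexon <- c(cr$gap_end[1] + 1L, cr$gap_end[1] + 24L)
        }
        mt <- tryCatch(apply_as_event(tx, intron, row$category, gap = gap,
                                      cryptic_exon = cexon),
                       error = function(e) NULL)
        if (is.null(mt)) next
        f <- predict_fate(mt, tx, ann$seqs)
        fates[[length(fates) + 1L]] <- data.frame(
          gene_id = row$gene_id, intron_id = row$intron_id,
          category = row$category, fate = f$fate %||% NA_character_,
          protein_change = f$protein_change %||% NA_character_,
          new_stop_position = f$new_stop_position %||% NA_integer_,
          flag = f$flag, stringsAsFactors = FALSE)
      }
      fate_df <- if (length(fates)) do.call(rbind, fates) else
        data.frame(gene_id = character(), intron_id = character(),
                   category = character(), fate = character(),
                   protein_change = character(),
                   new_stop_position = integer(), flag = character())
      wtsv(fate_df, "fates.tsv")
      counts <- table(factor(fate_df$fate, levels = c("protein", "NMD", "NSD")))
      wtsv(data.frame(fate = names(counts), n = as.integer(counts)),
           "fate_summary.tsv")
    }
  }
  log_path <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(list(subcommand = subcommand, seed = seed,
                            stages = stages,
                            reports = names(written),
                            package_version =
                              as.character(utils::packageVersion("minorintron"))),
                       log_path, auto_unbox = TRUE)
  written[["run_log.json"]] <- log_path
  invisible(written)
}
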