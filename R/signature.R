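#' Per-tissue expressed gene sets and their overlap
#'
#' A gene counts as expressed in a tissue when its mean TPM over that
#' tissue's replicates exceeds `threshold` (default 1 TPM). Genes from
#' `gene_list` absent from the matrix are treated as unexpressed (0 TPM).
#'
#' @param expr numeric matrix of TPM values, genes in rows, samples in
#'   columns.
#' @param samples data.frame with `sample_id`, `tissue`; sample ids must
#'   match `colnames(expr)`.
#' @param gene_list genes to interrogate (e.g. the minor intron-containing
#'   genes); defaults to all rows.
#' @param threshold TPM threshold (strict >).
#' @return list with `sets` (named list of expressed gene vectors per
#'   tissue), `intersection` (expressed in every tissue), `counts`, and
#'   `pairwise` (matrix of pairwise overlap counts).
#' @export
expressed_mig_overlap <- function(expr, samples, gene_list = rownames(expr),
                                  threshold = 1) {
  tissues <- unique(samples$tissue)
  if (any(!samples$sample_id %in% colnames(expr))) {
    stopf("sample sheet references samples absent from the matrix")
  }
  full <- matrix(0, nrow = length(gene_list), ncol = ncol(expr),
                 dimnames = list(gene_list, colnames(expr)))
  present <- intersect(gene_list, rownames(expr))
  full[present, ] <- expr[present, , drop = FALSE]
  sets <- lapply(setNames(tissues, tissues), function(tt) {
    cols <- samples$sample_id[samples$tissue == tt]
    if (length(cols) == 0L) stopf("tissue '%s' has zero samples", tt)
    means <- rowMeans(full[, cols, drop = FALSE])
    gene_list[means > threshold]
  })
  inter <- Reduce(intersect, sets)
  pw <- outer(tissues, tissues, Vectorize(function(a, b) {
    length(intersect(sets[[a]], sets[[b]]))
  }))
  dimnames(pw) <- list(tissues, tissues)
  list(sets = sets, intersection = inter,
       counts = vapply(sets, length, integer(1)), pairwise = pw)
}

#' Pairwise differential expression between two tissues
#'
#' The default engine is a seeded bootstrap over replicates: replicate
#' columns of each tissue are resampled with replacement `B` times, the
#' log2 fold change of mean TPM (after a 0.1 TPM pseudocount) is recomputed
#' for each resample, and the two-sided p-value is the bootstrap tail
#' probability that the fold change crosses zero. A gene is called
#' differentially expressed only when the point fold change exceeds 2 (or is
#' below 1/2) with p below 0.01. Externally computed DE tables can be
#' injected instead via `table`: a data.frame with columns `gene_id`,
#' `fold_change`, `p_value`.
#'
#' @param expr TPM matrix (genes x samples).
#' @param samples sample sheet (`sample_id`, `tissue`).
#' @param tissue_a,tissue_b the two tissues; fold changes are a over b.
#' @param B bootstrap resamples.
#' @param seed integer seed for the bootstrap.
#' @param pseudocount TPM pseudocount guarding against division by zero.
#' @param fc_threshold,p_threshold the joint DE rule (strict > / <).
#' @param table optional injected DE table replacing the bootstrap engine.
#' @return data.frame with gene_id, fold_change, p_value, direction
#'   ("up_in_a", "down_in_a", "nonDE").
#' @export
pairwise_de <- function(expr, samples, tissue_a, tissue_b, B = 1000,
                        seed = 1L, pseudocount = 0.1, fc_threshold = 2,
                        p_threshold = 0.01, table = NULL) {
  if (!is.null(table)) {
    dir <- ifelse(table$fold_change > fc_threshold & table$p_value < p_threshold,
                  "up_in_a",
                  ifelse(table$fold_change < 1 / fc_threshold &
                         table$p_value < p_threshold, "down_in_a", "nonDE"))
    return(data.frame(gene_id = table$gene_id,
                      fold_change = table$fold_change,
                      p_value = table$p_value, direction = dir,
                      stringsAsFactors = FALSE))
  }
  cols_a <- samples$sample_id[samples$tissue == tissue_a]
  cols_b <- samples$sample_id[samples$tissue == tissue_b]
  if (length(cols_a) < 2L || length(cols_b) < 2L) {
    stopf("bootstrap engine needs >= 2 replicates per tissue (%s: %d, %s: %d); inject a DE table instead",
          tissue_a, length(cols_a), tissue_b, length(cols_b))
  }
  a <- expr[, cols_a, drop = FALSE] + pseudocount
  b <- expr[, cols_b, drop = FALSE] + pseudocount
  fc <- rowMeans(a) / rowMeans(b)
  set.seed(seed)
  na <- ncol(a); nb <- ncol(b)
  ## bootstrap distribution of the log2 fold change, vectorized over genes
  pos <- integer(nrow(expr)); neg <- integer(nrow(expr))
  for (i in seq_len(B)) {
    lfc <- log2(rowMeans(a[, sample.int(na, na, replace = TRUE), drop = FALSE]) /
                rowMeans(b[, sample.int(nb, nb, replace = TRUE), drop = FALSE]))
    pos <- pos + (lfc >= 0)
    neg <- neg + (lfc <= 0)
  }
  p <- pmin(1, 2 * pmin(pos, neg) / B)
  dir <- ifelse(fc > fc_threshold & p < p_threshold, "up_in_a",
                ifelse(fc < 1 / fc_threshold & p < p_threshold,
                       "down_in_a", "nonDE"))
  data.frame(gene_id = rownames(expr), fold_change = unname(fc),
             p_value = unname(p), direction = dir, stringsAsFactors = FALSE)
}

#' Tissue Up/Down expression signatures by pairwise-DE intersection
#'
#' A gene belongs to a tissue's UpSignature when it is called upregulated in
#' that tissue in every one of its pairwise comparisons against all other
#' tissues (the intersection over comparisons); the DownSignature is the
#' analogous intersection of downregulated calls. All `choose(T, 2)`
#' comparisons must be present. A gene cannot be up against all others in
#' two tissues at once, so UpSignatures are pairwise disjoint by
#' construction; this is asserted on every run.
#'
#' @param de_calls named list of pairwise DE tables from [pairwise_de()];
#'   names are "tissueA|tissueB" with fold changes expressed as A over B.
#' @param tissues character vector of all tissues.
#' @return list per tissue with `up_signature`, `down_signature`, plus an
#'   `audit` table of per-gene per-comparison directions and `summary`
#'   counts, class `signature_result`.
#' @export
compute_signatures <- function(de_calls, tissues) {
  want <- utils::combn(tissues, 2)
  keys <- paste(want[1, ], want[2, ], sep = "|")
  have <- names(de_calls)
  canon <- function(k) {
    p <- strsplit(k, "|", fixed = TRUE)[[1]]
    paste(sort(p), collapse = "|")
  }
  missing <- setdiff(vapply(keys, canon, character(1)),
                     vapply(have, canon, character(1)))
  if (length(missing)) {
    stopf("missing pairwise comparison(s): %s", paste(missing, collapse = ", "))
  }
  dir_for <- function(tt, other) {
    k1 <- paste(tt, other, sep = "|")
    k2 <- paste(other, tt, sep = "|")
    if (k1 %in% have) {
      d <- de_calls[[k1]]
      setNames(d$direction, d$gene_id)
    } else {
      d <- de_calls[[k2]]
      flip <- c(up_in_a = "down_in_a", down_in_a = "up_in_a", nonDE = "nonDE")
      setNames(unname(flip[d$direction]), d$gene_id)
    }
  }
  universe <- sort(unique(unlist(lapply(de_calls, function(d) d$gene_id))))
  res <- list(); audit <- list()
  for (tt in tissues) {
    others <- setdiff(tissues, tt)
    dirs <- matrix(vapply(others, function(o) {
      unname(dir_for(tt, o)[universe])
    }, character(length(universe))), nrow = length(universe),
    dimnames = list(universe, others))
    up <- universe[apply(dirs == "up_in_a", 1, function(v) all(!is.na(v) & v))]
    down <- universe[apply(dirs == "down_in_a", 1, function(v) all(!is.na(v) & v))]
    res[[tt]] <- list(up_signature = up, down_signature = down)
    audit[[tt]] <- dirs
  }
  ups <- lapply(res, `[[`, "up_signature")
  overlap <- utils::combn(tissues, 2, function(p) {
    length(intersect(ups[[p[1]]], ups[[p[2]]]))
  })
  if (any(overlap > 0)) {
    stopf("internal error: UpSignatures are not pairwise disjoint")
  }
  structure(list(
    signatures = res, audit = audit,
    summary = data.frame(
      tissue = tissues,
      n_up = vapply(res, function(r) length(r$up_signature), integer(1)),
      n_down = vapply(res, function(r) length(r$down_signature), integer(1)),
      stringsAsFactors = FALSE),
    n_comparisons = length(keys)
  ), class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("Expression signatures over %d tissues (%d pairwise comparisons)\n",
              nrow(x$summary), x$n_comparisons))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
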