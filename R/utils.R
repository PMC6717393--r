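#' @importFrom stats aov kruskal.test p.adjust pnorm rbinom rlnorm rnorm runif
#'   setNames TukeyHSD wilcox.test quantile sd
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a DNA string
#'
#' Thin wrapper around Biostrings kept in one place so strand flips happen
#' through a single code path.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## significance stars at the thresholds used throughout the package
p_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", ""))))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## substring of a chromosome sequence, 1-based inclusive, with bounds check
seq_slice <- function(seqs, chrom, start, end) {
  if (!chrom %in% names(seqs)) {
    stopf("chromosome '%s' not present in the genome sequence", chrom)
  }
  n <- nchar(as.character(seqs[[chrom]]))
  if (start < 1L || end > n) {
    stopf("slice %d-%d outside chromosome '%s' (length %d)", start, end, chrom, n)
  }
  toupper(as.character(Biostrings::subseq(seqs[[chrom]], start, end)))
}
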