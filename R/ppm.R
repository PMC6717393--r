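#' Splice-site position probability matrices
#'
#' A PPM set holds per-position base probabilities for the splice-site models
#' used to call minor (U12-type) introns: the four 5' splice-site matrices
#' (minor AT-AC, minor GT-AG, major GT-AG, major GC-AG; 12 positions covering
#' -3..+9 around the donor), the two minor 3' splice-site matrices (14
#' positions covering -13..+1 around the acceptor) and the two minor
#' branch-point matrices (12 positions, with the branch adenosine at position
#' 9 or 10 respectively).
#'
#' The on-disk format is SpliceRack-style plain text: a `>name` header line
#' followed by four whitespace-delimited rows, one per base in A/C/G/T order,
#' whose columns are positions.
#'
#' @param path path to a PPM text file.
#' @return a named list of probability matrices (rows A/C/G/T, columns =
#'   positions), class `ppm_set`.
#' @export
#' @examples
#' ppms <- simulate_ppms(seed = 1)
#' f <- tempfile(fileext = ".txt")
#' write_ppms(ppms, f)
#' identical_names <- names(read_ppms(f))
read_ppms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stopf("no '>' matrix headers found in %s", path)
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    name <- sub("^>\\s*", "", lines[heads[i]])
    block <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(block) != 4L) {
      stopf("matrix '%s': expected 4 base rows, found %d", name, length(block))
    }
    rows <- lapply(block, function(l) {
      fields <- strsplit(trimws(l), "\\s+")[[1]]
      ## tolerate an optional leading base label column
      if (fields[1] %in% c(DNA_BASES, tolower(DNA_BASES))) fields <- fields[-1]
      as.numeric(fields)
    })
    wid <- unique(lengths(rows))
    if (length(wid) != 1L) stopf("matrix '%s': ragged rows", name)
    m <- do.call(rbind, rows)
    rownames(m) <- DNA_BASES
    validate_ppm(m, name)
    out[[name]] <- m
  }
  structure(out, class = "ppm_set")
}

validate_ppm <- function(m, name = "ppm") {
  if (any(m < 0)) stopf("matrix '%s': negative probability", name)
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-6)) {
    stopf("matrix '%s': column(s) %s do not sum to 1",
          name, paste(which(abs(cs - 1) > 1e-6), collapse = ","))
  }
  invisible(m)
}

#' @rdname read_ppms
#' @param ppms a `ppm_set` (or plain named list of probability matrices).
#' @param digits number of digits written per probability.
#' @export
write_ppms <- function(ppms, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  for (name in names(ppms)) {
    m <- ppms[[name]]
    writeLines(paste0(">", name), con)
    for (b in DNA_BASES) {
      writeLines(paste(c(b, formatC(m[b, ], digits = digits, format = "g")),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

## canonical matrix names; the classifier addresses matrices by these roles
PPM_NAMES <- c("minor_5ss_ATAC", "minor_5ss_GTAG", "major_5ss_GTAG",
               "major_5ss_GCAG", "minor_3ss_ATAC", "minor_3ss_GTAG",
               "bps_A9", "bps_A10")
FIVE_SS_NAMES <- PPM_NAMES[1:4]

#' Transform a position probability matrix into a log-odds PWM
#'
#' Every element is transformed as `log2(p / 0.25)` against the uniform
#' background; zero probabilities are first replaced by a pseudocount so no
#' log-odds value is infinite. The minimum and maximum achievable raw scores
#' (sums of per-column minima and maxima) are stored for rescaling.
#'
#' @param ppm probability matrix, rows A/C/G/T.
#' @param pseudocount replacement for zero probabilities (default 0.0001).
#' @param name optional matrix name carried through to the PWM.
#' @return list with elements `name`, `matrix` (log-odds), `m_min`, `m_max`
#'   and `na_score` (the log-odds value used for ambiguous bases), class `pwm`.
#' @export
#' @examples
#' p <- matrix(c(1, 0, 0, 0, 0.25, 0.25, 0.25, 0.25), 4,
#'             dimnames = list(c("A", "C", "G", "T"), NULL))
#' w <- build_pwm(p)
#' w$matrix["A", 1]  # log2(4) = 2
build_pwm <- function(ppm, pseudocount = 1e-4, name = NULL) {
  if (any(ppm < 0)) stopf("negative probability in PPM")
  p <- ppm
  p[p == 0] <- pseudocount
  lod <- log2(p / 0.25)
  structure(list(
    name = name,
    matrix = lod,
    m_min = sum(apply(lod, 2, min)),
    m_max = sum(apply(lod, 2, max)),
    na_score = log2(pseudocount / 0.25)
  ), class = "pwm")
}

#' @rdname build_pwm
#' @param ppms a `ppm_set`.
#' @return `build_pwm_set`: named list of `pwm` objects, class `pwm_set`.
#' @export
build_pwm_set <- function(ppms, pseudocount = 1e-4) {
  structure(
    lapply(setNames(names(ppms), names(ppms)),
           function(n) build_pwm(ppms[[n]], pseudocount, name = n)),
    class = "pwm_set")
}

#' Score a splice-site window against a PWM
#'
#' The raw score is the sum of the per-position log-odds values of the
#' observed bases. Ambiguity codes (N etc.) are scored with the pseudocount
#' log-odds value, the most conservative choice; windows with more than two
#' ambiguous bases are unscorable and return `NA`.
#'
#' @param window DNA string, same length as the PWM.
#' @param pwm a `pwm` object.
#' @param max_ambiguous windows with more ambiguous bases than this score `NA`.
#' @return raw score (numeric scalar), or `NA` if unscorable.
#' @export
raw_score <- function(window, pwm, max_ambiguous = 2L) {
  bases <- strsplit(toupper(window), "")[[1]]
  if (length(bases) != ncol(pwm$matrix)) {
    stopf("window length %d does not match PWM width %d",
          length(bases), ncol(pwm$matrix))
  }
  amb <- !bases %in% DNA_BASES
  if (sum(amb) > max_ambiguous) return(NA_real_)
  vals <- numeric(length(bases))
  ri <- match(bases[!amb], rownames(pwm$matrix))
  vals[!amb] <- pwm$matrix[cbind(ri, which(!amb))]
  vals[amb] <- pwm$na_score
  sum(vals)
}

#' Rescale a raw PWM score to the 0-100 scale
#'
#' Negative raw scores map linearly onto 0..50 (`50 * (m - m_min) / -m_min`)
#' and positive scores onto 50..100 (`50 + 50 * m / m_max`), so the minimum
#' achievable score is 0, a zero log-odds sum is 50 and the consensus is 100.
#' Scores outside the achievable range (possible only for ambiguous-base
#' substitutions) are clamped with a warning.
#'
#' @param m raw score.
#' @param pwm the `pwm` the score was computed against.
#' @return rescaled score in \[0, 100\], or `NA` if `m` is `NA`.
#' @export
rescale_score <- function(m, pwm) {
  if (is.na(m)) return(NA_real_)
  if (pwm$m_min >= 0 || pwm$m_max <= 0) {
    stopf("degenerate PWM '%s': m_min=%.3f m_max=%.3f",
          pwm$name %||% "?", pwm$m_min, pwm$m_max)
  }
  x <- if (m < 0) 50 * (m - pwm$m_min) / (-pwm$m_min) else 50 + 50 * m / pwm$m_max
  if (x < 0 || x > 100) {
    warnf("raw score %.3f outside [m_min, m_max] for '%s'; clamped",
          m, pwm$name %||% "?")
    x <- min(max(x, 0), 100)
  }
  x
}

## convenience: raw + rescale in one call
score_window <- function(window, pwm) rescale_score(raw_score(window, pwm), pwm)

#' Best branch-point score over all windows and both matrix variants
#'
#' Scores every putative branch-point window against both minor branch-point
#' PWMs (branch adenosine at position 9 or 10) and returns the best rescaled
#' score. Ties are broken by the smaller window index, then by the A9 variant.
#'
#' @param bps_windows character vector of 12-nt windows (may be empty).
#' @param pwm_a9,pwm_a10 the two branch-point `pwm` objects.
#' @return list with `score`, `window_index`, `variant` ("A9"/"A10"); all `NA`
#'   when no window is scorable.
#' @export
best_bps_score <- function(bps_windows, pwm_a9, pwm_a10) {
  if (length(bps_windows) == 0L) {
    return(list(score = NA_real_, window_index = NA_integer_,
                variant = NA_character_))
  }
  s9 <- vapply(bps_windows, score_window, numeric(1), pwm = pwm_a9,
               USE.NAMES = FALSE)
  s10 <- vapply(bps_windows, score_window, numeric(1), pwm = pwm_a10,
                USE.NAMES = FALSE)
  ## A9 listed first so that at equal score and index A9 wins the tie
  all_scores <- c(s9, s10)
  idx <- c(seq_along(bps_windows), seq_along(bps_windows))
  var <- rep(c("A9", "A10"), each = length(bps_windows))
  if (all(is.na(all_scores))) {
    return(list(score = NA_real_, window_index = NA_integer_,
                variant = NA_character_))
  }
  best <- max(all_scores, na.rm = TRUE)
  hits <- which(!is.na(all_scores) & all_scores == best)
  ## order ties by window index, then variant A9 before A10
  hits <- hits[order(idx[hits], match(var[hits], c("A9", "A10")))]
  k <- hits[1]
  list(score = best, window_index = idx[k], variant = var[k])
}
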