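# Match-style PWM scanning: information-weighted core/matrix similarity
# scores used to fine-map transcription-factor binding elements (TFBEs)
# inside dual-target regions.

#' Per-position information vector of a PWM
#'
#' `I(i) = sum_b f(i,b) * ln(4 f(i,b))`, with the `0 * ln 0` term defined as
#' 0. Values lie in `[0, ln 4]` nats: 0 for a uniform column, `ln 4` for a
#' fully conserved one. Natural logarithms are used; the base cancels in the
#' similarity-score ratio.
#'
#' @param pwm A `pwm` object.
#' @return Numeric vector of length `L`.
#' @export
information_vector <- function(pwm) {
  f <- pwm$freqs
  term <- ifelse(f > 0, f * log(4 * f), 0)
  rowSums(term)
}

# information-weighted frequency matrix and its per-window extrema
match_weights <- function(pwm, positions = seq_len(nrow(pwm$freqs))) {
  I <- information_vector(pwm)[positions]
  W <- pwm$freqs[positions, , drop = FALSE] * I
  list(W = W,
       max = sum(apply(W, 1L, max)),
       min = sum(apply(W, 1L, min)))
}

encode_dna <- function(seq) {
  if (length(seq) == 1L && nchar(seq) != 1L)
    seq <- strsplit(seq, "")[[1]]
  match(toupper(seq), c("A", "C", "G", "T"))
}

score_window <- function(wts, codes) {
  if (anyNA(codes)) return(NA_real_)
  cur <- sum(wts$W[cbind(seq_along(codes), codes)])
  if (wts$max == wts$min) return(0)
  (cur - wts$min) / (wts$max - wts$min)
}

#' Matrix similarity score of a sequence window
#'
#' The Match matrix similarity score:
#' `MSS = (Current - Min) / (Max - Min)` with
#' `Current = sum_i I(i) f(i, b_i)`, and `Max`/`Min` the per-position
#' information-weighted maxima/minima. Ranges over `[0, 1]`; 1 for the
#' consensus window, 0 for the anti-consensus. A degenerate matrix
#' (`Max == Min`) scores 0.
#'
#' @param pwm A `pwm` object of length `L`.
#' @param window Character scalar (or vector of single bases) of length `L`,
#'   A/C/G/T only; windows containing other letters score `NA`.
#' @return Numeric scalar in `[0, 1]` (or `NA`).
#' @export
matrix_similarity <- function(pwm, window) {
  codes <- encode_dna(window)
  if (length(codes) != nrow(pwm$freqs))
    stop("window length ", length(codes), " != matrix length ",
         nrow(pwm$freqs))
  score_window(match_weights(pwm), codes)
}

#' Core positions of a PWM
#'
#' The core is the 5 consecutive positions maximizing the summed information
#' vector (leftmost window on ties); for matrices of length <= 5 the core is
#' the whole matrix.
#'
#' @param pwm A `pwm` object.
#' @return Integer vector of core positions.
#' @export
core_positions <- function(pwm) {
  L <- nrow(pwm$freqs)
  if (L <= 5L) return(seq_len(L))
  I <- information_vector(pwm)
  sums <- vapply(seq_len(L - 4L), function(s) sum(I[s:(s + 4L)]), 0)
  s <- which.max(sums)  # which.max returns the leftmost maximum
  s:(s + 4L)
}

#' Core similarity score of a sequence window
#'
#' The matrix similarity formula restricted to the [core_positions()] of the
#' matrix, applied to the corresponding bases of the window.
#'
#' @inheritParams matrix_similarity
#' @return Numeric scalar in `[0, 1]` (or `NA`).
#' @export
core_similarity <- function(pwm, window) {
  codes <- encode_dna(window)
  if (length(codes) != nrow(pwm$freqs))
    stop("window length ", length(codes), " != matrix length ",
         nrow(pwm$freqs))
  pos <- core_positions(pwm)
  score_window(match_weights(pwm, pos), codes[pos])
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# score every window of a coded sequence; returns matrix of mss/css
scan_codes <- function(codes, wts_full, wts_core, core_off) {
  L <- nrow(wts_full$W); n <- length(codes) - L + 1L
  if (n < 1L) return(NULL)
  cur <- numeric(n); curc <- numeric(n); ok <- rep(TRUE, n)
  for (i in seq_len(L)) {
    ci <- codes[i:(i + n - 1L)]
    nas <- is.na(ci)
    ok <- ok & !nas
    ci[nas] <- 1L
    cur <- cur + wts_full$W[i, ][ci]
  }
  for (k in seq_along(core_off)) {
    i <- core_off[k]
    ci <- codes[i:(i + n - 1L)]
    ci[is.na(ci)] <- 1L
    curc <- curc + wts_core$W[k, ][ci]
  }
  mss <- if (wts_full$max == wts_full$min) rep(0, n) else
    (cur - wts_full$min) / (wts_full$max - wts_full$min)
  css <- if (wts_core$max == wts_core$min) rep(0, n) else
    (curc - wts_core$min) / (wts_core$max - wts_core$min)
  mss[!ok] <- NA_real_; css[!ok] <- NA_real_
  cbind(mss = mss, css = css)
}

#' Scan regions for binding elements with a PWM
#'
#' Slides the matrix over every window of each region on both strands and
#' reports windows whose core similarity and matrix similarity both reach
#' their cut-offs. Reverse-strand windows are scored on the reverse
#' complement; reported coordinates are always forward-strand genomic
#' (0-based half-open). Windows containing non-ACGT letters are skipped.
#'
#' @param pwm A `pwm` object.
#' @param regions Data frame with columns `chrom`, `start`, `end` and
#'   optionally `region_id` (e.g. a `dual_targets` table).
#' @param genome Named character vector of chromosome sequences (see
#'   [read_genome_fasta()]).
#' @param core_cutoff,matrix_cutoff Score thresholds in `[0, 1]`; defaults
#'   0.75 and 0.85.
#' @return Data frame of TFBE hits: `region_id`, `matrix`, `chrom`, `start`,
#'   `end`, `strand`, `core_score`, `matrix_score`, `sequence` (the scored
#'   bases, reverse-complemented for `-` hits).
#' @export
scan_pwm <- function(pwm, regions, genome, core_cutoff = 0.75,
                     matrix_cutoff = 0.85) {
  stopifnot(inherits(pwm, "pwm"))
  if (core_cutoff < 0 || core_cutoff > 1 || matrix_cutoff < 0 ||
      matrix_cutoff > 1)
    stop("cutoffs must lie in [0, 1]")
  L <- nrow(pwm$freqs)
  pos <- core_positions(pwm)
  wts_full <- match_weights(pwm)
  wts_core <- match_weights(pwm, pos)
  ids <- if ("region_id" %in% names(regions)) regions$region_id else
    sprintf("region_%d", seq_len(nrow(regions)))
  hits <- list()
  for (r in seq_len(nrow(regions))) {
    chrom <- regions$chrom[r]
    if (!chrom %in% names(genome))
      stop("chromosome not in genome: ", chrom)
    s0 <- regions$start[r]; e0 <- regions$end[r]
    seq_f <- substr(genome[[chrom]], s0 + 1L, e0)
    if (nchar(seq_f) < L) next
    codes_f <- encode_dna(seq_f)
    for (str in c("+", "-")) {
      codes <- if (str == "+") codes_f else encode_dna(revcomp(seq_f))
      sc <- scan_codes(codes, wts_full, wts_core, pos)
      if (is.null(sc)) next
      pass <- which(!is.na(sc[, "mss"]) & sc[, "mss"] >= matrix_cutoff &
                      sc[, "css"] >= core_cutoff)
      for (w in pass) {
        # w is the 1-based offset in the scanned (possibly revcomp) sequence
        gstart <- if (str == "+") s0 + w - 1L else e0 - (w - 1L) - L
        matched <- if (str == "+")
          substr(seq_f, w, w + L - 1L)
        else substr(as.character(revcomp(seq_f)), w, w + L - 1L)
        hits[[length(hits) + 1L]] <- data.frame(
          region_id = ids[r], matrix = pwm$name, chrom = chrom,
          start = as.integer(gstart), end = as.integer(gstart + L),
          strand = str, core_score = sc[w, "css"],
          matrix_score = sc[w, "mss"], sequence = matched,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(region_id = character(0), matrix = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      core_score = numeric(0), matrix_score = numeric(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
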