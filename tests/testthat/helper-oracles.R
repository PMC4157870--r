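# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (double loops, per-base bitmaps, exhaustive
# enumeration) and share no code with the package internals.

# all-pairs interval intersection, O(n^2)
oracle_intersect_pairs <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    s <- max(a$start[i], b$start[j]); e <- min(a$end[i], b$end[j])
    if (e > s) out[[length(out) + 1L]] <- data.frame(
      chrom = a$chrom[i], start = s, end = e, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start, df$end), ]
  df <- df[!duplicated(paste(df$chrom, df$start, df$end)), ]
  rownames(df) <- NULL
  df
}

# total covered bases of a union of intervals, via a per-base bitmap
oracle_union_coverage <- function(df) {
  tot <- 0L
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    hi <- max(sub$end)
    bit <- logical(hi)
    for (i in seq_len(nrow(sub)))
      bit[(sub$start[i] + 1L):sub$end[i]] <- TRUE
    tot <- tot + sum(bit)
  }
  tot
}

# all FOXA x ERalpha pairs with edge gap < maxd
oracle_dual_pairs <- function(fx, er, maxd) {
  out <- list()
  for (i in seq_len(nrow(fx))) for (j in seq_len(nrow(er))) {
    if (fx$chrom[i] != er$chrom[j]) next
    gap <- max(0L, max(fx$start[i], er$start[j]) -
                 min(fx$end[i], er$end[j]))
    if (gap < maxd) out[[length(out) + 1L]] <- data.frame(
      chrom = fx$chrom[i], fs = fx$start[i], fe = fx$end[i],
      es = er$start[j], ee = er$end[j], gap = gap,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  df <- do.call(rbind, out)
  df[order(df$chrom, df$fs, df$es), ]
}

# Match scores recomputed literally from the published formulas
oracle_match_scores <- function(freqs, window) {
  bases <- c("A", "C", "G", "T")
  freqs <- matrix(as.numeric(freqs), nrow = nrow(freqs), ncol = 4)
  L <- nrow(freqs)
  I <- numeric(L)
  for (i in 1:L) for (b in 1:4)
    if (freqs[i, b] > 0) I[i] <- I[i] + freqs[i, b] * log(4 * freqs[i, b])
  w <- strsplit(window, "")[[1]]
  score_on <- function(pos) {
    cur <- 0; mx <- 0; mn <- 0
    for (i in pos) {
      cur <- cur + I[i] * freqs[i, match(w[i], bases)]
      mx <- mx + I[i] * max(freqs[i, ])
      mn <- mn + I[i] * min(freqs[i, ])
    }
    if (mx == mn) 0 else (cur - mn) / (mx - mn)
  }
  core <- if (L <= 5) 1:L else {
    sums <- sapply(1:(L - 4), function(s) sum(I[s:(s + 4)]))
    s <- which(sums == max(sums))[1]
    s:(s + 4)
  }
  list(mss = score_on(1:L), css = score_on(core), core = core)
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# exhaustive scan of a sequence with an oracle scorer, both strands
oracle_scan <- function(freqs, seq, core_cut, mat_cut) {
  L <- nrow(freqs)
  hits <- list()
  for (str in c("+", "-")) {
    s <- if (str == "+") seq else oracle_revcomp(seq)
    n <- nchar(s) - L + 1
    if (n < 1) next
    for (w in seq_len(n)) {
      win <- substr(s, w, w + L - 1)
      if (grepl("[^ACGT]", win)) next
      sc <- oracle_match_scores(freqs, win)
      if (sc$mss >= mat_cut && sc$css >= core_cut) {
        start <- if (str == "+") w - 1L else nchar(seq) - (w - 1L) - L
        hits[[length(hits) + 1L]] <- data.frame(
          start = start, strand = str, mss = sc$mss, css = sc$css,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(NULL)
  df <- do.call(rbind, hits)
  df[order(df$start, df$strand), ]
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_mw_exact <- function(x, y) {
  vals <- c(x, y); nx <- length(x)
  r <- rank(vals)
  obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2  # observed U for x
  combs <- utils::combn(length(vals), nx)
  us <- apply(combs, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# subject table realizing given genotype-by-status counts per sex
subjects_from_counts <- function(female_cases = NULL, female_controls = NULL,
                                 male_cases = NULL, male_controls = NULL) {
  rows <- list()
  push <- function(counts, status, sex) {
    if (is.null(counts)) return()
    g <- rep(c("CC", "CG", "GG"), counts)
    rows[[length(rows) + 1L]] <<- data.frame(
      id = sprintf("%s%s%04d", substr(status, 1, 2), substr(sex, 1, 1),
                   seq_along(g)),
      status = status, sex = sex, age = 50, smoking = "never",
      drinking = "never", genotype = g, stringsAsFactors = FALSE)
  }
  push(female_cases, "case", "female")
  push(female_controls, "control", "female")
  push(male_cases, "case", "male")
  push(male_controls, "control", "male")
  do.call(rbind, rows)
}

# a deliberately asymmetric toy matrix used in several scan tests
toy_pwm_4 <- function() {
  pwm_from_counts(rbind(c(8, 1, 1, 0),
                        c(0, 6, 2, 2),
                        c(1, 1, 1, 7),
                        c(5, 5, 0, 0)), name = "TOY4")
}

all_windows <- function(L) {
  bases <- c("A", "C", "G", "T")
  apply(expand.grid(rep(list(bases), L)), 1, paste, collapse = "")
}
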