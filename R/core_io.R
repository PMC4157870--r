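#' @importFrom stats pchisq pnorm pt qnorm rbinom rnorm runif setNames
#'   chisq.test glm binomial coef kruskal.test wilcox.test rmultinom sd
#'   t.test vcov median quantile
#' @importFrom utils read.table write.table head
NULL

# ---- Genomic intervals -----------------------------------------------------

#' Construct a table of genomic intervals
#'
#' Intervals follow the BED convention throughout the package: 0-based,
#' half-open `[start, end)`. Strand may be `"+"`, `"-"` or `"."` (unstranded,
#' the usual case for ChIP-seq peaks).
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; `0 <= start < end`.
#' @param strand Character vector in `c("+", "-", ".")`, recycled.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != length(end))
    stop("start and end must have equal length")
  n <- length(start)
  chrom <- rep_len(as.character(chrom), if (n == 0L && length(chrom) == 1L) 0L else n)
  if (length(chrom) != n) stop("chrom and start must have equal length")
  strand <- rep_len(as.character(strand), n)
  if (n > 0) {
    if (any(is.na(start)) || any(is.na(end)))
      stop("interval coordinates must be integers")
    if (any(!nzchar(chrom)) || any(is.na(chrom)))
      stop("chrom must be non-empty")
    if (any(start < 0)) stop("start must be >= 0")
    bad <- which(end <= start)
    if (length(bad))
      stop("invalid interval(s) with end <= start at row(s) ",
           paste(head(bad, 5L), collapse = ", "))
    if (!all(strand %in% c("+", "-", ".")))
      stop("strand must be one of '+', '-', '.'")
  }
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

#' Construct a peak set
#'
#' A peak set is a collection of genomic intervals from one ChIP-seq
#' experiment (or a combination of experiments), labelled with the assayed
#' transcription factor, the cell line and optionally the replicate.
#'
#' @param intervals A data frame as returned by [genomic_intervals()].
#' @param factor Transcription-factor name, e.g. `"FOXA1"`, `"ERalpha"`.
#' @param cell_line Cell line, or `NA` if pooled/unknown.
#' @param replicate Replicate identifier, or `NA`.
#' @return An object of class `peak_set`.
#' @export
peak_set <- function(intervals, factor = NA_character_,
                     cell_line = NA_character_, replicate = NA_character_) {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end") %in% names(intervals)))
  if (is.null(intervals$strand)) intervals$strand <- "."
  intervals <- genomic_intervals(intervals$chrom, intervals$start,
                                 intervals$end, intervals$strand)
  structure(list(intervals = intervals,
                 factor = as.character(factor),
                 cell_line = as.character(cell_line),
                 replicate = as.character(replicate)),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("Peak set: %d interval(s), factor=%s, cell_line=%s, replicate=%s\n",
              nrow(x$intervals), x$factor, x$cell_line, x$replicate))
  invisible(x)
}

#' @export
length.peak_set <- function(x) nrow(x$intervals)

# sort + drop exact duplicate spans; canonical form used by set operations
sort_intervals <- function(df) {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  key <- paste(df$chrom, df$start, df$end)
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# bridge to IRanges/GenomicRanges: BED half-open -> 1-based closed and back
as_granges0 <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}
granges0_as_df <- function(gr, strand = ".") {
  genomic_intervals(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr) - 1L,
                    GenomicRanges::end(gr),
                    strand)
}

# ---- Peak file reading/writing --------------------------------------------

#' Read ChIP-seq peaks from a BED-family file
#'
#' Supports plain BED3, BED6 and ENCODE narrowPeak. In every dialect the
#' interval is taken from the first three columns; BED6/narrowPeak strand is
#' read from column 6. Track and comment lines are skipped. Coordinates are
#' kept as in the file (0-based half-open).
#'
#' @param path Path to the peak file.
#' @param dialect One of `"bed3"`, `"bed6"`, `"narrowPeak"`.
#' @param factor,cell_line,replicate Metadata labels attached to the result.
#' @return A [peak_set()].
#' @export
read_peaks <- function(path, dialect = c("bed3", "bed6", "narrowPeak"),
                       factor = NA_character_, cell_line = NA_character_,
                       replicate = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  min_fields <- switch(dialect, bed3 = 3L, bed6 = 6L, narrowPeak = 10L)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  chrom <- character(0); start <- integer(0); end <- integer(0)
  strand <- character(0)
  idx <- which(keep)
  if (length(idx)) {
    fields <- strsplit(lines[idx], "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf < min_fields)
    if (length(bad))
      stop(sprintf("malformed %s line %d in %s: expected >= %d fields, got %d",
                   dialect, idx[bad[1]], path, min_fields, nf[bad[1]]))
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
    end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
    badc <- which(is.na(start) | is.na(end))
    if (length(badc))
      stop(sprintf("malformed coordinates at line %d in %s", idx[badc[1]], path))
    inv <- which(end <= start)
    if (length(inv))
      stop(sprintf("invalid interval (end <= start) at line %d in %s",
                   idx[inv[1]], path))
    strand <- if (min_fields >= 6L) {
      s <- vapply(fields, `[[`, "", 6L)
      ifelse(s %in% c("+", "-"), s, ".")
    } else rep(".", length(idx))
  }
  peak_set(genomic_intervals(chrom, start, end, strand),
           factor = factor, cell_line = cell_line, replicate = replicate)
}

#' Write a peak set (or interval table) to a BED-family file
#'
#' @param x A [peak_set()] or an interval data frame.
#' @param path Output path.
#' @param dialect Output dialect; narrowPeak pads columns 7-10 with
#'   placeholder values (`0`/`-1`).
#' @param name Optional feature names (column 4); defaults to `"."`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(x, path, dialect = c("bed6", "bed3", "narrowPeak"),
                        name = NULL) {
  dialect <- match.arg(dialect)
  df <- if (inherits(x, "peak_set")) x$intervals else x
  if (is.null(df$strand)) df$strand <- "."
  n <- nrow(df)
  nm <- if (is.null(name)) rep(".", n) else rep_len(name, n)
  out <- switch(dialect,
    bed3 = df[, c("chrom", "start", "end")],
    bed6 = data.frame(df$chrom, df$start, df$end, nm, 0L, df$strand),
    narrowPeak = data.frame(df$chrom, df$start, df$end, nm, 0L, df$strand,
                            0, -1, -1, -1L))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- Gene annotation -------------------------------------------------------

#' Read a gene annotation table
#'
#' Expects a headerless TSV with columns `gene_id`, `chrom`, `start`, `end`,
#' `strand` (0-based half-open gene span). The transcription start site is
#' derived from the strand: `start` for `+` genes, `end - 1` for `-` genes.
#' Duplicate gene ids are kept with a warning.
#'
#' @param path Path to the annotation file.
#' @return A data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE,
                   col.names = c("gene_id", "chrom", "start", "end", "strand"))
  if (!all(df$strand %in% c("+", "-")))
    stop("unknown strand symbol(s): ",
         paste(unique(setdiff(df$strand, c("+", "-"))), collapse = ", "))
  genomic_intervals(df$chrom, df$start, df$end, df$strand)  # validation only
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup))
    warning("duplicate gene_id(s) kept: ", paste(dup, collapse = ", "))
  df$tss <- derive_tss(df$start, df$end, df$strand)
  df
}

#' Transcription start site of a gene span
#'
#' For `+`-strand genes the TSS is the span start; for `-`-strand genes it is
#' `end - 1` (the last base of the half-open span).
#'
#' @param start,end Gene span, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @return Integer vector of 0-based TSS positions.
#' @export
derive_tss <- function(start, end, strand) {
  ifelse(strand == "+", as.integer(start), as.integer(end) - 1L)
}

# ---- SNP catalog -----------------------------------------------------------

#' Read a SNP catalog
#'
#' Headerless TSV with columns `rsid`, `chrom`, `pos` (0-based), `ref`,
#' `alt`, `maf`. A missing or `NA` maf marks the variant's frequency as
#' unknown; such variants are retained. Positions may be converted from
#' 1-based with `one_based = TRUE`.
#'
#' @param path Path to the catalog.
#' @param one_based If `TRUE`, input positions are 1-based and are shifted
#'   down by one.
#' @return A data frame with columns `rsid`, `chrom`, `pos`, `ref`, `alt`,
#'   `maf` (`NA` = unknown).
#' @export
read_snp_table <- function(path, one_based = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE, fill = TRUE,
                    na.strings = c("NA", ".", ""))
  if (ncol(raw) == 5L) raw$V6 <- NA_real_
  if (ncol(raw) != 6L)
    stop("SNP table must have 5 or 6 columns (rsid chrom pos ref alt [maf])")
  names(raw) <- c("rsid", "chrom", "pos", "ref", "alt", "maf")
  raw$pos <- as.integer(raw$pos)
  if (one_based) raw$pos <- raw$pos - 1L
  raw$maf <- as.numeric(raw$maf)
  dup <- unique(raw$rsid[duplicated(raw$rsid)])
  if (length(dup))
    stop("duplicate rsid(s) in catalog: ", paste(dup, collapse = ", "))
  known <- !is.na(raw$maf)
  if (any(raw$maf[known] < 0 | raw$maf[known] > 0.5))
    stop("maf must lie in [0, 0.5] (minor-allele frequency); offending rsid(s): ",
         paste(raw$rsid[known & (raw$maf < 0 | raw$maf > 0.5)], collapse = ", "))
  if (any(raw$pos < 0)) stop("negative position(s) in SNP table")
  raw
}

#' Write a SNP catalog
#' @param snps Data frame as returned by [read_snp_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(snps, path) {
  write.table(snps[, c("rsid", "chrom", "pos", "ref", "alt", "maf")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- TRANSFAC matrices -----------------------------------------------------

#' Read TRANSFAC-format frequency matrices
#'
#' Parses one or more TRANSFAC matrix blocks (`ID`/`NA` name line, a
#' `P0 A C G T` header, numbered per-position count rows, `//` terminator).
#' Each count receives a pseudocount and rows are normalized to base
#' frequencies summing to one.
#'
#' @param path Path to the matrix file.
#' @param pseudo Non-negative pseudocount added to every cell before
#'   normalization. Default 0.
#' @return A list of `pwm` objects: `list(name, freqs, pseudo)` where
#'   `freqs` is an `L x 4` matrix with columns `A`, `C`, `G`, `T`.
#' @export
read_pwm_transfac <- function(path, pseudo = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (pseudo < 0) stop("pseudo must be >= 0")
  lines <- readLines(path)
  pwms <- list()
  name <- NULL; rows <- list()
  flush <- function() {
    if (length(rows)) {
      m <- do.call(rbind, rows)
      pwms[[length(pwms) + 1L]] <<- pwm_from_counts(m,
        name = if (is.null(name)) sprintf("matrix_%d", length(pwms) + 1L) else name,
        pseudo = pseudo)
    }
    name <<- NULL; rows <<- list()
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (grepl("^//", ln)) { flush(); next }
    if (grepl("^(ID|NA)\\s+", ln)) {
      if (is.null(name)) name <- sub("^(ID|NA)\\s+", "", ln)
      next
    }
    if (grepl("^P[0O]\\b", ln)) next
    if (grepl("^[0-9]+\\s", ln)) {
      parts <- strsplit(ln, "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(parts[2:5]))
      if (any(is.na(vals)))
        stop(sprintf("malformed matrix row at line %d in %s", i, path))
      rows[[length(rows) + 1L]] <- vals
    }
  }
  flush()
  if (!length(pwms)) stop("no matrix blocks found in ", path)
  pwms
}

#' Build a position-weight matrix from counts
#'
#' @param counts `L x 4` non-negative matrix (columns A, C, G, T).
#' @param name Matrix identifier.
#' @param pseudo Pseudocount added per cell before row normalization.
#' @return A `pwm` object.
#' @export
pwm_from_counts <- function(counts, name = "pwm", pseudo = 0) {
  counts <- as.matrix(counts) + pseudo
  if (ncol(counts) != 4L) stop("counts must have 4 columns (A C G T)")
  if (any(counts < 0)) stop("negative matrix cell")
  tot <- rowSums(counts)
  if (any(tot <= 0))
    stop("matrix row(s) with non-positive total: ",
         paste(which(tot <= 0), collapse = ", "))
  freqs <- counts / tot
  dimnames(freqs) <- list(NULL, c("A", "C", "G", "T"))
  structure(list(name = name, freqs = freqs, pseudo = pseudo), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': %d positions (pseudocount %g)\n", x$name,
              nrow(x$freqs), x$pseudo))
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM (per-position argmax base, ties -> first)
#' @param pwm A `pwm` object.
#' @return Character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste(colnames(pwm$freqs)[apply(pwm$freqs, 1L, which.max)], collapse = "")
}

#' Write matrices in TRANSFAC format
#' @param pwms List of `pwm` objects (or one `pwm`).
#' @param path Output path.
#' @param counts_scale Counts written as `round(freq * counts_scale)`.
#' @return `path`, invisibly.
#' @export
write_pwm_transfac <- function(pwms, path, counts_scale = 100) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w"); on.exit(close(con))
  for (p in pwms) {
    writeLines(c(sprintf("ID %s", p$name), "P0      A      C      G      T"), con)
    m <- round(p$freqs * counts_scale)
    for (i in seq_len(nrow(m)))
      writeLines(sprintf("%02d %6d %6d %6d %6d", i, m[i, 1], m[i, 2],
                         m[i, 3], m[i, 4]), con)
    writeLines("//", con)
  }
  invisible(path)
}

# ---- FASTA -----------------------------------------------------------------

#' Read a genome FASTA into a named character vector
#' @param path FASTA path.
#' @return Named character vector of upper-case sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
}

#' Write sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
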