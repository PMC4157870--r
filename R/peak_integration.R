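# Combining replicate, cross-cell-line and cross-factor ChIP-seq peak sets
# into the two TFBS datasets (FOXA, ERalpha) that feed dual-target detection.

#' Overlap-select peaks across two replicates
#'
#' For every pair of peaks (one from each replicate) sharing at least one
#' base, the retained region is by default their intersection span — the
#' conservative reading of selecting "overlapping peak locations". With
#' `keep = "union"` the merged span of the pair is kept instead.
#'
#' @param a,b [peak_set()]s from the same factor and cell line.
#' @param keep `"intersection"` (default) or `"union"`: which span to retain
#'   for an overlapping pair.
#' @return A [peak_set()] of the retained spans, sorted and deduplicated,
#'   with `replicate` set to `"merged"`.
#' @export
intersect_replicates <- function(a, b, keep = c("intersection", "union")) {
  keep <- match.arg(keep)
  stopifnot(inherits(a, "peak_set"), inherits(b, "peak_set"))
  if (!identical(a$factor, b$factor))
    stop("replicates must come from the same factor (got ",
         a$factor, " vs ", b$factor, ")")
  if (!identical(a$cell_line, b$cell_line))
    stop("replicates must come from the same cell line (got ",
         a$cell_line, " vs ", b$cell_line, ")")
  if (nrow(a$intervals) == 0L || nrow(b$intervals) == 0L)
    return(peak_set(genomic_intervals(character(0), integer(0), integer(0)),
                    factor = a$factor, cell_line = a$cell_line,
                    replicate = "merged"))
  ga <- as_granges0(a$intervals); gb <- as_granges0(b$intervals)
  ov <- GenomicRanges::findOverlaps(ga, gb, minoverlap = 1L)
  spans <- if (keep == "intersection") {
    GenomicRanges::pintersect(ga[S4Vectors::queryHits(ov)],
                              gb[S4Vectors::subjectHits(ov)])
  } else {
    GenomicRanges::punion(ga[S4Vectors::queryHits(ov)],
                          gb[S4Vectors::subjectHits(ov)], fill.gap = TRUE)
  }
  peak_set(sort_intervals(granges0_as_df(spans)),
           factor = a$factor, cell_line = a$cell_line, replicate = "merged")
}

#' Pool peak sets into one merged set
#'
#' Concatenates the sets (used for independent experiments, e.g. ERalpha in
#' two cell lines) and merges overlapping or bookended intervals into
#' maximal contiguous spans.
#'
#' @param sets Non-empty list of [peak_set()]s sharing a factor label.
#' @return A merged, sorted [peak_set()].
#' @export
union_peak_sets <- function(sets) {
  if (!is.list(sets) || length(sets) == 0L)
    stop("sets must be a non-empty list of peak sets")
  stopifnot(all(vapply(sets, inherits, TRUE, "peak_set")))
  facs <- unique(vapply(sets, `[[`, "", "factor"))
  if (length(facs) > 1L)
    stop("cannot union sets with different factors: ",
         paste(facs, collapse = ", "))
  cls <- unique(vapply(sets, `[[`, "", "cell_line"))
  all_df <- do.call(rbind, lapply(sets, `[[`, "intervals"))
  if (nrow(all_df) == 0L)
    return(peak_set(all_df, factor = facs,
                    cell_line = if (length(cls) == 1L) cls else "pooled"))
  # reduce() merges overlapping ranges and, by default, bookended ones too
  merged <- GenomicRanges::reduce(as_granges0(all_df))
  peak_set(sort_intervals(granges0_as_df(merged)), factor = facs,
           cell_line = if (length(cls) == 1L) cls else "pooled")
}

#' Combine FOXA1 and FOXA2 peaks into one FOXA set
#'
#' FOXA1 and FOXA2 bind largely redundantly in liver, so their peak sets are
#' pooled (union with merging) into a single set labelled `"FOXA"`.
#'
#' @param foxa1,foxa2 [peak_set()]s in the same coordinate system.
#' @return A merged [peak_set()] with factor `"FOXA"`.
#' @export
combine_factors <- function(foxa1, foxa2) {
  stopifnot(inherits(foxa1, "peak_set"), inherits(foxa2, "peak_set"))
  f1 <- foxa1; f2 <- foxa2
  f1$factor <- "FOXA"; f2$factor <- "FOXA"
  union_peak_sets(list(f1, f2))
}
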