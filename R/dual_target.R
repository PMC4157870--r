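# Dual-target detection: pairs of FOXA and ERalpha peaks lying closer than a
# distance threshold, interpreted as co-regulated regions, then restricted to
# gene promoter windows.

#' Find FOXA/ERalpha dual-target regions
#'
#' Reports one region per (FOXA peak, ERalpha peak) pair on the same
#' chromosome whose edge-to-edge gap is strictly less than `max_distance`
#' (overlapping pairs have distance 0). The region is the merged span of the
#' two peaks. Pairs are reported individually unless `merge = TRUE`, in
#' which case overlapping/bookended regions are collapsed afterwards (the
#' `distance` and peak columns then refer to the closest contributing pair).
#'
#' @param foxa,era [peak_set()]s for FOXA and ERalpha.
#' @param max_distance Maximum gap in bp (strict `<`); default 250.
#' @param merge Collapse overlapping dual regions? Default `FALSE`.
#' @param summit If `TRUE`, distance is measured between interval midpoints
#'   instead of edges.
#' @return A data frame of class `dual_targets` with columns `region_id`,
#'   `chrom`, `start`, `end`, `foxa_start`, `foxa_end`, `era_start`,
#'   `era_end`, `distance`, `genes` (empty until
#'   [intersect_with_promoters()]).
#' @export
find_dual_targets <- function(foxa, era, max_distance = 250, merge = FALSE,
                              summit = FALSE) {
  stopifnot(inherits(foxa, "peak_set"), inherits(era, "peak_set"))
  if (max_distance < 0) stop("max_distance must be >= 0")
  fi <- foxa$intervals; ei <- era$intervals
  empty <- data.frame(region_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      foxa_start = integer(0), foxa_end = integer(0),
                      era_start = integer(0), era_end = integer(0),
                      distance = integer(0), genes = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("dual_targets", "data.frame")
  if (nrow(fi) == 0L || nrow(ei) == 0L) return(empty)
  if (summit) {
    fm <- (fi$start + fi$end) %/% 2L
    em <- (ei$start + ei$end) %/% 2L
    gf <- GenomicRanges::GRanges(fi$chrom, IRanges::IRanges(fm + 1L, fm + 1L))
    ge <- GenomicRanges::GRanges(ei$chrom, IRanges::IRanges(em + 1L, em + 1L))
  } else {
    gf <- as_granges0(fi); ge <- as_granges0(ei)
  }
  # gap < max_distance <=> gap <= max_distance - 1 = maxgap
  ov <- GenomicRanges::findOverlaps(gf, ge,
                                    maxgap = as.integer(max_distance) - 1L,
                                    minoverlap = 0L)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  if (length(qi) == 0L) return(empty)
  dist <- pmax(0L, pmax(fi$start[qi], ei$start[si]) -
                    pmin(fi$end[qi], ei$end[si]))
  if (summit) {
    fm <- (fi$start + fi$end) %/% 2L
    em <- (ei$start + ei$end) %/% 2L
    dist <- abs(fm[qi] - em[si])
    keepd <- dist < max_distance
    qi <- qi[keepd]; si <- si[keepd]; dist <- dist[keepd]
    if (length(qi) == 0L) return(empty)
  }
  out <- data.frame(
    chrom = fi$chrom[qi],
    start = pmin(fi$start[qi], ei$start[si]),
    end = pmax(fi$end[qi], ei$end[si]),
    foxa_start = fi$start[qi], foxa_end = fi$end[qi],
    era_start = ei$start[si], era_end = ei$end[si],
    distance = as.integer(dist), genes = "",
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end, out$era_start), , drop = FALSE]
  if (merge) {
    red <- GenomicRanges::reduce(as_granges0(out))
    rdf <- granges0_as_df(red)
    hit <- GenomicRanges::findOverlaps(as_granges0(out), red)
    grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    best <- vapply(split(seq_len(nrow(out)), grp),
                   function(ix) ix[which.min(out$distance[ix])], 1L)
    out <- data.frame(chrom = rdf$chrom, start = rdf$start, end = rdf$end,
                      foxa_start = out$foxa_start[best],
                      foxa_end = out$foxa_end[best],
                      era_start = out$era_start[best],
                      era_end = out$era_end[best],
                      distance = out$distance[best], genes = "",
                      stringsAsFactors = FALSE)
  }
  out <- cbind(region_id = sprintf("dual_%05d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("dual_targets", "data.frame")
  out
}

#' Promoter windows upstream of gene TSSs
#'
#' The promoter is the `upstream` bp strictly upstream of the transcription
#' start site: `[tss - upstream, tss)` for `+` genes and
#' `[tss + 1, tss + 1 + upstream)` for `-` genes, clipped at position 0.
#'
#' @param genes Data frame as from [read_gene_annotation()] (needs columns
#'   `gene_id`, `chrom`, `strand`, `tss`).
#' @param upstream Window size in bp; default 5000.
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
promoters_from_genes <- function(genes, upstream = 5000) {
  if (upstream <= 0) stop("upstream must be > 0")
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(0L, genes$tss - as.integer(upstream)),
                  genes$tss + 1L)
  end <- ifelse(plus, genes$tss, genes$tss + 1L + as.integer(upstream))
  keep <- end > start  # a + gene with tss == 0 has an empty promoter
  data.frame(gene_id = genes$gene_id[keep], chrom = genes$chrom[keep],
             start = as.integer(start[keep]), end = as.integer(end[keep]),
             stringsAsFactors = FALSE)
}

#' Restrict dual-target regions to those overlapping promoters
#'
#' Keeps dual regions overlapping at least one promoter window by >= 1 bp
#' (full or partial overlap) and records the overlapping gene ids in the
#' `genes` column (comma-separated).
#'
#' @param duals Result of [find_dual_targets()].
#' @param promoters Result of [promoters_from_genes()].
#' @return Filtered `dual_targets` data frame with `genes` populated.
#' @export
intersect_with_promoters <- function(duals, promoters) {
  if (nrow(duals) == 0L || nrow(promoters) == 0L) {
    out <- duals[integer(0), , drop = FALSE]
    class(out) <- c("dual_targets", "data.frame")
    return(out)
  }
  gd <- as_granges0(duals)
  gp <- as_granges0(promoters)
  ov <- GenomicRanges::findOverlaps(gd, gp, minoverlap = 1L)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  genes_by_dual <- split(promoters$gene_id[si], qi)
  keep <- as.integer(names(genes_by_dual))
  out <- duals[keep, , drop = FALSE]
  out$genes <- vapply(genes_by_dual,
                      function(g) paste(unique(g), collapse = ","), "")
  rownames(out) <- NULL
  class(out) <- c("dual_targets", "data.frame")
  out
}
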