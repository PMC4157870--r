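# Final prioritization stages: intersect the SNP catalog with predicted
# binding elements and apply the common-variant (MAF) filter; run_pipeline()
# chains all stages and emits a stage-count report.

#' Variants falling inside predicted binding elements
#'
#' Emits one candidate per (variant, TFBE) pair where the variant position
#' lies inside the element's half-open span. A variant overlapping two
#' elements yields two candidate rows; deduplicate by `rsid` downstream if
#' needed.
#'
#' @param catalog SNP data frame (see [read_snp_table()]).
#' @param tfbes TFBE hit table (see [scan_pwm()]).
#' @param duals Optional `dual_targets` table used to attach the host
#'   region's promoter gene ids.
#' @return Data frame of candidates: `rsid`, `chrom`, `pos`, `ref`, `alt`,
#'   `maf`, `region_id`, `matrix`, `tfbe_start`, `tfbe_end`, `strand`,
#'   `core_score`, `matrix_score`, `gene_ids`, `is_common` (`NA` until
#'   [filter_common()] sets the threshold; here `maf > 0.05`).
#' @export
variants_in_tfbes <- function(catalog, tfbes, duals = NULL) {
  empty <- data.frame(rsid = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), maf = numeric(0),
                      region_id = character(0), matrix = character(0),
                      tfbe_start = integer(0), tfbe_end = integer(0),
                      strand = character(0), core_score = numeric(0),
                      matrix_score = numeric(0), gene_ids = character(0),
                      is_common = logical(0), stringsAsFactors = FALSE)
  if (nrow(catalog) == 0L || nrow(tfbes) == 0L) return(empty)
  gv <- GenomicRanges::GRanges(catalog$chrom,
                               IRanges::IRanges(catalog$pos + 1L,
                                                catalog$pos + 1L))
  gt <- GenomicRanges::GRanges(tfbes$chrom,
                               IRanges::IRanges(tfbes$start + 1L, tfbes$end))
  ov <- GenomicRanges::findOverlaps(gv, gt)
  vi <- S4Vectors::queryHits(ov); ti <- S4Vectors::subjectHits(ov)
  if (length(vi) == 0L) return(empty)
  gene_ids <- rep("", length(ti))
  if (!is.null(duals) && nrow(duals) > 0L) {
    m <- match(tfbes$region_id[ti], duals$region_id)
    gene_ids <- ifelse(is.na(m), "", duals$genes[m])
  }
  out <- data.frame(rsid = catalog$rsid[vi], chrom = catalog$chrom[vi],
                    pos = catalog$pos[vi], ref = catalog$ref[vi],
                    alt = catalog$alt[vi], maf = catalog$maf[vi],
                    region_id = tfbes$region_id[ti], matrix = tfbes$matrix[ti],
                    tfbe_start = tfbes$start[ti], tfbe_end = tfbes$end[ti],
                    strand = tfbes$strand[ti],
                    core_score = tfbes$core_score[ti],
                    matrix_score = tfbes$matrix_score[ti],
                    gene_ids = gene_ids,
                    is_common = !is.na(catalog$maf[vi]) &
                      catalog$maf[vi] > 0.05,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$tfbe_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep common variants (MAF strictly above a threshold)
#'
#' Candidates with unknown MAF are dropped; the number dropped is reported
#' in a message.
#'
#' @param cands Candidate table from [variants_in_tfbes()].
#' @param maf_threshold Threshold in `[0, 0.5]`; strict `>`. Default 0.05.
#' @return Filtered candidate table with `is_common = TRUE` throughout.
#' @export
filter_common <- function(cands, maf_threshold = 0.05) {
  if (maf_threshold < 0 || maf_threshold > 0.5)
    stop("maf_threshold must lie in [0, 0.5]")
  unknown <- is.na(cands$maf)
  if (any(unknown))
    message(sum(unknown), " candidate(s) with unknown MAF dropped")
  out <- cands[!unknown & cands$maf > maf_threshold, , drop = FALSE]
  out$is_common <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Run the full variant-prioritization pipeline
#'
#' Executes: replicate overlap selection per factor and cell line ->
#' cross-cell-line pooling -> FOXA1+FOXA2 combination -> dual-target
#' detection -> promoter intersection -> PWM scanning -> SNP intersection ->
#' common-variant filter. Deterministic given its inputs.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{foxa1_replicates, foxa2_replicates}{Lists of [peak_set()]s (or
#'       single sets) of replicate peaks; replicates are overlap-selected,
#'       a single set is used as is.}
#'     \item{era_sets}{List of ERalpha [peak_set()]s, one per cell line (or
#'       list of per-cell-line replicate lists), pooled by union.}
#'     \item{genes}{Gene annotation data frame.}
#'     \item{pwms}{List of `pwm` objects (FOXA matrices).}
#'     \item{snps}{SNP catalog data frame.}
#'     \item{genome}{Named character vector of sequences.}
#'     \item{max_distance, upstream, core_cutoff, matrix_cutoff,
#'       maf_threshold}{Parameters; defaults 250, 5000, 0.75, 0.85, 0.05.}
#'     \item{merge_dual}{Merge overlapping dual regions? Default `FALSE`.}
#'   }
#' @param out_dir Optional directory; when given, the report (JSON), the
#'   candidate table (TSV) and intermediate BED files are written there.
#' @return An object of class `pipeline_report`: a list with `report` (stage
#'   counts + parameters), `candidates` (common candidates),
#'   `all_candidates`, `tfbes`, `duals_promoter`, `foxa`, `era`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  p <- function(name, default) if (is.null(config[[name]])) default else config[[name]]
  max_distance <- p("max_distance", 250)
  upstream <- p("upstream", 5000)
  core_cutoff <- p("core_cutoff", 0.75)
  matrix_cutoff <- p("matrix_cutoff", 0.85)
  maf_threshold <- p("maf_threshold", 0.05)
  merge_dual <- p("merge_dual", FALSE)

  collapse_reps <- function(x, label) {
    if (inherits(x, "peak_set")) return(x)
    if (!is.list(x) || !length(x)) stop("empty replicate list for ", label)
    Reduce(intersect_replicates, x)  # >2 replicates fold left
  }
  foxa1 <- collapse_reps(config$foxa1_replicates, "FOXA1")
  foxa2 <- collapse_reps(config$foxa2_replicates, "FOXA2")
  foxa <- combine_factors(foxa1, foxa2)

  era_sets <- config$era_sets
  if (inherits(era_sets, "peak_set")) era_sets <- list(era_sets)
  era_sets <- lapply(era_sets, function(x)
    if (inherits(x, "peak_set")) x else collapse_reps(x, "ERalpha"))
  era <- union_peak_sets(era_sets)

  duals <- find_dual_targets(foxa, era, max_distance = max_distance,
                             merge = merge_dual)
  promoters <- promoters_from_genes(config$genes, upstream = upstream)
  duals_prom <- intersect_with_promoters(duals, promoters)

  tfbes <- do.call(rbind, lapply(config$pwms, scan_pwm,
                                 regions = duals_prom,
                                 genome = config$genome,
                                 core_cutoff = core_cutoff,
                                 matrix_cutoff = matrix_cutoff))
  if (is.null(tfbes))
    tfbes <- scan_pwm(pwm_from_counts(matrix(1, 1, 4)),
                      duals_prom[integer(0), ], config$genome)

  cands <- variants_in_tfbes(config$snps, tfbes, duals_prom)
  common <- filter_common(cands, maf_threshold)

  report <- list(
    n_foxa_peaks = nrow(foxa$intervals),
    n_era_peaks = nrow(era$intervals),
    n_dual = nrow(duals),
    n_dual_promoter = nrow(duals_prom),
    n_tfbe = nrow(tfbes),
    n_variants = length(unique(cands$rsid)),
    n_common = length(unique(common$rsid)),
    parameters = list(max_distance = max_distance, upstream = upstream,
                      core_cutoff = core_cutoff,
                      matrix_cutoff = matrix_cutoff,
                      maf_threshold = maf_threshold,
                      merge_dual = merge_dual))
  res <- structure(list(report = report, candidates = common,
                        all_candidates = cands, tfbes = tfbes,
                        duals_promoter = duals_prom, foxa = foxa, era = era),
                   class = "pipeline_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.table(common, file.path(out_dir, "candidates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_peaks(foxa, file.path(out_dir, "foxa.bed"))
    write_peaks(era, file.path(out_dir, "era.bed"))
    write_peaks(duals_prom[, c("chrom", "start", "end")],
                file.path(out_dir, "dual_promoter.bed"),
                name = duals_prom$region_id)
  }
  res
}

#' @export
print.pipeline_report <- function(x, ...) {
  r <- x$report
  cat("FOXA/ERalpha dual-site variant prioritization\n")
  cat(sprintf("  FOXA peaks (combined):          %d\n", r$n_foxa_peaks))
  cat(sprintf("  ERalpha peaks (pooled):         %d\n", r$n_era_peaks))
  cat(sprintf("  dual-target regions (< %g bp):  %d\n",
              r$parameters$max_distance, r$n_dual))
  cat(sprintf("  ... overlapping promoters:      %d\n", r$n_dual_promoter))
  cat(sprintf("  FOXA binding elements (TFBEs):  %d\n", r$n_tfbe))
  cat(sprintf("  variants in TFBEs:              %d\n", r$n_variants))
  cat(sprintf("  common variants (MAF > %g):     %d\n",
              r$parameters$maf_threshold, r$n_common))
  invisible(x)
}
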