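# Genotype-stratified qPCR relative expression by the 2^-dCt method, with
# duplicate-CV quality control and rank-based group comparisons.

#' Per-sample relative expression from qPCR Ct values
#'
#' Replicate Ct values are averaged per sample and gene;
#' `dCt = mean Ct(target) - mean Ct(reference)` and relative expression is
#' `2^-dCt`. The coefficient of variation of the replicate Ct values is
#' computed per gene (SD/mean of Ct by default, or of the linearized
#' `2^-Ct` values) and samples whose CV exceeds `cv_threshold` percent on
#' either gene are flagged `high_cv` — the convention that such samples are
#' re-assayed.
#'
#' @param records Data frame with columns `sample_id`, `genotype`,
#'   `ct_target`, `ct_reference`, `replicate` (and optionally `sex`).
#' @param cv_threshold CV threshold in percent; default 5.
#' @param cv_on `"ct"` (default) or `"linear"` (CV of `2^-Ct`).
#' @return Data frame of class `relative_expression`: `sample_id`,
#'   `genotype`, (`sex`,) `delta_ct`, `rel_expr`, `cv_target`, `cv_ref`,
#'   `qc_flag`.
#' @export
relative_expression <- function(records, cv_threshold = 5,
                                cv_on = c("ct", "linear")) {
  cv_on <- match.arg(cv_on)
  need <- c("sample_id", "genotype", "ct_target", "ct_reference")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  bad_ct <- c(records$ct_target, records$ct_reference)
  if (any(is.na(records$ct_reference)))
    stop("missing reference Ct for sample(s): ",
         paste(unique(records$sample_id[is.na(records$ct_reference)]),
               collapse = ", "))
  if (any(is.na(bad_ct)) || any(bad_ct <= 0 | bad_ct > 45))
    stop("Ct values must lie in (0, 45]")
  cv <- function(x) {
    if (length(x) < 2L) return(0)
    100 * sd(x) / mean(x)
  }
  sp <- split(records, records$sample_id)
  rows <- lapply(sp, function(r) {
    tgt <- r$ct_target; ref <- r$ct_reference
    cvt <- if (cv_on == "ct") cv(tgt) else cv(2^-tgt)
    cvr <- if (cv_on == "ct") cv(ref) else cv(2^-ref)
    d <- mean(tgt) - mean(ref)
    data.frame(sample_id = r$sample_id[1], genotype = r$genotype[1],
               sex = if ("sex" %in% names(r)) r$sex[1] else NA_character_,
               delta_ct = d, rel_expr = 2^-d,
               cv_target = cvt, cv_ref = cvr,
               qc_flag = if (max(cvt, cvr) > cv_threshold) "high_cv" else
                 "pass",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("relative_expression", "data.frame")
  out
}

# two-sided Mann-Whitney: exact for small combined n without ties, normal
# approximation with tie and continuity correction otherwise
mw_test <- function(x, y, exact_max_n = 20) {
  exact <- (length(x) + length(y)) <= exact_max_n &&
    !any(duplicated(c(x, y)))
  suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))$p.value
}

#' Compare expression between genotype groups
#'
#' Kruskal-Wallis rank test (tie-corrected) across all genotype groups with
#' at least `min_n` samples, plus pairwise two-sided Mann-Whitney tests for
#' each genotype pair and, when a `sex` column is present, male vs female.
#' Pairs with a group below `min_n` are skipped with a warning. If every
#' value is tied the Kruskal-Wallis p is reported as 1 with a warning.
#'
#' @param values A [relative_expression()] table (or any data frame with
#'   `rel_expr` and `genotype`).
#' @param min_n Minimum group size; default 2.
#' @param exact_max_n Combined-n bound for the exact Mann-Whitney; default
#'   20.
#' @return List of class `expression_tests`: `kw_p`, `kw_chi2`,
#'   `pairwise_mw_p` (named vector), `sex_mw_p` (or `NA`), `group_n`.
#' @export
group_compare <- function(values, min_n = 2, exact_max_n = 20) {
  g <- as.character(values$genotype)
  x <- values$rel_expr
  tabn <- table(g)
  use <- names(tabn)[tabn >= min_n]
  if (length(use) < 2L) stop("need >= 2 genotype groups with >= ", min_n,
                             " samples")
  keep <- g %in% use
  if (length(unique(x[keep])) == 1L) {
    warning("all expression values tied; Kruskal-Wallis degenerate, p = 1")
    kw_p <- 1; kw_chi2 <- 0
  } else {
    kw <- kruskal.test(x[keep], factor(g[keep]))
    kw_p <- kw$p.value; kw_chi2 <- unname(kw$statistic)
  }
  lv <- sort(unique(g))
  pairs <- utils::combn(lv, 2L, simplify = FALSE)
  mw <- vapply(pairs, function(pr) {
    if (any(tabn[pr] < min_n)) {
      warning("group(s) below min_n; skipping ", paste(pr, collapse = " vs "))
      return(NA_real_)
    }
    mw_test(x[g == pr[1]], x[g == pr[2]], exact_max_n)
  }, 0)
  names(mw) <- vapply(pairs, paste, "", collapse = "_vs_")
  sex_p <- NA_real_
  if ("sex" %in% names(values) && !all(is.na(values$sex))) {
    sx <- values$sex
    if (sum(sx == "male", na.rm = TRUE) >= min_n &&
        sum(sx == "female", na.rm = TRUE) >= min_n)
      sex_p <- mw_test(x[sx == "male" & !is.na(sx)],
                       x[sx == "female" & !is.na(sx)], exact_max_n)
  }
  structure(list(kw_p = kw_p, kw_chi2 = kw_chi2, pairwise_mw_p = mw,
                 sex_mw_p = sex_p, group_n = as.integer(tabn)),
            class = "expression_tests")
}

#' @export
print.expression_tests <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis across genotypes: p = %.3g\n", x$kw_p))
  for (nm in names(x$pairwise_mw_p))
    cat(sprintf("  Mann-Whitney %s: p = %.3g\n", nm, x$pairwise_mw_p[nm]))
  if (!is.na(x$sex_mw_p))
    cat(sprintf("  Mann-Whitney male vs female: p = %.3g\n", x$sex_mw_p))
  invisible(x)
}

#' Scatter plot of relative expression by genotype
#'
#' Vertical scatter of per-sample `2^-dCt` values per genotype group with a
#' horizontal segment at each group median.
#'
#' @param x A [relative_expression()] table.
#' @param ... Passed to [graphics::stripchart()].
#' @return `x`, invisibly.
#' @export
plot.relative_expression <- function(x, ...) {
  g <- factor(x$genotype)
  graphics::stripchart(x$rel_expr ~ g, vertical = TRUE, method = "jitter",
                       pch = 1, ylab = "relative expression (2^-dCt)",
                       xlab = "genotype", ...)
  med <- tapply(x$rel_expr, g, median)
  for (i in seq_along(med))
    graphics::segments(i - 0.2, med[i], i + 0.2, med[i], lwd = 2)
  invisible(x)
}
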