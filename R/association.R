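# Case-control association toolkit: genotype tabulation, Hardy-Weinberg
# equilibrium, crude and covariate-adjusted odds ratios under four genetic
# models, overall and sex-stratified, demographics comparison and a Wald
# power approximation.

GENO_LEVELS <- c("CC", "CG", "GG")

#' Bundle genotype-by-status counts
#'
#' @param cases,controls Length-3 integer vectors of genotype counts
#'   (hom-ref, het, hom-alt).
#' @param labels Genotype labels; default `c("CC","CG","GG")`.
#' @param stratum Label, e.g. `"overall"`, `"male"`, `"female"`.
#' @return An object of class `genotype_counts`.
#' @export
genotype_counts <- function(cases, controls, labels = GENO_LEVELS,
                            stratum = "overall") {
  stopifnot(length(cases) == 3L, length(controls) == 3L,
            all(cases >= 0), all(controls >= 0))
  structure(list(cases = setNames(as.integer(cases), labels),
                 controls = setNames(as.integer(controls), labels),
                 labels = labels, stratum = stratum),
            class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("Genotype counts (%s):\n", x$stratum))
  print(rbind(cases = x$cases, controls = x$controls))
  invisible(x)
}

#' Tabulate genotypes by case-control status within a stratum
#'
#' Subjects with missing genotype are excluded (a message reports how many).
#'
#' @param subjects Data frame with columns `status` (`"case"`/`"control"`),
#'   `sex` (`"male"`/`"female"`) and `genotype` (levels of `genotypes`, `NA`
#'   = missing).
#' @param stratum `"overall"`, `"male"` or `"female"`.
#' @param genotypes Genotype level labels, hom-ref / het / hom-alt order.
#' @return A [genotype_counts()].
#' @export
tabulate_genotypes <- function(subjects, stratum = c("overall", "male",
                                                     "female"),
                               genotypes = GENO_LEVELS) {
  stratum <- match.arg(stratum)
  s <- subjects
  if (stratum != "overall") s <- s[s$sex == stratum, , drop = FALSE]
  if (nrow(s) == 0L) stop("no subjects in stratum '", stratum, "'")
  miss <- is.na(s$genotype) | !(s$genotype %in% genotypes)
  if (all(miss)) stop("all genotypes missing in stratum '", stratum, "'")
  if (any(miss)) message(sum(miss), " subject(s) with missing genotype excluded")
  s <- s[!miss, , drop = FALSE]
  g <- factor(s$genotype, levels = genotypes)
  genotype_counts(table(g[s$status == "case"]),
                  table(g[s$status == "control"]),
                  labels = genotypes, stratum = stratum)
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' Estimates the allele frequency from the genotype counts, forms expected
#' counts `(N p^2, 2 N p q, N q^2)` and compares by a 1-df chi-square
#' goodness-of-fit test. Conventionally applied to the control group.
#'
#' @param counts Length-3 genotype counts (hom-ref, het, hom-alt), or a
#'   [genotype_counts()] (its `controls` slot is used).
#' @return List of class `hwe_result`: `chi2`, `df`, `p_value`,
#'   `expected_counts`, `allele_freq` (ref allele).
#' @export
hwe_test <- function(counts) {
  if (inherits(counts, "genotype_counts")) counts <- counts$controls
  o <- as.numeric(counts)
  stopifnot(length(o) == 3L, all(o >= 0))
  N <- sum(o)
  if (N <= 0) stop("empty genotype counts")
  p <- (2 * o[1] + o[2]) / (2 * N)
  q <- 1 - p
  if (p == 0 || p == 1) {
    warning("monomorphic marker: HWE test degenerate")
    e <- N * c(p^2, 2 * p * q, q^2)
    return(structure(list(chi2 = 0, df = 1L, p_value = 1,
                          expected_counts = e, allele_freq = p),
                     class = "hwe_result"))
  }
  e <- N * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((o - e)^2 / e)
  structure(list(chi2 = chi2, df = 1L,
                 p_value = pchisq(chi2, 1L, lower.tail = FALSE),
                 expected_counts = e, allele_freq = p),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE goodness-of-fit: chi2 = %.4g (df = 1), p = %.3f\n",
              x$chi2, x$p_value))
  invisible(x)
}

#' Odds ratio with Woolf confidence interval from a 2x2 table
#'
#' `OR = ad / bc` with the Woolf log-scale CI
#' `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`; for one binary
#' predictor this equals the logistic-regression ML estimate and Wald CI.
#' Tables with a zero cell receive the Haldane-Anscombe 0.5 correction and
#' are flagged.
#'
#' @param a Exposed cases.
#' @param b Unexposed cases.
#' @param c Exposed controls.
#' @param d Unexposed controls.
#' @param conf_level Confidence level; default 0.95.
#' @return List: `or`, `ci_lo`, `ci_hi`, `p_value` (two-sided Wald),
#'   `corrected` (zero-cell flag).
#' @export
odds_ratio_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(or = or,
       ci_lo = exp(log(or) - z * se),
       ci_hi = exp(log(or) + z * se),
       p_value = 2 * pnorm(-abs(log(or) / se)),
       corrected = corrected)
}

#' Recode genotype counts under a genetic model
#'
#' * `genotype`: two 2x2 contrasts, het vs hom-ref and hom-alt vs hom-ref;
#' * `dominant`: carriers (het + hom-alt) vs hom-ref;
#' * `recessive`: hom-alt vs (hom-ref + het);
#' * `additive`: per-subject allele dosage 0/1/2 (returned as counts by
#'   dosage for cases and controls).
#'
#' @param counts A [genotype_counts()].
#' @param model One of `"genotype"`, `"additive"`, `"dominant"`,
#'   `"recessive"`.
#' @return For 2x2 models, a list of contrasts, each
#'   `list(label, a, b, c, d)` with `a`/`c` = exposed cases/controls and
#'   `b`/`d` = unexposed; for `additive`, `list(label, dosage, case_counts,
#'   control_counts)`.
#' @export
model_recode <- function(counts, model = c("genotype", "additive",
                                           "dominant", "recessive")) {
  model <- match.arg(model)
  ca <- counts$cases; co <- counts$controls; lb <- counts$labels
  switch(model,
    genotype = list(
      list(label = paste(lb[2], "vs", lb[1]),
           a = ca[[2]], b = ca[[1]], c = co[[2]], d = co[[1]]),
      list(label = paste(lb[3], "vs", lb[1]),
           a = ca[[3]], b = ca[[1]], c = co[[3]], d = co[[1]])),
    dominant = list(
      list(label = sprintf("%s+%s vs %s", lb[2], lb[3], lb[1]),
           a = ca[[2]] + ca[[3]], b = ca[[1]],
           c = co[[2]] + co[[3]], d = co[[1]])),
    recessive = list(
      list(label = sprintf("%s vs %s+%s", lb[3], lb[1], lb[2]),
           a = ca[[3]], b = ca[[1]] + ca[[2]],
           c = co[[3]], d = co[[1]] + co[[2]])),
    additive = list(
      list(label = "per-allele", dosage = 0:2,
           case_counts = as.integer(ca), control_counts = as.integer(co))))
}

#' Maximum-likelihood logistic regression with Wald summaries
#'
#' Thin wrapper around the IRLS fit of [stats::glm()] that adds separation
#' and convergence diagnostics and reports odds ratios with Wald confidence
#' intervals.
#'
#' @param outcome 0/1 (or logical) response vector.
#' @param design Numeric matrix or data frame of predictors (no intercept
#'   column; one is added).
#' @param weights Optional case weights (e.g. cell counts for grouped data).
#' @param conf_level Confidence level; default 0.95.
#' @return Data frame with one row per predictor: `term`, `estimate`, `se`,
#'   `or`, `ci_lo`, `ci_hi`, `p_value`.
#' @export
fit_logistic <- function(outcome, design, weights = NULL, conf_level = 0.95) {
  y <- as.numeric(outcome)
  X <- as.data.frame(design)
  if (!nrow(X) || nrow(X) != length(y))
    stop("design and outcome sizes differ")
  dat <- cbind(.y = y, X)
  n_eff <- if (is.null(weights)) length(y) else sum(weights)
  if (n_eff <= ncol(X) + 1L)
    stop("more parameters than observations")
  fit <- suppressWarnings(glm(.y ~ ., data = dat, family = binomial(),
                              weights = weights))
  if (!fit$converged)
    stop("logistic regression did not converge after ",
         fit$iter, " IRLS iterations")
  cf <- summary(fit)$coefficients
  if (any(abs(cf[-1, 1]) > 15))
    stop("apparent complete separation: |log-odds coefficient| > 15")
  z <- qnorm(1 - (1 - conf_level) / 2)
  est <- cf[-1, 1]; se <- cf[-1, 2]
  data.frame(term = rownames(cf)[-1], estimate = est, se = se,
             or = exp(est), ci_lo = exp(est - z * se),
             ci_hi = exp(est + z * se),
             p_value = 2 * pnorm(-abs(est / se)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# crude association for one model from a genotype_counts; returns rows of
# the per-model association layout (additive fitted as a dosage logistic on grouped
# data, identical to the subject-level fit)
crude_from_counts <- function(counts, model, conf_level = 0.95) {
  rec <- model_recode(counts, model)
  rows <- lapply(rec, function(ct) {
    if (model == "additive") {
      y <- rep(c(1, 0), each = 3L)
      x <- c(ct$dosage, ct$dosage)
      w <- c(ct$case_counts, ct$control_counts)
      keep <- w > 0
      tab <- fit_logistic(y[keep], data.frame(dosage = x[keep]),
                          weights = w[keep], conf_level = conf_level)
      data.frame(model = model, contrast = ct$label,
                 stratum = counts$stratum,
                 cases = sum(ct$case_counts), controls = sum(ct$control_counts),
                 or = tab$or, ci_lo = tab$ci_lo, ci_hi = tab$ci_hi,
                 p_value = tab$p_value, stringsAsFactors = FALSE)
    } else {
      orr <- odds_ratio_2x2(ct$a, ct$b, ct$c, ct$d, conf_level)
      data.frame(model = model, contrast = ct$label,
                 stratum = counts$stratum,
                 cases = ct$a + ct$b, controls = ct$c + ct$d,
                 or = orr$or, ci_lo = orr$ci_lo, ci_hi = orr$ci_hi,
                 p_value = orr$p_value, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Crude association table from genotype counts alone
#'
#' Computes the crude (unadjusted) odds ratios, Woolf CIs and Wald p-values
#' for the requested genetic models directly from a genotype-by-status
#' count table — the printed-count route when subject-level data are not
#' available. Also reports the overall genotype-distribution chi-square
#' (3x2) p-value per stratum.
#'
#' @param counts A [genotype_counts()].
#' @param models Genetic models to compute.
#' @param conf_level Confidence level; default 0.95.
#' @return List with `table` (data frame of contrasts) and
#'   `genotype_dist_p` (3x2 Pearson chi-square p-value).
#' @export
association_from_counts <- function(counts,
                                    models = c("genotype", "additive",
                                               "dominant", "recessive"),
                                    conf_level = 0.95) {
  tab <- do.call(rbind, lapply(models, function(m)
    crude_from_counts(counts, m, conf_level)))
  m3 <- rbind(counts$cases, counts$controls)
  gd <- suppressWarnings(chisq.test(m3))
  list(table = tab, genotype_dist_p = gd$p.value)
}

# ---- Formula-free fitting interface over subject tables -------------------

adjust_design <- function(s, adjust, unknown = "level") {
  X <- list()
  for (v in adjust) {
    if (v == "age") {
      X$age <- s$age
    } else if (v %in% c("sex", "gender")) {
      X$sex_male <- as.numeric(s$sex == "male")
    } else if (v %in% c("smoking", "drinking")) {
      col <- s[[v]]
      if (unknown == "exclude") col[col == "unknown"] <- NA
      X[[paste0(v, "_ever")]] <- as.numeric(col == "ever")
      if (unknown == "level" && any(col == "unknown", na.rm = TRUE))
        X[[paste0(v, "_unknown")]] <- as.numeric(col == "unknown")
    } else stop("unknown covariate: ", v)
  }
  as.data.frame(X)
}

#' Fit case-control association models across strata
#'
#' The package's main model-fitting entry point: for each stratum and each
#' genetic model it computes the crude odds ratio (closed-form Woolf for
#' 2x2 contrasts, dosage logistic for the additive model) and, when
#' covariates are supplied, the adjusted odds ratio from a multivariable
#' logistic regression. Sex is only used as a covariate in the overall
#' stratum. Subjects with missing genotype (or, after `unknown = "exclude"`,
#' unknown covariate levels) are dropped listwise per analysis.
#'
#' @param subjects Subject data frame (columns `status`, `sex`, `age`,
#'   `smoking`, `drinking`, `genotype`).
#' @param models Genetic models; default all four.
#' @param strata Strata; default overall, male, female.
#' @param adjust Character vector of covariates (`"age"`, `"sex"`,
#'   `"smoking"`, `"drinking"`), or `NULL` for crude-only.
#' @param genotypes Genotype labels, hom-ref/het/hom-alt.
#' @param unknown Handling of unknown smoking/drinking in adjusted models:
#'   `"level"` (third indicator level, keeps n) or `"exclude"`.
#' @param conf_level Confidence level; default 0.95.
#' @return Object of class `assoc_fit`: list with `results` (data frame:
#'   model, contrast, stratum, cases, controls, or_crude, ci_crude_lo/hi,
#'   p_crude, or_adj, ci_adj_lo/hi, p_adj), `hwe` (control-group HWE per
#'   stratum), `counts`, and `genotype_dist_p` per stratum.
#' @export
assoc_scan <- function(subjects,
                       models = c("genotype", "additive", "dominant",
                                  "recessive"),
                       strata = c("overall", "male", "female"),
                       adjust = NULL, genotypes = GENO_LEVELS,
                       unknown = c("level", "exclude"), conf_level = 0.95) {
  unknown <- match.arg(unknown)
  models <- match.arg(models, several.ok = TRUE)
  rows <- list(); hwe <- list(); counts <- list(); gdp <- list()
  for (st in strata) {
    cnt <- suppressMessages(tabulate_genotypes(subjects, st, genotypes))
    counts[[st]] <- cnt
    hwe[[st]] <- hwe_test(cnt)
    m3 <- rbind(cnt$cases, cnt$controls)
    gdp[[st]] <- suppressWarnings(chisq.test(m3))$p.value
    s <- subjects
    if (st != "overall") s <- s[s$sex == st, , drop = FALSE]
    s <- s[!is.na(s$genotype) & s$genotype %in% genotypes, , drop = FALSE]
    gfac <- factor(s$genotype, levels = genotypes)
    dosage <- as.integer(gfac) - 1L
    y <- as.numeric(s$status == "case")
    adj_here <- if (st == "overall") adjust else
      setdiff(adjust, c("sex", "gender"))
    for (mod in models) {
      crude <- crude_from_counts(cnt, mod, conf_level)
      crude$or_adj <- NA_real_; crude$ci_adj_lo <- NA_real_
      crude$ci_adj_hi <- NA_real_; crude$p_adj <- NA_real_
      if (length(adj_here)) {
        gx <- switch(mod,
          genotype = data.frame(het = as.numeric(dosage == 1L),
                                hom = as.numeric(dosage == 2L)),
          additive = data.frame(dosage = dosage),
          dominant = data.frame(carrier = as.numeric(dosage >= 1L)),
          recessive = data.frame(hom = as.numeric(dosage == 2L)))
        X <- cbind(gx, adjust_design(s, adj_here, unknown))
        keep <- stats::complete.cases(X) & !is.na(y)
        tab <- fit_logistic(y[keep], X[keep, , drop = FALSE],
                            conf_level = conf_level)
        ng <- ncol(gx)
        crude$or_adj <- tab$or[seq_len(ng)]
        crude$ci_adj_lo <- tab$ci_lo[seq_len(ng)]
        crude$ci_adj_hi <- tab$ci_hi[seq_len(ng)]
        crude$p_adj <- tab$p_value[seq_len(ng)]
      }
      names(crude)[names(crude) == "or"] <- "or_crude"
      names(crude)[names(crude) == "ci_lo"] <- "ci_crude_lo"
      names(crude)[names(crude) == "ci_hi"] <- "ci_crude_hi"
      names(crude)[names(crude) == "p_value"] <- "p_crude"
      rows[[length(rows) + 1L]] <- crude
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(list(results = res, hwe = hwe, counts = counts,
                 genotype_dist_p = unlist(gdp), adjust = adjust),
            class = "assoc_fit")
}

#' @export
print.assoc_fit <- function(x, digits = 2, ...) {
  cat("Case-control association under genetic models\n")
  r <- x$results
  fmt <- function(or, lo, hi)
    ifelse(is.na(or), "-",
           sprintf(paste0("%.", digits, "f (%.", digits, "f, %.", digits,
                          "f)"), or, lo, hi))
  out <- data.frame(stratum = r$stratum, model = r$model,
                    contrast = r$contrast,
                    crude = fmt(r$or_crude, r$ci_crude_lo, r$ci_crude_hi),
                    adjusted = fmt(r$or_adj, r$ci_adj_lo, r$ci_adj_hi),
                    p = signif(ifelse(is.na(r$p_adj), r$p_crude, r$p_adj), 3))
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
summary.assoc_fit <- function(object, ...) {
  cat("Strata:", paste(names(object$counts), collapse = ", "), "\n")
  for (st in names(object$hwe))
    cat(sprintf("HWE (%s controls): p = %.3f\n", st,
                object$hwe[[st]]$p_value))
  print(object)
  invisible(object)
}

#' @export
coef.assoc_fit <- function(object, ...) {
  r <- object$results
  setNames(log(ifelse(is.na(r$or_adj), r$or_crude, r$or_adj)),
           paste(r$stratum, r$model, r$contrast, sep = ":"))
}

# ---- Demographics ----------------------------------------------------------

#' Two-sample t test from summary statistics
#'
#' @param mean1,sd1,n1 First group summaries.
#' @param mean2,sd2,n2 Second group summaries.
#' @param pooled Use the pooled-variance (classic) t instead of Welch.
#' @return List: `t`, `df`, `p_value`.
#' @export
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2, pooled = FALSE) {
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Pearson chi-square test on a cases-vs-controls count table
#'
#' Uncorrected Pearson chi-square (no Yates continuity correction), the
#' convention used for demographic comparisons here.
#'
#' @param case_counts,control_counts Integer vectors of category counts.
#' @return List: `chi2`, `df`, `p_value`.
#' @export
prop_chisq <- function(case_counts, control_counts) {
  m <- rbind(case_counts, control_counts)
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Compare demographics between cases and controls
#'
#' Age by two-sample t test (Welch by default); sex, smoking and drinking by
#' uncorrected Pearson chi-square with the `"unknown"` category excluded
#' from the test.
#'
#' @param subjects Subject data frame.
#' @param pooled_t Use pooled-variance t for age; default Welch.
#' @return Data frame: `variable`, `statistic`, `df`, `p_value`.
#' @export
demographics_compare <- function(subjects, pooled_t = FALSE) {
  ca <- subjects[subjects$status == "case", , drop = FALSE]
  co <- subjects[subjects$status == "control", , drop = FALSE]
  if (nrow(ca) < 2L || nrow(co) < 2L) stop("need >= 2 subjects per group")
  if (sd(ca$age, na.rm = TRUE) == 0 && sd(co$age, na.rm = TRUE) == 0)
    stop("zero age variance in both groups")
  tt <- t.test(ca$age, co$age, var.equal = pooled_t)
  rows <- list(data.frame(variable = "age", statistic = unname(tt$statistic),
                          df = unname(tt$parameter), p_value = tt$p.value))
  cat_test <- function(name, levels) {
    x1 <- table(factor(ca[[name]], levels = levels))
    x2 <- table(factor(co[[name]], levels = levels))
    pc <- prop_chisq(as.integer(x1), as.integer(x2))
    data.frame(variable = name, statistic = pc$chi2, df = pc$df,
               p_value = pc$p_value)
  }
  rows <- c(rows, list(cat_test("sex", c("male", "female")),
                       cat_test("smoking", c("never", "ever")),
                       cat_test("drinking", c("never", "ever"))))
  do.call(rbind, rows)
}

#' Power approximation for detecting an odds ratio in a case-control study
#'
#' Two-sided Wald-test power under the normal approximation: expected 2x2
#' cell counts are formed from the control exposure frequency and the
#' alternative odds ratio, the log-OR standard error from the Woolf
#' variance, and power is
#' `Phi(|ln OR|/SE - z) + Phi(-|ln OR|/SE - z)` at `z = z_{1 - alpha/2}`.
#'
#' @param n_case,n_control Group sizes.
#' @param detectable_or Alternative odds ratio.
#' @param control_freq Exposure frequency among controls (e.g. risk-allele
#'   frequency for a per-allele contrast).
#' @param alpha Two-sided significance level; default 0.05.
#' @return Power in `[0, 1]`.
#' @export
power_two_group <- function(n_case, n_control, detectable_or, control_freq,
                            alpha = 0.05) {
  stopifnot(n_case > 0, n_control > 0, detectable_or > 0,
            control_freq > 0, control_freq < 1, alpha > 0, alpha < 1)
  p0 <- control_freq
  odds1 <- detectable_or * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  a <- n_case * p1; b <- n_case * (1 - p1)
  c <- n_control * p0; d <- n_control * (1 - p0)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - alpha / 2)
  lo <- abs(log(detectable_or)) / se
  pnorm(lo - z) + pnorm(-lo - z)
}
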