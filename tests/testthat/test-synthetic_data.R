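test_that("fixture generation is fully deterministic under a seed", {
  d1 <- file.path(tempdir(), "fix1"); d2 <- file.path(tempdir(), "fix2")
  f1 <- make_regulatory_fixture(seed = 77, out_dir = d1)
  f2 <- make_regulatory_fixture(seed = 77, out_dir = d2)
  expect_identical(f1$truth, f2$truth)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  c1 <- simulate_cohort(n_case = 200, n_control = 200, seed = 5)
  c2 <- simulate_cohort(n_case = 200, n_control = 200, seed = 5)
  expect_identical(c1$subjects, c2$subjects)
  t1 <- simulate_ct_table(seed = 5); t2 <- simulate_ct_table(seed = 5)
  expect_identical(t1$records, t2$records)
})

test_that("fixture files re-parse losslessly through the package readers", {
  d <- file.path(tempdir(), "fixrt")
  fx <- make_regulatory_fixture(seed = 13, out_dir = d)
  cfg <- fx$config
  p1 <- read_peaks(file.path(d, "foxa1_rep1.bed"), "bed6")
  expect_equal(p1$intervals[, c("chrom", "start", "end")],
               cfg$foxa1_replicates[[1]]$intervals[, c("chrom", "start",
                                                       "end")])
  snps <- read_snp_table(file.path(d, "snps_synthetic.tsv"))
  expect_equal(snps$pos, cfg$snps$pos)
  expect_equal(snps$maf, cfg$snps$maf)
  genes <- read_gene_annotation(file.path(d, "genes.tsv"))
  expect_equal(genes$tss, cfg$genes$tss)
  gen <- read_genome_fasta(file.path(d, "genome_synthetic.fa"))
  expect_identical(gen[["chrS"]], cfg$genome[["chrS"]])
  pw <- read_pwm_transfac(file.path(d, "foxa_synthetic.transfac"))[[1]]
  expect_equal(pw$freqs, cfg$pwms[[1]]$freqs, tolerance = 1e-9)
})

test_that("planted bookkeeping matches the configured fixture sizes", {
  fx <- make_regulatory_fixture(n_planted = 5, n_common_variants = 2,
                                n_rare_variants = 1, seed = 3)
  expect_equal(nrow(fx$truth$planted_sites), 5L)
  expect_length(fx$truth$planted_common_rsids, 2L)
  expect_length(fx$truth$planted_rare_rsids, 1L)
  expect_true(all(fx$truth$planted_sites$gap < 250))
  # consensus really embedded at each planted motif start
  gen <- fx$config$genome[["chrS"]]
  for (m in fx$truth$planted_sites$motif_start)
    expect_equal(substr(gen, m + 1, m + 10), fx$truth$consensus)
  expect_error(make_regulatory_fixture(n_genes = 5, n_planted = 6),
               "genome too small|more planted")
})

test_that("simulated controls are in Hardy-Weinberg equilibrium", {
  set.seed(64)
  rej <- 0L; n_rep <- 300L
  for (i in seq_len(n_rep)) {
    coh <- simulate_cohort(n_case = 10, n_control = 600,
                           missing_rate = 0)
    cnt <- tabulate_genotypes(coh$subjects, "overall")
    if (hwe_test(cnt)$p_value < 0.05) rej <- rej + 1L
  }
  # ~5% nominal rejection; 3 sigma band for 300 Bernoulli(0.05) draws
  expect_lt(abs(rej / n_rep - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep) + 1e-9)
})

test_that("null cohorts give odds ratios centered on 1", {
  set.seed(11)
  n_rep <- 200L
  lors <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    coh <- simulate_cohort(n_case = 300, n_control = 300,
                           or_female = c(1, 1), or_male = c(1, 1),
                           missing_rate = 0)
    cnt <- tabulate_genotypes(coh$subjects, "overall")
    rec <- model_recode(cnt, "dominant")[[1]]
    lors[i] <- log(odds_ratio_2x2(rec$a, rec$b, rec$c, rec$d)$or)
  }
  expect_lt(abs(mean(lors)), 3 * sd(lors) / sqrt(n_rep))
})

test_that("stratum-specific effects are recovered from a large cohort", {
  coh <- simulate_cohort(n_case = 10000, n_control = 10000, prop_male = 0.5,
                         or_female = c(1.4, 2), or_male = c(1, 1),
                         missing_rate = 0, seed = 321)
  fit <- assoc_scan(coh$subjects, models = "genotype",
                    strata = c("male", "female"))
  r <- fit$results
  for (cs in list(c("female", "GG vs CC", 2), c("female", "CG vs CC", 1.4),
                  c("male", "GG vs CC", 1), c("male", "CG vs CC", 1))) {
    row <- r[r$stratum == cs[1] & r$contrast == cs[2], ]
    se <- (log(row$ci_crude_hi) - log(row$or_crude)) / qnorm(0.975)
    expect_lt(abs(log(row$or_crude) - log(as.numeric(cs[3]))), 3 * se)
  }
})

test_that("noise-free duplicates give zero CV and a doubled GG median", {
  ct0 <- simulate_ct_table(ct_noise_sd = 0, biological_sd = 0, seed = 8)
  re0 <- relative_expression(ct0$records)
  expect_true(all(re0$cv_target == 0 & re0$cv_ref == 0))
  expect_true(all(re0$qc_flag == "pass"))
  # construction: GG dCt shift of -1.3 cycles = 2^1.3-fold expression
  med <- tapply(re0$rel_expr, re0$genotype, median)
  expect_equal(unname(med["GG"] / med["CC"]), 2^1.3, tolerance = 1e-9)
})
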