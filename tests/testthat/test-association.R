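# Genotype counts per stratum for the rs1998056 HCC case-control cohort
# (1,081 cases / 2,008 controls; counts as genotyped).
FEM_CA <- c(51, 103, 61); FEM_CO <- c(133, 183, 80)
MAL_CA <- c(229, 448, 180); MAL_CO <- c(405, 815, 381)
ALL_CA <- c(280, 551, 241); ALL_CO <- c(538, 998, 461)

test_that("genotype tabulation reconstructs stratum counts", {
  subj <- subjects_from_counts(FEM_CA, FEM_CO, MAL_CA, MAL_CO)
  fem <- tabulate_genotypes(subj, "female")
  expect_equal(unname(fem$cases), FEM_CA)
  expect_equal(unname(fem$controls), FEM_CO)
  all <- tabulate_genotypes(subj, "overall")
  expect_equal(unname(all$cases), ALL_CA)
  expect_equal(unname(all$controls), ALL_CO)
  # missing genotypes are excluded with a message
  subj$genotype[1:5] <- NA
  expect_message(tabulate_genotypes(subj, "overall"), "5 subject")
  subj$genotype <- NA
  expect_error(tabulate_genotypes(subj, "overall"), "all genotypes missing")
})

test_that("genotype tabulation matches a hand count on random subjects", {
  set.seed(12)
  subj <- data.frame(
    id = sprintf("s%d", 1:400),
    status = sample(c("case", "control"), 400, TRUE),
    sex = sample(c("male", "female"), 400, TRUE),
    age = 50, smoking = "never", drinking = "never",
    genotype = sample(c("CC", "CG", "GG", NA), 400, TRUE),
    stringsAsFactors = FALSE)
  cnt <- suppressMessages(tabulate_genotypes(subj, "male"))
  hand <- function(st, g) sum(subj$status == st & subj$sex == "male" &
                                !is.na(subj$genotype) & subj$genotype == g)
  expect_equal(unname(cnt$cases),
               c(hand("case", "CC"), hand("case", "CG"), hand("case", "GG")))
  expect_equal(unname(cnt$controls),
               c(hand("control", "CC"), hand("control", "CG"),
                 hand("control", "GG")))
})

test_that("HWE goodness of fit reproduces the control-group result", {
  h <- hwe_test(ALL_CO)
  expect_equal(h$chi2, 0.001947, tolerance = 1e-3)
  expect_equal(round(h$p_value, 3), 0.965)
  expect_equal(sum(h$expected_counts), sum(ALL_CO))
  # exact HWE triple
  h0 <- hwe_test(c(25, 50, 25))
  expect_equal(h0$chi2, 0)
  expect_equal(h0$p_value, 1)
  # monomorphic marker degenerates with a warning
  expect_warning(hm <- hwe_test(c(100, 0, 0)), "monomorphic")
  expect_equal(hm$p_value, 1)
  # random triples match the direct formula
  set.seed(3)
  for (i in 1:25) {
    o <- as.numeric(rmultinom(1, 500, c(0.3, 0.5, 0.2)))
    p <- (2 * o[1] + o[2]) / (2 * sum(o))
    e <- sum(o) * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    expect_equal(hwe_test(o)$chi2, sum((o - e)^2 / e), tolerance = 1e-12)
  }
})

test_that("2x2 odds ratios use the Woolf CI and algebraic identities hold", {
  # female GG vs CC from the published counts
  gg <- odds_ratio_2x2(a = 61, b = 51, c = 80, d = 133)
  expect_equal(round(gg$or, 2), 1.99)
  expect_equal(round(gg$ci_lo, 2), 1.25)
  expect_equal(round(gg$ci_hi, 2), 3.16)
  # null table
  n0 <- odds_ratio_2x2(10, 10, 10, 10)
  expect_equal(n0$or, 1)
  expect_equal(n0$ci_lo * n0$ci_hi, 1, tolerance = 1e-12)
  # exposure flip inverts exactly
  set.seed(6)
  for (i in 1:20) {
    v <- sample(1:200, 4)
    o1 <- odds_ratio_2x2(v[1], v[2], v[3], v[4])
    o2 <- odds_ratio_2x2(v[2], v[1], v[4], v[3])
    expect_equal(o1$or * o2$or, 1, tolerance = 1e-12)
    expect_equal(o1$ci_lo, 1 / o2$ci_hi, tolerance = 1e-12)
  }
  # zero cell triggers the Haldane-Anscombe correction and a flag
  z <- odds_ratio_2x2(0, 10, 10, 10)
  expect_true(z$corrected)
  expect_true(is.finite(z$or) && z$or > 0)
})

test_that("model recoding reproduces the published collapsed cells", {
  fem <- genotype_counts(FEM_CA, FEM_CO, stratum = "female")
  dom <- model_recode(fem, "dominant")[[1]]
  expect_equal(c(dom$a, dom$b, dom$c, dom$d), c(164, 51, 263, 133))
  mal <- genotype_counts(MAL_CA, MAL_CO, stratum = "male")
  rec <- model_recode(mal, "recessive")[[1]]
  expect_equal(c(rec$a, rec$b, rec$c, rec$d), c(180, 677, 381, 1220))
  # dominant + recessive cells recompose the genotype triple
  gen <- model_recode(fem, "genotype")
  expect_equal(dom$a - gen[[2]]$a, FEM_CA[2])
  expect_equal(rec2 <- model_recode(fem, "recessive")[[1]]$b, sum(FEM_CA[1:2]))
  add <- model_recode(fem, "additive")[[1]]
  expect_equal(add$case_counts, FEM_CA)
  expect_equal(add$control_counts, FEM_CO)
})

test_that("logistic fit equals the closed form for one binary predictor", {
  # female GG vs CC as a single-predictor logistic regression
  y <- rep(c(1, 1, 0, 0), c(61, 51, 80, 133))
  x <- rep(c(1, 0, 1, 0), c(61, 51, 80, 133))
  fit <- fit_logistic(y, data.frame(gg = x))
  closed <- odds_ratio_2x2(61, 51, 80, 133)
  expect_equal(fit$or, closed$or, tolerance = 1e-6)
  expect_equal(fit$ci_lo, closed$ci_lo, tolerance = 1e-6)
  expect_equal(fit$ci_hi, closed$ci_hi, tolerance = 1e-6)
  expect_equal(fit$p_value, closed$p_value, tolerance = 1e-4)
  # complete separation is detected
  ys <- rep(c(1, 0), each = 20)
  xs <- rep(c(1, 0), each = 20)
  expect_error(fit_logistic(ys, data.frame(x = xs)), "separation")
})

test_that("dosage logistic reproduces the published additive odds ratio", {
  fem <- genotype_counts(FEM_CA, FEM_CO, stratum = "female")
  res <- association_from_counts(fem, models = "additive")$table
  expect_equal(round(res$or, 2), 1.41)
  expect_equal(round(res$ci_lo, 2), 1.12)
  expect_equal(round(res$ci_hi, 2), 1.78)
})

test_that("the full crude table matches the published per-model odds ratios", {
  expected <- rbind(
    c("female", "genotype", 2, 1.99), c("female", "genotype", 1, 1.47),
    c("female", "dominant", 1, 1.63), c("female", "additive", 1, 1.41),
    c("male", "genotype", 2, 0.84), c("male", "recessive", 1, 0.85),
    c("overall", "genotype", 1, 1.06), c("overall", "dominant", 1, 1.04))
  counts <- list(female = genotype_counts(FEM_CA, FEM_CO, stratum = "female"),
                 male = genotype_counts(MAL_CA, MAL_CO, stratum = "male"),
                 overall = genotype_counts(ALL_CA, ALL_CO,
                                           stratum = "overall"))
  for (i in seq_len(nrow(expected))) {
    st <- expected[i, 1]; mod <- expected[i, 2]
    k <- as.integer(expected[i, 3]); or_exp <- as.numeric(expected[i, 4])
    tab <- association_from_counts(counts[[st]], models = mod)$table
    expect_equal(round(tab$or[k], 2), or_exp,
                 info = paste(st, mod, k))
  }
})

test_that("adjusted fits recover planted effects within 3 SE at n = 20,000", {
  coh <- simulate_cohort(n_case = 10000, n_control = 10000,
                         or_female = c(1.65, 2), or_male = c(1, 1),
                         prop_male = 0.5, seed = 2024)
  fit <- assoc_scan(coh$subjects, models = "genotype",
                    strata = c("male", "female"),
                    adjust = c("age", "smoking", "drinking"))
  r <- fit$results
  fem_gg <- r[r$stratum == "female" & r$contrast == "GG vs CC", ]
  mal_gg <- r[r$stratum == "male" & r$contrast == "GG vs CC", ]
  se_f <- (log(fem_gg$ci_crude_hi) - log(fem_gg$or_crude)) / qnorm(0.975)
  se_m <- (log(mal_gg$ci_crude_hi) - log(mal_gg$or_crude)) / qnorm(0.975)
  expect_lt(abs(log(fem_gg$or_adj) - log(2)), 3 * se_f)
  expect_lt(abs(log(mal_gg$or_adj) - log(1)), 3 * se_m)
})

test_that("demographic comparisons reproduce the published summary tests", {
  smoke <- prop_chisq(c(647, 419), c(982, 1011))
  expect_equal(smoke$chi2, 36.4, tolerance = 0.01)
  expect_equal(smoke$p_value, 1.611e-9, tolerance = 0.001)
  drink <- prop_chisq(c(572, 486), c(898, 1092))
  expect_equal(drink$p_value, 2.583e-6, tolerance = 0.001)
  sex <- prop_chisq(c(866, 215), c(1611, 397))
  expect_equal(round(sex$p_value, 3), 0.937)
  # age from printed means/SDs (rounded inputs move p by ~1e-3)
  aget <- t_test_summary(54.96, 11.37, 1081, 55.56, 10.28, 2008)
  expect_lt(abs(aget$p_value - 0.149), 0.002)
  # identical groups give p = 1 on equal proportions
  eq <- prop_chisq(c(50, 50), c(100, 100))
  expect_equal(eq$p_value, 1)
})

test_that("demographics_compare runs on subject tables and flags imbalance", {
  coh <- simulate_cohort(n_case = 2000, n_control = 2000, seed = 31)
  dem <- demographics_compare(coh$subjects)
  expect_setequal(dem$variable, c("age", "sex", "smoking", "drinking"))
  expect_true(all(dem$p_value >= 0 & dem$p_value <= 1))
  # generator plants a real smoking imbalance (59.9% vs 48.9%)
  expect_lt(dem$p_value[dem$variable == "smoking"], 0.01)
})

test_that("power approximation is calibrated at the null and monotone", {
  expect_equal(power_two_group(1000, 2000, 1.0, 0.3), 0.05,
               tolerance = 1e-10)
  p1 <- power_two_group(500, 500, 1.3, 0.48)
  p2 <- power_two_group(2000, 2000, 1.3, 0.48)
  p3 <- power_two_group(2000, 2000, 1.6, 0.48)
  expect_lt(p1, p2); expect_lt(p2, p3)
})

test_that("power approximation agrees with a Monte-Carlo oracle", {
  n1 <- 1081; n2 <- 2008; p0 <- 0.48; or <- 1.3
  approx_power <- power_two_group(n1, n2, or, p0)
  set.seed(99)
  odds1 <- or * p0 / (1 - p0); p1 <- odds1 / (1 + odds1)
  a <- rbinom(50000, n1, p1); c_ <- rbinom(50000, n2, p0)
  b <- n1 - a; d <- n2 - c_
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  z <- log((a * d) / (b * c_)) / se
  mc <- mean(abs(z) > qnorm(0.975))
  expect_equal(approx_power, mc, tolerance = 0.01)
})
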