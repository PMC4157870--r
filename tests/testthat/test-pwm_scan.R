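test_that("information vector handles uniform, conserved and mixed columns", {
  p <- pwm_from_counts(rbind(c(1, 1, 1, 1),
                             c(4, 0, 0, 0),
                             c(2, 2, 0, 0)))
  iv <- information_vector(p)
  expect_equal(iv[1], 0)
  expect_equal(iv[2], log(4))
  expect_equal(iv[3], log(2))  # 2 * 0.5 * ln 2
  expect_true(all(iv >= 0 & iv <= log(4) + 1e-12))
})

test_that("matrix similarity is 1 at consensus, 0 at anti-consensus", {
  p <- toy_pwm_4()
  cons <- pwm_consensus(p)
  anti <- paste(colnames(p$freqs)[apply(p$freqs, 1, which.min)],
                collapse = "")
  expect_equal(matrix_similarity(p, cons), 1)
  expect_equal(matrix_similarity(p, anti), 0)
  expect_error(matrix_similarity(p, "ACG"), "length")
})

test_that("matrix and core scores match the brute-force oracle on all 256 windows", {
  p <- toy_pwm_4()
  for (w in all_windows(4)) {
    orc <- oracle_match_scores(p$freqs, w)
    expect_equal(matrix_similarity(p, w), orc$mss, tolerance = 1e-12)
    # L <= 5: core similarity is the full matrix similarity
    expect_equal(core_similarity(p, w), orc$mss, tolerance = 1e-12)
  }
})

test_that("core selection takes the leftmost max-information 5-mer on ties", {
  # identical columns everywhere: every 5-mer has equal information
  flat <- pwm_from_counts(matrix(rep(c(6, 2, 1, 1), each = 8), ncol = 4),
                          name = "TIE8")
  expect_equal(core_positions(flat), 1:5)
  # distinct high-information block is found wherever it sits
  counts <- matrix(rep(c(1, 1, 1, 1), each = 9), ncol = 4)
  counts[4:8, ] <- matrix(rep(c(20, 0, 0, 0), each = 5), ncol = 4)
  sharp <- pwm_from_counts(counts, name = "BLOCK9")
  expect_equal(core_positions(sharp), 4:8)
  # scores on an 8-mer tie case agree with the oracle
  set.seed(9)
  for (w in replicate(20, paste(sample(c("A", "C", "G", "T"), 8, TRUE),
                                collapse = ""))) {
    orc <- oracle_match_scores(flat$freqs, w)
    expect_equal(core_similarity(flat, w), orc$css, tolerance = 1e-12)
  }
})

test_that("region scanning finds planted sites and nothing below cutoff", {
  p <- foxa_pwm()
  cons <- pwm_consensus(p)
  set.seed(14)
  bg <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  seqstr <- paste0(substr(bg, 1, 100), cons, substr(bg, 101, 300))
  genome <- c(chr1 = seqstr)
  reg <- data.frame(region_id = "r1", chrom = "chr1", start = 0L,
                    end = nchar(seqstr))
  hits <- scan_pwm(p, reg, genome, core_cutoff = 0.95, matrix_cutoff = 0.99)
  fwd <- hits[hits$strand == "+", ]
  expect_true(any(fwd$start == 100L & fwd$matrix_score > 1 - 1e-9))
  expect_equal(fwd$sequence[fwd$start == 100L], cons)
  # a one-mismatch site fails perfect cutoffs
  mut <- cons
  substr(mut, 3, 3) <- "A"
  genome2 <- c(chr1 = paste0(substr(bg, 1, 100), mut, substr(bg, 101, 300)))
  h2 <- scan_pwm(p, reg, genome2, core_cutoff = 1, matrix_cutoff = 1)
  expect_equal(nrow(h2), 0L)
  # region shorter than the matrix yields an empty result, not an error
  short <- data.frame(region_id = "s", chrom = "chr1", start = 0L, end = 4L)
  expect_equal(nrow(scan_pwm(p, short, genome)), 0L)
})

test_that("scanning agrees with the exhaustive oracle on both strands", {
  p <- toy_pwm_4()
  set.seed(21)
  seqstr <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  reg <- data.frame(region_id = "r", chrom = "c", start = 0L, end = 200L)
  for (cuts in list(c(0.6, 0.7), c(0.8, 0.9), c(0, 0))) {
    got <- scan_pwm(p, reg, c(c = seqstr), cuts[1], cuts[2])
    exp <- oracle_scan(p$freqs, seqstr, cuts[1], cuts[2])
    expect_equal(nrow(got), if (is.null(exp)) 0L else nrow(exp))
    if (!is.null(exp)) {
      expect_setequal(paste(got$start, got$strand),
                      paste(exp$start, exp$strand))
      o <- order(got$start, got$strand); oe <- order(exp$start, exp$strand)
      expect_equal(got$matrix_score[o], exp$mss[oe], tolerance = 1e-12)
      expect_equal(got$core_score[o], exp$css[oe], tolerance = 1e-12)
    }
  }
})

test_that("reverse-complementing a region mirrors its hit set", {
  p <- toy_pwm_4()
  set.seed(4)
  seqstr <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  rc <- oracle_revcomp(seqstr)
  reg <- data.frame(region_id = "r", chrom = "c", start = 0L, end = 150L)
  h1 <- scan_pwm(p, reg, c(c = seqstr), 0.5, 0.6)
  h2 <- scan_pwm(p, reg, c(c = rc), 0.5, 0.6)
  # forward hits at s map to reverse hits at len - s - L
  expect_setequal(paste(150L - h1$start - 4L,
                        ifelse(h1$strand == "+", "-", "+")),
                  paste(h2$start, h2$strand))
})

test_that("raising either cutoff never adds hits; N windows are skipped", {
  p <- toy_pwm_4()
  set.seed(77)
  seqstr <- paste(sample(c("A", "C", "G", "T", "N"), 300, TRUE,
                         prob = c(rep(0.24, 4), 0.04)), collapse = "")
  reg <- data.frame(region_id = "r", chrom = "c", start = 0L, end = 300L)
  loose <- scan_pwm(p, reg, c(c = seqstr), 0.3, 0.4)
  tight <- scan_pwm(p, reg, c(c = seqstr), 0.6, 0.8)
  expect_lte(nrow(tight), nrow(loose))
  expect_true(all(paste(tight$start, tight$strand) %in%
                    paste(loose$start, loose$strand)))
  expect_false(any(grepl("N", loose$sequence)))
  expect_true(all(loose$matrix_score >= 0.4 & loose$matrix_score <= 1))
  expect_true(all(loose$core_score >= 0.3 & loose$core_score <= 1))
})
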