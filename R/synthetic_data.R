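# Seeded generators for every input the pipeline consumes, with planted
# ground truth: ENCODE-style peak sets with planted dual-target promoter
# regions, a dbSNP-style catalog with variants planted inside binding
# elements, case-control cohorts with stratum-specific odds ratios, and
# qPCR Ct tables with genotype-dependent shifts.

#' A sharp FOXA-like frequency matrix
#'
#' A 10-position forkhead-like matrix (consensus `TGTTTACTTA`) used by the
#' regulatory fixture generator: most positions are strongly conserved
#' (17/20 counts on the consensus base) with two softer positions, giving a
#' motif specific enough that planted consensus sites score 1 while random
#' background rarely passes the default cut-offs.
#'
#' @return A `pwm` object named `"FOXA_SYNTH"`.
#' @export
foxa_pwm <- function() {
  cons <- c("T", "G", "T", "T", "T", "A", "C", "T", "T", "A")
  counts <- matrix(1, length(cons), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(cons)) counts[i, cons[i]] <- 17
  counts[6, ] <- c(10, 2, 6, 2)   # softer positions flanking the core
  counts[10, ] <- c(8, 4, 4, 4)
  pwm_from_counts(counts, name = "FOXA_SYNTH")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a regulatory fixture with planted ground truth
#'
#' Builds a synthetic genome plus every upstream input of [run_pipeline()].
#' The chromosome is divided into 10-kb gene slots, each holding one
#' `+`-strand gene (body at slot offset 7000-9000, hence promoter at
#' 2000-7000). Feature classes never share a slot, which guarantees by
#' construction that: planted FOXA/ERalpha pairs (consensus motif embedded
#' in the FOXA peak, gap below the dual-target threshold, inside the
#' promoter) are always recovered; decoy single-factor peaks can never form
#' dual pairs; decoy dual pairs sit upstream of the promoter window; and
#' decoy SNPs (placed in gene bodies) can never fall inside a scanned
#' region.
#'
#' @param n_genes Number of gene slots; default 30.
#' @param n_planted Planted promoter-overlapping dual-target sites; each
#'   carries a consensus FOXA motif. Default 6.
#' @param n_common_variants,n_rare_variants Planted SNPs inside the motifs
#'   of the first planted sites with MAF above / below the 0.05 threshold.
#'   `n_common_variants + n_rare_variants <= n_planted`. Defaults 3 and 2.
#' @param n_decoy_foxa,n_decoy_era Slots holding a lone FOXA / ERalpha
#'   peak. Defaults 4 and 4.
#' @param n_decoy_dual Slots holding a dual pair outside the promoter.
#'   Default 3.
#' @param n_decoy_snps Decoy SNPs in gene bodies. Default 10.
#' @param slot_size Slot width in bp; default 10000.
#' @param seed Optional integer seed (set locally when given).
#' @param out_dir Optional directory; when given, genome FASTA, genes TSV,
#'   per-replicate peak BEDs, TRANSFAC matrix, SNP TSV and a truth JSON are
#'   written there.
#' @return List with `config` (ready for [run_pipeline()]) and `truth`
#'   (planted/decoy bookkeeping sufficient to score every stage).
#' @export
make_regulatory_fixture <- function(n_genes = 30, n_planted = 6,
                                    n_common_variants = 3,
                                    n_rare_variants = 2,
                                    n_decoy_foxa = 4, n_decoy_era = 4,
                                    n_decoy_dual = 3, n_decoy_snps = 10,
                                    slot_size = 10000, seed = NULL,
                                    out_dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_common_variants + n_rare_variants > n_planted)
    stop("more planted variants than planted sites")
  n_feature_slots <- n_planted + n_decoy_foxa + n_decoy_era + n_decoy_dual
  if (n_feature_slots > n_genes)
    stop("genome too small: ", n_genes, " slots for ", n_feature_slots,
         " features")
  if (slot_size < 10000) stop("slot_size must be >= 10000")
  pwm <- foxa_pwm()
  L <- nrow(pwm$freqs)
  cons <- pwm_consensus(pwm)
  glen <- n_genes * slot_size
  genome_chars <- strsplit(random_dna(glen), "")[[1]]
  genome <- NULL  # assembled after motif embedding

  slots <- sample(n_genes)  # random assignment of feature classes to slots
  planted_slots <- slots[seq_len(n_planted)]
  decoy_foxa_slots <- slots[n_planted + seq_len(n_decoy_foxa)]
  decoy_era_slots <- slots[n_planted + n_decoy_foxa + seq_len(n_decoy_era)]
  decoy_dual_slots <- slots[n_planted + n_decoy_foxa + n_decoy_era +
                              seq_len(n_decoy_dual)]

  genes <- data.frame(gene_id = sprintf("gene%03d", seq_len(n_genes)),
                      chrom = "chrS",
                      start = (seq_len(n_genes) - 1L) * slot_size + 7000L,
                      end = (seq_len(n_genes) - 1L) * slot_size + 9000L,
                      strand = "+", stringsAsFactors = FALSE)
  genes$tss <- derive_tss(genes$start, genes$end, genes$strand)

  f1r1 <- list(); f1r2 <- list(); f2r1 <- list(); f2r2 <- list()
  era_ecc <- list(); era_t47 <- list()
  add <- function(lst, s, e) { lst[[length(lst) + 1L]] <- c(s, e); lst }

  planted <- data.frame(slot = integer(0), gene_id = character(0),
                        motif_start = integer(0), foxa_start = integer(0),
                        foxa_end = integer(0), era_start = integer(0),
                        era_end = integer(0), gap = integer(0),
                        stringsAsFactors = FALSE)
  for (k in seq_len(n_planted)) {
    sl <- planted_slots[k]; s <- (sl - 1L) * slot_size
    m <- s + sample(3000:5000, 1L)            # motif inside the promoter
    genome_chars[(m + 1L):(m + L)] <- strsplit(cons, "")[[1]]
    # replicate peaks overlap; their intersection still contains the motif
    p1 <- c(m - 60L, m + L + 40L); p2 <- c(m - 40L, m + L + 60L)
    if (k %% 2L == 1L) { f1r1 <- add(f1r1, p1[1], p1[2]); f1r2 <- add(f1r2, p2[1], p2[2]) }
    else { f2r1 <- add(f2r1, p1[1], p1[2]); f2r2 <- add(f2r2, p2[1], p2[2]) }
    gap <- sample(0:249, 1L)
    es <- m + L + 40L + gap; ee <- es + 150L
    if (k %% 2L == 1L) era_ecc <- add(era_ecc, es, ee) else
      era_t47 <- add(era_t47, es, ee)
    planted <- rbind(planted, data.frame(
      slot = sl, gene_id = genes$gene_id[sl], motif_start = m,
      foxa_start = m - 40L, foxa_end = m + L + 40L, era_start = es,
      era_end = ee, gap = gap, stringsAsFactors = FALSE))
  }
  for (sl in decoy_foxa_slots) {
    s <- (sl - 1L) * slot_size
    f1r1 <- add(f1r1, s + 3000L, s + 3200L)
    f1r2 <- add(f1r2, s + 3050L, s + 3250L)
  }
  for (sl in decoy_era_slots) {
    s <- (sl - 1L) * slot_size
    era_ecc <- add(era_ecc, s + 3000L, s + 3200L)
  }
  for (sl in decoy_dual_slots) {           # dual pair upstream of promoter
    s <- (sl - 1L) * slot_size
    f2r1 <- add(f2r1, s + 100L, s + 300L)
    f2r2 <- add(f2r2, s + 150L, s + 350L)
    era_t47 <- add(era_t47, s + 400L, s + 600L)
  }

  to_ps <- function(lst, fac, cl, rep) {
    if (!length(lst))
      return(peak_set(genomic_intervals(character(0), integer(0), integer(0)),
                      factor = fac, cell_line = cl, replicate = rep))
    m <- do.call(rbind, lst)
    peak_set(genomic_intervals("chrS", m[, 1], m[, 2]), factor = fac,
             cell_line = cl, replicate = rep)
  }

  # planted SNPs inside planted motifs; decoys in gene bodies
  n_pv <- n_common_variants + n_rare_variants
  snp_rows <- list()
  for (k in seq_len(n_pv)) {
    pos <- planted$motif_start[k] + sample(0:(L - 1L), 1L)
    maf <- if (k <= n_common_variants) runif(1, 0.1, 0.5) else
      runif(1, 0.005, 0.049)
    ref <- genome_chars[pos + 1L]
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    snp_rows[[k]] <- data.frame(rsid = sprintf("rsP%04d", k), chrom = "chrS",
                                pos = pos, ref = ref, alt = alt, maf = maf,
                                stringsAsFactors = FALSE)
  }
  for (k in seq_len(n_decoy_snps)) {
    sl <- sample(n_genes, 1L)
    pos <- (sl - 1L) * slot_size + sample(7000:8999, 1L)  # gene body
    ref <- genome_chars[pos + 1L]
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    maf <- if (k %% 3L == 0L) NA_real_ else runif(1, 0.01, 0.5)
    snp_rows[[n_pv + k]] <- data.frame(rsid = sprintf("rsD%04d", k),
                                       chrom = "chrS", pos = pos, ref = ref,
                                       alt = alt, maf = maf,
                                       stringsAsFactors = FALSE)
  }
  snps <- do.call(rbind, snp_rows)

  genome <- c(chrS = paste(genome_chars, collapse = ""))
  config <- list(
    foxa1_replicates = list(to_ps(f1r1, "FOXA1", "HepG2", "rep1"),
                            to_ps(f1r2, "FOXA1", "HepG2", "rep2")),
    foxa2_replicates = list(to_ps(f2r1, "FOXA2", "HepG2", "rep1"),
                            to_ps(f2r2, "FOXA2", "HepG2", "rep2")),
    era_sets = list(to_ps(era_ecc, "ERalpha", "ECC-1", NA),
                    to_ps(era_t47, "ERalpha", "T47-D", NA)),
    genes = genes, pwms = list(pwm), snps = snps, genome = genome)
  truth <- list(planted_sites = planted,
                planted_common_rsids = snps$rsid[seq_len(n_common_variants)],
                planted_rare_rsids = if (n_rare_variants)
                  snps$rsid[n_common_variants + seq_len(n_rare_variants)]
                else character(0),
                decoy_rsids = grep("^rsD", snps$rsid, value = TRUE),
                n_planted = n_planted, n_decoy_dual = n_decoy_dual,
                slot_size = slot_size, consensus = cons)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_genome_fasta(genome, file.path(out_dir, "genome_synthetic.fa"))
    write.table(genes[, 1:5], file.path(out_dir, "genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    write_peaks(config$foxa1_replicates[[1]], file.path(out_dir, "foxa1_rep1.bed"))
    write_peaks(config$foxa1_replicates[[2]], file.path(out_dir, "foxa1_rep2.bed"))
    write_peaks(config$foxa2_replicates[[1]], file.path(out_dir, "foxa2_rep1.bed"))
    write_peaks(config$foxa2_replicates[[2]], file.path(out_dir, "foxa2_rep2.bed"))
    write_peaks(config$era_sets[[1]], file.path(out_dir, "era_ecc1.bed"))
    write_peaks(config$era_sets[[2]], file.path(out_dir, "era_t47d.bed"))
    write_pwm_transfac(pwm, file.path(out_dir, "foxa_synthetic.transfac"),
                       counts_scale = 20)
    write_snp_table(snps, file.path(out_dir, "snps_synthetic.tsv"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(config = config, truth = truth)
}

#' Simulate a case-control cohort with stratum-specific genotype effects
#'
#' Controls' genotypes are drawn in Hardy-Weinberg proportions at the given
#' risk-allele frequency. Cases' genotype distribution is tilted by the
#' genetic-model odds ratios of their sex stratum (retrospective sampling:
#' case probabilities proportional to HWE probabilities times the genotype
#' odds multipliers), so the stratified logistic fit recovers the planted
#' ORs. Covariates are drawn with case-control imbalance. Defaults mirror a
#' 1,081/2,008 hepatocellular-carcinoma cohort: ~80% male, risk-allele
#' control frequency 0.48, a female-only genotype effect, smoking 59.9% vs
#' 48.9% and drinking 52.9% vs 44.7%.
#'
#' @param n_case,n_control Group sizes; defaults 1081 and 2008.
#' @param maf Risk-allele frequency in controls; default 0.4807.
#' @param model Genetic model shaping the case tilt; default `"genotype"`.
#' @param or_female,or_male Odds multipliers: for `model = "genotype"` a
#'   length-2 vector (het, hom-alt vs hom-ref); for the other models a
#'   single OR. Defaults: female `c(1.5, 2)`, male `c(1, 1)`.
#' @param prop_male Probability a subject is male; default 0.801.
#' @param age_case,age_control `c(mean, sd)` of age; defaults
#'   `c(54.96, 11.37)` and `c(55.56, 10.28)`.
#' @param smoking_case,smoking_control,drinking_case,drinking_control
#'   `c(P(ever), P(unknown))`; defaults from the cohort above.
#' @param missing_rate Genotype missingness; default 0.006.
#' @param seed Optional integer seed.
#' @return List with `subjects` (data frame: id, status, sex, age, smoking,
#'   drinking, genotype) and `truth` (all parameters).
#' @export
simulate_cohort <- function(n_case = 1081, n_control = 2008, maf = 0.4807,
                            model = c("genotype", "additive", "dominant",
                                      "recessive"),
                            or_female = c(1.5, 2), or_male = c(1, 1),
                            prop_male = 0.801,
                            age_case = c(54.96, 11.37),
                            age_control = c(55.56, 10.28),
                            smoking_case = c(0.599, 0.014),
                            smoking_control = c(0.489, 0.007),
                            drinking_case = c(0.529, 0.021),
                            drinking_control = c(0.447, 0.009),
                            missing_rate = 0.006, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- match.arg(model)
  stopifnot(maf > 0, maf <= 0.5, all(or_female > 0), all(or_male > 0))
  weights <- function(or) {
    or <- as.numeric(or)
    switch(model,
           genotype = c(1, or[1], or[2]),
           additive = c(1, or[1], or[1]^2),
           dominant = c(1, or[1], or[1]),
           recessive = c(1, 1, or[1]))
  }
  hw <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  draw_geno <- function(n, w) {
    pr <- hw * w
    sample(GENO_LEVELS, n, replace = TRUE, prob = pr / sum(pr))
  }
  draw_cat <- function(n, p_ever, p_unknown) {
    sample(c("ever", "unknown", "never"), n, replace = TRUE,
           prob = c(p_ever, p_unknown, 1 - p_ever - p_unknown))
  }
  n <- n_case + n_control
  status <- rep(c("case", "control"), c(n_case, n_control))
  sex <- ifelse(runif(n) < prop_male, "male", "female")
  genotype <- character(n)
  is_case <- status == "case"
  for (sx in c("male", "female")) {
    w <- weights(if (sx == "male") or_male else or_female)
    i_case <- which(is_case & sex == sx)
    i_ctrl <- which(!is_case & sex == sx)
    genotype[i_case] <- draw_geno(length(i_case), w)
    genotype[i_ctrl] <- draw_geno(length(i_ctrl), c(1, 1, 1))
  }
  genotype[runif(n) < missing_rate] <- NA
  age <- numeric(n)
  age[is_case] <- pmax(18, rnorm(n_case, age_case[1], age_case[2]))
  age[!is_case] <- pmax(18, rnorm(n_control, age_control[1], age_control[2]))
  smoking <- character(n); drinking <- character(n)
  smoking[is_case] <- draw_cat(n_case, smoking_case[1], smoking_case[2])
  smoking[!is_case] <- draw_cat(n_control, smoking_control[1],
                                smoking_control[2])
  drinking[is_case] <- draw_cat(n_case, drinking_case[1], drinking_case[2])
  drinking[!is_case] <- draw_cat(n_control, drinking_control[1],
                                 drinking_control[2])
  subjects <- data.frame(id = sprintf("S%05d", seq_len(n)), status = status,
                         sex = sex, age = round(age, 1), smoking = smoking,
                         drinking = drinking, genotype = genotype,
                         stringsAsFactors = FALSE)
  list(subjects = subjects,
       truth = list(n_case = n_case, n_control = n_control, maf = maf,
                    model = model, or_female = or_female, or_male = or_male,
                    prop_male = prop_male, missing_rate = missing_rate))
}

#' Simulate a genotype-stratified qPCR Ct table
#'
#' Each sample receives a latent reference Ct and a latent dCt equal to a
#' baseline plus its genotype shift plus biological noise; technical
#' duplicates add independent measurement noise to both genes. Defaults
#' mirror a 72-tissue liver qPCR set with 22/38/12 CC/CG/GG carriers and a
#' ~2-fold expression increase for GG homozygotes (dCt shift of -1 cycle).
#'
#' @param n_per_genotype Named counts per genotype; default
#'   `c(CC = 22, CG = 38, GG = 12)`.
#' @param genotype_shift dCt shift per genotype in cycles; default
#'   `c(CC = 0, CG = -0.5, GG = -1.3)` (negative = higher expression).
#' @param ct_noise_sd Technical (duplicate) SD in cycles; default 0.15.
#' @param biological_sd Between-sample dCt SD; default 1.
#' @param baseline_ct_ref,baseline_delta Reference-gene Ct and baseline
#'   dCt; defaults 20 and 5.
#' @param n_replicates Technical replicates per sample; default 2.
#' @param prop_male Probability a donor is male; default 0.8.
#' @param seed Optional integer seed.
#' @return List with `records` (data frame: sample_id, genotype, sex,
#'   replicate, ct_target, ct_reference) and `truth` (parameters).
#' @export
simulate_ct_table <- function(n_per_genotype = c(CC = 22, CG = 38, GG = 12),
                              genotype_shift = c(CC = 0, CG = -0.5, GG = -1.3),
                              ct_noise_sd = 0.15, biological_sd = 1,
                              baseline_ct_ref = 20, baseline_delta = 5,
                              n_replicates = 2, prop_male = 0.8,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(ct_noise_sd >= 0, biological_sd >= 0, n_replicates >= 1)
  genos <- rep(names(n_per_genotype), n_per_genotype)
  n <- length(genos)
  rows <- list()
  for (i in seq_len(n)) {
    g <- genos[i]
    ref0 <- baseline_ct_ref + rnorm(1, 0, 0.5)
    d0 <- baseline_delta + genotype_shift[[g]] + rnorm(1, 0, biological_sd)
    sx <- if (runif(1) < prop_male) "male" else "female"
    for (r in seq_len(n_replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("T%03d", i), genotype = g, sex = sx,
        replicate = r,
        ct_target = ref0 + d0 + rnorm(1, 0, ct_noise_sd),
        ct_reference = ref0 + rnorm(1, 0, ct_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  list(records = records,
       truth = list(n_per_genotype = n_per_genotype,
                    genotype_shift = genotype_shift,
                    ct_noise_sd = ct_noise_sd, biological_sd = biological_sd,
                    baseline_ct_ref = baseline_ct_ref,
                    baseline_delta = baseline_delta,
                    n_replicates = n_replicates))
}
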