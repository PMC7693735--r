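test_that("simulated genotypes match HWE marginals and the stated MAF", {
  g <- simulate_genotypes(null_snp_table(1, maf = 0.5), 20000, seed = 2)
  freq <- table(factor(g$dosage[, 1], levels = 0:2)) / 20000
  expect_equal(as.numeric(freq), c(0.25, 0.5, 0.25), tolerance = 0.05)

  g2 <- simulate_genotypes(rbind(snp_spec("rs2073823", 0.215)), 50000,
                           seed = 3)
  expect_lt(abs(allele_frequency(g2$dosage[, 1])$maf - 0.215), 0.01)

  g3 <- simulate_genotypes(rbind(snp_spec("rs3763969", 0.120)), 50000,
                           seed = 4)
  expect_lt(abs(allele_frequency(g3$dosage[, 1])$maf - 0.120), 0.01)
})

test_that("HWE test p-values are uniform over simulated null SNPs", {
  g <- simulate_genotypes(null_snp_table(1000, maf = 0.3), 300, seed = 7)
  p <- vapply(seq_len(1000), function(j) hwe_test(g$dosage[, j])$p,
              numeric(1))
  # chi-square p-values are discrete, hence tied: KS is approximate here
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("LD blocks hit the target dosage r-squared", {
  mk <- function(r2) rbind(
    snp_spec("a", 0.3, ld_block = "B", target_r2 = r2),
    snp_spec("b", 0.3, ld_block = "B", target_r2 = r2))
  for (r2 in c(0.2, 0.6, 0.9)) {
    g <- simulate_genotypes(mk(r2), 10000, seed = 11)
    expect_lt(abs(ld_r2(g$dosage[, 1], g$dosage[, 2]) - r2), 0.1)
  }
  g1 <- simulate_genotypes(mk(1), 3000, seed = 12)
  expect_equal(ld_r2(g1$dosage[, 1], g1$dosage[, 2]), 1)
  expect_identical(g1$dosage[, 1], g1$dosage[, 2],
                   ignore_attr = TRUE)
})

test_that("invalid SNP parameters are rejected by name", {
  expect_error(snp_spec("bad1", 0.7), "bad1")
  expect_error(snp_spec("bad2", 0), "bad2")
  expect_error(snp_spec("bad3", 0.2, target_r2 = 1.5), "bad3")
  tab <- null_snp_table(2)
  tab$maf[2] <- -0.1
  expect_error(simulate_genotypes(tab, 10), "snp02")
})

test_that("generation is deterministic given config and seed", {
  cfg <- cohort_config(500, snps = null_snp_table(5), missing_rate = 0.02,
                       seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$phenotypes, b$phenotypes)
})

test_that("missingness is inserted at the configured MCAR rate", {
  g <- simulate_genotypes(null_snp_table(20), 2000, seed = 5,
                          missing_rate = 0.03)
  expect_lt(abs(mean(is.na(g$dosage)) - 0.03), 0.005)
  expect_error(cohort_config(100, missing_rate = 0.1), "missing_rate")
})

test_that("attained prevalence tracks the logistic intercept", {
  # null effects, rare-outcome intercept: binomial mean check over 10 seeds
  prevs <- vapply(1:10, function(sd) {
    eff <- effect_spec(intercept = stats::qlogis(0.008),
                       snp_betas = stats::setNames(numeric(0), character(0)))
    cfg <- cohort_config(5000, snps = null_snp_table(2),
                         covariate_moments = list(),
                         environment_moments = list(),
                         effects = eff, seed = sd)
    attr(simulate_cohort(cfg)$phenotypes, "prevalence")
  }, numeric(1))
  se <- sqrt(0.008 * 0.992 / (5000 * 10))
  expect_lt(abs(mean(prevs) - 0.008), 3 * se)
})

test_that("a degenerate intercept yields an all-control cohort", {
  eff <- effect_spec(intercept = stats::qlogis(1e-12),
                     snp_betas = stats::setNames(numeric(0), character(0)))
  cfg <- cohort_config(2000, snps = null_snp_table(2),
                       covariate_moments = list(),
                       environment_moments = list(), effects = eff,
                       seed = 1)
  expect_equal(sum(simulate_cohort(cfg)$phenotypes$outcome), 0)
})

test_that("effect specs referencing unknown SNPs are rejected", {
  eff <- effect_spec(snp_betas = c(ghost = 0.5))
  expect_error(cohort_config(100, snps = null_snp_table(3), effects = eff),
               "ghost")
  cfg <- cohort_config(50, snps = null_snp_table(3),
                       effects = effect_spec(
                         snp_betas = stats::setNames(numeric(0),
                                                     character(0))))
  geno <- simulate_genotypes(null_snp_table(2), 50, seed = 1)
  cfg$effects$snp_betas <- c(snp99 = 0.2)
  expect_error(simulate_phenotypes(geno, cfg), "snp99")
})

test_that("written cohorts round-trip exactly through the readers", {
  cfg <- cohort_config(30, snps = null_snp_table(4), missing_rate = 0.04,
                       seed = 21)
  coh <- simulate_cohort(cfg)
  gpath <- withr::local_tempfile(fileext = ".raw")
  ppath <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh$genotypes, coh$phenotypes, gpath, ppath)
  back <- read_genotypes(gpath)
  expect_identical(back$dosage, coh$genotypes$dosage)
  pheno <- read_phenotypes(ppath)
  expect_equal(pheno$outcome, coh$phenotypes$outcome)
  expect_equal(pheno$age, coh$phenotypes$age, tolerance = 1e-10)
})

test_that("file shape: header plus one line per subject; zero SNPs allowed", {
  coh <- simulate_cohort(cohort_config(3, snps = null_snp_table(2),
                                       seed = 1))
  gpath <- withr::local_tempfile(fileext = ".raw")
  ppath <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh$genotypes, coh$phenotypes, gpath, ppath)
  expect_length(readLines(gpath), 4L)

  empty <- coh$genotypes
  empty$dosage <- empty$dosage[, 0, drop = FALSE]
  empty$snps <- empty$snps[0, , drop = FALSE]
  expect_silent(write_cohort(empty, coh$phenotypes, gpath, ppath))
  expect_length(strsplit(readLines(gpath, n = 1), " ")[[1]], 6L)
})

test_that("mismatched subject counts are rejected on write", {
  coh <- simulate_cohort(cohort_config(5, snps = null_snp_table(2),
                                       seed = 1))
  expect_error(write_cohort(coh$genotypes, coh$phenotypes[1:3, ],
                            tempfile(), tempfile()),
               "subject counts")
})
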