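# Small simulation helpers shared across test files.

null_snp_table <- function(m, maf = 0.3, chromosome = NULL) {
  do.call(rbind, lapply(seq_len(m), function(i) {
    snp_spec(sprintf("snp%02d", i), maf,
             chromosome = if (is.null(chromosome)) i else chromosome[i])
  }))
}

# Case-control cohort with a planted 2-SNP penetrance-cell effect between
# the first two SNPs (co-carrier cells get `delta` extra log-odds).
epistatic_cohort <- function(n, m = 10, maf = 0.3, delta = 1.2,
                             base_logit = stats::qlogis(0.3), seed = 1L) {
  snps <- null_snp_table(m, maf)
  cells <- expand.grid(snp01 = 0:2, snp02 = 0:2)
  cells$delta <- ifelse(cells$snp01 >= 1 & cells$snp02 >= 1, delta, 0)
  eff <- effect_spec(intercept = base_logit,
                     snp_betas = stats::setNames(numeric(0), character(0)),
                     epistasis = list(snps = c("snp01", "snp02"),
                                      cells = cells))
  cfg <- cohort_config(n, snps = snps,
                       covariate_moments = list(age = c(53.7, 5.5)),
                       environment_moments = list(),
                       effects = eff, seed = seed)
  simulate_cohort(cfg)
}
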