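# Cohort with PRS categories and a configurable multiplicative G x E term.
gxe_cohort <- function(n, gxe_beta, seed, env_cutoff = 70) {
  panel <- null_snp_table(3, maf = 0.3)
  betas <- stats::setNames(rep(log(1.3), 3), panel$snp_id)
  eff <- effect_spec(intercept = stats::qlogis(0.1), snp_betas = betas,
                     gxe = if (gxe_beta != 0)
                       list(snps = panel$snp_id, env = "cho_pct",
                            cutoff = env_cutoff, beta = gxe_beta))
  coh <- simulate_cohort(cohort_config(
    n, snps = panel, covariate_moments = list(age = c(53.7, 5.5)),
    environment_moments = list(cho_pct = c(71.7, 20.8)),
    effects = eff, seed = seed))
  scan <- snp_scan(coh$genotypes, coh$phenotypes)
  ori <- orient_risk_alleles(scan, panel$snp_id)
  prs <- compute_prs(coh$genotypes, ori)
  coh$category <- categorize_prs(prs$prs)
  coh$env <- dichotomize(coh$phenotypes, env_spec("cho_pct", env_cutoff))
  coh
}

test_that("dichotomization sends the boundary to the high stratum", {
  d <- data.frame(age = c(54, 55, 56), glucose = c(100, 126, 150))
  expect_identical(as.character(dichotomize(d, env_spec("age", 55))),
                   c("low", "high", "high"))
  expect_identical(as.character(dichotomize(d, env_spec("glucose", 126))),
                   c("low", "high", "high"))
})

test_that("median and percentile cutoffs are computed from the data", {
  d <- data.frame(x = c(1:10, NA))
  med <- dichotomize(d, env_spec("x", source = "median"))
  expect_equal(attr(med, "cutoff"), 5.5)
  expect_true(is.na(med[11]))
  pct <- dichotomize(d, env_spec("x", source = "percentile",
                                 percentile = 0.67))
  expect_equal(sum(pct == "high", na.rm = TRUE), 3)
  expect_equal(attr(pct, "cutoff"),
               stats::quantile(1:10, 0.67, names = FALSE))
  expect_error(dichotomize(data.frame(x = rep(3, 5)),
                           env_spec("x", source = "median")), "degenerate")
  expect_error(dichotomize(d, env_spec("y", 1)), "not found")
  expect_error(dichotomize(data.frame(x = NA_real_), env_spec("x", 1)),
               "missing")
})

test_that("composite predicates build joint strata", {
  d <- data.frame(sbp = c(120, 135, 120), dbp = c(80, 80, 95))
  spec <- env_spec("bp", predicate = function(df)
    df$sbp >= 130 | df$dbp >= 90)
  expect_identical(as.character(dichotomize(d, spec)),
                   c("low", "high", "high"))
})

test_that("stratified ORs anchor the reference at 1 and detect G x E", {
  coh <- gxe_cohort(6000, gxe_beta = 0.25, seed = 51)
  tab <- stratified_or(coh$phenotypes$outcome, coh$category, coh$env,
                       coh$phenotypes, "age")
  expect_true(all(tab$or_[tab$level == "Low"] == 1))
  hi_high <- tab$or_[tab$stratum == "high" & tab$level == "High"]
  lo_high <- tab$or_[tab$stratum == "low" & tab$level == "High"]
  expect_gt(hi_high, lo_high)
})

test_that("null simulations give near-unit stratified ORs", {
  ors <- unlist(lapply(1:5, function(sd) {
    coh <- gxe_cohort(3000, gxe_beta = 0, seed = 60 + sd)
    coh$phenotypes$outcome <- stats::rbinom(3000, 1, 0.2)  # cut all signal
    tab <- stratified_or(coh$phenotypes$outcome, coh$category, coh$env)
    tab$or_[tab$level != "Low"]
  }))
  expect_lt(abs(mean(log(ors))), 0.15)
})

test_that("interaction test is 1 df, errors on constant products", {
  coh <- gxe_cohort(3000, gxe_beta = 0.3, seed = 71)
  ip <- interaction_p(coh$phenotypes$outcome, coh$category, coh$env,
                      coh$phenotypes, "age")
  expect_equal(ip$df, 1)
  expect_gt(ip$p, 0); expect_lte(ip$p, 1)
  const_env <- factor(rep("low", 3000), levels = c("low", "high"))
  expect_error(interaction_p(coh$phenotypes$outcome, coh$category,
                             const_env), "constant")
  ip2 <- interaction_p(coh$phenotypes$outcome, coh$category, coh$env,
                       ordinal = FALSE)
  expect_equal(ip2$df, 2)
})

test_that("a strong multiplicative G x E is detected with high power", {
  hits <- vapply(1:10, function(sd) {
    coh <- gxe_cohort(6000, gxe_beta = 0.3, seed = 200 + sd)
    interaction_p(coh$phenotypes$outcome, coh$category, coh$env)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("interaction p is invariant to swapping the stratum labels", {
  coh <- gxe_cohort(3000, gxe_beta = 0.2, seed = 81)
  flipped <- factor(ifelse(coh$env == "low", "high", "low"),
                    levels = c("low", "high"))
  p1 <- interaction_p(coh$phenotypes$outcome, coh$category, coh$env)$p
  p2 <- interaction_p(coh$phenotypes$outcome, coh$category, flipped)$p
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("without covariates the interaction model reproduces stratum ORs", {
  coh <- gxe_cohort(4000, gxe_beta = 0.2, seed = 91)
  tab <- stratified_or(coh$phenotypes$outcome, coh$category, coh$env)
  ip <- interaction_p(coh$phenotypes$outcome, coh$category, coh$env,
                      ordinal = FALSE)
  cf <- ip$full_fit$coefficients
  expect_equal(tab$or_[tab$stratum == "low" & tab$level == "Medium"],
               exp(cf[["prs_categoriesMedium"]]), tolerance = 1e-6)
  expect_equal(tab$or_[tab$stratum == "low" & tab$level == "High"],
               exp(cf[["prs_categoriesHigh"]]), tolerance = 1e-6)
})

test_that("the G x E report assembles per-environment rows and round-trips", {
  coh <- gxe_cohort(3000, gxe_beta = 0.2, seed = 95)
  specs <- list(env_spec("cho_pct", 70),
                env_spec("age", source = "median"))
  path <- withr::local_tempfile(fileext = ".tsv")
  rep_tab <- gei_report(coh$phenotypes$outcome, coh$category,
                        coh$phenotypes, specs, path = path)
  expect_equal(unique(rep_tab$environment), c("cho_pct", "age"))
  expect_equal(nrow(rep_tab), 12)  # 2 env x 2 strata x 3 categories
  back <- read_tsv(path)
  expect_equal(back$or_, rep_tab$or_, tolerance = 1e-10)

  empty <- gei_report(coh$phenotypes$outcome, coh$category,
                      coh$phenotypes, list())
  expect_equal(nrow(empty), 0)
  expect_true(all(c("environment", "interaction_p") %in% names(empty)))
})
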