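test_that("score residuals reduce to centered case/control indicators", {
  y <- c(rep(1, 5), rep(0, 5))
  sr <- score_residuals(y)
  expect_equal(sort(unique(round(sr$s, 10))), c(-0.5, 0.5))
  expect_lt(abs(sum(sr$s)), 1e-6 * length(y))

  y2 <- c(rep(1, 3), rep(0, 7))
  sr2 <- score_residuals(y2)
  expect_equal(unique(round(sr2$s[y2 == 1], 10)), 0.7)
  expect_equal(unique(round(sr2$s[y2 == 0], 10)), -0.3)

  # one binary covariate: residual is y minus the stratum prevalence
  y3 <- c(1, 1, 0, 0, 1, 0, 0, 0)
  z <- c(1, 1, 1, 1, 0, 0, 0, 0)
  sr3 <- score_residuals(y3, data.frame(z = z), "z")
  expect_equal(sr3$s, y3 - ifelse(z == 1, 0.5, 0.25), tolerance = 1e-6)
})

test_that("cell labeling follows the sum rule with ties and empties low", {
  g <- matrix(c(0, 0, 1, 1, 2, 2), ncol = 1,
              dimnames = list(NULL, "snp"))
  s <- c(0.5, 0.5, -0.5, 0.5, -0.5, 0.5)
  lab <- label_cells(g, s)
  tabs <- lab$cell_table
  expect_equal(tabs$label[tabs$key == 0], "high")  # sum +1
  expect_equal(tabs$label[tabs$key == 1], "low")   # tie, sum 0
  expect_equal(tabs$label[tabs$key == 2], "low")   # tie, sum 0
  # unseen tuple treated as low in evaluation
  ba <- balanced_accuracy(lab, matrix(rep(0:2, 2), ncol = 1), s)
  expect_true(is.finite(ba))
  expect_error(label_cells(matrix(0, 2, 7), s[1:2]), "k_max")
})

test_that("balanced accuracy hits its analytic anchors", {
  g <- matrix(c(rep(0, 4), rep(2, 4)), ncol = 1,
              dimnames = list(NULL, "snp"))
  s <- c(rep(0.5, 4), rep(-0.5, 4))  # genotype separates sign perfectly
  lab <- label_cells(g, s)
  expect_equal(balanced_accuracy(lab, g, s), 1)

  # all-low labeling: sensitivity 0, specificity 1
  lab_low <- lab
  lab_low$high_keys <- numeric(0)
  expect_equal(balanced_accuracy(lab_low, g, s), 0.5)

  # one-signed scores leave BA undefined
  expect_true(is.na(balanced_accuracy(lab, g, abs(s))))
})

test_that("no-covariate GMDR matches the brute-force MDR oracle exactly", {
  set.seed(41)
  for (rep in 1:30) {
    k <- sample(1:3, 1)
    n <- sample(10:30, 1)
    g <- matrix(sample(0:2, n * k, TRUE), n, k,
                dimnames = list(NULL, paste0("s", 1:k)))
    y <- stats::rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- score_residuals(y)$s
    lab <- label_cells(g, s)
    oracle <- mdr_oracle(g, y)
    expect_setequal(lab$high_keys, oracle_key_to_int(oracle$high_cells))
    expect_equal(balanced_accuracy(lab, g, s), oracle$ba,
                 tolerance = 1e-10)
  }
})

test_that("cross-validation is seeded, stratified and overfits training", {
  coh <- epistatic_cohort(600, m = 4, delta = 0, seed = 19)
  s <- score_residuals(coh$phenotypes$outcome, coh$phenotypes, "age")
  cv1 <- cross_validate(c("snp01", "snp02"), coh$genotypes, s, seed = 5)
  cv2 <- cross_validate(c("snp01", "snp02"), coh$genotypes, s, seed = 5)
  expect_identical(cv1, cv2)
  cv3 <- cross_validate(c("snp01", "snp02"), coh$genotypes, s, seed = 6)
  expect_false(identical(cv1$teba, cv3$teba))
  expect_error(cross_validate("snp01", coh$genotypes, s, n_folds = 1000),
               "folds")

  # under the null, training BA exceeds testing BA on average
  diffs <- vapply(1:15, function(sd) {
    coh <- epistatic_cohort(400, m = 3, delta = 0, seed = 100 + sd)
    s <- score_residuals(coh$phenotypes$outcome)
    cv <- cross_validate(c("snp01", "snp02"), coh$genotypes, s, seed = sd)
    attr(cv, "trba") - attr(cv, "teba")
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("permuting outcomes drives testing accuracy to chance", {
  coh <- epistatic_cohort(2000, m = 3, delta = 1.2, seed = 8)
  tebas <- vapply(1:100, function(i) {
    set.seed(3000 + i)
    y_perm <- sample(coh$phenotypes$outcome)
    s <- score_residuals(y_perm)
    attr(cross_validate(c("snp01", "snp02"), coh$genotypes, s,
                        seed = i), "teba")
  }, numeric(1))
  expect_lt(abs(mean(tebas) - 0.5), 0.02)
})

test_that("an embedded epistatic pair lifts testing accuracy above chance", {
  tebas <- vapply(1:5, function(sd) {
    coh <- epistatic_cohort(2000, seed = 400 + sd)
    s <- score_residuals(coh$phenotypes$outcome, coh$phenotypes, "age")
    attr(cross_validate(c("snp01", "snp02"), coh$genotypes, s, seed = sd),
         "teba")
  }, numeric(1))
  expect_gt(mean(tebas), 0.55)
})

test_that("signed-rank p-values are exact on their anchors", {
  expect_equal(sign_test(rep(0.5, 10)), 1)
  expect_equal(sign_test(rep(0.55, 10)), 2 / 1024, tolerance = 1e-12)
  # 5 above / 5 below with symmetric magnitudes
  sym <- 0.5 + c(1:5, -(1:5)) / 100
  expect_equal(sign_test(sym), 1)
  expect_error(sign_test(0.6), "folds")
  # cross-check the exact enumeration against the reference implementation
  set.seed(77)
  for (i in 1:10) {
    x <- round(stats::runif(8, 0.3, 0.7), 3)
    x <- x[x != 0.5]
    if (anyDuplicated(abs(x - 0.5))) next
    expect_equal(sign_test(x),
                 stats::wilcox.test(x, mu = 0.5, exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  # plain sign test option
  expect_equal(sign_test(rep(0.6, 10), method = "sign"),
               stats::binom.test(10, 10)$p.value)
})

test_that("model search finds the planted pair with high consistency", {
  coh <- epistatic_cohort(2000, seed = 23)
  s <- score_residuals(coh$phenotypes$outcome, coh$phenotypes, "age")
  res <- search_best_model(coh$genotypes, s,
                           coh$genotypes$snps$snp_id, k_range = 2,
                           seed = 11)
  expect_identical(res$snp_set[1], "snp01,snp02")
  expect_gte(res$cvc[1], 8)
  expect_lt(res$sign_p[1], 0.05)
  expect_equal(res$n_folds[1], 10)
})

test_that("search edge cases: single candidate, caps, greedy", {
  coh <- epistatic_cohort(500, m = 3, delta = 1.2, seed = 29)
  s <- score_residuals(coh$phenotypes$outcome)
  one <- search_best_model(coh$genotypes, s, "snp01", k_range = 1,
                           seed = 2)
  expect_identical(one$snp_set, "snp01")
  expect_equal(one$cvc, 10)  # single candidate: chosen by every fold

  expect_error(search_best_model(coh$genotypes, s,
                                 coh$genotypes$snps$snp_id, k_range = 2,
                                 seed = 2, max_models = 5),
               "greedy")
  greedy <- search_best_model(coh$genotypes, s,
                              coh$genotypes$snps$snp_id, k_range = 2,
                              seed = 11, strategy = "greedy")
  expect_identical(greedy$snp_set[1], "snp01,snp02")
  expect_error(search_best_model(coh$genotypes, s, "snp01", k_range = 4,
                                 seed = 1), "candidates")
})

test_that("null data rarely yields a significant sign test", {
  hits <- vapply(1:25, function(sd) {
    coh <- epistatic_cohort(400, m = 4, delta = 0, seed = 700 + sd)
    s <- score_residuals(coh$phenotypes$outcome)
    res <- search_best_model(coh$genotypes, s, coh$genotypes$snps$snp_id,
                             k_range = 2, seed = sd)
    res$sign_p[1] < 0.05
  }, logical(1))
  expect_lt(mean(hits), 0.35)
})
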