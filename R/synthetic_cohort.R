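#' Specify a simulated SNP
#'
#' @param snp_id Character id (e.g. "rs3763969").
#' @param maf Minor allele frequency, in (0, 0.5].
#' @param chromosome Integer chromosome label.
#' @param ld_block Optional block label; SNPs sharing a label are drawn from
#'   a common latent Gaussian factor so their dosages are correlated.
#' @param target_r2 Optional pairwise dosage r-squared in \[0, 1\] aimed at
#'   within the block.
#' @param minor_allele Counted allele letter used in .raw column headers.
#' @return A one-row data.frame; rbind rows to build a panel.
#' @export
snp_spec <- function(snp_id, maf, chromosome = 1L, ld_block = NA_character_,
                     target_r2 = NA_real_, minor_allele = "A") {
  if (!is.numeric(maf) || is.na(maf) || maf <= 0 || maf > 0.5) {
    stop("snp ", snp_id, ": maf must be in (0, 0.5], got ", maf)
  }
  if (!is.na(target_r2) && (target_r2 < 0 || target_r2 > 1)) {
    stop("snp ", snp_id, ": target_r2 must be in [0, 1], got ", target_r2)
  }
  data.frame(snp_id = as.character(snp_id),
             chromosome = as.integer(chromosome),
             maf = as.numeric(maf),
             ld_block = as.character(ld_block),
             target_r2 = as.numeric(target_r2),
             minor_allele = as.character(minor_allele),
             stringsAsFactors = FALSE)
}

#' Build a SNP table from the bundled candidate panel
#'
#' @param panel Data.frame as returned by [glaucoma_snp_panel()].
#' @return SNP table suitable for [simulate_genotypes()].
#' @export
snp_table_from_panel <- function(panel = glaucoma_snp_panel()) {
  do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    snp_spec(panel$snp_id[i], panel$maf[i], panel$chromosome[i],
             minor_allele = panel$minor_allele[i])
  }))
}

#' Specify the outcome-generating effects of a synthetic cohort
#'
#' The outcome is Bernoulli with
#' `logit(p) = intercept + sum(snp_betas * dosage) + sum(covariate_betas * x)
#'  + epistasis cell offset + gxe term`.
#'
#' @param intercept Baseline log-odds.  `stats::qlogis(0.008)` reproduces the
#'   rare-outcome regime of the reference cohort (377 / 48,197).
#' @param snp_betas Named numeric vector, per-minor-allele log odds ratios.
#'   Defaults to the log of the published panel ORs.
#' @param covariate_betas Named numeric vector of log-OR per unit of each
#'   covariate (names must match `covariate_moments`).
#' @param epistasis Optional penetrance-table delta: a list with `snps`
#'   (character vector of k SNP ids) and `cells` (data.frame with one column
#'   per SNP holding dosages 0/1/2 and a `delta` column of extra log-odds
#'   applied to subjects in that multilocus cell).
#' @param gxe Optional gene-environment effect: a list with `snps`
#'   (character), `env` (environment column name), `cutoff` (the indicator
#'   is `env >= cutoff`) and `beta` (log-OR per risk-allele-count unit when
#'   the indicator is on).  Risk alleles are oriented by the sign of each
#'   SNP's `snp_betas` entry (protective minor alleles count the major
#'   allele); SNPs without a main effect count the minor allele.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(intercept = stats::qlogis(0.008),
                        snp_betas = NULL, covariate_betas = NULL,
                        epistasis = NULL, gxe = NULL) {
  if (is.null(snp_betas)) {
    panel <- glaucoma_snp_panel()
    snp_betas <- stats::setNames(log(panel$or_), panel$snp_id)
  }
  if (!is.null(epistasis)) {
    stopifnot(is.list(epistasis), !is.null(epistasis$snps),
              is.data.frame(epistasis$cells),
              all(epistasis$snps %in% names(epistasis$cells)),
              "delta" %in% names(epistasis$cells))
  }
  if (!is.null(gxe)) {
    stopifnot(is.list(gxe), !is.null(gxe$snps), !is.null(gxe$env),
              is.numeric(gxe$cutoff), is.numeric(gxe$beta))
  }
  structure(list(intercept = intercept, snp_betas = snp_betas,
                 covariate_betas = covariate_betas,
                 epistasis = epistasis, gxe = gxe),
            class = "effect_spec")
}

#' Configuration of a synthetic case-control cohort
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param snps SNP table ([snp_spec()] rows); defaults to the bundled
#'   ten-SNP candidate panel.
#' @param covariate_moments,environment_moments Named lists; each element is
#'   `c(mean, sd)` (Gaussian) or a single probability in (0,1) (Bernoulli).
#' @param effects An [effect_spec()]; by default, the published per-SNP ORs
#'   for whichever panel SNPs are present in `snps` (so a custom SNP table
#'   defaults to a null outcome model at the rare-outcome intercept).
#' @param missing_rate Genotype missingness fraction in \[0, 0.04\]
#'   (missing-completely-at-random), matching a <4% call-rate regime.
#' @param seed Integer seed; mandatory, all randomness derives from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects, snps = snp_table_from_panel(),
                          covariate_moments = default_cohort_moments()[
                            c("age", "male", "bmi")],
                          environment_moments = default_cohort_moments()[
                            c("cho_pct", "glucose")],
                          effects = NULL, missing_rate = 0,
                          seed = 1L) {
  stopifnot(n_subjects >= 1)
  if (is.null(effects)) {
    panel <- glaucoma_snp_panel()
    betas <- stats::setNames(log(panel$or_), panel$snp_id)
    effects <- effect_spec(
      snp_betas = betas[names(betas) %in% snps$snp_id])
  }
  if (missing_rate < 0 || missing_rate > 0.04) {
    stop("missing_rate must be in [0, 0.04] (call-rate bound), got ",
         missing_rate)
  }
  eff_snps <- names(effects$snp_betas)
  if (!is.null(effects$epistasis)) eff_snps <- c(eff_snps, effects$epistasis$snps)
  if (!is.null(effects$gxe)) eff_snps <- c(eff_snps, effects$gxe$snps)
  missing_snps <- setdiff(eff_snps, snps$snp_id)
  if (length(missing_snps)) {
    stop("effect spec references SNPs absent from the panel: ",
         paste(missing_snps, collapse = ", "))
  }
  structure(list(n_subjects = as.integer(n_subjects), snps = snps,
                 covariate_moments = covariate_moments,
                 environment_moments = environment_moments,
                 effects = effects, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Expected dosage correlation between two HWE SNPs whose genotypes are cut
# from a standard bivariate Gaussian with latent correlation rho.  Used to
# calibrate rho against a target dosage r^2; the thresholding preserves the
# per-SNP HWE marginals exactly.
latent_dosage_cor <- function(rho, q1, q2) {
  if (rho >= 1) rho <- 1 - 1e-12
  t1 <- stats::qnorm(c(q1^2, q1^2 + 2 * q1 * (1 - q1)))
  t2 <- stats::qnorm(c(q2^2, q2^2 + 2 * q2 * (1 - q2)))
  s <- sqrt(1 - rho^2)
  f <- function(z) {
    d1 <- 2 * (z < t1[1]) + (z >= t1[1] & z < t1[2])
    cond2 <- 2 * stats::pnorm((t2[1] - rho * z) / s) +
      (stats::pnorm((t2[2] - rho * z) / s) -
         stats::pnorm((t2[1] - rho * z) / s))
    d1 * cond2 * stats::dnorm(z)
  }
  e12 <- stats::integrate(f, -8, 8, subdivisions = 400L)$value
  (e12 - 4 * q1 * q2) /
    sqrt(2 * q1 * (1 - q1) * 2 * q2 * (1 - q2))
}

# Solve for the latent correlation that yields the target dosage r^2.
calibrate_latent_rho <- function(target_r2, q1, q2) {
  if (target_r2 <= 0) return(0)
  target_r <- sqrt(target_r2)
  if (target_r2 >= 1 - 1e-9) return(1)
  upper <- latent_dosage_cor(0.999999, q1, q2)
  if (target_r >= upper) return(1)
  stats::uniroot(function(r) latent_dosage_cor(r, q1, q2) - target_r,
                 c(0, 0.999999), tol = 1e-8)$root
}

dosage_from_latent <- function(z, q) {
  t <- stats::qnorm(c(q^2, q^2 + 2 * q * (1 - q)))
  2 * (z < t[1]) + 1 * (z >= t[1] & z < t[2])
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Independent SNPs are drawn from HWE genotype probabilities (q^2, 2pq, p^2
#' for minor-allele dosages 2, 1, 0).  SNPs sharing an `ld_block` label are
#' thresholded from correlated latent Gaussians: the latent correlation is
#' calibrated numerically so the realized dosage r-squared approximates
#' `target_r2`, while HWE marginals are preserved exactly.  Missing entries
#' are inserted completely at random at `missing_rate`.
#'
#' @param snps SNP table ([snp_spec()] rows).
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param missing_rate MCAR missingness fraction.
#' @return A `genotype_matrix`: list with `dosage` (n x n_snp numeric matrix,
#'   NA = missing, colnames = snp ids, rownames = subject ids) and `snps`
#'   (the SNP table).
#' @export
simulate_genotypes <- function(snps, n, seed = 1L, missing_rate = 0) {
  stopifnot(n >= 1)
  bad <- which(is.na(snps$maf) | snps$maf <= 0 | snps$maf > 0.5)
  if (length(bad)) {
    stop("invalid maf for SNP ", paste(snps$snp_id[bad], collapse = ", "))
  }
  if (!is.null(snps$target_r2)) {
    bad <- which(!is.na(snps$target_r2) &
                   (snps$target_r2 < 0 | snps$target_r2 > 1))
    if (length(bad)) {
      stop("invalid target_r2 for SNP ",
           paste(snps$snp_id[bad], collapse = ", "))
    }
  }
  set.seed(seed)
  m <- nrow(snps)
  dosage <- matrix(NA_real_, n, m,
                   dimnames = list(sprintf("S%05d", seq_len(n)),
                                   snps$snp_id))
  blocks <- if (is.null(snps$ld_block)) rep(NA_character_, m) else snps$ld_block
  done <- rep(FALSE, m)
  for (j in seq_len(m)) {
    if (done[j]) next
    if (is.na(blocks[j])) {
      dosage[, j] <- dosage_from_latent(stats::rnorm(n), snps$maf[j])
      done[j] <- TRUE
    } else {
      idx <- which(blocks == blocks[j])
      r2s <- snps$target_r2[idx]
      r2 <- r2s[!is.na(r2s)][1]
      if (is.na(r2)) r2 <- 0
      qs <- snps$maf[idx]
      rho_pair <- calibrate_latent_rho(r2, qs[1], qs[length(qs)])
      a <- sqrt(rho_pair)  # common-factor loading: pairwise latent cor = a^2
      u <- stats::rnorm(n)
      for (k in idx) {
        z <- if (rho_pair >= 1) u else
          a * u + sqrt(1 - a^2) * stats::rnorm(n)
        dosage[, k] <- dosage_from_latent(z, snps$maf[k])
        done[k] <- TRUE
      }
    }
  }
  if (missing_rate > 0) {
    miss <- stats::runif(n * m) < missing_rate
    dosage[matrix(miss, n, m)] <- NA_real_
  }
  structure(list(dosage = dosage, snps = snps), class = "genotype_matrix")
}

# Linear predictor of the synthetic outcome model; missing dosages enter at
# their HWE expectation (2 * maf) so the predictor is defined for everyone.
synthetic_logit <- function(geno, pheno_df, effects) {
  dosage <- geno$dosage
  eta <- rep(effects$intercept, nrow(dosage))
  for (snp in names(effects$snp_betas)) {
    d <- dosage[, snp]
    d[is.na(d)] <- 2 * geno$snps$maf[geno$snps$snp_id == snp]
    eta <- eta + effects$snp_betas[[snp]] * d
  }
  for (nm in names(effects$covariate_betas)) {
    eta <- eta + effects$covariate_betas[[nm]] * pheno_df[[nm]]
  }
  if (!is.null(effects$epistasis)) {
    epi <- effects$epistasis
    sub <- dosage[, epi$snps, drop = FALSE]
    key <- apply(sub, 1L, paste, collapse = ",")
    cell_key <- apply(epi$cells[, epi$snps, drop = FALSE], 1L,
                      paste, collapse = ",")
    delta <- stats::setNames(epi$cells$delta, cell_key)[key]
    delta[is.na(delta)] <- 0
    eta <- eta + delta
  }
  if (!is.null(effects$gxe)) {
    g <- effects$gxe
    # risk-allele count: SNPs with a protective per-minor-allele beta are
    # counted on the major allele (2 - d); SNPs without a main effect
    # default to minor = risk
    sub <- dosage[, g$snps, drop = FALSE]
    for (snp in g$snps) {
      b <- effects$snp_betas[snp]
      if (!is.na(b) && b < 0) sub[, snp] <- 2 - sub[, snp]
    }
    risk <- rowSums(sub, na.rm = TRUE)
    ind <- as.numeric(pheno_df[[g$env]] >= g$cutoff)
    eta <- eta + g$beta * risk * ind
  }
  eta
}

draw_moment_columns <- function(moments, n) {
  out <- list()
  for (nm in names(moments)) {
    mom <- moments[[nm]]
    out[[nm]] <- if (length(mom) == 1L) {
      stats::rbinom(n, 1L, mom)
    } else {
      stats::rnorm(n, mom[1], mom[2])
    }
  }
  out
}

#' Simulate phenotypes, covariates and environments for a cohort
#'
#' Covariates and environment variables are drawn from the configured
#' moments (Gaussian for `c(mean, sd)`, Bernoulli for a single probability);
#' the binary outcome is Bernoulli with the logistic linear predictor of the
#' configured [effect_spec()].  The attained prevalence is attached as
#' attribute `"prevalence"`.
#'
#' @param genotypes A `genotype_matrix` (normally from
#'   [simulate_genotypes()] with the same config).
#' @param config A [cohort_config()].
#' @return Data.frame (`phenotype_table`) with `subject_id`, `outcome`
#'   (0/1) and one column per covariate / environment variable.
#' @export
simulate_phenotypes <- function(genotypes, config) {
  effects <- config$effects
  eff_snps <- names(effects$snp_betas)
  if (!is.null(effects$epistasis)) eff_snps <- c(eff_snps, effects$epistasis$snps)
  if (!is.null(effects$gxe)) eff_snps <- c(eff_snps, effects$gxe$snps)
  absent <- setdiff(eff_snps, colnames(genotypes$dosage))
  if (length(absent)) {
    stop("effect SNPs absent from genotype matrix: ",
         paste(absent, collapse = ", "))
  }
  n <- nrow(genotypes$dosage)
  set.seed(config$seed + 1L)
  pheno <- data.frame(subject_id = rownames(genotypes$dosage),
                      stringsAsFactors = FALSE)
  for (col in draw_moment_columns(c(config$covariate_moments,
                                    config$environment_moments), n)) {
    pheno[[length(pheno) + 1L]] <- col
  }
  names(pheno) <- c("subject_id", names(config$covariate_moments),
                    names(config$environment_moments))
  eta <- synthetic_logit(genotypes, pheno, effects)
  p <- stats::plogis(eta)
  pheno$outcome <- stats::rbinom(n, 1L, p)
  pheno <- pheno[, c("subject_id", "outcome",
                     setdiff(names(pheno), c("subject_id", "outcome")))]
  attr(pheno, "prevalence") <- mean(pheno$outcome)
  class(pheno) <- c("phenotype_table", "data.frame")
  pheno
}

#' Calibrate the outcome-model intercept to a target prevalence
#'
#' Solves for the intercept at which the expected cohort prevalence (the
#' mean of the per-subject outcome probabilities under the configured
#' effects, given the realized genotypes and the covariates the config will
#' draw) equals `target`.  Useful for emulating a stated case fraction
#' exactly regardless of the genetic and covariate effects in play.
#'
#' @param genotypes A `genotype_matrix` simulated from `config`.
#' @param config A [cohort_config()].
#' @param target Target prevalence in (0, 1).
#' @return The config with its effect intercept replaced.
#' @export
calibrate_intercept <- function(genotypes, config, target) {
  stopifnot(target > 0, target < 1)
  set.seed(config$seed + 1L)
  n <- nrow(genotypes$dosage)
  cols <- draw_moment_columns(c(config$covariate_moments,
                                config$environment_moments), n)
  pheno <- as.data.frame(cols, optional = TRUE)
  eff0 <- config$effects
  eff0$intercept <- 0
  eta <- synthetic_logit(genotypes, pheno, eff0)
  config$effects$intercept <- stats::uniroot(
    function(b) mean(stats::plogis(b + eta)) - target,
    c(-20, 10), tol = 1e-10)$root
  config
}

#' Write a simulated cohort to disk
#'
#' Genotypes go to PLINK `.raw`-dialect text (columns FID IID PAT MAT SEX
#' PHENOTYPE then `<snp_id>_<minor_allele>` dosages with NA for missing;
#' PHENOTYPE uses the PLINK 1/2 control/case coding), phenotypes to CSV,
#' and optionally the configuration to YAML.  Files round-trip exactly
#' through [read_genotypes()] / [read_phenotypes()].
#'
#' @param genotypes A `genotype_matrix`.
#' @param phenotypes A phenotype table with matching subjects.
#' @param genotype_path,phenotype_path Output paths.
#' @param config Optional [cohort_config()] echoed to `config_path` as YAML.
#' @param config_path Optional YAML path.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(genotypes, phenotypes, genotype_path,
                         phenotype_path, config = NULL, config_path = NULL) {
  if (nrow(genotypes$dosage) != nrow(phenotypes)) {
    stop("genotype and phenotype subject counts differ (",
         nrow(genotypes$dosage), " vs ", nrow(phenotypes), ")")
  }
  ids <- rownames(genotypes$dosage)
  geno_df <- data.frame(FID = ids, IID = ids, PAT = 0L, MAT = 0L,
                        SEX = 0L,
                        PHENOTYPE = phenotypes$outcome + 1L,
                        stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(genotypes$dosage) > 0) {
    snp_cols <- as.data.frame(genotypes$dosage, check.names = FALSE)
    names(snp_cols) <- paste0(genotypes$snps$snp_id, "_",
                              genotypes$snps$minor_allele)
    geno_df <- cbind(geno_df, snp_cols)
  }
  utils::write.table(geno_df, genotype_path, sep = " ", quote = FALSE,
                     row.names = FALSE, na = "NA")
  utils::write.csv(as.data.frame(phenotypes), phenotype_path,
                   row.names = FALSE, quote = FALSE)
  if (!is.null(config_path) && !is.null(config)) {
    echo <- list(n_subjects = config$n_subjects,
                 missing_rate = config$missing_rate, seed = config$seed,
                 snps = config$snps$snp_id,
                 covariates = names(config$covariate_moments),
                 environments = names(config$environment_moments))
    yaml::write_yaml(echo, config_path)
  }
  invisible(c(genotype_path, phenotype_path))
}

#' Simulate a complete cohort (genotypes + phenotypes) from one config
#'
#' @param config A [cohort_config()].
#' @return List with `genotypes` and `phenotypes`.
#' @export
simulate_cohort <- function(config) {
  geno <- simulate_genotypes(config$snps, config$n_subjects,
                             seed = config$seed,
                             missing_rate = config$missing_rate)
  phen <- simulate_phenotypes(geno, config)
  list(genotypes = geno, phenotypes = phen)
}
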