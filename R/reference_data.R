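#' Candidate SNP panel for the glaucoma case-control analysis
#'
#' The ten intronic/near-gene variants that survived the logistic screening
#' and LD-exclusion steps in the KoGES hospital-based glaucoma study, with
#' their published per-minor-allele adjusted odds ratios, minor allele
#' frequencies and Hardy-Weinberg p-values.  These values are the default
#' parameterisation of [simulate_genotypes()] and [effect_spec()]: the
#' simulator draws genotypes at these MAFs and wires the published ORs into
#' the outcome model, so synthetic cohorts have the marginal structure the
#' downstream scan, GMDR search and PRS stages expect.
#'
#' @return A data.frame with one row per SNP and columns `chromosome`,
#'   `snp_id`, `position`, `minor_allele`, `or_`, `ci_low`, `ci_high`,
#'   `p`, `gene`, `maf`, `hwe_p`.
#' @export
#' @examples
#' panel <- glaucoma_snp_panel()
#' range(panel$or_)
glaucoma_snp_panel <- function() {
  data.frame(
    chromosome   = c(4L, 7L, 8L, 9L, 9L, 12L, 13L, 15L, 16L, 18L),
    snp_id       = c("rs3763969", "rs1852542", "rs1020236", "rs523096",
                     "rs2073823", "rs12314390", "rs7335337", "rs1319859",
                     "rs12449180", "rs3902981"),
    position     = c(16648246L, 42096521L, 135543194L, 22019129L,
                     136132516L, 20597977L, 38221067L, 99230263L,
                     83547527L, 12658191L),
    minor_allele = c("T", "T", "C", "G", "A", "T", "G", "G", "G", "G"),
    or_          = c(0.63, 1.67, 1.48, 0.73, 1.33, 1.70, 1.78, 1.32,
                     1.42, 0.73),
    ci_low       = c(0.48, 1.24, 1.19, 0.57, 1.13, 1.29, 1.34, 1.13,
                     1.18, 0.62),
    ci_high      = c(0.83, 2.25, 1.83, 0.93, 1.56, 2.25, 2.37, 1.53,
                     1.69, 0.87),
    p            = c(9.7e-4, 6.6e-4, 4.4e-4, 1.0e-2, 7.6e-4, 1.8e-4,
                     7.8e-5, 3.5e-4, 1.3e-4, 3.6e-4),
    gene         = c("LDB2", "GLI3", "ZFAT", "CDKN2B", "ABO", "PDE3A",
                     "TRPC4", "IGF1R", "CDH13", "SPIRE1"),
    maf          = c(0.120, 0.041, 0.093, 0.134, 0.215, 0.048, 0.041,
                     0.300, 0.162, 0.300),
    hwe_p        = c(0.082, 0.559, 0.732, 0.972, 0.941, 0.558, 0.230,
                     0.226, 0.162, 0.492),
    stringsAsFactors = FALSE
  )
}

#' SNPs of the published best gene-gene interaction model
#'
#' The five-SNP subset of [glaucoma_snp_panel()] selected as the best GMDR
#' model in the source cohort (LDB2, CDKN2B, ABO, PDE3A, CDH13).
#'
#' @return Character vector of five SNP ids.
#' @export
glaucoma_best_model_snps <- function() {
  c("rs3763969", "rs523096", "rs2073823", "rs12314390", "rs12449180")
}

#' Published descriptive counts of the KoGES glaucoma cohort
#'
#' Summary counts from the hospital-based KoGES cohort (2004-2013) behind
#' the analysis this package implements: recruitment totals by sex,
#' non-response to the glaucoma question, case/control split, and the
#' categorical descriptive tables (lifestyle and metabolic-syndrome
#' frequencies by glaucoma status) with the percentages as published.
#' They anchor the simulator's defaults (prevalence, covariate mix) and let
#' the test-suite verify that the published group totals and within-group
#' percentages are internally consistent.
#'
#' @return A list with elements:
#'   \describe{
#'     \item{recruitment}{named integer vector: `men`, `women`,
#'       `no_answer` (excluded), `cases`, `controls`.}
#'     \item{categorical}{data.frame with columns `table`, `variable`,
#'       `level`, `group` ("control"/"case"), `count`, `pct_printed`
#'       (the published within-group percentage).}
#'   }
#' @export
koges_reference_counts <- function() {
  recruitment <- c(men = 20274L, women = 38371L, no_answer = 10448L,
                   cases = 377L, controls = 47820L)
  categorical <- data.frame(
    table = c(rep("lifestyle", 20L), rep("metabolic", 4L)),
    variable = c(
      "gender_male", "gender_male",
      rep("education", 6L), rep("income", 8L), rep("exercise", 4L),
      rep("metabolic_syndrome", 2L), rep("high_bp", 2L)
    ),
    level = c(
      "male", "male",
      rep(c("<high school", "high school", "college+"), each = 2L),
      rep(c("<$1000", "$1000-$2000", "$2000-$4000", ">$4000"), each = 2L),
      rep(c("no", "yes"), each = 2L),
      "yes", "yes", "yes", "yes"
    ),
    group = c(
      "control", "case",
      rep(c("control", "case"), 3L),
      rep(c("control", "case"), 4L),
      rep(c("control", "case"), 2L),
      "control", "case", "control", "case"
    ),
    count = c(
      16193L, 171L,
      6417L, 66L, 7689L, 60L, 20619L, 131L,
      4508L, 66L, 9722L, 78L, 20047L, 133L, 11084L, 79L,
      21531L, 145L, 26144L, 230L,
      6673L, 81L, 11627L, 138L
    ),
    pct_printed = c(
      33.9, 45.4,
      18.5, 25.7, 22.1, 23.4, 59.4, 51.0,
      9.94, 18.5, 21.4, 21.9, 44.2, 37.4, 24.4, 22.2,
      45.2, 38.7, 54.8, 61.3,
      14.0, 21.5, 24.3, 36.6
    ),
    stringsAsFactors = FALSE
  )
  list(recruitment = recruitment, categorical = categorical)
}

#' Default covariate and environment moments for synthetic cohorts
#'
#' Continuous moments (mean, sd) taken from the published cohort
#' descriptives: age 53.7 +/- 5.5 years, BMI 23.9 +/- 2.8 kg/m^2, energy
#' intake 1743 +/- 531 kcal/day, carbohydrate intake 71.7 +/- 20.8 energy%,
#' fasting serum glucose 95.0 +/- 20.2 mg/dL; male fraction 0.339.
#'
#' @return Named list usable as `covariate_moments` / `environment_moments`
#'   in [cohort_config()]: each element either `c(mean, sd)` for a Gaussian
#'   variable or a single probability for a Bernoulli one.
#' @export
default_cohort_moments <- function() {
  list(
    age       = c(53.7, 5.5),
    male      = 0.339,
    bmi       = c(23.9, 2.8),
    energy    = c(1743, 531),
    cho_pct   = c(71.7, 20.8),
    glucose   = c(95.0, 20.2)
  )
}
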