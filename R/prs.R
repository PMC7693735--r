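#' Orient model SNPs so the counted allele is the risk allele
#'
#' The risk allele of each model SNP is fixed by the sign of its per-allele
#' log-odds from the association scan: positive beta means the counted
#' (minor) allele raises risk and dosages are kept as-is; negative beta
#' means the major allele is the risk allele and dosages are reflected
#' (d -> 2 - d).  A zero beta leaves the risk allele undefined and is an
#' error.
#'
#' @param scan Scan table from [snp_scan()] covering every model SNP.
#' @param model_snps SNP ids of the model.
#' @return Data.frame (`risk_orientation`) with `snp_id`, `beta`, `flip`
#'   (TRUE when the recoding is d -> 2 - d) and `risk_is_minor`.
#' @export
orient_risk_alleles <- function(scan, model_snps) {
  idx <- match(model_snps, scan$snp_id)
  if (anyNA(idx)) {
    stop("no scan record for: ",
         paste(model_snps[is.na(idx)], collapse = ", "))
  }
  beta <- scan$beta[idx]
  if (any(beta == 0)) {
    stop("zero association beta, risk allele undefined for: ",
         paste(model_snps[beta == 0], collapse = ", "))
  }
  data.frame(snp_id = model_snps, beta = beta, flip = beta < 0,
             risk_is_minor = beta > 0, stringsAsFactors = FALSE)
}

# Apply a risk orientation to a dosage matrix: flipped SNPs get 2 - d.
recode_risk_dosage <- function(dosage, orientation) {
  out <- dosage[, orientation$snp_id, drop = FALSE]
  flip <- orientation$snp_id[orientation$flip]
  out[, flip] <- 2 - out[, flip, drop = FALSE]
  out
}

#' Unweighted risk-allele-count polygenic risk score
#'
#' The PRS of a subject is the integer sum of risk-allele counts (0/1/2 per
#' SNP after orientation) over the model SNPs, so it lies in \[0, 2k\].
#' Subjects missing any model genotype are excluded (`prs = NA`) under the
#' default policy, or have each missing dosage imputed with the rounded mean
#' risk-allele count of that SNP under `missing_policy = "impute"`.
#'
#' @param genotypes A `genotype_matrix` containing the model SNPs.
#' @param orientation A `risk_orientation` from [orient_risk_alleles()].
#' @param missing_policy "exclude" (default) or "impute".
#' @return Data.frame (`prs_assignment`) with `subject_id`, `prs`,
#'   `n_missing_model_snps`.
#' @export
compute_prs <- function(genotypes, orientation,
                        missing_policy = c("exclude", "impute")) {
  missing_policy <- match.arg(missing_policy)
  absent <- setdiff(orientation$snp_id, colnames(genotypes$dosage))
  if (length(absent)) {
    stop("model SNPs absent from genotypes: ",
         paste(absent, collapse = ", "))
  }
  risk <- recode_risk_dosage(genotypes$dosage, orientation)
  n_miss <- rowSums(is.na(risk))
  if (missing_policy == "impute") {
    for (j in seq_len(ncol(risk))) {
      fill <- round(mean(risk[, j], na.rm = TRUE))
      risk[is.na(risk[, j]), j] <- fill
    }
    prs <- as.integer(rowSums(risk))
  } else {
    prs <- ifelse(n_miss > 0, NA_integer_, as.integer(rowSums(risk)))
  }
  data.frame(subject_id = rownames(genotypes$dosage), prs = prs,
             n_missing_model_snps = n_miss, stringsAsFactors = FALSE)
}

#' Categorize PRS into Low / Medium / High
#'
#' Tertile mode places boundaries at the empirical 1/3 and 2/3 quantiles of
#' the scored subjects (type-1 quantiles, so boundaries are attained score
#' values and ties fall in the lower category).  Fixed mode applies closed
#' integer intervals `[0, c1]`, `[c1+1, c2]`, `[c2+1, 2k]` from
#' `fixed_cutoffs = c(c1, c2)`; the conventional glaucoma-model cutoffs are
#' `c(3, 5)` (categories 0-3, 4-5, >=6).
#'
#' @param scores Integer PRS vector (NAs allowed, returned as NA).
#' @param mode "tertile" (default) or "fixed".
#' @param fixed_cutoffs Two increasing boundary scores for fixed mode.
#' @return Factor with levels Low/Medium/High; boundaries in attribute
#'   `"cutoffs"` and category counts in `"sizes"`.
#' @export
categorize_prs <- function(scores, mode = c("tertile", "fixed"),
                           fixed_cutoffs = c(3, 5)) {
  mode <- match.arg(mode)
  usable <- scores[!is.na(scores)]
  if (!length(usable)) stop("no non-missing scores")
  if (mode == "tertile") {
    cuts <- stats::quantile(usable, c(1 / 3, 2 / 3), type = 1, names = FALSE)
    if (cuts[1] == max(usable)) {
      warning("degenerate score distribution; all subjects in Low")
    }
  } else {
    if (length(fixed_cutoffs) != 2 || diff(fixed_cutoffs) <= 0) {
      stop("fixed_cutoffs must be two increasing boundaries")
    }
    if (any(usable < 0)) stop("fixed cutoffs assume non-negative scores")
    cuts <- fixed_cutoffs
  }
  cat <- factor(ifelse(scores <= cuts[1], "Low",
                       ifelse(scores <= cuts[2], "Medium", "High")),
                levels = c("Low", "Medium", "High"))
  attr(cat, "cutoffs") <- cuts
  attr(cat, "sizes") <- table(cat)
  cat
}
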