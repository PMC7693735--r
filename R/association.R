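#' Maximum-likelihood logistic regression fit
#'
#' Fits a binomial GLM by iteratively reweighted least squares on a design
#' matrix that already contains its intercept column.  Rows with any missing
#' value are dropped (complete-case) and the used count reported.  Quasi-
#' complete separation is flagged (any |beta| > 15 clears the `converged`
#' flag with a warning).
#'
#' @param y Binary 0/1 outcome vector.
#' @param design Numeric matrix with named columns, including an intercept.
#' @return Object of class `glm_fit`: `coefficients`, `standard_errors`,
#'   `covariance`, `log_likelihood`, `converged`, `n_used`.
#' @export
fit_logistic <- function(y, design) {
  design <- as.matrix(design)
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  ok <- !is.na(y) & stats::complete.cases(design)
  y <- y[ok]
  x <- design[ok, , drop = FALSE]
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- suppressWarnings(
    stats::glm.fit(x, y, family = stats::binomial())
  )
  beta <- fit$coefficients
  w <- fit$weights
  xtwx <- crossprod(x * sqrt(w))
  covariance <- tryCatch(chol2inv(chol(xtwx)),
                         error = function(e) solve(xtwx))
  dimnames(covariance) <- list(colnames(x), colnames(x))
  se <- sqrt(diag(covariance))
  ll <- sum(stats::dbinom(y, 1L, fit$fitted.values, log = TRUE))
  converged <- isTRUE(fit$converged)
  if (any(abs(beta) > 15)) {
    warning("possible separation: |coefficient| > 15")
    converged <- FALSE
  }
  structure(list(coefficients = beta, standard_errors = se,
                 covariance = covariance, log_likelihood = ll,
                 fitted = fit$fitted.values, deviance = fit$deviance,
                 converged = converged, n_used = length(y)),
            class = "glm_fit")
}

# Build an intercept + covariates design from a data.frame (factors expanded
# with treatment contrasts); NULL covariates give the intercept-only design.
build_design <- function(data, covariate_names, n = nrow(data)) {
  if (is.null(covariate_names) || length(covariate_names) == 0L) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  missing_cov <- setdiff(covariate_names, names(data))
  if (length(missing_cov)) {
    stop("covariates not found: ", paste(missing_cov, collapse = ", "))
  }
  f <- stats::as.formula(paste("~", paste(covariate_names, collapse = " + ")))
  stats::model.matrix(f, stats::model.frame(f, data, na.action = stats::na.pass))
}

#' Covariate-adjusted per-SNP logistic association scan
#'
#' One logistic fit per SNP of `outcome ~ intercept + dosage + covariates`
#' under additive minor-allele coding, reporting the per-allele odds ratio,
#' Wald 95% confidence interval `exp(beta +/- 1.96 SE)` and two-sided Wald
#' p-value.  Rows with any missing value (dosage, outcome or covariate) are
#' dropped per SNP.  Monomorphic SNPs get `or_ = 1, p = 1, flagged = TRUE`.
#'
#' @param genotypes A `genotype_matrix`.
#' @param phenotypes Phenotype table with `subject_id`, `outcome` and the
#'   covariate columns.
#' @param covariate_names Character vector (may be NULL for crude ORs).
#' @return Data.frame (`snp_scan_table`) with one row per SNP: `snp_id`,
#'   `n_used`, `beta`, `se`, `or_`, `ci_low`, `ci_high`, `p`, `flagged`.
#' @export
snp_scan <- function(genotypes, phenotypes, covariate_names = NULL) {
  stopifnot(nrow(genotypes$dosage) == nrow(phenotypes))
  y <- phenotypes$outcome
  base_design <- build_design(phenotypes, covariate_names)
  rows <- lapply(colnames(genotypes$dosage), function(id) {
    g <- genotypes$dosage[, id]
    use <- !is.na(g) & !is.na(y) & stats::complete.cases(base_design)
    flag_row <- function(n_used) {
      data.frame(snp_id = id, n_used = n_used, beta = 0, se = NA_real_,
                 or_ = 1, ci_low = NA_real_, ci_high = NA_real_, p = 1,
                 flagged = TRUE, stringsAsFactors = FALSE)
    }
    if (sum(use) < 2 || stats::var(g[use]) == 0) return(flag_row(sum(use)))
    design <- cbind(base_design[use, , drop = FALSE], dosage = g[use])
    fit <- tryCatch(fit_logistic(y[use], design), error = function(e) NULL)
    if (is.null(fit)) return(flag_row(sum(use)))
    b <- fit$coefficients[["dosage"]]
    se <- fit$standard_errors[["dosage"]]
    z <- b / se
    data.frame(snp_id = id, n_used = fit$n_used, beta = b, se = se,
               or_ = exp(b),
               ci_low = exp(b - stats::qnorm(0.975) * se),
               ci_high = exp(b + stats::qnorm(0.975) * se),
               p = 2 * stats::pnorm(-abs(z)),
               flagged = !fit$converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select SNPs below a hard p-value gate
#'
#' @param scan A scan table from [snp_scan()].
#' @param p_threshold Selection gate (default 1e-4).
#' @return Character vector of snp_ids with `p < p_threshold`, ordered by
#'   ascending p.
#' @export
select_snps <- function(scan, p_threshold = 1e-4) {
  if (is.null(scan) || nrow(scan) == 0) return(character())
  hit <- scan[!is.na(scan$p) & scan$p < p_threshold, , drop = FALSE]
  hit$snp_id[order(hit$p)]
}

#' Adjusted odds ratios for a categorical exposure
#'
#' One multivariate logistic fit of the outcome on the exposure (treatment-
#' coded against its reference level) plus covariates; returns per-level
#' odds ratios with Wald 95% confidence intervals.  Empty exposure levels
#' are dropped with a warning.
#'
#' @param exposure Factor (or coercible); first level is the reference
#'   unless `ref` is given.
#' @param outcome Binary 0/1 vector.
#' @param data Data.frame holding the covariate columns (may be NULL).
#' @param covariate_names Covariate column names in `data`.
#' @param ref Reference level.
#' @return Data.frame with `level`, `or_`, `ci_low`, `ci_high`, `p`, `n`;
#'   the reference row has `or_ = 1` and NA interval.
#' @export
adjusted_or <- function(exposure, outcome, data = NULL,
                        covariate_names = NULL, ref = NULL) {
  exposure <- as.factor(exposure)
  if (!is.null(ref)) exposure <- stats::relevel(exposure, ref = ref)
  keep <- !is.na(exposure) & !is.na(outcome)
  exposure <- exposure[keep]
  outcome <- outcome[keep]
  if (!is.null(data)) data <- data[keep, , drop = FALSE]
  empty <- levels(exposure)[!levels(exposure) %in% unique(exposure)]
  if (length(empty)) {
    warning("dropping empty exposure level(s): ",
            paste(empty, collapse = ", "))
    exposure <- droplevels(exposure)
  }
  if (nlevels(exposure) < 2) {
    stop("exposure has fewer than 2 non-empty levels")
  }
  exp_design <- stats::model.matrix(~exposure)[, -1, drop = FALSE]
  colnames(exp_design) <- sub("^exposure", "", colnames(exp_design))
  cov_design <- build_design(if (is.null(data))
    data.frame(row.names = seq_along(outcome)) else data, covariate_names,
    n = length(outcome))
  design <- cbind(cov_design, exp_design)
  fit <- fit_logistic(outcome, design)
  lv <- levels(exposure)
  rows <- lapply(lv, function(l) {
    n_l <- sum(exposure == l & !is.na(outcome))
    if (l == lv[1]) {
      return(data.frame(level = l, or_ = 1, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_, n = n_l,
                        stringsAsFactors = FALSE))
    }
    b <- fit$coefficients[[l]]
    se <- fit$standard_errors[[l]]
    data.frame(level = l, or_ = exp(b),
               ci_low = exp(b - stats::qnorm(0.975) * se),
               ci_high = exp(b + stats::qnorm(0.975) * se),
               p = 2 * stats::pnorm(-abs(b / se)), n = n_l,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "fit") <- fit
  out
}
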