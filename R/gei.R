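#' Specify an environment dichotomization
#'
#' @param name Environment column name (or report label for composite
#'   predicates).
#' @param cutoff Stated threshold: values `< cutoff` form the low
#'   (reference) stratum, values `>= cutoff` the high stratum.  Ignored when
#'   `source` is "median"/"percentile" or a `predicate` is given.
#' @param source "stated" (use `cutoff`), "median" (50th percentile of the
#'   non-missing values) or "percentile" (use `percentile`).
#' @param percentile Probability for `source = "percentile"` (e.g. 0.67 for
#'   dietary-pattern scores).
#' @param predicate Optional function(data) returning TRUE for the high
#'   stratum, for composite rules (e.g. blood pressure from SBP and DBP
#'   jointly).
#' @return Object of class `environment_spec`.
#' @export
env_spec <- function(name, cutoff = NULL,
                     source = c("stated", "median", "percentile"),
                     percentile = NULL, predicate = NULL) {
  source <- match.arg(source)
  if (source == "stated" && is.null(predicate) &&
      (is.null(cutoff) || !is.finite(cutoff))) {
    stop("env ", name, ": a finite stated cutoff is required")
  }
  if (source == "percentile" &&
      (is.null(percentile) || percentile <= 0 || percentile >= 1)) {
    stop("env ", name, ": percentile must be in (0, 1)")
  }
  structure(list(name = name, cutoff = cutoff, source = source,
                 percentile = percentile, predicate = predicate),
            class = "environment_spec")
}

#' Dichotomize an environment variable
#'
#' Values below the cutoff go to the `low` (reference) stratum, values at or
#' above it to `high`; so a stated cutoff of 126 mg/dL sends a glucose of
#' exactly 126 to the high stratum.  Median and percentile cutoffs are
#' computed on the non-missing values.  Composite predicates return `high`
#' where TRUE.
#'
#' @param data Data.frame with the environment column(s).
#' @param spec An [env_spec()].
#' @return Factor with levels `low`, `high` (NA preserved); the realized
#'   cutoff is attached as attribute `"cutoff"` (NA for predicates).
#' @export
dichotomize <- function(data, spec) {
  if (!is.null(spec$predicate)) {
    hi <- spec$predicate(data)
    out <- factor(ifelse(hi, "high", "low"), levels = c("low", "high"))
    attr(out, "cutoff") <- NA_real_
    return(out)
  }
  x <- data[[spec$name]]
  if (is.null(x)) stop("environment column not found: ", spec$name)
  if (all(is.na(x))) stop("environment column all missing: ", spec$name)
  cutoff <- switch(spec$source,
                   stated = spec$cutoff,
                   median = stats::median(x, na.rm = TRUE),
                   percentile = stats::quantile(x, spec$percentile,
                                                na.rm = TRUE, names = FALSE))
  out <- factor(ifelse(x < cutoff, "low", "high"), levels = c("low", "high"))
  if (length(unique(stats::na.omit(out))) < 2) {
    stop("degenerate split for ", spec$name, " at cutoff ", cutoff)
  }
  attr(out, "cutoff") <- cutoff
  out
}

#' Stratified PRS-category odds ratios
#'
#' Within each environment stratum, adjusted odds ratios of the Medium and
#' High PRS categories against Low from a per-stratum logistic fit.
#' Stratum-by-category cells without both outcomes are flagged and their OR
#' omitted.
#'
#' @param outcome Binary 0/1 vector.
#' @param prs_categories Factor Low/Medium/High from [categorize_prs()].
#' @param env_binary Factor low/high from [dichotomize()].
#' @param data Data.frame with covariates.
#' @param covariate_names Adjustment covariates.
#' @return Data.frame with `stratum`, `level`, `or_`, `ci_low`, `ci_high`,
#'   `p`, `n`, `n_cases`, `flagged`.
#' @export
stratified_or <- function(outcome, prs_categories, env_binary, data = NULL,
                          covariate_names = NULL) {
  rows <- lapply(levels(env_binary), function(st) {
    in_st <- !is.na(env_binary) & env_binary == st &
      !is.na(prs_categories) & !is.na(outcome)
    if (!any(in_st)) return(NULL)
    if (length(unique(outcome[in_st])) < 2) {
      stop("stratum ", st, " contains a single outcome class")
    }
    tab <- adjusted_or(droplevels(prs_categories[in_st]), outcome[in_st],
                       data = if (is.null(data)) NULL else
                         data[in_st, , drop = FALSE],
                       covariate_names = covariate_names)
    n_cases <- vapply(tab$level, function(l) {
      sum(outcome[in_st][prs_categories[in_st] == l] == 1, na.rm = TRUE)
    }, numeric(1))
    zero_cell <- n_cases == 0 | n_cases == tab$n
    tab$or_[zero_cell & tab$level != levels(prs_categories)[1]] <- NA_real_
    cbind(data.frame(stratum = st, stringsAsFactors = FALSE), tab,
          data.frame(n_cases = n_cases, flagged = zero_cell))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multiplicative PRS-by-environment interaction test
#'
#' One-degree-of-freedom likelihood-ratio test of the product term in
#' `outcome ~ prs_ordinal * env + covariates`, where the PRS category is
#' coded ordinally 0/1/2 (Low/Medium/High) and the environment 0/1
#' (low/high).  A 2-df categorical product test is available via
#' `ordinal = FALSE`.
#'
#' @param outcome Binary 0/1 vector.
#' @param prs_categories Factor Low/Medium/High.
#' @param env_binary Factor low/high.
#' @param data,covariate_names Adjustment covariates.
#' @param ordinal Use the 1-df ordinal coding (default TRUE).
#' @return List with `p`, `df`, `lrt`, and the two `glm_fit`s.
#' @export
interaction_p <- function(outcome, prs_categories, env_binary, data = NULL,
                          covariate_names = NULL, ordinal = TRUE) {
  env01 <- as.numeric(env_binary == "high")
  cov_design <- build_design(if (is.null(data))
    data.frame(row.names = seq_along(outcome)) else data, covariate_names,
    n = length(outcome))
  if (ordinal) {
    prs_num <- as.numeric(prs_categories) - 1
    main <- cbind(cov_design, prs = prs_num, env = env01)
    prod_term <- matrix(prs_num * env01, ncol = 1,
                        dimnames = list(NULL, "prs:env"))
  } else {
    prs_design <- stats::model.matrix(~prs_categories)[, -1, drop = FALSE]
    main <- cbind(cov_design, prs_design, env = env01)
    prod_term <- prs_design * env01
    colnames(prod_term) <- paste0(colnames(prs_design), ":env")
  }
  ok <- stats::complete.cases(cbind(outcome, main, prod_term))
  if (all(prod_term[ok, 1] == prod_term[ok, 1][1])) {
    stop("product term is constant; interaction not estimable")
  }
  reduced <- fit_logistic(outcome[ok], main[ok, , drop = FALSE])
  full <- fit_logistic(outcome[ok],
                       cbind(main, prod_term)[ok, , drop = FALSE])
  lrt <- 2 * (full$log_likelihood - reduced$log_likelihood)
  df <- ncol(prod_term)
  list(p = stats::pchisq(max(lrt, 0), df = df, lower.tail = FALSE),
       df = df, lrt = lrt, full_fit = full, reduced_fit = reduced)
}

#' Stratified gene-environment interaction report
#'
#' Runs [dichotomize()], [stratified_or()] and [interaction_p()] for each
#' environment spec and assembles one long table: a row per stratum x PRS
#' category with the stratum ORs and the environment's interaction p-value.
#'
#' @param outcome,prs_categories,data As in [stratified_or()].
#' @param env_specs List of [env_spec()]s.
#' @param covariate_names Adjustment covariates.
#' @param path Optional TSV output path.
#' @return Data.frame with `environment`, `cutoff`, `stratum`, `level`,
#'   `or_`, `ci_low`, `ci_high`, `p`, `n`, `n_cases`, `interaction_p`.
#' @export
gei_report <- function(outcome, prs_categories, data, env_specs,
                       covariate_names = NULL, path = NULL) {
  rows <- lapply(env_specs, function(spec) {
    env_bin <- dichotomize(data, spec)
    ors <- stratified_or(outcome, prs_categories, env_bin, data,
                         covariate_names)
    ip <- interaction_p(outcome, prs_categories, env_bin, data,
                        covariate_names)
    cbind(data.frame(environment = spec$name,
                     cutoff = attr(env_bin, "cutoff"),
                     stringsAsFactors = FALSE),
          ors[, c("stratum", "level", "or_", "ci_low", "ci_high", "p",
                  "n", "n_cases")],
          data.frame(interaction_p = ip$p))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(environment = character(), cutoff = numeric(),
               stratum = character(), level = character(), or_ = numeric(),
               ci_low = numeric(), ci_high = numeric(), p = numeric(),
               n = numeric(), n_cases = numeric(),
               interaction_p = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(path)) write_tsv(out, path)
  out
}
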