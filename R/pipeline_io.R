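#' Write / read tab-separated pipeline tables
#'
#' All intermediate tables of the pipeline are written with these helpers so
#' every artifact round-trips through the package's own reader.
#'
#' @param x Data.frame.
#' @param path File path.
#' @return `read_tsv()` returns a data.frame; `write_tsv()` the path,
#'   invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Construct a genotype matrix from a dosage matrix
#'
#' @param dosage Numeric subjects x SNPs matrix with values 0/1/2/NA;
#'   column names are SNP ids.
#' @param chromosome Integer chromosome label(s), recycled over SNPs.
#' @param minor_allele Counted allele letter(s), recycled.
#' @return A `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, chromosome = 1L, minor_allele = "A") {
  dosage <- as.matrix(dosage)
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- paste0("snp", seq_len(ncol(dosage)))
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("S%05d", seq_len(nrow(dosage)))
  }
  structure(list(dosage = dosage,
                 snps = data.frame(snp_id = colnames(dosage),
                                   chromosome = rep_len(as.integer(chromosome),
                                                        ncol(dosage)),
                                   minor_allele = rep_len(minor_allele,
                                                          ncol(dosage)),
                                   stringsAsFactors = FALSE)),
            class = "genotype_matrix")
}

#' Read a genotype matrix from PLINK .raw text or VCF
#'
#' The `.raw` dialect is whitespace-delimited with columns FID IID PAT MAT
#' SEX PHENOTYPE followed by one additive-dosage column per SNP named
#' `<snp_id>_<counted_allele>` (values 0/1/2, NA for missing).  VCF input is
#' converted to alternate-allele dosage from the GT field; multiallelic
#' records are rejected.  Subject order is preserved.
#'
#' @param path Input file.
#' @param format "raw" or "vcf".
#' @param snp_meta Optional data.frame with `snp_id` and `chromosome` to
#'   attach chromosome labels to .raw input (the dialect itself carries
#'   none).
#' @return A `genotype_matrix` (list with `dosage` and `snps`); for .raw
#'   input, the PHENOTYPE column (1/2 coding) is attached as attribute
#'   `"phenotype"` recoded to 0/1 where present.
#' @export
read_genotypes <- function(path, format = c("raw", "vcf"), snp_meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") return(read_genotypes_vcf(path))
  df <- utils::read.table(path, header = TRUE, na.strings = "NA",
                          stringsAsFactors = FALSE, check.names = FALSE)
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!identical(names(df)[seq_along(fixed)], fixed)) {
    stop("malformed .raw header: expected columns ",
         paste(fixed, collapse = " "))
  }
  snp_cols <- names(df)[-seq_along(fixed)]
  m <- regmatches(snp_cols, regexec("^(.*)_([A-Za-z0-9]+)$", snp_cols))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed SNP column name(s): ",
         paste(snp_cols[bad], collapse = ", "))
  }
  snp_id <- vapply(m, `[`, character(1), 2L)
  allele <- vapply(m, `[`, character(1), 3L)
  dosage <- as.matrix(df[, snp_cols, drop = FALSE])
  storage.mode(dosage) <- "double"
  if (!all(dosage %in% c(0, 1, 2) | is.na(dosage))) {
    stop("dosages outside {0, 1, 2, NA} in ", path)
  }
  dimnames(dosage) <- list(df$IID, snp_id)
  chrom <- rep(NA_integer_, length(snp_id))
  if (!is.null(snp_meta)) {
    chrom <- snp_meta$chromosome[match(snp_id, snp_meta$snp_id)]
  }
  geno <- structure(list(dosage = dosage,
                         snps = data.frame(snp_id = snp_id,
                                           chromosome = chrom,
                                           minor_allele = allele,
                                           stringsAsFactors = FALSE)),
                    class = "genotype_matrix")
  ph <- df$PHENOTYPE
  if (all(ph %in% c(1, 2) | is.na(ph))) ph <- ph - 1L
  attr(geno, "phenotype") <- ph
  geno
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- if (is.matrix(fix)) fix else matrix(fix, nrow = 1,
                                             dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    stop("multiallelic record(s) not supported: ",
         paste(fix[multi, "ID"], collapse = ", "))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  allele_count <- function(x) {
    if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_real_)
    sum(as.numeric(strsplit(x, "[/|]")[[1]]))
  }
  dosage <- t(apply(gt, 1L, function(row) vapply(row, allele_count,
                                                 numeric(1))))
  if (ncol(gt) == 1L) dosage <- matrix(dosage, ncol = 1,
                                       dimnames = list(rownames(gt),
                                                       colnames(gt)))
  if (any(!is.na(dosage) & !(dosage %in% c(0, 1, 2)))) {
    stop("non-diploid GT encountered in ", path)
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  dosage <- t(dosage)  # subjects x SNPs
  colnames(dosage) <- ids
  structure(list(dosage = dosage,
                 snps = data.frame(snp_id = ids,
                                   chromosome = suppressWarnings(
                                     as.integer(fix[, "CHROM"])),
                                   minor_allele = fix[, "ALT"],
                                   stringsAsFactors = FALSE)),
            class = "genotype_matrix")
}

#' Read a phenotype/covariate/environment table
#'
#' CSV with a header; the outcome column must be binary, with the PLINK 1/2
#' control/case coding recoded to 0/1 (logged).  Duplicated subject ids are
#' an error.  When genotypes are supplied, the id overlap is reported and an
#' empty intersection is an error.
#'
#' @param path CSV path.
#' @param outcome_col Name of the outcome column (default "outcome").
#' @param id_col Name of the subject id column (default "subject_id").
#' @param genotypes Optional `genotype_matrix` to match ids against.
#' @return A `phenotype_table` data.frame.
#' @export
read_phenotypes <- function(path, outcome_col = "outcome",
                            id_col = "subject_id", genotypes = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!id_col %in% names(df)) stop("missing id column: ", id_col)
  if (!outcome_col %in% names(df)) stop("missing outcome column: ",
                                        outcome_col)
  if (anyDuplicated(df[[id_col]])) {
    stop("duplicated subject id(s): ",
         paste(unique(df[[id_col]][duplicated(df[[id_col]])]),
               collapse = ", "))
  }
  y <- df[[outcome_col]]
  vals <- sort(unique(stats::na.omit(y)))
  if (identical(vals, c(1, 2)) || identical(vals, c(1L, 2L))) {
    message("recoding outcome from 1/2 (control/case) to 0/1")
    y <- y - 1L
  } else if (!all(vals %in% c(0, 1))) {
    stop("outcome column must be binary 0/1 (or PLINK 1/2)")
  }
  df[[outcome_col]] <- as.integer(y)
  names(df)[names(df) == id_col] <- "subject_id"
  names(df)[names(df) == outcome_col] <- "outcome"
  if (!is.null(genotypes)) {
    overlap <- intersect(df$subject_id, rownames(genotypes$dosage))
    message(length(overlap), " of ", nrow(df),
            " phenotype subjects matched to genotypes")
    if (!length(overlap)) stop("no overlapping subject ids with genotypes")
  }
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Full pipeline configuration
#'
#' Bundles every stage threshold at its conventional default: call rate
#' >= 0.96 (<4% missing), HWE p > 0.05, heterozygosity < 0.30, association
#' gate p < 1e-4, LD exclusion r^2 >= 0.4, 10-fold cross-validation.
#'
#' @param covariate_names Covariates of the association scan / null model
#'   ("adjustment 1").
#' @param gmdr_covariates Covariates of the GMDR null model (defaults to
#'   `covariate_names`).
#' @param prs_covariates Covariates of the PRS-category OR model
#'   ("adjustment 2"; defaults to `covariate_names`).
#' @param env_specs List of [env_spec()]s for the interaction stage.
#' @param call_rate_min,hwe_p_min,het_max,p_gate,r2_threshold,k_range,n_folds,max_models,prs_mode,fixed_cutoffs,seed
#'   Stage settings; see the stage functions.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(covariate_names = NULL, gmdr_covariates = NULL,
                            prs_covariates = NULL, env_specs = list(),
                            call_rate_min = 0.96, hwe_p_min = 0.05,
                            het_max = 0.30, p_gate = 1e-4,
                            r2_threshold = 0.4, k_range = 1:3,
                            n_folds = 10L, max_models = 200000L,
                            prs_mode = "tertile", fixed_cutoffs = c(3, 5),
                            seed = 1L) {
  stopifnot(call_rate_min > 0, call_rate_min <= 1,
            hwe_p_min >= 0, hwe_p_min < 1,
            p_gate > 0, p_gate < 1,
            r2_threshold > 0, r2_threshold <= 1,
            n_folds >= 2)
  structure(list(covariate_names = covariate_names,
                 gmdr_covariates = if (is.null(gmdr_covariates))
                   covariate_names else gmdr_covariates,
                 prs_covariates = if (is.null(prs_covariates))
                   covariate_names else prs_covariates,
                 env_specs = env_specs, call_rate_min = call_rate_min,
                 hwe_p_min = hwe_p_min, het_max = het_max, p_gate = p_gate,
                 r2_threshold = r2_threshold, k_range = k_range,
                 n_folds = as.integer(n_folds),
                 max_models = as.integer(max_models), prs_mode = prs_mode,
                 fixed_cutoffs = fixed_cutoffs, seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_stop <- function(stage, ...) {
  stop("[stage: ", stage, "] ", ..., call. = FALSE)
}

#' Run the full PRS pipeline
#'
#' Chains the stages: per-SNP/per-sample QC, covariate-adjusted logistic
#' scan, hard p-gate selection, LD pruning, GMDR best-model search,
#' risk-allele PRS construction and categorization, PRS-category adjusted
#' ORs, and the stratified PRS-by-environment interaction report.  Every
#' intermediate table is written as TSV under `out_dir`, together with a
#' JSON manifest of the thresholds, seed and stage counts, and a run log.
#' The run is fully reproducible given the config seed.
#'
#' @param genotypes A `genotype_matrix`.
#' @param phenotypes A `phenotype_table` with matching subjects (same
#'   order; use [read_phenotypes()] / [read_genotypes()]).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every stage result (`qc`, `samples`,
#'   `scan`, `selected`, `pruned`, `gmdr`, `best_snps`, `prs`,
#'   `prs_or`, `gei`, `manifest`).
#' @export
run_pipeline <- function(genotypes, phenotypes, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  if (nrow(genotypes$dosage) != nrow(phenotypes)) {
    pipeline_stop("input", "genotype/phenotype subject counts differ")
  }

  log_line("qc: ", ncol(genotypes$dosage), " SNPs, ",
           nrow(genotypes$dosage), " subjects")
  qc <- snp_qc(genotypes, call_rate_min = config$call_rate_min,
               hwe_p_min = config$hwe_p_min)
  samples <- sample_stats(genotypes, max_het = config$het_max,
                          min_call = config$call_rate_min)
  write_tsv(qc, file.path(out_dir, "snp_qc.tsv"))
  write_tsv(samples, file.path(out_dir, "sample_qc.tsv"))
  kept <- qc$snp_id[qc$kept]
  if (!length(kept)) pipeline_stop("qc", "no SNP passed QC")
  geno_qc <- structure(list(
    dosage = genotypes$dosage[, kept, drop = FALSE],
    snps = genotypes$snps[genotypes$snps$snp_id %in% kept, , drop = FALSE]),
    class = "genotype_matrix")

  log_line("scan: ", length(kept), " SNPs, covariates: ",
           paste(config$covariate_names, collapse = ", "))
  scan <- snp_scan(geno_qc, phenotypes, config$covariate_names)
  scan_out <- merge(scan, qc[, c("snp_id", "maf", "hwe_p")], by = "snp_id",
                    sort = FALSE)
  scan_out$chromosome <- geno_qc$snps$chromosome[
    match(scan_out$snp_id, geno_qc$snps$snp_id)]
  write_tsv(scan_out, file.path(out_dir, "snp_scan.tsv"))

  selected <- select_snps(scan, p_threshold = config$p_gate)
  log_line("select: ", length(selected), " SNPs below p < ", config$p_gate)
  if (!length(selected)) {
    pipeline_stop("select", "no SNP passed the association gate (p < ",
                  config$p_gate, "); nothing to model")
  }

  assoc_p <- stats::setNames(scan$p, scan$snp_id)
  pruned <- ld_prune(geno_qc, assoc_p, snp_ids = selected,
                     r2_threshold = config$r2_threshold)
  write_tsv(data.frame(snp_id = pruned$kept_snps),
            file.path(out_dir, "ld_kept.tsv"))
  if (nrow(pruned$dropped_pairs)) {
    write_tsv(pruned$dropped_pairs, file.path(out_dir, "ld_dropped.tsv"))
  }
  log_line("prune: kept ", length(pruned$kept_snps), " of ",
           length(selected), " at r2 < ", config$r2_threshold)

  scores <- score_residuals(phenotypes$outcome, phenotypes,
                            config$gmdr_covariates)
  k_range <- config$k_range[config$k_range <= length(pruned$kept_snps)]
  if (!length(k_range)) pipeline_stop("gmdr", "k_range exceeds candidates")
  gmdr <- search_best_model(geno_qc, scores, pruned$kept_snps,
                            k_range = k_range, n_folds = config$n_folds,
                            seed = config$seed,
                            max_models = config$max_models)
  gmdr_out <- gmdr
  gmdr_out$cvc <- paste0(gmdr_out$cvc, "/", gmdr_out$n_folds)
  write_tsv(gmdr_out, file.path(out_dir, "gmdr_models.tsv"))
  best_snps <- strsplit(gmdr$snp_set[1], ",")[[1]]
  log_line("gmdr: best model {", paste(best_snps, collapse = ", "),
           "} TEBA ", round(gmdr$teba[1], 4), " CVC ", gmdr$cvc[1], "/",
           gmdr$n_folds[1])

  orientation <- orient_risk_alleles(scan, best_snps)
  prs <- compute_prs(geno_qc, orientation)
  prs$category <- categorize_prs(prs$prs, mode = config$prs_mode,
                                 fixed_cutoffs = config$fixed_cutoffs)
  write_tsv(prs, file.path(out_dir, "prs.tsv"))
  log_line("prs: cutoffs ",
           paste(attr(prs$category, "cutoffs"), collapse = "/"),
           "; sizes ", paste(table(prs$category), collapse = "/"))

  prs_or <- adjusted_or(prs$category, phenotypes$outcome, phenotypes,
                        config$prs_covariates)
  write_tsv(prs_or, file.path(out_dir, "prs_or.tsv"))

  gei <- NULL
  if (length(config$env_specs)) {
    gei <- gei_report(phenotypes$outcome, prs$category, phenotypes,
                      config$env_specs, config$prs_covariates,
                      path = file.path(out_dir, "gei_report.tsv"))
    log_line("gei: ", length(config$env_specs), " environments")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("gmdrprs")),
    seed = config$seed, n_subjects = nrow(genotypes$dosage),
    n_snps_input = ncol(genotypes$dosage),
    thresholds = list(call_rate_min = config$call_rate_min,
                      hwe_p_min = config$hwe_p_min,
                      het_max = config$het_max, p_gate = config$p_gate,
                      r2_threshold = config$r2_threshold,
                      n_folds = config$n_folds,
                      prs_mode = config$prs_mode,
                      fixed_cutoffs = config$fixed_cutoffs),
    covariates = list(scan = config$covariate_names,
                      gmdr = config$gmdr_covariates,
                      prs = config$prs_covariates),
    counts = list(snps_after_qc = length(kept),
                  snps_selected = length(selected),
                  snps_after_prune = length(pruned$kept_snps)),
    best_model = list(snps = best_snps, trba = gmdr$trba[1],
                      teba = gmdr$teba[1], cvc = gmdr$cvc[1],
                      sign_p = gmdr$sign_p[1])
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("done")
  invisible(list(qc = qc, samples = samples, scan = scan,
                 selected = selected, pruned = pruned, gmdr = gmdr,
                 best_snps = best_snps, prs = prs, prs_or = prs_or,
                 gei = gei, manifest = manifest))
}
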