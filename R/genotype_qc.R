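#' Minor allele frequency of a dosage column
#'
#' The counted-allele frequency is `sum(dosage) / (2 * n_nonmissing)`;
#' it is folded to the minor allele frequency (<= 0.5), with a flag saying
#' whether the counted allele was actually the major one.
#'
#' @param g Numeric dosage vector in \{0, 1, 2, NA\}.
#' @return List with `maf`, `counted_freq` (unfolded), `flipped`
#'   (TRUE when counted allele is the major allele), `n_used`.
#' @export
#' @examples
#' allele_frequency(c(0, 0, 1, 2))$maf  # 0.375
allele_frequency <- function(g) {
  g <- g[!is.na(g)]
  if (!length(g)) stop("all genotypes missing; allele frequency undefined")
  if (!all(g %in% c(0, 1, 2))) stop("dosages must be 0, 1, 2 or NA")
  counted <- sum(g) / (2 * length(g))
  flipped <- counted > 0.5
  list(maf = if (flipped) 1 - counted else counted,
       counted_freq = counted, flipped = flipped, n_used = length(g))
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom Pearson chi-square of the observed genotype counts
#' against the HWE expectation computed from the estimated allele frequency.
#' Monomorphic columns return `chi2 = 0, p = 1`.  For low-MAF SNPs an exact
#' mid-p test (conditional on allele counts) is available via `exact = TRUE`.
#'
#' @param g Dosage vector in \{0, 1, 2, NA\}.
#' @param exact Use the exact conditional mid-p test instead of the
#'   chi-square approximation (recommended for MAF < 0.05).
#' @return List with `chi2` (NA for the exact test) and `p`.
#' @export
#' @examples
#' hwe_test(rep(c(0, 1, 2), times = c(30, 40, 30)))  # chi2 = 4
hwe_test <- function(g, exact = FALSE) {
  g <- g[!is.na(g)]
  if (!length(g)) stop("no non-missing genotypes")
  n <- c(sum(g == 0), sum(g == 1), sum(g == 2))
  q <- (n[2] + 2 * n[3]) / (2 * sum(n))
  if (q == 0 || q == 1) return(list(chi2 = 0, p = 1))
  if (exact) return(list(chi2 = NA_real_, p = hwe_exact_midp(n)))
  expected <- sum(n) * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chi2 <- sum((n - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

# Exact HWE mid-p: distribution of the heterozygote count conditional on the
# observed minor-allele count, two-sided by summing genotype configurations
# no more probable than the observed one (mid-p halves the observed term).
hwe_exact_midp <- function(counts) {
  n <- sum(counts)
  n_minor <- counts[2] + 2 * counts[3]
  if (n_minor > n) {  # fold so the rare allele is counted
    n_minor <- 2 * n - n_minor
    counts <- rev(counts)
  }
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  logp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    lgamma(n + 1) - lgamma(hom_maj + 1) - lgamma(h + 1) -
      lgamma(hom_min + 1) + h * log(2)
  }, numeric(1))
  # normalize in log space (the allele-count terms are constant in h)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hets == counts[2])
  sum(p[p < p[obs]]) + 0.5 * sum(p[p == p[obs]])
}

#' Per-sample call rate and heterozygosity
#'
#' @param genotypes A `genotype_matrix`.
#' @param max_het Upper heterozygosity bound used for flagging (default
#'   0.30); set `het_upper = FALSE` to flag deficits instead.
#' @param min_call Minimum call rate (default 0.96, i.e. <4% missing).
#' @param het_upper Flag heterozygosity above (`TRUE`, default) or below
#'   the bound.
#' @return Data.frame with `subject_id`, `call_rate`, `heterozygosity`
#'   (NA when no genotype was called) and `flagged` with `reason`.
#' @export
sample_stats <- function(genotypes, max_het = 0.30, min_call = 0.96,
                         het_upper = TRUE) {
  d <- genotypes$dosage
  n_snps <- ncol(d)
  called <- rowSums(!is.na(d))
  call_rate <- if (n_snps > 0) called / n_snps else rep(NA_real_, nrow(d))
  het <- ifelse(called > 0, rowSums(d == 1, na.rm = TRUE) / called, NA_real_)
  reason <- character(nrow(d))
  reason[!is.na(call_rate) & call_rate < min_call] <- "low_call_rate"
  bad_het <- !is.na(het) &
    (if (het_upper) het > max_het else het < max_het)
  reason[bad_het] <- trimws(paste(reason[bad_het], "heterozygosity"))
  reason[is.na(het)] <- trimws(paste(reason[is.na(het)], "no_calls"))
  data.frame(subject_id = rownames(d), call_rate = call_rate,
             heterozygosity = het, flagged = reason != "",
             reason = reason, stringsAsFactors = FALSE)
}

#' Composite (dosage) linkage-disequilibrium r-squared
#'
#' Squared Pearson correlation of the two dosage columns over
#' pairwise-complete subjects.  Symmetric, and invariant to flipping either
#' SNP's counted allele (d -> 2 - d).
#'
#' @param a,b Dosage vectors.
#' @return r-squared in \[0, 1\]; 0 with a warning when either column has
#'   zero variance.
#' @export
ld_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) stop("fewer than 2 pairwise-complete subjects")
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("zero dosage variance; r2 defined as 0")
    return(0)
  }
  stats::cor(a, b)^2
}

#' LD pruning of a selected SNP set
#'
#' Within each chromosome, while any kept pair has dosage r-squared at or
#' above the threshold, the pair with the highest r-squared is resolved by
#' dropping its member with the larger association p-value (ties broken by
#' dropping the lexicographically larger snp_id).  The returned set contains
#' no same-chromosome pair at or above the threshold.
#'
#' @param genotypes A `genotype_matrix` containing (at least) the SNPs to
#'   prune.
#' @param snp_ids SNPs to prune (default: all in the matrix).
#' @param assoc_p Named numeric vector of association p-values, one per SNP.
#' @param r2_threshold Exclusion threshold (default 0.4).
#' @return List with `kept_snps` (input order preserved) and
#'   `dropped_pairs` (data.frame snp_a, snp_b, r2, dropped_id).
#' @export
ld_prune <- function(genotypes, assoc_p, snp_ids = genotypes$snps$snp_id,
                     r2_threshold = 0.4) {
  if (r2_threshold <= 0 || r2_threshold > 1) {
    stop("r2_threshold must be in (0, 1]")
  }
  missing_p <- setdiff(snp_ids, names(assoc_p))
  if (length(missing_p)) {
    stop("no association p-value for: ", paste(missing_p, collapse = ", "))
  }
  meta <- genotypes$snps
  chrom <- stats::setNames(meta$chromosome, meta$snp_id)[snp_ids]
  # SNPs of unknown chromosome (e.g. bare .raw input) are grouped together
  # and pruned against each other, the conservative choice
  chrom <- ifelse(is.na(chrom), "unknown", as.character(chrom))
  names(chrom) <- snp_ids
  kept <- snp_ids
  dropped <- data.frame(snp_a = character(), snp_b = character(),
                        r2 = numeric(), dropped_id = character(),
                        stringsAsFactors = FALSE)
  repeat {
    viol <- NULL
    for (chr in unique(chrom[kept])) {
      ids <- kept[chrom[kept] == chr]
      if (length(ids) < 2) next
      pairs <- utils::combn(ids, 2)
      for (k in seq_len(ncol(pairs))) {
        r2 <- ld_r2(genotypes$dosage[, pairs[1, k]],
                    genotypes$dosage[, pairs[2, k]])
        if (r2 >= r2_threshold) {
          viol <- rbind(viol, data.frame(a = pairs[1, k], b = pairs[2, k],
                                         r2 = r2, stringsAsFactors = FALSE))
        }
      }
    }
    if (is.null(viol)) break
    viol <- viol[order(-viol$r2, viol$a, viol$b), , drop = FALSE]
    a <- viol$a[1]; b <- viol$b[1]
    drop_id <- if (assoc_p[a] > assoc_p[b]) a
      else if (assoc_p[b] > assoc_p[a]) b
      else max(a, b)
    dropped <- rbind(dropped,
                     data.frame(snp_a = a, snp_b = b, r2 = viol$r2[1],
                                dropped_id = drop_id,
                                stringsAsFactors = FALSE))
    kept <- setdiff(kept, drop_id)
  }
  list(kept_snps = kept, dropped_pairs = dropped)
}

#' Per-SNP quality control
#'
#' Applies the standard candidate-SNP filters: call rate (default >= 0.96,
#' the <4% missingness bound), Hardy-Weinberg equilibrium (kept when
#' p > `hwe_p_min`, default 0.05) and polymorphism (MAF > `maf_min`).
#'
#' @param genotypes A `genotype_matrix`.
#' @param call_rate_min,hwe_p_min,maf_min QC thresholds.
#' @return Data.frame (`snp_qc_table`) with `snp_id`, `maf`, `call_rate`,
#'   `hwe_chi2`, `hwe_p`, `kept`, `reason`.
#' @export
snp_qc <- function(genotypes, call_rate_min = 0.96, hwe_p_min = 0.05,
                   maf_min = 0) {
  d <- genotypes$dosage
  rows <- lapply(colnames(d), function(id) {
    g <- d[, id]
    n_called <- sum(!is.na(g))
    call_rate <- n_called / length(g)
    if (n_called == 0) {
      return(data.frame(snp_id = id, maf = NA_real_, call_rate = 0,
                        hwe_chi2 = NA_real_, hwe_p = NA_real_,
                        kept = FALSE, reason = "all_missing",
                        stringsAsFactors = FALSE))
    }
    af <- allele_frequency(g)
    hwe <- hwe_test(g)
    reason <- character()
    if (call_rate < call_rate_min) reason <- c(reason, "call_rate")
    if (!is.na(hwe$p) && hwe$p <= hwe_p_min) reason <- c(reason, "hwe")
    if (af$maf <= maf_min) reason <- c(reason, "maf")
    data.frame(snp_id = id, maf = af$maf, call_rate = call_rate,
               hwe_chi2 = hwe$chi2, hwe_p = hwe$p,
               kept = length(reason) == 0,
               reason = paste(reason, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
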