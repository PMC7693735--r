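#' Score residuals for covariate-adjusted MDR
#'
#' Generalized MDR replaces case/control status with the score residual
#' `s_i = y_i - p_hat_i` from a null logistic model containing only the
#' covariates (and an intercept).  With no covariates, cases score
#' `1 - prevalence` and controls `-prevalence`, so the sign of `s` recovers
#' case/control status and the downstream machinery reduces to classic MDR.
#'
#' @param outcome Binary 0/1 vector.
#' @param data Data.frame with covariate columns (NULL for the unadjusted
#'   case).
#' @param covariate_names Covariates of the null model.
#' @return Object of class `score_residuals`: `s` (numeric, NA where the
#'   outcome or a covariate is missing) and `null_fit`.
#' @export
score_residuals <- function(outcome, data = NULL, covariate_names = NULL) {
  n <- length(outcome)
  design <- build_design(if (is.null(data))
    data.frame(row.names = seq_len(n)) else data, covariate_names, n = n)
  ok <- !is.na(outcome) & stats::complete.cases(design)
  fit <- fit_logistic(outcome[ok], design[ok, , drop = FALSE])
  s <- rep(NA_real_, n)
  s[ok] <- outcome[ok] - fit$fitted
  structure(list(s = s, null_fit = fit), class = "score_residuals")
}

# Integer multilocus cell key for a dosage submatrix (base-3 encoding);
# NA where any of the k genotypes is missing.
cell_keys <- function(geno_cols) {
  geno_cols <- as.matrix(geno_cols)
  drop(geno_cols %*% 3^(seq_len(ncol(geno_cols)) - 1))
}

#' Label multilocus genotype cells as high or low risk
#'
#' Training subjects are partitioned into the 3^k cells of the k-SNP
#' genotype tuple (subjects missing any of the k genotypes or the score are
#' excluded).  A cell is labeled `high` when the sum of score residuals in
#' it is strictly positive; ties, negative sums and empty cells are `low`.
#'
#' @param geno_cols n x k dosage matrix (values 0/1/2 or NA).
#' @param s Score residuals for the same subjects.
#' @param threshold Cell-sum threshold T (default 0).
#' @param k_max Guard on the interaction order (default 6).
#' @return Object of class `cell_labeling`: `snps`, `high_keys` (integer
#'   keys of high cells), `cell_table` (key, sum_s, n, label).
#' @export
label_cells <- function(geno_cols, s, threshold = 0, k_max = 6L) {
  geno_cols <- as.matrix(geno_cols)
  if (ncol(geno_cols) < 1L) stop("need at least one SNP column")
  if (ncol(geno_cols) > k_max) {
    stop("interaction order ", ncol(geno_cols), " exceeds k_max = ", k_max)
  }
  keys <- cell_keys(geno_cols)
  ok <- !is.na(keys) & !is.na(s)
  sums <- rowsum(s[ok], keys[ok])
  counts <- rowsum(rep(1L, sum(ok)), keys[ok])
  key_vals <- as.numeric(rownames(sums))
  # ties go low; the epsilon keeps exact ties from flipping high through
  # floating-point noise in the score residuals
  eps <- 1e-9 * max(1, sum(abs(s[ok])))
  label <- ifelse(sums[, 1] > threshold + eps, "high", "low")
  structure(list(snps = colnames(geno_cols),
                 high_keys = key_vals[label == "high"],
                 cell_table = data.frame(key = key_vals, sum_s = sums[, 1],
                                         n = counts[, 1], label = label,
                                         row.names = NULL)),
            class = "cell_labeling")
}

#' Balanced accuracy of a cell labeling on score residuals
#'
#' On the score scale, sensitivity is the fraction of positive score mass
#' captured by high-labeled cells and specificity the fraction of negative
#' score mass captured by low-labeled cells; balanced accuracy is their
#' mean.  Genotype tuples unseen in training are treated as low.  With
#' two-valued scores (no covariates) this is exactly classic MDR's
#' count-based balanced accuracy.
#'
#' @param labeling A `cell_labeling`.
#' @param geno_cols Dosage matrix of the evaluation subjects (same SNPs,
#'   same column order).
#' @param s Evaluation score residuals.
#' @return Balanced accuracy in \[0, 1\], or NA (with attribute
#'   `"undefined" = TRUE`) when the evaluation scores are all one-signed.
#' @export
balanced_accuracy <- function(labeling, geno_cols, s) {
  keys <- cell_keys(as.matrix(geno_cols))
  ok <- !is.na(keys) & !is.na(s)
  keys <- keys[ok]; s <- s[ok]
  high <- keys %in% labeling$high_keys
  pos <- pmax(s, 0); neg <- pmax(-s, 0)
  if (sum(pos) == 0 || sum(neg) == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  sens <- sum(pos[high]) / sum(pos)
  spec <- sum(neg[!high]) / sum(neg)
  (sens + spec) / 2
}

# Stratified fold assignment: subjects split by the sign of the score
# residual (cases vs controls) so every fold sees both classes.
make_folds <- function(s, n_folds, seed) {
  set.seed(seed)
  fold <- rep(NA_integer_, length(s))
  for (stratum in list(which(!is.na(s) & s > 0),
                       which(!is.na(s) & s <= 0))) {
    if (!length(stratum)) next
    fold[stratum] <- sample(rep_len(seq_len(n_folds), length(stratum)))
  }
  fold
}

# Train/test balanced accuracies of one SNP set over precomputed folds.
cv_model_keys <- function(keys, s, folds, n_folds, threshold = 0) {
  trba <- teba <- rep(NA_real_, n_folds)
  for (f in seq_len(n_folds)) {
    train <- !is.na(folds) & folds != f
    test <- !is.na(folds) & folds == f
    lab <- label_keys(keys[train], s[train], threshold)
    trba[f] <- ba_keys(lab, keys[train], s[train])
    teba[f] <- ba_keys(lab, keys[test], s[test])
  }
  list(trba = trba, teba = teba)
}

# Key-level variants of label_cells / balanced_accuracy used in the search
# inner loop (no matrix re-encoding per fold).
label_keys <- function(keys, s, threshold = 0) {
  ok <- !is.na(keys) & !is.na(s)
  sums <- rowsum(s[ok], keys[ok])
  eps <- 1e-9 * max(1, sum(abs(s[ok])))
  as.numeric(rownames(sums))[sums[, 1] > threshold + eps]
}

ba_keys <- function(high_keys, keys, s) {
  ok <- !is.na(keys) & !is.na(s)
  keys <- keys[ok]; s <- s[ok]
  pos <- pmax(s, 0); neg <- pmax(-s, 0)
  if (sum(pos) == 0 || sum(neg) == 0) return(NA_real_)
  high <- keys %in% high_keys
  (sum(pos[high]) / sum(pos) + sum(neg[!high]) / sum(neg)) / 2
}

#' Cross-validated balanced accuracies of one SNP set
#'
#' Folds are stratified by the sign of the score residual and fixed by the
#' seed.  Per fold, cells are labeled on the training 9/10 and balanced
#' accuracy evaluated on both the training part (TRBA) and the held-out
#' fold (TEBA, unseen genotype tuples treated as low).
#'
#' @param snp_set Character vector of SNP ids.
#' @param genotypes A `genotype_matrix`.
#' @param scores A `score_residuals` (or bare numeric vector).
#' @param n_folds Number of folds (default 10).
#' @param seed Fold seed.
#' @return Data.frame with columns `fold`, `trba`, `teba`; means attached
#'   as attributes `"trba"` and `"teba"`.
#' @export
cross_validate <- function(snp_set, genotypes, scores, n_folds = 10L,
                           seed = 1L) {
  s <- if (inherits(scores, "score_residuals")) scores$s else scores
  if (sum(!is.na(s)) < n_folds) stop("fewer usable subjects than folds")
  keys <- cell_keys(genotypes$dosage[, snp_set, drop = FALSE])
  folds <- make_folds(s, n_folds, seed)
  res <- cv_model_keys(keys, s, folds, n_folds)
  out <- data.frame(fold = seq_len(n_folds), trba = res$trba,
                    teba = res$teba)
  attr(out, "trba") <- mean(res$trba, na.rm = TRUE)
  attr(out, "teba") <- mean(res$teba, na.rm = TRUE)
  out
}

#' Exact test of per-fold testing accuracy against the null value
#'
#' Two-sided Wilcoxon signed-rank test of the per-fold TEBAs against 0.5
#' (zero differences dropped, Wilcoxon convention; midranks for ties).  The
#' null distribution is enumerated exactly over all sign assignments for up
#' to 20 non-zero folds, beyond which a normal approximation with tie
#' correction is used.  `method = "sign"` gives the plain exact sign test.
#'
#' @param per_fold_teba Numeric vector of per-fold TEBAs (NAs dropped).
#' @param null_value Null accuracy (default 0.5).
#' @param method "signed_rank" (default) or "sign".
#' @return Two-sided p-value; 1 when every fold equals the null value.
#' @export
sign_test <- function(per_fold_teba, null_value = 0.5,
                      method = c("signed_rank", "sign")) {
  method <- match.arg(method)
  d <- per_fold_teba[!is.na(per_fold_teba)] - null_value
  if (length(d) < 2) stop("need at least 2 folds")
  d <- round(d, 12)  # stabilize rank ties against floating-point noise
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  if (method == "sign") {
    return(stats::binom.test(sum(d > 0), n, 0.5)$p.value)
  }
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  if (n <= 20) {
    # exact: enumerate all 2^n sign vectors
    w_all <- 0
    for (i in seq_len(n)) {
      w_all <- as.vector(outer(w_all, c(0, r[i]), `+`))
    }
    mu <- sum(r) / 2
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
    return(min(1, p))
  }
  mu <- n * (n + 1) / 4
  sigma2 <- sum(r^2) / 4
  z <- (w_obs - mu) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Exhaustive or greedy GMDR best-model search
#'
#' For each interaction order k in `k_range`, every candidate SNP set (or a
#' greedy forward path when the exhaustive budget is exceeded) is
#' cross-validated on one shared, seeded fold split.  Within each fold the
#' model with the highest *training* balanced accuracy is that fold's
#' choice; the modal choice across folds is the order-k winner and its
#' cross-validation consistency (CVC) is the number of folds choosing it.
#' Reported TRBA/TEBA are fold means for the modal model, and the
#' signed-rank p-value tests its per-fold TEBAs against 0.5.  Models are
#' ranked by (significant sign test, higher TEBA, smaller k, lexicographic
#' SNP set).
#'
#' @param genotypes A `genotype_matrix`.
#' @param scores A `score_residuals` (or numeric vector).
#' @param candidates Candidate SNP ids.
#' @param k_range Integer vector of interaction orders to search.
#' @param n_folds,seed Cross-validation settings.
#' @param strategy "exhaustive" or "greedy".
#' @param max_models Budget on model x fold evaluations for the exhaustive
#'   search (default 200000).
#' @return Data.frame (`gmdr_result`), one row per k, ranked best first:
#'   `k`, `snp_set` (comma-joined), `trba`, `teba`, `cvc`, `n_folds`,
#'   `sign_p`; per-fold details in attribute `"per_fold"`.
#' @export
search_best_model <- function(genotypes, scores, candidates,
                              k_range = 1:3, n_folds = 10L, seed = 1L,
                              strategy = c("exhaustive", "greedy"),
                              max_models = 200000L) {
  strategy <- match.arg(strategy)
  s <- if (inherits(scores, "score_residuals")) scores$s else scores
  candidates <- sort(candidates)
  missing_cand <- setdiff(candidates, colnames(genotypes$dosage))
  if (length(missing_cand)) {
    stop("candidate SNPs absent from genotypes: ",
         paste(missing_cand, collapse = ", "))
  }
  folds <- make_folds(s, n_folds, seed)
  dosage <- genotypes$dosage

  eval_models <- function(model_list) {
    # training-BA matrix [model x fold] plus per-model teba rows
    trba <- teba <- matrix(NA_real_, length(model_list), n_folds)
    for (m in seq_along(model_list)) {
      keys <- cell_keys(dosage[, model_list[[m]], drop = FALSE])
      res <- cv_model_keys(keys, s, folds, n_folds)
      trba[m, ] <- res$trba
      teba[m, ] <- res$teba
    }
    list(trba = trba, teba = teba)
  }

  per_fold_all <- list()
  rows <- lapply(sort(unique(as.integer(k_range))), function(k) {
    if (k > length(candidates)) return(NULL)
    n_models <- choose(length(candidates), k)
    if (strategy == "exhaustive") {
      if (n_models * n_folds > max_models) {
        stop("exhaustive search at k = ", k, " needs ",
             n_models * n_folds, " model evaluations (cap ", max_models,
             "); use strategy = \"greedy\"")
      }
      models <- utils::combn(candidates, k, simplify = FALSE)
    } else {
      # seeded greedy forward selection on mean training BA
      current <- character()
      for (size in seq_len(k)) {
        additions <- setdiff(candidates, current)
        trial <- lapply(additions, function(a) sort(c(current, a)))
        ev <- eval_models(trial)
        best <- which.max(rowMeans(ev$trba, na.rm = TRUE))
        current <- trial[[best]]
      }
      models <- list(current)
    }
    ev <- eval_models(models)
    choice <- apply(ev$trba, 2L, function(col) {
      if (all(is.na(col))) NA_integer_ else which.max(col)
    })
    tab <- table(choice)
    modal <- as.integer(names(tab)[which.max(tab)])
    cvc <- as.integer(max(tab))
    snp_set <- models[[modal]]
    pf <- data.frame(fold = seq_len(n_folds),
                     trba = ev$trba[modal, ], teba = ev$teba[modal, ])
    per_fold_all[[as.character(k)]] <<- pf
    data.frame(k = k, snp_set = paste(snp_set, collapse = ","),
               trba = mean(pf$trba, na.rm = TRUE),
               teba = mean(pf$teba, na.rm = TRUE),
               cvc = cvc, n_folds = n_folds,
               sign_p = sign_test(pf$teba), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("k_range exceeds the number of candidates")
  ord <- order(!(out$sign_p < 0.05), -out$teba, out$k, out$snp_set)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "per_fold") <- per_fold_all
  class(out) <- c("gmdr_result", "data.frame")
  out
}
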