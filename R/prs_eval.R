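# Profile scoring (PLINK --score semantics) and predictive evaluation, plus
# a minimal LD-aware per-block ridge re-weighting so the blended LD
# reference can be exercised end-to-end.

#' Score individuals with a per-SNP weight set
#'
#' Computes, for each individual, the average (or sum) of
#' `weight x dosage` over the SNPs shared between the weight table and the
#' genotype matrix. Weight alleles are harmonized to the genotype alleles:
#' where the weight's allele pair is the reverse of the genotype's, the
#' weight's sign is flipped; irreconcilable pairs are dropped. Missing
#' dosages are mean-imputed from the in-sample allele frequency (`2 * AF`).
#' These are the defaults of PLINK's `--score`.
#'
#' @param geno a `geno_sim` (or any list with `dosage` matrix whose columns
#'   are named by SNP, and a `snps` data.frame with `snp`, `a1`, `a2`).
#' @param weights a [sumstats] table, a `blended_stats` table (its
#'   `b_blend` is used), or a data.frame with `snp`, `a1`, `a2` and `beta`.
#' @param convention `"average"` (default, PLINK-like) or `"sum"`.
#' @param standardize standardize dosage columns before weighting (for
#'   weights estimated on the standardized-genotype scale, as produced by
#'   the simulator's GWAS).
#' @return A `score_profile` data.frame: `sample_id`, `prs`, `n_snps_used`.
#' @export
prs_score <- function(geno, weights, convention = c("average", "sum"),
                      standardize = FALSE) {
  convention <- match.arg(convention)
  if (inherits(weights, "blended_stats")) {
    weights <- data.frame(snp = weights$snp, a1 = weights$a1, a2 = weights$a2,
                          beta = weights$b_blend, stringsAsFactors = FALSE)
  }
  for (col in c("snp", "a1", "a2", "beta")) {
    if (is.null(weights[[col]])) stop_validation("weights lack column '%s'", col)
  }
  idx <- match(weights$snp, geno$snps$snp)
  ok <- !is.na(idx)
  w <- weights[ok, , drop = FALSE]
  gsnp <- geno$snps[idx[ok], , drop = FALSE]
  same <- w$a1 == gsnp$a1 & w$a2 == gsnp$a2
  swap <- w$a1 == gsnp$a2 & w$a2 == gsnp$a1
  use <- same | swap
  if (!any(use)) stop_validation("no overlapping SNPs between weights and genotypes")
  wv <- ifelse(swap, -w$beta, w$beta)[use]
  cols <- gsnp$snp[use]
  D <- geno$dosage[, cols, drop = FALSE]
  if (anyNA(D)) {
    af2 <- colMeans(D, na.rm = TRUE)
    na_idx <- which(is.na(D), arr.ind = TRUE)
    D[na_idx] <- af2[na_idx[, 2]]
  }
  if (standardize) D <- scale(D)
  prs <- as.numeric(D %*% wv)
  # PLINK averages over observed alleles: 2 per SNP for diploid dosages
  if (convention == "average") prs <- prs / (2 * length(wv))
  out <- data.frame(sample_id = geno$sample_id %||% seq_len(nrow(D)),
                    prs = prs, n_snps_used = length(wv),
                    stringsAsFactors = FALSE)
  class(out) <- c("score_profile", "data.frame")
  out
}

#' Squared correlation between a PRS and a quantitative trait
#'
#' @param profile a `score_profile` (or numeric PRS vector).
#' @param phenotype observed quantitative phenotype.
#' @return Scalar r-squared.
#' @export
evaluate_quantitative <- function(profile, phenotype) {
  prs <- if (is.data.frame(profile)) profile$prs else profile
  check_same_length(prs = prs, phenotype = as.numeric(phenotype))
  stats::cor(prs, as.numeric(phenotype))^2
}

#' Area under the ROC curve of a PRS for a binary trait
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' case scores above a randomly chosen control, ties counted half.
#'
#' @param profile a `score_profile` (or numeric PRS vector).
#' @param labels 0/1 (or logical) case status.
#' @return Scalar AUC.
#' @export
evaluate_binary <- function(profile, labels) {
  prs <- if (is.data.frame(profile)) profile$prs else profile
  labels <- as.integer(as.logical(labels))
  check_same_length(prs = prs, labels = labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_validation("both cases and controls are required")
  r <- rank(prs)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' LD-aware per-block ridge re-weighting
#'
#' Converts marginal effect estimates into joint weights with a regularized
#' per-block solve, `(R + lambda I)^{-1} beta`. The `lambda -> Inf` limit is
#' proportional to the marginal weights; identity LD gives
#' `beta / (1 + lambda)`. A deliberately minimal stand-in for external PRS
#' machinery that lets the blended LD reference be exercised end-to-end.
#'
#' @param weights a [sumstats] or `blended_stats` table (effect column
#'   `beta` or `b_blend`).
#' @param ld an [ld_blockset]; SNPs of `weights` absent from `ld` keep their
#'   marginal weight.
#' @param shrinkage ridge penalty `lambda > 0`.
#' @return `weights` with the effect column replaced by the re-weighted
#'   values.
#' @export
block_ridge_prs <- function(weights, ld, shrinkage = 0.1) {
  stopifnot(inherits(ld, "ld_blockset"))
  if (shrinkage <= 0) stop_validation("shrinkage must be positive")
  col <- if (!is.null(weights$b_blend)) "b_blend" else "beta"
  if (is.null(weights[[col]])) stop_validation("weights lack an effect column")
  b <- weights[[col]]
  names(b) <- weights$snp
  out <- b
  for (k in seq_along(ld$matrices)) {
    R <- ld$matrices[[k]]
    ids <- intersect(rownames(R), weights$snp)
    if (!length(ids)) next
    Rk <- R[ids, ids, drop = FALSE]
    out[ids] <- solve(Rk + diag(shrinkage, length(ids)), b[ids])
  }
  weights[[col]] <- as.numeric(out)
  weights
}

#' Compare PRS weight sets on a test cohort
#'
#' Scores each weight set with the same scorer and evaluates r-squared
#' (quantitative phenotype) on the same individuals — the harness used to
#' compare proximal-only, meta-analysis and blended summary statistics.
#'
#' @param geno test-cohort `geno_sim`.
#' @param phenotype test-cohort phenotype.
#' @param weight_sets named list of weight tables (see [prs_score()]).
#' @param standardize passed to [prs_score()].
#' @return Named numeric vector of r-squared values.
#' @export
compare_prs <- function(geno, phenotype, weight_sets, standardize = TRUE) {
  vapply(weight_sets, function(w) {
    evaluate_quantitative(prs_score(geno, w, standardize = standardize), phenotype)
  }, 0)
}
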