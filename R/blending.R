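# Inverse-variance meta-analysis, lFDR-weighted blending, and assembly of a
# complete derived summary-statistics set.

#' Fixed-effect inverse-variance meta-analysis of two studies
#'
#' Precision weights \eqn{w_i = 1/\sigma_i^2} give
#' \eqn{\beta_{12} = (w_1\beta_1 + w_2\beta_2)/(w_1+w_2)} with
#' \deqn{\mathrm{Var}(\beta_{12}) = \frac{w_1^2\sigma_1^2 + w_2^2\sigma_2^2 +
#'  2 w_1 w_2 \rho \sigma_1 \sigma_2}{(w_1+w_2)^2},}
#' which reduces to \eqn{1/(w_1+w_2)} when the two estimators are
#' uncorrelated (`rho = 0`). The weights themselves are the usual
#' fixed-effect ones regardless of `rho`; shared subjects only inflate the
#' variance of the combination.
#'
#' @param b1,se1,b2,se2 per-SNP effect estimates and standard errors.
#' @param rho scalar overlap correlation from [estimate_overlap_rho()].
#' @return A `meta_result` list: `b12`, `se12`.
#' @export
inverse_variance_meta <- function(b1, se1, b2, se2, rho = 0) {
  check_same_length(b1 = b1, se1 = se1, b2 = b2, se2 = se2)
  check_numeric(se1, "se1", positive = TRUE)
  check_numeric(se2, "se2", positive = TRUE)
  w1 <- 1 / se1^2
  w2 <- 1 / se2^2
  b12 <- (w1 * b1 + w2 * b2) / (w1 + w2)
  v12 <- (w1^2 * se1^2 + w2^2 * se2^2 + 2 * w1 * w2 * rho * se1 * se2) /
    (w1 + w2)^2
  structure(list(b12 = b12, se12 = sqrt(v12)), class = "meta_result")
}

#' Blend proximal and meta-analysis estimates by the lFDR weight
#'
#' The blended effect is the convex combination
#' \deqn{\beta_{blend} = (1-\pi)\beta_1 + \pi\beta_{12}}
#' with \eqn{\pi} the per-SNP lFDR (probability that the two studies share a
#' common true effect). Treating \eqn{\pi} as a fixed plug-in weight, the
#' variance is
#' \deqn{(1-\pi)^2\sigma_1^2 + \pi^2\mathrm{Var}(\beta_{12}) +
#'  2\pi(1-\pi)\mathrm{Cov}(\beta_1,\beta_{12}),}
#' where \eqn{\mathrm{Cov}(\beta_1,\beta_{12}) = (w_1\sigma_1^2 +
#'  w_2\rho\sigma_1\sigma_2)/(w_1+w_2)}. P-values are two-sided normal.
#'
#' The effective sample size reported for downstream tools is
#' \eqn{n_{eff} = 1/(2\,AF(1-AF)\,\sigma_{blend}^2)}, capped at
#' \eqn{N_1 + N_2 - n_{shared}}; the alternative convention
#' \eqn{(1-\pi)N_1 + \pi(N_1+N_2)} is available via `n_eff_method`.
#'
#' @param b1,se1 proximal per-SNP estimates.
#' @param meta a `meta_result` from [inverse_variance_meta()] (must be built
#'   from the same SNP vectors).
#' @param lfdr per-SNP blending weights in `[0, 1]`.
#' @param rho scalar overlap correlation.
#' @param se2 adjunct standard errors (required for the covariance term when
#'   `rho > 0`).
#' @param af effect-allele frequencies (for `n_eff`; optional).
#' @param n1,n2 per-SNP (or scalar) sample sizes; optional.
#' @param n_shared number of shared subjects (scalar), used in the cap.
#' @param n_eff_method `"se_implied"` (default) or `"weighted"`.
#' @return A `blended_stats` data.frame: `b_blend`, `se_blend`, `pval_blend`,
#'   `n_eff`, `lfdr_used`, `source` (all rows `"blended"`).
#' @export
blend_effects <- function(b1, se1, meta, lfdr, rho = 0, se2 = NULL,
                          af = NULL, n1 = NULL, n2 = NULL, n_shared = 0,
                          n_eff_method = c("se_implied", "weighted")) {
  n_eff_method <- match.arg(n_eff_method)
  stopifnot(inherits(meta, "meta_result"))
  check_same_length(b1 = b1, se1 = se1, b12 = meta$b12, lfdr = lfdr)
  check_numeric(lfdr, "lfdr", min = 0, max = 1)
  check_numeric(se1, "se1", positive = TRUE)
  if (rho > 0 && is.null(se2)) {
    stop_validation("se2 is required for the covariance term when rho > 0")
  }
  m <- length(b1)
  pi_ <- lfdr
  w1 <- 1 / se1^2
  # Cov(beta1, beta12) = (w1*se1^2 + w2*rho*se1*se2) / (w1 + w2)
  if (is.null(se2)) {
    # rho = 0: cov = w1 se1^2 / (w1 + w2) and w2 comes from the identity
    # Var(b12) = 1/(w1+w2); valid only because rho = 0.
    wsum <- 1 / meta$se12^2
    cov1_12 <- w1 * se1^2 / wsum
  } else {
    check_numeric(se2, "se2", positive = TRUE)
    w2 <- 1 / se2^2
    wsum <- w1 + w2
    cov1_12 <- (w1 * se1^2 + w2 * rho * se1 * se2) / wsum
  }
  v_blend <- (1 - pi_)^2 * se1^2 + pi_^2 * meta$se12^2 +
    2 * pi_ * (1 - pi_) * cov1_12
  b_blend <- (1 - pi_) * b1 + pi_ * meta$b12
  se_blend <- sqrt(v_blend)
  pval <- 2 * stats::pnorm(-abs(b_blend / se_blend))
  pval <- pmin(pmax(pval, .Machine$double.xmin), 1)

  n_eff <- rep(NA_real_, m)
  if (!is.null(af)) {
    n_eff <- 1 / (2 * af * (1 - af) * se_blend^2)
    if (!is.null(n1) && !is.null(n2)) {
      cap <- n1 + n2 - n_shared
      n_eff <- pmin(n_eff, cap)
    }
  }
  if (n_eff_method == "weighted") {
    if (is.null(n1) || is.null(n2)) {
      stop_validation("n1 and n2 are required for the weighted n_eff convention")
    }
    n_eff <- (1 - pi_) * n1 + pi_ * (n1 + n2)
  }
  out <- data.frame(
    b_blend = b_blend, se_blend = se_blend, pval_blend = pval,
    n_eff = n_eff, lfdr_used = pi_,
    source = rep("blended", m), stringsAsFactors = FALSE
  )
  class(out) <- c("blended_stats", "data.frame")
  out
}

#' Append proximal-only SNPs unchanged
#'
#' SNPs genotyped only in the proximal study cannot be blended; their
#' original proximal effect, standard error, p-value and sample size are
#' carried through with `source = "proximal_passthrough"` so the output is a
#' complete summary-statistics set over all proximal SNPs.
#'
#' @param pair an `aligned_pair` from [harmonize_pair()].
#' @param blended a `blended_stats` table for the shared SNPs (with a `snp`
#'   column, as produced by [blend_sumstats()]).
#' @return `blended` with passthrough rows appended.
#' @export
passthrough_proximal_only <- function(pair, blended) {
  stopifnot(inherits(pair, "aligned_pair"))
  po <- pair$proximal_only
  if (nrow(po) == 0L) return(blended)
  if (is.null(blended$snp)) stop_validation("blended table lacks a 'snp' column")
  clash <- intersect(po$snp, blended$snp)
  if (length(clash)) {
    stop_validation("snp_id collision between blended and proximal-only rows: %s",
                    paste(utils::head(clash, 5), collapse = ", "))
  }
  add <- data.frame(
    snp = po$snp, chr = po$chr, bp = po$bp, a1 = po$a1, a2 = po$a2,
    af = po$af, b_blend = po$beta, se_blend = po$se, pval_blend = po$p,
    n_eff = po$n, lfdr_used = NA_real_, q_stat = NA_real_, q_pval = NA_real_,
    beta1 = po$beta, se1 = po$se, beta2 = NA_real_, se2 = NA_real_,
    source = "proximal_passthrough", stringsAsFactors = FALSE
  )
  add <- add[intersect(names(blended), names(add))]
  for (col in setdiff(names(blended), names(add))) add[[col]] <- NA
  out <- rbind(as.data.frame(blended), add[names(blended)])
  class(out) <- class(blended)
  out
}

#' Full summary-statistics blending pipeline
#'
#' Runs, over an allele-aligned study pair: overlap-correlation estimation,
#' the shared-control-adjusted Cochran's Q test, lFDR estimation, fixed-effect
#' meta-analysis, lFDR-weighted blending, and passthrough of proximal-only
#' SNPs. The result is a complete derived summary-statistics set (with audit
#' columns) that drops directly into downstream PRS tools via
#' [write_sumstats()].
#'
#' @param pair an `aligned_pair` from [harmonize_pair()].
#' @param overlap a [study_overlap()]; `NULL` means no shared subjects
#'   (`rho = 0`) unless `rho` is given directly.
#' @param rho overlap correlation; overrides `overlap` when non-NULL.
#' @param lfdr_opts list of options passed to [estimate_pi0()] /
#'   [estimate_lfdr()] (`lambda`, `method`, `lambda_fixed`, `bandwidth`).
#' @param n_eff_method effective-sample-size convention, see
#'   [blend_effects()].
#' @return A `blended_stats` data.frame with columns `snp, chr, bp, a1, a2,
#'   af` (proximal AF), `b_blend, se_blend, pval_blend, n_eff, lfdr_used,
#'   q_stat, q_pval, beta1, se1, beta2, se2, source`, plus attributes `rho`
#'   and `pi0`.
#' @export
blend_sumstats <- function(pair, overlap = NULL, rho = NULL,
                           lfdr_opts = list(),
                           n_eff_method = c("se_implied", "weighted")) {
  n_eff_method <- match.arg(n_eff_method)
  stopifnot(inherits(pair, "aligned_pair"))
  sh <- pair$shared
  if (nrow(sh) == 0L) stop_validation("no shared SNPs to blend")
  if (is.null(rho)) rho <- if (is.null(overlap)) 0 else estimate_overlap_rho(overlap)

  het <- cochran_q(sh$beta, sh$se, sh$beta2, sh$se2, rho = rho, snp = sh$snp)
  # Q p-values can underflow to 0 at extreme heterogeneity; clamp up front
  qp <- pmax(het$q_pval, .Machine$double.xmin)
  pi0_args <- lfdr_opts[intersect(names(lfdr_opts),
                                  c("lambda", "method", "lambda_fixed"))]
  pi0 <- do.call(estimate_pi0, c(list(p = qp), pi0_args))
  lf <- estimate_lfdr(qp, pi0 = pi0,
                      bandwidth = lfdr_opts$bandwidth %||% NULL)

  meta <- inverse_variance_meta(sh$beta, sh$se, sh$beta2, sh$se2, rho = rho)
  n_shared <- if (is.null(overlap)) 0 else overlap$n_shared
  bl <- blend_effects(sh$beta, sh$se, meta, lf$lfdr, rho = rho, se2 = sh$se2,
                      af = sh$af, n1 = sh$n, n2 = sh$n2, n_shared = n_shared,
                      n_eff_method = n_eff_method)
  out <- data.frame(
    snp = sh$snp, chr = sh$chr, bp = sh$bp, a1 = sh$a1, a2 = sh$a2,
    af = sh$af, # proximal AF: the target population is the proximal one
    b_blend = bl$b_blend, se_blend = bl$se_blend, pval_blend = bl$pval_blend,
    n_eff = bl$n_eff, lfdr_used = bl$lfdr_used,
    q_stat = het$q_stat, q_pval = het$q_pval,
    beta1 = sh$beta, se1 = sh$se, beta2 = sh$beta2, se2 = sh$se2,
    source = "blended", stringsAsFactors = FALSE
  )
  class(out) <- c("blended_stats", "data.frame")
  out <- passthrough_proximal_only(pair, out)
  attr(out, "rho") <- rho
  attr(out, "pi0") <- as.numeric(pi0)
  log_kv("blend_sumstats", snps = nrow(out), rho = rho, pi0 = as.numeric(pi0))
  out
}

#' Convert a blended table to a canonical sumstats table
#'
#' Maps `b_blend/se_blend/pval_blend/n_eff` onto the canonical
#' `beta/se/p/n` roles so the result can be written by [write_sumstats()] or
#' scored by [prs_score()].
#'
#' @param x a `blended_stats` table from [blend_sumstats()].
#' @return A `sumstats` table.
#' @export
as_sumstats <- function(x) {
  stopifnot(inherits(x, "blended_stats"))
  sumstats(snp = x$snp, chr = x$chr, bp = x$bp, a1 = x$a1, a2 = x$a2,
           af = x$af, beta = x$b_blend, se = x$se_blend, p = x$pval_blend,
           n = x$n_eff)
}

#' @export
print.blended_stats <- function(x, ...) {
  cat(sprintf("<blended_stats> %d SNPs (%d blended, %d passthrough)\n",
              nrow(x), sum(x$source == "blended"),
              sum(x$source == "proximal_passthrough")))
  if (!is.null(attr(x, "rho"))) {
    cat(sprintf("  rho = %.4f, pi0 = %.4f\n", attr(x, "rho"), attr(x, "pi0")))
  }
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}
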