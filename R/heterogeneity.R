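# Shared-subject overlap correlation and the shared-control-adjusted
# Cochran's Q heterogeneity test.

#' Study-overlap design description
#'
#' Records the subject counts of two case-control (or quantitative) GWAS and
#' how many subjects they share; this is what determines the correlation
#' `rho` between the two studies' effect estimators at null SNPs.
#'
#' @param n1_cases,n1_controls,n2_cases,n2_controls subject counts of study 1
#'   (proximal) and study 2 (adjunct).
#' @param n_shared_cases,n_shared_controls subjects present in both studies.
#' @param quantitative if `TRUE` the studies are quantitative-trait GWAS and
#'   `n1`, `n2`, `n_shared` total counts are used instead of case/control
#'   splits.
#' @param n1,n2,n_shared total sample sizes for the quantitative mode.
#' @return A `study_overlap` list.
#' @export
study_overlap <- function(n1_cases = 0, n1_controls = 0,
                          n2_cases = 0, n2_controls = 0,
                          n_shared_cases = 0, n_shared_controls = 0,
                          quantitative = FALSE,
                          n1 = n1_cases + n1_controls,
                          n2 = n2_cases + n2_controls,
                          n_shared = n_shared_cases + n_shared_controls) {
  cnt <- c(n1_cases = n1_cases, n1_controls = n1_controls,
           n2_cases = n2_cases, n2_controls = n2_controls,
           n_shared_cases = n_shared_cases,
           n_shared_controls = n_shared_controls,
           n1 = n1, n2 = n2, n_shared = n_shared)
  if (any(cnt < 0)) stop_validation("subject counts must be non-negative")
  if (!quantitative) {
    if (n_shared_cases > min(n1_cases, n2_cases)) {
      stop_validation("n_shared_cases exceeds a study's case count")
    }
    if (n_shared_controls > min(n1_controls, n2_controls)) {
      stop_validation("n_shared_controls exceeds a study's control count")
    }
  } else {
    if (n_shared > min(n1, n2)) stop_validation("n_shared exceeds a study's size")
  }
  structure(as.list(c(cnt, quantitative = quantitative)),
            class = "study_overlap")
}

#' Correlation between effect estimators induced by shared subjects
#'
#' For two case-control GWAS sharing `n_shared_cases` cases and
#' `n_shared_controls` controls, the effect estimators at a null SNP are
#' correlated with
#' \deqn{\rho = \frac{n_{sc}\sqrt{\frac{n_{1ctl}\,n_{2ctl}}{n_{1cas}\,n_{2cas}}}
#'  + n_{sctl}\sqrt{\frac{n_{1cas}\,n_{2cas}}{n_{1ctl}\,n_{2ctl}}}}{\sqrt{n_1 n_2}}}
#' with \eqn{n_i} the total size of study *i*. For quantitative traits the
#' corresponding expression is \eqn{n_{shared}/\sqrt{n_1 n_2}}. The result is
#' clipped to `[0, 1]`. The formula is validated by a Monte-Carlo oracle in
#' the package tests (simulated shared-control GWAS pairs).
#'
#' @param overlap a [study_overlap] object.
#' @return Scalar `rho` in `[0, 1]`.
#' @export
estimate_overlap_rho <- function(overlap) {
  stopifnot(inherits(overlap, "study_overlap"))
  o <- overlap
  if (isTRUE(o$quantitative == 1) || isTRUE(o$quantitative)) {
    if (o$n1 <= 0 || o$n2 <= 0) stop_validation("study sizes must be positive")
    rho <- o$n_shared / sqrt(o$n1 * o$n2)
  } else {
    if (o$n_shared_cases == 0 && o$n_shared_controls == 0) return(0)
    if (o$n1_cases <= 0 || o$n2_cases <= 0 || o$n1_controls <= 0 || o$n2_controls <= 0) {
      stop_validation(
        "case-control overlap correlation is undefined with a zero case or control count"
      )
    }
    n1 <- o$n1_cases + o$n1_controls
    n2 <- o$n2_cases + o$n2_controls
    rho <- (o$n_shared_cases * sqrt(o$n1_controls * o$n2_controls /
                                      (o$n1_cases * o$n2_cases)) +
              o$n_shared_controls * sqrt(o$n1_cases * o$n2_cases /
                                           (o$n1_controls * o$n2_controls))) /
      sqrt(n1 * n2)
  }
  min(max(rho, 0), 1)
}

#' Shared-control-adjusted Cochran's Q test
#'
#' Per-SNP heterogeneity test between the proximal and adjunct effect
#' estimates,
#' \deqn{Q = \frac{(\beta_1-\beta_2)^2}{\sigma_1^2+\sigma_2^2-2\rho\sigma_1\sigma_2},
#'  \quad Q \sim \chi^2_1 \text{ under homogeneity},}
#' where the \eqn{-2\rho\sigma_1\sigma_2} term accounts for the positive
#' correlation of the two estimators induced by shared subjects (without it
#' the test is conservative). `rho` is a single genome-wide scalar from
#' [estimate_overlap_rho()].
#'
#' @param b1,se1 proximal effect estimates and standard errors.
#' @param b2,se2 adjunct effect estimates and standard errors (allele-aligned,
#'   see [harmonize_pair()]).
#' @param rho scalar overlap correlation in `[0, 1)`.
#' @param snp optional SNP identifiers used in error messages.
#' @return A `heterogeneity_result` list: `q_stat`, `q_pval` (upper tail of
#'   \eqn{\chi^2_1}), `rho`.
#' @export
cochran_q <- function(b1, se1, b2, se2, rho = 0, snp = NULL) {
  check_same_length(b1 = b1, se1 = se1, b2 = b2, se2 = se2)
  check_numeric(se1, "se1", positive = TRUE)
  check_numeric(se2, "se2", positive = TRUE)
  if (length(rho) != 1 || is.na(rho) || rho < 0 || rho >= 1) {
    stop_validation("rho must be a scalar in [0, 1)")
  }
  denom <- se1^2 + se2^2 - 2 * rho * se1 * se2
  if (any(denom <= 0)) {
    i <- which(denom <= 0)[1]
    id <- if (!is.null(snp)) snp[i] else paste("index", i)
    stop_validation(
      "non-positive Q denominator at SNP %s (invalid rho or standard errors)", id
    )
  }
  q <- (b1 - b2)^2 / denom
  structure(
    list(q_stat = q,
         q_pval = stats::pchisq(q, df = 1, lower.tail = FALSE),
         rho = rho),
    class = "heterogeneity_result"
  )
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("<heterogeneity_result> %d SNPs, rho = %.4f\n",
              length(x$q_stat), x$rho))
  cat(sprintf("  Q: median %.3f, max %.1f; p < 1e-4 at %d SNPs\n",
              stats::median(x$q_stat), max(x$q_stat), sum(x$q_pval < 1e-4)))
  invisible(x)
}
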