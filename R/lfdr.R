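# Two-groups empirical-Bayes local false discovery rate: the blending
# weights pi = Pr(H0 | p) computed from the per-SNP Q-test p-values.

#' Estimate the null proportion pi0
#'
#' Storey-type estimator: \eqn{\pi_0(\lambda) = \#\{p > \lambda\} / (m(1-\lambda))}
#' is computed on a grid of `lambda` values and, for the `"smoother"` method,
#' a cubic smoothing spline fitted to the curve is evaluated at
#' `max(lambda)`; the `"fixed"` method returns \eqn{\pi_0(\lambda^*)} at a
#' single user-chosen point. The result is clipped to (0, 1].
#'
#' @param p p-values in (0, 1].
#' @param lambda increasing tuning grid in (0, 1); at least 4 values for the
#'   smoother.
#' @param method `"smoother"` (default; needs >= 100 p-values) or `"fixed"`.
#' @param lambda_fixed the \eqn{\lambda^*} for `method = "fixed"`.
#' @return A numeric scalar of class `pi0_estimate` with attributes `lambda`
#'   and `pi0_lambda` recording the tuning curve.
#' @export
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                         method = c("smoother", "fixed"), lambda_fixed = 0.5) {
  method <- match.arg(method)
  check_numeric(p, "p", min = 0, max = 1)
  if (any(p == 0)) {
    # numerically underflowed tests carry maximal evidence against the null
    warning("p-values of 0 clamped to the smallest positive representable value")
    p[p == 0] <- .Machine$double.xmin
  }
  if (length(unique(p)) == 1L) {
    stop_validation("all p-values identical; pi0 is undefined")
  }
  m <- length(p)
  if (method == "smoother") {
    if (m < 100) stop_validation("the smoother method needs at least 100 p-values")
    if (length(lambda) < 4 || is.unsorted(lambda, strictly = TRUE) ||
        any(lambda <= 0 | lambda >= 1)) {
      stop_validation("lambda must be an increasing grid in (0, 1) of length >= 4")
    }
    pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
    fit <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
  } else {
    if (lambda_fixed <= 0 || lambda_fixed >= 1) {
      stop_validation("lambda_fixed must lie in (0, 1)")
    }
    lambda <- lambda_fixed
    pi0_lambda <- mean(p > lambda_fixed) / (1 - lambda_fixed)
    pi0 <- pi0_lambda
  }
  if (pi0 <= 0) {
    warning("estimated pi0 <= 0; clipping to 1e-6")
    pi0 <- 1e-6
  }
  pi0 <- min(pi0, 1)
  structure(pi0, lambda = lambda, pi0_lambda = pi0_lambda,
            method = method, class = "pi0_estimate")
}

#' @export
print.pi0_estimate <- function(x, ...) {
  cat(sprintf("<pi0_estimate> pi0 = %.4f (%s, %d lambda values)\n",
              as.numeric(x), attr(x, "method"), length(attr(x, "lambda"))))
  invisible(x)
}

#' Local false discovery rate from p-values
#'
#' Two-groups model on the probit scale: with \eqn{x = \Phi^{-1}(p)}, the
#' marginal density \eqn{f(x)} is estimated by Gaussian kernel density
#' estimation (Silverman's rule bandwidth by default) and
#' \deqn{\mathrm{lfdr}(p) = \pi_0\,\varphi(x)/\hat f(x),}
#' since \eqn{\varphi}, the standard normal density, is the density of
#' \eqn{x} under the uniform null. Values are clipped to `[0, 1]` and then
#' made monotone non-decreasing in `p` by a cumulative-maximum pass (large p
#' means no heterogeneity evidence, so the blending weight on the
#' meta-analysis must not decrease with p).
#'
#' p-values of exactly 1 (Q = 0 SNPs) are retained by clamping to
#' \eqn{1 - 10^{-12}}; p = 0 is clamped to the smallest positive
#' representable value with a warning.
#'
#' @param p p-values in (0, 1].
#' @param pi0 null proportion; `NULL` estimates it via [estimate_pi0()].
#' @param bandwidth kernel bandwidth for the probit-scale KDE; `NULL` uses
#'   [stats::bw.nrd0()].
#' @param monotone apply the monotonization pass (default TRUE).
#' @return An `lfdr_result` list: `lfdr` (per-SNP weights in `[0,1]`), `pi0`,
#'   `lambda_grid` (the pi0 tuning record, for reproducibility).
#' @export
estimate_lfdr <- function(p, pi0 = NULL, bandwidth = NULL, monotone = TRUE) {
  if (!is.numeric(p) || anyNA(p)) stop_validation("p must be numeric without NAs")
  if (any(p > 1)) stop_validation("p-values greater than 1")
  if (any(p < 0)) stop_validation("negative p-values")
  if (any(p == 0)) {
    warning("p-values of 0 clamped to the smallest positive representable value")
    p[p == 0] <- .Machine$double.xmin
  }
  if (is.null(pi0)) pi0 <- estimate_pi0(p)
  lambda_grid <- list(lambda = attr(pi0, "lambda"),
                      pi0_lambda = attr(pi0, "pi0_lambda"))
  pi0 <- as.numeric(pi0)
  if (pi0 <= 0 || pi0 > 1) stop_validation("pi0 must lie in (0, 1]")

  x <- stats::qnorm(pmin(p, 1 - 1e-12))
  bw <- bandwidth %||% stats::bw.nrd0(x)
  d <- stats::density(x, bw = bw, n = 2048,
                      from = min(x) - 4 * bw, to = max(x) + 4 * bw)
  f <- stats::approx(d$x, d$y, xout = x, rule = 2)$y
  lfdr <- pmin(pi0 * stats::dnorm(x) / pmax(f, .Machine$double.xmin), 1)
  if (monotone) {
    o <- order(p)
    lfdr[o] <- cummax(lfdr[o])
  }
  structure(list(lfdr = lfdr, pi0 = pi0, lambda_grid = lambda_grid),
            class = "lfdr_result")
}

#' @export
print.lfdr_result <- function(x, ...) {
  cat(sprintf("<lfdr_result> %d SNPs, pi0 = %.4f\n", length(x$lfdr), x$pi0))
  cat(sprintf("  lfdr < 0.5 at %d SNPs; lfdr < 0.01 at %d SNPs\n",
              sum(x$lfdr < 0.5), sum(x$lfdr < 0.01)))
  invisible(x)
}
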