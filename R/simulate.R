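# Paired-GWAS simulator: genetic architectures with controllable sharing
# composition, block-structured genotypes, quantitative phenotypes, marginal
# GWAS, a fast analytic summary-statistics sampler, and a shared-control
# case-control design for exercising the overlap correlation.

#' Define a simulation scenario
#'
#' Captures a paired-trait genetic architecture: total and causal SNP counts,
#' per-trait heritability, and the *composition* of the genome-wide genetic
#' correlation — a fraction `shared_fraction` (P) of causal SNPs shared
#' between the traits with within-SNP effect correlation `shared_effect_cor`
#' (cor), the remainder trait-specific. The realized genetic correlation over
#' all causal SNPs is P * cor (the composition identity), so e.g. rG = 0.5
#' can arise from all causal SNPs shared at cor = 0.5 or from half shared at
#' cor = 1. Optionally `penetrant_snps` high-penetrance trait-specific SNPs
#' carry a fixed fraction `penetrant_h2_fraction` of each trait's non-shared
#' heritability (modeling genes such as NOD2 that differentiate otherwise
#' related diseases).
#'
#' @param m_snps total number of SNPs.
#' @param n_causal causal SNPs per trait.
#' @param h2 narrow-sense heritability per trait in `[0, 1]`.
#' @param shared_fraction P, fraction of causal SNPs shared, in `[0, 1]`.
#' @param shared_effect_cor cor, effect correlation at shared SNPs.
#' @param rg_target optional genome-wide genetic correlation; must equal
#'   `shared_fraction * shared_effect_cor` (hard error otherwise — the
#'   composition identity is enforced, not silently re-balanced).
#' @param penetrant_snps number of high-penetrance trait-specific SNPs per
#'   trait (0 disables).
#' @param penetrant_h2_fraction fraction of the non-shared heritability the
#'   penetrant SNPs carry (default 0.05).
#' @param n_total total training subjects across both studies.
#' @param split proximal/adjunct sample-size proportions (length 2, sums
#'   to 1).
#' @param n_shared_controls shared control count for binary designs.
#' @param maf_range minor-allele-frequency range for simulated SNPs.
#' @param ld_block_size SNPs per LD block.
#' @param ld_rho target adjacent-SNP dosage correlation; the within-block
#'   profile is AR(1), `ld_rho^|i-j|`, capped at 95% of the attainable bound
#'   for each MAF pair.
#' @param seed RNG seed applied by [simulate_study()]; `NULL` leaves the RNG
#'   state alone.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(m_snps = 10000, n_causal = 1000, h2 = 0.5,
                         shared_fraction = 0.5, shared_effect_cor = 1.0,
                         rg_target = NULL, penetrant_snps = 0,
                         penetrant_h2_fraction = 0.05,
                         n_total = 4000, split = c(0.5, 0.5),
                         n_shared_controls = 0,
                         maf_range = c(0.05, 0.5),
                         ld_block_size = 10, ld_rho = 0.65, seed = NULL) {
  if (h2 < 0 || h2 > 1) stop_validation("h2 must lie in [0, 1]")
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop_validation("shared_fraction must lie in [0, 1]")
  }
  if (abs(shared_effect_cor) > 1) stop_validation("|shared_effect_cor| <= 1 required")
  if (!is.null(rg_target) &&
      abs(rg_target - shared_fraction * shared_effect_cor) > 1e-8) {
    stop_validation(
      "infeasible composition: shared_fraction * shared_effect_cor = %.4f but rg_target = %.4f",
      shared_fraction * shared_effect_cor, rg_target
    )
  }
  if (n_causal > m_snps) stop_validation("n_causal exceeds m_snps")
  n_spec <- n_causal - round(shared_fraction * n_causal)
  if (penetrant_snps > 0 && n_spec < penetrant_snps) {
    stop_validation(
      "penetrant SNPs are trait-specific: need >= %d non-shared causal SNPs, have %d",
      penetrant_snps, n_spec
    )
  }
  if (round(shared_fraction * n_causal) + 2L * n_spec > m_snps) {
    stop_validation("causal SNP sets do not fit into m_snps")
  }
  if (length(split) != 2 || abs(sum(split) - 1) > 1e-8 || any(split <= 0)) {
    stop_validation("split must be two positive proportions summing to 1")
  }
  structure(
    list(m_snps = m_snps, n_causal = n_causal, h2 = h2,
         shared_fraction = shared_fraction,
         shared_effect_cor = shared_effect_cor,
         rg_target = rg_target %||% (shared_fraction * shared_effect_cor),
         penetrant_snps = penetrant_snps,
         penetrant_h2_fraction = penetrant_h2_fraction,
         n_total = n_total, split = split,
         n_shared_controls = n_shared_controls,
         maf_range = maf_range, ld_block_size = ld_block_size,
         ld_rho = ld_rho, seed = seed),
    class = "sim_scenario"
  )
}

# ---- latent-correlation calibration -----------------------------------------
# A gamete allele is 1{Z < qnorm(maf)} for a standard normal Z; dosages sum
# two independent gametes (Hardy-Weinberg). The dosage correlation implied by
# a latent correlation r follows from the bivariate-normal rectangle
# probability; by the Plackett identity dP/dr is the bivariate normal density,
# so Cov(B_i, B_j)(r) = int_0^r phi2(u; t_i, t_j) du, evaluated with 16-point
# Gauss-Legendre and inverted by bisection (vectorized over SNP pairs).

.GL16 <- list(
  x = c(0.00529953250417503, 0.0277124884633837, 0.0671843988060841,
        0.122297795822498, 0.191061877798678, 0.270991611171386,
        0.359198224610370, 0.452493745081181, 0.547506254918819,
        0.640801775389630, 0.729008388828614, 0.808938122201322,
        0.877702204177502, 0.932815601193916, 0.972287511536616,
        0.994700467495825),
  w = c(0.0135762297058770, 0.0311267619693239, 0.0475792558412464,
        0.0623144856277669, 0.0747979944082884, 0.0845782596975013,
        0.0913017075224618, 0.0947253052275343, 0.0947253052275343,
        0.0913017075224618, 0.0845782596975013, 0.0747979944082884,
        0.0623144856277669, 0.0475792558412464, 0.0311267619693239,
        0.0135762297058770)
)

.phi2 <- function(r, t1, t2) {
  s2 <- pmax(1 - r^2, 1e-12)
  exp(-(t1^2 - 2 * r * t1 * t2 + t2^2) / (2 * s2)) / (2 * pi * sqrt(s2))
}

# Cov(B1, B2) at latent correlation r (vectorized over pairs)
.bin_cov <- function(r, t1, t2) {
  acc <- 0
  for (k in seq_along(.GL16$x)) {
    acc <- acc + .GL16$w[k] * .phi2(r * .GL16$x[k], t1, t2)
  }
  r * acc
}

# dosage correlation from latent correlation
.dosage_corr <- function(r, maf1, maf2) {
  .bin_cov(r, stats::qnorm(maf1), stats::qnorm(maf2)) /
    sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
}

# latent correlation achieving a target dosage correlation (bisection)
.latent_from_dosage <- function(target, maf1, maf2, iters = 34L, rmax = 0.9999) {
  t1 <- stats::qnorm(maf1); t2 <- stats::qnorm(maf2)
  cv <- target * sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
  lo <- rep(-rmax, length(cv)); hi <- rep(rmax, length(cv))
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    up <- .bin_cov(mid, t1, t2) < cv
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  (lo + hi) / 2
}

# Frechet upper bound of the correlation of two Bernoulli indicators
.binary_corr_bound <- function(maf1, maf2) {
  (pmin(maf1, maf2) - maf1 * maf2) /
    sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
}

#' Build the SNP map of a scenario
#'
#' Draws per-SNP MAFs and alleles, lays SNPs out in LD blocks, and calibrates
#' the latent gamete correlations so the realized dosage LD matches the
#' designed AR(1) profile (capped at 95% of the attainable bound for each MAF
#' pair — high LD between SNPs of very different frequency is impossible, as
#' in real data). The map is drawn once per study and reused for every cohort
#' (training, adjunct, test) so all share the same variants.
#'
#' @param scenario a [sim_scenario()].
#' @param maf optional per-SNP MAF vector overriding the scenario draw (used
#'   for a second ancestry with shifted frequencies).
#' @param ld_rho optional override of the scenario's LD profile (second
#'   ancestry).
#' @return A `snp_map` list: `snps` (data.frame: snp, chr, bp, a1, a2, maf),
#'   `blocks` (manifest with 0-based half-open intervals), `latent_chol` and
#'   `ld` (designed dosage correlation matrix) per block.
#' @export
sim_snp_map <- function(scenario, maf = NULL, ld_rho = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  m <- scenario$m_snps
  bs <- scenario$ld_block_size
  rho_ld <- ld_rho %||% scenario$ld_rho
  if (is.null(maf)) {
    maf <- stats::runif(m, scenario$maf_range[1], scenario$maf_range[2])
  }
  # non-ambiguous allele pairs only, so downstream harmonization is exact
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pick <- sample.int(nrow(pairs), m, replace = TRUE)
  nb <- ceiling(m / bs)
  block_of <- rep(seq_len(nb), each = bs)[seq_len(m)]
  snps <- data.frame(
    snp = sprintf("snp%06d", seq_len(m)), chr = "1", bp = seq_len(m),
    a1 = pairs[pick, 1], a2 = pairs[pick, 2], maf = maf,
    block = block_of, stringsAsFactors = FALSE
  )
  blocks <- data.frame(
    block_id = sprintf("b%04d", seq_len(nb)), chr = "1",
    start = (seq_len(nb) - 1L) * bs,
    end = pmin(seq_len(nb) * bs, m),
    stringsAsFactors = FALSE
  )
  latent_chol <- vector("list", nb)
  ld <- vector("list", nb)
  for (k in seq_len(nb)) {
    idx <- which(block_of == k)
    s <- length(idx)
    mafb <- maf[idx]
    target <- rho_ld^abs(outer(seq_len(s), seq_len(s), "-"))
    bound <- outer(mafb, mafb, .binary_corr_bound)
    target <- pmin(target, 0.95 * bound)
    diag(target) <- 1
    ut <- which(upper.tri(target))
    L <- diag(s)
    if (length(ut)) {
      i <- row(target)[ut]; j <- col(target)[ut]
      L[ut] <- .latent_from_dosage(target[ut], mafb[i], mafb[j])
      L[lower.tri(L)] <- t(L)[lower.tri(L)]
    }
    ev <- eigen(L, symmetric = TRUE)
    if (min(ev$values) < 1e-8) {
      v <- pmax(ev$values, 1e-8)
      L <- ev$vectors %*% (v * t(ev$vectors))
      L <- L / tcrossprod(sqrt(diag(L)))
    }
    # designed dosage LD = forward map of the (possibly repaired) latent matrix
    R <- diag(s)
    if (length(ut)) {
      i <- row(target)[ut]; j <- col(target)[ut]
      R[ut] <- .dosage_corr(L[ut], mafb[i], mafb[j])
      R[lower.tri(R)] <- t(R)[lower.tri(R)]
    }
    dimnames(R) <- list(snps$snp[idx], snps$snp[idx])
    latent_chol[[k]] <- chol(L)
    ld[[k]] <- R
  }
  structure(list(snps = snps, blocks = blocks, latent_chol = latent_chol, ld = ld),
            class = "snp_map")
}

#' Designed LD reference of a SNP map
#'
#' @param map a `snp_map` from [sim_snp_map()].
#' @return An [ld_blockset] holding the designed per-block dosage
#'   correlation matrices.
#' @export
target_ld <- function(map) {
  stopifnot(inherits(map, "snp_map"))
  ld_blockset(map$blocks, map$ld)
}

#' Simulate genotype dosages for a cohort
#'
#' Two independent multivariate-normal gamete draws per individual are
#' thresholded at `qnorm(maf)` and summed, giving 0/1/2 dosages in
#' Hardy-Weinberg equilibrium with the map's calibrated within-block LD;
#' blocks are independent.
#'
#' @param map a `snp_map`.
#' @param n cohort size (the generator is desk-scale: `n * m` is capped at
#'   `5000 * 20000`).
#' @param sample_prefix prefix for generated sample identifiers.
#' @return A `geno_sim` list: `dosage` (n x m numeric matrix, columns named
#'   by SNP), `snps`, `blocks`, `sample_id`.
#' @export
simulate_genotypes <- function(map, n, sample_prefix = "ind") {
  stopifnot(inherits(map, "snp_map"))
  m <- nrow(map$snps)
  if (as.double(n) * m > 5000 * 20000) {
    stop_validation("cohort too large for the desk-scale generator (n*m > 1e8)")
  }
  thr <- stats::qnorm(map$snps$maf)
  G <- matrix(0, n, m)
  for (k in seq_len(nrow(map$blocks))) {
    idx <- which(map$snps$block == k)
    s <- length(idx)
    C <- map$latent_chol[[k]]
    tk <- rep(thr[idx], each = n)
    for (g in 1:2) {
      Z <- matrix(stats::rnorm(n * s), n, s) %*% C
      G[, idx] <- G[, idx] + (Z < tk)
    }
  }
  colnames(G) <- map$snps$snp
  structure(
    list(dosage = G, snps = map$snps, blocks = map$blocks,
         sample_id = sprintf("%s%05d", sample_prefix, seq_len(n))),
    class = "geno_sim"
  )
}

#' @export
print.geno_sim <- function(x, ...) {
  cat(sprintf("<geno_sim> %d individuals x %d SNPs (%d LD blocks)\n",
              nrow(x$dosage), ncol(x$dosage), nrow(x$blocks)))
  invisible(x)
}

#' Empirical within-block LD of a simulated cohort
#'
#' @param geno a `geno_sim`.
#' @return List of per-block dosage correlation matrices.
#' @export
realized_ld <- function(geno) {
  stopifnot(inherits(geno, "geno_sim"))
  lapply(seq_len(nrow(geno$blocks)), function(k) {
    stats::cor(geno$dosage[, geno$snps$block == k, drop = FALSE])
  })
}

#' Draw true per-SNP effects for a paired-trait architecture
#'
#' Shared causal SNPs receive effects from a bivariate normal with
#' correlation `shared_effect_cor`; each trait additionally has its own
#' disjoint set of trait-specific causal SNPs. Components are rescaled so
#' that, per trait and exactly per replicate, the shared effects carry
#' `P * h2`, the penetrant SNPs carry `penetrant_h2_fraction * (1-P) * h2`
#' (fixed alternating-sign effects of equal magnitude, so the stated share is
#' exact), and the remaining trait-specific effects the rest; each trait's
#' summed squared effects equal `h2` (effects are on the
#' standardized-genotype scale). Rescaling each trait by a positive constant
#' leaves the effect correlation untouched, so the empirical genetic
#' correlation over causal SNPs matches `P * cor` up to sampling noise.
#'
#' @param scenario a [sim_scenario()].
#' @return A `true_effects` list: `beta1`, `beta2` (length `m_snps`),
#'   `labels` (factor: null / shared / trait1_specific / trait2_specific /
#'   penetrant1 / penetrant2).
#' @export
draw_effects <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  m <- scenario$m_snps
  nc <- scenario$n_causal
  P <- scenario$shared_fraction
  corr <- scenario$shared_effect_cor
  h2 <- scenario$h2
  n_sh <- round(P * nc)
  n_sp <- nc - n_sh
  npen <- scenario$penetrant_snps

  idx <- sample.int(m, n_sh + 2L * n_sp)
  i_sh <- idx[seq_len(n_sh)]
  i_s1 <- idx[n_sh + seq_len(n_sp)]
  i_s2 <- idx[n_sh + n_sp + seq_len(n_sp)]
  beta1 <- numeric(m)
  beta2 <- numeric(m)
  labels <- rep("null", m)
  labels[i_sh] <- "shared"
  labels[i_s1] <- "trait1_specific"
  labels[i_s2] <- "trait2_specific"

  if (n_sh > 0 && h2 > 0 && P > 0) {
    z1 <- stats::rnorm(n_sh)
    z2 <- corr * z1 + sqrt(1 - corr^2) * stats::rnorm(n_sh)
    beta1[i_sh] <- z1 * sqrt(P * h2 / sum(z1^2))
    beta2[i_sh] <- z2 * sqrt(P * h2 / sum(z2^2))
  }
  v_ns <- (1 - P) * h2
  pen_frac <- if (npen > 0) scenario$penetrant_h2_fraction else 0
  for (tr in 1:2) {
    ii <- if (tr == 1) i_s1 else i_s2
    if (length(ii) == 0 || v_ns == 0) next
    b <- numeric(m)
    if (npen > 0) {
      ipen <- ii[seq_len(npen)]
      labels[ipen] <- paste0("penetrant", tr)
      # fixed effects, alternating sign: the 5% share is exact per replicate
      b[ipen] <- rep(c(1, -1), length.out = npen) *
        sqrt(pen_frac * v_ns / npen)
    }
    irest <- ii[setdiff(seq_along(ii), seq_len(npen))]
    if (length(irest)) {
      z <- stats::rnorm(length(irest))
      b[irest] <- z * sqrt((1 - pen_frac) * v_ns / sum(z^2))
    }
    if (tr == 1) beta1 <- beta1 + b else beta2 <- beta2 + b
  }
  structure(
    list(beta1 = beta1, beta2 = beta2,
         labels = factor(labels, levels = c("null", "shared",
                                            "trait1_specific", "trait2_specific",
                                            "penetrant1", "penetrant2"))),
    class = "true_effects"
  )
}

#' @export
print.true_effects <- function(x, ...) {
  cat("<true_effects>\n")
  print(table(x$labels))
  cu <- x$labels != "null"
  cat(sprintf("  empirical rG over causal SNPs: %.3f\n",
              stats::cor(x$beta1[cu], x$beta2[cu])))
  invisible(x)
}

#' Simulate a quantitative phenotype
#'
#' `y = G_std %*% beta + e` with the environmental noise scaled from the
#' realized genetic variance so that `var(G beta)/var(y) = h2` in
#' expectation. `h2 = 0` (or an all-zero effect vector) yields pure standard
#' normal noise.
#'
#' @param geno a `geno_sim`.
#' @param effects a `true_effects` object (or a numeric effect vector on the
#'   standardized-genotype scale).
#' @param h2 target heritability.
#' @param trait which trait's effects to use (1 or 2) when `effects` is a
#'   `true_effects` object.
#' @return Numeric phenotype vector with attributes `genetic_values` and
#'   `realized_h2` (= var(G beta)/var(y), the quantity the heritability
#'   calibration checks).
#' @export
simulate_phenotypes <- function(geno, effects, h2, trait = 1) {
  stopifnot(inherits(geno, "geno_sim"))
  beta <- if (inherits(effects, "true_effects")) {
    if (trait == 1) effects$beta1 else effects$beta2
  } else {
    effects
  }
  if (length(beta) != ncol(geno$dosage)) {
    stop_validation("effect vector length does not match SNP count")
  }
  n <- nrow(geno$dosage)
  gs <- scale(geno$dosage)
  gv <- as.numeric(gs %*% beta)
  vg <- stats::var(gv)
  if (h2 <= 0 || vg == 0) {
    y <- stats::rnorm(n)
    gv <- numeric(n)
  } else {
    y <- gv + stats::rnorm(n, sd = sqrt(vg * (1 - h2) / h2))
  }
  attr(y, "genetic_values") <- gv
  attr(y, "realized_h2") <- if (stats::var(y) > 0 && sum(gv^2) > 0) {
    stats::var(gv) / stats::var(y)
  } else 0
  y
}

#' Marginal per-SNP GWAS on standardized dosages
#'
#' Simple linear regression of the phenotype on each standardized SNP dosage
#' (the scale on which the simulator's true effects live): closed-form
#' slope, residual-based standard error, two-sided t p-value.
#'
#' @param geno a `geno_sim`.
#' @param y phenotype vector (quantitative, or 0/1 for the binary mode).
#' @return A [sumstats] table aligned with the map (allele `a1` is the
#'   counted allele; `af` is the sample frequency).
#' @export
run_marginal_gwas <- function(geno, y) {
  stopifnot(inherits(geno, "geno_sim"))
  G <- geno$dosage
  n <- nrow(G)
  if (length(y) != n) stop_validation("phenotype length does not match cohort size")
  yc <- y - mean(y)
  mu <- colMeans(G)
  sd_ <- sqrt(colMeans(G^2) - mu^2) * sqrt(n / (n - 1))
  if (any(sd_ == 0)) stop_validation("monomorphic SNP in cohort; increase n or MAF")
  sxy <- as.numeric(crossprod(G, yc)) # = sum (g - mean g) yc
  sxx <- (n - 1) * sd_^2
  b_raw <- sxy / sxx
  syy <- sum(yc^2)
  ssr <- pmax(syy - b_raw^2 * sxx, 0)
  se_raw <- sqrt(ssr / ((n - 2) * sxx))
  # standardized-genotype scale
  beta <- b_raw * sd_
  se <- se_raw * sd_
  tt <- beta / se
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  sumstats(snp = geno$snps$snp, chr = geno$snps$chr, bp = geno$snps$bp,
           a1 = geno$snps$a1, a2 = geno$snps$a2,
           af = pmin(pmax(mu / 2, 1e-6), 1 - 1e-6),
           beta = beta, se = se, p = p, n = n)
}

#' Analytic sampler of a paired GWAS's summary statistics
#'
#' Fast path standing in for individual-level simulation: per LD block the
#' estimated standardized effects are drawn jointly normal with mean
#' `R %*% beta_true` (the marginal-effect identity) and covariance `R/n`,
#' with cross-study covariance `rho * R / sqrt(n1 n2)` for shared subjects.
#' Distributionally consistent with [run_marginal_gwas()] at matched
#' parameters; the `n -> Inf` limit returns `R %*% beta_true` exactly.
#'
#' @param effects a `true_effects` object.
#' @param map the `snp_map` the effects refer to.
#' @param n1,n2 study sample sizes.
#' @param rho overlap correlation between the two studies' estimators.
#' @return List with `proximal` and `adjunct` [sumstats] tables.
#' @export
sample_sumstats_analytic <- function(effects, map, n1, n2, rho = 0) {
  stopifnot(inherits(effects, "true_effects"), inherits(map, "snp_map"))
  m <- nrow(map$snps)
  b1 <- numeric(m)
  b2 <- numeric(m)
  for (k in seq_len(nrow(map$blocks))) {
    idx <- which(map$snps$block == k)
    R <- map$ld[[k]]
    C <- chol(R)
    mu1 <- as.numeric(R %*% effects$beta1[idx])
    mu2 <- as.numeric(R %*% effects$beta2[idx])
    z1 <- stats::rnorm(length(idx))
    z2 <- stats::rnorm(length(idx))
    e1 <- as.numeric(crossprod(C, z1))
    e2 <- as.numeric(crossprod(C, rho * z1 + sqrt(1 - rho^2) * z2))
    b1[idx] <- mu1 + e1 / sqrt(n1)
    b2[idx] <- mu2 + e2 / sqrt(n2)
  }
  mk <- function(beta, se, n) {
    p <- 2 * stats::pnorm(-abs(beta / se))
    sumstats(snp = map$snps$snp, chr = map$snps$chr, bp = map$snps$bp,
             a1 = map$snps$a1, a2 = map$snps$a2, af = map$snps$maf,
             beta = beta, se = se, p = pmin(pmax(p, .Machine$double.xmin), 1),
             n = n)
  }
  list(proximal = mk(b1, rep(1 / sqrt(n1), m), n1),
       adjunct = mk(b2, rep(1 / sqrt(n2), m), n2))
}

#' Simulate a null case-control GWAS pair with a shared control pool
#'
#' Two case-control studies with disjoint cases and a fully shared control
#' pool, phenotype independent of genotype (every SNP null). Each study's
#' marginal association is fit by linear regression of the 0/1 status on the
#' dosage. Used to measure the empirical correlation of the two studies'
#' effect estimators and the calibration of the shared-control-adjusted Q
#' test.
#'
#' @param n1_cases,n2_cases case counts of the two studies.
#' @param n_shared_controls size of the shared control pool.
#' @param m_snps number of independent null SNPs (each SNP is one replicate
#'   of the design).
#' @param maf_range MAF range for the simulated SNPs.
#' @param chunk SNPs generated per chunk (memory control).
#' @return List with `study1`, `study2` ([sumstats] tables, standardized
#'   scale) and `overlap` (the matching [study_overlap()]).
#' @export
simulate_shared_control_pair <- function(n1_cases, n2_cases, n_shared_controls,
                                         m_snps = 2000,
                                         maf_range = c(0.05, 0.5),
                                         chunk = 250L) {
  nctl <- n_shared_controls
  y1 <- c(rep(1, n1_cases), rep(0, nctl))
  y2 <- c(rep(1, n2_cases), rep(0, nctl))
  y1c <- y1 - mean(y1)
  y2c <- y2 - mean(y2)
  fit <- function(G, yc) {
    n <- nrow(G)
    mu <- colMeans(G)
    sxx <- colSums(G^2) - n * mu^2
    sd_ <- sqrt(sxx / (n - 1))
    b <- as.numeric(crossprod(G, yc)) / sxx
    ssr <- pmax(sum(yc^2) - b^2 * sxx, 0)
    se <- sqrt(ssr / ((n - 2) * sxx))
    list(beta = b * sd_, se = se * sd_)
  }
  b1 <- se1 <- b2 <- se2 <- af <- numeric(m_snps)
  for (s in seq(1L, m_snps, by = chunk)) {
    k <- min(chunk, m_snps - s + 1L)
    id <- s:(s + k - 1L)
    maf <- stats::runif(k, maf_range[1], maf_range[2])
    af[id] <- maf
    Gs <- matrix(stats::rbinom(nctl * k, 2, rep(maf, each = nctl)), nctl, k)
    G1 <- rbind(matrix(stats::rbinom(n1_cases * k, 2, rep(maf, each = n1_cases)),
                       n1_cases, k), Gs)
    G2 <- rbind(matrix(stats::rbinom(n2_cases * k, 2, rep(maf, each = n2_cases)),
                       n2_cases, k), Gs)
    f1 <- fit(G1, y1c)
    f2 <- fit(G2, y2c)
    b1[id] <- f1$beta; se1[id] <- f1$se
    b2[id] <- f2$beta; se2[id] <- f2$se
  }
  snp <- sprintf("snp%06d", seq_len(m_snps))
  mk <- function(beta, se, n) {
    z <- beta / se
    sumstats(snp = snp, chr = "1", bp = seq_len(m_snps), a1 = "A", a2 = "G",
             af = af, beta = beta, se = se,
             p = pmin(pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin), 1),
             n = n)
  }
  list(
    study1 = mk(b1, se1, n1_cases + nctl),
    study2 = mk(b2, se2, n2_cases + nctl),
    overlap = study_overlap(n1_cases = n1_cases, n1_controls = nctl,
                            n2_cases = n2_cases, n2_controls = nctl,
                            n_shared_controls = nctl)
  )
}

#' Run a full simulated study
#'
#' Orchestrates one replicate: SNP map, true effects, proximal/adjunct
#' training GWAS (individual-level genotypes + phenotypes, or the fast
#' analytic sampler), and optionally a held-out test cohort with phenotypes
#' for both traits.
#'
#' @param scenario a [sim_scenario()]; its `seed` (if non-NULL) is applied
#'   once at entry, making the whole replicate deterministic.
#' @param gwas `"analytic"` (default) or `"individual"`.
#' @param n_test held-out test-cohort size (0 disables).
#' @return List: `scenario`, `map`, `effects`, `sumstats` (list with
#'   `proximal`/`adjunct`), `ld` (designed [ld_blockset]), and when
#'   requested `test` (a `geno_sim` plus `y1`, `y2`), plus `geno1`, `geno2`,
#'   `y1`, `y2` in individual mode.
#' @export
simulate_study <- function(scenario, gwas = c("analytic", "individual"),
                           n_test = 0) {
  gwas <- match.arg(gwas)
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  n1 <- round(scenario$n_total * scenario$split[1])
  n2 <- scenario$n_total - n1
  map <- sim_snp_map(scenario)
  effects <- draw_effects(scenario)
  out <- list(scenario = scenario, map = map, effects = effects,
              ld = target_ld(map))
  if (gwas == "analytic") {
    out$sumstats <- sample_sumstats_analytic(effects, map, n1, n2, rho = 0)
  } else {
    g1 <- simulate_genotypes(map, n1, sample_prefix = "p")
    g2 <- simulate_genotypes(map, n2, sample_prefix = "a")
    y1 <- simulate_phenotypes(g1, effects, scenario$h2, trait = 1)
    y2 <- simulate_phenotypes(g2, effects, scenario$h2, trait = 2)
    out$geno1 <- g1; out$geno2 <- g2; out$y1 <- y1; out$y2 <- y2
    out$sumstats <- list(proximal = run_marginal_gwas(g1, y1),
                         adjunct = run_marginal_gwas(g2, y2))
  }
  if (n_test > 0) {
    gt <- simulate_genotypes(map, n_test, sample_prefix = "t")
    out$test <- list(geno = gt,
                     y1 = simulate_phenotypes(gt, effects, scenario$h2, trait = 1),
                     y2 = simulate_phenotypes(gt, effects, scenario$h2, trait = 2))
  }
  out
}
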