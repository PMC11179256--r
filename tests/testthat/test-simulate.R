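test_that("scenario validation enforces the composition identity and feasibility", {
  expect_error(sim_scenario(shared_fraction = 0.5, shared_effect_cor = 1,
                            rg_target = 0.4),
               "infeasible composition", class = "prsblend_validation_error")
  expect_silent(sim_scenario(shared_fraction = 0.5, shared_effect_cor = 1,
                             rg_target = 0.5))
  expect_error(sim_scenario(m_snps = 100, n_causal = 200), "exceeds",
               class = "prsblend_validation_error")
  expect_error(sim_scenario(shared_fraction = 1, penetrant_snps = 5),
               "trait-specific", class = "prsblend_validation_error")
})

test_that("effect draws realize the requested rG composition", {
  # the same rG from two different compositions
  set.seed(28)
  for (cfg in list(c(P = 0.5, cor = 1.0), c(P = 1.0, cor = 0.5),
                   c(P = 1.0, cor = 0.25))) {
    rg <- replicate(6, {
      eff <- draw_effects(sim_scenario(m_snps = 5000, n_causal = 1000,
                                       shared_fraction = cfg[["P"]],
                                       shared_effect_cor = cfg[["cor"]]))
      causal <- eff$labels != "null"
      cor(eff$beta1[causal], eff$beta2[causal])
    })
    expect_equal(mean(rg), cfg[["P"]] * cfg[["cor"]], tolerance = 0.03)
  }
})

test_that("each trait's summed squared effects equal h2 exactly", {
  set.seed(29)
  for (P in c(0, 0.3, 1)) {
    eff <- draw_effects(sim_scenario(m_snps = 2000, n_causal = 300,
                                     shared_fraction = P, shared_effect_cor = 1,
                                     h2 = 0.37))
    expect_equal(sum(eff$beta1^2), 0.37, tolerance = 1e-12)
    expect_equal(sum(eff$beta2^2), 0.37, tolerance = 1e-12)
  }
})

test_that("penetrant SNPs carry exactly their share of the non-shared heritability", {
  for (seed in 1:5) {
    set.seed(seed)
    scen <- sim_scenario(m_snps = 4000, n_causal = 500, shared_fraction = 0.5,
                         shared_effect_cor = 1, penetrant_snps = 5)
    eff <- draw_effects(scen)
    for (tr in 1:2) {
      beta <- if (tr == 1) eff$beta1 else eff$beta2
      pen <- eff$labels == paste0("penetrant", tr)
      spec <- eff$labels %in% c(paste0("trait", tr, "_specific"),
                                paste0("penetrant", tr))
      expect_equal(sum(beta[pen]^2) / sum(beta[spec]^2), 0.05,
                   tolerance = 1e-10)
    }
  }
})

test_that("genotypes hit their MAF targets and the designed LD profile", {
  set.seed(30)
  scen <- toy_scenario(m_snps = 60, ld_block_size = 6, ld_rho = 0.65)
  map <- sim_snp_map(scen)
  g <- simulate_genotypes(map, 4000)
  expect_true(all(g$dosage %in% 0:2))
  expect_lt(max(abs(colMeans(g$dosage) / 2 - map$snps$maf)), 0.02)
  emp <- realized_ld(g)
  dev <- vapply(seq_along(emp), function(k) max(abs(emp[[k]] - map$ld[[k]])), 0)
  expect_lt(max(dev), 0.05)
  # independence across blocks
  cross <- cor(g$dosage[, 1:6], g$dosage[, 7:12])
  expect_lt(max(abs(cross)), 0.1)
  expect_lt(mean(abs(cross)), 0.03)
})

test_that("the desk-scale guard rejects oversized cohorts", {
  scen <- toy_scenario(m_snps = 100)
  map <- sim_snp_map(scen)
  expect_error(simulate_genotypes(map, 2e6), "desk-scale",
               class = "prsblend_validation_error")
})

test_that("phenotypes realize the target heritability and its edge cases", {
  set.seed(31)
  scen <- toy_scenario(m_snps = 500, n_causal = 50, ld_block_size = 5)
  map <- sim_snp_map(scen)
  eff <- draw_effects(scen)
  g <- simulate_genotypes(map, 3000)
  y <- simulate_phenotypes(g, eff, h2 = 0.5)
  expect_equal(attr(y, "realized_h2"), 0.5, tolerance = 0.05)
  # h2 = 0: pure noise
  y0 <- simulate_phenotypes(g, eff, h2 = 0)
  expect_equal(attr(y0, "realized_h2"), 0)
  expect_equal(sd(y0), 1, tolerance = 0.1)
  # scale invariance: doubling all effects leaves realized h2 unchanged
  # because the noise is rescaled from the realized genetic variance
  eff2 <- eff
  eff2$beta1 <- 2 * eff$beta1
  y2 <- simulate_phenotypes(g, eff2, h2 = 0.5)
  expect_equal(attr(y2, "realized_h2"), 0.5, tolerance = 0.05)
})

test_that("marginal GWAS agrees with lm() per SNP on the standardized scale", {
  set.seed(32)
  scen <- toy_scenario(m_snps = 10, n_causal = 2, ld_block_size = 5)
  map <- sim_snp_map(scen)
  g <- simulate_genotypes(map, 150)
  y <- rnorm(150) + 0.2 * scale(g$dosage[, 3])
  ss <- expect_no_log(run_marginal_gwas(g, as.numeric(y)))
  for (j in c(1, 3, 7)) {
    fit <- summary(lm(as.numeric(y) ~ scale(g$dosage[, j])))$coefficients
    expect_equal(ss$beta[j], fit[2, 1], tolerance = 1e-10)
    expect_equal(ss$se[j], fit[2, 2], tolerance = 1e-10)
    expect_equal(ss$p[j], fit[2, 4], tolerance = 1e-10)
  }
})

test_that("null GWAS z-scores are standard normal", {
  set.seed(33)
  scen <- toy_scenario(m_snps = 10000, n_causal = 10, ld_block_size = 10,
                       ld_rho = 0) # independent SNPs: z-scores are iid
  map <- sim_snp_map(scen)
  g <- simulate_genotypes(map, 500)
  ss <- expect_no_log(run_marginal_gwas(g, rnorm(500)))
  z <- ss$beta / ss$se
  expect_gt(stats::ks.test(z, "pnorm")$p.value, 0.01)
})

test_that("marginal effects converge to R beta within a block", {
  set.seed(34)
  scen <- toy_scenario(m_snps = 6, n_causal = 1, ld_block_size = 6,
                       ld_rho = 0.7)
  map <- sim_snp_map(scen)
  beta <- c(0.3, 0, 0, -0.1, 0, 0)
  mu <- as.numeric(map$ld[[1]] %*% beta)
  g <- simulate_genotypes(map, 4000)
  reps <- t(replicate(40, {
    y <- as.numeric(scale(g$dosage) %*% beta) + rnorm(4000, sd = 0.5)
    expect_no_log(run_marginal_gwas(g, y))$beta
  }))
  expect_lt(max(abs(colMeans(reps) - mu)), 0.02)
})

test_that("the analytic sampler matches the individual-level route in distribution", {
  set.seed(35)
  scen <- toy_scenario(m_snps = 20, n_causal = 4, ld_block_size = 5, h2 = 0.5)
  map <- sim_snp_map(scen)
  eff <- draw_effects(scen)
  n <- 800
  mu <- unlist(lapply(1:4, function(k) {
    idx <- which(map$snps$block == k)
    as.numeric(map$ld[[k]] %*% eff$beta1[idx])
  }))
  reps_an <- t(replicate(300, sample_sumstats_analytic(eff, map, n, n)$proximal$beta))
  g <- simulate_genotypes(map, n)
  # genotypes held fixed across replicates: their oracle is the full realized
  # correlation (in-sample cross-block correlations are not exactly zero)
  mu_ind <- as.numeric(cor(g$dosage) %*% eff$beta1)
  reps_ind <- t(replicate(300, {
    y <- simulate_phenotypes(g, eff, h2 = scen$h2)
    expect_no_log(run_marginal_gwas(g, as.numeric(y)))$beta
  }))
  expect_lt(max(abs(colMeans(reps_an) - mu)), 0.02)
  expect_lt(max(abs(colMeans(reps_ind) - mu_ind)), 0.01)
  # sampling scale agrees between the two routes
  expect_equal(mean(apply(reps_an, 2, sd)), mean(apply(reps_ind, 2, sd)),
               tolerance = 0.2)
})

test_that("the analytic sampler respects its overlap and infinite-n limits", {
  set.seed(36)
  scen <- toy_scenario(m_snps = 50, n_causal = 10, ld_block_size = 5)
  map <- sim_snp_map(scen)
  eff <- draw_effects(scen)
  # n -> Inf returns R beta exactly
  ss <- sample_sumstats_analytic(eff, map, 1e14, 1e14)
  mu <- unlist(lapply(seq_len(nrow(map$blocks)), function(k) {
    idx <- which(map$snps$block == k)
    as.numeric(map$ld[[k]] %*% eff$beta1[idx])
  }))
  expect_equal(ss$proximal$beta, mu, tolerance = 1e-6)
  # rho controls the cross-study error correlation
  null_eff <- eff
  null_eff$beta1[] <- 0
  null_eff$beta2[] <- 0
  draw_cor <- function(rho) {
    b <- replicate(400, {
      s <- sample_sumstats_analytic(null_eff, map, 1000, 1000, rho = rho)
      c(s$proximal$beta[1], s$adjunct$beta[1])
    })
    cor(b[1, ], b[2, ])
  }
  expect_lt(abs(draw_cor(0)), 0.15)
  expect_equal(draw_cor(0.6), 0.6, tolerance = 0.15)
})

test_that("simulate_study is deterministic under a scenario seed", {
  scen <- toy_scenario(m_snps = 100, n_causal = 10, n_total = 400, seed = 77)
  a <- simulate_study(scen)
  b <- simulate_study(scen)
  expect_identical(a$sumstats$proximal$beta, b$sumstats$proximal$beta)
  expect_identical(a$effects$beta2, b$effects$beta2)
})
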