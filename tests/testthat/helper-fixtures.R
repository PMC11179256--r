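# Shared fixture builders. Everything is generated in code; tests set their
# own seeds.

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_sumstats <- function(m = 5, seed = NULL, snp = sprintf("rs%d", seq_len(m)),
                         beta = NULL, se = NULL, af = NULL, n = 10000,
                         a1 = rep("A", m), a2 = rep("G", m)) {
  if (!is.null(seed)) set.seed(seed)
  sumstats(
    snp = snp, chr = rep("1", m), bp = seq_len(m) * 1000L,
    a1 = a1, a2 = a2,
    af = af %||% runif(m, 0.1, 0.9),
    beta = beta %||% rnorm(m, 0, 0.05),
    se = se %||% rep(0.02, m),
    p = runif(m, 0.01, 1), n = n
  )
}

# a small scenario that runs in well under a second
toy_scenario <- function(...) {
  args <- modifyList(
    list(m_snps = 400, n_causal = 40, h2 = 0.5, shared_fraction = 0.5,
         shared_effect_cor = 1, n_total = 1200, ld_block_size = 5,
         ld_rho = 0.6, seed = NULL),
    list(...)
  )
  do.call(sim_scenario, args)
}

expect_no_log <- function(expr) suppressMessages(expr)
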