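test_that("well-formed tables pass validation untouched and violations are dropped with counts", {
  x <- toy_sumstats(5, seed = 1)
  expect_s3_class(x, "sumstats")
  expect_equal(nrow(x), 5)
  expect_equal(sum(attr(x, "validation_report")), 0)

  y <- sumstats(
    snp = c("a", "b", "c", "d", "e", "e", "g"),
    chr = "1", bp = 1:7,
    a1 = c("A", "A", "AT", "A", "A", "A", "A"),
    a2 = c("G", "G", "G", "A", "G", "G", "G"),
    af = c(0.3, 1.2, 0.3, 0.3, 0.3, 0.3, 0.3),
    beta = 0.1, se = c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0), p = 0.5, n = 100
  )
  rep_ <- attr(y, "validation_report")
  expect_equal(nrow(y), 2) # a and e survive
  expect_equal(rep_[["bad_se"]], 1)
  expect_equal(rep_[["bad_af"]], 1)
  expect_equal(rep_[["non_snv_allele"]], 1)  # indels rejected at read time
  expect_equal(rep_[["identical_alleles"]], 1)
  expect_equal(rep_[["duplicate_snp"]], 1)
})

test_that("validation refuses empty results and p-values outside (0, 1]", {
  expect_error(
    sumstats(snp = "a", chr = "1", bp = 1, a1 = "A", a2 = "G",
             af = 0.5, beta = 0, se = 0, p = 0.5, n = 10),
    "no rows left", class = "prsblend_validation_error"
  )
  y <- sumstats(snp = c("a", "b", "c"), chr = "1", bp = 1:3, a1 = "A", a2 = "G",
                af = 0.5, beta = 0, se = 0.1, p = c(0, 0.5, 1), n = 10)
  expect_equal(y$snp, c("b", "c"))
  expect_equal(attr(y, "validation_report")[["bad_p"]], 1)
})

test_that("write/read round trip is lossless, for canonical and dialect headers", {
  x <- toy_sumstats(20, seed = 2, se = runif(20, 0.01, 0.05))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(x, path)
  y <- expect_no_log(read_sumstats(path))
  expect_identical(as.data.frame(x), as.data.frame(y))

  # same content under foreign column names, mapped via a dialect
  raw <- utils::read.table(path, header = TRUE, sep = "\t")
  names(raw) <- c("rsid", "chrom", "pos", "EA", "OA", "freq", "b", "stderr",
                  "pv", "samples")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(raw, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  z <- expect_no_log(read_sumstats(path2, dialect = c(
    snp = "rsid", chr = "chrom", bp = "pos", a1 = "EA", a2 = "OA",
    af = "freq", beta = "b", se = "stderr", p = "pv", n = "samples"
  )))
  expect_equal(as.data.frame(z), as.data.frame(x), tolerance = 1e-12)
})

test_that("a missing required column is a hard error naming the role", {
  x <- toy_sumstats(5, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(x, path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t")
  raw$SE <- NULL
  utils::write.table(raw, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(expect_no_log(read_sumstats(path)), "role 'se'",
               class = "prsblend_validation_error")
})

test_that("a scalar N is broadcast when the file has no N column", {
  x <- toy_sumstats(4, seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  raw <- as.data.frame(x)[setdiff(names(x), "n")]
  names(raw) <- c("SNP", "CHR", "BP", "A1", "A2", "AF", "B", "SE", "P")
  utils::write.table(raw, path, sep = "\t", quote = FALSE, row.names = FALSE)
  y <- expect_no_log(read_sumstats(path, n = 5000))
  expect_equal(y$n, rep(5000, 4))
})

test_that("harmonize aligns swapped alleles by flipping beta and af", {
  prox <- sumstats(snp = c("r1", "r2"), chr = "1", bp = 1:2,
                   a1 = c("A", "C"), a2 = c("G", "T"),
                   af = c(0.3, 0.4), beta = c(0.1, 0.2), se = 0.05,
                   p = 0.5, n = 100)
  adj <- sumstats(snp = c("r1", "r2"), chr = "1", bp = 1:2,
                  a1 = c("G", "C"), a2 = c("A", "T"),
                  af = c(0.7, 0.4), beta = c(-0.1, 0.2), se = 0.05,
                  p = 0.5, n = 100)
  pair <- expect_no_log(harmonize_pair(prox, adj))
  expect_equal(pair$shared$beta2, c(0.1, 0.2))
  expect_equal(pair$shared$af2, c(0.3, 0.4))
  expect_equal(pair$shared$flipped, c(TRUE, FALSE))
  expect_equal(pair$report[["n_flipped"]], 1)
})

test_that("strand-ambiguous pairs are dropped when requested, reported either way", {
  prox <- sumstats(snp = c("r1", "r2", "r3"), chr = "1", bp = 1:3,
                   a1 = c("A", "C", "A"), a2 = c("T", "G", "G"),
                   af = 0.3, beta = 0.1, se = 0.05, p = 0.5, n = 100)
  adj <- prox
  pair <- expect_no_log(harmonize_pair(prox, adj, drop_ambiguous = TRUE))
  expect_equal(pair$shared$snp, "r3")
  expect_equal(pair$report[["dropped_ambiguous"]], 2)
  pair2 <- expect_no_log(harmonize_pair(prox, adj, drop_ambiguous = FALSE))
  expect_equal(nrow(pair2$shared), 3)
})

test_that("SNPs absent from the adjunct study become proximal_only", {
  prox <- toy_sumstats(10, seed = 5)
  adj <- prox[1:7, ]
  class(adj) <- c("sumstats", "data.frame")
  pair <- expect_no_log(harmonize_pair(prox, adj))
  expect_equal(nrow(pair$shared), 7)
  expect_equal(nrow(pair$proximal_only), 3)
  expect_setequal(pair$proximal_only$snp, c("rs8", "rs9", "rs10"))
})

test_that("irreconcilable allele pairs are dropped and counted, never silent", {
  prox <- sumstats(snp = c("r1", "r2"), chr = "1", bp = 1:2,
                   a1 = c("A", "A"), a2 = c("G", "G"),
                   af = 0.3, beta = 0.1, se = 0.05, p = 0.5, n = 100)
  adj <- sumstats(snp = c("r1", "r2"), chr = "1", bp = 1:2,
                  a1 = c("A", "A"), a2 = c("G", "C"),
                  af = 0.3, beta = 0.1, se = 0.05, p = 0.5, n = 100)
  pair <- expect_no_log(harmonize_pair(prox, adj))
  expect_equal(pair$shared$snp, "r1")
  expect_equal(pair$report[["dropped_allele_mismatch"]], 1)
})

test_that("harmonization is idempotent and invariant to adjunct allele relabeling", {
  set.seed(6)
  prox <- toy_sumstats(30, a1 = sample(c("A", "C"), 30, TRUE),
                       a2 = sample(c("G", "T"), 30, TRUE))
  adj <- toy_sumstats(30, a1 = prox$a1, a2 = prox$a2)
  flip <- rep(c(TRUE, FALSE), 15)
  adj2 <- adj
  adj2$a1[flip] <- adj$a2[flip]
  adj2$a2[flip] <- adj$a1[flip]
  adj2$beta[flip] <- -adj$beta[flip]
  adj2$af[flip] <- 1 - adj$af[flip]
  p1 <- expect_no_log(harmonize_pair(prox, adj))
  p2 <- expect_no_log(harmonize_pair(prox, adj2))
  expect_equal(p1$shared[setdiff(names(p1$shared), "flipped")],
               p2$shared[setdiff(names(p2$shared), "flipped")])

  # re-harmonizing the already-aligned adjunct columns changes nothing
  adj_aligned <- sumstats(snp = p1$shared$snp, chr = p1$shared$chr,
                          bp = p1$shared$bp, a1 = p1$shared$a1,
                          a2 = p1$shared$a2, af = p1$shared$af2,
                          beta = p1$shared$beta2, se = p1$shared$se2,
                          p = p1$shared$p2, n = p1$shared$n2)
  prox_aligned <- prox[match(p1$shared$snp, prox$snp), ]
  class(prox_aligned) <- c("sumstats", "data.frame")
  p3 <- expect_no_log(harmonize_pair(prox_aligned, adj_aligned))
  expect_equal(p3$shared$beta2, p1$shared$beta2)
  expect_equal(p3$report[["n_flipped"]], 0)
})

test_that("position fallback matches SNPs whose identifiers differ", {
  prox <- toy_sumstats(5, seed = 7)
  adj <- prox
  adj$snp <- paste0("other_", adj$snp)
  class(adj) <- c("sumstats", "data.frame")
  expect_equal(nrow(expect_no_log(harmonize_pair(prox, adj))$shared), 0)
  pair <- expect_no_log(harmonize_pair(prox, adj, match_by = "position"))
  expect_equal(nrow(pair$shared), 5)
})

test_that("qc_filter applies the four sd-consistency rules", {
  # sigma_ss = 2/sqrt(1e4 * 0.02^2) = 1.0 > sigma_g + 0.1 = 0.748 -> removed
  x <- sumstats(snp = c("bad_ss", "bad_g", "ok"), chr = "1", bp = 1:3,
                a1 = "A", a2 = "G",
                af = c(0.3, 0.0008, 0.3),
                beta = 0.1,
                se = c(0.02, 1 / 6, 0.04),
                p = 0.5, n = 10000)
  expect_equal(2 / sqrt(10000 * 0.02^2), 1.0)
  expect_lt(sqrt(2 * 0.0008 * 0.9992), 0.05) # sd_g rule fires for the second SNP
  expect_equal(2 / sqrt(10000 * (1 / 6)^2), 0.12) # ... and no sd_ss rule does
  # third SNP: sd_ss = 0.5, inside all bands for sd_g ~ 0.648
  out <- expect_no_log(qc_filter(x))
  expect_equal(out$table$snp, "ok")
  expect_equal(out$report[["sd_ss_above_sd_g_plus_0.1"]], 1)
  expect_equal(out$report[["sd_g_below_0.05"]], 1)
  expect_equal(out$report[["removed_total"]], 2)
  expect_equal(nrow(out$dropped), 2)
})

test_that("qc_filter leaves a clean table untouched and errors without af or n", {
  set.seed(8)
  m <- 50
  af <- runif(m, 0.2, 0.8)
  n <- 50000
  se <- 2 / (sqrt(n) * sqrt(2 * af * (1 - af))) # sigma_ss == sigma_g exactly
  x <- toy_sumstats(m, af = af, se = se, n = n)
  out <- expect_no_log(qc_filter(x))
  expect_identical(as.data.frame(out$table), as.data.frame(x))
  expect_equal(out$report[["removed_total"]], 0)

  x_na <- x
  x_na$af[1] <- NA
  expect_error(qc_filter(x_na), "allele frequency",
               class = "prsblend_validation_error")
})

test_that("panel retention keeps panel members OR low-lfdr SNPs", {
  x <- toy_sumstats(6, seed = 9)
  panel <- x$snp[1:3]
  lfdr <- c(1, 1, 1, 0.5, 1, 0.0)
  out <- panel_retention_filter(x, panel, lfdr, lfdr_threshold = 1)
  expect_equal(nrow(out), 5) # brute-force: per-row predicate leaves out rs5 only
  expect_false("rs5" %in% out$snp)
  expect_true(all(out$snp %in% x$snp[c(1:4, 6)]))
  # first clause alone
  expect_true("rs1" %in% panel_retention_filter(x, panel, rep(1, 6))$snp)
  # second clause alone
  expect_true("rs6" %in% panel_retention_filter(x, character(), lfdr)$snp)
  expect_error(panel_retention_filter(x, panel, lfdr[1:3]),
               "length", class = "prsblend_validation_error")
})
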