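# Reading, validating, harmonizing, QC-filtering and writing GWAS
# summary-statistic tables.
#
# Canonical on-disk format: tab-separated with header
#   SNP CHR BP A1 A2 AF B SE P N
# where A1 is the effect allele, AF its frequency, B the effect size
# (log-odds for binary traits, per-allele on the trait scale otherwise),
# and BP a 1-based position. Internally columns are lower-case:
# snp, chr, bp, a1, a2, af, beta, se, p, n.

.SUMSTATS_COLS <- c("snp", "chr", "bp", "a1", "a2", "af", "beta", "se", "p", "n")
.CANONICAL_HEADER <- c("SNP", "CHR", "BP", "A1", "A2", "AF", "B", "SE", "P", "N")
.NUCLEOTIDES <- c("A", "C", "G", "T")

#' Construct a summary-statistics table
#'
#' Builds a validated `sumstats` object (a `data.frame`) from per-SNP vectors.
#' Rows violating the invariants (non-positive SE, allele frequency outside
#' (0,1), p-value outside (0,1], non-SNV or identical alleles, duplicated SNP
#' identifier, missing required fields) are dropped and counted in the
#' validation report attached as attribute `"validation_report"`.
#'
#' @param snp character SNP identifiers.
#' @param chr chromosome labels (coerced to character).
#' @param bp 1-based base-pair positions.
#' @param a1,a2 effect and other allele (single nucleotides A/C/G/T).
#' @param af effect-allele frequency in (0,1).
#' @param beta effect size estimate.
#' @param se standard error, strictly positive.
#' @param p association p-value in (0,1].
#' @param n per-SNP sample size; a scalar is broadcast to all SNPs.
#' @return A `sumstats` data.frame with attribute `"validation_report"`, a
#'   named integer vector of per-rule drop counts.
#' @export
sumstats <- function(snp, chr, bp, a1, a2, af, beta, se, p, n = NA_real_) {
  m <- length(snp)
  if (length(n) == 1L) n <- rep(as.numeric(n), m)
  x <- data.frame(
    snp = as.character(snp), chr = as.character(chr), bp = as.numeric(bp),
    a1 = toupper(as.character(a1)), a2 = toupper(as.character(a2)),
    af = as.numeric(af), beta = as.numeric(beta), se = as.numeric(se),
    p = as.numeric(p), n = as.numeric(n),
    stringsAsFactors = FALSE
  )
  validate_sumstats(x)
}

#' @rdname sumstats
#' @param x data.frame with the canonical internal columns.
#' @export
validate_sumstats <- function(x) {
  for (col in .SUMSTATS_COLS) {
    if (is.null(x[[col]])) stop_validation("missing required column for role '%s'", col)
  }
  x <- x[.SUMSTATS_COLS]
  for (col in c("snp", "chr", "a1", "a2")) x[[col]] <- as.character(x[[col]])
  for (col in c("bp", "af", "beta", "se", "p", "n")) x[[col]] <- as.numeric(x[[col]])
  drop <- c(
    missing_required = 0L, non_snv_allele = 0L, identical_alleles = 0L,
    bad_af = 0L, bad_se = 0L, bad_p = 0L, bad_bp = 0L, duplicate_snp = 0L
  )
  bad <- is.na(x$snp) | is.na(x$beta) | is.na(x$se) | is.na(x$p) |
    is.na(x$a1) | is.na(x$a2)
  drop["missing_required"] <- sum(bad)
  r <- !bad & (!(x$a1 %in% .NUCLEOTIDES) | !(x$a2 %in% .NUCLEOTIDES))
  drop["non_snv_allele"] <- sum(r); bad <- bad | r
  r <- !bad & x$a1 == x$a2
  drop["identical_alleles"] <- sum(r); bad <- bad | r
  r <- !bad & !is.na(x$af) & (x$af <= 0 | x$af >= 1)
  drop["bad_af"] <- sum(r); bad <- bad | r
  r <- !bad & x$se <= 0
  drop["bad_se"] <- sum(r); bad <- bad | r
  r <- !bad & (x$p <= 0 | x$p > 1)
  drop["bad_p"] <- sum(r); bad <- bad | r
  r <- !bad & !is.na(x$bp) & x$bp < 1
  drop["bad_bp"] <- sum(r); bad <- bad | r
  x <- x[!bad, , drop = FALSE]
  dup <- duplicated(x$snp)
  drop["duplicate_snp"] <- sum(dup)
  x <- x[!dup, , drop = FALSE]
  if (nrow(x) == 0L) stop_validation("no rows left after validation")
  rownames(x) <- NULL
  class(x) <- c("sumstats", "data.frame")
  attr(x, "validation_report") <- drop
  x
}

#' Read a GWAS summary-statistics file
#'
#' Reads a tab- or whitespace-separated file with a header and returns a
#' validated [sumstats] table. Non-canonical column names are mapped through
#' `dialect`, a named character vector from canonical role to file column,
#' e.g. `c(beta = "b", se = "StdErr", a1 = "EA")`. Roles:
#' `snp, chr, bp, a1, a2, af, beta, se, p, n`.
#'
#' @param path file path.
#' @param dialect named character vector mapping roles to file column names;
#'   `NULL` accepts the canonical header `SNP CHR BP A1 A2 AF B SE P N`
#'   (case-insensitively) or already-lower-case role names.
#' @param n total sample size broadcast to all SNPs when the file carries no
#'   `N` column.
#' @return A `sumstats` table; dropped-row counts are in
#'   `attr(x, "validation_report")`.
#' @export
read_sumstats <- function(path, dialect = NULL, n = NULL) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  nm <- names(dt)
  # map canonical header / lower-case roles first
  canon <- stats::setNames(.SUMSTATS_COLS, toupper(.CANONICAL_HEADER))
  hit <- canon[toupper(nm)]
  names(dt)[!is.na(hit)] <- hit[!is.na(hit)]
  lower_hit <- tolower(nm) %in% .SUMSTATS_COLS & is.na(hit)
  names(dt)[lower_hit] <- tolower(nm)[lower_hit]
  if (!is.null(dialect)) {
    bad_roles <- setdiff(names(dialect), .SUMSTATS_COLS)
    if (length(bad_roles)) {
      stop_validation("unknown dialect role(s): %s", paste(bad_roles, collapse = ", "))
    }
    for (role in names(dialect)) {
      col <- dialect[[role]]
      if (!col %in% nm) {
        stop_validation("dialect maps role '%s' to column '%s' absent from %s",
                        role, col, path)
      }
      names(dt)[nm == col] <- role
    }
  }
  if (is.null(dt[["n"]]) && !is.null(n)) dt$n <- as.numeric(n)
  if (is.null(dt[["n"]])) dt$n <- NA_real_
  for (col in setdiff(.SUMSTATS_COLS, names(dt))) {
    stop_validation("missing required column for role '%s' in %s", col, path)
  }
  x <- validate_sumstats(dt)
  log_kv("read_sumstats", path = path, rows = nrow(x),
         dropped = sum(attr(x, "validation_report")))
  x
}

#' Write summary statistics in the canonical format
#'
#' Writes the canonical tab-separated header `SNP CHR BP A1 A2 AF B SE P N`.
#' The round trip through [read_sumstats()] is lossless. With `audit = TRUE`
#' any extra columns (e.g. `lfdr`, `q`, `q_p`, `source` from
#' [blend_sumstats()]) are appended after the canonical ones.
#'
#' @param x a `sumstats` or `blended_stats` table.
#' @param path output file path.
#' @param audit append non-canonical audit columns.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path, audit = FALSE) {
  for (col in .SUMSTATS_COLS) {
    if (is.null(x[[col]])) stop_validation("missing required column for role '%s'", col)
  }
  out <- x[.SUMSTATS_COLS]
  names(out) <- .CANONICAL_HEADER
  if (audit) {
    extra <- setdiff(names(x), .SUMSTATS_COLS)
    for (col in extra) out[[col]] <- x[[col]]
  }
  # shortest-exact decimal so the read_sumstats round trip is lossless
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- NA
      out[[col]] <- v
    }
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> %d SNPs, %d chromosome(s)\n",
              nrow(x), length(unique(x$chr))))
  rep_ <- attr(x, "validation_report")
  if (!is.null(rep_) && sum(rep_) > 0) {
    cat("  dropped at validation:",
        paste(sprintf("%s=%d", names(rep_)[rep_ > 0], rep_[rep_ > 0]),
              collapse = ", "), "\n")
  }
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

.is_ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Pair and allele-align a proximal and an adjunct study
#'
#' Matches SNPs between the two studies and harmonizes the adjunct effects to
#' the proximal allele coding: where the adjunct allele pair is the reverse of
#' the proximal pair, its `beta` is sign-flipped and `af` complemented.
#' Strand-ambiguous pairs (A/T, C/G) are dropped when `drop_ambiguous` is set,
#' irreconcilable allele pairs are always dropped; all exclusions are counted
#' in the report, never silent. Proximal SNPs absent from the adjunct study go
#' to `proximal_only` and are later carried through unchanged by
#' [passthrough_proximal_only()].
#'
#' @param proximal,adjunct validated [sumstats] tables.
#' @param drop_ambiguous drop strand-ambiguous (A/T, C/G) SNPs (default TRUE,
#'   the safe choice when the two studies may differ in strand convention).
#' @param match_by `"id"` matches on SNP identifier; `"position"` falls back
#'   to chromosome:position:sorted-alleles for rows unmatched by identifier
#'   (cross-ancestry sources often mix identifier schemes).
#' @return An `aligned_pair` list with elements `shared` (data.frame carrying
#'   proximal columns plus adjunct `beta2, se2, af2, p2, n2` and a per-row
#'   `flipped` flag), `proximal_only` (a `sumstats` table) and `report`
#'   (named counts of matches, flips and drops).
#' @export
harmonize_pair <- function(proximal, adjunct, drop_ambiguous = TRUE,
                           match_by = c("id", "position")) {
  match_by <- match.arg(match_by)
  stopifnot(inherits(proximal, "sumstats"), inherits(adjunct, "sumstats"))
  report <- c(
    n_proximal = nrow(proximal), n_adjunct = nrow(adjunct),
    n_shared = 0L, n_proximal_only = 0L, n_adjunct_only = 0L,
    n_flipped = 0L, dropped_ambiguous = 0L, dropped_allele_mismatch = 0L
  )
  idx <- match(proximal$snp, adjunct$snp)
  if (match_by == "position") {
    poskey <- function(x) {
      al <- ifelse(x$a1 < x$a2, paste(x$a1, x$a2, sep = ":"),
                   paste(x$a2, x$a1, sep = ":"))
      paste(x$chr, x$bp, al, sep = ":")
    }
    miss <- is.na(idx)
    idx[miss] <- match(poskey(proximal)[miss], poskey(adjunct))
  }

  p <- proximal
  if (drop_ambiguous) {
    amb <- .is_ambiguous_pair(p$a1, p$a2)
    report["dropped_ambiguous"] <- sum(amb)
    p <- p[!amb, , drop = FALSE]
    idx <- idx[!amb]
  }
  matched <- !is.na(idx)
  adj <- adjunct[ifelse(matched, idx, 1L), , drop = FALSE] # placeholder rows unused

  same <- matched & adj$a1 == p$a1 & adj$a2 == p$a2
  swap <- matched & adj$a1 == p$a2 & adj$a2 == p$a1
  mism <- matched & !same & !swap
  report["dropped_allele_mismatch"] <- sum(mism)
  report["n_flipped"] <- sum(swap)

  beta2 <- ifelse(swap, -adj$beta, adj$beta)
  af2 <- ifelse(swap, 1 - adj$af, adj$af)

  keep <- same | swap
  shared <- p[keep, , drop = FALSE]
  shared$beta2 <- beta2[keep]
  shared$se2 <- adj$se[keep]
  shared$af2 <- af2[keep]
  shared$p2 <- adj$p[keep]
  shared$n2 <- adj$n[keep]
  shared$flipped <- swap[keep]
  rownames(shared) <- NULL
  class(shared) <- "data.frame"

  proximal_only <- p[!matched, , drop = FALSE]
  rownames(proximal_only) <- NULL
  class(proximal_only) <- c("sumstats", "data.frame")

  report["n_shared"] <- nrow(shared)
  report["n_proximal_only"] <- nrow(proximal_only)
  report["n_adjunct_only"] <- nrow(adjunct) - sum(matched)
  out <- structure(
    list(shared = shared, proximal_only = proximal_only, report = report),
    class = "aligned_pair"
  )
  log_kv("harmonize_pair", shared = report[["n_shared"]],
         proximal_only = report[["n_proximal_only"]],
         flipped = report[["n_flipped"]])
  out
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat("<aligned_pair>\n")
  print(x$report)
  invisible(x)
}

#' Summary-statistic quality-control filter
#'
#' Removes SNPs whose standard-error-implied scale is inconsistent with their
#' allele frequency, using the per-SNP quantities
#' \deqn{\sigma_{SS} = 2 / \sqrt{N \sigma_\beta^2}, \qquad
#'       \sigma_G = \sqrt{2\,AF(1-AF)}}
#' and the removal rules (any one triggers removal):
#' `sigma_ss < 0.5*sigma_g`, `sigma_ss > sigma_g + 0.1`, `sigma_ss < 0.1`,
#' `sigma_g < 0.05`. These are the recommended summary-statistic QC settings
#' of LDpred2.
#'
#' @param x a [sumstats] table with `af` and `n` present.
#' @return A list with `table` (surviving rows, order and values untouched),
#'   `report` (named per-rule removal counts plus `removed_total`), and
#'   `dropped` (the removed rows).
#' @export
qc_filter <- function(x) {
  stopifnot(inherits(x, "sumstats"))
  if (anyNA(x$af)) stop_validation("qc_filter requires allele frequency (af) for all rows")
  if (anyNA(x$n)) stop_validation("qc_filter requires sample size (n) for all rows")
  sigma_ss <- 2 / sqrt(x$n * x$se^2)
  sigma_g <- sqrt(2 * x$af * (1 - x$af))
  r1 <- sigma_ss < 0.5 * sigma_g
  r2 <- sigma_ss > sigma_g + 0.1
  r3 <- sigma_ss < 0.1
  r4 <- sigma_g < 0.05
  bad <- r1 | r2 | r3 | r4
  report <- c(
    sd_ss_below_half_sd_g = sum(r1), sd_ss_above_sd_g_plus_0.1 = sum(r2),
    sd_ss_below_0.1 = sum(r3), sd_g_below_0.05 = sum(r4),
    removed_total = sum(bad)
  )
  tab <- x[!bad, , drop = FALSE]
  rownames(tab) <- NULL
  if (nrow(tab)) class(tab) <- c("sumstats", "data.frame")
  log_kv("qc_filter", kept = nrow(tab), removed = sum(bad))
  list(table = tab, report = report, dropped = as.data.frame(x)[bad, , drop = FALSE])
}

#' Panel-or-low-lFDR SNP retention
#'
#' Keeps a SNP iff it belongs to the reference panel (e.g. HapMap3) OR its
#' trait-heterogeneity lFDR is below `lfdr_threshold`. The second clause
#' retains SNPs that differentiate the two traits even when they are absent
#' from the standard PRS panel.
#'
#' @param x a [sumstats] or blended table with a `snp` column.
#' @param panel_ids character vector of panel SNP identifiers.
#' @param lfdr per-SNP lFDR aligned with the rows of `x`.
#' @param lfdr_threshold retention threshold (default 1: any SNP with
#'   heterogeneity evidence short of "certainly null" is kept).
#' @return The filtered table (row order and values untouched).
#' @export
panel_retention_filter <- function(x, panel_ids, lfdr, lfdr_threshold = 1) {
  if (length(lfdr) != nrow(x)) {
    stop_validation("lfdr has length %d but table has %d rows", length(lfdr), nrow(x))
  }
  keep <- (x$snp %in% panel_ids) | (lfdr < lfdr_threshold)
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
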