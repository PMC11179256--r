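# Blended LD reference: per-block correlation matrices of the blended SNP
# effect estimates, derived from the proximal and adjunct LD panels and the
# per-SNP blending weights.
#
# On disk an LD block set is a directory with manifest.tsv
# (block_id, chr, start, end, n_snps, snp_file, matrix_file; start/end are
# 0-based half-open) plus one matrix file per block, either dense
# little-endian binary (magic "LDBM", int32 n, column-major doubles) or a
# plain TSV debug format.

#' Construct an LD block set
#'
#' @param manifest data.frame with columns `block_id`, `chr`, `start`, `end`
#'   (0-based half-open intervals) — `n_snps` is filled in automatically.
#' @param matrices list (one per manifest row) of symmetric SNP x SNP
#'   correlation matrices with unit diagonal; dimnames carry the SNP ids in
#'   block order.
#' @return An `ld_blockset` list with elements `manifest` and `matrices`.
#' @export
ld_blockset <- function(manifest, matrices) {
  if (nrow(manifest) != length(matrices)) {
    stop_validation("manifest has %d blocks but %d matrices supplied",
                    nrow(manifest), length(matrices))
  }
  for (col in c("block_id", "chr", "start", "end")) {
    if (is.null(manifest[[col]])) stop_validation("manifest lacks column '%s'", col)
  }
  manifest$n_snps <- vapply(matrices, nrow, 0L)
  for (i in seq_along(matrices)) {
    R <- matrices[[i]]
    if (!is.matrix(R) || nrow(R) != ncol(R)) {
      stop_validation("block %s: matrix is not square", manifest$block_id[i])
    }
    if (is.null(rownames(R))) stop_validation("block %s: matrix lacks SNP dimnames",
                                              manifest$block_id[i])
    if (max(abs(R - t(R))) > 1e-8) {
      stop_validation("block %s: matrix is not symmetric", manifest$block_id[i])
    }
    if (max(abs(diag(R) - 1)) > 1e-8) {
      stop_validation("block %s: diagonal is not 1", manifest$block_id[i])
    }
    if (max(abs(R)) > 1 + 1e-8) {
      stop_validation("block %s: entries outside [-1, 1]", manifest$block_id[i])
    }
  }
  # blocks must not overlap within a chromosome
  for (ch in unique(manifest$chr)) {
    mm <- manifest[manifest$chr == ch, , drop = FALSE]
    mm <- mm[order(mm$start), , drop = FALSE]
    if (nrow(mm) > 1 && any(mm$start[-1] < mm$end[-nrow(mm)])) {
      stop_validation("overlapping blocks on chromosome %s", ch)
    }
  }
  structure(list(manifest = manifest, matrices = matrices), class = "ld_blockset")
}

#' @export
print.ld_blockset <- function(x, ...) {
  cat(sprintf("<ld_blockset> %d blocks, %d SNPs\n",
              nrow(x$manifest), sum(x$manifest$n_snps)))
  invisible(x)
}

# all SNP ids of a block set, in manifest order
blockset_snps <- function(x) unlist(lapply(x$matrices, rownames), use.names = FALSE)

#' Blend one LD block
#'
#' The blended effect at SNP *i* is a linear combination of the two studies'
#' estimates with composite loadings
#' \eqn{a_i = (1-\pi_i) + \pi_i w_{1i}/(w_{1i}+w_{2i})} on study 1 and
#' \eqn{b_i = \pi_i w_{2i}/(w_{1i}+w_{2i})} on study 2
#' (\eqn{w = 1/\sigma^2}). Its cross-SNP covariance is
#' \deqn{a_i a_j R^{(1)}_{ij}\sigma_{1i}\sigma_{1j} +
#'       b_i b_j R^{(2)}_{ij}\sigma_{2i}\sigma_{2j} +
#'       \rho\,(a_i b_j \bar R_{ij}\sigma_{1i}\sigma_{2j} +
#'              a_j b_i \bar R_{ji}\sigma_{1j}\sigma_{2i})}
#' with \eqn{\bar R = (R^{(1)}+R^{(2)})/2} standing in for the unobservable
#' cross-panel LD (the term vanishes at `rho = 0`, the cross-ancestry
#' regime). The covariance matrix is normalized to a correlation matrix and
#' repaired to positive semi-definite by clipping negative eigenvalues at 0
#' and re-normalizing the diagonal.
#'
#' @param R1,R2 proximal and adjunct block correlation matrices over the same
#'   SNPs in the same order.
#' @param se1,se2 per-SNP standard errors (adjunct `Inf` means the SNP is
#'   proximal-only: its loadings collapse to `a = 1, b = 0`).
#' @param lfdr per-SNP blending weights.
#' @param rho scalar overlap correlation.
#' @return Blended correlation matrix (symmetric, unit diagonal, PSD).
#' @export
blend_ld_block <- function(R1, R2, se1, se2, lfdr, rho = 0) {
  m <- nrow(R1)
  if (!all(dim(R1) == dim(R2))) stop_validation("R1 and R2 differ in dimension")
  if (!is.null(rownames(R1)) && !is.null(rownames(R2)) &&
      !identical(rownames(R1), rownames(R2))) {
    stop_validation("SNP order mismatch between R1 and R2")
  }
  check_same_length(se1 = se1, se2 = se2, lfdr = lfdr)
  if (length(se1) != m) stop_validation("SE vectors do not match matrix dimension")
  check_numeric(lfdr, "lfdr", min = 0, max = 1)

  w1 <- 1 / se1^2
  w2 <- 1 / se2^2                       # 0 when se2 = Inf (proximal-only)
  wm1 <- w1 / (w1 + w2)
  wm2 <- w2 / (w1 + w2)
  a <- (1 - lfdr) + lfdr * wm1
  b <- lfdr * wm2
  s2 <- ifelse(is.finite(se2), se2, 0)  # b = 0 kills these terms anyway
  Rbar <- (R1 + R2) / 2
  # normalize through per-SNP unit loadings u1, u2 so the degenerate limits
  # (all weight on one study) reproduce that study's LD bit-exactly
  u1 <- a * se1
  u2 <- b * s2
  d <- sqrt(u1^2 + u2^2 + 2 * rho * u1 * u2)
  d[u2 == 0] <- u1[u2 == 0]
  d[u1 == 0] <- u2[u1 == 0]
  if (any(!is.finite(d) | d <= 0)) {
    stop_validation("non-positive blended variance in LD block")
  }
  u1 <- u1 / d
  u2 <- u2 / d
  C <- tcrossprod(u1) * R1 + tcrossprod(u2) * R2 +
    rho * (outer(u1, u2) * Rbar + t(outer(u1, u2) * Rbar))
  C <- (C + t(C)) / 2
  # PSD repair: eigenvalue clipping, then re-normalize the diagonal
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    v <- pmax(ev$values, 0)
    C <- ev$vectors %*% (v * t(ev$vectors))
    C <- C / tcrossprod(sqrt(diag(C)))
    C <- (C + t(C)) / 2
  }
  diag(C) <- 1
  dimnames(C) <- dimnames(R1)
  C
}

#' Blend two LD panels genome-wide
#'
#' Applies [blend_ld_block()] per block over the SNPs shared by the two
#' panels and the blended summary statistics; proximal-passthrough SNPs
#' (present in panel 1 only, or blended with `source =
#' "proximal_passthrough"`) keep their panel-1 rows/columns (their loadings
#' are `a = 1, b = 0`). Blended SNPs absent from both panels are dropped with
#' a warning and counted in the report.
#'
#' @param panel1,panel2 `ld_blockset` references for the proximal and adjunct
#'   studies; blocks are taken from `panel1`'s manifest.
#' @param blended a `blended_stats` table from [blend_sumstats()] (carries
#'   `se1`, `se2`, `lfdr_used`, `source` per SNP).
#' @param rho scalar overlap correlation (defaults to the one recorded on
#'   `blended`).
#' @return An `ld_blockset` with attribute `"report"`: per-block SNP losses.
#' @export
blend_ld_genome <- function(panel1, panel2, blended, rho = attr(blended, "rho") %||% 0) {
  stopifnot(inherits(panel1, "ld_blockset"), inherits(panel2, "ld_blockset"))
  if (is.null(blended$snp)) stop_validation("blended table lacks a 'snp' column")
  p2snps <- blockset_snps(panel2)
  dropped <- setdiff(blended$snp, c(blockset_snps(panel1), p2snps))
  if (length(dropped)) {
    warning(sprintf("%d blended SNP(s) absent from both LD panels; dropped",
                    length(dropped)))
  }
  mats <- vector("list", nrow(panel1$manifest))
  losses <- integer(nrow(panel1$manifest))
  keep_blocks <- logical(nrow(panel1$manifest))
  for (k in seq_len(nrow(panel1$manifest))) {
    R1full <- panel1$matrices[[k]]
    ids <- rownames(R1full)
    use <- ids[ids %in% blended$snp]
    losses[k] <- length(ids) - length(use)
    if (!length(use)) next
    keep_blocks[k] <- TRUE
    R1 <- R1full[use, use, drop = FALSE]
    row <- blended[match(use, blended$snp), , drop = FALSE]
    # adjunct LD: SNPs absent from panel2 act as proximal-only (se2 = Inf)
    in2 <- use %in% p2snps
    R2 <- diag(length(use))
    dimnames(R2) <- dimnames(R1)
    if (any(in2)) {
      # panel2 stores each SNP in exactly one block; locate it
      blk2 <- which(vapply(panel2$matrices, function(M) any(use %in% rownames(M)), TRUE))
      for (k2 in blk2) {
        M <- panel2$matrices[[k2]]
        common <- intersect(use, rownames(M))
        R2[common, common] <- M[common, common]
      }
    }
    se2 <- ifelse(in2 & row$source == "blended" & !is.na(row$se2), row$se2, Inf)
    lf <- ifelse(is.finite(se2), row$lfdr_used, 0)
    lf[is.na(lf)] <- 0
    mats[[k]] <- blend_ld_block(R1, R2, row$se1, se2, lf, rho = rho)
  }
  out <- ld_blockset(panel1$manifest[keep_blocks, , drop = FALSE], mats[keep_blocks])
  attr(out, "report") <- data.frame(
    block_id = panel1$manifest$block_id, snps_lost = losses
  )
  log_kv("blend_ld_genome", blocks = sum(keep_blocks),
         snps = sum(out$manifest$n_snps), dropped = length(dropped))
  out
}

#' Write an LD block set to a directory
#'
#' @param x an `ld_blockset`.
#' @param dir output directory (created if needed).
#' @param format `"binary"` (dense little-endian doubles behind a 16-byte
#'   header: magic `"LDBM"`, int32 SNP count, 8 reserved bytes) or `"tsv"`
#'   (plain-text debug matrices).
#' @return `dir`, invisibly.
#' @export
write_ld_blockset <- function(x, dir, format = c("binary", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "ld_blockset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- x$manifest
  man$snp_file <- sprintf("block_%s.snps", man$block_id)
  man$matrix_file <- sprintf("block_%s.%s", man$block_id,
                             if (format == "binary") "ldm" else "tsv")
  for (i in seq_len(nrow(man))) {
    R <- x$matrices[[i]]
    writeLines(rownames(R), file.path(dir, man$snp_file[i]))
    path <- file.path(dir, man$matrix_file[i])
    if (format == "binary") {
      con <- file(path, "wb")
      writeBin(charToRaw("LDBM"), con)
      writeBin(as.integer(nrow(R)), con, size = 4L, endian = "little")
      writeBin(raw(8), con)
      writeBin(as.numeric(R), con, size = 8L, endian = "little")
      close(con)
    } else {
      utils::write.table(R, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an LD block set written by [write_ld_blockset()]
#'
#' Validates symmetry and unit diagonal on load.
#'
#' @param dir directory containing `manifest.tsv` and the per-block files.
#' @return An `ld_blockset`.
#' @export
read_ld_blockset <- function(dir) {
  mpath <- file.path(dir, "manifest.tsv")
  if (!file.exists(mpath)) stop_validation("no manifest.tsv under %s", dir)
  man <- utils::read.table(mpath, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  mats <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    snps <- readLines(file.path(dir, man$snp_file[i]))
    path <- file.path(dir, man$matrix_file[i])
    if (grepl("\\.ldm$", path)) {
      con <- file(path, "rb")
      magic <- rawToChar(readBin(con, "raw", 4L))
      if (magic != "LDBM") { close(con); stop_validation("bad magic in %s", path) }
      nsnp <- readBin(con, "integer", 1L, size = 4L, endian = "little")
      readBin(con, "raw", 8L)
      R <- matrix(readBin(con, "numeric", nsnp * nsnp, size = 8L,
                          endian = "little"), nsnp, nsnp)
      close(con)
    } else {
      R <- as.matrix(utils::read.table(path, sep = "\t"))
    }
    if (nrow(R) != length(snps)) {
      stop_validation("block %s: matrix/SNP-list size mismatch", man$block_id[i])
    }
    dimnames(R) <- list(snps, snps)
    mats[[i]] <- R
  }
  ld_blockset(man[c("block_id", "chr", "start", "end")], mats)
}
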