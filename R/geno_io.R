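# Genotype fixture format: a directory with a dense little-endian dosage
# matrix (magic "DOSG", two int32 dims, doubles column-major; NA allowed)
# plus SNP and sample sidecar files. A simulation-scale interchange format,
# not a replacement for genotype containers (see the package non-goals).

#' Write a genotype fixture directory
#'
#' @param geno a `geno_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_geno_fixture <- function(geno, dir) {
  stopifnot(inherits(geno, "geno_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "dosage.bin"), "wb")
  writeBin(charToRaw("DOSG"), con)
  writeBin(as.integer(dim(geno$dosage)), con, size = 4L, endian = "little")
  writeBin(as.numeric(geno$dosage), con, size = 8L, endian = "little")
  close(con)
  utils::write.table(geno$snps, file.path(dir, "snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(geno$sample_id, file.path(dir, "samples.txt"))
  invisible(dir)
}

#' Read a genotype fixture directory
#'
#' @param dir directory written by [write_geno_fixture()].
#' @return A `geno_sim`.
#' @export
read_geno_fixture <- function(dir) {
  path <- file.path(dir, "dosage.bin")
  if (!file.exists(path)) stop_validation("no dosage.bin under %s", dir)
  con <- file(path, "rb")
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (magic != "DOSG") { close(con); stop_validation("bad magic in %s", path) }
  d <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  G <- matrix(readBin(con, "numeric", prod(d), size = 8L, endian = "little"),
              d[1], d[2])
  close(con)
  snps <- utils::read.table(file.path(dir, "snps.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE,
                            colClasses = c(chr = "character"))
  colnames(G) <- snps$snp
  samples <- readLines(file.path(dir, "samples.txt"))
  blocks <- if ("block" %in% names(snps)) {
    nb <- max(snps$block)
    data.frame(block_id = sprintf("b%04d", seq_len(nb)), chr = snps$chr[1],
               start = tapply(snps$bp, snps$block, min) - 1L,
               end = tapply(snps$bp, snps$block, max),
               stringsAsFactors = FALSE)
  } else {
    data.frame(block_id = "b0001", chr = snps$chr[1], start = 0L,
               end = max(snps$bp), stringsAsFactors = FALSE)
  }
  structure(list(dosage = G, snps = snps, blocks = blocks, sample_id = samples),
            class = "geno_sim")
}
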