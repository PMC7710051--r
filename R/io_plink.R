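## PLINK 1 binary triple (.bed/.bim/.fam), SNP-major layout.
## Two-bit codes per the v1.9 format: 00 = hom allele1, 01 = missing,
## 10 = het, 11 = hom allele2; samples packed 4 per byte, LSB first.
## Dosage here is the allele-1 count, so code -> dosage is 0->2, 1->NA,
## 2->1, 3->0.

BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))
CODE_TO_DOSE <- c(2L, NA_integer_, 1L, 0L)
DOSE_TO_CODE <- c(`0` = 3L, `1` = 2L, `2` = 0L) # NA -> 1L handled separately

#' Read a PLINK binary triple
#'
#' Reads `prefix.bed` / `.bim` / `.fam` into a [genotype_panel()]. Dosage is
#' the count of the .bim first allele (A1); missing calls stay `NA`. Sample
#' and SNP order is file order — never silently reordered.
#'
#' @param prefix Path prefix of the `.bed`/`.bim`/`.fam` triple.
#' @param exclude_sex_chrom Drop SNPs whose chromosome label denotes a sex
#'   chromosome (`X`, `Y`, `XY`, or PLINK numeric codes given via
#'   `sex_chrom_labels`). Default `TRUE`.
#' @param sex_chrom_labels Labels treated as sex chromosomes.
#' @return A [genotype_panel()].
#' @export
read_plink <- function(prefix, exclude_sex_chrom = TRUE,
                       sex_chrom_labels = c("X", "Y", "XY", "chrX", "chrY")) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing PLINK file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  fam <- read.table(paths[3], header = FALSE, stringsAsFactors = FALSE)
  bim <- read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  names(bim) <- c("chr", "id", "cm", "pos", "a1", "a2")
  if (any(is.na(bim$chr) | !nzchar(bim$chr))) {
    stop("unparseable chromosome token in .bim", call. = FALSE)
  }
  if (anyDuplicated(bim$id)) {
    stop("duplicate SNP ids in .bim: ",
         paste(head(unique(bim$id[duplicated(bim$id)]), 5), collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paths[1], what = "raw", n = file.info(paths[1])$size)
  if (length(raw) < 3L || !identical(raw[1:2], BED_MAGIC[1:2])) {
    stop("not a PLINK .bed file (bad magic bytes)", call. = FALSE)
  }
  if (raw[3] != BED_MAGIC[3]) {
    stop("only SNP-major .bed files are supported", call. = FALSE)
  }
  bps <- ceiling(n / 4) # bytes per SNP
  if (length(raw) != 3L + bps * m) {
    stop(sprintf(
      ".bed size inconsistent with .bim/.fam: expected %d data bytes (%d SNPs x %d bytes), found %d",
      bps * m, m, bps, length(raw) - 3L), call. = FALSE)
  }
  ints <- as.integer(raw[-(1:3)])
  dose <- matrix(NA_integer_, n, m)
  for (s in 0:3) {
    if (s + 1L > n) break
    rows <- seq.int(s + 1L, n, by = 4L)
    codes <- bitwAnd(bitwShiftR(ints, 2L * s), 3L)
    codes <- matrix(codes, nrow = bps, ncol = m)[seq_along(rows), , drop = FALSE]
    dose[rows, ] <- CODE_TO_DOSE[codes + 1L]
  }
  samples <- as.character(fam[[2]])
  panel <- genotype_panel(dose, bim[, c("id", "chr", "pos", "a1", "a2")],
                          samples)
  if (exclude_sex_chrom) {
    keep <- !(panel$map$chr %in% sex_chrom_labels)
    if (!all(keep)) panel <- subset_panel(panel, snps = which(keep))
  }
  panel
}

#' Write a PLINK binary triple
#'
#' Inverse of [read_plink()]; round-trips any valid panel bit-identically on
#' dosage and map.
#'
#' @param panel A [genotype_panel()].
#' @param prefix Output path prefix.
#' @return Invisibly, `prefix`.
#' @export
write_plink <- function(panel, prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- length(panel$samples)
  m <- nrow(panel$map)
  bps <- ceiling(n / 4)
  codes <- matrix(1L, nrow = 4L * bps, ncol = m) # pad rows are 'missing'
  d <- panel$dosage
  cd <- matrix(1L, n, m)
  cd[!is.na(d)] <- DOSE_TO_CODE[as.character(d[!is.na(d)])]
  codes[seq_len(n), ] <- cd
  codes[setdiff(seq_len(4L * bps), seq_len(n)), ] <- 0L # PLINK pads with zeros
  bytes <- integer(bps * m)
  for (s in 0:3) {
    rows <- seq.int(s + 1L, 4L * bps, by = 4L)
    bytes <- bytes + as.vector(bitwShiftL(codes[rows, , drop = FALSE], 2L * s))
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(BED_MAGIC, con)
  writeBin(as.raw(bytes), con)
  bim <- data.frame(chr = panel$map$chr, id = panel$map$id, cm = 0,
                    pos = panel$map$pos, a1 = panel$map$a1, a2 = panel$map$a2)
  write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = panel$samples, iid = panel$samples,
                    pat = 0, mat = 0, sex = 0, pheno = -9)
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
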