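#' Simulate a genotype panel with a tiled gene map
#'
#' Draws biallelic dosages independently per SNP as Binomial(2, p_j) with
#' p_j ~ Uniform(`maf_range`) — a Hardy–Weinberg, linkage-equilibrium panel
#' emulating a dense imputed SNP chip. SNPs are laid out on `n_chrom`
#' chromosomes at fixed spacing, and genes are tiled along each chromosome in
#' alternating gene / intergenic blocks so that roughly `gene_frac` of SNPs
#' fall inside genes; the remainder sit between named gene pairs. An optional
#' block-copy LD mode replicates a latent haplotype dosage within blocks of
#' `ld_block` consecutive SNPs for LD-sensitive checks.
#'
#' @param n Number of individuals.
#' @param m Number of SNPs.
#' @param n_chrom Number of chromosomes (default 5).
#' @param maf_range Interval for the generating allele frequency, within
#'   (0, 0.5].
#' @param gene_frac Target fraction of SNPs inside genes (default 0.6).
#' @param snps_per_gene SNPs per gene block (default 5).
#' @param spacing_bp Base pairs between adjacent SNPs (default 1000).
#' @param miss_rate Fraction of calls set missing at random (default 0).
#' @param ld_block Block size for the block-copy LD mode; 1 (default) means
#'   independent SNPs.
#' @param seed Integer seed; the draw is deterministic given all arguments.
#' @return A list with elements `panel` ([genotype_panel()]), `annotation`
#'   ([gene_annotation()]), and `freq` (the generating allele frequencies).
#' @export
simulate_genotypes <- function(n, m, n_chrom = 5,
                               maf_range = c(0.05, 0.5),
                               gene_frac = 0.6, snps_per_gene = 5,
                               spacing_bp = 1000, miss_rate = 0,
                               ld_block = 1, seed = 1) {
  check_scalar(n, "n", lower = 2)
  check_scalar(m, "m", lower = n_chrom)
  check_scalar(maf_range[1], "maf_range[1]", lower = 0, upper = 0.5,
               open_lower = TRUE)
  check_scalar(maf_range[2], "maf_range[2]", lower = maf_range[1], upper = 0.5)
  check_scalar(gene_frac, "gene_frac", lower = 0, upper = 1, open_lower = TRUE)
  check_scalar(miss_rate, "miss_rate", lower = 0, upper = 1, open_upper = TRUE)
  set.seed(seed)

  m_chr <- diff(round(seq(0, m, length.out = n_chrom + 1)))
  chr <- rep(paste0("chr", seq_len(n_chrom)), m_chr)
  pos <- unlist(lapply(m_chr, function(k) spacing_bp * seq_len(k)))
  p <- runif(m, maf_range[1], maf_range[2])

  if (ld_block > 1) {
    ## block-copy LD: one latent dosage per block, copied with small
    ## per-SNP mutation noise
    dose <- matrix(0L, n, m)
    start <- 1L
    while (start <= m) {
      idx <- start:min(start + ld_block - 1L, m)
      latent <- rbinom(n, 2, p[idx[1]])
      for (j in idx) {
        flip <- runif(n) < 0.05
        dose[, j] <- ifelse(flip, rbinom(n, 2, p[j]), latent)
      }
      p[idx] <- colMeans(dose[, idx, drop = FALSE]) / 2
      start <- start + length(idx)
    }
  } else {
    dose <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  }
  if (miss_rate > 0) {
    dose[runif(n * m) < miss_rate] <- NA_integer_
  }

  ## tile genes: gene block of `snps_per_gene` SNPs, then an intergenic gap
  ## sized so the covered fraction is about gene_frac
  gap <- max(1L, round(snps_per_gene * (1 - gene_frac) / gene_frac))
  ann <- list()
  offset <- 0L
  for (c_i in seq_len(n_chrom)) {
    mc <- m_chr[c_i]
    pos_c <- pos[offset + seq_len(mc)]
    j <- 1L
    g <- 1L
    while (j <= mc) {
      j_end <- min(j + snps_per_gene - 1L, mc)
      ann[[length(ann) + 1L]] <- data.frame(
        symbol = sprintf("GC%dN%d", c_i, g),
        chr = paste0("chr", c_i),
        start = pos_c[j], end = pos_c[j_end],
        stringsAsFactors = FALSE)
      g <- g + 1L
      j <- j_end + gap + 1L
    }
    offset <- offset + mc
  }
  ann <- do.call(rbind, ann)
  map <- data.frame(id = sprintf("rs%06d", seq_len(m)), chr = chr, pos = pos,
                    a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  list(panel = genotype_panel(dose, map),
       annotation = gene_annotation(ann$symbol, ann$chr, ann$start, ann$end),
       freq = p)
}
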