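#' Sample allele frequencies
#'
#' `p_j` is the allele-1 dosage sum over non-missing calls divided by twice
#' the non-missing count. SNPs with no non-missing call get `NaN` and are
#' listed in the `"all_missing"` attribute.
#'
#' @param panel A [genotype_panel()].
#' @param subset Integer map indices, or `NULL` for all SNPs.
#' @return Numeric vector of frequencies (named by SNP id).
#' @export
allele_freqs <- function(panel, subset = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- if (is.null(subset)) panel$dosage else panel$dosage[, subset, drop = FALSE]
  if (!ncol(d)) stop("empty SNP subset", call. = FALSE)
  nn <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * nn)
  flagged <- unname(which(nn == 0))
  if (length(flagged)) {
    p[flagged] <- NaN
    attr(p, "all_missing") <- flagged
  }
  p
}

#' SNP quality control
#'
#' Removes SNPs with minor allele frequency below `maf_min` (strict `<`,
#' matching the usual chip QC convention of excluding "MAF < threshold") or
#' with a missing-call fraction above `max_missing` (the PLINK `--geno`
#' convention). Map order is preserved; applying the same thresholds twice
#' is a no-op.
#'
#' @param panel A [genotype_panel()].
#' @param maf_min MAF threshold in \[0, 0.5).
#' @param max_missing Maximum tolerated missing-call fraction in \[0, 1\].
#' @return List with `panel` (filtered) and `report` (class `qc_report`:
#'   counts removed by each filter, their union, and retained).
#' @export
apply_snp_qc <- function(panel, maf_min = 0.01, max_missing = 0.1) {
  stopifnot(inherits(panel, "genotype_panel"))
  check_scalar(maf_min, "maf_min", lower = 0, upper = 0.5, open_upper = TRUE)
  check_scalar(max_missing, "max_missing", lower = 0, upper = 1)
  p <- suppressWarnings(allele_freqs(panel))
  maf <- pmin(p, 1 - p)
  miss <- colMeans(is.na(panel$dosage))
  fail_maf <- !is.nan(maf) & maf < maf_min
  fail_miss <- miss > max_missing | (is.nan(maf) & max_missing < 1)
  drop <- fail_maf | fail_miss
  if (all(drop)) stop("QC removed every SNP", call. = FALSE)
  report <- structure(list(n_input = ncol(panel$dosage),
                           n_removed_maf = sum(fail_maf),
                           n_removed_missing = sum(fail_miss),
                           n_removed = sum(drop),
                           n_retained = sum(!drop),
                           maf_min = maf_min, max_missing = max_missing),
                      class = "qc_report")
  panel_out <- if (any(drop)) subset_panel(panel, snps = which(!drop)) else panel
  list(panel = panel_out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "qc_report: %d SNPs in; removed %d (MAF < %g: %d, missing > %g: %d); retained %d\n",
    x$n_input, x$n_removed, x$maf_min, x$n_removed_maf, x$max_missing,
    x$n_removed_missing, x$n_retained))
  invisible(x)
}

#' Build a VanRaden genomic relationship matrix
#'
#' `G = M M' / (2 * sum(p_j (1 - p_j)))` where column `j` of `M` is the
#' dosage centred by `2 p_j`, with sample-estimated allele frequencies.
#' Missing dosages are mean-imputed (centred value 0) before the cross
#' product, which preserves the row-sum-zero identity of the centred
#' matrix. Monomorphic SNPs contribute zero to both numerator and
#' denominator; a subset that is entirely monomorphic is an error.
#'
#' @param panel A [genotype_panel()].
#' @param subset Integer map indices, or `NULL` for all SNPs.
#' @param name Label for the SNP set (used in reports).
#' @return Object of class `grm`: list with `mat` (N x N), `samples`,
#'   `denom` (the VanRaden denominator), `set_name`, `n_snps`.
#' @export
build_grm <- function(panel, subset = NULL, name = "all") {
  stopifnot(inherits(panel, "genotype_panel"))
  idx <- if (is.null(subset)) seq_len(nrow(panel$map)) else as.integer(subset)
  if (!length(idx)) stop("empty SNP subset", call. = FALSE)
  p <- suppressWarnings(allele_freqs(panel, idx))
  het <- 2 * p * (1 - p)
  het[is.nan(het)] <- 0
  denom <- sum(het)
  if (denom <= 0) {
    stop("all SNPs in subset `", name, "` are monomorphic (denominator 0)",
         call. = FALSE)
  }
  M <- panel$dosage[, idx, drop = FALSE]
  storage.mode(M) <- "double"
  M <- sweep(M, 2, 2 * p)
  M[is.na(M)] <- 0
  G <- tcrossprod(M) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(panel$samples, panel$samples)
  structure(list(mat = G, samples = panel$samples, denom = denom,
                 set_name = name, n_snps = length(idx)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm `%s`: %d individuals, %d SNPs, denominator %.3f, mean diag %.3f\n",
              x$set_name, length(x$samples), x$n_snps, x$denom,
              mean(diag(x$mat))))
  invisible(x)
}

## Extract the numeric matrix from a grm or plain matrix argument.
grm_matrix <- function(G) {
  if (inherits(G, "grm")) G$mat else as.matrix(G)
}

#' Combine GRMs built on disjoint SNP sets
#'
#' The GRM of a union of disjoint sets equals the denominator-weighted
#' combination of the sets' numerators:
#' `(d1 G1 + d2 G2) / (d1 + d2)` — exact, because allele frequencies are
#' per-SNP.
#'
#' @param g1,g2 Two [build_grm()] results on the same samples.
#' @param name Label for the combined set.
#' @return A `grm`.
#' @export
combine_grms <- function(g1, g2, name = paste(g1$set_name, g2$set_name,
                                              sep = "+")) {
  stopifnot(inherits(g1, "grm"), inherits(g2, "grm"),
            identical(g1$samples, g2$samples))
  denom <- g1$denom + g2$denom
  structure(list(mat = (g1$denom * g1$mat + g2$denom * g2$mat) / denom,
                 samples = g1$samples, denom = denom, set_name = name,
                 n_snps = g1$n_snps + g2$n_snps),
            class = "grm")
}

#' Regularize a GRM for inversion
#'
#' Returns `alpha * G + (1 - alpha) * I + ridge * I`. With `alpha = 1` and
#' `ridge = 0` the input is returned unchanged. Used where the mixed-model
#' equations require `G^-1` and the raw matrix is singular (e.g. more
#' individuals than SNPs in a subset).
#'
#' @param G A `grm` or numeric matrix.
#' @param alpha Blending weight in (0, 1\].
#' @param ridge Non-negative diagonal addition.
#' @return Same class as the input, regularized.
#' @export
regularize_grm <- function(G, alpha = 0.95, ridge = 0) {
  check_scalar(alpha, "alpha", lower = 0, upper = 1, open_lower = TRUE)
  check_scalar(ridge, "ridge", lower = 0)
  mat <- grm_matrix(G)
  if (alpha == 1 && ridge == 0) return(G)
  out <- alpha * mat + diag((1 - alpha) + ridge, nrow(mat))
  ev_min <- NULL
  ok <- tryCatch({chol(out); TRUE}, error = function(e) FALSE)
  if (!ok) {
    ev_min <- min(eigen(out, symmetric = TRUE, only.values = TRUE)$values)
    stop(sprintf(
      "regularized GRM still singular (smallest eigenvalue %.3e)", ev_min),
      call. = FALSE)
  }
  if (inherits(G, "grm")) {
    G$mat <- out
    G
  } else {
    out
  }
}

## Invert a GRM via Cholesky; on failure fall back to the default
## regularization (alpha = 0.95) once, with a message.
grm_inverse <- function(G) {
  mat <- grm_matrix(G)
  inv <- tryCatch(chol2inv(chol(mat)), error = function(e) NULL)
  if (is.null(inv)) {
    message("GRM `", if (inherits(G, "grm")) G$set_name else "?",
            "` is singular; applying default regularization (alpha = 0.95)")
    mat <- grm_matrix(regularize_grm(G, alpha = 0.95))
    inv <- chol2inv(chol(mat))
  }
  inv
}
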