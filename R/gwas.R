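## Build a fixed-effect design matrix from phenotype-table columns:
## treatment coding with the first level as reference, numeric columns
## as-is, plus an intercept. Errors listing aliased columns when rank
## deficient.
build_fixed_design <- function(pheno, fixed_cols) {
  if (!length(fixed_cols)) {
    return(matrix(1, nrow(pheno), 1, dimnames = list(NULL, "(Intercept)")))
  }
  absent <- setdiff(fixed_cols, names(pheno))
  if (length(absent)) {
    stop("fixed-effect column(s) absent: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  df <- pheno[, fixed_cols, drop = FALSE]
  for (nm in names(df)) {
    if (is.character(df[[nm]]) || is.logical(df[[nm]])) {
      df[[nm]] <- factor(df[[nm]])
    }
  }
  X <- model.matrix(~ ., data = df)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    aliased <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("fixed-effect design is rank deficient; aliased: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  X
}

#' Pre-adjust phenotypes for fixed effects
#'
#' Fills the corrected phenotype `y_c = y - X b_OLS + mean(y)` from an
#' ordinary least squares fit of the declared fixed effects on the complete
#' rows; scale and location are retained so `y_c` stays in trait units.
#' Rows with missing trait or missing covariates get `NA` in `y_c`.
#' Adjustment is idempotent (a projection).
#'
#' @param pheno A `phenotype_table` (see [read_phenotypes()]).
#' @param fixed_cols Covariate column names; defaults to the table's
#'   declared covariates.
#' @return The table with a `y_c` column filled.
#' @export
adjust_phenotype <- function(pheno, fixed_cols = attr(pheno, "covariates")) {
  fixed_cols <- fixed_cols %||% character(0)
  complete <- !is.na(pheno$y)
  if (length(fixed_cols)) {
    complete <- complete &
      complete.cases(pheno[, fixed_cols, drop = FALSE])
  }
  if (!any(complete)) stop("no complete rows to adjust", call. = FALSE)
  X <- build_fixed_design(pheno[complete, , drop = FALSE], fixed_cols)
  fit <- lm.fit(X, pheno$y[complete])
  yc <- rep(NA_real_, nrow(pheno))
  yc[complete] <- fit$residuals + mean(pheno$y[complete])
  pheno$y_c <- yc
  pheno
}

#' Leave-one-chromosome-out GRM set
#'
#' For each chromosome, the polygenic GRM built from all SNPs except those
#' on that chromosome — so a candidate SNP is never represented in its own
#' polygenic covariance (proximal contamination). Computed exactly via the
#' denominator-weighted decomposition
#' `G_loco = (d_all G_all - d_c G_c) / (d_all - d_c)`, which equals
#' building each complement from scratch because allele frequencies are
#' per-SNP. A chromosome with no SNPs gets the all-SNP GRM with a warning.
#'
#' @param panel A (post-QC) [genotype_panel()].
#' @param chromosomes Chromosome labels to produce (default: all in map).
#' @return Named list of `grm` objects, one per chromosome.
#' @export
loco_grm_set <- function(panel, chromosomes = unique(panel$map$chr)) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (length(unique(panel$map$chr)) < 2) {
    stop("LOCO needs at least 2 chromosomes", call. = FALSE)
  }
  g_all <- build_grm(panel, name = "all")
  out <- list()
  for (ch in chromosomes) {
    idx <- which(panel$map$chr == ch)
    if (!length(idx)) {
      warning("chromosome ", ch, " has no SNPs; using the all-SNP GRM")
      g <- g_all
      g$set_name <- paste0("loco_", ch)
      out[[ch]] <- g
      next
    }
    g_c <- build_grm(panel, idx, name = ch)
    denom <- g_all$denom - g_c$denom
    if (denom <= 0) {
      stop("complement of chromosome ", ch, " is monomorphic", call. = FALSE)
    }
    out[[ch]] <- structure(
      list(mat = (g_all$denom * g_all$mat - g_c$denom * g_c$mat) / denom,
           samples = panel$samples, denom = denom,
           set_name = paste0("loco_", ch),
           n_snps = g_all$n_snps - g_c$n_snps),
      class = "grm")
  }
  out
}

#' Genome-wide significance thresholds
#'
#' Bonferroni-style cutoffs for `m` tested markers: significant at
#' `0.05 / m`, suggestive at `0.1 / m`.
#'
#' @param m Number of tested markers (>= 1).
#' @return List with `significant` and `suggestive` p-value cutoffs.
#' @export
significance_thresholds <- function(m) {
  check_scalar(m, "m", lower = 1)
  list(significant = 0.05 / m, suggestive = 0.1 / m)
}

#' Mixed-model association scan over candidate SNPs
#'
#' For each candidate SNP, fits the single-marker mixed model
#' `y_c = mu 1 + D beta + g + e` by generalized least squares with
#' `V = sigma2_g G_loco + sigma2_E I` fixed per chromosome (the two-stage
#' MLMA scheme: variance components are estimated once per
#' leave-one-chromosome-out set, not per SNP). The Wald p-value uses the
#' normal approximation; an intercept is refit per SNP. Missing candidate
#' dosages are mean-imputed; monomorphic candidates are returned with `NA`
#' effect and flagged, not dropped.
#'
#' @param yc Corrected phenotype vector, one value per panel individual
#'   (complete).
#' @param panel A [genotype_panel()].
#' @param candidates Integer map indices of candidate SNPs, or a
#'   [snp_partition()] set name resolved via `partition`.
#' @param loco Named list of LOCO GRMs from [loco_grm_set()].
#' @param varcomp Either a single `list(sigma2g = , sigma2e = )` applied to
#'   every chromosome, or a named list per chromosome (e.g. each an
#'   [aireml()] fit on the matching LOCO GRM).
#' @param partition Optional [snp_partition()] when `candidates` is a set
#'   name.
#' @return Data frame (class `assoc_result`): snp, chr, pos, beta, se, p,
#'   neglog10p, monomorphic, significant, suggestive. Thresholds use the
#'   candidate count.
#' @export
assoc_scan <- function(yc, panel, candidates, loco, varcomp,
                       partition = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.character(candidates) && length(candidates) == 1 &&
      !is.null(partition)) {
    candidates <- partition[[candidates]]
  }
  candidates <- as.integer(candidates)
  if (!length(candidates)) stop("no candidate SNPs", call. = FALSE)
  n <- length(panel$samples)
  stopifnot(length(yc) == n, !anyNA(yc))
  thr <- significance_thresholds(length(candidates))

  get_vc <- function(ch) {
    vc <- if (inherits(varcomp, "varcomp_fit") ||
              !is.null(varcomp$sigma2g)) varcomp else varcomp[[ch]]
    if (is.null(vc)) stop("no variance components for chromosome ", ch,
                          call. = FALSE)
    if (inherits(vc, "varcomp_fit")) {
      list(sigma2g = sum(vc$varcomp), sigma2e = vc$sigma2e)
    } else {
      vc
    }
  }

  res <- vector("list", 0)
  for (ch in unique(panel$map$chr[candidates])) {
    idx <- candidates[panel$map$chr[candidates] == ch]
    if (is.null(loco[[ch]])) stop("no LOCO GRM for chromosome ", ch,
                                  call. = FALSE)
    vc <- get_vc(ch)
    V <- vc$sigma2g * grm_matrix(loco[[ch]]) + diag(vc$sigma2e, n)
    Vi <- chol2inv(chol(V))

    D <- panel$dosage[, idx, drop = FALSE]
    storage.mode(D) <- "double"
    cm <- colMeans(D, na.rm = TRUE)
    for (j in seq_along(idx)) D[is.na(D[, j]), j] <- cm[j]
    mono <- apply(D, 2, function(x) var(x) == 0 || !is.finite(var(x)))

    one <- rep(1, n)
    Vi1 <- Vi %*% one
    a11 <- drop(crossprod(one, Vi1))
    Viy <- Vi %*% yc
    b1 <- drop(crossprod(one, Viy))
    ViD <- Vi %*% D
    a12 <- drop(crossprod(one, ViD))   # 1'Vi d per SNP
    a22 <- colSums(D * ViD)            # d'Vi d
    b2 <- drop(crossprod(D, Viy))      # d'Vi y
    det2 <- a11 * a22 - a12^2
    beta <- (a11 * b2 - a12 * b1) / det2
    se <- sqrt(a11 / det2)
    beta[mono] <- NA_real_
    se[mono] <- NA_real_
    z <- beta / se
    p <- 2 * pnorm(-abs(z))
    p[!mono & p == 0] <- .Machine$double.xmin # guard exact zeros
    res[[length(res) + 1]] <- data.frame(
      snp = panel$map$id[idx], chr = ch, pos = panel$map$pos[idx],
      beta = beta, se = se, p = p, neglog10p = -log10(p),
      monomorphic = mono, stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, res)
  ## restore candidate order
  out <- out[match(panel$map$id[candidates], out$snp), , drop = FALSE]
  rownames(out) <- NULL
  out$significant <- !is.na(out$p) & out$p < thr$significant
  out$suggestive <- !is.na(out$p) & out$p < thr$suggestive
  attr(out, "thresholds") <- thr
  class(out) <- c("assoc_result", "data.frame")
  out
}
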