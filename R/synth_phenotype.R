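#' Specify a simulated genetic architecture
#'
#' The defaults describe the feature-enriched additive architecture used
#' throughout the package's validation runs: phenotypic variance 1, a
#' moderate heritability of 0.3, 100 additive QTL, and 80% of the additive
#' genetic variance carried by QTL inside the feature (`tm`) SNP set. Fixed
#' effects are additive level offsets (categorical) or linear slopes
#' (numeric) on the phenotype scale.
#'
#' @param h2 Target narrow-sense heritability in \[0, 1\].
#' @param n_qtl Number of QTL.
#' @param f_tm Fraction of additive genetic variance assigned to QTL inside
#'   the `tm` set, in \[0, 1\].
#' @param sigma2_p Total phenotypic variance (genetic + residual) on the
#'   trait scale; default 1.
#' @param mu Overall mean.
#' @param fixed Named list of fixed-effect specs. A categorical covariate is
#'   `list(levels = c(...), effects = c(...))` (levels sampled uniformly); a
#'   numeric covariate is `list(beta = , mean = , sd = )`.
#' @return Object of class `architecture_spec`.
#' @export
architecture_spec <- function(h2 = 0.3, n_qtl = 100, f_tm = 0.8,
                              sigma2_p = 1, mu = 0,
                              fixed = list(
                                site = list(levels = c("S1", "S2", "S3"),
                                            effects = c(0, 0.4, 0.8)),
                                age = list(beta = 0.02, mean = 900, sd = 30))) {
  check_scalar(h2, "h2", lower = 0, upper = 1)
  check_scalar(f_tm, "f_tm", lower = 0, upper = 1)
  check_scalar(n_qtl, "n_qtl", lower = 0)
  check_scalar(sigma2_p, "sigma2_p", lower = 0, open_lower = TRUE)
  for (nm in names(fixed)) {
    fx <- fixed[[nm]]
    if (!is.null(fx$levels) && length(fx$levels) != length(fx$effects)) {
      stop("fixed effect `", nm, "`: levels and effects differ in length",
           call. = FALSE)
    }
  }
  structure(list(h2 = h2, n_qtl = as.integer(n_qtl), f_tm = f_tm,
                 sigma2_p = sigma2_p, mu = mu, fixed = fixed),
            class = "architecture_spec")
}

#' Simulate a phenotype with a feature-enriched additive architecture
#'
#' QTL are sampled so that the expected share of additive genetic variance on
#' feature-set (`tm`) QTL equals `spec$f_tm`: `round(f_tm * n_qtl)` QTL are
#' placed in the `tm` set and the rest in its complement, and each QTL effect
#' is drawn `N(0, v_set / (n_set * 2 p_j (1 - p_j)))` with sample-estimated
#' allele frequencies, so every QTL contributes the same expected variance
#' and the bookkeeping matches the VanRaden 2p(1-p) standardization of the
#' GRM. The residual variance is set from the target heritability; fixed
#' effects are added per the spec.
#'
#' @param panel A [genotype_panel()].
#' @param partition A [snp_partition()] over the panel.
#' @param spec An [architecture_spec()].
#' @param seed Integer seed.
#' @return List with `pheno` (a `phenotype_table`) and `truth` (class
#'   `truth_set`: per-QTL effects, true breeding values, realized variance
#'   partition).
#' @export
simulate_phenotype <- function(panel, partition, spec = architecture_spec(),
                               seed = 1) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(partition, "snp_partition"),
            inherits(spec, "architecture_spec"))
  m <- nrow(panel$map)
  n <- length(panel$samples)
  if (length(partition$all) != m) {
    stop("partition does not match panel SNP count", call. = FALSE)
  }
  if (spec$n_qtl > m) stop("more QTL than SNPs", call. = FALSE)
  if (spec$f_tm > 0 && spec$h2 > 0 && length(partition$tm) == 0) {
    stop("f_tm > 0 but the tm set is empty", call. = FALSE)
  }
  set.seed(seed)

  sigma2_g <- spec$h2 * spec$sigma2_p
  sigma2_e <- (1 - spec$h2) * spec$sigma2_p

  n_tm <- if (spec$h2 > 0) min(round(spec$f_tm * spec$n_qtl),
                               length(partition$tm)) else 0L
  n_exp <- if (spec$h2 > 0) min(spec$n_qtl - n_tm, length(partition$exp)) else 0L
  qtl_tm <- if (n_tm > 0) sort(sample(partition$tm, n_tm)) else integer(0)
  qtl_exp <- if (n_exp > 0) sort(sample(partition$exp, n_exp)) else integer(0)
  qtl <- c(qtl_tm, qtl_exp)

  tbv <- rep(0, n)
  tbv_tm <- rep(0, n)
  effects <- numeric(0)
  if (length(qtl) && sigma2_g > 0) {
    p <- allele_freqs(panel, qtl)
    het <- 2 * p * (1 - p)
    het[!is.finite(het) | het <= 0] <- NA
    v_tm <- if (n_tm > 0) spec$f_tm * sigma2_g / n_tm else 0
    v_exp <- if (n_exp > 0) (1 - spec$f_tm) * sigma2_g / n_exp else 0
    v_per <- c(rep(v_tm, n_tm), rep(v_exp, n_exp))
    effects <- rnorm(length(qtl), 0, sqrt(v_per / het))
    effects[is.na(effects)] <- 0
    W <- panel$dosage[, qtl, drop = FALSE]
    W <- sweep(W, 2, 2 * p)
    W[is.na(W)] <- 0
    tbv <- drop(W %*% effects)
    if (n_tm > 0) {
      tbv_tm <- drop(W[, seq_len(n_tm), drop = FALSE] %*% effects[seq_len(n_tm)])
    }
  }

  ## fixed effects
  fx_total <- rep(spec$mu, n)
  covars <- list()
  for (nm in names(spec$fixed)) {
    fx <- spec$fixed[[nm]]
    if (!is.null(fx$levels)) {
      lv <- sample(fx$levels, n, replace = TRUE)
      fx_total <- fx_total + fx$effects[match(lv, fx$levels)]
      covars[[nm]] <- lv
    } else {
      x <- rnorm(n, fx$mean %||% 0, fx$sd %||% 1)
      fx_total <- fx_total + (fx$beta %||% 0) * x
      covars[[nm]] <- x
    }
  }

  e <- if (sigma2_e > 0) rnorm(n, 0, sqrt(sigma2_e)) else rep(0, n)
  y <- fx_total + tbv + e

  pheno <- data.frame(id = panel$samples, y = y, stringsAsFactors = FALSE)
  for (nm in names(covars)) pheno[[nm]] <- covars[[nm]]
  pheno$missing_y <- FALSE
  pheno$missing_covariate <- FALSE
  attr(pheno, "covariates") <- names(covars)
  class(pheno) <- c("phenotype_table", "data.frame")

  var_g <- var(tbv)
  truth <- structure(list(
    qtl = data.frame(index = qtl, id = panel$map$id[qtl],
                     effect = if (length(qtl)) effects else numeric(0),
                     in_tm = qtl %in% partition$tm,
                     stringsAsFactors = FALSE),
    tbv = setNames(tbv, panel$samples),
    realized_h2 = if (var_g + var(e) > 0) var_g / (var_g + var(e)) else 0,
    realized_f_tm = if (var_g > 0) var(tbv_tm) / var_g else NA_real_,
    sigma2_g = sigma2_g, sigma2_e = sigma2_e),
    class = "truth_set")
  list(pheno = pheno, truth = truth)
}
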