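#' Random k-fold assignment
#'
#' A random permutation under `seed` splits the samples into `k` folds whose
#' sizes differ by at most one.
#'
#' @param samples Sample id vector.
#' @param k Number of folds (>= 2, <= number of samples).
#' @param seed Integer seed.
#' @return Named integer vector of fold labels in 1..k.
#' @export
kfold_assign <- function(samples, k = 10, seed = 1) {
  n <- length(samples)
  check_scalar(k, "k", lower = 2)
  if (k > n) stop("k = ", k, " exceeds sample count ", n, call. = FALSE)
  set.seed(seed)
  sizes <- rep(n %/% k, k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  fold <- integer(n)
  fold[sample.int(n)] <- rep(seq_len(k), times = sizes)
  setNames(fold, samples)
}

#' Evenly spaced SNP control set
#'
#' Selects `count` SNPs at a fixed stride `floor(M / count)` through the
#' genome map order, starting from a seed-chosen offset — the evenly-mined
#' control panel matched in size to a feature set.
#'
#' @param panel A [genotype_panel()].
#' @param count Number of SNPs to select (1..M).
#' @param seed Integer seed for the offset.
#' @return Sorted integer map indices of length `count`; attach to a
#'   partition with [set_em()].
#' @export
evenly_spaced_subset <- function(panel, count, seed = 1) {
  stopifnot(inherits(panel, "genotype_panel"))
  M <- nrow(panel$map)
  check_scalar(count, "count", lower = 1, upper = M)
  count <- as.integer(count)
  stride <- M %/% count
  max_offset <- M - 1L - stride * (count - 1L)
  set.seed(seed)
  offset <- sample.int(max_offset + 1L, 1L) - 1L
  offset + stride * (seq_len(count) - 1L) + 1L
}

## Resolve a model label to the SNP index sets whose GRMs it uses.
model_sets <- function(model, partition) {
  label <- if (is.numeric(model)) {
    c("Im", "exp", "exp+tm")[model]
  } else {
    model
  }
  sets <- switch(label,
    "Im" = list(all = partition$all),
    "exp" = list(exp = partition$exp),
    "exp+tm" = list(exp = partition$exp, tm = partition$tm),
    "exp+em" = {
      if (is.null(partition$em)) {
        stop("partition has no em set; see evenly_spaced_subset()/set_em()",
             call. = FALSE)
      }
      list(exp_em = setdiff(partition$all, partition$em), em = partition$em)
    },
    stop("unknown model label: ", label, call. = FALSE))
  list(label = label, sets = sets)
}

#' Cross-validated GBLUP prediction accuracy
#'
#' Runs k-fold cross-validation of a genomic model: in each fold the
#' validation individuals' phenotype records are masked by removing their
#' rows from `Z` (their columns stay, all zero, so they receive GEBVs
#' through `G`), the mixed-model equations are solved on the training
#' records, and accuracy is the Pearson correlation `r(GEBV, y_c)` on the
#' validation fold. Reported as per-fold r, mean, and standard error
#' `sd(r) / sqrt(k)`.
#'
#' Variance components (hence the shrinkage `lambda_k = sigma2_E /
#' sigma2_k`) are re-estimated by [aireml()] on each training fold by
#' default; `varcomp_policy = "global"` estimates them once on the full
#' data, which avoids 10 REML runs when the model is only being compared
#' across SNP panels on identical folds.
#'
#' @param panel A [genotype_panel()].
#' @param pheno A `phenotype_table`; `y_c` is computed from its declared
#'   covariates if absent (see [adjust_phenotype()]).
#' @param partition A [snp_partition()].
#' @param model 1/"Im" (all SNPs), 2/"exp" (complement panel),
#'   3/"exp+tm" (two GRMs), or "exp+em" (evenly-spaced control two-GRM).
#' @param k Number of folds.
#' @param seed Seed for the fold assignment.
#' @param varcomp_policy `"per_fold"` (default) or `"global"`.
#' @param folds Optional precomputed fold labels (overrides `k`/`seed`),
#'   e.g. to share folds across model configurations.
#' @param grm_cache Optional environment used to reuse GRMs across calls.
#' @return Object of class `cv_result`: `label`, `fold_r`, `mean_r`, `se`,
#'   `folds`, `seed`, `varcomp` (global fit or per-fold list).
#' @export
cv_accuracy <- function(panel, pheno, partition, model, k = 10, seed = 1,
                        varcomp_policy = c("per_fold", "global"),
                        folds = NULL, grm_cache = NULL) {
  varcomp_policy <- match.arg(varcomp_policy)
  ms <- model_sets(model, partition)
  if (!"y_c" %in% names(pheno)) pheno <- adjust_phenotype(pheno)
  ids <- pheno$id
  stopifnot(identical(sort(ids), sort(panel$samples)))
  yc <- pheno$y_c[match(panel$samples, ids)]
  if (anyNA(yc)) stop("y_c has missing values", call. = FALSE)
  N <- length(yc)

  get_grm <- function(nm, idx) {
    key <- paste0(nm, "#", length(idx))
    if (!is.null(grm_cache) && !is.null(grm_cache[[key]])) {
      return(grm_cache[[key]])
    }
    g <- build_grm(panel, idx, name = nm)
    ## a VanRaden G with in-sample frequencies is singular (centred rows sum
    ## to zero); blend once so REML and the MME see the same matrix
    if (!tryCatch({chol(g$mat); TRUE}, error = function(e) FALSE)) {
      g <- regularize_grm(g, alpha = 0.95)
    }
    if (!is.null(grm_cache)) grm_cache[[key]] <- g
    g
  }
  grms <- Map(get_grm, names(ms$sets), ms$sets)

  if (is.null(folds)) folds <- kfold_assign(panel$samples, k, seed)
  k <- max(folds)

  ## invert each (regularized) GRM once; every fold (and, via the cache,
  ## every model configuration sharing the GRM) reuses the inverse
  ginvs <- lapply(names(grms), function(nm) {
    key <- paste0(nm, "#", length(ms$sets[[nm]]), "#inv")
    if (!is.null(grm_cache) && !is.null(grm_cache[[key]])) {
      return(grm_cache[[key]])
    }
    gi <- grm_inverse(grms[[nm]])
    if (!is.null(grm_cache)) grm_cache[[key]] <- gi
    gi
  })

  global_fit <- NULL
  if (varcomp_policy == "global") {
    global_fit <- aireml(yc, NULL, grms)
  }

  fold_r <- rep(NA_real_, k)
  fold_fits <- vector("list", k)
  for (f in seq_len(k)) {
    train <- which(folds != f)
    val <- which(folds == f)
    fit_vc <- if (varcomp_policy == "global") {
      global_fit
    } else {
      sub_gs <- lapply(grms, function(g) g$mat[train, train, drop = FALSE])
      names(sub_gs) <- names(grms)
      aireml(yc[train], NULL, sub_gs)
    }
    fold_fits[[f]] <- fit_vc
    lam <- fit_vc$sigma2e / pmax(fit_vc$varcomp, fit_vc$floor)
    comps <- lapply(seq_along(grms), function(j) {
      list(G = grms[[j]], lambda = lam[[j]], Ginv = ginvs[[j]])
    })
    names(comps) <- names(grms)
    Z <- incidence_matrix(panel$samples[train], panel$samples)
    fit <- solve_mme(yc[train], NULL, Z, comps)
    pred <- predict_validation(fit, panel$samples[val])
    if (sd(yc[val]) == 0 || sd(pred) == 0) {
      warning("fold ", f, ": zero variance; r undefined, excluded")
    } else {
      fold_r[f] <- cor(pred, yc[val])
    }
  }
  used <- !is.na(fold_r)
  structure(list(label = ms$label, fold_r = fold_r,
                 mean_r = mean(fold_r[used]),
                 se = sd(fold_r[used]) / sqrt(sum(used)),
                 folds = folds, seed = seed,
                 varcomp = global_fit %||% fold_fits),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result `%s`: mean r = %.3f +/- %.3f over %d folds\n",
              x$label, x$mean_r, x$se, length(x$fold_r)))
  invisible(x)
}

#' Compare genomic models by cross-validation on shared folds
#'
#' Runs the requested model configurations — the full panel (`Im`), the
#' feature-excluded panel (`exp`), the two-GRM feature model (`exp+tm`),
#' and the evenly-spaced two-GRM control (`exp+em`) — on identical fold
#' assignments and reports mean accuracy and standard error per model. The
#' `em` control set is drawn (size-matched to `tm`) if the partition lacks
#' one.
#'
#' @inheritParams cv_accuracy
#' @param models Character vector of configuration labels.
#' @return Data frame `model`, `mean_r`, `se` with attributes `"details"`
#'   (the `cv_result` objects) and `"folds"`.
#' @export
compare_models <- function(panel, pheno, partition, k = 10, seed = 1,
                           models = c("Im", "exp", "exp+tm", "exp+em"),
                           varcomp_policy = c("per_fold", "global")) {
  varcomp_policy <- match.arg(varcomp_policy)
  if ("exp+em" %in% models && is.null(partition$em)) {
    partition <- set_em(partition,
                        evenly_spaced_subset(panel, length(partition$tm),
                                             seed = derive_seed(seed, 101)))
  }
  if (!"y_c" %in% names(pheno)) pheno <- adjust_phenotype(pheno)
  folds <- kfold_assign(panel$samples, k, seed)
  cache <- new.env(parent = emptyenv())
  details <- lapply(models, function(mlab) {
    cv_accuracy(panel, pheno, partition, mlab, folds = folds,
                varcomp_policy = varcomp_policy, grm_cache = cache)
  })
  names(details) <- models
  out <- data.frame(model = models,
                    mean_r = vapply(details, `[[`, 0, "mean_r"),
                    se = vapply(details, `[[`, 0, "se"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "details") <- details
  attr(out, "folds") <- folds
  out
}
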