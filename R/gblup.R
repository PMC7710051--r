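#' Build an incidence matrix mapping records to individuals
#'
#' One row per phenotype record, one column per individual in the GRM; each
#' row carries a single 1. Individuals without a phenotype record get an
#' all-zero column, which is exactly how unphenotyped (e.g. validation)
#' individuals enter the mixed-model equations and receive a GEBV through
#' their genomic relationships.
#'
#' @param record_ids Sample id per phenotype record.
#' @param all_ids Sample ids of the GRM, in GRM order.
#' @return A `length(record_ids)` x `length(all_ids)` 0/1 matrix.
#' @export
incidence_matrix <- function(record_ids, all_ids) {
  j <- match(record_ids, all_ids)
  if (anyNA(j)) {
    stop("record id(s) not among GRM individuals: ",
         paste(head(record_ids[is.na(j)], 5), collapse = ", "), call. = FALSE)
  }
  Z <- matrix(0, length(record_ids), length(all_ids),
              dimnames = list(NULL, all_ids))
  Z[cbind(seq_along(j), j)] <- 1
  Z
}

## Coerce components argument: list of list(G=, lambda=) (solve_mme) or
## list(G=, sigma2=) (oracle). Returns matrices, names and weights.
parse_components <- function(components, weight_field) {
  if (!is.null(components$G)) components <- list(components)
  if (!length(components) || length(components) > 2) {
    stop("between 1 and 2 genomic components are supported", call. = FALSE)
  }
  nms <- names(components)
  if (is.null(nms)) nms <- rep("", length(components))
  out <- lapply(seq_along(components), function(k) {
    comp <- components[[k]]
    w <- comp[[weight_field]]
    if (is.null(w) || !is.finite(w) || w <= 0) {
      stop("component ", k, ": `", weight_field, "` must be positive",
           call. = FALSE)
    }
    nm <- if (nzchar(nms[k])) {
      nms[k]
    } else if (inherits(comp$G, "grm")) {
      comp$G$set_name
    } else {
      paste0("g", k)
    }
    list(mat = grm_matrix(comp$G), grm = comp$G, weight = w, name = nm,
         Ginv = comp$Ginv)
  })
  names(out) <- make.unique(vapply(out, `[[`, "", "name"))
  out
}

#' Solve the GBLUP mixed-model equations
#'
#' Solves, for one genomic component,
#' \deqn{[X'X, X'Z; Z'X, Z'Z + \lambda G^{-1}] [b; u] = [X'y; Z'y]}
#' and, for two components, the analogous 3-block system with
#' `Z'Z + lambda_k G_k^-1` on the diagonal and `Z'Z` off-diagonal, where
#' `lambda_k = sigma2_E / sigma2_k`. Unphenotyped individuals enter via
#' all-zero `Z` columns and receive GEBVs through `G`. The combined GEBV is
#' the sum of the per-component solutions.
#'
#' @param y Phenotype record vector.
#' @param X Fixed-effect design matrix (records x effects, full rank); a
#'   single intercept column if `NULL`.
#' @param Z Incidence matrix (records x individuals), e.g. from
#'   [incidence_matrix()]; identity if `NULL`.
#' @param components One component `list(G = , lambda = )` or a (optionally
#'   named) list of up to two such components. A component may carry a
#'   precomputed `Ginv` (e.g. when solving many folds against the same
#'   GRM); otherwise the inverse is computed here.
#' @return Object of class `mme_fit`: `beta`, `u` (named list per
#'   component), `gebv` (named vector over all individuals), `lambda`,
#'   `samples`, `residual_norm` (relative normal-equation residual).
#' @export
solve_mme <- function(y, X = NULL, Z = NULL, components) {
  comps <- parse_components(components, "lambda")
  nrec <- length(y)
  if (is.null(X)) X <- matrix(1, nrec, 1)
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("X is not full column rank", call. = FALSE)
  N <- nrow(comps[[1]]$mat)
  if (is.null(Z)) Z <- diag(1, nrec, N)
  Z <- as.matrix(Z)
  stopifnot(nrow(X) == nrec, nrow(Z) == nrec, ncol(Z) == N)

  p <- ncol(X)
  nk <- length(comps)
  XtX <- crossprod(X)
  XtZ <- crossprod(X, Z)
  ZtZ <- crossprod(Z)
  Xty <- crossprod(X, y)
  Zty <- crossprod(Z, y)

  dim_c <- p + nk * N
  C <- matrix(0, dim_c, dim_c)
  rhs <- numeric(dim_c)
  C[1:p, 1:p] <- XtX
  rhs[1:p] <- Xty
  for (k in seq_len(nk)) {
    rows <- p + (k - 1) * N + seq_len(N)
    C[1:p, rows] <- XtZ
    C[rows, 1:p] <- t(XtZ)
    rhs[rows] <- Zty
    Ginv <- comps[[k]]$Ginv %||% grm_inverse(comps[[k]]$grm)
    C[rows, rows] <- ZtZ + comps[[k]]$weight * Ginv
  }
  if (nk == 2) {
    r1 <- p + seq_len(N)
    r2 <- p + N + seq_len(N)
    C[r1, r2] <- ZtZ
    C[r2, r1] <- ZtZ
  }

  sol <- tryCatch({
    R <- chol(C)
    backsolve(R, backsolve(R, rhs, transpose = TRUE))
  }, error = function(e) {
    tryCatch(solve(C, rhs), error = function(e2) {
      stop("mixed-model coefficient matrix is singular (random-effect block)",
           call. = FALSE)
    })
  })
  ## one step of iterative refinement for a tight normal-equation residual
  r <- rhs - C %*% sol
  sol <- sol + tryCatch(solve(C, r), error = function(e) 0)
  resid_rel <- sqrt(sum((rhs - C %*% sol)^2)) / max(sqrt(sum(rhs^2)),
                                                    .Machine$double.eps)

  beta <- sol[1:p]
  u <- lapply(seq_len(nk), function(k) {
    rows <- p + (k - 1) * N + seq_len(N)
    setNames(sol[rows], colnames(Z))
  })
  names(u) <- names(comps)
  gebv <- Reduce(`+`, u)
  structure(list(beta = beta, u = u, gebv = gebv,
                 lambda = setNames(vapply(comps, `[[`, 0, "weight"),
                                   names(comps)),
                 samples = colnames(Z) %||% as.character(seq_len(N)),
                 residual_norm = resid_rel),
            class = "mme_fit")
}

#' @export
print.mme_fit <- function(x, ...) {
  cat("mme_fit:", length(x$gebv), "individuals,",
      length(x$u), "genomic component(s); lambda =",
      paste(signif(x$lambda, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Direct GLS/BLUP oracle
#'
#' Computes the identical quantities as [solve_mme()] by the generalized
#' least squares route: `V = sum_k sigma2_k Z G_k Z' + sigma2_E I`,
#' `b = (X'V^-1X)^-1 X'V^-1 y`, `u_k = sigma2_k G_k Z' V^-1 (y - Xb)`.
#' Dense and O(n^3) in the record count — intended as an independent
#' correctness oracle on small instances, not for production use.
#'
#' @inheritParams solve_mme
#' @param components One `list(G = , sigma2 = )` or a list of up to two.
#' @param sigma2e Residual variance (positive).
#' @return An `mme_fit` (with `lambda = sigma2e / sigma2_k`).
#' @export
gls_blup_oracle <- function(y, X = NULL, Z = NULL, components, sigma2e) {
  check_scalar(sigma2e, "sigma2e", lower = 0, open_lower = TRUE)
  comps <- parse_components(components, "sigma2")
  nrec <- length(y)
  if (is.null(X)) X <- matrix(1, nrec, 1)
  X <- as.matrix(X)
  N <- nrow(comps[[1]]$mat)
  if (is.null(Z)) Z <- diag(1, nrec, N)
  Z <- as.matrix(Z)

  V <- diag(sigma2e, nrec)
  for (k in seq_along(comps)) {
    V <- V + comps[[k]]$weight * (Z %*% comps[[k]]$mat %*% t(Z))
  }
  R <- tryCatch(chol(V), error = function(e) {
    stop("V is not positive definite", call. = FALSE)
  })
  Vi <- chol2inv(R)
  ViX <- Vi %*% X
  beta <- drop(solve(crossprod(X, ViX), crossprod(ViX, y)))
  resid <- y - X %*% beta
  Vir <- Vi %*% resid
  u <- lapply(comps, function(cp) {
    setNames(drop(cp$weight * cp$mat %*% crossprod(Z, Vir)), colnames(Z))
  })
  names(u) <- names(comps)
  gebv <- Reduce(`+`, u)
  structure(list(beta = beta, u = u, gebv = gebv,
                 lambda = setNames(sigma2e / vapply(comps, `[[`, 0, "weight"),
                                   names(comps)),
                 samples = colnames(Z) %||% as.character(seq_len(ncol(Z))),
                 residual_norm = NA_real_),
            class = "mme_fit")
}

#' Extract validation GEBVs from a fitted model
#'
#' Returns the GEBVs of the requested individuals, in the requested order.
#' Their `Z` columns must have been zero during fitting for this to be an
#' honest out-of-sample prediction (the function does not re-check that).
#'
#' @param fit An `mme_fit`.
#' @param validation_ids Sample ids (possibly empty).
#' @return Named numeric vector of GEBVs.
#' @export
predict_validation <- function(fit, validation_ids) {
  stopifnot(inherits(fit, "mme_fit"))
  if (!length(validation_ids)) return(setNames(numeric(0), character(0)))
  j <- match(validation_ids, fit$samples)
  if (anyNA(j)) {
    stop("id(s) not in fitted GRM: ",
         paste(head(validation_ids[is.na(j)], 5), collapse = ", "),
         call. = FALSE)
  }
  setNames(fit$gebv[j], validation_ids)
}
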