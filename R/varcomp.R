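## Coerce the Gs argument (one or two genomic covariance structures) to a
## named list of plain matrices.
as_G_list <- function(Gs) {
  if (inherits(Gs, "grm") || is.matrix(Gs)) Gs <- list(Gs)
  if (!length(Gs) || length(Gs) > 2) {
    stop("between 1 and 2 genomic components are supported", call. = FALSE)
  }
  nms <- names(Gs)
  if (is.null(nms)) nms <- rep("", length(Gs))
  mats <- lapply(seq_along(Gs), function(k) {
    if (!nzchar(nms[k])) {
      nms[k] <<- if (inherits(Gs[[k]], "grm")) Gs[[k]]$set_name else paste0("g", k)
    }
    grm_matrix(Gs[[k]])
  })
  names(mats) <- make.unique(nms)
  mats
}

#' Restricted log-likelihood of a variance-component model
#'
#' Evaluates the REML log-likelihood (up to the model-free constant)
#' `-0.5 * (log|V| + log|X'V^-1 X| + y' P y)` for
#' `V = sum_k sigma2_k G_k + sigma2_E I`, with `P` the REML projection
#' matrix. Computed via Cholesky factorizations, never explicit inverses.
#'
#' @param y Numeric response vector (no missing values).
#' @param X Fixed-effect design matrix (full column rank); a single
#'   intercept column if `NULL`.
#' @param Gs One genomic covariance structure ([build_grm()] result or
#'   matrix) or a list of up to two.
#' @param params Variance vector: one value per genomic component followed
#'   by the residual variance.
#' @return Scalar restricted log-likelihood.
#' @export
reml_loglik <- function(y, X = NULL, Gs, params) {
  mats <- as_G_list(Gs)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (length(params) != length(mats) + 1L) {
    stop("`params` must have one entry per genomic component plus residual",
         call. = FALSE)
  }
  V <- diag(params[length(params)], n)
  for (k in seq_along(mats)) V <- V + params[k] * mats[[k]]
  R <- tryCatch(chol(V), error = function(e) {
    stop("V is not positive definite at params = (",
         paste(signif(params, 6), collapse = ", "), ")", call. = FALSE)
  })
  ldV <- 2 * sum(log(diag(R)))
  Vi_y <- backsolve(R, backsolve(R, y, transpose = TRUE))
  Vi_X <- backsolve(R, backsolve(R, X, transpose = TRUE))
  XtViX <- crossprod(X, Vi_X)
  ldX <- determinant(XtViX, logarithm = TRUE)$modulus
  XtViy <- crossprod(X, Vi_y)
  yPy <- sum(y * Vi_y) - sum(XtViy * solve(XtViX, XtViy))
  as.numeric(-0.5 * (ldV + ldX + yPy))
}

#' Average-information REML for one or two genomic components
#'
#' Maximizes the restricted likelihood of
#' `y = X b + sum_k g_k + e`, `g_k ~ N(0, G_k sigma2_k)`,
#' `e ~ N(0, I sigma2_E)` by average-information (AI) updates with
#' step-halving and an EM fallback whenever an AI step proposes a negative
#' component or a likelihood decrease. Components that collapse are pinned
#' to a small floor (`1e-8 * var(y)`), and the convergence flag is honest:
#' hitting `max_iter` returns the best estimate with `converged = FALSE`
#' rather than an error.
#'
#' Initialization: the residual takes half the phenotypic variance of `y`
#' after fixed-effect projection, and the genomic components split the
#' other half equally.
#'
#' @inheritParams reml_loglik
#' @param init Optional starting variance vector (genomic components then
#'   residual).
#' @param tol_loglik Stop when the log-likelihood change is below this
#'   (default 1e-8).
#' @param tol_param Stop when the max relative parameter change is below
#'   this (default 1e-6).
#' @param max_iter Iteration cap (default 200).
#' @return Object of class `varcomp_fit`: `varcomp` (named genomic
#'   variances), `sigma2e`, `loglik`, `iterations`, `converged`, `se`
#'   (approximate standard errors from the inverse AI matrix), `history`.
#' @export
aireml <- function(y, X = NULL, Gs, init = NULL,
                   tol_loglik = 1e-8, tol_param = 1e-6, max_iter = 200) {
  mats <- as_G_list(Gs)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("X is not full column rank", call. = FALSE)
  nk <- length(mats)
  floor_v <- 1e-8 * var(y)

  if (is.null(init)) {
    r <- resid(lm.fit(X, y))
    v <- var(r)
    init <- c(rep(v / 2 / nk, nk), v / 2)
  }
  theta <- pmax(as.numeric(init), floor_v)

  ## Full covariance structures including the residual (identity) component.
  structs <- c(mats, list(diag(1, n)))

  eval_ll <- function(th) {
    tryCatch(reml_loglik(y, X, mats, th), error = function(e) -Inf)
  }

  ll <- eval_ll(theta)
  if (!is.finite(ll)) stop("initial parameter vector gives singular V",
                           call. = FALSE)
  ll_init <- ll
  history <- numeric(0)
  converged <- FALSE
  AI <- NULL
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    ## V, P, Py at current theta
    V <- diag(theta[nk + 1], n)
    for (k in seq_len(nk)) V <- V + theta[k] * mats[[k]]
    R <- chol(V)
    Vi <- chol2inv(R)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    P <- Vi - ViX %*% solve(XtViX, t(ViX))
    Py <- drop(P %*% y)

    ## score and AI matrix over all components (genomic + residual)
    U <- vapply(structs, function(S) drop(S %*% Py), numeric(n))
    score <- vapply(seq_len(nk + 1), function(k) {
      -0.5 * (sum(P * structs[[k]]) - sum(Py * U[, k]))
    }, 0)
    AI <- 0.5 * crossprod(U, P %*% U)

    ## active-set handling of the boundary: a component sitting at the
    ## floor with a downhill gradient is pinned there; updating it would
    ## only make EM creep (its update is damped by theta^2 near zero)
    pinned <- theta <= floor_v * (1 + 1e-8) & score < 0
    active <- which(!pinned)
    if (!length(active)) {
      converged <- TRUE
      history <- c(history, ll)
      break
    }

    delta <- tryCatch({
      d <- numeric(nk + 1)
      d[active] <- solve(AI[active, active, drop = FALSE], score[active])
      d
    }, error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(delta)) {
      step <- 1
      for (h in seq_len(8)) {
        cand <- pmax(theta + step * delta, floor_v)
        ll_new <- eval_ll(cand)
        if (is.finite(ll_new) && ll_new >= ll - 1e-10) {
          theta_new <- cand
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
    }
    if (!accepted) {
      ## EM fallback on the active components: guaranteed-ascent update
      em <- theta
      em[active] <- theta[active] + theta[active]^2 *
        vapply(active, function(k) {
          (sum(Py * U[, k]) - sum(P * structs[[k]])) / n
        }, 0)
      theta_new <- pmax(em, floor_v)
      ll_new <- eval_ll(theta_new)
      if (!is.finite(ll_new) || ll_new < ll - 1e-6) {
        ## no usable move: stop here
        history <- c(history, ll)
        break
      }
    }

    rel_change <- max(abs(theta_new - theta)[active] /
                        pmax(theta[active], floor_v))
    ll_change <- ll_new - ll
    theta <- theta_new
    ll <- ll_new
    history <- c(history, ll)
    if (rel_change < tol_param || abs(ll_change) < tol_loglik) {
      converged <- TRUE
      break
    }
  }

  se <- tryCatch(sqrt(diag(solve(AI))), error = function(e) rep(NA_real_, nk + 1))
  vc <- setNames(unname(theta[seq_len(nk)]), names(mats))
  structure(list(varcomp = vc, sigma2e = unname(theta[nk + 1]),
                 loglik = ll, loglik_init = ll_init,
                 iterations = iter, converged = converged,
                 se = setNames(se, c(names(mats), "residual")),
                 floor = floor_v, history = history,
                 n = n),
            class = "varcomp_fit")
}

#' @export
print.varcomp_fit <- function(x, ...) {
  cat("varcomp_fit (AI-REML):", if (x$converged) "converged" else
    "NOT converged", "in", x$iterations, "iterations\n")
  comps <- c(x$varcomp, residual = x$sigma2e)
  out <- data.frame(component = names(comps), estimate = as.numeric(comps),
                    se = as.numeric(x$se))
  print(out, row.names = FALSE)
  cat(sprintf("restricted logLik: %.4f\n", x$loglik))
  invisible(x)
}

#' Heritability under the three genomic models
#'
#' Model 1 (all SNPs, one GRM) and model 2 (feature-excluded panel, one GRM)
#' share the formula `h2 = sigma2_g / (sigma2_g + sigma2_E)`; model 3 (two
#' GRMs) uses `h2 = (sigma2_t + sigma2_-t) / (sigma2_t + sigma2_-t +
#' sigma2_E)`. The model number determines how many genomic components must
#' be present. Reported tables conventionally round half-away-from-zero to
#' two decimals; set `rounded = TRUE` for that form.
#'
#' @param est A [aireml()] fit, or a list `list(genetic = c(...),
#'   residual = )` of raw variance components.
#' @param model Genomic model: 1, 2 or 3.
#' @param rounded Return the 2-decimal half-away-from-zero rounding
#'   (default `FALSE` = full precision).
#' @return Heritability in \[0, 1\].
#' @export
#' @examples
#' heritability(list(genetic = 913.66, residual = 1287.6), model = 1,
#'              rounded = TRUE) # 0.42
heritability <- function(est, model, rounded = FALSE) {
  if (!model %in% 1:3) stop("model must be 1, 2 or 3", call. = FALSE)
  if (inherits(est, "varcomp_fit")) {
    genetic <- est$varcomp
    residual <- est$sigma2e
  } else if (is.list(est) && !is.null(est$genetic)) {
    genetic <- est$genetic
    residual <- est$residual
  } else {
    stop("`est` must be a varcomp_fit or list(genetic=, residual=)",
         call. = FALSE)
  }
  need <- if (model == 3) 2L else 1L
  if (length(genetic) != need) {
    stop(sprintf("model %d requires %d genomic component(s), got %d",
                 model, need, length(genetic)), call. = FALSE)
  }
  if (is.null(residual) || !is.finite(residual)) {
    stop("residual variance missing", call. = FALSE)
  }
  g <- sum(genetic)
  h2 <- if (g + residual <= 0) 0 else g / (g + residual)
  if (rounded) round_half_up(h2, 2) else h2
}
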