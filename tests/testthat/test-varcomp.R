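test_that("restricted log-likelihood matches a brute-force evaluation", {
  ## independent dense evaluation with determinant() and solve()
  set.seed(3)
  n <- 6
  G <- block_G(6, bs = 3, rho = 0.4)
  y <- c(1.2, -0.5, 0.3, 2.0, -1.1, 0.4)
  X <- cbind(1, c(0, 1, 0, 1, 0, 1))
  params <- c(1.3, 0.7)
  V <- params[1] * G + params[2] * diag(n)
  Vi <- solve(V)
  P <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi
  expected <- -0.5 * (as.numeric(determinant(V)$modulus) +
                        as.numeric(determinant(t(X) %*% Vi %*% X)$modulus) +
                        drop(t(y) %*% P %*% y))
  expect_equal(reml_loglik(y, X, list(G), params), expected,
               tolerance = 1e-10)
})

test_that("with G = I the likelihood is constant along the variance ridge", {
  set.seed(4)
  y <- rnorm(12)
  total <- 2.5
  lls <- vapply(seq(0.2, 2.2, by = 0.5), function(a) {
    reml_loglik(y, NULL, list(diag(12)), c(a, total - a))
  }, 0)
  expect_lt(max(lls) - min(lls), 1e-9)
})

test_that("scaling the phenotype scales the variance estimates by c^2", {
  G <- block_G(100)
  y <- draw_gaussian_pheno(G, 2, 1, seed = 5)
  f1 <- aireml(y, NULL, list(G))
  f2 <- aireml(3 * y, NULL, list(G))
  expect_equal(unname(f2$varcomp), unname(9 * f1$varcomp), tolerance = 1e-4)
  expect_equal(f2$sigma2e, 9 * f1$sigma2e, tolerance = 1e-4)
})

test_that("accepted AI-REML iterations never decrease the likelihood", {
  for (s in 1:5) {
    G <- block_G(80)
    y <- draw_gaussian_pheno(G, runif(1, 0.5, 3), runif(1, 0.5, 3), seed = s)
    f <- aireml(y, NULL, list(G))
    expect_gte(f$loglik, f$loglik_init - 1e-8)
    expect_true(all(diff(f$history) > -1e-6))
  }
})

test_that("estimates are invariant to a joint permutation of individuals", {
  G <- block_G(60)
  y <- draw_gaussian_pheno(G, 1.5, 1, seed = 7)
  X <- cbind(1, rnorm(60))
  f1 <- aireml(y, X, list(G))
  set.seed(8)
  perm <- sample(60)
  f2 <- aireml(y[perm], X[perm, ], list(G[perm, perm]))
  expect_equal(unname(f1$varcomp), unname(f2$varcomp), tolerance = 1e-6)
  expect_equal(f1$sigma2e, f2$sigma2e, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("two identical GRMs recover the one-GRM total on the summed scale", {
  sim <- simulate_genotypes(150, 600, seed = 17)
  G <- build_grm(sim$panel)
  part <- snp_partition(sim$panel$map$id, tm = 1:300)
  ph <- simulate_phenotype(sim$panel, part,
                           architecture_spec(h2 = 0.5, n_qtl = 80, f_tm = 0.5,
                                             fixed = list()), seed = 18)
  f1 <- aireml(ph$pheno$y, NULL, list(all = G))
  f3 <- aireml(ph$pheno$y, NULL, list(a = G, b = G))
  expect_equal(sum(f3$varcomp), sum(f1$varcomp), tolerance = 0.01)
  expect_equal(f3$sigma2e, f1$sigma2e, tolerance = 0.01)
})

test_that("a zero-heritability phenotype drives the genomic variance to the floor", {
  hits <- 0
  G <- block_G(500, bs = 10, rho = 0.8)
  for (s in 1:10) {
    set.seed(s + 400)
    y <- rnorm(500) # pure noise
    f <- aireml(y, NULL, list(G))
    if (f$varcomp[1] < 0.05 * var(y)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("heritability applies the three model formulas and validates input", {
  expect_equal(heritability(list(genetic = 913.66, residual = 1287.6), 1,
                            rounded = TRUE), 0.42)
  expect_equal(heritability(list(genetic = c(0.07, 0.04), residual = 0.55), 3,
                            rounded = TRUE), 0.17)
  expect_equal(heritability(list(genetic = 0, residual = 1), 2), 0)
  ## component-count contract per model
  expect_error(heritability(list(genetic = c(1, 2), residual = 1), 1),
               "requires 1")
  expect_error(heritability(list(genetic = 1, residual = 1), 3), "requires 2")
  ## from a fitted object
  G <- block_G(50)
  f <- aireml(draw_gaussian_pheno(G, 2, 1, seed = 11), NULL, list(G))
  h <- heritability(f, 1)
  expect_gte(h, 0)
  expect_lte(h, 1)
  ## half-away-from-zero rounding
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
})
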