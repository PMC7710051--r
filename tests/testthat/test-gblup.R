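test_that("the 3x3 hand-solved system is reproduced exactly", {
  fit <- solve_mme(c(1, -1), components = list(G = diag(2), lambda = 1))
  expect_equal(fit$beta, 0, tolerance = 1e-12)
  expect_equal(unname(fit$gebv), c(0.5, -0.5), tolerance = 1e-12)
})

test_that("MME and GLS-BLUP agree on random instances", {
  for (s in 1:6) {
    inst <- random_mme_instance(s, two_components = s %% 2 == 0)
    fits <- fit_both_routes(inst)
    expect_lt(max_rel_diff(fits$mme$beta, fits$gls$beta), 1e-8)
    for (k in seq_along(fits$mme$u)) {
      expect_lt(max_rel_diff(fits$mme$u[[k]], fits$gls$u[[k]]), 1e-8)
    }
  }
})

test_that("unphenotyped individuals get propagated GEBVs, identically by both routes", {
  inst <- random_mme_instance(31, two_components = TRUE, n_unphenotyped = 4)
  fits <- fit_both_routes(inst)
  unph <- inst$samples[-inst$phen_idx]
  expect_lt(max(abs(predict_validation(fits$mme, unph) -
                      predict_validation(fits$gls, unph))), 1e-8)
  ## a nonzero prediction flows through G for related individuals
  expect_gt(max(abs(predict_validation(fits$mme, unph))), 0)
})

test_that("infinite shrinkage recovers OLS and kills the random effect", {
  set.seed(21)
  n <- 40
  sim <- simulate_genotypes(n, 200, seed = 44)
  G <- regularize_grm(build_grm(sim$panel), 0.95)
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  fit <- solve_mme(y, X, NULL, list(G = G, lambda = 1e8))
  expect_lt(sqrt(sum(fit$gebv^2)), 1e-6 * sqrt(sum(y^2)))
  ols <- coef(lm(y ~ X - 1))
  expect_equal(unname(fit$beta), unname(ols), tolerance = 1e-6)
})

test_that("a floored second component reduces the two-GRM model to one GRM", {
  set.seed(22)
  n <- 80
  sim <- simulate_genotypes(n, 400, seed = 45)
  Ga <- regularize_grm(build_grm(sim$panel, 1:300, "a"), 0.95)
  Gb <- regularize_grm(build_grm(sim$panel, 301:400, "b"), 0.95)
  y <- rnorm(n)
  one <- solve_mme(y, NULL, NULL, list(G = Ga, lambda = 2))
  two <- solve_mme(y, NULL, NULL, list(list(G = Ga, lambda = 2),
                                       list(G = Gb, lambda = 1e9)))
  expect_lt(max(abs(one$gebv - two$gebv)), 1e-5)
  ## the combined GEBV is exactly the sum of the component solutions
  expect_equal(two$gebv, two$u[[1]] + two$u[[2]], tolerance = 1e-12)
})

test_that("adding a constant shifts the intercept only", {
  inst <- random_mme_instance(23)
  comps <- list(G = inst$comps[[1]], lambda = inst$sigma2e / inst$sigma2[1])
  f0 <- solve_mme(inst$y, inst$X, inst$Z, comps)
  f1 <- solve_mme(inst$y + 7, inst$X, inst$Z, comps)
  expect_equal(f1$beta[1], f0$beta[1] + 7, tolerance = 1e-8)
  expect_equal(f1$beta[-1], f0$beta[-1], tolerance = 1e-8)
  expect_lt(max(abs(f1$gebv - f0$gebv)), 1e-8)
})

test_that("the GEBV norm shrinks monotonically in lambda", {
  for (s in 1:10) {
    inst <- random_mme_instance(s + 600)
    norms <- vapply(c(0.5, 2, 8, 32, 128), function(lam) {
      f <- solve_mme(inst$y, inst$X, inst$Z,
                     list(G = inst$comps[[1]], lambda = lam))
      sqrt(sum(f$gebv^2))
    }, 0)
    expect_true(all(diff(norms) <= 1e-10))
  }
})

test_that("a single record with an intercept is absorbed by the fixed effect", {
  fit <- solve_mme(3.5, components = list(G = matrix(1), lambda = 2))
  expect_equal(fit$beta, 3.5, tolerance = 1e-10)
  expect_equal(unname(fit$gebv), 0, tolerance = 1e-10)
})

test_that("predict_validation honors order and rejects unknown ids", {
  inst <- random_mme_instance(25)
  fit <- fit_both_routes(inst)$mme
  ids <- inst$samples[c(5, 2, 9)]
  expect_identical(names(predict_validation(fit, ids)), ids)
  expect_equal(unname(predict_validation(fit, rev(ids))),
               rev(unname(predict_validation(fit, ids))))
  expect_length(predict_validation(fit, character(0)), 0)
  expect_error(predict_validation(fit, "nobody"), "not in fitted")
})

test_that("validation GEBVs track true breeding values when h2 is high", {
  sim <- simulate_genotypes(500, 400, seed = 71)
  part <- snp_partition(sim$panel$map$id, tm = 1:100)
  ph <- simulate_phenotype(sim$panel, part,
                           architecture_spec(h2 = 0.9, n_qtl = 200,
                                             f_tm = 0.25, fixed = list()),
                           seed = 72)
  G <- regularize_grm(build_grm(sim$panel), 0.95)
  val <- sim$panel$samples[401:500]
  train <- sim$panel$samples[1:400]
  Z <- incidence_matrix(train, sim$panel$samples)
  vc <- aireml(ph$pheno$y[1:400], NULL,
               list(G$mat[1:400, 1:400]))
  fit <- solve_mme(ph$pheno$y[1:400], NULL, Z,
                   list(G = G, lambda = vc$sigma2e / vc$varcomp[1]))
  r <- cor(predict_validation(fit, val), ph$truth$tbv[val])
  expect_gt(r, 0.5)
})
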