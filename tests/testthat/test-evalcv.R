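test_that("k-fold assignment balances sizes, is deterministic, partitions", {
  ids <- paste0("s", 1:103)
  f <- kfold_assign(ids, 10, seed = 2)
  expect_equal(sort(as.integer(table(f)), decreasing = TRUE),
               c(11L, 11L, 11L, rep(10L, 7)))
  expect_identical(f, kfold_assign(ids, 10, seed = 2))
  expect_setequal(names(f), ids)
  expect_setequal(unique(f), 1:10)
  expect_error(kfold_assign(ids[1:5], 10), "exceeds")
})

test_that("evenly spaced subsets follow the stride rule", {
  sim <- simulate_genotypes(10, 100, n_chrom = 2, seed = 61)
  idx <- evenly_spaced_subset(sim$panel, 10, seed = 3)
  expect_length(idx, 10)
  ## constant stride floor(M/count) = 10 from a fixed offset
  expect_equal(diff(idx), rep(10, 9))
  expect_gte(idx[1], 1)
  expect_lte(idx[10], 100)
  ## offset 0 reproduces map offsets {0, 10, ..., 90}
  idx0 <- idx - idx[1]
  expect_equal(idx0, seq(0, 90, by = 10))
  ## count = M selects everything
  expect_equal(evenly_spaced_subset(sim$panel, 100), 1:100)
  expect_error(evenly_spaced_subset(sim$panel, 0), "outside")
  ## attaching as the em control set
  part <- set_em(snp_partition(sim$panel$map$id, tm = 1:10), idx)
  expect_length(part$em, length(part$tm))
})

test_that("cross-validated accuracy approaches the upper limit when h2 is near 1", {
  sim <- simulate_genotypes(600, 150, n_chrom = 3, seed = 62)
  part <- snp_partition(sim$panel$map$id, tm = 1:50)
  ph <- simulate_phenotype(sim$panel, part,
                           architecture_spec(h2 = 0.98, n_qtl = 150,
                                             f_tm = 1 / 3, fixed = list()),
                           seed = 63)
  res <- cv_accuracy(sim$panel, ph$pheno, part, "Im", k = 10, seed = 64,
                     varcomp_policy = "global")
  expect_gt(res$mean_r, 0.9)
  expect_equal(res$se, sd(res$fold_r) / sqrt(10), tolerance = 1e-12)
})

test_that("a zero-heritability phenotype gives accuracy near zero", {
  sim <- simulate_genotypes(400, 300, seed = 65)
  part <- snp_partition(sim$panel$map$id, tm = 1:60)
  ph <- simulate_phenotype(sim$panel, part,
                           architecture_spec(h2 = 0, f_tm = 0,
                                             fixed = list()), seed = 66)
  res <- cv_accuracy(sim$panel, ph$pheno, part, "Im", k = 10, seed = 67,
                     varcomp_policy = "global")
  expect_lt(abs(res$mean_r), 2 * res$se + 0.1)
})

test_that("model comparisons share one fold assignment", {
  sim <- simulate_genotypes(200, 400, seed = 68)
  part <- snp_partition(sim$panel$map$id, tm = 1:80)
  ph <- simulate_phenotype(sim$panel, part,
                           architecture_spec(h2 = 0.5, n_qtl = 50,
                                             f_tm = 0.5, fixed = list()),
                           seed = 69)
  res <- compare_models(sim$panel, ph$pheno, part, k = 5, seed = 70,
                        models = c("Im", "exp", "exp+tm", "exp+em"),
                        varcomp_policy = "global")
  det <- attr(res, "details")
  for (d in det) expect_identical(d$folds, attr(res, "folds"))
  expect_equal(res$model, c("Im", "exp", "exp+tm", "exp+em"))
  expect_true(all(is.finite(res$mean_r)))
  ## determinism of the whole comparison
  res2 <- compare_models(sim$panel, ph$pheno, part, k = 5, seed = 70,
                         models = c("Im", "exp"), varcomp_policy = "global")
  expect_equal(res2$mean_r[1], res$mean_r[1], tolerance = 1e-10)
})

test_that("accuracy is invariant to a joint relabeling of samples", {
  sim <- simulate_genotypes(150, 300, seed = 71)
  part <- snp_partition(sim$panel$map$id, tm = 1:60)
  ph <- simulate_phenotype(sim$panel, part,
                           architecture_spec(h2 = 0.5, n_qtl = 40,
                                             f_tm = 0.5, fixed = list()),
                           seed = 72)
  folds <- kfold_assign(sim$panel$samples, 5, seed = 73)
  r1 <- cv_accuracy(sim$panel, ph$pheno, part, "Im", folds = folds,
                    varcomp_policy = "global")
  set.seed(74)
  perm <- sample(150)
  panel2 <- subset_panel(sim$panel, samples = perm)
  ph2 <- ph$pheno[perm, , drop = FALSE]
  attr(ph2, "covariates") <- attr(ph$pheno, "covariates")
  r2 <- cv_accuracy(panel2, ph2, part, "Im", folds = folds[perm],
                    varcomp_policy = "global")
  expect_equal(sort(r1$fold_r), sort(r2$fold_r), tolerance = 1e-6)
})
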