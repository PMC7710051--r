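test_that("phenotype adjustment is a projection that preserves scale", {
  set.seed(41)
  n <- 200
  site <- sample(c("A", "B"), n, replace = TRUE)
  y <- 10 + 5 * (site == "B") + rnorm(n)
  ph <- data.frame(id = paste0("s", 1:n), y = y, site = site,
                   stringsAsFactors = FALSE)
  attr(ph, "covariates") <- "site"
  class(ph) <- c("phenotype_table", "data.frame")
  adj <- adjust_phenotype(ph)
  ## planted offset removed within OLS error; variance reduced
  expect_lt(abs(mean(adj$y_c[adj$site == "B"]) -
                  mean(adj$y_c[adj$site == "A"])), 0.5)
  expect_lt(var(adj$y_c), var(y))
  expect_equal(mean(adj$y_c), mean(y), tolerance = 1e-10)
  ## idempotence
  again <- adjust_phenotype(adj)
  expect_equal(again$y_c, adj$y_c, tolerance = 1e-10)
  ## intercept-only adjustment is the identity
  ph0 <- ph
  attr(ph0, "covariates") <- character(0)
  expect_equal(adjust_phenotype(ph0)$y_c, y, tolerance = 1e-12)
  ## rank-deficient design names the aliased column
  ph2 <- ph
  ph2$site2 <- ph$site
  expect_error(adjust_phenotype(ph2, c("site", "site2")), "aliased.*site2")
})

test_that("LOCO GRMs are exact complements of the all-SNP GRM", {
  sim <- simulate_genotypes(50, 300, n_chrom = 2, seed = 51)
  loco <- loco_grm_set(sim$panel)
  expect_named(loco, c("chr1", "chr2"))
  g_all <- build_grm(sim$panel)
  for (ch in c("chr1", "chr2")) {
    g_c <- build_grm(sim$panel, which(sim$panel$map$chr == ch), ch)
    recon <- (loco[[ch]]$denom * loco[[ch]]$mat + g_c$denom * g_c$mat) /
      (loco[[ch]]$denom + g_c$denom)
    expect_lt(max(abs(recon - g_all$mat)), 1e-10)
    ## equals building the complement from scratch
    direct <- build_grm(sim$panel, which(sim$panel$map$chr != ch))
    expect_lt(max(abs(loco[[ch]]$mat - direct$mat)), 1e-10)
  }
  ## single chromosome has no complement
  one <- subset_panel(sim$panel, snps = which(sim$panel$map$chr == "chr1"))
  expect_error(loco_grm_set(one), "at least 2")
})

test_that("with zero genetic variance the scan reduces to simple regression", {
  set.seed(52)
  sim <- simulate_genotypes(120, 150, n_chrom = 2, seed = 53)
  yc <- rnorm(120)
  loco <- loco_grm_set(sim$panel)
  ## pass the OLS residual variance so standard errors are comparable
  cand <- which(sim$panel$map$chr == "chr2")[1:20]
  for (j in cand[1:5]) {
    d <- as.numeric(sim$panel$dosage[, j])
    ols <- summary(lm(yc ~ d))
    scan <- assoc_scan(yc, sim$panel, j, loco,
                       list(sigma2g = 0, sigma2e = ols$sigma^2))
    expect_equal(scan$beta, unname(coef(ols)["d", "Estimate"]),
                 tolerance = 1e-8)
    expect_equal(scan$se, unname(coef(ols)["d", "Std. Error"]),
                 tolerance = 1e-8)
  }
})

test_that("significance thresholds follow the Bonferroni rule", {
  thr <- significance_thresholds(17662)
  expect_equal(thr$significant, 0.05 / 17662)
  expect_equal(thr$significant, 2.83e-6, tolerance = 1e-3)
  expect_equal(significance_thresholds(1),
               list(significant = 0.05, suggestive = 0.1))
  for (m in c(10, 1000, 17662)) {
    thr <- significance_thresholds(m)
    expect_equal(thr$suggestive / thr$significant, 2)
  }
  expect_error(significance_thresholds(0), "outside")
})

test_that("the scan is invariant to candidate order and flags monomorphics", {
  sim <- simulate_genotypes(80, 200, n_chrom = 2, seed = 54)
  ## force one monomorphic candidate
  sim$panel$dosage[, 150] <- 1L
  yc <- rnorm(80)
  loco <- loco_grm_set(sim$panel)
  vc <- list(sigma2g = 0.3, sigma2e = 0.7)
  cand <- which(sim$panel$map$chr == "chr2")[40:70] # includes the monomorphic SNP
  s1 <- assoc_scan(yc, sim$panel, cand, loco, vc)
  s2 <- assoc_scan(yc, sim$panel, rev(cand), loco, vc)
  expect_equal(s1$p, s2$p[match(s1$snp, s2$snp)])
  mono_row <- s1[s1$snp == sim$panel$map$id[150], ]
  expect_true(mono_row$monomorphic)
  expect_true(is.na(mono_row$beta))
})

test_that("permuting the phenotype destroys a planted QTL signal", {
  sim <- simulate_genotypes(300, 600, n_chrom = 2, seed = 55)
  chr2 <- which(sim$panel$map$chr == "chr2")
  part <- snp_partition(sim$panel$map$id, tm = chr2[1:10])
  ph <- simulate_phenotype(sim$panel, part,
                           architecture_spec(h2 = 0.4, n_qtl = 10, f_tm = 1,
                                             fixed = list()), seed = 56)
  loco <- loco_grm_set(sim$panel)
  yc <- ph$pheno$y - mean(ph$pheno$y)
  vc <- aireml(yc, NULL, list(loco[["chr2"]]))
  obs <- assoc_scan(yc, sim$panel, chr2, loco, vc)
  thr <- -log10(attr(obs, "thresholds")$significant)
  expect_gt(max(obs$neglog10p), thr) # signal present
  exceed <- 0
  set.seed(57)
  for (i in 1:20) {
    sp <- assoc_scan(sample(yc), sim$panel, chr2, loco, vc)
    if (max(sp$neglog10p) > thr) exceed <- exceed + 1
  }
  expect_lte(exceed, 1) # >= 95% of permutations below threshold
})
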