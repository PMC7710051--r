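## Shared fixture builders. Everything is generated in code at test time.

## A tiny hand-specified panel: n individuals x m SNPs on one chromosome.
toy_panel <- function(dosage, chr = "chr1") {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  genotype_panel(dosage,
                 data.frame(id = paste0("rs", seq_len(m)), chr = chr,
                            pos = seq_len(m) * 100, a1 = "A", a2 = "B",
                            stringsAsFactors = FALSE),
                 samples = paste0("s", seq_len(nrow(dosage))))
}

toy_lexicon <- function() {
  gene_lexicon(c("SCD", "CAST", "IGF1", "MSC", "MSTN", "LEP", "DGAT1",
                 "CAPN1", "FABP4", "PPARG"),
               aliases = c(GDF8 = "MSTN"))
}

## Block-diagonal family relationship matrix (always positive definite).
block_G <- function(n, bs = 10, rho = 0.5) {
  stopifnot(n %% bs == 0)
  B <- matrix(rho, bs, bs)
  diag(B) <- 1
  G <- matrix(0, n, n)
  for (b in seq_len(n / bs)) {
    i <- (b - 1) * bs + seq_len(bs)
    G[i, i] <- B
  }
  G
}

## Draw y = mu + g + e with g ~ N(0, s2g * G), e ~ N(0, s2e * I).
draw_gaussian_pheno <- function(G, s2g, s2e, mu = 0, seed = 1) {
  set.seed(seed)
  n <- nrow(G)
  R <- chol(G)
  mu + drop(crossprod(R, rnorm(n))) * sqrt(s2g) + rnorm(n, 0, sqrt(s2e))
}

## Random small GBLUP instance with regularized (hence invertible) GRMs,
## optionally with unphenotyped individuals (zero Z columns).
random_mme_instance <- function(seed, two_components = FALSE,
                                n_unphenotyped = 0) {
  set.seed(seed)
  N <- sample(30:120, 1)
  m <- sample(150:300, 1)
  sim <- simulate_genotypes(N, m, n_chrom = 2, seed = seed + 5000)
  half <- floor(m / 2)
  comps <- if (two_components) {
    list(g1 = regularize_grm(build_grm(sim$panel, 1:half, "g1"), 0.95),
         g2 = regularize_grm(build_grm(sim$panel, (half + 1):m, "g2"), 0.95))
  } else {
    list(g1 = regularize_grm(build_grm(sim$panel, NULL, "g1"), 0.95))
  }
  phen_idx <- seq_len(N - n_unphenotyped)
  Z <- incidence_matrix(sim$panel$samples[phen_idx], sim$panel$samples)
  X <- cbind(1, rnorm(length(phen_idx)))
  y <- rnorm(length(phen_idx), sd = 2)
  sigma2 <- runif(length(comps), 0.3, 3)
  sigma2e <- runif(1, 0.3, 3)
  list(y = y, X = X, Z = Z, comps = comps, sigma2 = sigma2,
       sigma2e = sigma2e, samples = sim$panel$samples, phen_idx = phen_idx)
}

## Run solve_mme and gls_blup_oracle on the same instance; return both fits.
fit_both_routes <- function(inst) {
  mme_comps <- lapply(seq_along(inst$comps), function(k) {
    list(G = inst$comps[[k]], lambda = inst$sigma2e / inst$sigma2[k])
  })
  gls_comps <- lapply(seq_along(inst$comps), function(k) {
    list(G = inst$comps[[k]], sigma2 = inst$sigma2[k])
  })
  list(mme = solve_mme(inst$y, inst$X, inst$Z, mme_comps),
       gls = gls_blup_oracle(inst$y, inst$X, inst$Z, gls_comps,
                             inst$sigma2e))
}

max_rel_diff <- function(a, b) {
  max(abs(a - b)) / max(max(abs(b)), 1e-12)
}
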