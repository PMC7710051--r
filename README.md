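# tmgblup

Genomic prediction with literature-derived, feature-partitioned SNP
panels.

Breeders using GBLUP treat every marker identically: one genomic
relationship matrix (GRM), one variance component. When prior biological
knowledge suggests a subset of SNPs sits closer to causal variants — for
example SNPs in genes that published studies repeatedly associate with a
trait — fitting that subset as its *own* random effect lets the model
weight it differently, via the shrinkage ratio
λ<sub>k</sub> = σ²<sub>E</sub>/σ²<sub>k</sub> applied to each GRM in the
mixed-model equations. `tmgblup` implements the full workflow for
quantitative geneticists working with livestock-style data:

* **Text mining** — extract gene symbols from an abstract corpus by a
  deterministic dictionary rule (all-caps tokens matched against a
  lexicon, lowercase homographs like "impact" or "pigs" never match) and
  map mined genes, plus their intergenic flanks, onto a SNP panel,
  splitting it into feature (`tm`) and complement (`exp`) sets.
* **GRMs** — VanRaden relationship matrices
  G = MM′ / 2Σp<sub>j</sub>(1−p<sub>j</sub>) for arbitrary SNP subsets,
  with QC (MAF and call-rate filters), exact disjoint-set recombination,
  and regularized inversion.
* **Variance components** — average-information REML (with EM fallback
  and an honest convergence flag) for one or two genomic components, and
  the heritability formulas of the three genomic models:
  h² = σ²<sub>g</sub>/(σ²<sub>g</sub>+σ²<sub>E</sub>) for single-GRM
  models, h² = (σ²<sub>t</sub>+σ²<sub>−t</sub>)/(σ²<sub>t</sub>+σ²<sub>−t</sub>+σ²<sub>E</sub>)
  for the two-GRM model.
* **GBLUP** — mixed-model-equation solvers for the one- and two-GRM
  models, unphenotyped individuals entering through zero columns of Z,
  with a dense GLS oracle for verification.
* **GWAS** — leave-one-chromosome-out mixed-model association over the
  feature SNPs with Bonferroni (0.05/m) and suggestive (0.1/m)
  thresholds.
* **Evaluation** — 10-fold cross-validated accuracy r(GEBV, y<sub>c</sub>)
  on shared folds, against an evenly-spaced control panel of the same
  size as the feature set.
* **Synthetic data** — genotype, phenotype, and corpus generators with
  known ground truth (target h², QTL count, feature-enrichment fraction
  f<sub>tm</sub>), so the whole pipeline is testable offline.

## Worked example

```r
library(tmgblup)

sim  <- simulate_genotypes(n = 500, m = 2000, n_chrom = 5, seed = 42)
lex  <- gene_lexicon(sim$annotation$symbol)
corp <- simulate_corpus(lex, c(GC1N1 = 9, GC2N5 = 6, GC4N3 = 4),
                        n_docs = 25, seed = 7)

mined <- mine_genes(corp$corpus, lex)
top_frequency_table(mined, 3)
#>   symbol freq
#> 1  GC1N1    9
#> 2  GC2N5    6
#> 3  GC4N3    4

part <- select_snps(mined, sim$annotation, sim$panel)
part
#> snp_partition over 2000 SNPs: |tm| = 30 , |exp| = 1970
```

The mined frequencies are exactly the planted counts, and the three mined
genes (plus their intergenic flanks) cover 30 SNPs. Now simulate a trait
whose genetic variance is 60% concentrated on the feature set, estimate
the two-GRM variance components, and compare prediction accuracy:

```r
ph <- simulate_phenotype(sim$panel, part,
        architecture_spec(h2 = 0.4, n_qtl = 60, f_tm = 0.6), seed = 8)
ph$pheno <- adjust_phenotype(ph$pheno)

fit <- aireml(ph$pheno$y_c, NULL,
              list(exp = build_grm(sim$panel, part$exp, "exp"),
                   tm  = build_grm(sim$panel, part$tm, "tm")))
fit
#> varcomp_fit (AI-REML): converged in 7 iterations
#>  component  estimate        se
#>        exp 0.2786166 0.1247059
#>         tm 0.1263309 0.0486308
#>   residual 0.6345143 0.1214227
#> restricted logLik: -244.3276
heritability(fit, 3, rounded = TRUE)
#> [1] 0.39

compare_models(sim$panel, ph$pheno, part, k = 5, seed = 1,
               varcomp_policy = "global")
#>    model    mean_r         se
#> 1     Im 0.1992005 0.03952751
#> 2    exp 0.1454711 0.04133658
#> 3 exp+tm 0.3123500 0.02969482
#> 4 exp+em 0.2097781 0.04203759
```

The feature set carries far more variance per SNP than the complement
(0.126 over 30 SNPs versus 0.279 over 1970), the estimated h² (0.39)
recovers the simulated 0.4, and the two-GRM feature model (`exp+tm`)
clearly beats both the excluded panel (`exp`) and the size-matched
evenly-spaced control (`exp+em`) on identical folds.

The whole flow is also available as one call — `run_pipeline(config)`
(see `default_config()`), or from a shell via
`Rscript inst/scripts/run-pipeline.R --config cfg.yaml`.

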