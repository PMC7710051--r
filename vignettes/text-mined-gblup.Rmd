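---
title: "Genomic prediction with text-mined SNP panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction with text-mined SNP panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmgblup)
```

## The problem

Standard GBLUP assumes every SNP contributes a small, normally distributed
effect, regardless of biological prior knowledge. When a subset of markers
is believed to sit closer to causal variants — here, SNPs inside (and
between) genes that the literature repeatedly associates with a trait —
giving that subset its own variance component lets the model weight it
differently. `tmgblup` implements that idea end to end for livestock-style
data:

1. **Mining**: gene symbols are extracted from an abstract corpus by a
   dictionary rule, and mined genes are mapped to a SNP panel, splitting it
   into a feature set (`tm`) and its complement (`exp`).
2. **Modeling**: variance components and GEBVs are estimated under three
   genomic models — one GRM on all SNPs (model 1), one GRM on the
   complement (model 2), two GRMs fitted jointly (model 3).
3. **Evaluation**: a leave-one-chromosome-out association scan over the
   feature SNPs, and 10-fold cross-validated prediction accuracy including
   an evenly-spaced control panel of the same size as the feature set.

Because the motivating cattle data are proprietary, the package ships a
synthetic-data generator with known ground truth; every statistical claim
in the test suite is computed against that truth.

## Models

### Genomic relationship matrix

For a dosage matrix with allele frequencies $p_j$, the GRM is

$$G = \frac{MM'}{2\sum_j p_j(1-p_j)},$$

where column $j$ of $M$ is the dosage centred by $2p_j$. Frequencies are
always estimated from the post-QC sample — no external base-population
frequencies are accepted — and missing dosages are mean-imputed (centred
value 0), which preserves the row-sum-zero identity. A consequence worth
stating: with in-sample frequencies the centred rows sum to zero, so $G$
is always singular. Wherever $G^{-1}$ is required (the mixed-model
equations), `regularize_grm()` blends $\alpha G + (1-\alpha)I$ with
$\alpha = 0.95$ by default; REML itself never needs $G^{-1}$ and uses the
raw matrix.

Because frequencies are per-SNP, a GRM over a union of disjoint SNP sets
is exactly the denominator-weighted combination of the parts
(`combine_grms()`); the leave-one-chromosome-out GRMs are computed through
this identity rather than from scratch.

### Variance components

For one or two genomic components plus residual,
$V = \sum_k \sigma^2_k G_k + \sigma^2_E I$, the restricted log-likelihood
$-\tfrac12(\log|V| + \log|X'V^{-1}X| + y'Py)$ is maximized by
average-information updates with step-halving, falling back to an EM step
when an AI step proposes a negative component or a likelihood decrease.
Accepted iterations never decrease the likelihood; components that
collapse are pinned to a floor of $10^{-8}\,\mathrm{var}(y)$ and the
convergence flag is honest. Defaults: tolerance $10^{-8}$ on the
likelihood change and $10^{-6}$ relative on parameters, 200 iterations
maximum. Initialization is scale-free: the residual takes half the
phenotypic variance after fixed-effect projection and the genomic
components split the other half equally. Standard errors come from the
inverse AI matrix at convergence; no profile intervals are attempted.

Heritability is $h^2 = \sigma^2_g/(\sigma^2_g + \sigma^2_E)$ for the
single-GRM models and
$h^2 = (\sigma^2_t + \sigma^2_{-t})/(\sigma^2_t + \sigma^2_{-t} +
\sigma^2_E)$ for the two-GRM model; `heritability()` validates the
component count per model and offers the conventional half-away-from-zero
two-decimal rounding used in reported tables.

```{r herit}
heritability(list(genetic = 913.66, residual = 1287.6), model = 1,
             rounded = TRUE)
heritability(list(genetic = c(705.05, 171.76), residual = 1307.3),
             model = 3, rounded = TRUE)
```

### Mixed-model equations and prediction

With $\lambda_k = \sigma^2_E/\sigma^2_k$, `solve_mme()` solves the
one-component system

$$\begin{bmatrix} X'X & X'Z \\ Z'X & Z'Z + \lambda G^{-1} \end{bmatrix}
\begin{bmatrix} \hat b \\ \hat u \end{bmatrix} =
\begin{bmatrix} X'y \\ Z'y \end{bmatrix}$$

and its two-component analogue with $Z'Z + \lambda_k G_k^{-1}$ diagonal
blocks and $Z'Z$ off-diagonal. Unphenotyped individuals (the validation
fold) enter through all-zero columns of $Z$ and receive GEBVs through
their genomic relationships; the combined GEBV of the two-component model
is $\hat u_{-t} + \hat u_t$. The system is solved by Cholesky with one
step of iterative refinement; $\lambda$ values are always derived from an
AI-REML fit, never free inputs, mirroring the two-stage
estimate-then-predict flow. The independent correctness oracle
(`gls_blup_oracle()`) computes the same quantities through dense GLS
($\hat u_k = \sigma^2_k G_k Z' V^{-1}(y - X\hat b)$); the central test of
the package is machine-precision agreement between the two routes.

### Association scan

Phenotypes are first residualized for fixed effects by OLS
(`adjust_phenotype()`, a projection: idempotent, scale- and
location-preserving). Each candidate SNP is then tested by GLS under
$V = \sigma^2_g G_{\mathrm{loco}} + \sigma^2_E I$ with an intercept refit
per SNP and a Wald normal-approximation p-value. Components are estimated
once per left-out chromosome, not per SNP — the usual two-stage
mixed-linear-model association compromise. Only Bonferroni-style
thresholds are provided ($0.05/m$ significant, $0.1/m$ suggestive).

## Text mining

The extraction rule is deliberately simple and fully deterministic:
tokens are produced by splitting on every non-alphanumeric character, and
a token survives only if it is all uppercase letters/digits, at least two
characters, and contains a letter ("IGF-1" yields `IGF`; "impact" and
"pigs" never match; neither does "Cast"). Surviving tokens are matched
case-sensitively against an uppercase lexicon with optional alias
resolution. Frequency counts **occurrences** by default rather than
distinct articles — the stricter, round-trip-testable definition — with
`count_mode = "articles"` available. Known limitation, by design: a
symbol used with a different meaning in running caps text (an acronym
that collides with a gene symbol) is mined anyway; resolving such
homonyms is out of scope.

Mined genes map to SNPs by interval overlap; with
`include_intergenic = TRUE` a SNP between two annotated genes also joins
the feature set when either flanking gene is mined. Stretches before the
first or after the last gene of a chromosome have no flanking pair and
are never assigned; `flank_cap_kb` optionally caps the intergenic reach.
Both choices are configurable because annotation conventions differ.

## The synthetic generator

`simulate_genotypes()` draws dosages Binomial(2, $p_j$) with
$p_j \sim U(\text{maf\_range})$ — Hardy–Weinberg, linkage equilibrium —
and tiles named genes along each chromosome. `simulate_phenotype()`
places `round(f_tm * n_qtl)` QTL in the feature set, draws each effect
$N(0, v_{\mathrm{set}}/(n_{\mathrm{set}}\,2p_j(1-p_j)))$ so the expected
genetic-variance share on the feature set equals `f_tm` exactly under the
same $2p(1-p)$ standardization the GRM uses, and sets the residual
variance from the target $h^2$. Fixed effects are additive level offsets
(or linear slopes) on the phenotype scale. `simulate_corpus()` plants
exact symbol occurrence counts into lowercase filler prose with decoy
words and non-lexicon all-caps tokens.

What the generator does *not* emulate: linkage disequilibrium (an
optional block-copy mode exists for qualitative LD checks, but the
default is independent SNPs), selection, pedigree structure, and
non-additive effects. Passing tests therefore demonstrate correctness of
the estimators and the qualitative feature-partitioning advantage under
the assumed architecture — not that text mining helps on any particular
real population, where LD between panels blurs the partition.

Defaults state the validation conditions used throughout: $h^2 = 0.3$,
100 QTL, $f_{tm} = 0.8$, phenotypic variance 1. The prediction
comparisons run at $n = 1500$ individuals, $m = 5000$ SNPs, a feature set
of 250 SNPs, and 10 cross-validation seeds; REML recovery uses 50
replicates of $n = 500$ with a block-family covariance, and association
calibration pools 20 replicates of 1200 null SNPs. These sizes were
chosen as the smallest at which the Monte-Carlo bands in the tests are
comfortably stable.

## Numerical and design choices

* **Missing dosage** is a dedicated sentinel (`NA`, PLINK code `01`),
  never conflated with 0; inside $M$ it becomes the centred mean.
* **QC conventions**: "MAF below threshold" removes strictly smaller
  values; missingness uses the PLINK `--geno` reading (drop when the
  missing fraction exceeds the cutoff). QC is idempotent and order
  preserving. Duplicate SNP ids are rejected outright rather than
  silently deduplicated.
* **Coordinates** are 1-based inclusive throughout (BIM convention);
  index sets over the map are 1-based R indices in map order.
* **Fold assignment** is a seeded permutation with fold sizes differing
  by at most one; all model configurations in a comparison share the same
  folds. Folds are simple random draws — no family stratification, which
  matters for real half-sib data and is the main reason simulated
  accuracies are not comparable to published ones.
* **Variance-component policy in CV**: re-estimated on each training fold
  by default (no leakage); a `"global"` policy estimates them once per
  model on all data, which is what the bundled comparisons use since
  their purpose is ranking panels on identical folds, not unbiased
  absolute accuracy.
* **Accuracy** is $r(\mathrm{GEBV}, y_c)$ with $y_c$ adjusted once on the
  full data, not per fold; in the oracle limit (GEBV equal to the true
  breeding value) it concentrates near $\sqrt{h^2}$.
* The evenly-spaced control (`evenly_spaced_subset()`) uses stride
  $\lfloor M/\text{count}\rfloor$ from a seeded offset and returns plain
  map indices; `set_em()` attaches them to a partition.

## A worked toy run

```{r pipeline, eval = FALSE}
cfg <- default_config(seed = 11)
cfg$data$n <- 250; cfg$data$m <- 1500; cfg$cv$k <- 5
res <- run_pipeline(cfg, out_dir = tempfile("run"))
res$cv
```

The run directory contains the mined-genes table, QC report, SNP extract
list, variance components per model, and the cross-validated comparison,
each stamped with the MD5 hash of the resolved configuration; rerunning
the same configuration reproduces the tables byte for byte.

## Known limitations

* At most two genomic components; no covariance between random effects,
  no multi-trait REML, no dominance or epistasis.
* The GLS oracle is dense and intended for $n \le$ a few hundred.
* The association scan tests the named candidate set only (scanning all
  SNPs is possible but not the default), and Bonferroni is the only
  multiplicity correction offered.
* Published accuracies from the motivating study cannot be reproduced
  without its genotypes; the cross-validation machinery here validates
  the *pattern* (two-GRM feature model versus excluded panel and
  evenly-spaced control) in simulation.
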