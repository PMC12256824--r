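# scmrcoloc

Cell-type-resolved Mendelian randomization and Bayesian colocalization
from summary statistics.

## The problem

Genome-wide association studies (GWAS) locate disease risk loci but
rarely identify the causal gene, the direction of effect, or the cell
type in which the effect operates. Transcriptome-wide association
approaches bridge this gap by using *cis*-eQTLs — variants associated
with a gene's expression — as genetic instruments for the gene, but bulk
RNA-seq eQTLs blur cell-type specificity. `scmrcoloc` implements a
three-stage screen over cell-type-resolved eQTL summary statistics:

1. **Discovery MR** — for every gene × cell type, select independent
   *cis*-eQTL instruments (cis window, `p < 1e-5`, LD-clumped at
   `r² < 0.1`), harmonize alleles against the outcome GWAS, and estimate
   the causal effect of expression on the outcome; control the FDR by
   Benjamini–Hochberg.
2. **Replication MR** — re-test discovery survivors with instruments
   from an independent eQTL source, after coarsening fine-grained cell
   types onto the replication dataset's labels (a bundled 14→6 immune
   cell-type map is included).
3. **Colocalization** — for replicated hits, test whether expression and
   outcome share the *same* causal variant rather than distinct variants
   in LD, requiring a posterior probability of a shared variant
   (PPH4) ≥ 0.8. Loci with several independent eQTL signals are handled
   by stepwise conditional decomposition, colocalizing every signal pair
   and reporting the maximum PPH4.

Everything operates on summary statistics only (variant, alleles, EAF,
beta, SE, p, N) plus an LD correlation matrix — no genotype-level data.
A bundled simulator generates LD-structured summary statistics under
each causal configuration so the whole screen is testable end to end.

## The statistics

**Wald ratio** (single instrument): the causal effect of expression X on
outcome Y instrumented by variant g is

    β̂ = β̂_gY / β̂_gX,    se(β̂) = se(β̂_gY) / |β̂_gX|

(first-order; a second-order delta SE propagating exposure noise is
available). **IVW** (k > 1 instruments): with weights
w_j = β̂²_gX,j / se²(β̂_gY,j),

    β̂ = Σ_j β̂_gX,j β̂_gY,j / se²_j  ÷  Σ_j w_j,    se_FE = (Σ_j w_j)^(−1/2)

with a multiplicative random-effects variant (default) multiplying the
SE by max(1, φ̂), φ̂² the weighted residual variance about the fit.

**Colocalization**: per-SNP approximate Bayes factors
log ABF = ½[log(1−r) + r z²] with r = W/(W+V), V = se², W the prior
effect variance (sd 0.15 for quantitative, 0.2 for case-control traits);
the five hypothesis posteriors (H0 none / H1 trait-1 only / H2 trait-2
only / H3 both-distinct / H4 shared causal variant) come from
enumerating causal configurations with per-SNP priors
p1 = p2 = 1e-4, p12 = 1e-5, computed entirely in log space.

**Simulator**: marginal z-scores at a locus are drawn from the standard
model z ~ MVN(√n · R b, R), with R a block AR(1) LD matrix and b the
standardized causal effects; under mediation the outcome's causal effect
at the shared variant is α × the eQTL effect, so every variant's true
marginal ratio equals α.

## Worked example

```r
library(scmrcoloc)

# 20 genes x 3 cell types: 5 mediated (H4), 5 LD-confounded (H3), 10 null
st <- simulate_study(n_genes = 20, n_h4 = 5, n_h3 = 5, seed = 42)
res <- run_pipeline(st$discovery, st$replication, st$outcome, st$genes,
                    st$ld, st$map, pipeline_config(seed = 1))
res
#> <pipeline_result>
#>   tested:      40 gene x cell-type x outcome combinations
#>   discovery:   10 at FDR q < 0.05
#>   replication: 10 at FDR q < 0.05
#>   colocalized: 5 at max PPH4 >= 0.8

pr <- res$prioritized
pr[pr$pass, c("gene_id", "cell_type", "disc_beta", "disc_qvalue",
              "rep_beta", "rep_qvalue", "max_pph4")]
#>    gene_id cell_type disc_beta disc_qvalue rep_beta rep_qvalue max_pph4
#> 1  GENE001    CD4_NC     0.179    1.70e-14    0.124   5.35e-07    0.999
#> 6  GENE011    CD4_NC     0.215    1.17e-26    0.213   4.71e-25    1.000
#> 7  GENE012         B     0.182    3.98e-15    0.220   1.44e-23    1.000
#> 9  GENE019    CD4_NC     0.224    2.08e-30    0.257   1.38e-27    1.000
#> 10 GENE020    Mono_C     0.209    5.18e-26    0.150   5.04e-24    1.000
```

Forty gene × cell-type combinations carried at least one instrument; ten
passed both MR stages (the five mediated genes plus five LD-confounded
ones, whose instruments are merely correlated with a distinct outcome
variant); colocalization removed exactly the confounded five. The final
table matches the simulated truth: the five surviving rows are the five
genes simulated with a mediated effect (α = 0.2) in those same cell
types, with discovery estimates near α and PPH4 ≈ 1.

Single-locus pieces are available directly:

```r
loc <- simulate_locus(scenario("H4", alpha = 0.25, causal_variance_exp = 0.05,
                               n_exp = 10000, n_out = 50000, Q = 100), seed = 7)
coloc_abf(loc$exposure, loc$outcome)
#> <coloc_result> Q = 93 shared variants
#> PPH0 PPH1 PPH2 PPH3 PPH4
#>    0    0    0    0    1
```

A thin command-line front end over the same functions is installed at
`inst/cli/scmrcoloc.R` (subcommands `simulate`, `select-instruments`,
`harmonize`, `mr`, `coloc`, `pipeline`).

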