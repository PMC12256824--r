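---
title: "Methods: cell-type-resolved MR and colocalization from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type-resolved MR and colocalization from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmrcoloc)
```

## Overview

`scmrcoloc` screens cell-type-resolved *cis*-eQTL summary statistics for
genes whose expression causally influences a GWAS outcome, in a specific
cell type, via three stages: discovery two-sample MR, replication MR in
an independent eQTL source with coarsened cell-type labels, and Bayesian
colocalization as a guard against LD confounding. This vignette records
the statistical model behind each stage, the defaults and why they were
chosen, the numerical decisions, and what the bundled simulator does and
does not emulate.

## Data model and conventions

All inputs are marginal per-variant summary statistics: identifier,
chromosome, 1-based inclusive position, effect/other allele (forward
strand assumed), effect-allele frequency (EAF, optional), additive
effect `beta` per effect-allele copy (log-odds for case-control traits),
its standard error, p-value, and sample size. On read, rows violating
basic invariants (non-positive SE, invalid alleles, p outside (0, 1])
are dropped and counted rather than failing the file, because public
summary-statistics releases routinely contain a few malformed rows. A
p-value that disagrees with the two-sided normal p implied by
`|beta/se|` (relative discrepancy of −log10 p beyond 0.5) is recomputed
from `beta/se` with a warning: all downstream arithmetic consumes the
z-score, and a file's p column may have been truncated, rounded, or
derived from a different test.

LD enters as a signed correlation matrix `r` with a companion variant
list (the plain-text convention of common LD-reference exports); it is
required to be symmetric within 1e-8 (then symmetrized as
`(r + t(r))/2`) with unit diagonal within 1e-6. Signed `r` rather than
`r²` is stored because conditional analysis needs the sign; clumping
squares it.

## Instrument selection

Candidate instruments for a gene × cell type are the variants in the
gene's cis window with `p < 1e-5`, LD-clumped at `r² < 0.1`. Two window
conventions are supported because eQTL releases differ: `flank_gene`
extends 1 Mb beyond either end of the gene body, and `midpoint` takes a
fixed half-width (default 100 kb) around the gene midpoint. Both
thresholds are exposed in `selection_params()`.

Clumping is the standard greedy procedure: repeatedly keep the
unremoved variant with the smallest p and remove everything with
`r² ≥` threshold to it. Ties on p are broken by smaller position, then
lexicographic id, so results are identical across platforms. Variants
missing from the LD reference are dropped with a warning by default —
treating unknown LD as zero would admit correlated instruments — but a
per-source `missing_ld = "independent"` escape is available for
pre-pruned releases that publish only a few top variants per gene, for
which clumping may also be skipped entirely by passing no LD (a logged
notice is emitted). No weak-instrument F-statistic filter is applied;
the `p < 1e-5` threshold already bounds instrument strength below by
roughly `|z| > 4.4`.

## Harmonization

Exposure and outcome effects are aligned to the exposure's effect
allele: identical allele pairs pass through; swapped pairs negate the
outcome beta and reflect its EAF; strand-flipped pairs are relabeled via
complement first. Palindromic variants (A/T, G/C) are ambiguous from
labels alone. The default policy infers orientation from allele
frequency — both sides' EAFs must fall on the same side of 0.5, and the
variant is dropped when either minor-allele frequency exceeds 0.42 (too
close to 0.5 to call) or either EAF is missing. The 0.42 ceiling is the
convention of widely used two-sample MR harmonization code; a strict
`drop_all` policy is available, and the per-variant action code is kept
in the output for audit. Indels and irreconcilable allele pairs are
always dropped. Because the estimators consume harmonized pairs, every
MR estimate is invariant to which allele either input file happened to
call "effect" (this is property-tested).

## MR estimation

A single harmonized instrument yields the Wald ratio
`beta_out / beta_exp` with first-order SE `se_out / |beta_exp|`; more
than one yields IVW. The first-order Wald SE ignores exposure-side
noise, matching the convention of standard MR software; the second-order
delta SE is available by flag and agrees with the Monte-Carlo SD of the
ratio in tests. The IVW default is the multiplicative random-effects
variant, which multiplies the fixed-effect SE by `max(1, φ̂)` with `φ̂`
the weighted residual SD about the fitted slope — again the default
behavior of standard MR software; with one instrument IVW reduces
algebraically (and in this implementation exactly, to the last bit) to
the first-order Wald ratio. P-values use the standard normal rather than
a t reference, the usual summary-statistics convention.

FDR control is Benjamini–Hochberg. The default family is per outcome,
across all gene × cell-type tests for that outcome — multi-outcome
presentations of such screens are naturally per-outcome — with a
`global` family available; which family a published analysis pooled is
often unstated, so both are first-class. Cross-cell-type agreement of
MR estimates is summarized by a weighted Pearson correlation over shared
gene–outcome keys; the weight for a pair of estimates is
`1/(se_x² + se_y²)`, the precision of their difference, a natural choice
when "weighted" is otherwise unspecified; equal weights (plain Pearson)
are available and the scheme is recorded in the output metadata.

## Colocalization

Per-SNP approximate Bayes factors use the normal-normal form: with
`z = beta/se`, `V = se²`, `r = W/(W+V)`,
`log ABF = ½[log(1−r) + r z²]`. The prior effect SD `√W` defaults to
0.15 for quantitative traits (in trait-SD units) and 0.2 log-odds for
case-control traits — the established defaults of the Bayesian
colocalization framework; these are deliberately not estimated from the
data. Five-hypothesis posteriors come from enumerating causal
configurations with per-SNP priors `p1 = p2 = 1e-4`, `p12 = 1e-5`:

* `L1 = log p1 + logΣexp(l1)`, similarly `L2`;
* `L4 = log p12 + logΣexp(l1 + l2)`;
* `L3 = log p1 + log p2 + log(e^{S1+S2} − e^{S12})`, the two-causal sum
  minus its same-SNP diagonal.

All sums use log-sum-exp; the H3 subtraction uses a stable
log-diff-exp, and when the difference underflows (numerically
non-positive H3 mass, which can only happen when one SNP carries
essentially all of both traits' evidence) H3 is clamped to zero with a
warning. The implementation is tested for exact (1e-10 relative)
agreement with a brute-force enumeration over all `Q² + 2Q + 1`
configurations, for normalization to 1 within 1e-10, for exact
PPH1/PPH2 exchange under trait swap, and for monotonicity of PPH4 in
`p12`. Colocalization uses all shared variants in the region — not just
the instruments — since the posterior odds depend on the full local
evidence; inputs are allele-aligned first for auditability even though
the posteriors depend on z only through z².

### Multiple causal variants

When a locus carries more than one independent eQTL signal, marginal
statistics mix them and single-configuration colocalization can be
misled. The multi-signal mode decomposes each trait by forward stepwise
conditional analysis on summary statistics:
`z_{j|S} = (z_j − R_{jS} R_{SS}^{-1} z_S)/√(1 − R_{jS} R_{SS}^{-1} R_{Sj})`,
admitting an index variant while its conditional p is below `p_enter`
(default 1e-6, conservative), up to `max_signals = 10`, with a 1e-6
ridge on `R_SS`. Each selected index yields one association set
conditioned on all *other* indices, every cross pair of per-trait
signals is colocalized, and the maximum PPH4 over pairs is reported.
This stepwise-conditional decomposition is a deliberate, documented
approximation to fine-mapping-based credible-set decomposition
(sum-of-single-effects): it reproduces the *structure* — per-signal
colocalization with a max-PPH4 decision rule — without claiming
numerical equivalence to any particular fine-mapping implementation. In
the pipeline it is engaged exactly when the discovery MR used more than
one instrument, mirroring the single-IV/multi-IV split of the coloc
stage; single-instrument loci use the marginal posterior directly.

## The three-stage screen

Stage 2 tests only stage-1 survivors, after coarsening discovery cell
types through a many-to-one map (several fine-grained hits collapsing to
one replication label yield a single deduplicated replication test), and
its FDR family is the survivor set actually tested — consistent with
"replicate the significant discovery findings" rather than re-screening
everything; the alternative (FDR over all replication tests) is a
configuration away since published descriptions rarely say which was
used. Stage 3 colocalizes the *discovery* exposure's full-region
statistics against the outcome for stage-2 survivors. A hit passes
overall iff discovery q < 0.05, replication q < 0.05, and
max PPH4 ≥ 0.8. The funnel counts are monotone by construction and the
final flag is asserted to equal the conjunction of the three stage
flags on every row. Per-stage tables are always written for audit.

## The simulator

Marginal summary statistics at a locus are generated directly in
z-space from the standard multivariate-normal model of marginal
association statistics under LD: `z ~ MVN(√n · R b, R)` with `R` a
block AR(1) correlation matrix (`r_ij = ρ^{|i−j|}` within a block,
default ρ = 0.9, positive-definite by construction) and `b` the
standardized per-variant causal effects. Each causal variant's `b` is
set to `√(causal variance)`, EAFs are drawn once per locus from
Uniform(0.05, 0.5) and shared by both traits — the same variants have
one population frequency; drawing them independently per trait would
defeat frequency-based palindrome inference — and
`se_j = 1/√(2 n · eaf_j(1−eaf_j))`, `beta_j = z_j · se_j`. Traits are on
the standardized scale (SD 1), so the quantitative colocalization prior
applies without rescaling; case-control outcomes are emulated on the
log-odds scale via the effective-sample-size SE
`1/√(2 n φ(1−φ) eaf(1−eaf))` with case fraction φ, a documented
approximation.

The five causal configurations map onto the colocalization hypotheses.
Under H4 with mediation the outcome's causal effect at the shared
variant is `α ×` the eQTL effect, which makes the true marginal ratio
equal `α` at *every* variant in LD with it — the property that makes
Wald/IVW estimates consistent regardless of which tagging variant
selection picks. Under H3 the outcome's causal variant is distinct,
chosen so its LD with the eQTL variant falls in a configured
`[r²_min, r²_max]` range: capped low (≤ 0.01) to emulate genuinely
independent signals, or floored high (0.4–0.6) to emulate the
LD-confounded loci the colocalization stage exists to remove.

`simulate_study()` assembles a full discovery/replication bundle:
genes are labeled mediated (H4, in one designated cell type),
LD-confounded (H3), or null. Null genes carry *cis*-eQTLs in every cell
type with no outcome association (an expressed-but-irrelevant gene);
a gene with no eQTL at all would never enter MR and so would exercise
nothing. Replication exposures are regenerated with independent noise
at `n/8` of the discovery sample size (emulating a smaller replication
cohort) under the coarsened labels. Every locus derives a child seed
deterministically from (seed, gene, cell type, trait), so any subset of
the bundle regenerates identically in isolation, and identical seeds
give byte-identical pipeline outputs.

What the simulator does *not* emulate: realistic MAF spectra and
annotation-dependent genetic architecture, haplotype-level LD (AR(1)
blocks are a stylized stand-in), sample overlap between exposure and
outcome, polygenic background, horizontal pleiotropy, and expression
sparsity effects specific to single-cell measurement. Passing tests
therefore demonstrate correctness of the estimators and the screen's
operating characteristics *under the stated generative model*, not
performance on any particular cohort.

## Test and calibration problem sizes

The suite checks estimator calibration at sizes chosen to make
Monte-Carlo error small relative to the bounds asserted: colocalization
calibration uses 500 loci per scenario at Q = 500 variants,
n = 10,000, 1% causal variance (median PPH0 > 0.9 under the null,
PPH4 > 0.9 under sharing, PPH3 > 0.7 under distinct causal variants);
MR recovery uses 1,000 mediated loci at n = 50,000 with α = 0.2 (mean
estimate within 0.02, 95% CI coverage within [0.93, 0.97]), with 1%
causal variance for the single-instrument case and ~0.13% per signal
(marginal |z| ≈ 8) for the three-instrument case so that each signal's
LD shadows stay below the selection threshold and selection returns the
three index variants; the end-to-end screen uses 60 genes (15 mediated,
15 confounded at r² ≈ 0.5, 30 null) at Q = 200, n_exp = 10,000,
n_out = 50,000, 5% causal variance, asserting sensitivity ≥ 0.8 on
mediated pairs and ≥ 80% removal of confounded genes that survive both
MR stages. `scripts/acceptance.R` recomputes the same quantities at
moderately reduced replicate counts and writes them as JSON.

## Known limitations

* Wald/IVW with a handful of *cis* instruments cannot detect horizontal
  pleiotropy; no Egger or median estimators are provided because most
  gene × cell-type exposures carry a single instrument, where those
  methods are undefined. Colocalization guards against LD confounding
  but not against a shared variant with pleiotropic effects on
  neighboring genes.
* The stepwise-conditional multi-signal mode inherits the known
  fragilities of conditional analysis from summary statistics when the
  LD reference mismatches the association sample.
* No proxy-variant lookup: instruments absent from the outcome are
  dropped.
* The simulator's stylized LD and frequency model is intentional — it
  is exact for the estimators under test, not a portrait of real
  genomes.
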