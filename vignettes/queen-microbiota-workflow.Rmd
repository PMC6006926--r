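---
title: "Absolute-abundance compositional analysis of the queen gut microbiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute-abundance compositional analysis of the queen gut microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apicomp)
```

## The analysis problem

Honey bee queens and workers develop from the same genotype but differ
roughly ten-fold in lifespan, and their gut communities age differently.
`apicomp` implements an analysis chain for 16S rRNA amplicon surveys of
the queen alimentary tract — mouthparts, midgut, ileum, and rectum sampled
per queen — in which three measurement layers are combined:

1. **Read counts** per OTU and library (compositional: only ratios are
   informative);
2. **qPCR community sizes** — total 16S gene copies per DNA extraction —
   which restore an absolute scale;
3. **Fat-body protein carbonyl content** (nmol carbonyl per mg protein), a
   biological-age proxy that accumulates with oxidative damage and need
   not agree with chronological age.

The scientific questions are whether microbiota structure differs by
chronological age class and queen source, and whether it tracks biological
age, per gut niche.

## From reads to cells

Amplicon reads are proportional to 16S **gene copies**, not cells, and
bacterial genomes carry 1–15 rRNA operons. With per-sample qPCR total $T$
(gene copies), taxon read proportion $p_i$, and per-genome copy number
$c_i$, the estimated cell count is

$$\mathrm{cells}_i = T \, p_i / c_i .$$

The copy-number panel used for the queen core community is 4 copies for
core species, 5 for *Lactobacillus kunkeei*, 2 for *Bifidobacterium
asteroides*, and 1 for *Parasaccharibacter apium* and Acetobacteraceae
Alpha 2.1 (assigned from its closest characterized relative). OTUs ranked
10 and below by dataset-wide raw reads are pooled into one `other`
fraction corrected by the panel mean of 4.2 copies. This yields the exact
conservation identity checked by the test suite:
$\sum_i \mathrm{cells}_i c_i + \mathrm{other}\cdot 4.2 = T$.

A deliberate reading: "multiplying proportional abundance by copy number
and community size" is implemented as *division* of gene-copy mass by the
per-genome copy number (`direction = "divide"`), because the target
quantity is cells and literal multiplication would double-count multi-copy
genomes. The literal product is retained behind `direction = "multiply"`
for sensitivity analysis only.

Panels (top 9 named OTUs, top 37 for distance-based tests, top 200 for
networks) are always selected by **dataset-wide** raw read totals with
ties broken by OTU id, so every niche uses the same columns. By default
proportions are taken over all OTUs so that panel + other exhausts $T$;
`renormalize_panel = TRUE` instead renormalizes within the panel (both
conventions are defensible; the exhaustive one is the default because it
preserves conservation against the measured total).

## CLR and the statistical layer

Cell abundances remain compositional in structure (scaling a sample's
total must not change inference about ratios), so multivariate statistics
operate on centered log ratios,
$z_i = \ln x_i - \tfrac1D\sum_j \ln x_j$. Zeros are handled by
multiplicative replacement: each zero cell receives a fraction
`pseudo_frac` (default $5\times10^{-5}$, half a read at a typical
10k-read library) of the row total, positive entries are shrunk by the
factor that preserves the total. Expressing the pseudocount as a fraction
keeps CLR scale-invariant. Because CLR rows sum to zero, a $D$-taxon CLR
matrix has rank $D-1$; the MANOVA therefore runs on the 9 named taxa from
a CLR computed over the 10-column (panel + other) composition.

* **MANOVA / MANCOVA** (`manova_pillai()`, `mancova_pillai()`): Pillai's
  trace with Type III (partial) cross-products under sum-to-zero
  contrasts, required because the 2 × 2 age × source design is unbalanced
  (16/16/15/16). The F approximation is the standard $(s, m, n)$ form,
  exact when $s = 1$ — which holds for every term of the two-level design.
  The biological-age covariate (log carbonyl) enters as a regression
  column; factor terms are then tested on covariate-adjusted
  cross-products. `car::Manova` is used in the test suite as an
  independent cross-check, never as the implementation.
* **Wilcoxon screens** (`wilcoxon_by_taxon()`): exact enumeration when
  both groups have ≤ 8 untied observations, tie-corrected normal
  approximation otherwise; Bonferroni, Benjamini–Hochberg, and
  Benjamini–Yekutieli adjustments are reported side by side. "FDR" named
  separately from Benjamini–Hochberg is implemented as
  Benjamini–Yekutieli, the standard stricter FDR control under arbitrary
  dependence — BH is itself an FDR method, so the third correction must
  be the dependence-robust variant.
* **Pearson correlations** (`pearson_clr_carbonyl()`): per-taxon CLR
  score against natural-log carbonyl. The log base is configurable; the
  natural log is the default since only the correlation's magnitude and
  sign matter and they are base-invariant.
* **PCA biplots** (`pca_clr()`): eigendecomposition of the CLR
  covariance; covariance-biplot scaling, so taxon vector lengths are
  proportional to the standard deviation of that taxon's log-ratio to the
  rest of the panel; carbonyl is projected as a supplementary vector via
  its correlation with sample scores.
* **ANOSIM** (`anosim_test()`): Clarke's rank statistic
  $R = (\bar r_B - \bar r_W)/(M/2)$, $M = n(n-1)/2$; p by label
  permutation with the observed labeling counted in numerator and
  denominator, or exhaustive enumeration of all assignments for small
  two-group designs (then exact).
* **DistLM** (`distlm()`): Gower-centered inner products
  $G = -\tfrac12 J D^2 J$, pseudo-$F$ from trace ratios, permutation p.
  The distance metric is not dictated by the method; the default is
  Bray–Curtis on copy-corrected relative abundances (the conventional
  companion for abundance data), with Euclidean-on-CLR available. With a
  single predictor and no covariates, raw-label permutation and
  reduced-model residual permutation coincide; both names are accepted.
  On Euclidean distances of a univariate response the pseudo-$F$ equals
  the classical regression $F$ exactly, which the tests assert to
  $10^{-8}$.

## SparCC networks

`sparcc()` estimates correlations among unobserved absolute (basis)
abundances from counts alone. Counts are converted to fractions with a
uniform add-one Dirichlet prior taken at its posterior mean — a
deterministic choice, so that identical inputs give identical estimates
and the one-shot solution can be verified against an independent
linear-algebra oracle (averaging over Dirichlet draws adds Monte Carlo
noise without changing the estimand). Log-ratio variances
$t_{ij} = \operatorname{var}\log(x_i/x_j)$ are decomposed as
$t_{ij} = \omega_i + \omega_j - 2\rho_{ij}\sqrt{\omega_i\omega_j}$ under
the sparsity assumption; basis variances solve the induced linear system;
up to `n_inner_iter` (20) refinement rounds each exclude the
strongest-correlated pair above `exclusion_threshold` (0.1) from the
system, the convention of the original reference implementation. Pair
significance is a two-sided bootstrap pseudo-p from column-shuffled null
data, $(1 + \#\{|\rho^\ast| \ge |\rho|\})/(1 + n_\mathrm{boot})$.
Estimates on panels with more than 70% zero cells are flagged unreliable.

## The synthetic-study generator

`generate_study()` produces complete studies with the design the analysis
assumes: four cohorts (CA young/old n = 16 each, AZ young n = 15, AZ old
n = 16; 63 queens), four niches, one library per queen × niche (252
libraries). Its defaults encode the study conditions:

| parameter | default | rationale |
|---|---|---|
| niche community sizes (geometric mean, gene copies) | mouth 1.4 M, midgut 14.2 M, ileum 17.9 M, rectum 121.2 M | the published per-niche qPCR averages |
| library depths (Poisson mean, reads) | 21k / 25k / 30k / 38k | the published per-niche library averages |
| qPCR lognormal `sdlog` | 0.5 | dispersion is not published; ~65% CV is typical of between-host qPCR totals |
| Dirichlet concentration | 50 per niche | moderate compositional overdispersion for a simple, dominance-structured community |
| rare tail | 1.2% of mass over 60 OTUs, ≤ 10% prevalence each | the rare-biosphere mass and sporadic prevalence of non-core OTUs |
| carbonyl | young 2, old 4 nmol/mg, source shift 0.5, sd 0.75 | a strong chronological-age signal with overlapping cohorts, matching the qualitative picture of the aging assay |

Niche base compositions qualitatively reproduce the published structure:
mouth and midgut dominated by *P. apium* and *L. kunkeei*, the rectum by
*Lactobacillus* firm5, and the ileum intermediate, with firm5 and
*P. apium* its two most abundant species in cell units. Age and source
effects are injected as log2 fold changes on proportions (then
renormalized — a 2-fold effect on a taxon at base proportion $p$ changes
its proportion by factor $2/(1+p)$, which the recovery tests account
for). Carbonyl–taxon links act through rectum CLR scores so that
correlation and covariance analyses have a well-posed target. Everything
is reproducible from a single integer seed, and a `truth` object records
each injected effect.

What the generator does **not** emulate: sequencing error and chimeras,
primer bias, taxon-correlated qPCR efficiency, within-colony dependence
among queens, and compositional effects of one taxon's absolute change on
the measured total (qPCR totals are drawn independently of composition).
Passing recovery tests therefore demonstrate correctness of the
estimators under the stated model, not robustness to these artifacts.

## Numerical choices and degenerate inputs

* Conservation and CLR row-sum contracts are enforced to $10^{-9}$
  relative tolerance; in practice they hold to machine precision.
* Singular error cross-products (e.g. a full CLR panel, rank $D-1$) abort
  with advice to reduce the panel rather than silently pseudo-inverting.
* Zero qPCR totals, all-zero samples under Bray–Curtis, constant DistLM
  predictors, and all-zero CLR rows are errors; zero-read libraries are
  excluded with a warning, mirroring the handling of failed libraries.
* Negative SparCC basis-variance estimates are clipped to $10^{-10}$ with
  a warning; correlations are clamped to $[-1, 1]$.
* Percent change with age is $100(\bar x_{old}-\bar x_{young})/\bar
  x_{young}$, bounded below by −100 because cell counts are non-negative;
  a zero young mean yields `NA`.
* Permutation p-values always count the observed arrangement:
  $(1+b)/(1+B)$.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run at the design's scale where
it matters and scale down elsewhere: null size calibration uses 2000
replicate single-niche studies (n = 63) with 199 permutations per
replicate for the distance-based tests; effect recovery uses 500
replicates at n = 16 per group; SparCC recovery uses 20 taxa × 500
samples at depth 3000; the determinism check runs the full 252-library
pipeline twice with 199 permutations and 20 bootstrap shuffles.

## Known limitations

* The power of Wilcoxon screens on qPCR-normalized cells is bounded by
  community-size dispersion: with lognormal `sdlog` 0.5 totals, a 2-fold
  proportional effect at n = 16 per group is detected (BH-0.05) in
  roughly 40% of replicates, although its direction is recovered in
  ~99%. Detecting 2-fold effects reliably at that sample size requires
  either near-noiseless totals or analysis on the compositional scale.
* The MANCOVA treats the covariate as error-free; carbonyl assay noise
  attenuates its term.
* SparCC assumes most pairs uncorrelated ("sparsity"); dense interaction
  structures bias basis variances, and panels over 70% zeros are flagged
  rather than repaired.
* ANOSIM's permutation null assumes exchangeability across queens;
  repeated measures across niches must be analyzed per niche (as done
  throughout) rather than pooled.

## A worked example

```{r example, eval = FALSE}
st <- generate_study(study_config(seed = 1))
ca <- cell_abundance(st$otu, st$qpcr, default_copy_numbers())
clr <- clr_of_cells(ca)

rect <- subset_samples(st$otu, st$otu$metadata$niche == "rectum")
ca_r <- cell_abundance(rect, st$qpcr, default_copy_numbers())
z <- clr_of_cells(ca_r)$z[, 1:9]
manova_pillai(z, ca_r$metadata)

cfg <- run_config(simulate = TRUE, out_dir = "queen_run", seed = 1,
                  permutations = 999, n_boot = 100)
tabs <- run_pipeline(cfg)
```
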