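---
title: "Coexpression modules, drug susceptibility, and directional signature interaction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coexpression modules, drug susceptibility, and directional signature interaction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexdrug)
```

# What the package computes

`coexdrug` implements a network-integration workflow for bulk
transcriptomes of the kind used to ask whether two classes of drugs act on
the same transcriptional program in a tumor. Its stages are:

1. **Coexpression modules.** A weighted gene coexpression network is built
   from a genes × samples log-expression matrix; genes are clustered into
   modules via the topological overlap matrix (TOM), and each module is
   summarized by its eigengene (first principal component of the
   standardized module submatrix).
2. **External preservation.** Each module is re-scored in an independent
   cohort with a permutation Z statistic; modules that do not replicate
   are set aside.
3. **Functional and cell-type annotation.** One-sided Fisher overlap
   tests of module gene sets against gene-set libraries (pathways,
   cell-type markers, TF-target or kinase-substrate sets supplied as GMT
   files), with Benjamini–Hochberg correction per table.
4. **Localization.** Bulk samples are deconvolved into cell-type
   proportions with a nonnegative least-squares solver against a
   signature matrix, and module eigengenes are associated with
   proportions and continuous phenotypes (for instance a stromal
   tumor-infiltrating lymphocyte fraction) by Spearman correlation under
   an FDR rule.
5. **Drug susceptibility (OSM).** Each module is scored against a panel
   of drug perturbation signatures: per drug, the module's enrichment
   among the drug's most-responsive genes becomes a z score; z scores are
   combined across the panel (Stouffer by default) and standardized
   across modules. Run on a panel of opioid receptor modulators, this is
   an opioid susceptibility metric.
6. **Directional interaction.** Two drug-response signatures (for
   example a morphine signature and an anti-PD-L1 response signature)
   are intersected; the overlap is tested for enrichment, the sign
   agreement of the shared genes is tabulated (discordance fractions),
   and the two effect-score distributions are compared with a two-sample
   Kolmogorov–Smirnov test using the asymptotic p-value
   $p = 2\sum_{k\ge1}(-1)^{k-1}e^{-2k^2\lambda^2}$,
   $\lambda = \sqrt{nm/(n+m)}\,D$.

# The statistical model behind the generator

Every synthetic dataset follows a latent single-factor model per module:
gene $g$ in module $m$ has expression
$x_g = \ell_g f_m + \varepsilon_g$, with factor $f_m \sim N(0,1)$ across
samples, loading $\ell_g \in [0,1]$, and noise
$\varepsilon_g \sim N(0, \sigma^2)$. This matches the construct the
analysis assumes — the eigengene estimates $f_m$, and module membership
(kME) estimates $\ell_g/\sqrt{\ell_g^2+\sigma^2}$ — and it makes pairwise
correlations available in closed form,
$\mathrm{cor}(x_i, x_j) = \ell_i\ell_j / \sqrt{(\ell_i^2+\sigma^2)(\ell_j^2+\sigma^2)}$,
which the test suite uses as an oracle.

**Loadings.** Each module has a *hub tier* of `n_hubs = 3` genes at
loading 1.0 and a *bulk tier* declining linearly from `bulk_loading =
0.7` to `min_loading = 0.4`. The gap between tiers is essential: with a
smooth ramp, neighboring genes differ in expected kME by ~0.005 while the
sampling noise of a correlation at n = 200 is ~0.03, so "the hubs" would
not be a statistically identifiable set and hub-recovery checks would be
meaningless. The tier gap makes hub identity well defined without
changing the documented loading range.

**What the generator emulates and what it does not.** It reproduces the
features the pipeline's inferences rely on: planted modules with hubs, a
second cohort in which a chosen subset of modules is preserved (fresh
factors, same loadings) while the rest dissolve into noise, a bounded
phenotype driven by selected factors, Dirichlet cell-type mixtures
through a marker-block signature matrix, and signed per-gene drug scores
with an affected subset of a target module — including an opposing pair
on a shared module and a near-disjoint neutral drug. It does **not**
emulate count noise (no negative binomial layer), batch or library-size
effects, correlated factors, overlapping modules, or single-cell
structure. Passing the recovery suites therefore demonstrates
correctness of the inference machinery under its own assumptions, not
robustness to real RNA-seq artifacts.

# Parameters that matter

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `power` | auto from 1..20 | Soft-threshold exponent; chosen as the smallest power whose *signed* scale-free fit reaches `r2_target = 0.8`. |
| `mode` | unsigned | $a_{ij}=|\mathrm{cor}|^\beta$; `signed` uses $((1+\mathrm{cor})/2)^\beta$. |
| `cut_height` | 0.998 | Static cut on the 1−TOM dendrogram (dissimilarity units). See below. |
| `min_module_size` | 30 | Clusters below this size are unassigned (`grey`). |
| `merge_corr` | 0.75 | Modules whose eigengenes correlate above this are merged. |
| `n_perm` | 200 | Permutations for preservation Z; `z_threshold = 2` flags replicable modules. |
| `alpha`, `or_threshold` | 0.05, 1 | Raw-p + odds-ratio rule for overlap calls (cell-type and signature overlap). |
| `fdr` | 0.1 | BH threshold for eigengene–covariate associations — deliberately a *different* rule from the overlap calls; both rules coexist in the workflow. |
| `top_fraction` | 0.05 | Fraction of a drug signature kept (by \|score\|) as its responsive gene set. |

# Numerical and design choices

**Static cut, absolute height.** Module detection cuts the
average-linkage tree at an absolute dissimilarity (default 0.998) rather
than at a quantile of merge heights. A quantile cut cannot work when most
genes are background: the high quantiles of merge heights sit inside the
background merge band, so the cut either swallows the background into
giant pseudo-modules or dissolves everything, and no quantile serves both
structured and pure-noise inputs. An absolute height slightly below the
background band keeps background genes unassigned (their TOM
dissimilarities concentrate above 0.999 at moderate powers) while
collecting weakly loaded module genes. The price is scale sensitivity:
for small gene sets (a few hundred genes) or powers below ~3 the
background band descends below the default cut, and `power`/`cut_height`
should be set explicitly; the symptom is a single module containing most
genes. The full dynamic-hybrid cut algorithm is intentionally out of
scope: the static cut is reproducible and sufficient for
planted-structure recovery.

**Signed scale-free fit with density bins.** Connectivities are binned
into 10 equal-count (quantile) bins; because equal-count bins have
constant mass, the regression uses the empirical *density* (mass/width)
against mean connectivity, log–log. The fit index is negated when the
slope is positive — an increasing degree density contradicts scale-free
topology however high its R² — which prevents dense low-power networks
from being selected. On planted data the fit rises smoothly with power
(no knee), so the selected power may alternate between adjacent grid
values across realizations; module recovery is insensitive within that
band, and the report exposes `r_squared`, `slope` and `fit` per power for
inspection.

**Preservation null.** Both preservation statistics (test-cohort density;
reference-vs-test correlation of intramodular connectivity) are
standardized against random gene sets drawn from the *unassigned* genes
shared by both cohorts. Drawing from all non-module genes would put other
modules' coexpression into the null and bias Z downward for genuinely
non-preserved modules; with the unassigned pool a destroyed module lands
near Z = 0, as a null should. When too few unassigned genes exist the
pool widens (with a warning) to all genes outside the module. Two
degeneracies are handled explicitly: a permutation null with (numerically)
zero spread scores Z = 0 when the observation coincides with it — the
copy-cohort case, where every permuted connectivity correlation is
exactly 1 — and errors otherwise. Z_summary saturates at strong signal
(the connectivity component approaches its ceiling), so preservation
evidence should be read as thresholded, not as an effect-size scale.

**Fisher tests.** The one-sided p is the exact hypergeometric upper tail;
the odds ratio is the raw cross-product ratio (matching the scale on
which such tables are usually reported), with `Inf` for a zero
denominator and an explicit, never-silent Haldane–Anscombe variant. Exact
tails are conservative on small discrete tables, so enrichment z scores
have a slightly negative null mean for sets of a few genes in a small
universe; the effect vanishes for realistically sized sets.

**OSM.** The published description of the susceptibility metric is
verbal; the formula here — per-drug one-sided enrichment z =
$\Phi^{-1}(1-p)$ with p clipped to $[10^{-15}, 1-10^{-15}]$ (evaluated as
$-\Phi^{-1}(p)$ to preserve tail precision), Stouffer-combined across the
panel, then standardized across modules — is this package's concrete
reconstruction, not a reproduction; `mean` and `max` aggregations are
available behind a flag. Susceptibility is direction-agnostic
(thresholding on \|score\|): the metric asks whether a module is robustly
modulated, while directionality is the interaction stage's job. Note the
scaled score is bounded near $(k-1)/\sqrt{k(k-1)}$ when one of $k$
modules dominates, so comparisons of planted-effect strength should use
the raw combined z.

**Deconvolution.** A constrained least-squares deconvolver (per-sample
nonnegative least squares against the signature matrix, renormalized to
the simplex) stands in for support-vector-regression-based tools with the
same input/output contract; it is deterministic and dependency-light. An
all-zero solution falls back to uniform proportions with a warning —
expected when deconvolving log-scale values that can be negative.

**Associations.** Spearman correlation with average ranks is used for all
eigengene–covariate associations, for robustness and consistency with the
proportion–eigengene analyses; the p-value is the large-sample
approximation from `cor.test`.

**KS comparison.** The two effect-score vectors over the overlap genes
are treated as two independent samples (unpaired), and the p-value is the
asymptotic Kolmogorov series truncated at terms $<10^{-18}$, without
continuity correction; a paired sign summary is effectively available
through the discordance quadrant fractions. D is computed exactly over
the pooled support, so it is invariant under common monotone transforms.
Zero scores form their own category in the discordance table, counted but
excluded from the sign fractions.

**Determinism.** Every stochastic stage takes an explicit seed; the
pipeline derives a fixed substream per stage from the master seed, so a
stage can be re-run in isolation and still match the full run, and two
runs with the same configuration are byte-identical. Reports serialize
numbers with 17 significant digits so TSV round trips are lossless at
1e-12.

# Problem sizes in the validation suite

The recovery suites run the default study conditions: 5 modules × 60
genes plus 1000 background genes, 200 samples, unit noise; an external
cohort of 160 samples preserving four of the five modules; 20 replicate
seeds for module/hub/phenotype recovery and the interaction contrast, 40
for the susceptibility ranking, 200 permutations for preservation. Oracle
suites cap instances at 20 genes (TOM), a 60-gene universe (Fisher), and
200 pooled observations (KS), where brute-force enumeration is exact and
fast. These sizes were chosen so the whole suite exercises every claim at
the default conditions in a few minutes on one core.

# Known limitations

- The static cut requires sensible `power`/`cut_height` for small gene
  sets; there is no automatic adaptation.
- No block-wise network construction: memory is quadratic in genes, so
  ~30k-gene matrices need pre-filtering (`filter_genes`).
- Preservation uses a two-component Z, not the full multi-statistic
  composites in the literature; counts of "replicable" modules are
  threshold-dependent.
- The OSM is a documented reconstruction of a verbally described metric;
  rank-based connectivity-map scores are out of scope.
- Deconvolution assumes expression on a scale where mixing is
  approximately linear over the signature genes and offers no
  absolute-mode estimates.
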