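# coexdrug

Systems-biology toolkit for asking whether two classes of drugs converge
on the same transcriptional program in bulk tumor expression data. It was
built for the analysis pattern in which a tumor cohort yields gene
coexpression modules, a second cohort establishes which modules
replicate, modules are localized to cell types and clinical phenotypes,
a panel of perturbation signatures scores each module's drug
susceptibility, and two directional drug-response signatures are tested
for acting on a shared gene set in concordant or opposing directions —
for example, opioid analgesics versus immune-checkpoint inhibition in
triple-negative breast cancer. Intended users are computational
biologists who have expression matrices and signature tables on disk and
want a reproducible, scriptable pipeline rather than a collection of
notebook fragments.

## The model in brief

- **Modules.** From a genes × samples log-expression matrix, adjacency
  $a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$ (power $\beta$ chosen by
  signed scale-free fit), topological overlap
  $\mathrm{TOM}_{ij} = (\sum_{u} a_{iu}a_{uj} + a_{ij}) /
  (\min(k_i, k_j) + 1 - a_{ij})$, average-linkage clustering of
  $1-\mathrm{TOM}$ with a static cut; modules are named by size from the
  conventional color palette, `grey` = unassigned. Eigengene = first PC
  of the standardized module submatrix; kME = gene–eigengene correlation;
  hubs = top-kME genes.
- **Preservation.** Per module, density (mean $|\mathrm{cor}|$ in the
  test cohort) and connectivity agreement (correlation of intramodular
  connectivities across cohorts), each standardized against random
  unassigned gene sets: $Z_{\mathrm{summary}} \ge 2$ flags a replicable
  module.
- **Enrichment.** One-sided Fisher overlap (exact hypergeometric tail,
  raw cross-product odds ratio) with Benjamini–Hochberg correction per
  table; cell-type calls use `p < 0.05` and `OR > 1`, phenotype
  associations use Spearman rho at FDR 0.1.
- **Susceptibility (OSM).** Per (module, drug): enrichment of the module
  in the drug's top `5%` most-responsive genes as
  $z = \Phi^{-1}(1-p)$; per module: Stouffer combination
  $\sum_d z_d / \sqrt{n_d}$, standardized across modules.
- **Interaction.** Overlap enrichment of two signatures' gene sets, sign
  discordance quadrants of the shared genes, and a two-sample
  Kolmogorov–Smirnov test on the two effect-score vectors with the
  asymptotic p-value
  $2\sum_{k\ge1}(-1)^{k-1}e^{-2k^2\lambda^2}$,
  $\lambda=\sqrt{nm/(n+m)}\,D$.

A latent-factor synthetic-data generator (`simulate_study()` and
friends) produces every input with recorded ground truth, so each stage
is testable end to end without external downloads. See the methods
vignette (`vignettes/coexpression-drug-interaction.Rmd`) for assumptions,
parameter rationale, and limitations.

## Worked example

```r
library(coexdrug)

study <- simulate_study(seed = 1)          # synthetic cohort + ground truth
expr  <- filter_genes(study$expr)

sft     <- pick_soft_threshold(expr)       # chosen power: 3
tom     <- topological_overlap(build_adjacency(expr, sft$power))
modules <- merge_close_modules(expr, detect_modules(tom), 0.75)
table(modules)
#>      blue     brown     green      grey turquoise    yellow
#>        70        67        65       958        73        67

eig   <- compute_eigengenes(expr, modules)
assoc <- correlate_eigengene_covariate(eig, cbind(sTIL = study$phenotype))
head(assoc, 3)
#>   module covariate     rho  p_value  q_value significant
#> 1  brown      sTIL  0.8638 7.22e-61 3.61e-60        TRUE
#> 2   blue      sTIL -0.0326 6.47e-01 8.32e-01       FALSE
#> 3 yellow      sTIL  0.0256 7.19e-01 8.32e-01       FALSE

osm <- susceptibility_metric(modules, study$panel, universe = rownames(expr))
osm[, c("module", "raw_osm", "scaled_osm")]
#>      module raw_osm scaled_osm
#> 1     brown   15.88      1.763
#> 2    yellow   -2.65     -0.152
#> 3      blue   -6.19     -0.517
#> 4     green   -6.33     -0.532
#> 5 turquoise   -6.62     -0.562

top <- lapply(list(op = study$sig_opioid, ici = study$sig_ici),
              drug_response_geneset)
rep <- build_interaction_report(study$sig_opioid[top$op],
                                study$sig_ici[top$ici], rownames(expr))
c(rep$n_overlap, rep$enrichment$odds_ratio,
  rep$discordance$overall_discordance, rep$ks$D, rep$ks$p_value)
#> overlap: 32 | OR: 35.3 | discordance: 1 | KS D: 1  p: 2.53e-14
```

Reading the output: five detected modules; the `brown` module carries the
planted phenotype driver (its eigengene tracks the sTIL-like fraction,
rho = 0.86, the only FDR-significant association) and is the module the
four-drug panel targets (top scaled OSM, 1.76). The opioid-analog and
ICI-analog signatures share 32 of their top-responsive genes (odds ratio
35, far beyond chance), every shared gene moves in opposite directions
(discordance 1.0), and the two effect-score distributions differ
maximally (KS D = 1, p ≈ 3e-14) — the synthetic analog of an
opposing-regulation finding, with ground truth to check it against.

The same pipeline runs from the shell:

```sh
exec/coexdrug run --seed 1 --outdir run1      # 7 reports + run_log.yaml
exec/coexdrug simulate --seed 1 --outdir sim  # inputs as TSV/GMT + truth
```

File-based inputs (expression TSV, GMT libraries, long-format signature
tables, covariates) drive the identical stages via `run_pipeline()` with
a YAML configuration; see `?default_config`.

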