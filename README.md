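# ssnetgwas

Network-assisted analysis of genome-wide association study (GWAS) data in
R: gene-level association testing with a linkage-disequilibrium-aware
Monte Carlo null, dense module search on a node-weighted protein–protein
interaction (PPI) network, two-stage module significance evaluation,
a degree-preserving test of direct interconnectivity, and gene-set
over-representation analysis.

## Who this is for

GWAS of complex (e.g. autoimmune) diseases leave most of the genetic
architecture below the genome-wide significance threshold. This package
is for analysts who want to mine such data jointly with a PPI network:
genes whose products interact with associated genes are themselves
candidates ("guilt by association"), and *sets* of interacting genes can
carry a significant combined signal even when no single SNP does.

## The method

1. **Gene scores.** For each gene (body ± 20 kb, autosomes), the
   statistic is the sum of upper-tail χ²₁ quantiles of its SNP P-values,
   `T = Σⱼ Q(pⱼ)`. Its null is simulated from `N(0, R)` with `R` the SNP
   LD matrix, giving `p = (#{T⁽ᵇ⁾ ≥ T} + 1)/(B + 1)` with an adaptive
   number of draws `B` (10³ → 10⁴ → 10⁶).
2. **Node-weighted network.** Interactions supported by ≥ 2 unique
   publications form the graph; each scored gene gets weight
   `z = Φ⁻¹(1 − p)`. Genes in the MHC region with `p < 0.05`
   (*sigMHC-genes*) stay in the network but are left unweighted, are
   never search seeds, and rejoin the candidate list at the end.
3. **Dense module search.** From every weighted seed, greedily absorb the
   neighbor maximizing `Zm = Σz / √k`, accepting a step only if
   `Z(m+1) > Zm·(1 + r)` with `r = 0.1`.
4. **Evaluation.** Stage 1: median-center all module scores, fit a normal
   to the central 50% band (empirical null), keep modules with upper-tail
   `p_norm < 0.05`. Stage 2: compare each survivor against 10,000 random
   gene sets matched to its size and degree-quartile profile;
   keep `p_topo < 0.05`. Survivors ∪ sigMHC-genes = candidate genes.
5. **Connectivity.** Direct edges among module genes vs. a null from
   shuffling node labels within exact-degree classes (topology fixed).
6. **Enrichment.** One-sided Fisher exact tests against a GMT collection
   over the weighted-network background, Benjamini–Hochberg selection at
   adjusted `P < 0.25`.

A seeded synthetic-data generator (scale-free interactome with
publication counts, planted connected low-P module, mock MHC region,
AR(1)-LD SNP blocks) makes the whole pipeline testable without any
external download.

## Worked example

The numbered scripts under `analysis/` run a complete synthetic study
(1,000 genes, planted 8-gene module, 40 mock-MHC genes):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_gene_scores.R
Rscript analysis/03_build_network.R
Rscript analysis/04_search_modules.R
Rscript analysis/05_evaluate_modules.R
Rscript analysis/06_connectivity.R
Rscript analysis/07_enrichment.R
```

Output of the run shipped here (seed 2048):

```
simulated interactome: 1000 genes, 2994 interactions
planted module: g0020 g0033 g0044 g0544 g0614 g0643 g0829 g0890

scored 1000 genes from 1000 SNPs
genes with P < 0.05: 65

node-weighted network: 997 nodes, 2380 edges
weighted genes: 995 | sigMHC-genes: 2 (g0559 g0662)

948 distinct modules from 995 seeds
module sizes: 1-21 | top score: 7.761

empirical null: center 2.750, mu 0.239, sigma 2.837 (central_matching)
948 modules -> 5 past the score test -> 5 final
module genes: 16 | candidates incl. sigMHC: 18
planted genes recovered: 6 / 8

module genes: 16 | direct edges: 16
null mean 1.25 edges; permutation P = 0.0001 (10000 perms)

    term overlap set_size            p        p_adj
 PLANTED       6        8 1.659862e-10 6.639449e-10
    HALF       3       12 6.886133e-04 1.377227e-03
selected at BH-adjusted P < 0.25: PLANTED, HALF
```

Reading this: of 948 deduplicated greedy modules, 5 score in the extreme
tail of the empirical null *and* beat their degree-matched random
counterparts; their union (16 genes) contains 6 of the 8 planted signal
genes, is ~13× more densely self-connected than degree-matched chance
(16 observed edges vs. a null mean of 1.25; the P-value 1e-4 is the
permutation floor at 10,000 permutations), and is enriched for the
planted set. The two sigMHC-genes join the final 18-gene candidate list
without influencing the search. Recovery at this scale is seed-dependent
— see the vignette's discussion of empirical-null contamination.

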