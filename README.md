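# psdsim

Stochastic assembly and differential analysis of postsynaptic protein
complexes.

## What it is for

The postsynaptic density (PSD) is built from the same major scaffold
proteins in essentially every excitatory synapse, but their copy numbers
vary widely between brain regions. A *hypomorphic* mutation weakens a single
protein:protein interaction without abolishing it — and its functional
effect can still be region-specific, because complex formation depends on
the availability of every partner in the network, not just the two proteins
whose bond is weakened.

`psdsim` is for systems/computational neurobiologists who want to simulate
this. It provides:

* a **rule-based Gillespie engine** (C++ core) that assembles complexes from
  multivalent proteins under site-level binding rules with mass-action
  on/off rates;
* **topology-aware complex identities**: canonical keys under which two
  complexes coincide exactly when their labeled bond graphs are isomorphic
  (same composition with different binding patterns counts as different);
* a **region pipeline**: mRNA-to-copy-number scaling anchored on PSD-95,
  paired wild-type/mutant replicate simulations with common random numbers,
  and the region-by-complex abundance matrix;
* the **relevance score**: PCA of that matrix, with each complex scored by
  variance-weighted, L1-normalized absolute loadings
  (`r_j ∝ Σ_i λ_i |u_ij| / ||u_i||₁`, normalized to `Σ r_j = 1`), whose
  maximum defines the *most informative complex*;
* **paired statistics**: per-complex paired t-tests
  (`t = mean(a−b)/(sd(a−b)/√n)`, df = n−1, two-sided) across regions with
  Benjamini–Hochberg control, plus a Shapiro–Wilk normality screen.

The bundled `psd7_default` model covers NMDAR, AMPAR, PSD-95, SynGAP, GKAP,
Shank1 and Homer1 with eight binding rules; the default mutation scenario
multiplies the Shank1 PDZ : GKAP dissociation rate by 5.5 (the estimated
effect of the Shank1 R743H substitution). Any model can be supplied as a
YAML config; any region table as a flat TSV.

## Worked example

```r
library(psdsim)

# model + synthetic regions with the reference abundance statistics + the
# 5.5-fold Shank1 PDZ : GKAP off-rate mutation
ex <- make_psd7_experiment(seed = 1, n_regions = 10)

# paired wild-type/mutant replicates, common random numbers
pairs <- run_experiment(ex$regions, ex$model, ex$mutation,
                        n_rep = 10, base_seed = 0)
wt  <- assemble_matrix(pairs, "wt")
mut <- assemble_matrix(pairs, "mut")
dim(wt)
#> [1]     10 101623

# most informative complex by the PCA relevance score
r <- relevance(pca_abundance(wt))
mi <- most_informative(r)
composition_string(mi$key); mi$relevance
#> [1] "PSD-95"
#> [1] 0.4136782

# wild-type vs mutant displacement in the first two wild-type PCs
pd <- project_and_distance(wt, mut, k = 2)
c(mean = pd$mean, sd = pd$sd)
#>      mean        sd 
#> 0.6036186 0.6683120

# per-region paired test of the most informative complex, BH across regions
cmp <- compare_all(pairs, focus = mi$key)
head(cmp[cmp$key == mi$key, c("region_id", "mean_wt", "mean_mut", "t", "p")])
#>       region_id mean_wt mean_mut          t         p
#> 2118      R0001 309.257  309.184  0.3484095 0.7355438
#> 8622      R0002  30.195   30.458 -0.9562400 0.3639298
#> 27848     R0003  70.238   70.162  0.2502498 0.8080131
#> 42544     R0004   7.160    7.160  0.0000000 1.0000000
#> 56664     R0005   7.199    7.390 -1.6579192 0.1317106
#> 70495     R0006  23.231   23.022  1.2190302 0.2538182
```

Read: 10 synthetic regions produced 101,623 distinct complex topologies;
free PSD-95 carries the largest share (~41%) of the between-region variance
in complex space; the mutation displaces regions by 0.60 ± 0.67 abundance
units in the PC1/PC2 plane, and the per-region changes in the most
informative complex are small relative to replicate noise. With the identity mutation
(`mutation_spec("shank1_pdz_gkap", 1)`) and paired seeds, every t is 0,
every p is 1 and every distance is exactly 0 — the pipeline's built-in null.

A command-line front-end wraps the same steps
(`synth`, `simulate`, `analyze`, `demo` subcommands):

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "psdsim.R", package = "psdsim"))')" \
  demo --out demo_run --n-regions 10 --n-rep 5 --seed 1
```

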