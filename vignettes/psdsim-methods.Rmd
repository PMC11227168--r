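---
title: "Simulating postsynaptic complex formation and the effect of a hypomorphic mutation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating postsynaptic complex formation and the effect of a hypomorphic mutation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

The postsynaptic density (PSD) is a protein network built from the same major
scaffold proteins in essentially every excitatory synapse, yet its composition
varies widely between brain regions. A *hypomorphic* mutation — one that
weakens, but does not abolish, a single protein:protein interaction — can have
effects that are specific to particular cell types even though the interaction
itself occurs everywhere. `psdsim` asks this question in a controlled,
simulation-based setting: given per-region protein copy numbers, how does the
distribution of protein complexes change when one binding rule's dissociation
rate is multiplied by a constant factor, and in which regions is that change
statistically detectable?

The package implements the complete pipeline:

1. a **rule-based stochastic engine** (direct-method Gillespie) assembling
   complexes from multivalent proteins,
2. **topology-aware canonical identities** for the complexes formed,
3. a **region pipeline** producing paired wild-type/mutant replicate sets and
   a region-by-complex abundance matrix,
4. a **PCA-derived relevance score** identifying the most informative
   complexes, and
5. **paired t-tests with Benjamini–Hochberg control** per complex across
   regions.

## The seven-protein model

The bundled `psd7_default` model contains two receptors (NMDAR, AMPAR) and
five scaffolds (PSD-95, SynGAP, GKAP, Shank1, Homer1) with eight site-level
binding rules:

* NMDAR and AMPAR each carry two cytoplasmic tails binding the tandem PDZ1/2
  sites of PSD-95 (two identical copies per PSD-95);
* SynGAP binds PSD-95's PDZ3; GKAP bridges PSD-95's GK domain to the Shank1
  PDZ domain;
* Shank1 polymerizes head-to-tail through its SAM domain and recruits Homer1
  (EVH1 ↔ Shank1 proline-rich region); Homer1 self-associates through its
  coiled coil.

Homer1 tetramerization is approximated by pairwise chain self-association
(`cc_a` ↔ `cc_b`); this preserves Homer1's role as a cross-linker growing
large Shank/Homer assemblies without introducing a four-body rule.

Rates follow mass action per free site pair. Only the dissociation constant
matters for the stationary complex distribution, so every rule uses
`k_on = 1` (arbitrary inverse time) and imposes its affinity through `k_off`,
i.e. `Kd = k_off` in copy-number units. The shipped `Kd` values are
**placeholders at copy-number scale** (tens for the polymerizing rules up to
50 for the receptor tails), chosen once so that the receptor/scaffold
complexes of interest form at appreciable abundance while Shank1/Homer1 grow
much larger polymeric assemblies; any user-supplied table of measured
affinities can be substituted through the YAML model schema
(`load_model()`/`write_model()`).

The hypomorphic mutation is a `mutation_spec(rule, factor)`: the target
rule's `k_off` (hence its `Kd`) is multiplied, `k_on` untouched. The default
scenario multiplies the Shank1 PDZ : GKAP off-rate by **5.5**, the estimated
weakening of that interaction by the Shank1 R743H substitution; factor 1
is the identity and is used as the pipeline's exact null.

## The stochastic engine

The engine is a direct-method Gillespie simulator over association and
dissociation events, implemented in C++:

* association propensity of a rule = `k_on ×` (number of eligible free-site
  pairs). Pairs inside one complex are excluded by default
  (`allow_intra_complex_binding = FALSE`), so every complex is a **tree** in
  the bond graph; a flag enables ring closure for generality. For self-rules
  on a single site class, unordered pairs are counted.
* dissociation propensity = `k_off ×` (number of existing bonds of the rule).
* waiting times are exponential at the total propensity; one event is applied
  per step. Eligible pairs are sampled by rejection with an exact
  enumeration fallback, so sampling is uniform over eligible pairs even when
  most free sites sit in one large complex.

Complex membership is tracked incrementally (components merge on binding and
split on unbinding, with a bidirectional search that finds the smaller side
of a split). Species copy numbers are conserved *exactly* in every snapshot —
this is asserted in the test suite over thousands of snapshots.

A readable pure-R reference implementation of the same chain
(`sim_state()`, `event_propensities()`, `sim_step()`) is exposed for
inspection and is validated against both the compiled path and the exact
birth–death oracle below.

### Recording scheme and numerical choices

A run simulates to `t_end` and records the complex distribution at
`n_samples` snapshots evenly spaced over the last
`(1 - burn_in_fraction) · t_end`; reported abundances are snapshot means.
Defaults: `t_end = 5`, `burn_in_fraction = 0.5`, `n_samples = 100`. With the
fixture's rates the slowest rule relaxes on a timescale of `1/k_off ≈ 0.2`
time units, so the burn-in covers more than ten relaxation times; doubling
`t_end` moves the replicate-mean abundances of the dominant fixture
complexes by under ~2%, within Monte-Carlo noise at the default replicate
counts. Identical `(model, abundances, seed)` inputs give bitwise identical
results (a dedicated 64-bit generator is seeded per run; replicate `i` of a
set uses `base_seed + i`, and region `r` of an experiment offsets its seeds
by `(r-1) × 10000`, independent of scheduling).

The engine validation uses an exact oracle: for `A + B ⇌ AB` the bond count
is a one-dimensional birth–death chain whose stationary law follows from
detailed balance (`exact_dimer_equilibrium()`). The tests require the
simulated mean occupancy to sit within 3 Monte-Carlo standard errors of the
closed-form mean, and the full empirical bond-count distribution to pass a
chi-square goodness-of-fit against the exact law across seeds.

## Complex identity

Two complexes are the same iff their labeled bond graphs are isomorphic:
nodes carry species, edges carry the rule and the site name at each endpoint.
Identical site copies (the two PDZ1/2 of one PSD-95) are interchangeable —
edges record site *names*, never copy indices — while binding the *same*
versus a *different* PSD-95 copy in a larger assembly does change the
topology and therefore the identity.

`canonical_key()` returns a string invariant under instance renumbering: for
trees, a rooted canonical form minimized over the tree's one or two
centroids; for general graphs (rings/multi-edges, reachable only with
intra-complex binding enabled), color refinement followed by exhaustive
individualization, taking the minimum encoding over every branch. The test
suite enumerates **all** connected bond graphs realizable from the fixture
rule set up to 7 proteins (trees; the complete complex space of the default
acyclic dynamics) plus all ring/multi-edge closures up to 5 proteins, and
verifies that keys collide exactly when a brute-force permutation oracle
declares isomorphism.

Numeric complex ids are first-encounter conveniences maintained by
`complex_catalog()`; canonical keys are the stable identity (encounter order
is run-local and not comparable across implementations, so cross-run
analyses must join on keys, not ids).

## Region pipeline

Region tables are flat TSVs (`region_id`, `region_type`, one column per
protein). Expression data are converted to copies by `scale_mrna()`: one
**global** linear factor anchoring the across-region mean of PSD-95 to a
reference copy number (default 328.09). A per-region factor would erase the
between-region variation of PSD-95 itself — whose range spans 36–1067 copies
in the reference statistics — so a single global factor is used.

`run_region()` simulates both scenarios with **common random numbers**
(replicate `i` of wild-type and mutant share a seed, `paired_seeds = TRUE`).
This sharpens the paired comparison: the identity mutation then yields
*bitwise identical* scenarios, making every downstream statistic exactly
degenerate (t = 0, p = 1, distance 0) — the pipeline's null self-test. A
flag provides independent streams for users who prefer unpaired sampling.
Only the homozygous case is modeled (the mutant scenario contains mutant
protein only).

## Relevance and the most informative complex

Each region is a point in complex space (coordinates = complex abundances).
PCA is computed on the column-centered, *unscaled* region-by-complex matrix
(all abundances share one unit; variance-scaling would inflate rare-complex
noise) via the singular values of the centered matrix, with eigenvalue
`λ_i = σ_i²/(n−1)`.

The relevance of complex `j` combines the variance explained by each
component with the complex's contribution to it:

$$ r_j \;\propto\; \sum_i \lambda_i \frac{|u_{ij}|}{\lVert u_i \rVert_1},
   \qquad \sum_j r_j = 1 . $$

Each eigenvector enters through its L1-normalized absolute coordinates, so
the score is invariant to sign flips and its mean over `n` complexes is
exactly `1/n` (≈ 4.48·10⁻⁶ for the ~2.2·10⁵ complex types of a full-scale
run). The **most informative complex** is the arg-max of `r`; exact ties are
broken toward the smallest catalog id and flagged.

Wild-type/mutant displacement is measured in one common basis: the PCA is
fitted on the wild-type matrix and both scenarios are projected onto its
first `k` axes (default `k = 2`, the plotted plane; `k = Inf` uses all
components), both centered with the wild-type means. The per-region
Euclidean distance and its mean ± SD summarize how far regions move under
the mutation. Whether distances are taken in 2 PCs or all is a reporting
choice, not a modeling one; both modes are available.

## Paired statistics

For each (region, complex), `t = mean(a−b) / (sd(a−b)/√n)` on `n−1` degrees
of freedom with a two-sided p-value (df = 39 at the default 40 replicates).
Zero-variance differences — common for rare complexes with identical integer
counts — give the null result (t = 0, p = 1) when the mean difference is
zero and are flagged degenerate otherwise, avoiding spurious infinities in
full-table scans. Benjamini–Hochberg control is applied **across regions for
one focus complex** (the family behind a single reported threshold such as
the most informative complex's); complexes absent from a region in both
scenarios are excluded rather than tested. Appearance/disappearance of rare
supercomplexes is reported descriptively (`appearance_report()`), not
tested. A Shapiro–Wilk screen with BH control (`normality_check()`) checks
the normality assumption of the replicate means.

## Synthetic regions

`generate_regions()` draws per-protein copies from a truncated normal on the
profile's `[min, max]`, rounded to integers. The parent normal is
**moment-matched** so that the truncated distribution itself has the
profile's mean and SD; truncating a normal parameterized directly at the
profile values would bias the realized means upward by several standard
errors for the low-abundance proteins (NMDAR, Shank1, Homer1), and the
generated tables are meant to *reproduce* the reference statistics, not just
be inspired by them. A moment-matched log-normal is available behind
`distribution = "lognormal"` for skew-sensitivity checks. Proteins are drawn
independently: the between-protein correlation present in real expression
data is **not** emulated, and region types are round-robin labels without
type-specific profiles — so passing tests demonstrate the pipeline's
correctness and calibration, not biological conclusions about particular
brain regions. Real region tables load through the same reader and are fully
interchangeable with synthetic ones.

## Problem sizes and reproducibility

The test suite validates the engine against exact oracles on toy systems,
enumerates the canonicalization space exhaustively as described above, and
runs the end-to-end null (30 regions × 10 replicates) and the directional
mutation check (one region × 40 replicates) at the bundled fixture's scale.
`scripts/acceptance.R` re-runs the full pipeline from scratch at 48 regions
× 16 replicates per scenario (the full-scale setting of the study design is
524 × 40) and writes the principal quantities — complex-type count, PC1/PC2
variance shares, the top relevance share, PC-space displacement, BH results
for the most informative complex, the normality screen, and the engine-vs-
oracle dimer check — as JSON. All randomness in the script derives from its
`--seed` argument.

```{r}
library(psdsim)
ex <- make_psd7_experiment(seed = 1, n_regions = 30)
pairs <- run_experiment(ex$regions, ex$model, ex$mutation,
                        n_rep = 10, base_seed = 1000)
wt  <- assemble_matrix(pairs, "wt")
mut <- assemble_matrix(pairs, "mut")
r   <- relevance(pca_abundance(wt))
most_informative(r)
project_and_distance(wt, mut, k = 2)$mean
cmp <- compare_all(pairs, focus = most_informative(r)$key)
attr(cmp, "bh_threshold")
```

## Known limitations

* The fixture's site map and `Kd` values are a documented minimal topology
  with placeholder affinities, not measured constants; absolute abundances
  are therefore comparable only within a model configuration.
* No spatial organization, diffusion, compartments, or time-varying rates;
  no heterozygous (mixed wild-type/mutant) scenarios; no expression-level
  (pleiotropic) effects of the mutation.
* Complex ids are encounter-order artifacts; only canonical keys are stable.
* The acyclic default cannot form rings; enabling intra-complex binding is
  supported but uses the slower general canonicalizer for cyclic complexes.
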