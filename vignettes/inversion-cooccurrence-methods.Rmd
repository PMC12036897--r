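---
title: "Models and methods: segregation distortion and genotype-level co-occurrence of inversions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: segregation distortion and genotype-level co-occurrence of inversions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invcooccur)
```

## The experimental design and what it licenses

The package targets replicated F2 designs: inbred line crosses selfed to
produce F2 families, genotyped at a panel of chromosomal inversions as
RR / RI / II (reference homozygote, heterozygote, inverted homozygote).
Two facts make the statistics clean. First, Mendelian assortment fixes the
single-locus null at 1:2:1, so single-locus tests need no nuisance
parameters. Second, for loci on *different chromosomes* the gametic joint
distribution is the product of the marginals, so any association among
surviving F2 plants is a signature of differential survival (zygotic
viability selection) rather than linkage. All pairwise machinery in this
package therefore only ever tests cross-chromosome pairs; the within-
chromosome pairs are excluded at enumeration time.

## Single-locus segregation distortion

`williams_g_test()` computes the log-likelihood-ratio goodness-of-fit
statistic `G = 2 Σ O ln(O/E)` against expected class probabilities
(default 1:2:1), divided by the Williams small-sample correction
`q = 1 + (k² − 1) / (6 N (k − 1))`, `k = 3`, and referred to χ² with 2 df.
Zero observed counts contribute nothing to the sum (the `x log x → 0`
limit); no pseudo-counts or continuity corrections are applied — this rule
reproduces the reference worked examples to the printed precision (e.g.
counts 92/56/0 give G = 135.77). The segregation distortion value
`SDV = −log10 p` is computed on the log scale (`pchisq(..., log.p = TRUE)`),
so it stays finite where `p` underflows; for df 2 it equals `G / (2 ln 10)`
identically, which the suite asserts to machine precision.

The *mode* of selection is diagnosed sequentially. Stage 1
(`allele_balance_chi2()`) tests orientation transmission: with
`nR = 2·RR + RI` and `nI = RI + 2·II` alleles out of `2N`, the statistic
`2(nR − N)²/N` has 1 df and is zero exactly when RR = II. Stage 2 tests
the genotype distribution. The literature behind this sequential scheme
does not pin a unique second-stage formula, and the reference table's
printed χ²₂ column is not reproducible from either natural candidate (for
counts 53/95/3 the 1:2:1 χ² gives 43.2 and the Hardy–Weinberg-conditional
χ² gives 25.8, while the table prints 149.71 — yet for 28/95/28 the 1:2:1
χ² reproduces the printed 10.07 exactly). `selection_mode_test()` is
therefore a declared strategy point with two documented variants:
`one_two_one` (χ² against N/4, N/2, N/4; df 2) and `hwe_conditional`
(χ² against HW proportions at the observed allele frequency; df 1;
undefined and flagged when the allele frequency is 0 or 1). The default is
`one_two_one`, the variant that matches the verifiable printed value.
Classification: *gametic* when stage 1 rejects and stage 2 does not,
*zygotic* when stage 2 rejects, *none* otherwise, at a configurable level
(default 0.05). `sd_table()` applies all of this per segregating locus and
corrects the G-test p-values with Benjamini–Hochberg *within* the cross —
crosses are separate families and are corrected separately.

## The 3×3 omnibus test and its post hocs

For a locus pair, `omnibus_chi2_mc()` computes
`X² = Σ (O − E)²/E` and calibrates it by simulation, because expected
counts in the corner cells (double homozygotes, expected frequency 1/16)
are routinely small at F2 family sizes. Two expectation modes are exposed,
because the two natural framings differ and both are defensible:

* `margins` (default): `E = rᵢcⱼ/N`; null replicates are uniform random
  tables with both margins fixed, drawn with Patefield's algorithm
  (`r2dtable`). This conditions out single-locus distortion: a locus may
  be individually distorted without biasing the pair test.
* `mendelian`: `E = N·fᵢfⱼ` with `f = (¼, ½, ¼)`; null replicates are
  multinomial. This tests the joint Mendelian hypothesis instead.

The Monte-Carlo p-value is `(1 + #{X²* ≥ X²})/(B + 1)` (add-one rule, ties
counted; never exactly zero). `posthoc_residuals()` localizes a rejection:
standardized residuals `(O − E)/√(E(1 − rᵢ/N)(1 − cⱼ/N))` referred to the
standard normal (two-sided), corrected across the nine cells with
Benjamini–Yekutieli because the cells of one table are dependent, plus the
relative contribution `RC = 100·((O−E)²/E)/X²`, which sums to 100 by
construction. Cells are indexed row-major with rows = locus A, so cell 9
is (II, II) and cell 8 is (II, RI) — the convention used throughout,
including the simulator presets.

## The four 2×2 submatrices: a design decision that matters

Each locus pair decomposes into four dosage-state contrasts: HET/HET,
HOM/HOM, HET/HOM, HOM/HET (submatrices 1–4). There are two superficially
reasonable ways to build the 2×2 table for, say, HET(A) × HOM(B):

1. **Collapse**: presence = RI at A (respectively II at B), absence =
   anything else, all N individuals kept.
2. **Condition**: keep only individuals that are RR-or-RI at A *and*
   RR-or-II at B; presence = the state genotype, absence = RR.

We implement the conditional subtable (`table2x2_from_table3x3()`,
`state_pair_table2x2()`), and the choice is not cosmetic. Under a
viability perturbation of a single genotype-pair cell (survival rate `s`
on one of the nine cells), the conditional subtables that do not contain
the perturbed cell remain *exactly* independent — the renormalization
constant cancels within the subtable — so the four contrasts act as
separate detection channels that localize the perturbed cell. Collapsed
tables do not have this property: deflating the (II, II) cell induces an
odds ratio of 1.67 in the collapsed HET/HOM table at Mendelian
frequencies, so every channel would light up and the decomposition would
lose its diagnostic value. The package's simulation suite verifies the
channel separation directly (only submatrix 2 responds to a deflated
cell 9; submatrices 2 and 4 respond to the cell-8/cell-9 scenario).
`binarize_state()` itself keeps the simple whole-locus semantics (1 iff
the genotype equals the state's code, missing propagated), which is what
network node definitions and state enumeration use; the conditioning
happens at contrast time.

Missing genotypes are handled by pairwise-complete deletion: an individual
missing at either locus of a pair is dropped for that pair only, and the
count of dropped individuals is attached to the pair's 3×3 table.

## The two 0-centered co-occurrence indexes

**Centered Jaccard/Tanimoto.** For binary vectors with 2×2 counts
`(n11, n10, n01, n00)`, the Jaccard similarity `J = n11/(n11+n10+n01)` is
centered at its expectation under independence at the observed
prevalences `p = mA/n`, `q = mB/n`: `E[J] = pq/(p + q − pq)`, so
`cJ/T = J − E[J]` is positive under coupling and negative under repulsion.
Its null distribution is obtained by the bootstrap: the null model
permutes one vector against the other. Because a uniform permutation
fixes both margins, the permuted co-occurrence count `n11*` is exactly
hypergeometric, and the implementation samples it directly
(`rhyper`, B = 10,000 by default) — distributionally identical to explicit
shuffling (an explicit `method = "permutation"` is retained and the suite
checks both against an exhaustive placement enumeration at small n). The
two-sided p-value is `(1 + #{|cJ/T*| ≥ |cJ/T|})/(B + 1)`; ties count as
exceedances, the conservative choice, which we fix as the package's
definition since resampling tie-handling is rarely stated in field usage.

**Affinity score.** `affinity_alpha()` estimates the log odds ratio α of
the 2×2 table under the Fisher noncentral hypergeometric model with both
margins fixed — the maximizer of `P(n11 | n, mA, mB, odds = e^α)`, found by
solving `E_α[N11] = n11` (the conditional MLE, insensitive to state
prevalences). Tables whose `n11` sits at the boundary of its attainable
range have an infinite MLE and are reported as ±`cap` (default 10,
matching the convention of printing ±10.00 for boundary tables). The
p-value is the exact two-sided central hypergeometric test with the
minimum-likelihood tail rule; a mid-p variant is available but off by
default (the exact rule is the conservative standard). The suite
cross-checks both the MLE and the p-value against `fisher.test`'s
conditional estimate and against a dense-grid likelihood maximizer.

The two indexes agree in sign by construction whenever both are nonzero
and α is uncapped: `sign(cJ/T) = sign(n·n11 − mA·mB) = sign(n11·n00 −
n10·n01)`, an identity the suite tests. A contrast is flagged
`detected_by_all` when the cJ/T bootstrap p, the affinity exact p, and the
matching 3×3 post hoc cell's raw p are all below the level — the
coordinated-detection criterion used for network edge highlighting.

## The survival-rate simulator

`modified_expectation()` implements the viability model: expected cell
frequencies `f_mod,i = f_e,i·sᵢ / Σⱼ f_e,j·sⱼ`, where `s` is a
genotype-combination survival rate (1 = Mendelian, <1 = deflation). The
output is invariant to rescaling `s`, so only relative survival matters.
`simulate_tables()` draws each table multinomially with `n_individuals`
(default 400) over `f_mod` — the sampling law is our definitional choice
(the natural one for zygotic viability selection acting independently on
Mendelian zygotes conditioned on a fixed number of survivors scored).
Three presets fix the calibration scenarios: `null` (all s = 1), `alt1`
(cell 9 deflated to s = 0.2), `alt2` (cell 8 at s = 0.2, cell 9 at s = 1,
all other cells at s = 0.7).

`evaluate_frameworks()` runs all nine tests per table — one omnibus
Monte-Carlo p and a cJ/T and affinity p per submatrix — and returns the
nine p-value streams with rejection-rate and Kolmogorov–Smirnov summaries.
Inner replicate counts default to B = 1,000 in simulation mode (10,000 in
single-table mode); the package's distributional checks use 5,000 null
tables and 2,000 tables per alternative, a scale at which a rejection-rate
shift of two percentage points is resolvable while the whole
characterization runs in about a minute. Whether the omnibus test should
condition on margins or use known Mendelian expectations in simulations is
genuinely open; both are exposed (`expectation =`), with `margins` the
default everywhere for consistency with the real-data analysis.

Two numerical notes. First, the exact conditional 2×2 tests are discrete:
at n = 400 their attainable size at nominal 0.05 is about 0.040–0.044, so
null rejection rates sit slightly *below* nominal. The acceptance checks
compare empirical rates against the exactly computed attained level of
each stream (a closed-form average over the hypergeometric null given each
table's margins, including the bootstrap's B-replicate discretization)
rather than pretending the attainable size is 0.05. Second, p-values from
the add-one rule live on `{1/(B+1), ..., 1}`; their histograms show the
corresponding granularity.

`ld_metrics()` is provided for contrast with the haplotype-level view:
`D = p_AB − p_A p_B` and `D′ = D/D_max`, with the standard positive/negative
normalizers and `D′ = 0` at `D = 0`; monomorphic loci are flagged `NA`.
These operate on gamete frequencies and are not part of the genotype-level
pipeline.

## Networks, motifs, heterogeneity

`build_network()` turns contrasts into an undirected simple graph: nodes
are dosage states (printed suffixes `_1` = HET, `_2` = HOM_INV; the suffix
convention is our inference from the reference tables, where `_2` states
never appear for loci lacking II individuals), edges carry the cJ/T weight
and raw bootstrap p, with significance at raw p < 0.05 and a parallel flag
for omnibus-BH significance; node importance is eigenvector centrality on
absolute weights. Raw (not FDR-adjusted) p-values weight the edges
deliberately: the networks are descriptive syntheses, and the replicated-G
and motif stages supply the confirmatory statistics.

`motif_census()` counts connected induced subgraphs on 3 and 4 nodes
(path/triangle; path/star/cycle/tadpole/diamond/complete) via igraph's
isomorphism-class machinery, verified against brute-force subset
enumeration. Aliases `s.3.1–s.3.2` and `s.4.1–s.4.6` order classes within
a size by edge count, then ascending degree sequence — the canonical
(size, edges, degree-sequence) triple is the ground truth and the aliases
are cosmetic. `motif_enrichment()` builds the null by degree-preserving
double-edge swaps (10 attempted swaps per edge per replicate, R = 1,000 by
default; both configurable — the defaults trade Markov-chain mixing
against runtime), computes one-sided overrepresentation p-values
`(1 + #{null ≥ obs})/(R + 1)` (only overrepresentation is of interest),
Z-scores and observed/expected ratios from the null moments, excludes
classes observed fewer than `min_count = 200` times *before* BH
correction, and flags graphs too sparse to rewire.

`replicated_g()` decomposes association across crosses:
`G_total = Σ G_cross` (df = Σ df), `G_pooled` from the summed table (df 1),
`G_het = G_total − G_pooled`. The per-cross G is the plain independence G —
no Williams correction inside the decomposition, because additivity
(`G_total = G_pooled + G_het`, asserted to 1e−9) only holds for raw G;
a corrected variant would break the identity and is not offered inside
this function. Degenerate crosses (an empty margin) contribute G = 0 with
df 0 and are recorded. `sdv_interaction_summary()` closes the loop between
the single-locus and pairwise scales with Spearman correlations between a
locus's SDV and (a) its count of nominally significant pairwise tests and
(b) its mean pairwise p-value; constant inputs yield `NA` rather than a
spurious coefficient.

## The synthetic-cross generator

`simulate_f2_cross()` draws independent 1:2:1 genotypes per segregating
locus (loci are unlinked in the generator even within a chromosome label,
since the analysis only ever tests cross-chromosome pairs — simulating
linkage would add machinery the tests never exercise), applies zygotic
viability selection as the product of single-locus and pairwise survival
rates, and rejection-samples to the target number of survivors; only
post-fertilization selection is simulated, matching the regime the
sequential test diagnoses in this design. Missing calls are inserted
uniformly at `missing_rate`. `simulate_study_bundle()` fixes the emulated
study conditions: nine crosses with family sizes 92–188, 64 loci on 14
chromosomes, each locus segregating per cross with probability 0.55
(giving roughly half the pairwise space valid, as in the reference
design), one planted single-locus effect (s_II = 0.2) and one planted
cross-chromosome pair effect (s on (II, II) = 0.2) per cross — the same
effect size as the simulator's alternative presets — and a 2% missing-call
rate, a realistic genotyping dropout. These defaults are the bundle's
definition of "realistic" and are not tuned per analysis.

What the generator does *not* emulate: linkage and recombination maps,
gametic-phase distortion, genotyping error structure beyond uniform
dropout, and family structure within a cross. Tests that pass on this
generator therefore certify the statistics under the design's idealized
assumptions (independent assortment, zygotic selection, missing-at-random
calls), not robustness to correlated genotyping artifacts in real data.

## Degenerate inputs and tie-breaking, collected

* Empty tables, all-zero survival vectors, negative counts: hard errors.
* All-zero binary vectors and degenerate 2×2 margins: the contrast is
  invalid (error in the low-level functions; skipped with a recorded
  reason in `pairwise_contrasts`).
* Omnibus tables with an empty row/column under `margins` mode: statistic
  computed over non-degenerate cells and flagged.
* Monte-Carlo and bootstrap ties count toward the tail (conservative);
  the add-one rule bounds every resampled p away from zero.
* `hwe_conditional` at allele frequency 0 or 1: statistic undefined,
  flagged, classification falls back on stage 1.
* Spearman correlations on constant vectors: `NA`, never 0.

## Known limitations

* The four contrasts of a pair share one table and are not independent;
  the package reports them jointly and leaves family-wise interpretation
  to the BY-corrected post hocs and the `detected_by_all` flag.
* The second stage of the selection-mode test is a strategy point, not a
  settled formula; conclusions about gametic vs zygotic mode should cite
  the variant used (it is recorded in the output).
* Motif enrichment p-values depend on the rewiring chain's mixing; very
  dense or very sparse graphs mix poorly, and the `rewire_failed` flag
  marks the degenerate case.
* Bootstrap/Monte-Carlo resolution is bounded by B; with B = 10,000 the
  smallest attainable p is ~1e−4, which matters when screening thousands
  of contrasts at stringent FDR.
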