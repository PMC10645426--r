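---
title: "Relative binding energies from Spec-seq counts: models, estimation, and target classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative binding energies from Spec-seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specseqr)
```

# The measurement and its model

Spec-seq measures a transcription factor's sequence specificity by letting a
library of binding-site variants compete for one protein pool at
equilibrium, separating protein-bound from unbound DNA on a native gel, and
sequencing both fractions. For a protein `P` and site `S_i` under mass
action,

$$P + S_i \rightleftharpoons P{\cdot}S_i, \qquad
K_A(S_i) = \frac{[P{\cdot}S_i]}{[P]\,[S_i]},$$

so the ratio of a variant's concentration in the bound fraction to its
concentration in the unbound fraction is $K_A(S_i)\,[P]$. Because every
variant sees the same free-protein concentration, $[P]$ cancels from any
ratio of these odds, and relative affinities are measurable without knowing
$[P]$ — the quantity that is hardest to measure. With read counts standing
in for concentrations,

$$\frac{K_A(S_x)}{K_A(S_{ref})} \approx
\frac{N_B(S_x)\,N_U(S_{ref})}{N_B(S_{ref})\,N_U(S_x)},$$

and the relative binding energy is the natural logarithm of that ratio. We
report

$$\Delta\Delta G(x) =
\ln\frac{N_B(ref)/N_U(ref)}{N_B(x)/N_U(x)} \;\; [kT],$$

so the reference (consensus) sits at exactly 0 and weaker binders are
positive. A natural-log affinity ratio is dimensionless and therefore an
energy in units of kT; `energy_kcal_per_mol()` applies the constant
conversion (0.593 kcal/mol per kT at 25 °C) for readers who prefer molar
units.

```{r energies}
lib <- specseq_library("TAANNN", flank5 = "ACGTACGTAC", flank3 = "GTCAGTCAGT")
truth <- truth_pwm(lib, "TAATCC",
                   matrix(c(1.9, 2.3, 2.1, 0,
                            1.0, 0,   0.6, 1.3,
                            0.8, 0,   0.4, 1.1), 4, 3,
                          dimnames = list(c("A", "C", "G", "T"), NULL)))
sim <- simulate_counts(simulation_config(truth, lib, seed = 1,
                                         reads_per_fraction = c(1e6, 1e6)))
et <- relative_energies(sim$fc, "TAATCC")
head(et$energies, 3)
```

## Tunable parameters

* `pseudocount` (default 1, dimensionless count): added to all four counts in
  each odds ratio so zero-count variants get finite energies. At the read
  depths where Spec-seq is informative its bias is negligible; `0` is allowed
  when every used count is positive.
* `min_reads` (default 10 reads per fraction): variants below the floor are
  reported as missing rather than as unstable log-ratios. The assay
  description states no floor; 10 is a conservative default for count data
  whose log-ratio variance is roughly the sum of reciprocal counts. The
  reference must pass the floor — without an anchor there is no table.
* `max_mismatch` (default 2): the regression neighborhood around the
  consensus. Restricting the fit to at most two mismatches keeps the additive
  model in the regime where it approximates homeodomain energetics well;
  far-from-consensus variants are both noisier (weak binding, few bound
  reads) and more likely to bind in alternate registers.

# The energy PWM regression

`fit_epwm()` models $\Delta\Delta G$ as a sum of independent per-position,
per-base contributions, fitted by least squares over the mismatch
neighborhood. The encoding is anchored: the consensus base of each position
is fixed at 0 kT and there is no intercept, so the model predicts exactly 0
for the consensus rather than being re-centered after the fact. Whether the
original analysis used an intercept is not documented; anchoring is this
package's choice and makes the anchor invariant structural instead of
statistical.

Numerical notes:

* The design matrix has one indicator column per (variable position,
  non-consensus base): 9 coefficients for a `TAANNN` library. The solve is
  `stats::lm.fit` with pivoting; the test suite checks it against an explicit
  normal-equations solution.
* A base never observed in the neighborhood gives an all-zero column; its
  coefficient is reported `NA` (missing), never extrapolated, and any
  prediction touching it propagates `NA`.
* `residual_sd` is $\sqrt{RSS/(n - \mathrm{rank})}$; on noiseless additive
  input it is 0 to machine precision.
* Fixed core positions (the `TAA` in `TAANNN`) are never fitted: the library
  cannot vary them, so mismatches are counted only at randomized positions.

For display, `logo_matrix()` mean-centers each variable position's four
energies (columns then sum to 0, tolerance far below 1e-9 kT) and negates
them so preferred bases plot upward; fixed positions are flagged as
information-free rather than drawn from data.

## Comparing experiments

`compare_energy_tables()` pairs variants measured in both tables and reports
Pearson r, the root-mean-square difference, a per-experiment noise level,
and the best linear fit of the second table on the first (ordinary least
squares by default; total least squares behind `fit = "tls"` for when both
axes carry comparable error). Both tables are anchored at 0, so a constant
offset between them is impossible by construction; slope deviations from 1
indicate a specificity scale change (e.g. a mutant more or less
discriminating than wild type). The published analyses quote a single
"noise level" without a formula; here it is defined as
$\mathrm{sd}(a-b)/\sqrt{2}$ — the per-experiment standard deviation under the
assumption that both replicates contribute equal independent noise — and the
definition travels with every report.

# The synthetic-data generator

`simulate_counts()` draws the two read pools from the equilibrium model the
estimator assumes: occupancy $\theta_i = A e^{-E_i}/(1 + A e^{-E_i})$ at
protein activity $A$ (free protein concentration times the reference
association constant), bound pool multinomial with probabilities
$\propto a_i \theta_i$, unbound $\propto a_i (1-\theta_i)$, where $a_i$ is
the library composition (uniform by default). Two properties make it a
useful oracle:

* In `expected` mode the exact expected counts are emitted; running the
  estimator on them returns the truth energies to better than 1e-12 kT for
  any activity, because $A$ cancels from every odds ratio. This is the
  mechanical form of measuring relative affinity without knowing the free
  protein concentration.
* Sampled mode is a faithful generative model of counting noise, so
  estimator error must shrink as depth grows; the tests check a full decade
  ladder from 1e3 to 1e6 reads per fraction.

`emit_reads()` wraps each counted molecule in the conserved flanks and
applies i.i.d. per-base substitution errors. Read matching discards any read
with a conserved-region mismatch, so the flank-reject rate at error rate $e$
is $1-(1-e)^{L}$ for flank length $L$ — a closed form the round-trip tests
check against a 99% binomial interval. What the generator does **not**
model, and what passing tests therefore cannot certify about real data: PCR
amplification bias, gel-extraction artifacts, position-correlated sequencing
errors, alternate binding registers, and cooperative or dimeric binding. Read
depth stands in for library amplification. One root seed drives every
stream; derived per-component seeds (`derive_seed()`) keep stages
independently reproducible.

The default study conditions are activity 1 (consensus half-bound, the
informative regime for an EMSA), 1e6 reads per fraction (typical for a
MiSeq-scale Spec-seq run), uniform library composition, and per-position
penalties up to ~1-3 kT, which spans the dynamic range homeodomain
monomers show between consensus and weakest sites.

# Target classification

The downstream stage consumes differential tables (id, log2FC, FDR, cpm)
produced upstream by the standard count-model packages — they are inputs
here, not re-estimated. The classification chain:

1. `lost_peaks()`: binding lost in the mutant — ChIP log2FC strictly below
   −1 and FDR strictly below 5e-2.
2. `assign_peaks()`: each peak to the closest TSS within 100 kb (inclusive),
   peak position = interval midpoint, BED coordinates 0-based half-open.
   Exact distance ties break to the lexicographically smallest gene id, and
   the rule is recorded in the result. The stated rule is implemented
   directly rather than reproducing any annotation tool's internals.
3. `classify_genes()`: over genes with at least one lost peak,
   `dependent_activated` if adult expression log2FC < −0.6 and FDR < 1e-5,
   `dependent_suppressed` if log2FC > 0.6 at the same FDR cut, otherwise
   `independent`. "Not significantly affected" is operationalized as the
   complement (FDR ≥ 1e-5 or |log2FC| ≤ 0.6) and recorded in the
   provenance; the classification universe is peak-associated genes, also
   recorded.
4. `call_deg()`: cpm ≥ 5 (inclusive, "at least"), |log2FC| strictly > 1,
   FDR strictly < 1e-2.

Every fold-change and FDR threshold is strict as printed; the cpm floor and
the distance cap are inclusive as printed ("at least", "within"). Boundary
unit tests pin each one.

`simulate_targetome_tables()` plants the classes with effect distributions
truncated strictly inside the thresholds (ChIP log2FC ~ normal(−2, 0.5)
truncated below −1, and so on), so recovery must be exact — any
misclassification is a code defect, not bad luck. Decoy peaks are placed
more than 100 kb from every TSS to exercise the distance rule, and retained
(non-lost) peaks to exercise the ChIP thresholds.

`developmental_correlation()` computes sample-wise Pearson correlations over
a gene set between a query expression matrix and a developmental reference.
The transform is `log2(cpm + 1)` by default (raw cpm and per-gene z-scores
are options); the original figure does not state its transform, so the
choice is recorded on the result. In the generator, each activated gene
ramps up monotonically at its own rate across five pseudo-ages — the
gene-specific rates are what make distinct ages distinguishable by
correlation; a shared ramp shape would leave all ages equally correlated.

# Problem sizes and known limitations

The test suite and the acceptance script use the 64-variant `TAANNN`
library at 1e6 reads per fraction for count-level simulations (multinomial
draws are cheap at any depth) and 5e4-1e5 reads per fraction where actual
read strings are emitted and re-parsed; the targetome stage uses 600 genes
and ~700 peaks. These sizes give sub-percent Monte-Carlo noise on every
checked quantity while keeping a full run in seconds.

Limitations: the energy model is strictly additive (no dinucleotide or
epistatic terms); energies carry no error bars; libraries are single-core
with `N`-only degeneracy (no IUPAC codes, no spaced dimers); read matching
is fixed-offset with no indel handling; and the classification stage
implements printed thresholds on supplied statistics rather than refitting
differential models.
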