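# specseqr

Estimation of transcription-factor binding specificity from Spec-seq
experiments, and threshold-based classification of the factor's regulatory
targets.

## The problem

Spec-seq quantifies protein–DNA binding specificity by incubating a library
of binding-site variants with a purified DNA-binding domain, separating
protein-bound from unbound DNA on a native gel (an EMSA), and sequencing
both fractions. Under mass-action equilibrium the bound/unbound count odds of
each variant are proportional to its association constant times the free
protein concentration, so the free protein concentration cancels from every
ratio of odds and the **relative binding energy** of variant *x* against the
consensus reference is directly measurable:

```
ΔΔG(x) = ln[ (N_B(ref)/N_U(ref)) / (N_B(x)/N_U(x)) ]   (kT)
```

with the consensus at exactly 0 kT and weaker binders positive. Fitting
these energies with an anchored additive model gives an **energy position
weight matrix** (ePWM): one energy contribution per position and base, the
consensus base fixed at 0 per position. This is the modelling used to
characterize homeodomain (HD) monomer specificity — `TAANNN` libraries
probing the 3′ half of the HD site, where residue-50 contacts read out the
`CC`/`TA`-type preferences — and to compare wild-type against
disease-associated HD mutants.

Downstream, the package implements the corresponding regulatory-target
logic on differential-binding and differential-expression tables: peaks lost
in a mutant (ChIP log2FC < −1, FDR < 5e-2), assignment of peaks to the
closest TSS within 100 kb, classification of peak-associated genes into
dependent-activated / dependent-suppressed / independent by adult expression
thresholds (±0.6 log2FC, FDR 1e-5), differential-expression calls
(cpm ≥ 5, |log2FC| > 1, FDR < 1e-2), and sample-wise developmental
correlation of a gene set against a reference time course.

A biophysical simulator generates every input with known ground truth —
equilibrium bound/unbound partitioning of a library under an additive energy
model, FASTQ reads with conserved flanks and sequencing errors, and planted
differential tables — so each stage is verifiable end to end without
external data. All simulated reference models are synthetic.

## Worked example

```r
library(specseqr)

lib <- specseq_library("TAANNN", flank5 = "ACGTACGTAC", flank3 = "GTCAGTCAGT")

# synthetic WT-like truth: consensus TAATCC, penalties in kT
beta <- matrix(c(1.9, 2.3, 2.1, 0,
                 1.0, 0,   0.6, 1.3,
                 0.8, 0,   0.4, 1.1), 4, 3,
               dimnames = list(c("A", "C", "G", "T"), NULL))
truth <- truth_pwm(lib, "TAATCC", beta)

sim <- simulate_counts(simulation_config(truth, lib, seed = 1,
                                         reads_per_fraction = c(1e6, 1e6)))
et <- relative_energies(sim$fc, "TAATCC", pseudocount = 1, min_reads = 10)
et
#> Energy table: 64/64 variants measured, reference TAATCC = 0 kT
#>   range 0.000 .. 4.723 kT (pseudocount 1, min_reads 10)

fit_epwm(et, max_mismatch = 2)
#> Energy PWM anchored at TAATCC (37 variants fit, R^2 0.9999, residual sd 0.0106 kT)
#>    pos4  pos5  pos6
#> A 1.910 1.004 0.806
#> C 2.299 0.000 0.000
#> G 2.092 0.592 0.401
#> T 0.000 1.297 1.099

rep2 <- relative_energies(simulate_counts(simulation_config(truth, lib,
          seed = 2, reads_per_fraction = c(1e6, 1e6)))$fc, "TAATCC")
compare_energy_tables(et, rep2)
#> Energy comparison over 64 shared variants
#>   r = 1.000, rms difference = 0.028 kT, noise level = 0.018 kT
#>   best OLS fit: slope 1.000, intercept 0.012 kT
```

Reading the output: all 64 variants cleared the 10-read floor; the energy
range spans consensus (0 kT) to the weakest site (4.7 kT, ~110-fold weaker
affinity). The regression on the 37 variants within two mismatches of the
consensus recovers the planted penalties to ~0.01 kT, and two independent
simulated replicates agree with r ≈ 1 and a per-experiment noise level of
0.018 kT — the scale real replicate pairs of this assay show.
`logo_matrix()` turns the fitted ePWM into a mean-centered, negated matrix
for energy-logo rendering.

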