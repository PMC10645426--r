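#!/usr/bin/env Rscript
# Stage 2: from counts to binding models. Recounts the demonstration FASTQ,
# estimates relative binding energies for every experiment, fits anchored
# additive energy PWMs on the two-mismatch neighborhoods, and writes energy
# tables, ePWMs and logo matrices under results/.

suppressMessages(library(specseqr))

dir.create("results/models", showWarnings = FALSE, recursive = TRUE)
lib_fwd <- read_library_json("results/specseq/library_forward.json")
lib_rev <- read_library_json("results/specseq/library_reverse.json")

# FASTQ -> counts, with QC (how many reads were lost to flank errors)
fc_fastq <- count_fractions(read_reads("results/specseq/bound.fastq.gz"),
                            read_reads("results/specseq/unbound.fastq.gz"),
                            lib_fwd)
qc <- qc_summary(fc_fastq)
write_report_json(qc, "results/models/fastq_qc.json")
cat(sprintf("FASTQ recount: discard fraction %.3f (bound), %.3f (unbound); coverage %.2f\n",
            qc$discard_fraction[1], qc$discard_fraction[2], qc$coverage))

fit_one <- function(tag, lib, reference) {
  fc <- read_counts(sprintf("results/specseq/counts_%s.tsv", tag), lib)
  et <- relative_energies(fc, reference, pseudocount = 1, min_reads = 10)
  write_energy_table(et, sprintf("results/models/energies_%s.tsv", tag))
  pwm <- fit_epwm(et, max_mismatch = 2)
  write_pwm(pwm, sprintf("results/models/epwm_%s.tsv", tag))
  write_pwm(logo_matrix(pwm), sprintf("results/models/logo_%s.tsv", tag))
  cat(sprintf("  %-10s ref %s: %2d/64 variants measured, fit on %2d, R^2 %.4f, residual sd %.3f kT\n",
              tag, reference, et$n_used, pwm$fit$n_variants_fit,
              pwm$fit$r_squared, pwm$fit$residual_sd))
  list(et = et, pwm = pwm)
}

cat("Binding models (anchored regression on <=2-mismatch variants):\n")
wt1 <- fit_one("wt_rep1", lib_fwd, "TAATCC")
wt2 <- fit_one("wt_rep2", lib_fwd, "TAATCC")
mut <- fit_one("mut", lib_fwd, "TAATTA")
rev <- fit_one("wt_reverse", lib_rev, "GGATTA")

# the 3' half of the WT-like model carries the specificity, as expected for
# a K50-class homeodomain
cat("WT-like ePWM (kT, consensus bases at 0):\n")
print(round(wt1$pwm$beta, 2))
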