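#!/usr/bin/env Rscript
# Stage 3: compare energy tables between replicates, between genotypes, and
# between strands. Replicates from one truth should correlate near-perfectly
# with a small noise level; a specificity-switching mutant should correlate
# poorly with wild type; the reverse-strand control should reproduce the
# forward-strand energies once mapped back to forward-motif space.

suppressMessages(library(specseqr))

dir.create("results/comparisons", showWarnings = FALSE, recursive = TRUE)
lib_fwd <- read_library_json("results/specseq/library_forward.json")
lib_rev <- read_library_json("results/specseq/library_reverse.json")

et <- function(tag, lib, ref) {
  relative_energies(read_counts(sprintf("results/specseq/counts_%s.tsv", tag),
                                lib), ref)
}
wt1 <- et("wt_rep1", lib_fwd, "TAATCC")
wt2 <- et("wt_rep2", lib_fwd, "TAATCC")
mut <- et("mut", lib_fwd, "TAATTA")
rev <- et("wt_reverse", lib_rev, "GGATTA")

rep_cmp <- compare_energy_tables(wt1, wt2)
write_report_json(rep_cmp, "results/comparisons/wt_replicates.json")
cat(sprintf("WT replicate 1 vs 2: r = %.3f, noise level = %.3f kT, slope = %.3f\n",
            rep_cmp$pearson_r, rep_cmp$noise_level, rep_cmp$fit_slope))

mut_cmp <- compare_energy_tables(wt1, mut)
write_report_json(mut_cmp, "results/comparisons/wt_vs_mut.json")
cat(sprintf("WT vs specificity mutant: r = %.3f (distinct consensus, energies reshuffled)\n",
            mut_cmp$pearson_r))

# reverse-strand control: map the reverse library's energies into forward
# space through the cross-strand variant map (rebuilt from the forward
# library; a JSON definition carries no variant map), then compare with
# replicate 1
strand_map <- reverse_complement_library(lib_fwd)$variant_map
rev_fwd <- rev
rev_fwd$energies$variant <- unname(strand_map[rev$energies$variant])
rev_fwd$energies <- rev_fwd$energies[order(rev_fwd$energies$variant), ]
rev_fwd$reference_variant <- unname(strand_map["GGATTA"])
strand_cmp <- compare_energy_tables(wt1, rev_fwd)
write_report_json(strand_cmp, "results/comparisons/forward_vs_reverse.json")
cat(sprintf("Forward vs reverse-strand library (forward space): r = %.3f\n",
            strand_cmp$pearson_r))
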