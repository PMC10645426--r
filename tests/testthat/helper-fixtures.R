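# Shared fixtures: a small homeodomain-style library and ground-truth
# additive energy models, all built in code.

demo_library <- function(flank5 = "ACGTACGTAC", flank3 = "GTCAGTCAGT") {
  specseq_library("TAANNN", flank5 = flank5, flank3 = flank3,
                  name = "hd_forward")
}

# Synthetic wild-type-like truth: consensus TAATCC, fixed per-position
# penalties (kT) for the non-consensus bases.
wt_truth_beta <- function() {
  beta <- matrix(0, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  beta[, 1] <- c(A = 1.9, C = 2.3, G = 2.1, T = 0)    # pos 4, ref T
  beta[, 2] <- c(A = 1.0, C = 0, G = 0.6, T = 1.3)    # pos 5, ref C
  beta[, 3] <- c(A = 0.8, C = 0, G = 0.4, T = 1.1)    # pos 6, ref C
  beta
}

wt_truth <- function(lib = demo_library()) {
  truth_pwm(lib, "TAATCC", wt_truth_beta())
}

# Random anchored truth model with per-position penalties in
# [0, max_penalty] kT, so variant energies span [0, 3 * max_penalty].
random_truth <- function(lib, reference = "TAATCC", seed = 1,
                         max_penalty = 1) {
  set.seed(seed)
  pos <- which(strsplit(lib$core_pattern, "")[[1]] == "N")
  refc <- strsplit(reference, "")[[1]]
  beta <- matrix(stats::runif(4 * length(pos), 0, max_penalty), 4, length(pos),
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(pos)) beta[refc[pos[j]], j] <- 0
  truth_pwm(lib, reference, beta)
}

# Independent brute-force oracle: mismatch count over all core positions.
brute_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
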