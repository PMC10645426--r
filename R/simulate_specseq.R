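#' Equilibrium occupancy of a binding site
#'
#' Single-site mass-action occupancy at protein activity `A` (the product of
#' free protein concentration and the reference association constant):
#' \deqn{\theta = \frac{A e^{-E}}{1 + A e^{-E}}}
#' with `E` the site's relative binding energy in kT. Occupancy is strictly
#' decreasing in energy and equals `A / (1 + A)` at the reference (`E = 0`).
#'
#' @param energy relative binding energy in kT (vectorized).
#' @param activity positive unitless protein activity.
#' @return occupancy probability in (0, 1).
#' @export
occupancy <- function(energy, activity) {
  stopifnot(activity > 0)
  w <- activity * exp(-energy)
  w / (1 + w)
}

#' Configure a Spec-seq simulation
#'
#' Bundles the ground-truth additive energy model with the experimental
#' knobs: protein activity, library composition, sequencing depth per gel
#' fraction, per-base read error rate, and the root seed.
#'
#' @param truth_pwm an `energy_pwm` giving the ground-truth additive
#'   energies (see [truth_pwm()]).
#' @param library a [specseq_library()] whose core pattern matches the truth
#'   model.
#' @param activity positive protein activity `A` (free protein concentration
#'   times reference association constant); default 1 puts the reference at
#'   50% occupancy.
#' @param abundance optional per-variant relative library composition
#'   (recycled/normalized to sum 1); default uniform.
#' @param reads_per_fraction named or length-2 vector `(bound, unbound)` of
#'   total reads to draw per fraction.
#' @param error_rate per-base substitution probability for emitted reads,
#'   in `[0, 0.2]`.
#' @param seed integer root seed; all component streams derive from it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(truth_pwm, library, activity = 1,
                              abundance = NULL,
                              reads_per_fraction = c(bound = 1e6, unbound = 1e6),
                              error_rate = 0, seed = 1) {
  stopifnot(inherits(truth_pwm, "energy_pwm"),
            inherits(library, "specseq_library"),
            activity > 0,
            error_rate >= 0, error_rate <= 0.2,
            length(reads_per_fraction) == 2, all(reads_per_fraction >= 0))
  if (truth_pwm$core_pattern != library$core_pattern) {
    stop("truth model and library have different core patterns", call. = FALSE)
  }
  nv <- length(library$variants)
  if (is.null(abundance)) {
    abundance <- rep(1 / nv, nv)
  } else {
    stopifnot(length(abundance) == nv, all(abundance >= 0), sum(abundance) > 0)
    abundance <- abundance / sum(abundance)
  }
  reads_per_fraction <- stats::setNames(as.numeric(reads_per_fraction),
                                        c("bound", "unbound"))
  structure(
    list(truth_pwm = truth_pwm, library = library, activity = activity,
         abundance = abundance, reads_per_fraction = reads_per_fraction,
         error_rate = error_rate, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Build a ground-truth energy PWM directly from coefficients
#'
#' Convenience constructor for simulations: supply per-position energy
#' penalties for the non-reference bases (reference bases are 0 by the
#' anchored encoding).
#'
#' @param library a [specseq_library()].
#' @param reference_variant the consensus sequence (energy 0).
#' @param beta 4 x n_variable_positions numeric matrix (rows A/C/G/T) of
#'   energy contributions in kT; entries at the reference base of each
#'   position must be 0. Column order follows the library's variable
#'   positions.
#' @return an `energy_pwm` usable as simulation truth or with
#'   [predict_energy()].
#' @export
truth_pwm <- function(library, reference_variant, beta) {
  stopifnot(inherits(library, "specseq_library"))
  reference_variant <- clean_seq(reference_variant, what = "reference variant")
  if (!reference_variant %in% library$variants) {
    stop("reference variant is not in the library", call. = FALSE)
  }
  positions <- variable_positions(library)
  beta <- as.matrix(beta)
  stopifnot(nrow(beta) == 4, ncol(beta) == length(positions))
  dimnames(beta) <- list(DNA_BASES, paste0("pos", positions))
  refc <- strsplit(reference_variant, "")[[1]]
  for (j in seq_along(positions)) {
    if (abs(beta[refc[positions[j]], j]) > 1e-12) {
      stop(sprintf("beta at the reference base of position %d must be 0",
                   positions[j]), call. = FALSE)
    }
  }
  structure(
    list(positions = positions, beta = beta,
         reference_variant = reference_variant,
         core_pattern = library$core_pattern,
         fit = list(r_squared = NA_real_, residual_sd = 0,
                    n_variants_fit = 0L)),
    class = "energy_pwm"
  )
}

#' Simulate bound/unbound fraction counts under equilibrium binding
#'
#' Each variant is bound with probability given by its occupancy; the bound
#' read pool is multinomial over variants with probabilities proportional to
#' `abundance * theta` and the unbound pool proportional to
#' `abundance * (1 - theta)`. In `"expected"` mode the exact expected counts
#' are returned instead of sampling (un-rounded by default, so odds ratios
#' reproduce the truth energies exactly; `round = TRUE` gives integer
#' counts).
#'
#' Because both fractions scale with the same protein activity, the
#' estimated relative energies are invariant to `A`: it cancels from every
#' odds ratio, which is what lets relative affinities be measured without
#' knowing the free protein concentration.
#'
#' @param cfg a [simulation_config()].
#' @param mode `"sample"` (multinomial draws, seeded) or `"expected"`.
#' @param round in expected mode, round counts to integers (default FALSE).
#' @return list with `fc` (a `fraction_counts`) and `truth` (list with the
#'   per-variant `energies`, `theta`, `p_bound`, `p_unbound`,
#'   `expected_bound`, `expected_unbound`, and the `config` echo).
#' @export
simulate_counts <- function(cfg, mode = c("sample", "expected"),
                            round = FALSE) {
  stopifnot(inherits(cfg, "simulation_config"))
  mode <- match.arg(mode)
  lib <- cfg$library
  energies <- predict_energy(cfg$truth_pwm, lib$variants)
  theta <- occupancy(energies, cfg$activity)
  wb <- cfg$abundance * theta
  wu <- cfg$abundance * (1 - theta)
  if (sum(wb) <= 0) stop("degenerate bound fraction: all occupancies are 0",
                         call. = FALSE)
  if (sum(wu) <= 0) stop("degenerate unbound fraction: all occupancies are 1",
                         call. = FALSE)
  pb <- wb / sum(wb)
  pu <- wu / sum(wu)
  eb <- cfg$reads_per_fraction["bound"] * pb
  eu <- cfg$reads_per_fraction["unbound"] * pu
  if (mode == "sample") {
    set.seed(derive_seed(cfg$seed, "counts"))
    nb <- as.vector(stats::rmultinom(1, cfg$reads_per_fraction["bound"], pb))
    nu <- as.vector(stats::rmultinom(1, cfg$reads_per_fraction["unbound"], pu))
  } else {
    nb <- if (round) base::round(eb) else eb
    nu <- if (round) base::round(eu) else eu
  }
  list(
    fc = fraction_counts(lib, nb, nu),
    truth = list(energies = stats::setNames(energies, lib$variants),
                 theta = stats::setNames(theta, lib$variants),
                 p_bound = pb, p_unbound = pu,
                 expected_bound = unname(eb), expected_unbound = unname(eu),
                 config = cfg)
  )
}

# Apply iid per-base substitution errors to a character vector of reads.
add_read_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0) return(reads)
  len <- nchar(reads[1])
  n_err <- stats::rbinom(length(reads), len, error_rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    pos <- sample.int(len, n_err[i])
    chars <- strsplit(reads[i], "")[[1]]
    chars[pos] <- vapply(chars[pos],
                         function(b) sample(setdiff(DNA_BASES, b), 1),
                         character(1))
    reads[i] <- paste0(chars, collapse = "")
  }
  reads
}

#' Emit sequencing reads for counted molecules
#'
#' Every counted molecule becomes `flank5 + core + flank3`, with independent
#' per-base substitution errors at `error_rate`. Quality is a constant
#' string; read names encode the fraction and a serial number. Counts are
#' rounded to integers if needed.
#'
#' @param fc a `fraction_counts` object.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed for the error process.
#' @return list with `bound` and `unbound`, each a list of `reads` and
#'   `names` character vectors, ready for [write_fastq()].
#' @export
emit_reads <- function(fc, error_rate = 0, seed = 1) {
  stopifnot(inherits(fc, "fraction_counts"),
            error_rate >= 0, error_rate <= 0.2)
  lib <- fc$library
  template <- paste0(lib$flank5, fc$counts$variant, lib$flank3)
  one_fraction <- function(counts, tag, stream) {
    counts <- base::round(counts)
    reads <- rep(template, counts)
    set.seed(derive_seed(seed, stream))
    reads <- add_read_errors(reads, error_rate)
    list(reads = reads,
         names = sprintf("%s_%07d", tag, seq_along(reads)))
  }
  list(bound = one_fraction(fc$counts$n_bound, "bound", "errors_bound"),
       unbound = one_fraction(fc$counts$n_unbound, "unbound", "errors_unbound"))
}
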