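#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

# Boltzmann factor at 25 degrees C: multiply an energy in kT by this to get
# kcal/mol.
KT_TO_KCAL <- 0.593

#' Convert energies from kT to kcal/mol
#'
#' Relative binding energies are natural-log affinity ratios and therefore
#' dimensionless multiples of the thermal energy kT. At 25 degrees C one kT is
#' 0.593 kcal/mol.
#'
#' @param x numeric vector of energies in kT.
#' @return numeric vector of energies in kcal/mol.
#' @export
energy_kcal_per_mol <- function(x) {
  x * KT_TO_KCAL
}

#' Derive a reproducible sub-seed for a named random stream
#'
#' All stochastic components draw from streams derived deterministically from
#' one root seed, so independent stages (count sampling, read errors, planted
#' tables) do not share or perturb each other's random state.
#'
#' @param seed integer root seed.
#' @param stream character label of the component stream.
#' @return an integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, length(stream) == 1)
  # FNV-1a style mix of the label folded into the root seed; kept below
  # 2^31 - 1 so the result is a valid R integer seed.
  h <- as.double(seed %% 2147483647)
  for (b in utf8ToInt(as.character(stream))) {
    h <- ((h + b) * 16777619) %% 2147483647
  }
  as.integer(h)
}

# Uppercase and validate a nucleotide string over an allowed alphabet.
clean_seq <- function(x, allow_n = FALSE, what = "sequence") {
  x <- toupper(as.character(x))
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- grepl(sprintf("[^%s]", alphabet), x)
  if (any(bad)) {
    stop(sprintf("invalid character in %s: %s", what, x[bad][1]), call. = FALSE)
  }
  x
}

# Stable non-cryptographic hash of a character scalar, for provenance lines.
config_hash <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(paste(x, collapse = "\n"))) {
    h <- ((h %% 2^24) * 16777619 + bitwAnd(h, 4278190080) / 16777216 + b) %% 4294967296
  }
  sprintf("%08x", h)
}

# Standard provenance header lines for text outputs.
provenance_lines <- function(extra = character()) {
  ver <- as.character(utils::packageVersion("specseqr"))
  out <- sprintf("# specseqr %s", ver)
  if (length(extra)) out <- c(out, paste0("# ", extra))
  out
}
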