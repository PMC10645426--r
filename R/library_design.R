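#' Enumerate all concrete variants of a randomized-core pattern
#'
#' A Spec-seq library randomizes a small number of positions (written `N`)
#' inside an otherwise fixed core, e.g. `TAANNN` for monomeric homeodomain
#' sites. This expands the pattern into every concrete sequence, in
#' lexicographic order.
#'
#' @param core_pattern pattern string over `{A,C,G,T,N}`; at most 12 `N`
#'   positions (4^12 variants is the enumeration bound).
#' @return character vector of `4^n_N` unique variants, lexicographically
#'   sorted.
#' @examples
#' length(enumerate_library("TAANNN")) # 64
#' enumerate_library("TAATCC")         # a single fixed variant
#' @export
enumerate_library <- function(core_pattern) {
  pat <- clean_seq(core_pattern, allow_n = TRUE, what = "core pattern")
  chars <- strsplit(pat, "")[[1]]
  npos <- which(chars == "N")
  if (length(npos) > 12) {
    stop(sprintf("pattern has %d randomized positions; enumeration bound is 12",
                 length(npos)), call. = FALSE)
  }
  if (length(npos) == 0) {
    return(pat)
  }
  # expand.grid varies its first factor fastest; feeding the randomized
  # positions in reverse order makes earlier positions vary slowest, which is
  # lexicographic order directly.
  grid <- expand.grid(rep(list(DNA_BASES), length(npos)),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(npos)), drop = FALSE]
  template <- matrix(chars, nrow = nrow(grid), ncol = length(chars), byrow = TRUE)
  template[, npos] <- as.matrix(grid)
  apply(template, 1, paste0, collapse = "")
}

#' Define a Spec-seq binding-site library
#'
#' Bundles the fixed flanking (conserved) sequences, the randomized core
#' pattern, the strand the motif sits on, and the enumerated variant list.
#' Flanks carry any constant barcode sequence; they are user-supplied
#' configuration, never assumed.
#'
#' @param core_pattern pattern over `{A,C,G,T,N}`, e.g. `"TAANNN"`.
#' @param flank5,flank3 fixed conserved sequences 5' and 3' of the core
#'   (may be empty strings).
#' @param name label for the library.
#' @param strand `"forward"` or `"reverse"`: which strand the motif pattern
#'   describes.
#' @return an object of class `specseq_library` with fields `name`, `flank5`,
#'   `core_pattern`, `flank3`, `strand`, `variants` (lexicographic), and
#'   `variant_map` (named vector mapping each variant to its forward-motif
#'   -space equivalent; identity for forward libraries).
#' @export
specseq_library <- function(core_pattern, flank5 = "", flank3 = "",
                            name = core_pattern,
                            strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  variants <- enumerate_library(core_pattern)
  lib <- list(
    name = as.character(name),
    flank5 = clean_seq(flank5, what = "flank5"),
    core_pattern = clean_seq(core_pattern, allow_n = TRUE, what = "core pattern"),
    flank3 = clean_seq(flank3, what = "flank3"),
    strand = strand,
    variants = variants,
    variant_map = stats::setNames(variants, variants)
  )
  class(lib) <- "specseq_library"
  lib
}

#' @export
print.specseq_library <- function(x, ...) {
  cat(sprintf("Spec-seq library '%s' (%s strand)\n", x$name, x$strand))
  cat(sprintf("  %s [%s] %s  (%d variants)\n",
              x$flank5, x$core_pattern, x$flank3, length(x$variants)))
  invisible(x)
}

# Indices of the randomized (N) positions of a library's core pattern.
variable_positions <- function(library) {
  which(strsplit(library$core_pattern, "")[[1]] == "N")
}

#' Variants within a mismatch radius of a reference
#'
#' Collects every library variant that differs from the reference at no more
#' than `max_mismatch` randomized positions. Fixed core positions are
#' identical across the whole library, so only the randomized positions can
#' mismatch. Energy-PWM fitting uses the radius-2 neighborhood of the
#' consensus.
#'
#' @param reference a library variant (usually the consensus).
#' @param library a [specseq_library()].
#' @param max_mismatch nonnegative integer radius.
#' @return an object of class `variant_neighborhood`: list with `reference`,
#'   `max_mismatch`, `members` (lexicographic character vector containing the
#'   reference), `mismatches` (named integer vector over members).
#' @examples
#' lib <- specseq_library("TAANNN")
#' length(hamming_neighborhood("TAATCC", lib, 2)$members) # 37
#' @export
hamming_neighborhood <- function(reference, library, max_mismatch) {
  stopifnot(inherits(library, "specseq_library"))
  reference <- clean_seq(reference, what = "reference variant")
  if (!reference %in% library$variants) {
    stop(sprintf("reference %s is not a variant of library '%s'",
                 reference, library$name), call. = FALSE)
  }
  stopifnot(max_mismatch >= 0)
  vp <- variable_positions(library)
  refc <- strsplit(reference, "")[[1]][vp]
  varm <- do.call(rbind, strsplit(library$variants, ""))[, vp, drop = FALSE]
  mm <- rowSums(varm != matrix(refc, nrow = nrow(varm), ncol = length(vp),
                               byrow = TRUE))
  keep <- mm <= max_mismatch
  structure(
    list(reference = reference,
         max_mismatch = as.integer(max_mismatch),
         members = library$variants[keep],
         mismatches = stats::setNames(as.integer(mm[keep]),
                                      library$variants[keep])),
    class = "variant_neighborhood"
  )
}

#' Reverse-complement a library
#'
#' Builds the library whose variants are the reverse complements of the
#' input's, with the strand flag flipped and flanks swapped/reverse-
#' complemented. The returned `variant_map` links each new variant back to
#' forward-motif space, so energies measured on a reverse-strand library can
#' be reported against the forward motif. Applying the operation twice is the
#' identity.
#'
#' @param library a [specseq_library()].
#' @return a new `specseq_library`.
#' @export
reverse_complement_library <- function(library) {
  stopifnot(inherits(library, "specseq_library"))
  rc <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  }
  new_variants <- rc(library$variants)
  # carry each variant's forward-space identity across the flip
  new_map <- stats::setNames(unname(library$variant_map), new_variants)
  ord <- order(new_variants, method = "radix")
  lib <- list(
    name = paste0(library$name, "_rc"),
    flank5 = if (nzchar(library$flank3)) rc(library$flank3) else "",
    flank3 = if (nzchar(library$flank5)) rc(library$flank5) else "",
    core_pattern = rc(library$core_pattern),
    strand = if (library$strand == "forward") "reverse" else "forward",
    variants = new_variants[ord],
    variant_map = new_map[ord]
  )
  # undo the name doubling on a round trip
  lib$name <- sub("_rc_rc$", "", lib$name)
  class(lib) <- "specseq_library"
  lib
}
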