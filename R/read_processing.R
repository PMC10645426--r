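#' Match reads against a library layout
#'
#' A read is accepted only if both conserved flanks match exactly
#' (Hamming-0, fixed offset) and the core substring is one of the library's
#' enumerated variants; any mismatch in the conserved regions rejects the
#' read. No indel alignment is attempted: Spec-seq reads are short amplicons
#' with the core at a known offset.
#'
#' @param reads character vector of read sequences (case-insensitive).
#' @param library a [specseq_library()].
#' @return data.frame with columns `variant` (the core, or `NA` on reject)
#'   and `reason` (`"ok"`, `"too_short"`, `"invalid_base"`,
#'   `"flank_mismatch"`, `"unknown_variant"`).
#' @export
match_reads <- function(reads, library) {
  stopifnot(inherits(library, "specseq_library"))
  n5 <- nchar(library$flank5)
  nc <- nchar(library$core_pattern)
  n3 <- nchar(library$flank3)
  reads <- toupper(as.character(reads))

  variant <- rep(NA_character_, length(reads))
  reason <- rep("ok", length(reads))

  short <- nchar(reads) < n5 + nc + n3
  reason[short] <- "too_short"

  bad <- !short & grepl("[^ACGTN]", reads)
  reason[bad] <- "invalid_base"

  live <- !short & !bad
  f5 <- substr(reads, 1L, n5)
  core <- substr(reads, n5 + 1L, n5 + nc)
  f3 <- substr(reads, n5 + nc + 1L, n5 + nc + n3)
  flank_bad <- live & (f5 != library$flank5 | f3 != library$flank3)
  reason[flank_bad] <- "flank_mismatch"

  live <- live & !flank_bad
  unknown <- live & !(core %in% library$variants)
  reason[unknown] <- "unknown_variant"

  ok <- live & !unknown
  variant[ok] <- core[ok]
  data.frame(variant = variant, reason = reason, stringsAsFactors = FALSE)
}

#' Match a single read
#'
#' Scalar convenience wrapper around [match_reads()].
#'
#' @param read one read sequence.
#' @param library a [specseq_library()].
#' @return list with `variant` (core string or `NA`) and `reason`.
#' @export
match_read <- function(read, library) {
  m <- match_reads(read, library)
  list(variant = m$variant[1], reason = m$reason[1])
}

#' Count library variants in bound and unbound read pools
#'
#' Tallies accepted reads per variant for each gel fraction and records why
#' rejected reads were discarded. Counting is order-independent and never
#' fatal on malformed reads.
#'
#' @param bound_reads,unbound_reads character vectors of read sequences
#'   (may be empty).
#' @param library a [specseq_library()].
#' @return an object of class `fraction_counts`: list with `library`,
#'   `counts` (data.frame `variant`, `n_bound`, `n_unbound` over the full
#'   enumerated library, lexicographic), `totals` (named accepted totals),
#'   and `n_discarded` (fraction x reason table).
#' @export
count_fractions <- function(bound_reads, unbound_reads, library) {
  stopifnot(inherits(library, "specseq_library"))
  reasons <- c("too_short", "invalid_base", "flank_mismatch",
               "unknown_variant")
  tally <- function(reads) {
    m <- match_reads(reads, library)
    counts <- table(factor(m$variant, levels = library$variants))
    rejects <- table(factor(m$reason[m$reason != "ok"], levels = reasons))
    list(counts = as.vector(counts), rejects = as.integer(rejects))
  }
  b <- tally(bound_reads)
  u <- tally(unbound_reads)
  disc <- rbind(bound = b$rejects, unbound = u$rejects)
  colnames(disc) <- reasons
  fraction_counts(
    library = library,
    n_bound = b$counts,
    n_unbound = u$counts,
    n_discarded = disc
  )
}

#' Construct a fraction-counts object from per-variant counts
#'
#' @param library a [specseq_library()].
#' @param n_bound,n_unbound nonnegative counts, one per library variant in
#'   the library's (lexicographic) variant order, or named vectors keyed by
#'   variant. Expected-count simulations may carry non-integer values.
#' @param n_discarded optional fraction x reason matrix of discarded-read
#'   tallies.
#' @return a `fraction_counts` object (see [count_fractions()]).
#' @export
fraction_counts <- function(library, n_bound, n_unbound, n_discarded = NULL) {
  stopifnot(inherits(library, "specseq_library"))
  expand <- function(x, fraction) {
    if (!is.null(names(x))) {
      extra <- setdiff(names(x), library$variants)
      if (length(extra)) {
        stop(sprintf("%s counts name non-library variants: %s",
                     fraction, extra[1]), call. = FALSE)
      }
      full <- stats::setNames(numeric(length(library$variants)),
                              library$variants)
      full[names(x)] <- x
      x <- full
    }
    stopifnot(length(x) == length(library$variants), all(x >= 0),
              all(is.finite(x)))
    unname(x)
  }
  counts <- data.frame(
    variant = library$variants,
    n_bound = expand(n_bound, "bound"),
    n_unbound = expand(n_unbound, "unbound"),
    stringsAsFactors = FALSE
  )
  if (is.null(n_discarded)) {
    n_discarded <- matrix(0L, nrow = 2, ncol = 4,
                          dimnames = list(c("bound", "unbound"),
                                          c("too_short", "invalid_base",
                                            "flank_mismatch",
                                            "unknown_variant")))
  }
  structure(
    list(library = library,
         counts = counts,
         totals = c(bound = sum(counts$n_bound),
                    unbound = sum(counts$n_unbound)),
         n_discarded = n_discarded),
    class = "fraction_counts"
  )
}

#' @export
print.fraction_counts <- function(x, ...) {
  cat(sprintf("Fraction counts over %d variants of '%s'\n",
              nrow(x$counts), x$library$name))
  cat(sprintf("  accepted: bound %s, unbound %s; discarded: %d\n",
              format(x$totals["bound"]), format(x$totals["unbound"]),
              sum(x$n_discarded)))
  invisible(x)
}

#' Quality summary of a fraction-counts object
#'
#' @param fc a `fraction_counts` object.
#' @return list with per-fraction accepted totals, discarded tallies and
#'   discard fractions, and `coverage`: the fraction of library variants
#'   observed at least once in both fractions.
#' @export
qc_summary <- function(fc) {
  stopifnot(inherits(fc, "fraction_counts"))
  disc <- rowSums(fc$n_discarded)
  total_reads <- fc$totals + disc
  list(
    accepted = fc$totals,
    discarded = disc,
    discard_fraction = ifelse(total_reads > 0, disc / total_reads, 0),
    discard_reasons = fc$n_discarded,
    coverage = mean(fc$counts$n_bound >= 1 & fc$counts$n_unbound >= 1)
  )
}
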