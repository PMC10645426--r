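#' Read sequences from FASTQ or plain text
#'
#' FASTQ (optionally gzip-compressed) is parsed with Biostrings; a plain
#' file with one sequence per line is also accepted.
#'
#' @param path file path; `.fastq`/`.fq` (optionally `.gz`) or plain text.
#' @param format `"auto"`, `"fastq"`, or `"lines"`.
#' @return character vector of read sequences.
#' @export
read_reads <- function(path, format = c("auto", "fastq", "lines")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) "fastq" else "lines"
  }
  if (format == "fastq") {
    unname(as.character(Biostrings::readDNAStringSet(path, format = "fastq")))
  } else {
    x <- readLines(path)
    x[nzchar(x) & !startsWith(x, "#")]
  }
}

#' Write reads as FASTQ
#'
#' @param reads character vector of sequences.
#' @param names read names (defaults to serial numbers).
#' @param path output path (`.gz` suffix compresses).
#' @param quality_char constant per-base quality character (default `"I"`).
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path, names = NULL, quality_char = "I") {
  if (is.null(names)) names <- sprintf("read_%07d", seq_along(reads))
  stopifnot(length(names) == length(reads))
  dna <- Biostrings::DNAStringSet(reads)
  base::names(dna) <- names
  quals <- Biostrings::BStringSet(vapply(nchar(reads), function(n) {
    strrep(quality_char, n)
  }, character(1)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write / read TSV with `#` provenance headers
#'
#' The universal tabular dialect used by every writer in the package: plain
#' TSV preceded by `#` comment lines carrying the tool version and any
#' metadata, so files stay diff-able and stream-able while remaining
#' self-describing.
#'
#' @param df data.frame to write.
#' @param path file path.
#' @param meta character vector of extra metadata lines (written as
#'   `# <line>`).
#' @return the path (write) or the data.frame with the comment lines in a
#'   `meta` attribute (read).
#' @export
write_tsv_commented <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_commented
#' @param ... passed on to [utils::read.table()].
#' @export
read_tsv_commented <- function(path, ...) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  df <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE, ...)
  attr(df, "meta") <- meta
  df
}

#' Write / read a variant counts table
#'
#' TSV with columns `variant`, `n_bound`, `n_unbound` under `#` provenance
#' lines.
#'
#' @param fc a `fraction_counts` object.
#' @param path file path.
#' @return `write_counts` returns the path invisibly; `read_counts` returns a
#'   `fraction_counts` (discard tallies are not round-tripped).
#' @export
write_counts <- function(fc, path) {
  stopifnot(inherits(fc, "fraction_counts"))
  write_tsv_commented(fc$counts, path,
                      meta = sprintf("library: %s (%s)", fc$library$name,
                                     fc$library$core_pattern))
}

#' @rdname write_counts
#' @param library the [specseq_library()] the counts belong to.
#' @export
read_counts <- function(path, library) {
  df <- read_tsv_commented(path)
  stopifnot(all(c("variant", "n_bound", "n_unbound") %in% names(df)))
  fraction_counts(library,
                  stats::setNames(df$n_bound, df$variant),
                  stats::setNames(df$n_unbound, df$variant))
}

#' Write / read an energy table
#'
#' TSV with columns `variant`, `ddG_kT`, `n_bound`, `n_unbound`, `in_fit`
#' under `#` metadata (reference, pseudocount, min_reads, units).
#'
#' @param et an `energy_table`.
#' @param path file path.
#' @export
write_energy_table <- function(et, path) {
  stopifnot(inherits(et, "energy_table"))
  write_tsv_commented(
    et$energies, path,
    meta = c(sprintf("reference: %s", et$reference_variant),
             "units: kT",
             sprintf("pseudocount: %g", et$pseudocount),
             sprintf("min_reads: %d", et$min_reads))
  )
}

#' @rdname write_energy_table
#' @param library the [specseq_library()] the table belongs to.
#' @export
read_energy_table <- function(path, library) {
  df <- read_tsv_commented(path)
  meta <- attr(df, "meta")
  ref <- sub("^# reference: ", "", grep("^# reference: ", meta, value = TRUE))
  pc <- as.numeric(sub("^# pseudocount: ", "",
                       grep("^# pseudocount: ", meta, value = TRUE)))
  mr <- as.integer(sub("^# min_reads: ", "",
                       grep("^# min_reads: ", meta, value = TRUE)))
  structure(
    list(library = library, reference_variant = ref, energies = df,
         pseudocount = pc, min_reads = mr, n_used = sum(df$in_fit)),
    class = "energy_table"
  )
}

#' Write an energy PWM or logo matrix
#'
#' TSV with one row per core position and columns `position`, `A`, `C`, `G`,
#' `T`, under `#` metadata lines (reference, units, fit diagnostics; fixed
#' positions are listed and carry `NA` energies).
#'
#' @param x an `energy_pwm` or `logo_matrix`.
#' @param path file path.
#' @export
write_pwm <- function(x, path) {
  if (inherits(x, "energy_pwm")) {
    ncore <- nchar(x$core_pattern)
    mat <- matrix(NA_real_, nrow = ncore, ncol = 4,
                  dimnames = list(NULL, DNA_BASES))
    mat[x$positions, ] <- t(x$beta)
    meta <- c(sprintf("reference: %s", x$reference_variant),
              "units: kT",
              sprintf("residual_sd: %.6g", x$fit$residual_sd),
              sprintf("r_squared: %.6g", x$fit$r_squared),
              sprintf("fixed_positions: %s",
                      paste(setdiff(seq_len(ncore), x$positions),
                            collapse = ",")))
  } else if (inherits(x, "logo_matrix")) {
    mat <- x$energies
    meta <- c("matrix: mean-centered logo energies (display is the negation)",
              "units: kT",
              sprintf("fixed_positions: %s",
                      paste(x$fixed_positions, collapse = ",")))
  } else {
    stop("x must be an energy_pwm or logo_matrix", call. = FALSE)
  }
  df <- data.frame(position = seq_len(nrow(mat)), mat, check.names = FALSE)
  write_tsv_commented(df, path, meta = meta)
}

#' Write / read BED intervals
#'
#' Minimal BED (chrom, start, end, name) in 0-based half-open coordinates.
#' Malformed records are reported with their line number.
#'
#' @param df data.frame `chrom`, `start`, `end`, `id`.
#' @param path file path.
#' @export
write_bed <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end", "id") %in% names(df)))
  utils::write.table(df[, c("chrom", "start", "end", "id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track")
  fields <- strsplit(lines[keep], "\t")
  lineno <- which(keep)
  n <- lengths(fields)
  if (any(n < 4)) {
    stop(sprintf("BED line %d: expected at least 4 fields, got %d",
                 lineno[which(n < 4)[1]], n[which(n < 4)[1]]), call. = FALSE)
  }
  df <- data.frame(
    chrom = vapply(fields, `[`, character(1), 1),
    start = suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2))),
    end = suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3))),
    id = vapply(fields, `[`, character(1), 4),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(df$start) | is.na(df$end))
  if (length(bad)) {
    stop(sprintf("BED line %d: non-numeric coordinates", lineno[bad[1]]),
         call. = FALSE)
  }
  bad <- which(df$end <= df$start)
  if (length(bad)) {
    stop(sprintf("BED line %d: end <= start", lineno[bad[1]]), call. = FALSE)
  }
  df
}

#' Write / read a differential table
#'
#' TSV `id`, `log2FC`, `fdr`, `cpm` under `#` provenance lines.
#'
#' @param df differential table data.frame.
#' @param path file path.
#' @export
write_differential_table <- function(df, path) {
  write_tsv_commented(differential_table(df), path)
}

#' @rdname write_differential_table
#' @export
read_differential_table <- function(path) {
  differential_table(read_tsv_commented(path))
}

#' Write / read an expression matrix
#'
#' TSV with a `gene` id column followed by one column per sample.
#'
#' @param mat gene x sample numeric matrix with rownames.
#' @param path file path.
#' @export
write_expression_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write_tsv_commented(df, path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv_commented(path, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene
  mat
}

#' Write a comparison or QC report as JSON
#'
#' @param x a `comparison_report`, [qc_summary()] result, or any list of
#'   scalars/vectors.
#' @param path output path.
#' @export
write_report_json <- function(x, path) {
  if (inherits(x, "comparison_report")) {
    x <- x[setdiff(names(x), "pairs")]
  }
  x$specseqr_version <- as.character(utils::packageVersion("specseqr"))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write / read a library definition
#'
#' JSON with keys `name`, `flank5`, `core_pattern`, `flank3`, `strand`.
#'
#' @param library a [specseq_library()].
#' @param path file path.
#' @export
write_library_json <- function(library, path) {
  stopifnot(inherits(library, "specseq_library"))
  jsonlite::write_json(
    library[c("name", "flank5", "core_pattern", "flank3", "strand")],
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_library_json
#' @export
read_library_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  specseq_library(core_pattern = x$core_pattern, flank5 = x$flank5,
                  flank3 = x$flank3, name = x$name, strand = x$strand)
}
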