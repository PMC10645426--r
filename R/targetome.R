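#' Validate a differential table
#'
#' Differential statistics (log2FC, FDR, cpm) are produced upstream by the
#' usual count-model packages; here they are inputs. This checks the contract:
#' unique ids, FDR in \[0, 1\].
#'
#' @param df data.frame with columns `id`, `log2FC`, `fdr` and optionally
#'   `cpm`.
#' @return the validated data.frame (invisibly the same object).
#' @export
differential_table <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("id", "log2FC", "fdr") %in% names(df)))
  if (anyDuplicated(df$id)) {
    stop("differential table ids are not unique", call. = FALSE)
  }
  if (any(df$fdr < 0 | df$fdr > 1, na.rm = TRUE)) {
    stop("FDR values must lie in [0, 1]", call. = FALSE)
  }
  df
}

#' Peaks lost in the mutant
#'
#' Selects peaks bound in the wild-type sample but lost in the mutant:
#' ChIP log2FC strictly below `fc_cut` and FDR strictly below `fdr_cut`.
#' Both inequalities are strict, so a peak sitting exactly at a threshold is
#' excluded.
#'
#' @param chip differential table over peaks.
#' @param fc_cut log2 fold-change cutoff (default -1).
#' @param fdr_cut FDR cutoff (default 5e-2).
#' @return character vector of peak ids, sorted.
#' @export
lost_peaks <- function(chip, fc_cut = -1, fdr_cut = 0.05) {
  chip <- differential_table(chip)
  sort(chip$id[chip$log2FC < fc_cut & chip$fdr < fdr_cut])
}

#' Assign peaks to the closest TSS within a distance cap
#'
#' Each peak is assigned to the gene whose TSS is nearest to the peak
#' midpoint; peaks whose nearest TSS lies farther than `max_distance` stay
#' unassigned. Coordinates are 0-based half-open; the peak position is the
#' interval midpoint and a TSS is the start of its 1-bp interval. Exact
#' distance ties are broken by the lexicographically smallest gene id (the
#' tie rule is recorded in the result).
#'
#' @param peaks data.frame `chrom`, `start`, `end`, `id` (BED-like).
#' @param tss data.frame `chrom`, `start`, `end`, `id` with gene ids;
#'   1-bp intervals.
#' @param max_distance maximum assignable midpoint-to-TSS distance in bp
#'   (default 100000, inclusive).
#' @return an object of class `peak_gene_map`: list with `assignments`
#'   (data.frame `peak_id`, `gene_id` (`NA` if unassigned), `distance`),
#'   `max_distance`, `tie_break`.
#' @export
assign_peaks <- function(peaks, tss, max_distance = 100000) {
  check_bed <- function(df, what) {
    stopifnot(is.data.frame(df),
              all(c("chrom", "start", "end", "id") %in% names(df)))
    bad <- which(df$end <= df$start)
    if (length(bad)) {
      stop(sprintf("%s record %d (%s): end <= start", what, bad[1],
                   df$id[bad[1]]), call. = FALSE)
    }
    df
  }
  peaks <- check_bed(peaks, "peak")
  tss <- check_bed(tss, "tss")

  out <- data.frame(peak_id = peaks$id, gene_id = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  mid <- (peaks$start + peaks$end) / 2
  for (chr in unique(peaks$chrom)) {
    tchr <- tss[tss$chrom == chr, , drop = FALSE]
    pidx <- which(peaks$chrom == chr)
    if (nrow(tchr) == 0 || length(pidx) == 0) next
    ord <- order(tchr$start, method = "radix")
    pos <- tchr$start[ord]
    gid <- tchr$id[ord]
    for (i in pidx) {
      k <- findInterval(mid[i], pos)
      cand <- unique(pmin(pmax(c(k, k + 1), 1L), length(pos)))
      dmin <- min(abs(pos[cand] - mid[i]))
      if (dmin > max_distance) next
      # collect every equidistant TSS (duplicated positions included) and
      # break the tie lexicographically
      ties <- which(abs(pos - mid[i]) == dmin)
      out$gene_id[i] <- min(gid[ties])
      out$distance[i] <- dmin
    }
  }
  structure(
    list(assignments = out, max_distance = max_distance,
         tie_break = "lexicographically smallest gene id"),
    class = "peak_gene_map"
  )
}

#' Classify genes by dependence on the transcription factor
#'
#' The classification universe is the set of genes with at least one lost
#' peak assigned within the distance cap. Among those, a gene is
#' `dependent_activated` if its adult expression is significantly down
#' (log2FC strictly below `act_fc` and FDR strictly below `fdr_cut`),
#' `dependent_suppressed` if significantly up (log2FC strictly above
#' `sup_fc`, same FDR cut), and `independent` otherwise (not significantly
#' affected: FDR at or above the cut, or |log2FC| at or below the band).
#' Genes in the expression table without a lost peak are `unassigned`;
#' genes with a lost peak but missing from the expression table are
#' `missing_expression`.
#'
#' @param lost character vector of lost peak ids (see [lost_peaks()]).
#' @param map a `peak_gene_map` from [assign_peaks()].
#' @param rna_p21 adult differential expression table.
#' @param act_fc activation log2FC cutoff (default -0.6).
#' @param sup_fc suppression log2FC cutoff (default 0.6).
#' @param fdr_cut expression FDR cutoff (default 1e-5).
#' @return an object of class `gene_class_table`: list with `labels`
#'   (data.frame `gene_id`, `class`), `counts` (named tally over classes),
#'   `provenance` (thresholds and universe definition).
#' @export
classify_genes <- function(lost, map, rna_p21, act_fc = -0.6, sup_fc = 0.6,
                           fdr_cut = 1e-5) {
  stopifnot(inherits(map, "peak_gene_map"))
  rna_p21 <- differential_table(rna_p21)
  asg <- map$assignments
  peak_genes <- unique(asg$gene_id[!is.na(asg$gene_id) &
                                     asg$peak_id %in% lost])
  all_genes <- union(rna_p21$id, peak_genes)
  class <- stats::setNames(rep("unassigned", length(all_genes)), all_genes)

  considered <- intersect(peak_genes, rna_p21$id)
  class[setdiff(peak_genes, rna_p21$id)] <- "missing_expression"
  lfc <- stats::setNames(rna_p21$log2FC, rna_p21$id)[considered]
  fdr <- stats::setNames(rna_p21$fdr, rna_p21$id)[considered]
  cls <- ifelse(lfc < act_fc & fdr < fdr_cut, "dependent_activated",
                ifelse(lfc > sup_fc & fdr < fdr_cut, "dependent_suppressed",
                       "independent"))
  class[considered] <- cls

  labels <- data.frame(gene_id = all_genes, class = unname(class),
                       stringsAsFactors = FALSE)
  labels <- labels[order(labels$gene_id, method = "radix"), , drop = FALSE]
  rownames(labels) <- NULL
  lvl <- c("dependent_activated", "dependent_suppressed", "independent",
           "unassigned", "missing_expression")
  structure(
    list(labels = labels,
         counts = table(factor(labels$class, levels = lvl)),
         provenance = list(
           act_fc = act_fc, sup_fc = sup_fc, fdr_cut = fdr_cut,
           universe = "genes with >=1 lost peak assigned within max_distance",
           independent_rule = "FDR >= fdr_cut OR |log2FC| <= band"
         )),
    class = "gene_class_table"
  )
}

#' @export
print.gene_class_table <- function(x, ...) {
  cat("Gene dependence classes:\n")
  print(x$counts)
  invisible(x)
}

#' Call differentially expressed genes
#'
#' A gene is differentially expressed if it passes the expression floor
#' (cpm at least `cpm_min`, inclusive — "at least 5 cpm"), its absolute
#' log2 fold-change strictly exceeds `fc_abs` (more than twofold), and its
#' FDR is strictly below `fdr_cut`.
#'
#' @param diff differential table with a `cpm` column.
#' @param fc_abs absolute log2FC cutoff (default 1).
#' @param fdr_cut FDR cutoff (default 1e-2).
#' @param cpm_min expression floor in cpm (default 5).
#' @return data.frame `id`, `log2FC`, `direction` (`"up"`/`"down"`), sorted
#'   by id.
#' @export
call_deg <- function(diff, fc_abs = 1, fdr_cut = 1e-2, cpm_min = 5) {
  diff <- differential_table(diff)
  stopifnot("cpm" %in% names(diff))
  keep <- diff$cpm >= cpm_min & abs(diff$log2FC) > fc_abs & diff$fdr < fdr_cut
  out <- data.frame(id = diff$id[keep],
                    log2FC = diff$log2FC[keep],
                    direction = ifelse(diff$log2FC[keep] > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  out[order(out$id, method = "radix"), , drop = FALSE]
}

#' Sample-wise developmental correlation of a gene set
#'
#' Pearson correlation between every query sample and every reference sample,
#' computed over the expression of a gene set (e.g. the dependent-activated
#' genes), after a common transform. The default transform is
#' `log2(cpm + 1)`; raw cpm and per-gene z-scores are available.
#'
#' @param query,reference gene x sample expression matrices (cpm) with gene
#'   rownames.
#' @param gene_set character vector of gene ids; at least 3 must be present
#'   in both matrices.
#' @param transform one of `"log2cpm"`, `"cpm"`, `"zscore"`.
#' @return matrix of Pearson r (query samples x reference samples) with
#'   attributes `n_genes` and `transform`.
#' @export
developmental_correlation <- function(query, reference, gene_set,
                                      transform = c("log2cpm", "cpm",
                                                    "zscore")) {
  transform <- match.arg(transform)
  stopifnot(is.matrix(query), is.matrix(reference),
            !is.null(rownames(query)), !is.null(rownames(reference)))
  shared <- intersect(gene_set, intersect(rownames(query),
                                          rownames(reference)))
  if (length(shared) < 3) {
    stop(sprintf("only %d genes of the set are present in both matrices; need at least 3",
                 length(shared)), call. = FALSE)
  }
  tf <- switch(transform,
               log2cpm = function(m) log2(m + 1),
               cpm = identity,
               zscore = function(m) t(scale(t(m))))
  q <- tf(query[shared, , drop = FALSE])
  r <- tf(reference[shared, , drop = FALSE])
  out <- stats::cor(q, r)
  attr(out, "n_genes") <- length(shared)
  attr(out, "transform") <- transform
  out
}
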