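#' Simulate planted target-classification inputs
#'
#' Generates the full set of downstream inputs with known truth: a ChIP
#' differential-binding table over peaks, RNA differential tables at two ages
#' (an immature and an adult time point), peak and TSS coordinate tables
#' (0-based half-open), a developmental reference expression matrix over five
#' pseudo-ages, a query expression matrix, and the planted labels.
#'
#' Every gene gets one "lost" peak near its TSS (ChIP log2FC below -1 with
#' FDR below 5e-2), so that the classification universe — genes with at
#' least one lost peak within 100 kb — covers all planted genes. Class
#' identity is planted through the adult RNA table: dependent-activated
#' genes draw log2FC from a normal(-2, 0.5) truncated strictly below -0.6
#' with FDR well under 1e-5; dependent-suppressed genes mirror them
#' positively; independent genes draw small fold-changes with large FDR.
#' Truncation at the thresholds guarantees the classifier can recover the
#' planted labels exactly. Decoy peaks are placed farther than 100 kb from
#' every TSS, and additional retained (non-lost) peaks are planted near
#' genes. Activated genes get monotone increasing developmental expression;
#' query samples are noisy copies of single reference pseudo-age profiles.
#'
#' @param n_genes number of genes.
#' @param class_proportions named proportions for
#'   `dependent_activated`, `dependent_suppressed`, `independent`
#'   (must sum to 1).
#' @param n_decoy_peaks lost peaks placed > 100 kb from every TSS.
#' @param n_retained_peaks non-lost peaks near random genes.
#' @param seed integer root seed.
#' @return list with `chip`, `rna_p21`, `rna_p10` (data.frames `id`,
#'   `log2FC`, `fdr`, `cpm`), `peaks`, `tss` (data.frames `chrom`, `start`,
#'   `end`, `id`), `dev_reference`, `dev_query` (gene x sample cpm
#'   matrices), and `truth` (planted labels, lost peak ids, class counts,
#'   query-to-age map).
#' @export
simulate_targetome_tables <- function(n_genes = 600,
                                      class_proportions = c(
                                        dependent_activated = 0.25,
                                        dependent_suppressed = 0.10,
                                        independent = 0.65),
                                      n_decoy_peaks = 40,
                                      n_retained_peaks = 60,
                                      seed = 1) {
  stopifnot(abs(sum(class_proportions) - 1) < 1e-8,
            setequal(names(class_proportions),
                     c("dependent_activated", "dependent_suppressed",
                       "independent")))
  set.seed(derive_seed(seed, "targetome"))

  genes <- sprintf("gene%05d", seq_len(n_genes))
  n_act <- round(n_genes * class_proportions[["dependent_activated"]])
  n_sup <- round(n_genes * class_proportions[["dependent_suppressed"]])
  n_ind <- n_genes - n_act - n_sup
  labels <- sample(rep(c("dependent_activated", "dependent_suppressed",
                         "independent"), c(n_act, n_sup, n_ind)))
  names(labels) <- genes

  # strictly-truncated normal draws keep every planted record inside its
  # class's strict thresholds
  rtrunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
    out <- stats::rnorm(n, mean, sd)
    bad <- which(out <= lower | out >= upper)
    while (length(bad)) {
      out[bad] <- stats::rnorm(length(bad), mean, sd)
      bad <- which(out <= lower | out >= upper)
    }
    out
  }

  # TSSs 300 kb apart on one synthetic chromosome: a peak within 100 kb of
  # its own TSS cannot be closer to a neighbor
  spacing <- 300000L
  tss_pos <- spacing * seq_len(n_genes)
  tss <- data.frame(chrom = "chrS", start = tss_pos, end = tss_pos + 1L,
                    id = genes, stringsAsFactors = FALSE)

  peak_near <- function(gene_idx, ids) {
    d <- sample(0:90000, length(gene_idx), replace = TRUE) *
      sample(c(-1L, 1L), length(gene_idx), replace = TRUE)
    mid <- tss_pos[gene_idx] + d
    data.frame(chrom = "chrS", start = mid - 200L, end = mid + 200L,
               id = ids, stringsAsFactors = FALSE)
  }

  lost_gene_peaks <- peak_near(seq_len(n_genes),
                               sprintf("peak%05d", seq_len(n_genes)))
  # decoys live in the dead zone between consecutive TSSs: >100 kb from both
  decoy_mid <- spacing * sample(seq_len(n_genes - 1), n_decoy_peaks,
                                replace = TRUE) + spacing / 2 +
    sample(-40000:40000, n_decoy_peaks, replace = TRUE)
  decoys <- data.frame(chrom = "chrS", start = as.integer(decoy_mid - 200),
                       end = as.integer(decoy_mid + 200),
                       id = sprintf("decoy%04d", seq_len(n_decoy_peaks)),
                       stringsAsFactors = FALSE)
  retained <- peak_near(sample(seq_len(n_genes), n_retained_peaks,
                               replace = TRUE),
                        sprintf("kept%04d", seq_len(n_retained_peaks)))
  peaks <- rbind(lost_gene_peaks, decoys, retained)

  lost_ids <- c(lost_gene_peaks$id, decoys$id)
  chip <- data.frame(
    id = peaks$id,
    log2FC = c(rtrunc(length(lost_ids), -2, 0.5, upper = -1),
               stats::rnorm(n_retained_peaks, 0, 0.3)),
    fdr = c(stats::runif(length(lost_ids), 1e-8, 0.049),
            stats::runif(n_retained_peaks, 0.2, 1)),
    cpm = stats::rlnorm(nrow(peaks), log(20), 0.5),
    stringsAsFactors = FALSE
  )

  act <- labels == "dependent_activated"
  sup <- labels == "dependent_suppressed"
  lfc21 <- numeric(n_genes)
  fdr21 <- numeric(n_genes)
  lfc21[act] <- rtrunc(sum(act), -2, 0.5, upper = -0.6)
  lfc21[sup] <- rtrunc(sum(sup), 2, 0.5, lower = 0.6)
  lfc21[!act & !sup] <- stats::runif(sum(!act & !sup), -0.5, 0.5)
  fdr21[act | sup] <- stats::runif(sum(act | sup), 1e-12, 9e-6)
  fdr21[!act & !sup] <- stats::runif(sum(!act & !sup), 0.05, 1)
  cpm21 <- stats::rlnorm(n_genes, log(50), 0.8)
  rna_p21 <- data.frame(id = genes, log2FC = lfc21, fdr = fdr21, cpm = cpm21,
                        stringsAsFactors = FALSE)

  # immature retinas show attenuated versions of the adult effects
  rna_p10 <- data.frame(
    id = genes,
    log2FC = 0.4 * lfc21 + stats::rnorm(n_genes, 0, 0.2),
    fdr = pmin(1, fdr21 * 10^stats::runif(n_genes, 0, 3)),
    cpm = cpm21 * stats::rlnorm(n_genes, 0, 0.3),
    stringsAsFactors = FALSE
  )

  # developmental reference: five pseudo-ages; each activated gene ramps up
  # monotonically at its own rate (so the cross-age expression profile is
  # gene-specific and ages are mutually distinguishable), everything else
  # stays flat (times lognormal noise)
  ages <- c("P3", "P7", "P10", "P14", "P21")
  base_cpm <- stats::rlnorm(n_genes, log(30), 0.6)
  profile <- outer(base_cpm, rep(1, 5))
  growth <- stats::runif(sum(act), 1.3, 3)
  profile[act, ] <- base_cpm[act] * t(vapply(growth, function(g) g^(0:4),
                                             numeric(5)))
  noise <- matrix(stats::rlnorm(n_genes * 5, 0, 0.05), n_genes, 5)
  dev_reference <- profile * noise
  dimnames(dev_reference) <- list(genes, ages)

  query_ages <- seq_along(ages)
  qnoise <- matrix(stats::rlnorm(n_genes * 5, 0, 0.05), n_genes, 5)
  dev_query <- profile[, query_ages] * qnoise
  dimnames(dev_query) <- list(genes, paste0("query_", ages))

  list(
    chip = chip, rna_p21 = rna_p21, rna_p10 = rna_p10,
    peaks = peaks, tss = tss,
    dev_reference = dev_reference, dev_query = dev_query,
    truth = list(
      labels = labels,
      lost_peak_ids = sort(lost_ids),
      decoy_peak_ids = decoys$id,
      class_counts = c(dependent_activated = n_act,
                       dependent_suppressed = n_sup,
                       independent = n_ind),
      query_age_of = stats::setNames(query_ages, colnames(dev_query)),
      seed = seed
    )
  )
}
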