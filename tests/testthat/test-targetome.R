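test_that("lost peaks require strictly passing both thresholds", {
  chip <- data.frame(
    id = c("p1", "p2", "p3", "p4", "p5"),
    log2FC = c(-2.0, -1.0, -1.5, -0.9, -3.0),
    fdr = c(0.01, 0.01, 0.05, 0.001, 0.049),
    cpm = 10
  )
  lost <- lost_peaks(chip)
  expect_identical(lost, c("p1", "p5"))
  # boundary values sit exactly at the cutoffs and are excluded
  expect_false("p2" %in% lost) # log2FC == -1
  expect_false("p3" %in% lost) # FDR == 0.05
})

test_that("peaks go to the closest TSS within the distance cap", {
  tss <- data.frame(chrom = "chr1",
                    start = c(100000, 220000, 500000),
                    end = c(100001, 220001, 500001),
                    id = c("geneA", "geneB", "geneC"))
  peaks <- data.frame(
    chrom = "chr1",
    start = c(150000 - 200,  # 50 kb from A, 70 kb from B
              650000 - 200,  # 150 kb from C
              160000 - 200,  # equidistant from A (60 kb) and B (60 kb)
              400000 - 200), # exactly 100 kb from C
    end = c(150000 + 200, 650000 + 200, 160000 + 200, 400000 + 200),
    id = c("pk1", "pk2", "pk3", "pk4")
  )
  m <- assign_peaks(peaks, tss)
  a <- m$assignments
  expect_identical(a$gene_id[a$peak_id == "pk1"], "geneA")
  expect_equal(a$distance[a$peak_id == "pk1"], 50000)
  expect_true(is.na(a$gene_id[a$peak_id == "pk2"]))
  # exact ties break to the lexicographically smallest gene id
  expect_identical(a$gene_id[a$peak_id == "pk3"], "geneA")
  # "within 100 kb" is inclusive
  expect_identical(a$gene_id[a$peak_id == "pk4"], "geneC")
  expect_equal(a$distance[a$peak_id == "pk4"], 100000)
})

test_that("peak assignment matches a brute-force all-pairs scan", {
  set.seed(19)
  n_t <- 40; n_p <- 120
  tss <- data.frame(chrom = sample(c("chr1", "chr2"), n_t, replace = TRUE),
                    start = sample(1:5e6, n_t))
  tss$end <- tss$start + 1
  tss$id <- sprintf("g%03d", seq_len(n_t))
  mid <- sample(1:5e6, n_p)
  peaks <- data.frame(chrom = sample(c("chr1", "chr2"), n_p, replace = TRUE),
                      start = mid - 100, end = mid + 100,
                      id = sprintf("p%03d", seq_len(n_p)))
  m <- assign_peaks(peaks, tss, max_distance = 100000)$assignments

  for (i in seq_len(n_p)) {
    cand <- tss[tss$chrom == peaks$chrom[i], ]
    if (nrow(cand) == 0) { expect_true(is.na(m$gene_id[i])); next }
    d <- abs(cand$start - (peaks$start[i] + peaks$end[i]) / 2)
    dmin <- min(d)
    if (dmin > 100000) {
      expect_true(is.na(m$gene_id[i]))
    } else {
      expect_identical(m$gene_id[i], min(cand$id[d == dmin]))
      expect_equal(m$distance[i], dmin)
    }
  }
})

test_that("malformed intervals are rejected with their position", {
  tss <- data.frame(chrom = "chr1", start = 10, end = 11, id = "g1")
  bad <- data.frame(chrom = "chr1", start = 100, end = 100, id = "p1")
  expect_error(assign_peaks(bad, tss), "end <= start")
})

test_that("gene classification applies the printed thresholds strictly", {
  tss <- data.frame(chrom = "chr1", start = (1:6) * 1e6,
                    end = (1:6) * 1e6 + 1,
                    id = sprintf("g%d", 1:6))
  peaks <- data.frame(chrom = "chr1", start = (1:6) * 1e6 + 5000,
                      end = (1:6) * 1e6 + 5400,
                      id = sprintf("pk%d", 1:6))
  m <- assign_peaks(peaks, tss)
  lost <- sprintf("pk%d", 1:5) # g6's peak is not lost
  rna <- data.frame(
    id = sprintf("g%d", 1:7), # g7 has no peak at all
    log2FC = c(-1.2, 1.2, -0.6, -0.8, 0.2, -2.0, -3.0),
    fdr = c(1e-8, 1e-8, 1e-8, 1e-5, 0.5, 1e-9, 1e-9),
    cpm = 50
  )
  gc <- classify_genes(lost, m, rna)
  lab <- stats::setNames(gc$labels$class, gc$labels$gene_id)
  expect_identical(unname(lab["g1"]), "dependent_activated")
  expect_identical(unname(lab["g2"]), "dependent_suppressed")
  # boundaries: log2FC == -0.6 and FDR == 1e-5 both fail the strict cuts
  expect_identical(unname(lab["g3"]), "independent")
  expect_identical(unname(lab["g4"]), "independent")
  expect_identical(unname(lab["g5"]), "independent")
  # no lost peak / no peak: outside the classification universe
  expect_identical(unname(lab["g6"]), "unassigned")
  expect_identical(unname(lab["g7"]), "unassigned")
  # labels partition the gene universe
  expect_equal(sum(gc$counts), nrow(gc$labels))
})

test_that("genes with lost peaks but no expression record are tracked", {
  tss <- data.frame(chrom = "chr1", start = 1e6, end = 1e6 + 1, id = "g1")
  peaks <- data.frame(chrom = "chr1", start = 1e6 + 1000, end = 1e6 + 1400,
                      id = "pk1")
  m <- assign_peaks(peaks, tss)
  rna <- data.frame(id = "other", log2FC = 0, fdr = 1, cpm = 10)
  gc <- classify_genes("pk1", m, rna)
  lab <- stats::setNames(gc$labels$class, gc$labels$gene_id)
  expect_identical(unname(lab["g1"]), "missing_expression")
})

test_that("differential calls respect the cpm floor and strict cuts", {
  d <- data.frame(
    id = c("a", "b", "c", "d", "e", "f"),
    log2FC = c(1.5, 3.0, 1.0, -1.4, 1.6, 1.6),
    fdr = c(1e-4, 1e-9, 1e-4, 1e-4, 1e-2, 1e-4),
    cpm = c(20, 2, 20, 5, 20, 4.9)
  )
  deg <- call_deg(d)
  expect_identical(deg$id, c("a", "d"))
  expect_identical(deg$direction, c("up", "down"))
  # "at least 5 cpm" is inclusive: d sits exactly at 5 and is kept
  expect_true("d" %in% deg$id)
  # log2FC == 1 ("more than") and fdr == 1e-2 ("smaller than") are strict
  expect_false("c" %in% deg$id)
  expect_false("e" %in% deg$id)
  expect_false("b" %in% deg$id) # cpm below the floor despite huge effect
})

test_that("planted targetome tables are recovered exactly", {
  for (seed in c(1, 7, 2024)) {
    tt <- simulate_targetome_tables(seed = seed)
    lost <- lost_peaks(tt$chip)
    expect_identical(lost, tt$truth$lost_peak_ids)

    m <- assign_peaks(tt$peaks, tt$tss)
    a <- m$assignments
    # decoys sit farther than 100 kb from every TSS
    expect_true(all(is.na(a$gene_id[a$peak_id %in% tt$truth$decoy_peak_ids])))

    gc <- classify_genes(lost, m, tt$rna_p21)
    lab <- stats::setNames(gc$labels$class, gc$labels$gene_id)
    truth <- tt$truth$labels
    expect_identical(unname(lab[names(truth)]), unname(truth))
    expect_equal(as.vector(gc$counts[names(tt$truth$class_counts)]),
                 unname(tt$truth$class_counts))
  }
})

test_that("developmental correlation is transform-aware and affine-invariant", {
  genes <- sprintf("g%02d", 1:20)
  set.seed(5)
  ref <- matrix(rlnorm(20 * 4, log(20), 1), 20, 4,
                dimnames = list(genes, paste0("age", 1:4)))
  q <- cbind(same = ref[, 2], affine = 3 * ref[, 2] + 7)
  rownames(q) <- genes
  cc <- developmental_correlation(q, ref, genes, transform = "cpm")
  expect_equal(unname(cc["same", "age2"]), 1, tolerance = 1e-12)
  expect_equal(unname(cc["affine", "age2"]), 1, tolerance = 1e-12)
  expect_true(all(cc >= -1 & cc <= 1))
  expect_identical(attr(cc, "n_genes"), 20L)

  expect_error(developmental_correlation(q, ref, genes[1:2]), "at least 3")
})

test_that("query samples correlate maximally with their source pseudo-age", {
  tt <- simulate_targetome_tables(seed = 11)
  act <- names(tt$truth$labels)[tt$truth$labels == "dependent_activated"]
  cc <- developmental_correlation(tt$dev_query, tt$dev_reference, act)
  expect_identical(unname(apply(cc, 1, which.max)),
                   unname(tt$truth$query_age_of))
})
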