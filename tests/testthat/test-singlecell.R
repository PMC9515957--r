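test_that("chain pairing forms pair keys and reports unpaired cells", {
  cells <- data.frame(
    cell_id = c("c1", "c2", "c3"),
    tra = c("CAVHNTDKLIF", "", "CAVX;CAVY"),
    trb = c("CASSPGQGGGYTF", "CASSONLYB", "CASSZ"),
    tissue = "TUMOR")
  out <- pairChains(contigs_from_cells(cells))
  expect_equal(out$pair_key[out$cell_id == "c1"],
               "CAVHNTDKLIF:CASSPGQGGGYTF")
  expect_false(out$paired[out$cell_id == "c2"])  # TRB only
  expect_true(out$multi_chain[out$cell_id == "c3"])
  rep <- attr(out, "unpaired_report")
  expect_equal(unname(rep["cells"]), 3)
  expect_equal(unname(rep["paired"]), 1)
})

test_that("doublet filtering removes multi-chain cells only", {
  cells <- data.frame(
    cell_id = c("ok", "dblB", "dblA"),
    tra = c("CAVA", "CAVB", "CAVC;CAVD"),
    trb = c("CASSA", "CASSB;CASSC", "CASSD"))
  out <- filterDoublets(pairChains(contigs_from_cells(cells)))
  expect_equal(out$removed, 2)
  expect_equal(out$cells$cell_id, "ok")
})

test_that("size classes use the published boundaries", {
  expect_equal(as.character(assignSizeClass(c(1, 2, 4, 5, 20, 21))),
               c("singleton", "small", "small", "medium", "medium", "large"))
  expect_error(assignSizeClass(0))
})

test_that("clonotype density fractions sum to one", {
  cells <- data.frame(
    cell_id = sprintf("c%02d", 1:31),
    tra = "CAVA",
    trb = c(rep("CASSBIG", 21), rep("CASSMED", 5), rep("CASSSM", 2),
            "CASS1", "CASS2", "CASS3"))
  cells$tra <- paste0("CAV", cells$trb)  # distinct pairs per TRB
  pc <- pairedClonotypes(pairChains(contigs_from_cells(cells)))
  dens <- clonotypeDensity(pc)
  expect_equal(sum(dens$density), 1)
  expect_equal(dens$n_pairs[dens$size_class == "large"], 1L)
  expect_equal(dens$density[dens$size_class == "singleton"], 0.5)  # 3 of 6
  # all singletons
  solo <- data.frame(cell_id = c("a", "b"), tra = c("CAVA", "CAVB"),
                     trb = c("CASSA", "CASSB"))
  d2 <- clonotypeDensity(pairedClonotypes(pairChains(contigs_from_cells(solo))))
  expect_equal(d2$density[d2$size_class == "singleton"], 1)
})

test_that("MTX-triplet and dense expression inputs load identically", {
  set.seed(21)
  m <- matrix(rpois(40, 2), nrow = 8,
              dimnames = list(sprintf("G%d", 1:8), sprintf("c%d", 1:5)))
  d <- tempfile(); dir.create(d)
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), file.path(d, "matrix.mtx"))
  writeLines(rownames(m), file.path(d, "features.tsv"))
  writeLines(colnames(m), file.path(d, "barcodes.tsv"))
  dense <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene = rownames(m), m), dense, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_equal(as.matrix(readCellCounts(d)), m)
  expect_equal(readCellCounts(dense), m)
  incomplete <- tempfile(); dir.create(incomplete)
  expect_error(readCellCounts(incomplete), "triplet incomplete")
})

test_that("lineage assignment partitions cells into four labels", {
  counts <- rbind(CD4 = c(3, 0, 2, 0), CD8A = c(0, 4, 4, 0),
                  CD8B = c(0, 1, 0, 0), GZMB = c(5, 5, 5, 5))
  colnames(counts) <- paste0("c", 1:4)
  lin <- assignLineage(counts)
  expect_equal(unname(lin), c("CD4", "CD8", "DP", "unassigned"))
  expect_error(assignLineage(counts[4, , drop = FALSE]), "absent")
})

test_that("phenotype classification recovers marker-driven labels", {
  set.seed(2)
  mk <- defaultMarkerTable()
  genes <- geneUniverse()
  # cells expressing only naive markers score as naive
  counts <- matrix(rpois(length(genes) * 40, 1), nrow = length(genes),
                   dimnames = list(genes, paste0("c", 1:40)))
  naive_cells <- 1:10
  counts[mk$naive, naive_cells] <- counts[mk$naive, naive_cells] + 20L
  eff_cells <- 11:20
  counts[mk$T_eff, eff_cells] <- counts[mk$T_eff, eff_cells] + 20L
  lab <- classifyPhenotype(normalizeCells(counts))$label
  expect_true(all(lab[naive_cells] == "naive"))
  expect_true(all(lab[eff_cells] == "T_eff"))
  # an all-zero cell is never assigned
  counts0 <- counts
  counts0[, 40] <- 0L
  lab0 <- classifyPhenotype(normalizeCells(counts0))$label
  expect_equal(lab0[40], "unassigned")
  # unknown markers are dropped with a warning
  expect_warning(
    classifyPhenotype(normalizeCells(counts),
                      marker_table = list(odd = c("NOTAGENE", "GZMB"))),
    "absent")
})

test_that("gene-set scores average member genes and contrast groups", {
  m <- matrix(c(1, 2, 3, 0, 0, 0), nrow = 3,
              dimnames = list(c("GZMB", "PRF1", "IFNG"), c("hi", "lo")))
  sc <- scoreGeneSet(m, "effector")
  expect_equal(unname(sc$score), c(2, 0))
  # protein aliases map to gene symbols
  m2 <- matrix(1:2, nrow = 2, dimnames = list(c("HAVCR2", "PDCD1"), "c"))
  sc2 <- scoreGeneSet(m2, c("TIM3", "PD1"))
  expect_setequal(sc2$genes_used, c("HAVCR2", "PDCD1"))
  expect_error(scoreGeneSet(m, c("NOPE1", "NOPE2")), "empty intersection")
  # identical groups give t near 0
  set.seed(3)
  mm <- matrix(rnorm(300, 5), nrow = 3,
               dimnames = list(c("GZMB", "PRF1", "IFNG"), NULL))
  grp <- rep(c("A", "B"), each = 50)
  out <- scoreGeneSet(mm, "effector", groups = grp, contrast = c("A", "B"))
  expect_lt(abs(out$contrast$t), 2.5)
})

test_that("exhaustion scores separate tumor-restricted from shared clones", {
  cfg <- synthConfig(seed = 19, n_patients = 1, clones_per_patient = 300,
                     depths = c(TUMOR = 10000, NAT = 10000, PBMC = 10000),
                     sc_cells = 400)
  sc <- generateCells(cfg)
  lc <- normalizeCells(sc$counts)
  ct <- sc$cell_truth
  keep <- ct$pattern %in% c("TUMOR", "ALL")
  out <- scoreGeneSet(lc[, ct$cell_id[keep]], "exhaustion",
                      groups = ct$pattern[keep],
                      contrast = c("TUMOR", "ALL"))
  gs <- out$group_summary
  expect_gt(gs$mean[gs$group == "TUMOR"], gs$mean[gs$group == "ALL"])
  expect_lt(out$contrast$p, 0.01)
})

test_that("marker finding enforces min.pct and logFC thresholds", {
  set.seed(4)
  genes <- c(sprintf("BG%03d", 1:60), "SPARSE", "MARK")
  n <- 120
  counts <- matrix(rpois(length(genes) * n, 2), nrow = length(genes),
                   dimnames = list(genes, paste0("c", 1:n)))
  cl <- rep(c("A", "B"), each = n / 2)
  # MARK: strong cluster-A marker; SPARSE: huge in a few cells only
  counts["MARK", cl == "A"] <- rpois(n / 2, 10)
  counts["SPARSE", ] <- 0L
  counts["SPARSE", which(cl == "A")[1:5]] <- 50L
  lc <- normalizeCells(counts)
  mk <- findMarkers(lc, cl)
  a <- mk[mk$cluster == "A", ]
  expect_true("MARK" %in% a$gene)
  expect_false("SPARSE" %in% a$gene)  # expressed in <25% of the cluster
  expect_true(all(abs(a$logfc) >= 0.25))
  expect_true(all(a$pct_in >= 0.25))
  expect_error(findMarkers(lc, rep("A", n)), "two clusters")
  expect_warning(findMarkers(lc, c(rep("A", 2), rep("B", n - 2))), "fewer")
})

test_that("planted cluster markers are recovered at FDR 0.05", {
  set.seed(8)
  genes <- c(sprintf("BG%03d", 1:180), sprintf("DE%02d", 1:20))
  n <- 300
  counts <- matrix(rpois(length(genes) * n, 3), nrow = length(genes),
                   dimnames = list(genes, paste0("c", 1:n)))
  cl <- rep(c("A", "B"), c(100, 200))
  de <- sprintf("DE%02d", 1:20)
  counts[de, cl == "A"] <- rpois(20 * 100, 12)  # 4-fold elevation
  mk <- findMarkers(normalizeCells(counts), cl)
  hit <- mk$gene[mk$cluster == "A" & mk$p_adj < 0.05 & mk$logfc > 0]
  expect_gte(length(intersect(de, hit)), 18)
})

test_that("bulk and single-cell frequencies correlate when concordant", {
  bulk <- filterProductive(rep_from_counts(
    c(CASSA = 50, CASSB = 30, CASSC = 15, CASSD = 4, CASSE = 1)))
  pairs <- data.frame(pair_key = paste0("CAV:", c("CASSA", "CASSB", "CASSC",
                                                  "CASSD", "CASSE")),
                      trb_cdr3_aa = c("CASSA", "CASSB", "CASSC", "CASSD",
                                      "CASSE"),
                      cell_count = c(50L, 30L, 15L, 4L, 1L))
  out <- correlateBulkSc(bulk, pairs)
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_equal(out$n_matched, 5)
  # permuted frequencies decorrelate
  set.seed(10)
  n <- 100
  counts <- sort(rpois(n, 20) + 1, decreasing = TRUE)
  aa <- sprintf("CASS%03d", 1:n)
  bulk2 <- filterProductive(rep_from_counts(setNames(counts, aa)))
  pairs2 <- data.frame(pair_key = paste0("CAV:", aa), trb_cdr3_aa = aa,
                       cell_count = sample(counts))
  expect_lt(abs(correlateBulkSc(bulk2, pairs2)$r), 0.2)
  # too few matches is flagged
  expect_warning(out3 <- correlateBulkSc(bulk, pairs[1:2, ]), "matched")
  expect_true(is.na(out3$r))
})

test_that("DP-containing clonotypes are summarized by tissue pattern", {
  cells <- data.frame(
    cell_id = sprintf("c%02d", 1:9),
    tra = "CAVA", trb = "CASSMIX", tissue = "TUMOR")
  cells$trb[8:9] <- "CASSDPONLY"
  ct <- pairChains(contigs_from_cells(cells))
  ct$lineage <- c(rep("CD8", 5), "DP", "DP", "DP", "DP")
  out <- dpClonotypeAnalysis(ct)
  mix <- out$clonotypes[out$clonotypes$pair_key == "CAVA:CASSMIX", ]
  expect_equal(mix$dp_cells, 2L)
  expect_equal(mix$sp_cells, 5L)
  expect_false(mix$dp_only)
  only <- out$clonotypes[out$clonotypes$pair_key == "CAVA:CASSDPONLY", ]
  expect_true(only$dp_only)
  expect_equal(out$pattern_summary$n, 2L)  # both DP-containing, both TUMOR
})

test_that("planted DP-clonotype pattern composition is recovered exactly", {
  # 56 DP-containing clonotypes: 26 TUMOR, 20 ALL, 10 TN
  pat <- rep(c("TUMOR", "ALL", "TN"), c(26, 20, 10))
  rows <- list()
  for (i in seq_along(pat)) {
    tissues <- switch(pat[i], TUMOR = "TUMOR",
                      ALL = c("TUMOR", "NAT", "PBMC"), TN = c("TUMOR", "NAT"))
    # one DP cell in tumor plus one single-positive cell per tissue
    rows[[i]] <- data.frame(
      cell_id = sprintf("k%02d_%d", i, seq_len(length(tissues) + 1)),
      tra = sprintf("CAV%02d", i), trb = sprintf("CASS%02d", i),
      tissue = c("TUMOR", tissues),
      lineage = c("DP", rep("CD8", length(tissues))))
  }
  tab <- do.call(rbind, rows)
  ct <- pairChains(contigs_from_cells(tab[, c("cell_id", "tra", "trb",
                                              "tissue")]))
  ct$lineage <- tab$lineage[match(ct$cell_id, tab$cell_id)]
  out <- dpClonotypeAnalysis(ct)
  ps <- out$pattern_summary
  expect_equal(ps$n[ps$pattern == "TUMOR"], 26L)
  expect_equal(ps$n[ps$pattern == "ALL"], 20L)
  expect_equal(ps$n[ps$pattern == "TN"], 10L)
  expect_equal(sum(out$clonotypes$dp_cells > 0), 56)
})

test_that("phenotype recovery degrades monotonically with expression noise", {
  rec <- vapply(c(0, 0.6, 1.2), function(ns) {
    cfg <- synthConfig(seed = 29, n_patients = 1, clones_per_patient = 200,
                       depths = c(TUMOR = 5000, NAT = 5000, PBMC = 5000),
                       sc_cells = 250, expression_noise_sd = ns)
    sc <- generateCells(cfg)
    lab <- classifyPhenotype(normalizeCells(sc$counts))$label
    mean(lab == sc$cell_truth$phenotype)
  }, numeric(1))
  expect_true(all(diff(rec) <= 0))
  expect_gte(rec[1], 0.9)
})
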