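#' Pair TRA/TRB chains per cell
#'
#' From a long contig table (one row per recovered chain), assigns each
#' cell with exactly one TRA and one TRB CDR3 a pair key
#' `"<TRA aa>:<TRB aa>"`. Cells lacking either chain are left unpaired but
#' retained (they still carry expression); cells with more than one chain
#' of a kind are flagged `multi_chain` for [filterDoublets()].
#'
#' @param contigs data.frame with columns `cell_id`, `chain`
#'   (`"TRA"`/`"TRB"`), `cdr3` (aa), `cdr3_nt`; optional `sample_id`,
#'   `tissue`, `patient_id` carried through.
#' @return data.frame, one row per cell: `cell_id`, `n_tra`, `n_trb`,
#'   `tra_cdr3_aa`, `trb_cdr3_aa`, `tra_cdr3_nt`, `trb_cdr3_nt`,
#'   `pair_key`, `paired`, `multi_chain` (+ carried metadata). Attribute
#'   `unpaired_report` counts the pairing outcomes.
#' @export
pairChains <- function(contigs) {
  need <- c("cell_id", "chain", "cdr3")
  miss <- setdiff(need, names(contigs))
  if (length(miss))
    stop("contig table missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(contigs$cdr3_nt)) contigs$cdr3_nt <- NA_character_
  contigs$cdr3 <- toupper(trimws(contigs$cdr3))
  meta_cols <- intersect(c("sample_id", "tissue", "patient_id"), names(contigs))
  ids <- unique(contigs$cell_id)
  is_tra <- contigs$chain == "TRA"
  n_tra <- table(factor(contigs$cell_id[is_tra], levels = ids))
  n_trb <- table(factor(contigs$cell_id[!is_tra], levels = ids))
  cells <- data.frame(cell_id = ids,
                      n_tra = as.integer(n_tra[ids]),
                      n_trb = as.integer(n_trb[ids]),
                      stringsAsFactors = FALSE)
  # single-chain fields: take the (unique) contig of each kind via match
  mt <- match(ids, contigs$cell_id[is_tra])
  mb <- match(ids, contigs$cell_id[!is_tra])
  cells$tra_cdr3_aa <- ifelse(cells$n_tra == 1, contigs$cdr3[is_tra][mt], NA)
  cells$trb_cdr3_aa <- ifelse(cells$n_trb == 1, contigs$cdr3[!is_tra][mb], NA)
  cells$tra_cdr3_nt <- ifelse(cells$n_tra == 1, contigs$cdr3_nt[is_tra][mt], NA)
  cells$trb_cdr3_nt <- ifelse(cells$n_trb == 1, contigs$cdr3_nt[!is_tra][mb], NA)
  mi <- match(ids, contigs$cell_id)
  for (mc in meta_cols) cells[[mc]] <- contigs[[mc]][mi]
  cells$multi_chain <- cells$n_tra >= 2 | cells$n_trb >= 2
  cells$paired <- cells$n_tra == 1 & cells$n_trb == 1
  cells$pair_key <- ifelse(cells$paired,
                           paste(cells$tra_cdr3_aa, cells$trb_cdr3_aa, sep = ":"),
                           NA_character_)
  attr(cells, "unpaired_report") <- c(
    cells = nrow(cells), paired = sum(cells$paired),
    missing_chain = sum(cells$n_tra == 0 | cells$n_trb == 0),
    multi_chain = sum(cells$multi_chain))
  cells
}

#' Remove putative doublets
#'
#' Cells with more than one TRA or more than one TRB CDR3 detected are
#' removed (two cells captured together produce multi-chain profiles).
#'
#' @param cells output of [pairChains()]
#' @return list with `cells` (retained rows) and `removed` (count)
#' @export
filterDoublets <- function(cells) {
  stopifnot("multi_chain" %in% names(cells))
  keep <- !cells$multi_chain
  list(cells = cells[keep, , drop = FALSE], removed = sum(!keep))
}

#' Clone size class from cell count
#'
#' Boundaries: singleton = 1 cell, small = 2-4, medium = 5-20,
#' large = more than 20 cells.
#'
#' @param cell_count integer vector of cells per clonotype (>= 1)
#' @return factor with levels singleton < small < medium < large
#' @export
assignSizeClass <- function(cell_count) {
  stopifnot(all(cell_count >= 1))
  cut(cell_count, breaks = c(0, 1, 4, 20, Inf),
      labels = c("singleton", "small", "medium", "large"),
      ordered_result = TRUE)
}

#' Aggregate cells into paired clonotypes
#'
#' Collapses paired, doublet-filtered cells to unique TRA/TRB-CDR3 pairs.
#' Cells with identical TRB but different TRA are distinct clonotypes.
#'
#' @param cells output of [pairChains()] (post [filterDoublets()]);
#'   optional `tissue` column drives the tissue pattern.
#' @return data.frame per pair: `pair_key`, `tra_cdr3_aa`, `trb_cdr3_aa`,
#'   `cell_count`, `multiplet`, `size_class`, per-tissue cell counts and
#'   `pattern` when tissue is available.
#' @export
pairedClonotypes <- function(cells) {
  cc <- cells[cells$paired, , drop = FALSE]
  if (!nrow(cc)) stop("no paired cells")
  n <- tapply(cc$cell_id, cc$pair_key, length)
  keys <- names(n)
  first <- cc[!duplicated(cc$pair_key), , drop = FALSE]
  first <- first[match(keys, first$pair_key), ]
  out <- data.frame(pair_key = keys,
                    tra_cdr3_aa = first$tra_cdr3_aa,
                    trb_cdr3_aa = first$trb_cdr3_aa,
                    cell_count = as.integer(n),
                    stringsAsFactors = FALSE)
  out$multiplet <- out$cell_count >= 2
  out$size_class <- assignSizeClass(out$cell_count)
  if ("tissue" %in% names(cc) && !all(is.na(cc$tissue))) {
    for (ts in intersect(.TISSUES, unique(cc$tissue))) {
      cnt <- tapply(cc$tissue == ts, cc$pair_key, sum)
      out[[paste0("cells_", ts)]] <- as.integer(cnt[keys])
    }
    occ <- tapply(cc$tissue, cc$pair_key, unique)
    out$pattern <- vapply(occ[keys], classifyTissuePattern, character(1))
  }
  out <- out[order(-out$cell_count, out$pair_key), ]
  rownames(out) <- NULL
  out
}

#' Clonotype density by size class
#'
#' The number of unique TRA/TRB pairs in each size class as a fraction of
#' all unique pairs.
#'
#' @param pairs output of [pairedClonotypes()]
#' @return data.frame `size_class`, `n_pairs`, `density` (fractions sum
#'   to 1)
#' @export
clonotypeDensity <- function(pairs) {
  stopifnot(nrow(pairs) >= 1)
  tab <- table(pairs$size_class)
  data.frame(size_class = names(tab), n_pairs = as.integer(tab),
             density = as.integer(tab) / nrow(pairs))
}

#' Build a SingleCellExperiment for chain-annotated T cells
#'
#' @param counts genes x cells count matrix (dense or sparse); colnames are
#'   cell ids
#' @param cells per-cell table from [pairChains()] (rows matched to columns
#'   by `cell_id`; cells absent from the table get NA chain fields)
#' @return a [SingleCellExperiment::SingleCellExperiment] with `counts`
#'   assay and the chain/pair fields in `colData`
#' @export
buildCellExperiment <- function(counts, cells) {
  stopifnot(!is.null(colnames(counts)))
  m <- match(colnames(counts), cells$cell_id)
  cd <- cells[m, setdiff(names(cells), "cell_id"), drop = FALSE]
  rownames(cd) <- colnames(counts)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(cd))
}

#' Read a cells-by-genes expression matrix
#'
#' Accepts either a 10X-style MTX triplet directory (`matrix.mtx` plus
#' `features.tsv`/`genes.tsv` and `barcodes.tsv`) or a dense TSV with gene
#' ids in the first column and one column per cell.
#'
#' @param path directory containing the MTX triplet, or a TSV file path
#' @return genes x cells count matrix (sparse for MTX input)
#' @export
readCellCounts <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    feats <- Filter(file.exists,
                    file.path(path, c("features.tsv", "genes.tsv")))[1]
    bcs <- file.path(path, "barcodes.tsv")
    if (!file.exists(mtx) || is.na(feats) || !file.exists(bcs))
      stop("MTX triplet incomplete in ", path,
           " (need matrix.mtx, features.tsv/genes.tsv, barcodes.tsv)")
    m <- Matrix::readMM(mtx)
    rownames(m) <- utils::read.delim(feats, header = FALSE)[[1]]
    colnames(m) <- utils::read.delim(bcs, header = FALSE)[[1]]
    return(m)
  }
  as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
}

#' Library-size normalization
#'
#' Counts per cell are scaled to a fixed library size (default 10,000) and
#' log1p-transformed: the conventional single-cell normalization.
#'
#' @param x counts matrix (genes x cells) or a SingleCellExperiment with a
#'   `counts` assay
#' @param scale target library size
#' @return matrix of normalized log expression (or the SCE with a
#'   `logcounts` assay added)
#' @export
normalizeCells <- function(x, scale = 1e4) {
  if (methods::is(x, "SingleCellExperiment")) {
    SummarizedExperiment::assay(x, "logcounts") <-
      normalizeCells(SummarizedExperiment::assay(x, "counts"), scale)
    return(x)
  }
  lib <- Matrix::colSums(x)
  lib[lib == 0] <- 1
  log1p(sweep(as.matrix(x), 2, lib, "/") * scale)
}

#' CD4/CD8 lineage assignment from raw counts
#'
#' A cell is CD4 when its CD4 count reaches `min_count` and its summed
#' CD8A+CD8B count does not; CD8 symmetrically; double-positive (DP) when
#' both do; unassigned otherwise.
#'
#' @param counts genes x cells raw count matrix
#' @param cd4_genes,cd8_genes marker genes (defaults CD4; CD8A, CD8B)
#' @param min_count positivity threshold in raw counts (default 1)
#' @return character vector (per cell) in \{CD4, CD8, DP, unassigned\}
#' @export
assignLineage <- function(counts, cd4_genes = "CD4",
                          cd8_genes = c("CD8A", "CD8B"), min_count = 1) {
  g4 <- intersect(cd4_genes, rownames(counts))
  g8 <- intersect(cd8_genes, rownames(counts))
  if (!length(g4) || !length(g8))
    stop("lineage genes absent from the count matrix")
  s4 <- Matrix::colSums(counts[g4, , drop = FALSE])
  s8 <- Matrix::colSums(counts[g8, , drop = FALSE])
  ifelse(s4 >= min_count & s8 >= min_count, "DP",
         ifelse(s4 >= min_count, "CD4",
                ifelse(s8 >= min_count, "CD8", "unassigned")))
}

#' Default phenotype marker table
#'
#' Reads the marker table shipped with the package (phenotype label ->
#' marker genes), a compact stand-in for classifier marker files used with
#' bulk-derived signatures. Users may supply their own table of the same
#' shape to [classifyPhenotype()].
#'
#' @return named list phenotype -> character vector of gene symbols
#' @export
defaultMarkerTable <- function() {
  path <- system.file("extdata", "phenotype_markers.tsv", package = "tilclone")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(tab$gene, tab$phenotype), unique)
}

#' Default gene sets (exhaustion, activation, effector, proliferation)
#'
#' Exhaustion: ICOS, HAVCR2, CTLA4, PDCD1, LAG3, TIGIT. Activation:
#' TNFRSF9, CD69, IL2RA. Effector: GZMB, PRF1, IFNG. Proliferation: MKI67,
#' TOP2A, CCNB1. Protein aliases (TIM3, PD1, CD25, TNFSR9) are mapped to
#' gene symbols by [mapGeneAliases()].
#'
#' @return named list of gene vectors
#' @export
defaultGeneSets <- function() {
  list(exhaustion = c("ICOS", "HAVCR2", "CTLA4", "PDCD1", "LAG3", "TIGIT"),
       activation = c("TNFRSF9", "CD69", "IL2RA"),
       effector = c("GZMB", "PRF1", "IFNG"),
       proliferation = c("MKI67", "TOP2A", "CCNB1"))
}

.GENE_ALIASES <- c(TIM3 = "HAVCR2", PD1 = "PDCD1", CD25 = "IL2RA",
                   TNFSR9 = "TNFRSF9", TNFRSF9 = "TNFRSF9", TBET = "TBX21",
                   "IL-7R" = "IL7R")

#' Map protein aliases to gene symbols
#'
#' @param genes character vector possibly containing protein-name aliases
#' @return character vector of gene symbols
#' @export
mapGeneAliases <- function(genes) {
  up <- toupper(genes)
  ifelse(up %in% names(.GENE_ALIASES), unname(.GENE_ALIASES[up]), up)
}

#' Marker-score phenotype classification
#'
#' Scores each cell for each phenotype as the mean, over that phenotype's
#' markers, of log-normalized expression relative to the gene's baseline
#' (its lower-quartile expression across cells — robust to a marker being
#' elevated in even a majority cell state, unlike mean- or median-centered
#' z-scores). The argmax label is assigned when it leads the runner-up by
#' `min_score_margin` (otherwise `"unassigned"`). Markers absent from the
#' matrix are dropped with a warning; a phenotype with no present markers
#' never wins.
#'
#' @param logcounts normalized (library-size scaled, log1p) genes x cells
#'   matrix
#' @param marker_table named list phenotype -> marker genes (default
#'   [defaultMarkerTable()])
#' @param min_score_margin required lead over the runner-up (log-units;
#'   default 0, i.e. plain argmax)
#' @return list with `label` (per cell) and `scores` (phenotype x cell
#'   matrix)
#' @export
classifyPhenotype <- function(logcounts, marker_table = defaultMarkerTable(),
                              min_score_margin = 0) {
  logcounts <- as.matrix(logcounts)
  baseline <- apply(logcounts, 1, stats::quantile, probs = 0.25, names = FALSE)
  z <- logcounts - baseline
  scores <- do.call(rbind, lapply(names(marker_table), function(ph) {
    genes <- intersect(mapGeneAliases(marker_table[[ph]]), rownames(z))
    missing <- setdiff(mapGeneAliases(marker_table[[ph]]), rownames(z))
    if (length(missing))
      warning("phenotype ", ph, ": marker(s) absent from matrix: ",
              paste(missing, collapse = ", "))
    if (!length(genes)) return(rep(-Inf, ncol(z)))
    colMeans(z[genes, , drop = FALSE])
  }))
  rownames(scores) <- names(marker_table)
  label <- apply(scores, 2, function(s) {
    if (all(!is.finite(s))) return("unassigned")
    ord <- order(s, decreasing = TRUE)
    lead <- s[ord[1]] - if (length(s) > 1) s[ord[2]] else -Inf
    if (lead >= min_score_margin) names(s)[ord[1]] else "unassigned"
  })
  # all-zero cells carry no signal: never assign them
  label[colSums(logcounts) == 0] <- "unassigned"
  list(label = unname(label), scores = scores)
}

#' Mean gene-set score per cell, with a group contrast
#'
#' The score is the mean normalized expression over the set's genes
#' (aliases mapped). When `groups` is given, per-group means and SDs are
#' reported with a two-sample t statistic between `contrast` groups.
#'
#' @param logcounts normalized genes x cells matrix
#' @param gene_set character vector of genes (or a name from
#'   [defaultGeneSets()])
#' @param groups optional per-cell grouping (e.g. tissue pattern)
#' @param contrast length-2 vector of group labels to test (default: first
#'   two by group mean)
#' @return list with `score` (per cell), and when grouped `group_summary`
#'   and `contrast` (t, p)
#' @export
scoreGeneSet <- function(logcounts, gene_set, groups = NULL, contrast = NULL) {
  if (is.character(gene_set) && length(gene_set) == 1 &&
      gene_set %in% names(defaultGeneSets()))
    gene_set <- defaultGeneSets()[[gene_set]]
  genes <- intersect(mapGeneAliases(gene_set), rownames(logcounts))
  if (!length(genes))
    stop("gene set has empty intersection with the expression matrix")
  score <- colMeans(as.matrix(logcounts[genes, , drop = FALSE]))
  out <- list(score = score, genes_used = genes)
  if (!is.null(groups)) {
    gs <- split(score, groups)
    out$group_summary <- data.frame(
      group = names(gs),
      n = vapply(gs, length, integer(1)),
      mean = vapply(gs, mean, numeric(1)),
      sd = vapply(gs, stats::sd, numeric(1)))
    if (is.null(contrast)) contrast <- utils::head(names(gs), 2)
    if (length(contrast) == 2 && all(contrast %in% names(gs))) {
      a <- gs[[contrast[1]]]; b <- gs[[contrast[2]]]
      if (length(a) > 1 && length(b) > 1 && (stats::sd(a) > 0 || stats::sd(b) > 0)) {
        tt <- stats::t.test(a, b)
        out$contrast <- data.frame(group_a = contrast[1], group_b = contrast[2],
                                   t = unname(tt$statistic), p = tt$p.value)
      }
    }
  }
  out
}

#' Per-cluster marker genes
#'
#' For each cluster versus all other cells: keeps genes expressed in at
#' least `min_pct` of the cluster's cells with an absolute log fold-change
#' (difference of mean log-normalized expression) of at least `min_logfc`,
#' ranks them by Wilcoxon rank-sum test, and adjusts p-values by
#' Benjamini-Hochberg within cluster. Clusters of fewer than 3 cells are
#' skipped with a warning.
#'
#' @param logcounts normalized genes x cells matrix
#' @param clusters per-cell cluster labels
#' @param min_pct minimum expressing fraction in the cluster (default 0.25)
#' @param min_logfc minimum |log fold-change| (default 0.25)
#' @return data.frame `cluster`, `gene`, `pct_in`, `pct_out`, `logfc`,
#'   `p`, `p_adj`, ordered by cluster then p
#' @export
findMarkers <- function(logcounts, clusters, min_pct = 0.25, min_logfc = 0.25) {
  logcounts <- as.matrix(logcounts)
  if (length(unique(clusters)) < 2) stop("need at least two clusters")
  res <- list()
  for (cl in sort(unique(as.character(clusters)))) {
    inc <- clusters == cl
    if (sum(inc) < 3) {
      warning("cluster ", cl, " has fewer than 3 cells; skipped")
      next
    }
    pct_in <- rowMeans(logcounts[, inc, drop = FALSE] > 0)
    pct_out <- rowMeans(logcounts[, !inc, drop = FALSE] > 0)
    logfc <- rowMeans(logcounts[, inc, drop = FALSE]) -
      rowMeans(logcounts[, !inc, drop = FALSE])
    keep <- which(pct_in >= min_pct & abs(logfc) >= min_logfc)
    if (!length(keep)) next
    p <- vapply(keep, function(g)
      stats::wilcox.test(logcounts[g, inc], logcounts[g, !inc])$p.value,
      numeric(1))
    res[[cl]] <- data.frame(cluster = cl, gene = rownames(logcounts)[keep],
                            pct_in = pct_in[keep], pct_out = pct_out[keep],
                            logfc = logfc[keep], p = p,
                            p_adj = stats::p.adjust(p, "BH"),
                            stringsAsFactors = FALSE)
    res[[cl]] <- res[[cl]][order(res[[cl]]$p, res[[cl]]$gene), ]
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Correlate single-cell and bulk clonal frequencies
#'
#' Matches single-cell clonotypes to the bulk repertoire by TRB-CDR3
#' amino-acid sequence (cell counts of pairs sharing a TRB are summed) and
#' reports the Pearson correlation of clonal frequencies, on the raw scale
#' and on log10 frequencies as a secondary statistic.
#'
#' @param bulk a productive-filtered [Repertoire-class]
#' @param pairs output of [pairedClonotypes()]
#' @param min_matches minimum matched clonotypes (default 5; fewer gives
#'   NA correlations with a warning)
#' @return data.frame `r`, `r_log10`, `n_matched`, `n_bulk_only`,
#'   `n_sc_only`
#' @export
correlateBulkSc <- function(bulk, pairs, min_matches = 5) {
  sc_n <- tapply(pairs$cell_count, pairs$trb_cdr3_aa, sum)
  sc_freq <- sc_n / sum(pairs$cell_count)
  rec <- clonotypes(bulk)
  rec <- rec[rec$productive, , drop = FALSE]
  bfreq <- tapply(rec$frequency, rec$cdr3_aa, sum)
  common <- intersect(names(sc_freq), names(bfreq))
  if (length(common) < min_matches) {
    warning("only ", length(common), " matched clonotypes; correlation undefined")
    return(data.frame(r = NA_real_, r_log10 = NA_real_,
                      n_matched = length(common),
                      n_bulk_only = length(bfreq) - length(common),
                      n_sc_only = length(sc_freq) - length(common)))
  }
  x <- as.numeric(bfreq[common]); y <- as.numeric(sc_freq[common])
  data.frame(r = stats::cor(x, y),
             r_log10 = stats::cor(log10(x), log10(y)),
             n_matched = length(common),
             n_bulk_only = length(bfreq) - length(common),
             n_sc_only = length(sc_freq) - length(common))
}

#' Clonotypes containing CD4+CD8+ double-positive cells
#'
#' Summarizes, per clonotype, how many member cells are double positive
#' versus single positive, flags DP-only clonotypes (none were observed in
#' practice: every DP-containing clonotype also carried single-positive
#' cells, which this flag lets one check), and tallies DP-containing
#' clonotypes by tissue pattern.
#'
#' @param cells paired, doublet-filtered cell table with a `lineage`
#'   column (from [assignLineage()]) and optionally `tissue`
#' @return list with `clonotypes` (per-clonotype table: `pair_key`,
#'   `dp_cells`, `sp_cells`, `cell_count`, `dp_only`, `multiplet`,
#'   `pattern`) and `pattern_summary` (DP-containing clonotypes by
#'   pattern)
#' @export
dpClonotypeAnalysis <- function(cells) {
  stopifnot("lineage" %in% names(cells))
  cc <- cells[cells$paired, , drop = FALSE]
  dp <- tapply(cc$lineage == "DP", cc$pair_key, sum)
  sp <- tapply(cc$lineage %in% c("CD4", "CD8"), cc$pair_key, sum)
  n <- tapply(cc$cell_id, cc$pair_key, length)
  keys <- names(n)
  tab <- data.frame(pair_key = keys,
                    dp_cells = as.integer(dp[keys]),
                    sp_cells = as.integer(sp[keys]),
                    cell_count = as.integer(n),
                    stringsAsFactors = FALSE)
  tab$dp_only <- tab$dp_cells == tab$cell_count & tab$dp_cells > 0
  tab$multiplet <- tab$cell_count >= 2
  if ("tissue" %in% names(cc)) {
    occ <- tapply(cc$tissue, cc$pair_key, unique)
    tab$pattern <- vapply(occ[keys], classifyTissuePattern, character(1))
  }
  dp_tab <- tab[tab$dp_cells > 0, , drop = FALSE]
  summ <- if ("pattern" %in% names(tab) && nrow(dp_tab)) {
    as.data.frame(table(pattern = dp_tab$pattern), responseName = "n")
  } else NULL
  list(clonotypes = tab, pattern_summary = summ)
}
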