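#' Synthetic cohort configuration
#'
#' Assembles and validates the parameters of the synthetic multi-tissue
#' cohort generator. Defaults emulate the statistical structure of a
#' nephrectomy cohort profiled by survey-level bulk TRB sequencing,
#' droplet scRNAseq and mIHC: heavy-tailed (Zipf) clone abundances with a
#' dominant clone in the 5-25% range, seven tissue-distribution patterns,
#' phenotype-dependent marker expression, occasional convergent
#' nucleotypes, planted interior-motif families, a donor-wise control
#' library, and inside/outside border point intensities.
#'
#' @param seed integer RNG seed; all outputs are deterministic given it
#' @param n_patients number of patients (default 14)
#' @param clones_per_patient unique clones per patient (default 2500)
#' @param zipf_exponent clone-abundance Zipf exponent (default 1.2)
#' @param tissue_pattern_probs named 7-vector over TUMOR, NAT, PBMC, TN,
#'   TP, PN, ALL; must sum to 1
#' @param depths named per-tissue sequencing depths (reads; default 1e5
#'   each; minimum 100)
#' @param nonproductive_rate fraction of emitted rows that are
#'   non-productive rearrangements (default 0.15)
#' @param sc_cells cells per single-cell sample (default 4000)
#' @param doublet_rate cell-doublet rate (default 0.03)
#' @param dp_rate CD4+CD8+ double-positive cell rate (default 0.022)
#' @param phenotype_shift fold-elevation of a phenotype's own markers
#'   (default 2)
#' @param exhaustion_shift additional log-unit shift of exhaustion genes
#'   in tumor-restricted clones (default 1)
#' @param expression_noise_sd extra per-cell-per-gene log-normal noise SD
#'   (default 0)
#' @param convergence_rate fraction of clones with two nucleotypes
#'   (default 0.05)
#' @param motif_family_sizes planted motif-family sizes (default 5, 4, 3)
#' @param n_control_donors control-library donors (default 55)
#' @param patient_unique_rate fraction of clones absent from the control
#'   library (default 0.639)
#' @param spatial_intensity named list per class of `c(inside, outside)`
#'   intensities in cells/mm^2 (defaults CD8 500/100, CD4 300/150)
#' @param ki67_prob Ki67 positivity probability (default 0.15)
#' @param spatial_window `c(xmin, xmax, ymin, ymax)` in um
#' @param border_shape `"straight"` or `"sinusoid"`
#' @return validated config list (class `tilclone_config`)
#' @export
synthConfig <- function(seed = 1,
                        n_patients = 14,
                        clones_per_patient = 2500,
                        zipf_exponent = 1.2,
                        tissue_pattern_probs = c(TUMOR = 0.15, NAT = 0.15,
                                                 PBMC = 0.20, TN = 0.08,
                                                 TP = 0.12, PN = 0.10,
                                                 ALL = 0.20),
                        depths = c(TUMOR = 1e5, NAT = 1e5, PBMC = 1e5),
                        nonproductive_rate = 0.15,
                        sc_cells = 4000,
                        doublet_rate = 0.03,
                        dp_rate = 0.022,
                        phenotype_shift = 2,
                        exhaustion_shift = 1,
                        expression_noise_sd = 0,
                        convergence_rate = 0.05,
                        motif_family_sizes = c(5, 4, 3),
                        n_control_donors = 55,
                        patient_unique_rate = 0.639,
                        spatial_intensity = list(CD8 = c(inside = 500, outside = 100),
                                                 CD4 = c(inside = 300, outside = 150)),
                        ki67_prob = 0.15,
                        spatial_window = c(-1000, 1000, 0, 1000),
                        border_shape = c("straight", "sinusoid")) {
  cfg <- list(seed = as.integer(seed), n_patients = n_patients,
              clones_per_patient = clones_per_patient,
              zipf_exponent = zipf_exponent,
              tissue_pattern_probs = tissue_pattern_probs,
              depths = depths, nonproductive_rate = nonproductive_rate,
              sc_cells = sc_cells, doublet_rate = doublet_rate,
              dp_rate = dp_rate, phenotype_shift = phenotype_shift,
              exhaustion_shift = exhaustion_shift,
              expression_noise_sd = expression_noise_sd,
              convergence_rate = convergence_rate,
              motif_family_sizes = motif_family_sizes,
              n_control_donors = n_control_donors,
              patient_unique_rate = patient_unique_rate,
              spatial_intensity = spatial_intensity,
              ki67_prob = ki67_prob, spatial_window = spatial_window,
              border_shape = match.arg(border_shape))
  bad <- character()
  pp <- cfg$tissue_pattern_probs
  if (length(pp) != 7 || abs(sum(pp) - 1) > 1e-8 || any(pp < 0))
    bad <- c(bad, "tissue_pattern_probs (7 non-negative values summing to 1)")
  if (!setequal(names(pp), c("TUMOR", "NAT", "PBMC", "TN", "TP", "PN", "ALL")))
    bad <- c(bad, "tissue_pattern_probs names")
  for (fld in c("nonproductive_rate", "doublet_rate", "dp_rate",
                "convergence_rate", "patient_unique_rate", "ki67_prob"))
    if (cfg[[fld]] < 0 || cfg[[fld]] > 1) bad <- c(bad, fld)
  if (any(cfg$depths < 100)) bad <- c(bad, "depths (each >= 100)")
  if (any(unlist(cfg$spatial_intensity) < 0)) bad <- c(bad, "spatial_intensity")
  if (length(bad))
    stop("invalid config field(s): ", paste(bad, collapse = "; "))
  class(cfg) <- "tilclone_config"
  cfg
}

# amino-acid alphabet with fixed interior frequencies (rough CDR3 usage:
# G/S/L-rich) and a two-codon back-translation table
.AA <- c("A","C","D","E","F","G","H","I","K","L",
         "M","N","P","Q","R","S","T","V","W","Y")
.AA_FREQ <- c(6,1,4,5,4,12,2,3,3,9, 1,4,4,6,7,12,6,5,2,4) / 100
.CODONS <- list(A = c("GCT","GCC"), C = c("TGT","TGC"), D = c("GAT","GAC"),
                E = c("GAA","GAG"), F = c("TTT","TTC"), G = c("GGA","GGC"),
                H = c("CAT","CAC"), I = c("ATT","ATC"), K = c("AAA","AAG"),
                L = c("CTG","CTC"), M = c("ATG","ATG"), N = c("AAT","AAC"),
                P = c("CCT","CCC"), Q = c("CAA","CAG"), R = c("AGA","CGC"),
                S = c("AGC","TCT"), T = c("ACT","ACC"), V = c("GTT","GTC"),
                W = c("TGG","TGG"), Y = c("TAT","TAC"))

.translate_back <- function(aa, variant = 1L) {
  paste(vapply(strsplit(aa, "")[[1]], function(a) {
    cs <- .CODONS[[a]]
    if (variant == 1L || length(unique(cs)) == 1L) cs[1] else cs[2]
  }, ""), collapse = "")
}

.MOTIF_POOL <- c("QGAD", "WNTE", "RLGH", "KDFV", "MPYE", "HQWS")

.random_cdr3 <- function(n, min_int = 5, max_int = 9, motif = NULL) {
  lens <- sample(min_int:max_int, n, replace = TRUE)
  vapply(lens, function(L) {
    int <- paste(sample(.AA, L, replace = TRUE, prob = .AA_FREQ), collapse = "")
    if (!is.null(motif)) {
      pos <- sample(max(1, L - nchar(motif) + 1), 1)
      substr(int, pos, pos + nchar(motif) - 1) <- motif
    }
    paste0("CASS", int, "YF")
  }, "")
}

#' Generate a multi-tissue bulk repertoire cohort with ground truth
#'
#' For each patient, clone abundances follow a normalized Zipf law over
#' ranks; each clone draws a tissue-distribution pattern; per-tissue reads
#' are multinomial at the configured depth over the clones occupying that
#' tissue (abundances renormalized within tissue). CDR3 amino-acid
#' sequences are templated (`CASS` + interior + `YF`) with i.i.d.
#' interiors; a configurable fraction of clones carry two nucleotypes
#' encoding the same amino-acid sequence. Interior motif families are
#' planted in the first tumor-occupying clones of patient 1. Control-donor
#' library membership is planted per clone. Non-productive rows (stop
#' codon in the junction) are appended at the configured rate.
#'
#' @param config a [synthConfig()]
#' @param dir optional directory: when given, ImmunoSEQ-style TSVs plus a
#'   sample sheet and truth JSON are written there
#' @return list with `repertoires` (named list of [Repertoire-class],
#'   non-productive rows included), `truth` (per-clone table + config),
#'   `control_library` (donor_id, cdr3_aa)
#' @export
generateRepertoireSet <- function(config = synthConfig(), dir = NULL) {
  stopifnot(inherits(config, "tilclone_config"))
  set.seed(config$seed)
  pat_ids <- sprintf("P%02d", seq_len(config$n_patients))
  labs <- names(config$tissue_pattern_probs)
  truth <- list(); reps <- list(); lib_rows <- list()
  for (pi in seq_along(pat_ids)) {
    pid <- pat_ids[pi]
    n <- config$clones_per_patient
    ab <- (1 / seq_len(n))^config$zipf_exponent
    ab <- ab / sum(ab)
    pattern <- sample(labs, n, replace = TRUE,
                      prob = config$tissue_pattern_probs)
    # unique amino-acid sequences; motif families planted in patient 1 tumor
    aa <- .random_cdr3(n)
    while (anyDuplicated(aa)) {
      d <- duplicated(aa)
      aa[d] <- .random_cdr3(sum(d))
    }
    if (pi == 1 && length(config$motif_family_sizes)) {
      idx <- which(pattern %in% c("TUMOR", "TN", "TP", "ALL"))
      at <- 0
      for (f in seq_along(config$motif_family_sizes)) {
        sz <- config$motif_family_sizes[f]
        take <- idx[seq.int(at + 1, at + sz)]
        aa[take] <- .random_cdr3(sz, min_int = 7, max_int = 9,
                                 motif = .MOTIF_POOL[f])
        at <- at + sz
      }
      while (anyDuplicated(aa)) {  # re-deduplicate outside families
        d <- which(duplicated(aa))
        d <- setdiff(d, idx[seq_len(at)])
        if (!length(d)) break
        aa[d] <- .random_cdr3(length(d))
      }
    }
    convergent <- stats::runif(n) < config$convergence_rate
    nt1 <- vapply(aa, .translate_back, "", variant = 1L)
    nt2 <- ifelse(convergent, vapply(aa, .translate_back, "", variant = 2L), NA)
    in_library <- stats::runif(n) >= config$patient_unique_rate
    prevalence <- ifelse(in_library,
                         pmax(1, round(stats::runif(n, 0.02, 0.6) *
                                         config$n_control_donors)) /
                           config$n_control_donors, 0)
    v <- sample(sprintf("TRBV%02d", 1:30), n, replace = TRUE)
    j <- sample(sprintf("TRBJ%d-%d", rep(1:2, each = 6), 1:6), n, replace = TRUE)
    clone_tab <- data.frame(patient_id = pid, clone = seq_len(n),
                            cdr3_aa = aa, cdr3_nt = nt1, cdr3_nt2 = nt2,
                            v_gene = v, j_gene = j,
                            abundance = ab, pattern = pattern,
                            convergent = convergent,
                            prevalence = prevalence,
                            stringsAsFactors = FALSE)
    truth[[pid]] <- clone_tab
    # control library rows for shared clones
    nshare <- round(prevalence * config$n_control_donors)
    sh <- which(nshare > 0)
    if (length(sh))
      lib_rows[[pid]] <- data.frame(
        donor_id = sprintf("D%02d", unlist(lapply(sh, function(i)
          sample(config$n_control_donors, nshare[i])))),
        cdr3_aa = rep(aa[sh], nshare[sh]), stringsAsFactors = FALSE)
    for (ts in c("TUMOR", "NAT", "PBMC")) {
      occ <- vapply(pattern, function(p)
        ts %in% switch(p, TUMOR = "TUMOR", NAT = "NAT", PBMC = "PBMC",
                       TN = c("TUMOR", "NAT"), TP = c("TUMOR", "PBMC"),
                       PN = c("PBMC", "NAT"),
                       ALL = c("TUMOR", "NAT", "PBMC")), logical(1))
      p_ts <- ab * occ
      if (!any(p_ts > 0)) next
      p_ts <- p_ts / sum(p_ts)
      counts <- as.integer(stats::rmultinom(1, config$depths[[ts]], p_ts))
      det <- counts > 0
      rec <- data.frame(cdr3_nt = nt1[det], cdr3_aa = aa[det],
                        v_gene = v[det], j_gene = j[det],
                        read_count = counts[det], productive = TRUE,
                        stringsAsFactors = FALSE)
      # convergent clones: split reads between the two nucleotypes
      cv <- det & convergent & counts >= 2
      if (any(cv)) {
        half <- pmax(1L, as.integer(counts[cv] * 0.4))
        rec$read_count[match(which(cv), which(det))] <- counts[cv] - half
        rec <- rbind(rec, data.frame(cdr3_nt = nt2[cv], cdr3_aa = aa[cv],
                                     v_gene = v[cv], j_gene = j[cv],
                                     read_count = half, productive = TRUE,
                                     stringsAsFactors = FALSE))
      }
      # non-productive rows
      n_np <- round(nrow(rec) * config$nonproductive_rate /
                      (1 - config$nonproductive_rate))
      if (n_np > 0) {
        np_aa <- .random_cdr3(n_np)
        substr(np_aa, 6, 6) <- "*"
        rec <- rbind(rec, data.frame(
          cdr3_nt = vapply(gsub("\\*", "W", np_aa), .translate_back, ""),
          cdr3_aa = np_aa,
          v_gene = sample(v, n_np, replace = TRUE),
          j_gene = sample(j, n_np, replace = TRUE),
          read_count = sample(1:20, n_np, replace = TRUE),
          productive = FALSE, stringsAsFactors = FALSE))
      }
      sid <- paste(pid, ts, sep = "_")
      reps[[sid]] <- Repertoire(rec, sample_id = sid, patient_id = pid,
                                tissue = ts)
    }
  }
  truth_tab <- do.call(rbind, truth)
  rownames(truth_tab) <- NULL
  lib <- unique(do.call(rbind, lib_rows))
  out <- list(repertoires = reps,
              truth = list(clones = truth_tab, config = config,
                           motif_pool = .MOTIF_POOL[
                             seq_along(config$motif_family_sizes)]),
              control_library = lib)
  if (!is.null(dir)) writeSyntheticCohort(out, dir)
  out
}

#' Write a synthetic cohort to disk in consumer dialects
#'
#' Emits one ImmunoSEQ-style TSV per sample, a sample sheet, the control
#' library TSV, and the clone-level truth as JSON.
#'
#' @param cohort output of [generateRepertoireSet()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
writeSyntheticCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sheet <- do.call(rbind, lapply(cohort$repertoires, function(r) {
    fn <- paste0(sampleId(r), ".tsv")
    rec <- clonotypes(r)
    utils::write.table(
      data.frame(nucleotide = rec$cdr3_nt, aminoAcid = rec$cdr3_aa,
                 count = rec$read_count,
                 frequencyCount = rec$frequency,
                 vGeneName = rec$v_gene, jGeneName = rec$j_gene,
                 sequenceStatus = ifelse(rec$productive, "In", "Out")),
      file.path(dir, fn), sep = "\t", quote = FALSE, row.names = FALSE)
    data.frame(sample_id = sampleId(r), patient_id = patientId(r),
               tissue = tissueOf(r), path = fn, stringsAsFactors = FALSE)
  }))
  utils::write.table(sheet, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$control_library))
    utils::write.table(cohort$control_library,
                       file.path(dir, "control_library.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth$clones, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}

.PHENO_BY_PATTERN <- list(
  TUMOR = c(T_em = 0.55, T_eff = 0.10, T_scm = 0.10, T_cm = 0.10,
            T_reg = 0.10, Th1 = 0.05),
  ALL  = c(T_eff = 0.60, T_em = 0.15, T_cm = 0.10, Th1 = 0.10, naive = 0.05),
  TN   = c(T_em = 0.35, T_eff = 0.30, T_cm = 0.20, Th1 = 0.15),
  TP   = c(T_eff = 0.45, T_em = 0.25, T_cm = 0.15, Th1 = 0.15),
  PN   = c(T_cm = 0.30, naive = 0.30, Th2 = 0.20, Th17 = 0.20),
  NAT  = c(T_cm = 0.30, naive = 0.25, Th1 = 0.15, Th2 = 0.15, T_reg = 0.15),
  PBMC = c(naive = 0.40, T_cm = 0.25, T_scm = 0.15, Th2 = 0.10, Th17 = 0.10))

.CD8_PHENO <- c("T_eff", "T_em", "T_cm", "T_scm")

#' The synthetic 300-gene universe
#'
#' All default phenotype markers, gene-set members, lineage and CD3 genes,
#' padded with neutral filler genes to 300.
#'
#' @return character vector of 300 gene symbols
#' @export
geneUniverse <- function() {
  core <- unique(c(unlist(defaultMarkerTable()), unlist(defaultGeneSets()),
                   "CD4", "CD8A", "CD8B", "CD3D", "CD3E", "CD3G", "MKI67"))
  c(core, sprintf("GENE%03d", seq_len(300 - length(core))))
}

#' Generate single-cell chain and expression tables with ground truth
#'
#' Cells are sampled per tissue from the bulk clone abundances of one
#' patient; each clone carries one TRA partner (so TRA/TRB pair keys map
#' 1:1 to bulk clones), a lineage and a phenotype drawn from
#' pattern-dependent profiles. Doublets (a second chain pair in the same
#' droplet) are injected at the configured rate, and double-positive
#' lineage at `dp_rate` (concentrated in tumor, emulating its observed
#' enrichment there). Expression counts are Poisson around a log-normal
#' per-gene baseline, with the cell phenotype's markers elevated
#' `phenotype_shift`-fold, exhaustion genes shifted in tumor-restricted
#' clones, and CD4/CD8A/CD8B driven by lineage.
#'
#' @param config a [synthConfig()]
#' @param cohort output of [generateRepertoireSet()] (its truth supplies
#'   the clone table); defaults to generating one
#' @param patient patient id to sample cells for (default first)
#' @return list with `contigs` (long chain table), `counts` (genes x
#'   cells), `cell_truth` (per-cell clone, lineage, phenotype, doublet,
#'   tissue), `clone_truth`
#' @export
generateCells <- function(config = synthConfig(), cohort = NULL,
                          patient = NULL) {
  stopifnot(inherits(config, "tilclone_config"))
  if (is.null(cohort)) cohort <- generateRepertoireSet(config)
  set.seed(config$seed + 1L)
  clones <- cohort$truth$clones
  if (is.null(patient)) patient <- clones$patient_id[1]
  clones <- clones[clones$patient_id == patient, , drop = FALSE]
  genes <- geneUniverse()
  markers <- defaultMarkerTable()
  exh <- defaultGeneSets()$exhaustion
  base <- stats::rlnorm(length(genes), meanlog = -0.5, sdlog = 1)
  names(base) <- genes
  marker_genes <- unique(unlist(markers))
  set_genes <- setdiff(unique(c(exh, unlist(defaultGeneSets()))), marker_genes)
  # classifier markers (GZMB, CCL5, NKG7, ...) are among the
  # highest-expressed genes in T cells; fold-changes on them carry the
  # classification signal
  base[marker_genes] <- 15
  base[set_genes] <- 0.2
  base[c("CD3D", "CD3E", "CD3G")] <- 2
  # clone-level assignments
  n <- nrow(clones)
  pheno <- vapply(clones$pattern, function(p) {
    pr <- .PHENO_BY_PATTERN[[p]]
    sample(names(pr), 1, prob = pr)
  }, "")
  lineage <- ifelse(pheno %in% .CD8_PHENO, "CD8", "CD4")
  tra <- .random_cdr3(n)
  tra <- sub("^CASS", "CAV", tra)  # alpha-chain prefix
  while (anyDuplicated(tra)) {
    d <- duplicated(tra)
    tra[d] <- sub("^CASS", "CAV", .random_cdr3(sum(d)))
  }
  tra_nt <- vapply(tra, .translate_back, "")
  occ_of <- function(p) switch(p, TUMOR = "TUMOR", NAT = "NAT", PBMC = "PBMC",
                               TN = c("TUMOR", "NAT"), TP = c("TUMOR", "PBMC"),
                               PN = c("PBMC", "NAT"),
                               ALL = c("TUMOR", "NAT", "PBMC"))
  cell_rows <- list()
  for (ts in c("TUMOR", "NAT", "PBMC")) {
    occ <- vapply(clones$pattern, function(p) ts %in% occ_of(p), logical(1))
    p_ts <- clones$abundance * occ
    p_ts <- p_ts / sum(p_ts)
    idx <- sample.int(n, config$sc_cells, replace = TRUE, prob = p_ts)
    cell_rows[[ts]] <- data.frame(tissue = ts, clone = idx,
                                  stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, cell_rows)
  ncell <- nrow(cells)
  cells$cell_id <- sprintf("%s_%s_C%05d", patient, cells$tissue, seq_len(ncell))
  cells$doublet <- stats::runif(ncell) < config$doublet_rate
  # DP cells concentrated in tumor (~5:1 tumor : other)
  w_dp <- ifelse(cells$tissue == "TUMOR", 5, 1)
  n_dp <- round(config$dp_rate * ncell)
  dp_idx <- sample.int(ncell, n_dp, prob = w_dp)
  cells$lineage <- lineage[cells$clone]
  cells$lineage[dp_idx] <- "DP"
  cells$phenotype <- pheno[cells$clone]
  cells$pattern <- clones$pattern[cells$clone]
  # chain table: one TRA + one TRB per cell; doublets gain a second pair
  mk_contigs <- function(ci) {
    cl <- cells$clone[ci]
    nt_b <- ifelse(clones$convergent[cl] & stats::runif(length(cl)) < 0.4,
                   clones$cdr3_nt2[cl], clones$cdr3_nt[cl])
    rbind(data.frame(cell_id = cells$cell_id[ci], chain = "TRA",
                     cdr3 = tra[cl], cdr3_nt = tra_nt[cl],
                     tissue = cells$tissue[ci], stringsAsFactors = FALSE),
          data.frame(cell_id = cells$cell_id[ci], chain = "TRB",
                     cdr3 = clones$cdr3_aa[cl], cdr3_nt = nt_b,
                     tissue = cells$tissue[ci], stringsAsFactors = FALSE))
  }
  contigs <- mk_contigs(seq_len(ncell))
  if (any(cells$doublet)) {
    dbl <- which(cells$doublet)
    extra <- mk_contigs(dbl)
    other <- sample.int(n, length(dbl), replace = TRUE)
    extra$cdr3 <- c(tra[other], clones$cdr3_aa[other])
    extra$cdr3_nt <- c(tra_nt[other], clones$cdr3_nt[other])
    contigs <- rbind(contigs, extra)
  }
  contigs <- contigs[order(contigs$cell_id, contigs$chain, contigs$cdr3), ]
  rownames(contigs) <- NULL
  # expression
  lam <- matrix(base, nrow = length(genes), ncol = ncell,
                dimnames = list(genes, cells$cell_id))
  for (ph in unique(cells$phenotype)) {
    g <- intersect(markers[[ph]], genes)
    sel <- cells$phenotype == ph
    lam[g, sel] <- base[g] * config$phenotype_shift
  }
  tum_restricted <- cells$pattern == "TUMOR"
  lam[exh, tum_restricted] <- lam[exh, tum_restricted] * exp(config$exhaustion_shift)
  # co-receptor transcripts off-lineage are ambient-level only
  lam["CD4", ] <- ifelse(cells$lineage %in% c("CD4", "DP"), 3, 0.001)
  lam["CD8A", ] <- ifelse(cells$lineage %in% c("CD8", "DP"), 3, 0.001)
  lam["CD8B", ] <- ifelse(cells$lineage %in% c("CD8", "DP"), 2, 0.001)
  if (config$expression_noise_sd > 0)
    lam <- lam * matrix(stats::rlnorm(length(lam), 0,
                                      config$expression_noise_sd),
                        nrow = nrow(lam))
  counts <- matrix(stats::rpois(length(lam), lam), nrow = nrow(lam),
                   dimnames = dimnames(lam))
  cells$pair_key_true <- paste(tra[cells$clone], clones$cdr3_aa[cells$clone],
                               sep = ":")
  list(contigs = contigs, counts = counts, cell_truth = cells,
       clone_truth = cbind(clones, tra_cdr3_aa = tra, phenotype = pheno,
                           lineage = lineage))
}

#' Generate a synthetic mIHC cell table with ground truth
#'
#' Marker-class point patterns are homogeneous Poisson on each side of a
#' tumor border (straight vertical line at x = 0, or a sinusoid around
#' it), with class-specific inside/outside intensities over a rectangular
#' tissue window; tumor is the x < border side. Ki67 positivity is
#' Bernoulli per cell.
#'
#' @param config a [synthConfig()]
#' @return list with `cells` (x, y, CD3, CD4, CD8, Ki67, CAIX), `border`
#'   (vertex data.frame, tumor on the left), `mask` (window vector),
#'   `truth` (intensities, ki67_prob)
#' @export
generateSpatial <- function(config = synthConfig()) {
  stopifnot(inherits(config, "tilclone_config"))
  set.seed(config$seed + 2L)
  w <- config$spatial_window
  border <- if (config$border_shape == "straight") {
    data.frame(x = c(0, 0), y = c(w[3], w[4]))
  } else {
    yy <- seq(w[3], w[4], length.out = 101)
    data.frame(x = 100 * sin(2 * pi * yy / (w[4] - w[3])), y = yy)
  }
  # areas (mm^2) of the two sides, by grid for generality
  pitch <- 5
  gx <- seq(w[1] + pitch / 2, w[2], by = pitch)
  gy <- seq(w[3] + pitch / 2, w[4], by = pitch)
  grid <- expand.grid(x = gx, y = gy)
  gd <- signedDistance(grid, border, "left")
  a_in <- sum(gd < 0) * pitch^2 * 1e-6
  a_out <- sum(gd >= 0) * pitch^2 * 1e-6
  pts <- list()
  for (cls in names(config$spatial_intensity)) {
    ii <- config$spatial_intensity[[cls]]
    for (side in c("inside", "outside")) {
      lam <- ii[[side]] * if (side == "inside") a_in else a_out
      npt <- stats::rpois(1, lam)
      got <- 0; acc <- list()
      while (got < npt) {   # rejection sample uniform points on the side
        cand <- data.frame(x = stats::runif(2 * npt, w[1], w[2]),
                           y = stats::runif(2 * npt, w[3], w[4]))
        d <- signedDistance(cand, border, "left")
        keep <- if (side == "inside") d < 0 else d >= 0
        cand <- cand[keep, , drop = FALSE]
        take <- utils::head(cand, npt - got)
        acc[[length(acc) + 1]] <- take
        got <- got + nrow(take)
      }
      if (npt > 0) {
        p <- do.call(rbind, acc)
        p$class <- cls
        pts[[paste(cls, side)]] <- p
      }
    }
  }
  cells <- do.call(rbind, pts)
  rownames(cells) <- NULL
  cells$CD3 <- TRUE
  cells$CD4 <- cells$class == "CD4"
  cells$CD8 <- cells$class == "CD8"
  cells$Ki67 <- stats::runif(nrow(cells)) < config$ki67_prob
  d <- signedDistance(cells, border, "left")
  cells$CAIX <- d < 0   # tumor-side cells sit in CAIX+ tissue
  cells$class <- NULL
  list(cells = cells, border = border, mask = w,
       truth = list(intensity = config$spatial_intensity,
                    ki67_prob = config$ki67_prob,
                    area_inside_mm2 = a_in, area_outside_mm2 = a_out))
}
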