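test_that("the seven tissue patterns partition all nonempty subsets", {
  expect_equal(classifyTissuePattern("TUMOR"), "TUMOR")
  expect_equal(classifyTissuePattern("NAT"), "NAT")
  expect_equal(classifyTissuePattern("PBMC"), "PBMC")
  expect_equal(classifyTissuePattern(c("TUMOR", "NAT")), "TN")
  expect_equal(classifyTissuePattern(c("TUMOR", "PBMC")), "TP")
  expect_equal(classifyTissuePattern(c("PBMC", "NAT")), "PN")
  expect_equal(classifyTissuePattern(c("TUMOR", "NAT", "PBMC")), "ALL")
  # order of occurrence does not matter
  expect_equal(classifyTissuePattern(c("PBMC", "TUMOR")), "TP")
  # each of the 7 nonempty subsets maps to a distinct label
  subsets <- unlist(lapply(1:3, function(k)
    combn(c("TUMOR", "NAT", "PBMC"), k, simplify = FALSE)), recursive = FALSE)
  labs <- vapply(subsets, classifyTissuePattern, character(1))
  expect_equal(sort(labs),
               sort(c("TUMOR", "NAT", "PBMC", "TN", "TP", "PN", "ALL")))
  expect_error(classifyTissuePattern("SPLEEN"), "unknown tissue")
  expect_error(classifyTissuePattern(character()), "empty")
})

test_that("expansion calls use a strict 1% threshold", {
  expect_true(flagExpanded(0.046))
  expect_true(flagExpanded(0.24))
  expect_false(flagExpanded(0.01))
  expect_true(flagExpanded(0.010000001))
  expect_equal(flagExpanded(c(0.005, 0.02), threshold = 0.01),
               c(FALSE, TRUE))
})

test_that("clonotype tracking assigns patterns and expansion flags", {
  mk <- function(tissue, counts) filterProductive(
    rep_from_counts(counts, sample_id = paste0("S_", tissue),
                    patient_id = "P1", tissue = tissue))
  reps <- list(
    mk("TUMOR", c(CASSDOM = 30, CASSTN = 20, CASSALL = 50, CASSBIG = 900)),
    mk("NAT",   c(CASSTN = 10, CASSALL = 10, CASSPN = 80)),
    mk("PBMC",  c(CASSALL = 5, CASSPN = 5, CASSP = 90)))
  tr <- trackClonotypes(reps)
  row <- function(k) tr[tr$key == k, ]
  expect_equal(row("CASSDOM")$pattern, "TUMOR")
  expect_true(row("CASSDOM")$expanded_in_tumor)  # 30/1000 = 3%
  expect_equal(row("CASSTN")$pattern, "TN")
  expect_equal(row("CASSALL")$pattern, "ALL")
  expect_equal(row("CASSPN")$pattern, "PN")
  expect_false(row("CASSPN")$expanded_in_tumor)
  expect_equal(row("CASSP")$pattern, "PBMC")
  # pattern counts partition the key set exactly
  pc <- patternCounts(tr)
  expect_equal(sum(pc$n), nrow(tr))
  # invariance to sample ordering
  tr2 <- trackClonotypes(rev(reps))
  expect_equal(tr2[order(tr2$key), ], tr[order(tr$key), ])
  # duplicate tissue is an ambiguity error
  expect_error(trackClonotypes(c(reps, reps[1])), "merge")
})

test_that("down-sampling reads never adds shared patterns", {
  cfg <- synthConfig(seed = 31, n_patients = 1, clones_per_patient = 300,
                     depths = c(TUMOR = 20000, NAT = 20000, PBMC = 20000))
  co <- generateRepertoireSet(cfg)
  reps <- lapply(co$repertoires, filterProductive)
  tr_full <- trackClonotypes(reps)
  # subsample each repertoire to 10% of reads
  set.seed(99)
  reps_sub <- lapply(reps, function(r) {
    rec <- clonotypes(r)
    reads <- rep(seq_len(nrow(rec)), rec$read_count)
    keep <- table(sample(reads, round(length(reads) * 0.1)))
    idx <- as.integer(names(keep))
    rec2 <- rec[idx, ]
    rec2$read_count <- as.integer(keep)
    Repertoire(rec2, sample_id = sampleId(r), patient_id = patientId(r),
               tissue = tissueOf(r))
  })
  tr_sub <- trackClonotypes(reps_sub)
  occ <- function(tr) {
    m <- as.matrix(tr[, grep("^count_", names(tr))]) > 0
    rownames(m) <- tr$key
    m
  }
  of <- occ(tr_full); os <- occ(tr_sub)
  common <- intersect(rownames(of), rownames(os))
  # every tissue detection after down-sampling was present at full depth
  expect_true(all(of[common, ] >= os[common, ]))
})

test_that("alluvial tables enumerate top clonotypes with explicit zeros", {
  mk <- function(tissue, counts) filterProductive(
    rep_from_counts(counts, sample_id = tissue, patient_id = "P1",
                    tissue = tissue))
  set.seed(7)
  counts <- setNames(sample(1:50, 50), sprintf("CASS%03d", 1:50))
  reps <- list(mk("TUMOR", counts[1:30]), mk("NAT", counts[11:40]),
               mk("PBMC", counts[21:50]))
  tr <- trackClonotypes(reps)
  tab <- alluvialTable(tr, n = 120)
  # 50 unique clonotypes x 3 tissues
  expect_equal(nrow(tab), 150)
  expect_true(all(tab$frequency[tab$key == "CASS001" &
                                  tab$tissue != "TUMOR"] == 0))
  # n = 1: union of the three per-tissue top clones
  t1 <- alluvialTable(tr, n = 1)
  expect_lte(length(unique(t1$key)), 3)
  expect_equal(nrow(t1), length(unique(t1$key)) * 3)

  # tumor-restricted planted clones show zero rivulets outside tumor
  reps2 <- list(mk("TUMOR", c(CASSLRGTNYGYTF = 35, CASGLTGSVEQFF = 15,
                              CASSWGAEAFF = 10, CASSOTHER = 40)),
                mk("NAT", c(CASSOTHER = 10, CASSN = 90)),
                mk("PBMC", c(CASSOTHER = 10, CASSB = 90)))
  tab2 <- alluvialTable(trackClonotypes(reps2), n = 120)
  for (k in c("CASSLRGTNYGYTF", "CASGLTGSVEQFF", "CASSWGAEAFF")) {
    expect_equal(tab2$frequency[tab2$key == k & tab2$tissue == "NAT"], 0)
    expect_equal(tab2$frequency[tab2$key == k & tab2$tissue == "PBMC"], 0)
  }
})

test_that("longitudinal persistence flags clones seen at every timepoint", {
  mk <- function(tp, counts) filterProductive(
    rep_from_counts(counts, sample_id = paste0("S", tp), patient_id = "P7",
                    tissue = "PBMC", timepoint = tp))
  reps <- list(mk("surgery", c(CASSKEEP = 30, CASSDROP = 20, CASSREST = 950)),
               mk("year1", c(CASSKEEP = 38, CASSREST = 962)))
  out <- longitudinalPersistence(reps)
  keep <- out[out$key == "CASSKEEP", ]
  expect_true(keep$persistent)
  expect_equal(keep$max_frequency, 0.038)
  expect_false(out[out$key == "CASSDROP", ]$persistent)
  expect_warning(longitudinalPersistence(reps[1]), "timepoints")
})

test_that("planted stable clone frequencies are recovered at depth 1e5", {
  set.seed(11)
  probs <- c(0.03, 0.01, rep(0.96 / 200, 200))
  aa <- c("CASSKEEP", "CASSMID", sprintf("CASS%03d", 1:200))
  mk <- function(tp) {
    counts <- as.integer(rmultinom(1, 1e5, probs))
    keep <- counts > 0
    filterProductive(rep_from_counts(setNames(counts[keep], aa[keep]),
                                     patient_id = "P", tissue = "PBMC",
                                     timepoint = tp))
  }
  out <- longitudinalPersistence(list(mk("t0"), mk("t1")))
  k <- out[out$key == "CASSKEEP", ]
  # multinomial sampling error at n = 1e5, p = 0.03 is ~0.0005
  expect_equal(k$freq_t0, 0.03, tolerance = 0.1)
  expect_equal(k$freq_t1, 0.03, tolerance = 0.1)
  expect_true(k$persistent)
})
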