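test_that("database matching is exact on CDR3 with summed frequencies", {
  db <- data.frame(cdr3_aa = c("CASSPGQGGGYTF", "CASSIRSSYEQYF"),
                   antigen = c("M. tuberculosis", "EBV"))
  rep <- filterProductive(rep_from_counts(
    c(CASSPGQGGGYTF = 10, CASSPRIVATE = 80, CASSOTHER = 10)))
  out <- matchDatabase(rep, db)
  expect_equal(nrow(out$hits), 1)
  expect_equal(out$hits$antigen, "M. tuberculosis")
  expect_equal(out$summary$annotated_unique_fraction, 1 / 3)
  expect_equal(out$summary$annotated_frequency, 0.1)

  # empty database: no hits, zero annotated fraction
  empty <- data.frame(cdr3_aa = character(), antigen = character())
  out0 <- matchDatabase(rep, empty)
  expect_equal(nrow(out0$hits), 0)
  expect_equal(out0$summary$annotated_unique_fraction, 0)
  expect_error(matchDatabase(rep, data.frame(x = 1)), "format error")
  # annotated + unannotated fractions always total 1
  expect_equal(out$summary$annotated_unique_fraction +
                 (1 - out$summary$annotated_unique_fraction), 1)
})

test_that("annotated fraction reproduces planted cohort arithmetic", {
  # 194 planted database-matching clonotypes among 389,813 uniques
  n_total <- 389813
  n_hit <- 194
  uniq <- data.frame(cdr3_aa = sprintf("CASS%06d", seq_len(n_total)))
  db <- data.frame(cdr3_aa = sprintf("CASS%06d", seq_len(n_hit)),
                   antigen = "planted")
  out <- matchDatabase(uniq, db)
  expect_equal(out$summary$annotated_unique, n_hit)
  expect_equal(out$summary$annotated_unique_fraction, 194 / 389813)
  expect_equal(round(100 * out$summary$annotated_unique_fraction, 2), 0.05)
})

test_that("control-library screening computes prevalence per donor", {
  lib <- data.frame(
    donor_id = sprintf("D%02d", c(1:33, 1:55)),
    cdr3_aa = c(rep("CASSSHARED", 33), rep("CASSCOMMON", 55)))
  out <- screenControlLibrary(c("CASSSHARED", "CASSCOMMON", "CASSMINE"), lib)
  expect_equal(out$prevalence[out$cdr3_aa == "CASSSHARED"], 0.6)  # 33/55
  expect_equal(out$prevalence[out$cdr3_aa == "CASSCOMMON"], 1)
  expect_true(out$patient_unique[out$cdr3_aa == "CASSMINE"])
  expect_false(any(out$patient_unique[out$cdr3_aa != "CASSMINE"]))
  # prevalence is monotone non-decreasing as donors are added
  lib2 <- rbind(lib, data.frame(donor_id = "D34", cdr3_aa = "CASSSHARED"))
  out2 <- screenControlLibrary(c("CASSSHARED", "CASSCOMMON", "CASSMINE"), lib2)
  expect_true(all(out2$donors_carrying >= out$donors_carrying))
})

test_that("planted patient-unique fraction is recovered by exact matching", {
  cfg <- synthConfig(seed = 17, n_patients = 4, clones_per_patient = 800,
                     depths = c(TUMOR = 30000, NAT = 30000, PBMC = 30000))
  co <- generateRepertoireSet(cfg)
  truth <- co$truth$clones
  tum <- co$repertoires[grep("TUMOR", names(co$repertoires))]
  keys <- unique(unlist(lapply(tum, function(r) {
    rec <- clonotypes(filterProductive(r))
    rec$cdr3_aa
  })))
  scr <- screenControlLibrary(keys, co$control_library)
  planted <- mean(truth$prevalence[match(keys, truth$cdr3_aa)] == 0)
  expect_equal(mean(scr$patient_unique), planted, tolerance = 0.01)
})

test_that("public-clonotype detection applies both thresholds", {
  coh <- data.frame(
    patient_id = c(sprintf("P%02d", 1:10), sprintf("P%02d", 1:2),
                   sprintf("P%02d", 1:10)),
    key = c(rep("CASSPUBLIC", 10), rep("CASSRARE", 2), rep("CASSFEW", 10)),
    cell_count = c(c(12, rep(2, 9)), c(30, 30), rep(3, 10)))
  out <- findPublicClonotypes(coh)
  expect_equal(out$key, "CASSPUBLIC")        # 10 patients, 12-cell tumor
  expect_equal(out$patients_detected, 10L)
  expect_equal(out$max_cells_per_tumor, 12L) # CASSRARE: 2 patients only;
                                             # CASSFEW: fails 11-cell bound
  expect_error(findPublicClonotypes(coh[coh$patient_id == "P01", ]),
               "two patients")
})

test_that("public-clone detection matches a brute-force scan", {
  set.seed(23)
  coh <- data.frame(
    patient_id = sample(sprintf("P%02d", 1:14), 3000, replace = TRUE),
    key = sample(sprintf("CASS%03d", 1:150), 3000, replace = TRUE),
    cell_count = rpois(3000, 4) + 1L)
  coh <- coh[!duplicated(coh[, 1:2]), ]
  got <- findPublicClonotypes(coh, min_patients = 10, min_cells = 11)
  # brute force over every key
  brute <- character()
  for (k in unique(coh$key)) {
    sub <- coh[coh$key == k, ]
    if (length(unique(sub$patient_id)) >= 10 && max(sub$cell_count) >= 11)
      brute <- c(brute, k)
  }
  expect_setequal(got$key, brute)
  # invariant to row order
  got2 <- findPublicClonotypes(coh[sample(nrow(coh)), ],
                               min_patients = 10, min_cells = 11)
  expect_equal(got, got2)
})

test_that("convergent nucleotypes need two supported nucleotide variants", {
  rec <- data.frame(
    cdr3_aa = c("CASSLVSGELFF", "CASSLVSGELFF", "CASSSINGLE",
                "CASSWEAK", "CASSWEAK"),
    cdr3_nt = c("AATGCA", "AATGCC", "TTTAAA", "CCCGGG", "CCCGGA"),
    cell_count = c(3L, 2L, 7L, 5L, 1L))
  out <- detectConvergence(rec)
  conv <- out[out$cdr3_aa == "CASSLVSGELFF", ]
  expect_true(conv$convergent)
  expect_equal(conv$n_nucleotypes, 2)
  expect_false(out[out$cdr3_aa == "CASSSINGLE", ]$convergent)
  # two nucleotypes but one supported by a single cell: not convergent
  expect_false(out[out$cdr3_aa == "CASSWEAK", ]$convergent)
  # ambiguous nucleotides are excluded with a warning
  rec$cdr3_nt[3] <- "TTTNAA"
  expect_warning(out2 <- detectConvergence(rec), "excluded")
  expect_false("CASSSINGLE" %in% out2$cdr3_aa)
})

test_that("case/control frequency contrast recovers planted enrichment", {
  mkrep <- function(freqs, id) {
    counts <- round(freqs * 1e5)
    filterProductive(rep_from_counts(counts, sample_id = id))
  }
  cases <- list(mkrep(c(CASSPUB = 0.01, CASSREST = 0.99), "case1"))
  ctrls <- list(mkrep(c(CASSPUB = 1e-5, CASSREST = 0.99999), "ctrl1"))
  out <- caseControlFrequencyContrast("CASSPUB", cases, ctrls)
  expect_equal(out$ratio, 1000, tolerance = 0.01)
  expect_equal(out$log10_ratio, 3, tolerance = 0.01)
  # equal means give ratio 1
  out2 <- caseControlFrequencyContrast("CASSPUB", cases, cases)
  expect_equal(out2$ratio, 1)
  # absent from controls: infinite, flagged
  ctrl0 <- list(mkrep(c(CASSOTHER = 1), "ctrl0"))
  out3 <- caseControlFrequencyContrast("CASSPUB", cases, ctrl0)
  expect_true(is.infinite(out3$ratio))
})

test_that("planted 100x enrichment is recovered within 10% at depth 1e5", {
  set.seed(71)
  ratios <- replicate(20, {
    p_case <- 1e-2; p_ctrl <- 1e-4
    draw <- function(p, id) {
      n <- max(1L, rbinom(1, 1e5, p))
      filterProductive(rep_from_counts(
        setNames(c(n, 1e5 - n), c("CASSPUB", "CASSREST")), sample_id = id))
    }
    cases <- lapply(1:4, function(i) draw(p_case, paste0("ca", i)))
    ctrls <- lapply(1:4, function(i) draw(p_ctrl, paste0("co", i)))
    caseControlFrequencyContrast("CASSPUB", cases, ctrls)$ratio
  })
  expect_equal(mean(ratios), 100, tolerance = 0.1)
})
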