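#' Read a VDJdb-style annotation table
#'
#' Accepts either the VDJdb export header (`cdr3`, `v`, `j`,
#' `antigen.epitope`, `antigen.species`) or a generic table with `cdr3_aa`
#' and `antigen` columns.
#'
#' @param path TSV path
#' @return data.frame with columns `cdr3_aa`, `v_gene`, `j_gene`,
#'   `antigen`, `species`
#' @export
readAnnotationDb <- function(path) {
  db <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  nm <- names(db)
  cdr3 <- if ("cdr3_aa" %in% nm) db$cdr3_aa else db[["cdr3"]]
  antigen <- if ("antigen" %in% nm) db$antigen else db[["antigen.epitope"]]
  if (is.null(cdr3) || is.null(antigen))
    stop("format error: annotation db needs cdr3/cdr3_aa and antigen columns")
  data.frame(cdr3_aa = toupper(trimws(cdr3)),
             v_gene = if ("v" %in% nm) db$v else db[["v_gene"]] %||% NA,
             j_gene = if ("j" %in% nm) db$j else db[["j_gene"]] %||% NA,
             antigen = antigen,
             species = db[["antigen.species"]] %||% db[["species"]] %||% NA,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Match clonotypes against a specificity database
#'
#' Exact-match annotation of CDR3 amino-acid sequences against a database
#' of TRB sequences with known antigen associations. Optionally the V gene
#' must also agree (`require_v`). Reports both the hits and the annotated
#' share of the sample: the fraction of unique clonotypes with a hit and
#' their summed clonal frequency.
#'
#' @param x a [Repertoire-class] or a data.frame with `cdr3_aa` (and
#'   optionally `frequency`, `v_gene`)
#' @param db annotation table as from [readAnnotationDb()]
#' @param require_v also require V-gene identity (default FALSE)
#' @return list with `hits` (clonotype x db-row matches) and `summary`
#'   (`annotated_unique_fraction`, `annotated_frequency`)
#' @export
matchDatabase <- function(x, db, require_v = FALSE) {
  if (!all(c("cdr3_aa", "antigen") %in% names(db)))
    stop("format error: annotation db needs cdr3_aa and antigen columns")
  rec <- if (methods::is(x, "Repertoire")) {
    r <- clonotypes(x); r[r$productive, , drop = FALSE]
  } else x
  uniq <- rec[!duplicated(rec$cdr3_aa), , drop = FALSE]
  m <- merge(uniq[, intersect(c("cdr3_aa", "v_gene", "frequency"), names(uniq)),
                  drop = FALSE],
             db, by = "cdr3_aa", suffixes = c("", ".db"))
  if (require_v && nrow(m) && "v_gene" %in% names(m) && "v_gene.db" %in% names(m))
    m <- m[!is.na(m$v_gene.db) & m$v_gene == m$v_gene.db, , drop = FALSE]
  hit_aa <- unique(m$cdr3_aa)
  afrac <- length(hit_aa) / max(nrow(uniq), 1L)
  afreq <- if ("frequency" %in% names(rec))
    sum(rec$frequency[rec$cdr3_aa %in% hit_aa]) else NA_real_
  list(hits = m,
       summary = data.frame(unique_clonotypes = nrow(uniq),
                            annotated_unique = length(hit_aa),
                            annotated_unique_fraction = afrac,
                            annotated_frequency = afreq))
}

#' Screen clonotypes against a control-donor sequence library
#'
#' The library maps donor to the set of TRB-CDR3 amino-acid sequences that
#' donor carries. Prevalence of a clonotype is the fraction of donors
#' carrying it; a clonotype absent from every donor is patient-unique.
#'
#' @param cdr3_aa character vector of query sequences
#' @param library data.frame with columns `donor_id`, `cdr3_aa`
#' @return data.frame `cdr3_aa`, `donors_carrying`, `prevalence`,
#'   `patient_unique`
#' @export
screenControlLibrary <- function(cdr3_aa, library) {
  stopifnot(all(c("donor_id", "cdr3_aa") %in% names(library)))
  q <- toupper(trimws(cdr3_aa))
  n_donors <- length(unique(library$donor_id))
  lib <- unique(library[, c("donor_id", "cdr3_aa")])
  carriers <- table(factor(lib$cdr3_aa[lib$cdr3_aa %in% q], levels = unique(q)))
  nc <- as.integer(carriers[match(unique(q), names(carriers))])
  nc[is.na(nc)] <- 0L
  out <- data.frame(cdr3_aa = unique(q), donors_carrying = nc,
                    prevalence = nc / n_donors,
                    stringsAsFactors = FALSE)
  out$patient_unique <- out$prevalence == 0
  out
}

#' Detect public clonotypes across a tumor cohort
#'
#' A clonotype is called public when it is detected in at least
#' `min_patients` patients and reaches at least `min_cells` cells in at
#' least one tumor ("over 10 cells/tumor" read as >= 11, "shared by 10 to
#' 14 tumors" as >= 10 patients).
#'
#' @param cohort data.frame with columns `patient_id`, `key` (TRB-CDR3 aa,
#'   optionally a TRA:TRB pair key), `cell_count` (cells of that clonotype
#'   in that patient's tumor)
#' @param min_patients minimum number of patients sharing the clonotype
#' @param min_cells minimum cells in the best tumor
#' @return data.frame of public clonotypes ranked by `patients_detected`
#'   then `max_cells_per_tumor`
#' @export
findPublicClonotypes <- function(cohort, min_patients = 10, min_cells = 11) {
  stopifnot(all(c("patient_id", "key", "cell_count") %in% names(cohort)))
  if (length(unique(cohort$patient_id)) < 2)
    stop("cohort must pool at least two patients")
  pd <- tapply(cohort$patient_id, cohort$key, function(z) length(unique(z)))
  mc <- tapply(cohort$cell_count, cohort$key, max)
  keys <- names(pd)
  out <- data.frame(key = keys,
                    patients_detected = as.integer(pd),
                    max_cells_per_tumor = as.integer(mc[keys]),
                    stringsAsFactors = FALSE)
  out <- out[out$patients_detected >= min_patients &
               out$max_cells_per_tumor >= min_cells, , drop = FALSE]
  out <- out[order(-out$patients_detected, -out$max_cells_per_tumor, out$key), ]
  rownames(out) <- NULL
  out
}

#' Group nucleotypes and detect convergent recombination
#'
#' A nucleotype is a distinct nucleotide sequence encoding a given CDR3
#' amino-acid sequence. A clonotype is convergent when at least two
#' distinct nucleotypes are each supported by at least `min_support`
#' cells or reads. Records whose nucleotide sequence contains ambiguous
#' bases (N) are excluded with a warning.
#'
#' @param records data.frame with `cdr3_aa`, `cdr3_nt` and a support column
#'   (`cell_count` or `read_count`; the first found is used)
#' @param min_support minimum cells/reads per nucleotype (default 2)
#' @return data.frame per clonotype: `cdr3_aa`, `n_nucleotypes`,
#'   `n_supported_nucleotypes`, `total_support`, `convergent`
#' @export
detectConvergence <- function(records, min_support = 2) {
  sup_col <- intersect(c("cell_count", "read_count", "support"), names(records))[1]
  if (is.na(sup_col)) stop("no support column (cell_count/read_count) found")
  if (!all(c("cdr3_aa", "cdr3_nt") %in% names(records)))
    stop("records need cdr3_aa and cdr3_nt columns")
  ok <- !is.na(records$cdr3_nt) & !grepl("N", records$cdr3_nt, fixed = TRUE)
  if (any(!ok))
    warning(sum(!ok), " record(s) lacking an unambiguous nucleotide sequence excluded")
  rec <- records[ok, , drop = FALSE]
  sup <- tapply(rec[[sup_col]], list(rec$cdr3_aa, rec$cdr3_nt), sum)
  out <- do.call(rbind, lapply(rownames(sup), function(aa) {
    s <- sup[aa, ]
    s <- s[!is.na(s)]
    data.frame(cdr3_aa = aa,
               n_nucleotypes = length(s),
               n_supported_nucleotypes = sum(s >= min_support),
               total_support = sum(s),
               convergent = sum(s >= min_support) >= 2,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Case vs control clonal-frequency contrast
#'
#' For each clonotype, the ratio of its mean clonal frequency among the
#' case repertoires that carry it to the mean among carrier control
#' repertoires. Clonotypes with no control carriers get an infinite ratio
#' and are excluded from summary means.
#'
#' @param keys CDR3 amino-acid sequences to contrast
#' @param case_reps,control_reps lists of [Repertoire-class]
#' @return data.frame `key`, `mean_frequency_cases`,
#'   `mean_frequency_controls`, `ratio`, `log10_ratio`
#' @export
caseControlFrequencyContrast <- function(keys, case_reps, control_reps) {
  carrier_mean <- function(reps, k) {
    fr <- vapply(reps, function(r) {
      rec <- clonotypes(r)
      sum(rec$frequency[rec$productive & rec$cdr3_aa == k])
    }, numeric(1))
    fr <- fr[fr > 0]
    if (!length(fr)) NA_real_ else mean(fr)
  }
  out <- do.call(rbind, lapply(keys, function(k) {
    mc <- carrier_mean(case_reps, k)
    mn <- carrier_mean(control_reps, k)
    if (is.na(mc)) stop("clonotype ", k, " not detected in any case repertoire")
    ratio <- if (is.na(mn)) Inf else mc / mn
    data.frame(key = k, mean_frequency_cases = mc,
               mean_frequency_controls = mn,
               ratio = ratio, log10_ratio = log10(ratio),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
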