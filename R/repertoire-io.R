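#' Read a bulk TRB-CDR3 repertoire file
#'
#' Reads a tab-separated rearrangement export and returns a [Repertoire-class].
#' Two dialects are auto-detected from the header:
#' \describe{
#'   \item{ImmunoSEQ-export style}{columns `nucleotide`, `aminoAcid`,
#'     `count` (or `count (templates/reads)`), optional `vGeneName`,
#'     `jGeneName`, `frequencyCount`, `sequenceStatus` (`"In"` = productive).}
#'   \item{AIRR Rearrangement}{columns `junction`, `junction_aa`,
#'     `duplicate_count`, optional `v_call`, `j_call`, `productive`.}
#' }
#' The package's own canonical dialect (`cdr3_nt`, `cdr3_aa`, `read_count`,
#' ...) is also accepted. Rows are aggregated by nucleotide sequence and
#' productive frequencies recomputed; the parse is summarized in a
#' `"parse_report"` attribute.
#'
#' @param path file path to a TSV.
#' @param sample_id,patient_id,tissue,timepoint sample metadata (see
#'   [readSampleSheet()] for batch loading).
#' @return a [Repertoire-class]; attribute `parse_report` holds row counts.
#' @export
readRepertoire <- function(path, sample_id = basename(path), patient_id = NA,
                           tissue = NA, timepoint = NA) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  nm <- names(raw)
  pick <- function(...) {
    for (cand in c(...)) if (cand %in% nm) return(raw[[cand]])
    NULL
  }
  nt <- pick("cdr3_nt", "junction", "nucleotide")
  aa <- pick("cdr3_aa", "junction_aa", "aminoAcid")
  count <- pick("read_count", "duplicate_count", "count (templates/reads)",
                "count (reads)", "count")
  if (is.null(nt)) stop("format error: no nucleotide-sequence column ",
                        "(expected one of cdr3_nt / junction / nucleotide)")
  if (is.null(aa)) stop("format error: no amino-acid-sequence column ",
                        "(expected one of cdr3_aa / junction_aa / aminoAcid)")
  if (is.null(count)) stop("format error: no count column ",
                           "(expected one of read_count / duplicate_count / count)")
  v <- pick("v_gene", "v_call", "vGeneName")
  j <- pick("j_gene", "j_call", "jGeneName")
  freq <- pick("frequency", "frequencyCount", "duplicate_frequency")
  prod <- pick("productive")
  status <- pick("sequenceStatus")
  if (is.null(prod) && !is.null(status)) prod <- toupper(status) == "IN"
  if (!is.null(prod) && !is.logical(prod))
    prod <- toupper(as.character(prod)) %in% c("T", "TRUE", "1", "YES")
  rec <- data.frame(cdr3_nt = nt, cdr3_aa = aa, read_count = count,
                    stringsAsFactors = FALSE)
  if (!is.null(v)) rec$v_gene <- v
  if (!is.null(j)) rec$j_gene <- j
  if (!is.null(freq)) rec$frequency <- as.numeric(freq)
  if (!is.null(prod)) rec$productive <- prod
  rep <- Repertoire(rec, sample_id = sample_id, patient_id = patient_id,
                    tissue = tissue, timepoint = timepoint)
  if (!any(clonotypes(rep)$productive))
    stop("empty repertoire: no productive records in ", path)
  attr(rep, "parse_report") <- list(
    path = path, rows_read = nrow(raw),
    records = length(rep),
    productive = sum(clonotypes(rep)$productive),
    nonproductive = sum(!clonotypes(rep)$productive))
  rep
}

#' Write a repertoire in the canonical dialect
#'
#' Columns: cdr3_nt, cdr3_aa, v_gene, j_gene, read_count, frequency,
#' productive. Reading the file back yields an identical object, and
#' re-writing it an identical file.
#'
#' @param x a [Repertoire-class]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
writeRepertoire <- function(x, path) {
  rec <- clonotypes(x)[, .REP_COLS]
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet and load its repertoires
#'
#' The sample sheet is a TSV with columns `sample_id`, `patient_id`,
#' `tissue`, `path` and optionally `timepoint`. Relative paths are resolved
#' against the sheet's directory. Duplicate (patient, tissue, timepoint)
#' combinations are an error.
#'
#' @param sheet_path path to the sample-sheet TSV
#' @return named list of [Repertoire-class] objects (names = sample_id)
#' @export
readSampleSheet <- function(sheet_path) {
  sheet <- utils::read.delim(sheet_path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "tissue", "path")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(sheet$timepoint)) sheet$timepoint <- NA
  key <- paste(sheet$patient_id, sheet$tissue, sheet$timepoint)
  if (anyDuplicated(key))
    stop("duplicate (patient_id, tissue, timepoint) in sample sheet: ",
         key[duplicated(key)][1])
  base <- dirname(sheet_path)
  reps <- lapply(seq_len(nrow(sheet)), function(i) {
    p <- sheet$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    readRepertoire(p, sample_id = sheet$sample_id[i],
                   patient_id = sheet$patient_id[i],
                   tissue = sheet$tissue[i], timepoint = sheet$timepoint[i])
  })
  names(reps) <- sheet$sample_id
  reps
}
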