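#' Repertoire: a bulk TRB-CDR3 repertoire for one sample
#'
#' Container for the unique productive (and, before filtering, flagged
#' non-productive) TRB rearrangements observed in one biospecimen, together
#' with its sample metadata. Records are aggregated by CDR3 nucleotide
#' sequence; frequencies are always recomputed so that productive
#' frequencies sum to 1 (file-supplied frequencies, when present, are kept
#' in `file_frequency` for QC only).
#'
#' @slot records data.frame with columns `cdr3_nt`, `cdr3_aa`, `v_gene`,
#'   `j_gene`, `read_count`, `frequency`, `productive` (and optionally
#'   `file_frequency`). One row per unique `cdr3_nt`.
#' @slot sampleId,patientId,tissue,timepoint sample metadata. `tissue` is
#'   conventionally one of `"TUMOR"`, `"NAT"`, `"PBMC"` but the class does
#'   not restrict the vocabulary.
#' @slot totalProductiveReads total read count over productive records.
#'
#' @seealso [readRepertoire()], [filterProductive()], [repertoireDiversity()]
#' @export
setClass("Repertoire",
  representation(
    records = "data.frame",
    sampleId = "character",
    patientId = "character",
    tissue = "character",
    timepoint = "character",
    totalProductiveReads = "numeric"
  ),
  prototype(
    records = data.frame(),
    sampleId = NA_character_, patientId = NA_character_,
    tissue = NA_character_, timepoint = NA_character_,
    totalProductiveReads = 0
  )
)

.REP_COLS <- c("cdr3_nt", "cdr3_aa", "v_gene", "j_gene",
               "read_count", "frequency", "productive")

setValidity("Repertoire", function(object) {
  rec <- object@records
  msg <- character()
  miss <- setdiff(.REP_COLS, names(rec))
  if (length(miss))
    msg <- c(msg, paste("records missing column(s):", paste(miss, collapse = ", ")))
  if (!length(msg) && nrow(rec)) {
    if (any(rec$read_count < 1 | rec$read_count != round(rec$read_count)))
      msg <- c(msg, "read_count must be a positive integer")
    if (anyDuplicated(rec$cdr3_nt))
      msg <- c(msg, "duplicate cdr3_nt after aggregation")
    p <- rec$frequency[rec$productive]
    if (length(p) && abs(sum(p) - 1) > 1e-9)
      msg <- c(msg, "productive frequencies must sum to 1 (tolerance 1e-9)")
    aa <- rec$cdr3_aa[rec$productive]
    if (length(aa) && any(grepl("[*_]", aa)))
      msg <- c(msg, "productive cdr3_aa contains stop/frameshift characters ('*'/'_')")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn Repertoire number of unique clonotype records (all rows)
#' @param x,object a `Repertoire`
#' @export
setMethod("length", "Repertoire", function(x) nrow(x@records))

setMethod("show", "Repertoire", function(object) {
  rec <- object@records
  cat("Repertoire:", object@sampleId,
      sprintf("(patient %s, %s%s)\n", object@patientId, object@tissue,
              if (is.na(object@timepoint)) "" else paste0(", ", object@timepoint)))
  cat(sprintf("  %d unique rearrangements (%d productive), %d productive reads\n",
              nrow(rec), sum(rec$productive), as.integer(object@totalProductiveReads)))
  if (nrow(rec)) {
    top <- utils::head(rec[order(-ifelse(is.na(rec$frequency), 0, rec$frequency)), ], 3)
    cat("  top clonotypes:",
        paste(sprintf("%s (%.3g)", top$cdr3_aa, top$frequency), collapse = ", "), "\n")
  }
})

#' Accessors for Repertoire objects
#'
#' @param x a [Repertoire-class] object
#' @return `clonotypes()` the record data.frame; the others the
#'   corresponding metadata scalar.
#' @name repertoire-accessors
NULL

#' @rdname repertoire-accessors
#' @export
clonotypes <- function(x) x@records

#' @rdname repertoire-accessors
#' @export
sampleId <- function(x) x@sampleId

#' @rdname repertoire-accessors
#' @export
patientId <- function(x) x@patientId

#' @rdname repertoire-accessors
#' @export
tissueOf <- function(x) x@tissue

#' @rdname repertoire-accessors
#' @export
timepointOf <- function(x) x@timepoint

#' Construct a Repertoire from a record table
#'
#' Normalizes sequences (uppercase, whitespace-stripped), aggregates
#' duplicate `cdr3_nt` rows by summing read counts, and recomputes
#' productive frequencies.
#'
#' @param records data.frame with at least `cdr3_nt`, `cdr3_aa`,
#'   `read_count`; `v_gene`, `j_gene`, `productive` optional (productive
#'   defaults to a frame/stop-codon heuristic on `cdr3_aa`).
#' @param sample_id,patient_id,tissue,timepoint sample metadata.
#' @return a [Repertoire-class]
#' @export
Repertoire <- function(records, sample_id = NA, patient_id = NA,
                       tissue = NA, timepoint = NA) {
  stopifnot(is.data.frame(records))
  need <- c("cdr3_nt", "cdr3_aa", "read_count")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("record table missing mandatory column(s): ", paste(miss, collapse = ", "))
  rec <- records
  rec$cdr3_nt <- toupper(trimws(as.character(rec$cdr3_nt)))
  rec$cdr3_aa <- toupper(trimws(as.character(rec$cdr3_aa)))
  if (is.null(rec$v_gene)) rec$v_gene <- NA_character_
  if (is.null(rec$j_gene)) rec$j_gene <- NA_character_
  if (is.null(rec$productive))
    rec$productive <- !grepl("[*_]", rec$cdr3_aa) & nzchar(rec$cdr3_aa)
  rec$productive <- as.logical(rec$productive)
  rec$read_count <- as.integer(rec$read_count)
  rec <- rec[rec$read_count >= 1, , drop = FALSE]
  has_ff <- "frequency" %in% names(records)
  # aggregate by nucleotide sequence
  if (anyDuplicated(rec$cdr3_nt)) {
    agg <- stats::aggregate(read_count ~ cdr3_nt, data = rec, FUN = sum)
    first <- rec[!duplicated(rec$cdr3_nt), , drop = FALSE]
    first$read_count <- NULL
    rec <- merge(first, agg, by = "cdr3_nt", sort = FALSE)
  }
  if (has_ff) {
    rec$file_frequency <- rec$frequency
  }
  tot <- sum(rec$read_count[rec$productive])
  rec$frequency <- ifelse(rec$productive, rec$read_count / tot, NA_real_)
  rec <- rec[order(-rec$read_count, rec$cdr3_aa, rec$cdr3_nt), , drop = FALSE]
  rownames(rec) <- NULL
  keep <- c(.REP_COLS, intersect("file_frequency", names(rec)))
  methods::new("Repertoire",
      records = rec[, keep, drop = FALSE],
      sampleId = as.character(sample_id), patientId = as.character(patient_id),
      tissue = as.character(tissue), timepoint = as.character(timepoint),
      totalProductiveReads = tot)
}
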