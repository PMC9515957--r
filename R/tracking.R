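.TISSUES <- c("TUMOR", "NAT", "PBMC")

#' Classify a clonotype's tissue-distribution pattern
#'
#' Maps the set of tissues a clonotype is detected in to one of seven
#' labels that partition the nonempty subsets of \{TUMOR, NAT, PBMC\}:
#' the three tissue-specific labels, the pairwise labels TN (tumor-NAT),
#' TP (tumor-PBMC), PN (PBMC-NAT), and ALL.
#'
#' @param occurrences character vector (or list of vectors) of tissues the
#'   clonotype occurs in; values must be among TUMOR, NAT, PBMC.
#' @return the pattern label(s)
#' @export
classifyTissuePattern <- function(occurrences) {
  if (is.list(occurrences))
    return(vapply(occurrences, classifyTissuePattern, character(1)))
  occ <- unique(occurrences)
  bad <- setdiff(occ, .TISSUES)
  if (length(bad))
    stop("unknown tissue label(s): ", paste(bad, collapse = ", "))
  if (!length(occ)) stop("occurrence set is empty")
  has <- .TISSUES %in% occ
  code <- paste(ifelse(has, c("T", "N", "P"), ""), collapse = "")
  switch(code,
         "T" = "TUMOR", "N" = "NAT", "P" = "PBMC",
         "TN" = "TN", "TP" = "TP", "NP" = "PN", "TNP" = "ALL")
}

#' Expanded-clonotype call
#'
#' A clonotype is called expanded when its frequency strictly exceeds the
#' threshold (default 1% of the repertoire).
#'
#' @param frequency numeric vector of clonal frequencies in \[0, 1\]
#' @param threshold expansion threshold (default 0.01)
#' @return logical vector
#' @export
flagExpanded <- function(frequency, threshold = 0.01) {
  stopifnot(all(frequency >= 0 & frequency <= 1, na.rm = TRUE))
  frequency > threshold
}

#' Track clonotypes across the tissues of one patient
#'
#' Matches clonotypes (by CDR3 amino-acid sequence, or nucleotide sequence
#' for convergence-aware analyses) across all repertoires of a patient,
#' records per-tissue frequencies and read counts, classifies the tissue
#' pattern, and flags tumor expansion. A clonotype counts as present in a
#' tissue when it has at least `min_count` reads there. Patterns are
#' assigned over the tissues actually assayed; `tissues_assayed` records
#' how many, so ALL is never claimed from fewer than three.
#'
#' @param reps list of productive-filtered [Repertoire-class] objects, all
#'   from one patient, at most one per tissue.
#' @param key `"cdr3_aa"` (default, matching cross-tissue comparisons) or
#'   `"cdr3_nt"`.
#' @param min_count minimum reads for "detected in tissue" (default 1).
#' @param expanded_threshold tumor-expansion frequency threshold.
#' @return data.frame, one row per unique key: `key`, `freq_<tissue>` and
#'   `count_<tissue>` per assayed tissue, `pattern`, `expanded_in_tumor`,
#'   `tissues_assayed`.
#' @export
trackClonotypes <- function(reps, key = c("cdr3_aa", "cdr3_nt"),
                            min_count = 1, expanded_threshold = 0.01) {
  key <- match.arg(key)
  stopifnot(length(reps) >= 1)
  tissues <- vapply(reps, tissueOf, character(1))
  pats <- unique(vapply(reps, patientId, character(1)))
  if (length(pats) > 1)
    stop("repertoires span multiple patients: ", paste(pats, collapse = ", "))
  if (anyDuplicated(tissues))
    stop("ambiguity: more than one repertoire for tissue ",
         tissues[duplicated(tissues)][1], "; merge timepoints explicitly")
  tissues <- intersect(.TISSUES, tissues)  # canonical order
  per <- lapply(reps, function(r) {
    rec <- clonotypes(r)
    rec <- rec[rec$productive, c(key, "frequency", "read_count")]
    agg <- stats::aggregate(rec[, c("frequency", "read_count")],
                            by = list(key = rec[[key]]), FUN = sum)
    agg
  })
  names(per) <- vapply(reps, tissueOf, character(1))
  keys <- sort(unique(unlist(lapply(per, `[[`, "key"))))
  out <- data.frame(key = keys, stringsAsFactors = FALSE)
  present <- matrix(FALSE, length(keys), length(tissues),
                    dimnames = list(keys, tissues))
  for (ts in tissues) {
    m <- match(keys, per[[ts]]$key)
    fr <- ifelse(is.na(m), 0, per[[ts]]$frequency[m])
    ct <- ifelse(is.na(m), 0L, per[[ts]]$read_count[m])
    out[[paste0("freq_", ts)]] <- fr
    out[[paste0("count_", ts)]] <- ct
    present[, ts] <- ct >= min_count
  }
  out$pattern <- apply(present, 1, function(v)
    classifyTissuePattern(tissues[v]))
  out$expanded_in_tumor <- if ("TUMOR" %in% tissues)
    flagExpanded(out$freq_TUMOR, expanded_threshold) else FALSE
  out$tissues_assayed <- length(tissues)
  out
}

#' Summary of tissue-pattern counts
#'
#' @param tracked output of [trackClonotypes()]
#' @return data.frame of counts per pattern over the 7 labels (zero-count
#'   patterns included); counts sum to `nrow(tracked)`.
#' @export
patternCounts <- function(tracked) {
  labs <- c("TUMOR", "NAT", "PBMC", "TN", "TP", "PN", "ALL")
  n <- vapply(labs, function(l) sum(tracked$pattern == l), integer(1))
  data.frame(pattern = labs, n = n, fraction = n / nrow(tracked))
}

#' Long-format table for alluvial plots of top clonotypes
#'
#' Builds the classic alluvial input: the union of each tissue's `n` most
#' frequent clonotypes, one row per clonotype x tissue with explicit zeros
#' where a clonotype is absent from a tissue.
#'
#' @param tracked output of [trackClonotypes()]
#' @param n top clonotypes per tissue (default 120)
#' @return data.frame `key`, `tissue`, `frequency`, ordered by key then
#'   tissue (deterministic)
#' @export
alluvialTable <- function(tracked, n = 120) {
  stopifnot(nrow(tracked) >= 1)
  fcols <- grep("^freq_", names(tracked), value = TRUE)
  tissues <- sub("^freq_", "", fcols)
  sel <- sort(unique(unlist(lapply(fcols, function(cl) {
    ord <- order(-tracked[[cl]], tracked$key)
    tracked$key[utils::head(ord, n)]
  }))))
  long <- expand.grid(key = sel, tissue = tissues,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- match(long$key, tracked$key)
  long$frequency <- vapply(seq_len(nrow(long)), function(i)
    tracked[[paste0("freq_", long$tissue[i])]][m[i]], numeric(1))
  long <- long[order(long$key, long$tissue), ]
  rownames(long) <- NULL
  long
}

#' Clonotype persistence across timepoints
#'
#' Tabulates each clonotype's frequency trajectory across repeated sampling
#' of the same tissue and flags clonotypes detected at every timepoint as
#' persistent.
#'
#' @param reps list of productive-filtered [Repertoire-class] objects for
#'   one patient/tissue at >= 2 timepoints.
#' @param key `"cdr3_aa"` or `"cdr3_nt"`
#' @return data.frame `key`, one `freq_<timepoint>` column per timepoint,
#'   `persistent`, `max_frequency`. With a single timepoint a warning is
#'   raised and an empty data.frame returned.
#' @export
longitudinalPersistence <- function(reps, key = c("cdr3_aa", "cdr3_nt")) {
  key <- match.arg(key)
  tps <- vapply(reps, timepointOf, character(1))
  if (length(unique(tps)) < 2) {
    warning("fewer than two timepoints; nothing to track")
    return(data.frame(key = character(), persistent = logical(),
                      max_frequency = numeric()))
  }
  per <- lapply(reps, function(r) {
    rec <- clonotypes(r)
    rec <- rec[rec$productive, , drop = FALSE]
    agg <- stats::aggregate(rec$frequency, by = list(key = rec[[key]]), FUN = sum)
    names(agg)[2] <- "frequency"
    agg
  })
  keys <- sort(unique(unlist(lapply(per, `[[`, "key"))))
  out <- data.frame(key = keys, stringsAsFactors = FALSE)
  for (i in seq_along(per)) {
    m <- match(keys, per[[i]]$key)
    out[[paste0("freq_", tps[i])]] <- ifelse(is.na(m), 0, per[[i]]$frequency[m])
  }
  fmat <- as.matrix(out[, -1, drop = FALSE])
  out$persistent <- rowSums(fmat > 0) == length(per)
  out$max_frequency <- apply(fmat, 1, max)
  out
}
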