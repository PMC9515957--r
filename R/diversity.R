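#' Remove non-productive rearrangements
#'
#' Drops records flagged non-productive (out-of-frame or containing a stop
#' codon) and recomputes frequencies over the remaining records so they sum
#' to 1.
#'
#' @param x a [Repertoire-class]
#' @return a [Repertoire-class] containing only productive records
#' @export
filterProductive <- function(x) {
  rec <- clonotypes(x)
  rec <- rec[rec$productive, , drop = FALSE]
  if (!nrow(rec)) stop("empty repertoire: all records are non-productive")
  Repertoire(rec, sample_id = sampleId(x), patient_id = patientId(x),
             tissue = tissueOf(x), timepoint = timepointOf(x))
}

#' Shannon-entropy diversity and clonality of a repertoire
#'
#' Computes, over the unique productive clonotypes with frequencies
#' \eqn{p_i}: Shannon entropy \eqn{H = -\sum p_i \ln p_i}, normalized
#' entropy \eqn{H / \ln U} (U = number of unique productive clonotypes;
#' base-invariant), and clonality \eqn{1 - H/\ln U}. Clonality is 0 for a
#' perfectly even repertoire and 1 for a monoclonal one. For U = 1 the
#' normalized entropy is the indeterminate 0/0; the limit of a vanishing
#' second clone gives clonality 1, which is the convention used.
#'
#' @param x a [Repertoire-class] (non-productive records are ignored) or a
#'   numeric vector of clonotype frequencies summing to 1.
#' @return data.frame with columns `unique_count`, `entropy`
#'   (natural-log units), `normalized_entropy`, `clonality`.
#' @export
repertoireDiversity <- function(x) {
  if (methods::is(x, "Repertoire")) {
    rec <- clonotypes(x)
    p <- rec$frequency[rec$productive]
  } else {
    p <- as.numeric(x)
  }
  p <- p[p > 0]
  U <- length(p)
  if (U == 0L) stop("empty repertoire: no productive clonotypes")
  H <- -sum(p * log(p))
  nH <- if (U == 1L) 1 else H / log(U)
  data.frame(unique_count = U, entropy = H,
             normalized_entropy = if (U == 1L) 0 else nH,
             clonality = if (U == 1L) 1 else 1 - nH)
}

#' Diversity summary for a set of repertoires
#'
#' @param reps list of [Repertoire-class]
#' @return data.frame, one row per sample, with metadata and the columns of
#'   [repertoireDiversity()]
#' @export
diversityTable <- function(reps) {
  do.call(rbind, lapply(reps, function(r) {
    cbind(data.frame(sample_id = sampleId(r), patient_id = patientId(r),
                     tissue = tissueOf(r), stringsAsFactors = FALSE),
          repertoireDiversity(r))
  }))
}

#' Repertoire similarity score
#'
#' The number of unique sequences shared by two samples as a fraction of
#' the total number of unique sequences in the two samples. The total is
#' by default the deduplicated union of the two sets (Jaccard-style);
#' `denominator = "sum"` instead divides by the sum of the two unique
#' counts.
#'
#' @param a,b [Repertoire-class] objects (productive records are compared)
#' @param key sequence identity level: `"cdr3_aa"` (default) or `"cdr3_nt"`
#' @param denominator `"union"` (default) or `"sum"`
#' @return a fraction in \[0, 1\]; symmetric in its arguments
#' @export
similarityScore <- function(a, b, key = c("cdr3_aa", "cdr3_nt"),
                            denominator = c("union", "sum")) {
  key <- match.arg(key)
  denominator <- match.arg(denominator)
  ua <- unique(clonotypes(a)[[key]][clonotypes(a)$productive])
  ub <- unique(clonotypes(b)[[key]][clonotypes(b)$productive])
  if (!length(ua) && !length(ub))
    stop("similarity undefined: both repertoires are empty")
  shared <- length(intersect(ua, ub))
  denom <- switch(denominator,
                  union = length(union(ua, ub)),
                  sum = length(ua) + length(ub))
  shared / denom
}

#' Most frequent clonotypes of a repertoire
#'
#' Returns the `n` highest-frequency productive clonotypes. Ties are broken
#' lexicographically by `cdr3_aa`, then `cdr3_nt`, so the result is
#' deterministic.
#'
#' @param x a [Repertoire-class]
#' @param n number of clonotypes requested (if fewer exist, all are
#'   returned with a warning)
#' @return data.frame of records ordered by decreasing frequency
#' @export
topClonotypes <- function(x, n = 120) {
  stopifnot(n >= 1)
  rec <- clonotypes(x)
  rec <- rec[rec$productive, , drop = FALSE]
  rec <- rec[order(-rec$frequency, rec$cdr3_aa, rec$cdr3_nt), , drop = FALSE]
  if (nrow(rec) < n) {
    warning("repertoire has only ", nrow(rec), " clonotypes (requested ", n, ")")
    n <- nrow(rec)
  }
  out <- utils::head(rec, n)
  rownames(out) <- NULL
  out
}
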