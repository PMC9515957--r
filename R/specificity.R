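.interior <- function(cdr3) substr(cdr3, 4L, nchar(cdr3) - 3L)

.kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  unique(vapply(seq_len(n - k + 1L), function(i) substr(s, i, i + k - 1L), ""))
}

#' Mine shared interior motifs from a CDR3 set
#'
#' Enumerates k-mers (k in `k_values`) from CDR3 interiors — the first and
#' last 3 residues, which are largely germline-templated, are trimmed —
#' and keeps motifs carried by at least `min_clonotypes` distinct CDR3s.
#' When a reference (background) set is supplied, a motif must additionally
#' be fold-enriched by at least `min_fold` over the reference interior
#' k-mer carrier frequency; the reference carrier count takes a pseudocount
#' of 1 so unseen motifs remain scoreable.
#'
#' Sequences too short to have an interior of length k (length < k + 6)
#' are skipped; the number skipped is reported as an attribute.
#'
#' @param cdr3_set character vector of CDR3 amino-acid sequences
#' @param reference optional background CDR3 set
#' @param k_values motif lengths (default 3 and 4)
#' @param min_clonotypes minimum distinct member CDR3s per motif (default 3)
#' @param min_fold minimum enrichment over reference (default 10)
#' @return data.frame `kmer`, `support`, `enrichment_fold` (NA without a
#'   reference), plus attribute `members`: named list kmer -> member CDR3s
#' @export
mineMotifs <- function(cdr3_set, reference = NULL, k_values = c(3, 4),
                       min_clonotypes = 3, min_fold = 10) {
  seqs <- unique(toupper(trimws(cdr3_set)))
  motifs <- list(); skipped <- 0L
  carrier <- function(set, k) {
    # kmer -> distinct carrier sequences
    res <- new.env(parent = emptyenv())
    for (s in set) {
      int <- .interior(s)
      if (nchar(s) < k + 6) next
      for (km in .kmers(int, k))
        assign(km, c(get0(km, envir = res, ifnotfound = character()), s),
               envir = res)
    }
    res
  }
  out <- list()
  for (k in k_values) {
    skipped <- skipped + sum(nchar(seqs) < k + 6)
    env <- carrier(seqs, k)
    ref_env <- if (!is.null(reference)) carrier(unique(toupper(reference)), k)
    ref_n <- if (!is.null(reference)) length(unique(toupper(reference)))
    for (km in ls(env)) {
      mem <- unique(get(km, envir = env))
      if (length(mem) < min_clonotypes) next
      fold <- NA_real_
      if (!is.null(reference)) {
        ref_c <- length(get0(km, envir = ref_env, ifnotfound = character()))
        fold <- (length(mem) / length(seqs)) / ((ref_c + 1) / (ref_n + 1))
        if (fold < min_fold) next
      }
      out[[km]] <- list(kmer = km, support = length(mem), fold = fold,
                        members = mem)
    }
  }
  if (!length(out)) {
    res <- data.frame(kmer = character(), support = integer(),
                      enrichment_fold = numeric())
    attr(res, "members") <- list()
    attr(res, "skipped") <- skipped
    return(res)
  }
  res <- data.frame(kmer = vapply(out, `[[`, "", "kmer"),
                    support = vapply(out, function(z) z$support, integer(1)),
                    enrichment_fold = vapply(out, function(z) z$fold, numeric(1)),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$support, res$kmer), ]
  rownames(res) <- NULL
  attr(res, "members") <- lapply(out, `[[`, "members")[res$kmer]
  attr(res, "skipped") <- skipped
  res
}

.hamming_pairs <- function(seqs, radius = 1) {
  # all pairs of equal-length sequences within the given Hamming distance
  pairs <- matrix(integer(), 0, 2)
  for (len in unique(nchar(seqs))) {
    idx <- which(nchar(seqs) == len)
    if (length(idx) < 2) next
    chars <- do.call(rbind, strsplit(seqs[idx], ""))
    for (a in seq_len(length(idx) - 1)) {
      d <- rowSums(chars[(a + 1):length(idx), , drop = FALSE] !=
                     matrix(chars[a, ], length(idx) - a, len, byrow = TRUE))
      hit <- which(d <= radius)
      if (length(hit))
        pairs <- rbind(pairs, cbind(idx[a], idx[a + hit]))
    }
  }
  pairs
}

#' Build predicted-specificity groups
#'
#' Groups CDR3 sequences as the connected components of a graph whose
#' edges join (i) sequences sharing an enriched interior motif and (ii)
#' equal-length sequences within Hamming distance `hamming_radius`.
#' Ungrouped sequences form singleton groups, so the groups partition the
#' input set. Group ids are canonical: groups are ordered by their
#' lexicographically smallest member.
#'
#' @param cdr3_set character vector of CDR3 amino-acid sequences
#' @param motifs output of [mineMotifs()] on the same set (or NULL to use
#'   near-identity edges only)
#' @param hamming_radius near-identity radius at equal length (default 1)
#' @return data.frame `cdr3_aa`, `group_id`, `group_size`; attribute
#'   `groups` = named list of member vectors
#' @export
buildGroups <- function(cdr3_set, motifs = NULL, hamming_radius = 1) {
  seqs <- sort(unique(toupper(trimws(cdr3_set))))
  g <- igraph::make_empty_graph(n = length(seqs), directed = FALSE)
  edges <- integer()
  if (!is.null(motifs)) {
    for (mem in attr(motifs, "members")) {
      idx <- match(intersect(mem, seqs), seqs)
      if (length(idx) >= 2)
        edges <- c(edges, rbind(idx[1], idx[-1]))  # star suffices for a component
    }
  }
  hp <- .hamming_pairs(seqs, hamming_radius)
  if (nrow(hp)) edges <- c(edges, t(hp))
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  # canonical ids: order components by smallest member (seqs already sorted)
  first <- !duplicated(comp)
  rank <- match(comp, comp[first])
  gid <- sprintf("G%04d", rank)
  size <- as.integer(table(gid)[gid])
  out <- data.frame(cdr3_aa = seqs, group_id = gid, group_size = size,
                    stringsAsFactors = FALSE)
  attr(out, "groups") <- split(out$cdr3_aa, out$group_id)
  out
}

#' Per-tissue specificity-group size statistics
#'
#' Restricts each group to the members observed in each tissue and
#' summarizes unique sequences per (nonempty) group and tissue, with
#' pairwise two-sample t statistics between tissues on the group-size
#' vectors.
#'
#' @param groups output of [buildGroups()]
#' @param membership data.frame `cdr3_aa`, `tissue`
#' @return list with `per_tissue` (tissue, n_groups, mean_size, sd_size)
#'   and `contrasts` (tissue_a, tissue_b, t, p)
#' @export
groupStats <- function(groups, membership) {
  stopifnot(all(c("cdr3_aa", "tissue") %in% names(membership)))
  membership$cdr3_aa <- toupper(trimws(membership$cdr3_aa))
  tissues <- unique(membership$tissue)
  sizes <- lapply(tissues, function(ts) {
    present <- unique(membership$cdr3_aa[membership$tissue == ts])
    sub <- groups[groups$cdr3_aa %in% present, , drop = FALSE]
    as.integer(table(sub$group_id))
  })
  names(sizes) <- tissues
  per <- data.frame(tissue = tissues,
                    n_groups = vapply(sizes, length, integer(1)),
                    mean_size = vapply(sizes, function(z) mean(z), numeric(1)),
                    sd_size = vapply(sizes, function(z)
                      if (length(z) > 1) stats::sd(z) else 0, numeric(1)))
  contrasts <- NULL
  if (length(tissues) >= 2) {
    cmb <- utils::combn(tissues, 2)
    contrasts <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      a <- sizes[[cmb[1, i]]]; b <- sizes[[cmb[2, i]]]
      tt <- if (length(a) > 1 && length(b) > 1 &&
                (stats::sd(a) > 0 || stats::sd(b) > 0))
        stats::t.test(a, b) else list(statistic = NA, p.value = NA)
      data.frame(tissue_a = cmb[1, i], tissue_b = cmb[2, i],
                 t = unname(tt$statistic), p = tt$p.value)
    }))
  }
  list(per_tissue = per, contrasts = contrasts)
}

#' Specificity grouping across pooled patients
#'
#' Pools CDR3 sets from several (typically HLA-matched) patients, mines
#' motifs and builds groups on the pooled set, and labels each group with
#' the number of patients contributing members.
#'
#' @param pooled data.frame `cdr3_aa`, `patient_id`
#' @param ... passed to [mineMotifs()]
#' @param hamming_radius passed to [buildGroups()]
#' @return the [buildGroups()] table with a `patient_multiplicity` column
#' @export
crossPatientGrouping <- function(pooled, ..., hamming_radius = 1) {
  stopifnot(all(c("cdr3_aa", "patient_id") %in% names(pooled)))
  if (length(unique(pooled$patient_id)) < 2)
    stop("pooled set must contain at least two patients")
  pooled$cdr3_aa <- toupper(trimws(pooled$cdr3_aa))
  motifs <- mineMotifs(pooled$cdr3_aa, ...)
  groups <- buildGroups(pooled$cdr3_aa, motifs, hamming_radius = hamming_radius)
  pat <- split(pooled$patient_id, pooled$cdr3_aa)
  mult <- vapply(split(groups$cdr3_aa, groups$group_id), function(mem)
    length(unique(unlist(pat[mem]))), integer(1))
  groups$patient_multiplicity <- as.integer(mult[groups$group_id])
  groups
}
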