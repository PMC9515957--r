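# shared in-code fixtures

# a small repertoire from named read counts (all productive unless the
# name carries a stop codon)
rep_from_counts <- function(counts, sample_id = "S1", patient_id = "P1",
                            tissue = "TUMOR", timepoint = NA) {
  aa <- names(counts)
  nt <- vapply(seq_along(aa), function(i)
    paste(sample(c("A", "C", "G", "T"), 3 * nchar(aa[i]), replace = TRUE),
          collapse = ""), "")
  Repertoire(data.frame(cdr3_nt = nt, cdr3_aa = aa,
                        read_count = as.integer(counts),
                        productive = !grepl("\\*", aa),
                        stringsAsFactors = FALSE),
             sample_id = sample_id, patient_id = patient_id,
             tissue = tissue, timepoint = timepoint)
}

# repertoire with explicit nucleotide sequences (aa -> list of nt counts)
rep_from_nt <- function(tab, ...) {
  Repertoire(tab, ...)
}

write_immunoseq <- function(df, path) {
  write.table(data.frame(nucleotide = df$cdr3_nt, aminoAcid = df$cdr3_aa,
                         count = df$read_count,
                         vGeneName = df$v_gene %||% "TRBV01",
                         jGeneName = df$j_gene %||% "TRBJ1-1",
                         sequenceStatus = ifelse(df$productive, "In", "Out")),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_airr <- function(df, path) {
  write.table(data.frame(junction = df$cdr3_nt, junction_aa = df$cdr3_aa,
                         duplicate_count = df$read_count,
                         v_call = df$v_gene %||% "TRBV01",
                         j_call = df$j_gene %||% "TRBJ1-1",
                         productive = ifelse(df$productive, "T", "F")),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small deterministic contig table builder: one row per chain
contigs_from_cells <- function(cells) {
  do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    tra <- strsplit(cells$tra[i], ";")[[1]]
    trb <- strsplit(cells$trb[i], ";")[[1]]
    tra <- tra[nzchar(tra)]; trb <- trb[nzchar(trb)]
    tis <- if (is.null(cells$tissue)) NA else cells$tissue[i]
    rbind(
      if (length(tra)) data.frame(cell_id = cells$cell_id[i], chain = "TRA",
                                  cdr3 = tra, cdr3_nt = NA, tissue = tis),
      if (length(trb)) data.frame(cell_id = cells$cell_id[i], chain = "TRB",
                                  cdr3 = trb, cdr3_nt = NA, tissue = tis))
  }))
}
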