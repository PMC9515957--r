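# independent brute-force union-find oracle for specificity grouping
uf_groups <- function(seqs, motifs, radius = 1) {
  seqs <- sort(unique(seqs))
  parent <- seq_along(seqs)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (mem in attr(motifs, "members")) {
    idx <- match(intersect(mem, seqs), seqs)
    if (length(idx) >= 2) for (i in idx[-1]) union(idx[1], i)
  }
  hd <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  for (i in seq_along(seqs)) for (j in seq_len(i - 1))
    if (nchar(seqs[i]) == nchar(seqs[j]) && hd(seqs[i], seqs[j]) <= radius)
      union(i, j)
  roots <- vapply(seq_along(seqs), find, integer(1))
  split(seqs, roots)
}
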