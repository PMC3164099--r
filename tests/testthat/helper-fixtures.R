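# Small in-code fixtures shared across test files.

make_aln <- function(seqs, ids = NULL, reference_id = NULL, classes = NULL) {
  if (is.null(ids)) ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("i%02d_%02d_cDNA", 1, seq_along(seqs))
  mat <- matrix(unlist(strsplit(unname(seqs), "")), nrow = length(seqs),
                byrow = TRUE)
  rownames(mat) <- ids
  if (is.null(reference_id)) reference_id <- ids[1]
  info <- suppressWarnings(
    ampliclone:::parse_clone_headers(ids, reference_id))
  clone_alignment(mat, info, reference_id, classes)
}

# two divergent 30-nt basics differing at 10 spread-out sites
toy_basics <- function() {
  x <- "GCTGGCACTGTCCCAATCAACGACTTCCGT"
  xv <- strsplit(x, "")[[1]]
  yv <- xv
  for (p in c(1, 4, 7, 10, 13, 16, 19, 22, 25, 28))
    yv[p] <- setdiff(c("A", "C", "G", "T"), xv[p])[1]
  list(x = x, y = paste(yv, collapse = ""),
       diff_sites = c(1, 4, 7, 10, 13, 16, 19, 22, 25, 28))
}

mutate_str <- function(s, pos, to) {
  v <- strsplit(s, "")[[1]]
  v[pos] <- to
  paste(v, collapse = "")
}

splice_str <- function(a, b, bp) {
  paste0(substr(a, 1, bp), substr(b, bp + 1, nchar(b)))
}
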