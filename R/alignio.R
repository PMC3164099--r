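#' @importFrom stats pchisq pnorm rpois runif sd setNames rexp
#' @importFrom utils read.delim write.table combn head
NULL

ALN_ALPHABET <- c("A", "C", "G", "T", "-", "N")

#' Construct a clone alignment
#'
#' A `clone_alignment` holds equal-length aligned sequences for a set of
#' cloned amplicons plus a reference, a per-clone identity table
#' (individual, clone, source) parsed from FASTA headers, and an optional
#' per-column class annotation (exon1/intron1/exon2/intron2/exon3).
#'
#' @param mat Character matrix, one row per sequence, one column per
#'   alignment column, values in A/C/G/T/-/N. Row names are sequence ids.
#' @param info Data frame with columns `id`, `individual`, `clone`,
#'   `source` (one row per row of `mat`).
#' @param reference_id Id of the reference sequence (must be a row name).
#' @param classes Optional character vector of per-column class labels.
#' @return An object of class `clone_alignment`.
#' @export
clone_alignment <- function(mat, info, reference_id, classes = NULL) {
  stopifnot(is.matrix(mat), is.character(mat))
  if (is.null(rownames(mat))) stop("alignment matrix must have row names")
  bad <- !mat %in% ALN_ALPHABET
  dim(bad) <- dim(mat)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-IUPAC symbol '%s' in record '%s' at column %d",
                 mat[bad][1L], rownames(mat)[idx[1L]], idx[2L]))
  }
  if (!reference_id %in% rownames(mat))
    stop(sprintf("reference '%s' not found in alignment", reference_id))
  if (!is.null(classes) && length(classes) != ncol(mat))
    stop("column class vector length must equal alignment width")
  if (anyDuplicated(info$id)) stop("duplicate sequence ids")
  structure(list(mat = mat, info = info, reference_id = reference_id,
                 classes = classes),
            class = "clone_alignment")
}

#' @export
print.clone_alignment <- function(x, ...) {
  cat(sprintf("clone_alignment: %d sequences x %d columns\n",
              nrow(x$mat), ncol(x$mat)))
  cat(sprintf("  reference: %s\n", x$reference_id))
  src <- table(x$info$source, useNA = "ifany")
  cat("  sources:", paste(sprintf("%s=%d", names(src), src), collapse = ", "),
      "\n")
  if (!is.null(x$classes))
    cat("  column classes:",
        paste(unique(x$classes), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.clone_alignment <- function(x) dim(x$mat)

parse_clone_headers <- function(ids, reference_id) {
  m <- regmatches(ids, regexec("^([^_]+)_([^_]+)_(cDNA|gDNA)$", ids))
  ok <- lengths(m) == 4L
  info <- data.frame(id = ids,
                     individual = NA_character_,
                     clone = NA_character_,
                     source = NA_character_,
                     stringsAsFactors = FALSE)
  info$individual[ok] <- vapply(m[ok], `[`, "", 2L)
  info$clone[ok] <- vapply(m[ok], `[`, "", 3L)
  info$source[ok] <- vapply(m[ok], `[`, "", 4L)
  refs <- ids == reference_id | grepl("^ref($|_)", ids)
  unparsed <- ids[!ok & !refs]
  if (length(unparsed))
    warning(sprintf("%d header(s) do not follow <individual>_<clone>_<source>: %s",
                    length(unparsed),
                    paste(head(unparsed, 3L), collapse = ", ")))
  key <- paste(info$individual, info$clone, info$source)
  if (anyDuplicated(key[ok]))
    stop("duplicate individual/clone/source identity in alignment")
  info
}

#' Read an aligned FASTA file of cloned amplicon sequences
#'
#' Headers are expected to follow the `<individual>_<clone>_<source>`
#' convention (source is `cDNA` or `gDNA`); the reference header is exempt.
#' Column classes (exon/intron structure) can be supplied as a TSV sidecar
#' with columns `class`, `start`, `end` in 0-based half-open coordinates.
#'
#' @param path Path to the aligned FASTA file.
#' @param reference_id Header of the reference sequence.
#' @param classes_path Optional path to the column-class sidecar TSV.
#' @return A [clone_alignment].
#' @export
read_alignment <- function(path, reference_id, classes_path = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file")
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L)
    stop(sprintf("alignment error: records have unequal lengths (%s)",
                 paste(sort(unique(w)), collapse = ", ")))
  mat <- t(vapply(as.character(seqs),
                  function(s) strsplit(s, "", fixed = TRUE)[[1L]],
                  character(w[1L])))
  mat[] <- toupper(mat)
  rownames(mat) <- names(seqs)
  classes <- if (!is.null(classes_path))
    read_column_classes(classes_path, ncol(mat)) else NULL
  info <- parse_clone_headers(names(seqs), reference_id)
  clone_alignment(mat, info, reference_id, classes)
}

#' Write a clone alignment as unwrapped FASTA
#'
#' @param aln A [clone_alignment].
#' @param path Output path.
#' @export
write_alignment <- function(aln, path) {
  lines <- character(2L * nrow(aln$mat))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(aln$mat))
  lines[c(FALSE, TRUE)] <- apply(aln$mat, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a column-class sidecar table
#'
#' @param path TSV with columns `class`, `start`, `end` (0-based half-open).
#' @param width Expected total alignment width.
#' @return Character vector of per-column class labels.
#' @export
read_column_classes <- function(path, width) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("class", "start", "end") %in% names(tab)))
  tab <- tab[order(tab$start), , drop = FALSE]
  if (any(tab$start < 0L) || any(tab$end > width) ||
      any(tab$end <= tab$start))
    stop("invalid column-class intervals")
  if (any(tab$start[-1L] != tab$end[-nrow(tab)]))
    stop("column-class intervals must tile the alignment contiguously")
  if (tab$start[1L] != 0L || tab$end[nrow(tab)] != width)
    stop("column classes must cover every alignment column")
  rep(tab$class, tab$end - tab$start)
}

#' Write a column-class sidecar table
#'
#' @param classes Per-column class labels.
#' @param path Output TSV path.
#' @export
write_column_classes <- function(classes, path) {
  r <- rle(classes)
  end <- cumsum(r$lengths)
  tab <- data.frame(class = r$values, start = end - r$lengths, end = end)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default peptide-domain partition of the coding region
#'
#' The 300-nt coding region splits into the signal peptide (60 nt), the
#' mature peptide (120 nt) and the anionic C-terminal region (120 nt).
#' Intervals are 0-based half-open in coding coordinates.
#'
#' @param signal,mature,cterm Integer length-2 vectors `c(start, end)`.
#' @return Named list of intervals, class `domain_partition`.
#' @export
default_partition <- function(signal = c(0L, 60L), mature = c(60L, 180L),
                              cterm = c(180L, 300L)) {
  p <- list(signal = as.integer(signal), mature = as.integer(mature),
            cterm = as.integer(cterm))
  if (p$signal[1L] != 0L || p$mature[1L] != p$signal[2L] ||
      p$cterm[1L] != p$mature[2L])
    stop("partition intervals must be contiguous from 0")
  structure(p, class = "domain_partition")
}

#' Map coding positions to peptide domains
#'
#' @param pos Integer vector of 0-based coding positions.
#' @param partition A [default_partition]-style partition.
#' @return Character vector of domain names.
#' @export
domain_of <- function(pos, partition = default_partition()) {
  out <- rep(NA_character_, length(pos))
  for (d in names(partition)) {
    iv <- partition[[d]]
    out[pos >= iv[1L] & pos < iv[2L]] <- d
  }
  if (anyNA(out)) stop("position outside the coding partition")
  out
}

coding_classes <- c("exon1", "exon2", "exon3")

coding_columns <- function(aln) {
  if (is.null(aln$classes)) seq_len(ncol(aln$mat))
  else which(aln$classes %in% coding_classes)
}

#' Extract a sub-alignment for a column class or peptide domain
#'
#' `region` may be a column class (`exon1`, `intron1`, ...), `"coding"`
#' (all exon columns), or a peptide-domain name from `partition`
#' (`signal`, `mature`, `cterm`), which is resolved through coding
#' coordinates. The returned alignment keeps clone identities; the
#' attribute `coding_range` reports the selected coding interval 0-based
#' half-open.
#'
#' @param aln A [clone_alignment].
#' @param region Region name.
#' @param partition Domain partition used for domain regions.
#' @return A [clone_alignment] of the selected columns.
#' @export
extract_region <- function(aln, region, partition = default_partition()) {
  if (region %in% names(partition)) {
    cc <- coding_columns(aln)
    iv <- partition[[region]]
    if (iv[2L] > length(cc)) stop("partition exceeds coding length")
    cols <- cc[(iv[1L] + 1L):iv[2L]]
    rng <- iv
  } else if (region == "coding") {
    cols <- coding_columns(aln)
    rng <- c(0L, length(cols))
  } else {
    if (is.null(aln$classes) || !region %in% aln$classes)
      stop(sprintf("region error: '%s' not present", region))
    cols <- which(aln$classes == region)
    rng <- NULL
  }
  if (length(cols) == 0L) stop("region error: empty region")
  out <- clone_alignment(aln$mat[, cols, drop = FALSE], aln$info,
                         aln$reference_id,
                         if (!is.null(aln$classes)) aln$classes[cols])
  attr(out, "coding_range") <- rng
  out
}

#' Subset a clone alignment by sequence
#'
#' @param aln A [clone_alignment].
#' @param ids Character vector of ids, or a logical/integer index over rows.
#' @param keep_reference Keep the reference row even if not selected.
#' @return A [clone_alignment].
#' @export
subset_clones <- function(aln, ids, keep_reference = FALSE) {
  if (is.character(ids)) sel <- rownames(aln$mat) %in% ids
  else { sel <- rep(FALSE, nrow(aln$mat)); sel[ids] <- TRUE }
  if (keep_reference) sel[rownames(aln$mat) == aln$reference_id] <- TRUE
  if (!any(sel)) stop("no sequences selected")
  ref <- if (aln$reference_id %in% rownames(aln$mat)[sel])
    aln$reference_id else rownames(aln$mat)[sel][1L]
  clone_alignment(aln$mat[sel, , drop = FALSE],
                  aln$info[sel, , drop = FALSE], ref, aln$classes)
}

#' Collapse an alignment into exact-match haplotypes
#'
#' Columns containing a gap in any retained sequence are ignored for
#' identity (complete deletion), because gaps in a joint cDNA/gDNA
#' alignment are co-alignment artifacts. Sequences whose `N` fraction over
#' the compared columns exceeds `max_missing` are excluded with a message;
#' remaining `N`s match anything and such sequences join the first
#' compatible haplotype in deterministic order.
#'
#' @param aln A [clone_alignment].
#' @param max_missing Maximum tolerated per-sequence `N` fraction.
#' @return Data frame with columns `haplotype`, `count` and a list column
#'   `members` (clone ids), ordered by descending count then haplotype.
#' @export
collapse_haplotypes <- function(aln, max_missing = 0.05) {
  if (nrow(aln$mat) < 1L) stop("insufficient data: no sequences")
  mat <- aln$mat
  keep_col <- colSums(mat == "-") == 0L
  mat <- mat[, keep_col, drop = FALSE]
  nfrac <- rowSums(mat == "N") / max(1L, ncol(mat))
  if (any(nfrac > max_missing)) {
    message(sprintf("excluding %d sequence(s) with >%.0f%% missing data: %s",
                    sum(nfrac > max_missing), 100 * max_missing,
                    paste(rownames(mat)[nfrac > max_missing], collapse = ", ")))
    mat <- mat[nfrac <= max_missing, , drop = FALSE]
  }
  if (nrow(mat) == 0L) stop("insufficient data: all sequences excluded")
  seqs <- apply(mat, 1L, paste, collapse = "")
  has_n <- grepl("N", seqs, fixed = TRUE)
  groups <- list()
  for (i in order(has_n, rownames(mat))) {
    s <- seqs[[i]]
    hit <- 0L
    if (has_n[i]) {
      for (g in seq_along(groups)) {
        t <- groups[[g]]$haplotype
        sv <- strsplit(s, "")[[1L]]; tv <- strsplit(t, "")[[1L]]
        if (all(sv == tv | sv == "N" | tv == "N")) { hit <- g; break }
      }
    } else {
      hit <- match(s, vapply(groups, `[[`, "", "haplotype"), nomatch = 0L)
    }
    if (hit == 0L) {
      groups[[length(groups) + 1L]] <-
        list(haplotype = s, members = rownames(mat)[i])
    } else {
      groups[[hit]]$members <- c(groups[[hit]]$members, rownames(mat)[i])
    }
  }
  out <- data.frame(haplotype = vapply(groups, `[[`, "", "haplotype"),
                    count = vapply(groups, function(g)
                      length(g$members), 0L),
                    stringsAsFactors = FALSE)
  out$members <- I(lapply(groups, `[[`, "members"))
  out <- out[order(-out$count, out$haplotype), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a codon change as synonymous or nonsynonymous
#'
#' @param ref_codon,alt_codon Gap-free 3-mers over A/C/G/T (codons with
#'   gaps or N return `"undeterminable"` rather than erroring).
#' @return `"synonymous"`, `"nonsynonymous"` or `"undeterminable"`.
#' @export
classify_codon_change <- function(ref_codon, alt_codon) {
  code <- Biostrings::GENETIC_CODE
  ok <- function(c) nchar(c) == 3L &&
    all(strsplit(c, "")[[1L]] %in% c("A", "C", "G", "T"))
  if (!ok(ref_codon) || !ok(alt_codon)) return("undeterminable")
  if (code[[ref_codon]] == code[[alt_codon]]) "synonymous" else "nonsynonymous"
}

translate_codon <- function(codon) {
  if (!grepl("^[ACGT]{3}$", codon)) return(NA_character_)
  Biostrings::GENETIC_CODE[[codon]]
}

#' Write a haplotype table as TSV
#'
#' @param haps Result of [collapse_haplotypes].
#' @param path Output path.
#' @export
write_haplotypes <- function(haps, path) {
  tab <- data.frame(haplotype = haps$haplotype, count = haps$count,
                    members = vapply(haps$members, paste, "", collapse = ","))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
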