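#' Build a full-sib family cross from a peak table
#'
#' @param peaks Data frame with columns `family`, `member`, `intron`,
#'   `size`; `member` is `father`, `mother` or an offspring id.
#' @param family_id Which family to keep (default: the only one present).
#' @return Object of class `family_cross`: per-intron peak sets for both
#'   parents and every offspring.
#' @export
family_cross <- function(peaks, family_id = NULL) {
  if (!is.null(family_id)) peaks <- peaks[peaks$family == family_id, ]
  if (!nrow(peaks)) stop("no rows for this family")
  fam <- unique(peaks$family)
  if (length(fam) > 1L) stop("peak table spans multiple families")
  get_member <- function(m) {
    sub <- peaks[peaks$member == m, ]
    lapply(split(sub$size, sub$intron), function(s) sort(unique(s)))
  }
  members <- unique(peaks$member)
  off_ids <- setdiff(members, c("father", "mother"))
  structure(list(family_id = fam,
                 father = get_member("father"),
                 mother = get_member("mother"),
                 offspring = setNames(lapply(off_ids, get_member), off_ids)),
            class = "family_cross")
}

#' @export
print.family_cross <- function(x, ...) {
  cat(sprintf("family_cross '%s': %d offspring\n", x$family_id,
              length(x$offspring)))
  for (p in c("father", "mother"))
    for (intr in names(x[[p]]))
      cat(sprintf("  %s intron %s: %s\n", p, intr,
                  paste(x[[p]][[intr]], collapse = "/")))
  invisible(x)
}

# all unordered pairs (B1, B2) of allele blocks covering `peaks`;
# a peak may sit in both blocks (hidden duplicate allele)
enumerate_block_pairs <- function(peaks) {
  p <- length(peaks)
  out <- list(); seen <- character(0)
  for (code in seq_len(3L^p) - 1L) {
    digs <- (code %/% 3L^(seq_len(p) - 1L)) %% 3L  # 0 = B1, 1 = B2, 2 = both
    b1 <- sort(peaks[digs != 1L]); b2 <- sort(peaks[digs != 0L])
    if (!length(b1) || !length(b2)) next
    key <- paste(paste(b1, collapse = ","), paste(b2, collapse = ","),
                 sep = "|")
    key2 <- paste(paste(b2, collapse = ","), paste(b1, collapse = ","),
                  sep = "|")
    if (key %in% seen || key2 %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- list(b1 = b1, b2 = b2,
                                    dup = sum(digs == 2L))
  }
  out
}

#' Infer co-transmission blocks of parental alleles at one intron
#'
#' Searches, jointly over both parents, for a partition of each parent's
#' peaks into two gamete blocks (alleles transmitted together, possibly
#' with a hidden duplicated allele appearing in both blocks) such that
#' every offspring's peak set equals the union of one father block and
#' one mother block. Offspring peaks absent from both parents are flagged
#' as incompatibilities. With fewer than 8 offspring a power warning is
#' issued (an always-co-transmitted pair arises by chance with
#' probability 2 (1/2)^n under independence).
#'
#' @param cross A [family_cross].
#' @param intron Intron label (matching the peak table).
#' @return List with `father_blocks`, `mother_blocks` (lists of 2 integer
#'   vectors), `n_consistent`, `violating` offspring ids,
#'   `incompatible_peaks`, and `duplicates` (hidden duplicate count).
#' @export
infer_parental_haplotypes <- function(cross, intron) {
  f <- cross$father[[intron]]; m <- cross$mother[[intron]]
  if (is.null(f) || is.null(m)) stop("parent not genotyped at this intron")
  off <- lapply(cross$offspring, `[[`, intron)
  off <- off[!vapply(off, is.null, TRUE)]
  n_off <- length(off)
  if (n_off < 8L)
    warning(sprintf(paste0("only %d offspring: co-transmission blocks have",
                           " low power (chance probability 2*(1/2)^%d)"),
                    n_off, n_off))
  incompat <- lapply(off, function(p) setdiff(p, union(f, m)))
  incompat <- incompat[vapply(incompat, length, 0L) > 0L]
  fp <- enumerate_block_pairs(f); mp <- enumerate_block_pairs(m)
  off_keys <- vapply(off, function(p) paste(sort(p), collapse = ","), "")
  best <- NULL
  all_res <- list()
  for (fb in fp) for (mb in mp) {
    ukeys <- c(paste(sort(union(fb$b1, mb$b1)), collapse = ","),
               paste(sort(union(fb$b1, mb$b2)), collapse = ","),
               paste(sort(union(fb$b2, mb$b1)), collapse = ","),
               paste(sort(union(fb$b2, mb$b2)), collapse = ","))
    cons <- off_keys %in% ukeys
    score <- sum(cons)
    dup <- fb$dup + mb$dup
    all_res[[length(all_res) + 1L]] <-
      list(score = score, dup = dup, fb = fb, mb = mb, cons = cons)
    if (is.null(best) || score > best$score ||
        (score == best$score && dup < best$dup)) {
      best <- list(score = score, dup = dup, fb = fb, mb = mb, cons = cons)
    }
  }
  # peak sets often admit several equally consistent partitions (hidden
  # duplicates cannot be told from heterozygosity without peak heights);
  # keep all score-maximal ones, duplicate-poorest first, so downstream
  # linkage analysis can choose the most parsimonious overall explanation
  ties <- Filter(function(r) r$score == best$score, all_res)
  ties <- ties[order(vapply(ties, `[[`, 0, "dup"))]
  if (length(ties) > 40L) ties <- ties[1:40]
  list(father_blocks = list(best$fb$b1, best$fb$b2),
       mother_blocks = list(best$mb$b1, best$mb$b2),
       n_consistent = best$score,
       n_offspring = n_off,
       violating = names(off)[!best$cons],
       incompatible_peaks = incompat,
       duplicates = best$dup,
       ties = lapply(ties, function(r)
         list(father_blocks = list(r$fb$b1, r$fb$b2),
              mother_blocks = list(r$mb$b1, r$mb$b2),
              duplicates = r$dup)))
}

#' Pearson chi-square test of a segregation ratio
#'
#' No continuity correction; df = classes - 1.
#'
#' @param observed Integer vector of genotype-class counts.
#' @param ratio Expected proportions (default equal).
#' @return List with `observed`, `expected`, `chi2`, `df`, `p`.
#' @export
chi_square_segregation <- function(observed,
                                   ratio = rep(1, length(observed))) {
  if (length(observed) < 2L) stop("need at least 2 classes")
  ratio <- ratio / sum(ratio)
  expected <- sum(observed) * ratio
  if (any(expected <= 0)) stop("zero expected count")
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(observed = observed, expected = expected, chi2 = chi2, df = df,
       p = pchisq(chi2, df, lower.tail = FALSE))
}

# which father/mother block combination explains this offspring's peaks
offspring_combo <- function(peaks, fblocks, mblocks) {
  hits <- NULL
  for (i in 1:2) for (j in 1:2) {
    if (identical(sort(union(fblocks[[i]], mblocks[[j]])), sort(peaks)))
      hits <- rbind(hits, c(i, j))
  }
  hits
}

#' Count offspring per father-block x mother-block genotype class
#'
#' Offspring whose peak set is explained by more than one block
#' combination are reported as ambiguous and excluded from the counts.
#'
#' @param cross A [family_cross].
#' @param blocks Result of [infer_parental_haplotypes] for the intron.
#' @param intron Intron label.
#' @return List with the 2x2 count matrix and ambiguous/unexplained ids.
#' @export
genotype_class_counts <- function(cross, blocks, intron) {
  counts <- matrix(0L, 2L, 2L,
                   dimnames = list(paste0("F", 1:2), paste0("M", 1:2)))
  ambiguous <- character(0); unexplained <- character(0)
  for (id in names(cross$offspring)) {
    p <- cross$offspring[[id]][[intron]]
    if (is.null(p)) next
    hits <- offspring_combo(p, blocks$father_blocks, blocks$mother_blocks)
    if (is.null(hits)) unexplained <- c(unexplained, id)
    else if (nrow(hits) > 1L) ambiguous <- c(ambiguous, id)
    else counts[hits[1L, 1L], hits[1L, 2L]] <-
        counts[hits[1L, 1L], hits[1L, 2L]] + 1L
  }
  list(counts = counts, ambiguous = ambiguous, unexplained = unexplained)
}

linkage_for <- function(cross, blocks1, blocks2, introns) {
  out <- list()
  for (parent in c("father", "mother")) {
    bl1 <- if (parent == "father") blocks1$father_blocks else
      blocks1$mother_blocks
    bl2 <- if (parent == "father") blocks2$father_blocks else
      blocks2$mother_blocks
    tab <- matrix(0L, 2L, 2L)
    recs <- character(0); used <- character(0); skipped <- character(0)
    received <- NULL
    for (id in names(cross$offspring)) {
      p1 <- cross$offspring[[id]][[introns[1L]]]
      p2 <- cross$offspring[[id]][[introns[2L]]]
      if (is.null(p1) || is.null(p2)) { skipped <- c(skipped, id); next }
      h1 <- offspring_combo(p1, blocks1$father_blocks, blocks1$mother_blocks)
      h2 <- offspring_combo(p2, blocks2$father_blocks, blocks2$mother_blocks)
      col_p <- if (parent == "father") 1L else 2L
      b1 <- unique(h1[, col_p]); b2 <- unique(h2[, col_p])
      if (is.null(h1) || is.null(h2) ||
          length(b1) != 1L || length(b2) != 1L) {
        skipped <- c(skipped, id); next
      }
      tab[b1, b2] <- tab[b1, b2] + 1L
      used <- c(used, id)
      received <- rbind(received, data.frame(id = id, b1 = b1, b2 = b2))
    }
    if (length(skipped))
      message(sprintf("%s: %d offspring excluded from linkage test",
                      parent, length(skipped)))
    # a parent is informative only when both introns show two observed
    # block labels: a constant label carries no linkage evidence (the
    # parent's transmission there is masked by the other parent or the
    # partition is not identifiable from peak sets)
    informative <- !is.null(received) &&
      length(unique(received$b1)) == 2L &&
      length(unique(received$b2)) == 2L
    # majority phase: pair each intron-1 block with its modal intron-2 block
    diag_sum <- tab[1L, 1L] + tab[2L, 2L]
    anti_sum <- tab[1L, 2L] + tab[2L, 1L]
    phase <- if (diag_sum >= anti_sum) c(1L, 2L) else c(2L, 1L)
    n_rec <- 0L
    if (informative) {
      is_rec <- received$b2 != phase[received$b1]
      n_rec <- sum(is_rec)
      recs <- received$id[is_rec]
    }
    out[[parent]] <- list(table = tab, phase = phase,
                          informative = informative,
                          n_recombinant = n_rec, recombinant_ids = recs,
                          n_informative = if (informative) length(used)
                          else 0L,
                          complete = n_rec == 0L)
  }
  out$complete_disequilibrium <- out$father$complete && out$mother$complete
  out$n_recombinant <- out$father$n_recombinant + out$mother$n_recombinant
  out
}

#' Test intron-intron genotypic linkage within a family
#'
#' For each parent, tabulates which intron-1 block vs intron-2 block each
#' offspring received (offspring with ambiguous block assignment at
#' either intron are excluded with a log message). Phase is set by the
#' majority pairing; offspring off the majority diagonal are recombinant.
#' A parent whose labels do not vary at both introns is uninformative and
#' contributes no recombinants. When the chosen block partitions imply
#' recombinant offspring, the equally consistent tied partitions from
#' [infer_parental_haplotypes] are also evaluated and the configuration
#' implying the fewest recombination events is reported — a recombination
#' event is no more parsimonious than a hidden duplicate allele, and peak
#' sets alone cannot rank one above the other.
#'
#' @param cross A [family_cross].
#' @param blocks1,blocks2 Block inferences for introns 1 and 2.
#' @param introns Labels of the two introns.
#' @return List per parent with the 2x2 table, recombinant count and ids,
#'   and `complete` (TRUE when no recombinant offspring), plus overall
#'   `complete_disequilibrium` and the block partitions used.
#' @export
test_intron_linkage <- function(cross, blocks1, blocks2,
                                introns = c("1", "2")) {
  out <- linkage_for(cross, blocks1, blocks2, introns)
  out$blocks_used <- list(blocks1[c("father_blocks", "mother_blocks")],
                          blocks2[c("father_blocks", "mother_blocks")])
  t1 <- blocks1$ties; t2 <- blocks2$ties
  if (out$n_recombinant > 0L && (length(t1) > 1L || length(t2) > 1L)) {
    if (is.null(t1)) t1 <- list(blocks1)
    if (is.null(t2)) t2 <- list(blocks2)
    for (p1 in t1) {
      for (p2 in t2) {
        alt <- suppressMessages(linkage_for(cross, p1, p2, introns))
        if (alt$n_recombinant < out$n_recombinant) {
          alt$blocks_used <- list(p1[c("father_blocks", "mother_blocks")],
                                  p2[c("father_blocks", "mother_blocks")])
          out <- alt
        }
        if (out$n_recombinant == 0L) break
      }
      if (out$n_recombinant == 0L) break
    }
  }
  out
}

#' Locus-number verdict from a family's transmission pattern
#'
#' `two_linked_loci` when any parent carries a multi-allele
#' co-transmission block or more than 2 peaks at an intron with a
#' consistent partition; `single_locus` when all parents show at most 2
#' peaks and singleton blocks; `unresolved` when no consistent partition
#' exists.
#'
#' @param cross A [family_cross].
#' @param blocks Named list intron -> [infer_parental_haplotypes] result.
#' @return List with `verdict` and `rationale`.
#' @export
fit_locus_model <- function(cross, blocks) {
  multi <- FALSE; inconsistent <- FALSE; manypeaks <- FALSE
  for (intr in names(blocks)) {
    b <- blocks[[intr]]
    if (length(b$violating) > b$n_offspring / 4) inconsistent <- TRUE
    for (side in c("father_blocks", "mother_blocks"))
      if (any(vapply(b[[side]], length, 0L) > 1L)) multi <- TRUE
    if (length(cross$father[[intr]]) > 2L ||
        length(cross$mother[[intr]]) > 2L) manypeaks <- TRUE
  }
  if (inconsistent)
    list(verdict = "unresolved",
         rationale = "no block partition explains the offspring")
  else if (multi || manypeaks)
    list(verdict = "two_linked_loci",
         rationale = paste("a parent transmits a multi-allele block or",
                           "carries >2 alleles at an intron"))
  else
    list(verdict = "single_locus",
         rationale = "all parents <=2 peaks with singleton blocks (consistent, not proof)")
}

#' Read a family peak table
#'
#' @param path TSV with columns `family`, `member`, `intron`, `size`.
#' @return Data frame.
#' @export
read_family_peaks <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(intron = "character"))
  stopifnot(all(c("family", "member", "intron", "size") %in% names(tab)))
  tab
}
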