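hamming_nongap <- function(a, b) {
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  sum(a[ok] != b[ok])
}

#' Detect a recombinant (chimeric) clone against a set of basic sequences
#'
#' Informative sites are the columns where the individual's basic
#' sequences are not all identical. The clone is called recombinant when
#' its states can be segmented into 2 to `max_breakpoints + 1` runs, each
#' run supported by at least `min_run` sites matching one donor basic,
#' adjacent runs attributed to different donors, with at most
#' `max_mismatch` leftover sites (isolated mismatches, which become
#' somatic variant candidates) and strictly fewer leftover sites than the
#' best single-donor explanation. Among valid segmentations the one with
#' fewest segments, then fewest mismatches, is returned.
#'
#' @param clone_seq Character vector (one row of the coding alignment).
#' @param basics Character matrix of basic sequences (rows), same width.
#' @param min_run Minimum informative sites supporting each segment.
#' @param max_mismatch Maximum discounted isolated mismatches.
#' @param max_breakpoints Maximum number of breakpoints.
#' @return A list describing the call (donors, breakpoints 0-based,
#'   supporting_sites, mismatch positions), or `NULL`.
#' @export
detect_recombinants <- function(clone_seq, basics, min_run = 2L,
                                max_mismatch = 2L, max_breakpoints = 2L) {
  nb <- nrow(basics)
  if (is.null(nb) || nb < 2L) {
    message("recombination test skipped: fewer than 2 basic sequences")
    return(NULL)
  }
  L <- length(clone_seq)
  inf_sites <- which(apply(basics, 2L, function(col)
    length(unique(col[col %in% c("A", "C", "G", "T")])) > 1L))
  m <- length(inf_sites)
  if (m < 2L * min_run) return(NULL)
  # match[i, b]: does the clone agree with basic b at informative site i
  match_mat <- vapply(seq_len(nb), function(b)
    clone_seq[inf_sites] == basics[b, inf_sites], logical(m))
  dim(match_mat) <- c(m, nb)
  single_best <- min(m - colSums(match_mat))
  cum <- rbind(0L, apply(match_mat, 2L, cumsum))  # cum[i + 1, b]
  dim(cum) <- c(m + 1L, nb)
  best <- NULL
  # two segments: exact search over the cut and the ordered donor pair,
  # vectorized over cut positions
  cuts <- seq_len(m - 1L)
  for (a in seq_len(nb)) for (b in seq_len(nb)) {
    if (a == b) next
    left <- cum[cuts + 1L, a]
    right <- cum[m + 1L, b] - cum[cuts + 1L, b]
    mism <- m - left - right
    ok <- left >= min_run & right >= min_run &
      mism <= max_mismatch & mism < single_best
    if (any(ok)) {
      i <- cuts[ok][which.min(mism[ok])]
      if (is.null(best) || (m - left[i] - right[i]) < best$mismatch)
        best <- list(cuts = i, donors = c(a, b),
                     matches = c(left[i], right[i]),
                     mismatch = m - left[i] - right[i], nseg = 2L)
    }
  }
  # three segments only when no two-segment explanation exists
  if (is.null(best) && max_breakpoints >= 2L && m >= 3L * min_run) {
    idx <- seq_len(m)
    for (a in seq_len(nb)) for (b in seq_len(nb)) for (cc in seq_len(nb)) {
      if (a == b || b == cc) next
      # total matches for cut pair (i, j) decompose into f(i) + g(j)
      f <- cum[idx + 1L, a] - cum[idx + 1L, b]          # i = 1..m
      g <- cum[idx + 1L, b] + cum[m + 1L, cc] - cum[idx + 1L, cc]
      tot <- outer(f[1:(m - 2L)], g[2:(m - 1L)], "+")   # i, then j = i+1..
      mid <- outer(-cum[(1:(m - 2L)) + 1L, b], cum[(2:(m - 1L)) + 1L, b],
                   "+")
      left <- cum[(1:(m - 2L)) + 1L, a]
      right <- cum[m + 1L, cc] - cum[(2:(m - 1L)) + 1L, cc]
      okm <- outer(seq_len(m - 2L), 2:(m - 1L), "<") &   # j > i
        (mid >= min_run) &
        outer(left >= min_run, rep(TRUE, m - 2L), "&") &
        outer(rep(TRUE, m - 2L), right >= min_run, "&")
      mism <- m - tot
      okm <- okm & (mism <= max_mismatch) & (mism < single_best)
      if (any(okm)) {
        pick <- which(okm & mism == min(mism[okm]), arr.ind = TRUE)[1L, ]
        i <- pick[1L]; j <- (2:(m - 1L))[pick[2L]]
        cand <- list(cuts = c(i, j), donors = c(a, b, cc),
                     matches = c(cum[i + 1L, a],
                                 cum[j + 1L, b] - cum[i + 1L, b],
                                 cum[m + 1L, cc] - cum[j + 1L, cc]),
                     mismatch = m - tot[pick[1L], pick[2L]], nseg = 3L)
        if (is.null(best) || cand$mismatch < best$mismatch) best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)
  bounds <- c(0L, best$cuts, m)
  # breakpoint interval: between last donor-supported site of a segment
  # and first donor-supported site of the next
  bp <- matrix(0L, nrow = best$nseg - 1L, ncol = 2L)
  mm_pos <- integer(0)
  for (s in seq_len(best$nseg)) {
    idx <- (bounds[s] + 1L):bounds[s + 1L]
    mism_here <- idx[!match_mat[idx, best$donors[s]]]
    mm_pos <- c(mm_pos, inf_sites[mism_here])
    if (s < best$nseg) {
      last_sup <- max(idx[match_mat[idx, best$donors[s]]])
      nidx <- (bounds[s + 1L] + 1L):bounds[s + 2L]
      first_sup <- min(nidx[match_mat[nidx, best$donors[s + 1L]]])
      bp[s, ] <- c(inf_sites[last_sup] - 1L, inf_sites[first_sup] - 1L)
    }
  }
  list(donors = best$donors, breakpoints = bp,
       cut_sites = inf_sites[best$cuts],  # 1-based last site of each segment
       supporting_sites = best$matches, n_mismatch = best$mismatch,
       mismatch_positions = mm_pos - 1L)
}

# rebuild the spliced sequence implied by a recombinant call; donors
# agree between consecutive informative sites, so the reconstruction is
# unambiguous
splice_from_call <- function(rec, bmat) {
  recon <- bmat[rec$donors[1L], ]
  bnd <- c(rec$cut_sites, ncol(bmat))
  for (s in seq_along(rec$donors)[-1L]) {
    rng <- (bnd[s - 1L] + 1L):bnd[s]
    recon[rng] <- bmat[rec$donors[s], rng]
  }
  recon
}

donor_at_position <- function(rec, pos_1based) {
  rec$donors[findInterval(pos_1based, c(1L, rec$cut_sites + 1L))]
}

#' Infer per-individual basic (germline) sequences and classify clones
#'
#' Greedy-iterative procedure: collapse the individual's clones into
#' haplotypes; seed with the most frequent haplotype; repeatedly promote
#' the haplotype farthest (Hamming over non-gap sites) from all current
#' basics to basic status when that distance is at least `tau`, its clone
#' support at least `min_support`, and it is not explainable as a chimera
#' of the current basics; finally assign every clone to its nearest
#' basic, with residual differences recorded as somatic variant
#' candidates. Clones tied between basics, or farther than `max_residual`
#' from every basic, are flagged ambiguous. Recombinant clones are
#' detected with [detect_recombinants]; their residual isolated
#' mismatches are also recorded as variant candidates.
#'
#' @param aln A [clone_alignment] restricted to one individual's clones
#'   (coding region only).
#' @param tau Minimum divergence (sites) between basic sequences.
#' @param min_support Minimum clone support to promote a basic.
#' @param min_run,max_mismatch,max_breakpoints Passed to
#'   [detect_recombinants].
#' @param max_residual Maximum residual substitutions for assignment.
#' @return An object of class `basic_set`: individual id, basics
#'   (character vector), support, an assignment table, variant table
#'   (0-based positions) and recombinant calls.
#' @export
infer_basic_sequences <- function(aln, tau = 3L, min_support = 2L,
                                  min_run = 2L, max_mismatch = 2L,
                                  max_breakpoints = 2L, max_residual = 3L) {
  mat <- as_site_matrix(aln)
  if (nrow(mat) < 2L) stop("insufficient data: need at least 2 clones")
  indiv <- if (inherits(aln, "clone_alignment")) {
    u <- unique(aln$info$individual[!is.na(aln$info$individual)])
    if (length(u) > 1L) stop("alignment spans more than one individual")
    if (length(u)) u else NA_character_
  } else NA_character_
  keep_col <- colSums(matrix(mat == "-", nrow(mat))) == 0L
  work <- mat[, keep_col, drop = FALSE]
  col_map <- which(keep_col)
  seqs <- apply(work, 1L, paste, collapse = "")
  hap_tab <- table(seqs)
  haps <- names(hap_tab)[order(-as.integer(hap_tab), names(hap_tab))]
  hap_count <- as.integer(hap_tab[haps])
  hap_mat <- t(vapply(haps, function(s) strsplit(s, "")[[1L]],
                      character(ncol(work))))
  basics_idx <- 1L
  repeat {
    bmat <- hap_mat[basics_idx, , drop = FALSE]
    cand <- setdiff(seq_along(haps), basics_idx)
    cand <- cand[hap_count[cand] >= min_support]
    if (!length(cand)) break
    dists <- vapply(cand, function(h)
      min(vapply(basics_idx, function(b)
        hamming_nongap(hap_mat[h, ], hap_mat[b, ]), 0)), 0)
    cand <- cand[dists >= tau]; dists <- dists[dists >= tau]
    if (!length(cand)) break
    ord <- order(-dists, haps[cand])
    promoted <- FALSE
    for (h in cand[ord]) {
      chim <- if (length(basics_idx) >= 2L)
        suppressMessages(detect_recombinants(hap_mat[h, ], bmat, min_run,
                                             max_mismatch, max_breakpoints))
      else NULL
      if (is.null(chim)) {
        basics_idx <- c(basics_idx, h)
        promoted <- TRUE
        break
      }
    }
    if (!promoted) break
  }
  bmat <- hap_mat[basics_idx, , drop = FALSE]
  basics_full_rows <- lapply(basics_idx, function(h)
    mat[match(TRUE, seqs == haps[h]), ])
  ids <- rownames(mat)

  # a germline sequence whose every clone carries a somatic mutation has
  # no exact-haplotype support; such clones surface as ambiguous, so
  # promotion and assignment iterate to a fixed point, promoting the
  # consensus of any cluster of >= min_support mutually close ambiguous
  # clones that is sufficiently divergent and not chimera-explainable
  cluster_consensus <- function(rows) {
    cons <- work[rows[1L], ]
    for (j in seq_len(ncol(work))) {
      st <- work[rows, j]
      st <- st[st %in% c("A", "C", "G", "T")]
      if (!length(st)) next
      tab <- sort(table(st), decreasing = TRUE)
      top <- names(tab)[tab == tab[1L]]
      cons[j] <- sort(top)[1L]
    }
    cons
  }

  repeat {
    nb <- nrow(bmat)
    assign_tab <- data.frame(clone_id = ids, status = NA_character_,
                             basic = NA_integer_, n_variants = 0L,
                             stringsAsFactors = FALSE)
    variants <- NULL
    recombinants <- list()
    support <- integer(nb)
    for (i in seq_along(ids)) {
      cl <- work[i, ]
    rec <- if (nb >= 2L)
      suppressMessages(detect_recombinants(cl, bmat, min_run, max_mismatch,
                                           max_breakpoints))
    else NULL
    if (!is.null(rec)) {
      rec$clone_id <- ids[i]
      # residual somatic candidates: the clone versus its reconstructed
      # splice, over the whole region (not only informative sites)
      recon <- splice_from_call(rec, bmat)
      ok <- cl %in% c("A", "C", "G", "T") & recon %in% c("A", "C", "G", "T")
      pos_w <- which(ok & cl != recon)
      if (length(pos_w) > max_residual) {
        # the best chimera explanation still leaves an implausible
        # mutation load (e.g. the true donor sequence was never
        # recovered): unresolved, not force-called
        assign_tab$status[i] <- "ambiguous"
        next
      }
      assign_tab$status[i] <- "recombinant"
      assign_tab$n_variants[i] <- length(pos_w)
      if (length(pos_w)) {
        variants <- rbind(variants, data.frame(
          clone_id = ids[i], position = col_map[pos_w] - 1L,
          basic_state = recon[pos_w], clone_state = cl[pos_w],
          donor_basic = donor_at_position(rec, pos_w),
          on_recombinant = TRUE, stringsAsFactors = FALSE))
      }
      rec$mismatch_positions <- col_map[pos_w] - 1L
      rec$breakpoints[] <- col_map[rec$breakpoints + 1L] - 1L
      rec$cut_sites <- col_map[rec$cut_sites] - 1L
      recombinants[[length(recombinants) + 1L]] <- rec
      next
    }
    d <- vapply(seq_len(nb), function(b) hamming_nongap(cl, bmat[b, ]), 0)
    dmin <- min(d)
    if (sum(d == dmin) > 1L || dmin > max_residual) {
      assign_tab$status[i] <- "ambiguous"
      next
    }
    b <- which.min(d)
    assign_tab$status[i] <- "assigned"
    assign_tab$basic[i] <- b
    assign_tab$n_variants[i] <- dmin
    support[b] <- support[b] + 1L
    if (dmin > 0L) {
      ok <- cl %in% c("A", "C", "G", "T") &
        bmat[b, ] %in% c("A", "C", "G", "T")
      pos_w <- which(ok & cl != bmat[b, ])
      variants <- rbind(variants, data.frame(
        clone_id = ids[i], position = col_map[pos_w] - 1L,
        basic_state = bmat[b, pos_w], clone_state = cl[pos_w],
        donor_basic = b, on_recombinant = FALSE,
        stringsAsFactors = FALSE))
    }
    }  # end clone loop
    # second-stage promotion from ambiguous clusters
    amb <- which(assign_tab$status == "ambiguous")
    promoted <- FALSE
    if (length(amb) >= min_support) {
      amb <- amb[order(ids[amb])]
      tried <- logical(length(amb))
      for (k in seq_along(amb)) {
        if (tried[k]) next
        close_k <- which(vapply(amb, function(j)
          hamming_nongap(work[amb[k], ], work[j, ]) <= 2L * max_residual,
          TRUE))
        tried[close_k] <- TRUE
        if (length(close_k) < min_support) next
        cons <- cluster_consensus(amb[close_k])
        dmin <- min(vapply(seq_len(nb), function(b)
          hamming_nongap(cons, bmat[b, ]), 0))
        if (dmin < tau) next
        chim <- if (nb >= 2L)
          suppressMessages(detect_recombinants(cons, bmat, min_run,
                                               max_mismatch,
                                               max_breakpoints))
        else NULL
        if (!is.null(chim)) next
        bmat <- rbind(bmat, cons)
        full <- mat[amb[close_k][1L], ]
        full[col_map] <- cons
        basics_full_rows[[length(basics_full_rows) + 1L]] <- full
        promoted <- TRUE
        break
      }
    }
    if (!promoted) break
  }
  basics_full <- vapply(basics_full_rows, paste, "", collapse = "")
  if (is.null(variants))
    variants <- data.frame(clone_id = character(0), position = integer(0),
                           basic_state = character(0),
                           clone_state = character(0),
                           donor_basic = integer(0),
                           on_recombinant = logical(0))
  structure(list(individual_id = indiv, basics = basics_full,
                 basic_matrix = bmat, column_map = col_map,
                 support = support, assignments = assign_tab,
                 variants = variants, recombinants = recombinants,
                 n_sites = ncol(mat)),
            class = "basic_set")
}

#' @export
print.basic_set <- function(x, ...) {
  cat(sprintf("basic_set for individual %s: %d basic sequence(s)\n",
              x$individual_id, length(x$basics)))
  st <- table(factor(x$assignments$status,
                     c("assigned", "recombinant", "ambiguous")))
  cat(sprintf("  clones: %d assigned, %d recombinant, %d ambiguous\n",
              st[["assigned"]], st[["recombinant"]], st[["ambiguous"]]))
  cat(sprintf("  somatic variant candidates: %d\n", nrow(x$variants)))
  invisible(x)
}

#' Classify every individual in an alignment
#'
#' Splits the coding alignment by individual (for one source) and runs
#' [infer_basic_sequences] on each.
#'
#' @param aln A [clone_alignment]; the coding region is extracted if
#'   column classes are present.
#' @param source `"cDNA"` or `"gDNA"`.
#' @param ... Passed to [infer_basic_sequences].
#' @return Named list of `basic_set` objects.
#' @export
classify_individuals <- function(aln, source = "cDNA", ...) {
  cod <- if (!is.null(aln$classes)) extract_region(aln, "coding") else aln
  sel <- which(cod$info$source == source & !is.na(cod$info$individual))
  if (!length(sel)) stop(sprintf("no %s clones in alignment", source))
  inds <- unique(cod$info$individual[sel])
  out <- lapply(inds, function(iv) {
    rows <- sel[cod$info$individual[sel] == iv]
    sub <- subset_clones(cod, rows)
    infer_basic_sequences(sub, ...)
  })
  names(out) <- inds
  out
}

#' Somatic mutation rate per site
#'
#' rate = total somatic variant candidates / (clones x coding sites).
#' By default recombinant clones contribute both their residual variants
#' and their share of the denominator; with
#' `include_recombinants = FALSE` they are excluded from both. Ambiguous
#' clones are always excluded.
#'
#' @param classified List of `basic_set` objects (one per individual).
#' @param coding_sites Number of coding sites surveyed per clone.
#' @param include_recombinants Include recombinant clones.
#' @return List with `rate`, `numerator`, `denominator`, `n_clones`,
#'   `n_excluded`.
#' @export
somatic_mutation_rate <- function(classified, coding_sites,
                                  include_recombinants = TRUE) {
  if (!length(classified)) stop("empty input: no classified individuals")
  num <- 0L; ncl <- 0L; nexc <- 0L
  for (bs in classified) {
    a <- bs$assignments
    keep_status <- if (include_recombinants) c("assigned", "recombinant")
    else "assigned"
    ncl <- ncl + sum(a$status %in% keep_status)
    nexc <- nexc + sum(!a$status %in% keep_status)
    v <- bs$variants
    if (!include_recombinants) v <- v[!v$on_recombinant, , drop = FALSE]
    num <- num + nrow(v)
  }
  if (ncl == 0L) stop("empty input: no classified clones")
  den <- ncl * coding_sites
  list(rate = num / den, numerator = num, denominator = den,
       n_clones = ncl, n_excluded = nexc)
}

# probability that a clean splice of donors (a, b) with a uniform
# breakpoint is detectable: the breakpoint must leave at least min_run
# informative sites (over the full basic set: segment support can come
# from sites where the donors agree but another basic differs) on both
# sides, and at least one donor-differing site on each side (otherwise
# the splice equals a pure basic)
detectability_pair <- function(bmat, a, b, min_run = 2L) {
  acgt <- c("A", "C", "G", "T")
  inf <- which(apply(bmat, 2L, function(col)
    length(unique(col[col %in% acgt])) > 1L))
  pab <- which(bmat[a, ] != bmat[b, ] & bmat[a, ] %in% acgt &
                 bmat[b, ] %in% acgt)
  M <- length(inf)
  L <- ncol(bmat)
  if (M < 2L * min_run || length(pab) < 2L) return(0)
  lo <- max(inf[min_run], pab[1L])
  hi <- min(inf[M - min_run + 1L] - 1L, pab[length(pab)] - 1L)
  max(0L, hi - lo + 1L) / (L - 1L)
}

#' Per-individual recombinant fraction, mean and standard error
#'
#' Per individual: recombinant clones / classified clones (assigned +
#' recombinant). The mean is taken over individuals, SE = sd / sqrt(k).
#' With `correct_detectability = TRUE` each individual's fraction is
#' divided by the probability that a recombinant with a uniform
#' breakpoint between two of its basic sequences (support-weighted donor
#' pairs) leaves at least `min_run` informative sites on both sides.
#'
#' @param classified List of `basic_set` objects.
#' @param correct_detectability Apply the detectability correction.
#' @param min_run Segment-support threshold used in detection.
#' @return List with `mean`, `se`, `fractions`, and `detect_prob` when
#'   corrected.
#' @export
recombination_rate <- function(classified, correct_detectability = FALSE,
                               min_run = 2L) {
  if (!length(classified)) stop("empty input")
  fr <- vapply(classified, function(bs) {
    a <- bs$assignments
    n <- sum(a$status %in% c("assigned", "recombinant"))
    if (n == 0L) return(NA_real_)
    sum(a$status == "recombinant") / n
  }, 0)
  detp <- NULL
  if (correct_detectability) {
    # weight donor pairs by basic support (support tracks gene-copy
    # multiplicity in expectation); ambiguous clones estimate the mass
    # of germline copies that were never recovered — a recombinant
    # sourced from or donated by such a copy is undetectable, so that
    # mass enters the weights with detectability zero
    detp <- vapply(classified, function(bs) {
      nb <- length(bs$basics)
      if (nb < 2L) return(NA_real_)
      s <- pmax(bs$support, 1L)
      amb <- sum(bs$assignments$status == "ambiguous")
      tot <- 0
      for (a in seq_len(nb)) for (b in seq_len(nb)) {
        if (a == b) next
        w <- (s[a] / (sum(s) + amb)) * (s[b] / (sum(s[-a]) + amb))
        tot <- tot + w * detectability_pair(bs$basic_matrix, a, b, min_run)
      }
      tot
    }, 0)
    ntot <- vapply(classified, function(bs) nrow(bs$assignments), 0L)
    nrec <- vapply(classified, function(bs)
      sum(bs$assignments$status == "recombinant"), 0L)
    ok <- !is.na(detp) & detp > 0
    fr[ok] <- (nrec[ok] / ntot[ok]) / detp[ok]
  }
  fr_ok <- fr[!is.na(fr)]
  k <- length(fr_ok)
  list(mean = mean(fr_ok),
       se = if (k > 1L) sd(fr_ok) / sqrt(k) else 0,
       fractions = fr, detect_prob = detp)
}

#' Annotate somatic variant candidates with occurrence, effect and domain
#'
#' Occurrence is computed sample-wide: a variant at a coding column that
#' is already variable among the basic sequences of all individuals is a
#' `recurrent_site` variant; otherwise it is a `singleton`. Effect is the
#' codon-level consequence of the single substitution against the
#' assigned basic sequence; domain follows the peptide partition.
#'
#' @param classified List of `basic_set` objects (same coding frame).
#' @param partition Domain partition.
#' @return Data frame of all variants with `individual`, `occurrence`,
#'   `effect`, `domain` columns added (positions 0-based).
#' @export
annotate_variants <- function(classified, partition = default_partition()) {
  all_basics <- unique(unlist(lapply(classified, `[[`, "basics")))
  bmat <- t(vapply(all_basics, function(s) strsplit(s, "")[[1L]],
                   character(nchar(all_basics[1L]))))
  variable_cols <- which(apply(bmat, 2L, function(col)
    length(unique(col[col %in% c("A", "C", "G", "T")])) > 1L)) - 1L
  out <- NULL
  for (nm in names(classified)) {
    bs <- classified[[nm]]
    v <- bs$variants
    if (!nrow(v)) next
    v$individual <- if (!is.na(bs$individual_id)) bs$individual_id else nm
    v$occurrence <- ifelse(v$position %in% variable_cols,
                           "recurrent_site", "singleton")
    v$domain <- domain_of(v$position, partition)
    v$effect <- NA_character_
    for (r in seq_len(nrow(v))) {
      basic_seq <- strsplit(bs$basics[v$donor_basic[r]], "")[[1L]]
      pos0 <- v$position[r]
      cod_i <- pos0 %/% 3L
      within <- pos0 %% 3L
      ref_codon <- paste(basic_seq[(3L * cod_i + 1L):(3L * cod_i + 3L)],
                         collapse = "")
      alt <- strsplit(ref_codon, "")[[1L]]
      alt[within + 1L] <- v$clone_state[r]
      v$effect[r] <- classify_codon_change(ref_codon,
                                           paste(alt, collapse = ""))
    }
    out <- rbind(out, v)
  }
  if (is.null(out))
    out <- data.frame(clone_id = character(0), position = integer(0),
                      basic_state = character(0), clone_state = character(0),
                      on_recombinant = logical(0), individual = character(0),
                      occurrence = character(0), domain = character(0),
                      effect = character(0))
  rownames(out) <- NULL
  out
}

#' Domain profile of somatic mutation
#'
#' Per domain: substitution events per domain site, distinct mutated
#' positions, and the nonsynonymous fraction; the overall nonsynonymous
#' fraction is attached as attribute `overall_nonsyn`.
#'
#' @param variants Annotated variant table from [annotate_variants].
#' @param partition Domain partition.
#' @return Data frame, one row per domain.
#' @export
domain_mutation_profile <- function(variants,
                                    partition = default_partition()) {
  doms <- names(partition)
  lens <- vapply(partition, function(iv) iv[2L] - iv[1L], 0L)
  if (nrow(variants) &&
      any(variants$position < 0L |
            variants$position >= sum(lens)))
    stop("consistency error: variant outside the coding region")
  out <- data.frame(domain = doms, length = as.integer(lens),
                    n_events = 0L, n_sites = 0L, proportion = 0,
                    nonsyn_fraction = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(doms)) {
    v <- variants[variants$domain == doms[i], , drop = FALSE]
    out$n_events[i] <- nrow(v)
    out$n_sites[i] <- length(unique(v$position))
    out$proportion[i] <- nrow(v) / lens[i]
    det <- v$effect %in% c("synonymous", "nonsynonymous")
    if (any(det))
      out$nonsyn_fraction[i] <- mean(v$effect[det] == "nonsynonymous")
  }
  det <- variants$effect %in% c("synonymous", "nonsynonymous")
  attr(out, "overall_nonsyn") <- if (any(det))
    mean(variants$effect[det] == "nonsynonymous") else NA_real_
  out
}

#' Cross-check cDNA and gDNA classifications of one individual
#'
#' Compares basic sequences (exact match over shared coding columns) and
#' somatic variant candidates (position + state) between the cDNA and
#' gDNA classification of the same individual.
#'
#' @param cdna_basics,gdna_basics `basic_set` objects for one individual.
#' @return List with matched basic pairs, private basics per side, and
#'   shared/private variant counts.
#' @export
crosscheck_gdna_cdna <- function(cdna_basics, gdna_basics) {
  if (!identical(cdna_basics$individual_id, gdna_basics$individual_id))
    stop("identity error: basic sets are from different individuals")
  cb <- cdna_basics$basics; gb <- gdna_basics$basics
  matched <- NULL
  for (i in seq_along(cb)) {
    j <- match(cb[i], gb)
    if (!is.na(j)) matched <- rbind(matched, c(cdna = i, gdna = j))
  }
  key <- function(v) paste(v$position, v$clone_state)
  cv <- key(cdna_basics$variants); gv <- key(gdna_basics$variants)
  list(individual = cdna_basics$individual_id,
       matched = matched,
       cdna_only = setdiff(seq_along(cb),
                           if (is.null(matched)) integer(0) else matched[, 1L]),
       gdna_only = setdiff(seq_along(gb),
                           if (is.null(matched)) integer(0) else matched[, 2L]),
       shared_variants = length(intersect(cv, gv)),
       cdna_private_variants = length(setdiff(cv, gv)),
       gdna_private_variants = length(setdiff(gv, cv)))
}
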