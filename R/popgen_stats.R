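as_site_matrix <- function(x) {
  if (inherits(x, "clone_alignment")) x$mat
  else if (is.matrix(x) && is.character(x)) x
  else stop("expected a clone_alignment or character matrix")
}

site_states <- function(col) {
  tab <- table(col[col %in% c("A", "C", "G", "T")])
  tab[tab > 0L]
}

#' Harmonic-number constants used by theta and the neutrality tests
#'
#' @param n Sample size.
#' @return `a1` = sum of 1/i for i in 1..(n-1).
#' @export
harmonic_a1 <- function(n) sum(1 / seq_len(n - 1L))

#' Count segregating, singleton and parsimony-informative sites
#'
#' A site is segregating when at least two nucleotide states occur among
#' the sequences that are not gap/N there; it is parsimony-informative
#' when at least two states each occur at least twice, and a singleton
#' site otherwise. `eta` counts total mutations as (states - 1) summed
#' over sites.
#'
#' @param aln A [clone_alignment] or character matrix.
#' @return List with `S`, `singletons`, `parsimony_informative`, `eta`,
#'   and `sites` (0-based positions of segregating sites).
#' @export
segregating_sites <- function(aln) {
  mat <- as_site_matrix(aln)
  if (nrow(mat) < 2L) stop("insufficient data: need at least 2 sequences")
  S <- 0L; singletons <- 0L; informative <- 0L; eta <- 0L
  segsites <- integer(0)
  for (j in seq_len(ncol(mat))) {
    tab <- site_states(mat[, j])
    if (length(tab) >= 2L) {
      S <- S + 1L
      eta <- eta + length(tab) - 1L
      segsites <- c(segsites, j - 1L)
      if (sum(tab >= 2L) >= 2L) informative <- informative + 1L
      else singletons <- singletons + 1L
    }
  }
  list(S = S, singletons = singletons, parsimony_informative = informative,
       eta = eta, sites = segsites)
}

#' Watterson's per-site theta
#'
#' theta_W = (S / L) / a1 with a1 the (n-1)-th harmonic number.
#'
#' @param S Number of segregating sites.
#' @param n Number of sequences.
#' @param L Number of sites surveyed.
#' @return Per-site theta_W.
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2L) stop("insufficient data: need at least 2 sequences")
  if (L < 1L) stop("L must be positive")
  (S / L) / harmonic_a1(n)
}

pairwise_diff_total <- function(mat, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  n <- nrow(mat)
  miss <- !(mat %in% c("A", "C", "G", "T"))
  dim(miss) <- dim(mat)
  if (deletion == "complete") {
    keep <- colSums(miss) == 0L
    mat <- mat[, keep, drop = FALSE]
    L <- ncol(mat)
    tot <- 0
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      tot <- tot + sum(mat[i, ] != mat[j, ])
    list(mean_diff = tot / choose(n, 2L), L = L,
         per_site = if (L > 0L) tot / choose(n, 2L) / L else 0)
  } else {
    dsum <- 0; persite <- 0; npairs <- choose(n, 2L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ok <- !miss[i, ] & !miss[j, ]
      d <- sum(mat[i, ok] != mat[j, ok])
      dsum <- dsum + d
      persite <- persite + if (any(ok)) d / sum(ok) else 0
    }
    list(mean_diff = dsum / npairs, L = ncol(mat),
         per_site = persite / npairs)
  }
}

#' Per-site nucleotide diversity (pi)
#'
#' Average pairwise Hamming distance per site. Under the default complete
#' deletion, columns with any gap or N are dropped before comparison;
#' under pairwise deletion each pair is compared over its mutually
#' resolved sites and the per-pair per-site values are averaged.
#'
#' @param aln A [clone_alignment] or character matrix.
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @return Per-site pi.
#' @export
nucleotide_diversity_pi <- function(aln, deletion = c("complete", "pairwise")) {
  mat <- as_site_matrix(aln)
  if (nrow(mat) < 2L) stop("insufficient data: need at least 2 sequences")
  pairwise_diff_total(mat, deletion)$per_site
}

#' Haplotype diversity with small-sample correction
#'
#' Hd = n/(n-1) (1 - sum p_i^2) over exact-match haplotype frequencies.
#'
#' @param aln A [clone_alignment].
#' @return Hd in `[0, 1]`.
#' @export
haplotype_diversity <- function(aln) {
  mat <- as_site_matrix(aln)
  n <- nrow(mat)
  if (n < 2L) stop("insufficient data: need at least 2 sequences")
  if (!inherits(aln, "clone_alignment")) {
    ids <- rownames(mat)
    if (is.null(ids)) ids <- paste0("s", seq_len(n))
    rownames(mat) <- ids
    info <- data.frame(id = ids, individual = NA, clone = NA, source = NA)
    aln <- clone_alignment(mat, info, ids[1L])
  }
  haps <- collapse_haplotypes(aln)
  p <- haps$count / sum(haps$count)
  n <- sum(haps$count)
  n / (n - 1) * (1 - sum(p^2))
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Tajima's D from summary quantities
#'
#' D = (pi_total - S/a1) / sqrt(e1 S + e2 S (S-1)), with pi_total the
#' average number of pairwise differences (not per site).
#'
#' @param S Segregating sites.
#' @param n Sample size.
#' @param pi_total Mean pairwise difference count.
#' @return D, or `NA` (flagged via attribute `defined`) when S = 0.
#' @export
tajimas_d <- function(S, n, pi_total) {
  if (n < 2L) stop("insufficient data: need at least 2 sequences")
  if (S == 0L)
    return(structure(NA_real_, defined = FALSE))
  k <- tajima_constants(n)
  d <- (pi_total - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  structure(d, defined = TRUE)
}

#' Tajima's D for an alignment
#'
#' @param aln A [clone_alignment] or character matrix.
#' @param deletion Deletion policy passed to the pairwise comparison.
#' @return D with attribute `defined`.
#' @export
tajimas_d_aln <- function(aln, deletion = "complete") {
  mat <- as_site_matrix(aln)
  ss <- segregating_sites(mat)
  pd <- pairwise_diff_total(mat, deletion)
  tajimas_d(ss$S, nrow(mat), pd$mean_diff)
}

fu_li_constants <- function(n) {
  an <- sum(1 / seq_len(n - 1L))
  bn <- sum(1 / seq_len(n - 1L)^2)
  an1 <- an + 1 / n
  cn <- if (n == 2L) 1 else 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- 1 + (an^2 / (bn + an^2)) * (cn - (n + 1) / (n - 1))
  uD <- an - 1 - vD
  vDs <- ((n / (n - 1))^2 * bn + an^2 * dn -
            2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  uDs <- (n / (n - 1)) * (an - n / (n - 1)) - vDs
  list(an = an, bn = bn, cn = cn, dn = dn,
       uD = uD, vD = vD, uDs = uDs, vDs = vDs)
}

#' Fu and Li's D statistics
#'
#' The star variant D* needs no outgroup and contrasts total mutations
#' (eta) with singleton mutations (eta_s). The outgroup variant polarizes
#' mutations with an outgroup sequence and contrasts eta with external
#' (derived-singleton) mutations.
#'
#' @param aln A [clone_alignment] or character matrix (ingroup only).
#' @param variant `"star"` (default) or `"outgroup"`.
#' @param outgroup Character vector (one sequence, same width) required
#'   for the outgroup variant.
#' @return The statistic, with attribute `defined` (FALSE when eta = 0).
#' @export
fu_li_d <- function(aln, variant = c("star", "outgroup"), outgroup = NULL) {
  variant <- match.arg(variant)
  mat <- as_site_matrix(aln)
  n <- nrow(mat)
  if (n < 3L) stop("insufficient data: need at least 3 sequences")
  k <- fu_li_constants(n)
  eta <- 0L; eta_s <- 0L; eta_e <- 0L
  if (variant == "outgroup") {
    if (is.null(outgroup)) stop("outgroup variant requires an outgroup sequence")
    if (is.character(outgroup) && length(outgroup) == 1L)
      outgroup <- strsplit(outgroup, "")[[1L]]
    if (length(outgroup) != ncol(mat))
      stop("outgroup length must match alignment width")
  }
  for (j in seq_len(ncol(mat))) {
    tab <- site_states(mat[, j])
    if (length(tab) < 2L) next
    eta <- eta + length(tab) - 1L
    eta_s <- eta_s + sum(tab == 1L)
    if (variant == "outgroup") {
      anc <- outgroup[j]
      if (anc %in% names(tab))
        eta_e <- eta_e + sum(tab == 1L & names(tab) != anc)
    }
  }
  if (eta == 0L) return(structure(NA_real_, defined = FALSE))
  d <- if (variant == "star")
    ((n / (n - 1)) * eta - k$an * eta_s) /
      sqrt(k$uDs * eta + k$vDs * eta^2)
  else
    (eta - k$an * eta_e) / sqrt(k$uD * eta + k$vD * eta^2)
  structure(d, defined = TRUE)
}

biallelic_sites <- function(mat) {
  keep <- integer(0); alleles <- list()
  for (j in seq_len(ncol(mat))) {
    tab <- site_states(mat[, j])
    if (length(tab) == 2L) {
      keep <- c(keep, j)
      alleles[[length(alleles) + 1L]] <- names(tab)
    }
  }
  list(cols = keep, alleles = alleles)
}

four_gametes <- function(x, y) {
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  length(unique(paste(x[ok], y[ok]))) == 4L
}

#' Hudson-Kaplan minimum number of recombination events (Rm)
#'
#' Applies the four-gamete test to all pairs of biallelic segregating
#' sites and reduces the incompatible intervals to a maximal set of
#' non-overlapping intervals; its size is the minimum number of
#' recombination events needed to explain the sample.
#'
#' @param aln A [clone_alignment] or character matrix.
#' @return List with `rm` and `intervals` (matrix of 0-based site
#'   position pairs bounding each required event).
#' @export
hudson_kaplan_rm <- function(aln) {
  mat <- as_site_matrix(aln)
  ba <- biallelic_sites(mat)
  cols <- ba$cols
  m <- length(cols)
  ivs <- NULL
  if (m >= 2L) {
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      if (four_gametes(mat[, cols[i]], mat[, cols[j]]))
        ivs <- rbind(ivs, c(cols[i] - 1L, cols[j] - 1L))
    }
  }
  if (is.null(ivs))
    return(list(rm = 0L, intervals = matrix(integer(0), ncol = 2L)))
  # drop intervals that strictly contain another incompatible interval
  minimal <- rep(TRUE, nrow(ivs))
  for (i in seq_len(nrow(ivs))) for (j in seq_len(nrow(ivs))) {
    if (i != j && ivs[j, 1L] >= ivs[i, 1L] && ivs[j, 2L] <= ivs[i, 2L] &&
        (ivs[j, 1L] > ivs[i, 1L] || ivs[j, 2L] < ivs[i, 2L]))
      minimal[i] <- FALSE
  }
  ivs <- ivs[minimal, , drop = FALSE]
  ivs <- ivs[order(ivs[, 2L], ivs[, 1L]), , drop = FALSE]
  chosen <- NULL; last_end <- -Inf
  for (r in seq_len(nrow(ivs))) {
    if (ivs[r, 1L] >= last_end) {
      chosen <- rbind(chosen, ivs[r, ])
      last_end <- ivs[r, 2L]
    }
  }
  list(rm = nrow(chosen), intervals = chosen)
}

ng86_cache <- new.env(parent = emptyenv())

ng86_codon_syn_sites <- function(codon) {
  hit <- ng86_cache[[paste0("s_", codon)]]
  if (!is.null(hit)) return(hit)
  bases <- c("A", "C", "G", "T")
  cv <- strsplit(codon, "")[[1L]]
  aa <- translate_codon(codon)
  if (is.na(aa) || aa == "*") {
    ng86_cache[[paste0("s_", codon)]] <- NA_real_
    return(NA_real_)
  }
  s <- 0
  for (p in 1:3) for (b in setdiff(bases, cv[p])) {
    alt <- cv; alt[p] <- b
    alt_aa <- translate_codon(paste(alt, collapse = ""))
    if (!is.na(alt_aa) && alt_aa != "*" && alt_aa == aa) s <- s + 1 / 3
  }
  ng86_cache[[paste0("s_", codon)]] <- s
  s
}

ng86_path_counts <- function(c1, c2) {
  key <- paste0("p_", c1, c2)
  hit <- ng86_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- ng86_path_counts_raw(c1, c2)
  ng86_cache[[key]] <- res
  res
}

ng86_path_counts_raw <- function(c1, c2) {
  v1 <- strsplit(c1, "")[[1L]]; v2 <- strsplit(c2, "")[[1L]]
  diffpos <- which(v1 != v2)
  k <- length(diffpos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- if (k == 1L) list(diffpos)
  else if (k == 2L) list(diffpos, rev(diffpos))
  else {
    idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    lapply(idx, function(o) diffpos[o])
  }
  tally <- NULL
  for (path in perms) {
    cur <- v1; sd <- 0; nd <- 0; blocked <- FALSE
    for (p in path) {
      nxt <- cur; nxt[p] <- v2[p]
      aa1 <- translate_codon(paste(cur, collapse = ""))
      aa2 <- translate_codon(paste(nxt, collapse = ""))
      if (is.na(aa1) || is.na(aa2) || aa2 == "*" || aa1 == "*") {
        blocked <- TRUE; break
      }
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (!blocked) tally <- rbind(tally, c(sd, nd))
  }
  if (is.null(tally)) return(c(sd = k / 2, nd = k / 2))
  c(sd = mean(tally[, 1L]), nd = mean(tally[, 2L]))
}

#' Nei-Gojobori (1986) counting Ka/Ks with Jukes-Cantor correction
#'
#' Pathway-counting estimate of synonymous (Ks) and nonsynonymous (Ka)
#' substitution rates averaged over all sequence pairs. Codons containing
#' gaps or N in either member of a pair are skipped. omega = Ka/Ks is
#' flagged undefined when Ks is zero.
#'
#' @param aln A [clone_alignment] or character matrix, codon-aligned.
#' @return List with `ka`, `ks`, `omega`, `defined`, `n_pairs`.
#' @export
ng86_kaks <- function(aln) {
  mat <- as_site_matrix(aln)
  if (ncol(mat) %% 3L != 0L)
    stop("frame error: alignment length must be divisible by 3")
  n <- nrow(mat)
  if (n < 2L) stop("insufficient data: need at least 2 sequences")
  ncod <- ncol(mat) %/% 3L
  # collapse to unique sequences: identical pairs contribute zero
  # distance but still count toward the pair average
  seqs <- apply(mat, 1L, paste, collapse = "")
  tab <- table(seqs)
  uh <- names(tab); cnt <- as.integer(tab)
  codons <- lapply(uh, function(s)
    substring(s, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod)))
  npairs_total <- n * (n - 1L) / 2L
  ka_sum <- 0; ks_sum <- 0; npairs_used <- 0
  nu <- length(uh)
  pair_iter <- if (nu >= 2L) combn(nu, 2L, simplify = FALSE) else list()
  for (pr in pair_iter) {
    i <- pr[1L]; j <- pr[2L]
    Ssites <- 0; Nsites <- 0; sdiff <- 0; ndiff <- 0
    for (c in seq_len(ncod)) {
      c1 <- codons[[i]][c]; c2 <- codons[[j]][c]
      s1 <- ng86_codon_syn_sites(c1); s2 <- ng86_codon_syn_sites(c2)
      if (is.na(s1) || is.na(s2)) next
      Ssites <- Ssites + (s1 + s2) / 2
      Nsites <- Nsites + 3 - (s1 + s2) / 2
      if (c1 != c2) {
        pc <- ng86_path_counts(c1, c2)
        sdiff <- sdiff + pc[["sd"]]; ndiff <- ndiff + pc[["nd"]]
      }
    }
    if (Ssites + Nsites == 0) next
    ps <- if (Ssites > 0) sdiff / Ssites else 0
    pn <- if (Nsites > 0) ndiff / Nsites else 0
    jc <- function(p) if (p < 0.75) -3 / 4 * log(1 - 4 * p / 3) else NaN
    w <- cnt[i] * cnt[j]
    ks_sum <- ks_sum + w * jc(ps)
    ka_sum <- ka_sum + w * jc(pn)
    npairs_used <- npairs_used + w
  }
  # identical-sequence pairs add zero distance
  ka <- ka_sum / npairs_total; ks <- ks_sum / npairs_total
  defined <- is.finite(ks) && ks > 0 && is.finite(ka)
  list(ka = ka, ks = ks, omega = if (defined) ka / ks else NA_real_,
       defined = defined, n_pairs = npairs_total)
}

#' Full diversity summary for one alignment region
#'
#' Computes the row of a diversity table: n, sites, S (singletons,
#' parsimony-informative), eta, pi, Watterson's theta, haplotype
#' diversity, Tajima's D, Fu and Li's D* and Hudson-Kaplan Rm, plus the
#' Nei-Gojobori omega when the region is in frame.
#'
#' @param aln A [clone_alignment] or character matrix for one region.
#' @param region Label carried into the output.
#' @param deletion Deletion policy for pi.
#' @param kaks Compute omega (needs in-frame codon alignment).
#' @return One-row data frame.
#' @export
diversity_stats <- function(aln, region = "all", deletion = "complete",
                            kaks = FALSE) {
  mat <- as_site_matrix(aln)
  ss <- segregating_sites(mat)
  pd <- pairwise_diff_total(mat, deletion)
  td <- tajimas_d(ss$S, nrow(mat), pd$mean_diff)
  fl <- fu_li_d(mat, "star")
  hd <- haplotype_diversity(if (inherits(aln, "clone_alignment")) aln else mat)
  rm_ <- hudson_kaplan_rm(mat)$rm
  om <- if (kaks && ncol(mat) %% 3L == 0L) ng86_kaks(mat)$omega else NA_real_
  data.frame(region = region, n = nrow(mat), sites = ncol(mat),
             S = ss$S, singletons = ss$singletons,
             informative = ss$parsimony_informative, eta = ss$eta,
             pi = pd$per_site,
             theta_w = watterson_theta(ss$S, nrow(mat), ncol(mat)),
             hd = hd,
             tajima_d = as.numeric(td), fu_li_d = as.numeric(fl),
             rm = rm_, omega = om, stringsAsFactors = FALSE)
}
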