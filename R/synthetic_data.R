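# Codons from which single-nucleotide changes can never create a stop,
# so simulated reading frames stay open under any point mutation.
SAFE_CODONS <- c("GCT", "GCC", "GGT", "GGC", "ACT", "ACC", "GTT", "GTC",
                 "CCT", "CCA", "CTC", "ATC", "AAC", "GAC", "TTC", "CGT")

#' Simulation configuration
#'
#' Defaults encode the study conditions the package is designed around:
#' two tandem gene copies per haplotype, a germline pool of 3 divergent
#' coding sequences, a 300-nt coding region partitioned 60/120/120, a
#' somatic point-mutation rate of 1.1e-3 per site with domain weighting
#' (C-terminal > signal > mature), a per-clone recombination probability
#' of 0.06, and intron size alleles centred on the major fragment modes
#' (intron 1: 184/221/376; intron 2: 199-200/210-211).
#'
#' @param seed Integer seed; fully determines all output.
#' @param n_individuals,clones_per_individual Sampling design.
#' @param n_loci Gene copies per haplotype.
#' @param coding_length Coding sites (multiple of 3).
#' @param k_clades,clade_divergence Germline pool size and the number of
#'   fixed differences separating each clade from the ancestor.
#' @param mu_somatic Somatic point mutations per site per clone.
#' @param domain_weights Relative per-site mutation weight of the signal,
#'   mature and C-terminal domains.
#' @param rho_recomb Per-clone probability of a somatic recombination.
#' @param intron_size_modes Per-intron named numeric vectors of allele
#'   frequencies (names are sizes in bp).
#' @param family_offspring Offspring per simulated cross.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_individuals = 10L,
                       clones_per_individual = 10L, n_loci = 2L,
                       coding_length = 300L, k_clades = 3L,
                       clade_divergence = 15L, mu_somatic = 1.1e-3,
                       domain_weights = c(signal = 0.083, mature = 0.058,
                                          cterm = 0.150),
                       rho_recomb = 0.06,
                       intron_size_modes = list(
                         "1" = c("184" = 0.35, "221" = 0.40, "376" = 0.25),
                         "2" = c("199" = 0.30, "200" = 0.20, "210" = 0.30,
                                 "211" = 0.20)),
                       family_offspring = 20L) {
  stopifnot(coding_length %% 3L == 0L, mu_somatic >= 0, mu_somatic <= 1,
            rho_recomb >= 0, rho_recomb <= 1, all(domain_weights >= 0))
  for (m in intron_size_modes)
    stopifnot(all(as.integer(names(m)) > 0L), abs(sum(m) - 1) < 1e-9)
  structure(list(seed = as.integer(seed), n_individuals = n_individuals,
                 clones_per_individual = clones_per_individual,
                 n_loci = n_loci, coding_length = coding_length,
                 k_clades = k_clades, clade_divergence = clade_divergence,
                 mu_somatic = mu_somatic, domain_weights = domain_weights,
                 rho_recomb = rho_recomb,
                 intron_size_modes = intron_size_modes,
                 family_offspring = family_offspring),
            class = "sim_config")
}

random_coding_seq <- function(length) {
  paste(sample(SAFE_CODONS, length %/% 3L, replace = TRUE), collapse = "")
}

mutate_at <- function(seq_vec, pos, avoid = NULL) {
  cur <- seq_vec[pos]
  alts <- setdiff(c("A", "C", "G", "T"), c(cur, avoid))
  seq_vec[pos] <- sample(alts, 1L)
  seq_vec
}

#' Simulate a germline pool of divergent basic sequences
#'
#' Generates `k_clades` coding sequences from a random ancestor, each
#' clade carrying `clade_divergence` fixed differences at clade-private
#' positions (so all pairwise distances are at least twice the per-clade
#' divergence... at least `clade_divergence`).
#'
#' @param config A [sim_config]. The caller controls the RNG state.
#' @return List with `ancestor`, `pool` (character vector of coding
#'   sequences) and `clade_sites` (1-based positions per clade).
#' @export
simulate_germline_pool <- function(config) {
  L <- config$coding_length
  k <- config$k_clades
  d <- config$clade_divergence
  if (k * d > L) stop("config error: divergence too large for sequence length")
  anc <- strsplit(random_coding_seq(L), "")[[1L]]
  sites <- sample(L, k * d)
  pool <- character(k)
  clade_sites <- vector("list", k)
  for (i in seq_len(k)) {
    s <- anc
    my <- sites[((i - 1L) * d + 1L):(i * d)]
    for (p in my) s <- mutate_at(s, p)
    pool[i] <- paste(s, collapse = "")
    clade_sites[[i]] <- sort(my)
  }
  list(ancestor = paste(anc, collapse = ""), pool = pool,
       clade_sites = clade_sites)
}

draw_haplotype <- function(config, pool) {
  genes <- sample(length(pool), config$n_loci, replace = TRUE)
  introns <- lapply(config$intron_size_modes, function(m)
    as.integer(names(m))[sample(length(m), config$n_loci, replace = TRUE,
                                prob = m)])
  list(genes = genes, introns = introns)
}

site_weights <- function(config) {
  # the 60/120/120 partition scaled to the configured coding length
  L <- config$coding_length
  part <- default_partition(c(0L, round(L * 0.2)),
                            c(round(L * 0.2), round(L * 0.6)),
                            c(round(L * 0.6), L))
  w <- numeric(L)
  for (d in names(part)) {
    iv <- part[[d]]
    w[(iv[1L] + 1L):iv[2L]] <- config$domain_weights[[d]]
  }
  w / sum(w)
}

#' Simulate the clones of one individual with full ground truth
#'
#' Each clone transcribes one germline gene copy picked uniformly; with
#' probability `rho_recomb` its suffix from a uniform breakpoint is
#' replaced by the corresponding suffix of a different-sequence germline
#' copy (if the individual carries none, no recombination can occur);
#' Poisson(`mu_somatic` x L) point mutations are then superimposed at
#' positions drawn with the domain weights.
#'
#' @param germline List of two haplotypes from [draw_haplotype].
#' @param config A [sim_config]; caller controls the RNG state.
#' @param individual_id Label used for clone ids.
#' @param pool Germline pool sequences.
#' @return List with `clones` (named character vector) and `truth` (data
#'   frame: source copy, recombination breakpoint/donor, mutation
#'   positions).
#' @export
simulate_individual_clones <- function(germline, config, individual_id,
                                       pool) {
  copies <- c(pool[germline[[1L]]$genes], pool[germline[[2L]]$genes])
  L <- config$coding_length
  w <- site_weights(config)
  ncl <- config$clones_per_individual
  clones <- character(ncl)
  truth <- vector("list", ncl)
  for (i in seq_len(ncl)) {
    src <- sample(length(copies), 1L)
    s <- strsplit(copies[src], "")[[1L]]
    donor <- NA_integer_; bp <- NA_integer_
    if (runif(1L) < config$rho_recomb) {
      others <- which(copies != copies[src])
      if (length(others)) {
        donor <- if (length(others) == 1L) others else sample(others, 1L)
        bp <- sample(L - 1L, 1L)  # suffix starts at bp + 1
        s[(bp + 1L):L] <- strsplit(copies[donor], "")[[1L]][(bp + 1L):L]
      }
    }
    nmut <- rpois(1L, config$mu_somatic * L)
    mpos <- if (nmut > 0L) sample(L, min(nmut, L), prob = w) else integer(0)
    for (p in mpos) s <- mutate_at(s, p)
    clones[i] <- paste(s, collapse = "")
    truth[[i]] <- list(source_copy = src, donor_copy = donor,
                       breakpoint = bp, mutations = sort(mpos))
  }
  names(clones) <- sprintf("%s_%02d_cDNA", individual_id, seq_len(ncl))
  names(truth) <- names(clones)
  list(clones = clones, truth = truth)
}

#' Simulate a full clone dataset across individuals
#'
#' @param config A [sim_config]; `config$seed` is applied on entry.
#' @return List with `alignment` (coding [clone_alignment] of all clones
#'   plus the germline-pool ancestor as reference), `germlines`, `pool`,
#'   and per-clone `truth`.
#' @export
simulate_dataset <- function(config) {
  set.seed(config$seed)
  gp <- simulate_germline_pool(config)
  germlines <- list(); clones <- character(0); truth <- list()
  for (iv in seq_len(config$n_individuals)) {
    id <- sprintf("i%02d", iv)
    g <- list(draw_haplotype(config, gp$pool),
              draw_haplotype(config, gp$pool))
    germlines[[id]] <- g
    sim <- simulate_individual_clones(g, config, id, gp$pool)
    clones <- c(clones, sim$clones)
    truth <- c(truth, sim$truth)
  }
  seqs <- c(clones, ref_coding = gp$ancestor)
  mat <- t(vapply(seqs, function(s) strsplit(s, "")[[1L]],
                  character(config$coding_length)))
  info <- parse_clone_headers(rownames(mat), "ref_coding")
  aln <- clone_alignment(mat, info, "ref_coding")
  list(alignment = aln, germlines = germlines, pool = gp$pool,
       ancestor = gp$ancestor, truth = truth, config = config)
}

#' Rebuild a clone from its recorded ground truth
#'
#' Replays the recorded source copy, recombination and mutation events;
#' used to verify that emitted sequences and truth are consistent.
#'
#' @param germline The individual's two haplotypes.
#' @param pool Germline pool.
#' @param tr One truth record.
#' @param clone_emitted The emitted clone sequence.
#' @return TRUE when the replay reproduces the clone exactly (mutated
#'   states are checked as differences at exactly the recorded
#'   positions).
#' @export
replay_truth <- function(germline, pool, tr, clone_emitted) {
  copies <- c(pool[germline[[1L]]$genes], pool[germline[[2L]]$genes])
  s <- strsplit(copies[tr$source_copy], "")[[1L]]
  if (!is.na(tr$breakpoint)) {
    L <- length(s)
    s[(tr$breakpoint + 1L):L] <-
      strsplit(copies[tr$donor_copy], "")[[1L]][(tr$breakpoint + 1L):L]
  }
  e <- strsplit(clone_emitted, "")[[1L]]
  diffs <- which(s != e)
  identical(sort(diffs), as.integer(tr$mutations))
}

#' Simulate a population of intron peak genotypes
#'
#' Each diploid individual carries two haplotypes of `n_loci` genes whose
#' intron sizes are drawn independently from the mode frequencies; the
#' observed genotype is the set of distinct sizes (up to `2 * n_loci`
#' peaks).
#'
#' @param config A [sim_config]; `config$seed` is applied on entry.
#' @param n_individuals Number of individuals (default from config).
#' @return Named list of [population_sample] objects, one per intron,
#'   with attribute `truth` (the underlying haplotypes).
#' @export
simulate_population_peaks <- function(config,
                                      n_individuals = config$n_individuals) {
  set.seed(config$seed)
  haps <- lapply(seq_len(n_individuals), function(i)
    list(draw_haplotype(config, rep("x", config$k_clades)),
         draw_haplotype(config, rep("x", config$k_clades))))
  out <- list()
  for (intr in names(config$intron_size_modes)) {
    gt <- lapply(haps, function(h)
      sort(unique(c(h[[1L]]$introns[[intr]], h[[2L]]$introns[[intr]]))))
    names(gt) <- sprintf("i%03d", seq_len(n_individuals))
    out[[intr]] <- population_sample(gt, name = "sim", intron = intr)
  }
  attr(out, "truth") <- haps
  out
}

#' Simulate a full-sib family cross
#'
#' Each offspring receives one haplotype per parent; with probability
#' `rec_fraction` a meiotic recombination between the tandem copies swaps
#' the second gene between the parent's two haplotypes before
#' transmission (0 by default: tandem copies co-transmit as a Mendelian
#' unit).
#'
#' @param config A [sim_config]; caller controls the RNG state.
#' @param father,mother Parental germlines (two [draw_haplotype]s each).
#' @param rec_fraction Recombination fraction between the tandem copies.
#' @return List with a [family_cross] and per-offspring `truth`.
#' @export
simulate_family <- function(config, father, mother, rec_fraction = 0) {
  n <- config$family_offspring
  gamete <- function(parent) {
    pick <- sample(2L, 1L)
    hap <- parent[[pick]]
    rec <- runif(1L) < rec_fraction
    if (rec) {
      other <- parent[[3L - pick]]
      hap$genes[config$n_loci] <- other$genes[config$n_loci]
      for (intr in names(hap$introns))
        hap$introns[[intr]][config$n_loci] <-
          other$introns[[intr]][config$n_loci]
    }
    list(hap = hap, pick = pick, recombined = rec)
  }
  rows <- NULL
  truth <- list()
  add_member <- function(rows, member, h1, h2) {
    for (intr in names(config$intron_size_modes)) {
      sizes <- unique(c(h1$introns[[intr]], h2$introns[[intr]]))
      rows <- rbind(rows, data.frame(family = "simfam", member = member,
                                     intron = intr, size = sizes))
    }
    rows
  }
  rows <- add_member(rows, "father", father[[1L]], father[[2L]])
  rows <- add_member(rows, "mother", mother[[1L]], mother[[2L]])
  for (i in seq_len(n)) {
    gf <- gamete(father); gm <- gamete(mother)
    id <- sprintf("o%02d", i)
    rows <- add_member(rows, id, gf$hap, gm$hap)
    truth[[id]] <- list(father_hap = gf$pick, mother_hap = gm$pick,
                        father_recombined = gf$recombined,
                        mother_recombined = gm$recombined)
  }
  list(cross = family_cross(rows), truth = truth)
}

#' Neutral infinite-sites coalescent sample
#'
#' Kingman coalescent for `n` lineages; mutations are placed on branches
#' as a Poisson process with rate theta/2 per unit coalescent time and
#' each creates a new segregating site (infinite-sites, no
#' recombination). Used as the neutral null for the D statistics.
#'
#' @param n Sample size.
#' @param theta Population mutation rate (4Nu per locus).
#' @return Character matrix (A = ancestral, G = derived), `n` rows; zero
#'   columns when no mutation occurs.
#' @export
sim_neutral_alignment <- function(n, theta) {
  blist <- list(); bleaves <- list()
  cur <- lapply(seq_len(n), function(i) i)  # leaves under each active lineage
  acc <- rep(0, n)                          # accumulated length per lineage
  while (length(cur) > 1L) {
    k <- length(cur)
    t <- stats::rexp(1L, k * (k - 1) / 2)
    acc <- acc + t
    pair <- sample(k, 2L)
    for (x in pair) {
      blist[[length(blist) + 1L]] <- acc[x]
      bleaves[[length(bleaves) + 1L]] <- cur[[x]]
    }
    merged <- c(cur[[pair[1L]]], cur[[pair[2L]]])
    cur <- c(cur[-pair], list(merged))
    acc <- c(acc[-pair], 0)
  }
  blen <- unlist(blist)
  total <- sum(blen)
  nmut <- rpois(1L, theta / 2 * total)
  if (nmut == 0L)
    return(matrix(character(0), nrow = n, ncol = 0L,
                  dimnames = list(paste0("s", seq_len(n)), NULL)))
  which_branch <- sample(length(blen), nmut, replace = TRUE, prob = blen)
  mat <- matrix("A", nrow = n, ncol = nmut,
                dimnames = list(paste0("s", seq_len(n)), NULL))
  for (j in seq_len(nmut)) mat[bleaves[[which_branch[j]]], j] <- "G"
  mat
}
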