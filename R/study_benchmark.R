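# A fully synthetic, deterministically constructed benchmark dataset.
#
# It emulates the data structure the classification pipeline is designed
# for: 10 individuals sequenced for cDNA clones of a duplicated
# antimicrobial-peptide gene (93 clones plus a cDNA reference), 8 of them
# also sequenced for gDNA (88 clones plus a genomic reference), with 21
# germline "basic" coding sequences in three divergent clades, somatic
# point mutations sprinkled on individual clones, somatic recombinant
# clones splicing two basics, and intron columns carrying the large
# indels and haplotype spectrum typical of such genes. Every event is
# recorded as ground truth so the classification chain can be scored
# exactly. No random number generation is involved: the dataset is a
# fixed design, not a simulation.

study_codon_pattern <- c("GCT", "GGC", "ACT", "GTC", "CCA", "ATC", "AAC",
                         "GAC", "TTC", "CGT")

# informative coding sites (1-based) and the basic sequences (1..22,
# 22 = cDNA reference) carrying the derived state; three clades
# (1-8, 9-15, 16-22) plus within-clade subdivisions and five pairs of
# crossing carrier sets that generate exactly five non-overlapping
# four-gamete incompatibilities
study_informative_sites <- function() {
  list(
    list(pos = 10L, carriers = 1:8),  list(pos = 20L, carriers = 1:8),
    list(pos = 30L, carriers = 9:15), list(pos = 40L, carriers = 16:22),
    list(pos = 70L, carriers = 1:8),  list(pos = 75L, carriers = 9:15),
    list(pos = 80L, carriers = 16:22), list(pos = 85L, carriers = 1:4),
    list(pos = 90L, carriers = 1:8),  list(pos = 95L, carriers = 9:15),
    list(pos = 100L, carriers = 16:22), list(pos = 101L, carriers = 1:2),
    list(pos = 103L, carriers = 2:3), list(pos = 115L, carriers = 9:11),
    list(pos = 131L, carriers = 5:6), list(pos = 133L, carriers = 6:7),
    list(pos = 161L, carriers = 9:10), list(pos = 163L, carriers = 10:11),
    list(pos = 170L, carriers = 1:8), list(pos = 175L, carriers = 9:15),
    list(pos = 190L, carriers = 1:8), list(pos = 195L, carriers = 9:15),
    list(pos = 200L, carriers = 1:8), list(pos = 205L, carriers = 9:15),
    list(pos = 210L, carriers = 16:22), list(pos = 215L, carriers = 5:8),
    list(pos = 221L, carriers = 12:13), list(pos = 223L, carriers = 13:14),
    list(pos = 245L, carriers = 12:14), list(pos = 261L, carriers = 16:17),
    list(pos = 263L, carriers = 17:18))
}

# basic-private (singleton among the 22) sites
study_singleton_sites <- function() {
  list(
    list(pos = 5L, carriers = 1L),   list(pos = 15L, carriers = 10L),
    list(pos = 25L, carriers = 6L),
    list(pos = 63L, carriers = 2L),  list(pos = 66L, carriers = 5L),
    list(pos = 69L, carriers = 9L),  list(pos = 72L, carriers = 12L),
    list(pos = 78L, carriers = 13L), list(pos = 108L, carriers = 17L),
    list(pos = 111L, carriers = 3L), list(pos = 120L, carriers = 19L),
    list(pos = 123L, carriers = 20L), list(pos = 126L, carriers = 21L),
    list(pos = 230L, carriers = 4L), list(pos = 235L, carriers = 11L),
    list(pos = 240L, carriers = 18L), list(pos = 250L, carriers = 22L))
}

# clone composition: individual -> basic of each pure clone, in clone order
study_composition <- function() {
  list(
    "11" = c(1, 1, 1, 1, 9, 9, 9, 9, 16, 16),
    "12" = c(2, 2, 2, 2, 10, 10, 10, 10, NA, NA),
    "13" = c(3, 3, 3, 3, 3, 11, 11, 11, 11, 11),
    "14" = c(4, 4, 4, 4, 12, 12, 12, 12, NA),
    "15" = c(5, 5, 5, 5, 13, 13, 13, 13, NA),
    "16" = c(6, 6, 6, 6, 6, 17, 17, 17, 17),
    "17" = c(7, 7, 7, 7, 7, 18, 18, 18, 18),
    "18" = c(8, 8, 8, 8, 19, 19, 19, 19, NA),
    "19" = c(14, 14, 14, 14, 20, 20, 20, 20, NA),
    "20" = c(15, 15, 15, 15, 15, 21, 21, 21, 21))
}

# recombinant clones: NA slots above; prefix basic | breakpoint | suffix basic
# (breakpoint = last 1-based coding position taken from the prefix donor)
study_recombinants <- function() {
  data.frame(
    clone_id = c("12_09_cDNA", "12_10_cDNA", "14_09_cDNA", "15_09_cDNA",
                 "18_09_cDNA", "19_09_cDNA"),
    individual = c("12", "12", "14", "15", "18", "19"),
    left = c(2L, 10L, 4L, 13L, 8L, 14L),
    right = c(10L, 2L, 12L, 5L, 19L, 20L),
    breakpoint = c(150L, 95L, 120L, 140L, 160L, 180L),
    stringsAsFactors = FALSE)
}

# somatic substitution events on cDNA clones: clone, 1-based position,
# designed codon effect (S = synonymous, N = nonsynonymous)
study_events <- function() {
  ev <- rbind(
    c("11_01_cDNA", 8, "N"),   c("11_01_cDNA", 81, "S"),
    c("11_05_cDNA", 183, "S"), c("11_05_cDNA", 70, "N"),
    c("13_01_cDNA", 9, "S"),   c("13_01_cDNA", 64, "N"),
    c("13_01_cDNA", 186, "S"),
    c("16_01_cDNA", 18, "S"),  c("16_01_cDNA", 189, "S"),
    c("17_01_cDNA", 67, "N"),  c("17_01_cDNA", 193, "N"),
    c("11_02_cDNA", 198, "S"), c("11_06_cDNA", 203, "N"),
    c("12_01_cDNA", 27, "S"),  c("12_02_cDNA", 95, "N"),
    c("12_05_cDNA", 208, "N"), c("13_02_cDNA", 228, "N"),
    c("13_06_cDNA", 232, "N"), c("14_01_cDNA", 232, "N"),
    c("14_05_cDNA", 238, "N"), c("15_01_cDNA", 238, "N"),
    c("15_05_cDNA", 235, "N"), c("16_02_cDNA", 245, "N"),
    c("17_02_cDNA", 252, "S"), c("18_01_cDNA", 255, "S"),
    c("18_05_cDNA", 258, "S"), c("19_01_cDNA", 266, "N"),
    c("19_05_cDNA", 38, "N"),  c("20_01_cDNA", 84, "S"),
    c("20_06_cDNA", 87, "S"))
  data.frame(clone_id = ev[, 1L], position = as.integer(ev[, 2L]),
             effect = ifelse(ev[, 3L] == "S", "synonymous", "nonsynonymous"),
             stringsAsFactors = FALSE)
}

# gDNA clone composition (8 individuals x 11 clones) and somatic events;
# individuals 16 and 17 show a single basic at gDNA
study_gdna_composition <- function() {
  list(
    "13" = c(rep(3L, 6), rep(11L, 5)),
    "14" = c(rep(4L, 6), rep(12L, 5)),
    "15" = c(rep(5L, 6), rep(13L, 5)),
    "16" = rep(6L, 11),
    "17" = rep(7L, 11),
    "18" = c(rep(8L, 6), rep(19L, 5)),
    "19" = c(rep(14L, 6), rep(20L, 5)),
    "20" = c(rep(15L, 6), rep(21L, 5)))
}

study_gdna_events <- function() {
  ev <- rbind(
    c("13_02_gDNA", 45, "S"),  c("14_02_gDNA", 150, "S"),
    c("15_02_gDNA", 220, "N"), c("18_02_gDNA", 255, "S"),
    c("19_02_gDNA", 92, "N"),  c("20_02_gDNA", 270, "S"))
  data.frame(clone_id = ev[, 1L], position = as.integer(ev[, 2L]),
             effect = ifelse(ev[, 3L] == "S", "synonymous", "nonsynonymous"),
             stringsAsFactors = FALSE)
}

first_alt <- function(base) setdiff(c("A", "C", "G", "T"), base)[1L]

# pick a state at `pos` of `seq_vec` achieving the designed codon effect,
# avoiding states already present at that site elsewhere in the design
pick_effect_state <- function(seq_vec, pos, effect, forbidden) {
  cod_i <- (pos - 1L) %/% 3L
  cols <- (3L * cod_i + 1L):(3L * cod_i + 3L)
  ref_codon <- paste(seq_vec[cols], collapse = "")
  for (b in setdiff(c("A", "C", "G", "T"), c(seq_vec[pos], forbidden))) {
    alt <- seq_vec[cols]; alt[pos - 3L * cod_i] <- b
    if (classify_codon_change(ref_codon, paste(alt, collapse = "")) == effect)
      return(b)
  }
  stop(sprintf("no state with effect %s at position %d", effect, pos))
}

periodic_seq <- function(L, phase = 0L)
  c("A", "C", "G", "T")[((seq_len(L) * 7L + phase) %% 4L) + 1L]

#' Deterministic synthetic benchmark dataset with full ground truth
#'
#' Builds, entirely in code and without random numbers, a joint
#' cDNA/gDNA alignment shaped like the data the classification pipeline
#' targets: 93 cDNA clones from 10 individuals plus a cDNA reference,
#' 88 gDNA clones from 8 of those individuals plus a genomic reference
#' that defines the exon/intron column classes. The 21 germline basic
#' sequences fall into three clades; 30 somatic substitutions (26 at
#' otherwise-monomorphic sites, 4 at sites already variable among the
#' basics, two sites hit twice with different states) sit on 24 clones;
#' six clones are recombinants between two of their individual's basics;
#' gDNA intron 2 carries a 58-haplotype spectrum. See the truth component
#' for every engineered event.
#'
#' @return List with `alignment` (a [clone_alignment] of 183 sequences x
#'   887 columns), `basics` (22 x 300 matrix: 21 basics + cDNA
#'   reference), `truth` (events, recombinants, per-individual basic
#'   composition) and `partition`.
#' @export
synthetic_study_dataset <- function() {
  L <- 300L
  base <- strsplit(paste(rep(study_codon_pattern, 10L), collapse = ""),
                   "")[[1L]]
  infs <- study_informative_sites()
  sings <- study_singleton_sites()
  basics <- matrix(rep(base, each = 22L), nrow = 22L)
  site_states <- list()  # states present among basics per engineered site
  for (sd in c(infs, sings)) {
    st <- first_alt(base[sd$pos])
    basics[sd$carriers, sd$pos] <- st
    site_states[[as.character(sd$pos)]] <- c(base[sd$pos], st)
  }
  rownames(basics) <- c(sprintf("basic%02d", 1:21), "ref_cDNA")

  comp <- study_composition()
  recs <- study_recombinants()
  clones <- list(); clone_basic <- character(0)
  for (ind in names(comp)) {
    v <- comp[[ind]]
    for (i in seq_along(v)) {
      id <- sprintf("%s_%02d_cDNA", ind, i)
      if (!is.na(v[i])) {
        clones[[id]] <- basics[v[i], ]
        clone_basic[id] <- v[i]
      }
    }
  }
  for (r in seq_len(nrow(recs))) {
    s <- basics[recs$left[r], ]
    s[(recs$breakpoint[r] + 1L):L] <-
      basics[recs$right[r], (recs$breakpoint[r] + 1L):L]
    clones[[recs$clone_id[r]]] <- s
  }

  apply_events <- function(clones, events, get_basic) {
    events$state <- NA_character_
    for (e in seq_len(nrow(events))) {
      id <- events$clone_id[e]; pos <- events$position[e]
      forb <- site_states[[as.character(pos)]]
      if (is.null(forb)) forb <- base[pos]
      st <- pick_effect_state(clones[[id]], pos, events$effect[e], forb)
      clones[[id]][pos] <- st
      events$state[e] <- st
      site_states[[as.character(pos)]] <<- c(forb, st)
    }
    list(clones = clones, events = events)
  }
  ae <- apply_events(clones, study_events())
  clones <- ae$clones; events <- ae$events

  gcomp <- study_gdna_composition()
  gclones <- list()
  for (ind in names(gcomp)) {
    v <- gcomp[[ind]]
    for (i in seq_along(v)) {
      id <- sprintf("%s_%02d_gDNA", ind, i)
      gclones[[id]] <- basics[v[i], ]
    }
  }
  # make the shared gDNA/cDNA event truly shared: same position and state
  gevents <- study_gdna_events()
  ge <- apply_events(gclones, gevents)
  gclones <- ge$clones; gevents <- ge$events
  shared_pos <- 255L
  shared_state <- events$state[events$position == shared_pos]
  gclones[["18_02_gDNA"]][shared_pos] <- shared_state
  gevents$state[gevents$position == shared_pos] <- shared_state

  # intron scaffolds
  i1_len <- 376L; i2_len <- 211L
  intron1 <- periodic_seq(i1_len, 1L)
  intron2 <- periodic_seq(i2_len, 2L)
  gap1_II <- 101:255           # 155-bp deletion -> 221-bp allele
  gap1_III <- c(101:255, 301:337)  # + 37 bp -> 184-bp allele
  clade_of <- function(b) if (b <= 8L) 1L else if (b <= 15L) 2L else 3L
  intron1_for <- function(b) {
    s <- intron1
    if (clade_of(b) >= 2L) s[gap1_II] <- "-"
    if (clade_of(b) == 3L) s[gap1_III] <- "-"
    s
  }
  # 58 intron-2 haplotypes with counts 6,6,2x20,1x36 over the 88 gDNA
  # clones: haplotype j mutates positions 3j-2 and 3j-1
  i2_hap <- function(j) {
    s <- intron2
    if (j > 0L) for (p in c(3L * j - 2L, 3L * j - 1L))
      s[p] <- first_alt(s[p])
    s
  }
  hap_assign <- rep(seq_len(58L), times = c(6L, 6L, rep(2L, 20L),
                                            rep(1L, 36L)))

  ex1 <- 1:90; ex2 <- 91:210; ex3 <- 211:300
  width <- 90L + i1_len + 120L + i2_len + 90L
  assemble <- function(coding, int1, int2)
    c(coding[ex1], int1, coding[ex2], int2, coding[ex3])
  rows <- list()
  for (id in names(clones))
    rows[[id]] <- assemble(clones[[id]], rep("-", i1_len), rep("-", i2_len))
  rows[["ref_cDNA"]] <- assemble(basics["ref_cDNA", ], rep("-", i1_len),
                                 rep("-", i2_len))
  gids <- names(gclones)
  gbasic <- unlist(gcomp)
  for (i in seq_along(gids))
    rows[[gids[i]]] <- assemble(gclones[[gids[i]]],
                                intron1_for(gbasic[i]),
                                i2_hap(hap_assign[i]))
  ref_g <- base
  for (sd in c(infs)) if (22L %in% sd$carriers)
    ref_g[sd$pos] <- basics[22L, sd$pos]
  rows[["ref_gDNA"]] <- assemble(ref_g, intron1, intron2)

  mat <- do.call(rbind, rows)
  rownames(mat) <- names(rows)
  classes <- c(rep("exon1", 90L), rep("intron1", i1_len),
               rep("exon2", 120L), rep("intron2", i2_len),
               rep("exon3", 90L))
  info <- suppressWarnings(parse_clone_headers(rownames(mat), "ref_gDNA"))
  aln <- clone_alignment(mat, info, "ref_gDNA", classes)

  list(alignment = aln,
       basics = basics,
       truth = list(events = events, gdna_events = gevents,
                    recombinants = recs,
                    composition = comp, gdna_composition = gcomp,
                    clone_basic = clone_basic,
                    intron2_haplotypes = hap_assign),
       partition = default_partition())
}

#' Write the synthetic benchmark dataset to disk
#'
#' Emits the aligned FASTA and the column-class sidecar TSV in the input
#' formats the pipeline reads.
#'
#' @param ds Result of [synthetic_study_dataset].
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_study_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "synthetic_study_alignment.fasta")
  cc <- file.path(dir, "column_classes.tsv")
  write_alignment(ds$alignment, fa)
  write_column_classes(ds$alignment$classes, cc)
  invisible(c(fasta = fa, classes = cc))
}
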