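test_that("basic inference recovers two basics plus one somatic variant", {
  tb <- toy_basics()
  seqs <- c(rep(tb$x, 5), rep(tb$y, 4), mutate_str(tb$x, 3, "A"))
  names(seqs) <- sprintf("01_%02d_cDNA", seq_along(seqs))
  bs <- infer_basic_sequences(make_aln(seqs))
  expect_setequal(bs$basics, c(tb$x, tb$y))
  expect_equal(sum(bs$assignments$status == "assigned"), 10)
  expect_equal(nrow(bs$variants), 1)
  expect_equal(bs$variants$position, 2L)  # 0-based
  expect_equal(bs$variants$clone_state, "A")
})

test_that("identical clones give one basic and no variants", {
  seqs <- setNames(rep(toy_basics()$x, 10),
                   sprintf("01_%02d_cDNA", 1:10))
  bs <- infer_basic_sequences(make_aln(seqs))
  expect_length(bs$basics, 1)
  expect_equal(nrow(bs$variants), 0)
  expect_true(all(bs$assignments$status == "assigned"))
})

test_that("classification is invariant to clone input order", {
  tb <- toy_basics()
  seqs <- c(rep(tb$x, 4), rep(tb$y, 4),
            mutate_str(tb$x, 6, "A"), splice_str(tb$x, tb$y, 15))
  names(seqs) <- sprintf("01_%02d_cDNA", seq_along(seqs))
  bs1 <- infer_basic_sequences(make_aln(seqs))
  set.seed(9)
  perm <- sample(seq_along(seqs))
  bs2 <- infer_basic_sequences(make_aln(seqs[perm]))
  expect_setequal(bs1$basics, bs2$basics)
  key <- function(bs) {
    a <- bs$assignments[order(bs$assignments$clone_id), ]
    paste(a$clone_id, a$status, a$n_variants)
  }
  expect_identical(key(bs1), key(bs2))
})

test_that("every clone lands in exactly one status class", {
  ds <- synthetic_study_dataset()
  cls <- classify_individuals(ds$alignment, "cDNA")
  for (bs in cls) {
    st <- bs$assignments$status
    expect_true(all(st %in% c("assigned", "recombinant", "ambiguous")))
    expect_equal(length(st), nrow(bs$assignments))
  }
})

test_that("recombinant detection finds clean splices and not point mutants", {
  tb <- toy_basics()
  bm <- rbind(strsplit(tb$x, "")[[1]], strsplit(tb$y, "")[[1]])
  # half-and-half splice: one breakpoint, donors 1 then 2
  spl <- strsplit(splice_str(tb$x, tb$y, 15), "")[[1]]
  rec <- detect_recombinants(spl, bm)
  expect_false(is.null(rec))
  expect_equal(rec$donors, c(1L, 2L))
  expect_equal(nrow(rec$breakpoints), 1)
  expect_equal(rec$n_mismatch, 0)
  # breakpoint interval lies between informative sites 13 and 16 (1-based)
  expect_equal(rec$breakpoints[1, ], c(12L, 15L))
  # a single informative-site switch is a mutation, not a recombinant
  single <- strsplit(tb$x, "")[[1]]
  yv <- strsplit(tb$y, "")[[1]]
  single[16] <- yv[16]
  expect_null(detect_recombinants(single, bm))
  # fewer than two basics: no test possible
  expect_message(
    expect_null(detect_recombinants(spl, bm[1, , drop = FALSE])),
    "fewer than 2")
})

test_that("a three-donor clone yields two breakpoints", {
  tb <- toy_basics()
  zv <- strsplit(tb$x, "")[[1]]
  for (p in c(2, 5, 8, 11, 14, 17, 20, 23, 26, 29))
    zv[p] <- setdiff(c("A", "C", "G", "T"), zv[p])[2]
  z <- paste(zv, collapse = "")
  bm <- rbind(strsplit(tb$x, "")[[1]], strsplit(tb$y, "")[[1]], zv)
  cl <- strsplit(splice_str(splice_str(tb$x, tb$y, 10), z, 20), "")[[1]]
  rec <- detect_recombinants(cl, bm)
  expect_false(is.null(rec))
  expect_equal(rec$donors, c(1L, 2L, 3L))
  expect_equal(nrow(rec$breakpoints), 2)
})

test_that("no recombinants are called when none were simulated", {
  cfg <- sim_config(seed = 101, n_individuals = 30L,
                    clones_per_individual = 10L, rho_recomb = 0)
  sim <- simulate_dataset(cfg)
  cls <- classify_individuals(sim$alignment, "cDNA")
  n_rec <- sum(vapply(cls, function(bs)
    sum(bs$assignments$status == "recombinant"), 0L))
  expect_equal(n_rec, 0)
})

test_that("greedy classification attains the brute-force minimal event count", {
  # constructed cases within the procedure's claimed regime: both basics
  # supported by unmutated clones, splices with interior breakpoints,
  # clones carrying at most 2 somatic substitutions
  tb <- toy_basics()
  noninf <- setdiff(1:30, tb$diff_sites)
  set.seed(12)
  for (rep in 1:10) {
    seqs <- c(rep(tb$x, 3), rep(tb$y, 3))
    # one or two point-mutant clones
    for (k in seq_len(sample(1:2, 1))) {
      pos <- sample(noninf, sample(1:2, 1))
      s <- tb$x
      for (p in pos)
        s <- mutate_str(s, p, setdiff(c("A", "C", "G", "T"),
                                      substr(s, p, p))[1])
      seqs <- c(seqs, s)
    }
    # one recombinant with an interior breakpoint (>= 2 informative
    # sites on each side), sometimes carrying one extra substitution
    bp <- sample(tb$diff_sites[3:(length(tb$diff_sites) - 2)], 1)
    r <- splice_str(tb$x, tb$y, bp)
    if (runif(1) < 0.5) {
      p <- sample(noninf, 1)
      r <- mutate_str(r, p, setdiff(c("A", "C", "G", "T"),
                                    substr(r, p, p))[1])
    }
    seqs <- c(seqs, r)
    names(seqs) <- sprintf("01_%02d_cDNA", seq_along(seqs))
    clones <- t(vapply(unname(seqs), function(s) strsplit(s, "")[[1]],
                       character(30)))
    rownames(clones) <- names(seqs)
    bs <- infer_basic_sequences(clones, tau = 3L, min_support = 2L)
    expect_true(all(bs$assignments$status != "ambiguous"))
    greedy_events <- nrow(bs$variants) + length(bs$recombinants)
    expect_equal(greedy_events, oracle_min_events(clones))
  }
})

test_that("somatic mutation rate arithmetic and conventions", {
  ds <- synthetic_study_dataset()
  cls <- classify_individuals(ds$alignment, "cDNA")
  mu <- somatic_mutation_rate(cls, 300)
  expect_equal(mu$numerator, 30)
  expect_equal(mu$denominator, 93 * 300)
  expect_equal(mu$rate, 30 / 27900)
  # excluding recombinant clones shrinks the denominator only (their
  # residual variant count here is zero)
  mu2 <- somatic_mutation_rate(cls, 300, include_recombinants = FALSE)
  expect_equal(mu2$denominator, (93 - 6) * 300)
  expect_equal(mu2$numerator, 30)
  expect_error(somatic_mutation_rate(list(), 300), "empty")
})

test_that("recombination rate mean and SE follow the sample formulas", {
  mk <- function(frac, n = 10) {
    nr <- round(frac * n)
    list(assignments = data.frame(
      clone_id = paste0("c", 1:n),
      status = c(rep("recombinant", nr), rep("assigned", n - nr)),
      basic = NA, n_variants = 0),
      basics = c("AAAA", "TTTT"), basic_matrix = NULL, support = c(1, 1))
  }
  rr <- recombination_rate(list(a = mk(0.2), b = mk(0)))
  expect_equal(rr$mean, 0.1)
  expect_equal(rr$se, 0.1)
  rr0 <- recombination_rate(lapply(1:5, function(i) mk(0)))
  expect_equal(rr0$mean, 0)
  expect_equal(rr0$se, 0)
})

test_that("variant annotation separates recurrent sites from singletons", {
  tb <- toy_basics()
  # two individuals sharing the variable architecture; a somatic change
  # at a site already variable among basics is recurrent
  mk_ind <- function(ind, extra_pos, extra_state) {
    seqs <- c(rep(tb$x, 3), rep(tb$y, 3),
              mutate_str(tb$x, extra_pos, extra_state))
    names(seqs) <- sprintf("%s_%02d_cDNA", ind, seq_along(seqs))
    infer_basic_sequences(make_aln(seqs))
  }
  cls <- list("01" = mk_ind("01", 2, "G"),   # site 2 monomorphic -> singleton
              "02" = mk_ind("02", 4, "C"))   # site 4 variable among basics
  p <- default_partition(c(0, 6), c(6, 18), c(18, 30))
  va <- annotate_variants(cls, p)
  expect_equal(nrow(va), 2)
  expect_equal(va$occurrence[va$position == 1], "singleton")
  expect_equal(va$occurrence[va$position == 3], "recurrent_site")
})

test_that("domain mutation profile reproduces per-domain proportions", {
  v <- data.frame(
    clone_id = paste0("c", 1:9), position = c(10, 20, 61, 100, 150,
                                              200, 210, 220, 220),
    basic_state = "A", clone_state = "T", on_recombinant = FALSE,
    domain = c("signal", "signal", "mature", "mature", "mature",
               "cterm", "cterm", "cterm", "cterm"),
    effect = c("synonymous", "nonsynonymous", "synonymous",
               "nonsynonymous", "nonsynonymous", "nonsynonymous",
               "nonsynonymous", "nonsynonymous", "synonymous"))
  prof <- domain_mutation_profile(v)
  expect_equal(prof$n_events, c(2L, 3L, 4L))
  expect_equal(prof$n_sites, c(2L, 3L, 3L))
  expect_equal(prof$proportion, c(2 / 60, 3 / 120, 4 / 120))
  expect_equal(attr(prof, "overall_nonsyn"), 6 / 9)
  bad <- v; bad$position[1] <- 400
  expect_error(domain_mutation_profile(bad), "consistency")
  empty <- v[0, ]
  prof0 <- domain_mutation_profile(empty)
  expect_true(all(prof0$proportion == 0))
})

test_that("cDNA/gDNA cross-check reports concordance and private basics", {
  tb <- toy_basics()
  mk <- function(ind, src, basics2 = TRUE, mut_pos = NULL) {
    seqs <- if (basics2) c(rep(tb$x, 3), rep(tb$y, 3)) else rep(tb$x, 6)
    if (!is.null(mut_pos)) seqs <- c(seqs, mutate_str(tb$x, mut_pos, "A"))
    names(seqs) <- sprintf("%s_%02d_%s", ind, seq_along(seqs), src)
    infer_basic_sequences(make_aln(seqs))
  }
  full <- crosscheck_gdna_cdna(mk("01", "cDNA"), mk("01", "gDNA"))
  expect_equal(nrow(full$matched), 2)
  expect_length(full$cdna_only, 0)
  expect_equal(full$shared_variants, 0)

  part <- crosscheck_gdna_cdna(mk("01", "cDNA"),
                               mk("01", "gDNA", basics2 = FALSE))
  expect_length(part$cdna_only, 1)

  disj <- crosscheck_gdna_cdna(mk("01", "cDNA", mut_pos = 3),
                               mk("01", "gDNA", mut_pos = 6))
  expect_equal(disj$shared_variants, 0)
  expect_equal(disj$cdna_private_variants, 1)

  expect_error(crosscheck_gdna_cdna(mk("01", "cDNA"), mk("02", "gDNA")),
               "identity")
})
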